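# Report rendering: fixed column order, documented rounding
# (populations whole %, distances 2 decimals, half away from zero),
# thresholds embedded as comment lines so every table is self-describing.

threshold_header <- function(criteria, folded_threshold) {
  sprintf("# distance_cutoff_A: %g\tangle_min_deg: %g\tfolded_threshold_A: %g",
          criteria$distance_cutoff, criteria$angle_min, folded_threshold)
}

#' Render a pattern table report
#'
#' Tab-separated, columns `pattern`, `percent`, one per fingerprint bond,
#' `average`, `folded` (`f`/`u`, `NA` for unpopulated patterns). Populations
#' are rounded to whole percent, distances to 2 decimals (half away from
#' zero). `scope = "top"` keeps the significant patterns (rounded population
#' >= 1%), `scope = "full"` all 16.
#'
#' @param table a [pattern_table()].
#' @param file output path, or `NULL` to return the lines.
#' @param scope `"top"` or `"full"`.
#' @return the report lines, invisibly if written to `file`.
#' @export
render_pattern_table <- function(table, file = NULL,
                                 scope = c("top", "full")) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "pattern_table"))
  df <- as.data.frame(table)
  if (scope == "top") df <- df[df$significant, , drop = FALSE]
  fp <- setdiff(names(df), c("pattern", "n_frames", "population",
                             "average", "folded", "significant"))
  header <- paste(c("pattern", "percent", fp, "average", "folded"),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(df$pattern[i],
            fmt_num(df$population[i], 0),
            vapply(fp, function(b) fmt_num(df[[b]][i], 2), character(1)),
            fmt_num(df$average[i], 2),
            if (is.na(df$folded[i])) "NA" else if (df$folded[i]) "f" else "u"),
          collapse = "\t")
  }, character(1))
  lines <- c("# pattern table",
             threshold_header(attr(table, "criteria"),
                              attr(table, "folded_threshold")),
             header, rows)
  emit_report(lines, file)
}

#' Render a transition map report
#'
#' Tab-separated matrix of integer-rounded percentages; first column `from`,
#' destination states as remaining columns. Undefined rows print `NA`.
#'
#' @param map a [transition_map()] with percentages.
#' @param file output path, or `NULL` to return the lines.
#' @return the report lines, invisibly if written to `file`.
#' @export
render_transition_map <- function(map, file = NULL) {
  stopifnot(inherits(map, "transition_map"))
  if (is.null(map$percentages)) abort_config("map has no percentages")
  header <- paste(c("from", map$states), collapse = "\t")
  rows <- vapply(seq_along(map$states), function(i)
    paste(c(map$states[i], fmt_num(map$percentages[i, ], 0)), collapse = "\t"),
    character(1))
  emit_report(c("# transition map (row percentages)", header, rows), file)
}

#' Render a folding pathway report
#'
#' One line `state -> state (p%)` chain, followed by the per-step
#' second-best (alternative branch) annotations; a start-equals-end pathway
#' renders as the single state with no arrows.
#'
#' @param pathway a [extract_pathway()] result.
#' @param file output path, or `NULL` to return the lines.
#' @return the report lines, invisibly if written to `file`.
#' @export
render_pathway <- function(pathway, file = NULL) {
  stopifnot(inherits(pathway, "folding_pathway"))
  emit_report(c("# most probable folding pathway", format_pathway(pathway)),
              file)
}

#' Render a folding summary report
#'
#' @param summary a [overall_folding_ratio()] result.
#' @param file output path, or `NULL` to return the lines.
#' @param mode which mode is the headline ratio (`"pattern"` or `"frame"`).
#' @return the report lines, invisibly if written to `file`.
#' @export
render_folding_summary <- function(summary, file = NULL,
                                   mode = c("pattern", "frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(summary, "folding_summary"))
  headline <- if (mode == "frame") summary$frame_level else summary$pattern_level
  lines <- c("# folding summary",
             sprintf("folded_threshold_A\t%g", summary$threshold),
             sprintf("n_frames\t%d", summary$n_frames),
             sprintf("folded_pct_pattern_level\t%s", fmt_num(summary$pattern_level, 2)),
             sprintf("folded_pct_frame_level\t%s", fmt_num(summary$frame_level, 2)),
             sprintf("mode\t%s", mode),
             sprintf("folding_ratio_pct\t%s", fmt_num(headline, 2)))
  emit_report(lines, file)
}

emit_report <- function(lines, file) {
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Write the full report set for an analysis
#'
#' Writes `pattern_table.tsv`, `folding_summary.tsv`, `transition_map.tsv`,
#' `pathway.txt` and a machine-readable `analysis.json` (unrounded values,
#' raw transition counts) into `dir`. Output is byte-stable: rerunning on
#' identical inputs reproduces identical files.
#'
#' @param table a [pattern_table()].
#' @param map a [transition_map()] with counts and percentages.
#' @param pathway a [extract_pathway()] result (or `NULL` to skip).
#' @param summary a [overall_folding_ratio()] result.
#' @param dir output directory (created if needed).
#' @param scope pattern-table / map scope: `"top"` (significant patterns,
#'   map aggregating the rest as `"other"`) or `"full"` (all 16).
#' @param mode headline folding-ratio mode.
#' @return named character vector of the written file paths, invisibly.
#' @export
render_reports <- function(table, map, pathway, summary, dir,
                           scope = c("top", "full"),
                           mode = c("pattern", "frame")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(pattern_table = file.path(dir, "pattern_table.tsv"),
           folding_summary = file.path(dir, "folding_summary.tsv"),
           transition_map = file.path(dir, "transition_map.tsv"),
           pathway = file.path(dir, "pathway.txt"),
           analysis = file.path(dir, "analysis.json"))
  render_pattern_table(table, out["pattern_table"], scope = scope)
  map_out <- if (scope == "top" && !is.null(map$counts)) {
    sig <- table$pattern[table$significant]
    if (length(sig) >= 2L) restrict_map(map, sig) else map
  } else map
  render_transition_map(map_out, out["transition_map"])
  if (!is.null(pathway)) render_pathway(pathway, out["pathway"])
  else writeLines("# most probable folding pathway\nNA", out["pathway"])
  render_folding_summary(summary, out["folding_summary"], mode = mode)

  payload <- list(
    thresholds = list(
      distance_cutoff_A = attr(table, "criteria")$distance_cutoff,
      angle_min_deg = attr(table, "criteria")$angle_min,
      folded_threshold_A = attr(table, "folded_threshold")),
    pattern_table = as.data.frame(table),
    folding = summary[c("pattern_level", "frame_level", "n_frames")],
    transition_counts = map$counts,
    transition_percent = map$percentages,
    pathway = if (is.null(pathway)) NULL else
      list(states = pathway$states, steps = pathway$steps))
  jsonlite::write_json(payload, out["analysis"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(out)
}

#' Run the complete analysis pipeline
#'
#' Executes geometry extraction (or geometry-table import), pattern
#' classification, folding analysis, transition counting, normalisation and
#' pathway extraction, then writes all reports plus a provenance log into
#' the output directory. Any stage failure is re-raised with the stage name
#' and already-written outputs are removed.
#'
#' @param config a named list or path to a YAML file with fields:
#'   `trajectory` (path(s)), `format` (`"pdb"`/`"dcd"`), `topology`,
#'   `hbond_config` (path) — or alternatively `geometry_table` (path);
#'   `distance_cutoff` (Å, default 3), `angle_min` (deg, default 120),
#'   `folded_threshold` (Å, default 3), `mode` (`"pattern"`/`"frame"`),
#'   `scope` (`"top"`/`"full"`), `out_dir` (required), `seed` (default 1).
#' @return invisibly, a list with the `hairpin_fit`, the `pathway` and the
#'   written `files`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_io(sprintf("config not found: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("'config' must be a list or a YAML path")
  if (is.null(config$out_dir)) abort_config("config field 'out_dir' is required")
  mode <- match.arg(config$mode %||% "pattern", c("pattern", "frame"))
  scope <- match.arg(config$scope %||% "top", c("top", "full"))
  criteria <- hb_criteria(config$distance_cutoff %||% 3.0,
                          config$angle_min %||% 120)
  thr <- config$folded_threshold %||% 3.0

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cls <- setdiff(class(e), c("error", "condition"))
      abort(sprintf("stage '%s': %s", name, conditionMessage(e)),
            if (length(cls)) cls[1] else "hairpin_compute_error")
    })
  }

  series <- if (!is.null(config$geometry_table)) {
    stage("geometry_import", read_geometry_table(config$geometry_table))
  } else {
    if (is.null(config$trajectory) || is.null(config$hbond_config))
      abort_config("config requires 'trajectory' + 'hbond_config', or 'geometry_table'")
    defs <- stage("hbond_config", read_hbond_config(config$hbond_config))
    bundle <- stage("trajectory_read",
                    read_trajectory(unlist(config$trajectory),
                                    format = config$format %||% "pdb",
                                    topology = config$topology))
    stage("geometry_extraction", extract_geometries(bundle, defs))
  }

  fit <- stage("pattern_analysis",
               hairpin_fit(series, criteria, thr, mode = mode))
  pathway <- stage("pathway_extraction",
                   tryCatch(extract_pathway(fit$transition_map),
                            hairpin_pathway_error = function(e) {
                              warning(conditionMessage(e))
                              NULL
                            }))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- tryCatch(
    stage("report_rendering", {
      f <- render_reports(fit$table, fit$transition_map, pathway,
                          fit$folding, config$out_dir,
                          scope = scope, mode = mode)
      prov <- file.path(config$out_dir, "provenance.txt")
      cfg_echo <- config[order(names(config))]
      writeLines(c(
        sprintf("hairpinfold version: %s",
                as.character(utils::packageVersion("hairpinfold"))),
        sprintf("n_frames: %d", fit$n_frames),
        sprintf("n_runs: %d", fit$n_runs),
        sprintf("mode: %s", mode),
        sprintf("scope: %s", scope),
        "config:",
        vapply(names(cfg_echo), function(k)
          sprintf("  %s: %s", k, paste(format(cfg_echo[[k]]), collapse = ", ")),
          character(1))), prov)
      c(f, provenance = prov)
    }),
    error = function(e) {
      unlink(file.path(config$out_dir,
                       c("pattern_table.tsv", "folding_summary.tsv",
                         "transition_map.tsv", "pathway.txt",
                         "analysis.json", "provenance.txt")))
      stop(e)
    })
  invisible(list(fit = fit, pathway = pathway, files = files))
}
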