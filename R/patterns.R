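#' Enumerate all open/closed patterns
#'
#' For `n_bonds` fingerprint bonds there are `2^n_bonds` patterns. Order is
#' canonical binary order with the first bond most significant and
#' `o` < `c`, i.e. for 4 bonds: `oooo`, `oooc`, `ooco`, ..., `cccc`.
#'
#' @param n_bonds number of fingerprint bonds (default 4).
#' @return character vector of `2^n_bonds` pattern labels.
#' @export
#' @examples
#' all_patterns()      # 16 labels
all_patterns <- function(n_bonds = 4L) {
  vapply(0:(2^n_bonds - 1L), function(i) {
    bits <- as.integer(intToBits(i))[n_bonds:1]  # first bond most significant
    paste0(ifelse(bits == 1L, "c", "o"), collapse = "")
  }, character(1))
}

#' Assign a pattern label to every frame
#'
#' Classifies each fingerprint bond in each frame with [classify_hbond()] and
#' concatenates the states into the frame's 4-character pattern.
#'
#' @param series a [geometry_series()].
#' @param criteria an [hb_criteria()] object.
#' @return data frame with columns `run`, `frame`, `pattern`.
#' @export
assign_patterns <- function(series, criteria = hb_criteria()) {
  fp <- fingerprint_labels(series)
  chars <- lapply(fp, function(lab)
    classify_hbond(series[[paste0(lab, "_dist")]],
                   series[[paste0(lab, "_angle")]], criteria))
  data.frame(run = series$run, frame = series$frame,
             pattern = do.call(paste0, chars), stringsAsFactors = FALSE)
}

#' Per-pattern population and distance table
#'
#' Tabulates, over all frames, the population of each of the 16 patterns,
#' the per-bond mean hydrogen-bond distances within each pattern, the overall
#' mean (arithmetic mean of the four per-bond means), and the strict
#' folded/unfolded classification of [classify_folded()]. All 16 patterns are
#' present in the output; patterns with no frames have `NA` distances and
#' folded flag. The `significant` column flags patterns whose population
#' rounds to at least 1%.
#'
#' @param series a [geometry_series()].
#' @param criteria an [hb_criteria()] object.
#' @param folded_threshold folded threshold in Å (strict `<`).
#' @return data frame of class `pattern_table` with columns `pattern`,
#'   `n_frames`, `population` (%), one mean-distance column per fingerprint
#'   bond, `average` (Å), `folded`, `significant`.
#' @export
pattern_table <- function(series, criteria = hb_criteria(),
                          folded_threshold = 3.0) {
  if (!is.data.frame(series) || nrow(series) == 0L)
    abort_config("'series' must be a non-empty geometry series")
  fp <- fingerprint_labels(series)
  pats <- all_patterns(length(fp))
  assigned <- assign_patterns(series, criteria)
  fac <- factor(assigned$pattern, levels = pats)
  n <- as.integer(table(fac))
  population <- 100 * n / nrow(series)

  dmat <- as.matrix(series[, paste0(fp, "_dist")])
  means <- matrix(NA_real_, length(pats), length(fp),
                  dimnames = list(pats, fp))
  occ <- which(n > 0)
  sums <- rowsum(dmat, group = fac)  # rows only for occupied levels
  means[rownames(sums), ] <- sums / n[match(rownames(sums), pats)]
  average <- rowMeans(means)
  folded <- ifelse(is.na(average), NA, average < folded_threshold)

  out <- data.frame(pattern = pats, n_frames = n, population = population,
                    stringsAsFactors = FALSE)
  for (j in seq_along(fp)) out[[fp[j]]] <- means[, j]
  out$average <- average
  out$folded <- folded
  out$significant <- round_half_away(population) >= 1
  structure(out,
            criteria = criteria, folded_threshold = folded_threshold,
            n_frames_total = nrow(series),
            class = c("pattern_table", "data.frame"))
}

#' @export
print.pattern_table <- function(x, digits = 2, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf(
    "Pattern table: %d frames; closed iff d <= %g A & angle >= %g deg; folded iff mean d < %g A\n",
    attr(x, "n_frames_total"), crit$distance_cutoff, crit$angle_min,
    attr(x, "folded_threshold")))
  df <- as.data.frame(x)
  df <- df[order(-df$population), ]
  df$population <- round_half_away(df$population)
  num <- vapply(df, is.double, logical(1)) & names(df) != "population"
  df[num] <- lapply(df[num], round_half_away, digits = digits)
  print(df[df$n_frames > 0, ], row.names = FALSE)
  if (any(df$n_frames == 0))
    cat(sprintf("(%d unpopulated patterns not shown)\n", sum(df$n_frames == 0)))
  invisible(x)
}

#' Overall folding ratio
#'
#' Pattern-level mode (the default, matching the construction of the
#' per-pattern table): the folded fraction is the summed population of
#' patterns classified folded. Frame-level mode classifies every frame by the
#' mean of its own four fingerprint distances and counts folded frames; it is
#' computed whenever `series` is supplied. The two agree exactly when all
#' frames of a pattern share identical geometry.
#'
#' @param table a [pattern_table()].
#' @param series optional [geometry_series()] for the frame-level mode.
#' @return object of class `folding_summary` with elements `pattern_level`
#'   and `frame_level` (percentages), `threshold`, `n_frames`.
#' @export
overall_folding_ratio <- function(table, series = NULL) {
  stopifnot(inherits(table, "pattern_table"))
  threshold <- attr(table, "folded_threshold")
  pattern_level <- sum(table$population[table$folded %in% TRUE])
  frame_level <- NA_real_
  if (!is.null(series)) {
    fp <- fingerprint_labels(series)
    fmean <- rowMeans(as.matrix(series[, paste0(fp, "_dist")]))
    frame_level <- 100 * mean(fmean < threshold)
  }
  structure(list(pattern_level = pattern_level, frame_level = frame_level,
                 threshold = threshold, n_frames = attr(table, "n_frames_total")),
            class = "folding_summary")
}

#' @export
print.folding_summary <- function(x, ...) {
  cat(sprintf("Folded fraction (pattern-level): %.1f%% of %d frames (mean HB distance < %g A)\n",
              x$pattern_level, x$n_frames, x$threshold))
  if (!is.na(x$frame_level))
    cat(sprintf("Folded fraction (frame-level):   %.1f%%\n", x$frame_level))
  invisible(x)
}

#' Co-occurrence of auxiliary hydrogen bonds with fingerprint patterns
#'
#' For each auxiliary bond (e.g. a side-chain to backbone hydrogen bond),
#' computes the overall percentage of frames in which it is closed, and the
#' conditional percentage within each fingerprint pattern. This quantifies
#' whether an auxiliary interaction preferentially accompanies particular
#' hairpin conformations.
#'
#' @param series a [geometry_series()] containing the fingerprint bonds.
#' @param aux labels of the auxiliary bonds; default: all non-fingerprint
#'   bonds in `series` (or in `aux_series` if given).
#' @param criteria an [hb_criteria()] object.
#' @param aux_series optional separate geometry series carrying the auxiliary
#'   bond columns; must align frame-by-frame with `series`.
#' @return object of class `aux_cooccurrence`: list with `overall` (named
#'   percentage vector), `conditional` (aux-by-pattern percentage matrix,
#'   `NA` for unpopulated patterns) and `pattern_n` (frames per pattern).
#' @export
auxiliary_cooccurrence <- function(series, aux = NULL,
                                   criteria = hb_criteria(),
                                   aux_series = NULL) {
  src <- aux_series %||% series
  if (!is.null(aux_series)) {
    if (nrow(aux_series) != nrow(series) ||
        any(aux_series$run != series$run) ||
        any(aux_series$frame != series$frame))
      abort("auxiliary series does not align frame-by-frame with the fingerprint series",
            "hairpin_alignment_error")
  }
  aux <- aux %||% setdiff(bond_labels(src), fingerprint_labels(series))
  if (length(aux) == 0L)
    abort_config("no auxiliary bonds found")
  miss <- setdiff(paste0(aux, "_dist"), names(src))
  if (length(miss))
    abort_config(paste("auxiliary bond columns missing:", paste(miss, collapse = ", ")))

  pats <- all_patterns(4L)
  pat <- factor(assign_patterns(series, criteria)$pattern, levels = pats)
  pattern_n <- as.integer(table(pat))
  names(pattern_n) <- pats

  conditional <- matrix(NA_real_, length(aux), length(pats),
                        dimnames = list(aux, pats))
  overall <- numeric(length(aux))
  names(overall) <- aux
  for (b in aux) {
    closed <- classify_hbond(src[[paste0(b, "_dist")]],
                             src[[paste0(b, "_angle")]], criteria) == "c"
    overall[b] <- 100 * mean(closed)
    cc <- tapply(closed, pat, function(z) 100 * mean(z))
    conditional[b, names(cc)] <- as.numeric(cc)
  }
  structure(list(overall = overall, conditional = conditional,
                 pattern_n = pattern_n),
            class = "aux_cooccurrence")
}

#' @export
print.aux_cooccurrence <- function(x, digits = 1, ...) {
  cat("Auxiliary H-bond closed frequencies (% of frames)\n\nOverall:\n")
  print(round_half_away(x$overall, digits))
  cat("\nConditional on pattern (populated patterns only):\n")
  keep <- x$pattern_n > 0
  print(round_half_away(x$conditional[, keep, drop = FALSE], digits))
  invisible(x)
}
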