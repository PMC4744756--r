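#' Fit the hydrogen-bond pattern model of hairpin folding
#'
#' The central entry point of the package. Takes a per-frame hydrogen-bond
#' geometry series and estimates the empirical pattern model: every frame is
#' assigned a 4-character open/closed fingerprint, per-pattern populations
#' and mean distances are tabulated, each pattern is classified
#' folded/unfolded by the strict mean-distance rule, the overall folding
#' ratio is computed (pattern-level and frame-level), and frame-to-frame
#' transitions within each run are counted and row-normalised into a
#' population change map.
#'
#' @param series a [geometry_series()] (from [extract_geometries()],
#'   [read_geometry_table()] or [emit_geometries()]).
#' @param criteria an [hb_criteria()] object.
#' @param folded_threshold folded threshold in Å (strict `<`; default 3.0).
#' @param mode `"pattern"` (default) or `"frame"`: which folding-ratio
#'   definition is reported as *the* folding ratio; both are computed.
#' @return object of class `hairpin_fit` with components `patterns`
#'   (per-frame labels), `table` (the [pattern_table()]), `folding`
#'   (the [overall_folding_ratio()] summary), `transition_map` (normalised
#'   [transition_map()] over all 16 states), `criteria`, `folded_threshold`,
#'   `mode`, `n_frames`, `n_runs`, `call`.
#' @seealso [extract_pathway()], [summary.hairpin_fit()],
#'   [simulate.hairpin_fit()]
#' @export
#' @examples
#' spec <- read_markov_spec(system.file("extdata", "markov_ser3.yaml",
#'                                      package = "hairpinfold"),
#'                          n_runs = 2, n_frames_per_run = 400, seed = 7)
#' series <- emit_geometries(generate_pattern_chain(spec), seed = 7)
#' fit <- hairpin_fit(series)
#' fit
#' coef(fit)
hairpin_fit <- function(series, criteria = hb_criteria(),
                        folded_threshold = 3.0,
                        mode = c("pattern", "frame")) {
  mode <- match.arg(mode)
  if (!is.data.frame(series) || nrow(series) == 0L)
    abort_config("'series' must be a non-empty geometry series")
  patterns <- assign_patterns(series, criteria)
  table <- pattern_table(series, criteria, folded_threshold)
  folding <- overall_folding_ratio(table, series)
  tmap <- normalize_map(count_transitions(patterns))
  structure(list(patterns = patterns, table = table, folding = folding,
                 transition_map = tmap, criteria = criteria,
                 folded_threshold = folded_threshold, mode = mode,
                 n_frames = nrow(series),
                 n_runs = length(unique(series$run)),
                 call = match.call()),
            class = "hairpin_fit")
}

#' Folding ratio of a fit under its reporting mode
#' @param fit a [hairpin_fit()].
#' @return single percentage.
#' @export
folding_ratio <- function(fit) {
  stopifnot(inherits(fit, "hairpin_fit"))
  if (fit$mode == "frame") fit$folding$frame_level else fit$folding$pattern_level
}

#' @export
print.hairpin_fit <- function(x, ...) {
  cat(sprintf("Hairpin H-bond pattern fit: %d frames in %d run(s)\n",
              x$n_frames, x$n_runs))
  print(x$criteria)
  sig <- as.data.frame(x$table)
  sig <- sig[sig$significant, c("pattern", "population", "folded")]
  sig <- sig[order(-sig$population), ]
  cat("Significant patterns (population >= 1%):\n")
  cat(paste(sprintf("  %s %3.0f%% (%s)", sig$pattern,
                    round_half_away(sig$population),
                    ifelse(sig$folded, "f", "u")), collapse = "\n"), "\n")
  cat(sprintf("Folding ratio (%s-level): %.1f%%\n", x$mode, folding_ratio(x)))
  invisible(x)
}

#' @export
coef.hairpin_fit <- function(object, what = c("populations", "transitions"),
                             ...) {
  what <- match.arg(what)
  if (what == "populations") {
    p <- object$table$population
    names(p) <- object$table$pattern
    p
  } else {
    as.matrix(object$transition_map, "percentages")
  }
}

#' Summarise a hairpin pattern fit
#'
#' @param object a [hairpin_fit()].
#' @param ... unused.
#' @return object of class `summary.hairpin_fit`: the populated pattern
#'   table, folding summary, transition map restricted to significant
#'   patterns (rest aggregated as `"other"`), and the extracted folding
#'   pathway (`NULL` when no complete pathway exists in the map).
#' @export
summary.hairpin_fit <- function(object, ...) {
  sig <- object$table$pattern[object$table$significant]
  map6 <- if (length(sig) >= 2L)
    restrict_map(object$transition_map, sig) else object$transition_map
  pathway <- tryCatch(extract_pathway(object$transition_map),
                      hairpin_error = function(e) NULL)
  structure(list(fit = object, significant = sig, map = map6,
                 pathway = pathway),
            class = "summary.hairpin_fit")
}

#' @export
print.summary.hairpin_fit <- function(x, ...) {
  print(x$fit$table)
  cat("\n")
  print(x$fit$folding)
  cat("\nTransition map (significant patterns, % per row):\n")
  print(x$map)
  cat("\nMost probable folding pathway (oooo -> cccc):\n")
  if (is.null(x$pathway)) cat("  no complete pathway in the transition map\n")
  else print(x$pathway)
  invisible(x)
}

#' Simulate pattern trajectories from a fitted model
#'
#' Resamples new pattern sequences from the estimated transition matrix,
#' restricted to the states observed in the fit (rows renormalised over
#' those states); the initial distribution is the estimated population
#' vector. This is the parametric-bootstrap counterpart of the synthetic
#' generator.
#'
#' @param object a [hairpin_fit()].
#' @param nsim number of independent runs to simulate.
#' @param seed integer seed (required for reproducibility; default 1).
#' @param n_frames frames per simulated run; default: average run length of
#'   the fitted data.
#' @param ... unused.
#' @return named list of pattern label vectors, as
#'   [generate_pattern_chain()].
#' @export
simulate.hairpin_fit <- function(object, nsim = 1, seed = 1L,
                                 n_frames = NULL, ...) {
  obs <- object$table$pattern[object$table$n_frames > 0]
  obs <- obs[object$transition_map$row_defined[obs]]
  if (length(obs) < 2L)
    abort_compute("fewer than 2 observed states with transitions; nothing to simulate")
  P <- object$transition_map$percentages[obs, obs, drop = FALSE] / 100
  rs <- rowSums(P)
  if (any(rs == 0))
    abort_compute("an observed state only transitions to unobserved states")
  P <- P / rs
  init <- object$table$population[match(obs, object$table$pattern)]
  init <- init / sum(init)
  spec <- markov_spec(obs, P, initial_distribution = init, n_runs = nsim,
                      n_frames_per_run = n_frames %||%
                        max(2L, floor(object$n_frames / object$n_runs)),
                      seed = seed)
  generate_pattern_chain(spec)
}

#' Plot a hairpin pattern fit
#'
#' `type = "map"` draws the transition-percentage matrix of the significant
#' patterns as a shaded image with printed percentages (rows = origin,
#' columns = destination); `type = "populations"` draws a population bar
#' chart with folded patterns shaded.
#'
#' @param x a [hairpin_fit()].
#' @param type `"map"` or `"populations"`.
#' @param ... passed to the underlying base graphics call.
#' @return `x`, invisibly.
#' @export
plot.hairpin_fit <- function(x, type = c("map", "populations"), ...) {
  type <- match.arg(type)
  if (type == "populations") {
    tab <- as.data.frame(x$table)
    tab <- tab[tab$n_frames > 0, ]
    tab <- tab[order(-tab$population), ]
    graphics::barplot(tab$population, names.arg = tab$pattern, las = 2,
                      col = ifelse(tab$folded %in% TRUE, "grey30", "grey80"),
                      ylab = "population (%)", ...)
    graphics::legend("topright", fill = c("grey30", "grey80"),
                     legend = c("folded", "unfolded"), bty = "n")
  } else {
    s <- summary(x)
    m <- as.matrix(s$map, "percentages")
    k <- nrow(m)
    graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                    col = grDevices::grey.colors(64, start = 0.95, end = 0.2),
                    axes = FALSE, xlab = "to", ylab = "from", ...)
    graphics::axis(1, seq_len(k), colnames(m), las = 2)
    graphics::axis(2, seq_len(k), rev(rownames(m)), las = 2)
    for (i in seq_len(k)) for (j in seq_len(k))
      if (!is.na(m[i, j]))
        graphics::text(j, k + 1 - i, formatC(round_half_away(m[i, j]),
                                             format = "d"),
                       col = if (m[i, j] > 50) "white" else "black", cex = 0.8)
    graphics::box()
  }
  invisible(x)
}
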