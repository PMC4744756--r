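#' Construct a transition map
#'
#' A transition map holds frame-to-frame pattern transition counts and/or
#' row-normalised percentages (rows = origin pattern, columns = destination).
#' Usually built via [count_transitions()] + [normalize_map()]; percentages
#' can also be supplied directly, e.g. when transcribing a published map.
#'
#' @param counts square matrix of non-negative integer transition counts.
#' @param percentages square matrix of row percentages.
#' @param states ordered state labels (defaults to the dimnames of the
#'   supplied matrix).
#' @return object of class `transition_map`.
#' @export
transition_map <- function(counts = NULL, percentages = NULL, states = NULL) {
  m <- counts %||% percentages
  if (is.null(m)) abort_config("supply 'counts' and/or 'percentages'")
  states <- states %||% rownames(m)
  if (is.null(states)) abort_config("state labels required")
  check_sq <- function(x, what) {
    if (!is.matrix(x) || nrow(x) != length(states) || ncol(x) != length(states))
      abort_config(sprintf("'%s' must be a %d x %d matrix",
                           what, length(states), length(states)))
    dimnames(x) <- list(states, states)
    x
  }
  if (!is.null(counts)) {
    counts <- check_sq(counts, "counts")
    if (any(counts < 0) || any(counts != round(counts)))
      abort_config("'counts' must be non-negative integers")
  }
  if (!is.null(percentages)) percentages <- check_sq(percentages, "percentages")
  row_defined <- if (!is.null(counts)) rowSums(counts) > 0
                 else apply(percentages, 1, function(r) !all(is.na(r)))
  names(row_defined) <- states
  structure(list(states = states, counts = counts,
                 percentages = percentages, row_defined = row_defined),
            class = "transition_map")
}

#' Count frame-to-frame pattern transitions
#'
#' Every consecutive within-run frame pair `(t, t+1)` increments the count
#' from the pattern at `t` to the pattern at `t+1`; self-transitions land on
#' the diagonal. Pairs spanning run boundaries are never counted, since
#' independent production runs carry no dynamical information across their
#' junction.
#'
#' @param patterns per-frame pattern labels: either the data frame returned
#'   by [assign_patterns()] (columns `run`, `pattern`) or a list of per-run
#'   character vectors.
#' @param states ordered state labels; default: all 16 four-bond patterns if
#'   every observed label is one, otherwise the sorted distinct labels.
#' @return a [transition_map()] with `counts` filled.
#' @export
count_transitions <- function(patterns, states = NULL) {
  runs <- if (is.data.frame(patterns)) {
    split(patterns$pattern, patterns$run)
  } else if (is.list(patterns)) {
    lapply(patterns, as.character)
  } else {
    list(as.character(patterns))
  }
  labs <- unique(unlist(runs, use.names = FALSE))
  if (is.null(states)) {
    states <- if (all(labs %in% all_patterns(4L))) all_patterns(4L)
              else sort(labs)
  }
  unknown <- setdiff(labs, states)
  if (length(unknown))
    abort_config(paste("pattern label(s) not in 'states':",
                       paste(unknown, collapse = ", ")))
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  for (x in runs) {
    if (length(x) < 2L) next
    from <- factor(x[-length(x)], levels = states)
    to <- factor(x[-1L], levels = states)
    counts <- counts + unclass(table(from, to))
  }
  storage.mode(counts) <- "integer"
  transition_map(counts = counts, states = states)
}

#' Row-normalise a transition map to percentages
#'
#' `percentages[i, j] = 100 * counts[i, j] / rowsum(i)`. Rows with no
#' outgoing transitions are marked undefined (`NA` row, `row_defined`
#' `FALSE`) rather than raising a division error.
#'
#' @param map a [transition_map()] with counts filled.
#' @return the map with `percentages` filled.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "transition_map"))
  if (is.null(map$counts)) abort_config("map has no counts to normalise")
  rs <- rowSums(map$counts)
  pct <- 100 * map$counts / ifelse(rs == 0, NA_real_, rs)
  map$percentages <- pct
  map$row_defined <- rs > 0
  names(map$row_defined) <- map$states
  map
}

#' Restrict a transition map to selected states
#'
#' Collapses all remaining states into a single `"other"` aggregate row and
#' column (or drops them), recomputing percentages from the aggregated
#' counts. Mirrors presenting only the prevalent conformations of a full
#' 16-state map.
#'
#' @param map a [transition_map()] with counts filled.
#' @param states states to keep, in order.
#' @param other if `TRUE` (default) aggregate the rest as `"other"`;
#'   otherwise drop them.
#' @return a new [transition_map()].
#' @export
restrict_map <- function(map, states, other = TRUE) {
  stopifnot(inherits(map, "transition_map"))
  if (is.null(map$counts)) abort_config("restrict_map requires counts")
  missing <- setdiff(states, map$states)
  if (length(missing))
    abort_config(paste("state(s) not in map:", paste(missing, collapse = ", ")))
  rest <- setdiff(map$states, states)
  if (!other || length(rest) == 0L) {
    cnt <- map$counts[states, states, drop = FALSE]
    return(normalize_map(transition_map(counts = cnt, states = states)))
  }
  grp <- ifelse(map$states %in% states, map$states, "other")
  agg <- rowsum(t(rowsum(map$counts, grp)), grp)
  new_states <- c(states, "other")
  cnt <- t(agg)[new_states, new_states, drop = FALSE]
  storage.mode(cnt) <- "integer"
  normalize_map(transition_map(counts = cnt, states = new_states))
}

#' @export
print.transition_map <- function(x, digits = 0, ...) {
  cat(sprintf("Transition map over %d states (rows = from, columns = to)\n",
              length(x$states)))
  if (!is.null(x$percentages)) {
    m <- round_half_away(x$percentages, digits)
    print(m)
    if (any(!x$row_defined))
      cat("Rows with no outgoing transitions:",
          paste(x$states[!x$row_defined], collapse = ", "), "\n")
  } else {
    print(x$counts)
  }
  invisible(x)
}

#' @export
as.matrix.transition_map <- function(x, what = c("percentages", "counts"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  if (is.null(m)) abort_config(sprintf("map has no %s", what))
  m
}

n_closed <- function(label) {
  vapply(strsplit(label, ""), function(ch) sum(ch == "c"), integer(1))
}

#' Extract the most probable folding pathway from a transition map
#'
#' Greedy walk from `start` to `end`: at each state, move to the destination
#' with the highest transition percentage among states that are neither the
#' current state nor already visited. The second-best destination at each
#' step is recorded as the alternative branch. Ties are broken first towards
#' the destination with more closed bonds, then by lexicographically smaller
#' label, so the output is deterministic. Already-visited states are skipped
#' (never re-entered), which prevents the raw greedy rule from cycling.
#'
#' @param map a [transition_map()] with percentages filled.
#' @param start start pattern (default the fully open `"oooo"`).
#' @param end end pattern (default the fully closed `"cccc"`).
#' @return object of class `folding_pathway`: list with `states` (the
#'   ordered pattern sequence) and `steps` (data frame `from`, `to`,
#'   `percent`, `alt_to`, `alt_percent`).
#' @export
extract_pathway <- function(map, start = "oooo", end = "cccc") {
  stopifnot(inherits(map, "transition_map"))
  if (is.null(map$percentages))
    abort_config("map has no percentages; call normalize_map() first")
  if (!start %in% map$states) abort_config(sprintf("start state '%s' not in map", start))
  if (!end %in% map$states) abort_config(sprintf("end state '%s' not in map", end))
  visited <- start
  cur <- start
  steps <- list()
  while (cur != end) {
    cand <- setdiff(map$states, visited)
    vals <- map$percentages[cur, cand]
    ok <- !is.na(vals) & vals > 0
    if (!length(cand) || !any(ok)) {
      abort(sprintf(
        "pathway extraction stuck at '%s' before reaching '%s' (partial path: %s)",
        cur, end, paste(visited, collapse = " -> ")),
        "hairpin_pathway_error", data = list(partial = visited))
    }
    cand <- cand[ok]
    vals <- vals[ok]
    ord <- order(-vals, -n_closed(cand), cand)
    best <- cand[ord[1]]
    steps[[length(steps) + 1L]] <- data.frame(
      from = cur, to = best, percent = vals[ord[1]],
      alt_to = if (length(ord) > 1L) cand[ord[2]] else NA_character_,
      alt_percent = if (length(ord) > 1L) vals[ord[2]] else NA_real_,
      stringsAsFactors = FALSE)
    visited <- c(visited, best)
    cur <- best
  }
  steps <- if (length(steps)) do.call(rbind, steps)
           else data.frame(from = character(0), to = character(0),
                           percent = numeric(0), alt_to = character(0),
                           alt_percent = numeric(0))
  structure(list(states = visited, steps = steps), class = "folding_pathway")
}

#' @export
print.folding_pathway <- function(x, ...) {
  if (nrow(x$steps) == 0L) {
    cat(x$states[1], "\n")
    return(invisible(x))
  }
  cat(format_pathway(x), sep = "\n")
  invisible(x)
}

format_pathway <- function(x) {
  if (nrow(x$steps) == 0L) return(x$states[1])
  main <- paste0(x$states[1], paste0(
    vapply(seq_len(nrow(x$steps)), function(i)
      sprintf(" -> %s (%s%%)", x$steps$to[i],
              formatC(round_half_away(x$steps$percent[i]), format = "d")),
      character(1)), collapse = ""))
  alts <- vapply(seq_len(nrow(x$steps)), function(i) {
    if (is.na(x$steps$alt_to[i])) return(NA_character_)
    sprintf("  step %d alternative: %s -> %s (%s%%)", i, x$steps$from[i],
            x$steps$alt_to[i],
            formatC(round_half_away(x$steps$alt_percent[i]), format = "d"))
  }, character(1))
  c(main, alts[!is.na(alts)])
}
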