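#' Hydrogen-bond detection criteria
#'
#' Geometric criteria under which a hydrogen bond is considered formed
#' ("closed"): the hydrogen--acceptor distance must not exceed
#' `distance_cutoff` and the donor--hydrogen--acceptor angle must be at least
#' `angle_min`. The defaults (3 Å, 120°) are the standard detection criteria
#' for backbone amide hydrogen bonds in MD post-processing. Both boundaries
#' are inclusive: a bond at exactly 3.0 Å and 120° counts as closed.
#'
#' @param distance_cutoff maximum hydrogen--acceptor distance in Å (> 0).
#' @param angle_min minimum donor--hydrogen--acceptor angle in degrees,
#'   in `[0, 180]`; 180° is a perfectly linear bond.
#' @return an object of class `hb_criteria`.
#' @export
#' @examples
#' hb_criteria()
#' hb_criteria(distance_cutoff = 3.5, angle_min = 130)
hb_criteria <- function(distance_cutoff = 3.0, angle_min = 120) {
  if (!is.numeric(distance_cutoff) || length(distance_cutoff) != 1L ||
      !is.finite(distance_cutoff) || distance_cutoff <= 0)
    abort_config("'distance_cutoff' must be a single positive finite number (Å)")
  if (!is.numeric(angle_min) || length(angle_min) != 1L ||
      !is.finite(angle_min) || angle_min < 0 || angle_min > 180)
    abort_config("'angle_min' must be a single number in [0, 180] degrees")
  structure(list(distance_cutoff = as.numeric(distance_cutoff),
                 angle_min = as.numeric(angle_min)),
            class = "hb_criteria")
}

#' @export
print.hb_criteria <- function(x, ...) {
  cat(sprintf("H-bond criteria: closed iff distance <= %g A and angle >= %g deg\n",
              x$distance_cutoff, x$angle_min))
  invisible(x)
}

#' Classify a hydrogen bond as open or closed
#'
#' A bond is closed when the hydrogen--acceptor distance is at or below the
#' cutoff *and* the donor--hydrogen--acceptor angle is at or above the lower
#' limit; otherwise it is open. Vectorised over `distance` and `angle`.
#'
#' @param distance hydrogen--acceptor distance(s) in Å, positive and finite.
#' @param angle donor--hydrogen--acceptor angle(s) in degrees, in `[0, 180]`.
#' @param criteria an [hb_criteria()] object.
#' @return character vector of `"c"` (closed) / `"o"` (open), one per input.
#' @export
#' @examples
#' classify_hbond(c(2.2, 2.2, 3.0), c(160, 100, 120))  # "c" "o" "c"
classify_hbond <- function(distance, angle, criteria = hb_criteria()) {
  stopifnot(inherits(criteria, "hb_criteria"))
  if (length(distance) != length(angle))
    abort_config("'distance' and 'angle' must have equal length")
  if (!is.numeric(distance) || !is.numeric(angle) ||
      any(!is.finite(distance)) || any(!is.finite(angle)))
    abort_config("distances and angles must be finite numbers")
  if (any(distance <= 0))
    abort_config("distances must be positive")
  if (any(angle < 0 | angle > 180))
    abort_config("angles must lie in [0, 180] degrees")
  closed <- distance <= criteria$distance_cutoff & angle >= criteria$angle_min
  ifelse(closed, "c", "o")
}

#' Build a 4-character pattern label from bond states
#'
#' Concatenates the open/closed states of the fingerprint bonds, in HB1..HB4
#' order, into a pattern label such as `"cocc"`.
#'
#' @param states length-4 vector of bond states: logical (`TRUE` = closed),
#'   or character `"c"`/`"o"` (also accepts `"closed"`/`"open"`).
#' @return single pattern label string.
#' @export
#' @examples
#' assign_pattern(c("c", "o", "o", "c"))
#' assign_pattern(c(TRUE, TRUE, TRUE, TRUE))
assign_pattern <- function(states) {
  if (length(states) != 4L)
    abort_config(sprintf("exactly 4 bond states required, got %d", length(states)))
  if (is.logical(states)) {
    if (anyNA(states)) abort_config("bond states must not be NA")
    chars <- ifelse(states, "c", "o")
  } else if (is.character(states)) {
    chars <- c(closed = "c", open = "o", c = "c", o = "o")[tolower(states)]
    if (anyNA(chars))
      abort_config("character states must be 'c'/'o' or 'closed'/'open'")
  } else {
    abort_config("'states' must be logical or character")
  }
  paste0(chars, collapse = "")
}

#' Folded/unfolded classification from per-bond mean distances
#'
#' The overall mean is the arithmetic mean of the four per-bond mean
#' hydrogen-bond distances; a conformation is folded iff that mean is
#' *strictly* below the threshold. The inequality is strict: a pattern whose
#' mean distance is exactly 3.00 Å is unfolded.
#'
#' @param mean_distances four positive finite per-bond mean distances (Å).
#' @param threshold folded threshold in Å (default 3.0).
#' @return list with elements `mean` (Å) and `folded` (logical).
#' @export
#' @examples
#' classify_folded(c(2.40, 3.70, 2.17, 2.13))  # mean 2.60, folded
#' classify_folded(c(2.26, 3.72, 3.83, 2.19))  # mean 3.00, unfolded
classify_folded <- function(mean_distances, threshold = 3.0) {
  if (length(mean_distances) != 4L)
    abort_config("exactly 4 per-bond mean distances required")
  if (!is.numeric(mean_distances) || any(!is.finite(mean_distances)) ||
      any(mean_distances <= 0))
    abort_config("mean distances must be positive finite numbers")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    abort_config("'threshold' must be a single positive number")
  m <- mean(mean_distances)
  list(mean = m, folded = m < threshold)
}
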