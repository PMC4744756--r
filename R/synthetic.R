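#' Markov-chain specification for synthetic pattern dynamics
#'
#' Defines the ground-truth process for synthetic trajectories: a Markov
#' chain over pattern labels, the number of independent runs and frames per
#' run, and a seed. The defaults for run structure (11 runs) mirror a
#' typical multi-run production protocol.
#'
#' @param states ordered pattern labels.
#' @param transition_matrix row-stochastic matrix (rows sum to 1 within
#'   1e-12); rows/columns in `states` order.
#' @param initial_distribution probability vector for frame 1 of each run;
#'   default: the stationary distribution of the matrix.
#' @param n_runs number of independent runs (>= 1).
#' @param n_frames_per_run frames per run (>= 2).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return object of class `markov_spec`.
#' @export
markov_spec <- function(states, transition_matrix,
                        initial_distribution = NULL,
                        n_runs = 11L, n_frames_per_run = 5000L, seed = 1L) {
  if (!is.matrix(transition_matrix) ||
      nrow(transition_matrix) != length(states) ||
      ncol(transition_matrix) != length(states))
    abort_config("'transition_matrix' must be square with one row per state")
  if (any(transition_matrix < 0) || any(transition_matrix > 1))
    abort_config("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    abort_config("transition matrix rows must sum to 1 (within 1e-12)")
  dimnames(transition_matrix) <- list(states, states)
  initial_distribution <- initial_distribution %||%
    stationary_distribution(transition_matrix)
  if (length(initial_distribution) != length(states) ||
      any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-8)
    abort_config("'initial_distribution' must be a probability vector over the states")
  if (n_runs < 1L) abort_config("'n_runs' must be >= 1")
  if (n_frames_per_run < 2L) abort_config("'n_frames_per_run' must be >= 2")
  structure(list(states = states,
                 transition_matrix = transition_matrix,
                 initial_distribution = as.numeric(initial_distribution),
                 n_runs = as.integer(n_runs),
                 n_frames_per_run = as.integer(n_frames_per_run),
                 seed = as.integer(seed)),
            class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf("Markov spec: %d states (%s), %d run(s) x %d frames, seed %d\n",
              length(x$states), paste(x$states, collapse = ", "),
              x$n_runs, x$n_frames_per_run, x$seed))
  invisible(x)
}

#' Read a Markov spec from a YAML file
#'
#' Expected fields: `states` (list of labels), `transition_matrix` (list of
#' rows, any positive row weights -- each row is normalised to sum to 1, so
#' integer percentage rows may be transcribed as printed), and optionally
#' `initial_distribution`, `n_runs`, `n_frames_per_run`, `seed`.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [markov_spec()] (e.g. `seed`).
#' @return a [markov_spec()].
#' @export
read_markov_spec <- function(path, ...) {
  if (!file.exists(path)) abort_io(sprintf("Markov spec not found: '%s'", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$states) || is.null(y$transition_matrix))
    abort_config(sprintf("'%s': 'states' and 'transition_matrix' required", path))
  P <- do.call(rbind, lapply(y$transition_matrix, as.numeric))
  if (any(P < 0) || any(rowSums(P) <= 0))
    abort_config("transition matrix rows must be non-negative with positive sum")
  P <- P / rowSums(P)
  args <- list(states = unlist(y$states), transition_matrix = P)
  for (f in c("initial_distribution", "n_runs", "n_frames_per_run", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(markov_spec, args)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The left fixed-point probability vector `pi` with `pi P = pi`, computed
#' from the unit left eigenvector. For an irreducible chain it is unique; if
#' the unit eigenvalue is degenerate (reducible chain with several closed
#' classes) the result is not unique and the function warns or errors per
#' `on_reducible`.
#'
#' @param transition_matrix row-stochastic square matrix.
#' @param on_reducible `"error"` (default) or `"warn"`.
#' @return probability vector summing to 1, named by the matrix dimnames.
#' @export
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
#' stationary_distribution(P)  # (0.75, 0.25)
stationary_distribution <- function(transition_matrix,
                                    on_reducible = c("error", "warn")) {
  on_reducible <- match.arg(on_reducible)
  P <- transition_matrix
  if (!is.matrix(P) || nrow(P) != ncol(P))
    abort_config("'transition_matrix' must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    abort_config("'transition_matrix' must be row-stochastic")
  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) == 0L) abort_compute("no unit eigenvalue found")
  if (length(unit) > 1L) {
    msg <- "transition matrix is reducible: stationary distribution is not unique"
    if (on_reducible == "error") abort_compute(msg)
    warning(msg)
  }
  v <- Re(e$vectors[, unit[1]])
  pi <- v / sum(v)
  pi[abs(pi) < 1e-14] <- 0
  if (any(pi < 0)) abort_compute("eigenvector has negative entries; matrix ill-conditioned")
  pi <- pi / sum(pi)
  names(pi) <- rownames(P)
  pi
}

#' Generate per-run pattern sequences from a Markov spec
#'
#' Frame 1 of each run is drawn from the initial distribution; frame `t+1`
#' from the transition-matrix row of the pattern at `t`. Runs are
#' independent. Identical spec and seed give byte-identical output.
#'
#' @param spec a [markov_spec()].
#' @return named list (`run1`, `run2`, ...) of character vectors of pattern
#'   labels.
#' @export
generate_pattern_chain <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  set.seed(spec$seed)
  P <- spec$transition_matrix
  cum <- t(apply(P, 1, cumsum))
  cum0 <- cumsum(spec$initial_distribution)
  k <- length(spec$states)
  runs <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    n <- spec$n_frames_per_run
    u <- stats::runif(n)
    idx <- integer(n)
    idx[1] <- findInterval(u[1], cum0, left.open = TRUE) + 1L
    for (t in 2:n)
      idx[t] <- findInterval(u[t], cum[idx[t - 1L], ], left.open = TRUE) + 1L
    runs[[r]] <- spec$states[pmin(idx, k)]
  }
  names(runs) <- paste0("run", seq_len(spec$n_runs))
  runs
}

#' Geometry emission parameters for synthetic trajectories
#'
#' Pattern-conditional distributions from which per-bond geometries are
#' drawn. Closed bonds: normal distance and angle, truncated to the
#' detection region; open bonds: normal distance and uniform angle, truncated
#' to its complement. Defaults mimic backbone amide H-bond geometry: a
#' closed bond sits near 2.2 Å and 155°, an open bond is long (~6 Å) with a
#' broad angle; the specific values are arbitrary but realistic.
#'
#' @param closed_dist_mean,closed_dist_sd closed-bond distance (Å).
#' @param closed_angle_mean,closed_angle_sd closed-bond angle (degrees).
#' @param open_dist_mean,open_dist_sd open-bond distance (Å).
#' @param open_angle_min,open_angle_max open-bond angle range (degrees).
#' @return object of class `emission_params`.
#' @export
emission_params <- function(closed_dist_mean = 2.2, closed_dist_sd = 0.2,
                            closed_angle_mean = 155, closed_angle_sd = 12,
                            open_dist_mean = 6.0, open_dist_sd = 1.5,
                            open_angle_min = 60, open_angle_max = 180) {
  if (closed_dist_mean >= open_dist_mean)
    abort_config("closed distance mean must be below open distance mean")
  if (closed_dist_sd <= 0 || closed_angle_sd <= 0 || open_dist_sd <= 0)
    abort_config("standard deviations must be positive")
  if (open_angle_min < 0 || open_angle_max > 180 ||
      open_angle_min >= open_angle_max)
    abort_config("open angle range must be within [0, 180] with min < max")
  structure(as.list(environment()), class = "emission_params")
}

# Rejection-sample n (distance, angle) pairs consistent with the intended
# open/closed state. Cap: 1000 rounds; exceeding it means the emission
# distributions are inconsistent with the detection criteria.
draw_state_geometry <- function(n, closed, params, criteria, max_rounds = 1000L) {
  if (n == 0L) return(list(dist = numeric(0), angle = numeric(0)))
  d <- numeric(n); a <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    m <- length(todo)
    if (closed) {
      d[todo] <- stats::rnorm(m, params$closed_dist_mean, params$closed_dist_sd)
      a[todo] <- stats::rnorm(m, params$closed_angle_mean, params$closed_angle_sd)
    } else {
      d[todo] <- stats::rnorm(m, params$open_dist_mean, params$open_dist_sd)
      a[todo] <- stats::runif(m, params$open_angle_min, params$open_angle_max)
    }
    valid <- d[todo] > 0 & a[todo] >= 0 & a[todo] <= 180
    detected <- d[todo] <= criteria$distance_cutoff & a[todo] >= criteria$angle_min
    keep <- valid & (if (closed) detected else !detected)
    todo <- todo[!keep]
    if (!length(todo)) return(list(dist = d, angle = a))
  }
  abort_config(sprintf(
    "emission distributions inconsistent with detection criteria: %d value(s) still rejected after %d draws",
    length(todo), max_rounds))
}

#' Emit per-frame geometries for pattern sequences
#'
#' For every frame and fingerprint bond, draws a (distance, angle) pair from
#' the closed or open emission distribution according to the pattern
#' character, rejection-resampling any draw that would violate the intended
#' classification under `criteria`. Classifying the emitted series therefore
#' exactly recovers the generating patterns.
#'
#' @param chains list of per-run pattern label vectors
#'   (see [generate_pattern_chain()]).
#' @param params an [emission_params()] object.
#' @param criteria an [hb_criteria()] object.
#' @param seed integer seed.
#' @param labels bond labels for the columns (default `HB1`..`HB4`).
#' @return a [geometry_series()].
#' @export
emit_geometries <- function(chains, params = emission_params(),
                            criteria = hb_criteria(), seed = 1L,
                            labels = paste0("HB", 1:4)) {
  stopifnot(inherits(params, "emission_params"), inherits(criteria, "hb_criteria"))
  if (!is.list(chains)) chains <- list(chains)
  nb <- unique(nchar(unlist(chains, use.names = FALSE)))
  if (length(nb) != 1L || nb != length(labels))
    abort_config("all patterns must have one character per bond label")
  set.seed(as.integer(seed))
  out <- lapply(seq_along(chains), function(r) {
    pats <- chains[[r]]
    n <- length(pats)
    res <- data.frame(run = r, frame = seq_len(n))
    for (b in seq_along(labels)) {
      ch <- substr(pats, b, b)
      dd <- numeric(n); aa <- numeric(n)
      for (state in c("c", "o")) {
        sel <- which(ch == state)
        g <- draw_state_geometry(length(sel), state == "c", params, criteria)
        dd[sel] <- g$dist
        aa[sel] <- g$angle
      }
      res[[paste0(labels[b], "_dist")]] <- dd
      res[[paste0(labels[b], "_angle")]] <- aa
    }
    res
  })
  geometry_series(do.call(rbind, out), fingerprint = labels)
}

#' Place a donor/hydrogen/acceptor triplet realising a target geometry
#'
#' The donor sits at the origin, the hydrogen at (1, 0, 0) Å, and the
#' acceptor in the xy-plane such that the hydrogen--acceptor distance equals
#' `distance` and the donor--hydrogen--acceptor angle equals `angle`.
#' [extract_geometries()] on these coordinates recovers the inputs to 1e-9.
#'
#' @param distance hydrogen--acceptor distance (Å, > 0).
#' @param angle donor--hydrogen--acceptor angle (degrees, in `[0, 180]`).
#' @return 3 x 3 numeric matrix with rows `donor`, `hydrogen`, `acceptor`.
#' @export
#' @examples
#' emit_coordinates(2, 180)  # acceptor at (3, 0, 0)
#' emit_coordinates(2, 90)   # acceptor at (1, 2, 0)
emit_coordinates <- function(distance, angle) {
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
      distance <= 0)
    abort_config("'distance' must be a single positive number")
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle) ||
      angle < 0 || angle > 180)
    abort_config("'angle' must be a single number in [0, 180]")
  th <- angle * pi / 180
  h <- c(1, 0, 0)
  acceptor <- h + distance * c(-cos(th), sin(th), 0)
  m <- rbind(donor = c(0, 0, 0), hydrogen = h, acceptor = acceptor)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a synthetic geometry series as a multi-model PDB trajectory
#'
#' Realises each frame's per-bond geometries as explicit atom triplets (via
#' [emit_coordinates()], each bond offset along z so triplets do not
#' overlap) and writes one PDB MODEL per frame. Useful for exercising the
#' trajectory reader end to end; the companion H-bond config describing the
#' synthetic atom naming is returned (and optionally written as YAML).
#' Multi-run series are written to one file per run
#' (`<stem>_run<k>.pdb`).
#'
#' @param series a [geometry_series()].
#' @param path output PDB path (used as stem when the series has several runs).
#' @param config_path optional path for the matching H-bond YAML config.
#' @return list with `paths` (PDB files, one per run) and `config`
#'   (`hbond_config` data frame), invisibly.
#' @export
write_synthetic_pdb <- function(series, path, config_path = NULL) {
  labels <- bond_labels(series)
  nb <- length(labels)
  defs <- data.frame(
    label = labels,
    donor = sprintf("GLY %d N", seq_len(nb) * 10 + 1),
    hydrogen = sprintf("GLY %d HN", seq_len(nb) * 10 + 1),
    acceptor = sprintf("ALA %d O", seq_len(nb) * 10 + 2),
    auxiliary = c(rep(FALSE, min(4L, nb)), rep(TRUE, max(0L, nb - 4L))),
    stringsAsFactors = FALSE)
  runs <- sort(unique(series$run))
  paths <- character(length(runs))
  for (ri in seq_along(runs)) {
    sub <- series[series$run == runs[ri], , drop = FALSE]
    xyz <- t(vapply(seq_len(nrow(sub)), function(i) {
      coords <- lapply(seq_len(nb), function(b) {
        m <- emit_coordinates(sub[[paste0(labels[b], "_dist")]][i],
                              sub[[paste0(labels[b], "_angle")]][i])
        m + matrix(c(0, 0, 20 * b), 3, 3, byrow = TRUE)
      })
      as.numeric(t(do.call(rbind, coords)))
    }, numeric(9L * nb)))
    p <- if (length(runs) == 1L) path
         else sub("\\.pdb$", sprintf("_run%d.pdb", runs[ri]), path)
    bio3d::write.pdb(
      file = p, xyz = xyz,
      resno = rep(seq_len(nb) * 10, each = 3) + rep(c(1, 1, 2), nb),
      resid = rep(c("GLY", "GLY", "ALA"), nb),
      elety = rep(c("N", "HN", "O"), nb))
    paths[ri] <- p
  }
  if (!is.null(config_path)) {
    yaml::write_yaml(list(bonds = lapply(seq_len(nb), function(i) {
      b <- list(label = defs$label[i], donor = defs$donor[i],
                hydrogen = defs$hydrogen[i], acceptor = defs$acceptor[i])
      if (defs$auxiliary[i]) b$auxiliary <- TRUE
      b
    })), config_path)
  }
  invisible(list(paths = paths, config = validate_hbond_defs(defs)))
}
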