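# Shared fixture builders. Everything is generated in code; the only files
# read are the small plain-text reference tables shipped under extdata.

extdata <- function(name) system.file("extdata", name, package = "hairpinfold")

read_reference_patterns <- function(peptide) {
  df <- utils::read.table(extdata("reference_patterns.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  df[df$peptide == peptide, ]
}

read_reference_map <- function(peptide) {
  df <- utils::read.table(extdata(sprintf("reference_transitions_%s.tsv", peptide)),
                          header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  transition_map(percentages = as.matrix(df), states = rownames(df))
}

# Geometry series in which every bond of a frame has a fixed geometry
# determined only by its open/closed character: exact hand-computable
# populations and means.
make_series <- function(chains, closed_d = 2.2, open_d = 6.0,
                        closed_a = 160, open_a = 90) {
  if (!is.list(chains)) chains <- list(chains)
  rows <- lapply(seq_along(chains), function(r) {
    pats <- chains[[r]]
    df <- data.frame(run = r, frame = seq_along(pats))
    for (b in 1:4) {
      ch <- substr(pats, b, b)
      df[[paste0("HB", b, "_dist")]] <- ifelse(ch == "c", closed_d, open_d)
      df[[paste0("HB", b, "_angle")]] <- ifelse(ch == "c", closed_a, open_a)
    }
    df
  })
  geometry_series(do.call(rbind, rows))
}

# A trajectory bundle built directly in memory: 4 bonds, 12 atoms, one
# donor/hydrogen/acceptor triplet per bond.
synthetic_atoms <- function() {
  data.frame(resid = rep(c("GLY", "GLY", "ALA"), 4),
             resno = rep(1:4 * 10, each = 3) + rep(c(1, 1, 2), 4),
             elety = rep(c("N", "HN", "O"), 4),
             stringsAsFactors = FALSE)
}

synthetic_defs <- function() {
  validate_defs <- getFromNamespace("validate_hbond_defs", "hairpinfold")
  validate_defs(data.frame(
    label = paste0("HB", 1:4),
    donor = sprintf("GLY %d N", 1:4 * 10 + 1),
    hydrogen = sprintf("GLY %d HN", 1:4 * 10 + 1),
    acceptor = sprintf("ALA %d O", 1:4 * 10 + 2),
    auxiliary = FALSE, stringsAsFactors = FALSE))
}

# frames: list of 12x3 coordinate matrices (atom order as synthetic_atoms)
bundle_from_frames <- function(frames) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  structure(list(runs = list(list(atoms = synthetic_atoms(), xyz = xyz)),
                 frame_interval = NA_real_),
            class = "trajectory_bundle")
}

# 12x3 coordinates realising the given per-bond (distance, angle) targets,
# each triplet offset so atoms are spatially distinct.
frame_coords <- function(dists, angles) {
  do.call(rbind, lapply(1:4, function(b)
    emit_coordinates(dists[b], angles[b]) +
      matrix(c(0, 0, 20 * b), 3, 3, byrow = TRUE)))
}
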