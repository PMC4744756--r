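#' Read a hydrogen-bond definition config
#'
#' The config is a YAML file with a top-level `bonds:` list; each entry names
#' one hydrogen bond:
#'
#' ```yaml
#' bonds:
#'   - label: HB1
#'     donor:    "ALA 2 N"
#'     hydrogen: "ALA 2 HN"
#'     acceptor: "VAL 9 O"
#'   - label: S3OH
#'     donor:    "SER 3 OG"
#'     hydrogen: "SER 3 HG"
#'     acceptor: "ALA 2 O"
#'     auxiliary: true
#' ```
#'
#' Atom identifiers are `"RESNAME RESID ATOMNAME"` triplets, matched exactly
#' and case-insensitively against the topology. Bonds are returned in
#' declared order; the first four non-auxiliary bonds are the hairpin
#' fingerprint bonds HB1..HB4, any `auxiliary: true` bonds are analysed only
#' for co-occurrence.
#'
#' @param path path to the YAML config.
#' @return data frame of class `hbond_config` with columns `label`, `donor`,
#'   `hydrogen`, `acceptor`, `auxiliary`.
#' @export
read_hbond_config <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("H-bond config not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  bonds <- cfg$bonds %||% cfg
  if (!is.list(bonds) || length(bonds) == 0L)
    abort_config(sprintf("'%s': no bond definitions found", path))
  defs <- do.call(rbind, lapply(bonds, function(b) {
    for (f in c("label", "donor", "hydrogen", "acceptor"))
      if (is.null(b[[f]]))
        abort_config(sprintf("bond definition missing field '%s'", f))
    data.frame(label = as.character(b$label),
               donor = as.character(b$donor),
               hydrogen = as.character(b$hydrogen),
               acceptor = as.character(b$acceptor),
               auxiliary = isTRUE(b$auxiliary),
               stringsAsFactors = FALSE)
  }))
  validate_hbond_defs(defs)
}

validate_hbond_defs <- function(defs) {
  dup <- defs$label[duplicated(defs$label)]
  if (length(dup))
    abort_config(paste("duplicate bond labels:", paste(unique(dup), collapse = ", ")))
  same <- apply(defs[, c("donor", "hydrogen", "acceptor")], 1,
                function(x) any(duplicated(toupper(trimws(x)))))
  if (any(same))
    abort_config(paste("donor, hydrogen and acceptor must be distinct atoms in bond(s):",
                       paste(defs$label[same], collapse = ", ")))
  n_fp <- sum(!defs$auxiliary)
  if (n_fp < 4L)
    abort_config(sprintf(
      "at least 4 non-auxiliary (fingerprint) bonds required, got %d", n_fp))
  class(defs) <- c("hbond_config", "data.frame")
  defs
}

#' Read an MD trajectory into a bundle of runs
#'
#' Each input file becomes one run; multiple files form multiple runs in
#' argument order. The required format is multi-model PDB (`format = "pdb"`,
#' one `MODEL` per frame; a file without `MODEL` records is a single frame).
#' Binary DCD trajectories are supported optionally via `format = "dcd"`
#' with a PDB `topology` file providing atom names. Coordinates are in Å.
#'
#' @param paths one or more trajectory file paths.
#' @param format `"pdb"` (default) or `"dcd"`.
#' @param topology PDB file with the atom records matching the DCD frames
#'   (required for `format = "dcd"`).
#' @param frame_interval time between saved frames in ps (metadata only).
#' @return object of class `trajectory_bundle`: a list with `runs` (each run
#'   a list with `atoms` data frame and an `xyz` frames-by-3N coordinate
#'   matrix) and `frame_interval`.
#' @export
read_trajectory <- function(paths, format = c("pdb", "dcd"), topology = NULL,
                            frame_interval = NA_real_) {
  format <- match.arg(format)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort_io(paste("trajectory file(s) not found:", paste(missing, collapse = ", ")))
  runs <- switch(format,
    pdb = lapply(paths, read_run_pdb),
    dcd = {
      if (is.null(topology))
        abort_config("DCD trajectories require a PDB 'topology' file")
      atoms <- read_run_pdb(topology)$atoms
      lapply(paths, function(p) {
        xyz <- tryCatch(bio3d::read.dcd(p, verbose = FALSE),
                        error = function(e) abort_io(
                          sprintf("cannot read DCD '%s': %s", p, conditionMessage(e))))
        xyz <- matrix(xyz, ncol = ncol(xyz))
        if (ncol(xyz) != 3L * nrow(atoms))
          abort_io(sprintf(
            "DCD '%s' has %d atoms but topology has %d", p, ncol(xyz) / 3, nrow(atoms)))
        list(atoms = atoms, xyz = xyz)
      })
    })
  structure(list(runs = runs, frame_interval = frame_interval),
            class = "trajectory_bundle")
}

# Count ATOM/HETATM records per MODEL block before handing the file to
# bio3d: read.pdb silently recycles coordinates when models have unequal
# atom counts, so the structural error must be raised here.
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(sum(is_atom))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    abort_io(sprintf("'%s': unbalanced MODEL/ENDMDL records", path))
  counts <- vapply(seq_along(starts), function(i)
    sum(is_atom[starts[i]:ends[i]]), integer(1))
  bad <- which(counts != counts[1])
  if (length(bad))
    abort(sprintf(
      "'%s': frame %d has %d atoms, expected %d (inconsistent atom count)",
      path, bad[1], counts[bad[1]], counts[1]), "hairpin_structure_error")
  counts[1]
}

read_run_pdb <- function(path) {
  n_atoms <- check_model_atom_counts(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort_io(
      sprintf("cannot read PDB '%s': %s", path, conditionMessage(e))))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  atoms <- pdb$atom[seq_len(n_atoms), c("resid", "resno", "elety")]
  rownames(atoms) <- NULL
  list(atoms = atoms, xyz = xyz)
}

#' @export
print.trajectory_bundle <- function(x, ...) {
  nf <- vapply(x$runs, function(r) nrow(r$xyz), integer(1))
  cat(sprintf("Trajectory bundle: %d run(s), %s frames, %d atoms\n",
              length(x$runs), paste(nf, collapse = "+"),
              nrow(x$runs[[1]]$atoms)))
  if (!is.na(x$frame_interval))
    cat(sprintf("Frame interval: %g ps\n", x$frame_interval))
  invisible(x)
}

# Resolve "RESNAME RESID ATOMNAME" to a single atom row index.
resolve_atom <- function(atoms, id) {
  parts <- strsplit(trimws(id), "\\s+")[[1]]
  if (length(parts) != 3L)
    abort(sprintf("atom identifier '%s' is not a 'RESNAME RESID ATOMNAME' triplet", id),
          "hairpin_lookup_error")
  hit <- which(toupper(atoms$resid) == toupper(parts[1]) &
               atoms$resno == suppressWarnings(as.integer(parts[2])) &
               toupper(atoms$elety) == toupper(parts[3]))
  if (length(hit) == 0L)
    abort(sprintf("atom identifier '%s' matches no atom", id), "hairpin_lookup_error")
  if (length(hit) > 1L)
    abort(sprintf("atom identifier '%s' is ambiguous (%d matches)", id, length(hit)),
          "hairpin_lookup_error")
  hit
}

#' Reduce a trajectory to per-frame hydrogen-bond geometries
#'
#' For every frame and every defined bond, computes the Euclidean
#' hydrogen--acceptor distance (Å) and the donor--hydrogen--acceptor angle
#' (degrees, 180° = collinear; the angle at the hydrogen between the
#' directions to donor and acceptor).
#'
#' @param bundle a [read_trajectory()] bundle.
#' @param defs an `hbond_config` (see [read_hbond_config()]).
#' @return a [geometry_series()] with one row per frame.
#' @export
extract_geometries <- function(bundle, defs) {
  stopifnot(inherits(bundle, "trajectory_bundle"))
  if (!is.data.frame(defs)) abort_config("'defs' must be an hbond_config data frame")
  defs <- validate_hbond_defs(as.data.frame(defs))
  out <- lapply(seq_along(bundle$runs), function(r) {
    run <- bundle$runs[[r]]
    idx <- lapply(seq_len(nrow(defs)), function(i) c(
      d = resolve_atom(run$atoms, defs$donor[i]),
      h = resolve_atom(run$atoms, defs$hydrogen[i]),
      a = resolve_atom(run$atoms, defs$acceptor[i])))
    res <- data.frame(run = r, frame = seq_len(nrow(run$xyz)))
    for (i in seq_len(nrow(defs))) {
      g <- triplet_geometry(run$xyz, idx[[i]]["d"], idx[[i]]["h"], idx[[i]]["a"])
      res[[paste0(defs$label[i], "_dist")]] <- g$distance
      res[[paste0(defs$label[i], "_angle")]] <- g$angle
    }
    res
  })
  df <- do.call(rbind, out)
  geometry_series(df, fingerprint = defs$label[!defs$auxiliary][1:4])
}

# vectorised over frames: xyz is frames x 3N, k indexes atoms
triplet_geometry <- function(xyz, kd, kh, ka) {
  col3 <- function(k) xyz[, (3L * k - 2L):(3L * k), drop = FALSE]
  D <- col3(kd); H <- col3(kh); A <- col3(ka)
  u <- D - H
  v <- A - H
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  if (any(nu == 0) || any(nv == 0))
    abort_compute("coincident atoms: zero-length bond vector")
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  list(distance = nv, angle = acos(cosang) * 180 / pi)
}
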