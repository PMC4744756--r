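#' Per-frame hydrogen-bond geometry table
#'
#' A geometry series is the reduced representation of a trajectory: one row
#' per frame with columns `run`, `frame`, and, for every named bond `L`,
#' `L_dist` (hydrogen--acceptor distance, Å) and `L_angle`
#' (donor--hydrogen--acceptor angle, degrees). The first four non-auxiliary
#' bonds are the hairpin fingerprint bonds HB1..HB4; any further bonds are
#' auxiliary (e.g. side-chain hydrogen bonds analysed for co-occurrence).
#'
#' @param df data frame with the columns described above.
#' @param fingerprint character vector of the four fingerprint bond labels;
#'   defaults to the first four bonds found in the column names.
#' @return `df` with class `geometry_series` and a `fingerprint` attribute.
#' @export
geometry_series <- function(df, fingerprint = NULL) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    abort_config("geometry series must be a non-empty data frame")
  if (!all(c("run", "frame") %in% names(df)))
    abort_config("geometry series requires 'run' and 'frame' columns")
  labels <- bond_labels(df)
  if (length(labels) == 0L)
    abort_config("no '<label>_dist'/'<label>_angle' column pairs found")
  miss <- setdiff(c(paste0(labels, "_dist"), paste0(labels, "_angle")), names(df))
  if (length(miss))
    abort_config(paste("missing geometry columns:", paste(miss, collapse = ", ")))
  fingerprint <- fingerprint %||% labels[seq_len(min(4L, length(labels)))]
  if (length(fingerprint) != 4L)
    abort_config("exactly 4 fingerprint bonds are required for the hairpin analysis")
  if (!all(fingerprint %in% labels))
    abort_config("fingerprint labels not present in the series")
  for (lab in labels) {
    d <- df[[paste0(lab, "_dist")]]
    a <- df[[paste0(lab, "_angle")]]
    if (any(!is.finite(d)) || any(d <= 0))
      abort_config(sprintf("bond '%s': distances must be positive and finite", lab))
    if (any(!is.finite(a)) || any(a < 0 | a > 180))
      abort_config(sprintf("bond '%s': angles must lie in [0, 180] degrees", lab))
  }
  ord_ok <- all(unlist(tapply(df$frame, df$run, function(f) all(diff(f) > 0))))
  if (!ord_ok)
    abort_config("frame indices must be strictly increasing within each run")
  structure(df, fingerprint = fingerprint,
            class = unique(c("geometry_series", class(df))))
}

#' Bond labels present in a geometry series
#'
#' @param series a geometry series (or plain data frame with geometry columns).
#' @return character vector of bond labels, in column order.
#' @export
bond_labels <- function(series) {
  nm <- names(series)
  sub("_dist$", "", grep("_dist$", nm, value = TRUE))
}

#' Fingerprint bond labels of a geometry series
#'
#' @inheritParams bond_labels
#' @return the four fingerprint bond labels.
#' @export
fingerprint_labels <- function(series) {
  fp <- attr(series, "fingerprint", exact = TRUE)
  if (is.null(fp)) {
    labels <- bond_labels(series)
    if (length(labels) < 4L)
      abort_config("geometry series has fewer than 4 bonds")
    fp <- labels[1:4]
  }
  fp
}

#' Auxiliary (non-fingerprint) bond labels of a geometry series
#'
#' @inheritParams bond_labels
#' @return character vector, possibly empty.
#' @export
auxiliary_labels <- function(series) {
  setdiff(bond_labels(series), fingerprint_labels(series))
}

#' @export
print.geometry_series <- function(x, ...) {
  labels <- bond_labels(x)
  cat(sprintf("Geometry series: %d frames, %d run(s), bonds: %s\n",
              nrow(x), length(unique(x$run)), paste(labels, collapse = ", ")))
  cat(sprintf("Fingerprint bonds: %s\n",
              paste(fingerprint_labels(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a geometry series to a tab-separated file
#'
#' Columns: `run`, `frame`, then `<label>_dist`, `<label>_angle` per bond.
#' Values are written at full precision.
#'
#' @param series a [geometry_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_table <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a geometry series from a tab-separated file
#'
#' @param path file written by [write_geometry_table()] (or equivalent:
#'   header row naming `run`, `frame` and `<label>_dist`/`<label>_angle`
#'   column pairs).
#' @param fingerprint optional fingerprint labels (default: first four bonds).
#' @return a [geometry_series()].
#' @export
read_geometry_table <- function(path, fingerprint = NULL) {
  if (!file.exists(path))
    abort_io(sprintf("geometry table not found: '%s'", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  geometry_series(df, fingerprint = fingerprint)
}
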