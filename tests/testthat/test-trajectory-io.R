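test_that("extract_geometries reproduces hand-constructed geometries", {
  # collinear: donor (0,0,0), hydrogen (1,0,0), acceptor (3,0,0)
  f1 <- frame_coords(rep(2, 4), rep(180, 4))
  # right angle: acceptor at (1,0,2) relative to donor/hydrogen axis
  f2 <- frame_coords(rep(2, 4), rep(90, 4))
  series <- extract_geometries(bundle_from_frames(list(f1, f2)),
                               synthetic_defs())
  expect_equal(nrow(series), 2L)
  for (b in paste0("HB", 1:4)) {
    expect_equal(series[[paste0(b, "_dist")]], c(2, 2), tolerance = 1e-12)
    expect_equal(series[[paste0(b, "_angle")]], c(180, 90), tolerance = 1e-9)
  }
})

test_that("geometries agree with a brute-force vector oracle on random placements", {
  set.seed(42)
  n <- 100
  frames <- list()
  expected <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) {
    m <- matrix(stats::rnorm(36, sd = 3), 12, 3)
    frames[[i]] <- m
    for (b in 1:4) {
      D <- m[3 * b - 2, ]; H <- m[3 * b - 1, ]; A <- m[3 * b, ]
      # oracle: direct arccos of the normalised dot product, scalar math
      u <- D - H; v <- A - H
      cosang <- sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2))
      expected[i, b] <- sqrt(sum((A - H)^2))
      expected[i, 4 + b] <- acos(max(-1, min(1, cosang))) * 180 / pi
    }
  }
  series <- extract_geometries(bundle_from_frames(frames), synthetic_defs())
  for (b in 1:4) {
    expect_equal(series[[paste0("HB", b, "_dist")]], expected[, b],
                 tolerance = 1e-9)
    expect_equal(series[[paste0("HB", b, "_angle")]], expected[, 4 + b],
                 tolerance = 1e-9)
  }
})

test_that("distances and angles are invariant under rigid rotation + translation", {
  set.seed(7)
  base <- matrix(stats::rnorm(36, sd = 2), 12, 3)
  # random rotation from QR of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- matrix(c(5, -3, 11), 12, 3, byrow = TRUE)
  moved <- base %*% R + shift
  s1 <- extract_geometries(bundle_from_frames(list(base)), synthetic_defs())
  s2 <- extract_geometries(bundle_from_frames(list(moved)), synthetic_defs())
  geom_cols <- grep("_(dist|angle)$", names(s1), value = TRUE)
  for (cl in geom_cols)
    expect_equal(s1[[cl]], s2[[cl]], tolerance = 1e-9)
})

test_that("swapping donor and acceptor roles preserves the angle by construction", {
  fwd <- frame_coords(rep(2, 4), rep(120, 4))
  swapped <- fwd
  for (b in 1:4) {  # swap rows of donor and acceptor within each triplet
    swapped[3 * b - 2, ] <- fwd[3 * b, ]
    swapped[3 * b, ] <- fwd[3 * b - 2, ]
  }
  # donor arm is length 1, acceptor arm length 2: after the swap the
  # distance changes (1 not 2) but the angle at the hydrogen is unchanged
  s1 <- extract_geometries(bundle_from_frames(list(fwd)), synthetic_defs())
  s2 <- extract_geometries(bundle_from_frames(list(swapped)), synthetic_defs())
  expect_equal(s1$HB1_angle, s2$HB1_angle, tolerance = 1e-9)
  expect_equal(s2$HB1_dist, 1, tolerance = 1e-9)
  expect_equal(s1$HB1_dist, 2, tolerance = 1e-9)
})

test_that("multi-model PDB round trip preserves frame structure and geometry", {
  spec <- markov_spec(c("oooo", "cccc"),
                      matrix(c(.5, .5, .5, .5), 2, byrow = TRUE),
                      n_runs = 1, n_frames_per_run = 5, seed = 3)
  series <- emit_geometries(generate_pattern_chain(spec), seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  res <- write_synthetic_pdb(series, pdb, config_path = cfg)
  defs <- read_hbond_config(cfg)
  expect_equal(defs$label, paste0("HB", 1:4))
  bundle <- read_trajectory(pdb)
  expect_length(bundle$runs, 1L)
  expect_equal(nrow(bundle$runs[[1]]$xyz), 5L)
  back <- extract_geometries(bundle, defs)
  # PDB fixed-format coordinates have 3 decimals: recovery to ~1e-2
  for (b in paste0("HB", 1:4)) {
    expect_equal(back[[paste0(b, "_dist")]], series[[paste0(b, "_dist")]],
                 tolerance = 1e-2)
    expect_equal(back[[paste0(b, "_angle")]], series[[paste0(b, "_angle")]],
                 tolerance = 1e-1)
  }
})

test_that("each trajectory file becomes one run, in argument order", {
  chains <- list(rep("cccc", 3), rep("oooo", 4), rep("cocc", 2))
  series <- emit_geometries(chains, seed = 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  res <- write_synthetic_pdb(series, pdb)
  expect_length(res$paths, 3L)
  bundle <- read_trajectory(res$paths)
  expect_length(bundle$runs, 3L)
  expect_equal(vapply(bundle$runs, function(r) nrow(r$xyz), integer(1)),
               c(3L, 4L, 2L))
})

test_that("a model with a missing atom raises a structural error naming the frame", {
  series <- emit_geometries(list(rep("cccc", 3)), seed = 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(series, pdb)
  lines <- readLines(pdb)
  atom_idx <- grep("^ATOM", lines)
  # drop one atom from the second model (atoms 13..24)
  writeLines(lines[-atom_idx[15]], pdb)
  expect_error(read_trajectory(pdb), "frame 2",
               class = "hairpin_structure_error")
})

test_that("missing files and unresolvable atoms raise labelled errors", {
  expect_error(read_trajectory("/nonexistent/file.pdb"), "not found",
               class = "hairpin_io_error")
  f <- frame_coords(rep(2, 4), rep(150, 4))
  bundle <- bundle_from_frames(list(f))
  defs <- synthetic_defs()
  defs$donor[1] <- "TRP 99 N"
  expect_error(extract_geometries(bundle, defs), "TRP 99 N",
               class = "hairpin_lookup_error")
  # ambiguous: duplicate atom entry
  b2 <- bundle
  b2$runs[[1]]$atoms$resno[4] <- 11  # second bond's donor now collides with first
  expect_error(extract_geometries(b2, synthetic_defs()), "ambiguous",
               class = "hairpin_lookup_error")
})

test_that("H-bond configs are validated", {
  cfg <- extdata("hbond_config.yaml")
  defs <- read_hbond_config(cfg)
  expect_s3_class(defs, "hbond_config")
  expect_equal(defs$label, paste0("HB", 1:4))
  expect_equal(defs$acceptor[1], "VAL 9 O")
  expect_false(any(defs$auxiliary))

  dup <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(bonds = rep(list(list(
    label = "HB1", donor = "A 1 N", hydrogen = "A 1 H",
    acceptor = "B 2 O")), 4)), dup)
  expect_error(read_hbond_config(dup), "duplicate",
               class = "hairpin_config_error")

  few <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(bonds = lapply(1:3, function(i) list(
    label = paste0("HB", i), donor = sprintf("A %d N", i),
    hydrogen = sprintf("A %d H", i), acceptor = sprintf("B %d O", i)))), few)
  expect_error(read_hbond_config(few), "non-auxiliary",
               class = "hairpin_config_error")

  # four fingerprint bonds plus an auxiliary fifth is accepted
  aux <- withr::local_tempfile(fileext = ".yaml")
  bonds <- lapply(1:4, function(i) list(
    label = paste0("HB", i), donor = sprintf("A %d N", i),
    hydrogen = sprintf("A %d H", i), acceptor = sprintf("B %d O", i)))
  bonds[[5]] <- list(label = "S3OH", donor = "SER 3 OG",
                     hydrogen = "SER 3 HG", acceptor = "ALA 2 O",
                     auxiliary = TRUE)
  yaml::write_yaml(list(bonds = bonds), aux)
  defs5 <- read_hbond_config(aux)
  expect_equal(nrow(defs5), 5L)
  expect_equal(sum(defs5$auxiliary), 1L)
  expect_equal(defs5$label[5], "S3OH")
})

test_that("geometry tables round-trip through TSV", {
  series <- emit_geometries(list(c("cocc", "cccc", "oooo")), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_table(series, f)
  back <- read_geometry_table(f)
  expect_equal(as.data.frame(back), as.data.frame(series), tolerance = 1e-12)
  expect_equal(fingerprint_labels(back), paste0("HB", 1:4))
})
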