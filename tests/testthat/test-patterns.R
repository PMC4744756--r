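test_that("hydrogen-bond classification applies both criteria with inclusive boundaries", {
  expect_equal(classify_hbond(2.2, 160), "c")
  expect_equal(classify_hbond(2.2, 100), "o")   # angle below the lower limit
  expect_equal(classify_hbond(3.5, 160), "o")   # distance above the cutoff
  expect_equal(classify_hbond(3.0, 120), "c")   # both boundaries inclusive
  expect_equal(classify_hbond(c(2, 4), c(150, 150)), c("c", "o"))
  expect_error(classify_hbond(NaN, 150), class = "hairpin_config_error")
  expect_error(classify_hbond(2, Inf), class = "hairpin_config_error")
})

test_that("classification is monotone in distance and angle", {
  set.seed(11)
  d <- runif(300, 0.5, 6)
  a <- runif(300, 0, 180)
  closed <- classify_hbond(d, a) == "c"
  # decreasing distance or increasing angle never flips closed -> open
  closer <- classify_hbond(pmax(d - runif(300, 0, 2), 1e-3), a) == "c"
  expect_true(all(closer[closed]))
  straighter <- classify_hbond(d, pmin(a + runif(300, 0, 40), 180)) == "c"
  expect_true(all(straighter[closed]))
})

test_that("pattern labels map bond states in HB1..HB4 order", {
  expect_equal(assign_pattern(c("c", "o", "o", "c")), "cooc")
  expect_equal(assign_pattern(rep(TRUE, 4)), "cccc")
  expect_equal(assign_pattern(rep("open", 4)), "oooo")
  expect_error(assign_pattern(c("c", "o")), class = "hairpin_config_error")
  expect_error(assign_pattern(c("c", "o", "x", "c")),
               class = "hairpin_config_error")
})

test_that("there are exactly 16 patterns for four bonds", {
  pats <- all_patterns()
  expect_length(pats, 16L)
  expect_length(unique(pats), 16L)
  expect_true(all(nchar(pats) == 4L))
  expect_equal(pats[1], "oooo")
  expect_equal(pats[16], "cccc")
  expect_true(all(c("cooc", "cocc", "ccoc", "oooc") %in% pats))
})

test_that("folded classification uses the strict mean rule", {
  r <- classify_folded(c(5.87, 9.67, 8.06, 5.00))
  expect_equal(r$mean, 7.15, tolerance = 1e-12)
  expect_false(r$folded)
  r <- classify_folded(c(2.40, 3.70, 2.17, 2.13))
  expect_equal(r$mean, 2.60, tolerance = 1e-12)
  expect_true(r$folded)
  # boundary case: mean exactly at the threshold is unfolded
  r <- classify_folded(c(2.26, 3.72, 3.83, 2.19))
  expect_equal(r$mean, 3.00, tolerance = 1e-12)
  expect_false(r$folded)
  expect_error(classify_folded(c(2, 2, NA, 2)), class = "hairpin_config_error")
})

test_that("printed reference rows are reproduced: averages to 0.01 A, flags exactly", {
  for (pep in c("ser3", "abu3")) {
    ref <- read_reference_patterns(pep)
    expect_equal(nrow(ref), 6L)
    for (i in seq_len(nrow(ref))) {
      r <- classify_folded(as.numeric(ref[i, c("HB1", "HB2", "HB3", "HB4")]))
      expect_lt(abs(r$mean - ref$average[i]), 0.01 + 1e-9)
      expect_equal(r$folded, ref$folded[i] == "f")
    }
  }
})

test_that("pattern table populations and means match hand counts", {
  s <- make_series(rep("cccc", 4))
  tab <- pattern_table(s)
  expect_equal(nrow(tab), 16L)
  expect_equal(tab$population[tab$pattern == "cccc"], 100)
  expect_equal(sum(tab$n_frames), 4L)

  s <- make_series(c("cccc", "cccc", "oooo", "oooo"),
                   closed_d = 2.0, open_d = 8.0)
  tab <- pattern_table(s)
  expect_equal(tab$population[tab$pattern == "cccc"], 50)
  expect_equal(tab$population[tab$pattern == "oooo"], 50)
  expect_equal(unlist(tab[tab$pattern == "cccc", paste0("HB", 1:4)]),
               rep(2, 4), ignore_attr = TRUE)
  expect_equal(unlist(tab[tab$pattern == "oooo", paste0("HB", 1:4)]),
               rep(8, 4), ignore_attr = TRUE)
  expect_true(tab$folded[tab$pattern == "cccc"])
  expect_false(tab$folded[tab$pattern == "oooo"])
  expect_true(all(is.na(tab$average[tab$n_frames == 0])))
  # unrounded populations sum to 100 exactly
  expect_equal(sum(tab$population), 100, tolerance = 1e-12)
})

test_that("populations of a long chain match the analytic stationary distribution", {
  spec <- read_markov_spec(extdata("markov_ser3.yaml"), seed = 20260930)
  chains <- generate_pattern_chain(spec)         # 11 x 5000 frames
  series <- emit_geometries(chains, seed = 101)
  tab <- pattern_table(series)
  pi <- stationary_distribution(spec$transition_matrix)
  n <- sum(tab$n_frames)
  for (st in spec$states) {
    obs <- tab$population[tab$pattern == st] / 100
    # frames are autocorrelated: use the empirical between-run SE, floored
    # by the iid binomial SE
    per_run <- vapply(chains, function(x) mean(x == st), numeric(1))
    se <- max(stats::sd(per_run) / sqrt(length(per_run)),
              sqrt(pi[st] * (1 - pi[st]) / n))
    expect_lt(abs(obs - pi[st]), 3 * se)
  }
  expect_equal(sum(tab$population), 100, tolerance = 1e-9)
})

test_that("folding ratio aggregates folded-pattern populations", {
  # folded patterns at 40% and 20%, unfolded at 40% -> 60%
  chains <- c(rep("cccc", 40), rep("cocc", 20), rep("oooo", 40))
  s <- make_series(chains, closed_d = 2.0, open_d = 4.0)
  # cocc mean = (2+4+2+2)/4 = 2.5 -> folded; oooo mean 4 -> unfolded
  tab <- pattern_table(s)
  fs <- overall_folding_ratio(tab, s)
  expect_equal(fs$pattern_level, 60)
  # identical geometry within each pattern: frame-level agrees exactly
  expect_equal(fs$frame_level, fs$pattern_level)

  only_closed <- pattern_table(make_series(rep("cccc", 10)))
  expect_equal(overall_folding_ratio(only_closed)$pattern_level, 100)
})

test_that("pattern-level folded set matches the prediction from emission means", {
  params <- emission_params()
  spec <- read_markov_spec(extdata("markov_ser3.yaml"),
                           n_runs = 4, n_frames_per_run = 4000, seed = 88)
  series <- emit_geometries(generate_pattern_chain(spec), params, seed = 88)
  tab <- pattern_table(series)
  occupied <- tab$pattern[tab$n_frames >= 50]
  for (st in occupied) {
    pred <- classify_folded(ifelse(strsplit(st, "")[[1]] == "c",
                                   params$closed_dist_mean,
                                   params$open_dist_mean))$folded
    expect_equal(tab$folded[tab$pattern == st], pred,
                 info = paste("pattern", st))
  }
})

test_that("auxiliary co-occurrence recovers exact and planted frequencies", {
  chains <- c(rep("cocc", 3), rep("cccc", 5), rep("oooo", 2))
  s <- make_series(chains)
  # attach an aux bond closed exactly on the cocc frames
  s$S3OH_dist <- ifelse(chains == "cocc", 2.0, 6.0)
  s$S3OH_angle <- ifelse(chains == "cocc", 170, 80)
  s <- geometry_series(as.data.frame(s), fingerprint = paste0("HB", 1:4))
  cc <- auxiliary_cooccurrence(s)
  expect_equal(cc$overall[["S3OH"]], 30)  # = population of cocc
  expect_equal(cc$conditional["S3OH", "cocc"], 100)
  expect_equal(cc$conditional["S3OH", "cccc"], 0)
  expect_true(is.na(cc$conditional["S3OH", "ccoc"]))

  # aux bond never closed
  s$S3OH_dist <- 6.0
  cc0 <- auxiliary_cooccurrence(s)
  expect_equal(unname(cc0$overall), 0)
  expect_true(all(cc0$conditional[!is.na(cc0$conditional)] == 0))

  # misaligned separate aux series
  aux <- as.data.frame(s)[1:5, ]
  expect_error(auxiliary_cooccurrence(s, aux = "S3OH", aux_series = aux),
               class = "hairpin_alignment_error")

  # planted closure probabilities: 0.5 inside cocc, 0.1 elsewhere
  set.seed(202)
  n <- 8000
  pats <- sample(c("cocc", "cccc", "oooo"), n, TRUE, prob = c(.5, .3, .2))
  s2 <- make_series(pats)
  p_closed <- ifelse(pats == "cocc", 0.5, 0.1)
  closed <- stats::runif(n) < p_closed
  s2$AUX_dist <- ifelse(closed, 2.2, 6.0)
  s2$AUX_angle <- ifelse(closed, 160, 90)
  s2 <- geometry_series(as.data.frame(s2), fingerprint = paste0("HB", 1:4))
  cc2 <- auxiliary_cooccurrence(s2)
  for (st in c("cocc", "cccc", "oooo")) {
    m <- sum(pats == st)
    p <- if (st == "cocc") 0.5 else 0.1
    se <- sqrt(p * (1 - p) / m)
    expect_lt(abs(cc2$conditional["AUX", st] / 100 - p), 3 * se)
  }
})
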