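test_that("trait patterns are unit-norm, near-orthogonal and seeded", {
  parc <- make_parcellation(100)

  p1 <- generate_trait_patterns(parc, n_traits = 1, seed = 5)
  expect_equal(sqrt(sum(p1^2)), 1.0)

  p5 <- generate_trait_patterns(parc, n_traits = 5, seed = 5)
  expect_equal(dim(p5), c(5, 4950))
  expect_equal(sqrt(rowSums(p5^2)), rep(1, 5))
  gram <- p5 %*% t(p5)
  expect_true(all(abs(gram[upper.tri(gram)]) < 0.3))

  expect_identical(p5, generate_trait_patterns(parc, n_traits = 5,
                                               seed = 5))

  # infeasible orthogonality budget signals n_traits too large
  tiny <- make_parcellation(22)
  expect_error(
    generate_trait_patterns(tiny, n_traits = 120, seed = 1,
                            max_cosine = 0.05, max_tries = 3),
    "near-orthogonal")
})

test_that("weight generation plants the group effect and session jitter", {
  gw <- generate_weights(c("PD-MCI" = 23, "PD-CN" = 19, "HC" = 21),
                         n_traits = 5, seed = 2)
  expect_equal(dim(gw$weights), c(126, 5))
  expect_equal(sum(gw$index$session == "monoband"), 63)
  expect_equal(as.vector(table(gw$index$group)[c("PD-MCI", "PD-CN", "HC")]),
               c(46, 38, 42))

  # zero jitter: both sessions of a subject carry identical weights
  gw0 <- generate_weights(c(A = 4, B = 3), n_traits = 2,
                          session_effect_sd = 0, seed = 3)
  mono <- gw0$weights[gw0$index$session == "monoband", ]
  multi <- gw0$weights[gw0$index$session == "multiband", ]
  expect_identical(mono, multi)

  # planted shift moves the effect group's mean by effect_size on average
  expect_equal(mean(gw$weights[gw$index$group == "PD-MCI", 1]) -
                 mean(gw$weights[gw$index$group != "PD-MCI", 1]),
               1.5, tolerance = 0.5)

  expect_error(generate_weights(c(A = 4), effect_group = "Z"), "unknown")
  expect_error(generate_weights(c(A = 4), session_effect_sd = -1), ">= 0")
})

test_that("a null effect leaves groups exchangeable", {
  diffs <- vapply(1:100, function(s) {
    gw <- generate_weights(c(A = 10, B = 10), n_traits = 1,
                           effect_size = 0, seed = s)
    mean(gw$weights[gw$index$group == "A", 1]) -
      mean(gw$weights[gw$index$group == "B", 1])
  }, numeric(1))
  # mean of per-seed mean differences ~ N(0, ~0.32/10): 4 SE band
  expect_lt(abs(mean(diffs)), 4 * 0.32 / 10)
})

test_that("synthetic FC is the bounded map of the planted mixture", {
  parc <- make_parcellation(30)
  pat <- generate_trait_patterns(parc, 1, seed = 4)
  gw <- generate_weights(c(A = 2), n_traits = 1, session_effect_sd = 0,
                         effect_size = 0, seed = 4)
  sf <- synthesize_fc(pat, gw$weights, gw$index, edge_noise_sd = 0,
                      seed = 4)
  # noiseless single trait: edge vector is exactly tanh(w * pattern)
  expect_equal(sf$edges[1, ], tanh(gw$weights[1, 1] * pat[1, ]),
               ignore_attr = TRUE, tolerance = 1e-14)

  for (fc in sf$fc) {
    expect_identical(fc$values, t(fc$values))
    expect_equal(diag(fc$values), rep(1, 30), ignore_attr = TRUE)
    expect_true(all(abs(fc$values[upper.tri(fc$values)]) < 1))
  }
})

test_that("edge noise degrades the planted-signal correlation monotonically", {
  parc <- make_parcellation(30)
  pat <- generate_trait_patterns(parc, 3, seed = 6)
  gw <- generate_weights(c(A = 6, B = 6), n_traits = 3, seed = 6)
  sds <- c(0, 0.05, 0.2, 0.8)
  cors <- vapply(sds, function(sd) {
    mean(vapply(1:5, function(s) {
      sf <- synthesize_fc(pat, gw$weights, gw$index, sd, seed = 100 + s)
      stats::cor(as.vector(sf$composite), as.vector(sf$noisy))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cors[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(cors) < 0))
})

test_that("edge-noise calibration hits the target signal fraction", {
  parc <- make_parcellation(50)
  pat <- generate_trait_patterns(parc, 4, seed = 7)
  gw <- generate_weights(c(A = 10, B = 10), n_traits = 4, seed = 7)
  sd <- calibrate_edge_noise(pat, gw$weights, target_r2 = 0.5)
  sf <- synthesize_fc(pat, gw$weights, gw$index, sd, seed = 7)
  sig <- mean(apply(sf$composite, 2, stats::var))
  tot <- mean(apply(sf$noisy, 2, stats::var))
  expect_equal(sig / tot, 0.5, tolerance = 0.05)
})

test_that("synthetic time series realize the target correlation", {
  # independence: identity target leaves pairwise correlations near zero
  ts <- synthesize_timeseries(diag(20), 500, seed = 8)
  r <- stats::cor(ts$values)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 3 / sqrt(500)), 0.97)
  expect_equal(ts$correction, 0)

  # a PD target is matched to Monte-Carlo accuracy at T = 10000
  set.seed(9)
  a <- matrix(rnorm(15 * 15), 15)
  target <- stats::cov2cor(crossprod(a) + 5 * diag(15))
  ts <- synthesize_timeseries(target, 10000, seed = 9)
  emp <- stats::cor(ts$values)
  expect_lte(mean(abs(emp[upper.tri(emp)] - target[upper.tri(target)])),
             0.05)

  # determinism under the seed
  ts2 <- synthesize_timeseries(target, 100, seed = 10)
  ts3 <- synthesize_timeseries(target, 100, seed = 10)
  expect_identical(ts2$values, ts3$values)
  expect_error(synthesize_timeseries(matrix(0, 2, 3), 10), "square")
})

test_that("clinical table links outcomes to the planted trait weights", {
  gw <- generate_weights(c("PD-MCI" = 15, "PD-CN" = 12, "HC" = 12),
                         n_traits = 2, seed = 11)
  clin <- synthesize_clinical(gw$weights, gw$index, effect_trait = 1,
                              seed = 11)
  expect_equal(nrow(clin), 39)

  # HC carry exactly zero on the motor scale (not-acquired coding)
  expect_true(all(clin$mds_updrs_iii[clin$group == "HC"] == 0))
  expect_true(all(clin$mds_updrs_iii[clin$group != "HC"] != 0))

  # raw scores back-compute from z via control stats: recomputing z from
  # raw recovers the generated composites' two-test mean structure
  zs <- compute_zscores(clin, default_control_stats())
  mw <- vapply(clin$subject_id, function(s) {
    mean(gw$weights[gw$index$subject == s, 1])
  }, numeric(1))
  # strong negative default link for memory/attention
  expect_lt(stats::cor(zs$composites$attention, mw), -0.3)
  expect_error(
    synthesize_clinical(gw$weights, gw$index,
                        control_stats = data.frame(test = "moca",
                                                   mean = 26, sd = 3)),
    "missing control_stats")
  expect_error(
    synthesize_clinical(gw$weights, gw$index,
                        coeff_map = list(nonsense = 1)),
    "unknown coeff_map")
})

test_that("cohorts are deterministic and satisfy FC invariants", {
  co1 <- small_cohort(seed = 21)
  co2 <- small_cohort(seed = 21)
  expect_identical(co1$group$matrix, co2$group$matrix)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$ground_truth$trait_patterns,
                   co2$ground_truth$trait_patterns)
  expect_equal(nrow(co1$group$matrix), 32)  # 16 subjects x 2 sessions

  fc <- co1$fc[[1]]$values
  expect_identical(fc, t(fc))
  expect_equal(diag(fc), rep(1, 40), ignore_attr = TRUE)
})

test_that("written cohorts round-trip through the on-disk layout", {
  co <- simulate_cohort(group_sizes = c(A = 2, B = 2), n_roi = 20,
                        n_traits = 2, include_timeseries = TRUE,
                        n_timepoints = 60, seed = 31)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "parcellation.tsv")))
  expect_length(list.files(file.path(dir, "timeseries")), 8)
  expect_length(list.files(file.path(dir, "motion")), 8)
  ts <- read_timeseries(file.path(dir, "timeseries", "A_01_monoband.tsv"))
  expect_equal(dim(ts), c(60, 20))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$effect_trait_index, 1)
  expect_equal(do.call(rbind, lapply(seq_len(2), function(i)
    gt$trait_patterns[i, ])), co$ground_truth$trait_patterns,
    tolerance = 1e-12, ignore_attr = TRUE)
})
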