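test_that("z-scoring follows the control-referenced formula and mean-of-two composites", {
  cs <- data.frame(test = c("span_inverse", "digit_symbol", "trail_making",
                            "phonemic_fluency", "ravlt", "rocf",
                            "semantic_fluency", "boston_naming",
                            "vosp_objects", "vosp_numeric"),
                   mean = 10, sd = 2)
  raw <- data.frame(subject_id = c("s1", "s2"))
  for (t in cs$test) raw[[t]] <- c(10, 8)
  zs <- compute_zscores(raw, cs)

  expect_equal(unname(unlist(zs$z["s1" == zs$z$subject_id, cs$test])),
               rep(0, 10))            # raw at control mean
  expect_equal(zs$z$ravlt[2], -1.0)   # raw 8, mean 10, sd 2

  # domain composite is the unweighted mean of its two test z-scores
  raw$span_inverse <- 10 + 2 * c(-0.343, -0.343)
  raw$digit_symbol <- 10 + 2 * c(-0.346, -0.346)
  zs <- compute_zscores(raw, cs)
  expect_equal(zs$composites$attention, c(-0.3445, -0.3445))

  expect_error(compute_zscores(raw, transform(cs, sd = 0)), "positive")
  expect_error(compute_zscores(raw[-2], cs), "missing")
})

test_that("MCI classification applies the 1.5 SD / two-test rule strictly", {
  cs <- data.frame(test = unique(unlist(cognitive_domains())),
                   mean = 0, sd = 1)
  tests <- cs$test
  z_fix <- matrix(0, 12, 10, dimnames = list(NULL, tests))
  # s2: two impaired tests in one domain -> MCI
  z_fix[2, c("span_inverse", "digit_symbol")] <- -1.6
  # s3: two impaired tests across domains -> MCI
  z_fix[3, c("ravlt", "boston_naming")] <- c(-2.0, -1.51)
  # s4: one deeply impaired test only -> CN
  z_fix[4, "trail_making"] <- -2.5
  # s5: exactly at the threshold is not impaired -> CN
  z_fix[5, c("ravlt", "rocf")] <- -1.5
  # s6: one at threshold + one beyond -> CN (only one strict impairment)
  z_fix[6, c("ravlt", "rocf")] <- c(-1.5, -1.6)
  # s7: three impaired -> MCI
  z_fix[7, c("ravlt", "rocf", "moca_dummy" = "trail_making")] <- -1.7
  # s8-s12 random mild scores, none below -1.5
  z_fix[8:12, ] <- runif(50, -1.4, 0.5)

  raw <- data.frame(subject_id = sprintf("s%d", 1:12))
  for (t in tests) raw[[t]] <- z_fix[, t]  # mean 0 sd 1: raw == z
  res <- classify_mci(compute_zscores(raw, cs))
  expect_equal(res$status,
               c("CN", "MCI", "MCI", "CN", "CN", "CN", "MCI",
                 rep("CN", 5)))
  expect_equal(res$n_impaired[7], 3L)
  expect_match(res$impaired_tests[2], "span_inverse,digit_symbol")
})

test_that("rmANOVA group F reduces to classical one-way ANOVA on subject means", {
  set.seed(2)
  gw <- generate_weights(c(A = 10, B = 10), n_traits = 1,
                         effect_size = 0.8, seed = 2)
  subjects <- make_subject_table(gw$index, seed = 2)
  res <- rm_anova_trait(gw$weights[, 1], gw$index, subjects,
                        covariates = character(0))

  # independent closed-form one-way ANOVA on session means
  means <- tapply(gw$weights[, 1],
                  gw$index$subject, mean)
  grp <- subjects$group[match(names(means), subjects$subject_id)]
  gm <- mean(means)
  ssb <- sum(tapply(means, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum((means - ave(means, grp))^2)
  f_oracle <- (ssb / 1) / (ssw / 18)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 18)

  # identical weights for every row: no between-group variance
  flat <- rm_anova_trait(rep(0.7, 40), gw$index, subjects,
                         covariates = character(0))
  expect_equal(flat$f, 0)

  subjects$age <- 50
  expect_error(rm_anova_trait(gw$weights[, 1], gw$index, subjects,
                              covariates = "age"), "age")
})

test_that("BH adjustment matches the step-up oracle and flags correctly", {
  expect_equal(fdr_adjust(0.03)$q_values, 0.03)

  p <- c(0.001, 0.02, 0.03, 0.04, 0.2)
  res <- fdr_adjust(p, q = 0.05)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_identical(fdr_adjust(p)$q_values, oracle_bh(p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise post-hoc F equals squared t for the simple design", {
  set.seed(4)
  gw <- generate_weights(c(A = 9, B = 8, C = 7), n_traits = 1,
                         effect_size = 1, seed = 4)
  subjects <- make_subject_table(gw$index, seed = 4)
  res <- posthoc_pairwise(gw$weights[, 1], gw$index, subjects,
                          c("A", "B"), covariates = character(0))
  means <- tapply(gw$weights[, 1], gw$index$subject, mean)
  grp <- subjects$group[match(names(means), subjects$subject_id)]
  tt <- t.test(means[grp == "A"], means[grp == "B"], var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # one subject per group: NA rather than a silent number
  tiny_idx <- gw$index[gw$index$subject %in% c("A_01", "B_01"), ]
  tiny_sub <- subjects[subjects$subject_id %in% c("A_01", "B_01"), ]
  deg <- posthoc_pairwise(gw$weights[gw$index$subject %in%
                                       c("A_01", "B_01"), 1],
                          tiny_idx, tiny_sub, c("A", "B"),
                          covariates = character(0))
  expect_true(is.na(deg$f) && is.na(deg$p))
  expect_error(posthoc_pairwise(gw$weights[, 1], gw$index, subjects,
                                c("A", "Z")), "not present")
})

test_that("post-hoc p-values are uniform under permuted group labels", {
  set.seed(5)
  gw <- generate_weights(c(A = 12, B = 12), n_traits = 1,
                         effect_size = 0, seed = 5)
  subjects <- make_subject_table(gw$index, seed = 5)
  pvals <- vapply(1:400, function(i) {
    subjects$group <- sample(subjects$group)
    posthoc_pairwise(gw$weights[, 1], gw$index, subjects, c("A", "B"),
                     covariates = character(0))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("nested-model F matches an RSS oracle and guards collinearity", {
  set.seed(6)
  n <- 60
  for (i in 1:50) {
    data <- data.frame(age = rnorm(n, 70, 5),
                       sequence = sample(c("monoband", "multiband"), n,
                                         replace = TRUE),
                       avg_enorm = abs(rnorm(n, 0.1, 0.03)),
                       tgm = rnorm(n, 620, 40),
                       etiv = rnorm(n, 1500, 100),
                       cognition = rnorm(n))
    w <- rnorm(n) + 0.3 * data$cognition
    res <- nested_model_f(w, data, "cognition")
    x0 <- stats::model.matrix(~ age + sequence + avg_enorm + tgm + etiv,
                              data)
    x1 <- cbind(x0, data$cognition)
    oracle <- oracle_partial_f(w, x0, x1)
    expect_equal(res$f, oracle$f, tolerance = 1e-8)
    expect_equal(res$p, oracle$p, tolerance = 1e-8)
    # the overall augmented-model F against the intercept-only model
    oracle_all <- oracle_partial_f(w, x1[, 1, drop = FALSE], x1)
    expect_equal(res$f_overall, oracle_all$f, tolerance = 1e-8)
  }
  expect_equal(res$df1, 1)
  expect_equal(res$df2, n - 7)

  # a copy of a baseline variable is rejected as collinear
  data$age_copy <- data$age
  expect_error(nested_model_f(w, data, "age_copy"), "collinear")
})

test_that("nested-model F grows as the explanatory noise shrinks", {
  set.seed(7)
  n <- 126
  data <- data.frame(age = rnorm(n, 70, 5),
                     sequence = rep(c("monoband", "multiband"), n / 2),
                     avg_enorm = abs(rnorm(n, 0.1, 0.03)),
                     tgm = rnorm(n, 620, 40),
                     etiv = rnorm(n, 1500, 100))
  w <- rnorm(n)
  fs <- vapply(c(2, 0.5, 0.1, 0.01), function(noise_sd) {
    data$expl <- w + rnorm(n, 0, noise_sd)
    nested_model_f(w, data, "expl")$f
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_lt(nested_model_f(w, transform(data, expl = w + rnorm(n, 0, 1e-8)),
                           "expl")$p, 1e-100)
})

test_that("null nested-model screening rejects at the nominal rate", {
  set.seed(8)
  n <- 126
  rejections <- vapply(1:200, function(i) {
    data <- data.frame(age = rnorm(n, 70, 5),
                       sequence = rep(c("monoband", "multiband"), n / 2),
                       avg_enorm = abs(rnorm(n, 0.1, 0.03)),
                       tgm = rnorm(n, 620, 40),
                       etiv = rnorm(n, 1500, 100),
                       expl = rnorm(n))
    nested_model_f(rnorm(n), data, "expl")$p < 0.05
  }, logical(1))
  # binomial 99.9% band around 0.05 with 200 draws
  expect_gte(mean(rejections), 0.05 - 3.3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(mean(rejections), 0.05 + 3.3 * sqrt(0.05 * 0.95 / 200))
})

test_that("screen_traits adjusts across the trait family", {
  set.seed(9)
  gw <- generate_weights(c(A = 12, B = 10, C = 10), n_traits = 6,
                         effect_trait = 2, effect_size = 2, seed = 9)
  subjects <- make_subject_table(gw$index, seed = 9)
  scr <- screen_traits(gw$weights, gw$index, subjects)
  expect_equal(nrow(scr), 6)
  expect_true(all(scr$q_value >= scr$p))
  expect_true(scr$significant[2])
  expect_identical(scr$significant, unname(scr$q_value <= 0.05))
})
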