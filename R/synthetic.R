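# Seeded synthetic cohorts with planted FC-traits. The generator emulates
# the study conditions the pipeline targets: three groups (23/19/21
# subjects), two acquisition sessions per subject (monoband/multiband),
# latent edge-level traits shared across subjects with subject-specific
# weights, one trait carrying a standardized group shift, session-level
# weight jitter, edge noise calibrated to a target signal R-squared, and
# covariates/cognitive scores linearly linked to the planted trait's
# weights.

DEFAULT_GROUP_SIZES <- c("PD-MCI" = 23L, "PD-CN" = 19L, "HC" = 21L)

#' Generate network-block-structured trait patterns
#'
#' Each pattern concentrates its nonzero mass on a randomly chosen set of
#' within/between-network edge blocks (2 to 4 blocks), with loadings drawn
#' i.i.d. standard normal on a `block_density` fraction of the block's
#' edges, then unit L2-normalized. Patterns are kept mutually
#' near-orthogonal: a candidate whose absolute cosine with any accepted
#' pattern reaches `max_cosine` is re-drawn, and generation fails after
#' `max_tries` re-draws (a sign that `n_traits` is too large for the edge
#' space).
#'
#' @param parcellation Parcellation lookup table (needs >= 2 networks).
#' @param n_traits Number of patterns to generate (>= 1).
#' @param block_density Fraction of a chosen block's edges carrying nonzero
#'   loadings, in (0, 1].
#' @param seed Integer seed; identical seed and arguments give bit-identical
#'   output.
#' @param max_cosine Orthogonality bound on pairwise |cosine|.
#' @param max_tries Re-draw budget per pattern.
#' @return An `n_traits` x E matrix with unit-norm rows.
#' @export
generate_trait_patterns <- function(parcellation, n_traits,
                                    block_density = 0.5, seed = 1L,
                                    max_cosine = 0.3, max_tries = 100L) {
  validate_parcellation(parcellation)
  if (n_traits < 1) stop("n_traits must be >= 1")
  if (block_density <= 0 || block_density > 1) {
    stop("block_density must lie in (0, 1]")
  }
  networks <- unique(parcellation$network)
  if (length(networks) < 2) stop("parcellation must define >= 2 networks")
  r <- nrow(parcellation)
  pairs <- edge_pairs(r)
  net_i <- parcellation$network[pairs$i]
  net_j <- parcellation$network[pairs$j]
  edge_block <- paste(pmin(net_i, net_j), pmax(net_i, net_j), sep = "~")
  blocks <- unique(edge_block)
  e_count <- nrow(pairs)

  set.seed(seed)
  patterns <- matrix(0, n_traits, e_count)
  for (t in seq_len(n_traits)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      n_blocks <- sample(2:min(4, length(blocks)), 1)
      chosen <- sample(blocks, n_blocks)
      in_block <- edge_block %in% chosen
      active <- in_block & (stats::runif(e_count) <= block_density)
      if (!any(active)) next
      p <- numeric(e_count)
      p[active] <- stats::rnorm(sum(active))
      p <- p / sqrt(sum(p^2))
      if (t == 1 ||
          max(abs(patterns[seq_len(t - 1), , drop = FALSE] %*% p)) <
            max_cosine) {
        patterns[t, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not draw ", n_traits, " mutually near-orthogonal ",
           "patterns in ", max_tries, " tries; n_traits too large for E")
    }
  }
  patterns
}

#' Generate subject-session trait weights with a planted group effect
#'
#' Baseline weights are drawn i.i.d. standard normal per subject and trait;
#' the `effect_trait` column of the `effect_group` subjects is shifted by
#' `effect_size` (a standardized mean difference, since baseline SD is 1).
#' Each subject's weights are copied to both sessions with independent
#' N(0, `session_effect_sd`^2) jitter, giving M = 2 x sum(group_sizes)
#' rows ordered subject-major with monoband first.
#'
#' @param group_sizes Named integer vector: subjects per group.
#' @param n_traits Number of traits.
#' @param effect_trait Index of the trait carrying the group effect.
#' @param effect_size Standardized mean weight shift for the effect group.
#' @param effect_group Name of the shifted group (default the first).
#' @param session_effect_sd SD of the per-session weight jitter (>= 0).
#' @param seed Integer seed.
#' @return A list with `weights` (M x n_traits), `index` (data.frame:
#'   subject, session, group) and `subject_weights` (the per-subject
#'   baseline matrix, S x n_traits).
#' @export
generate_weights <- function(group_sizes = DEFAULT_GROUP_SIZES, n_traits = 5L,
                             effect_trait = 1L, effect_size = 1.5,
                             effect_group = names(group_sizes)[1],
                             session_effect_sd = 0.3, seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector")
  }
  if (!effect_group %in% names(group_sizes)) {
    stop("unknown group: ", effect_group)
  }
  if (session_effect_sd < 0) stop("session_effect_sd must be >= 0")
  if (effect_trait < 1 || effect_trait > n_traits) {
    stop("effect_trait out of range")
  }
  set.seed(seed)
  groups <- rep(names(group_sizes), times = group_sizes)
  n_subj <- length(groups)
  subject_id <- sprintf("%s_%02d", groups, unlist(lapply(group_sizes,
                                                         seq_len)))
  base <- matrix(stats::rnorm(n_subj * n_traits), n_subj, n_traits)
  base[groups == effect_group, effect_trait] <-
    base[groups == effect_group, effect_trait] + effect_size

  m <- 2L * n_subj
  weights <- matrix(NA_real_, m, n_traits)
  for (s in seq_len(n_subj)) {
    jitter1 <- stats::rnorm(n_traits, 0, session_effect_sd)
    jitter2 <- stats::rnorm(n_traits, 0, session_effect_sd)
    weights[2 * s - 1, ] <- base[s, ] + jitter1
    weights[2 * s, ] <- base[s, ] + jitter2
  }
  index <- data.frame(
    subject = rep(subject_id, each = 2),
    session = rep(c("monoband", "multiband"), n_subj),
    group = rep(groups, each = 2),
    stringsAsFactors = FALSE
  )
  rownames(base) <- subject_id
  list(weights = weights, index = index, subject_weights = base)
}

#' Edge-noise SD achieving a target planted-signal R-squared
#'
#' Computes the per-edge variance of the noiseless composite (weights x
#' patterns), averaged over edges, and returns the noise SD for which the
#' planted signal would explain `target_r2` of the total per-edge variance.
#'
#' @param patterns n_traits x E pattern matrix.
#' @param weights M x n_traits weight matrix.
#' @param target_r2 Desired signal fraction of variance, in (0, 1).
#' @return The edge noise SD.
#' @export
calibrate_edge_noise <- function(patterns, weights, target_r2 = 0.5) {
  if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0, 1)")
  composite <- weights %*% patterns
  signal_var <- mean(apply(composite, 2, stats::var))
  sqrt(signal_var * (1 - target_r2) / target_r2)
}

#' Synthesize FC matrices from planted traits
#'
#' Each row's edge vector is the weighted sum of the trait patterns plus
#' i.i.d. N(0, `edge_noise_sd`^2) edge noise, squashed through tanh — a
#' monotone bounded map keeping synthetic correlations in (-1, 1) while
#' preserving the rank order of the latent mixture — and devectorized to a
#' symmetric matrix with unit diagonal.
#'
#' @param patterns n_traits x E matrix.
#' @param weights M x n_traits matrix.
#' @param index Row index (data.frame with `subject`, `session`).
#' @param edge_noise_sd Edge noise SD (>= 0).
#' @param seed Integer seed.
#' @return A list with `fc` (named list of `list(values, subject, session)`
#'   keyed `"subject|session"`), `edges` (M x E squashed edge matrix),
#'   `noisy` (pre-squash edge matrix) and `composite` (noiseless planted
#'   mixture).
#' @export
synthesize_fc <- function(patterns, weights, index, edge_noise_sd,
                          seed = 1L) {
  if (ncol(weights) != nrow(patterns)) stop("weights/patterns mismatch")
  if (edge_noise_sd < 0) stop("edge_noise_sd must be >= 0")
  set.seed(seed)
  composite <- weights %*% patterns
  noisy <- composite +
    matrix(stats::rnorm(length(composite), 0, edge_noise_sd),
           nrow(composite), ncol(composite))
  edges <- tanh(noisy)
  fc <- lapply(seq_len(nrow(edges)), function(i) {
    list(values = devectorize_fc(edges[i, ]),
         subject = index$subject[i], session = index$session[i])
  })
  names(fc) <- paste(index$subject, index$session, sep = "|")
  rownames(edges) <- names(fc)
  list(fc = fc, edges = edges, noisy = noisy, composite = composite)
}

#' Synthesize a ROI time-series table with a target correlation structure
#'
#' Draws `n_timepoints` rows from a zero-mean multivariate normal whose
#' correlation equals the nearest positive-definite repair of `fc_target`:
#' eigenvalues are clipped at `eig_floor` and the matrix re-normalized to
#' unit diagonal. The maximum absolute entrywise correction applied is
#' reported.
#'
#' @param fc_target Symmetric correlation matrix with unit diagonal.
#' @param n_timepoints Number of frames T (T > R recommended).
#' @param seed Integer seed.
#' @param eig_floor Eigenvalue floor for the positive-definite repair.
#' @return A list with `values` (T x R matrix) and `correction` (max
#'   absolute change made to `fc_target`).
#' @export
synthesize_timeseries <- function(fc_target, n_timepoints, seed = 1L,
                                  eig_floor = 1e-6) {
  fc_target <- as.matrix(fc_target)
  if (nrow(fc_target) != ncol(fc_target)) stop("fc_target must be square")
  e <- eigen((fc_target + t(fc_target)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  fixed <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(fixed))
  fixed <- fixed * tcrossprod(d)
  correction <- max(abs(fixed - fc_target))
  set.seed(seed)
  r <- nrow(fixed)
  z <- matrix(stats::rnorm(n_timepoints * r), n_timepoints, r)
  list(values = z %*% chol(fixed), correction = correction)
}

#' Synthesize a realignment-parameter table with injected motion spikes
#'
#' Six rigid-body parameters evolve as a slow random walk; a configurable
#' fraction of frames receives a translation spike large enough to trip the
#' standard 0.4 ENORM censoring rule, and a (smaller) fraction receives a
#' despiked-voxel fraction above the 10% rule.
#'
#' @param n_frames Number of frames.
#' @param spike_rate Fraction of frames carrying a motion spike.
#' @param despike_rate Fraction of frames with an elevated despike fraction.
#' @param seed Integer seed.
#' @return Data.frame with six parameter columns (`trans_x` ... `rot_z`) and
#'   `despike_fraction`.
#' @export
synthesize_motion <- function(n_frames, spike_rate = 0.03,
                              despike_rate = 0.01, seed = 1L) {
  set.seed(seed)
  params <- apply(matrix(stats::rnorm(n_frames * 6, 0, 0.02), n_frames, 6),
                  2, cumsum)
  n_spike <- round(spike_rate * n_frames)
  if (n_spike > 0 && n_frames > 2) {
    at <- sample(2:n_frames, n_spike)
    params[at, 1] <- params[at, 1] +
      stats::runif(n_spike, 0.5, 1.5) * sample(c(-1, 1), n_spike, TRUE)
  }
  despike <- stats::runif(n_frames, 0, 0.04)
  n_desp <- round(despike_rate * n_frames)
  if (n_desp > 0) {
    at <- sample(seq_len(n_frames), n_desp)
    despike[at] <- stats::runif(n_desp, 0.12, 0.30)
  }
  out <- as.data.frame(params)
  names(out) <- c("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z")
  out$despike_fraction <- despike
  out
}

#' Control-sample statistics for the synthetic cognitive battery
#'
#' Plausible normative means and SDs for the ten tests of the five-domain
#' battery plus global cognition screens, used to back-compute raw scores
#' from synthetic z-scores. Synthetic stand-ins, not published norms.
#'
#' @return Data.frame with columns `test`, `mean`, `sd`.
#' @export
default_control_stats <- function() {
  data.frame(
    test = c("span_inverse", "digit_symbol", "trail_making",
             "phonemic_fluency", "ravlt", "rocf", "semantic_fluency",
             "boston_naming", "vosp_objects", "vosp_numeric",
             "moca", "mmse"),
    mean = c(4.5, 45, 40, 16, 9, 20, 20, 52, 17, 8, 26.4, 29.3),
    sd   = c(1.2, 10, 12, 4.5, 3, 6, 5, 6, 2, 1.5, 2.9, 0.87),
    stringsAsFactors = FALSE
  )
}

# Group-wise covariate distributions (mean, sd) or male fraction; values
# follow the cohort's printed demographics where available, otherwise
# realistic magnitudes for an elderly sample.
.covariate_params <- function() {
  list(
    age = list("PD-CN" = c(66.58, 7), "PD-MCI" = c(72.22, 5.43),
               "HC" = c(68.65, 3.9), default = c(70, 6)),
    male_frac = list("PD-CN" = 0.80, "PD-MCI" = 0.522, "HC" = 0.524,
                     default = 0.5),
    education = list("PD-CN" = c(13.84, 3), "PD-MCI" = c(8.96, 2.5),
                     "HC" = c(12.85, 3), default = c(12, 3)),
    tgm = c(620, 55),       # total grey matter, cm^3
    etiv = c(1500, 140),    # estimated total intracranial volume, cm^3
    avg_enorm = c(0.1, 0.045),
    updrs = c(20, 8)        # PD groups' motor-score base
  )
}

#' Default linear links between the effect trait's weights and outcomes
#'
#' Coefficients on the subject's mean effect-trait weight: negative for
#' cognitive variables (a stronger trait expression worsens cognition in
#' the affected group) and positive for the motor score.
#'
#' @return Named list of coefficients.
#' @export
default_coeff_map <- function() {
  list(attention = -0.6, executive = -0.3, memory = -0.6,
       language = -0.4, visuospatial = -0.2,
       moca = -1.2, mmse = -0.5, mds_updrs_iii = 4.0)
}

#' Synthesize a subject covariate and clinical table
#'
#' Each listed variable equals an intercept plus its coefficient times the
#' subject's mean effect-trait weight plus Gaussian noise. Domain z-score
#' composites are split into two per-test z-scores whose mean is exactly
#' the composite; raw test scores are back-computed from z via the control
#' statistics (raw = control mean + z x control SD). Covariates (age,
#' gender, education, TGM, eTIV, average ENORM) are drawn from configured
#' group-wise distributions. HC subjects carry exactly 0 on MDS-UPDRS-III,
#' the coding used for scales not acquired in controls.
#'
#' @param weights M x n_traits weight matrix.
#' @param index Row index with `subject`, `session`, `group`.
#' @param effect_trait Column of `weights` linked to the outcomes.
#' @param coeff_map Named list of linear coefficients; keys must be domain
#'   names, `"moca"`, `"mmse"` or `"mds_updrs_iii"`.
#' @param control_stats Control statistics table covering every test of
#'   `domains` plus moca/mmse.
#' @param domains Domain-to-test map (default [cognitive_domains()]).
#' @param seed Integer seed.
#' @param residual_sd SD of the noise on each composite/score.
#' @param test_scatter_sd SD of the within-domain split between the two
#'   tests.
#' @return Data.frame, one row per subject: identifiers, group, covariates,
#'   clinical scores and raw scores for the ten tests.
#' @export
synthesize_clinical <- function(weights, index, effect_trait = 1L,
                                coeff_map = default_coeff_map(),
                                control_stats = default_control_stats(),
                                domains = cognitive_domains(), seed = 1L,
                                residual_sd = 0.5, test_scatter_sd = 0.25) {
  allowed <- c(names(domains), "moca", "mmse", "mds_updrs_iii")
  bad <- setdiff(names(coeff_map), allowed)
  if (length(bad) > 0) stop("unknown coeff_map key(s): ",
                            paste(bad, collapse = ", "))
  tests <- unique(unlist(domains, use.names = FALSE))
  no_stats <- setdiff(c(tests, "moca", "mmse"), control_stats$test)
  if (length(no_stats) > 0) {
    stop("missing control_stats for: ", paste(no_stats, collapse = ", "))
  }
  cs <- function(tst) control_stats[control_stats$test == tst, ][1, ]
  cf <- function(key) if (is.null(coeff_map[[key]])) 0 else coeff_map[[key]]

  subj_rows <- !duplicated(index$subject)
  subject_id <- index$subject[subj_rows]
  group <- index$group[subj_rows]
  n_subj <- length(subject_id)
  mw <- vapply(subject_id, function(s) {
    mean(weights[index$subject == s, effect_trait])
  }, numeric(1))

  pars <- .covariate_params()
  pick <- function(tab, g) if (!is.null(tab[[g]])) tab[[g]] else tab$default

  set.seed(seed)
  age <- vapply(group, function(g) {
    p <- pick(pars$age, g); stats::rnorm(1, p[1], p[2])
  }, numeric(1))
  gender <- vapply(group, function(g) {
    if (stats::runif(1) < pick(pars$male_frac, g)) "male" else "female"
  }, character(1))
  education <- vapply(group, function(g) {
    p <- pick(pars$education, g); max(stats::rnorm(1, p[1], p[2]), 2)
  }, numeric(1))
  tgm <- stats::rnorm(n_subj, pars$tgm[1], pars$tgm[2])
  etiv <- stats::rnorm(n_subj, pars$etiv[1], pars$etiv[2])
  avg_enorm <- abs(stats::rnorm(n_subj, pars$avg_enorm[1],
                                pars$avg_enorm[2]))

  out <- data.frame(subject_id = subject_id, group = group, age = age,
                    gender = gender, education = education, tgm = tgm,
                    etiv = etiv, avg_enorm = avg_enorm,
                    stringsAsFactors = FALSE)

  for (dom in names(domains)) {
    composite <- cf(dom) * mw + stats::rnorm(n_subj, 0, residual_sd)
    d <- stats::rnorm(n_subj, 0, test_scatter_sd)
    z1 <- composite + d
    z2 <- composite - d
    pair <- domains[[dom]]
    s1 <- cs(pair[1]); s2 <- cs(pair[2])
    out[[pair[1]]] <- s1$mean + z1 * s1$sd
    out[[pair[2]]] <- s2$mean + z2 * s2$sd
  }
  for (screen in c("moca", "mmse")) {
    s <- cs(screen)
    z <- cf(screen) * mw / s$sd + stats::rnorm(n_subj, 0, residual_sd)
    out[[screen]] <- s$mean + z * s$sd
  }
  updrs <- pars$updrs[1] + cf("mds_updrs_iii") * mw +
    stats::rnorm(n_subj, 0, pars$updrs[2] / 2)
  updrs[group == "HC"] <- 0
  out$mds_updrs_iii <- updrs
  out
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: parcellation, planted trait patterns, weights with
#' a group effect, FC matrices (and optionally ROI time series plus motion
#' tables realizing them), clinical/covariate table, and the ground truth
#' needed to score recovery. Edge noise defaults to the level at which the
#' planted signal explains `target_r2` of per-edge variance.
#'
#' @param group_sizes Named subjects-per-group vector (default 23/19/21).
#' @param n_roi Number of ROIs (default 100; use 408 for full-scale runs).
#' @param n_traits Number of planted traits.
#' @param effect_trait,effect_group,effect_size Planted group effect: which
#'   trait, which group, and the standardized weight shift.
#' @param session_effect_sd Session-level weight jitter SD.
#' @param target_r2 Planted-signal variance fraction used to calibrate the
#'   edge noise when `edge_noise_sd` is `NULL`.
#' @param edge_noise_sd Explicit edge noise SD (overrides `target_r2`).
#' @param block_density Density of nonzero loadings within chosen blocks.
#' @param include_timeseries If `TRUE`, also synthesize T x R time series
#'   realizing each FC matrix, plus realignment tables.
#' @param n_timepoints Frames per session when time series are generated.
#' @param seed Integer master seed; all internal draws derive from it.
#' @return A list of class `synthetic_cohort` with `parcellation`,
#'   `subjects`, `fc`, `group` (a `group_fc`), `timeseries`, `motion`
#'   (both `NULL` unless requested) and `ground_truth`.
#' @export
simulate_cohort <- function(group_sizes = DEFAULT_GROUP_SIZES, n_roi = 100L,
                            n_traits = 5L, effect_trait = 1L,
                            effect_group = names(group_sizes)[1],
                            effect_size = 1.5, session_effect_sd = 0.3,
                            target_r2 = 0.5, edge_noise_sd = NULL,
                            block_density = 0.5,
                            include_timeseries = FALSE,
                            n_timepoints = 300L, seed = 1L) {
  parc <- make_parcellation(n_roi)
  patterns <- generate_trait_patterns(parc, n_traits,
                                      block_density = block_density,
                                      seed = seed)
  gw <- generate_weights(group_sizes, n_traits, effect_trait = effect_trait,
                         effect_size = effect_size,
                         effect_group = effect_group,
                         session_effect_sd = session_effect_sd,
                         seed = seed + 1000L)
  if (is.null(edge_noise_sd)) {
    edge_noise_sd <- calibrate_edge_noise(patterns, gw$weights, target_r2)
  }
  sf <- synthesize_fc(patterns, gw$weights, gw$index, edge_noise_sd,
                      seed = seed + 2000L)
  subjects <- synthesize_clinical(gw$weights, gw$index,
                                  effect_trait = effect_trait,
                                  seed = seed + 3000L)

  timeseries <- NULL
  motion <- NULL
  if (include_timeseries) {
    timeseries <- vector("list", length(sf$fc))
    motion <- vector("list", length(sf$fc))
    names(timeseries) <- names(sf$fc)
    names(motion) <- names(sf$fc)
    for (i in seq_along(sf$fc)) {
      ts <- synthesize_timeseries(sf$fc[[i]]$values, n_timepoints,
                                  seed = seed + 4000L + i)
      timeseries[[i]] <- ts$values
      motion[[i]] <- synthesize_motion(n_timepoints,
                                       seed = seed + 10000L + i)
    }
  }

  ground_truth <- list(
    trait_patterns = patterns,
    true_weights = gw$weights,
    subject_weights = gw$subject_weights,
    effect_trait_index = as.integer(effect_trait),
    effect_group = effect_group,
    group_effect_size = effect_size,
    session_noise_sd = session_effect_sd,
    edge_noise_sd = edge_noise_sd,
    seed = as.integer(seed)
  )
  structure(list(parcellation = parc, subjects = subjects, fc = sf$fc,
                 group = group_fc(sf$edges, gw$index),
                 timeseries = timeseries, motion = motion,
                 ground_truth = ground_truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "synthetic cohort: %d subjects (%s), %d ROIs, %d planted traits\n",
    nrow(x$subjects),
    paste(sprintf("%s=%d", names(table(x$subjects$group)),
                  table(x$subjects$group)), collapse = ", "),
    nrow(x$parcellation), nrow(gt$trait_patterns)))
  cat(sprintf(
    "  effect: trait %d, group %s, size %.2f; edge noise SD %.4f\n",
    gt$effect_trait_index, gt$effect_group, gt$group_effect_size,
    gt$edge_noise_sd))
  invisible(x)
}

#' Write a synthetic cohort to the on-disk layout the pipeline reads
#'
#' Writes the parcellation and covariate tables, per-session time-series
#' and motion TSVs (when present), and a ground-truth JSON for tests.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  utils::write.table(cohort$subjects, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$timeseries)) {
    ts_dir <- file.path(dir, "timeseries")
    mo_dir <- file.path(dir, "motion")
    dir.create(ts_dir, showWarnings = FALSE)
    dir.create(mo_dir, showWarnings = FALSE)
    for (key in names(cohort$timeseries)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      stem <- paste0(parts[1], "_", parts[2])
      write_timeseries(cohort$timeseries[[key]],
                       file.path(ts_dir, paste0(stem, ".tsv")))
      utils::write.table(cohort$motion[[key]],
                         file.path(mo_dir, paste0(stem, "_motion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  gt <- cohort$ground_truth
  gt$trait_patterns <- unname(apply(gt$trait_patterns, 1, identity,
                                    simplify = FALSE))
  gt$true_weights <- unname(apply(gt$true_weights, 1, identity,
                                  simplify = FALSE))
  gt$subject_weights <- unname(apply(gt$subject_weights, 1, identity,
                                     simplify = FALSE))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
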