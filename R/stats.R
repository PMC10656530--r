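# Statistical analyses on trait weights and cognition: control-referenced
# z-scoring with domain composites, MCI classification (Level-II style
# rule), covariate-adjusted repeated-measures ANOVA with BH-FDR across
# traits, pairwise post-hoc tests, and baseline-vs-augmented nested-model F
# regressions for cognitive/clinical associations.

#' The five-domain cognitive battery layout
#'
#' Each cognitive domain is evaluated by exactly two tests; the domain
#' composite is the unweighted mean of the two test z-scores. The default
#' layout covers attention/working memory (inverse span, digit-symbol),
#' executive function (trail making, phonemic fluency), memory (RAVLT
#' delayed recall, ROCF immediate recall), language (semantic fluency,
#' Boston naming) and visuospatial abilities (VOSP object decision, VOSP
#' number location).
#'
#' @return Named list mapping each domain to its two test names.
#' @export
cognitive_domains <- function() {
  list(
    attention    = c("span_inverse", "digit_symbol"),
    executive    = c("trail_making", "phonemic_fluency"),
    memory       = c("ravlt", "rocf"),
    language     = c("semantic_fluency", "boston_naming"),
    visuospatial = c("vosp_objects", "vosp_numeric")
  )
}

#' Control-referenced z-scores and domain composites
#'
#' z = (raw score - control mean) / control SD per test, using the stored
#' control-sample statistics; each domain composite is the unweighted mean
#' of its two tests' z-scores.
#'
#' @param raw Data.frame with a `subject_id` column and one column per test.
#' @param control_stats Data.frame with columns `test`, `mean`, `sd` giving
#'   the control-sample statistics per test; every requested test must
#'   appear and have `sd > 0`.
#' @param domains Named list mapping domains to pairs of test names; default
#'   [cognitive_domains()].
#' @return A list of class `zscore_table`: `z` (subject x test z-scores),
#'   `composites` (subject x domain), `control_stats`, `domains`.
#' @export
compute_zscores <- function(raw, control_stats,
                            domains = cognitive_domains()) {
  tests <- unique(unlist(domains, use.names = FALSE))
  missing <- setdiff(tests, names(raw))
  if (length(missing) > 0) {
    stop("raw scores missing for test(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(tests, control_stats$test)
  if (length(bad) > 0) {
    stop("no control statistics for test(s): ", paste(bad, collapse = ", "))
  }
  n_per_domain <- lengths(domains)
  if (any(n_per_domain != 2)) {
    stop("each domain must map to exactly two tests")
  }
  z <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  for (tst in tests) {
    cs <- control_stats[control_stats$test == tst, ][1, ]
    if (!is.finite(cs$sd) || cs$sd <= 0) {
      stop("control SD must be positive for test: ", tst)
    }
    z[[tst]] <- (raw[[tst]] - cs$mean) / cs$sd
  }
  composites <- data.frame(subject_id = raw$subject_id,
                           stringsAsFactors = FALSE)
  for (dom in names(domains)) {
    pair <- domains[[dom]]
    composites[[dom]] <- (z[[pair[1]]] + z[[pair[2]]]) / 2
  }
  structure(list(z = z, composites = composites,
                 control_stats = control_stats, domains = domains),
            class = "zscore_table")
}

#' Classify subjects as MCI from their z-score table
#'
#' A subject is classified as MCI when strictly more than `|threshold|`
#' standard deviations below control values (z strictly less than
#' `threshold`) on at least `min_tests` tests of the battery, whether the
#' impaired tests fall in one cognitive domain or across several. A z
#' exactly at the threshold does not count as impaired.
#'
#' @param zscores A `zscore_table` from [compute_zscores()].
#' @param threshold Impairment cut on z (default -1.5).
#' @param min_tests Minimum number of impaired tests (default 2).
#' @return Data.frame with `subject_id`, `n_impaired`, `impaired_tests`
#'   (comma-separated) and `status` (`"MCI"` or `"CN"`).
#' @export
classify_mci <- function(zscores, threshold = -1.5, min_tests = 2L) {
  tests <- unique(unlist(zscores$domains, use.names = FALSE))
  zt <- zscores$z
  if (anyNA(zt[tests])) stop("missing z-score; cannot classify")
  impaired <- as.matrix(zt[tests]) < threshold
  n_imp <- rowSums(impaired)
  data.frame(
    subject_id = zt$subject_id,
    n_impaired = as.integer(n_imp),
    impaired_tests = apply(impaired, 1, function(r) {
      paste(tests[r], collapse = ",")
    }),
    status = ifelse(n_imp >= min_tests, "MCI", "CN"),
    stringsAsFactors = FALSE
  )
}

# Merge one trait's weights with subject-level data; sanity-check design.
.weight_frame <- function(weights, index, subjects, covariates) {
  if (length(weights) != nrow(index)) stop("weights do not match index")
  need <- c("subject_id", "group", covariates)
  missing <- setdiff(need, names(subjects))
  if (length(missing) > 0) {
    stop("subject table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- data.frame(subject = index$subject, session = index$session,
                   w = as.numeric(weights), stringsAsFactors = FALSE)
  df <- merge(df, subjects[need], by.x = "subject", by.y = "subject_id",
              sort = FALSE)
  counts <- table(df$subject)
  if (any(counts != 2)) stop("every subject needs exactly two weight rows")
  for (cv in covariates) {
    v <- df[[cv]]
    if (length(unique(v)) < 2) {
      stop("constant covariate makes the design rank-deficient: ", cv)
    }
  }
  df
}

#' Repeated-measures ANOVA for one trait's weights
#'
#' Mixed-design ANOVA on the M subject-session weights with group as the
#' between-subjects factor, acquisition sequence (monoband/multiband) as the
#' within-subject factor, and the listed covariates. Implemented in two
#' strata: the between-subjects group F comes from ordinary least squares on
#' the per-subject session means, comparing covariates-only against
#' covariates + group; the within-subject sequence F comes from the paired
#' monoband-multiband differences. For a two-group balanced design with no
#' covariates the group F reduces to the classical one-way ANOVA F on
#' subject means.
#'
#' @param weights Numeric vector of length M (one trait's weights).
#' @param index Data.frame with `subject`, `session` aligned with `weights`.
#' @param subjects Subject-level data.frame with `subject_id`, `group` and
#'   the covariate columns.
#' @param covariates Covariate column names adjusted for in the
#'   between-subjects stratum (default age, gender, TGM).
#' @return A list with `f` and `p` (group effect), `df1`, `df2`,
#'   `f_sequence`, `p_sequence`.
#' @export
rm_anova_trait <- function(weights, index, subjects,
                           covariates = c("age", "gender", "tgm")) {
  df <- .weight_frame(weights, index, subjects, covariates)
  means <- stats::aggregate(w ~ subject, data = df, FUN = mean)
  subj_df <- merge(means, unique(df[c("subject", "group", covariates)]),
                   by = "subject", sort = FALSE)
  subj_df$group <- factor(subj_df$group)
  if (nlevels(subj_df$group) < 2) stop("need at least two groups")

  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit0 <- stats::lm(stats::as.formula(paste("w ~", rhs0)), data = subj_df)
  fit1 <- stats::lm(stats::as.formula(paste("w ~", rhs0, "+ group")),
                    data = subj_df)
  cmp <- stats::anova(fit0, fit1)
  # degenerate case: no residual variance left anywhere (e.g. constant
  # weights) — report a null effect rather than a 0/0 artifact
  if (stats::deviance(fit0) < 1e-20) {
    f_group <- 0
    p_group <- 1
  } else {
    f_group <- cmp$F[2]
    if (!is.finite(f_group)) f_group <- 0
    p_group <- cmp$`Pr(>F)`[2]
    if (!is.finite(p_group)) p_group <- 1
  }

  # within-subject stratum: paired sequence differences
  wide <- stats::reshape(df[c("subject", "session", "w")],
                         idvar = "subject", timevar = "session",
                         direction = "wide")
  d <- wide$w.monoband - wide$w.multiband
  if (stats::sd(d) == 0) {
    f_seq <- if (mean(d) == 0) 0 else Inf
    p_seq <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(d)
    f_seq <- unname(tt$statistic)^2
    p_seq <- tt$p.value
  }

  list(f = f_group, p = p_group,
       df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
       f_sequence = f_seq, p_sequence = p_seq)
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' Step-up adjusted p-values (monotone-enforced) via the standard BH
#' procedure; a test is flagged when its adjusted value is at or below `q`,
#' matching the step-up rejection rule p(i) <= (i/n) q.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `q_values` and logical `significant`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, significant = qv <= q)
}

#' Covariate-adjusted pairwise post-hoc test between two groups
#'
#' The same two-stage model as [rm_anova_trait()], restricted to one pair of
#' groups; the 1-df group contrast F equals the square of the corresponding
#' covariate-adjusted t statistic. When either group has fewer than two
#' subjects, or no residual degrees of freedom remain, the result carries
#' `NA` rather than a silently unreliable number.
#'
#' @inheritParams rm_anova_trait
#' @param pair Character vector of the two group labels to compare.
#' @return A list with `f`, `p`, `df1`, `df2` (NA when the design is
#'   degenerate).
#' @export
posthoc_pairwise <- function(weights, index, subjects, pair,
                             covariates = c("age", "gender", "tgm")) {
  if (length(pair) != 2) stop("pair must name exactly two groups")
  if (!all(pair %in% subjects$group)) {
    stop("group not present: ", paste(setdiff(pair, subjects$group),
                                      collapse = ", "))
  }
  keep_subj <- subjects$subject_id[subjects$group %in% pair]
  keep_rows <- index$subject %in% keep_subj
  sub_subjects <- subjects[subjects$subject_id %in% keep_subj, , drop = FALSE]
  if (any(table(sub_subjects$group) < 2)) {
    return(list(f = NA_real_, p = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_))
  }
  res <- tryCatch(
    rm_anova_trait(weights[keep_rows], index[keep_rows, , drop = FALSE],
                   sub_subjects, covariates = covariates),
    error = function(e) NULL)
  if (is.null(res) || res$df2 < 1) {
    return(list(f = NA_real_, p = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_))
  }
  list(f = res$f, p = res$p, df1 = res$df1, df2 = res$df2)
}

#' Nested-model (partial) F test for one explanatory variable
#'
#' Fits a baseline ordinary-least-squares model of the M subject-session
#' weights on the variables of non-interest (by default age, MR sequence,
#' average ENORM, TGM and eTIV) and an augmented model adding one
#' explanatory variable, over the pooled session rows. Reports the partial F
#' for the added variable (1 numerator df), the augmented model's overall F
#' (mirroring the 6-regressor reporting convention), and the R-squared gain.
#'
#' @param weights Numeric vector of length M.
#' @param data Data.frame with M rows containing every baseline variable and
#'   the explanatory variable.
#' @param explanatory Name of the single added variable.
#' @param baseline_vars Names of the baseline variables of non-interest.
#' @return A list with `f` (partial F), `p`, `df1`, `df2`, `delta_r2`,
#'   `f_overall`, `p_overall`, `df_overall`.
#' @export
nested_model_f <- function(weights, data, explanatory,
                           baseline_vars = c("age", "sequence", "avg_enorm",
                                             "tgm", "etiv")) {
  need <- c(baseline_vars, explanatory)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("data missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- data[need]
  df$w <- as.numeric(weights)
  if (anyNA(df)) stop("variables must be complete over all rows")

  rhs0 <- paste(baseline_vars, collapse = " + ")
  fit1 <- stats::lm(stats::as.formula(
    paste("w ~", rhs0, "+", explanatory)), data = df)
  mm <- stats::model.matrix(fit1)
  if (qr(mm)$rank < ncol(mm) || kappa(mm, exact = TRUE) > 1e10) {
    stop("explanatory variable '", explanatory,
         "' is collinear with the baseline design")
  }
  fit0 <- stats::lm(stats::as.formula(paste("w ~", rhs0)), data = df)
  cmp <- stats::anova(fit0, fit1)
  s1 <- summary(fit1)
  s0 <- summary(fit0)
  fo <- s1$fstatistic
  list(f = cmp$F[2], p = cmp$`Pr(>F)`[2],
       df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
       delta_r2 = s1$r.squared - s0$r.squared,
       f_overall = unname(fo[1]),
       p_overall = stats::pf(fo[1], fo[2], fo[3], lower.tail = FALSE),
       df_overall = unname(fo[2:3]))
}

#' Screen all trait weights for a group effect under FDR control
#'
#' Runs [rm_anova_trait()] for every trait and applies Benjamini-Hochberg
#' adjustment across the family.
#'
#' @param weight_matrix M x n_traits matrix of weights (one column per
#'   trait).
#' @param index Row index data.frame (`subject`, `session`).
#' @param subjects Subject-level covariate table.
#' @param covariates Covariates for the between-subjects stratum.
#' @param q FDR level.
#' @return Data.frame with one row per trait: `trait`, `f`, `p`, `q_value`,
#'   `significant`.
#' @export
screen_traits <- function(weight_matrix, index, subjects,
                          covariates = c("age", "gender", "tgm"),
                          q = 0.05) {
  weight_matrix <- as.matrix(weight_matrix)
  res <- lapply(seq_len(ncol(weight_matrix)), function(k) {
    rm_anova_trait(weight_matrix[, k], index, subjects, covariates)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  adj <- fdr_adjust(p, q = q)
  data.frame(
    trait = if (is.null(colnames(weight_matrix))) {
      seq_len(ncol(weight_matrix))
    } else colnames(weight_matrix),
    f = vapply(res, `[[`, numeric(1), "f"),
    p = p,
    q_value = adj$q_values,
    significant = adj$significant,
    stringsAsFactors = FALSE
  )
}

#' Association of one trait's weights with cognitive/clinical variables
#'
#' For each listed variable, compares the baseline variables-of-non-interest
#' model against the model augmented with that variable via
#' [nested_model_f()] over the pooled subject-session rows.
#'
#' @param weights Numeric vector of length M.
#' @param data M-row data.frame carrying baseline and explanatory columns.
#' @param variables Character vector of explanatory variable names, tested
#'   one at a time.
#' @param baseline_vars Baseline variable names.
#' @param alpha Significance threshold on the partial-F p-value (default
#'   0.01, the convention for post-hoc and association tests).
#' @return Data.frame: `variable`, `f`, `p`, `delta_r2`, `f_overall`,
#'   `significant`.
#' @export
trait_associations <- function(weights, data, variables,
                               baseline_vars = c("age", "sequence",
                                                 "avg_enorm", "tgm", "etiv"),
                               alpha = 0.01) {
  rows <- lapply(variables, function(v) {
    res <- nested_model_f(weights, data, v, baseline_vars)
    data.frame(variable = v, f = res$f, p = res$p,
               delta_r2 = res$delta_r2, f_overall = res$f_overall,
               significant = res$p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
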