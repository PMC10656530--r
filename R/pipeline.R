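# Orchestration: a single YAML-style configuration drives the end-to-end
# pipeline censor -> FC -> assemble -> identifiability sweep -> trait
# extraction -> group screening and associations -> characterization, with
# every intermediate written to disk and declared in a JSON run report.

#' Default pipeline configuration
#'
#' All thresholds mirror the standard analysis choices: ENORM censoring at
#' 0.4 mm, despiking at 10%, subject exclusion above 20% censored volumes,
#' FDR at q < 0.05, post-hoc/association significance at p < 0.01, and
#' characterization of the 1% strongest edges. The Fisher z-transform of
#' edge correlations before PCA/ICA is off by default and exposed as a
#' flag.
#'
#' @param data_dir Input directory (layout written by [write_cohort()]).
#' @param output_dir Output directory.
#' @param seed Integer seed recorded in every report and used for every
#'   stochastic stage.
#' @return Nested configuration list.
#' @export
default_config <- function(data_dir = "data", output_dir = "output",
                           seed = 1L) {
  list(
    paths = list(data_dir = data_dir, output_dir = output_dir),
    seed = as.integer(seed),
    censoring = list(enorm_limit = 0.4, despike_limit = 0.10,
                     max_censored_fraction = 0.20),
    fc = list(fisher_z = FALSE),
    sweep = list(stride = 1L),
    ica = list(n_components = NULL, n_runs = 100L,
               match_threshold = 0.75, min_frequency = 0.75,
               tol = 1e-6, maxit = 1000L),
    stats = list(fdr_q = 0.05, posthoc_alpha = 0.01,
                 rm_covariates = c("age", "gender", "tgm"),
                 baseline_vars = c("age", "sequence", "avg_enorm",
                                   "tgm", "etiv"),
                 hc_clinical_zeros = TRUE),
    characterization = list(pct = 1.0, normalization = "zscore",
                            t_low = 1.0, t_high = 1.5),
    simulate = list(group_sizes = c("PD-MCI" = 23L, "PD-CN" = 19L,
                                    "HC" = 21L),
                    n_roi = 100L, n_traits = 5L, effect_trait = 1L,
                    effect_size = 1.5, session_effect_sd = 0.3,
                    target_r2 = 0.5, block_density = 0.5,
                    include_timeseries = TRUE, n_timepoints = 300L)
  )
}

# Recursive defaults merge: user values override, unknown keys kept.
.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path Path to a YAML configuration file.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_config(), user)
  gs <- cfg$simulate$group_sizes
  if (is.list(gs)) cfg$simulate$group_sizes <- unlist(gs)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!is.null(config$simulate$group_sizes)) {
    # a named vector would serialize as a plain sequence; keep the names
    config$simulate$group_sizes <- as.list(config$simulate$group_sizes)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Simulate a synthetic cohort onto disk per the configuration
#'
#' Wraps [simulate_cohort()] and [write_cohort()] using the `simulate`
#' block of the configuration; the files land in `paths$data_dir` in
#' exactly the layout [run_pipeline()] reads.
#'
#' @param config Configuration list (see [default_config()]).
#' @return The cohort, invisibly.
#' @export
simulate_to_disk <- function(config = default_config()) {
  sim <- config$simulate
  cohort <- simulate_cohort(
    group_sizes = sim$group_sizes, n_roi = sim$n_roi,
    n_traits = sim$n_traits, effect_trait = sim$effect_trait,
    effect_size = sim$effect_size,
    session_effect_sd = sim$session_effect_sd,
    target_r2 = sim$target_r2, block_density = sim$block_density,
    include_timeseries = isTRUE(sim$include_timeseries),
    n_timepoints = sim$n_timepoints, seed = config$seed)
  write_cohort(cohort, config$paths$data_dir)
  invisible(cohort)
}

# Load the on-disk cohort inputs.
.load_inputs <- function(config) {
  dd <- config$paths$data_dir
  parc_path <- file.path(dd, "parcellation.tsv")
  if (!file.exists(parc_path)) {
    stop("missing parcellation file: ", parc_path)
  }
  parc <- read_parcellation(parc_path)
  cov_path <- file.path(dd, "covariates.tsv")
  if (!file.exists(cov_path)) stop("missing covariate table: ", cov_path)
  subjects <- utils::read.delim(cov_path, stringsAsFactors = FALSE)
  ts_dir <- file.path(dd, "timeseries")
  ts_files <- if (dir.exists(ts_dir)) {
    list.files(ts_dir, pattern = "\\.tsv$", full.names = TRUE)
  } else character(0)
  if (length(ts_files) == 0) {
    stop("no time-series files under ", ts_dir)
  }
  list(parcellation = parc, subjects = subjects, ts_files = ts_files,
       motion_dir = file.path(dd, "motion"))
}

#' Run the full FC-trait pipeline
#'
#' Executes censoring, FC construction, group-matrix assembly, the
#' differential-identifiability sweep, robust ICA trait extraction, the
#' group screening with FDR plus post-hoc and association tests for
#' significant traits, and trait characterization. Every intermediate
#' artifact is written under `paths$output_dir` and declared in the JSON
#' run report; rerunning with an identical configuration and seed
#' reproduces the outputs byte for byte.
#'
#' @param config Configuration list (see [default_config()]).
#' @param through Last stage to execute, one of `"censor"`, `"build-fc"`,
#'   `"sweep"`, `"extract"`, `"test"`, `"characterize"` (the default runs
#'   everything); earlier stages always run, so each stage command is a
#'   pipeline prefix.
#' @return The run report (also written as `report.json`), invisibly
#'   containing the chosen K, significant traits and the file manifest.
#' @export
run_pipeline <- function(config = default_config(),
                         through = "characterize") {
  stages <- c("censor", "build-fc", "sweep", "extract", "test",
              "characterize")
  last <- match(match.arg(through, stages), stages)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  add <- function(paths) manifest <<- c(manifest, unname(paths))
  group <- NULL; sweep <- NULL; traits <- NULL; stats_res <- NULL

  inputs <- .stage("load", .load_inputs(config))
  parc <- inputs$parcellation
  subjects <- inputs$subjects

  # --- censoring -----------------------------------------------------------
  cens <- config$censoring
  masks <- list()
  censor_report <- .stage("censor", {
    stems <- sub("\\.tsv$", "", basename(inputs$ts_files))
    for (stem in stems) {
      parts <- regmatches(stem, regexec("^(.*)_(monoband|multiband)$",
                                        stem))[[1]]
      if (length(parts) != 3) stop("unrecognized time-series file: ", stem)
      subj <- parts[2]; sess <- parts[3]
      mo_path <- file.path(inputs$motion_dir,
                           paste0(stem, "_motion.tsv"))
      if (file.exists(mo_path)) {
        mo <- utils::read.delim(mo_path)
        enorm <- compute_enorm(as.matrix(mo[, 1:6]))
        despike <- if ("despike_fraction" %in% names(mo)) {
          mo$despike_fraction
        } else NULL
        mask <- censor_frames(enorm, despike,
                              enorm_limit = cens$enorm_limit,
                              despike_limit = cens$despike_limit)
      } else {
        ts_tmp <- read_timeseries(file.path(dirname(inputs$ts_files[1]),
                                            paste0(stem, ".tsv")))
        mask <- rep(TRUE, nrow(ts_tmp))
      }
      if (is.null(masks[[subj]])) masks[[subj]] <- list()
      masks[[subj]][[sess]] <- mask
    }
    excl <- exclude_subjects(masks, cens$max_censored_fraction)
    path <- file.path(out_dir, "censoring_report.tsv")
    utils::write.table(excl$report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)
    excl
  })
  included <- censor_report$included

  # --- FC construction and assembly ---------------------------------------
  if (last >= 2) group <- .stage("build-fc", {
    fcs <- list()
    for (f in inputs$ts_files) {
      stem <- sub("\\.tsv$", "", basename(f))
      parts <- regmatches(stem, regexec("^(.*)_(monoband|multiband)$",
                                        stem))[[1]]
      subj <- parts[2]; sess <- parts[3]
      if (!subj %in% included) next
      ts <- read_timeseries(f)
      if (ncol(ts) != nrow(parc)) {
        stop("time series ", f, " has ", ncol(ts),
             " ROIs but the parcellation has ", nrow(parc))
      }
      fc <- compute_fc(ts, keep_mask = masks[[subj]][[sess]])
      fcs[[length(fcs) + 1]] <- list(values = fc, subject = subj,
                                     session = sess)
    }
    g <- assemble_group_matrix(fcs)
    if (isTRUE(config$fc$fisher_z)) {
      clipped <- pmin(pmax(g$matrix, -1 + 1e-7), 1 - 1e-7)
      g <- group_fc(atanh(clipped), g$index)
    }
    path <- file.path(out_dir, "group_fc.tsv")
    add(write_group_matrix(g, path))
    g
  })

  # --- identifiability sweep ----------------------------------------------
  if (last >= 3) sweep <- .stage("sweep", {
    sw <- sweep_identifiability(group, stride = config$sweep$stride)
    add(write_idiff_curve(sw, file.path(out_dir, "idiff_curve.tsv")))
    add(write_group_matrix(sw$reconstructed,
                           file.path(out_dir, "group_fc_reconstructed.tsv")))
    sw
  })

  # --- trait extraction ----------------------------------------------------
  if (last >= 4) traits <- .stage("extract", {
    ica <- config$ica
    n_comp <- if (is.null(ica$n_components)) {
      sweep$optimal_k
    } else ica$n_components
    tr <- extract_traits(sweep$reconstructed, n_components = n_comp,
                         n_runs = ica$n_runs,
                         match_threshold = ica$match_threshold,
                         min_frequency = ica$min_frequency,
                         seed = config$seed, tol = ica$tol,
                         maxit = ica$maxit)
    add(write_traits(tr, file.path(out_dir, "traits")))
    tr
  })
  wm <- if (last >= 4) trait_weight_matrix(traits) else NULL

  # --- statistics ----------------------------------------------------------
  st <- config$stats
  if (last >= 5) stats_res <- .stage("test", {
    zs <- compute_zscores(subjects, default_control_stats())
    mci <- classify_mci(zs)
    screening <- screen_traits(wm$weights, wm$index, subjects,
                               covariates = st$rm_covariates,
                               q = st$fdr_q)
    path <- file.path(out_dir, "trait_screening.tsv")
    utils::write.table(screening, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)
    path <- file.path(out_dir, "mci_classification.tsv")
    utils::write.table(mci, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)

    sig_idx <- which(screening$significant)
    groups <- unique(subjects$group)
    pairs <- if (length(groups) >= 2) utils::combn(groups, 2,
                                                   simplify = FALSE) else list()
    posthoc_rows <- list()
    assoc_rows <- list()
    if (length(sig_idx) > 0) {
      # M-row design for associations: pooled sessions, subject-level
      # covariates and composites replicated per row
      subj_cols <- cbind(
        subjects[c("subject_id", "group", "age", "gender", "tgm",
                   "etiv", "avg_enorm", "moca", "mmse", "mds_updrs_iii")],
        zs$composites[names(cognitive_domains())])
      at <- match(wm$index$subject, subj_cols$subject_id)
      row_data <- cbind(sequence = wm$index$session,
                        subj_cols[at, , drop = FALSE])
      rownames(row_data) <- NULL
      assoc_vars <- c(names(cognitive_domains()), "moca", "mmse",
                      "mds_updrs_iii")
      if (!isTRUE(st$hc_clinical_zeros)) {
        keep <- row_data$group != "HC"
      } else {
        keep <- rep(TRUE, nrow(row_data))
      }
      for (k in sig_idx) {
        w_k <- wm$weights[, k]
        for (pr in pairs) {
          ph <- posthoc_pairwise(w_k, wm$index, subjects, pr,
                                 covariates = st$rm_covariates)
          posthoc_rows[[length(posthoc_rows) + 1]] <- data.frame(
            trait = screening$trait[k], group_a = pr[1], group_b = pr[2],
            f = ph$f, p = ph$p,
            significant = !is.na(ph$p) & ph$p < st$posthoc_alpha,
            stringsAsFactors = FALSE)
        }
        assoc <- trait_associations(w_k[keep],
                                    row_data[keep, , drop = FALSE],
                                    assoc_vars,
                                    baseline_vars = st$baseline_vars,
                                    alpha = st$posthoc_alpha)
        assoc$trait <- screening$trait[k]
        assoc_rows[[length(assoc_rows) + 1]] <- assoc
      }
    }
    posthoc <- if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else
      data.frame()
    assoc <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else
      data.frame()
    path <- file.path(out_dir, "posthoc.tsv")
    utils::write.table(posthoc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)
    path <- file.path(out_dir, "associations.tsv")
    utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)
    list(screening = screening, posthoc = posthoc, associations = assoc,
         mci = mci, sig_idx = sig_idx)
  })

  # --- characterization ----------------------------------------------------
  if (last >= 6) .stage("characterize", {
    ch <- config$characterization
    for (k in stats_res$sig_idx) {
      summ <- summarize_trait(traits[[k]], parc, pct = ch$pct,
                              normalization = ch$normalization,
                              t_low = ch$t_low, t_high = ch$t_high)
      add(export_plot_data(summ, file.path(out_dir, "characterization")))
    }
    invisible(NULL)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("connica")),
    seed = config$seed,
    through = stages[last],
    n_subjects_included = length(included),
    n_subjects_excluded = length(setdiff(names(masks), included)),
    optimal_k = sweep$optimal_k,
    idiff_original = sweep$original$i_diff,
    idiff_optimal = sweep$optimal$i_diff,
    n_traits_extracted = if (is.null(traits)) NULL else length(traits),
    n_significant_traits = if (is.null(stats_res)) NULL else
      length(stats_res$sig_idx),
    significant_traits = if (is.null(stats_res)) NULL else
      stats_res$screening$trait[stats_res$sig_idx],
    label_rule = sprintf(
      "network score < %.2f: '-'; < %.2f: '+'; else '++'",
      config$characterization$t_low, config$characterization$t_high),
    config = config,
    manifest = manifest
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  report$manifest <- c(report$manifest, report_path)
  invisible(report)
}
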