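#' Study configuration for the end-to-end pipeline
#'
#' @param trials_dir,subjects_csv paths to a cohort on disk (delimited
#'   trial files named `<subject>_<session>.csv` plus a subject table), or
#' @param synthetic a [cohort_spec()] to simulate instead of reading.
#' @param quantities,axes kinectome types to analyse.
#' @param filter_policy a list(`cutoff_hz`, `order`) low-pass applied to
#'   positions before differentiation (see [axis_series()]), or `NULL`
#'   for none. Default: 4th-order zero-phase Butterworth at 4 Hz, a
#'   passband comfortably above the locomotor harmonics of a ~1-s gait
#'   cycle; without it the second and third derivatives of optical marker
#'   data are dominated by broadband noise, which differentiation
#'   amplifies by (2 pi f)^order.
#' @param n_perm permutations per test (default 10000).
#' @param consensus_iter Louvain runs per consensus round (default 100).
#' @param n_null random IR curves (default 100).
#' @param ir_threshold IR level defining edges of interest (default 0.99).
#' @param k_folds cross-validation folds (default 5).
#' @param seed master seed; stage seeds are spawned from it.
#' @param output_dir where artifacts are written (`NULL`: nothing written).
#' @return List of class `study_config`.
#' @export
study_config <- function(trials_dir = NULL, subjects_csv = NULL,
                         synthetic = NULL,
                         quantities = c("acceleration", "jerk"),
                         axes = c("ML", "AP", "V"),
                         filter_policy = list(cutoff_hz = 4, order = 4),
                         n_perm = 10000, consensus_iter = 100,
                         n_null = 100, ir_threshold = 0.99,
                         k_folds = 5, seed = 1, output_dir = NULL) {
  if (is.null(synthetic) && (is.null(trials_dir) || is.null(subjects_csv))) {
    stop_kin("provide either trials_dir + subjects_csv or a synthetic cohort_spec")
  }
  if (!all(axes %in% c("ML", "AP", "V"))) stop_kin("axes must be within ML, AP, V")
  if (!all(quantities %in% c("acceleration", "jerk"))) {
    stop_kin("quantities must be within acceleration, jerk")
  }
  counts <- c(n_perm, consensus_iter, n_null, k_folds)
  if (any(counts < 1)) stop_kin("all counts must be positive")
  structure(
    list(
      trials_dir = trials_dir, subjects_csv = subjects_csv,
      synthetic = synthetic, quantities = quantities, axes = axes,
      filter_policy = filter_policy, n_perm = n_perm,
      consensus_iter = consensus_iter, n_null = n_null,
      ir_threshold = ir_threshold, k_folds = k_folds,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "study_config"
  )
}

load_study_cohort <- function(config, marker_set = default_marker_set()) {
  if (!is.null(config$synthetic)) {
    return(generate_cohort(config$synthetic, marker_set))
  }
  subjects <- read_subjects(config$subjects_csv)
  files <- list.files(config$trials_dir, pattern = "_(test|retest)\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop_kin("no trial files in ", config$trials_dir)
  trials <- lapply(files, function(f) {
    base <- sub("\\.csv$", "", basename(f))
    session <- sub("^.*_", "", base)
    sid <- sub("_(test|retest)$", "", base)
    read_trial(f, format = "delimited", marker_set = marker_set,
               subject_id = sid, session = session)
  })
  list(trials = trials, subjects = subjects, truth = NULL)
}

#' Run the full kinectome study
#'
#' Orchestrates the pipeline on one cohort: builds all kinectomes, runs
#' the modularity, fingerprint, edge-selection and topology stages, and
#' (when the cohort has two groups, or `config2` supplies a comparison
#' cohort) the group comparisons and the clinical prediction model.
#' Artifacts are written to `config$output_dir` when set; a summary report
#' is returned and, when writing, stored as `report.json`.
#'
#' @param config a [study_config()].
#' @param config2 optional second cohort (comparison group) configuration;
#'   its trials are analysed with the same settings.
#' @param marker_set marker set common to all trials.
#' @param feature_marker marker whose weighted degree feeds the clinical
#'   model (`NULL`: the top marker flagged by node-occurrence
#'   significance).
#' @param feature_type kinectome type of the clinical feature as
#'   `c(quantity, axis)` (default acceleration, ML).
#' @return List of class `study_report`.
#' @export
run_study <- function(config, config2 = NULL,
                      marker_set = default_marker_set(),
                      feature_marker = NULL,
                      feature_type = c("acceleration", "ML")) {
  t_start <- Sys.time()
  log_msg <- function(...) message("[kinectome] ", ...)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  analyse_cohort <- function(cohort, cfg, tag) {
    pairing <- validate_session(cohort$trials, cohort$subjects)
    types <- expand.grid(
      quantity = cfg$quantities, axis = cfg$axes,
      stringsAsFactors = FALSE
    )
    log_msg("cohort '", tag, "': ", nrow(pairing), " subjects, ",
            nrow(types), " kinectome types (seed ", cfg$seed, ")")

    kins <- list() # [[type]][[session]] = list of kinectomes by subject
    for (ti in seq_len(nrow(types))) {
      q <- types$quantity[ti]; a <- types$axis[ti]
      key <- paste(q, a, sep = ".")
      kins[[key]] <- list(test = list(), retest = list())
      for (si in seq_len(nrow(pairing))) {
        for (sess in c("test", "retest")) {
          tr <- cohort$trials[[pairing[[sess]][si]]]
          kins[[key]][[sess]][[si]] <-
            build_kinectome(axis_series(tr, q, a, cfg$filter_policy))
        }
      }
    }

    res <- list(subjects = cohort$subjects, pairing = pairing, types = types)
    res$kinectomes <- kins
    res$edge_mats <- lapply(kins, function(k) {
      list(test = stack_edges(k$test), retest = stack_edges(k$retest))
    })

    # group-level mean/SD of the test-session kinectomes
    res$group_stats <- lapply(kins, function(k) {
      list(
        mean = group_edge_stats(k$test, "mean"),
        sd = group_edge_stats(k$test, "sd")
      )
    })

    # modularity: per-subject partitions pooled over quantities, per axis
    seed_mod <- spawn_seed(cfg$seed, 1L)
    res$allegiance <- list()
    res$group_partition <- list()
    for (a in intersect(c("ML", "AP", "V"), cfg$axes)) {
      parts <- list()
      for (q in cfg$quantities) {
        key <- paste(q, a, sep = ".")
        for (si in seq_along(kins[[key]]$test)) {
          adjacency <- prepare_adjacency(kins[[key]]$test[[si]])
          parts[[length(parts) + 1L]] <-
            louvain(adjacency, seed = spawn_seed(seed_mod, length(parts) + 1L))
        }
      }
      alg <- allegiance(parts)
      res$allegiance[[a]] <- alg
      res$group_partition[[a]] <- group_communities(
        alg, seed = spawn_seed(seed_mod, 999L), n_iter = cfg$consensus_iter
      )
    }

    # fingerprint per type
    res$fingerprint <- lapply(res$edge_mats, function(em) {
      fingerprint_scores(identifiability_matrix(em$test, em$retest))
    })

    # edge selection per type
    seed_es <- spawn_seed(cfg$seed, 3L)
    res$edge_selection <- list()
    for (key in names(res$edge_mats)) {
      em <- res$edge_mats[[key]]
      icc <- edge_icc(em$test, em$retest)
      curve <- ir_curve(em$test, em$retest, icc$edge_order)
      band <- null_ir_curves(
        em$test, em$retest, n_null = cfg$n_null,
        seed = spawn_seed(seed_es, match(key, names(res$edge_mats)))
      )
      eoi <- suppressWarnings(edges_of_interest(curve, cfg$ir_threshold))
      res$edge_selection[[key]] <- list(
        icc = icc, curve = curve, null_band = band, edges_of_interest = eoi
      )
    }

    # degrees per type (test session)
    res$degrees <- lapply(kins, function(k) {
      t(vapply(k$test, weighted_degree, numeric(nrow(marker_set))))
    })
    res
  }

  cohort1 <- load_study_cohort(config, marker_set)
  res1 <- analyse_cohort(cohort1, config, config$synthetic$group_label %||% "cohort1")
  report <- list(config = unclass(config)[setdiff(
                   names(config),
                   c("synthetic", "output_dir", "trials_dir", "subjects_csv")
                 )],
                 group1 = summarize_cohort(res1))
  full <- list(group1 = res1)

  if (!is.null(config2)) {
    cohort2 <- load_study_cohort(config2, marker_set)
    res2 <- analyse_cohort(cohort2, config2, config2$synthetic$group_label %||% "cohort2")
    full$group2 <- res2
    seed_cmp <- spawn_seed(config$seed, 4L)

    # SD comparison per type (mean over unique edges of the SD matrix,
    # permuting subject labels between the groups)
    sd_tests <- list()
    for (key in names(res1$kinectomes)) {
      sd_tests[[key]] <- permutation_sd_compare(
        res1$kinectomes[[key]]$test, res2$kinectomes[[key]]$test,
        n_perm = config$n_perm, seed = spawn_seed(seed_cmp, match(key, names(res1$kinectomes)))
      )
    }
    report$sd_comparison <- lapply(sd_tests, function(p) {
      list(observed = p$observed_stat, p_value = p$p_value)
    })
    report$sd_bonferroni_cutoff <- bonferroni_cutoff(length(sd_tests))

    # fingerprint comparisons: I-self, I-others, I-diff per type
    fp_tests <- list()
    for (key in names(res1$edge_mats)) {
      s1 <- res1$fingerprint[[key]]; s2 <- res2$fingerprint[[key]]
      for (score in c("iself", "iothers")) {
        ps <- paste0(score, "_per_subject")
        fp_tests[[paste(key, score, sep = ".")]] <- permutation_compare(
          s1[[ps]], s2[[ps]], n_perm = config$n_perm,
          seed = spawn_seed(seed_cmp, 100L + length(fp_tests))
        )
      }
      fp_tests[[paste(key, "idiff", sep = ".")]] <- permutation_compare(
        s1$iself_per_subject - s1$iothers_per_subject,
        s2$iself_per_subject - s2$iothers_per_subject,
        n_perm = config$n_perm, seed = spawn_seed(seed_cmp, 100L + length(fp_tests))
      )
    }
    report$fingerprint_comparison <- lapply(fp_tests, function(p) {
      list(observed = p$observed_stat, p_value = p$p_value)
    })
    report$fingerprint_bonferroni_cutoff <- bonferroni_cutoff(length(fp_tests))
  }

  # flagged markers from pooled AP/ML edges of interest of group1
  pooled_keys <- grep("\\.(ML|AP)$", names(res1$edge_selection), value = TRUE)
  edge_sets <- lapply(res1$edge_selection[pooled_keys], function(e) {
    as.integer(e$edges_of_interest)
  })
  edge_sets <- edge_sets[lengths(edge_sets) > 0]
  if (length(edge_sets)) {
    occ <- node_occurrence_significance(
      edge_sets, n_markers = nrow(marker_set),
      seed = spawn_seed(config$seed, 5L)
    )
    flagged <- marker_set$label[occ$significant]
    report$node_occurrence <- list(
      counts = stats::setNames(occ$counts, marker_set$label),
      flagged = flagged
    )
  } else {
    flagged <- character(0)
    report$node_occurrence <- list(counts = NULL, flagged = flagged)
  }

  # clinical model on group1 when it has motor scores and a feature marker
  fm <- feature_marker %||% (if (length(flagged)) flagged[1] else NULL)
  key_feat <- paste(feature_type[1], feature_type[2], sep = ".")
  if (!is.null(fm) && key_feat %in% names(res1$degrees) &&
      !anyNA(res1$subjects$motor_score) &&
      stats::sd(res1$subjects$motor_score) > 0 &&
      nrow(res1$subjects) >= max(2 * config$k_folds, 6) &&
      # every CV training fold must support the 5-coefficient model
      nrow(res1$subjects) - ceiling(nrow(res1$subjects) / config$k_folds) >= 6) {
    deg <- res1$degrees[[key_feat]][, fm]
    feats <- data.frame(
      degree = deg,
      age = res1$subjects$age,
      education = res1$subjects$education,
      gender = res1$subjects$sex,
      motor_score = res1$subjects$motor_score
    )
    model <- fit_clinical_model(
      feats, k = config$k_folds, seed = spawn_seed(config$seed, 6L)
    )
    sp <- spearman_corr(deg, res1$subjects$motor_score)
    report$clinical_model <- list(
      feature_marker = fm, feature_type = key_feat,
      coefficients = model$coefficients,
      r_squared = model$r_squared, cv_r_squared = model$cv_r_squared,
      vif = as.list(model$vif_per_predictor),
      spearman_rho = sp$rho, spearman_p = sp$p_value
    )
    full$clinical_model <- model
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))

  if (!is.null(out_dir)) {
    write_study_artifacts(full, report, out_dir, marker_set)
  }
  structure(
    list(report = report, details = full),
    class = "study_report"
  )
}

summarize_cohort <- function(res) {
  list(
    n_subjects = nrow(res$pairing),
    kinectome_types = names(res$kinectomes),
    fingerprint = lapply(res$fingerprint, function(s) {
      list(
        iself = s$iself, iothers = s$iothers,
        idiff_pct = 100 * s$idiff, ir_pct = 100 * s$ir
      )
    }),
    edges_to_threshold = lapply(res$edge_selection, function(e) {
      attr(e$edges_of_interest, "n_edges") %||% 0L
    }),
    group_partition = lapply(res$group_partition, function(p) {
      as.integer(p$community_id)
    })
  )
}

write_study_artifacts <- function(full, report, out_dir, marker_set) {
  res <- full$group1
  for (key in names(res$group_stats)) {
    write_kinectome(res$group_stats[[key]]$mean,
                    file.path(out_dir, paste0("mean_", key, ".csv")))
    write_kinectome(res$group_stats[[key]]$sd,
                    file.path(out_dir, paste0("sd_", key, ".csv")))
  }
  for (a in names(res$allegiance)) {
    write_kinectome(res$allegiance[[a]]$matrix,
                    file.path(out_dir, paste0("allegiance_", a, ".csv")))
    utils::write.csv(
      data.frame(marker = marker_set$label,
                 community = res$group_partition[[a]]$community_id),
      file.path(out_dir, paste0("partition_", a, ".csv")), row.names = FALSE
    )
  }
  for (key in names(res$edge_selection)) {
    es <- res$edge_selection[[key]]
    utils::write.csv(
      data.frame(
        count = es$curve$edge_counts, ir = es$curve$ir_values,
        null_mean = es$null_band$null_mean, null_p99 = es$null_band$null_p99
      ),
      file.path(out_dir, paste0("ir_curve_", key, ".csv")), row.names = FALSE
    )
  }
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE
  )
}

#' Permutation comparison of group kinectome variability
#'
#' Statistic: mean over the unique edges of the element-wise
#' across-subject SD matrix, compared between two groups of kinectomes by
#' permuting subject labels.
#'
#' @param kins_a,kins_b lists of [build_kinectome()] objects.
#' @param n_perm,seed see [permutation_compare()].
#' @return A `perm_test` object.
#' @export
permutation_sd_compare <- function(kins_a, kins_b, n_perm = 10000, seed = NULL) {
  va <- t(vapply(kins_a, vectorize, numeric(length(vectorize(kins_a[[1]])))))
  vb <- t(vapply(kins_b, vectorize, numeric(ncol(va))))
  stat <- function(xa, xb) {
    abs(mean(apply(xa, 2, stats::sd)) - mean(apply(xb, 2, stats::sd)))
  }
  observed <- stat(va, vb)
  pooled <- rbind(va, vb)
  na <- nrow(va)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(pooled), na)
      stat(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
    }, numeric(1))
  })
  structure(
    list(
      observed_stat = observed, null_stats = null_stats,
      p_value = (sum(null_stats >= observed) + 1) / (n_perm + 1),
      n_perm = n_perm, seed = seed
    ),
    class = "perm_test"
  )
}
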