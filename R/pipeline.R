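# End-to-end orchestration: per-subject kinematics -> waveforms -> per-sex
# clustering -> pooled PCA -> statistics layer.

#' Per-subject waveform extraction
#'
#' Runs the kinematic chain for one marker trial: centroid, double
#' differentiation, rotation into the pelvic frame, events (ground-truth
#' table when present, surrogate detector otherwise), step segmentation,
#' 80/20 normalization and step averaging. Also computes the vertical
#' excursion of the centroid.
#'
#' @param trial a `marker_trial`.
#' @param cfg a [run_config()].
#' @param use_truth_events prefer the trial's own event table when present.
#' @return A `step_waveform` with an extra `vertical_excursion_mm` element.
#' @export
subject_waveform <- function(trial, cfg = run_config(),
                             use_truth_events = TRUE) {
  centroid <- pelvic_centroid(trial$dynamic)
  acc_g <- double_differentiate(centroid, cfg)
  acc_l <- global_to_local(acc_g, trial$dynamic, trial$static)
  ev <- if (use_truth_events && !is.null(trial$events)) trial$events
        else detect_events(acc_l, cfg)
  steps <- suppressMessages(segment_steps(acc_l, ev))
  norm <- lapply(steps, time_normalize,
                 stance_points = cfg$stance_points,
                 flight_points = cfg$flight_points)
  w <- average_steps(norm, subject_id = trial$meta$subject_id,
                     stance_points = cfg$stance_points)
  w$vertical_excursion_mm <- vertical_excursion(centroid, ev)
  w
}

#' Run the full sub-grouping pipeline
#'
#' Given a cohort (marker-level trials or a waveform-level cohort), this
#' extracts per-subject step waveforms, clusters each sex stratum with Ward
#' linkage and variance-ratio cluster-number selection (with the
#' reference-null no-sub-structure check), fits one pooled PCA across all
#' subjects, screens components by group eta-squared, attributes flagged
#' components to the VT/AP/ML axes via squared loadings, reconstructs
#' group-mean waveforms, and runs the comparison layer (demographics,
#' involvement/injury-site chi-squared, vertical excursion, peak joint
#' angles, flagged PC scores) plus Pearson correlations of flagged PCs with
#' the variables that differed.
#'
#' Group labels for the pooled analyses are `male` plus one label per
#' female cluster; with two female clusters the smaller is `C1` and the
#' larger `C2`.
#'
#' @param cohort list of `marker_trial`s (from [make_cohort()] or
#'   [read_cohort()]) or a `waveform_cohort` (from
#'   [make_waveform_cohort()]).
#' @param cfg a [run_config()]; its `seed` drives the null checks.
#' @param use_truth_events prefer generator event tables when present.
#' @return A `run_manifest`: list with `config`, `seed`, `waveforms`,
#'   `meta`, `assignments` (subject/sex/cluster/group data frame), `strata`
#'   (per-sex `cluster_solution`s), `pca`, `feature_matrix`, `pc_summary`,
#'   `reconstructions`, `comparisons` (data frame), `comparison_objects`,
#'   `correlations`, `timings`, `warnings`.
#' @export
run_pipeline <- function(cohort, cfg = run_config(), use_truth_events = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warns <- character()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  if (inherits(cohort, "waveform_cohort")) {
    waveforms <- cohort$waveforms
    meta <- cohort$meta
  } else {
    waveforms <- lapply(cohort, function(tr) {
      tryCatch(subject_waveform(tr, cfg, use_truth_events),
               error = function(e)
                 stop("waveform stage failed for subject ",
                      tr$meta$subject_id, ": ", conditionMessage(e)))
    })
    meta <- do.call(rbind, lapply(cohort, `[[`, "meta"))
    meta$vertical_excursion_mm <-
      vapply(waveforms, `[[`, 0, "vertical_excursion_mm")
  }
  ids <- vapply(waveforms, `[[`, "", "subject_id")
  stopifnot(identical(ids, meta$subject_id))
  tick("waveforms")

  # per-sex clustering on the stratum's own standardized matrix
  seeds <- derive_seeds(cfg$seed %||% 1L, 4L)
  strata <- list()
  cluster_of <- setNames(rep(NA_character_, length(ids)), ids)
  for (sx in unique(meta$sex)) {
    keep <- which(meta$sex == sx)
    if (length(keep) < 4) {
      warns <- c(warns, paste0("stratum '", sx, "' has < 4 subjects; skipped"))
      next
    }
    fm_s <- build_feature_matrix(waveforms[keep])
    sol <- select_k(fm_s$X_std, k_range = cfg$k_range,
                    labels = fm_s$subjects, null_check = TRUE,
                    n_null = cfg$n_null,
                    seed = seeds[if (sx == "male") 1L else 2L])
    strata[[sx]] <- sol
    cl <- sol$labels
    if (isTRUE(sol$no_substructure)) {
      cluster_of[names(cl)] <- "1"
    } else {
      cluster_of[names(cl)] <- as.character(cl)
    }
  }
  tick("clustering")

  # pooled group labels: males as one group; female clusters ordered by size
  group <- ifelse(meta$sex == "male", "male", NA_character_)
  fcl <- cluster_of[meta$sex == "female"]
  if (length(fcl) && !all(is.na(fcl))) {
    sizes <- sort(table(fcl))
    glab <- setNames(paste0("C", seq_along(sizes)), names(sizes))
    group[meta$sex == "female"] <- glab[fcl]
  }
  assignments <- data.frame(subject_id = ids, sex = meta$sex,
                            cluster = unname(cluster_of[ids]),
                            group = group, stringsAsFactors = FALSE)

  # pooled PCA across sexes (one shared basis for group comparisons)
  fm <- build_feature_matrix(waveforms)
  if (any(fm$zero_variance))
    warns <- c(warns, paste0(sum(fm$zero_variance),
                             " zero-variance feature column(s)"))
  pca <- fit_pca(fm)
  es <- pc_effect_sizes(pca, group, threshold = cfg$effect_size_threshold)
  rl <- t(vapply(seq_len(ncol(pca$scores)),
                 function(j) relative_loading(pca, fm, j), numeric(3)))
  pc_summary <- data.frame(pc = es$pc,
                           explained_pct = pca$explained_pct,
                           eta_squared = es$eta_squared,
                           large_effect = es$large_effect,
                           vt_loading_pct = rl[, "VT"],
                           ap_loading_pct = rl[, "AP"],
                           ml_loading_pct = rl[, "ML"])
  flagged <- es$pc[es$large_effect]
  reconstructions <- lapply(flagged, function(j) {
    lapply(split(pca$scores[, j], group), function(s)
      reconstruct(pca, j, mean(s)))
  })
  names(reconstructions) <- paste0("PC", flagged)
  tick("pca")

  # statistics layer over the pooled groups
  comp_objs <- list()
  numeric_vars <- c("age", "height", "mass", "running_speed", "years_running",
                    "vertical_excursion_mm",
                    paste0("peak_", PEAK_ANGLE_NAMES))
  numeric_vars <- intersect(numeric_vars, names(meta))
  try_compare <- function(values, v) {
    tryCatch(compare_groups(values, group, alpha = cfg$alpha, variable = v),
             error = function(e) {
               warns <<- c(warns, paste0("comparison '", v, "' skipped: ",
                                         conditionMessage(e)))
               NULL
             })
  }
  for (v in numeric_vars)
    comp_objs[[v]] <- try_compare(meta[[v]], v)
  for (j in flagged) {
    v <- paste0("PC", j, "_score")
    comp_objs[[v]] <- try_compare(pca$scores[, j], v)
  }
  comp_objs <- Filter(Negate(is.null), comp_objs)
  cat_tests <- list()
  for (v in intersect(c("involvement", "injury_site"), names(meta))) {
    cv <- tryCatch(suppressWarnings(cramers_v(table(group, meta[[v]]))),
                   error = function(e) NULL)
    if (!is.null(cv)) cat_tests[[v]] <- cv
  }
  comparisons <- rbind(
    do.call(rbind, lapply(comp_objs, function(x) data.frame(
      variable = x$variable, test_used = x$test_used,
      statistic = x$statistic, df = paste(x$df, collapse = ","),
      p_value = x$p_value, effect_size = x$effect_size,
      effect_type = x$effect_type,
      posthoc = if (is.null(x$posthoc)) "" else
        paste(sprintf("%s:%.4g", x$posthoc$pair, x$posthoc$p_adjusted),
              collapse = "; ")))),
    do.call(rbind, lapply(names(cat_tests), function(v) data.frame(
      variable = v, test_used = "chi_squared",
      statistic = cat_tests[[v]]$chi2, df = as.character(cat_tests[[v]]$df),
      p_value = cat_tests[[v]]$p, effect_size = cat_tests[[v]]$v,
      effect_type = "cramers_v", posthoc = ""))))
  rownames(comparisons) <- NULL

  differed <- vapply(comp_objs, function(x) x$p_value < cfg$alpha, TRUE)
  diff_vars <- setdiff(names(differed)[differed], paste0("PC", flagged, "_score"))
  correlations <- NULL
  if (length(flagged) && length(diff_vars)) {
    correlations <- do.call(rbind, lapply(flagged, function(j) {
      do.call(rbind, lapply(diff_vars, function(v) {
        pr <- pearson_r(pca$scores[, j], meta[[v]])
        data.frame(pc = j, variable = v, r = pr$r, p = pr$p)
      }))
    }))
  }
  tick("stats")

  structure(list(config = cfg, seed = cfg$seed, waveforms = waveforms,
                 meta = meta, assignments = assignments, strata = strata,
                 pca = pca, feature_matrix = fm, pc_summary = pc_summary,
                 reconstructions = reconstructions,
                 comparisons = comparisons, comparison_objects = comp_objs,
                 categorical_tests = cat_tests,
                 correlations = correlations,
                 timings = as.list(timings), warnings = warns),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", nrow(x$assignments), " subjects\n", sep = "")
  for (s in names(x$strata)) {
    sol <- x$strata[[s]]
    cat("  ", s, ": k = ", sol$k_selected,
        if (isTRUE(sol$no_substructure)) " (no sub-structure)", "\n",
        sep = "")
  }
  fl <- x$pc_summary[x$pc_summary$large_effect, , drop = FALSE]
  if (nrow(fl))
    cat("  large-effect PCs: ",
        paste(sprintf("PC%d (eta2 %.2f, %.1f%% var)", fl$pc, fl$eta_squared,
                      fl$explained_pct), collapse = ", "), "\n", sep = "")
  invisible(x)
}
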