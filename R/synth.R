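# Subject-level synthesis: marker-level trials (full pipeline input) and a
# waveform-level fast path (pipeline mid-point) from the same per-subject
# parameter draws.

MARKER_OFFSETS <- rbind(  # rigid pelvic shell, lab axes (x,y,z) in mm
  P1 = c(80, 60, -20),
  P2 = c(80, -60, -20),
  P3 = c(-70, 50, 30),
  P4 = c(-70, -50, 30))

# Draw one subject's realized archetype (jittered waveform parameters,
# excursion target, demographics, peak angles) from the current RNG stream.
realize_subject <- function(spec, subject_id) {
  r <- spec
  jit <- function(x) x * (1 + stats::rnorm(1, 0, spec$amp_cv))
  r$vt_peak_g <- jit(spec$vt_peak_g)
  r$ap_peak_g <- jit(spec$ap_peak_g)
  r$ml_peak_g <- jit(spec$ml_peak_g)
  shift <- function(x, lo = 0.05, hi = 0.95) {
    # timing jitter is specified in cycle fraction; convert to stance fraction
    pmin(hi, pmax(lo, x + stats::rnorm(1, 0, spec$phase_sd / spec$stance_fraction)))
  }
  r$ap_peak_phase <- shift(spec$ap_peak_phase, lo = 0.3)
  r$ml_peak_phase <- shift(spec$ml_peak_phase)
  r$vertical_excursion_mm <-
    max(20, stats::rnorm(1, spec$vertical_excursion_mm, spec$excursion_sd_mm))
  # re-calibrated for the realized parameters
  r$vt_eff_peak <- NULL; r$vt_cos_amp <- NULL

  demo <- stats::rnorm(length(spec$demo_means), spec$demo_means, spec$demo_sds)
  names(demo) <- names(spec$demo_means)
  demo <- pmax(demo, c(age = 18, height = 1.4, mass = 40,
                       running_speed = 1.5, years_running = 0.5)[names(demo)])
  ang <- stats::rnorm(length(spec$peak_angle_means), spec$peak_angle_means,
                      spec$peak_angle_sds)
  names(ang) <- names(spec$peak_angle_means)
  meta <- data.frame(subject_id = subject_id, sex = spec$sex,
                     age = demo[["age"]], height = demo[["height"]],
                     mass = demo[["mass"]],
                     running_speed = demo[["running_speed"]],
                     years_running = demo[["years_running"]],
                     involvement = if (stats::runif(1) < spec$p_unilateral)
                       "unilateral" else "bilateral",
                     injury_site = if (stats::runif(1) < spec$p_single_site)
                       "single" else "multiple",
                     stringsAsFactors = FALSE)
  for (a in names(ang)) meta[[paste0("peak_", a)]] <- ang[[a]]
  list(spec = r, meta = meta, yaw_phase = stats::runif(1, 0, 2 * pi))
}

#' Ground-truth time-normalized step waveform of an archetype
#'
#' Evaluates the archetype waveform at exactly the phases the 80/20
#' normalization grid visits for this archetype's (frame-snapped) step
#' period and stance fraction. This is the reference against which the full
#' marker pipeline is checked.
#'
#' @param spec an [archetype_spec()] (possibly a realized subject spec).
#' @param cfg a [run_config()].
#' @return 3 x (stance_points + flight_points) matrix, rows VT/AP/ML.
#' @export
truth_step_waveform <- function(spec, cfg = run_config()) {
  period <- period_frames(spec, cfg$sampling_rate)
  to <- as.integer(round(spec$stance_fraction * period))
  stance_ph <- seq(0, to - 1, length.out = cfg$stance_points) / period
  flight_ph <- seq(to, period - 1, length.out = cfg$flight_points) / period
  waveform_model(c(stance_ph, flight_ph), spec)
}

#' Generate one synthetic subject (marker level)
#'
#' Builds a full motion-capture trial for one subject drawn from an
#' archetype: the pelvis translates along the double integral of the
#' subject's realized acceleration waveform (rotated by a small periodic
#' yaw), four markers ride rigidly on the pelvis, and white positional noise
#' is added to every marker coordinate. Ground-truth local accelerations,
#' events (exact, on the frame grid) and the realized excursion are
#' recorded. The same seed always yields an identical trial.
#'
#' @param spec an [archetype_spec()].
#' @param seed integer seed.
#' @param cfg a [run_config()].
#' @param noise_sd_mm marker noise SD; defaults to the archetype's
#'   `marker_noise_mm`. Set 0 for exact rigid trajectories.
#' @return A `marker_trial`: list with `dynamic`, `static`
#'   (trajectory tables), `events` (event table), `truth_local_acc`
#'   (data frame `frame, time, vt, ap, ml` in m/s^2), `truth_excursion_mm`,
#'   `meta` (one-row subject metadata), `archetype`, `realized`
#'   (the subject's realized [archetype_spec()]) and `period_frames`.
#' @export
make_subject <- function(spec, seed, cfg = run_config(),
                         noise_sd_mm = spec$marker_noise_mm) {
  with_seed(seed, {
    rs <- realize_subject(spec, sprintf("%s_s%d", spec$name, seed))
    build_marker_trial(rs, cfg, noise_sd_mm)
  })
}

build_marker_trial <- function(rs, cfg, noise_sd_mm) {
  spec <- calibrate_excursion(rs$spec, sampling_rate = cfg$sampling_rate)
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  period <- period_frames(spec, fs)
  n_frames <- as.integer(round(spec$trial_seconds * fs))

  # integrate the global acceleration on a 10x oversampled grid so that
  # trapezoidal error is negligible relative to the SG recovery tolerance
  ov <- 10L
  nf <- n_frames * ov
  tf <- (seq_len(nf) - 1) * dt / ov
  ph <- (tf * fs / period) %% 1
  a_loc <- waveform_model(ph, spec)                      # rows VT/AP/ML
  yaw <- (spec$yaw_amp_deg * pi / 180) * sin(2 * pi * ph + rs$yaw_phase)
  cy <- cos(yaw); sy <- sin(yaw)
  a_lab <- rbind(x = cy * a_loc["AP", ] - sy * a_loc["ML", ],
                 y = sy * a_loc["AP", ] + cy * a_loc["ML", ],
                 z = a_loc["VT", ])
  pos <- apply(a_lab, 1, function(a) {
    v <- as.numeric(pracma::cumtrapz(tf, a))
    v <- v - mean(v)                                     # no net drift
    as.numeric(pracma::cumtrapz(tf, v))
  })                                                     # nf x 3, metres
  keep <- seq(1, nf, by = ov)
  pos <- pos[keep, , drop = FALSE] * 1000                # mm at 200 Hz
  yaw200 <- yaw[keep]
  t200 <- tf[keep]

  marker_xyz <- function(positions, yaws) {
    do.call(rbind, lapply(seq_len(nrow(MARKER_OFFSETS)), function(m) {
      r <- MARKER_OFFSETS[m, ]
      cyy <- cos(yaws); syy <- sin(yaws)
      data.frame(frame = seq_along(yaws) - 1L,
                 time = (seq_along(yaws) - 1L) * dt,
                 marker_id = rownames(MARKER_OFFSETS)[m],
                 x = positions[, 1] + cyy * r[1] - syy * r[2],
                 y = positions[, 2] + syy * r[1] + cyy * r[2],
                 z = positions[, 3] + r[3],
                 stringsAsFactors = FALSE)
    }))
  }
  dyn <- marker_xyz(pos, yaw200)
  n_static <- as.integer(fs)                             # 1-s static trial
  static <- marker_xyz(matrix(0, n_static, 3), rep(0, n_static))
  if (noise_sd_mm > 0) {
    for (cc in c("x", "y", "z")) {
      dyn[[cc]] <- dyn[[cc]] + stats::rnorm(nrow(dyn), 0, noise_sd_mm)
      static[[cc]] <- static[[cc]] + stats::rnorm(nrow(static), 0, noise_sd_mm)
    }
  }
  dyn <- validate_trajectories(dyn)
  static <- validate_trajectories(static)

  strikes <- seq(0L, n_frames - 1L, by = period)
  strikes <- strikes[strikes + period <= n_frames - 1L]
  to_off <- as.integer(round(spec$stance_fraction * period))
  events <- validate_events(data.frame(
    step_index = seq_along(strikes) - 1L,
    foot_strike_frame = strikes,
    toe_off_frame = strikes + to_off,
    next_strike_frame = strikes + period))

  ph200 <- ((seq_len(n_frames) - 1L) %% period) / period
  truth <- waveform_model(ph200, spec)
  truth_local_acc <- data.frame(frame = seq_len(n_frames) - 1L, time = t200,
                                vt = truth["VT", ], ap = truth["AP", ],
                                ml = truth["ML", ])
  structure(list(dynamic = dyn, static = static, events = events,
                 truth_local_acc = truth_local_acc,
                 truth_excursion_mm = spec$vertical_excursion_mm,
                 meta = rs$meta, archetype = spec$name, realized = spec,
                 period_frames = period),
            class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  cat("<marker_trial> ", x$meta$subject_id, ": ",
      length(unique(x$dynamic$marker_id)), " markers, ",
      max(x$dynamic$frame) + 1L, " frames, ", nrow(x$events), " steps\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic cohort (marker level)
#'
#' Concatenates per-archetype subjects with per-subject seeds derived from
#' `seed`, then shuffles subject order deterministically. Defaults emulate
#' the reference cohort composition: 44 males, 26 + 40 females.
#'
#' @param specs list of [archetype_spec()]s; default [default_archetypes()].
#' @param seed integer master seed.
#' @param cfg a [run_config()].
#' @param noise_sd_mm marker noise override applied to every archetype
#'   (`NULL` keeps each archetype's own value).
#' @return List of `marker_trial` objects.
#' @export
make_cohort <- function(specs = default_archetypes(), seed = 1,
                        cfg = run_config(), noise_sd_mm = NULL) {
  stopifnot(length(specs) >= 1)
  total <- sum(vapply(specs, function(s) as.numeric(s$n_subjects), numeric(1)))
  seeds <- derive_seeds(seed, total + 1L)
  trials <- vector("list", total)
  i <- 0L
  for (sp in specs) {
    for (j in seq_len(sp$n_subjects)) {
      i <- i + 1L
      trials[[i]] <- make_subject(
        sp, seeds[i], cfg,
        noise_sd_mm = if (is.null(noise_sd_mm)) sp$marker_noise_mm
                      else noise_sd_mm)
    }
  }
  ord <- with_seed(seeds[total + 1L], sample.int(total))
  trials[ord]
}

#' Generate a synthetic cohort at the waveform level (fast path)
#'
#' Draws the same per-subject realizations as [make_cohort()] but emits the
#' step-averaged, time-normalized waveform each subject would contribute to
#' the feature matrix directly (ground-truth waveform plus residual
#' per-point noise emulating what survives step averaging), skipping marker
#' synthesis and kinematic recovery. Intended for simulation studies that
#' exercise the clustering/statistics layers over many seeded cohorts.
#'
#' @inheritParams make_cohort
#' @return List with `waveforms` (list of `step_waveform`), `meta`
#'   (row-bound subject metadata with a `vertical_excursion_mm` column
#'   carrying each subject's realized excursion) and `archetype`
#'   (character vector of ground-truth labels), classed `waveform_cohort`.
#' @export
make_waveform_cohort <- function(specs = default_archetypes(), seed = 1,
                                 cfg = run_config()) {
  stopifnot(length(specs) >= 1)
  total <- sum(vapply(specs, function(s) as.numeric(s$n_subjects), numeric(1)))
  seeds <- derive_seeds(seed, total + 1L)
  waveforms <- vector("list", total)
  metas <- vector("list", total)
  labels <- character(total)
  i <- 0L
  for (sp in specs) {
    for (j in seq_len(sp$n_subjects)) {
      i <- i + 1L
      res <- with_seed(seeds[i], {
        rs <- realize_subject(sp, sprintf("%s_s%d", sp$name, seeds[i]))
        w <- truth_step_waveform(calibrate_excursion(rs$spec,
                                                     sampling_rate = cfg$sampling_rate),
                                 cfg)
        w <- w + matrix(stats::rnorm(length(w), 0, sp$resid_noise_ms2),
                        nrow(w))
        list(rs = rs, w = w)
      })
      n_pts <- cfg$stance_points + cfg$flight_points
      waveforms[[i]] <- structure(
        list(subject_id = res$rs$meta$subject_id, axes = res$w,
             n_steps_averaged = NA_integer_,
             phase_grid = (seq_len(n_pts) - 1) / n_pts,
             stance_points = cfg$stance_points),
        class = "step_waveform")
      m <- res$rs$meta
      m$vertical_excursion_mm <- res$rs$spec$vertical_excursion_mm
      metas[[i]] <- m
      labels[i] <- sp$name
    }
  }
  ord <- with_seed(seeds[total + 1L], sample.int(total))
  structure(list(waveforms = waveforms[ord],
                 meta = do.call(rbind, metas[ord]),
                 archetype = labels[ord]),
            class = "waveform_cohort")
}
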