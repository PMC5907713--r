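# Acceleration archetypes. Each archetype is a smooth periodic 3-axis
# acceleration model of one step cycle (phase 0 = foot strike, stance on
# [0, stance_fraction), flight on [stance_fraction, 1)), built from a small
# number of Gaussian bumps per axis plus one vertical fundamental sinusoid
# whose amplitude is calibrated so the double-integrated vertical position
# has a prescribed peak-to-peak excursion. Amplitudes are in g, converted to
# m/s^2 at evaluation time.

#' Construct an acceleration archetype
#'
#' An archetype fixes the deterministic waveform shape of one sub-group of
#' runners plus the sampling distributions for between-subject variation
#' (amplitude/phase jitter, excursion, demographics, peak joint angles).
#'
#' Waveform anatomy per axis:
#' * VT: one positive Gaussian impact peak in early stance balanced by a
#'   broad negative bump in flight, plus an excursion-matching fundamental
#'   cosine aligned with the impact peak; the pair is calibrated so the
#'   total VT value at the peak phase equals exactly `vt_peak_g * 9.81`
#'   and the double-integrated position has the prescribed peak-to-peak
#'   excursion (see [calibrate_excursion()]).
#' * AP: a biphasic braking/propulsion pair - a negative (posterior) bump in
#'   early stance and a positive (anterior) bump of amplitude `ap_peak_g` at
#'   `ap_peak_phase` of stance; equal widths make the pair zero-mean.
#' * ML: one lateral bump of amplitude `ml_peak_g` at `ml_peak_phase` of
#'   stance, balanced by a broad opposite bump in the second half-cycle.
#'
#' @param name archetype label, e.g. `"male"`, `"female_C1"`, `"female_C2"`.
#' @param sex `"male"` or `"female"`.
#' @param n_subjects default number of subjects drawn from this archetype.
#' @param cadence steps per minute.
#' @param stance_fraction fraction of the step cycle spent in stance.
#' @param trial_seconds length of the dynamic trial.
#' @param vertical_excursion_mm mean peak-to-peak vertical pelvis excursion.
#' @param excursion_sd_mm between-subject SD of the excursion.
#' @param vt_peak_g,ap_peak_g,ml_peak_g axis peak amplitudes in g.
#' @param ap_peak_phase,ml_peak_phase peak timing as a fraction of stance.
#' @param vt_width,ap_width,ml_width Gaussian bump SDs in cycle fraction.
#' @param amp_cv between-subject coefficient of variation of amplitudes.
#' @param phase_sd between-subject SD of bump timing (cycle fraction).
#' @param resid_noise_ms2 residual per-point noise (m/s^2) of a step-averaged
#'   waveform, used by the waveform-level generator fast path.
#' @param marker_noise_mm white positional noise SD added to every marker
#'   coordinate.
#' @param yaw_amp_deg amplitude of the periodic pelvic yaw oscillation.
#' @param peak_angle_means,peak_angle_sds named numeric vectors (degrees)
#'   over `ankle_eversion, knee_flexion, knee_abduction,
#'   knee_external_rotation, hip_adduction, hip_internal_rotation`.
#' @param demo_means,demo_sds named numeric vectors over
#'   `age, height, mass, running_speed, years_running`.
#' @param p_unilateral probability of unilateral involvement.
#' @param p_single_site probability of a single injury site.
#' @return An object of class `archetype_spec`.
#' @seealso [default_archetypes()], [waveform_model()], [make_subject()]
#' @export
archetype_spec <- function(name, sex, n_subjects,
                           cadence = 170, stance_fraction = 0.65,
                           trial_seconds = 22,
                           vertical_excursion_mm, excursion_sd_mm = 2,
                           vt_peak_g, ap_peak_g, ap_peak_phase,
                           ml_peak_g, ml_peak_phase,
                           vt_width = 0.07, ap_width = 0.07, ml_width = 0.08,
                           amp_cv = 0.06, phase_sd = 0.012,
                           resid_noise_ms2 = 0.25,
                           marker_noise_mm = 0.5, yaw_amp_deg = 4,
                           peak_angle_means = NULL, peak_angle_sds = NULL,
                           demo_means = NULL, demo_sds = NULL,
                           p_unilateral = 0.5, p_single_site = 0.75) {
  stopifnot(stance_fraction > 0, stance_fraction < 1,
            vt_peak_g > 0, ap_peak_g > 0, ml_peak_g > 0,
            ap_peak_phase > 0, ap_peak_phase < 1,
            ml_peak_phase > 0, ml_peak_phase < 1,
            n_subjects >= 1, cadence > 0, vertical_excursion_mm > 0)
  spec <- list(name = name, sex = sex, n_subjects = as.integer(n_subjects),
               cadence = cadence, stance_fraction = stance_fraction,
               trial_seconds = trial_seconds,
               vertical_excursion_mm = vertical_excursion_mm,
               excursion_sd_mm = excursion_sd_mm,
               vt_peak_g = vt_peak_g, ap_peak_g = ap_peak_g,
               ap_peak_phase = ap_peak_phase, ml_peak_g = ml_peak_g,
               ml_peak_phase = ml_peak_phase, vt_width = vt_width,
               ap_width = ap_width, ml_width = ml_width,
               amp_cv = amp_cv, phase_sd = phase_sd,
               resid_noise_ms2 = resid_noise_ms2,
               marker_noise_mm = marker_noise_mm,
               yaw_amp_deg = yaw_amp_deg,
               peak_angle_means = peak_angle_means,
               peak_angle_sds = peak_angle_sds,
               demo_means = demo_means, demo_sds = demo_sds,
               p_unilateral = p_unilateral, p_single_site = p_single_site,
               vt_eff_peak = NULL, vt_cos_amp = NULL)
  class(spec) <- "archetype_spec"
  spec
}

#' Default archetype library
#'
#' Three archetypes emulating the reference cohort: 44 males, 26 females of
#' sub-group C1 and 40 of sub-group C2. Scalar anchors (group sizes,
#' vertical excursions 104.7/88.8/98.9 mm, peak-angle and demographic
#' means/SDs) follow the reference study's descriptive tables; the waveform
#' contrasts encode its qualitative findings: C2 has a higher vertical peak,
#' a greater forward peak and delayed AP/ML peaks; both female groups have
#' higher, later ML peaks than males; C1 matches males in VT/AP.
#' Acceleration amplitudes themselves are free design parameters (no
#' numeric amplitudes are published) chosen at physiological scale.
#'
#' @return Named list of three [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  angles <- function(...) {
    v <- c(...)
    names(v) <- PEAK_ANGLE_NAMES
    v
  }
  demo <- function(...) {
    v <- c(...)
    names(v) <- META_NUMERIC
    v
  }
  list(
    male = archetype_spec(
      "male", "male", 44,
      vertical_excursion_mm = 104.7, excursion_sd_mm = 2.1,
      vt_peak_g = 3.0, ap_peak_g = 1.2, ap_peak_phase = 0.55,
      ml_peak_g = 0.45, ml_peak_phase = 0.22,
      peak_angle_means = angles(7.2, 44.6, 9.3, 10.0, 8.2, 12.7),
      peak_angle_sds = angles(0.6, 0.9, 0.7, 1.4, 0.7, 1.1),
      demo_means = demo(35.1, 1.79, 77.2, 2.66, 8.6),
      demo_sds = demo(1.5, 0.01, 1.3, 0.03, 8.0),
      p_unilateral = 20 / 44, p_single_site = 33 / 44),
    female_C1 = archetype_spec(
      "female_C1", "female", 26,
      vertical_excursion_mm = 88.8, excursion_sd_mm = 2.7,
      vt_peak_g = 3.0, ap_peak_g = 1.2, ap_peak_phase = 0.55,
      ml_peak_g = 0.65, ml_peak_phase = 0.30,
      peak_angle_means = angles(4.1, 43.2, 11.9, 11.1, 10.9, 18.3),
      peak_angle_sds = angles(0.8, 1.2, 0.9, 1.8, 0.9, 1.4),
      demo_means = demo(30.9, 1.66, 59.1, 2.60, 7.0),
      demo_sds = demo(2.0, 0.01, 1.7, 0.04, 7.1),
      p_unilateral = 13 / 26, p_single_site = 19 / 26),
    female_C2 = archetype_spec(
      "female_C2", "female", 40,
      vertical_excursion_mm = 98.9, excursion_sd_mm = 2.2,
      vt_peak_g = 3.6, ap_peak_g = 1.5, ap_peak_phase = 0.65,
      ml_peak_g = 0.65, ml_peak_phase = 0.38,
      peak_angle_means = angles(4.2, 44.2, 12.4, 7.6, 11.6, 15.8),
      peak_angle_sds = angles(0.7, 0.9, 0.7, 1.4, 0.7, 1.1),
      demo_means = demo(36.4, 1.66, 63.4, 2.57, 9.0),
      demo_sds = demo(1.6, 0.01, 1.4, 0.03, 7.7),
      p_unilateral = 14 / 40, p_single_site = 32 / 40)
  )
}

# Gaussian bump table of an archetype: one row per bump,
# columns axis/amp (m/s^2)/center (cycle fraction)/width (cycle fraction).
# Balancing bumps make each axis integrate to ~0 over a cycle
# (amp * width sums to zero per axis; wrap-around mass is negligible).
bump_table <- function(spec) {
  sf <- spec$stance_fraction
  g <- GRAVITY
  c_vt <- 0.15 * sf
  vt_amp <- spec$vt_eff_peak %||% (spec$vt_peak_g * g)
  rbind(
    data.frame(axis = "vt", amp = vt_amp, center = c_vt,
               width = spec$vt_width),
    data.frame(axis = "vt",
               amp = -vt_amp * spec$vt_width / 0.08,
               center = sf + 0.4 * (1 - sf), width = 0.08),
    data.frame(axis = "ap", amp = spec$ap_peak_g * g,
               center = spec$ap_peak_phase * sf, width = spec$ap_width),
    data.frame(axis = "ap", amp = -spec$ap_peak_g * g,
               center = 0.45 * spec$ap_peak_phase * sf,
               width = spec$ap_width),
    data.frame(axis = "ml", amp = spec$ml_peak_g * g,
               center = spec$ml_peak_phase * sf, width = spec$ml_width),
    data.frame(axis = "ml",
               amp = -spec$ml_peak_g * g * spec$ml_width / 0.12,
               center = 0.75, width = 0.12)
  )
}

# Periodic Gaussian bump sum at cycle phases (vectorized; images k = -1,0,1
# cover wrap-around since widths << 1).
eval_bumps <- function(phase, bumps) {
  out <- numeric(length(phase))
  for (i in seq_len(nrow(bumps))) {
    for (k in -1:1) {
      d <- phase - bumps$center[i] + k
      out <- out + bumps$amp[i] * exp(-d^2 / (2 * bumps$width[i]^2))
    }
  }
  out
}

# Effective step period in seconds: an integer number of frames at
# `sampling_rate` closest to 60/cadence, so that ground-truth events lie
# exactly on the frame grid.
period_frames <- function(spec, sampling_rate = 200) {
  max(2L, as.integer(round(sampling_rate * 60 / spec$cadence)))
}

#' Calibrate the vertical excursion of an archetype
#'
#' The VT waveform is the impact bump pair plus an excursion corrector:
#' a fundamental cosine aligned with the impact peak minus the equally
#' sized aligned 3rd harmonic. The two corrector terms cancel exactly at
#' the peak phase, so the VT peak value stays `vt_peak_g * 9.81` while the
#' corrector's double-integrated position (dominated by the fundamental,
#' the 3rd harmonic being 9-fold attenuated) moves the peak-to-peak
#' vertical excursion onto `target_mm`. The corrector amplitude is solved
#' by root finding on the numerically integrated cycle.
#'
#' @param spec an [archetype_spec()].
#' @param target_mm target excursion; defaults to the spec's own value.
#' @param sampling_rate frame rate defining the snapped step period.
#' @return The spec with `$vt_eff_peak` (bump amplitude, m/s^2) and
#'   `$vt_cos_amp` (corrector amplitude, m/s^2) filled in.
#' @export
calibrate_excursion <- function(spec, target_mm = spec$vertical_excursion_mm,
                                sampling_rate = 200) {
  period_s <- period_frames(spec, sampling_rate) / sampling_rate
  n <- 2000L
  ph <- (seq_len(n) - 1) / n
  tt <- ph * period_s
  c_vt <- 0.15 * spec$stance_fraction
  om1 <- 2 * pi / period_s
  peak_target <- spec$vt_peak_g * GRAVITY
  cosal <- cos(2 * pi * (ph - c_vt))

  # bump amplitude absorbing the balance bump's wrap-around tail so the
  # bump pair alone contributes exactly peak_target at the peak phase
  amp_b <- peak_target
  for (it in 1:4) {
    sp2 <- spec
    sp2$vt_eff_peak <- amp_b
    vt_b <- bump_table(sp2)
    vt_b <- vt_b[vt_b$axis == "vt", ]
    amp_b <- amp_b - (eval_bumps(c_vt, vt_b) - peak_target)
  }
  # excursion corrector: aligned fundamental minus aligned 3rd harmonic
  # (equal amplitudes cancel at the peak phase; position response is
  # dominated by the fundamental)
  corr <- cosal - cos(3 * 2 * pi * (ph - c_vt))
  a_b <- eval_bumps(ph, vt_b)
  p2p_err <- function(a1) {
    a <- a_b + a1 * corr
    v <- as.numeric(pracma::cumtrapz(tt, a))
    v <- v - mean(v)
    p <- as.numeric(pracma::cumtrapz(tt, v))
    (max(p) - min(p)) * 1000 - target_mm
  }
  grid <- seq(-0.8, 0.8, by = 0.05) * peak_target
  vals <- vapply(grid, p2p_err, 0)
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn))
    stop("cannot reach excursion ", target_mm,
         " mm with this archetype's waveform")
  i <- sgn[which.min(abs(grid[sgn]))]
  a1 <- stats::uniroot(p2p_err, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  spec$vt_cos_amp <- a1
  spec$vt_eff_peak <- amp_b
  spec
}

#' Evaluate an archetype's 3-axis acceleration waveform
#'
#' Deterministic smooth periodic function of the step-cycle phase. The mean
#' over one cycle is ~0 on every axis, and the VT value at the VT peak phase
#' equals `vt_peak_g * 9.81` to within 1%.
#'
#' @param phase numeric vector of cycle fractions in `[0, 1)`.
#' @param spec an [archetype_spec()] (calibrated on the fly if needed).
#' @return 3 x length(phase) matrix, rows `VT`, `AP`, `ML`, in m/s^2.
#' @examples
#' sp <- default_archetypes()$female_C1
#' w <- waveform_model(seq(0, 0.99, by = 0.01), sp)
#' rowMeans(w)  # ~0 per axis
#' @export
waveform_model <- function(phase, spec) {
  if (any(!is.finite(phase)) || any(phase < 0 | phase >= 1))
    stop("phase must lie in [0, 1)")
  if (is.null(spec$vt_cos_amp)) spec <- calibrate_excursion(spec)
  bumps <- bump_table(spec)
  c_vt <- 0.15 * spec$stance_fraction
  vt <- eval_bumps(phase, bumps[bumps$axis == "vt", ]) +
    spec$vt_cos_amp * (cos(2 * pi * (phase - c_vt)) -
                         cos(3 * 2 * pi * (phase - c_vt)))
  ap <- eval_bumps(phase, bumps[bumps$axis == "ap", ])
  ml <- eval_bumps(phase, bumps[bumps$axis == "ml", ])
  out <- rbind(VT = vt, AP = ap, ML = ml)
  colnames(out) <- NULL
  out
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat("<archetype_spec> ", x$name, " (", x$sex, "), n = ", x$n_subjects,
      "\n", sep = "")
  cat(sprintf("  VT %.2fg | AP %.2fg @ %.2f stance | ML %.2fg @ %.2f stance | excursion %.1f mm\n",
              x$vt_peak_g, x$ap_peak_g, x$ap_peak_phase, x$ml_peak_g,
              x$ml_peak_phase, x$vertical_excursion_mm))
  invisible(x)
}
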