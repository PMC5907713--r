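specs <- default_archetypes()

test_that("waveform model anchors the VT peak and integrates to zero", {
  for (sp in specs) {
    spc <- calibrate_excursion(sp)
    c_vt <- 0.15 * spc$stance_fraction
    vt_peak <- waveform_model(c_vt, spc)["VT", 1]
    expect_lt(abs(vt_peak - sp$vt_peak_g * 9.81), 0.01 * sp$vt_peak_g * 9.81)
    w <- waveform_model(seq(0, 1 - 1e-3, length.out = 1000), spc)
    peaks <- apply(abs(w), 1, max)
    expect_true(all(abs(rowMeans(w)) < 0.01 * peaks))
  }
  expect_error(waveform_model(1.2, specs$male), "phase")
  expect_error(waveform_model(-0.1, specs$male), "phase")
})

test_that("C2 has a higher VT peak and a later ML peak than C1", {
  ph <- seq(0, 1 - 1e-4, length.out = 5000)
  w1 <- waveform_model(ph, calibrate_excursion(specs$female_C1))
  w2 <- waveform_model(ph, calibrate_excursion(specs$female_C2))
  expect_gt(max(w2["VT", ]), max(w1["VT", ]))
  expect_gt(ph[which.max(w2["ML", ])], ph[which.max(w1["ML", ])])
  # both female archetypes have higher, later ML peaks than males
  wm <- waveform_model(ph, calibrate_excursion(specs$male))
  for (wf in list(w1, w2)) {
    expect_gt(max(wf["ML", ]), max(wm["ML", ]))
    expect_gt(ph[which.max(wf["ML", ])], ph[which.max(wm["ML", ])])
  }
})

test_that("subjects are deterministic in the seed and rigid without noise", {
  sp <- specs$female_C1
  sp$trial_seconds <- 3
  t1 <- make_subject(sp, seed = 9)
  t2 <- make_subject(sp, seed = 9)
  expect_identical(t1, t2)
  t3 <- make_subject(sp, seed = 10)
  expect_false(identical(t1$dynamic$x, t3$dynamic$x))

  t0 <- make_subject(sp, seed = 9, noise_sd_mm = 0)
  xyz <- split(t0$dynamic[c("x", "y", "z")], t0$dynamic$marker_id)
  pair_d <- function(a, b) sqrt(rowSums((as.matrix(a) - as.matrix(b))^2))
  d12 <- pair_d(xyz[[1]], xyz[[2]])
  d13 <- pair_d(xyz[[1]], xyz[[3]])
  expect_lt(max(d12) - min(d12), 1e-6)
  expect_lt(max(d13) - min(d13), 1e-6)
})

test_that("noise-free trajectories reproduce the configured excursion", {
  sub <- cached_subject()
  tr <- sub$trial
  z <- sub$centroid$z
  per_step <- vapply(seq_len(nrow(tr$events)), function(i) {
    sel <- sub$centroid$frame >= tr$events$foot_strike_frame[i] &
      sub$centroid$frame < tr$events$next_strike_frame[i]
    diff(range(z[sel]))
  }, 0)
  expect_lt(abs(mean(per_step) - tr$truth_excursion_mm),
            0.005 * tr$truth_excursion_mm)
})

test_that("cohorts have the reference composition and are seed-stable", {
  co <- make_waveform_cohort(specs, seed = 1)
  expect_length(co$waveforms, 110)
  expect_equal(sum(co$meta$sex == "female"), 66)
  expect_equal(unname(table(co$archetype)[c("male", "female_C1", "female_C2")]),
               c(44, 26, 40), ignore_attr = TRUE)
  co2 <- make_waveform_cohort(specs, seed = 1)
  expect_identical(co$meta, co2$meta)
  co3 <- make_waveform_cohort(specs, seed = 2)
  expect_false(identical(co$meta$age, co3$meta$age))

  one <- list(archetype_spec("solo", "female", 1, vertical_excursion_mm = 90,
                             vt_peak_g = 3, ap_peak_g = 1.2,
                             ap_peak_phase = 0.55, ml_peak_g = 0.6,
                             ml_peak_phase = 0.3,
                             peak_angle_means = specs$male$peak_angle_means,
                             peak_angle_sds = specs$male$peak_angle_sds,
                             demo_means = specs$male$demo_means,
                             demo_sds = specs$male$demo_sds))
  expect_length(make_waveform_cohort(one, seed = 3)$waveforms, 1)
})

test_that("archetypes the clustering must separate are well-spaced", {
  co <- make_waveform_cohort(specs, seed = 11)
  X <- t(vapply(co$waveforms,
                function(w) c(w$axes["VT", ], w$axes["AP", ], w$axes["ML", ]),
                numeric(300)))
  lab <- co$archetype
  mu <- lapply(split(seq_len(nrow(X)), lab),
               function(i) colMeans(X[i, , drop = FALSE]))
  wsd <- vapply(split(seq_len(nrow(X)), lab), function(i) {
    Xi <- X[i, , drop = FALSE]
    sqrt(mean(rowSums(sweep(Xi, 2, colMeans(Xi))^2)))
  }, 0)
  dist_between <- function(a, b) sqrt(sum((mu[[a]] - mu[[b]])^2))
  # the female sub-groups drive the cluster analysis: > 3x within-spread
  expect_gt(dist_between("female_C1", "female_C2") / max(wsd), 3)
  # males differ from both female archetypes (mainly via the ML axis)
  expect_gt(dist_between("male", "female_C1") / max(wsd), 2)
  expect_gt(dist_between("male", "female_C2") / max(wsd), 3)
})

test_that("dynamic trials carry 60-80 steps at the default cadence", {
  sub <- cached_subject()
  expect_gte(nrow(sub$trial$events), 60)
  expect_lte(nrow(sub$trial$events), 80)
})
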