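test_that("step segmentation honors half-open intervals and drops edges", {
  n <- 80
  acc <- data.frame(frame = 0:(n - 1), time = (0:(n - 1)) / 200,
                    vt = sin(1:n), ap = cos(1:n), ml = 0.5 * sin(1:n))
  ev <- data.frame(step_index = 0L, foot_strike_frame = 0L,
                   toe_off_frame = 50L, next_strike_frame = 80L)
  steps <- segment_steps(acc, ev)
  expect_length(steps, 1)
  expect_equal(ncol(steps[[1]]$stance), 50)
  expect_equal(ncol(steps[[1]]$flight), 30)
  expect_equal(unname(steps[[1]]$stance["VT", 1]), acc$vt[1])

  n2 <- 160
  acc2 <- data.frame(frame = 0:(n2 - 1), time = (0:(n2 - 1)) / 200,
                     vt = sin(1:n2), ap = cos(1:n2), ml = 0.5 * sin(1:n2))
  acc2$vt[1:6] <- NA  # invalid edge region
  ev2 <- data.frame(step_index = 0:2,
                    foot_strike_frame = c(0L, 80L, 160L),
                    toe_off_frame = c(50L, 110L, 200L),
                    next_strike_frame = c(80L, 160L, 240L))
  expect_message(steps2 <- segment_steps(acc2, ev2), "dropped")
  expect_length(steps2, 1)
  expect_equal(attr(steps2, "n_dropped"), 2)
  acc$vt <- NA
  expect_error(suppressMessages(segment_steps(acc, ev)), "usable")
})

test_that("time normalization is exact where it should be", {
  step <- list(stance = matrix(rnorm(240), 3, 80,
                               dimnames = list(c("VT", "AP", "ML"), NULL)),
               flight = matrix(rnorm(60), 3, 20,
                               dimnames = list(c("VT", "AP", "ML"), NULL)))
  expect_equal(time_normalize(step), cbind(step$stance, step$flight),
               tolerance = 1e-12, ignore_attr = TRUE)

  ramp <- list(stance = matrix(rep(seq(0, 1, length.out = 55), each = 3), 3),
               flight = matrix(rep(seq(1, 0, length.out = 25), each = 3), 3))
  out <- time_normalize(ramp)
  expect_equal(out[1, 1:80], seq(0, 1, length.out = 80), tolerance = 1e-12)
  expect_equal(out[2, 81:100], seq(1, 0, length.out = 20), tolerance = 1e-12)

  # resampling a sine from double density matches direct evaluation
  dense <- list(stance = matrix(rep(sin(2 * pi * seq(0, 0.65,
                                                     length.out = 160)),
                                    each = 3), 3),
                flight = matrix(rep(sin(2 * pi * seq(0.65, 1,
                                                     length.out = 40)),
                                    each = 3), 3))
  out <- time_normalize(dense)
  ref <- c(sin(2 * pi * seq(0, 0.65, length.out = 80)),
           sin(2 * pi * seq(0.65, 1, length.out = 20)))
  expect_lt(max(abs(out[1, ] - ref)), 0.005)

  expect_error(time_normalize(list(stance = matrix(1, 3, 1),
                                   flight = ramp$flight)), "degenerate")
})

test_that("step averaging is the element-wise mean", {
  w <- matrix(rnorm(300), 3, 100, dimnames = list(c("VT", "AP", "ML"), NULL))
  avg <- average_steps(list(w, w, w), subject_id = "s1")
  expect_s3_class(avg, "step_waveform")
  expect_equal(avg$axes, w)
  expect_equal(avg$n_steps_averaged, 3)
  opp <- average_steps(list(w, -w))
  expect_equal(opp$axes, 0 * w)
  # idempotence of normalization on an already-normalized step
  renorm <- time_normalize(list(stance = w[, 1:80], flight = w[, 81:100]))
  expect_equal(renorm, w, tolerance = 1e-12)
})

test_that("step averages converge on the archetype waveform under noise", {
  sub <- cached_subject()
  cfg <- sub$cfg
  tr <- make_subject(default_archetypes()$female_C1, seed = 12, cfg = cfg)
  sw <- subject_waveform(tr, cfg)
  expect_gte(sw$n_steps_averaged, 58)
  ref <- truth_step_waveform(tr$realized, cfg)
  # step-averaged waveform within a few within-step standard errors
  expect_lt(sqrt(mean((sw$axes - ref)^2)), 0.5)
})

test_that("feature matrix is 110 x 300, standardized, and order-preserving", {
  co <- make_waveform_cohort(default_archetypes(), seed = 21)
  fm <- build_feature_matrix(co$waveforms)
  expect_equal(dim(fm$X_raw), c(110, 300))
  expect_equal(dim(fm$X_std), c(110, 300))
  expect_equal(fm$subjects, vapply(co$waveforms, `[[`, "", "subject_id"))
  expect_lt(max(abs(colMeans(fm$X_std))), 1e-9)
  expect_lt(max(abs(apply(fm$X_std, 2, sd) - 1)), 1e-9)
  expect_equal(nrow(fm$column_map), 300)
  expect_equal(unname(table(fm$column_map$axis)[c("VT", "AP", "ML")]),
               c(100, 100, 100), ignore_attr = TRUE)
  expect_equal(anyDuplicated(fm$column_map[c("axis", "point")]), 0)
  # VT block first, raw values traceable to the source waveform
  expect_equal(fm$X_raw[3, 1:100], unname(co$waveforms[[3]]$axes["VT", ]))

  expect_error(build_feature_matrix(co$waveforms[c(1, 1)]), "duplicate")
  expect_error(build_feature_matrix(co$waveforms[1]), "2 subjects")
})

test_that("zero-variance columns are flagged, not divided by zero", {
  w1 <- list(subject_id = "a",
             axes = matrix(1, 3, 100,
                           dimnames = list(c("VT", "AP", "ML"), NULL)))
  w2 <- w1
  w2$subject_id <- "b"
  class(w1) <- class(w2) <- "step_waveform"
  fm <- build_feature_matrix(list(w1, w2))
  expect_true(all(fm$zero_variance))
  expect_true(all(is.finite(fm$X_std)))
})
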