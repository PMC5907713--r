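cfg <- run_config()

test_that("pelvic centroid averages markers and flags missing ones", {
  one <- toy_trajectory(markers = list(M1 = c(3, 4, 5)))
  cen <- pelvic_centroid(one)
  expect_equal(unname(as.matrix(cen[c("x", "y", "z")])),
               matrix(c(3, 4, 5), 10, 3, byrow = TRUE))
  cube <- toy_trajectory(markers = list(
    A = c(0, 0, 0), B = c(10, 0, 0), C = c(0, 10, 0), D = c(10, 10, 0),
    E = c(0, 0, 10), F = c(10, 0, 10), G = c(0, 10, 10), H = c(10, 10, 10)))
  cen <- pelvic_centroid(cube)
  expect_equal(unname(as.matrix(cen[c("x", "y", "z")])),
               matrix(5, 10, 3))
  broken <- cube[!(cube$marker_id == "C" & cube$frame == 4), ]
  expect_error(pelvic_centroid(broken), "4")
})

test_that("SG derivative reproduces polynomials exactly and sines to 1%", {
  dt <- 1 / 200
  t <- seq(0, 2, by = dt)
  expect_lt(max(abs(stats::na.omit(sg_derivative(rep(4, 100), dt)))), 1e-12)
  d3 <- sg_derivative(t^3, dt, 11, 4)
  ok <- !is.na(d3)
  expect_equal(d3[ok], 3 * t[ok]^2, tolerance = 1e-9)
  d <- sg_derivative(sin(2 * pi * 3 * t), dt, 11, 4)
  ok <- !is.na(d)
  ref <- 6 * pi * cos(2 * pi * 3 * t)
  expect_lt(max(abs(d[ok] - ref[ok])) / max(abs(ref)), 0.01)
  expect_error(sg_derivative(1:5, dt, 11, 4), "shorter")
  expect_error(sg_derivative(1:20, dt, 4, 4), "order")
})

test_that("SG kernels agree with the signal package on odd windows", {
  for (p in list(c(11, 4), c(9, 3), c(7, 2))) {
    ours <- pelviclust:::sg_kernel(p[1], p[2])
    ref <- signal::sgolay(p[2], p[1], m = 1)
    mid <- (p[1] + 1) / 2
    expect_equal(unname(ours), unname(ref[mid, ]), tolerance = 1e-9)
  }
})

test_that("even SG windows evaluate at the documented half-sample shift", {
  dt <- 1 / 200
  t <- seq(0, 1, by = dt)
  d <- sg_derivative(t^3, dt, 10, 4)
  ok <- which(!is.na(d))
  # derivative evaluated at t + dt/2, stored at t
  expect_equal(d[ok], 3 * (t[ok] + dt / 2)^2, tolerance = 1e-9)
})

test_that("double differentiation recovers constant and sinusoidal accel", {
  n <- 600
  t <- (0:(n - 1)) / 200
  pos_mm <- cbind(0.5 * 1 * t^2, 0.5 * 2 * t^2, 0.5 * 3 * t^2) * 1000
  acc <- double_differentiate(pos_mm, cfg)
  ok <- !is.na(acc$vt)
  expect_equal(unique(round(acc$ap[ok], 9)), 1)
  expect_equal(unique(round(acc$ml[ok], 9)), 2)
  expect_equal(unique(round(acc$vt[ok], 9)), 3)
  for (f in c(1, 3, 5)) {
    A <- 0.05
    z <- A * sin(2 * pi * f * t) * 1000
    acc <- double_differentiate(cbind(0, 0, z), cfg)
    ok <- !is.na(acc$vt)
    ref <- -A * (2 * pi * f)^2 * sin(2 * pi * f * t)
    expect_lt(sqrt(mean((acc$vt[ok] - ref[ok])^2)) / sqrt(mean(ref[ok]^2)),
              0.02, label = paste("f =", f))
  }
})

test_that("rigid pose estimation is exact, proper and noise-tolerant", {
  S <- rbind(c(80, 60, -20), c(80, -60, -20), c(-70, 50, 30), c(-70, -50, 30))
  id <- estimate_pose(S, S)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(id$residual, 0, tolerance = 1e-12)

  Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- estimate_pose(S %*% t(Rz90), S)
  expect_equal(rot$rotation, Rz90, tolerance = 1e-9)
  expect_equal(det(rot$rotation), 1, tolerance = 1e-12)

  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  set.seed(1)
  angle_err <- replicate(50, {
    noisy <- S %*% t(Rz) + matrix(rnorm(12, 0, 0.5), 4, 3)
    p <- estimate_pose(noisy, S)
    expect_gt(p$residual, 0)
    rel <- p$rotation %*% t(Rz)
    acos(min(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
  })
  expect_lt(stats::quantile(angle_err, 0.95), 0.5)

  collinear <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(estimate_pose(collinear, collinear), "collinear|degenerate")
})

test_that("global-to-local undoes a constant yaw and the generator's pose", {
  traj <- toy_trajectory(n_frames = 6)
  acc <- data.frame(frame = 0:5, time = (0:5) / 200,
                    vt = rep(1, 6), ap = rep(2, 6), ml = rep(3, 6))
  # static == dynamic: local equals global
  loc <- global_to_local(acc, traj, traj)
  expect_equal(loc[c("vt", "ap", "ml")], acc[c("vt", "ap", "ml")],
               tolerance = 1e-9)
  # constant 90 degree yaw: global AP maps onto local ML and vice versa
  rot_markers <- toy_trajectory(n_frames = 6)
  xy <- as.matrix(rot_markers[c("x", "y")])
  rot_markers$x <- -xy[, 2]
  rot_markers$y <- xy[, 1]
  loc <- global_to_local(acc, rot_markers, traj)
  expect_equal(loc$vt, rep(1, 6), tolerance = 1e-9)
  expect_equal(loc$ap, rep(3, 6), tolerance = 1e-9)   # R^T maps y -> local x
  expect_equal(loc$ml, rep(-2, 6), tolerance = 1e-9)
})

test_that("the kinematic chain recovers the archetype waveform (noise-free)", {
  sub <- cached_subject()
  tr <- sub$trial
  ok <- which(!is.na(sub$acc_l$vt))
  rec <- as.matrix(sub$acc_l[ok, c("vt", "ap", "ml")])
  tru <- as.matrix(tr$truth_local_acc[ok, c("vt", "ap", "ml")])
  expect_lt(sqrt(mean((rec - tru)^2)) / sqrt(mean(tru^2)), 0.02)
  for (axn in 1:3)
    expect_lt(sqrt(mean((rec[, axn] - tru[, axn])^2)) /
                sqrt(mean(tru[, axn]^2)), 0.03)
})

test_that("event detection matches ground truth and rejects flat signals", {
  cfg_l <- run_config()
  tr <- make_subject(default_archetypes()$male, seed = 7, cfg = cfg_l)
  acc_l <- global_to_local(double_differentiate(pelvic_centroid(tr$dynamic),
                                                cfg_l),
                           tr$dynamic, tr$static)
  ev <- detect_events(acc_l, cfg_l)
  truth <- tr$events$foot_strike_frame
  det <- ev$foot_strike_frame
  near <- vapply(truth, function(f) min(abs(det - f)), 0)
  expect_gte(mean(near <= 2), 0.95)           # within 10 ms at 200 Hz
  expect_true(all(attr(ev, "confidence") > 0 & attr(ev, "confidence") <= 1))

  flat <- acc_l
  flat$vt <- 0.01
  flat$ap <- 0
  flat$ml <- 0
  expect_error(detect_events(flat, cfg_l), "periodic|flat")

  # externally supplied events bypass the detector
  expect_identical(detect_events(acc_l, cfg_l, events = tr$events),
                   validate_events(tr$events))
})

test_that("vertical excursion is the mean per-step peak-to-peak height", {
  n <- 400
  fr <- 0:(n - 1)
  A <- 12
  cen <- data.frame(frame = fr, time = fr / 200, x = 0, y = 0,
                    z = A * sin(2 * pi * fr / 100))
  ev <- data.frame(step_index = 0:2, foot_strike_frame = c(0L, 100L, 200L),
                   toe_off_frame = c(65L, 165L, 265L),
                   next_strike_frame = c(100L, 200L, 300L))
  expect_equal(vertical_excursion(cen, ev), 2 * A, tolerance = 1e-3)
  cen$z <- 5
  expect_equal(vertical_excursion(cen, ev), 0)
  expect_error(vertical_excursion(cen[1:10, ],
                                  data.frame(step_index = 0L,
                                             foot_strike_frame = 500L,
                                             toe_off_frame = 560L,
                                             next_strike_frame = 600L)),
               "steps")
})
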