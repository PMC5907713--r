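# Marker-cluster kinematics: centroid path, Savitzky-Golay double
# differentiation, rigid-body pose (Kabsch), global-to-local rotation of
# accelerations, surrogate event detection, vertical excursion.

#' Centroid of the pelvic marker cluster
#'
#' @param dynamic a `trajectory_table` with >= 3 markers (a single marker is
#'   accepted and passed through, e.g. for an accelerometer surrogate).
#' @return Data frame `frame, time, x, y, z` (mm), one row per frame.
#' @export
pelvic_centroid <- function(dynamic) {
  n_mark <- length(unique(dynamic$marker_id))
  counts <- table(dynamic$frame)
  bad <- counts != n_mark
  if (any(bad))
    stop("missing marker in frame ", names(counts)[bad][1])
  dynamic <- validate_trajectories(dynamic)
  agg <- stats::aggregate(dynamic[c("x", "y", "z")],
                          by = list(frame = dynamic$frame), FUN = mean)
  agg <- agg[order(agg$frame), ]
  tm <- dynamic$time[!duplicated(dynamic$frame)]
  tm <- tm[order(dynamic$frame[!duplicated(dynamic$frame)])]
  data.frame(frame = agg$frame, time = tm, x = agg$x, y = agg$y, z = agg$z)
}

# First-derivative Savitzky-Golay kernel. `u` holds symmetric sample offsets
# (half-integers for even windows); derivative of the LS polynomial fit,
# evaluated at the window center u = 0, is the second row of the
# pseudoinverse of the Vandermonde matrix.
sg_kernel <- function(window, order) {
  u <- (0:(window - 1)) - (window - 1) / 2
  A <- outer(u, 0:order, `^`)
  pinv <- solve(crossprod(A), t(A))
  pinv[2, ]
}

#' Savitzky-Golay first derivative
#'
#' Slides a least-squares polynomial fit of the given order over the signal
#' and evaluates the fitted polynomial's derivative analytically at the
#' window center. Odd windows are centered on a sample; an even window's
#' center falls between samples, so its output carries a documented
#' half-sample latency (the derivative at `t + dt/2` is stored at `t`).
#' Half-window edges are returned as `NA` and must be excluded downstream.
#'
#' @param x uniformly sampled numeric vector.
#' @param dt sampling interval in seconds.
#' @param window window length in samples (`> order`).
#' @param order polynomial order (>= the signal's local polynomial degree
#'   for exact reproduction).
#' @return Numeric vector of `length(x)` first-derivative estimates with
#'   `NA` in the half-window edge regions.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' d <- sg_derivative(t^3, 1 / 200, 11, 4)   # equals 3 t^2 away from edges
#' @export
sg_derivative <- function(x, dt, window = 11, order = 4) {
  window <- as.integer(window); order <- as.integer(order)
  if (order >= window) stop("window must exceed the polynomial order")
  n <- length(x)
  if (n < window) stop("signal shorter than the filter window (", n, " < ",
                       window, ")")
  if (anyNA(x)) stop("signal contains NA")
  w <- sg_kernel(window, order)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  emb <- stats::embed(x, window)        # row j: x[j+w-1], ..., x[j]
  out <- rep(NA_real_, n)
  out[(half_lo + 1L):(n - half_hi)] <- as.numeric(emb %*% rev(w)) / dt
  out
}

#' Double differentiation of a position trajectory
#'
#' Two sequential Savitzky-Golay derivative passes over each coordinate of
#' a centroid path, converting millimetres to metres. The invalid edge
#' region grows by one half-window per pass (one full window total).
#'
#' @param position data frame `frame, time, x, y, z` (mm) or an n x 3
#'   matrix of lab coordinates.
#' @param cfg a [run_config()] (supplies `sampling_rate`, `sg_window`,
#'   `sg_order`).
#' @return An acceleration series: data frame `frame, time, vt, ap, ml`
#'   (m/s^2) with attribute `frame_label = "global"`; edge rows are `NA`.
#' @export
double_differentiate <- function(position, cfg = run_config()) {
  if (is.matrix(position))
    position <- data.frame(frame = seq_len(nrow(position)) - 1L,
                           time = (seq_len(nrow(position)) - 1L) / cfg$sampling_rate,
                           x = position[, 1], y = position[, 2],
                           z = position[, 3])
  dt <- 1 / cfg$sampling_rate
  dd <- function(v) {
    v1 <- sg_derivative(v, dt, cfg$sg_window, cfg$sg_order)
    ok <- !is.na(v1)
    v2 <- rep(NA_real_, length(v))
    v2[ok] <- sg_derivative(v1[ok], dt, cfg$sg_window, cfg$sg_order)
    v2
  }
  acc <- data.frame(frame = position$frame, time = position$time,
                    vt = dd(position$z) / 1000,
                    ap = dd(position$x) / 1000,
                    ml = dd(position$y) / 1000)
  attr(acc, "frame_label") <- "global"
  acc
}

#' Least-squares rigid pose from marker sets
#'
#' Orthogonal-Procrustes (Kabsch) fit of the rotation + translation mapping
#' the static (local-frame) marker positions onto one frame's markers, with
#' reflection correction so the rotation is proper.
#'
#' @param frame_markers M x 3 matrix of marker positions in one dynamic
#'   frame (mm).
#' @param static_markers M x 3 matrix of the same markers in the static
#'   trial (defines the local frame; M >= 3, non-collinear).
#' @return A `rigid_pose`: list with `rotation` (3 x 3, local to global,
#'   det = +1), `translation` (length-3, mm) and `residual` (RMS fit error,
#'   mm).
#' @export
estimate_pose <- function(frame_markers, static_markers) {
  frame_markers <- as.matrix(frame_markers)
  static_markers <- as.matrix(static_markers)
  if (nrow(static_markers) < 3 || nrow(frame_markers) != nrow(static_markers))
    stop("need >= 3 matched markers")
  cs <- colMeans(static_markers); cf <- colMeans(frame_markers)
  S <- sweep(static_markers, 2, cs)
  Fm <- sweep(frame_markers, 2, cf)
  sv_s <- svd(S)$d
  if (sv_s[2] < 1e-6 * max(sv_s[1], 1e-12))
    stop("degenerate (collinear) marker configuration")
  H <- crossprod(S, Fm)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  fit <- S %*% t(R)
  residual <- sqrt(mean(rowSums((Fm - fit)^2)))
  structure(list(rotation = R, translation = as.numeric(cf - R %*% cs),
                 residual = residual),
            class = "rigid_pose")
}

# marker matrix (M x 3, ordered by marker id) for one frame
.markers_at <- function(traj, frame, ids) {
  rows <- traj[traj$frame == frame, ]
  rows <- rows[match(ids, rows$marker_id), ]
  as.matrix(rows[c("x", "y", "z")])
}

#' Rotate global accelerations into the pelvic frame
#'
#' Per frame, estimates the pelvis pose from the dynamic markers against
#' their static-trial configuration (static markers are time-averaged) and
#' premultiplies the global acceleration vector by the transpose of that
#' frame's rotation. The local frame coincides with the global frame in the
#' static pose.
#'
#' @param acc global acceleration series from [double_differentiate()].
#' @param dynamic,static trajectory tables of the dynamic and static
#'   trials.
#' @return The acceleration series in the local frame
#'   (`frame_label = "local"`), plus a `pose_residual_mm` attribute with
#'   the per-frame RMS rigid-fit error.
#' @export
global_to_local <- function(acc, dynamic, static) {
  dynamic <- validate_trajectories(dynamic)
  static <- validate_trajectories(static)
  ids <- sort(unique(dynamic$marker_id))
  if (!setequal(ids, unique(static$marker_id)))
    stop("dynamic and static trials carry different marker sets")
  S <- stats::aggregate(static[c("x", "y", "z")],
                        by = list(marker_id = static$marker_id), FUN = mean)
  S <- as.matrix(S[match(ids, S$marker_id), c("x", "y", "z")])
  frames <- acc$frame
  if (!all(frames %in% dynamic$frame))
    stop("acceleration frames not aligned with the dynamic trial")

  # pre-split dynamic rows by frame for speed
  dyn <- dynamic[order(dynamic$frame, dynamic$marker_id), ]
  M <- length(ids)
  xyz <- as.matrix(dyn[c("x", "y", "z")])
  n_frames <- nrow(dyn) / M
  out <- as.matrix(acc[c("ap", "ml", "vt")])  # lab order x, y, z
  res <- rep(NA_real_, nrow(acc))
  valid <- which(!is.na(acc$vt))
  frame_index <- match(acc$frame, unique(dyn$frame))
  for (i in valid) {
    fi <- frame_index[i]
    P <- xyz[((fi - 1) * M + 1):(fi * M), , drop = FALSE]
    pose <- estimate_pose(P, S)
    if (abs(det(pose$rotation) - 1) > 1e-9)
      stop("improper rotation at frame ", acc$frame[i])
    out[i, ] <- as.numeric(crossprod(pose$rotation, out[i, ]))
    res[i] <- pose$residual
  }
  loc <- data.frame(frame = acc$frame, time = acc$time,
                    vt = out[, 3], ap = out[, 1], ml = out[, 2])
  loc[is.na(acc$vt), c("vt", "ap", "ml")] <- NA_real_
  attr(loc, "frame_label") <- "local"
  attr(loc, "pose_residual_mm") <- res
  loc
}

#' Detect running gait events from vertical pelvic acceleration
#'
#' Surrogate detector: foot strikes are taken as the onsets of the
#' prominent vertical acceleration peaks (walking back from each peak to
#' the last 40%-of-peak upward crossing), with peaks separated by at least
#' 0.4 of the cadence period estimated from the dominant frequency of the
#' VT power spectrum. Toe-offs are placed at `cfg$stance_fraction` of each
#' strike-to-strike interval. If `events` is supplied the detector is
#' bypassed and the provided table is validated and returned.
#'
#' @param acc_local local-frame acceleration series (>= 3 s of valid
#'   signal).
#' @param cfg a [run_config()].
#' @param events optional externally measured event table (passthrough).
#' @return An `event_table` (0-based frames) with a `confidence` attribute
#'   (per-step peak height relative to the largest peak).
#' @export
detect_events <- function(acc_local, cfg = run_config(), events = NULL) {
  if (!is.null(events)) return(validate_events(events))
  fs <- cfg$sampling_rate
  ok <- which(!is.na(acc_local$vt))
  if (length(ok) < 3 * fs) stop("need at least 3 s of valid signal")
  off <- ok[1] - 1L                 # rows before the valid region
  vt <- acc_local$vt[ok]
  if (stats::sd(vt) < 1e-8) stop("no periodic structure found (flat signal)")

  # cadence from the dominant spectral line in the 1.2-4.5 Hz band
  v <- vt - mean(vt)
  n <- length(v)
  pw <- Mod(stats::fft(v))^2
  freq <- (seq_len(n) - 1) * fs / n
  band <- which(freq >= 1.2 & freq <= 4.5)
  if (max(pw[band]) < 5 * stats::median(pw[freq > 0.5 & freq <= 20]))
    stop("no periodic structure found in 1.2-4.5 Hz band")
  f_step <- freq[band[which.max(pw[band])]]
  period <- fs / f_step

  pk <- pracma::findpeaks(vt, minpeakdistance = max(2L, round(0.4 * period)),
                          minpeakheight = 0.5 * stats::quantile(vt, 0.98))
  if (is.null(pk) || nrow(pk) < 3) stop("no periodic structure found")
  locs <- sort(pk[, 2])
  heights <- vt[locs]

  strikes <- vapply(seq_along(locs), function(j) {
    i <- locs[j]; thr <- 0.4 * heights[j]
    lo <- max(1L, i - as.integer(round(0.8 * period)))
    below <- which(vt[lo:i] < thr)
    as.integer(if (!length(below)) lo else lo + below[length(below)])
  }, 0L)
  keepers <- !duplicated(strikes)
  strikes <- strikes[keepers]; heights <- heights[keepers]
  if (length(strikes) < 2) stop("no periodic structure found")

  frames0 <- acc_local$frame[ok[1]] + strikes - 1L  # 0-based frames
  iv <- diff(frames0)
  ev <- data.frame(step_index = seq_len(length(frames0) - 1L) - 1L,
                   foot_strike_frame = frames0[-length(frames0)],
                   toe_off_frame = frames0[-length(frames0)] +
                     as.integer(round(cfg$stance_fraction * iv)),
                   next_strike_frame = frames0[-1])
  ev <- validate_events(ev)
  attr(ev, "confidence") <- heights[-length(heights)] / max(heights)
  ev
}

#' Vertical excursion of the pelvic centroid
#'
#' Mean over step cycles of the peak-to-peak vertical coordinate of the
#' centroid within each `[strike, next_strike)` interval.
#'
#' @param centroid data frame from [pelvic_centroid()] (mm).
#' @param events an `event_table`.
#' @return Excursion in mm.
#' @export
vertical_excursion <- function(centroid, events) {
  events <- validate_events(events)
  p2p <- vapply(seq_len(nrow(events)), function(i) {
    sel <- centroid$frame >= events$foot_strike_frame[i] &
      centroid$frame < events$next_strike_frame[i]
    if (!any(sel)) return(NA_real_)
    z <- centroid$z[sel]
    max(z) - min(z)
  }, 0)
  p2p <- p2p[!is.na(p2p)]
  if (!length(p2p)) stop("no complete steps within the centroid trajectory")
  mean(p2p)
}
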