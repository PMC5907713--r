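# Step segmentation, 80/20 time normalization, step averaging, and the
# subjects-by-300 standardized feature matrix.

#' Segment a local acceleration series into step phases
#'
#' Each step contributes a stance segment `[strike, toe_off)` and a flight
#' segment `[toe_off, next_strike)` (frames 0-based, half-open). Steps that
#' overlap the invalid (NA) edge regions of the differentiated signal are
#' dropped; the number dropped is reported via a message and the
#' `n_dropped` attribute.
#'
#' @param acc_local local-frame acceleration series.
#' @param events an `event_table`.
#' @return List of steps, each a list with `stance` and `flight` 3 x L
#'   matrices (rows VT/AP/ML), with attribute `n_dropped`.
#' @export
segment_steps <- function(acc_local, events) {
  events <- validate_events(events)
  A <- t(as.matrix(acc_local[c("vt", "ap", "ml")]))
  rownames(A) <- c("VT", "AP", "ML")
  frame0 <- acc_local$frame[1]
  idx <- function(f) f - frame0 + 1L
  steps <- list()
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    fs <- events$foot_strike_frame[i]
    to <- events$toe_off_frame[i]
    ns <- events$next_strike_frame[i]
    if (fs < frame0 || ns > acc_local$frame[nrow(acc_local)] + 1L) {
      dropped <- dropped + 1L
      next
    }
    stance <- A[, idx(fs):(idx(to) - 1L), drop = FALSE]
    flight <- A[, idx(to):(idx(ns) - 1L), drop = FALSE]
    if (anyNA(stance) || anyNA(flight)) {
      dropped <- dropped + 1L
      next
    }
    steps[[length(steps) + 1L]] <- list(stance = stance, flight = flight)
  }
  if (dropped > 0)
    message(dropped, " step(s) dropped (overlapping invalid edge region)")
  if (!length(steps)) stop("zero usable steps")
  attr(steps, "n_dropped") <- dropped
  steps
}

#' Time-normalize one step to the stance/flight grid
#'
#' Stance and flight are resampled independently to `stance_points` and
#' `flight_points` samples by linear interpolation on closed-endpoint
#' grids, then concatenated. A phase already at its target length is
#' returned unchanged.
#'
#' @param step list with `stance` and `flight` 3 x L matrices.
#' @param stance_points,flight_points target lengths (defaults 80 / 20).
#' @return 3 x (stance_points + flight_points) matrix, rows VT/AP/ML.
#' @export
time_normalize <- function(step, stance_points = 80, flight_points = 20) {
  resample <- function(M, m) {
    L <- ncol(M)
    if (L < 2) stop("degenerate phase: fewer than 2 samples")
    t(apply(M, 1, function(v)
      stats::approx(seq(0, 1, length.out = L), v,
                    xout = seq(0, 1, length.out = m))$y))
  }
  out <- cbind(resample(step$stance, stance_points),
               resample(step$flight, flight_points))
  rownames(out) <- c("VT", "AP", "ML")
  out
}

#' Average normalized steps into a subject waveform
#'
#' @param normalized_steps list of 3 x 100 matrices from [time_normalize()].
#' @param subject_id subject identifier carried on the result.
#' @param stance_points stance grid length (for the phase map).
#' @return A `step_waveform`: list with `subject_id`, `axes` (3 x 100,
#'   element-wise mean), `n_steps_averaged`, `phase_grid` (cycle fractions)
#'   and `stance_points`.
#' @export
average_steps <- function(normalized_steps, subject_id = NA_character_,
                          stance_points = 80) {
  if (!length(normalized_steps)) stop("no steps to average")
  axes <- Reduce(`+`, normalized_steps) / length(normalized_steps)
  n_pts <- ncol(axes)
  structure(list(subject_id = subject_id, axes = axes,
                 n_steps_averaged = length(normalized_steps),
                 phase_grid = (seq_len(n_pts) - 1) / n_pts,
                 stance_points = as.integer(stance_points)),
            class = "step_waveform")
}

#' @export
print.step_waveform <- function(x, ...) {
  cat("<step_waveform> ", x$subject_id, ": 3 x ", ncol(x$axes),
      " (", x$n_steps_averaged, " steps averaged)\n", sep = "")
  invisible(x)
}

#' Assemble the subjects-by-300 feature matrix
#'
#' Concatenates each subject's VT, AP and ML waveforms (in that order) into
#' one row vector and column-standardizes across subjects. Zero-variance
#' columns are left unscaled and flagged rather than divided by zero.
#'
#' @param waveforms list of `step_waveform`s with identical grids.
#' @return A `feature_matrix`: list with `subjects`, `X_raw`, `X_std`
#'   (n x 3*points), `column_map` (axis and cycle point per column),
#'   `col_means`, `col_sds`, `zero_variance` (logical flags).
#' @export
build_feature_matrix <- function(waveforms) {
  if (length(waveforms) < 2) stop("need at least 2 subjects")
  ids <- vapply(waveforms, `[[`, "", "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ", ids[duplicated(ids)][1])
  n_pts <- ncol(waveforms[[1]]$axes)
  if (!all(vapply(waveforms, function(w) ncol(w$axes) == n_pts, TRUE)))
    stop("inconsistent waveform grids")
  X_raw <- t(vapply(waveforms,
                    function(w) c(w$axes["VT", ], w$axes["AP", ], w$axes["ML", ]),
                    numeric(3 * n_pts)))
  rownames(X_raw) <- ids
  column_map <- data.frame(column = seq_len(3 * n_pts),
                           axis = rep(c("VT", "AP", "ML"), each = n_pts),
                           point = rep(seq_len(n_pts), 3))
  mu <- colMeans(X_raw)
  sdv <- apply(X_raw, 2, stats::sd)
  zero_var <- sdv < 1e-12
  scl <- ifelse(zero_var, 1, sdv)
  X_std <- sweep(sweep(X_raw, 2, ifelse(zero_var, 0, mu)), 2, scl, `/`)
  structure(list(subjects = ids, X_raw = X_raw, X_std = X_std,
                 column_map = column_map, col_means = mu, col_sds = sdv,
                 zero_variance = zero_var),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X_raw), " subjects x ", ncol(x$X_raw),
      " features (", sum(x$zero_variance), " zero-variance columns)\n",
      sep = "")
  invisible(x)
}

# subset a list of waveforms + rebuild (strata share the same machinery)
subset_feature_matrix <- function(waveforms, keep) {
  build_feature_matrix(waveforms[keep])
}
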