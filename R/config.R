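#' Run configuration
#'
#' Bundles every tunable numeric parameter of the analysis chain. Defaults
#' reproduce the reference processing pipeline: 200 Hz capture, 4th-order
#' Savitzky-Golay derivative filtering, 80/20 stance/flight step
#' normalization, cluster counts searched over 2..10, and a large-effect
#' threshold of eta-squared > 0.14.
#'
#' @param sampling_rate capture rate in Hz.
#' @param sg_window Savitzky-Golay window length in samples. Odd windows are
#'   evaluated at the exact window center; even windows are honored via a
#'   half-sample-shift evaluation (see [sg_derivative()]).
#' @param sg_order polynomial order of the Savitzky-Golay fit; must be
#'   smaller than the window length.
#' @param stance_points,flight_points number of resampled points for the
#'   stance and flight phases of each step cycle (defaults 80 and 20).
#' @param k_range integer vector of cluster counts to score with the
#'   variance ratio criterion (lower bound must be >= 2).
#' @param effect_size_threshold eta-squared above which a principal
#'   component is flagged as carrying a large group effect.
#' @param alpha significance level for all hypothesis tests.
#' @param stance_fraction fraction of the strike-to-strike interval assigned
#'   to stance when toe-off events must be synthesized (running stance is
#'   roughly 60-70% of the step at endurance speeds).
#' @param n_null number of reference-null datasets for the no-sub-structure
#'   check in [select_k()].
#' @param seed integer seed driving every stochastic stage; `NULL` leaves
#'   the caller's RNG untouched.
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$stance_points + cfg$flight_points  # 100-point step cycle
#' @export
run_config <- function(sampling_rate = 200,
                       sg_window = 11,
                       sg_order = 4,
                       stance_points = 80,
                       flight_points = 20,
                       k_range = 2:10,
                       effect_size_threshold = 0.14,
                       alpha = 0.05,
                       stance_fraction = 0.65,
                       n_null = 99,
                       seed = NULL) {
  stopifnot(sampling_rate > 0, sg_window >= 2, sg_order >= 1)
  if (sg_order >= sg_window)
    stop("sg_order (", sg_order, ") must be smaller than sg_window (",
         sg_window, ")")
  stopifnot(stance_points >= 2, flight_points >= 2)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2) stop("k_range lower bound must be >= 2")
  stopifnot(effect_size_threshold > 0, alpha > 0, alpha < 1,
            stance_fraction > 0, stance_fraction < 1, n_null >= 1)
  structure(
    list(sampling_rate = sampling_rate, sg_window = as.integer(sg_window),
         sg_order = as.integer(sg_order),
         stance_points = as.integer(stance_points),
         flight_points = as.integer(flight_points), k_range = k_range,
         effect_size_threshold = effect_size_threshold, alpha = alpha,
         stance_fraction = stance_fraction, n_null = as.integer(n_null),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = " ")))
  }
  invisible(x)
}
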