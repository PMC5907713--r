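# External representations. All tables are plain CSV; the lab frame is
# right-handed with X = antero-posterior (anterior positive), Y =
# medio-lateral, Z = vertical (up positive). Coordinates are millimetres,
# frame indices 0-based, step intervals half-open [strike, next_strike).

TRAJ_COLS <- c("frame", "time", "marker_id", "x", "y", "z")
EVENT_COLS <- c("step_index", "foot_strike_frame", "toe_off_frame",
                "next_strike_frame")
PEAK_ANGLE_NAMES <- c("ankle_eversion", "knee_flexion", "knee_abduction",
                      "knee_external_rotation", "hip_adduction",
                      "hip_internal_rotation")
META_NUMERIC <- c("age", "height", "mass", "running_speed", "years_running")

#' Validate a marker trajectory table
#'
#' Checks the invariants every downstream stage relies on: all markers share
#' one strictly increasing, gap-free frame set; the sampling interval is
#' constant; all coordinates are finite.
#'
#' @param df data frame with columns `frame, time, marker_id, x, y, z`
#'   (millimetres, seconds).
#' @param sampling_rate optional expected rate in Hz, checked against the
#'   time column.
#' @return The validated data frame, ordered by marker then frame,
#'   invisibly classed as `trajectory_table`.
#' @export
validate_trajectories <- function(df, sampling_rate = NULL) {
  miss <- setdiff(TRAJ_COLS, names(df))
  if (length(miss))
    stop("trajectory table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("trajectory table contains non-finite coordinates")
  df <- df[order(df$marker_id, df$frame), , drop = FALSE]
  frames_by_marker <- split(df$frame, df$marker_id)
  ref <- frames_by_marker[[1]]
  for (m in names(frames_by_marker)) {
    fr <- frames_by_marker[[m]]
    d <- diff(fr)
    if (any(d <= 0))
      stop("frames not strictly increasing for marker '", m, "' at frame ",
           fr[which(d <= 0)[1] + 1L])
    if (any(d != d[1]))
      stop("gap in frame numbering for marker '", m, "' at frame ",
           fr[which(d != d[1])[1] + 1L])
    if (!identical(fr, ref))
      stop("marker '", m, "' does not share the common frame set")
  }
  tm <- df$time[df$marker_id == names(frames_by_marker)[1]]
  dts <- diff(tm)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6)
    stop("irregular sampling: time steps vary between ",
         signif(min(dts), 6), " and ", signif(max(dts), 6), " s")
  if (!is.null(sampling_rate) && length(dts)) {
    if (abs(1 / stats::median(dts) - sampling_rate) > 0.01 * sampling_rate)
      stop("file sampling rate ", signif(1 / stats::median(dts), 6),
           " Hz does not match configured rate ", sampling_rate, " Hz")
  }
  rownames(df) <- NULL
  class(df) <- c("trajectory_table", "data.frame")
  invisible(df)
}

#' Read marker trajectories
#'
#' @param path file path.
#' @param dialect `"csv"` (canonical; header `frame,time,marker_id,x,y,z`)
#'   or `"c3d"`. C3D support is feature-gated and unavailable in this build;
#'   convert C3D point data to the CSV dialect upstream.
#' @param cfg optional [run_config()] whose `sampling_rate` is checked
#'   against the file.
#' @return A validated `trajectory_table` data frame (coordinates in mm).
#' @export
read_trajectories <- function(path, dialect = c("csv", "c3d"), cfg = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d")
    stop("C3D input is not enabled in this build; export the point section ",
         "to the trajectory CSV dialect (frame,time,marker_id,x,y,z)")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trajectories(df, sampling_rate = if (!is.null(cfg)) cfg$sampling_rate)
}

#' @rdname read_trajectories
#' @param df trajectory table to write.
#' @export
write_trajectories <- function(df, path) {
  utils::write.csv(df[TRAJ_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a gait event table
#'
#' Frames are 0-based; each step is the half-open interval
#' `[foot_strike_frame, next_strike_frame)` with
#' `foot_strike < toe_off < next_strike`, and steps must be ordered and
#' non-overlapping.
#'
#' @param df data frame with columns `step_index, foot_strike_frame,
#'   toe_off_frame, next_strike_frame`.
#' @return The validated data frame, invisibly, classed `event_table`.
#' @export
validate_events <- function(df) {
  miss <- setdiff(EVENT_COLS, names(df))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$step_index), , drop = FALSE]
  bad <- !(df$foot_strike_frame < df$toe_off_frame &
             df$toe_off_frame < df$next_strike_frame)
  if (any(bad))
    stop("event ordering violated (need strike < toe-off < next strike) at step ",
         df$step_index[which(bad)[1]])
  if (nrow(df) > 1) {
    ov <- df$foot_strike_frame[-1] < df$next_strike_frame[-nrow(df)]
    if (any(ov))
      stop("overlapping steps at step ", df$step_index[which(ov)[1] + 1L])
  }
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  invisible(df)
}

#' Read / write gait event tables
#' @param path file path.
#' @return `read_events()` returns a validated `event_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_events(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_events
#' @param df event table to write.
#' @export
write_events <- function(df, path) {
  utils::write.csv(df[EVENT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write subject metadata
#'
#' One row per subject: `subject_id`, `sex` (male/female), demographics
#' (`age` years, `height` m, `mass` kg, `running_speed` m/s,
#' `years_running`), injury descriptors (`involvement`
#' unilateral/bilateral, `injury_site` single/multiple) and the six peak
#' joint angles in degrees as columns `peak_<angle>`.
#'
#' @param path file path.
#' @return A data frame of subject metadata.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", META_NUMERIC)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subject table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subject table")
  bad <- !df$sex %in% c("male", "female")
  if (any(bad)) stop("invalid sex value for subject ", df$subject_id[bad][1])
  df
}

#' @rdname read_subjects
#' @param df subject metadata data frame.
#' @export
write_subjects <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a run configuration as flat YAML
#' @param path file path.
#' @return `read_config()` returns a [run_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param cfg a [run_config()] object.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a full analysis report
#'
#' Serializes a completed [run_pipeline()] manifest as six files in
#' `out_dir`: cluster assignments, linkage tables, variance-ratio profiles,
#' a principal-component summary, the group-comparison table, and a
#' machine-readable run summary (YAML with the configuration echo and seed).
#' Numeric content is deterministic for a fixed seed and configuration.
#'
#' @param results a `run_manifest` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Data frame manifest of the files written.
#' @export
write_report <- function(results, out_dir) {
  if (!inherits(results, "run_manifest"))
    stop("results must be a run_manifest from run_pipeline()")
  if (is.null(results$assignments) || nrow(results$assignments) == 0)
    stop("refusing to write report: empty cluster solution")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  fp <- function(f) file.path(out_dir, f)
  wcsv <- function(d, f) utils::write.csv(d, fp(f), row.names = FALSE)

  wcsv(results$assignments, "cluster_assignments.csv")

  link <- do.call(rbind, lapply(names(results$strata), function(s) {
    m <- results$strata[[s]]$tree$merges
    cbind(stratum = s, m)
  }))
  wcsv(link, "linkage.csv")

  vrc <- do.call(rbind, lapply(names(results$strata), function(s) {
    v <- results$strata[[s]]$vrc_by_k
    data.frame(stratum = s, k = as.integer(names(v)), vrc = unname(v))
  }))
  wcsv(vrc, "variance_ratio.csv")

  wcsv(results$pc_summary, "pc_summary.csv")
  wcsv(results$comparisons, "group_comparisons.csv")

  summ <- list(
    seed = results$seed,
    config = unclass(results$config),
    n_subjects = nrow(results$assignments),
    groups = as.list(table(results$assignments$group)),
    k_selected = lapply(results$strata, `[[`, "k_selected"),
    no_substructure = lapply(results$strata, `[[`, "no_substructure"),
    timings_s = results$timings,
    warnings = results$warnings)
  yaml::write_yaml(summ, fp("run_summary.yaml"))

  files <- c("cluster_assignments.csv", "linkage.csv", "variance_ratio.csv",
             "pc_summary.csv", "group_comparisons.csv", "run_summary.yaml")
  data.frame(file = files, path = vapply(files, fp, ""), row.names = NULL)
}

#' Write / read a synthetic cohort as CSV files
#'
#' `write_cohort()` lays a marker-trial cohort out as `subjects.csv` plus
#' `<id>_dynamic.csv`, `<id>_static.csv`, `<id>_events.csv` per subject;
#' `read_cohort()` reconstructs the trial list (without generator ground
#' truth, which is not an external format).
#'
#' @param cohort list of `marker_trial` objects from [make_cohort()].
#' @param dir directory.
#' @param cfg optional [run_config()] for validation on read.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   of `marker_trial` objects.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort, `[[`, "meta"))
  write_subjects(meta, file.path(dir, "subjects.csv"))
  for (tr in cohort) {
    id <- tr$meta$subject_id
    write_trajectories(tr$dynamic, file.path(dir, paste0(id, "_dynamic.csv")))
    write_trajectories(tr$static, file.path(dir, paste0(id, "_static.csv")))
    write_events(tr$events, file.path(dir, paste0(id, "_events.csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, cfg = NULL) {
  meta <- read_subjects(file.path(dir, "subjects.csv"))
  lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$subject_id[i]
    dyn <- file.path(dir, paste0(id, "_dynamic.csv"))
    sta <- file.path(dir, paste0(id, "_static.csv"))
    evt <- file.path(dir, paste0(id, "_events.csv"))
    if (!file.exists(sta))
      stop("missing static trial file for subject ", id)
    structure(list(dynamic = read_trajectories(dyn, cfg = cfg),
                   static = read_trajectories(sta, cfg = cfg),
                   events = read_events(evt),
                   meta = meta[i, , drop = FALSE]),
              class = "marker_trial")
  })
}
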