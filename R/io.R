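# CSV dialects for marker, IMU and heel-contact event data, and tidy
# result writers. All readers validate rather than coerce: errors name
# the offending column or row. Units in files are SI (m, s, m/s^2,
# rad/s); millimetres appear only in reports.

check_time_column <- function(time_s, what, jitter = 1e-6) {
  if (length(time_s) == 0) stopf("data error: %s file is empty", what)
  dup <- which(duplicated(time_s))
  if (length(dup) > 0) {
    stopf("data error: duplicated timestamp in %s at row %d (t = %g s)",
          what, dup[1], time_s[dup[1]])
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0) {
    stopf("data error: non-monotonic time in %s at row %d", what, bad[1] + 1)
  }
  if (length(time_s) > 2) {
    dtv <- diff(time_s)
    if (max(dtv) - min(dtv) > jitter) {
      stopf("data error: %s time grid not uniform (jitter %.2e s exceeds %.0e s)",
            what, max(dtv) - min(dtv), jitter)
    }
  }
  invisible(time_s)
}

#' Read a marker trajectory CSV
#'
#' Expected header: `time_s`, then `ASIS_L_x, ASIS_L_y, ASIS_L_z`,
#' `ASIS_R_*`, `TOE_L_*`, `TOE_R_*`, positions in metres (lab frame: x
#' mediolateral +right, y anterior, z up from the belt surface). The time
#' grid must be strictly increasing and uniform within 1e-6 s jitter.
#'
#' @param path CSV file path.
#' @return Marker data frame.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", marker_columns())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("schema error in %s: missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  check_time_column(df$time_s, "marker data")
  df[, need]
}

#' Write a marker trajectory CSV
#'
#' @param markers Marker data frame (see [read_markers()]).
#' @param path Output path.
#' @export
write_markers <- function(markers, path) {
  check_marker_series(markers)
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' Read a 6-axis IMU CSV
#'
#' Expected header: `time_s, ax, ay, az, gx, gy, gz` (m/s^2, rad/s);
#' the site label is taken from a `site` column if present, else from
#' the file name without extension.
#'
#' @param path CSV file path.
#' @param site Optional site label overriding the file-derived one.
#' @return IMU data frame with attribute `site`.
#' @export
read_imu <- function(path, site = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", IMU_CHANNELS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("schema error in %s: missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  check_time_column(df$time_s, "IMU data")
  site <- site %||% (if ("site" %in% names(df)) df$site[1] else
    sub("\\.[^.]*$", "", basename(path)))
  out <- df[, need]
  attr(out, "site") <- site
  out
}

#' Write a 6-axis IMU CSV
#'
#' @param rec IMU data frame.
#' @param path Output path.
#' @param site Optional site label written as a `site` column.
#' @export
write_imu <- function(rec, path, site = attr(rec, "site")) {
  check_imu_recording(rec)
  out <- rec[, c("time_s", IMU_CHANNELS)]
  if (!is.null(site)) out$site <- site
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a heel-contact event CSV
#'
#' Expected header: `time_s, foot` with foot in left/right; times must be
#' strictly increasing.
#'
#' @param path CSV file path.
#' @return Event data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_s", "foot"), names(df))
  if (length(missing) > 0) {
    stopf("schema error in %s: missing column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  check_events(df)
}

#' Write a heel-contact event CSV
#'
#' @param events Event data frame (`time_s`, `foot`).
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  check_events(events)
  utils::write.csv(events[, c("time_s", "foot")], path, row.names = FALSE)
  invisible(path)
}

#' Write analysis results as tidy CSV
#'
#' Placement grids are written one row per cell with deterministic order
#' (single sites sorted first, then pairs lexicographically);
#' cross-validation results one row per fold x repetition; step-label
#' data frames as is. Rewriting the same result yields a byte-identical
#' file.
#'
#' @param x A `placement_grid`, `cv_result`, or data frame of step
#'   labels.
#' @param path Output path.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "placement_grid")) {
    df <- as.data.frame(x)
    single <- df$site_a == df$site_b
    df <- rbind(df[single, ][order(df$site_a[single]), ],
                df[!single, ][order(df$site_a[!single], df$site_b[!single]), ])
    rownames(df) <- NULL
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "cv_result")) {
    utils::write.csv(x$folds, path, row.names = FALSE)
  } else if (is.data.frame(x)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    stopf("I/O error: unsupported result type '%s'", class(x)[1])
  }
  invisible(path)
}

#' Write all components of a synthetic trial to a directory
#'
#' Emits `markers.csv`, `events.csv`, `labels.csv` (ground-truth step
#' labels) and one `imu_<site>.csv` per site, in the package CSV
#' dialects.
#'
#' @param trial A [generate_gait_trial()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_markers(trial$markers, file.path(dir, "markers.csv"))
  write_events(trial$events, file.path(dir, "events.csv"))
  utils::write.csv(trial$truth, file.path(dir, "labels.csv"), row.names = FALSE)
  for (site in names(trial$imu)) {
    write_imu(trial$imu[[site]], file.path(dir, paste0("imu_", site, ".csv")),
              site = site)
  }
  invisible(dir)
}
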