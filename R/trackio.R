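#' Construct a track set
#'
#' A track set is the unit of all diffusion statistics: a table of
#' per-molecule localizations (track id, frame index, x/y position in
#' micrometres, optional cell id and spot intensity) together with the
#' acquisition frame interval. Localizations are sorted by track and frame;
#' duplicate `(track_id, frame)` pairs are rejected.
#'
#' @param localizations data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` and optionally `cell_id`, `intensity`.
#' @param frame_interval_s acquisition frame interval in seconds (e.g. 0.030
#'   for a 30 ms stream acquisition).
#' @param condition_label optional label for the experimental condition
#'   (e.g. `"-DNA"`, `"+DNA"`).
#' @param loc_error_um optional known per-coordinate localization error
#'   (standard deviation, micrometres).
#' @return An object of class `track_set`.
#' @export
track_set <- function(localizations, frame_interval_s,
                      condition_label = NULL, loc_error_um = NULL) {
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(localizations))
  if (length(missing_cols) > 0L) {
    stop("localizations lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be a single positive number")
  }
  loc <- as.data.frame(localizations)
  loc$track_id <- as.character(loc$track_id)
  loc$frame <- as.integer(loc$frame)
  if (nrow(loc) > 0L) {
    if (anyNA(loc$frame) || any(loc$frame < 0L)) {
      stop("frame indices must be non-negative integers")
    }
    if (!all(is.finite(loc$x_um)) || !all(is.finite(loc$y_um))) {
      stop("coordinates must be finite")
    }
    loc <- loc[order(loc$track_id, loc$frame), , drop = FALSE]
    dup <- duplicated(loc[, c("track_id", "frame")])
    if (any(dup)) {
      stop("duplicate (track_id, frame) pair(s), first for track ",
           loc$track_id[which(dup)[1L]])
    }
    rownames(loc) <- NULL
  }
  structure(
    list(localizations = loc, frame_interval_s = frame_interval_s,
         condition_label = condition_label, loc_error_um = loc_error_um),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$localizations$track_id)
  cat("<track_set> ", length(ids), " tracks, ",
      nrow(x$localizations), " localizations, dt = ",
      x$frame_interval_s, " s",
      if (!is.null(x$condition_label)) paste0(" [", x$condition_label, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Number of tracks in a track set
#' @param ts a `track_set`
#' @return integer count of distinct tracks.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  length(unique(ts$localizations$track_id))
}

# split localizations into per-track data.frames (ordered by frame)
split_tracks <- function(ts) {
  loc <- ts$localizations
  split(loc, factor(loc$track_id, levels = unique(loc$track_id)))
}

#' Read a track table from CSV
#'
#' The track-table dialect has a required header
#' `track_id,frame,x_um,y_um[,cell_id,intensity]`; lines starting with `#`
#' are comments. Coordinates may alternatively be supplied in nanometres as
#' `x_nm,y_nm` with `units = "nm"`.
#'
#' @param path file path.
#' @param frame_interval_s frame interval in seconds.
#' @param units `"um"` (default) or `"nm"`; with `"nm"` the coordinate
#'   columns are `x_nm,y_nm` and are converted to micrometres.
#' @param condition_label,loc_error_um passed to [track_set()].
#' @return a `track_set`. Parse errors (missing columns, non-numeric
#'   coordinates, duplicate `(track_id, frame)` rows) name the offending
#'   file line.
#' @export
read_tracks <- function(path, frame_interval_s, units = c("um", "nm"),
                        condition_label = NULL, loc_error_um = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  if (length(line_no) < 1L) stop("empty track table: ", path)
  df <- utils::read.csv(text = lines[keep], stringsAsFactors = FALSE)
  data_line <- line_no[-1L]  # file line of each data row
  xcol <- if (units == "nm") "x_nm" else "x_um"
  ycol <- if (units == "nm") "y_nm" else "y_um"
  required <- c("track_id", "frame", xcol, ycol)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("frame", xcol, ycol)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(path, " line ", data_line[bad[1L]], ": non-numeric value in '",
           col, "'")
    }
    df[[col]] <- v
  }
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup)) {
    stop(path, " line ", data_line[which(dup)[1L]],
         ": duplicate (track_id, frame) row")
  }
  scale <- if (units == "nm") 1e-3 else 1
  out <- data.frame(track_id = as.character(df$track_id),
                    frame = as.integer(df$frame),
                    x_um = df[[xcol]] * scale,
                    y_um = df[[ycol]] * scale,
                    stringsAsFactors = FALSE)
  if ("cell_id" %in% names(df)) out$cell_id <- as.character(df$cell_id)
  if ("intensity" %in% names(df)) out$intensity <- as.numeric(df$intensity)
  track_set(out, frame_interval_s, condition_label = condition_label,
            loc_error_um = loc_error_um)
}

#' Write a track table to CSV
#'
#' Emits the same dialect that [read_tracks()] consumes, so a write/read
#' cycle round-trips losslessly.
#'
#' @param ts a `track_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  utils::write.csv(ts$localizations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by length and continuity
#'
#' Keeps tracks with at least `min_steps` steps (a track of n localizations
#' has n - 1 steps; 6 localizations = 5 steps is the boundary kept case at
#' the default) and, optionally, only non-interrupted tracks whose
#' consecutive frames differ by exactly one. This is the standard admission
#' filter applied before any diffusion statistic.
#'
#' @param ts a `track_set`.
#' @param min_steps minimum number of steps (default 5).
#' @param require_uninterrupted drop tracks with frame gaps (default TRUE).
#' @return a filtered `track_set`; track order is preserved. Idempotent.
#' @export
filter_tracks <- function(ts, min_steps = 5L, require_uninterrupted = TRUE) {
  stopifnot(inherits(ts, "track_set"))
  loc <- ts$localizations
  if (nrow(loc) == 0L) return(ts)
  keep_ids <- vapply(split_tracks(ts), function(tr) {
    n_steps <- nrow(tr) - 1L
    if (n_steps < min_steps) return(FALSE)
    if (require_uninterrupted && n_steps > 0L &&
        any(diff(tr$frame) != 1L)) return(FALSE)
    TRUE
  }, logical(1L))
  ids <- names(keep_ids)[keep_ids]
  out <- ts
  out$localizations <- loc[loc$track_id %in% ids, , drop = FALSE]
  rownames(out$localizations) <- NULL
  out
}

#' Locate the cut point of a photobleaching trace
#'
#' Stream-acquisition movies reach the single-molecule level only after the
#' initial bulk bleaching; the convention implemented here trims frames
#' until the relative intensity decline over a trailing window,
#' `(I[t - window] - I[t]) / I[t - window]`, first falls below
#' `decline_threshold` (default 10%).
#'
#' @param trace numeric intensity vector, or a two-column data.frame
#'   `frame,intensity`; frames are 0-based.
#' @param decline_threshold relative decline in (0, 1], default 0.10.
#' @param window trailing window in frames (>= 1).
#' @return the first 0-based frame index at which the decline criterion is
#'   met, or `NA_integer_` (with a warning) if the trace keeps declining by
#'   at least the threshold throughout ("no cut point").
#' @export
trim_bleaching <- function(trace, decline_threshold = 0.10, window = 1L) {
  if (is.data.frame(trace)) trace <- trace$intensity
  trace <- as.numeric(trace)
  if (!(decline_threshold > 0 && decline_threshold <= 1)) {
    stop("decline_threshold must lie in (0, 1]")
  }
  window <- as.integer(window)
  if (window < 1L || length(trace) < window + 1L) {
    stop("trace must be at least window + 1 frames long, window >= 1")
  }
  if (all(trace == 0)) stop("all-zero intensity trace")
  for (t in seq.int(window, length(trace) - 1L)) {  # 0-based frame t
    i_prev <- trace[t - window + 1L]
    i_now <- trace[t + 1L]
    if (i_prev <= 0) next
    if ((i_prev - i_now) / i_prev < decline_threshold) return(t)
  }
  warning("no cut point: trace declines by >= threshold throughout")
  NA_integer_
}

#' Pooled displacement sample at a given lag
#'
#' Pools, over all tracks, the Euclidean distance r between localizations
#' `lag` frames apart within the same track (the jump distance), and its
#' square u = r^2 (the squared displacement). These samples feed the
#' jump-distance and SQD mixture fits.
#'
#' @param ts a `track_set`.
#' @param lag lag in frames (default 1 = consecutive detections).
#' @return an object of class `jump_sample` with fields `lag`,
#'   `values_r_um`, `values_u_um2`, `n_steps`, `frame_interval_s`,
#'   `condition_label`. An empty sample (lag not realized in any track)
#'   carries `n_steps = 0` and a warning.
#' @export
displacement_sample <- function(ts, lag = 1L) {
  stopifnot(inherits(ts, "track_set"))
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  r <- unlist(lapply(split_tracks(ts), function(tr) {
    idx <- match(tr$frame + lag, tr$frame)
    ok <- !is.na(idx)
    if (!any(ok)) return(numeric(0L))
    sqrt((tr$x_um[idx[ok]] - tr$x_um[ok])^2 +
         (tr$y_um[idx[ok]] - tr$y_um[ok])^2)
  }), use.names = FALSE)
  if (length(r) == 0L) warning("empty displacement sample at lag ", lag)
  structure(
    list(lag = lag, values_r_um = r, values_u_um2 = r^2,
         n_steps = length(r), frame_interval_s = ts$frame_interval_s,
         condition_label = ts$condition_label),
    class = "jump_sample"
  )
}

#' @export
print.jump_sample <- function(x, ...) {
  cat("<jump_sample> lag ", x$lag, ", ", x$n_steps, " steps, dt = ",
      x$frame_interval_s, " s\n", sep = "")
  invisible(x)
}

#' MSD analysis and localization-error estimation
#'
#' Computes the ensemble-and-time-averaged mean squared displacement
#' MSD(tau) over lags 1..`max_lag` and fits a weighted line
#' MSD = intercept + slope * t. For 2D Brownian motion observed with
#' per-coordinate localization error sigma, slope = 4D and
#' intercept = 4 sigma^2, so sigma = sqrt(intercept / 4). The associated
#' confinement radius is defined as 3 sigma (e.g. sigma = 36.23 nm gives
#' the radius 108.7 nm used for the competence-pilin data).
#'
#' @param ts a `track_set`.
#' @param max_lag largest lag in frames (>= 2; default 4 — short-lag fits
#'   minimize confinement bias when estimating sigma).
#' @return an object of class `msd_curve` with fields `lags`, `msd_um2`,
#'   `n_pairs`, `slope_um2_per_s`, `intercept_um2`, `D_um2_s`,
#'   `loc_error_um`, `confinement_radius_um`, `negative_intercept` (flag:
#'   a negative fitted intercept is floored to sigma = 0 with a warning).
#' @export
msd_localization <- function(ts, max_lag = 4L) {
  stopifnot(inherits(ts, "track_set"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 2L) stop("max_lag must be >= 2")
  dt <- ts$frame_interval_s
  lags <- seq_len(max_lag)
  samples <- lapply(lags, function(l) displacement_sample(ts, lag = l))
  msd <- vapply(samples, function(s) mean(s$values_u_um2), numeric(1L))
  n_pairs <- vapply(samples, function(s) s$n_steps, numeric(1L))
  ok <- n_pairs > 0L
  if (sum(ok) < 2L) stop("not enough lags with data for an MSD fit")
  fit <- stats::lm(msd[ok] ~ I(lags[ok] * dt), weights = n_pairs[ok])
  intercept <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])
  negative_intercept <- intercept < 0
  if (negative_intercept) {
    warning("negative fitted MSD intercept; localization error set to 0")
  }
  loc_error <- sqrt(max(intercept, 0) / 4)
  structure(
    list(lags = lags, msd_um2 = msd, n_pairs = n_pairs,
         slope_um2_per_s = slope, intercept_um2 = intercept,
         D_um2_s = slope / 4, loc_error_um = loc_error,
         confinement_radius_um = 3 * loc_error,
         negative_intercept = negative_intercept,
         frame_interval_s = dt),
    class = "msd_curve"
  )
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("<msd_curve> lags 1..", max(x$lags),
      ", D = ", signif(x$D_um2_s, 3), " um^2/s, sigma = ",
      signif(x$loc_error_um * 1e3, 3), " nm, confinement radius = ",
      signif(x$confinement_radius_um * 1e3, 4), " nm\n", sep = "")
  invisible(x)
}
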