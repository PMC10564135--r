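# Per-track mobility classification and projection into a standardized
# rod-shaped cell. The standardized cell is 3 um long and 1 um wide,
# centred at the origin with its long axis along x (long axis spans
# [-1.5, 1.5] um, short axis [-0.5, 0.5] um).

STD_CELL_LENGTH <- 3
STD_CELL_WIDTH <- 1

#' Classify tracks as confined, transition or mobile
#'
#' Slides a window of `window_steps + 1` consecutive localizations along
#' each track; a window is "inside" when the maximum distance of its
#' localizations from the window centroid is at most `radius_um`. A track
#' is `confined` if every window is inside, `mobile` if none is, and
#' `transition` otherwise (the track switches between confined and more
#' mobile movement). The radius is conventionally 3x the localization
#' error from MSD analysis (108.7 nm for the competence-pilin data,
#' see [msd_localization()]).
#'
#' @param ts a `track_set` whose tracks all have at least `window_steps`
#'   steps (apply [filter_tracks()] first).
#' @param radius_um confinement radius in um (> 0).
#' @param window_steps window length in steps (default 5, the minimum
#'   admissible track length, so the shortest track forms one window).
#' @return a data.frame of class `track_classification` with columns
#'   `track_id`, `label` (factor confined/transition/mobile),
#'   `n_windows`, plus attributes `radius_um` and `window_steps`.
#' @export
classify_tracks <- function(ts, radius_um, window_steps = 5L) {
  stopifnot(inherits(ts, "track_set"))
  if (!(is.numeric(radius_um) && length(radius_um) == 1L && radius_um > 0)) {
    stop("radius_um must be a single positive number")
  }
  window_steps <- as.integer(window_steps)
  trs <- split_tracks(ts)
  n_steps <- vapply(trs, nrow, integer(1L)) - 1L
  if (any(n_steps < window_steps)) {
    stop(sum(n_steps < window_steps), " track(s) shorter than window_steps; ",
         "apply filter_tracks() first")
  }
  res <- lapply(trs, function(tr) {
    n <- nrow(tr)
    w <- window_steps + 1L
    n_win <- n - w + 1L
    inside <- logical(n_win)
    for (i in seq_len(n_win)) {
      x <- tr$x_um[i:(i + w - 1L)]
      y <- tr$y_um[i:(i + w - 1L)]
      inside[i] <- max(sqrt((x - mean(x))^2 + (y - mean(y))^2)) <= radius_um
    }
    if (all(inside)) "confined" else if (!any(inside)) "mobile" else "transition"
  })
  out <- data.frame(track_id = names(res),
                    label = factor(unlist(res),
                                   levels = c("confined", "transition",
                                              "mobile")),
                    n_windows = vapply(trs, nrow, integer(1L)) - window_steps,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "radius_um") <- radius_um
  attr(out, "window_steps") <- window_steps
  class(out) <- c("track_classification", "data.frame")
  out
}

#' Read cell outlines from CSV
#'
#' Outline dialect: `cell_id,x1_um,y1_um,x2_um,y2_um,width_um` — the
#' pole-to-pole centerline endpoints plus the cell width.
#'
#' @param path file path.
#' @return a data.frame of outlines; rows with `length < width` are
#'   rejected.
#' @export
read_outlines <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("cell_id", "x1_um", "y1_um", "x2_um", "y2_um", "width_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing outline column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  len <- sqrt((df$x2_um - df$x1_um)^2 + (df$y2_um - df$y1_um)^2)
  if (any(!(len >= df$width_um & df$width_um > 0))) {
    stop("outline(s) with length < width or non-positive width")
  }
  df$cell_id <- as.character(df$cell_id)
  df
}

std_cell_inside <- function(x, y, tol = 1e-9) {
  rod_inside2d(x, y, STD_CELL_LENGTH, STD_CELL_WIDTH, tol = tol)
}

#' Project localizations into the standardized cell
#'
#' Maps each localization into the frame of its cell (rotation by the cell
#' orientation around the centerline midpoint) and rescales the long and
#' short axes to the standardized 3 x 1 um cell, so that points from cells
#' of different sizes become comparable. Points falling outside the
#' standardized silhouette (possible through localization noise or
#' anisotropic rescaling) are clamped to its boundary and flagged.
#'
#' @param ts a `track_set` whose localizations carry `cell_id`.
#' @param outlines outline data.frame as from [read_outlines()] or
#'   [sim_outline()].
#' @param classification optional `track_classification`; adds a `label`
#'   column for downstream subsetting.
#' @return an object of class `normalized_projection`: a list with
#'   `points` (data.frame `track_id,frame,x,y,clamped[,label]` in
#'   standardized-cell um) and `clamped_fraction`.
#' @export
project_standard_cell <- function(ts, outlines, classification = NULL) {
  stopifnot(inherits(ts, "track_set"))
  loc <- ts$localizations
  if (!"cell_id" %in% names(loc) || anyNA(loc$cell_id)) {
    stop("all localizations must carry a cell_id")
  }
  idx <- match(loc$cell_id, outlines$cell_id)
  if (anyNA(idx)) {
    stop("missing outline for cell_id(s): ",
         paste(unique(loc$cell_id[is.na(idx)]), collapse = ", "))
  }
  o <- outlines[idx, , drop = FALSE]
  mx <- (o$x1_um + o$x2_um) / 2
  my <- (o$y1_um + o$y2_um) / 2
  theta <- atan2(o$y2_um - o$y1_um, o$x2_um - o$x1_um)
  len <- sqrt((o$x2_um - o$x1_um)^2 + (o$y2_um - o$y1_um)^2)
  dx <- loc$x_um - mx
  dy <- loc$y_um - my
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  xs <- xr * STD_CELL_LENGTH / len
  ys <- yr * STD_CELL_WIDTH / o$width_um
  clamped <- !std_cell_inside(xs, ys)
  if (any(clamped)) {
    b <- rod_boundary_project2d(xs[clamped], ys[clamped],
                                STD_CELL_LENGTH, STD_CELL_WIDTH)
    xs[clamped] <- b$bx
    ys[clamped] <- b$by
  }
  pts <- data.frame(track_id = loc$track_id, frame = loc$frame,
                    x = xs, y = ys, clamped = clamped,
                    stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    pts$label <- classification$label[match(pts$track_id,
                                            classification$track_id)]
  }
  structure(
    list(points = pts, clamped_fraction = mean(clamped),
         cell_length_um = STD_CELL_LENGTH, cell_width_um = STD_CELL_WIDTH),
    class = "normalized_projection"
  )
}

#' @export
print.normalized_projection <- function(x, ...) {
  cat("<normalized_projection> ", nrow(x$points), " points in a ",
      x$cell_length_um, " x ", x$cell_width_um, " um standardized cell (",
      signif(100 * x$clamped_fraction, 3), "% clamped)\n", sep = "")
  invisible(x)
}

#' Binned density map over the standardized cell
#'
#' 2D histogram of projected localizations over the standardized 3 x 1 um
#' cell at the given bin size (the heat-map representation of confined
#' tracks), optionally restricted to one classification label.
#'
#' @param projection a `normalized_projection`.
#' @param bin_size_um bin edge length in um (default 0.05, a 60 x 20
#'   grid); must not exceed the cell dimensions.
#' @param subset optional label filter (`"confined"`, `"transition"`,
#'   `"mobile"`); requires the projection to carry labels.
#' @return a list of class `density_grid` with `counts` (rows = y bins,
#'   columns = x bins; the grid total equals the point count),
#'   `normalized` (counts / max), `bin_size_um`, `x_breaks`, `y_breaks`.
#' @export
density_map <- function(projection, bin_size_um = 0.05, subset = NULL) {
  stopifnot(inherits(projection, "normalized_projection"))
  pts <- projection$points
  if (!is.null(subset)) {
    if (is.null(pts$label)) stop("projection carries no labels to subset on")
    pts <- pts[!is.na(pts$label) & pts$label == subset, , drop = FALSE]
  }
  if (nrow(pts) == 0L) stop("no points to bin")
  L <- projection$cell_length_um
  W <- projection$cell_width_um
  if (bin_size_um > W || bin_size_um > L || bin_size_um <= 0) {
    stop("bin_size_um must be positive and no larger than the cell")
  }
  x_breaks <- seq(-L / 2, L / 2, by = bin_size_um)
  if (x_breaks[length(x_breaks)] < L / 2) x_breaks <- c(x_breaks, L / 2)
  y_breaks <- seq(-W / 2, W / 2, by = bin_size_um)
  if (y_breaks[length(y_breaks)] < W / 2) y_breaks <- c(y_breaks, W / 2)
  xi <- cut(pts$x, x_breaks, include.lowest = TRUE, labels = FALSE)
  yi <- cut(pts$y, y_breaks, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, length(y_breaks) - 1L, length(x_breaks) - 1L)
  for (i in seq_along(xi)) {
    counts[yi[i], xi[i]] <- counts[yi[i], xi[i]] + 1L
  }
  structure(
    list(counts = counts, normalized = counts / max(counts),
         bin_size_um = bin_size_um, x_breaks = x_breaks, y_breaks = y_breaks,
         n_points = nrow(pts)),
    class = "density_grid"
  )
}

#' Write a density grid as a plain matrix CSV
#'
#' One `#` header line records the bin size and extents; rows are y bins
#' (bottom to top), columns x bins.
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @param normalized write the max-1 normalized copy instead of raw
#'   counts.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path, normalized = FALSE) {
  stopifnot(inherits(grid, "density_grid"))
  m <- if (normalized) grid$normalized else grid$counts
  header <- sprintf("# bin_size_um=%g x=[%g,%g] y=[%g,%g]",
                    grid$bin_size_um, min(grid$x_breaks), max(grid$x_breaks),
                    min(grid$y_breaks), max(grid$y_breaks))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
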