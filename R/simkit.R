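#' Simulation configuration for two-state membrane diffusion
#'
#' Ground-truth generative parameters for synthetic track sets. The default
#' values emulate the conditions under which competence-pilin dynamics were
#' recorded: a 30 ms stream acquisition, ~35 nm per-coordinate localization
#' error, a slow/static population of about a third of the molecules (an
#' immobile anchor whose apparent mobility is pure localization error,
#' sigma^2/dt ~ 0.04 um^2/s), a fast membrane-diffusing population with
#' apparent D ~ 0.51 um^2/s, bleaching-limited track lengths, and a
#' 3 x 1 um spherocylindrical cell.
#'
#' @param n_tracks number of molecules to simulate (before the minimum-step
#'   filter).
#' @param frame_interval_s frame interval in seconds (default 0.030).
#' @param slow_fraction probability that a molecule starts in the slow
#'   state (default 0.324).
#' @param D_slow_true true diffusion coefficient of the slow state in
#'   um^2/s, before localization noise (default 0: immobile anchor).
#' @param D_fast_true true diffusion coefficient of the fast state
#'   (default 0.47, i.e. apparent 0.51 with the default sigma).
#' @param loc_error_um per-coordinate localization error sigma in um
#'   (default `sqrt(0.04 * 0.030)` = 0.0346, so that sigma^2/dt = 0.04).
#' @param confinement_radius_true_um excursion bound of the anchored state
#'   in um; 0 (default) means a perfectly immobile anchor.
#' @param switch_rate_sm,switch_rate_ms slow->fast and fast->slow switching
#'   rates in 1/s (default 0 = no transitions).
#' @param bleach_survival_p per-frame survival probability of the
#'   fluorophore (default 0.88; track length = 1 + geometric number of
#'   extra steps).
#' @param min_steps minimum steps for a track to be kept (default 5).
#' @param cell_length_um,cell_width_um cell dimensions in um (default 3, 1).
#' @param geometry_mode `"surface3d"` (diffusion on the spherocylinder
#'   surface, orthographically projected to the focal midplane; default) or
#'   `"planar2d"` (reflected 2D diffusion inside the cell silhouette).
#' @param seed integer seed; identical configurations reproduce identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_tracks = 1000L,
                       frame_interval_s = 0.030,
                       slow_fraction = 0.324,
                       D_slow_true = 0,
                       D_fast_true = 0.47,
                       loc_error_um = sqrt(0.04 * 0.030),
                       confinement_radius_true_um = 0,
                       switch_rate_sm = 0,
                       switch_rate_ms = 0,
                       bleach_survival_p = 0.88,
                       min_steps = 5L,
                       cell_length_um = 3,
                       cell_width_um = 1,
                       geometry_mode = c("surface3d", "planar2d"),
                       seed = 1L) {
  geometry_mode <- match.arg(geometry_mode)
  num <- c(frame_interval_s = frame_interval_s, slow_fraction = slow_fraction,
           D_slow_true = D_slow_true, D_fast_true = D_fast_true,
           loc_error_um = loc_error_um,
           confinement_radius_true_um = confinement_radius_true_um,
           switch_rate_sm = switch_rate_sm, switch_rate_ms = switch_rate_ms,
           bleach_survival_p = bleach_survival_p,
           cell_length_um = cell_length_um, cell_width_um = cell_width_um)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("non-finite or negative simulation parameter(s): ",
         paste(names(num)[!is.finite(num) | num < 0], collapse = ", "))
  }
  if (slow_fraction > 1) stop("slow_fraction must lie in [0, 1]")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (!(bleach_survival_p < 1)) stop("bleach_survival_p must be < 1")
  if (!(cell_length_um >= cell_width_um && cell_width_um > 0)) {
    stop("cell dimensions must satisfy length >= width > 0")
  }
  if (n_tracks < 0L) stop("n_tracks must be >= 0")
  structure(
    list(n_tracks = as.integer(n_tracks), frame_interval_s = frame_interval_s,
         slow_fraction = slow_fraction, D_slow_true = D_slow_true,
         D_fast_true = D_fast_true, loc_error_um = loc_error_um,
         confinement_radius_true_um = confinement_radius_true_um,
         switch_rate_sm = switch_rate_sm, switch_rate_ms = switch_rate_ms,
         bleach_survival_p = bleach_survival_p,
         min_steps = as.integer(min_steps),
         cell_length_um = cell_length_um, cell_width_um = cell_width_um,
         geometry_mode = geometry_mode, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default cell outline matching a simulation configuration
#'
#' The simulator places all tracks in a single cell centred at the origin
#' with its long axis along x; this returns the corresponding outline table
#' (pole-to-pole centerline endpoints plus width) for the projection stage.
#'
#' @param config a `sim_config`.
#' @param cell_id outline identifier (default `"cell_1"`).
#' @return a one-row outline data.frame
#'   (`cell_id,x1_um,y1_um,x2_um,y2_um,width_um`).
#' @export
sim_outline <- function(config, cell_id = "cell_1") {
  stopifnot(inherits(config, "sim_config"))
  data.frame(cell_id = cell_id,
             x1_um = -config$cell_length_um / 2, y1_um = 0,
             x2_um = config$cell_length_um / 2, y2_um = 0,
             width_um = config$cell_width_um,
             stringsAsFactors = FALSE)
}

# run code with the global RNG state saved and restored
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a two-state track set with ground truth
#'
#' Each molecule is assigned an initial state (slow with probability
#' `slow_fraction`); the fast state performs Brownian steps with variance
#' `2 * D_fast_true * dt` per coordinate, the slow state is tethered to an
#' anchor (immobile when `confinement_radius_true_um = 0`, otherwise
#' reflected within that radius). Optional two-state Markov switching uses
#' the configured rates. Track length is `1 + rgeom` steps under the
#' per-frame bleaching survival probability; tracks shorter than
#' `min_steps` are discarded. Independent Gaussian localization noise is
#' added to every observed coordinate. In `surface3d` mode molecules move
#' on the spherocylinder surface and are orthographically projected onto
#' the focal midplane; in `planar2d` mode they diffuse in the 2D silhouette
#' with specular reflection at the boundary.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_result`:
#'   \describe{
#'     \item{tracks}{the observed `track_set` (noisy positions).}
#'     \item{truth}{data.frame `track_id,dominant_state` (ground-truth
#'       label per kept track; the majority state, ties to `"slow"`).}
#'     \item{states}{data.frame `track_id,step,state` (per-step state).}
#'     \item{true_positions}{data.frame of noise-free positions
#'       (`track_id,frame,x_um,y_um[,z_um]`).}
#'   }
#' @export
simulate_trackset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    dt <- cfg$frame_interval_s
    L <- cfg$cell_length_um
    W <- cfg$cell_width_um
    n <- cfg$n_tracks
    if (n == 0L) stop("no tracks simulated: n_tracks is 0")
    steps <- 1L + stats::rgeom(n, prob = 1 - cfg$bleach_survival_p)
    keep <- which(steps >= cfg$min_steps)
    if (length(keep) == 0L) {
      stop("no simulated track survived the min_steps filter")
    }
    sd_fast <- sqrt(2 * cfg$D_fast_true * dt)
    sd_slow <- sqrt(2 * cfg$D_slow_true * dt)
    p_sm <- 1 - exp(-cfg$switch_rate_sm * dt)
    p_ms <- 1 - exp(-cfg$switch_rate_ms * dt)
    rc <- cfg$confinement_radius_true_um
    surface <- cfg$geometry_mode == "surface3d"

    obs_list <- true_list <- state_list <- vector("list", length(keep))
    dominant <- character(length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      s <- steps[i]
      id <- sprintf("trk_%05d", i)
      # per-step states (state governs the displacement of that step)
      st <- integer(s)  # 0 = slow, 1 = fast
      cur <- as.integer(stats::runif(1L) >= cfg$slow_fraction)
      for (t in seq_len(s)) {
        st[t] <- cur
        if (cur == 0L && p_sm > 0 && stats::runif(1L) < p_sm) cur <- 1L
        else if (cur == 1L && p_ms > 0 && stats::runif(1L) < p_ms) cur <- 0L
      }
      if (surface) {
        pos <- matrix(NA_real_, s + 1L, 3L)
        pos[1L, ] <- rod_sample_surface3d(1L, L, W)
        anchor <- pos[1L, ]
        for (t in seq_len(s)) {
          p <- pos[t, ]
          if (st[t] == 1L) {
            p <- p + stats::rnorm(3L, sd = sd_fast)
            p <- drop(rod_project_surface3d(rbind(p), L, W))
          } else if (rc > 0) {
            p <- p + stats::rnorm(3L, sd = sd_slow)
            d <- p - anchor
            nd <- sqrt(sum(d^2))
            if (nd > rc) p <- anchor + d * (2 * rc - nd) / nd
            p <- drop(rod_project_surface3d(rbind(p), L, W))
          }  # rc == 0: immobile anchor, p unchanged
          if (st[t] == 0L && rc == 0) p <- anchor
          if (t < s && st[t] == 1L && st[t + 1L] == 0L) anchor <- p
          pos[t + 1L, ] <- p
        }
        true_xy <- pos[, 1:2, drop = FALSE]
        true_df <- data.frame(track_id = id, frame = 0:s,
                              x_um = pos[, 1L], y_um = pos[, 2L],
                              z_um = pos[, 3L], stringsAsFactors = FALSE)
      } else {
        pos <- matrix(NA_real_, s + 1L, 2L)
        pos[1L, ] <- rod_sample_inside2d(1L, L, W)
        anchor <- pos[1L, ]
        for (t in seq_len(s)) {
          p <- pos[t, ]
          if (st[t] == 1L) {
            p <- p + stats::rnorm(2L, sd = sd_fast)
            p <- drop(rod_reflect_inside2d(p[1L], p[2L], L, W))
          } else if (rc > 0) {
            p <- p + stats::rnorm(2L, sd = sd_slow)
            d <- p - anchor
            nd <- sqrt(sum(d^2))
            if (nd > rc) p <- anchor + d * max(2 * rc - nd, 0) / nd
          } else {
            p <- anchor
          }
          if (t < s && st[t] == 1L && st[t + 1L] == 0L) anchor <- p
          pos[t + 1L, ] <- p
        }
        true_xy <- pos
        true_df <- data.frame(track_id = id, frame = 0:s,
                              x_um = pos[, 1L], y_um = pos[, 2L],
                              stringsAsFactors = FALSE)
      }
      obs <- true_xy + matrix(stats::rnorm(2L * (s + 1L),
                                           sd = cfg$loc_error_um),
                              s + 1L, 2L)
      obs_list[[j]] <- data.frame(track_id = id, frame = 0:s,
                                  x_um = obs[, 1L], y_um = obs[, 2L],
                                  cell_id = "cell_1",
                                  stringsAsFactors = FALSE)
      true_list[[j]] <- true_df
      state_list[[j]] <- data.frame(track_id = id, step = seq_len(s),
                                    state = ifelse(st == 1L, "fast", "slow"),
                                    stringsAsFactors = FALSE)
      dominant[j] <- if (mean(st == 0L) >= 0.5) "slow" else "fast"
    }
    ts <- track_set(do.call(rbind, obs_list), frame_interval_s = dt,
                    loc_error_um = cfg$loc_error_um)
    structure(
      list(tracks = ts,
           truth = data.frame(track_id = sprintf("trk_%05d", keep),
                              dominant_state = dominant,
                              stringsAsFactors = FALSE),
           states = do.call(rbind, state_list),
           true_positions = do.call(rbind, true_list),
           config = cfg),
      class = "sim_result"
    )
  })
}

#' Filament simulation configuration
#'
#' Parameters of the synthetic surface-filament (pilus) generator. The
#' defaults reflect the measured competence-pilus length distribution,
#' about 0.5 um with tens-of-nm spread.
#'
#' @param n_filaments number of filaments.
#' @param length_mean_nm,length_sd_nm mean and SD of the realized arc
#'   length in nm (normal, truncated at > 0).
#' @param curvature_sd per-node direction perturbation in radians.
#' @param nodes_per_filament nodes per polyline (>= 2).
#' @param seed integer seed.
#' @return an object of class `filament_sim_config`.
#' @export
filament_sim_config <- function(n_filaments = 40L,
                                length_mean_nm = 505,
                                length_sd_nm = 155,
                                curvature_sd = 0.1,
                                nodes_per_filament = 20L,
                                seed = 1L) {
  if (!(length_mean_nm > 0)) stop("length_mean_nm must be > 0")
  if (length_sd_nm < 0) stop("length_sd_nm must be >= 0")
  if (nodes_per_filament < 2L) stop("nodes_per_filament must be >= 2")
  if (n_filaments < 0L) stop("n_filaments must be >= 0")
  if (curvature_sd < 0) stop("curvature_sd must be >= 0")
  structure(
    list(n_filaments = as.integer(n_filaments),
         length_mean_nm = length_mean_nm, length_sd_nm = length_sd_nm,
         curvature_sd = curvature_sd,
         nodes_per_filament = as.integer(nodes_per_filament),
         seed = as.integer(seed)),
    class = "filament_sim_config"
  )
}

#' Simulate surface filaments on a cell outline
#'
#' Each filament is a polyline anchored on the cell silhouette boundary,
#' heading outward along the local normal, with per-segment direction
#' perturbed by `curvature_sd`; its realized arc length is drawn from
#' Normal(mean, sd) truncated at > 0 and divided evenly over the segments,
#' so the polyline arc length equals the drawn length exactly.
#'
#' @param config a [filament_sim_config()].
#' @param outline a one-row outline data.frame
#'   (`cell_id,x1_um,y1_um,x2_um,y2_um,width_um`), e.g. from
#'   [sim_outline()].
#' @return a data.frame `filament_id,node_index,x_nm,y_nm,cell_id`
#'   (coordinates in nm, cell centre at the origin); zero rows when
#'   `n_filaments = 0`.
#' @export
simulate_filaments <- function(config, outline) {
  stopifnot(inherits(config, "filament_sim_config"))
  if (config$n_filaments == 0L) {
    return(data.frame(filament_id = character(0L), node_index = integer(0L),
                      x_nm = numeric(0L), y_nm = numeric(0L),
                      cell_id = character(0L), stringsAsFactors = FALSE))
  }
  L_nm <- with(outline, sqrt((x2_um - x1_um)^2 + (y2_um - y1_um)^2)) * 1e3
  W_nm <- outline$width_um * 1e3
  with_local_seed(config$seed, {
    out <- vector("list", config$n_filaments)
    for (i in seq_len(config$n_filaments)) {
      len <- -1
      while (len <= 0) {
        len <- stats::rnorm(1L, config$length_mean_nm, config$length_sd_nm)
      }
      perim <- rod_boundary_at2d(0, L_nm, W_nm)$perimeter
      b <- rod_boundary_at2d(stats::runif(1L, 0, perim), L_nm, W_nm)
      n_seg <- config$nodes_per_filament - 1L
      seg <- len / n_seg
      theta <- atan2(b$ny, b$nx) +
        c(0, cumsum(stats::rnorm(n_seg - 1L, sd = config$curvature_sd)))
      x <- b$x + c(0, cumsum(seg * cos(theta)))
      y <- b$y + c(0, cumsum(seg * sin(theta)))
      out[[i]] <- data.frame(filament_id = sprintf("fil_%04d", i),
                             node_index = seq_len(n_seg + 1L),
                             x_nm = x, y_nm = y,
                             cell_id = outline$cell_id[1L],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate a photobleaching intensity trace
#'
#' `intensity[i] = n0 * exp(-k_bleach * i) + Gaussian noise`, clipped at 0,
#' for frames i = 0..n_frames-1. Used to exercise the bleach-trimming rule.
#'
#' @param n_frames number of frames (>= 1).
#' @param n0 initial intensity (> 0).
#' @param k_bleach bleaching rate per frame (>= 0).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @return a data.frame `frame,intensity` (frames 0-based).
#' @export
simulate_bleach_trace <- function(n_frames, n0, k_bleach, noise_sd = 0,
                                  seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be >= 1")
  if (!(n0 > 0)) stop("n0 must be > 0")
  if (k_bleach < 0) stop("k_bleach must be >= 0")
  with_local_seed(seed, {
    frame <- 0:(n_frames - 1L)
    intensity <- n0 * exp(-k_bleach * frame)
    if (noise_sd > 0) intensity <- intensity + stats::rnorm(n_frames, sd = noise_sd)
    data.frame(frame = frame, intensity = pmax(intensity, 0))
  })
}
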