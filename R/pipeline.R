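# Stage orchestration: simulate / fit / classify / project / compare /
# report over a YAML configuration, with one root seed, per-stage seed
# derivation, machine-readable logs and a config hash recorded in every
# output.

#' Load a pipeline configuration
#'
#' Reads a YAML pipeline configuration and fills defaults. Top-level keys:
#' `seed` (root seed), `output_dir`, `frame_interval_s`, `min_steps`, `k`,
#' `max_lag`, `radius_mode` (`"three_sigma"` or `"fixed_um"`),
#' `radius_um`, `bin_size_um`, `ci_method`, `conditions` (list of
#' `label` + either `tracks:` path or `simulate:` block of [sim_config()]
#' fields), and optional `filaments` ([filament_sim_config()] fields).
#'
#' @param path YAML file path.
#' @return a list of class `pipeline_config` with `config_hash` attached
#'   (md5 of the file).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, output_dir = "smtkit_out",
                   frame_interval_s = 0.030, min_steps = 5L, k = 2L,
                   max_lag = 4L, radius_mode = "three_sigma",
                   radius_um = 0.1087, bin_size_um = 0.05,
                   ci_method = "linearized")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!cfg$radius_mode %in% c("three_sigma", "fixed_um")) {
    stop("radius_mode must be 'three_sigma' or 'fixed_um'")
  }
  if (is.null(cfg$conditions) || length(cfg$conditions) == 0L) {
    stop("config must define at least one condition")
  }
  labs <- vapply(cfg$conditions, function(x) x$label %||% "", character(1L))
  if (any(!nzchar(labs)) || anyDuplicated(labs)) {
    stop("every condition needs a unique label")
  }
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

safe_label <- function(label) {
  label <- gsub("+", "plus", gsub("-", "minus", label, fixed = TRUE),
                fixed = TRUE)
  gsub("[^A-Za-z0-9]+", "_", label)
}

# per-stage seed derivation from the root seed (documented, stays < 2^31)
stage_seed <- function(root, stage_index, condition_index = 0L) {
  (as.integer(root) + 7919L * as.integer(stage_index) +
     104729L * as.integer(condition_index)) %% 2147483647L
}

pipeline_log <- function(cfg, stage, message) {
  line <- sprintf("%s level=info stage=%s hash=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  cfg$config_hash, message)
  cat(line, "\n", sep = "",
      file = file.path(cfg$output_dir, "pipeline.log"), append = TRUE)
  invisible(line)
}

condition_track_file <- function(cfg, cond) {
  if (!is.null(cond$tracks)) return(cond$tracks)
  file.path(cfg$output_dir,
            paste0("tracks_", safe_label(cond$label), ".csv"))
}

#' Run a pipeline stage
#'
#' Executes one subcommand of the analysis pipeline against a
#' configuration; all outputs land in the configured output directory and
#' every run is appended to `pipeline.log` with the config hash.
#' \describe{
#'   \item{simulate}{generates a track set per condition carrying a
#'     `simulate:` block; writes track, ground-truth and outline CSVs.}
#'   \item{fit}{filters tracks, pools one-lag displacements and fits the
#'     k-component SQD mixture with confidence intervals; writes
#'     `fit_<label>.json`.}
#'   \item{classify}{classifies tracks against the confinement radius
#'     (fixed, or 3x the MSD localization error); writes
#'     `classes_<label>.csv`.}
#'   \item{project}{projects localizations into the standardized cell and
#'     writes confined-track density grids.}
#'   \item{compare}{simultaneous shared-D fit across all conditions
#'     (needs >= 2); writes a two-column `compare.csv` summary plus
#'     `bubble.csv` (fraction, D per condition) for bubble plots.}
#'   \item{report}{aggregates the per-condition fit reports into
#'     `report.json` with provenance (config hash, seed, package
#'     version).}
#' }
#'
#' @param config a `pipeline_config` or a path to a YAML file.
#' @param subcommand one of `"simulate"`, `"fit"`, `"classify"`,
#'   `"project"`, `"compare"`, `"report"`.
#' @return invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config,
                         subcommand = c("simulate", "fit", "classify",
                                        "project", "compare", "report")) {
  subcommand <- match.arg(subcommand)
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(subcommand,
                simulate = stage_simulate(cfg),
                fit = stage_fit(cfg),
                classify = stage_classify(cfg),
                project = stage_project(cfg),
                compare = stage_compare(cfg),
                report = stage_report(cfg))
  invisible(out)
}

stage_simulate <- function(cfg) {
  paths <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[ci]]
    if (is.null(cond$simulate)) next
    args <- cond$simulate
    args$frame_interval_s <- args$frame_interval_s %||% cfg$frame_interval_s
    args$min_steps <- args$min_steps %||% cfg$min_steps
    args$seed <- args$seed %||% stage_seed(cfg$seed, 1L, ci)
    sim <- simulate_trackset(do.call(sim_config, args))
    lab <- safe_label(cond$label)
    tr_path <- file.path(cfg$output_dir, paste0("tracks_", lab, ".csv"))
    gt_path <- file.path(cfg$output_dir, paste0("truth_", lab, ".csv"))
    ol_path <- file.path(cfg$output_dir, paste0("outline_", lab, ".csv"))
    write_tracks(sim$tracks, tr_path)
    utils::write.csv(sim$truth, gt_path, row.names = FALSE, quote = FALSE)
    utils::write.csv(sim_outline(sim$config), ol_path, row.names = FALSE,
                     quote = FALSE)
    pipeline_log(cfg, "simulate",
                 sprintf("label=%s tracks=%d seed=%d", cond$label,
                         n_tracks(sim$tracks), sim$config$seed))
    paths[[cond$label]] <- tr_path
  }
  if (length(paths) == 0L) stop("no condition carries a simulate block")
  paths
}

load_condition <- function(cfg, cond) {
  path <- condition_track_file(cfg, cond)
  if (!file.exists(path)) {
    stop("condition '", cond$label, "': track file not found: ", path,
         " (run the simulate stage or point 'tracks:' at a file)")
  }
  ts <- read_tracks(path, frame_interval_s = cfg$frame_interval_s,
                    condition_label = cond$label)
  filter_tracks(ts, min_steps = cfg$min_steps)
}

stage_fit <- function(cfg) {
  paths <- list()
  for (cond in cfg$conditions) {
    ts <- load_condition(cfg, cond)
    smp <- displacement_sample(ts, lag = 1L)
    fit <- fit_sqd_cdf(smp, k = cfg$k)
    fit <- confidence_intervals(fit, method = cfg$ci_method)
    rep <- c(list(condition = cond$label, config_hash = cfg$config_hash,
                  seed = cfg$seed), fit_report(fit))
    path <- file.path(cfg$output_dir,
                      paste0("fit_", safe_label(cond$label), ".json"))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    pipeline_log(cfg, "fit", sprintf("label=%s k=%d r2=%.5f", cond$label,
                                     fit$k, fit$r_squared))
    paths[[cond$label]] <- path
  }
  paths
}

pipeline_radius <- function(cfg, ts) {
  if (cfg$radius_mode == "fixed_um") return(cfg$radius_um)
  msd <- msd_localization(ts, max_lag = cfg$max_lag)
  if (msd$confinement_radius_um <= 0) {
    stop("three_sigma radius mode: MSD intercept gave a zero radius; ",
         "use radius_mode: fixed_um")
  }
  msd$confinement_radius_um
}

stage_classify <- function(cfg) {
  paths <- list()
  for (cond in cfg$conditions) {
    ts <- load_condition(cfg, cond)
    radius <- pipeline_radius(cfg, ts)
    cl <- classify_tracks(ts, radius_um = radius,
                          window_steps = cfg$min_steps)
    path <- file.path(cfg$output_dir,
                      paste0("classes_", safe_label(cond$label), ".csv"))
    utils::write.csv(cl[, c("track_id", "label")], path, row.names = FALSE,
                     quote = FALSE)
    pipeline_log(cfg, "classify",
                 sprintf("label=%s radius_um=%.4f confined=%d of %d",
                         cond$label, radius, sum(cl$label == "confined"),
                         nrow(cl)))
    paths[[cond$label]] <- path
  }
  paths
}

stage_project <- function(cfg) {
  paths <- list()
  for (cond in cfg$conditions) {
    ts <- load_condition(cfg, cond)
    lab <- safe_label(cond$label)
    ol_path <- cond$outlines %||%
      file.path(cfg$output_dir, paste0("outline_", lab, ".csv"))
    outlines <- read_outlines(ol_path)
    cl_path <- file.path(cfg$output_dir, paste0("classes_", lab, ".csv"))
    classification <- NULL
    if (file.exists(cl_path)) {
      cl <- utils::read.csv(cl_path, stringsAsFactors = FALSE)
      cl$label <- factor(cl$label,
                         levels = c("confined", "transition", "mobile"))
      classification <- cl
    }
    proj <- project_standard_cell(ts, outlines, classification)
    grid <- density_map(proj, bin_size_um = cfg$bin_size_um,
                        subset = if (!is.null(classification)) "confined")
    path <- file.path(cfg$output_dir, paste0("density_", lab, ".csv"))
    write_density_grid(grid, path)
    pipeline_log(cfg, "project",
                 sprintf("label=%s points=%d clamped=%.4f", cond$label,
                         nrow(proj$points), proj$clamped_fraction))
    paths[[cond$label]] <- path
  }
  paths
}

stage_compare <- function(cfg) {
  if (length(cfg$conditions) < 2L) stop("compare needs >= 2 conditions")
  samples <- list()
  for (cond in cfg$conditions) {
    samples[[cond$label]] <- displacement_sample(load_condition(cfg, cond))
  }
  fits <- simultaneous_fit(samples, k = cfg$k)
  labels <- names(fits)
  k <- cfg$k
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(
      quantity = c(sprintf("Pop_%d_percent", i), sprintf("D_%d_um2_s", i)),
      t(vapply(fits, function(f) {
        c(100 * f$components$fraction[i], f$components$D_app_um2_s[i])
      }, numeric(2L))), check.names = FALSE)
  }))
  names(rows) <- c("quantity", labels)
  cmp_path <- file.path(cfg$output_dir, "compare.csv")
  utils::write.csv(rows, cmp_path, row.names = FALSE, quote = FALSE)
  bubble <- do.call(rbind, lapply(labels, function(l) {
    data.frame(condition = l,
               component = seq_len(k),
               fraction = fits[[l]]$components$fraction,
               D_app_um2_s = fits[[l]]$components$D_app_um2_s,
               stringsAsFactors = FALSE)
  }))
  bub_path <- file.path(cfg$output_dir, "bubble.csv")
  utils::write.csv(bubble, bub_path, row.names = FALSE, quote = FALSE)
  pipeline_log(cfg, "compare",
               sprintf("conditions=%d shared_D=%s", length(labels),
                       paste(signif(fits[[1L]]$components$D_app_um2_s, 4),
                             collapse = "/")))
  list(compare = cmp_path, bubble = bub_path)
}

stage_report <- function(cfg) {
  fit_files <- Sys.glob(file.path(cfg$output_dir, "fit_*.json"))
  fits <- lapply(fit_files, jsonlite::read_json)
  report <- list(
    provenance = list(config_hash = cfg$config_hash, seed = cfg$seed,
                      package = "smtkit",
                      version = as.character(utils::packageVersion("smtkit"))),
    conditions = fits
  )
  path <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pipeline_log(cfg, "report", sprintf("conditions=%d", length(fits)))
  list(report = path)
}
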