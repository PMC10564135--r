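# Small quantitative operations outside the tracking chain: filament
# (pilus) morphometrics, pilus-positive cell fractions, transformation
# frequency, and the dye-mass formula for fluorescent DNA labelling.

#' Read filament traces from CSV
#'
#' Dialect: `filament_id,node_index,x_nm,y_nm[,cell_id]`; `#` comments.
#'
#' @param path file path.
#' @return a data.frame of filament nodes ordered by id and node index.
#' @export
read_filaments <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("filament_id", "node_index", "x_nm", "y_nm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing filament column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(df$x_nm)) || !all(is.finite(df$y_nm))) {
    stop(path, ": non-finite filament coordinates")
  }
  df$filament_id <- as.character(df$filament_id)
  df[order(df$filament_id, df$node_index), , drop = FALSE]
}

#' Filament arc-length statistics
#'
#' The length of a traced filament is its polyline arc length: the sum of
#' consecutive node-to-node Euclidean distances. Returns per-filament
#' lengths and the sample mean/SD (n - 1 denominator), the statistics
#' reported for competence-pilus length distributions.
#'
#' @param traces filament node data.frame
#'   (`filament_id,node_index,x_nm,y_nm`), e.g. from [read_filaments()]
#'   or [simulate_filaments()].
#' @return a list with `lengths_nm` (named per filament), `mean_nm`,
#'   `sd_nm`, `n`.
#' @export
filament_length_stats <- function(traces) {
  if (is.null(traces) || nrow(traces) == 0L) stop("no filament traces")
  by_fil <- split(traces, traces$filament_id)
  lengths <- vapply(names(by_fil), function(id) {
    tr <- by_fil[[id]]
    if (nrow(tr) < 2L) stop("filament '", id, "' has fewer than 2 nodes")
    tr <- tr[order(tr$node_index), , drop = FALSE]
    sum(sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2))
  }, numeric(1L))
  list(lengths_nm = lengths, mean_nm = mean(lengths),
       sd_nm = if (length(lengths) > 1L) stats::sd(lengths) else NA_real_,
       n = length(lengths))
}

#' Positive fraction with a Wilson 95% interval
#'
#' Fraction of positive counts (e.g. cells displaying pilus structures
#' among all analyzed cells: 64/318 gives 20.1%) with the Wilson score
#' 95% confidence interval.
#'
#' @param positives,total non-negative counts, `positives <= total`,
#'   `total > 0`.
#' @return a list with `fraction`, `lower`, `upper`, `positives`, `total`.
#' @export
positive_fraction <- function(positives, total) {
  if (!(total > 0)) stop("total must be > 0")
  if (positives < 0 || positives > total) {
    stop("positives must lie in [0, total]")
  }
  p <- positives / total
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  list(fraction = p, lower = max(centre - half, 0),
       upper = min(centre + half, 1), positives = positives, total = total)
}

#' Transformation frequency per microgram of DNA
#'
#' Dividing the transformant CFU/ml by the number of viable cells/ml per
#' microgram of added DNA: `(cfu_per_ml / viable_per_ml) / dna_ug`.
#'
#' @param cfu_per_ml transformant colony-forming units per ml (>= 0).
#' @param viable_per_ml viable cells per ml (> 0).
#' @param dna_ug added DNA mass in micrograms (> 0).
#' @return the transformation frequency (per ug DNA).
#' @export
transformation_frequency <- function(cfu_per_ml, viable_per_ml, dna_ug) {
  if (cfu_per_ml < 0) stop("cfu_per_ml must be >= 0")
  if (!(viable_per_ml > 0)) stop("viable_per_ml must be > 0")
  if (!(dna_ug > 0)) stop("dna_ug must be > 0")
  (cfu_per_ml / viable_per_ml) / dna_ug
}

#' Dye mass for fluorescent DNA labelling
#'
#' Mass of amine-reactive dye needed for a tenfold molar excess over the
#' DNA to be labelled: `m_fluor = (m_dna / M_dna) * 10 * M_fluor`.
#'
#' @param m_dna DNA mass in ug (>= 0).
#' @param M_dna DNA molecular mass in g/mol (> 0).
#' @param M_fluor fluorophore molecular mass in g/mol (> 0).
#' @return dye mass in ug.
#' @export
dye_mass <- function(m_dna, M_dna, M_fluor) {
  if (m_dna < 0) stop("m_dna must be >= 0")
  if (!(M_dna > 0) || !(M_fluor > 0)) {
    stop("molecular masses must be > 0")
  }
  (m_dna / M_dna) * 10 * M_fluor
}
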