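# Shared fixtures and independent oracles, built in code at test time.

# wrap a vector of squared displacements as a jump_sample
make_jump_sample <- function(u, dt = 0.03, label = NULL) {
  structure(
    list(lag = 1L, values_r_um = sqrt(u), values_u_um2 = u,
         n_steps = length(u), frame_interval_s = dt,
         condition_label = label),
    class = "jump_sample"
  )
}

# deterministic sample placed at the exact model quantiles of a
# single-population squared-displacement distribution
exact_quantile_u <- function(n, D, dt = 0.03) {
  q <- (seq_len(n) - 0.5) / n
  -4 * D * dt * log(1 - q)
}

# random draws from a k-component squared-displacement mixture
draw_mixture_u <- function(n, f, D, dt = 0.03, seed = 1L) {
  set.seed(seed)
  comp <- sample.int(length(f), n, replace = TRUE, prob = f)
  stats::rexp(n, rate = 1 / (4 * D[comp] * dt))
}

# brute-force 50^3 grid-search minimizer of the two-component SQD-CDF SSE;
# the inner fraction profile is evaluated in closed form per (D1, D2) pair
grid_search_sqd2 <- function(u, dt, f_grid, D1_grid, D2_grid) {
  u <- sort(u)
  p <- (seq_along(u) - 0.5) / length(u)
  E1 <- exp(-outer(u, 4 * D1_grid * dt, "/"))
  E2 <- exp(-outer(u, 4 * D2_grid * dt, "/"))
  best <- list(sse = Inf)
  for (i in seq_along(D1_grid)) {
    e1 <- E1[, i]
    for (j in seq_along(D2_grid)) {
      A <- e1 - E2[, j]
      C <- 1 - E2[, j] - p
      cc <- sum(C * C); ac <- sum(A * C); aa <- sum(A * A)
      sse_f <- cc - 2 * f_grid * ac + f_grid^2 * aa
      m <- which.min(sse_f)
      if (sse_f[m] < best$sse) {
        best <- list(sse = sse_f[m], f1 = f_grid[m], D1 = D1_grid[i],
                     D2 = D2_grid[j])
      }
    }
  }
  best
}

# construct a track_set from a list of coordinate matrices
tracks_from_coords <- function(coords, dt = 0.03, cell_id = NULL) {
  df <- do.call(rbind, lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    out <- data.frame(track_id = sprintf("t%03d", i),
                      frame = seq_len(nrow(m)) - 1L,
                      x_um = m[, 1L], y_um = m[, 2L],
                      stringsAsFactors = FALSE)
    if (!is.null(cell_id)) out$cell_id <- cell_id
    out
  }))
  track_set(df, frame_interval_s = dt)
}
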