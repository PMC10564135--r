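test_that("zero-motion configuration yields identical localizations per track", {
  cfg <- sim_config(n_tracks = 50, slow_fraction = 1, D_slow_true = 0,
                    D_fast_true = 0, loc_error_um = 0,
                    confinement_radius_true_um = 0, seed = 4)
  sim <- simulate_trackset(cfg)
  for (tr in split(sim$tracks$localizations,
                   sim$tracks$localizations$track_id)) {
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
  expect_true(all(sim$truth$dominant_state == "slow"))
})

test_that("pure-fast ensemble matches the one-step moment 4(D dt + sigma^2)", {
  D <- 0.5; sigma <- 0.036; dt <- 0.03
  cfg <- sim_config(n_tracks = 4000, slow_fraction = 0, D_fast_true = D,
                    loc_error_um = sigma, bleach_survival_p = 0.9,
                    geometry_mode = "planar2d", cell_length_um = 100,
                    cell_width_um = 50, frame_interval_s = dt, seed = 8)
  smp <- displacement_sample(filter_tracks(simulate_trackset(cfg)$tracks))
  expect_gt(smp$n_steps, 2e4)
  # independent Monte-Carlo oracle: direct draws of one step + noise change
  set.seed(99)
  n_mc <- 2e5
  step_u <- (rnorm(n_mc, sd = sqrt(2 * D * dt)) +
               rnorm(n_mc, sd = sigma * sqrt(2)))^2 +
            (rnorm(n_mc, sd = sqrt(2 * D * dt)) +
               rnorm(n_mc, sd = sigma * sqrt(2)))^2
  oracle <- mean(step_u)
  expect_equal(oracle, 4 * (D * dt + sigma^2), tolerance = 0.02)
  se <- sqrt(stats::var(smp$values_u_um2) / smp$n_steps +
               stats::var(step_u) / n_mc)
  expect_lt(abs(mean(smp$values_u_um2) - oracle), 3 * se)
})

test_that("realized slow composition sits in the exact binomial 99% interval", {
  cfg <- sim_config(n_tracks = 5000, slow_fraction = 0.324,
                    geometry_mode = "planar2d", cell_length_um = 100,
                    cell_width_um = 50, seed = 21)
  sim <- simulate_trackset(cfg)
  n_slow <- sum(sim$truth$dominant_state == "slow")
  ci <- stats::binom.test(n_slow, nrow(sim$truth),
                          conf.level = 0.99)$conf.int
  expect_gte(0.324, ci[1])
  expect_lte(0.324, ci[2])
})

test_that("identical configurations and seeds reproduce identical output", {
  cfg <- sim_config(n_tracks = 100, switch_rate_sm = 2, switch_rate_ms = 2,
                    confinement_radius_true_um = 0.05, D_slow_true = 0.01,
                    seed = 33)
  expect_identical(simulate_trackset(cfg), simulate_trackset(cfg))
  cfg2 <- sim_config(n_tracks = 100, switch_rate_sm = 2, switch_rate_ms = 2,
                     confinement_radius_true_um = 0.05, D_slow_true = 0.01,
                     seed = 34)
  expect_false(identical(simulate_trackset(cfg)$tracks$localizations,
                         simulate_trackset(cfg2)$tracks$localizations))
})

test_that("true positions respect the configured cell geometry", {
  for (mode in c("planar2d", "surface3d")) {
    cfg <- sim_config(n_tracks = 150, geometry_mode = mode, seed = 12)
    tp <- simulate_trackset(cfg)$true_positions
    expect_true(all(smtkit:::rod_inside2d(tp$x_um, tp$y_um, 3, 1)),
                info = mode)
    if (mode == "surface3d") {
      # points lie on the spherocylinder surface: distance to axis = W/2
      a <- smtkit:::rod_half_axis(3, 1)
      cx <- pmin(pmax(tp$x_um, -a), a)
      d <- sqrt((tp$x_um - cx)^2 + tp$y_um^2 + tp$z_um^2)
      expect_equal(d, rep(0.5, length(d)), tolerance = 1e-8)
    }
  }
})

test_that("state switching produces mixed-state tracks for classifier tests", {
  cfg <- sim_config(n_tracks = 400, slow_fraction = 0.5, switch_rate_sm = 5,
                    switch_rate_ms = 5, bleach_survival_p = 0.95, seed = 2)
  sim <- simulate_trackset(cfg)
  n_states <- tapply(sim$states$state, sim$states$track_id,
                     function(s) length(unique(s)))
  expect_gt(mean(n_states == 2L), 0.3)
  # per-track state sequence length equals the track's step count
  steps <- table(sim$states$track_id)
  locs <- table(sim$tracks$localizations$track_id)
  expect_identical(as.integer(steps), as.integer(locs) - 1L)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(D_fast_true = -1), "negative")
  expect_error(sim_config(slow_fraction = 1.2), "slow_fraction")
  expect_error(sim_config(cell_length_um = 0.5, cell_width_um = 1), "length")
  expect_error(sim_config(frame_interval_s = NaN), "non-finite|negative")
  cfg <- sim_config(n_tracks = 20, bleach_survival_p = 0.01, min_steps = 50)
  expect_error(simulate_trackset(cfg), "min_steps")
})

test_that("straight filaments have exactly the configured length", {
  outline <- data.frame(cell_id = "c1", x1_um = -1.5, y1_um = 0,
                        x2_um = 1.5, y2_um = 0, width_um = 1)
  cfg <- filament_sim_config(n_filaments = 10, length_mean_nm = 500,
                             length_sd_nm = 0, curvature_sd = 0,
                             nodes_per_filament = 5, seed = 1)
  fil <- simulate_filaments(cfg, outline)
  st <- filament_length_stats(fil)
  expect_equal(unname(st$lengths_nm), rep(500, 10), tolerance = 1e-9)
  # straight: end-to-end distance equals arc length
  for (tr in split(fil, fil$filament_id)) {
    e2e <- sqrt(diff(range(tr$x_nm))^2 + diff(range(tr$y_nm))^2)
    expect_equal(e2e, 500, tolerance = 1e-6)
  }
})

test_that("filament sample mean tracks the configured length distribution", {
  outline <- data.frame(cell_id = "c1", x1_um = -1.5, y1_um = 0,
                        x2_um = 1.5, y2_um = 0, width_um = 1)
  cfg <- filament_sim_config(n_filaments = 40, length_mean_nm = 539,
                             length_sd_nm = 40, curvature_sd = 0.1,
                             nodes_per_filament = 20, seed = 5)
  st <- filament_length_stats(simulate_filaments(cfg, outline))
  expect_equal(st$n, 40)
  expect_lt(abs(st$mean_nm - 539), 3 * 40 / sqrt(40))
  # empty case
  cfg0 <- filament_sim_config(n_filaments = 0)
  expect_equal(nrow(simulate_filaments(cfg0, outline)), 0L)
  expect_error(filament_sim_config(length_mean_nm = 0), "length_mean")
})

test_that("bleach traces follow the exponential decay model", {
  tr <- simulate_bleach_trace(10, n0 = 500, k_bleach = 0, noise_sd = 0)
  expect_equal(tr$intensity, rep(500, 10))
  tr2 <- simulate_bleach_trace(10, n0 = 1000, k_bleach = 0.2, noise_sd = 0)
  expect_equal(tr2$intensity[tr2$frame == 5], 1000 * exp(-1),
               tolerance = 1e-12)
  n1 <- simulate_bleach_trace(50, 1000, 0.1, noise_sd = 20, seed = 9)
  n2 <- simulate_bleach_trace(50, 1000, 0.1, noise_sd = 20, seed = 9)
  expect_identical(n1, n2)
  expect_true(all(n1$intensity >= 0))
  expect_error(simulate_bleach_trace(0, 100, 0.1), "n_frames")
})
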