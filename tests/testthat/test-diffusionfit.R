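dt <- 0.03

test_that("single-population fits recover D from exact-quantile samples", {
  smp <- make_jump_sample(exact_quantile_u(2000, D = 0.1, dt = dt), dt)
  fit <- fit_sqd_cdf(smp, k = 1)
  expect_equal(fit$components$D_app_um2_s, 0.1, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  fit_jd <- fit_jd_pdf(smp, k = 1)
  expect_equal(fit_jd$components$D_app_um2_s, 0.1, tolerance = 0.02)
})

test_that("k=1 least squares agrees with the moment estimator within 2%", {
  set.seed(71)
  u <- rexp(1e4, rate = 1 / (4 * 0.25 * dt))
  smp <- make_jump_sample(u, dt)
  fit <- fit_sqd_cdf(smp, k = 1)
  moment <- mean(u) / (4 * dt)
  expect_lt(abs(fit$components$D_app_um2_s - moment) / moment, 0.02)
})

test_that("the mixture optimizer matches a 50^3 grid-search minimizer", {
  u <- draw_mixture_u(3000, f = c(0.5, 0.5), D = c(0.05, 0.5), dt = dt,
                      seed = 81)
  fit <- fit_sqd_cdf(make_jump_sample(u, dt), k = 2)
  f_grid <- seq(0.02, 0.98, length.out = 50)
  D1_grid <- seq(0.01, 0.15, length.out = 50)
  D2_grid <- seq(0.2, 1.0, length.out = 50)
  grid <- grid_search_sqd2(u, dt, f_grid, D1_grid, D2_grid)
  expect_lte(fit$sse, grid$sse + 1e-12)  # optimizer at least as good
  expect_lt(abs(fit$components$fraction[1] - grid$f1),
            1.5 * diff(f_grid[1:2]))
  expect_lt(abs(fit$components$D_app_um2_s[1] - grid$D1),
            1.5 * diff(D1_grid[1:2]))
  expect_lt(abs(fit$components$D_app_um2_s[2] - grid$D2),
            1.5 * diff(D2_grid[1:2]))
})

test_that("SQD and JD estimators agree on the same mixture sample", {
  u <- draw_mixture_u(8000, f = c(0.4, 0.6), D = c(0.05, 0.5), dt = dt,
                      seed = 19)
  smp <- make_jump_sample(u, dt)
  f_sqd <- fit_sqd_cdf(smp, k = 2)
  f_jd <- fit_jd_pdf(smp, k = 2)
  expect_equal(f_jd$components$fraction, f_sqd$components$fraction,
               tolerance = 0.08)
  expect_equal(f_jd$components$D_app_um2_s, f_sqd$components$D_app_um2_s,
               tolerance = 0.10)
  # maximum-likelihood cross-check estimator lands in the same place
  f_ml <- fit_sqd_ml(smp, k = 2)
  expect_equal(f_ml$components$fraction, f_sqd$components$fraction,
               tolerance = 0.05)
  expect_equal(f_ml$components$D_app_um2_s, f_sqd$components$D_app_um2_s,
               tolerance = 0.08)
})

test_that("one population cannot describe strongly bimodal data", {
  u <- draw_mixture_u(6000, f = c(0.45, 0.55), D = c(0.04, 0.5), dt = dt,
                      seed = 42)
  smp <- make_jump_sample(u, dt)
  f1 <- fit_sqd_cdf(smp, k = 1)
  f2 <- fit_sqd_cdf(smp, k = 2)
  expect_gt(f2$r_squared, f1$r_squared + 0.005)
  q1 <- qq_diagnostic(smp, f1)
  q2 <- qq_diagnostic(smp, f2)
  expect_gt(q1$max_abs_deviation, 3 * q2$max_abs_deviation)
})

test_that("fits are invariant to step order and always normalized", {
  set.seed(55)
  for (i in 1:5) {
    f_true <- runif(1, 0.2, 0.8)
    u <- draw_mixture_u(1500, f = c(f_true, 1 - f_true),
                        D = sort(runif(2, 0.02, 0.8)), dt = dt,
                        seed = 100 + i)
    smp <- make_jump_sample(u, dt)
    fit <- fit_sqd_cdf(smp, k = 2, n_starts = 4)
    perm <- make_jump_sample(u[sample.int(length(u))], dt)
    fit_p <- fit_sqd_cdf(perm, k = 2, n_starts = 4)
    expect_equal(fit_p$components, fit$components, tolerance = 1e-8)
    expect_equal(sum(fit$components$fraction), 1, tolerance = 1e-9)
    expect_false(is.unsorted(fit$components$D_app_um2_s))
  }
})

test_that("sample-size guards and corrected-D reporting behave", {
  smp_small <- make_jump_sample(exact_quantile_u(4, 0.1, dt), dt)
  expect_error(fit_sqd_cdf(smp_small, k = 3), "too small")
  expect_warning(fit_sqd_cdf(make_jump_sample(exact_quantile_u(60, 0.1, dt),
                                              dt), k = 2),
                 "fewer than")
  sigma <- 0.036
  smp <- make_jump_sample(exact_quantile_u(2000, 0.25, dt), dt)
  fit <- fit_sqd_cdf(smp, k = 1, sigma_mode = "corrected", sigma = sigma)
  expect_equal(fit$components$D_true_um2_s,
               fit$components$D_app_um2_s - sigma^2 / dt, tolerance = 1e-9)
  # flooring at zero when sigma^2/dt exceeds the apparent D
  slow <- make_jump_sample(exact_quantile_u(2000, 0.03, dt), dt)
  fit0 <- fit_sqd_cdf(slow, k = 1, sigma_mode = "corrected", sigma = 0.04)
  expect_equal(fit0$components$D_true_um2_s, 0)
})

test_that("qq deviation is ~0 for self-consistent samples and matches a direct oracle", {
  fit <- fit_sqd_cdf(make_jump_sample(exact_quantile_u(3000, 0.2, dt), dt),
                     k = 1)
  smp_model <- make_jump_sample(
    -4 * fit$components$D_app_um2_s * dt *
      log(1 - (seq_len(3000) - 0.5) / 3000), dt)
  qq <- qq_diagnostic(smp_model, fit)
  expect_lt(qq$max_abs_deviation, 2e-4)
  # 10-point brute-force oracle on a mixture fit
  u <- draw_mixture_u(4000, c(0.5, 0.5), c(0.05, 0.5), dt, seed = 3)
  smp <- make_jump_sample(u, dt)
  fit2 <- fit_sqd_cdf(smp, k = 2)
  qq10 <- qq_diagnostic(smp, fit2, n_quantiles = 10)
  probs <- (1:10) / 11
  oracle_meas <- quantile(u, probs, names = FALSE)
  oracle_mod <- vapply(probs, function(p) {
    g <- seq(0, max(u) * 2, length.out = 2e5)
    cdf <- 1 - fit2$components$fraction[1] *
      exp(-g / (4 * fit2$components$D_app_um2_s[1] * dt)) -
      fit2$components$fraction[2] *
      exp(-g / (4 * fit2$components$D_app_um2_s[2] * dt))
    g[which.max(cdf >= p)]
  }, numeric(1))
  expect_equal(qq10$measured_quantiles, oracle_meas, tolerance = 1e-10)
  expect_equal(qq10$modelled_quantiles, oracle_mod, tolerance = 1e-3)
  expect_equal(qq10$max_abs_deviation,
               max(abs(oracle_meas - oracle_mod)), tolerance = 1e-3)
})

test_that("component selection keeps k=1 on single-population data", {
  chosen <- vapply(1:10, function(i) {
    set.seed(200 + i)
    u <- rexp(2000, rate = 1 / (4 * 0.2 * dt))
    smp <- make_jump_sample(u, dt)
    fits <- list(fit_sqd_cdf(smp, 1, n_starts = 4),
                 fit_sqd_cdf(smp, 2, n_starts = 4))
    select_components(smp, fits)$chosen_k
  }, integer(1))
  expect_gte(mean(chosen == 1L), 0.9)
})

test_that("component selection picks k=2 for a well-separated two-population mixture", {
  u <- draw_mixture_u(8000, f = c(0.3, 0.7), D = c(0.05, 0.5), dt = dt,
                      seed = 77)
  smp <- make_jump_sample(u, dt)
  fits <- list(fit_sqd_cdf(smp, 1), fit_sqd_cdf(smp, 2))
  sel <- select_components(smp, fits)
  expect_equal(sel$chosen_k, 2L)
  # identical duplicate fits: smaller k wins
  sel_dup <- select_components(smp, list(fits[[2]],
                                         `class<-`(c(fits[[2]][-2], k = 3L),
                                                   "diffusion_fit")))
  expect_equal(sel_dup$chosen_k, 2L)
})

test_that("confidence intervals shrink with n and the two methods agree", {
  widths <- vapply(c(500, 5000), function(n) {
    set.seed(n)
    u <- rexp(n, rate = 1 / (4 * 0.2 * dt))
    fit <- confidence_intervals(fit_sqd_cdf(make_jump_sample(u, dt), k = 1))
    fit$components$D_hi - fit$components$D_lo
  }, numeric(1))
  expect_lt(widths[2], widths[1])
  u <- draw_mixture_u(4000, c(0.4, 0.6), c(0.05, 0.5), dt, seed = 31)
  fit <- fit_sqd_cdf(make_jump_sample(u, dt), k = 2)
  lin <- confidence_intervals(fit, "linearized")
  boot <- confidence_intervals(fit, "bootstrap", n_boot = 100, seed = 2)
  for (i in 1:2) {
    expect_lt(max(lin$components$D_lo[i], boot$components$D_lo[i]),
              min(lin$components$D_hi[i], boot$components$D_hi[i]))
    expect_lt(max(lin$components$fraction_lo[i],
                  boot$components$fraction_lo[i]),
              min(lin$components$fraction_hi[i],
                  boot$components$fraction_hi[i]))
  }
})

test_that("bootstrap intervals cover the generating parameters", {
  f_true <- 0.35; D_true <- c(0.05, 0.5)
  hits <- 0L; total <- 0L
  for (i in 1:25) {
    u <- draw_mixture_u(1200, c(f_true, 1 - f_true), D_true, dt,
                        seed = 400 + i)
    fit <- fit_sqd_cdf(make_jump_sample(u, dt), k = 2, n_starts = 3)
    fit <- confidence_intervals(fit, "bootstrap", n_boot = 80, seed = i)
    comp <- fit$components
    hits <- hits +
      (comp$fraction_lo[1] <= f_true && f_true <= comp$fraction_hi[1]) +
      (comp$D_lo[1] <= D_true[1] && D_true[1] <= comp$D_hi[1]) +
      (comp$D_lo[2] <= D_true[2] && D_true[2] <= comp$D_hi[2])
    total <- total + 3L
  }
  expect_gte(hits / total, 0.9)
})

test_that("simultaneous shared-D fits pool conditions correctly", {
  u <- draw_mixture_u(3000, c(0.4, 0.6), c(0.05, 0.4), dt, seed = 9)
  s1 <- make_jump_sample(u, dt)
  # two identical samples: shared fit equals the independent fit
  fits <- simultaneous_fit(list(a = s1, b = s1), k = 2)
  indep <- fit_sqd_cdf(s1, k = 2)
  expect_equal(fits$a$components$fraction, indep$components$fraction,
               tolerance = 0.01)
  expect_equal(fits$a$components$D_app_um2_s, indep$components$D_app_um2_s,
               tolerance = 0.02)
  expect_equal(fits$a$components$D_app_um2_s, fits$b$components$D_app_um2_s)
  # equal Ds, different fractions: both recovered
  ua <- draw_mixture_u(6000, c(0.32, 0.68), c(0.04, 0.5), dt, seed = 101)
  ub <- draw_mixture_u(6000, c(0.47, 0.53), c(0.04, 0.5), dt, seed = 102)
  fits2 <- simultaneous_fit(list(minus = make_jump_sample(ua, dt),
                                 plus = make_jump_sample(ub, dt)), k = 2)
  expect_lt(abs(fits2$minus$components$fraction[1] - 0.32), 0.03)
  expect_lt(abs(fits2$plus$components$fraction[1] - 0.47), 0.03)
  expect_equal(fits2$minus$components$D_app_um2_s,
               fits2$plus$components$D_app_um2_s)
  expect_equal(fits2$minus$components$D_app_um2_s, c(0.04, 0.5),
               tolerance = 0.1)
  # genuinely different Ds: the shared constraint shows lack of fit
  uc <- draw_mixture_u(6000, c(0.32, 0.68), c(0.04, 0.15), dt, seed = 103)
  sc <- make_jump_sample(uc, dt)
  sa <- make_jump_sample(ua, dt)
  fits3 <- simultaneous_fit(list(a = sa, c = sc), k = 2)
  indep_sse <- fit_sqd_cdf(sa, k = 2)$sse + fit_sqd_cdf(sc, k = 2)$sse
  expect_gt(attr(fits3, "total_sse"), indep_sse * 1.5)
  # mismatched frame intervals are rejected
  s_bad <- make_jump_sample(uc, dt = 0.05)
  expect_error(simultaneous_fit(list(a = sa, b = s_bad), k = 2),
               "frame interval")
})

test_that("fit reports serialize all components", {
  u <- draw_mixture_u(2000, c(0.5, 0.5), c(0.05, 0.5), dt, seed = 5)
  fit <- confidence_intervals(fit_sqd_cdf(make_jump_sample(u, dt), k = 2))
  rep <- fit_report(fit)
  expect_equal(rep$k, 2L)
  expect_equal(rep$component_1_fraction + rep$component_2_fraction, 1,
               tolerance = 1e-9)
  expect_length(rep$component_2_D_ci95, 2L)
})
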