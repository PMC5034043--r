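th300 <- thermo_state(300)

test_that("zwanzig_window handles degenerate distributions exactly", {
  expect_equal(zwanzig_window(window_samples(1, 0.9, rep(0, 100)), th300), 0)
  expect_equal(zwanzig_window(window_samples(1, 0.9, rep(1.0, 7)), th300), 1.0)
  expect_error(zwanzig_window(numeric(0), th300), "empty")
})

test_that("zwanzig_window is numerically stable for extreme energies", {
  # exact for a constant regardless of magnitude (naive exp would overflow)
  expect_equal(zwanzig_window(window_samples(1, 0, rep(-5000, 10)), th300),
               -5000)
  expect_equal(zwanzig_window(window_samples(1, 0, rep(5000, 10)), th300),
               5000)
})

test_that("Gaussian work samples recover the closed-form free energy", {
  g <- gen_work_samples(mu = 2.0, sigma = 0.5, n = 1e6, seed = 21,
                        thermo = th300)
  expect_equal(g$truth$dg, 2.0 - 0.25 / (2 * th300$rt), tolerance = 1e-12)
  expect_equal(g$truth$dg, 1.790, tolerance = 2e-3)
  est <- zwanzig_window(g$samples, th300)
  # standard error of the estimator from batching the iid samples
  b <- matrix(g$samples$delta_u, nrow = 1e4)
  ests <- apply(b, 2, function(x) zwanzig_window(window_samples(1, 0, x), th300))
  se <- stats::sd(ests) / sqrt(ncol(b))
  expect_lt(abs(est - g$truth$dg), 3 * se)
})

test_that("estimator bias shrinks as the sample size grows", {
  errs <- vapply(c(1e2, 1e4, 1e6), function(n) {
    g <- gen_work_samples(2.0, 0.5, n, seed = 33, thermo = th300)
    abs(zwanzig_window(g$samples, th300) - g$truth$dg)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("the Jensen bound holds for arbitrary sample sets", {
  set.seed(17)
  for (i in 1:20) {
    du <- stats::rnorm(200, mean = stats::runif(1, -2, 2),
                       sd = stats::runif(1, 0, 2))
    expect_lte(zwanzig_window(window_samples(1, 0.5, du), th300), mean(du))
  }
})

test_that("accumulation sums windows and validates the lambda path", {
  w0 <- list(window_samples(1, 0.5, rep(0, 5)),
             window_samples(0.5, 0, rep(0, 5)))
  expect_equal(accumulate_decoupling(w0, th300)$dg_decouple, 0)

  w <- list(window_samples(1, 0.5, stats::rnorm(100, 1, 0.3)),
            window_samples(0.5, 0, stats::rnorm(100, 0.5, 0.3)))
  acc <- accumulate_decoupling(w, th300)
  expect_equal(acc$dg_decouple,
               zwanzig_window(w[[1]], th300) + zwanzig_window(w[[2]], th300))
  expect_equal(nrow(acc$per_window), 2L)

  # gaps and direction reversals are schedule errors
  bad <- list(window_samples(1, 0.6, 0), window_samples(0.5, 0, 0))
  expect_error(accumulate_decoupling(bad, th300), "contiguous")
  zig <- list(window_samples(1, 0.5, 0), window_samples(0.5, 0.8, 0))
  expect_error(accumulate_decoupling(zig, th300), "monotone")
})

test_that("a reversed lambda path negates the total on the same samples", {
  set.seed(4)
  fwd <- list(window_samples(1, 0.5, stats::rnorm(200, 1, 0.4)),
              window_samples(0.5, 0, stats::rnorm(200, 0.4, 0.2)))
  rev <- lapply(rev(fwd), function(w) {
    window_samples(w$lambda_to, w$lambda_from, -w$delta_u)
  })
  expect_equal(accumulate_decoupling(rev, th300)$dg_decouple,
               -accumulate_decoupling(fwd, th300)$dg_decouple)
})

test_that("standard-state correction follows -RT log(V_site/V0)", {
  expect_equal(standard_state_correction(1660, th300, v0 = 1660), 0)
  expect_equal(standard_state_correction(166, th300, v0 = 1660),
               th300$rt * log(10))
  expect_equal(standard_state_correction(166, th300, v0 = 1660), 1.373,
               tolerance = 1e-3)
  expect_equal(standard_state_correction(16600, th300, v0 = 1660),
               -th300$rt * log(10))
  expect_error(standard_state_correction(-5, th300), "positive")
})

test_that("K_D and free energy convert consistently in both directions", {
  expect_equal(kd_from_delta_g(0, th300), 1)
  expect_equal(kd_from_delta_g(-7.85, th300), 1.9e-6, tolerance = 0.01)
  expect_equal(kd_from_delta_g(-th300$rt * log(1e6), th300), 1e-6)
  for (kd in c(1e-9, 2.4e-6, 0.5, 3)) {
    expect_equal(kd_from_delta_g(delta_g_from_kd(kd, th300), th300), kd)
  }
  # strictly increasing in dg0
  dgs <- seq(-10, 2, by = 0.5)
  expect_true(all(diff(vapply(dgs, kd_from_delta_g, numeric(1),
                              thermo = th300)) > 0))
})

test_that("half-away-from-zero significant rounding behaves as printed tables do", {
  expect_equal(signif_half_up(0.35, 1), 0.4)
  expect_equal(signif_half_up(-0.35, 1), -0.4)
  expect_equal(signif_half_up(10.7, 1), 10)
  expect_equal(signif_half_up(1070, 1), 1000)
  expect_equal(signif_half_up(1070, 2), 1100)
  expect_equal(signif_half_up(0, 1), 0)
})

test_that("delta bands reproduce the printed affinity-table ranges", {
  b <- kd_uncertainty_band(2.0e-6, delta = 1, thermo = th300, sig_figs = 1)
  expect_equal(b$low_rounded * 1e6, 0.4)
  expect_equal(b$high_rounded * 1e6, 10)
  b <- kd_uncertainty_band(200e-6, delta = 1, thermo = th300, sig_figs = 1)
  expect_equal(b$low_rounded * 1e6, 40)
  expect_equal(b$high_rounded * 1e6, 1000)
  b0 <- kd_uncertainty_band(5e-6, delta = 0, thermo = th300)
  expect_equal(b0$low, 5e-6)
  expect_equal(b0$high, 5e-6)
  # band width strictly increasing in delta
  widths <- vapply(c(0, 0.5, 1, 2), function(d) {
    b <- kd_uncertainty_band(1e-6, d, th300)
    b$high - b$low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("end-to-end decoupling matches deterministic quadrature", {
  for (sys in list(toy_single_well(), toy_three_well())) {
    sch <- lambda_schedule(24, 10000, 1000)
    w <- window_work_samples(sys, th300, sch, seed = 7)
    acc <- accumulate_decoupling(w, th300)
    expect_lt(abs(acc$dg_decouple - dg_decouple_quadrature(sys, th300)), 0.1)
  }
})

test_that("splitting a window leaves the quadrature-oracle total unchanged", {
  sys <- toy_single_well()
  rt <- th300$rt
  zl <- function(lam) site_config_integral(sys, th300, lambda = lam)$z
  total_direct <- rt * log(zl(1) / zl(0))
  # exact per-window free energies for two different tilings of [1, 0]
  tiling1 <- c(1, 0.5, 0)
  tiling2 <- c(1, 0.75, 0.5, 0.25, 0)
  for (lams in list(tiling1, tiling2)) {
    dg <- sum(vapply(seq_len(length(lams) - 1), function(k) {
      -rt * log(zl(lams[k + 1]) / zl(lams[k]))
    }, numeric(1)))
    expect_equal(dg, total_direct, tolerance = 1e-9)
  }
})

test_that("fep_estimate assembles dG0, K_D and band with the stated convention", {
  w <- list(window_samples(1, 0.5, rep(3, 10)),
            window_samples(0.5, 0, rep(2, 10)))
  fe <- fep_estimate(w, th300, v_site = 166, dg_solv = 0.5, delta = 1,
                     v0 = 1660)
  expect_equal(fe$dg_decouple, 5)
  expect_equal(fe$dg_volume, th300$rt * log(10))
  expect_equal(fe$dg0, -(5 + 0.5) + th300$rt * log(10))
  expect_equal(fe$kd, exp(fe$dg0 / th300$rt))
  expect_equal(fe$band$low, fe$kd * exp(-1 / th300$rt))
  expect_gte(fe$diagnostics$jensen_gap, 0)
})

test_that("window samples round-trip through CSV", {
  w <- list(window_samples(1, 0.5, c(0.1, 0.2, -0.3)),
            window_samples(0.5, 0, c(0.4, 0.5)))
  path <- tempfile(fileext = ".csv")
  write_windows_csv(w, path)
  w2 <- read_windows_csv(path)
  expect_equal(length(w2), 2L)
  expect_equal(w2[[1]]$delta_u, w[[1]]$delta_u)
  expect_equal(w2[[2]]$lambda_from, 0.5)
})
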