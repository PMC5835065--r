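test_that("oxidation product is guild-specific", {
  cv <- growth_curve(c(0, 10), no2_uM = c(10, 20), no3_uM = c(0, 5))
  expect_equal(oxidation_product(cv, "AOB"), c(10, 25))
  expect_equal(oxidation_product(cv, "NOB"), c(0, 5))

  cv2 <- growth_curve(c(0, 10), no2_uM = c(10, 20))
  expect_error(oxidation_product(cv2, "AOB"), "AOB")
  expect_error(oxidation_product(cv2, "NOB"), "NOB")

  cv3 <- growth_curve(c(0, 10), no2_uM = c(1, 2), no3_uM = c(0, 0))
  expect_warning(oxidation_product(cv3, "NOB"), "all-zero")
})

test_that("window selection implements the R-squared acceptance rule", {
  # exact exponential: the full range is selected with R^2 = 1
  t <- seq(0, 50, 5)
  s <- 100 * exp(0.02 * t)
  w <- select_window(s, t)
  expect_equal(c(w$start_idx, w$end_idx), c(1L, length(t)))
  expect_equal(w$r2, 1)

  # product below detection (zero) during lag: window starts at onset
  t2 <- seq(0, 100, 4)
  s2 <- ifelse(t2 < 24, 0, 100 * exp(0.05 * (t2 - 24)))
  w2 <- select_window(s2, t2)
  expect_equal(w2$t_start, 24)

  # a flat positive plateau is (mostly) rejected by the R^2 rule
  s3 <- ifelse(t2 < 24, 10, 10 * exp(0.08 * (t2 - 24)))
  w3 <- select_window(s3, t2)
  expect_gte(w3$t_start, 12)
  expect_gte(w3$r2, 0.99)

  # declining series: no acceptable window
  expect_error(select_window(100 * exp(-0.02 * t), t),
               "no exponential phase")
  expect_error(select_window(s, t, r2_min = 2), "r2_min")
  expect_error(select_window(s, t, min_points = 2), "min_points")

  # noisy exponential: whatever is accepted satisfies the rule
  set.seed(21)
  for (i in 1:5) {
    sn <- 100 * exp(0.02 * t) * ln_noise(length(t), 0.03)
    wn <- select_window(sn, t)
    expect_gte(wn$r2, 0.99)
  }
})

test_that("growth rate is the log-linear slope; lag is window start", {
  t <- seq(0, 50, 5)
  s <- 100 * exp(0.02 * t)
  gf <- growth_rate(s, t, select_window(s, t))
  expect_equal(gf$mu, 0.02, tolerance = 1e-10)
  expect_equal(gf$lag_h, 0)
  expect_equal(gf$r2, 1)
  expect_gte(gf$n_points, 4)

  # growth starting at t = 24: lag is 24 h
  t2 <- seq(0, 120, 4)
  s2 <- ifelse(t2 < 24, 0, 100 * exp(0.05 * (t2 - 24)))
  gf2 <- growth_rate(s2, t2, select_window(s2, t2))
  expect_equal(gf2$lag_h, 24)
  expect_equal(gf2$mu, 0.05, tolerance = 1e-10)

  # lag additivity: shifting the clock by delta shifts lag by exactly delta
  for (delta in c(7, 30)) {
    ts <- t2 + delta
    gfs <- growth_rate(s2, ts, select_window(s2, ts))
    expect_equal(gfs$lag_h, gf2$lag_h + delta)
  }
  # ... and a later inoculation time removes it again
  gfi <- growth_rate(s2, t2 + 7, select_window(s2, t2 + 7),
                     inoculation_time = 7)
  expect_equal(gfi$lag_h, gf2$lag_h)

  # 5% noise around mu = 0.02: recovered within 10%
  set.seed(33)
  sn <- 100 * exp(0.02 * t2) * ln_noise(length(t2), 0.05)
  gfn <- growth_rate(sn, t2, select_window(sn, t2))
  expect_lte(abs(gfn$mu - 0.02) / 0.02, 0.10)
})

test_that("the Monod rate law behaves as specified", {
  # half-saturation: mu(ks) = mu_max / 2 exactly
  expect_equal(monod_mu(25.9, 0.028, 25.9), 0.014)
  expect_equal(monod_mu(0, 0.028, 25.9), 0)
  # hand-computed: 0.028 * 500 / 525.9
  expect_equal(monod_mu(500, 0.028, 25.9), 0.02662103, tolerance = 1e-6)

  # strictly increasing in S, saturating at mu_max
  S <- seq(0, 5000, 50)
  mu <- monod_mu(S, 0.021, 71.8)
  expect_true(all(diff(mu) > 0))
  expect_lt(max(mu), 0.021)
  expect_equal(monod_mu(1e9, 0.021, 71.8), 0.021, tolerance = 1e-6)

  expect_error(monod_mu(-1, 0.02, 25), "non-negative")
  expect_error(monod_mu(1, 0, 25), "mu_max")
  expect_error(monod_mu(1, 0.02, 0), "ks")
})

test_that("Monod fitting recovers parameters and surfaces diagnostics", {
  S <- substrate_grid
  # noiseless self-consistency at the published coupled-culture values
  f <- fit_monod(S, monod_mu(S, 0.028, 25.9))
  expect_equal(f$mu_max, 0.028, tolerance = 1e-6)
  expect_equal(f$ks, 25.9, tolerance = 1e-6)
  expect_true(f$converged)
  expect_lt(f$rss, 1e-12)

  # methods on the fit object
  expect_named(coef(f), c("mu_max", "ks"))
  expect_equal(predict(f, newdata = 25.9), f$mu_max / 2, tolerance = 1e-5)
  expect_equal(length(residuals(f)), 5L)

  # 5% multiplicative noise at the solo-culture values, 20 seeds:
  # median relative Ks error stays within 25%
  errs <- vapply(1:20, function(sd) {
    set.seed(sd)
    mu <- monod_mu(S, 0.021, 71.8) * ln_noise(length(S), 0.05)
    abs(fit_monod(S, mu)$ks - 71.8) / 71.8
  }, numeric(1))
  expect_lte(median(errs), 0.25)

  # bias shrinks as replicate count grows
  mean_err <- vapply(c(1, 4, 16), function(nr) {
    mean(vapply(1:15, function(sd) {
      set.seed(sd * 100 + nr)
      Sr <- rep(S, nr)
      mu <- monod_mu(Sr, 0.021, 71.8) * ln_noise(length(Sr), 0.05)
      abs(fit_monod(Sr, mu)$ks - 71.8) / 71.8
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_err[3], mean_err[1])

  expect_error(fit_monod(c(100, 100, 100), c(0.01, 0.011, 0.012)),
               "distinct")
  expect_error(fit_monod(S, rep(0, 5)), "zero")
})

test_that("qPCR standard-curve quantification round-trips", {
  st <- data.frame(log10_copies = 3:6, ct = 30 - 3.3219 * (3:6 - 3))
  q <- qpcr_quantify(st, 23.356)
  expect_equal(q$copies, 1e5, tolerance = 0.01)
  # slope -3.3219 is perfect doubling: efficiency 100%
  expect_equal(q$curve$efficiency, 1, tolerance = 1e-3)
  expect_lt(q$curve$slope, 0)

  # round trip within 0.5% anywhere in the standards' range
  for (x in c(1.2e3, 4.7e4, 8.3e5)) {
    ct_x <- q$curve$slope * log10(x) + q$curve$intercept
    expect_equal(qpcr_quantify(st, ct_x)$copies, x, tolerance = 0.005)
  }

  # published endpoint copy numbers give the published fold increase
  ct_lo <- q$curve$slope * log10(2.2e4) + q$curve$intercept
  ct_hi <- q$curve$slope * log10(3.2e5) + q$curve$intercept
  fold <- qpcr_quantify(st, ct_hi)$copies / qpcr_quantify(st, ct_lo)$copies
  expect_equal(fold, 14.5, tolerance = 0.1 / 14.5)

  expect_error(qpcr_quantify(data.frame(log10_copies = c(3, 3.5, 4),
                                        ct = c(30, 28, 27))), "2 log10")
  inv <- data.frame(log10_copies = 3:6, ct = 20 + 3.3 * (3:6))
  expect_error(qpcr_quantify(inv), "inverted")
})
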