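test_that("body-weight scaling applies the power law to every parameter", {
  p <- ribomab01_params()
  # at the reference weight the coefficients are the effective values
  e1 <- scale_params(p, 1)
  expect_equal(e1$cl, p$cl)
  expect_equal(e1$k_elim, p$k_elim)
  e70 <- scale_params(p, 70)
  expect_equal(e70$cl, 0.28 * 70^0.79, tolerance = 1e-12)
  expect_equal(e70$k_elim, 0.041 * 70^-0.14, tolerance = 1e-12)
  # mRNA-LNP half-life of ~31 h in human
  expect_equal(log(2) / e70$k_elim, 30.6, tolerance = 0.01)
  expect_error(scale_params(p, 0), "positive")
  expect_error(scale_params(p, -2), "positive")
})

test_that("simulation is zero without dosing and linear in dose", {
  p <- ribomab01_params()
  tt <- c(0, 1, 6, 24, 120)
  empty <- dose_regimen(numeric(0), numeric(0))
  prof0 <- tm_simulate(p, empty, tt, weight = 2.5)
  expect_equal(prof0$conc, rep(0, 5))
  r1 <- tm_simulate(p, dose_regimen(0, 50), tt, weight = 2.5)
  r2 <- tm_simulate(p, dose_regimen(0, 100), tt, weight = 2.5)
  expect_equal(r2$conc[-1], 2 * r1$conc[-1], tolerance = 1e-12)
  expect_equal(r1$conc[1], 0)  # nothing translated yet at t = 0
  expect_error(tm_simulate(p, dose_regimen(0, 1), c(5, 1), weight = 1),
               "sorted")
})

test_that("spectral and stiff-ODE routes agree to 1e-6 for both
           reference antibodies across the weight range", {
  tt <- c(0.5, 1, 3, 6, 12, 24, 48, 96, 168, 336, 504)
  for (p in list(ribomab01_params(), ribomab02_params())) {
    for (w in c(0.025, 2.5, 70)) {
      reg <- dose_regimen(0, 100)
      a <- tm_simulate(p, reg, tt, weight = w, method = "analytic")
      o <- tm_simulate(p, reg, tt, weight = w, method = "ode",
                       rtol = 1e-10, atol = 1e-12)
      expect_lt(max(abs(a$conc - o$conc) / o$conc), 1e-6)
    }
  }
  # infusion input
  p <- ribomab01_params()
  reg <- dose_regimen(0, 100, duration = 2)
  a <- tm_simulate(p, reg, tt, weight = 70, method = "analytic")
  o <- tm_simulate(p, reg, tt, weight = 70, method = "ode",
                   rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(a$conc - o$conc) / o$conc), 1e-6)
})

test_that("the analytic bolus solution matches the simulator and has the
           right limits", {
  p <- ribomab01_params()
  tt <- seq(0, 1000, length.out = 50)
  cf <- closed_form_profile(p, 100, weight = 2.5)
  sim <- tm_simulate(p, dose_regimen(0, 100), tt, weight = 2.5)
  expect_lt(max(abs(cf(tt[-1]) - sim$conc[-1]) / sim$conc[-1]), 1e-6)
  expect_equal(cf(0), 0)
  # no translation, no antibody
  p0 <- p; p0$k_translate <- 1e-12
  cf0 <- closed_form_profile(p0, 100, weight = 2.5)
  expect_lt(max(cf0(tt)), 1e-10)
})

test_that("closed-form DAUC matches its formula and ignores volumes", {
  p <- ribomab01_params()
  expect_equal(closed_form_dauc(p, 70), 0.2392, tolerance = 1e-3)
  expect_equal(closed_form_dauc(p, 70),
               0.043451 / (0.022619 * 8.031), tolerance = 1e-4)
  p2 <- p; p2$k_translate <- 2 * p$k_translate
  expect_equal(closed_form_dauc(p2, 70), 2 * closed_form_dauc(p, 70),
               tolerance = 1e-12)
  p3 <- p; p3$v1 <- 99; p3$v2 <- 7; p3$q <- 5
  expect_equal(closed_form_dauc(p3, 70), closed_form_dauc(p, 70),
               tolerance = 1e-12)
})

test_that("simulated dose-normalized exposure reproduces the closed form
           and is dose-invariant", {
  p <- ribomab01_params()
  for (dose in c(10, 3000)) {
    eff <- scale_params(p, 70)
    lam <- min(abs(eigen(ribopk:::.sys_matrix(eff),
                         only.values = TRUE)$values))
    tt <- seq(0, 10 * log(2) / lam, length.out = 500)
    prof <- tm_simulate(p, dose_regimen(0, dose), tt, weight = 70)
    res <- auc_inf(prof$time[-1], prof$conc[-1])
    expect_lt(abs(res$auc_inf / dose / closed_form_dauc(p, 70) - 1),
              0.005)
  }
})

test_that("multiple dosing obeys superposition and keeps all states
           non-negative", {
  p <- ribomab01_params()
  tt <- seq(0, 800, by = 4)
  multi <- tm_simulate(p, dose_regimen(c(0, 168, 336), c(100, 50, 100)),
                       tt, weight = 2.5)
  single <- function(t0, amt) {
    shifted <- pmax(tt - t0, 0)
    out <- numeric(length(tt))
    cf <- closed_form_profile(p, amt, weight = 2.5)
    out[tt >= t0] <- cf(shifted[tt >= t0])
    out
  }
  sup <- single(0, 100) + single(168, 50) + single(336, 100)
  pos <- sup > 1e-9  # skip the identically-zero point at t = 0
  expect_lt(max(abs(multi$conc[pos] - sup[pos]) / sup[pos]), 1e-8)
  expect_true(all(attr(multi, "state") >= 0))
  inf <- tm_simulate(p, dose_regimen(c(0, 24), c(10, 10),
                                     duration = c(6, 0)),
                     tt, weight = 0.025)
  expect_true(all(attr(inf, "state") >= 0))
})

test_that("cross-species projection multiplies by the configured powers
           and is the identity at the source weight", {
  p <- ribomab01_params()
  eff <- scale_params(p, 2.5)
  sc_nhp <- scaling_config("nhp")
  same <- project_params(eff, 2.5, sc_nhp)
  expect_equal(unclass(same), unclass(eff), tolerance = 1e-12)
  human <- project_params(eff, 70, sc_nhp)
  # no translation-rate adjustment from NHP
  expect_equal(human$k_translate, eff$k_translate, tolerance = 1e-12)
  expect_equal(human$cl, eff$cl * 28^0.80, tolerance = 1e-12)
  expect_equal(human$v1, eff$v1 * 28, tolerance = 1e-12)
  # mouse source scales the translation rate with -0.51
  effm <- scale_params(p, 0.025)
  hm <- project_params(effm, 70, scaling_config("mouse"))
  expect_equal(hm$k_translate, effm$k_translate * 2800^-0.51,
               tolerance = 1e-12)
  expect_equal(hm$cl, effm$cl * 2800^0.80, tolerance = 1e-12)
  # a config missing an exponent for a present parameter is an error
  incomplete <- structure(c(k_elim = -0.1, cl = 0.8, v1 = 1, v2 = 1,
                            k_translate = 0), class = "scaling_config")
  expect_error(project_params(eff, 70, incomplete), "lacks exponents")
  expect_error(scaling_config("other"), "supply it explicitly")
})

test_that("percentile bands collapse onto the deterministic profile
           without variability and are ordered with it", {
  p <- ribomab01_params()
  tt <- c(6, 24, 72, 168)
  reg <- dose_regimen(0, 100)
  det <- tm_simulate(p, reg, tt, weight = 2.5)$conc
  b0 <- tm_percentile_bands(p, reg, tt, weight = 2.5, n = 20, seed = 5)
  expect_equal(unname(b0[, "p50"]), det, tolerance = 1e-12)
  p$omega <- c(cl = 0.3, k_translate = 0.2)
  b <- tm_percentile_bands(p, reg, tt, weight = 2.5, n = 200, seed = 5)
  expect_true(all(b[, "p10"] <= b[, "p50"] & b[, "p50"] <= b[, "p90"]))
})
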