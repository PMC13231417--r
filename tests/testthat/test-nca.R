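test_that("cmax/tmax picks the maximum with earliest-tie rule", {
  expect_equal(compute_cmax_tmax(c(1, 2), c(10, 5)),
               list(cmax = 10, tmax = 1))
  expect_equal(compute_cmax_tmax(c(1, 2), c(5, 5)),
               list(cmax = 5, tmax = 1))
  m <- mono_profile(c(0.5, 1, 2, 4, 8))
  expect_equal(compute_cmax_tmax(m$time, m$conc)$tmax, 0.5)
  expect_true(is.na(compute_cmax_tmax(numeric(0), numeric(0))$cmax))
})

test_that("lambda-z is exact on mono-exponential data and flags
           non-estimable profiles", {
  m <- mono_profile(c(4, 8, 12, 24))
  lz <- fit_lambda_z(m$time, m$conc)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(lz$t_half, log(2) / 0.1, tolerance = 1e-10)
  # rising profile: no negative slope anywhere
  ris <- fit_lambda_z(c(1, 2, 4, 8), c(1, 2, 3, 4))
  expect_false(ris$estimable)
  # fewer than 3 usable points
  expect_false(fit_lambda_z(c(1, 2), c(3, 1))$estimable)
  # explicit point count
  lz3 <- fit_lambda_z(m$time, m$conc, n_points = 3)
  expect_equal(lz3$n_points, 3L)
  expect_equal(lz3$lambda_z, 0.1, tolerance = 1e-10)
})

test_that("lambda-z recovers the generating constant from noisy data", {
  set.seed(31)
  tt <- c(2, 4, 8, 16, 24, 36, 48, 60)
  conc <- 10 * exp(-0.1 * tt) * (1 + rnorm(8, 0, 0.05))
  lz <- fit_lambda_z(tt, conc)
  expect_true(lz$estimable)
  expect_lt(abs(lz$lambda_z / 0.1 - 1), 0.1)
})

test_that("linear-up/log-down trapezoid matches hand and closed-form
           results and is additive", {
  # rising segment linear, falling segment logarithmic
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 10, 5)),
               5 + 5 / log(2), tolerance = 1e-12)
  # constant profile
  expect_equal(auc_trapezoid(c(0, 3), c(2, 2)), 6)
  # dense mono-exponential vs analytic integral
  tt <- seq(0, 50, by = 0.25)
  m <- mono_profile(tt)
  expect_equal(auc_trapezoid(m$time, m$conc, 0, 50),
               100 * (1 - exp(-5)), tolerance = 1e-3)
  # additivity over adjacent intervals, with interpolated split points
  for (split in c(7, 13.3, 25)) {
    expect_equal(auc_trapezoid(m$time, m$conc, 0, split) +
                   auc_trapezoid(m$time, m$conc, split, 50),
                 auc_trapezoid(m$time, m$conc, 0, 50),
                 tolerance = 1e-12)
  }
  expect_error(auc_trapezoid(c(0, 1), c(1, 1), 1, 0), "t_end")
})

test_that("infinite-time extrapolation reproduces closed forms", {
  # complete mono-exponential from t = 0: AUC = C0 / k exactly
  m <- mono_profile(c(0, 1, 2, 4, 8, 16, 24, 36, 48, 72))
  ai <- auc_inf(m$time, m$conc)
  expect_equal(ai$auc_inf, 100, tolerance = 1e-6)
  expect_gte(ai$auc_inf, ai$auc_last)
  # profile truncated at one half-life: 50% extrapolated
  th <- log(2) / 0.1
  m2 <- mono_profile(seq(0, th, length.out = 12))
  ai2 <- auc_inf(m2$time, m2$conc)
  expect_lt(abs(ai2$extrap_pct - 50), 1)
  # lambda-z not estimable: auc_inf absent, auc_last still reported
  ai3 <- auc_inf(c(1, 2, 4), c(1, 2, 3))
  expect_true(is.na(ai3$auc_inf))
  expect_gt(ai3$auc_last, 0)
})

test_that("dataset-level NCA dose-normalizes exposure and is invariant
           to simultaneous dose/concentration scaling", {
  tt <- rich_schedule
  conc <- 0.0696 * exp(-0.005 * (tt - 3)) * pmin(1, tt / 3)
  ds <- pk_dataset(
    records = data.frame(subject_id = "h1", species = "human",
                         weight = 70, time = tt, conc = conc,
                         blq = FALSE),
    doses = data.frame(subject_id = "h1", time = 0, amount = 100,
                       duration = 0))
  res <- nca(ds)
  expect_equal(res$cmax, 0.0696)
  expect_equal(res$dcmax, 6.96e-4)  # cmax / dose
  # doubling all concentrations and the dose leaves DCmax and DAUC fixed
  ds2 <- ds
  ds2$records$conc <- 2 * ds2$records$conc
  ds2$doses$amount <- 2 * ds2$doses$amount
  res2 <- nca(ds2)
  expect_equal(res2$dcmax, res$dcmax, tolerance = 1e-12)
  expect_equal(res2$dauc, res$dauc, tolerance = 1e-12)
})

test_that("BLQ observations are excluded and group statistics match the
           direct formulas", {
  set.seed(9)
  n <- 10
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- mono_profile(c(1, 2, 4, 8, 16, 24, 48),
                      c0 = exp(rnorm(1, log(0.1), 0.2)))
    data.frame(subject_id = sprintf("s%02d", i), species = "nhp",
               weight = 2.5, time = m$time, conc = m$conc, blq = FALSE)
  }))
  # one spurious BLQ row that would otherwise distort the terminal fit
  recs$blq[recs$time == 48 & recs$subject_id == "s01"] <- TRUE
  doses <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                      time = 0, amount = 50, duration = 0)
  ds <- pk_dataset(recs, doses)
  res <- nca(ds)
  expect_equal(res$n_lambda_points[res$subject_id == "s01"] +
                 1L, res$n_lambda_points[res$subject_id == "s02"])
  s <- summary(res)
  gm <- s[s$parameter == "cmax", ]
  expect_equal(gm$geo_mean, exp(mean(log(res$cmax))), tolerance = 1e-12)
  expect_equal(gm$n, n)
  expect_equal(gm$mean, mean(res$cmax), tolerance = 1e-12)
})

test_that("multiple-dose subjects use the first interval by default and
           per-interval mode reports AUC(0-tau)", {
  p <- ribomab01_params()
  reg <- dose_regimen(c(0, 168), 100)
  tt <- c(1, 3, 6, 24, 48, 72, 120, 167, 169, 171, 174, 192, 216, 240)
  prof <- tm_simulate(p, reg, tt, weight = 2.5)
  ds <- pk_dataset(
    records = data.frame(subject_id = "s1", species = "nhp",
                         weight = 2.5, time = tt, conc = prof$conc,
                         blq = FALSE),
    doses = data.frame(subject_id = "s1", time = c(0, 168), amount = 100,
                       duration = 0))
  res1 <- nca(ds)
  expect_equal(nrow(res1), 1)
  # first-interval Cmax, not the higher post-accumulation one
  expect_equal(res1$cmax, max(prof$conc[tt < 168]))
  resi <- nca(ds, per_interval = TRUE)
  expect_equal(nrow(resi), 2)
  expect_false(is.na(resi$auc_tau[1]))
})
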