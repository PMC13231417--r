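test_that("the profiled objective matches its closed form and is
           invariant to subject order", {
  p <- ribomab01_params()
  des <- study_design(
    study_arm("nhp", 3, 100, c(1, 6, 24, 72, 168, 336)),
    study_arm("mouse", 3, 1, c(1, 6, 24, 72, 168, 336)))
  ds <- generate_study(des, p, seed = 12, sigma = 0.1, lloq = NA)
  spec <- default_fit_spec()
  phi <- unlist(p[spec$free])
  is_str <- !grepl("^alpha", spec$free)
  phi[is_str] <- log(phi[is_str])
  obj <- tm_objective(phi, ds, spec)
  # independent computation of the profiled likelihood
  pred <- vapply(seq_len(nrow(ds$records)), function(i) {
    r <- ds$records[i, ]
    tm_simulate(p, dose_regimen(0, ds$doses$amount[
      ds$doses$subject_id == r$subject_id]), r$time,
      weight = r$weight)$conc[1]
  }, numeric(1))
  rr <- log(ds$records$conc) - log(pred)
  n <- length(rr)
  expect_equal(obj, n / 2 * (log(2 * pi * mean(rr^2)) + 1),
               tolerance = 1e-10)
  # permuting subjects leaves the objective unchanged
  ord <- c(4:6, 1:3)
  ids <- unique(ds$records$subject_id)[ord]
  rec2 <- do.call(rbind, lapply(ids, function(id)
    ds$records[ds$records$subject_id == id, ]))
  dos2 <- do.call(rbind, lapply(ids, function(id)
    ds$doses[ds$doses$subject_id == id, ]))
  ds2 <- pk_dataset(rec2, dos2)
  expect_equal(tm_objective(phi, ds2, spec), obj, tolerance = 1e-12)
})

test_that("noiseless multispecies data are recovered to numerical
           precision", {
  p <- ribomab01_params()
  des <- default_study_designs()[["multispecies-rich"]]
  des$arms <- lapply(des$arms, function(a) { a$n <- 1L; a })
  ds <- generate_study(des, p, seed = 1, sigma = 0, lloq = NA)
  fit <- fit_translational(ds, default_fit_spec(), seed = 2, starts = 2)
  truth <- c(k_elim = 0.041, alpha_k_elim = -0.14, k_translate = 0.27,
             alpha_k_translate = -0.43, cl = 0.28, alpha_cl = 0.79,
             q = 1.02, alpha_q = 1.03)
  est <- coef(fit)[names(truth)]
  str_nm <- c("k_elim", "k_translate", "cl", "q")
  expect_lt(max(abs(est[str_nm] / truth[str_nm] - 1)), 1e-3)
  expect_lt(max(abs(est[!names(est) %in% str_nm] -
                      truth[!names(truth) %in% str_nm])), 1e-4)
  expect_lt(fit$sigma, 1e-4)
  # accepted-iterate objective trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
  expect_equal(min(fit$trace), fit$objective)
})

test_that("identifiability and design guards reject degenerate problems", {
  p <- ribomab01_params()
  des <- study_design(study_arm("nhp", 2, 100, c(1, 6, 24, 72, 168)))
  ds <- generate_study(des, p, seed = 3, sigma = 0.1, lloq = NA)
  # free exponent with a single body weight
  expect_error(fit_translational(ds, default_fit_spec(), starts = 1),
               "unidentifiable")
  # fewer observations than free parameters
  des2 <- study_design(study_arm("nhp", 1, 100, c(1, 6, 24)))
  ds2 <- generate_study(des2, p, seed = 4, sigma = 0, lloq = NA)
  spec2 <- fit_spec(
    free = c("k_elim", "k_translate", "cl", "q"),
    fixed = c(v1 = 100, v2 = 114, alpha_k_elim = 0,
              alpha_k_translate = 0, alpha_cl = 0, alpha_q = 0))
  ds2$records <- ds2$records[1:3, ]
  expect_error(fit_translational(pk_dataset(ds2$records, ds2$doses),
                                 spec2, starts = 1), "fewer usable")
  # single-species fitter refuses multispecies input
  desm <- study_design(study_arm("nhp", 1, 100, c(1, 6, 24)),
                       study_arm("mouse", 1, 1, c(1, 6, 24)))
  dsm <- generate_study(desm, p, seed = 5, sigma = 0, lloq = NA)
  expect_error(fit_single_species(dsm, fixed = c(v1 = 1, v2 = 1)),
               "exactly one species")
  # all-BLQ dataset has nothing to fit
  dsb <- generate_study(des, p, seed = 6, sigma = 0, lloq = NA)
  dsb$records$blq <- TRUE
  expect_error(fit_translational(pk_dataset(dsb$records, dsb$doses),
                                 default_fit_spec()),
               "no usable observations")
})

test_that("estimates are invariant to a common rescaling of
           concentration and dose units", {
  p <- ribomab01_params()
  des <- study_design(
    study_arm("nhp", 2, 100, rich_schedule),
    study_arm("human", 2, 3000, rich_schedule))
  ds <- generate_study(des, p, seed = 21, sigma = 0.1, lloq = NA)
  spec <- fit_spec(
    free = c("k_elim", "k_translate", "cl", "alpha_cl"),
    fixed = c(alpha_k_elim = -0.14, alpha_k_translate = -0.43,
              v1 = 40.1, alpha_v1 = 1, v2 = 45.6, alpha_v2 = 1,
              q = 1.02, alpha_q = 1.03))
  fit1 <- fit_translational(ds, spec, seed = 1, starts = 1)
  ds_ng <- ds  # e.g. ng/mL with ng doses
  ds_ng$records$conc <- 1000 * ds_ng$records$conc
  ds_ng$records$lloq <- 1000 * ds_ng$records$lloq
  ds_ng$doses$amount <- 1000 * ds_ng$doses$amount
  fit2 <- fit_translational(ds_ng, spec, seed = 1, starts = 1)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
})

test_that("single-species fits recover effective parameters and expose
           them for projection", {
  p <- ribomab01_params()
  eff <- scale_params(p, 2.5)
  des <- study_design(study_arm("nhp", 6, 100, rich_schedule))
  ds <- generate_study(des, p, seed = 33, sigma = 0, lloq = NA)
  fit <- fit_single_species(ds, fixed = c(v1 = eff$v1, v2 = eff$v2),
                            seed = 34, starts = 2)
  est <- coef(fit)
  truth <- unlist(eff[c("k_elim", "k_translate", "cl", "q")])
  expect_lt(max(abs(est[names(truth)] / truth - 1)), 1e-3)
  eff_hat <- as_effective_params(fit)
  expect_s3_class(eff_hat, "tm_params_eff")
  expect_equal(eff_hat$weight, 2.5)
  expect_lt(abs(closed_form_dauc(eff_hat) / closed_form_dauc(eff) - 1),
            0.05)
})

test_that("free parameters are recovered without material bias over
           seeded noisy replicates", {
  p <- ribomab01_params()
  sched <- rich_schedule
  des <- study_design(
    study_arm("mouse", 2, 1, sched), study_arm("rat", 2, 10, sched),
    study_arm("nhp", 2, 100, sched), study_arm("human", 2, 3000, sched))
  spec <- fit_spec(
    free = c("k_elim", "k_translate", "cl", "alpha_cl"),
    fixed = c(alpha_k_elim = -0.14, alpha_k_translate = -0.43,
              v1 = 40.1, alpha_v1 = 1, v2 = 45.6, alpha_v2 = 1,
              q = 1.02, alpha_q = 1.03))
  est <- t(vapply(1:20, function(r) {
    ds <- generate_study(des, p, seed = 1000 + r, sigma = 0.15,
                         lloq = NA)
    coef(fit_translational(ds, spec, seed = r, starts = 1))
  }, numeric(4)))
  truth <- c(k_elim = 0.041, k_translate = 0.27, cl = 0.28)
  rel_bias <- apply(sweep(est[, names(truth)], 2, truth, "/") - 1, 2,
                    median)
  expect_lt(max(abs(rel_bias)), 0.1)
  expect_lt(abs(median(est[, "alpha_cl"]) - 0.79), 0.1)
})

test_that("two-stage estimation with pooled structural constants
           recovers the generating between-subject variability", {
  p <- ribomab01_params()
  p$omega <- c(cl = 0.3)
  eff <- scale_params(p, 2.5)
  des <- study_design(study_arm("nhp", 100, 100, rich_schedule))
  ds <- generate_study(des, p, seed = 7, sigma = 0.05, lloq = NA)
  pooled <- fit_single_species(
    ds, free = c("k_elim", "k_translate", "cl", "q"),
    fixed = c(v1 = eff$v1, v2 = eff$v2), seed = 1, starts = 2)
  pc <- coef(pooled)
  ts <- fit_two_stage(
    ds, free = "cl",
    fixed = c(k_elim = pc[["k_elim"]], k_translate = pc[["k_translate"]],
              q = pc[["q"]], v1 = eff$v1, v2 = eff$v2))
  expect_equal(nrow(ts$individual), 100)
  expect_lt(abs(ts$omega[["cl"]] / 0.3 - 1), 0.25)
})

test_that("fit methods expose coefficients, residuals, predictions and
           replicate simulation coherently", {
  p <- ribomab01_params()
  des <- study_design(study_arm("nhp", 3, 100, rich_schedule))
  ds <- generate_study(des, p, seed = 55, sigma = 0.1, lloq = NA)
  eff <- scale_params(p, 2.5)
  fit <- fit_single_species(ds, fixed = c(v1 = eff$v1, v2 = eff$v2),
                            seed = 56, starts = 1)
  expect_named(coef(fit), c("k_elim", "k_translate", "cl", "q"))
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$sigma,
               tolerance = 1e-12)
  prof <- predict(fit, dose_regimen(0, 100), c(1, 24, 168), weight = 2.5)
  expect_s3_class(prof, "tm_profile")
  sims <- simulate(fit, nsim = 2, seed = 57)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "pk_dataset")
  expect_equal(nrow(sims[[1]]$records), fit$n_obs)
  expect_s3_class(logLik(fit), "logLik")
  expect_output(print(summary(fit)), "sigma")
})
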