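#' Define one arm of a synthetic multispecies study
#'
#' @param species Species label (`"mouse"`, `"rat"`, `"nhp"`, `"human"`,
#'   or any other tag).
#' @param n Number of subjects (>= 1).
#' @param dose Dose amount in ug per administration (> 0).
#' @param schedule Sampling times in h after the first dose (sorted,
#'   positive).
#' @param weight Body weight in kg; defaults to the species' typical
#'   weight from [species_weights()].
#' @param dose_times Administration times in h (default single dose at 0).
#' @param duration Infusion duration in h (0 = bolus).
#' @param seed_offset Integer offset added to the study seed for this
#'   arm, so arms draw from independent, individually reproducible
#'   streams.
#' @return A list of class `study_arm`.
#' @export
study_arm <- function(species, n, dose, schedule,
                      weight = unname(species_weights()[species]),
                      dose_times = 0, duration = 0, seed_offset = NULL) {
  if (is.na(weight) || !is.finite(weight) || weight <= 0) {
    stop("no default weight for species '", species,
         "'; supply weight explicitly", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(dose <= 0)) stop("doses must be > 0", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE) || any(schedule <= 0)) {
    stop("schedule must be strictly increasing and positive",
         call. = FALSE)
  }
  structure(list(species = species, n = as.integer(n), dose = dose,
                 schedule = schedule, weight = weight,
                 dose_times = dose_times, duration = duration,
                 seed_offset = seed_offset),
            class = "study_arm")
}

#' Define a synthetic study design
#'
#' @param ... `study_arm` objects.
#' @param label Study label stored in the generated dataset's metadata.
#' @return A list of class `study_design`.
#' @export
study_design <- function(..., label = "synthetic") {
  arms <- list(...)
  if (length(arms) == 1 && !inherits(arms[[1]], "study_arm")) {
    arms <- arms[[1]]
  }
  if (!length(arms) || !all(vapply(arms, inherits, logical(1),
                                   "study_arm"))) {
    stop("study_design takes study_arm objects", call. = FALSE)
  }
  for (i in seq_along(arms)) {
    if (is.null(arms[[i]]$seed_offset)) arms[[i]]$seed_offset <- i
  }
  structure(list(arms = arms, label = label), class = "study_design")
}

#' Built-in study designs
#'
#' Designs emulating the multispecies IV studies behind each compound:
#' `"bnt141-like"` (mouse, rat, NHP, human; human sampling at end of a
#' 1 h infusion and 3, 6, 24, 48, 72, 168, 336, 504 h), `"bnt142-like"`
#' (mouse, NHP, human; human sampling at end of infusion and 3, 6, 10,
#' 24, 48, 168 h), `"mrna1944-like"` (NHP only, extended sampling), and
#' `"multispecies-rich"`, the single-bolus rich-sampling four-species
#' design used for parameter-recovery experiments. Preclinical group
#' sizes and dose levels are not public; the defaults (n = 12/species,
#' dose levels spanning ~1 ug in mouse to ~3 mg in human) are
#' conventional choices.
#'
#' @return Named list of [study_design()] objects.
#' @export
default_study_designs <- function() {
  rich <- c(1, 3, 6, 12, 24, 48, 72, 120, 168, 240, 336, 504)
  human_141 <- c(1, 3, 6, 24, 48, 72, 168, 336, 504)
  human_142 <- c(1, 3, 6, 10, 24, 48, 168)
  list(
    "bnt141-like" = study_design(
      study_arm("mouse", 12, 10, rich),
      study_arm("rat", 12, 50, rich),
      study_arm("nhp", 12, 500, rich),
      study_arm("human", 12, 3000, human_141, duration = 1),
      label = "bnt141-like"),
    "bnt142-like" = study_design(
      study_arm("mouse", 12, 10, rich),
      study_arm("nhp", 12, 500, rich),
      study_arm("human", 12, 3000, human_142, duration = 1),
      label = "bnt142-like"),
    "mrna1944-like" = study_design(
      study_arm("nhp", 12, 1000, c(rich, 672, 1008)),
      label = "mrna1944-like"),
    "multispecies-rich" = study_design(
      study_arm("mouse", 12, 1, rich),
      study_arm("rat", 12, 10, rich),
      study_arm("nhp", 12, 100, rich),
      study_arm("human", 12, 3000, rich),
      label = "multispecies-rich")
  )
}

#' Generate a synthetic concentration-time study
#'
#' Simulates every subject of a [study_design()] from the translational
#' model: per subject, each structural parameter is multiplied by a
#' log-normal factor `exp(eta)`, `eta ~ N(0, omega^2)`; the profile is
#' simulated at the arm's schedule; proportional residual noise
#' `C_obs = C_pred * (1 + eps)`, `eps ~ N(0, sigma^2)`, is applied and
#' truncated at zero; and observations below the LLOQ are flagged BLQ.
#'
#' @param design A [study_design()].
#' @param params A `tm_params` whose `omega` and `sigma_prop` define the
#'   variability (overridable via `omega` / `sigma`).
#' @param seed Integer seed; each arm uses `seed + seed_offset`, so the
#'   generation is fully reproducible and arms are mutually independent.
#' @param omega,sigma Optional overrides of `params$omega` /
#'   `params$sigma_prop`.
#' @param lloq Lower limit of quantification in ug/mL; `NULL` (default)
#'   sets it per arm at 1% of the arm's median Cmax; `NA` disables BLQ
#'   flagging.
#' @param residual `"truncated-normal"` (the literal proportional-error
#'   model, clamped at 0) or `"lognormal"`
#'   (`C_obs = C_pred * exp(eps)`).
#' @return A `pk_dataset`.
#' @export
#' @examples
#' d <- default_study_designs()[["multispecies-rich"]]
#' ds <- generate_study(d, ribomab01_params(), seed = 1, sigma = 0.15)
generate_study <- function(design, params, seed = NULL, omega = NULL,
                           sigma = NULL, lloq = NULL,
                           residual = c("truncated-normal", "lognormal")) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "tm_params"))
  residual <- match.arg(residual)
  if (is.null(omega)) omega <- params$omega
  if (is.null(sigma)) sigma <- params$sigma_prop
  rec_list <- list()
  dose_list <- list()
  n_trunc <- 0L
  n_draw <- 0L
  for (arm in design$arms) {
    if (!is.null(seed)) set.seed(seed + arm$seed_offset)
    eff0 <- scale_params(params, arm$weight)
    reg <- dose_regimen(arm$dose_times,
                        rep_len(arm$dose, length(arm$dose_times)),
                        arm$duration)
    preds <- matrix(NA_real_, length(arm$schedule), arm$n)
    for (j in seq_len(arm$n)) {
      eff <- eff0
      for (nm in names(omega)) {
        if (!is.null(eff[[nm]]) && omega[[nm]] > 0) {
          eff[[nm]] <- eff[[nm]] * exp(stats::rnorm(1, 0, omega[[nm]]))
        }
      }
      preds[, j] <- tm_simulate(eff, reg, arm$schedule)$conc
    }
    eps <- matrix(stats::rnorm(length(preds), 0, sigma), nrow(preds))
    obs <- switch(residual,
                  "truncated-normal" = preds * (1 + eps),
                  "lognormal" = preds * exp(eps))
    n_draw <- n_draw + length(obs)
    n_trunc <- n_trunc + sum(obs < 0)
    obs[obs < 0] <- 0
    arm_lloq <- if (is.null(lloq)) {
      0.01 * stats::median(apply(preds, 2, max))
    } else lloq
    for (j in seq_len(arm$n)) {
      id <- sprintf("%s_%02d", arm$species, j)
      blq <- if (is.na(arm_lloq)) rep(FALSE, nrow(preds)) else
        obs[, j] < arm_lloq
      rec_list[[id]] <- data.frame(
        subject_id = id, species = arm$species, weight = arm$weight,
        time = arm$schedule, conc = obs[, j], blq = blq,
        lloq = if (is.na(arm_lloq)) NA_real_ else arm_lloq)
      dose_list[[id]] <- data.frame(
        subject_id = id, time = reg$time, amount = reg$amount,
        duration = reg$duration)
    }
  }
  if (n_trunc > 0.25 * n_draw) {
    warning("more than 25% of residual draws were truncated at zero; ",
            "sigma is implausibly large", call. = FALSE)
  }
  pk_dataset(do.call(rbind, rec_list), do.call(rbind, dose_list),
             metadata = list(label = design$label, seed = seed,
                             sigma = sigma))
}

#' Generate species-level exposures from a power law
#'
#' Draws `value = p0 * w^alpha * exp(eta)` with
#' `eta ~ N(0, log(1 + cv^2))` at each body weight, for
#' `n_replicates` independent replicate sets - the generating process
#' behind allometric-exponent recovery experiments.
#'
#' @param p0 Power-law coefficient (> 0).
#' @param alpha Allometric exponent.
#' @param weights Body weights in kg (> 0).
#' @param lognormal_cv Coefficient of variation of the log-normal noise
#'   (>= 0; 0 gives the exact power law).
#' @param n_replicates Number of replicate sets.
#' @param seed Integer seed.
#' @return data.frame with columns `replicate`, `weight`, `value`.
#' @export
generate_powerlaw_exposures <- function(p0, alpha, weights,
                                        lognormal_cv = 0,
                                        n_replicates = 1, seed = NULL) {
  if (p0 <= 0) stop("p0 must be > 0", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  if (lognormal_cv < 0) stop("lognormal_cv must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + lognormal_cv^2))
  out <- expand.grid(weight = weights, replicate = seq_len(n_replicates))
  out <- out[, c("replicate", "weight")]
  out$value <- p0 * out$weight^alpha *
    exp(stats::rnorm(nrow(out), 0, sdlog))
  rownames(out) <- NULL
  out
}
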