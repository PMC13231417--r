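#' Assemble a prediction report
#'
#' Computes the signed prediction ratio and fold error for each
#' observed/predicted pair, the evaluation layout used for human
#' exposure predictions.
#'
#' @param pairs data.frame with columns `compound`, `parameter`
#'   (`"DCmax"` or `"DAUC"`), `observed` (may be `NA`: prediction-only
#'   rows), `predicted`, `source_species`, `method` (`"allometry"` or
#'   `"model"`).
#' @return data.frame of class `prediction_report` with added `ratio`
#'   (pred/obs), `fold` (>= 1) and `direction` columns.
#' @export
prediction_report <- function(pairs) {
  needed <- c("compound", "parameter", "observed", "predicted",
              "source_species", "method")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols)) {
    stop("pairs is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- pairs[, needed]
  out$ratio <- NA_real_
  out$fold <- NA_real_
  out$direction <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (is.na(out$observed[i])) next
    fe <- fold_error(out$predicted[i], out$observed[i])
    out$ratio[i] <- fe$ratio
    out$fold[i] <- fe$fold
    out$direction[i] <- fe$direction
  }
  class(out) <- c("prediction_report", "data.frame")
  out
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Human exposure prediction report\n")
  arrow <- c(over = "↑", under = "↓", exact = "=")
  disp <- data.frame(
    compound = x$compound, parameter = x$parameter,
    method = x$method, from = x$source_species,
    observed = signif(x$observed, 3), predicted = signif(x$predicted, 3),
    error = ifelse(is.na(x$fold), "",
                   sprintf("(%s %.2f)", arrow[x$direction], x$fold))
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Summarize a prediction report
#'
#' @param object A `prediction_report`.
#' @param ... Unused.
#' @return data.frame with, per method and source species, the number of
#'   evaluable rows, the maximum fold error and the geometric mean fold
#'   error.
#' @export
summary.prediction_report <- function(object, ...) {
  ev <- object[!is.na(object$fold), ]
  groups <- unique(ev[, c("method", "source_species")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sub <- ev[ev$method == groups$method[g] &
                ev$source_species == groups$source_species[g], ]
    data.frame(method = groups$method[g],
               source_species = groups$source_species[g],
               n = nrow(sub), max_fold = max(sub$fold),
               geo_mean_fold = geometric_mean(sub$fold))
  }))
  rownames(out) <- NULL
  out
}

#' Allometric human prediction workflow
#'
#' Projects species-level dose-normalized exposures (DCmax, DAUC) to the
#' target weight with the generalized single-species exponents and
#' reports fold errors against the observed human values.
#'
#' @param species_exposures data.frame with columns `compound`,
#'   `parameter`, `species`, `weight` (kg), `value`.
#' @param human_observed data.frame with columns `compound`, `parameter`,
#'   `value`; compounds/parameters without an observed value get
#'   prediction-only rows.
#' @param exponents Named vector of generalized exponents per source
#'   species (defaults: mouse -1.26, nhp -0.75).
#' @param w_target Target body weight in kg.
#' @return A `prediction_report`.
#' @export
allometry_workflow <- function(species_exposures, human_observed,
                               exponents = c(mouse = -1.26, nhp = -0.75),
                               w_target = 70) {
  if (any(!species_exposures$species %in% names(exponents))) {
    stop("no generalized exponent supplied for species: ",
         paste(setdiff(unique(species_exposures$species),
                       names(exponents)), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(species_exposures)), function(i) {
    r <- species_exposures[i, ]
    pred <- allometric_predict(r$value, r$weight, w_target,
                               exponents[[r$species]])
    obs <- human_observed$value[
      human_observed$compound == r$compound &
        human_observed$parameter == r$parameter]
    data.frame(compound = r$compound, parameter = r$parameter,
               observed = if (length(obs)) obs[1] else NA_real_,
               predicted = pred, source_species = r$species,
               method = "allometry")
  })
  prediction_report(do.call(rbind, rows))
}

#' Model-based single-species human projection workflow
#'
#' Projects a single-species translational-model fit to the target
#' weight with [project_params()], simulates the target concentration-time
#' profile under the given regimen, derives DCmax (maximum concentration
#' of the first dosing interval divided by the dose) and DAUC (both the
#' closed form k_translate/(k_elim*CL) and NCA on the simulated
#' single-dose profile), and reports fold errors against the observed
#' values.
#'
#' @param fit A `tm_fit` from [fit_single_species()], or a
#'   `tm_params_eff` carrying its source `weight`.
#' @param scaling A [scaling_config()].
#' @param regimen The target-species [dose_regimen()].
#' @param human_observed Optional data.frame with columns `parameter`
#'   (`"DCmax"`, `"DAUC"`) and `value`.
#' @param w_target Target body weight in kg (default 70).
#' @param times Simulation grid in h; defaults to a dense grid covering
#'   the regimen plus ten terminal half-lives.
#' @param compound Compound label for the report.
#' @param percentile_n Monte Carlo replicates for the percentile band
#'   (0 disables; requires `omega` on the parameters to be informative).
#' @param seed Seed for the percentile band draws.
#' @return List with `report` (a `prediction_report`), `profile` (the
#'   simulated `tm_profile`), `dcmax`, `dauc_closed`, `dauc_nca`,
#'   `params_target` (the projected `tm_params_eff`) and optionally
#'   `bands`.
#' @export
model_projection_workflow <- function(fit, scaling, regimen,
                                      human_observed = NULL,
                                      w_target = 70, times = NULL,
                                      compound = "compound",
                                      percentile_n = 0, seed = NULL) {
  eff_src <- if (inherits(fit, "tm_fit")) as_effective_params(fit) else
    fit
  if (!inherits(eff_src, "tm_params_eff")) {
    stop("fit must be a tm_fit or tm_params_eff", call. = FALSE)
  }
  eff_t <- project_params(eff_src, w_target, scaling)
  # terminal half-life from the slowest system eigenvalue
  lam <- eigen(.sys_matrix(eff_t), only.values = TRUE)$values
  t_half <- log(2) / min(abs(Re(lam)))
  if (is.null(times)) {
    t_end <- max(regimen$time + regimen$duration) + 10 * t_half
    times <- sort(unique(c(regimen$time,
                           seq(0, t_end, length.out = 800))))
  }
  profile <- tm_simulate(eff_t, regimen, times)
  # first dosing interval: dose 1 up to dose 2 (or the whole grid)
  t1_end <- if (nrow(regimen) > 1) regimen$time[2] else max(times)
  first <- profile[profile$time <= t1_end, ]
  dose1 <- regimen$amount[1]
  dcmax <- max(first$conc) / dose1
  dauc_closed <- closed_form_dauc(eff_t)
  # NCA route on a simulated single-dose profile over ten half-lives
  single <- tm_simulate(eff_t, dose_regimen(regimen$time[1], dose1,
                                            regimen$duration[1]),
                        seq(regimen$time[1] + regimen$duration[1],
                            regimen$time[1] + 12 * t_half,
                            length.out = 600))
  nca_row <- .nca_profile(single$time, single$conc, dose = dose1)
  obs_val <- function(p) {
    if (is.null(human_observed)) return(NA_real_)
    v <- human_observed$value[human_observed$parameter == p]
    if (length(v)) v[1] else NA_real_
  }
  src <- attr(fit, "source_species")
  if (is.null(src)) src <- sprintf("%g kg", eff_src$weight)
  report <- prediction_report(data.frame(
    compound = compound, parameter = c("DCmax", "DAUC"),
    observed = c(obs_val("DCmax"), obs_val("DAUC")),
    predicted = c(dcmax, dauc_closed),
    source_species = src, method = "model"))
  out <- list(report = report, profile = profile, dcmax = dcmax,
              dauc_closed = dauc_closed, dauc_nca = nca_row$dauc,
              params_target = eff_t)
  if (percentile_n > 0) {
    out$bands <- tm_percentile_bands(eff_t, regimen, times,
                                     n = percentile_n, seed = seed)
  }
  out
}
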