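#' Fit an allometric power law
#'
#' Fits `P = P0 * W^alpha` by ordinary least squares of `ln(value)` on
#' `ln(weight)`, the standard log-log-linear treatment of interspecies
#' scaling: `P0 = exp(intercept)` is the parameter value of a 1 kg animal
#' and `alpha` the allometric exponent.
#'
#' @param weights Body weights in kg (> 0, at least two distinct).
#' @param values Parameter values (> 0), same length.
#' @return An object of class `power_fit` with elements `p0`, `alpha`,
#'   `se_alpha`, `se_log_p0`, `r_squared`, `n`, and the underlying `lm`
#'   fit. Supports `print`, `coef` and `predict(fit, weights)`.
#' @export
#' @examples
#' fit <- fit_power_law(c(0.025, 0.25, 2.5, 70),
#'                      1e-3 * c(0.025, 0.25, 2.5, 70)^-1.29)
#' coef(fit)
fit_power_law <- function(weights, values) {
  if (length(weights) != length(values) || length(weights) < 2) {
    stop("need at least two (weight, value) pairs", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop("values must be positive", call. = FALSE)
  }
  if (length(unique(weights)) < 2) {
    stop("all weights are equal: the log-log design is singular",
         call. = FALSE)
  }
  fit <- stats::lm(log(values) ~ log(weights))
  cf <- stats::coef(fit)
  # summary.lm warns on an exactly perfect fit, a legitimate case here
  sm <- suppressWarnings(summary(fit))
  structure(list(
    p0 = exp(unname(cf[1])), alpha = unname(cf[2]),
    se_alpha = unname(sm$coefficients[2, 2]),
    se_log_p0 = unname(sm$coefficients[1, 2]),
    r_squared = sm$r.squared, n = length(weights), lm = fit
  ), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric power law: P = %.4g * W^%.4g  (n = %d, R^2 = %.4f)\n",
    x$p0, x$alpha, x$n, x$r_squared))
  cat(sprintf("  exponent SE = %.4g\n", x$se_alpha))
  invisible(x)
}

#' @export
coef.power_fit <- function(object, ...) {
  c(p0 = object$p0, alpha = object$alpha)
}

#' @export
predict.power_fit <- function(object, weights, ...) {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  object$p0 * weights^object$alpha
}

#' Single-species allometric prediction
#'
#' Carries a parameter value from one body weight to another under a
#' fixed exponent: `value_target = value_source * (w_target/w_source)^alpha`.
#'
#' @param value_source Parameter value in the source species (> 0).
#' @param w_source,w_target Body weights in kg (> 0).
#' @param alpha Allometric exponent.
#' @return The projected value.
#' @export
#' @examples
#' allometric_predict(1, 2.5, 70, -0.75)  # multiplier 28^-0.75
allometric_predict <- function(value_source, w_source, w_target, alpha) {
  if (any(!is.finite(w_source) | w_source <= 0) ||
      any(!is.finite(w_target) | w_target <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (any(!is.finite(value_source) | value_source <= 0)) {
    stop("value_source must be positive", call. = FALSE)
  }
  value_source * (w_target / w_source)^alpha
}

#' Fold error between a prediction and an observation
#'
#' The accuracy metric of translational PK: `ratio = predicted/observed`,
#' `fold = max(ratio, 1/ratio) >= 1`, with the direction recording over-
#' or under-prediction. A prediction within 2-fold is conventionally
#' considered acceptable.
#'
#' @param predicted,observed Positive values.
#' @return An object of class `fold_error`: list with `ratio`, `fold`
#'   and `direction` (`"over"`, `"under"` or `"exact"`).
#' @export
#' @examples
#' fold_error(1.15e-3, 6.96e-4)  # 1.65-fold over
fold_error <- function(predicted, observed) {
  if (!is.finite(predicted) || predicted <= 0 ||
      !is.finite(observed) || observed <= 0) {
    stop("predicted and observed must be positive", call. = FALSE)
  }
  ratio <- predicted / observed
  structure(list(
    ratio = ratio, fold = max(ratio, 1 / ratio),
    direction = if (ratio > 1) "over" else if (ratio < 1) "under"
    else "exact"
  ), class = "fold_error")
}

#' @export
print.fold_error <- function(x, ...) {
  arrow <- switch(x$direction, over = "↑", under = "↓", "=")
  cat(sprintf("(%s %.3g)\n", arrow, x$fold))
  invisible(x)
}

#' Generalized-exponent grid search
#'
#' Scans a grid of allometric exponents for single-species human
#' prediction. For each exponent every source-species exposure value is
#' projected to the target weight with [allometric_predict()]; the
#' geometric mean of the predicted/observed ratios is the performance
#' metric, and the selected exponent is the grid point whose metric is
#' closest to 1 in log space (i.e. no systematic over- or
#' under-prediction). Ties go to the exponent nearer the grid midpoint,
#' then to the smaller magnitude. With `fold = TRUE` the ratios are
#' folded to >= 1 before averaging, an alternative reading of "mean
#' prediction error".
#'
#' @param species_values data.frame with columns `parameter`, `value`
#'   (source-species exposure) and `weight` (source body weight, kg).
#' @param human_observed Named numeric vector of observed target values,
#'   names matching `species_values$parameter`.
#' @param w_target Target body weight in kg (default 70).
#' @param grid_min,grid_max,step Exponent grid specification.
#' @param fold Use folded (>= 1) ratios as the metric.
#' @return An object of class `exponent_grid`: list with `grid`
#'   (data.frame of `exponent`, `metric`) and `selected_exponent`.
#' @export
grid_search_exponent <- function(species_values, human_observed,
                                 w_target = 70, grid_min, grid_max,
                                 step = 0.01, fold = FALSE) {
  if (!nrow(species_values)) stop("species_values is empty", call. = FALSE)
  if (!length(human_observed)) {
    stop("human_observed is empty", call. = FALSE)
  }
  if (grid_min >= grid_max || step <= 0) {
    stop("need grid_min < grid_max and step > 0", call. = FALSE)
  }
  obs <- human_observed[match(species_values$parameter,
                              names(human_observed))]
  if (any(is.na(obs))) {
    stop("human_observed lacks values for: ",
         paste(unique(species_values$parameter[is.na(obs)]),
               collapse = ", "), call. = FALSE)
  }
  grid <- seq(grid_min, grid_max, by = step)
  metric <- vapply(grid, function(a) {
    pred <- allometric_predict(species_values$value,
                               species_values$weight, w_target, a)
    r <- pred / obs
    if (fold) r <- pmax(r, 1 / r)
    geometric_mean(r)
  }, numeric(1))
  score <- abs(log(metric))
  best <- score <= min(score) + 1e-12
  cand <- grid[best]
  if (length(cand) > 1) {
    mid <- (grid_min + grid_max) / 2
    cand <- cand[order(abs(cand - mid), abs(cand))]
  }
  structure(list(grid = data.frame(exponent = grid, metric = metric),
                 selected_exponent = cand[1], fold = fold),
            class = "exponent_grid")
}

#' @export
print.exponent_grid <- function(x, ...) {
  cat(sprintf(
    "Generalized-exponent grid search (%d exponents, %s metric)\n",
    nrow(x$grid), if (x$fold) "folded geometric-mean" else
      "geometric-mean ratio"))
  i <- which(x$grid$exponent == x$selected_exponent)
  cat(sprintf("  selected exponent: %.3g (metric %.4g)\n",
              x$selected_exponent, x$grid$metric[i]))
  invisible(x)
}
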