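#' Geometric mean
#'
#' `exp(mean(log(x)))`; defined only for strictly positive values.
#'
#' @param x Numeric vector, all elements > 0.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x) {
  if (!length(x) || any(!is.finite(x) | x <= 0)) {
    stop("geometric_mean requires a non-empty, strictly positive vector",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Maximum concentration and its time
#'
#' @param time,conc Ordered observation times (h) and concentrations
#'   (ug/mL) of a single profile, BLQ points already removed.
#' @return List with `cmax` and `tmax` (earliest time of the maximum);
#'   both `NA` when no usable observation exists.
#' @export
compute_cmax_tmax <- function(time, conc) {
  keep <- is.finite(conc)
  if (!any(keep)) return(list(cmax = NA_real_, tmax = NA_real_))
  time <- time[keep]; conc <- conc[keep]
  i <- which.max(conc)  # which.max returns the first (earliest) maximum
  list(cmax = conc[i], tmax = time[i])
}

#' Terminal slope (lambda-z) estimation
#'
#' Fits `ln(conc)` against time over a terminal window and returns the
#' negated slope. In automatic mode every candidate terminal window - from
#' the last 3 points up to all points strictly after tmax (tmax itself
#' excluded) - is scanned and the window maximizing adjusted R-squared is
#' chosen; ties within 1e-4 go to the window with more points, the common
#' best-fit convention of NCA software.
#'
#' @param time,conc A single profile (BLQ removed); only strictly positive
#'   concentrations can enter the regression.
#' @param n_points Explicit number of terminal points to use instead of
#'   the automatic scan.
#' @return List with `lambda_z` (1/h), `intercept` (ln scale), `t_half`
#'   (h), `n_points`, `adj_r2`, and `estimable`. A rising terminal phase
#'   (non-positive slope) or fewer than 3 usable points yields
#'   `estimable = FALSE` with `NA` results - a flag, not an error.
#' @export
fit_lambda_z <- function(time, conc, n_points = NULL) {
  not_est <- list(lambda_z = NA_real_, intercept = NA_real_,
                  t_half = NA_real_, n_points = NA_integer_,
                  adj_r2 = NA_real_, estimable = FALSE)
  keep <- is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  n <- length(time)
  if (n < 3) return(not_est)
  tmax <- compute_cmax_tmax(time, conc)$tmax
  after <- which(time > tmax)
  if (!is.null(n_points)) {
    if (n_points < 3 || n_points > n) return(not_est)
    starts <- n - n_points + 1
  } else {
    if (length(after) < 3) return(not_est)
    # windows ending at the last point, from 3 points up to all after tmax
    starts <- seq(n - 2, min(after), by = -1)
  }
  best <- NULL
  for (s in starts) {
    tt <- time[s:n]; cc <- log(conc[s:n])
    m <- length(tt)
    fit <- stats::lm.fit(cbind(1, tt), cc)
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) next
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((cc - mean(cc))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (adj > best$adj_r2 - 1e-4 && m > best$n_points)) {
      best <- list(lambda_z = -slope,
                   intercept = unname(fit$coefficients[1]),
                   t_half = log(2) / -slope, n_points = m,
                   adj_r2 = adj, estimable = TRUE)
    }
  }
  if (is.null(best)) return(not_est)
  best
}

# interpolate a concentration at t: log-linear when descending between
# positive values, linear otherwise
.interp_conc <- function(time, conc, t) {
  if (t <= time[1]) return(conc[1])
  if (t >= time[length(time)]) return(conc[length(conc)])
  i <- findInterval(t, time)
  t1 <- time[i]; t2 <- time[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
  if (t == t1) return(c1)
  f <- (t - t1) / (t2 - t1)
  if (c1 > c2 && c2 > 0) c1 * (c2 / c1)^f else c1 + f * (c2 - c1)
}

#' Linear-up/log-down trapezoidal AUC
#'
#' Area under a concentration-time profile between two times. Ascending
#' or zero-bounded segments use the linear trapezoid
#' `(C1 + C2) / 2 * dt`; strictly descending positive segments use the
#' logarithmic trapezoid `(C1 - C2) * dt / ln(C1 / C2)`, the usual IV
#' default. Endpoints inside the sampled range are interpolated with the
#' matching rule.
#'
#' @param time,conc A single profile (BLQ removed), times strictly
#'   increasing.
#' @param t_start,t_end Integration limits (default: full profile).
#' @param method `"linuplogdown"` or `"linear"`.
#' @return The area in ug*h/mL.
#' @export
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 10, 5))  # 5 + 7.2135
auc_trapezoid <- function(time, conc, t_start = min(time),
                          t_end = max(time),
                          method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  if (t_end < t_start) stop("t_end must be >= t_start", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  inner <- time > t_start & time < t_end
  tt <- c(t_start, time[inner], t_end)
  cc <- c(.interp_conc(time, conc, t_start), conc[inner],
          .interp_conc(time, conc, t_end))
  c1 <- cc[-length(cc)]; c2 <- cc[-1]; dt <- diff(tt)
  logdown <- method == "linuplogdown" & c1 > c2 & c2 > 0
  seg <- ifelse(logdown,
                (c1 - c2) * dt / log(c1 / c2),
                (c1 + c2) / 2 * dt)
  sum(seg)
}

#' AUC extrapolated to infinity
#'
#' `AUC(0-last) + C_last_pred / lambda_z`, where `C_last_pred` is the
#' lambda-z regression value at the last observation time (switch to the
#' observed value with `use_predicted_clast = FALSE`).
#'
#' @param time,conc A single profile (BLQ removed).
#' @param lz A [fit_lambda_z()] result; computed automatically when
#'   omitted.
#' @param method AUC method, see [auc_trapezoid()].
#' @param use_predicted_clast Use the regression-predicted last
#'   concentration (default) rather than the observed one.
#' @return List with `auc_last`, `auc_inf` (`NA` when lambda-z is not
#'   estimable), and `extrap_pct`, the extrapolated percentage of
#'   `auc_inf`.
#' @export
auc_inf <- function(time, conc, lz = NULL,
                    method = c("linuplogdown", "linear"),
                    use_predicted_clast = TRUE) {
  method <- match.arg(method)
  keep <- is.finite(conc)
  time <- time[keep]; conc <- conc[keep]
  a_last <- auc_trapezoid(time, conc, method = method)
  if (is.null(lz)) lz <- fit_lambda_z(time, conc)
  if (!isTRUE(lz$estimable)) {
    return(list(auc_last = a_last, auc_inf = NA_real_,
                extrap_pct = NA_real_))
  }
  t_last <- time[length(time)]
  c_last <- if (use_predicted_clast) {
    exp(lz$intercept - lz$lambda_z * t_last)
  } else {
    conc[length(conc)]
  }
  a_inf <- a_last + c_last / lz$lambda_z
  list(auc_last = a_last, auc_inf = a_inf,
       extrap_pct = 100 * (a_inf - a_last) / a_inf)
}

# NCA of a single profile given its dose
.nca_profile <- function(time, conc, dose, tau = NA_real_,
                         method = "linuplogdown") {
  cm <- compute_cmax_tmax(time, conc)
  lz <- fit_lambda_z(time, conc)
  ai <- auc_inf(time, conc, lz = lz, method = method)
  a_tau <- if (is.finite(tau)) {
    auc_trapezoid(time, conc, t_start = min(time), t_end = tau,
                  method = method)
  } else NA_real_
  data.frame(
    cmax = cm$cmax, tmax = cm$tmax, auc_last = ai$auc_last,
    auc_inf = ai$auc_inf, auc_tau = a_tau, extrap_pct = ai$extrap_pct,
    lambda_z = lz$lambda_z, t_half = lz$t_half,
    n_lambda_points = lz$n_points, adj_r2 = lz$adj_r2,
    dose = dose, dcmax = cm$cmax / dose, dauc = ai$auc_inf / dose
  )
}

#' Noncompartmental analysis of a PK dataset
#'
#' Per-subject NCA: Cmax/tmax, AUC(0-last), AUC(0-inf) with terminal
#' extrapolation, lambda-z and half-life, and the dose-normalized
#' exposures DCmax = Cmax/dose (1/mL) and DAUC = AUC(0-inf)/dose (h/mL).
#' BLQ observations are excluded from all computations. For subjects with
#' multiple doses the default analyses the first dosing interval
#' (observations before the second dose), with DAUC extrapolated to
#' infinity from that interval; `per_interval = TRUE` instead returns one
#' row per dosing interval with AUC(0-tau).
#'
#' @param ds A `pk_dataset`.
#' @param per_interval Analyse every dosing interval separately.
#' @param method AUC method, see [auc_trapezoid()].
#' @return A data.frame of class `nca_result`, one row per subject (or
#'   per subject-interval), carrying `subject_id`, `species`, `weight`
#'   and the NCA parameters. Summarize by group with
#'   [summary.nca_result()].
#' @export
nca <- function(ds, per_interval = FALSE,
                method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "pk_dataset"))
  rec <- ds$records[!ds$records$blq, ]
  out <- list()
  for (id in unique(rec$subject_id)) {
    r <- rec[rec$subject_id == id, ]
    d <- ds$doses[ds$doses$subject_id == id, ]
    d <- d[order(d$time), ]
    if (!nrow(r)) next
    if (per_interval && nrow(d) > 1) {
      ends <- c(d$time[-1], Inf)
      for (k in seq_len(nrow(d))) {
        sel <- r$time >= d$time[k] & r$time < ends[k]
        if (sum(sel) < 2) next
        row <- .nca_profile(r$time[sel] - d$time[k], r$conc[sel],
                            dose = d$amount[k],
                            tau = if (is.finite(ends[k]))
                              ends[k] - d$time[k] else NA_real_,
                            method = method)
        row <- cbind(data.frame(subject_id = id, species = r$species[1],
                                weight = r$weight[1], interval = k), row)
        out[[length(out) + 1]] <- row
      }
    } else {
      end1 <- if (nrow(d) > 1) d$time[2] else Inf
      sel <- r$time < end1
      if (sum(sel) < 1) next
      row <- .nca_profile(r$time[sel] - d$time[1], r$conc[sel],
                          dose = d$amount[1],
                          tau = if (is.finite(end1)) end1 - d$time[1]
                          else NA_real_, method = method)
      row <- cbind(data.frame(subject_id = id, species = r$species[1],
                              weight = r$weight[1], interval = 1L), row)
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nca_result", "data.frame")
  res
}

#' Descriptive statistics of NCA results by species and dose
#'
#' For each NCA parameter and species-by-dose group: n, arithmetic mean,
#' SD, CV%, median, geometric mean, geometric CV%, minimum and maximum.
#' The geometric statistics are reported only when all contributing
#' values are strictly positive.
#'
#' @param object An `nca_result`.
#' @param parameters Which columns to summarize.
#' @param ... Unused.
#' @return A data.frame of class `nca_summary`.
#' @export
summary.nca_result <- function(object,
                               parameters = c("cmax", "auc_last",
                                              "auc_inf", "t_half",
                                              "dcmax", "dauc"), ...) {
  groups <- unique(object[, c("species", "dose")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- object[object$species %in% groups$species[g] &
                    object$dose == groups$dose[g], ]
    for (p in parameters) {
      x <- sub[[p]]
      x <- x[is.finite(x)]
      if (!length(x)) next
      pos <- all(x > 0)
      gsd <- if (pos && length(x) > 1) stats::sd(log(x)) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        species = groups$species[g], dose = groups$dose[g], parameter = p,
        n = length(x), mean = mean(x), sd = stats::sd(x),
        cv_pct = 100 * stats::sd(x) / mean(x), median = stats::median(x),
        geo_mean = if (pos) geometric_mean(x) else NA_real_,
        geo_cv_pct = if (is.finite(gsd)) 100 * sqrt(exp(gsd^2) - 1)
        else NA_real_,
        min = min(x), max = max(x)
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nca_summary", "data.frame")
  res
}
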