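#' Translational model parameters
#'
#' The mechanistic cross-species model couples three processes: first-order
#' elimination of the administered mRNA-LNP (rate `k_elim`), first-order,
#' non-consumptive translation of the remaining mRNA-LNP into circulating
#' antibody (rate `k_translate`), and one- or two-compartment disposition
#' of the translated antibody (clearance `cl`, central volume `v1`, and,
#' when a distribution phase is visible, peripheral volume `v2` with
#' intercompartmental clearance `q`). Every structural parameter `p` is
#' scaled across species as `p * W^alpha_p`, where `W` is body weight in
#' kg; the stored values are therefore the power-law coefficients, i.e.
#' the parameter values of a 1 kg reference animal.
#'
#' @param k_elim mRNA-LNP elimination rate coefficient (1/h at W = 1 kg).
#' @param k_translate translation rate coefficient (1/h at W = 1 kg).
#' @param cl antibody clearance coefficient (mL/h at W = 1 kg).
#' @param v1 central volume coefficient (mL at W = 1 kg).
#' @param v2 peripheral volume coefficient (mL at W = 1 kg), or `NULL`
#'   for one-compartment antibody disposition.
#' @param q intercompartmental clearance coefficient (mL/h at W = 1 kg),
#'   or `NULL`; `v2` and `q` must be both present or both absent.
#' @param alpha_k_elim,alpha_k_translate,alpha_cl,alpha_v1,alpha_v2,alpha_q
#'   allometric exponents of the corresponding parameters (dimensionless).
#' @param omega named numeric vector of log-normal between-subject
#'   standard deviations (names among the structural parameter names);
#'   absent names mean no variability on that parameter.
#' @param sigma_prop proportional residual error standard deviation.
#' @return An object of class `tm_params`.
#' @export
#' @examples
#' p <- ribomab01_params()
#' scale_params(p, 70)$cl  # effective human clearance, mL/h
tm_params <- function(k_elim, k_translate, cl, v1, v2 = NULL, q = NULL,
                      alpha_k_elim = 0, alpha_k_translate = 0,
                      alpha_cl = 0, alpha_v1 = 0, alpha_v2 = 0,
                      alpha_q = 0, omega = numeric(0), sigma_prop = 0) {
  if (is.null(v2) != is.null(q)) {
    stop("v2 and q must be both present (2-compartment) or both NULL",
         call. = FALSE)
  }
  vals <- list(k_elim = k_elim, k_translate = k_translate, cl = cl,
               v1 = v1, v2 = v2, q = q)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      stop("structural parameter '", nm, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (length(omega)) {
    if (is.null(names(omega)) ||
        !all(names(omega) %in% .tm_structural)) {
      stop("omega must be named with structural parameter names",
           call. = FALSE)
    }
    if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  }
  if (sigma_prop < 0) stop("sigma_prop must be >= 0", call. = FALSE)
  structure(list(
    k_elim = k_elim, alpha_k_elim = alpha_k_elim,
    k_translate = k_translate, alpha_k_translate = alpha_k_translate,
    cl = cl, alpha_cl = alpha_cl,
    v1 = v1, alpha_v1 = alpha_v1,
    v2 = v2, alpha_v2 = if (is.null(v2)) NULL else alpha_v2,
    q = q, alpha_q = if (is.null(q)) NULL else alpha_q,
    omega = omega, sigma_prop = sigma_prop
  ), class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat("Translational model parameters (coefficients at W = 1 kg):\n")
  for (nm in .tm_structural) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-12s %10.4g   alpha = %6.3f\n", nm, x[[nm]],
                x[[paste0("alpha_", nm)]]))
  }
  if (is.null(x$v2)) cat("  (one-compartment antibody disposition)\n")
  if (length(x$omega)) {
    cat("  IIV sd:", paste(sprintf("%s=%.3g", names(x$omega), x$omega),
                           collapse = ", "), "\n")
  }
  if (x$sigma_prop > 0) cat("  proportional residual sd:", x$sigma_prop, "\n")
  invisible(x)
}

#' Reference parameter set for the RiboMab01 (BNT141) translational model
#'
#' Published multispecies estimates for the full-IgG1 RiboMab01 expressed
#' from BNT141: two-compartment antibody disposition with volumes fixed to
#' the recombinant reference antibody and volume exponents fixed at 1.
#'
#' @return A `tm_params` object.
#' @export
ribomab01_params <- function() {
  tm_params(k_elim = 0.041, alpha_k_elim = -0.14,
            k_translate = 0.27, alpha_k_translate = -0.43,
            cl = 0.28, alpha_cl = 0.79,
            v1 = 40.1, alpha_v1 = 1,
            v2 = 45.6, alpha_v2 = 1,
            q = 1.02, alpha_q = 1.03)
}

#' Reference parameter set for the RiboMab02.1 (BNT142) translational model
#'
#' Published multispecies estimates for the bispecific Fab-scFv RiboMab02.1
#' expressed from BNT142; only one elimination phase was observed, so the
#' antibody disposition is one-compartment (no `v2`/`q`).
#'
#' @return A `tm_params` object.
#' @export
ribomab02_params <- function() {
  tm_params(k_elim = 0.0282, alpha_k_elim = -0.042,
            k_translate = 0.043, alpha_k_translate = -0.59,
            cl = 7.68, alpha_cl = 0.80,
            v1 = 58.4, alpha_v1 = 1)
}

#' Scale translational parameters to a body weight
#'
#' Applies the power law `p_eff = p * W^alpha_p` to every structural
#' parameter.
#'
#' @param p A `tm_params` object.
#' @param weight Body weight in kg (> 0).
#' @return An object of class `tm_params_eff`: named list of effective
#'   values (`k_elim`, `k_translate` in 1/h; `cl`, `q` in mL/h; `v1`,
#'   `v2` in mL) plus the `weight`, `omega` and `sigma_prop` carried over.
#' @export
scale_params <- function(p, weight) {
  stopifnot(inherits(p, "tm_params"))
  if (!is.finite(weight) || weight <= 0) {
    stop("weight must be a positive number", call. = FALSE)
  }
  eff <- list()
  for (nm in .tm_structural) {
    if (is.null(p[[nm]])) next
    eff[[nm]] <- p[[nm]] * weight^p[[paste0("alpha_", nm)]]
  }
  eff$weight <- weight
  eff$omega <- p$omega
  eff$sigma_prop <- p$sigma_prop
  structure(eff, class = "tm_params_eff")
}

#' Effective (species-level) translational parameters
#'
#' Directly constructs the effective parameter set of one species, e.g.
#' from a single-species fit, bypassing the power-law coefficients.
#'
#' @param k_elim,k_translate,cl,v1,v2,q effective values at `weight`
#'   (1/h, 1/h, mL/h, mL, mL, mL/h).
#' @param weight body weight in kg the values refer to.
#' @param omega,sigma_prop variability terms, as in [tm_params()].
#' @return An object of class `tm_params_eff`.
#' @export
tm_params_eff <- function(k_elim, k_translate, cl, v1, v2 = NULL,
                          q = NULL, weight, omega = numeric(0),
                          sigma_prop = 0) {
  if (is.null(v2) != is.null(q)) {
    stop("v2 and q must be both present or both NULL", call. = FALSE)
  }
  vals <- list(k_elim = k_elim, k_translate = k_translate, cl = cl,
               v1 = v1, v2 = v2, q = q)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v) && (!is.finite(v) || v <= 0)) {
      stop("effective parameter '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive",
                                              call. = FALSE)
  structure(c(vals[!vapply(vals, is.null, logical(1))],
              list(weight = weight, omega = omega,
                   sigma_prop = sigma_prop)),
            class = "tm_params_eff")
}

#' Cross-species projection exponents
#'
#' The generalized exponents used to project fitted single-species model
#' parameters to another body weight: -0.10 for mRNA-LNP elimination, 0.80
#' for antibody clearance, 1 for both volumes, 0.65 for intercompartmental
#' clearance, and for the translation rate -0.51 when projecting from
#' mouse but 0 (no adjustment) when projecting from NHP, reflecting the
#' similar translational efficiency of NHP and human.
#'
#' @param source_species `"mouse"`, `"nhp"`, or `"other"` (requires
#'   `k_translate` to be supplied explicitly).
#' @param ... named exponent overrides (e.g. `cl = 0.75`).
#' @return Named numeric vector of projection exponents, class
#'   `scaling_config`.
#' @export
scaling_config <- function(source_species = c("nhp", "mouse", "other"),
                           ...) {
  source_species <- match.arg(source_species)
  exps <- c(k_elim = -0.10, cl = 0.80, v1 = 1, v2 = 1, q = 0.65,
            k_translate = switch(source_species, mouse = -0.51,
                                 nhp = 0, other = NA_real_))
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || !all(names(dots) %in% names(exps))) {
      stop("overrides must be named with structural parameter names",
           call. = FALSE)
    }
    exps[names(dots)] <- dots
  }
  if (any(is.na(exps))) {
    stop("scaling_config: no exponent available for ",
         paste(names(exps)[is.na(exps)], collapse = ", "),
         "; supply it explicitly", call. = FALSE)
  }
  structure(exps, class = "scaling_config", source_species = source_species)
}

#' Project effective parameters to another body weight
#'
#' Multiplies each effective parameter by `(w_target / w_source)^alpha`
#' with the exponents of a [scaling_config()]. This is the single-species
#' projection step of the translational framework: fit the model in one
#' species, then carry the parameters to human.
#'
#' @param eff A `tm_params_eff` object (e.g. from [scale_params()] or a
#'   single-species fit).
#' @param w_target Target body weight in kg.
#' @param scaling A [scaling_config()].
#' @param w_source Source body weight in kg; defaults to `eff$weight`.
#' @return A `tm_params_eff` at `w_target`.
#' @export
project_params <- function(eff, w_target, scaling, w_source = eff$weight) {
  stopifnot(inherits(eff, "tm_params_eff"))
  if (!is.finite(w_source) || w_source <= 0 ||
      !is.finite(w_target) || w_target <= 0) {
    stop("weights must be positive", call. = FALSE)
  }
  present <- intersect(.tm_structural, names(eff))
  missing_exp <- setdiff(present, names(scaling))
  if (length(missing_exp)) {
    stop("scaling config lacks exponents for: ",
         paste(missing_exp, collapse = ", "), call. = FALSE)
  }
  ratio <- w_target / w_source
  out <- eff
  for (nm in present) out[[nm]] <- eff[[nm]] * ratio^scaling[[nm]]
  out$weight <- w_target
  out
}

# resolve params + weight into an effective set
.as_eff <- function(params, weight = NULL) {
  if (inherits(params, "tm_params_eff")) return(params)
  if (inherits(params, "tm_params")) {
    if (is.null(weight)) {
      stop("weight is required when params are power-law coefficients",
           call. = FALSE)
    }
    return(scale_params(params, weight))
  }
  stop("params must be a tm_params or tm_params_eff object", call. = FALSE)
}
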