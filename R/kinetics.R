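#' First-order antibiotic decay model in absorbed dose
#'
#' Under electron-beam irradiation the concentration of a dissolved
#' antibiotic decays exponentially with absorbed dose D:
#' \deqn{C_a(D) = C_0 e^{-\alpha D}}
#' where \eqn{\alpha} (kGy^-1) is the decomposition rate per unit dose and
#' \eqn{C_0} the concentration of the non-irradiated solution in relative
#' units (conventionally 100).
#'
#' @param C0 initial relative concentration, > 0
#' @param alpha decomposition rate per kGy, >= 0
#' @param analyte optional analyte name carried along for labelling
#' @return an object of class \code{antibiotic_kinetics}
#' @export
antibiotic_kinetics <- function(C0 = 100, alpha, analyte = NULL) {
  stopifnot(is.numeric(C0), length(C0) == 1L, is.finite(C0), C0 > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  structure(list(C0 = C0, alpha = alpha, analyte = analyte),
            class = "antibiotic_kinetics")
}

#' Threshold-dose kinetics of a degradation product
#'
#' A degradation product accumulates from the decomposing parent antibiotic
#' and simultaneously decomposes itself; below a threshold dose D0 its
#' concentration is zero (the product is not yet detectable). With the
#' parent law \eqn{C_a(D) = C_0 e^{-\alpha D}}, the product obeys
#' \deqn{dC_p/dD = -\beta C_p + k C_a(D), \quad C_p(D_0) = 0,}
#' with closed form (Heaviside onset at D0)
#' \deqn{C_p(D) = H(D - D_0)\, \frac{k C_0}{\beta - \alpha}
#'   \left[e^{(\beta-\alpha) D} - e^{(\beta-\alpha) D_0}\right] e^{-\beta D}.}
#'
#' @param beta product decomposition rate per kGy, >= 0
#' @param D0 threshold dose in kGy, >= 0
#' @param k formation coefficient per kGy, >= 0 (fraction of decomposing
#'   parent molecules converted into this product, per unit dose)
#' @param parent an \code{antibiotic_kinetics} for the parent antibiotic
#' @param analyte optional analyte name (accurate-mass string)
#' @return an object of class \code{product_kinetics}
#' @export
product_kinetics <- function(beta, D0 = 0, k, parent, analyte = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
            is.numeric(D0), length(D0) == 1L, is.finite(D0), D0 >= 0,
            is.numeric(k), length(k) == 1L, is.finite(k), k >= 0,
            inherits(parent, "antibiotic_kinetics"))
  structure(list(beta = beta, D0 = D0, k = k, parent = parent,
                 analyte = analyte),
            class = "product_kinetics")
}

#' @export
print.antibiotic_kinetics <- function(x, ...) {
  cat(sprintf("antibiotic kinetics%s: C0 = %g rel.un., alpha = %g kGy^-1\n",
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$C0, x$alpha))
  invisible(x)
}

#' @export
print.product_kinetics <- function(x, ...) {
  cat(sprintf(
    "product kinetics%s: beta = %g kGy^-1, D0 = %g kGy, k = %g kGy^-1 (parent alpha = %g)\n",
    if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]"),
    x$beta, x$D0, x$k, x$parent$alpha))
  invisible(x)
}

check_dose <- function(dose) {
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0)) {
    stop("dose must be non-negative (kGy)", call. = FALSE)
  }
  as.numeric(dose)
}

#' Antibiotic concentration at a given dose
#'
#' Evaluates \eqn{C_a(D) = C_0 e^{-\alpha D}}. Vectorized over \code{dose}.
#'
#' @param model an \code{antibiotic_kinetics}
#' @param dose absorbed dose(s) in kGy, >= 0
#' @return concentration(s) in relative units
#' @export
antibiotic_concentration <- function(model, dose) {
  stopifnot(inherits(model, "antibiotic_kinetics"))
  dose <- check_dose(dose)
  model$C0 * exp(-model$alpha * dose)
}

#' Degradation-product concentration at a given dose
#'
#' Evaluates the threshold-onset closed form (see
#' \code{\link{product_kinetics}}). The removable singularity at
#' \eqn{\beta = \alpha} is handled by the analytic limit
#' \eqn{C_p(D) = k C_0 (D - D_0) e^{-\beta D}}; the general and the limit
#' branch are blended for \eqn{|\beta-\alpha|} below a small cutoff where
#' the direct formula loses precision. \eqn{C_p(D_0) = 0} exactly and
#' \eqn{C_p \ge 0} everywhere.
#'
#' @param model a \code{product_kinetics}
#' @param dose absorbed dose(s) in kGy, >= 0
#' @return concentration(s) in relative units
#' @export
product_concentration <- function(model, dose) {
  stopifnot(inherits(model, "product_kinetics"))
  dose <- check_dose(dose)
  product_conc_num(dose, model$parent$C0, model$parent$alpha,
                   model$beta, model$D0, model$k)
}

# numeric kernel shared with the fitting code (no S3 dispatch in the inner
# loop); uses expm1 for the near-degenerate beta ~ alpha regime
product_conc_num <- function(dose, C0, alpha, beta, D0, k) {
  out <- numeric(length(dose))
  on_ <- dose > D0
  if (!any(on_)) return(out)
  d <- dose[on_]
  g <- beta - alpha
  if (abs(g) < 1e-8) {
    # analytic limit of the (beta - alpha) denominator
    out[on_] <- k * C0 * (d - D0) * exp(-beta * d)
  } else {
    # k C0/g * (e^{g d} - e^{g D0}) e^{-beta d}
    #   = k C0/g * e^{g D0} * expm1(g (d - D0)) * e^{-beta d}
    out[on_] <- k * C0 / g * exp(g * D0) * expm1(g * (d - D0)) * exp(-beta * d)
  }
  pmax(out, 0)
}

#' Removal percentage at a given dose
#'
#' \eqn{100 (1 - e^{-\alpha D})}: the percentage of the initial antibiotic
#' removed by irradiation with dose D. Monotone non-decreasing in dose and
#' bounded in [0, 100).
#'
#' @param model an \code{antibiotic_kinetics}
#' @param dose absorbed dose(s) in kGy, >= 0
#' @return removal percentage(s)
#' @export
removal_percent <- function(model, dose) {
  stopifnot(inherits(model, "antibiotic_kinetics"))
  dose <- check_dose(dose)
  100 * (1 - exp(-model$alpha * dose))
}

#' Dose at which a degradation product peaks
#'
#' Setting \eqn{dC_p/dD = 0} in the threshold-onset model gives
#' \deqn{D^* = D_0 + \frac{\ln(\beta/\alpha)}{\beta - \alpha}}
#' for \eqn{\beta \ne \alpha}, and the limit \eqn{D^* = D_0 + 1/\alpha} for
#' \eqn{\beta = \alpha}. Requires both a formation channel (k > 0) and at
#' least one positive rate.
#'
#' @param model a \code{product_kinetics}
#' @return the dose in kGy at which the product concentration is maximal
#' @export
product_peak_dose <- function(model) {
  stopifnot(inherits(model, "product_kinetics"))
  alpha <- model$parent$alpha
  beta <- model$beta
  if (model$k <= 0) stop("peak dose undefined: k = 0 (no formation)", call. = FALSE)
  if (alpha <= 0 && beta <= 0) {
    stop("peak dose undefined: alpha = beta = 0 (concentration never decays)",
         call. = FALSE)
  }
  if (alpha <= 0) {
    # parent never decays: C_p grows towards k C0 / beta, no interior max
    stop("peak dose undefined: alpha = 0 (product concentration is monotone)",
         call. = FALSE)
  }
  if (abs(beta - alpha) < 1e-10) {
    model$D0 + 1 / alpha
  } else if (beta <= 0) {
    # product stable: C_p(D) increases to its supremum as the parent empties;
    # formally the stationary-point formula diverges
    stop("peak dose undefined: beta = 0 (product concentration is monotone)",
         call. = FALSE)
  } else {
    model$D0 + log(beta / alpha) / (beta - alpha)
  }
}

#' Evaluate a model registry on a dose grid without noise
#'
#' Produces one observation per analyte, dose and (single) replicate with
#' the area equal to the exact model concentration. This deterministic
#' forward evaluation is the backbone of parameter-recovery checks: fitting
#' its output must return the generating coefficients.
#'
#' @param models a list of \code{antibiotic_kinetics} and/or
#'   \code{product_kinetics} objects; names are used as analyte identifiers
#'   when a model carries none
#' @param doses dose grid in kGy, >= 0
#' @return a \code{peak_table} with one replicate per dose per analyte
#' @export
simulate_noiseless <- function(models, doses) {
  doses <- check_dose(doses)
  if (is.null(names(models))) names(models) <- rep("", length(models))
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    analyte <- if (!is.null(m$analyte)) m$analyte
               else if (nzchar(names(models)[i])) names(models)[i]
               else stop("model ", i, " has no analyte name", call. = FALSE)
    conc <- if (inherits(m, "antibiotic_kinetics")) {
      antibiotic_concentration(m, doses)
    } else if (inherits(m, "product_kinetics")) {
      product_concentration(m, doses)
    } else {
      stop("unsupported model class for analyte ", analyte, call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(analyte))
    data.frame(dose_kGy = doses, replicate = 1L, analyte = analyte,
               mz = ifelse(is.na(mz), 0, mz), rt_min = NA_real_,
               area = conc, censored = FALSE, stringsAsFactors = FALSE)
  })
  peak_table(do.call(rbind, rows), metadata = list(generator = "noiseless"))
}

#' Bundled kinetic coefficient set
#'
#' The fitted dose-response coefficients for seven antibiotics (tetracycline,
#' doxycycline, ampicillin, amoxicillin, benzylpenicillin, streptomycin,
#' chloramphenicol) and their thirteen detected degradation products under
#' 1 MeV electron-beam irradiation, shipped with the package as the default
#' "realistic" parameter set for simulation and for parameter-recovery
#' studies. Rates are per kGy, C0 on the 100-relative-unit scale.
#'
#' @return a tibble with columns \code{analyte}, \code{role}
#'   (\code{"antibiotic"} or \code{"product"}), \code{parent}, \code{C0},
#'   \code{alpha}, \code{se_alpha}, \code{r_corr}, \code{beta},
#'   \code{se_beta}, \code{D0}, \code{se_D0}, \code{k}, \code{se_k}
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "kinetic_coefficients.csv", package = "ebikin")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a model registry from a coefficient table
#'
#' Converts a coefficient table in the layout of
#' \code{\link{reference_coefficients}} into a named list of
#' \code{antibiotic_kinetics} / \code{product_kinetics} objects suitable for
#' \code{\link{simulate_noiseless}} and \code{\link{generate_peak_table}}.
#'
#' @param coefs a coefficient table; defaults to the bundled set
#' @return named list of kinetic model objects
#' @export
reference_models <- function(coefs = reference_coefficients()) {
  coefs <- as.data.frame(coefs)
  models <- list()
  ab_rows <- coefs[coefs$role == "antibiotic", , drop = FALSE]
  for (i in seq_len(nrow(ab_rows))) {
    r <- ab_rows[i, ]
    models[[r$analyte]] <- antibiotic_kinetics(C0 = r$C0, alpha = r$alpha,
                                               analyte = r$analyte)
  }
  pr_rows <- coefs[coefs$role == "product", , drop = FALSE]
  for (i in seq_len(nrow(pr_rows))) {
    r <- pr_rows[i, ]
    parent <- models[[r$parent]]
    if (is.null(parent)) {
      stop("product ", r$analyte, " references unknown parent ", r$parent,
           call. = FALSE)
    }
    models[[r$analyte]] <- product_kinetics(beta = r$beta, D0 = r$D0, k = r$k,
                                            parent = parent,
                                            analyte = r$analyte)
  }
  models
}
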