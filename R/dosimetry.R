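#' Fricke ferrous-sulfate dosimetry parameters
#'
#' Constants of the Fricke dose relation
#' \deqn{D = \frac{k\,\Delta S}{\rho\, G(\mathrm{Fe^{3+}})\, l\, \epsilon}}
#' where \eqn{\Delta S} is the optical-density change of the irradiated
#' ferrous-sulfate solution at 304 nm (Fe2+ oxidised to Fe3+ by the
#' radiolysis radicals). The defaults are the standard values for
#' accelerated electrons below 10 MeV.
#'
#' @param deltaS optical density difference, >= 0 (absorbance units)
#' @param k dimensionless coefficient (default 9.65e6; absorbs the unit
#'   conversions of G and epsilon)
#' @param rho solution density, g/cm^3 (default 1.024)
#' @param G_Fe3 radiation-chemical yield of Fe3+, ions/100 eV (default 15.6)
#' @param l optical path, cm (default 1)
#' @param epsilon molar extinction coefficient of Fe3+, L/(mol cm)
#'   (default 2160)
#' @return an object of class \code{fricke_params}
#' @export
fricke_params <- function(deltaS, k = 9.65e6, rho = 1.024, G_Fe3 = 15.6,
                          l = 1, epsilon = 2160) {
  stopifnot(is.numeric(deltaS), all(deltaS >= 0),
            k > 0, rho > 0, G_Fe3 > 0, l > 0, epsilon > 0)
  structure(list(deltaS = deltaS, k = k, rho = rho, G_Fe3 = G_Fe3,
                 l = l, epsilon = epsilon),
            class = "fricke_params")
}

#' Absorbed dose from a Fricke dosimeter reading
#'
#' Evaluates the Fricke relation (see \code{\link{fricke_params}}); exactly
#' linear and homogeneous in the optical-density change. Vectorized over
#' \code{deltaS}.
#'
#' @param params a \code{fricke_params}
#' @return absorbed dose in Gy
#' @export
fricke_dose <- function(params) {
  stopifnot(inherits(params, "fricke_params"))
  denom <- params$rho * params$G_Fe3 * params$l * params$epsilon
  if (denom == 0) stop("zero denominator in Fricke relation", call. = FALSE)
  params$k * params$deltaS / denom
}

#' Read an irradiation-session log
#'
#' CSV with header \code{session_id,time_s,current_nA,charge_nC,dose_Gy};
#' one row per session group (exposure time, beam current, charge collected
#' on the duralumin sample plate, Fricke-measured dose).
#'
#' @param path CSV path; defaults to the bundled session log
#' @return a tibble of sessions
#' @export
read_sessions <- function(path = system.file("extdata",
                                             "irradiation_sessions.csv",
                                             package = "ebikin")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("session_id", "time_s", "charge_nC", "dose_Gy")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("session log missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- c("time_s", "charge_nC", "dose_Gy")
  for (cn in num) x[[cn]] <- as.numeric(x[[cn]])
  if (any(x$charge_nC < 0, na.rm = TRUE) || any(x$dose_Gy < 0, na.rm = TRUE)) {
    stop("negative charge or dose in session log", call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Calibrate the charge-to-dose conversion from session logs
#'
#' Zero-intercept least squares of dose on collected charge: the physics
#' forces D = 0 at Q = 0, so the calibration is a single slope
#' \eqn{\hat s = \sum D_i Q_i / \sum Q_i^2} (Gy/nC). Residual diagnostics
#' (per-session residuals and the maximum relative deviation of the
#' per-session dose/charge ratios from the slope) are reported alongside.
#'
#' @param sessions tibble from \code{\link{read_sessions}} (columns
#'   \code{charge_nC}, \code{dose_Gy})
#' @return list with \code{slope_Gy_per_nC}, \code{residuals_Gy},
#'   \code{max_rel_dev}, \code{n}
#' @export
calibrate_charge_to_dose <- function(sessions) {
  q <- sessions$charge_nC
  d <- sessions$dose_Gy
  keep <- !is.na(q) & !is.na(d)
  q <- q[keep]; d <- d[keep]
  if (length(q) == 0L || all(q == 0)) {
    stop("cannot calibrate: no sessions with positive charge", call. = FALSE)
  }
  slope <- sum(d * q) / sum(q * q)
  resid <- d - slope * q
  ratios <- d[q > 0] / q[q > 0]
  list(slope_Gy_per_nC = slope,
       residuals_Gy = resid,
       max_rel_dev = max(abs(ratios - slope) / slope),
       n = length(q))
}

#' Predict absorbed dose from collected charge
#'
#' @param charge_nC charge collected on the sample plate, nC, >= 0
#' @param slope_Gy_per_nC calibration slope, > 0
#' @return predicted dose in Gy
#' @export
predict_dose <- function(charge_nC, slope_Gy_per_nC) {
  if (!is.numeric(charge_nC) || any(charge_nC < 0)) {
    stop("charge must be non-negative", call. = FALSE)
  }
  stopifnot(slope_Gy_per_nC > 0)
  slope_Gy_per_nC * charge_nC
}

#' Convert between Gy and kGy
#'
#' Dosimetry works in Gy (session logs, Fricke readings) while the kinetic
#' model works in kGy; these helpers bridge the two scales.
#'
#' @param dose_Gy dose in Gy
#' @return dose in kGy
#' @export
gy_to_kgy <- function(dose_Gy) dose_Gy / 1000

#' @rdname gy_to_kgy
#' @param dose_kGy dose in kGy
#' @export
kgy_to_gy <- function(dose_kGy) dose_kGy * 1000
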