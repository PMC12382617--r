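#' Configuration for the synthetic peak-table generator
#'
#' Describes a simulated measurement campaign: which kinetic models to
#' sample from, the dose grid, the replication, the multiplicative noise
#' level and the limit of detection. The defaults emulate the triplicate
#' design of the underlying experiments: doses {0, 0.1, 1, 3, 7} kGy,
#' three replicates, 10% relative noise (peak-area relative standard
#' deviations in LC-MS dose series are capped at 20%), and a limit of
#' detection of 0.1% of the parent's initial signal.
#'
#' @param models named list of \code{antibiotic_kinetics} /
#'   \code{product_kinetics} (default: the bundled coefficient set)
#' @param doses dose grid in kGy
#' @param replicates replicates per dose, >= 1
#' @param cv coefficient of variation of the multiplicative noise, in
#'   [0, 0.2]
#' @param lod_fraction limit of detection as a fraction of the parent
#'   antibiotic's C0 (areas below it are recorded as censored "ND")
#' @param seed integer RNG seed
#' @return an object of class \code{generator_config}
#' @export
generator_config <- function(models = reference_models(),
                             doses = c(0, 0.1, 1, 3, 7),
                             replicates = 3L,
                             cv = 0.10,
                             lod_fraction = 0.001,
                             seed = 1L) {
  doses <- check_dose(doses)
  stopifnot(length(replicates) == 1L, replicates >= 1L,
            is.numeric(cv), length(cv) == 1L, cv >= 0,
            is.numeric(lod_fraction), length(lod_fraction) == 1L,
            lod_fraction >= 0,
            length(seed) == 1L, is.finite(seed))
  if (cv > 0.20) {
    stop("cv must be <= 0.20: relative peak-area scatter above 20% is ",
         "outside the regime the generator emulates", call. = FALSE)
  }
  structure(list(models = models, doses = doses,
                 replicates = as.integer(replicates), cv = cv,
                 lod_fraction = lod_fraction, seed = as.integer(seed)),
            class = "generator_config")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", .GlobalEnv, inherits = FALSE)
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, .GlobalEnv)
    }
  })
  expr
}

#' Generate a noisy synthetic peak table
#'
#' For every analyte, dose and replicate, the area is the exact model
#' concentration times (1 + e) with e ~ Normal(0, cv) truncated below at
#' -1 (areas cannot go negative). Areas below the limit of detection
#' (\code{lod_fraction} of the parent antibiotic's C0) are recorded as
#' censored with area 0 -- in particular every product observation at doses
#' at or below its threshold dose D0 is censored when the LOD is positive.
#' Fully reproducible from the config seed; the caller's RNG state is left
#' untouched.
#'
#' @param config a \code{generator_config}
#' @return a \code{peak_table}
#' @export
generate_peak_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  models <- config$models
  if (is.null(names(models))) names(models) <- rep("", length(models))
  with_local_seed(config$seed, {
    rows <- lapply(seq_along(models), function(i) {
      m <- models[[i]]
      analyte <- if (!is.null(m$analyte)) m$analyte else names(models)[i]
      if (inherits(m, "antibiotic_kinetics")) {
        conc_fun <- function(d) antibiotic_concentration(m, d)
        lod <- config$lod_fraction * m$C0
      } else {
        conc_fun <- function(d) product_concentration(m, d)
        lod <- config$lod_fraction * m$parent$C0
      }
      grid <- expand.grid(dose_kGy = config$doses,
                          replicate = seq_len(config$replicates))
      conc <- conc_fun(grid$dose_kGy)
      eps <- pmax(stats::rnorm(nrow(grid), 0, config$cv), -1)
      area <- conc * (1 + eps)
      censored <- area < lod
      area[censored] <- 0
      mz <- suppressWarnings(as.numeric(analyte))
      data.frame(dose_kGy = grid$dose_kGy, replicate = grid$replicate,
                 analyte = analyte, mz = ifelse(is.na(mz), 0, mz),
                 rt_min = NA_real_, area = area, censored = censored,
                 stringsAsFactors = FALSE)
    })
    peak_table(do.call(rbind, rows),
               metadata = list(generator = "synthetic", seed = config$seed,
                               cv = config$cv,
                               lod_fraction = config$lod_fraction))
  })
}

#' Generate a null removal dataset (no antibiotic effect)
#'
#' Produces per-replicate removal percentages for a set of antibiotic
#' labels that all share one decomposition rate, so any apparent
#' between-antibiotic differences are pure noise. Removal at dose D is
#' \eqn{100(1 - e^{-\alpha D})} plus additive iid Gaussian noise on the
#' percent scale. This construction matches the additive homoscedastic
#' error model of the classical two-factor ANOVA, which makes the dataset
#' a clean calibration input for the F test's type-I error (see the
#' methods vignette for why removal derived from noisy areas normalized by
#' a noisy dose-0 baseline would not be).
#'
#' @param antibiotics character vector of antibiotic labels
#' @param alpha the shared decomposition rate, per kGy
#' @param doses dose grid (dose 0 is excluded: removal there is identically
#'   zero)
#' @param replicates replicates per cell
#' @param sd_percent standard deviation of the removal noise, percentage
#'   points
#' @param seed integer RNG seed
#' @return a tibble with columns \code{antibiotic}, \code{dose_kGy},
#'   \code{replicate}, \code{removal_percent}
#' @export
generate_null_removal <- function(antibiotics = c("A", "B", "C", "D"),
                                  alpha = 1.28,
                                  doses = c(0.1, 1, 3, 7),
                                  replicates = 3L,
                                  sd_percent = 3,
                                  seed = 1L) {
  stopifnot(length(antibiotics) >= 2L, alpha >= 0, sd_percent >= 0,
            replicates >= 1L)
  doses <- check_dose(doses)
  doses <- doses[doses > 0]
  with_local_seed(seed, {
    grid <- expand.grid(antibiotic = antibiotics, dose_kGy = doses,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- 100 * (1 - exp(-alpha * grid$dose_kGy))
    grid$removal_percent <- mu + stats::rnorm(nrow(grid), 0, sd_percent)
    tibble::as_tibble(grid)
  })
}
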