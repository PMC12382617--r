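#' Fit the exponential decay law to an antibiotic dose series
#'
#' Least-squares estimation of the decomposition rate alpha (and optionally
#' C0) in \eqn{C_a(D) = C_0 e^{-\alpha D}} from all replicate peak areas of
#' one analyte. Censored ("not detected") observations enter as zeros.
#' Initialization is deterministic: alpha from a log-linear regression of
#' the positive per-dose means, then Levenberg-Marquardt refinement.
#'
#' @param table a \code{peak_table}
#' @param analyte the antibiotic to fit
#' @param fix_C0_at_100 if \code{TRUE} (default), C0 is fixed at 100
#'   relative units (the scale of a normalized table); if \code{FALSE}, C0
#'   is estimated jointly with alpha
#' @param use_means fit per-dose replicate means instead of all points
#' @return an object of class \code{antibiotic_fit}: list with
#'   \code{model} (\code{antibiotic_kinetics}), \code{se_alpha},
#'   \code{se_C0} (NA when fixed), \code{r_corr}, \code{rss}, \code{n_obs}
#' @export
fit_antibiotic <- function(table, analyte, fix_C0_at_100 = TRUE,
                           use_means = FALSE) {
  validate_peak_table(table)
  sub <- table[table$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no observations for analyte ", analyte, call. = FALSE)
  if (use_means) {
    agg <- stats::aggregate(area ~ dose_kGy, data = sub, FUN = mean)
    dose <- agg$dose_kGy; y <- agg$area
  } else {
    dose <- sub$dose_kGy; y <- sub$area
  }
  if (length(unique(dose)) < 3L || !any(dose == 0)) {
    stop("need >= 3 distinct doses including dose 0 to fit ", analyte,
         call. = FALSE)
  }
  if (all(sub$censored[sub$dose_kGy == 0])) {
    stop("all dose-0 observations for ", analyte, " are censored", call. = FALSE)
  }

  # deterministic init: log-linear regression on positive per-dose means
  mu <- tapply(y, dose, mean)
  d_lvl <- as.numeric(names(mu))
  pos <- mu > 0
  C0_init <- if (fix_C0_at_100) 100 else max(mu[d_lvl == 0], 100)
  alpha_init <- if (sum(pos) >= 2L) {
    fit0 <- stats::lm(log(mu[pos]) ~ d_lvl[pos])
    max(0, -unname(stats::coef(fit0)[2L]))
  } else 1

  df_fit <- data.frame(dose = dose, y = y)
  if (stats::var(y) == 0) {
    # degenerate constant series: no decay
    C0_hat <- if (fix_C0_at_100) 100 else mean(y)
    warning("constant series for ", analyte,
            ": no decay; correlation undefined", call. = FALSE)
    model <- antibiotic_kinetics(C0 = C0_hat, alpha = 0, analyte = analyte)
    return(structure(list(model = model, se_alpha = 0,
                          se_C0 = NA_real_, r_corr = NA_real_,
                          rss = sum((y - C0_hat)^2), n_obs = length(y)),
                     class = "antibiotic_fit"))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 200)
  fit <- if (fix_C0_at_100) {
    minpack.lm::nlsLM(y ~ 100 * exp(-alpha * dose), data = df_fit,
                      start = list(alpha = alpha_init),
                      lower = 0, control = ctrl)
  } else {
    minpack.lm::nlsLM(y ~ C0 * exp(-alpha * dose), data = df_fit,
                      start = list(C0 = C0_init, alpha = alpha_init),
                      lower = c(0, 0), control = ctrl)
  }
  est <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se_of <- function(par) {
    if (is.null(sm) || !par %in% rownames(sm)) NA_real_
    else unname(sm[par, "Std. Error"])
  }
  alpha_hat <- unname(est[["alpha"]])
  C0_hat <- if (fix_C0_at_100) 100 else unname(est[["C0"]])
  fitted_y <- C0_hat * exp(-alpha_hat * dose)
  model <- antibiotic_kinetics(C0 = C0_hat, alpha = alpha_hat, analyte = analyte)
  structure(list(
    model = model,
    se_alpha = se_of("alpha"),
    se_C0 = if (fix_C0_at_100) NA_real_ else se_of("C0"),
    r_corr = goodness_r_corr(y, fitted_y),
    rss = sum((y - fitted_y)^2),
    n_obs = length(y)
  ), class = "antibiotic_fit")
}

#' @export
print.antibiotic_fit <- function(x, ...) {
  cat(sprintf(
    "antibiotic fit [%s]: C0 = %.4g, alpha = %.4g +/- %.2g kGy^-1, R_corr = %.3g (n = %d)\n",
    x$model$analyte, x$model$C0, x$model$alpha, x$se_alpha, x$r_corr, x$n_obs))
  invisible(x)
}

# profile RSS over (beta | D0) with k profiled out analytically:
# the model is linear in k, so for fixed (beta, D0) the optimal k is
# sum(y*f)/sum(f^2) with f the unit-k prediction.
product_rss_profile <- function(log_beta, D0, dose, y, C0, alpha) {
  beta <- exp(log_beta)
  f <- product_conc_num(dose, C0, alpha, beta, D0, 1)
  sf2 <- sum(f * f)
  if (sf2 == 0) return(list(rss = sum(y * y), k = 0))
  k <- max(0, sum(y * f) / sf2)
  list(rss = sum((y - k * f)^2), k = k)
}

best_beta_at_D0 <- function(D0, dose, y, C0, alpha,
                            log_beta_grid = log(10^seq(-2, 2, length.out = 41))) {
  rss_g <- vapply(log_beta_grid, function(lb)
    product_rss_profile(lb, D0, dose, y, C0, alpha)$rss, numeric(1))
  i <- which.min(rss_g)
  lo <- log_beta_grid[max(1L, i - 1L)]
  hi <- log_beta_grid[min(length(log_beta_grid), i + 1L)]
  opt <- stats::optimize(function(lb)
    product_rss_profile(lb, D0, dose, y, C0, alpha)$rss,
    interval = c(lo, hi), tol = 1e-10)
  list(log_beta = opt$minimum, rss = opt$objective)
}

#' Fit the threshold-dose product law to a degradation-product dose series
#'
#' Estimates (beta, D0, k) of the Heaviside-onset product model with the
#' parent parameters (C0, alpha) frozen at their fitted values. Because the
#' onset makes the objective non-smooth in D0, the threshold is located by
#' a grid search over [0, max dose] (with beta profiled by golden-section
#' search and k profiled analytically at each candidate) followed by a
#' Nelder-Mead refinement of all three parameters; ties in the grid RSS are
#' broken towards the smallest D0. Censored observations enter as zeros.
#' Standard errors come from the Gauss-Newton covariance with residual
#' variance.
#'
#' @param table a \code{peak_table}
#' @param analyte the degradation product to fit (accurate-mass label)
#' @param parent an \code{antibiotic_fit} or \code{antibiotic_kinetics} for
#'   the parent antibiotic
#' @param D0_grid_step grid step for the threshold-dose search, kGy
#' @return an object of class \code{product_fit}: list with \code{model}
#'   (\code{product_kinetics}), \code{se_beta}, \code{se_D0}, \code{se_k},
#'   \code{rss}, \code{n_obs}
#' @export
fit_product <- function(table, analyte, parent, D0_grid_step = 0.01) {
  validate_peak_table(table)
  if (inherits(parent, "antibiotic_fit")) parent <- parent$model
  stopifnot(inherits(parent, "antibiotic_kinetics"))
  sub <- table[table$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no observations for analyte ", analyte, call. = FALSE)
  dose <- sub$dose_kGy
  y <- sub$area
  if (all(y == 0)) stop("no signal: all observations for ", analyte,
                        " are zero/censored", call. = FALSE)
  if (length(unique(dose[y > 0])) < 3L) {
    stop("need >= 3 distinct doses with non-zero signal for ", analyte,
         call. = FALSE)
  }
  C0 <- parent$C0
  alpha <- parent$alpha
  dmax <- max(dose)

  # stage 1: D0 grid with profiled (beta, k); smallest-D0 tie-break is
  # automatic since which.min returns the first (i.e. smallest-D0) minimum
  D0_grid <- seq(0, dmax, by = D0_grid_step)
  grid_fit <- lapply(D0_grid, best_beta_at_D0, dose = dose, y = y,
                     C0 = C0, alpha = alpha)
  rss_grid <- vapply(grid_fit, `[[`, numeric(1), "rss")
  i_best <- which.min(rss_grid)
  D0_hat <- D0_grid[i_best]
  lb_hat <- grid_fit[[i_best]]$log_beta
  k_hat <- product_rss_profile(lb_hat, D0_hat, dose, y, C0, alpha)$k
  rss_hat <- rss_grid[i_best]

  # stage 2: joint Nelder-Mead refinement on (log beta, D0, log k); the
  # refinement never worsens the grid objective (fall back to grid optimum)
  if (k_hat > 0) {
    obj <- function(p) {
      D0 <- min(max(p[2L], 0), dmax)
      f <- product_conc_num(dose, C0, alpha, exp(p[1L]), D0, exp(p[3L]))
      sum((y - f)^2)
    }
    start <- c(lb_hat, D0_hat, log(k_hat))
    ref <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    # polish: restart once from the refined point (Nelder-Mead can stall)
    ref2 <- stats::optim(ref$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000))
    if (ref2$value <= rss_hat) {
      lb_hat <- ref2$par[1L]
      D0_hat <- min(max(ref2$par[2L], 0), dmax)
      k_hat <- exp(ref2$par[3L])
      rss_hat <- ref2$value
    }
  }
  beta_hat <- exp(lb_hat)
  model <- product_kinetics(beta = beta_hat, D0 = D0_hat, k = k_hat,
                            parent = parent, analyte = analyte)

  # Gauss-Newton covariance at the solution; forward differences keep the
  # D0 derivative on one side of the onset kink
  n <- length(y)
  p <- 3L
  se <- rep(NA_real_, 3L)
  if (n > p) {
    theta <- c(beta_hat, D0_hat, k_hat)
    pred <- function(th) product_conc_num(dose, C0, alpha, th[1L], th[2L], th[3L])
    J <- matrix(0, n, p)
    h <- pmax(abs(theta), 1e-4) * 1e-6
    f0 <- pred(theta)
    for (j in seq_len(p)) {
      th <- theta; th[j] <- th[j] + h[j]
      J[, j] <- (pred(th) - f0) / h[j]
    }
    s2 <- rss_hat / (n - p)
    cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  structure(list(model = model, se_beta = se[1L], se_D0 = se[2L],
                 se_k = se[3L], rss = rss_hat, n_obs = n),
            class = "product_fit")
}

#' @export
print.product_fit <- function(x, ...) {
  cat(sprintf(
    "product fit [%s]: beta = %.4g +/- %.2g, D0 = %.4g +/- %.2g kGy, k = %.4g +/- %.2g (n = %d)\n",
    x$model$analyte, x$model$beta, x$se_beta, x$model$D0, x$se_D0,
    x$model$k, x$se_k, x$n_obs))
  invisible(x)
}

#' Reconstruct the initial antibiotic concentration from a marker signal
#'
#' Given the full kinetic shape of a degradation marker (beta, D0, k and the
#' parent's alpha), the product model is linear in the parent's initial
#' concentration C0. The estimate is the linear least-squares projection
#' \deqn{\hat C_0 = \sum_i y_i f_i / \sum_i f_i^2,}
#' where f_i is the unit-C0 model prediction at dose i. This is how a
#' measured marker dose series is inverted to the contamination level of
#' the source water before treatment.
#'
#' @param table a \code{peak_table} holding the marker observations
#' @param product a \code{product_kinetics} whose parent C0 defines the
#'   unit shape (the parent C0 is ignored; the shape is evaluated at C0 = 1)
#' @param analyte marker analyte name; defaults to \code{product$analyte}
#' @return list with \code{C0_hat}, \code{se}, \code{n_obs}
#' @export
reconstruct_initial <- function(table, product, analyte = product$analyte) {
  validate_peak_table(table)
  stopifnot(inherits(product, "product_kinetics"))
  sub <- table[table$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no observations for analyte ", analyte, call. = FALSE)
  dose <- sub$dose_kGy
  y <- sub$area
  f <- product_conc_num(dose, 1, product$parent$alpha, product$beta,
                        product$D0, product$k)
  sf2 <- sum(f * f)
  if (sf2 == 0) {
    stop("initial concentration unidentifiable: all doses at or below the ",
         "threshold dose D0", call. = FALSE)
  }
  C0_hat <- sum(y * f) / sf2
  resid <- y - C0_hat * f
  n <- length(y)
  se <- if (n > 1L) sqrt(sum(resid^2) / (n - 1L) / sf2) else NA_real_
  list(C0_hat = C0_hat, se = se, n_obs = n)
}

#' Goodness-of-fit correlation between observed and fitted values
#'
#' Pearson correlation between the observed and fitted series, reported
#' clipped to [0, 1] (an anti-correlated fit reports 0). Returns \code{NA}
#' with a warning when either series is constant, where the correlation is
#' undefined (e.g. a no-decay series).
#'
#' @param observed observed values
#' @param fitted fitted values
#' @return correlation in [0, 1], or \code{NA} if undefined
#' @export
goodness_r_corr <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2L)
  if (stats::var(observed) == 0 || stats::var(fitted) == 0) {
    warning("correlation undefined for constant series", call. = FALSE)
    return(NA_real_)
  }
  min(max(stats::cor(observed, fitted), 0), 1)
}

#' Fit every analyte in a table against a model registry layout
#'
#' Convenience driver: fits the decay law to every antibiotic and the
#' threshold-dose law to every product listed in a roles table (layout of
#' \code{\link{reference_coefficients}}), products conditional on their
#' parent fit.
#'
#' @param table a \code{peak_table}
#' @param roles data frame with columns \code{analyte}, \code{role},
#'   \code{parent}; defaults to the bundled registry restricted to analytes
#'   present in \code{table}
#' @param fix_C0_at_100 passed to \code{\link{fit_antibiotic}}
#' @param D0_grid_step passed to \code{\link{fit_product}}
#' @return a tibble with one row per fitted analyte (estimates and SEs)
#' @export
fit_all <- function(table, roles = NULL, fix_C0_at_100 = TRUE,
                    D0_grid_step = 0.01) {
  if (is.null(roles)) {
    roles <- as.data.frame(reference_coefficients())[, c("analyte", "role", "parent")]
  }
  roles <- roles[roles$analyte %in% unique(table$analyte), , drop = FALSE]
  ab_fits <- list()
  rows <- list()
  for (a in roles$analyte[roles$role == "antibiotic"]) {
    fit <- fit_antibiotic(table, a, fix_C0_at_100 = fix_C0_at_100)
    ab_fits[[a]] <- fit
    rows[[a]] <- tibble::tibble(
      analyte = a, role = "antibiotic", parent = NA_character_,
      C0 = fit$model$C0, alpha = fit$model$alpha, se_alpha = fit$se_alpha,
      r_corr = fit$r_corr, beta = NA_real_, se_beta = NA_real_,
      D0 = NA_real_, se_D0 = NA_real_, k = NA_real_, se_k = NA_real_,
      rss = fit$rss, n_obs = fit$n_obs)
  }
  pr <- roles[roles$role == "product", , drop = FALSE]
  for (i in seq_len(nrow(pr))) {
    a <- pr$analyte[i]
    parent <- ab_fits[[pr$parent[i]]]
    if (is.null(parent)) next
    fit <- tryCatch(fit_product(table, a, parent, D0_grid_step = D0_grid_step),
                    error = function(e) {
                      warning("skipping product ", a, ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    rows[[a]] <- tibble::tibble(
      analyte = a, role = "product", parent = pr$parent[i],
      C0 = NA_real_, alpha = NA_real_, se_alpha = NA_real_, r_corr = NA_real_,
      beta = fit$model$beta, se_beta = fit$se_beta,
      D0 = fit$model$D0, se_D0 = fit$se_D0,
      k = fit$model$k, se_k = fit$se_k,
      rss = fit$rss, n_obs = fit$n_obs)
  }
  do.call(rbind, rows)
}
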