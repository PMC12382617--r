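# Independent numerical oracles for the closed-form kinetics.
#
# Classical fixed-step RK4, vectorized across parameter draws: the state is
# a vector (one component per draw) and the derivative is evaluated
# componentwise. Deliberately written from the defining ODEs, not from the
# package's closed forms.

rk4_integrate <- function(deriv, y0, t0, t1, n_steps) {
  h <- (t1 - t0) / n_steps
  t <- t0
  y <- y0
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(y0))
  out[1L, ] <- y
  for (i in seq_len(n_steps)) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * h
    out[i + 1L, ] <- y
  }
  list(t = t0 + (0:n_steps) * h, y = out)
}

# dC_a/dD = -alpha C_a, C_a(0) = C0; trajectory over [0, dmax]
rk4_antibiotic <- function(C0, alpha, dmax = 10, n_steps = 4000) {
  rk4_integrate(function(D, y) -alpha * y, y0 = rep(C0, length(alpha)),
                t0 = 0, t1 = dmax, n_steps = n_steps)
}

# dC_p/dD = -beta C_p + k C0 e^{-alpha D}, C_p(D0) = 0, integrated in
# tau = D - D0 so all draws share a grid; doses are D0 + tau
rk4_product <- function(C0, alpha, beta, D0, k, tau_max = 10, n_steps = 4000) {
  deriv <- function(tau, y) -beta * y + k * C0 * exp(-alpha * (D0 + tau))
  res <- rk4_integrate(deriv, y0 = rep(0, length(alpha)),
                       t0 = 0, t1 = tau_max, n_steps = n_steps)
  list(dose = outer(res$t, D0, `+`), y = res$y)
}

# sup-norm error normalized by the sup of the reference curve (pointwise
# relative error is meaningless where the concentration underflows)
normalized_sup_err <- function(x, ref) {
  max(abs(x - ref)) / max(abs(ref))
}

# generating models used across tests (the bundled tetracycline row and its
# first degradation product)
tc_model <- function() antibiotic_kinetics(C0 = 100, alpha = 1.28,
                                           analyte = "tetracycline")
dp460_model <- function(parent = tc_model()) {
  product_kinetics(beta = 0.65, D0 = 0.98, k = 0.14, parent = parent,
                   analyte = "461.1549")
}

random_peak_table <- function(seed, n_analytes = 2L, censor_some = TRUE) {
  set.seed(seed)
  doses <- c(0, 0.1, 1, 3, 7)
  rows <- do.call(rbind, lapply(seq_len(n_analytes), function(i) {
    grid <- expand.grid(dose_kGy = doses, replicate = 1:3)
    data.frame(dose_kGy = grid$dose_kGy, replicate = grid$replicate,
               analyte = paste0("analyte", i),
               mz = round(stats::runif(1, 100, 600), 4),
               rt_min = round(stats::runif(nrow(grid), 0.5, 12), 2),
               area = stats::runif(nrow(grid), 0, 3e9),
               censored = FALSE, stringsAsFactors = FALSE)
  }))
  if (censor_some) {
    idx <- sample(nrow(rows), 3L)
    rows$censored[idx] <- TRUE
    rows$area[idx] <- 0
  }
  peak_table(rows)
}
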