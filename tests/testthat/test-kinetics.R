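test_that("antibiotic decay law: identity at dose 0, monotone decay, conserved C0", {
  m <- tc_model()
  expect_equal(antibiotic_concentration(m, 0), 100)
  d <- seq(0, 10, by = 0.1)
  conc <- antibiotic_concentration(m, d)
  expect_true(all(diff(conc) < 0))
  # C_a(D) e^{alpha D} is constant at C0
  expect_equal(conc * exp(m$alpha * d), rep(100, length(d)), tolerance = 1e-12)
  expect_error(antibiotic_concentration(m, -0.1), "non-negative")
})

test_that("closed-form antibiotic decay matches the RK4 oracle", {
  res <- rk4_antibiotic(C0 = 100, alpha = 1.28)
  closed <- antibiotic_concentration(tc_model(), res$t)
  expect_lt(normalized_sup_err(closed, res$y[, 1L]), 1e-6)
  # frozen oracle value at 7 kGy (RK4 gives 0.012845; ~0.0128 rel.un.)
  expect_equal(antibiotic_concentration(tc_model(), 7),
               res$y[which.min(abs(res$t - 7)), 1L], tolerance = 1e-6)
  expect_equal(antibiotic_concentration(tc_model(), 7), 0.0128, tolerance = 5e-3)
})

test_that("product law: zero at and below threshold, non-negative, continuous onset", {
  dp <- dp460_model()
  expect_identical(product_concentration(dp, dp$D0), 0)
  expect_identical(product_concentration(dp, 0.5), 0)
  d <- seq(0, 10, by = 0.001)
  cp <- product_concentration(dp, d)
  expect_true(all(cp >= 0))
  # continuity at D0: values just above the onset are small
  expect_lt(product_concentration(dp, dp$D0 + 1e-8), 1e-6)
  # no formation channel
  dp0 <- product_kinetics(beta = 0.65, D0 = 0.98, k = 0, parent = tc_model())
  expect_equal(product_concentration(dp0, d), rep(0, length(d)))
  # beta < alpha branch is also non-negative
  dp_lo <- product_kinetics(beta = 0.2, D0 = 0.5, k = 0.1, parent = tc_model())
  expect_true(all(product_concentration(dp_lo, d) >= 0))
})

test_that("closed-form product kinetics matches the RK4 oracle, including the beta = alpha limit", {
  dp <- dp460_model()
  res <- rk4_product(100, 1.28, 0.65, 0.98, 0.14)
  closed <- product_concentration(dp, res$dose[, 1L])
  expect_lt(normalized_sup_err(closed, res$y[, 1L]), 1e-6)
  # frozen oracle value at 3 kGy (~1.23 rel.un.)
  i3 <- which.min(abs(res$dose[, 1L] - 3))
  expect_equal(product_concentration(dp, 3), res$y[i3, 1L], tolerance = 1e-6)
  expect_equal(product_concentration(dp, 3), 1.23, tolerance = 5e-3)

  # removable singularity: beta == alpha and nearly-equal rates agree
  dp_eq <- product_kinetics(beta = 1.28, D0 = 0.5, k = 0.1, parent = tc_model())
  res_eq <- rk4_product(100, 1.28, 1.28, 0.5, 0.1)
  expect_lt(normalized_sup_err(product_concentration(dp_eq, res_eq$dose[, 1L]),
                               res_eq$y[, 1L]), 1e-6)
  d <- seq(0.5, 10, by = 0.01)
  dp_near <- product_kinetics(beta = 1.28 + 5e-5, D0 = 0.5, k = 0.1,
                              parent = tc_model())
  expect_equal(product_concentration(dp_near, d),
               product_concentration(dp_eq, d), tolerance = 1e-3)
})

test_that("removal percentage is bounded, monotone and matches the decay law", {
  m <- tc_model()
  expect_equal(removal_percent(m, 0), 0)
  d <- seq(0, 10, by = 0.25)
  r <- removal_percent(m, d)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r < 100))
  # alpha = 1.28 at 7 kGy clears the printed tetracycline removal of 99.9%
  expect_gte(removal_percent(m, 7), 99.9)
  # slowest antibiotic in the bundled set
  expect_equal(removal_percent(antibiotic_kinetics(100, 0.56), 7), 98.0,
               tolerance = 1e-3)
})

test_that("product peak dose matches the argmax of the concentration curve", {
  cases <- list(
    dp460_model(),                                              # beta < alpha
    product_kinetics(beta = 1, D0 = 0, k = 1,
                     parent = antibiotic_kinetics(100, 1)),     # beta == alpha
    product_kinetics(beta = 3.38, D0 = 2.33, k = 0.12,
                     parent = antibiotic_kinetics(100, 2.38))   # beta > alpha
  )
  for (dp in cases) {
    dstar <- product_peak_dose(dp)
    grid <- seq(0, 15, by = 1e-4)
    argmax <- grid[which.max(product_concentration(dp, grid))]
    expect_lt(abs(dstar - argmax), 1e-4 + 1e-8)
  }
  # analytic limit: beta = alpha = 1, D0 = 0 peaks at exactly 1 kGy
  expect_equal(product_peak_dose(cases[[2L]]), 1)
  # bundled DP-TC-460 peaks near 2.06 kGy, inside the 0.1-3 kGy window
  expect_equal(product_peak_dose(dp460_model()), 2.06, tolerance = 1e-2)

  expect_error(product_peak_dose(
    product_kinetics(beta = 1, D0 = 0, k = 0, parent = tc_model())), "k = 0")
  expect_error(product_peak_dose(
    product_kinetics(beta = 0, D0 = 0, k = 1,
                     parent = antibiotic_kinetics(100, 0))), "alpha = beta = 0")
})

test_that("bundled tetracycline products peak in the low-dose window", {
  models <- reference_models()
  # the four products detected at 1 kGy peak inside 0.1-3 kGy
  for (a in c("461.1549", "400.1024", "384.1074", "416.1334")) {
    dstar <- product_peak_dose(models[[a]])
    expect_gte(dstar, 0.1)
    expect_lte(dstar, 3)
  }
  # the slow late product (beta = 0.10, D0 = 1.04) peaks just past the
  # window: D* = D0 + ln(beta/alpha)/(beta - alpha) = 3.20 kGy
  expect_equal(product_peak_dose(models[["437.1205"]]), 3.20, tolerance = 1e-2)
})

test_that("noiseless simulation reproduces the model curves pointwise", {
  models <- list(tc_model(), dp460_model(),
                 product_kinetics(beta = 1.44, D0 = 0.09, k = 0.10,
                                  parent = tc_model(), analyte = "400.1024"))
  doses <- c(0, 0.1, 1, 3, 7)
  tab <- simulate_noiseless(models, doses)
  expect_equal(nrow(tab), 15L)
  expect_equal(tab$area[tab$analyte == "tetracycline"],
               antibiotic_concentration(tc_model(), doses))
  expect_equal(tab$area[tab$analyte == "461.1549"],
               product_concentration(dp460_model(), doses))
  # dose-0 snapshot equals C0 for the antibiotic
  tab0 <- simulate_noiseless(list(tc_model()), 0)
  expect_equal(tab0$area, 100)
})

test_that("closed forms agree with RK4 across randomized parameters including the near-degenerate band", {
  set.seed(42)
  n <- 60
  alpha <- stats::runif(n, 0.05, 5)
  beta <- stats::runif(n, 0.05, 5)
  near <- seq_len(10)  # force |beta - alpha| <= 1e-4 for a band of draws
  beta[near] <- alpha[near] + stats::runif(10, -1e-4, 1e-4)
  D0 <- stats::runif(n, 0, 3)
  k <- stats::runif(n, 0.01, 1)

  res_a <- rk4_antibiotic(100, alpha)
  for (j in seq_len(n)) {
    closed <- antibiotic_concentration(antibiotic_kinetics(100, alpha[j]), res_a$t)
    expect_lt(normalized_sup_err(closed, res_a$y[, j]), 1e-6)
  }
  res_p <- rk4_product(100, alpha, beta, D0, k)
  for (j in seq_len(n)) {
    dp <- product_kinetics(beta = beta[j], D0 = D0[j], k = k[j],
                           parent = antibiotic_kinetics(100, alpha[j]))
    closed <- product_concentration(dp, res_p$dose[, j])
    expect_lt(normalized_sup_err(closed, res_p$y[, j]), 1e-6)
  }
})

test_that("the bundled registry builds every model and round-trips its coefficients", {
  coefs <- reference_coefficients()
  models <- reference_models(coefs)
  expect_length(models, nrow(coefs))
  expect_equal(models[["benzylpenicillin"]]$alpha, 2.51)
  expect_equal(models[["461.1549"]]$D0, 0.98)
  expect_equal(models[["461.1549"]]$parent$alpha, 1.28)
  expect_equal(models[["290.1232"]]$k, 0.74)
})
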