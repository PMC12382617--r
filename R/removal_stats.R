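#' Removal percentages with Student-t confidence intervals
#'
#' Per replicate, removal at dose D is
#' \eqn{100 (1 - \mathrm{area}(D) / \overline{\mathrm{area}}(0))} where the
#' baseline is the mean non-censored dose-0 area. For each dose the mean
#' removal over replicates and the halfwidth of the two-sided Student-t
#' confidence interval are reported.
#'
#' @param table a \code{peak_table}
#' @param analyte the antibiotic to summarize
#' @param conf confidence level (default 0.95)
#' @return a tibble with columns \code{antibiotic}, \code{dose_kGy},
#'   \code{n}, \code{mean_removal}, \code{ci_halfwidth}, plus a
#'   \code{replicates} list-column of per-replicate removals
#' @export
removal_table <- function(table, analyte, conf = 0.95) {
  validate_peak_table(table)
  sub <- table[table$analyte == analyte, , drop = FALSE]
  base_sel <- sub$dose_kGy == 0 & !sub$censored
  if (!any(base_sel)) stop("no non-censored dose-0 data for ", analyte,
                           call. = FALSE)
  baseline <- mean(sub$area[base_sel])
  doses <- sort(unique(sub$dose_kGy))
  rows <- lapply(doses, function(d) {
    a <- sub$area[sub$dose_kGy == d]
    removal <- 100 * (1 - a / baseline)
    n <- length(removal)
    hw <- if (n > 1L) {
      stats::qt(1 - (1 - conf) / 2, df = n - 1L) * stats::sd(removal) / sqrt(n)
    } else NA_real_
    tibble::tibble(antibiotic = analyte, dose_kGy = d, n = n,
                   mean_removal = mean(removal), ci_halfwidth = hw,
                   replicates = list(removal))
  })
  do.call(rbind, rows)
}

#' Balanced two-factor ANOVA with interaction
#'
#' Classical fixed-effects decomposition for a balanced antibiotic x dose
#' design with replication, computed directly from sums of squares:
#' \eqn{SS_{total} = SS_A + SS_B + SS_{AB} + SS_{error}}. F statistics use
#' the error mean square; p-values come from the F distribution. Only
#' balanced designs (equal replication in every cell) are supported.
#'
#' @param data data frame with one observation per row
#' @param response name of the response column (e.g. removal percentage)
#' @param factor_a name of the first factor column (antibiotic)
#' @param factor_b name of the second factor column (dose)
#' @return an object of class \code{anova2}: list with \code{table}
#'   (tibble of SS, df, MS, F, p per term), \code{grand_mean},
#'   \code{cell_n}, \code{means_a}, \code{means_b}, \code{df_error},
#'   \code{ms_error}
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (anyNA(y)) stop("missing response values", call. = FALSE)
  counts <- table(A, B)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stop("unsupported design: two_way_anova requires balanced replication ",
         "(equal n in every cell)", call. = FALSE)
  }
  n <- as.vector(counts)[1L]
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  a <- nlevels(A); b <- nlevels(B)
  N <- length(y)
  gm <- mean(y)
  mean_a <- tapply(y, A, mean)
  mean_b <- tapply(y, B, mean)
  mean_ab <- tapply(y, list(A, B), mean)

  ss_a <- b * n * sum((mean_a - gm)^2)
  ss_b <- a * n * sum((mean_b - gm)^2)
  ss_cells <- n * sum((mean_ab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cells

  df_a <- a - 1L
  df_b <- b - 1L
  df_ab <- df_a * df_b
  df_err <- N - a * b
  if (df_err <= 0L) stop("no error degrees of freedom (need replication)",
                         call. = FALSE)
  ms <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ss_err / df_err)
  # a zero between-groups SS is no evidence against the null whatever the
  # error MS (covers the all-identical-cells degenerate case, where 0/0
  # would otherwise yield NaN)
  f <- c(ifelse(c(ss_a, ss_b, ss_ab) == 0, 0, ms[1:3] / ms[4L]), NA_real_)
  p <- c(stats::pf(f[1:3], c(df_a, df_b, df_ab), df_err, lower.tail = FALSE),
         NA_real_)
  tab <- tibble::tibble(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "error"),
    df = c(df_a, df_b, df_ab, df_err),
    sum_sq = c(ss_a, ss_b, ss_ab, ss_err),
    mean_sq = ms, F = f, p = p)
  structure(list(table = tab, grand_mean = gm, cell_n = n,
                 means_a = mean_a, means_b = mean_b,
                 df_error = df_err, ms_error = ms[4L],
                 n_per_a = b * n,
                 factor_a = factor_a, factor_b = factor_b,
                 data = data.frame(y = y, A = A, B = B)),
            class = "anova2")
}

#' @export
print.anova2 <- function(x, ...) {
  cat("two-factor ANOVA (", x$factor_a, " x ", x$factor_b, ")\n", sep = "")
  print(as.data.frame(x$table))
  invisible(x)
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' For every pair of levels of factor A, the studentized-range statistic
#' \eqn{q_{ij} = |\bar y_i - \bar y_j| / \sqrt{MSE / n}} with n the number
#' of observations per level, referred to the studentized-range
#' distribution with the ANOVA error degrees of freedom
#' (\code{stats::ptukey}). A seed-controlled permutation reference is
#' available as an alternative: the null distribution of the maximum q over
#' pairs under random relabelling of factor-A levels (so the permutation
#' p-values are family-wise, like Tukey's).
#'
#' @param fit an \code{anova2}
#' @param alpha family-wise significance level (default 0.05)
#' @param method \code{"ptukey"} (default) or \code{"permutation"}
#' @param n_perm number of permutations for the fallback (>= 10000 advised)
#' @param seed RNG seed for the permutation method
#' @return a tibble with columns \code{level_i}, \code{level_j},
#'   \code{diff}, \code{q}, \code{p}, \code{significant}
#' @export
tukey_hsd <- function(fit, alpha = 0.05, method = c("ptukey", "permutation"),
                      n_perm = 10000, seed = 1L) {
  stopifnot(inherits(fit, "anova2"))
  method <- match.arg(method)
  means <- fit$means_a
  lev <- names(means)
  if (length(lev) < 2L) stop("need >= 2 levels for pairwise comparison",
                             call. = FALSE)
  n_group <- fit$n_per_a
  se <- sqrt(fit$ms_error / n_group)
  pairs <- utils::combn(lev, 2L)
  diff <- as.numeric(means[pairs[1L, ]] - means[pairs[2L, ]])
  q <- abs(diff) / se
  if (method == "ptukey") {
    p <- stats::ptukey(q, nmeans = length(lev), df = fit$df_error,
                       lower.tail = FALSE)
  } else {
    dat <- fit$data
    q_max_null <- numeric(n_perm)
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    for (i in seq_len(n_perm)) {
      A_perm <- sample(dat$A)
      m <- tapply(dat$y, A_perm, mean)
      q_max_null[i] <- (max(m) - min(m)) / se
    }
    p <- vapply(q, function(qi) mean(q_max_null >= qi), numeric(1))
  }
  tibble::tibble(level_i = pairs[1L, ], level_j = pairs[2L, ],
                 diff = unname(diff), q = unname(q), p = unname(p),
                 significant = unname(p < alpha))
}

#' Two-factor ANOVA on a removal dataset
#'
#' Thin wrapper preparing a removal dataset (columns \code{antibiotic},
#' \code{dose_kGy}, \code{replicate}, \code{removal_percent}) for
#' \code{\link{two_way_anova}}. Dose-0 cells are excluded by default: at
#' dose 0 removal is identically 0 with zero variance, a degenerate cell
#' that would only dilute the error term.
#'
#' @param removal_data data frame of per-replicate removal percentages
#' @param include_dose0 keep the degenerate dose-0 cells (default FALSE)
#' @return an \code{anova2}
#' @export
removal_anova <- function(removal_data, include_dose0 = FALSE) {
  if (!include_dose0) {
    removal_data <- removal_data[removal_data$dose_kGy > 0, , drop = FALSE]
  }
  two_way_anova(removal_data, response = "removal_percent",
                factor_a = "antibiotic", factor_b = "dose_kGy")
}
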