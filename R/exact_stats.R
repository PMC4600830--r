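## Exact 2x2 statistics on allele-count tables.
##
## All routines condition on the table margins. With rows (case, control)
## and columns (variant, reference), the variant-allele count in cases, a,
## follows a Fisher noncentral hypergeometric distribution with odds-ratio
## parameter psi; psi = 1 gives the central hypergeometric used by the
## two-sided test. Point masses are accumulated on the log scale so allele
## totals of ~1e5 (needed by the power search) stay stable.

.table_support <- function(m1, m2, k) {
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  lo:hi
}

.check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    abort("table cells must be non-negative integers",
          class = "cpgburden_domain_error")
  }
}

## log Fisher-noncentral-hypergeometric weights over the support, up to the
## normalizing constant
.fnch_logw <- function(support, m1, m2, k, log_psi) {
  lchoose(m1, support) + lchoose(m2, k - support) + support * log_psi
}

.fnch_probs <- function(support, m1, m2, k, log_psi) {
  lw <- .fnch_logw(support, m1, m2, k, log_psi)
  w <- exp(lw - max(lw))
  w / sum(w)
}

.fnch_mean <- function(support, m1, m2, k, log_psi) {
  sum(support * .fnch_probs(support, m1, m2, k, log_psi))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on the margins and sums the central hypergeometric point
#' probabilities of every table whose probability does not exceed that of
#' the observed table (the minimum-likelihood two-sided rule, as in the
#' standard exact-test convention), with a small relative tolerance on the
#' comparison to absorb floating-point ties.
#'
#' @param a,b,c,d Cell counts: variant/reference alleles in cases (`a`,`b`)
#'   and controls (`c`,`d`). Vectorised.
#' @param rel_tol Relative tolerance for the probability comparison.
#' @return Two-sided p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' fisher_two_sided(5, 849, 6, 2422)  # 0.167...
fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  one <- function(a, b, c, d) {
    .check_cells(a, b, c, d)
    m1 <- a + b; m2 <- c + d; k <- a + c
    support <- .table_support(m1, m2, k)
    lp <- dhyper(support, m1, m2, k, log = TRUE)
    obs <- dhyper(a, m1, m2, k, log = TRUE)
    min(1, sum(exp(lp[lp <= obs + log1p(rel_tol)])))
  }
  unname(mapply(one, a, b, c, d))
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximising the Fisher noncentral hypergeometric
#' likelihood of the table conditional on its margins — the estimate
#' reported by standard exact-test software. Solved as the root of
#' `E[a | psi] = a` by monotone bisection on `log(psi)`.
#'
#' Boundary conventions: `a` at the lower support bound (e.g. `a = 0` with
#' `c > 0`) gives 0; `a` at the upper bound (e.g. `c = 0` with `a > 0`)
#' gives `Inf`. A table with no variant alleles at all (`a = c = 0`) or no
#' reference alleles carries no information about the odds ratio: the
#' estimate is undefined and `NA` is returned (with a warning) —
#' deliberately distinct from the boundary values 0 and `Inf`.
#'
#' @inheritParams fisher_two_sided
#' @param tol Convergence tolerance on `log(psi)`.
#' @return Odds-ratio estimate(s) in `[0, Inf]`.
#' @export
#' @examples
#' conditional_mle_or(5, 849, 6, 2422)  # 2.37...
conditional_mle_or <- function(a, b, c, d, tol = 1e-8) {
  one <- function(a, b, c, d) {
    .check_cells(a, b, c, d)
    m1 <- a + b; m2 <- c + d; k <- a + c
    support <- .table_support(m1, m2, k)
    if (length(support) == 1L) {
      warn("odds ratio undefined: table margins admit a single table")
      return(NA_real_)
    }
    if (a == support[1]) return(0)
    if (a == support[length(support)]) return(Inf)
    f <- function(lp) .fnch_mean(support, m1, m2, k, lp) - a
    lo <- -1; hi <- 1
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    exp((lo + hi) / 2)
  }
  unname(mapply(one, a, b, c, d))
}

#' Exact confidence interval for the odds ratio
#'
#' Inverts the one-sided noncentral hypergeometric tail tests at
#' `(1 - level)/2` in each tail. When the observed count sits on a support
#' boundary the corresponding bound is 0 or `Inf` (one-sided interval), as
#' in `[0.1, Inf]`-style reporting for zero-control-carrier tables.
#'
#' @inheritParams conditional_mle_or
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `ci_lo`, `ci_hi` (one row per table).
#' @export
#' @examples
#' exact_or_ci(5, 849, 6, 2422)  # ~[0.57, 9.38]
exact_or_ci <- function(a, b, c, d, level = 0.95, tol = 1e-8) {
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  one <- function(a, b, c, d) {
    .check_cells(a, b, c, d)
    m1 <- a + b; m2 <- c + d; k <- a + c
    support <- .table_support(m1, m2, k)
    if (length(support) == 1L) {
      return(c(NA_real_, NA_real_))
    }
    upper_tail <- function(lp) {  # P(X >= a | psi)
      p <- .fnch_probs(support, m1, m2, k, lp)
      sum(p[support >= a])
    }
    lower_tail <- function(lp) {  # P(X <= a | psi)
      p <- .fnch_probs(support, m1, m2, k, lp)
      sum(p[support <= a])
    }
    solve_log_psi <- function(g, target) {
      ## g is monotone increasing in log(psi) for the upper tail and
      ## decreasing for the lower tail; normalise to increasing
      f <- function(lp) g(lp) - target
      lo <- -1; hi <- 1
      while (f(lo) > 0 && lo > -700) lo <- lo * 2
      while (f(hi) < 0 && hi < 700) hi <- hi * 2
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    ci_lo <- if (a == support[1]) 0
             else exp(solve_log_psi(function(lp) upper_tail(lp), alpha))
    ci_hi <- if (a == support[length(support)]) Inf
             else exp(solve_log_psi(function(lp) -lower_tail(lp), -alpha))
    c(ci_lo, ci_hi)
  }
  res <- matrix(mapply(one, a, b, c, d), nrow = 2L)
  tibble(ci_lo = res[1, ], ci_hi = res[2, ])
}

#' Exact association statistics for a set of 2x2 tables
#'
#' Adds, per row of a table tibble (as built by [build_tables()] or
#' [cpg_split_tables()]): the two-sided Fisher exact p-value, the
#' conditional-MLE odds ratio, the raw sample cross-product ratio, and the
#' exact confidence interval.
#'
#' @param tables Tibble with integer columns `a`, `b`, `c`, `d`.
#' @param level Confidence level for the exact interval.
#' @return The input tibble with columns `p_value`, `or_cmle`, `or_sample`,
#'   `ci_lo`, `ci_hi` appended.
#' @export
exact_test <- function(tables, level = 0.95) {
  tables <- as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  if (nrow(tables) == 0L) {
    return(mutate(tables, p_value = double(), or_cmle = double(),
                  or_sample = double(), ci_lo = double(),
                  ci_hi = double()))
  }
  ci <- exact_or_ci(tables$a, tables$b, tables$c, tables$d, level = level)
  tables %>%
    mutate(
      p_value = fisher_two_sided(.data$a, .data$b, .data$c, .data$d),
      or_cmle = conditional_mle_or(.data$a, .data$b, .data$c, .data$d),
      or_sample = (.data$a * .data$d) / (.data$b * .data$c)
    ) %>%
    bind_cols(ci)
}

#' Mantel-Haenszel combination of stratified 2x2 tables
#'
#' Fixed-effect common odds ratio `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`
#' with a Robins-Breslow-Greenland confidence interval on the log scale,
#' plus the Mantel-Haenszel chi-squared score test of association:
#' `(|sum a_i - sum E_i| - 1/2)^2 / sum V_i` with hypergeometric mean and
#' variance per stratum, referred to a chi-squared distribution with one
#' degree of freedom. The 1/2 continuity correction is on by default,
#' matching the reference implementation.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d`, one row per
#'   stratum; an `ancestry` (or other label) column is carried through.
#' @param correct Apply the continuity correction to the test statistic.
#' @param level Confidence level for the RBG interval.
#' @return An object of class `mh_result` with elements `or`, `ci_lo`,
#'   `ci_hi`, `chi_sq`, `p_value`, `k`, `correct`, `level`, `tables`.
#'   [tidy()] and [glance()] methods return one-row tibbles.
#' @export
#' @examples
#' tabs <- tibble::tibble(a = c(5, 12, 2), b = c(849, 3772, 162),
#'                        c = c(6, 14, 32), d = c(2422, 8586, 4374))
#' mantel_haenszel(tabs)
mantel_haenszel <- function(tables, correct = TRUE, level = 0.95) {
  tables <- as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  k <- nrow(tables)
  if (k < 1L) {
    abort("at least one stratum is required",
          class = "cpgburden_domain_error")
  }
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c_ <- as.numeric(tables$c); d <- as.numeric(tables$d)
  .check_cells(a, b, c_, d)
  n <- a + b + c_ + d
  R <- a * d / n
  S <- b * c_ / n
  or <- if (sum(R) == 0 && sum(S) == 0) NA_real_
        else if (sum(S) == 0) Inf
        else sum(R) / sum(S)

  ## Robins-Breslow-Greenland variance of log(OR_MH)
  if (is.finite(or) && or > 0) {
    P <- (a + d) / n
    Q <- (b + c_) / n
    v <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
    z <- qnorm(1 - (1 - level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * sqrt(v))
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  ## score test on sum(a) against its conditional expectation
  m1 <- a + b; m2 <- c_ + d; kk <- a + c_
  E <- kk * m1 / n
  V <- m1 * m2 * kk * (n - kk) / (n^2 * (n - 1))
  if (sum(V) == 0) {
    abort("degenerate strata: zero conditional variance",
          class = "cpgburden_degenerate_error")
  }
  dev <- abs(sum(a) - sum(E)) - (if (correct) 0.5 else 0)
  chi_sq <- max(dev, 0)^2 / sum(V)
  p <- pchisq(chi_sq, df = 1, lower.tail = FALSE)

  structure(
    list(or = or, ci_lo = ci[1], ci_hi = ci[2], chi_sq = chi_sq,
         p_value = p, k = k, correct = correct, level = level,
         tables = tables),
    class = "mh_result"
  )
}

#' @export
print.mh_result <- function(x, ...) {
  cat("Mantel-Haenszel combination of", x$k, "strata\n")
  cat(sprintf("  common OR = %.3f, %d%% CI [%.3f, %.3f]\n", x$or,
              round(100 * x$level), x$ci_lo, x$ci_hi))
  cat(sprintf("  chi-squared = %.3f (1 df%s), p = %.4g\n", x$chi_sq,
              if (x$correct) ", continuity-corrected" else "", x$p_value))
  invisible(x)
}

#' @describeIn mantel_haenszel Tidy one-row summary of an `mh_result`.
#' @param x An `mh_result`.
#' @param ... Unused.
#' @method tidy mh_result
#' @export
tidy.mh_result <- function(x, ...) {
  tibble(estimate = x$or, conf.low = x$ci_lo, conf.high = x$ci_hi,
         statistic = x$chi_sq, p.value = x$p_value,
         method = paste0("Mantel-Haenszel",
                         if (x$correct) " (continuity-corrected)"))
}

#' @describeIn mantel_haenszel Model-level summary (strata count, level).
#' @method glance mh_result
#' @export
glance.mh_result <- function(x, ...) {
  tibble(n.strata = x$k, conf.level = x$level, estimate = x$or,
         statistic = x$chi_sq, p.value = x$p_value)
}

#' Bonferroni-adjusted per-test significance level
#'
#' @param alpha_family Family-wise error rate.
#' @param m Number of tests, `>= 1`.
#' @return `alpha_family / m`.
#' @export
#' @examples
#' bonferroni(0.05, 3)  # 0.01666...
bonferroni <- function(alpha_family, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    abort("m must be a positive integer", class = "cpgburden_config_error")
  }
  stopifnot(alpha_family > 0, alpha_family < 1)
  alpha_family / m
}
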