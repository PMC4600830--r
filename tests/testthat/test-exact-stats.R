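test_that("exact test reproduces the published per-stratum statistics", {
  # targeted-region totals: cases 5/854 vs controls 6/2428
  expect_equal(round(fisher_two_sided(5, 849, 6, 2422), 2), 0.17)
  # published as 2.37; the conditional MLE is 2.3766 (the reference
  # implementation agrees), one unit of the last printed digit away
  expect_equal(conditional_mle_or(5, 849, 6, 2422), 2.3766,
               tolerance = 1e-4)
  ci <- exact_or_ci(5, 849, 6, 2422)
  expect_equal(round(ci$ci_lo, 1), 0.6)
  expect_equal(round(ci$ci_hi, 1), 9.4)
  # singleton case variant, absent from controls
  expect_equal(round(fisher_two_sided(1, 853, 0, 2428), 2), 0.26)
  expect_equal(conditional_mle_or(1, 853, 0, 2428), Inf)
  ci0 <- exact_or_ci(1, 853, 0, 2428)
  expect_equal(round(ci0$ci_lo, 1), 0.1)
  expect_equal(ci0$ci_hi, Inf)
  # exome stratum: 12/3784 vs 14/8600
  expect_equal(round(conditional_mle_or(12, 3772, 14, 8586), 2), 1.95)
  # schizophrenia R952H: 1/286 vs 5/2428 (p published as 0.50; the exact
  # two-sided value is 0.4877)
  expect_equal(fisher_two_sided(1, 285, 5, 2423), 0.4877, tolerance = 1e-4)
  expect_equal(round(conditional_mle_or(1, 285, 5, 2423), 2), 1.70)
  # balanced table
  expect_equal(fisher_two_sided(3, 7, 3, 7), 1)
  # zero case carriers
  expect_equal(conditional_mle_or(0, 854, 5, 2423), 0)
  expect_error(fisher_two_sided(-1, 3, 2, 2),
               class = "cpgburden_domain_error")
})

test_that("two-sided p equals the enumeration oracle on all margins n <= 40", {
  rel <- 1 + 1e-7
  n_checked <- 0L
  for (m1 in 1:39) {
    for (m2 in 1:(40 - m1)) {
      n <- m1 + m2
      for (k in 0:n) {
        support <- max(0, k - m2):min(k, m1)
        # direct enumeration with binomial coefficients, no dhyper
        probs <- choose(m1, support) * choose(m2, k - support) /
          choose(n, k)
        want <- vapply(seq_along(support), function(i) {
          min(1, sum(probs[probs <= probs[i] * rel]))
        }, numeric(1))
        got <- fisher_two_sided(support, m1 - support,
                                k - support, m2 - (k - support))
        expect_equal(got, want, tolerance = 1e-12)
        n_checked <- n_checked + length(support)
      }
    }
  }
  expect_gt(n_checked, 1e5)
})

test_that("exact statistics agree with the reference implementation", {
  set.seed(42)
  for (i in 1:50) {
    m1 <- sample(2:300, 1); m2 <- sample(2:500, 1)
    k <- sample(1:(min(m1, m2)), 1)
    a <- sample(max(0, k - m2):min(k, m1), 1)
    tab <- matrix(c(a, k - a, m1 - a, m2 - (k - a)), 2)
    ref <- stats::fisher.test(tab)
    expect_equal(fisher_two_sided(a, m1 - a, k - a, m2 - (k - a)),
                 ref$p.value, tolerance = 1e-6)
    # estimate/CI agreement is limited by the reference's root-finding
    # tolerance (its bounds miss the nominal 0.025 tail by up to ~1e-3
    # relative; the bisection here hits it to 1e-8)
    expect_equal(conditional_mle_or(a, m1 - a, k - a, m2 - (k - a)),
                 unname(ref$estimate), tolerance = 1e-2)
    ci <- exact_or_ci(a, m1 - a, k - a, m2 - (k - a))
    expect_equal(c(ci$ci_lo, ci$ci_hi), ref$conf.int, tolerance = 1e-2,
                 ignore_attr = TRUE)
  }
})

test_that("conditional MLE is monotone in a and sits inside its own CI", {
  m1 <- 100L; m2 <- 300L; k <- 12L
  ors <- vapply(1:11, function(a) {
    conditional_mle_or(a, m1 - a, k - a, m2 - (k - a))
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
  for (a in c(1L, 4L, 8L, 11L)) {
    or <- conditional_mle_or(a, m1 - a, k - a, m2 - (k - a))
    ci <- exact_or_ci(a, m1 - a, k - a, m2 - (k - a))
    expect_true(ci$ci_lo <= or && or <= ci$ci_hi)
  }
  # sparse-table limit: approaches the odds-of-counts times totals ratio
  or <- conditional_mle_or(5, 849, 6, 2422)
  expect_equal(or, (5 / 6) * (2428 / 854), tolerance = 0.01)
})

test_that("degenerate tables return NA estimates rather than 0 or Inf", {
  expect_warning(or <- conditional_mle_or(0, 100, 0, 200), "undefined")
  expect_true(is.na(or))
  ci <- exact_or_ci(0, 100, 0, 200)
  expect_true(is.na(ci$ci_lo) && is.na(ci$ci_hi))
  expect_equal(fisher_two_sided(0, 100, 0, 200), 1)
})

test_that("Mantel-Haenszel combination reproduces the published values", {
  mh_all <- mantel_haenszel(ctrd_all_tables())
  expect_equal(round(mh_all$or, 2), 2.00)
  expect_equal(round(mh_all$chi_sq, 2), 4.77)
  expect_equal(round(mh_all$p_value, 2), 0.03)
  expect_equal(round(mh_all$ci_lo, 1), 1.1)
  expect_equal(round(mh_all$ci_hi, 1), 3.6)
  mh_cpg <- mantel_haenszel(ctrd_cpg_tables())
  expect_equal(round(mh_cpg$or, 1), 2.5)
  expect_lt(mh_cpg$p_value, 0.01)
  mh_split <- mantel_haenszel(fullgene_cpg_split())
  expect_equal(round(mh_split$or, 2), 2.71)
  expect_equal(round(mh_split$p_value, 2), 0.01)
})

test_that("Mantel-Haenszel agrees with the reference implementation", {
  check_vs_ref <- function(tabs, correct = TRUE) {
    arr <- array(rbind(tabs$a, tabs$b, tabs$c, tabs$d),
                 dim = c(2, 2, nrow(tabs)))
    ref <- stats::mantelhaen.test(arr, correct = correct)
    mine <- mantel_haenszel(tabs, correct = correct)
    expect_equal(mine$or, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mine$chi_sq, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(c(mine$ci_lo, mine$ci_hi), ref$conf.int, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  check_vs_ref(ctrd_all_tables())
  check_vs_ref(ctrd_all_tables(), correct = FALSE)
  check_vs_ref(fullgene_cpg_split())
  set.seed(7)
  for (i in 1:20) {
    tabs <- tibble::tibble(a = rpois(3, 8) + 1, b = rpois(3, 400) + 10,
                           c = rpois(3, 8) + 1, d = rpois(3, 900) + 10)
    check_vs_ref(tabs)
  }
})

test_that("Mantel-Haenszel structural properties", {
  one <- tibble::tibble(a = 7, b = 93, c = 3, d = 197)
  # a single stratum reduces to the sample cross-product ratio
  expect_equal(mantel_haenszel(one)$or, (7 * 197) / (93 * 3))
  # identical strata give the single-stratum estimate
  expect_equal(mantel_haenszel(one[c(1, 1, 1), ])$or,
               mantel_haenszel(one)$or)
  # permuting strata is a no-op
  tabs <- ctrd_all_tables()
  expect_equal(mantel_haenszel(tabs[c(3, 1, 2), ])$or,
               mantel_haenszel(tabs)$or)
  # strata exactly at their conditional expectation give chi = 0, p = 1
  null_tab <- tibble::tibble(a = 5, b = 95, c = 10, d = 190)
  mh0 <- mantel_haenszel(null_tab[c(1, 1), ], correct = FALSE)
  expect_equal(mh0$chi_sq, 0)
  expect_equal(mh0$p_value, 1)
  expect_error(mantel_haenszel(tibble::tibble(a = integer(), b = integer(),
                                              c = integer(), d = integer())),
               class = "cpgburden_domain_error")
})

test_that("tidy and glance summarise a Mantel-Haenszel fit", {
  mh <- mantel_haenszel(ctrd_all_tables())
  td <- tidy(mh)
  expect_equal(td$estimate, mh$or)
  expect_equal(td$p.value, mh$p_value)
  gl <- glance(mh)
  expect_equal(gl$n.strata, 3L)
})

test_that("Bonferroni-adjusted level matches the three-cohort correction", {
  expect_equal(round(bonferroni(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), class = "cpgburden_config_error")
})

test_that("MH interval covers a simulated common odds ratio", {
  strata <- default_strata()
  n_case <- 2L * strata$n_individuals[strata$role == "case"]
  n_ctrl <- 2L * strata$n_individuals[strata$role == "control"]
  p0 <- 0.004
  for (psi in c(1, 2.5)) {
    p1 <- psi * p0 / (1 - p0 + psi * p0)  # case frequency at common OR psi
    withr::with_seed(2024, {
      covered <- vapply(1:100, function(i) {
        a <- rbinom(3, n_case, p1)
        c_ <- rbinom(3, n_ctrl, p0)
        tabs <- tibble::tibble(a = a, b = n_case - a,
                               c = c_, d = n_ctrl - c_)
        mh <- mantel_haenszel(tabs)
        is.finite(mh$ci_lo) && mh$ci_lo <= psi && psi <= mh$ci_hi
      }, logical(1))
      expect_gte(sum(covered), 90)
    })
  }
})
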