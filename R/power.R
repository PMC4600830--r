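#' Minimal control alleles for exact-test significance of a rare allele
#'
#' Given an observed rare-allele count in cases, finds the smallest total
#' number of control alleles `N` such that the two-sided Fisher exact test
#' of cases (`case_carriers` of `case_total`) against controls
#' (`control_carriers` of `N`) reaches `p <= alpha`. The control *carrier
#' count* is held fixed while the control denominator grows — the sampling
#' model in which the variant is so rare that genotyping more controls is
#' not expected to find further carriers.
#'
#' The search doubles `N` until significance is reached and then refines by
#' bisection; in this regime the p-value is non-increasing in `N`, and
#' minimality is verified directly at `N - 1`. The search starts where the
#' implied control frequency does not exceed the case frequency, so a
#' "significant" table reflecting control enrichment at a tiny `N` is
#' never returned. With zero control carriers and a single case carrier
#' the two-sided p-value is `case_total / (case_total + N)` once
#' `N > case_total`, so for `alpha < 0.5` the answer has the closed form
#' `ceiling(case_total * (1 - alpha) / alpha)`, which the search
#' reproduces exactly.
#'
#' @param case_carriers Variant allele count in cases (must be positive:
#'   with no case carriers no control sample size can reach significance).
#' @param case_total Total case alleles.
#' @param control_carriers Variant allele count in controls, held fixed.
#' @param alpha Per-test significance level, in `(0, 1)`.
#' @param n_max Search ceiling on the control allele total.
#' @return A one-row tibble: `n_control_alleles` (the exact minimum),
#'   `n_rounded` (two significant figures, the conventional way such
#'   requirements are quoted), `p_at_n`, `alpha`.
#' @export
#' @examples
#' min_control_alleles(1, 854, 0, alpha = 0.0167)
min_control_alleles <- function(case_carriers, case_total,
                                control_carriers = 0, alpha,
                                n_max = 1e9) {
  stopifnot(length(case_carriers) == 1L, length(case_total) == 1L,
            length(control_carriers) == 1L)
  if (case_carriers < 0 || control_carriers < 0 ||
      case_carriers > case_total) {
    abort("carrier counts must be non-negative and within totals",
          class = "cpgburden_config_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "cpgburden_config_error")
  }
  if (case_carriers == 0) {
    abort("significance unreachable: no variant alleles observed in cases",
          class = "cpgburden_unreachable_error")
  }
  p_at <- function(n) {
    fisher_two_sided(case_carriers, case_total - case_carriers,
                     control_carriers, n - control_carriers)
  }
  ## start where the control frequency is at or below the case frequency:
  ## significance reached at a smaller N would reflect control enrichment,
  ## the opposite of the question being asked
  n0 <- max(1, control_carriers,
            ceiling(control_carriers * case_total / case_carriers))
  if (p_at(n0) <= alpha) {
    hi <- n0
  } else {
    n <- n0
    while (p_at(n) > alpha) {
      if (n >= n_max) {
        abort(sprintf("no significant configuration below n_max = %g alleles",
                      n_max),
              class = "cpgburden_unreachable_error")
      }
      n <- min(2 * n, n_max)
    }
    lo <- max(n0, n %/% 2)  # p(lo) > alpha
    hi <- n                 # p(hi) <= alpha
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (p_at(mid) > alpha) lo <- mid else hi <- mid
    }
  }
  stopifnot(p_at(hi) <= alpha)
  tibble(n_control_alleles = hi, n_rounded = signif(hi, 2),
         p_at_n = p_at(hi), alpha = alpha)
}
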