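#' Filter observations to rare variants
#'
#' Retains observations whose ancestry-matched reference minor allele
#' frequency is strictly below `maf_threshold`; unknown MAF (`NA`) is
#' retained (a variant absent from reference panels is treated as rare).
#' The comparison is strict: a variant at exactly the threshold is removed.
#'
#' @param observations Tibble with a `maf_reference` column (fractions).
#' @param maf_threshold Rarity threshold as a fraction, in `(0, 1]`;
#'   default `0.01` (1%).
#' @return The filtered tibble.
#' @export
filter_rare <- function(observations, maf_threshold = 0.01) {
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      maf_threshold <= 0 || maf_threshold > 1) {
    abort("maf_threshold must be a fraction in (0, 1]",
          class = "cpgburden_config_error")
  }
  observations <- as_tibble(observations)
  if (!"maf_reference" %in% names(observations)) {
    abort("observations need a maf_reference column",
          class = "cpgburden_io_error")
  }
  filter(observations,
         is.na(.data$maf_reference) | .data$maf_reference < maf_threshold)
}

#' Allele frequency as a percentage
#'
#' @param carrier_alleles Observed variant allele count(s).
#' @param n_alleles Total allele count(s) (2N); must be positive.
#' @return Numeric percentage(s), `100 * carrier / total`.
#' @export
#' @examples
#' allele_frequency(2, 854)  # 0.234... (%), prints as 0.23
allele_frequency <- function(carrier_alleles, n_alleles) {
  if (any(n_alleles <= 0)) {
    abort("allele frequency undefined for a zero-allele stratum",
          class = "cpgburden_config_error")
  }
  if (any(carrier_alleles < 0 | carrier_alleles > n_alleles)) {
    abort("carrier_alleles must lie in [0, n_alleles]",
          class = "cpgburden_config_error")
  }
  100 * carrier_alleles / n_alleles
}

check_observations_against_manifest <- function(observations, manifest) {
  unknown <- setdiff(unique(observations$stratum), manifest$stratum)
  if (length(unknown)) {
    abort(paste0("observations reference strata missing from the manifest: ",
                 paste(unknown, collapse = ", ")),
          class = "cpgburden_integrity_error")
  }
  tot <- observations %>%
    group_by(.data$stratum) %>%
    summarise(carriers = sum(.data$carrier_alleles), .groups = "drop") %>%
    left_join(manifest, by = "stratum")
  bad <- tot$carriers > tot$n_alleles
  if (any(bad)) {
    abort(paste0("carrier alleles exceed 2N in stratum ",
                 paste(tot$stratum[bad], collapse = ", ")),
          class = "cpgburden_integrity_error")
  }
  invisible(TRUE)
}

#' Build per-ancestry 2x2 allele-count tables
#'
#' Pools qualifying variant observations into one case/control allele-count
#' table per ancestry (collapsing burden): `a` = variant alleles in cases,
#' `b` = remaining case alleles, `c`/`d` likewise for controls, with margins
#' fixed at twice the manifest individual counts. The counting unit is
#' alleles (2N), and multiple distinct rare variants in a stratum pool by
#' summing carrier alleles.
#'
#' @param observations Annotated observation tibble (see
#'   [annotate_variants()]) with `stratum` and `carrier_alleles` columns.
#' @param manifest Stratum manifest (see [read_manifest()]); each ancestry
#'   must have exactly one case and one control stratum.
#' @param class_filter Optional data-masking expression selecting the
#'   variant class, e.g. `consequence == "synonymous"` or
#'   `cpg_impact %in% c("disrupted", "gained")`. Default keeps all rows.
#'   Rows with `cpg_impact == "indeterminate"` that the filter drops
#'   trigger a warning: such sites are excluded from CpG-class tables
#'   rather than guessed.
#' @param region Optional region name: keep only variants inside it
#'   (requires the `in_region` flag or `aa_pos` plus `transcript`).
#' @param transcript Transcript used to resolve `region` when the
#'   observations carry no `in_region` column.
#' @return A tibble with one row per ancestry: `ancestry`, `a`, `b`, `c`,
#'   `d`, `n_case_alleles`, `n_control_alleles`.
#' @export
build_tables <- function(observations, manifest, class_filter = NULL,
                         region = NULL, transcript = NULL) {
  observations <- as_tibble(observations)
  manifest <- validate_manifest(manifest)
  if (nrow(observations)) {
    check_observations_against_manifest(observations, manifest)
  }

  if (!is.null(region) && nrow(observations)) {
    if ("in_region" %in% names(observations) && !is.null(region)) {
      observations <- filter(observations, .data$in_region)
    } else if (!is.null(transcript)) {
      keep <- in_region(transcript, aa_of_position(observations$pos_c), region)
      observations <- observations[keep, ]
    } else {
      abort("region filtering needs an in_region column or a transcript",
            class = "cpgburden_config_error")
    }
  }

  cf <- enquo(class_filter)
  if (!quo_is_null(cf) && nrow(observations)) {
    keep <- eval_tidy(cf, data = observations)
    ## a pre-built quosure passed by value evaluates to itself; unwrap it
    if (rlang::is_quosure(keep)) keep <- eval_tidy(keep, data = observations)
    if ("cpg_impact" %in% names(observations)) {
      dropped_ind <- !keep & observations$cpg_impact == "indeterminate"
      if (any(dropped_ind)) {
        warn(sprintf(
          "%d observation(s) with indeterminate CpG context excluded by the class filter",
          sum(dropped_ind)))
      }
    }
    observations <- observations[keep, ]
  }

  counts <- observations %>%
    group_by(stratum = .data$stratum) %>%
    summarise(carriers = sum(.data$carrier_alleles), .groups = "drop")

  man <- manifest %>%
    left_join(counts, by = "stratum") %>%
    mutate(carriers = dplyr::coalesce(.data$carriers, 0L))

  pairs <- man %>%
    group_by(.data$ancestry) %>%
    summarise(n_case = sum(.data$role == "case"),
              n_control = sum(.data$role == "control"), .groups = "drop")
  if (any(pairs$n_case != 1L | pairs$n_control != 1L)) {
    abort("each ancestry needs exactly one case and one control stratum",
          class = "cpgburden_config_error")
  }

  cases <- filter(man, .data$role == "case")
  ctrls <- filter(man, .data$role == "control")
  out <- tibble(
    ancestry = cases$ancestry,
    a = as.integer(cases$carriers),
    b = cases$n_alleles - as.integer(cases$carriers),
    n_case_alleles = cases$n_alleles
  ) %>%
    left_join(tibble(ancestry = ctrls$ancestry,
                     c = as.integer(ctrls$carriers),
                     d = ctrls$n_alleles - as.integer(ctrls$carriers),
                     n_control_alleles = ctrls$n_alleles),
              by = "ancestry") %>%
    select("ancestry", "a", "b", "c", "d",
           "n_case_alleles", "n_control_alleles")
  ## keep the manifest's ancestry order
  out[match(unique(manifest$ancestry), out$ancestry), ]
}

#' CpG-affecting versus non-affecting variant split
#'
#' Builds, per ancestry, the 2x2 table comparing how case and control rare
#' variants divide between CpG-affecting (disrupted or gained) and
#' non-affecting sites, together with the percentage split within each
#' group. Indeterminate sites are excluded with a warning.
#'
#' @inheritParams build_tables
#' @return A tibble with one row per ancestry: `ancestry`, `a` (case CpG
#'   alleles), `b` (case non-CpG), `c` (control CpG), `d` (control non-CpG),
#'   `case_total`, `case_pct_cpg`, `control_total`, `control_pct_cpg`.
#' @export
cpg_split_tables <- function(observations, manifest) {
  observations <- as_tibble(observations)
  manifest <- validate_manifest(manifest)
  if (!"cpg_impact" %in% names(observations)) {
    abort("observations must be annotated (cpg_impact column missing)",
          class = "cpgburden_io_error")
  }
  if (nrow(observations)) {
    check_observations_against_manifest(observations, manifest)
  }
  n_ind <- sum(observations$cpg_impact == "indeterminate")
  if (n_ind > 0L) {
    warn(sprintf(
      "%d observation(s) with indeterminate CpG context excluded from the CpG split",
      n_ind))
    observations <- filter(observations, .data$cpg_impact != "indeterminate")
  }
  counts <- observations %>%
    mutate(cpg = .data$cpg_impact %in% c("disrupted", "gained")) %>%
    group_by(stratum = .data$stratum, cpg = .data$cpg) %>%
    summarise(n = sum(.data$carrier_alleles), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "cpg", values_from = "n",
                       values_fill = 0L,
                       names_prefix = "cpg_") %>%
    (function(d) {
      if (!"cpg_TRUE" %in% names(d)) d$cpg_TRUE <- 0L
      if (!"cpg_FALSE" %in% names(d)) d$cpg_FALSE <- 0L
      d
    })

  man <- manifest %>%
    left_join(counts, by = "stratum") %>%
    mutate(cpg_TRUE = dplyr::coalesce(.data$cpg_TRUE, 0L),
           cpg_FALSE = dplyr::coalesce(.data$cpg_FALSE, 0L),
           total = .data$cpg_TRUE + .data$cpg_FALSE)

  cases <- filter(man, .data$role == "case")
  ctrls <- filter(man, .data$role == "control")
  out <- tibble(
    ancestry = cases$ancestry,
    a = as.integer(cases$cpg_TRUE), b = as.integer(cases$cpg_FALSE),
    case_total = as.integer(cases$total),
    case_pct_cpg = ifelse(cases$total > 0, 100 * cases$cpg_TRUE / cases$total,
                          NA_real_)
  ) %>%
    left_join(tibble(
      ancestry = ctrls$ancestry,
      c = as.integer(ctrls$cpg_TRUE), d = as.integer(ctrls$cpg_FALSE),
      control_total = as.integer(ctrls$total),
      control_pct_cpg = ifelse(ctrls$total > 0,
                               100 * ctrls$cpg_TRUE / ctrls$total, NA_real_)),
      by = "ancestry") %>%
    select("ancestry", "a", "b", "c", "d", "case_total", "case_pct_cpg",
           "control_total", "control_pct_cpg")
  out[match(unique(manifest$ancestry), out$ancestry), ]
}
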