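## Pipeline driver and fixed-format rendering.
##
## Output formats are deliberately rigid (p and OR to two decimals,
## frequencies to two decimals, "Inf" literal for infinite bounds,
## scientific notation with a one-decimal mantissa below 0.01) so that
## re-running on identical inputs is byte-identical.

#' Fixed-format number rendering for burden reports
#'
#' @param p,x Numeric vectors.
#' @param lo,hi CI bounds.
#' @return Character vectors.
#' @name formatting
NULL

#' @rdname formatting
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.01,
                {
                  e <- floor(log10(p))
                  sprintf("%.1f x 10^%d", p / 10^e, e)
                },
                sprintf("%.2f", p)))
}

#' @rdname formatting
#' @export
format_or <- function(x) {
  ifelse(is.na(x), "NA", ifelse(is.infinite(x), "Inf", sprintf("%.2f", x)))
}

#' @rdname formatting
#' @export
format_ci <- function(lo, hi) {
  f1 <- function(v) ifelse(is.infinite(v), "Inf", sprintf("%.1f", v))
  ifelse(is.na(lo) | is.na(hi), "NA",
         paste0("[", f1(lo), "-", f1(hi), "]"))
}

resolve_transcript <- function(x) {
  if (inherits(x, "transcript_model")) return(x)
  if (is.list(x) && all(c("fasta", "exons", "meta") %in% names(x))) {
    return(read_transcript_model(x$fasta, x$exons, x$meta))
  }
  abort("transcript must be a transcript_model or a list of fasta/exons/meta paths",
        class = "cpgburden_config_error")
}

resolve_table <- function(x, reader) {
  if (is.data.frame(x)) as_tibble(x) else reader(x)
}

#' Run the full stratified burden analysis
#'
#' Drives annotation, rarity filtering, table construction, exact
#' per-stratum tests and Mantel-Haenszel combination, and renders three
#' fixed-format report tables: a per-variant table (coding and protein
#' names on both isoforms where an offset is registered, counts,
#' frequencies, exact statistics against the matched controls), a
#' per-class stratified table with combined statistics (classes: all,
#' non-synonymous, synonymous, CpG-affecting, non-CpG-affecting), and a
#' CpG-vs-non-CpG split of the full set of rare variants. Record counts
#' surviving each stage are logged via `message()`.
#'
#' @param transcript A [transcript_model()] or a list of paths
#'   (`fasta`, `exons`, `meta`).
#' @param observations Observation tibble or path to an observations TSV.
#' @param manifest Manifest tibble or path to a manifest TSV.
#' @param maf_threshold Rarity threshold fraction; default 0.01.
#' @param region Region restriction for the per-class table (default
#'   `"CTRD"` when registered; `NULL` for the whole CDS).
#' @param mh_correct Continuity correction for the combined test.
#' @param alpha_family,m Family-wise level and number of tests for the
#'   Bonferroni-adjusted per-test alpha quoted in the summary.
#' @param out_dir Optional directory; when given, the three tables are
#'   written as TSV and a JSON summary of all statistics is written
#'   alongside.
#' @return An object of class `burden_report`: list with tibbles
#'   `per_variant`, `per_class`, `cpg_split`, the `combined` tidy rows of
#'   each class-level Mantel-Haenszel fit, and `alpha` (the per-test
#'   level).
#' @export
run_burden <- function(transcript, observations, manifest,
                       maf_threshold = 0.01, region = "CTRD",
                       mh_correct = TRUE, alpha_family = 0.05, m = 3,
                       out_dir = NULL) {
  transcript <- resolve_transcript(transcript)
  observations <- resolve_table(observations, read_observations)
  manifest <- resolve_table(manifest, read_manifest)
  manifest <- validate_manifest(manifest)

  message(sprintf("[input] %d observation rows, %d strata",
                  nrow(observations), nrow(manifest)))
  annotated <- annotate_variants(observations, transcript)
  rare <- filter_rare(annotated, maf_threshold)
  message(sprintf("[filter_rare] %d of %d rows retained (MAF < %g)",
                  nrow(rare), nrow(annotated), maf_threshold))

  has_region <- !is.null(region) && !is.null(transcript$regions) &&
    region %in% transcript$regions$region
  region_use <- if (has_region) region else NULL

  per_variant <- per_variant_table(rare, manifest, transcript)

  classes <- list(
    all = NULL,
    nonsynonymous = rlang::quo(.data$consequence == "nonsynonymous"),
    synonymous = rlang::quo(.data$consequence == "synonymous"),
    cpg_affected = rlang::quo(.data$cpg_impact %in% c("disrupted", "gained")),
    cpg_not_affected = rlang::quo(.data$cpg_impact == "none")
  )
  per_class_list <- purrr::imap(classes, function(q, nm) {
    tabs <- if (is.null(q)) {
      build_tables(rare, manifest, region = region_use,
                   transcript = transcript)
    } else {
      build_tables(rare, manifest, class_filter = q, region = region_use,
                   transcript = transcript)
    }
    strat <- exact_test(tabs)
    mh <- tryCatch(mantel_haenszel(tabs, correct = mh_correct),
                   cpgburden_degenerate_error = function(e) NULL)
    list(class = nm, strat = strat, mh = mh)
  })
  per_class <- purrr::map_dfr(per_class_list, function(e) {
    mutate(e$strat, variant_class = e$class, .before = 1)
  })
  combined <- purrr::map_dfr(per_class_list, function(e) {
    row <- if (is.null(e$mh)) {
      tibble(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
             statistic = NA_real_, p.value = NA_real_,
             method = "Mantel-Haenszel (degenerate strata)")
    } else {
      tidy(e$mh)
    }
    mutate(row, variant_class = e$class, .before = 1)
  })
  message(sprintf("[per_class] %d classes x %d ancestries tested",
                  length(per_class_list), length(unique(per_class$ancestry))))

  ## full-gene CpG vs non-CpG split (no region restriction)
  cpg_split <- cpg_split_tables(rare, manifest)
  split_informative <- filter(cpg_split,
                              .data$a + .data$b > 0, .data$c + .data$d > 0,
                              .data$a + .data$c > 0, .data$b + .data$d > 0)
  cpg_split_tests <- exact_test(split_informative)
  cpg_split_mh <- if (nrow(split_informative) >= 1L &&
                      sum(split_informative$a + split_informative$c) > 0 &&
                      sum(split_informative$b + split_informative$d) > 0) {
    mantel_haenszel(split_informative, correct = mh_correct)
  } else NULL

  alpha <- bonferroni(alpha_family, m)
  report <- structure(
    list(per_variant = per_variant, per_class = per_class,
         combined = combined, cpg_split = cpg_split_tests,
         cpg_split_combined = cpg_split_mh, alpha = alpha,
         maf_threshold = maf_threshold, region = region_use),
    class = "burden_report")
  if (!is.null(out_dir)) write_burden_report(report, out_dir)
  report
}

per_variant_table <- function(rare, manifest, transcript) {
  if (nrow(rare) == 0L) {
    return(tibble(ancestry = character(), c_name = character(),
                  p_name = character(), c_name_alt = character(),
                  p_name_alt = character(), rs_id = character(),
                  case_alleles = integer(), case_total = integer(),
                  case_freq_pct = double(), control_alleles = integer(),
                  control_total = integer(), control_freq_pct = double(),
                  p_value = double(), odds_ratio = double(),
                  ci = character()))
  }
  man <- manifest
  rare2 <- left_join(rare, select(man, "stratum", "ancestry", "role",
                                  "n_alleles"),
                     by = "stratum")
  off <- transcript$offsets
  c_off <- if (!is.null(off) && nrow(off)) off$c_offset[1] else NA_integer_
  p_off <- if (!is.null(off) && nrow(off)) off$p_offset[1] else NA_integer_

  per <- rare2 %>%
    group_by(.data$ancestry, .data$pos_c, .data$ref, .data$alt,
             .data$protein_change, .data$ref_aa, .data$aa_pos,
             .data$alt_aa) %>%
    summarise(
      rs_id = dplyr::first(stats::na.omit(.data$rs_id)) %|na|% "-",
      case_alleles = sum(.data$carrier_alleles[.data$role == "case"]),
      control_alleles = sum(.data$carrier_alleles[.data$role == "control"]),
      .groups = "drop")

  totals <- man %>%
    group_by(.data$ancestry) %>%
    summarise(case_total = sum(.data$n_alleles[.data$role == "case"]),
              control_total = sum(.data$n_alleles[.data$role == "control"]),
              .groups = "drop")

  per <- left_join(per, totals, by = "ancestry") %>%
    mutate(
      c_name = paste0("c.", .data$pos_c, " ", .data$ref, ">", .data$alt),
      p_name = .data$protein_change,
      c_name_alt = if (!is.na(c_off))
        paste0("c.", .data$pos_c + c_off, " ", .data$ref, ">", .data$alt)
        else NA_character_,
      p_name_alt = if (!is.na(p_off))
        paste0("p.", .data$ref_aa, .data$aa_pos + p_off, .data$alt_aa)
        else NA_character_,
      case_freq_pct = allele_frequency(.data$case_alleles, .data$case_total),
      control_freq_pct = allele_frequency(.data$control_alleles,
                                          .data$control_total)
    )
  stats <- exact_test(tibble(a = per$case_alleles,
                             b = per$case_total - per$case_alleles,
                             c = per$control_alleles,
                             d = per$control_total - per$control_alleles))
  per %>%
    mutate(p_value = stats$p_value, odds_ratio = stats$or_cmle,
           ci = format_ci(stats$ci_lo, stats$ci_hi)) %>%
    select("ancestry", "c_name", "p_name", "c_name_alt", "p_name_alt",
           "rs_id", "case_alleles", "case_total", "case_freq_pct",
           "control_alleles", "control_total", "control_freq_pct",
           "p_value", "odds_ratio", "ci") %>%
    arrange(.data$ancestry, .data$c_name)
}

#' Write the rendered tables of a burden report
#'
#' @param report A `burden_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
write_burden_report <- function(report, out_dir) {
  stopifnot(inherits(report, "burden_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pv <- report$per_variant %>%
    mutate(case_freq_pct = sprintf("%.2f", .data$case_freq_pct),
           control_freq_pct = sprintf("%.2f", .data$control_freq_pct),
           p_value = format_p(.data$p_value),
           odds_ratio = format_or(.data$odds_ratio))
  pc <- report$per_class %>%
    mutate(p_value = format_p(.data$p_value),
           odds_ratio = format_or(.data$or_cmle),
           ci = format_ci(.data$ci_lo, .data$ci_hi)) %>%
    select("variant_class", "ancestry", "a", "b", "c", "d",
           "p_value", "odds_ratio", "ci")
  cb <- report$combined %>%
    mutate(p_value = format_p(.data$p.value),
           odds_ratio = format_or(.data$estimate),
           ci = format_ci(.data$conf.low, .data$conf.high)) %>%
    select("variant_class", "p_value", "odds_ratio", "ci")
  cs <- report$cpg_split %>%
    mutate(case_pct_cpg = sprintf("%.0f", .data$case_pct_cpg),
           control_pct_cpg = sprintf("%.0f", .data$control_pct_cpg),
           p_value = format_p(.data$p_value),
           odds_ratio = format_or(.data$or_cmle),
           ci = format_ci(.data$ci_lo, .data$ci_hi)) %>%
    select("ancestry", "a", "b", "c", "d", "case_total", "case_pct_cpg",
           "control_total", "control_pct_cpg", "p_value", "odds_ratio", "ci")

  paths <- list(per_variant = file.path(out_dir, "per_variant.tsv"),
                per_class = file.path(out_dir, "per_class.tsv"),
                combined = file.path(out_dir, "combined.tsv"),
                cpg_split = file.path(out_dir, "cpg_split.tsv"),
                summary = file.path(out_dir, "summary.json"))
  readr::write_tsv(pv, paths$per_variant)
  readr::write_tsv(pc, paths$per_class)
  readr::write_tsv(cb, paths$combined)
  readr::write_tsv(cs, paths$cpg_split)
  summary <- list(
    alpha_per_test = report$alpha,
    maf_threshold = report$maf_threshold,
    region = report$region,
    combined = report$combined,
    cpg_split_combined = if (!is.null(report$cpg_split_combined))
      tidy(report$cpg_split_combined) else NULL
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' @export
print.burden_report <- function(x, ...) {
  cat("<burden_report>\n")
  cat(sprintf("  %d per-variant rows; %d class x ancestry tests; per-test alpha %.4f\n",
              nrow(x$per_variant), nrow(x$per_class), x$alpha))
  cmb <- x$combined
  for (i in seq_len(nrow(cmb))) {
    cat(sprintf("  combined %-17s OR %s %s p %s\n", cmb$variant_class[i],
                format_or(cmb$estimate[i]),
                format_ci(cmb$conf.low[i], cmb$conf.high[i]),
                format_p(cmb$p.value[i])))
  }
  invisible(x)
}

#' @describeIn run_burden Class-level stratified + combined rows in tidy
#'   form.
#' @param x A `burden_report`.
#' @param ... Unused.
#' @method tidy burden_report
#' @export
tidy.burden_report <- function(x, ...) {
  strat <- x$per_class %>%
    select("variant_class", "ancestry", estimate = "or_cmle",
           conf.low = "ci_lo", conf.high = "ci_hi", p.value = "p_value")
  comb <- x$combined %>%
    mutate(ancestry = "combined") %>%
    select("variant_class", "ancestry", "estimate", "conf.low",
           "conf.high", "p.value")
  bind_rows(strat, comb)
}

#' @describeIn run_burden One-row report summary.
#' @method glance burden_report
#' @export
glance.burden_report <- function(x, ...) {
  all_row <- filter(x$combined, .data$variant_class == "all")
  tibble(n_variants = nrow(x$per_variant),
         n_classes = length(unique(x$per_class$variant_class)),
         alpha_per_test = x$alpha,
         or_all_combined = all_row$estimate[1],
         p_all_combined = all_row$p.value[1])
}

#' Forest plot of stratified and combined odds ratios
#'
#' One panel per variant class; per-ancestry conditional-MLE odds ratios
#' with exact intervals, and the combined Mantel-Haenszel estimate, on a
#' log axis. Non-finite estimates or bounds cannot be drawn on a log axis
#' and are dropped with a warning.
#'
#' @param object A `burden_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_report
#' @export
autoplot.burden_report <- function(object, ...) {
  df <- tidy(object)
  drop <- !is.finite(df$estimate) | df$estimate <= 0
  if (any(drop)) {
    warn(sprintf("%d non-finite or zero odds ratio(s) not drawn", sum(drop)))
    df <- df[!drop, ]
  }
  df$conf.low[!is.finite(df$conf.low) | df$conf.low <= 0] <- NA
  df$conf.high[!is.finite(df$conf.high)] <- NA
  df$ancestry <- factor(df$ancestry,
                        levels = rev(unique(df$ancestry)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$ancestry)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high,
                                          colour = .data$ancestry == "combined"),
                             show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant_class)) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Run the rare-allele power analysis
#'
#' Thin wrapper over [min_control_alleles()] that defaults the per-test
#' significance level to the Bonferroni-adjusted family level.
#'
#' @inheritParams min_control_alleles
#' @param alpha Per-test level; default `bonferroni(alpha_family, m)`.
#' @param alpha_family,m Family-wise level and number of tests used when
#'   `alpha` is not given.
#' @return The one-row tibble from [min_control_alleles()], with `alpha`
#'   attached.
#' @export
run_power <- function(case_carriers, case_total, control_carriers = 0,
                      alpha = NULL, alpha_family = 0.05, m = 3) {
  if (is.null(alpha)) alpha <- bonferroni(alpha_family, m)
  min_control_alleles(case_carriers, case_total, control_carriers,
                      alpha = alpha)
}
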