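## Synthetic study generator.
##
## Emulates the structure of a targeted-sequencing / exome case-control
## study of a single CpG-rich coding transcript: a CGN(arginine)-enriched
## CDS with a C-terminal regulatory region, multi-ancestry case/control
## strata at fixed sizes, and rare variant sites with requested consequence
## and CpG classes at binomially sampled carrier allele counts.

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1, paste0, collapse = ""),
  STOP_CODONS)

CGN_CODONS <- paste0("CG", BASES)

#' Generate a synthetic CpG-rich reference transcript
#'
#' Builds a CDS of `n_codons` codons starting with ATG and containing no
#' internal stop codon, in which each subsequent codon is independently an
#' arginine CGN codon with probability `arg_cgn_fraction` (these create the
#' CpG dinucleotides whose disruption the annotation module classifies) and
#' otherwise uniform over the remaining non-stop codons. The CDS is split
#' into five exons with one-base intronic flanks at internal edges (the
#' outermost flanks are left unknown, so variants at the extreme CDS ends
#' exercise the indeterminate-context path). A `CTRD`-style region is
#' registered over the 3' third of the protein, with a short `ISO`
#' subdomain inside it, and a `+69 nt / +23 aa` offset to a synthetic
#' sibling isoform accession is attached.
#'
#' Deterministic for a given `seed`.
#'
#' @param seed Integer seed.
#' @param n_codons Number of codons; default 1200, the scale of a large
#'   transporter CDS.
#' @param arg_cgn_fraction Target fraction of CGN codons, in `[0, 1)`.
#' @return A [transcript_model()].
#' @export
generate_reference <- function(seed, n_codons = 1200,
                               arg_cgn_fraction = 0.15) {
  stopifnot(n_codons >= 30)
  if (arg_cgn_fraction < 0 || arg_cgn_fraction >= 1) {
    abort("arg_cgn_fraction must lie in [0, 1)",
          class = "cpgburden_config_error")
  }
  withr::with_seed(seed, {
    non_cgn <- setdiff(NONSTOP_CODONS, CGN_CODONS)
    is_cgn <- stats::runif(n_codons - 1L) < arg_cgn_fraction
    codons <- ifelse(is_cgn,
                     sample(CGN_CODONS, n_codons - 1L, replace = TRUE),
                     sample(non_cgn, n_codons - 1L, replace = TRUE))
    cds <- paste0("ATG", paste(codons, collapse = ""))
    n <- nchar(cds)
    bounds <- sort(sample(2:(n - 1L), 4L))
    exons <- tibble(
      exon_index = 1:5,
      c_start = c(1L, bounds),
      c_end = c(bounds - 1L, n),
      flank_5p = c(NA_character_, sample(BASES, 4L, replace = TRUE)),
      flank_3p = c(sample(BASES, 4L, replace = TRUE), NA_character_)
    )
    ctrd_start <- (2L * n_codons) %/% 3L + 1L
    iso_start <- ctrd_start + (n_codons %/% 10L)
    regions <- tibble(
      region = c("CTRD", "ISO"),
      start_aa = c(ctrd_start, iso_start),
      end_aa = c(n_codons, min(iso_start + 15L, n_codons))
    )
    offsets <- tibble(from_id = "SYN_TX1", to_id = "SYN_TX2",
                      c_offset = 69L, p_offset = 23L)
    transcript_model(cds, transcript_id = "SYN_TX1", protein_id = "SYN_PX1",
                     exons = exons, regions = regions, offsets = offsets)
  })
}

#' Specify a synthetic case-control study
#'
#' Defaults encode the study conditions the package targets: three
#' ancestry strata — a targeted-screening stratum of 427 cases vs 1214
#' controls (FC), and two exome strata of 1892 vs 4300 (EA) and 82 vs 2203
#' (AA) individuals — with rare variant sites at allele frequencies in the
#' 0.04–0.7% range, a configurable consequence/CpG class mix, and a
#' fraction of sites made common (>1%) so the rarity filter has work to do.
#'
#' @param strata Tibble with `stratum`, `ancestry`, `role`,
#'   `n_individuals`.
#' @param variant_specs Tibble with one row per site: `rel_pos` (relative
#'   CDS position in `(0, 1]`), `consequence` (`"synonymous"` or
#'   `"nonsynonymous"`), `cpg` (`"disrupted"`, `"gained"` or `"none"`),
#'   `freq_case`, `freq_control` (allele-frequency fractions).
#' @param maf_common_fraction Fraction of sites whose reference MAF is
#'   drawn above 1% (so they are removed by [filter_rare()]).
#' @param seed Integer seed; drives the whole generation through a
#'   documented split (`seed` for the reference, `seed + 1` for the
#'   cohort draw).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(strata = default_strata(),
                        variant_specs = default_variant_specs(),
                        maf_common_fraction = 0.2,
                        seed = 1L) {
  strata <- as_tibble(strata)
  variant_specs <- as_tibble(variant_specs)
  stopifnot(all(c("rel_pos", "consequence", "cpg", "freq_case",
                  "freq_control") %in% names(variant_specs)))
  if (any(variant_specs$freq_case < 0 | variant_specs$freq_case > 1 |
          variant_specs$freq_control < 0 | variant_specs$freq_control > 1)) {
    abort("allele frequencies must lie in [0, 1]",
          class = "cpgburden_config_error")
  }
  if (any(strata$n_individuals < 1L)) {
    abort("strata sizes must be >= 1", class = "cpgburden_config_error")
  }
  structure(list(strata = strata, variant_specs = variant_specs,
                 maf_common_fraction = maf_common_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @describeIn cohort_spec The default three-ancestry stratum manifest.
#' @export
default_strata <- function() {
  tibble(
    stratum = c("FC_case", "FC_control", "EA_case", "EA_control",
                "AA_case", "AA_control"),
    ancestry = rep(c("FC", "EA", "AA"), each = 2),
    role = rep(c("case", "control"), 3),
    n_individuals = c(427L, 1214L, 1892L, 4300L, 82L, 2203L)
  )
}

#' @describeIn cohort_spec Default rare-site mix: ten sites inside the
#'   3' regulatory region spanning synonymous/non-synonymous and
#'   CpG-affecting/non-affecting classes at frequencies 0.04-0.7%.
#' @export
default_variant_specs <- function() {
  tibble(
    rel_pos = seq(0.70, 0.97, length.out = 10),
    consequence = rep(c("nonsynonymous", "synonymous"), 5),
    cpg = rep(c("disrupted", "gained", "none", "disrupted", "none"), 2),
    freq_case = c(0.0023, 0.0012, 0.0007, 0.0041, 0.0012,
                  0.0035, 0.0004, 0.0021, 0.0062, 0.0015),
    freq_control = c(0.0021, 0.0004, 0.0004, 0.0021, 0.0008,
                     0.0021, 0.0004, 0.0012, 0.0041, 0.0008)
  )
}

## Find a (pos, alt) near the requested position realising the requested
## consequence and CpG classes on this transcript; deterministic scan
## ordered by distance from the target.
find_site <- function(transcript, target_pos, consequence, cpg) {
  n <- nchar(transcript$cds)
  order_pos <- order(abs(seq_len(n) - target_pos))
  for (pos in order_pos) {
    ref <- substring(transcript$cds, pos, pos)
    ctx <- context_at(transcript, pos)
    for (alt in setdiff(BASES, ref)) {
      cons <- classify_consequence(transcript, pos, ref, alt)$consequence
      if (cons != consequence) next
      impact <- classify_cpg_impact(ref, alt, ctx$ctx_5p, ctx$ctx_3p)
      if (impact == cpg) {
        return(list(pos_c = pos, ref = ref, alt = alt,
                    ctx_5p = ctx$ctx_5p, ctx_3p = ctx$ctx_3p))
      }
    }
  }
  abort(sprintf(
    "no site with consequence '%s' and CpG class '%s' achievable near c.%d",
    consequence, cpg, target_pos), class = "cpgburden_generation_error")
}

#' Generate a synthetic case-control variant dataset
#'
#' Realises a [cohort_spec()] on a transcript: each requested site is
#' placed at the nearest CDS position where the requested consequence and
#' CpG classes are achievable (the generator chooses ref/alt/context so
#' that re-annotation reproduces the requested labels exactly), and
#' carrier allele counts are drawn independently per stratum as
#' `Binomial(2N, freq)` — the rare-variant regime where cohort sizes dwarf
#' carrier counts. Sites selected to be common are additionally given a
#' reference MAF above 1%; rare sites carry their control frequency as the
#' reference MAF.
#'
#' Deterministic for a given spec seed; zero-carrier draws are absent from
#' the output.
#'
#' @param spec A [cohort_spec()].
#' @param transcript A [transcript_model()]; default
#'   `generate_reference(spec$seed)`.
#' @return A list of class `synthetic_cohort`: `observations` (tibble, one
#'   row per site x stratum with carriers), `manifest` (tibble), `sites`
#'   (the realised site table), `transcript`.
#' @export
generate_cohort <- function(spec, transcript = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(transcript)) transcript <- generate_reference(spec$seed)
  n <- nchar(transcript$cds)
  vs <- spec$variant_specs
  sites <- purrr::pmap_dfr(
    list(vs$rel_pos, vs$consequence, vs$cpg),
    function(rp, cons, cpg) {
      s <- find_site(transcript, max(1L, min(n, round(rp * n))), cons, cpg)
      as_tibble(s)
    })
  sites <- bind_cols(sites, vs[c("consequence", "cpg", "freq_case",
                                 "freq_control")])
  if (anyDuplicated(sites$pos_c)) {
    abort("variant specs resolved to duplicate CDS positions; spread rel_pos",
          class = "cpgburden_generation_error")
  }
  manifest <- validate_manifest(spec$strata)
  withr::with_seed(spec$seed + 1L, {
    n_sites <- nrow(sites)
    common <- stats::runif(n_sites) < spec$maf_common_fraction
    maf_ref <- ifelse(common, stats::runif(n_sites, 0.012, 0.2),
                      sites$freq_control)
    freq_mult <- ifelse(common, maf_ref / pmax(sites$freq_control, 1e-6), 1)
    obs <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
      st <- manifest[i, ]
      freq <- if (st$role == "case") sites$freq_case else sites$freq_control
      freq <- pmin(1, freq * freq_mult)  # common sites are common everywhere
      carriers <- rbinom(n_sites, st$n_alleles, freq)
      tibble(
        transcript_id = transcript$transcript_id,
        pos_c = sites$pos_c, ref = sites$ref, alt = sites$alt,
        ctx_5p = sites$ctx_5p, ctx_3p = sites$ctx_3p,
        rs_id = sprintf("synth%04d", sites$pos_c),
        stratum = st$stratum,
        carrier_alleles = carriers,
        maf_reference = maf_ref
      )
    })
    obs <- filter(obs, .data$carrier_alleles > 0L)
    structure(list(observations = obs, manifest = manifest,
                   sites = sites, transcript = transcript),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact dialects the pipeline reads back: `observations.tsv`,
#' `manifest.tsv`, plus the transcript files via
#' [write_transcript_model()]. Byte-identical for identical specs.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, a named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_transcript_model(cohort$transcript, dir)
  paths$observations <- file.path(dir, "observations.tsv")
  paths$manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(cohort$observations, paths$observations)
  readr::write_tsv(select(cohort$manifest, -"n_alleles"), paths$manifest)
  invisible(paths)
}
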