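#' Classify the coding consequence of a single-nucleotide variant
#'
#' Translates the reference and alternate codons with the standard genetic
#' code. Equal residues give `synonymous`; differing non-stop residues give
#' `nonsynonymous`; any involvement of a stop codon (gain or loss) gives
#' `other`. The reference base must match the transcript at `pos_c`.
#'
#' @param transcript A [transcript_model()].
#' @param pos_c CDS coordinate of the substitution (scalar).
#' @param ref,alt Single reference/alternate bases, `ref != alt`.
#' @return A one-row tibble: `consequence`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   `protein_change` (e.g. `"p.R952H"`).
#' @export
#' @examples
#' tx <- transcript_model("ATGCGCCCG", "TX1")
#' classify_consequence(tx, 5, "G", "A")  # CGC -> CAC, p.R2H
classify_consequence <- function(transcript, pos_c, ref, alt) {
  stopifnot(inherits(transcript, "transcript_model"))
  pos_c <- as.integer(pos_c)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is_base(ref) || !is_base(alt) || ref == alt) {
    abort("ref and alt must be distinct bases in A/C/G/T",
          class = "cpgburden_variant_error")
  }
  if (pos_c < 1L || pos_c > nchar(transcript$cds)) {
    abort("pos_c outside the coding sequence",
          class = "cpgburden_bounds_error")
  }
  tx_base <- substring(transcript$cds, pos_c, pos_c)
  if (tx_base != ref) {
    abort(sprintf(
      "reference mismatch at c.%d: transcript has %s, observation says %s",
      pos_c, tx_base, ref), class = "cpgburden_integrity_error")
  }
  aa_pos <- aa_of_position(pos_c)
  span <- codon_span(transcript, aa_pos)
  ref_codon <- span$codon
  offset_in_codon <- pos_c - span$c_start + 1L
  alt_codon <- ref_codon
  substring(alt_codon, offset_in_codon, offset_in_codon) <- alt
  ref_aa <- unname(GENETIC_CODE_1[ref_codon])
  alt_aa <- unname(GENETIC_CODE_1[alt_codon])
  consequence <- if (ref_aa == alt_aa) "synonymous"
                 else if (ref_aa == "*" || alt_aa == "*") "other"
                 else "nonsynonymous"
  tibble(consequence = consequence, aa_pos = aa_pos,
         ref_aa = ref_aa, alt_aa = alt_aa,
         protein_change = paste0("p.", ref_aa, aa_pos, alt_aa))
}

#' Classify the CpG-site impact of a substitution
#'
#' A substitution affects a CpG dinucleotide only through the two pairs that
#' include the substituted base, so the one-base context on each side is
#' sufficient. The reference window (`ctx_5p, ref, ctx_3p`) and alternate
#' window (`ctx_5p, alt, ctx_3p`) are scanned for a `CG` overlapping the
#' variant base: present before but not after is `disrupted`; after but not
#' before is `gained`; both or neither is `none`. Because the reverse
#' complement of `CG` is `CG`, the call is strand-symmetric. If a context
#' base needed to decide is `"unknown"` (or `NA`) the call is
#' `indeterminate` — sequence is never guessed.
#'
#' All arguments are vectorised.
#'
#' @param ref,alt Reference and alternate bases.
#' @param ctx_5p,ctx_3p One-base context on each side, or `"unknown"`.
#' @return Character vector in
#'   `c("disrupted", "gained", "none", "indeterminate")`.
#' @export
#' @examples
#' classify_cpg_impact("G", "A", "C", "T")  # CG -> CA: disrupted
#' classify_cpg_impact("T", "C", "A", "G")  # TG -> CG: gained
classify_cpg_impact <- function(ref, alt, ctx_5p, ctx_3p) {
  ref <- toupper(ref); alt <- toupper(alt)
  norm <- function(x) {
    x <- toupper(as.character(x))
    x[!x %in% BASES] <- NA_character_
    x
  }
  c5 <- norm(ctx_5p); c3 <- norm(ctx_3p)
  if (any(!ref %in% BASES) || any(!alt %in% BASES) || any(ref == alt)) {
    abort("ref and alt must be distinct bases in A/C/G/T",
          class = "cpgburden_variant_error")
  }
  ## Kleene three-valued logic: NA context propagates exactly when the
  ## unknown base could flip the call
  cg_with <- function(base) (c5 == "C" & base == "G") | (base == "C" & c3 == "G")
  ref_cg <- cg_with(ref)
  alt_cg <- cg_with(alt)
  out <- dplyr::case_when(
    is.na(ref_cg) | is.na(alt_cg) ~ "indeterminate",
    ref_cg & !alt_cg ~ "disrupted",
    !ref_cg & alt_cg ~ "gained",
    TRUE ~ "none"
  )
  out
}

#' Annotate a table of variant observations
#'
#' Data-frame-in, data-frame-out composition of [classify_consequence()],
#' [classify_cpg_impact()] and region membership. Rows must carry
#' `pos_c`, `ref`, `alt`; context columns `ctx_5p`/`ctx_3p` are used when
#' present and non-`NA`, otherwise derived from the transcript via
#' [context_at()] (exon-edge positions without a stored flank come back
#' `"unknown"` and annotate `indeterminate`).
#'
#' @param variants Data frame of variant rows (one per observation; repeated
#'   variants are fine).
#' @param transcript A [transcript_model()].
#' @param region Region name used for the `in_region` flag; default `"CTRD"`
#'   when registered on the transcript, else no flag is added.
#' @return The input tibble with added columns `consequence`, `aa_pos`,
#'   `ref_aa`, `alt_aa`, `protein_change`, `cpg_impact`, and (when a region
#'   is available) `in_region`.
#' @export
annotate_variants <- function(variants, transcript, region = "CTRD") {
  stopifnot(inherits(transcript, "transcript_model"))
  variants <- as_tibble(variants)
  req <- c("pos_c", "ref", "alt")
  if (!all(req %in% names(variants))) {
    abort("variants need columns pos_c, ref, alt",
          class = "cpgburden_io_error")
  }
  if (nrow(variants) == 0L) {
    out <- mutate(variants, consequence = character(), aa_pos = integer(),
                  ref_aa = character(), alt_aa = character(),
                  protein_change = character(), cpg_impact = character())
    if (!is.null(transcript$regions) && region %in% transcript$regions$region)
      out$in_region <- logical()
    return(out)
  }
  ## fill missing context from the transcript
  if (!"ctx_5p" %in% names(variants)) variants$ctx_5p <- NA_character_
  if (!"ctx_3p" %in% names(variants)) variants$ctx_3p <- NA_character_
  derived <- context_at(transcript, variants$pos_c)
  variants$ctx_5p <- dplyr::coalesce(variants$ctx_5p, derived$ctx_5p)
  variants$ctx_3p <- dplyr::coalesce(variants$ctx_3p, derived$ctx_3p)

  cons <- purrr::pmap_dfr(
    list(variants$pos_c, variants$ref, variants$alt),
    function(p, r, a) classify_consequence(transcript, p, r, a))
  out <- bind_cols(variants, cons)
  out$cpg_impact <- classify_cpg_impact(out$ref, out$alt,
                                        out$ctx_5p, out$ctx_3p)
  if (!is.null(transcript$regions) &&
      region %in% transcript$regions$region) {
    out$in_region <- in_region(transcript, out$aa_pos, region)
  }
  out
}
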