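# Fixtures built in code: a transcript with the codon layout of the
# published screening region (CGN arginine codons at the known variant
# sites), and the published per-stratum allele counts, so table-building
# and statistics can be checked against printed values.

# 1200-codon transcript; filler GCT (Ala) with specific codons planted so
# the classic variants fall where their c./p. names say:
#   codon 935 GAT (+ codon 936 starting G)  -> c.2805 T>C  p.D935D, CpG gain
#   codon 952 CGC                           -> c.2855 G>A  p.R952H, CpG loss
#   codon 987 CCG                           -> c.2961 G>A  p.P987P, CpG loss
#   codon 1048 CGG                          -> c.3142 C>T  p.R1048W, CpG loss
#   codon 1049 CGC                          -> c.3145 C>T  p.R1049C, CpG loss
paper_like_transcript <- function() {
  codons <- rep("GCT", 1200)
  codons[1] <- "ATG"
  codons[935] <- "GAT"
  codons[936] <- "GGT"
  codons[952] <- "CGC"
  codons[987] <- "CCG"
  codons[1048] <- "CGG"
  codons[1049] <- "CGC"
  transcript_model(
    paste(codons, collapse = ""),
    transcript_id = "TX_MAIN", protein_id = "PX_MAIN",
    regions = data.frame(region = c("CTRD", "ISO"),
                         start_aa = c(894, 1022), end_aa = c(1086, 1037)),
    offsets = data.frame(from_id = "TX_MAIN", to_id = "TX_ALT",
                         c_offset = 69L, p_offset = 23L)
  )
}

fc_manifest <- function() {
  tibble::tibble(
    stratum = c("FC_case", "FC_control"),
    ancestry = c("FC", "FC"),
    role = c("case", "control"),
    n_individuals = c(427L, 1214L)
  )
}

# published targeted-screening observations for the ASD stratum:
# carrier allele counts per variant in cases and matched controls
fc_observations <- function() {
  v <- tibble::tibble(
    pos_c = c(2855L, 2961L, 3142L, 3145L),
    ref   = c("G", "G", "C", "C"),
    alt   = c("A", "A", "T", "T"),
    rs_id = c("rs142740233", "rs550491448", "rs369042030", NA),
    case_carriers    = c(2L, 1L, 1L, 1L),
    control_carriers = c(5L, 0L, 0L, 1L),
    maf_reference = c(0.0021, NA, NA, 4.12e-6)
  )
  dplyr::bind_rows(
    dplyr::mutate(v, stratum = "FC_case", carrier_alleles = case_carriers),
    dplyr::mutate(v, stratum = "FC_control",
                  carrier_alleles = control_carriers)
  ) |>
    dplyr::filter(carrier_alleles > 0L) |>
    dplyr::mutate(transcript_id = "TX_MAIN") |>
    dplyr::select(transcript_id, pos_c, ref, alt, rs_id, stratum,
                  carrier_alleles, maf_reference)
}

# the three published targeted-region strata as a table tibble
ctrd_all_tables <- function() {
  tibble::tibble(
    ancestry = c("FC", "EA", "AA"),
    a = c(5L, 12L, 2L), b = c(849L, 3772L, 162L),
    c = c(6L, 14L, 32L), d = c(2422L, 8586L, 4374L)
  )
}

ctrd_cpg_tables <- function() {
  tibble::tibble(
    ancestry = c("FC", "EA", "AA"),
    a = c(5L, 11L, 2L), b = c(849L, 3773L, 162L),
    c = c(6L, 9L, 29L), d = c(2422L, 8591L, 4377L)
  )
}

fullgene_cpg_split <- function() {
  tibble::tibble(
    ancestry = c("EA", "AA"),
    a = c(41L, 8L), b = c(9L, 1L),
    c = c(72L, 122L), d = c(42L, 46L)
  )
}

complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", unknown = "unknown")[x]
}
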