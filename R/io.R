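#' Read a transcript model from FASTA + exon table + metadata
#'
#' The on-disk dialect is: a single-record FASTA holding the spliced CDS; a
#' TSV exon table (`exon_index`, `c_start`, `c_end`, optional `flank_5p`,
#' `flank_3p`); and a YAML metadata file with keys `transcript_id`,
#' `protein_id`, optional `regions` (name -> `[start_aa, end_aa]`) and
#' optional `offsets` (list of `{from_id, to_id, c_offset, p_offset}`).
#'
#' @param fasta Path to the CDS FASTA.
#' @param exons Path to the exon TSV.
#' @param meta Path to the YAML metadata.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(fasta, exons, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    abort("CDS FASTA must contain exactly one record",
          class = "cpgburden_io_error")
  }
  cds <- as.character(seqs[[1]])
  ex <- readr::read_tsv(exons, show_col_types = FALSE,
                        col_types = readr::cols(
                          exon_index = "i", c_start = "i", c_end = "i",
                          .default = "c"))
  md <- yaml::read_yaml(meta)
  regions <- NULL
  if (!is.null(md$regions) && length(md$regions)) {
    regions <- tibble(
      region = names(md$regions),
      start_aa = unname(vapply(md$regions,
                               function(r) as.integer(r[[1]]), 1L)),
      end_aa = unname(vapply(md$regions,
                             function(r) as.integer(r[[2]]), 1L))
    )
  }
  offsets <- NULL
  if (!is.null(md$offsets) && length(md$offsets)) {
    offsets <- purrr::map_dfr(md$offsets, ~tibble(
      from_id = .x$from_id, to_id = .x$to_id,
      c_offset = as.integer(.x$c_offset), p_offset = as.integer(.x$p_offset)))
  }
  transcript_model(cds, transcript_id = md$transcript_id,
                   protein_id = md$protein_id %||% NA_character_,
                   exons = ex, regions = regions, offsets = offsets)
}

#' Write a transcript model to FASTA + exon table + metadata
#'
#' Inverse of [read_transcript_model()]; files are written under `dir` as
#' `cds.fasta`, `exons.tsv`, `transcript.yaml`.
#'
#' @param transcript A [transcript_model()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_transcript_model <- function(transcript, dir) {
  stopifnot(inherits(transcript, "transcript_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "cds.fasta"),
                exons = file.path(dir, "exons.tsv"),
                meta = file.path(dir, "transcript.yaml"))
  seq <- Biostrings::DNAStringSet(setNames(transcript$cds,
                                           transcript$transcript_id))
  Biostrings::writeXStringSet(seq, paths$fasta, width = 70L)
  readr::write_tsv(transcript$exons, paths$exons)
  md <- list(transcript_id = transcript$transcript_id,
             protein_id = transcript$protein_id)
  if (!is.null(transcript$regions)) {
    md$regions <- setNames(
      purrr::map2(transcript$regions$start_aa, transcript$regions$end_aa, c),
      transcript$regions$region)
  }
  if (!is.null(transcript$offsets)) {
    md$offsets <- purrr::pmap(transcript$offsets, list)
  }
  yaml::write_yaml(md, paths$meta)
  invisible(paths)
}

#' Read variant observations
#'
#' Observations are one row per (variant, stratum): columns `transcript_id`,
#' `pos_c`, `ref`, `alt`, `ctx_5p`, `ctx_3p`, `rs_id`, `stratum`,
#' `carrier_alleles`, `maf_reference`. `maf_reference` is the
#' ancestry-matched reference minor-allele fraction used by [filter_rare()]
#' (`NA` = unknown, treated as rare).
#'
#' @param path Path to the observations TSV.
#' @return A tibble.
#' @export
read_observations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    transcript_id = "c", pos_c = "i", ref = "c", alt = "c",
    ctx_5p = "c", ctx_3p = "c", rs_id = "c", stratum = "c",
    carrier_alleles = "i", maf_reference = "d"))
}

#' Read a stratum manifest
#'
#' One row per cohort stratum: `stratum` (unique label), `ancestry`
#' (pairing key, e.g. FC/EA/AA), `role` (`case` or `control`),
#' `n_individuals`. Allele totals are always `2 * n_individuals`.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stratum = "c", ancestry = "c", role = "c",
                           n_individuals = "i"))
  validate_manifest(man)
}

validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  req <- c("stratum", "ancestry", "role", "n_individuals")
  if (!all(req %in% names(manifest))) {
    abort("manifest needs columns stratum, ancestry, role, n_individuals",
          class = "cpgburden_io_error")
  }
  if (!all(manifest$role %in% c("case", "control"))) {
    abort("manifest role must be 'case' or 'control'",
          class = "cpgburden_io_error")
  }
  if (anyDuplicated(manifest$stratum)) {
    abort("manifest stratum labels must be unique",
          class = "cpgburden_io_error")
  }
  if (any(manifest$n_individuals < 1L)) {
    abort("manifest n_individuals must be >= 1",
          class = "cpgburden_io_error")
  }
  mutate(manifest, n_alleles = 2L * .data$n_individuals)
}
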