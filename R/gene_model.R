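#' Build a coding-transcript model
#'
#' A `transcript_model` carries everything the annotation and burden steps
#' need to know about one coding transcript: the spliced coding sequence
#' (CDS), the exon structure expressed in CDS coordinates, optional one-base
#' intronic flanks at each exon edge (used only to decide CpG context across
#' an exon boundary), named protein-coordinate regions (for example a
#' C-terminal regulatory domain), and coordinate offsets to sibling isoforms.
#'
#' All nucleotide coordinates are 1-based, inclusive, HGVS-c.-style positions
#' on the coding sequence; protein coordinates are 1-based residue indices.
#' Genomic and UTR coordinates are deliberately out of scope.
#'
#' @param cds Character scalar, the coding sequence (A/C/G/T only); its
#'   length must be a multiple of 3.
#' @param transcript_id Accession string naming the transcript.
#' @param protein_id Accession string naming the encoded protein.
#' @param exons Data frame with columns `exon_index`, `c_start`, `c_end` and
#'   optionally `flank_5p`, `flank_3p` (single intronic bases, or `NA` when
#'   unknown). Spans must be non-overlapping, ordered, and partition
#'   `1..nchar(cds)`. Defaults to a single exon covering the whole CDS.
#' @param regions Data frame with columns `region`, `start_aa`, `end_aa`
#'   naming protein-coordinate spans, or `NULL`.
#' @param offsets Data frame with columns `from_id`, `to_id`, `c_offset`,
#'   `p_offset` describing fixed coordinate shifts to other isoforms
#'   (`c_offset` must equal `3 * p_offset`), or `NULL`.
#'
#' @return An object of class `transcript_model`.
#' @seealso [read_transcript_model()], [codon_span()], [in_region()]
#' @export
#' @examples
#' tx <- transcript_model("ATGCGCTAA", "TX1", "PX1",
#'                        regions = data.frame(region = "CTRD",
#'                                             start_aa = 2, end_aa = 3))
#' codon_span(tx, 2)
transcript_model <- function(cds, transcript_id, protein_id = NA_character_,
                             exons = NULL, regions = NULL, offsets = NULL) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    abort(sprintf("CDS length (%d) must be a positive multiple of 3", n),
          class = "cpgburden_model_error")
  }
  if (grepl("[^ACGT]", cds)) {
    abort("CDS may contain only A/C/G/T", class = "cpgburden_model_error")
  }
  if (is.null(exons)) {
    exons <- tibble(exon_index = 1L, c_start = 1L, c_end = n)
  }
  exons <- as_tibble(exons)
  req <- c("exon_index", "c_start", "c_end")
  if (!all(req %in% names(exons))) {
    abort("exon table needs columns exon_index, c_start, c_end",
          class = "cpgburden_model_error")
  }
  if (!"flank_5p" %in% names(exons)) exons$flank_5p <- NA_character_
  if (!"flank_3p" %in% names(exons)) exons$flank_3p <- NA_character_
  exons <- arrange(exons, .data$c_start)
  if (exons$c_start[1] != 1L || exons$c_end[nrow(exons)] != n ||
      (nrow(exons) > 1L &&
       any(exons$c_start[-1] != exons$c_end[-nrow(exons)] + 1L))) {
    abort("exon spans must partition 1..nchar(cds)",
          class = "cpgburden_model_error")
  }
  n_aa <- n %/% 3L
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    if (!all(c("region", "start_aa", "end_aa") %in% names(regions))) {
      abort("regions need columns region, start_aa, end_aa",
            class = "cpgburden_model_error")
    }
    if (any(regions$start_aa < 1L | regions$end_aa > n_aa |
            regions$start_aa > regions$end_aa)) {
      abort("region spans must lie within 1..nchar(cds)/3",
            class = "cpgburden_model_error")
    }
  }
  if (!is.null(offsets)) {
    offsets <- as_tibble(offsets)
    if (!all(c("from_id", "to_id", "c_offset", "p_offset") %in%
             names(offsets))) {
      abort("offsets need columns from_id, to_id, c_offset, p_offset",
            class = "cpgburden_model_error")
    }
    if (any(offsets$c_offset != 3L * offsets$p_offset)) {
      abort("isoform offsets must satisfy c_offset = 3 * p_offset",
            class = "cpgburden_model_error")
    }
  }
  structure(
    list(transcript_id = transcript_id, protein_id = protein_id, cds = cds,
         exons = exons, regions = regions, offsets = offsets),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id,
      if (!is.na(x$protein_id)) paste0(" (", x$protein_id, ")"), "\n",
      sep = "")
  cat("  CDS: ", nchar(x$cds), " nt / ", nchar(x$cds) %/% 3L, " codons, ",
      nrow(x$exons), " exon(s)\n", sep = "")
  if (!is.null(x$regions)) {
    cat("  regions: ",
        paste0(x$regions$region, " [", x$regions$start_aa, "-",
               x$regions$end_aa, "]", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Codon span and sequence for a protein position
#'
#' Maps a 1-based residue index to the CDS coordinates of its codon and
#' returns the codon sequence.
#'
#' @param transcript A [transcript_model()].
#' @param aa_index Vector of 1-based residue indices.
#' @return A tibble with columns `aa_index`, `c_start`, `c_end`, `codon`.
#' @export
#' @examples
#' tx <- transcript_model("ATGCGCTAA", "TX1")
#' codon_span(tx, 1:2)
codon_span <- function(transcript, aa_index) {
  stopifnot(inherits(transcript, "transcript_model"))
  n_aa <- nchar(transcript$cds) %/% 3L
  aa_index <- as.integer(aa_index)
  if (any(is.na(aa_index)) || any(aa_index < 1L | aa_index > n_aa)) {
    abort(sprintf("aa_index out of range 1..%d", n_aa),
          class = "cpgburden_bounds_error")
  }
  c_start <- 3L * (aa_index - 1L) + 1L
  tibble(aa_index = aa_index, c_start = c_start, c_end = c_start + 2L,
         codon = substring(transcript$cds, c_start, c_start + 2L))
}

#' Residue index of a CDS position
#'
#' @param pos_c Vector of 1-based CDS coordinates.
#' @return Integer vector of 1-based residue indices.
#' @export
aa_of_position <- function(pos_c) {
  (as.integer(pos_c) - 1L) %/% 3L + 1L
}

#' Construct an isoform coordinate offset
#'
#' A fixed shift between the coding coordinates of two isoforms of the same
#' gene (e.g. a longer isoform whose numbering runs 69 nt / 23 residues
#' ahead). The invariant `c_offset == 3 * p_offset` is enforced.
#'
#' @param from_id,to_id Accession strings.
#' @param c_offset Signed nucleotide offset.
#' @param p_offset Signed residue offset.
#' @return A list of class `isoform_offset`.
#' @export
isoform_offset <- function(from_id, to_id, c_offset, p_offset = c_offset / 3) {
  if (c_offset != 3 * p_offset) {
    abort("c_offset must equal 3 * p_offset", class = "cpgburden_model_error")
  }
  structure(list(from_id = from_id, to_id = to_id,
                 c_offset = as.integer(c_offset),
                 p_offset = as.integer(p_offset)),
            class = "isoform_offset")
}

#' Map a coding coordinate onto a sibling isoform
#'
#' @param pos_c Vector of CDS coordinates in the source isoform.
#' @param offset An [isoform_offset()], or a bare integer nucleotide offset.
#' @return Vector of CDS coordinates in the target isoform.
#' @export
#' @examples
#' map_isoform(2855, isoform_offset("NM_A", "NM_B", 69, 23))  # 2924
map_isoform <- function(pos_c, offset) {
  c_off <- if (inherits(offset, "isoform_offset")) offset$c_offset
           else as.integer(offset)
  out <- as.integer(pos_c) + c_off
  if (any(out < 1L)) {
    abort("mapped position < 1: offset leaves the target coding sequence",
          class = "cpgburden_bounds_error")
  }
  out
}

#' Invert an isoform offset
#' @param offset An [isoform_offset()].
#' @return The reverse [isoform_offset()].
#' @export
invert_offset <- function(offset) {
  stopifnot(inherits(offset, "isoform_offset"))
  isoform_offset(offset$to_id, offset$from_id,
                 -offset$c_offset, -offset$p_offset)
}

#' Test membership of a residue in a named region
#'
#' @param transcript A [transcript_model()] with registered regions.
#' @param aa_index Vector of residue indices.
#' @param region Region name registered on the transcript.
#' @return Logical vector.
#' @export
#' @examples
#' tx <- transcript_model(strrep("GCT", 1000), "TX1",
#'                        regions = data.frame(region = "CTRD",
#'                                             start_aa = 894, end_aa = 1000))
#' in_region(tx, c(893, 894), "CTRD")
in_region <- function(transcript, aa_index, region) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (is.null(transcript$regions) ||
      !region %in% transcript$regions$region) {
    abort(sprintf("region '%s' is not registered on %s", region,
                  transcript$transcript_id),
          class = "cpgburden_config_error")
  }
  r <- transcript$regions[transcript$regions$region == region, ][1, ]
  aa_index >= r$start_aa & aa_index <= r$end_aa
}

#' Translate a coding sequence
#'
#' Codon-by-codon lookup in the standard genetic code; stop codons render
#' as `*`.
#'
#' @param cds Character scalar, length a multiple of 3.
#' @return Character scalar amino-acid sequence.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3L == 0L)
  starts <- seq(1L, nchar(cds), by = 3L)
  paste(GENETIC_CODE_1[substring(cds, starts, starts + 2L)], collapse = "")
}

#' One-base sequence context around a CDS position
#'
#' Returns the bases immediately 5' and 3' of `pos_c`. Within an exon these
#' come from the CDS itself; at an exon edge the stored intronic flank base
#' is used, and `"unknown"` is returned when no flank was supplied. Variants
#' whose CpG context is `"unknown"` on the needed side annotate as
#' `indeterminate` rather than guessing sequence.
#'
#' @param transcript A [transcript_model()].
#' @param pos_c Vector of CDS coordinates.
#' @return A tibble with columns `ctx_5p`, `ctx_3p`.
#' @export
context_at <- function(transcript, pos_c) {
  stopifnot(inherits(transcript, "transcript_model"))
  pos_c <- as.integer(pos_c)
  n <- nchar(transcript$cds)
  if (any(pos_c < 1L | pos_c > n)) {
    abort("pos_c outside the coding sequence",
          class = "cpgburden_bounds_error")
  }
  ex <- transcript$exons
  exon_of <- findInterval(pos_c, ex$c_start)
  one <- function(p, e) {
    c5 <- if (p == ex$c_start[e]) ex$flank_5p[e] %|na|% "unknown"
          else substring(transcript$cds, p - 1L, p - 1L)
    c3 <- if (p == ex$c_end[e]) ex$flank_3p[e] %|na|% "unknown"
          else substring(transcript$cds, p + 1L, p + 1L)
    c(c5, c3)
  }
  ctx <- mapply(one, pos_c, exon_of)
  tibble(ctx_5p = ctx[1, ], ctx_3p = ctx[2, ])
}
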