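test_that("coding consequences of the classic screening variants", {
  tx <- paper_like_transcript()
  r <- classify_consequence(tx, 2855, "G", "A")  # CGC -> CAC
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$protein_change, "p.R952H")
  r <- classify_consequence(tx, 2961, "G", "A")  # CCG -> CCA
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$protein_change, "p.P987P")
  r <- classify_consequence(tx, 2805, "T", "C")  # GAT -> GAC
  expect_equal(r$consequence, "synonymous")
  expect_equal(r$protein_change, "p.D935D")
  r <- classify_consequence(tx, 3142, "C", "T")  # CGG -> TGG
  expect_equal(r$protein_change, "p.R1048W")
  r <- classify_consequence(tx, 3145, "C", "T")  # CGC -> TGC
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$protein_change, "p.R1049C")
})

test_that("consequence classifier rejects invalid input", {
  tx <- paper_like_transcript()
  expect_error(classify_consequence(tx, 2855, "C", "A"),
               class = "cpgburden_integrity_error")
  expect_error(classify_consequence(tx, 2855, "G", "G"),
               class = "cpgburden_variant_error")
  expect_error(classify_consequence(tx, 0, "G", "A"),
               class = "cpgburden_bounds_error")
})

test_that("stop involvement classifies as 'other'", {
  # TAT -> TAA is a stop gain; TGG -> TGA likewise
  tx <- transcript_model("ATGTATTGG", "T")
  expect_equal(classify_consequence(tx, 6, "T", "A")$consequence, "other")
  expect_equal(classify_consequence(tx, 9, "G", "A")$consequence, "other")
})

test_that("consequence agrees with a full-CDS translate-and-compare oracle", {
  tx <- generate_reference(17, n_codons = 150)
  n <- nchar(tx$cds)
  set.seed(170)
  for (i in 1:200) {
    pos <- sample(4:n, 1)  # skip the start codon for a cleaner oracle
    ref <- substring(tx$cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mine <- classify_consequence(tx, pos, ref, alt)
    mutated <- tx$cds
    substring(mutated, pos, pos) <- alt
    p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(tx$cds)))
    p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mutated)))
    n_diff <- sum(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
    oracle <- if (n_diff == 0) "synonymous"
              else if (grepl("\\*", p_alt)) "other"
              else "nonsynonymous"
    expect_equal(mine$consequence, oracle,
                 info = sprintf("pos %d %s>%s", pos, ref, alt))
  }
})

test_that("CpG impact matches a window-scanning oracle on all 192 cases", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(c5 = bases, ref = bases, alt = bases, c3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  expect_equal(nrow(grid), 192L)

  # independent oracle: scan the literal 3-mer for CG occurrences and keep
  # those overlapping the middle (variant) base
  scan_cg_mid <- function(w) {
    hits <- gregexpr("CG", w, fixed = TRUE)[[1]]
    any(hits %in% c(1L, 2L))  # CG at offset 1 or 2 touches position 2
  }
  oracle <- function(c5, ref, alt, c3) {
    r <- scan_cg_mid(paste0(c5, ref, c3))
    a <- scan_cg_mid(paste0(c5, alt, c3))
    if (r && !a) "disrupted" else if (!r && a) "gained" else "none"
  }
  got <- classify_cpg_impact(grid$ref, grid$alt, grid$c5, grid$c3)
  want <- mapply(oracle, grid$c5, grid$ref, grid$alt, grid$c3)
  expect_equal(got, unname(want))

  # every C>T / G>A substitution destroying an overlapping CG is 'disrupted'
  deam <- grid[(grid$ref == "C" & grid$alt == "T" & grid$c3 == "G") |
               (grid$ref == "G" & grid$alt == "A" & grid$c5 == "C"), ]
  expect_true(all(classify_cpg_impact(deam$ref, deam$alt,
                                      deam$c5, deam$c3) == "disrupted"))
})

test_that("CpG impact is strand-symmetric", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(c5 = bases, ref = bases, alt = bases, c3 = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  fwd <- classify_cpg_impact(grid$ref, grid$alt, grid$c5, grid$c3)
  # reverse complement: swap and complement the flanks, complement ref/alt
  rev <- classify_cpg_impact(complement_base(grid$ref),
                             complement_base(grid$alt),
                             complement_base(grid$c3),
                             complement_base(grid$c5))
  expect_equal(fwd, rev)
})

test_that("a substitution shifting one CG onto another nets to 'none'", {
  # CCG -> CGG: the middle C>G destroys the right-hand CG but creates a
  # left-hand one; no CpG count changes
  expect_equal(classify_cpg_impact("C", "G", "C", "G"), "none")
})

test_that("unknown context is indeterminate only when it could flip the call", {
  expect_equal(classify_cpg_impact("G", "A", "unknown", "T"),
               "indeterminate")  # a 5' C would make the ref window CG
  expect_equal(classify_cpg_impact("C", "T", "A", "unknown"),
               "indeterminate")
  # neither allele can form a CG with any context: decidable without it
  expect_equal(classify_cpg_impact("A", "T", "unknown", "unknown"), "none")
  expect_equal(classify_cpg_impact("T", "C", "A", "unknown"),
               "indeterminate")  # alt C before unknown G would be a gain
})

test_that("exactly one impact class is returned per site", {
  tx <- generate_reference(23, n_codons = 80)
  n <- nchar(tx$cds)
  set.seed(231)
  pos <- sample(seq_len(n), 50)
  ref <- substring(tx$cds, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
  ctx <- context_at(tx, pos)
  out <- classify_cpg_impact(ref, alt, ctx$ctx_5p, ctx$ctx_3p)
  expect_true(all(out %in% c("disrupted", "gained", "none", "indeterminate")))
  expect_length(out, 50)
})

test_that("annotate_variants composes classifiers, context and region flag", {
  tx <- paper_like_transcript()
  obs <- tibble::tibble(
    transcript_id = "TX_MAIN",
    pos_c = c(2855L, 2805L, 30L),
    ref = c("G", "T", "T"), alt = c("A", "C", "G")
  )
  ann <- annotate_variants(obs, tx)
  expect_equal(ann$consequence, c("nonsynonymous", "synonymous",
                                  "synonymous"))
  expect_equal(ann$protein_change[1:2], c("p.R952H", "p.D935D"))
  # R952H sits mid-codon after a C: its CpG is destroyed; D935D creates one
  expect_equal(ann$cpg_impact[1:2], c("disrupted", "gained"))
  expect_equal(ann$in_region, c(TRUE, TRUE, FALSE))
})

test_that("all four detected coding variants of the screen affect a CpG", {
  tx <- paper_like_transcript()
  ann <- annotate_variants(fc_observations(), tx)
  expect_true(all(ann$cpg_impact %in% c("disrupted", "gained")))
})

test_that("variants at an unflanked CDS end annotate indeterminate", {
  tx <- paper_like_transcript()  # single exon, no flanks
  last <- nchar(tx$cds)
  ref <- substring(tx$cds, last, last)
  alt <- setdiff(c("C", "G"), ref)[1]
  ann <- annotate_variants(
    tibble::tibble(pos_c = last, ref = ref, alt = alt), tx)
  expect_equal(ann$cpg_impact, "indeterminate")
})
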