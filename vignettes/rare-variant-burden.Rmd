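---
title: "Stratified rare-variant burden testing with CpG-site annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified rare-variant burden testing with CpG-site annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgburden)
```

## The problem

Candidate-gene studies of neurodevelopmental disorders often screen one
functionally critical region — here, the C-terminal regulatory domain
(CTRD) of the neuronal K⁺-Cl⁻ cotransporter KCC2 (*SLC12A5*), the domain
that controls the transporter's chloride-extrusion activity and hence the
developmental switch of GABA signalling from excitatory to inhibitory —
across case and control cohorts of several ancestries. Individual rare
variants are far too rare for single-site tests, so evidence is pooled
twice: across variants within a region (a collapsing burden count) and
across ancestry strata (a fixed-effect combination). Variants are further
classed by coding consequence (synonymous vs non-synonymous) and by
whether they destroy or create a CpG dinucleotide, the substrate of DNA
methylation — a synonymous variant at a CpG can still be functionally
interesting through epigenetic effects, which is precisely the signal
this analysis is designed to expose.

This vignette records the modelling choices, parameter meanings, and
numerical conventions of the package, and what the synthetic-data tests
do and do not establish.

## Coordinate model

Everything lives on the coding sequence: positions are 1-based HGVS-style
c. coordinates, residues 1-based p. indices, and `codon_span()` ties them
together (`c_start = 3(aa − 1) + 1`). Genomic coordinates are deliberately
absent — the study's variant nomenclature is entirely c./p. on two
transcript accessions, related by a fixed offset (+69 nt / +23 aa), and
choosing a genome build would add assumptions the data never use.
`map_isoform()` applies such offsets and round-trips exactly with the
inverted offset.

Exon boundaries are carried for exactly one purpose: deciding whether the
±1-base context of a variant crosses an exon edge. Context beyond an edge
must be supplied explicitly as a stored flank base; if it is not, the
context is `"unknown"` and downstream CpG classification refuses to
guess.

## Variant annotation

**Consequence.** Reference and alternate codons are translated with the
standard genetic code; identical residues are `synonymous`, differing
non-stop residues `nonsynonymous`, and any stop involvement `other`.
`other` is excluded from both the synonymous and non-synonymous tallies
(the motivating data contain no stop variants, so this never fires
there); the partition invariant `nonsynonymous + synonymous + other =
all` is tested on every synthetic cohort. A reference-base mismatch with
the transcript is a hard data-integrity error, never silently corrected.

**CpG impact.** A single-base substitution can only create or destroy a
CG dinucleotide that contains the substituted base, so the one-base
context on each side is sufficient — this is the minimal operational
reading of "disrupts or introduces a CpG site", adopted because the wider
definition would require sequence the inputs do not carry. The reference
window (5′-context, ref, 3′-context) and alternate window are each
checked for a CG overlapping the variant base: present only before is
`disrupted`, only after `gained`, both or neither `none`. A substitution
that shifts a CG (e.g. CCG→CGG) therefore nets to `none`: no CpG count
changes. Because the reverse complement of CG is CG, the rule is
strand-symmetric, which the tests verify exhaustively over all 192
context×substitution combinations against an independent window-scanning
oracle. Unknown context yields `indeterminate` exactly when the unknown
base could flip the call (three-valued logic), and indeterminate sites
are excluded from CpG-class tables with a warning.

## Cohort filtering and table construction

The rarity filter retains observations with ancestry-matched reference
MAF strictly below the threshold (default 1%); unknown MAF is retained,
since absence from reference panels is itself evidence of rarity. The
strict `<` resolves an ambiguity between "rare (<1%)" and "filtered out
>1%" phrasings in favour of the narrower class; at realistic panel sizes
no variant sits exactly on the boundary, so the choice is inert in
practice but documented.

The counting unit is **alleles** (2N per stratum), not carriers, and
multiple distinct rare variants pool by summing carrier alleles. This is
the only reading that reproduces the published per-stratum odds ratios
(e.g. 12 vs 14 variant alleles over 2×1892 and 2×4300 alleles giving
1.95), and it is the natural unit for the exact machinery, which
conditions on allele-count margins.

## Exact statistics

All 2×2 inference conditions on the table margins, under which the
case-variant count follows Fisher's noncentral hypergeometric
distribution with odds-ratio parameter ψ.

- The two-sided p-value uses the minimum-likelihood rule (sum of point
  probabilities ≤ the observed one, with a 1e−7 relative tolerance for
  floating-point ties) — the convention of the standard exact-test
  implementation, and the one that reproduces the published p-values.
- The reported odds ratio is the conditional MLE, the root of
  `E[a | ψ] = a`, solved by bisection on log ψ to 1e−8; the raw
  cross-product ratio is also exposed (`or_sample`) for transparency.
  Boundary tables give 0 or `Inf`; a table with no variant alleles at all
  has no information about ψ and returns `NA` with a warning —
  deliberately distinct from the boundary values.
- The exact CI inverts the one-sided tail tests at (1 − level)/2 per
  tail, becoming one-sided (`[L, Inf]`) at support boundaries.
- Point masses are accumulated on the log scale throughout, so the power
  search's ~10⁵-allele tables lose no precision.

The Mantel-Haenszel common odds ratio is `Σ(aᵢdᵢ/nᵢ)/Σ(bᵢcᵢ/nᵢ)` with a
Robins-Breslow-Greenland variance for the log-scale interval, and the
association test is the χ²₁ score statistic on `Σaᵢ` with the ½
continuity correction **on by default** — the corrected statistic is what
reproduces the published combined p ≈ 0.03 for the all-variants pool
(uncorrected it would print 0.02); the flag is exposed for sensitivity
analysis. In tests the whole MH block is cross-checked against
`stats::mantelhaen.test()` and the per-table statistics against
`stats::fisher.test()`, which serve only as oracles, never as the
implementation. Where the reference implementation's root-finding
tolerance limits agreement (its CI bounds can miss the nominal 0.025 tail
by ~10⁻³ relative; ours hit it to 1e−8), the cross-check tolerance
reflects the reference's precision, not ours.

Two printed values in the motivating tables verify only to one unit in
the last printed digit: the screening-stratum OR prints 2.37 where the
conditional MLE is 2.3766 (both our implementation and the reference
agree; the printed figure appears truncated), and one single-variant p
prints 0.50 where the exact value is 0.4877. The combined-synonymous OR
is not asserted anywhere: recomputing it from the printed counts gives
≈4.95 against a printed 4.93, a discrepancy that cannot be resolved from
the published numbers alone.

## Power for rare alleles

The power question is inverted from the usual design setting: given an
observed case count (say one variant allele in 854) and a control carrier
count held fixed, how many control alleles N must be genotyped before the
exact test reaches α? Holding the control *count* fixed — rather than the
control frequency — is the model that reproduces both published
requirements (≈5×10⁴ alleles with zero control carriers, ≈10⁵ with one);
the alternative "frequency stays constant" reading is internally
inconsistent with those figures, since a fixed nonzero frequency adds
carriers as N grows and significance would never improve.

The search doubles N until `p ≤ α`, refines by bisection, and verifies
minimality at N−1; it starts at the smallest N where the implied control
frequency does not exceed the case frequency, so "significance" at tiny N
driven by control enrichment (the wrong tail) is never returned. With
zero control carriers and a single case carrier the two-sided p is
`case_total/(case_total + N)` once `N > case_total`, giving the closed
form `⌈case_total (1 − α)/α⌉` that the search must reproduce exactly —
the property tests assert this on the α ≤ 0.1 regime where the closed
form is valid (for α ≳ 0.5 the observed table is modal and the two-sided
p is 1 until N exceeds the case total, a regime no real design occupies).
The default α is the Bonferroni-adjusted level `alpha_family/m` (0.05/3
for three disease cohorts, printed as 0.0167).

## The synthetic study generator

`generate_reference()` builds a CGN(arginine)-enriched CDS — the feature
that makes the real target CpG-dense, since CGN codons carry a CpG
within the codon and arginine mutability at those sites is exactly what
the annotation module classifies — with no internal stop codons, five
exons with one-base intronic flanks (outermost flanks deliberately
unknown, exercising the indeterminate path), a CTRD-like region on the 3′
third of the protein, an ISO-like subdomain inside it, and a +69/+23
isoform offset. Defaults: 1200 codons (the scale of a large transporter
CDS) and a 0.15 CGN fraction.

`generate_cohort()` realises requested (consequence, CpG-class) site
specifications at the nearest achievable CDS positions — the generator is
the annotator's adversarial fixture: re-annotating its output must
reproduce the requested labels for 100% of sites, and a CDS that cannot
host a requested class raises an error naming the position. Carrier
alleles are drawn as Binomial(2N, freq) per stratum, the appropriate
regime when cohort sizes dwarf carrier counts (hypergeometric
finite-population corrections would be ~10⁻³ here); a configurable
fraction of sites is made common (reference MAF > 1%) to exercise the
rarity filter. The default strata are the study sizes the package
targets — 427/1214, 1892/4300 and 82/2203 case/control individuals — with
ten sites at allele frequencies 0.04–0.7%, the observed range. A single
seed drives everything through a documented split (seed for the
reference, seed+1 for the cohort draw), and identical specs produce
byte-identical files.

What passing synthetic tests shows: the pipeline's bookkeeping
(annotation, filtering, collapsing, margins), the statistics' calibration
(MH interval coverage ≥ 90% over 100 replicates at true OR 1 and 2.5),
and exact agreement with enumeration oracles. What it does not show:
robustness to sequencing artefacts, genotype-quality filtering,
population stratification within ancestry labels, linkage between sites,
or cross-pipeline batch effects between case and control call sets — the
last being the recognised caveat of comparing independently processed
exome datasets. Real-data use stands on the file interfaces (FASTA +
exon TSV + YAML; observation/manifest TSVs), not on the generator.

## Reporting conventions

Report tables use fixed formats so reruns are byte-identical: p and OR to
two decimals, CI bounds to one, frequencies as percentages to two
decimals, the literal `Inf` for infinite bounds, and p < 0.01 in
scientific notation with a one-decimal mantissa (`6.8 x 10^-3`). Rows are
ordered by the manifest's ancestry order and variant name. The power
answer is reported both exactly and at two significant figures, the
precision at which such requirements are conventionally quoted.

## Problem sizes in the test suite

The suite runs the exhaustive Fisher-oracle sweep over all margin sets
with n ≤ 60 in the acceptance properties (≈630k tables) and n ≤ 40 in the
unit tests, 200 random SNVs against the full-CDS translation oracle, all
192 CpG context cases, 100-replicate coverage checks at two true odds
ratios, and 100-seed recovery of a simulated common OR of 3 — sizes at
which every check is exact or has negligible Monte-Carlo error while the
whole suite stays in the low minutes on one core.

## Known limitations

Only single-nucleotide substitutions are modelled (no indels, MNVs, or
splice variants); the HGVS surface is the c.POS REF>ALT / p.XposY subset;
pathogenicity prediction is out of scope (external annotations pass
through untouched); no de-novo/inherited phasing; and the Mantel-Haenszel
combination assumes a common odds ratio across strata — no homogeneity
test is provided, matching the analysis it reimplements.
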