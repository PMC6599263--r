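---
title: "Tracking mutational and neoantigen evolution in colorectal cancer models"
author: "crcevo developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking mutational and neoantigen evolution in colorectal cancer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcevo)
```

## The problem

Colorectal cancers (CRC) with defects in DNA repair — loss of mismatch
repair (MLH1, MSH2, MSH6, PMS2; microsatellite-unstable, MSI), proofreading
mutations in polymerase epsilon (*POLE*), or base-excision-repair lesions
(*MUTYH*, *EXO1*) — do not merely carry many mutations: they keep acquiring
them. Serially sampling the same model (a cell line at day 0 and day 90, a
xenograft, or a patient-derived xenograft across generations F1–F4) turns
the mutation catalog into a time series. From that series one can measure
the per-day rate of newly acquired somatic alterations, watch subclones
appear and disappear, track which mutational processes remain active, and
ask how the predicted neoantigen repertoire — the immunologically visible
surface of the genome — turns over.

`crcevo` implements that longitudinal analysis as a set of small, pure
stages, plus a seeded synthetic-data generator that emulates the four
DNA-repair states so every stage is testable offline.

## Variant filtering

Somatic calls are filtered by three predicates, applied in order:

1. **Strand support.** Alleles supported by reads on only one strand are
   discarded; strand counting excludes read-terminal positions
   (`alt_fwd >= 1 AND alt_rev >= 1`).
2. **Allelic frequency and read support.** A variant is kept iff its
   allelic frequency (alt reads / depth) is at least 10% *and* the exact
   binomial upper tail `P(X >= alt_count)` with
   `X ~ Binomial(depth, error_rate)` is at most 0.05. The binomial null is
   a per-read error rate; its value is not dictated by any published
   pipeline description we re-implement, so it is a configurable parameter
   with default 0.01 — the test asks "could sequencing noise at 1% per-read
   error produce this much alt support?". Both bounds are closed (`>=`
   10%, `<=` 0.05): the exclusion rule is stated for the complements
   ("lower than", "greater than"), and we take that wording literally.
3. **Key lists.** Variants whose `(chrom, pos, ref, alt)` key appears in a
   common-SNP database or a panel of normals are removed as germline or
   recurrent artifacts.

Variant identity is the exact `(chrom, pos, ref, alt)` tuple, 1-based VCF
convention, one alt per record (multi-allelic records must be decomposed).
Indels are not re-normalised: all catalogs compared by this package come
from one calling pipeline (or from the bundled generator), where the
representation is consistent. The cascade is a pure predicate — idempotent
and order-independent — and the test suite checks it against a brute-force
conjunction oracle on randomized catalogs.

## Subtraction and lineage tracking

`subtract_catalogs(later, earlier)` splits keys into **gained** (only
later), **lost** (only earlier), and **shared**, retaining both allelic
frequencies for shared keys so clonal (trunk, AF near 50%) and subclonal
variants can be distinguished downstream. Over a lineage tree
(`lineage_subtract`), each generation is compared to its immediate parent —
F2 against F1, F3 against F2, and so on — with the root reported as
baseline. Two algebraic identities pin the semantics down and are tested
property-style: gained and lost are disjoint and reconstruct the inputs
together with the shared set; and replaying per-generation gains/losses
from the root reconstructs the leaf catalog (telescoping).

## Burden, selection, rate

* `tmb()`: coding alterations per megabase. The coding footprint is a
  parameter (default 38 Mb, a typical human exome capture) because the
  denominator used for any particular published number is rarely stated.
* `ns_s_ratio()`: (missense + nonsense + frameshift) / synonymous, the
  crude selection readout used to contrast in-vitro passaging (neutral,
  around 3:1 — the genetic code's own NS:S balance) with in-vivo passaging
  (purifying selection pushes it down). Zero synonymous counts yield an
  explicit "undefined" flag, never a division error.
* `doubling_time(n, t) = t / n` and `growth_rate(dt) = ln(2) / dt`: the
  exponential-growth model with a fixed number of cells per plate at
  confluence; the split ratio cancels, making both formulas
  base-independent ratios. The shipped growth table
  (`inst/extdata/cell_line_growth.tsv`) reproduces the printed growth rate
  from the printed doubling time to 2 decimals in 42/45 rows; the three
  discrepant rows are exactly the ones where rounding the doubling time to
  2 decimals crosses the growth-rate rounding boundary, i.e. the printed
  growth rates were computed from unrounded doubling times. The regression
  test therefore uses the analytic error bound
  `0.005 + ln(2) * 0.005 / DT^2` rather than exact equality.
* `mutation_rate()` and `classify_evolvability()`: gained alterations per
  day, with the **EVOLVING** label at a closed bound of at least 10
  alterations/day (configurable). "Normalising to doubling time" is
  arithmetically the same as dividing by calendar days (gained /
  (doublings x DT) = gained / t), so the per-day rate is primary; a
  per-doubling rate is reported alongside for transparency.

## Mutational spectra and signature refitting

SNVs are binned into the canonical 96 trinucleotide channels: six
pyrimidine-centric substitution subtypes (C>A, C>G, C>T, T>A, T>C, T>G)
crossed with the 5' and 3' flanking bases; purine-reference SNVs are
reverse-complemented (allele and flanks) before binning; indels are
ignored; SNVs without context (contig edge) are skipped and tallied, so
`sum(spectrum) + skipped` always equals the SNV count.

Refitting against a signature matrix is nonnegative least squares on the
raw counts (Lawson–Hanson active set, implemented in the package and tested
against a brute-force support-set oracle). Published pipelines in this
space typically delegate refitting to external services whose algorithm is
not documented; NNLS is the standard, deterministic choice for refitting
known signatures to a catalog. Samples with fewer than 10 mutations are
refused outright — below that, contributions are noise. Exposure profiles
are clustered with the Euclidean metric and average linkage
(`stats::hclust`; ties merge lowest-index first, so trees are deterministic
under a fixed input order).

The package bundles six deterministic synthetic signatures (`clock_ct`,
`mmr_ct`, `pole_ca`, `mutyh_ca`, `apobec`, `flat`) whose shapes mimic the
repair-deficiency-relevant processes without being the canonical human
catalog; a real 96 x S matrix in the documented TSV layout is accepted
anywhere a signature matrix is taken. Nothing is downloaded at test time.

## Neoantigen candidates

For each gained, protein-altering variant the corresponding cDNA is edited
(`mutate_cdna`), translated (halting at the first stop codon, no
readthrough), and every 8–11-mer of the mutant protein that covers an
altered residue is enumerated — at most 8+9+10+11 = 38 peptides for an
interior missense change; for frameshifts, every peptide overlapping the
novel frame from the variant codon to the first stop. Peptides identical
to a wild-type k-mer are excluded: the term neoantigen presupposes absence
from the unmutated proteome, and the window-restricted enumeration plus
wild-type subtraction provably equals the exhaustive mutant-minus-wild-type
k-mer set difference (tested against that oracle).

Binding prediction is pluggable: any `function(peptide, allele) ->
percentile rank`. The bundled `mock_predictor()` is a seeded hash —
deterministic, uniform on [0, 100) — so the full pipeline runs and is
testable without external MHC software; a wrapper around a real predictor
drops in unchanged. Candidates must satisfy **rank < 0.5** (strict) and
**FPKM > 10** (strict); variants in genes absent from the expression table
are dropped with a warning tally. Because the counting unit for published
neoantigen totals is generally ambiguous, it is pinned down here: rows are
unique `(peptide, allele, variant)` triples, per-sample class totals count
unique `(peptide, allele)` pairs, split by source class (SNV vs frameshift
vs in-frame indel).

## Ploidy estimation

A two-step estimator in *gene-ordinal* space (genes numbered along each
chromosome — the natural coordinate of a per-gene depth profile):

1. **Relative gene copy number.** The sample is treated as diploid overall:
   the median depth across all coding regions is the 2N level and each
   gene's relative GCN is `2 x (gene median / overall median)`. The
   wording "the ratio ... considered as the relative GCN" is ambiguous
   between the ratio and twice the ratio; we use twice (so 2 = diploid)
   and say so here.
2. **Segmentation.** Circular binary segmentation of per-chromosome log2
   GCN ratios: the maximal arc-vs-rest two-sample statistic is tested
   against a permutation null (default 1000 shuffles, explicit seed),
   splits are accepted at p <= 0.01, minimum segment width 3 ordinals. The
   scale factor of the statistic cancels under permutation, so no variance
   estimate is needed; as alpha approaches 0 the algorithm returns a single
   segment (the permutation p-value is bounded below by 1/(n_perm+1)).
3. **Absolute copy number.** Heterozygous variants on a segment of copy
   number N sit at allele fractions k/N: one 50% peak at 2N, peaks at
   33%/66% at 3N, 25/50/75 at 4N. Candidate N in 1..8 is scored by an
   earth-mover-flavoured mismatch between the modes of the smoothed AF
   density (Gaussian kernel, bandwidth 0.03) and the k/N grid: the
   height-weighted distance from each mode to its nearest grid peak plus a
   fixed penalty (0.05) per grid peak with no mode within
   `max(2 x bw, 0.25/N)`. The penalty is what separates N = 2 from N = 4
   when only a 50% peak exists, and N = 3 from N = 6 for a 33/66 pattern.
   Ties break toward the N closest to the relative GCN. Degenerate inputs
   never crash: segments with fewer than 10 AFs fall back to rounding the
   relative GCN (flagged `fallback`), and segments with relative GCN < 0.5
   are called homozygous deletions from depth alone (no AF grid exists at
   N = 0).

A uniformly triploid genome is an instructive corner case: depth
normalisation erases the depth signal entirely (every gene sits at the
overall median), and only the 33/66 allelic-frequency structure identifies
N = 3. The test suite covers exactly this case. Purity is assumed 1 (cell
lines); there is no tumor-content correction and no allele-specific CN.

## The synthetic-data generator (and what a green test does not show)

`sim_config()` fixes a stated world; all defaults were chosen once, from
the study designs being emulated, and are not tuned to test outcomes:

* **Reference**: 80 genes (120–280 codons) on 4 contigs, each gene a
  complete CDS (ATG ... stop, no internal stop) laid plus-strand with 30 bp
  spacers; cDNA = genomic slice. MMR-deficient configs embed a >= 6 bp
  homopolymer run in every CDS to host slippage indels.
* **Accrual**: events are Poisson(days x rate). Preset rates: `mss` 0.8
  SNV + 0.1 indel per day (stable), `msi` 5 + 10 (indel-rich, evolving),
  `pole` 16 + 0.5 (SNV-rich, evolving), `mutyh` 14 + 0.7 (C>A-rich,
  evolving), `pdx` = msi rates over an F1→F4 lineage at 60 days per
  generation. Rates were set so the *called* (post-filter) rate of the
  hypermutant presets clears the 10/day EVOLVING bound, mirroring the
  classification of MSI/POLE models, while `mss` stays far below it.
* **Clonality**: baseline variants are clonal (AF 0.5) with probability
  0.8; newly gained in-vitro events are mostly subclonal (clonal with
  probability 0.1; subclonal AF uniform on 0.05–0.25). Ten percent of
  inherited subclonal variants are lost per interval; in the PDX lineage
  clonal variants may be gained and lost too — the in-vitro/in-vivo
  contrast reproduced qualitatively.
* **Reads**: depth ~ negative binomial (mean 100, size 50); alt reads
  binomial at the true AF; strand split binomial(1/2) after a small
  terminal-position deduction (8%); artifact variants injected at AF 0.02
  at 0.2 per true variant, one third strand-biased, to give the filter
  cascade something to remove.
* **Expression**: log-normal FPKM (median 30), 20% of genes forced below
  the FPKM > 10 bound.

One RNG stream per stage is derived from the master seed, so stages can be
regenerated independently and everything is byte-reproducible.

What the generator does *not* emulate: alignment and mapping artifacts,
base-quality structure, mouse-read contamination, indel representation
ambiguity, subclonal copy-number change, transcript isoforms, and any
linkage between expression and mutation. A green end-to-end test
establishes that the statistics and bookkeeping are correct under the
stated model — not that the pipeline is robust to real sequencing
pathology.

## Numerical and design choices

* Exact binomial tails via `pbinom` (upper tail), checked against naive
  pmf summation to 1e-12 up to depth 500.
* NNLS tolerance is relative to `max |A'b|`; exposures are reported raw
  (mutation-count scale) and normalised.
* CBS permutation p-value uses the add-one estimator `(exceed + 1) /
  (n_perm + 1)`; the permutation seed is always explicit.
* The EVOLVING bound (10/day), rank bound (0.5), FPKM bound (10), AF bound
  (0.10), and binomial alpha (0.05) are all exposed as parameters with
  these defaults.
* Rounding for table-facing output is half-away-from-zero
  (`round_half_up`), 2 decimals; internal arithmetic is full precision.
* Known limitation: the growth-table regression cannot reproduce 3 of 45
  printed growth rates exactly (see above); the package treats the analytic
  rounding bound as the correct statement of agreement.
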