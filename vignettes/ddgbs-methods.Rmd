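---
title: "Designing and evaluating double-digest GBS experiments with ddgbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating double-digest GBS experiments with ddgbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgbs)
```

## The design problem

Double-digest genotyping by sequencing (ddGBS) reduces a genome to the
set of restriction fragments cut by two enzymes, sequences only the
fragments that received both adapters, and calls SNPs on the resulting
loci. Whether a ddGBS experiment succeeds is decided before any
sequencing happens: by the enzyme pair (which fixes the number, size
distribution, and genomic spread of sequenceable fragments), by the
library design (barcodes, adapter ratios, size selection), and by the
sequencing volume per sample. `ddgbs` implements the computable part of
that design loop: in silico digestion, library design checks, the
summary statistics used to score enzyme combinations, saturation
analysis for sequencing-volume planning, and depth-stratified genotype
quality control — together with a read simulator so the whole chain can
be exercised and tested without any external data.

## In silico digestion

A restriction enzyme is a recognition motif (IUPAC codes allowed) plus
a cut offset on the top strand; `ddgbs_enzymes()` ships seven enzymes
commonly screened for vertebrate genomes (EcoRI, HinP1I, ApeKI, PstI,
MseI, MspI, BglII). Coordinates are 0-based and half-open, and a cut
position is a between-base index, which makes fragment arithmetic exact
and BED export direct.

Three modelling choices deserve a note:

* **One cut per duplex site.** A restriction site found on both strands
  is a single physical site and contributes a single fragmentation
  point, placed at `cut_offset` from the motif start (top-strand
  orientation). Sites found only on the bottom strand — possible for
  non-palindromic user-supplied motifs — cut at the mirrored offset.
  All seven shipped motifs are reverse-complement palindromes, so for
  them the double-strand scan equals the single-strand scan. A
  consequence worth knowing: because staggered cutters are asymmetric,
  cut coordinates on a reverse-complemented sequence map back through
  the *mirrored* offset, not the original one; the test suite asserts
  exactly that reflection law.
* **Ambiguity codes in the genome never match motif letters other than
  N.** Assembly gaps are long `N` runs; letting `N` match `A/C/G/T`
  motif letters would invent thousands of cut sites inside gaps.
* **Overlapping degenerate matches each cut, then coordinates are
  deduplicated.** A coordinate produced by both enzymes is labelled by
  enzyme A (a documented, arbitrary precedence) and counted once.

Fragments are classified by their bounding cuts: `AB` fragments (one
end per enzyme) are the sequenceable class, because the barcode adapter
ligates only to enzyme-A overhangs and the common adapter only to
enzyme-B overhangs; `AA`/`BB` fragments receive the same adapter twice
and do not amplify; `terminal` fragments touch a sequence boundary,
lack one ligatable overhang, and are excluded from all downstream
library simulation. Size selection (`size_select()`, default
300–650 bp) is modelled as a hard window — the soft tails of bead-based
selection belong to the simulator, not to the digest. Because it is not
stated whether published in silico fragment counts refer to all
fragments or only a size class, `double_digest()` reports the full
classed count and `size_select()` the windowed count, and both are
labelled as such.

## Library design

`generate_barcodes()` reimplements the usual GBS barcode constraints:
lengths staggered across 6–9 bases (so restriction-site positions vary
across the flow cell), no `GG` start, a minimum pairwise Hamming
distance over the shared prefix (distance is computed over the shorter
barcode's length, because demultiplexing is prefix-based), and no
recreation of either enzyme's recognition site when the barcode is
concatenated to the enzyme-A overhang remnant. The search is rejection
sampling with a consecutive-rejection budget; when the constraint space
is (near-)exhausted it fails naming the binding constraint rather than
looping forever.

`compute_adapter_ratio()` scales barcode-adapter and common-adapter
parts in proportion to the predicted enzyme-A and enzyme-B cut-end
counts, normalized to a user-chosen total and rounded half-up to one
decimal. Published ratios of this kind (for example 0.8 : 15) are
wet-lab values whose exact derivation includes molar conversions not
reproduced here; the package deliberately defines only the
proportionality and leaves the total as a parameter.

`demultiplex()` implements the strict "good barcode read" rule: a read
is assigned only on a perfect prefix match, with longest-match-first
resolving nested barcodes (no published rule exists; longest-match is
the only order that makes nested sets unambiguous). The residual enzyme
overhang after the barcode is *kept* on the trimmed read — trimming it
is not universal practice and keeping it preserves the tag/fragment
correspondence used downstream. Error-tolerant (1-mismatch)
demultiplexing is a non-goal.

## Evaluation statistics

For an enzyme-combination screen in which a few samples are sequenced
individually and as a pool:

* **FCI** (fragment consistency index) = mean per-sample fragment count
  / pooled fragment count. Values near 1 mean the same loci are
  recovered in every individual; low values forecast missing data.
  Reported at 4 decimals.
* **Depth** = good barcode reads / fragment count, reported at 2
  decimals; the unrounded product `depth × fragments` recovers the read
  count exactly.
* **CV of per-fragment depth across samples**
  (`cv_depth_distribution()`): one CV per fragment, summarized as
  mean ± SD. Heavy-tailed per-fragment amplification shows up directly
  here.
* **SNP density per chromosome** (`snp_density_table()`): SNPs/Mb, and
  the CV of density across chromosomes as a uniformity score.
* **Region summaries** (`summarize_regions()`): annotation category
  counts to percentages (3 decimals), exonic subcategories as
  percentages of exonic (2 decimals).

All CVs use the sample SD (n−1) over the mean. Published tables of this
kind are reproducible with either SD convention at the printed
precision, so the choice is documented rather than load-bearing. Two
deliberate rounding rules: all report rounding is half-up (base R's
`round()` is half-to-even, which disagrees with how such tables are
printed), and in table-comparison mode the density table's mean/CV are
computed from integer-rounded densities, because printed tables round
the per-chromosome densities first and their summary rows are
consistent with the rounded inputs; `use_rounded = FALSE` gives the
full-precision summary, and both agree at two decimals on the bundled
example.

## Saturation, ORP and SRP

`build_saturation_curve()` subsamples a tag table at increasing
proportions (default grid 0.1/0.2/0.5/0.8/1.0). Subsampling is *nested*
— one global permutation of reads, with each proportion a prefix —
rather than independent per proportion, which guarantees the fragment
count is non-decreasing along the curve; independent subsamples can
produce decreasing counts by chance, which the downstream definitions
do not tolerate. A fragment is counted when at least one of its tags
reaches the minimum tag count `c` (default 3, the conventional
GBS-pipeline threshold): this is the tag-level reading of the
threshold, matching pipelines that first discard tags seen fewer than
`c` times.

Two decision points summarize a curve:

* **ORP** (optimal read-count point): the read volume minimizing unit
  sequencing cost (cost per discovered fragment). It is located on the
  observed grid without interpolation, since it is defined on observed
  points; a minimum on the first or last grid point is flagged
  `boundary` because the optimum is then not bracketed. A finer grid at
  the low-proportion end resolves the interior minimum better; the
  default grid is the conventional one.
* **SRP** (saturated read-count point): the smallest read volume at
  which fragment discovery has plateaued. The plateau is detected on
  forward finite-difference slopes: the SRP exists only when all slopes
  from some point onward are at most `slope_tol` (default one new
  fragment per 10^5 reads), and then equals the smallest read count
  attaining the maximum observed fragment count. This phrasing resolves
  an ambiguity in "first point where the slope reaches zero": it
  returns the first point *on* the plateau, not the last point before
  it. Libraries sequenced below saturation simply have no SRP
  (`reached = FALSE`), the common outcome in practice.

When both exist, ORP ≤ SRP.

## Genotype QC and concordance

`filter_snps()` applies the standard post-calling filter in a fixed
order: per-call depth/quality masking first (DP < 5 or GQ < 98 becomes
missing), then site-level filters — biallelic only, minor allele
frequency (computed from non-missing calls *after* masking; the
ordering is a documented choice since published pipelines rarely state
it), site call rate ≥ 0.6 — and finally a sample call-rate filter
(≥ 0.01). The operation is idempotent and an empty result is valid.

`concordance()` compares GBS calls to chip calls at shared sites and
samples, stratified by GBS call depth (2×–12×). Allele orientation is
harmonized by flipping chip dosages at REF/ALT-swapped sites;
strand-ambiguous A/T and C/G sites, where a swap cannot be
distinguished from a strand flip, are dropped and counted. Consistency
is reported over chip-homozygous calls, chip-heterozygous calls, and
the call-weighted total (not the average of the two percentages — the
weighting is a documented choice). Concordance is defined
pre-imputation; imputation itself is out of scope.

`ld_decay()` uses genotype-based r²: the squared Pearson correlation of
ALT-dosage vectors over samples with both calls present. No phasing is
assumed (none is available for a typical F0 panel), so haplotype-based
D′/r² estimators are deliberately not offered; monomorphic pairs are
excluded and counted, and the decay distance is the first distance-bin
center whose mean r² drops to the threshold (default 0.1).

## The simulator

`simulate_reads()` emulates exactly the features the other modules
measure, and nothing more:

* fragments come from a real in silico digest of the (synthetic or
  supplied) genome, size-selected to the configured window;
* reads are drawn from the enzyme-A (barcoded) end of each fragment in
  one orientation, as in single-end GBS; read length defaults to 91 bp
  (a typical trimmed short-read length);
* per-(fragment, sample) expected depth is
  `mean_depth × LN(0, σ) / E[LN]` with Poisson counts around it. The
  lognormal is a modelling choice — no published dispersion model
  exists, only empirical depth-CV distributions — picked because its CV
  has the closed form √(exp(σ²) − 1), which turns depth-CV recovery
  into a testable parameter-recovery problem. Abundance is drawn
  independently per sample *and* fragment; a shared per-fragment draw
  would make the across-sample CV collapse to Poisson noise;
* planted SNPs are placed inside the sequenced fragment ends (so they
  are observable), with Hardy–Weinberg genotypes at MAFs drawn from a
  configurable range; heterozygotes emit either allele per read with
  probability 1/2; substitution errors are added per base;
* `simulate_chip()` re-reports the truth genotypes with independent
  per-call errors, emulating an array platform;
* `sim_genotype_calls()` returns the truth genotypes with realized
  per-fragment depths as an idealized caller — variant calling itself
  is out of scope, so concordance properties are tested against truth,
  not against a caller's artifacts.

What the simulator does **not** emulate: PCR duplicates, indels,
quality-score profiles, methylation-dependent digestion failure,
index hopping, bead-selection soft size tails, and reference-alignment
artifacts. Tests passing on simulated data therefore demonstrate the
*arithmetic and algorithmic* correctness of the statistics and the
qualitative regimes (U-shaped unit cost, depth-CV scaling, concordance
recovery), not that real libraries will match any particular number.

Tag-to-fragment assignment in the simulated pipeline
(`fragment_read_index()` + `tally_tags()`) is by exact prefix match on
the fragment's expected read start. It stands in for alignment at desk
scale; unlike an aligner it drops tags whose key window contains an
error or an ALT allele (they are counted as unassigned), which slightly
thins tag tables at realistic error rates and is documented behaviour,
not a bug.

## Problem sizes and determinism

The test suite and the reproduction script run entirely on synthetic
data: genomes of 0.05–2 Mb, 2–24 samples, mean depths 5–50×, a few
dozen to ~10^3 planted SNPs — sizes chosen so the full suite completes
in well under a minute per module while keeping enough fragments
(~100–150 per 2 Mb for EcoRI–MseI at 300–650 bp) for the stochastic
assertions' tolerances. Every stochastic routine takes an explicit
seed, restores the caller's RNG state, and is byte-reproducible given
its configuration. Statistical assertions use explicit tolerances
(binomial standard errors, or the ±0.1 band for depth-CV recovery)
rather than exact equality.

## Known limitations

* Digestion is sequence-deterministic: methylation sensitivity (a real
  cause of under-digestion for some enzymes) is not modelled, because
  no quantitative model is available — only empirical observations.
* The demultiplexer is exact-match only, matching the "good barcode
  read" definition; reads with barcode-region errors are discarded, not
  rescued.
* `ld_decay()` is quadratic per chromosome over sites within the
  distance window; it is meant for the filtered marker sets of a design
  study, not for millions of sites.
* The ORP is reported on the observed grid; with the default 5-point
  grid its resolution is coarse, and a finer grid should be supplied
  when the cost minimum matters precisely.
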