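---
title: "APOBEC3 signature enrichment, association and breakpoint analysis: methods"
author: "apobecsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APOBEC3 signature enrichment, association and breakpoint analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. The worked numbers in the README and the quantities
in `scripts/acceptance.R` are all produced by the code described here;
nothing below states an empirical result that the tests or the
acceptance script do not themselves compute.

## The enrichment model

APOBEC3 deamination leaves C>T and C>G substitutions at cytosines in a
T·C·W trinucleotide context (W ∈ {A, T}); on the opposite strand the same
event reads as G>A/G>C in W·G·A. For one sample, four counts are
accumulated over every *qualifying* mutation (by default C>T/C>G and the
strand mirrors G>A/G>C; an `all_c_mutations` mode drops the alt-allele
restriction):

* `mutations_tcw` — mutated Cs whose reference trinucleotide is TCW (or
  Gs in WGA);
* `mutations_c` — all qualifying mutated Cs (or Gs);
* `context_tcw` — TCW (or WGA) motif occurrences fully inside the
  `(2w + 1)`-nt window centred on each mutation, `w = 20` by default;
* `context_c` — C (or G) bases inside those windows.

The fold enrichment is `E = (mutations_tcw * context_c) /
(mutations_c * context_tcw)`: the TCW-share of the sample's cytosine
mutations relative to the TCW-share of cytosines available around them.
`E = 1` means the motif is hit no more often than its local availability
predicts.

Assumptions and conventions worth making explicit:

* **Reference, not mutant, decides the motif.** Trinucleotide membership
  is read off the bases flanking the position in the reference.
* **Windows are counted per mutation.** Overlapping windows of nearby
  mutations each contribute in full; no deduplication. The context is
  defined per mutated base, and deduplication would make the denominator
  depend on mutation clustering in an uncontrolled way.
* **Constant window length.** Windows overhanging a chromosome end are
  padded with `N` (which never matches C/G/TCW/WGA) rather than
  truncated, keeping the per-mutation denominators comparable.
* **Strand symmetry.** Reverse-complementing the catalog and the
  reference leaves all four counts, E and p unchanged; this is enforced
  by property tests.

### Significance and classification

Each sample's TCW over-representation is tested one-sided on the 2×2
table `[[mutations_tcw, mutations_c − mutations_tcw], [context_tcw,
context_c − context_tcw]]` with the exact hypergeometric (Fisher) tail.
This is a design decision: the classification rule used here is stated in
terms of a BH-corrected p-value without naming the test, and the exact
Fisher tail is the only exact test consistent with the four counts the
enrichment formula defines. Samples with no qualifying mutations carry no
evidence and get `p = 1`; a zero denominator term makes E *undefined*
(reported as `NA` with a flag), never silently zero or infinite.

p-values are BH-adjusted across the cohort's samples, and a sample is
called **APOBEC high** iff `q < alpha` (default 0.05) **and**
`E > fold_threshold` (default 2); undefined E is always low. Both
defaults are the analysis' operating thresholds and are surfaced in
`enrichment_config()` / `pipeline_config()`.

## Gene-alteration association

Alteration statuses are binary per (gene, sample, class): SNV means at
least one non-silent mutation assigned to the gene (gene assignment is an
input; this package does no annotation); amplification means gene copy
number ≥ 2× sample ploidy; loss means copy number at least one copy below
ploidy (`CN ≤ ploidy − 1`). The loss phrasing "≤ 1 copy number relative
to ploidy" admits a second reading (`CN ≤ ploidy`), which would flag
every non-amplified gene; it is kept available as `loss_rule = "ratio"`
but is not the default. Samples missing a copy-number value for a gene
are excluded from that gene's CN tests rather than zero-filled.

The association statistic is the difference in alteration proportion,
high − low, one-sided for enrichment in the high class — the simplest
exchangeable statistic consistent with asking which alterations travel
with APOBEC-high status. The null is built by shuffling the high/low
labels: `n_perm` uniform random permutations (default 100,000) with the
add-one-smoothed estimate `p = (1 + #[stat* ≥ stat]) / (1 + n_perm)`.
When the number of distinct label assignments `choose(n, n_high)` is at
most 10^5 the test switches to exhaustive enumeration and the p-value is
exact — exactness at no cost on small strata. Floating-point ties in the
permuted statistic are absorbed with a 1e-12 tolerance on the ≥
comparison.

The cohort is tested first over all genes and classes, then the test is
repeated within each subtype (HER2, Basal, LumA, LumB). BH correction is
applied over the genes within each (stratum, class) — so a stratum's
q-values depend only on that stratum's p-values — and a gene is flagged
at `q < 0.1`. Strata with a single APOBEC class are skipped with a
message, not an error. Each (stratum, class, gene) test draws its
permutations from a seed substream derived from the master seed, so
results do not depend on evaluation order.

APOBEC class vs subtype is tested with an uncorrected Pearson chi-square
on the 2×K contingency table; post hoc, all subtype pairs are compared
with two-proportion chi-square tests (equivalent to the global test
restricted to the pair) and BH-corrected over the pairs. The post hoc
procedure is a design choice; pairwise two-proportion chi-square is the
natural unit consistent with the global statistic.

### Calibration of the permutation p-value

With a binary alteration vector the permutation statistic has coarse
discrete support (the count of altered samples among the high group), so
the Monte-Carlo p-value is conservative rather than uniform under the
null — a property of any permutation test on sparse binary data, not an
implementation artifact. The package's null-calibration tests therefore
permute an exchangeable *continuous* score through the same
`permutation_test()` machinery, where the null p-value distribution is
uniform up to the 1/(n_perm + 1) grid; exactness on binary data is
checked separately against exhaustive enumeration. Consumers should read
small permutation p-values on rare binary alterations as conservative.

## Breakpoint burden

A breakpoint is a boundary between *adjacent* same-chromosome segments
whose copy numbers differ by at least `min_delta` (default 0.5 on
absolute copy number); chromosome boundaries never count, and adjacency
is by segment order, not genomic distance, so assembly gaps do not
silently split counts. The counting rule is a design decision — the
standard segmentation-derived proxy — since segment files do not mark
breakpoints explicitly. Counts are invariant under a constant shift of
all copy numbers.

High vs low counts are compared with a two-sided Mann–Whitney U test: U
from rank sums with midrank ties; exact p by the full rank distribution
when the combined sample size is ≤ 20 with no ties, otherwise the normal
approximation with tie correction and continuity correction. The
direction of any shift is reported from the class medians rather than
folded into a one-sided test.

## The synthetic cohort

`cohort_spec()` defaults describe the study conditions the analysis is
built for: 755 tumours; PAM50 proportions LumA 0.45, LumB 0.20, Basal
0.18, HER2 0.10, Normal 0.07 (a typical breast-cohort mix); negative-
binomial mutation loads (mean 60, dispersion 2 — exome-scale burden);
APOBEC-high prevalence per subtype (HER2 0.55, Basal 0.30, LumB 0.25,
LumA 0.10, Normal 0.08), skewed toward HER2 so the subtype chi-square
stage has the structure it is meant to detect; `apobec_fraction_high =
0.5` (half of a high sample's mutations drawn from TCW/WGA sites) vs
pure background in low samples; a 10-entry driver panel (TP53, CDH1,
NCOR1, PTEN, NF1, PIK3CA SNVs; ERBB2, CCND1 amplification; TP53, KMT2C
loss) with base rates of the order seen in breast cohorts and moderate
planted odds ratios; Poisson breakpoint means 40 (high) vs 20 (low);
ploidy 2. `prop_high` accepts either a single number or the per-subtype
vector; the per-subtype form is the default because a flat prevalence
would make the subtype association stage vacuous.

Generation details that matter for interpretation:

* The reference is i.i.d. with GC 0.41; at that composition the TCW
  context fraction among cytosines is in the high single digits of a
  percent, so `apobec_fraction = 0.5` yields E well above the fold
  threshold while `apobec_fraction = 0` concentrates E near 1.
* Signature mutations pick a TCW or WGA centre uniformly (strand chosen
  by the site drawn), C>T/C>G with equal odds; background mutations are
  uniform over positions with a uniform non-reference alt. Positions are
  sampled without replacement within a sample.
* Amplified gene draws land in `[2·ploidy, 2·ploidy + 2]`, lost draws in
  `[max(0, ploidy − 2), ploidy − 1]`, neutral draws at ploidy — so the
  calling thresholds recover the planted status exactly, by construction.
* Segment profiles place a Poisson number of breakpoints uniformly on a
  5-chromosome map and alternate copy numbers by ±1 around ploidy, so
  every adjacent pair clears the default `min_delta`.
* All randomness flows from one master seed through per-component,
  per-sample substreams (`substream_seed()`), so adding samples does not
  perturb earlier samples and whole cohorts are byte-identical across
  runs.

What the generator does *not* emulate: real trinucleotide composition
and replication-timing structure of the human genome, signature-weighted
background mutation spectra (a CpG-biased background is out of scope),
clonal structure, gene lengths (SNV statuses are drawn per gene, not per
base), or correlated copy-number landscapes. Passing recovery tests on
these cohorts therefore demonstrates that the statistics detect the
structure they model — not that real tumours satisfy that model.

## Numerical choices and degenerate inputs

* Exact hypergeometric tails via `phyper`; verified against direct
  enumeration over every 2×2 table with total ≤ 60 at 1e-12.
* BH via `p.adjust(method = "BH")`; verified against the step-up
  definition on random vectors.
* `mutations_c = 0` → p = 1; `context_tcw = 0` or `mutations_c = 0` → E
  undefined → class low, flagged.
* Empty mutation sets give all-zero counts (not an error); empty
  catalogs give an empty, fully-typed result table.
* Non-ACGTN reference characters become `N` on read; `N` never matches a
  motif and never counts as context.
* Overlapping segments, `end < start`, unknown subtypes, non-positive
  ploidy and out-of-range p-values are validation errors that name the
  offending sample/chromosome/column.

## Problem sizes in the tests

The test-suite and acceptance-script sizes are the package's chosen
operating points: all 635,376 count tables with total ≤ 60 for the exact
test; 100 random catalogs (30 mutations on 1.2-kb references) for the
motif-counter oracle and strand symmetry; a 200-sample cohort (mean 120
mutations) for classification recovery; 1,000 null replicates at n = 100
with 2,000 permutations for calibration; 100 cohorts (n = 200, 30%
high, base rate 0.15, odds ratio 8, 10,000 permutations) for association
recovery; 100 simulations of 50-vs-50 Poisson(40)/Poisson(20) draws for
breakpoint power; and a 40-sample end-to-end run, twice, for
determinism. The analysis drivers and the acceptance script additionally
run the full 755-sample default cohort with the full 100,000-permutation
association pass.

## Known limitations

* The per-sample significance test assumes the four counts form a
  sampling-without-replacement contrast; burden-correlated covariates
  (total mutation load, regional composition) are not modelled.
* The permutation test does not condition on mutation burden, and the
  cohort-level pass shuffles labels across subtypes rather than within
  them; both are deliberate scope limits.
* Gene-level SNV status relies on upstream gene assignment and
  silent/non-silent calls; the package does not annotate.
* The Mann–Whitney normal approximation is used for all tied or larger
  samples; in deep tails its relative error grows, which matters only
  when exact tail probabilities below ~1e-4 are themselves of interest.
* Log2-ratio segment input requires an externally supplied ploidy; the
  conversion `CN = ploidy · 2^value` assumes the ratio is centred on the
  sample's average copy number.
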