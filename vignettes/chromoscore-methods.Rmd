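---
title: "Chromothripsis scoring and downstream analyses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromothripsis scoring and downstream analyses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chromothripsis is a catastrophic mutational event in which one or a few
chromosomes shatter and are reassembled imperfectly, leaving two genomic
footprints: a dense cluster of breakpoints, and copy-number segments that
oscillate among a small set of integer states. `chromoscore` detects this
footprint in segmented total copy-number profiles, annotates the calls, and
runs the association analyses that typically follow in a pan-cancer study:
per-chromosome enrichment, TERT-locus connectivity, breakpoint-microhomology
contrasts, fusion validation and count regression, and cohort/longitudinal
tables.

All coordinates in the package are 0-based half-open, the native convention
of BED and BEDPE. A single convention throughout eliminates off-by-one
drift; the SEG-like segment input is therefore *declared* 0-based half-open
in the reader's documentation.

# The scoring model

The scorer works per sample and chromosome:

1. **States.** The caller's (possibly fractional) total copy number is
   rounded half-up to an integer state (`2.5` becomes `3`). Segmentation
   callers differ in whether they emit integers; half-up rounding is a
   deterministic, documented choice.
2. **Switches.** Runs of adjacent segments with equal states are merged;
   every boundary between unequal merged states is one *switch*, located at
   the start of the downstream segment.
3. **Window.** The densest window is the largest set of consecutive
   switches whose inclusive span (last minus first position) is at most the
   window size, 50 Mb by default. "Within 50 Mb" is read as inclusive: two
   switches exactly 50 Mb apart are one window. The boundary is tested
   explicitly.
4. **Tiers.** At least 10 switches in the densest window give a
   high-confidence call, 8–9 intermediate, 6–7 low; fewer give none. The
   thresholds are configuration, with these defaults.
5. **Region and annotation.** The call region is the minimal hull of every
   switch that lies in at least one window qualifying at the achieved tier.
   The number of distinct states is counted over segments overlapping the
   region; at most 3 distinct states makes the call *canonical*. The region
   is annotated for centromere overlap and for telomere involvement, the
   latter using a 1 Mb margin from either chromosome end (no published
   margin exists; 1 Mb is exposed as `telomere_margin`).

Switch clusters separated by more than one window span are reported as
separate calls on the same chromosome. Sex chromosomes are scored like
autosomes, and segmentations derived from exome data are scored by the same
operations — resolution differences live in the input, not the algorithm.

# The synthetic cohort generator

No patient-level data ships with the package; every downstream analysis is
exercised on seeded synthetic cohorts whose structure mirrors what the
analyses assume:

* **Planted events.** A positive sample carries events on 1–5 distinct
  chromosomes (weights favouring 1–2, so most positives are multi- or
  single-chromosome in realistic proportions). Each event spans 20–45 Mb,
  places `rpois(25) + 10` breakpoints uniformly in the region, and
  oscillates among exactly *k* states (*k* weighted towards 2–3, giving a
  majority of canonical events). The first region segment carries the
  baseline state, so the realized switch count is the breakpoint count, or
  one more when the oscillation parity forces a non-baseline final segment;
  the truth table records the realized count.
* **Join classes.** One SV per internal junction, with orientations drawn
  uniformly over the four head/tail combinations — the fragment-join
  randomness hallmark.
* **Background.** Sporadic CNVs are long (5–30 Mb) and sparse
  (`rpois(2)` per sample), carved only into baseline stretches, so they
  rarely assemble six switches within 50 Mb by chance; this keeps
  specificity testable. Sporadic SVs (`rpois(30)`) are uniform genome-wide.
* **Homology.** Breakpoint homology lengths are drawn per group from a
  categorical distribution over the five bins 0–1, 2, 3–5, 6–9, ≥10 bp,
  then uniformly within the bin (10–50 bp in the top bin). Chromothriptic
  junctions favour short homologies, background SVs long ones, emulating
  the end-joining versus homology-mediated repair contrast.
* **Covariates.** TERT gain probability is higher in positive samples
  (0.35 vs 0.15); fusions arise per SV at a base rate of 0.02 with a
  planted rate ratio of 5 in positive samples; signature exposures are
  log-normal with a 2× multiplicative shift for designated signatures in
  positive samples.
* **Longitudinal pairs** are planted under three scenarios: `stable`
  (identical chromothriptic chromosomes at both timepoints), `lost`
  (first timepoint only) and `gained` (second only).

What the generator does **not** model: subclonal copy-number fractions,
purity/ploidy mixtures, breakpoint hotspots within a region, read-level
noise, or a mechanistic model of micronucleation/bridge resolution. Passing
planted-recovery tests therefore demonstrates the correctness of the
scoring logic under clean segmentations, not performance on noisy real
segmentations.

# Downstream analyses

**Per-chromosome enrichment.** For each tumour, regions of exactly the
observed sizes are re-placed uniformly over feasible start positions on
autosomes + X (the Y chromosome is excluded from the null pool),
non-overlapping within the tumour; 50,000 permutations by default. The
published success rule is ambiguous, so both readings are implemented:
`peak` (default — a permutation succeeds for chromosome *c* when its
*maximum* per-chromosome count reaches the observed count on *c*) and
`per-chromosome`. The empirical p-value uses the add-one correction
`(1 + successes) / (1 + N)` so it can never be zero, and Bonferroni
correction is applied across chromosomes. Tiers high + intermediate are
pooled by default, matching how entity-level enrichment figures are usually
drawn; the tier filter is a flag.

**TERT genome walking.** From the TERT locus (chr5:1,253,282–1,295,184,
GRCh37) the walk scans upstream and downstream; each breakend encountered
may be traversed, jumping to its partner and continuing in the direction
implied by the partner's orientation (head → decreasing coordinates,
tail → increasing). At most two SVs are followed per direction and the
cumulative intra-chromosomal scanned distance is capped at 50 Mb; the jump
itself adds no distance, since walking distance describes genomic
traversal. A sample is linked when a path with at least one traversal
touches a chromothriptic region. Orientation semantics at the *incoming*
breakend are deliberately permissive (any encountered breakend is
traversable); only the outgoing direction is constrained. Linkage is
contrasted against TERT-gain status with a Pearson chi-square without
continuity correction (Yates by flag).

**Microhomology.** Homology lengths are binned into 0–1, 2, 3–5, 6–9 and
≥10 bp; length exactly 10 goes to the top bin (the published bin labels
leave 10 unassigned between "6–9" and ">10"). Unknown homology lengths are
excluded rather than imputed. Per-bin proportions are contrasted between
groups by maximum-likelihood beta regression with a logit mean link and a
single precision parameter (no dispersion covariates), fitted via
`mgcv::gam(..., family = betar())`. Boundary proportions are shrunk by the
Smithson–Verkuilen transform `(y(n-1) + 0.5)/n` because the beta likelihood
is undefined at 0 and 1. Eligibility mirrors the usual entity filter: at
least 15 cases with at least 5 per group. The region-wise unit is the
chromothriptic *chromosome* (either-end rule for translocations);
region-level splitting is available as a flag.

**Fusions.** Only medium/high-confidence fusion calls are validated, each
breakpoint independently against the nearest same-chromosome SV breakend of
the same sample, within 200 kb (inclusive); strand is ignored because
fusion and SV callers disagree on orientation conventions. The excess of
fusions in chromothripsis-positive tumours is modelled as
`fusions ~ log(SV count) + status` with a log link — the only family in
which "*x* times more fusions for a given number of SVs" is a coefficient.
Negative binomial is the default for overdispersion robustness (Poisson by
flag). Because the status effect is additive on the log scale,
`exp(coefficient)` and the ratio of fitted lines at any reference SV count
coincide; one number is reported.

**Cohort tables.** Prevalence is reported per entity for entities with at
least 5 cases (smaller entities separately). The germline two-hit contrast
is a two-sided Fisher exact test on carriers; the TERT-gain and
ATRX-truncation contrasts are pairwise chi-squares against the
neither-group at the high + intermediate tier; signature contrasts are
two-sided Wilcoxon rank-sum tests on `log2(exposure + 1)` (zeros exist, so
a pseudo-count of 1 is added; absolute exposures and fractions are both
accepted since the rank test is scale-invariant within a signature), with
Bonferroni correction over the signatures tested. Longitudinal pairs are
classified as `both-negative`, `lost`, `gained`, `stable` (identical
chromothriptic chromosome sets; a Jaccard threshold below 1 relaxes this)
or `changed`.

# Numerical and design notes

* The densest-window search is a two-pointer scan, checked against
  exhaustive enumeration over all switch-index pairs on 1,000 random
  profiles; ties break to the leftmost window.
* Monte-Carlo p-values are validated against exact multinomial enumeration
  on a 3-chromosome toy genome, and contingency tests against closed-form
  Pearson/hypergeometric arithmetic.
* Scoring is invariant under joint scaling of coordinates and window size,
  and the tier can only rise when a switch is added inside a qualifying
  window; both are property tests.
* Test and acceptance problem sizes (200-sample cohorts, 30 longitudinal
  pairs, 100–200 regression replicates, 2,000–5,000 permutations against
  enumeration oracles) were chosen so the full suite completes in a few
  minutes on one CPU while keeping Monte-Carlo error well inside the
  asserted margins.
* Degenerate inputs are flagged, not silently dropped: empty homology
  profiles, constant proportions, single-status regressions, and empty
  contingency strata all return explicit flags or errors.

# Known limitations

* The scorer uses copy-number switches only; it does not corroborate
  switches with SV evidence, test fragment-join randomness statistically,
  or estimate subclonality. It is a faithful implementation of tiered
  visual-scoring rules, not a replacement for SV-aware callers.
* The enrichment null is uniform over feasible placements; no
  GC/mappability matching.
* Beta-regression assumes a common precision parameter across groups.
* The walk does not reconstruct derivative chromosomes; it answers a
  connectivity question only.

# A worked example

```{r, eval = FALSE}
library(chromoscore)

cfg <- cohort_config(seed = 1, n_samples = 60, longitudinal_pairs = 5)
sim <- simulate_cohort(cfg)
sc  <- score_cohort(sim$segments, sim$genome)

head(sc$calls)
prevalence(sc$calls, sim$metadata)$overall

enr <- enrichment_test(sc$calls[sc$calls$sample %in%
                                  sim$metadata$sample, ],
                       sim$genome, n_perm = 2000, seed = 1)
head(enr[order(enr$p_adj), ])

link <- tert_linkage(sim$svs, sc$calls, sim$genome)
tert_linkage_contrast(link, sim$metadata)

prof <- homology_profiles(split_by_region(sim$svs, sc$calls), by = "region")
classify_longitudinal(sc$calls, sim$pairs, metadata = sim$metadata)
```
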