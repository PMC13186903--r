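---
title: "Genetic-background stratification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-background stratification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplostrat)
```

`haplostrat` does two things: it recovers the dominant genetic background of
experimental animals from SNP-chip genotypes against purebred reference
panels, and it re-analyses remodeling phenotypes stratified by that
background. This vignette documents the models and the choices behind them
in enough detail that a maintainer could defend or change any of them.

## The distance model

The genetic analysis works entirely on an allele-sharing distance (ASD)
computed over 4-SNP haplotype blocks.

**Informative-SNP filter.** Chip data arrive as dosages of the
lexicographically larger allele (0/1/2/missing). Markers are kept when the
minor-allele frequency over all animals is at least `maf_min` (default
0.01) and the call rate at least `call_rate_min` (default 0.90). These are
ordinary array-QC defaults; they are configurable because the QC that
defines "informative" in any given dataset is a property of that dataset,
not of the method. The filter is idempotent and the report counts removals
per criterion.

**Blocks.** Each chromosome's markers are partitioned into non-overlapping
runs of exactly 4 consecutive SNPs subject to span < 150 kb and adjacent
gaps < 50 kb (both strict). The partition is a single greedy left-to-right
scan: a run grows while both constraints hold, emits a block at size 4, and
restarts at the first violating marker, stranding never-emitted run members
as unassigned. With the default parameters the gap bound implies the span
bound (3 gaps × < 50 kb < 150 kb), but the span check is enforced anyway so
non-default parameters behave correctly. The greedy scan is deterministic
and, for fixed block size on a sorted map, leaves no 4-run on the table
that an alternative split of the same run segment could rescue; a dynamic
programming partition would add complexity without changing the distance
materially. Markers in short trailing runs are excluded from the distance
rather than merged into undersized blocks, keeping block semantics uniform.

**Sharing statistic.** The chip genotypes are unphased and no phasing step
exists in the pipeline, so sharing is computed at the genotype level:
per-marker identity-by-state fraction $s(a,b) = 1 - |a-b|/2$, averaged
within a block, then averaged across blocks, and $d = 1 -$ mean sharing.
This is a deliberate, documented approximation to haplotype-level sharing:
the block structure still matters through missing-data handling (a block
contributes to a pair only when fully observed in both animals — whole-block
pairwise deletion) and through equal per-block weighting, but within-block
phase is ignored. The statistic is symmetric, bounded in [0, 1], zero on
the diagonal, and invariant to flipping the dosage orientation at any
subset of markers; it is not guaranteed to satisfy the triangle inequality,
and nothing downstream assumes it does. Pairs whose usable-block fraction
falls below `min_valid_fraction` (default 0.5) raise an error instead of
silently returning a noisy distance.

## Structure and assignment

**MDS.** "Projecting onto the plane" a distance matrix is done with
classical (Torgerson) scaling — double-centre the squared distances and take
the top eigenpairs — rather than Sammon or non-metric variants, because the
display is diagnostic and the classical solution is exact for Euclidean
input. Negative eigenvalues (ASD need not be Euclidean) are reported and
their axes zero-filled, never silently clipped; axes whose eigenvalue is
zero to numerical precision (relative tolerance 1e-9) are zeroed to avoid
eigensolver dust. Axes are sign-fixed so the reference-panel-A centroid is
non-negative, making plots reproducible across platforms.

**UPGMA.** Clustering uses size-weighted average linkage with node height
equal to half the merge distance. Ties in the closest pair are broken by
the lexicographically smallest pair of smallest member-leaf labels
(within a relative tolerance of 1e-12), and the leaf order puts the child
containing the lexicographically smallest leaf on the left, so dendrograms
and heatmap orderings are byte-reproducible regardless of input order. The
implementation is the package's own because this determinism is part of the
contract; tests check it against a brute-force average-linkage reference
that recomputes all cluster averages from scratch at every step, and
against exact cophenetic recovery on ultrametric inputs.

**Assignment rule.** The published workflow reads backgrounds off the MDS
plot and clustered heatmap; that visual rule is made explicit as
nearest-mean-panel: for each experimental animal, mean ASD to each
reference panel, dominance score $(d_B - d_A)/(d_A + d_B) \in [-1, 1]$,
label by sign. The score is continuous and antisymmetric under swapping
panels, so the MDS/heatmap become diagnostics rather than the classifier.
A `tie_band` (default 0) turns near-ties into `UNASSIGNED`; it exists
because a genuinely intermediate animal is a real possibility in admixed
farm stock, and the stratified report excludes and counts such animals
rather than forcing a label.

## The statistical layer

All group contrasts are two-sided at a flagged 0.05 threshold, with no
multiplicity correction — the analysis is exploratory and the report header
carries that caveat verbatim rather than burying it.

**Mann–Whitney U.** Midranks throughout. Exact mode enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled midranks and takes the
two-sided p as the probability of a U at least as far from $n_1 n_2 / 2$
as observed; this handles ties exactly, which `stats::wilcox.test` refuses
to do in exact mode. Auto mode switches to the tie-corrected,
continuity-corrected normal approximation above a combined size of 20 —
$\binom{20}{10} = 184{,}756$ enumerated splits is the largest table, and
the enumeration index matrices are cached per $(n_1, n_2)$ so repeated
contrasts at the same group sizes cost one enumeration.

**Fisher's exact test.** Two-sided p by summing hypergeometric
probabilities not exceeding the observed table's (relative tie tolerance
1e-7), computed from `stats::dhyper`; the independent cross-checks in the
tests are an explicit `choose()`-based enumeration and
`stats::fisher.test`. The sample odds ratio is reported, with zero cells
yielding flagged infinite/zero estimates rather than pseudo-counts.

**ΔΔCt.** Per sample, ΔCt = target Ct − reference (ACTB) Ct; ΔΔCt centres
on the arithmetic mean of the breed-matched control group's ΔCt (animals
are unpaired, so per-sample pairing is not available); fold = $2^{-\Delta\Delta Ct}$.
Two identities are enforced exactly: control-group mean ΔΔCt is 0, and
adding any constant to all of a sample's Ct values cancels. Report
contrasts are tested on ΔCt (rank tests are invariant to the monotone
fold transform, and cross-breed contrasts must not depend on per-breed
baselines); fold changes are shown for display.

**AF endpoints.** An inducing episode is strictly longer than
`episode_min_s` (default 10 s, matching the definition of AF as an episode
with irregular RR intervals lasting longer than 10 s; a 10.0 s episode does
not count). Animal-level inducibility (any inducing episode) and
stimulation-level inducibility (fraction of burst stimulations inducing)
are both reported and both tested with Fisher's exact test. The
stimulation-level test pools stimulations across animals and therefore
ignores within-animal clustering; the report flags this rather than
modelling it — mixed-effects modelling is out of scope.

**Fibrosis heterogeneity.** The "fibrosis difference" correlated with AF
burden is defined here as max − min of the ten per-image fibrosis
percentages within an atrial region; the per-image SD is computed alongside
as an alternative spread measure. Both are per-animal summaries computable
from per-image data; the choice of range over SD follows the spread-style
axis the analysis plots, and keeping both makes the choice auditable.

## The synthetic cohort

The generator exists so the pipeline can be exercised and validated without
animal data, and its defaults are the study conditions, not tuning knobs:
46,298 autosomal SNPs spread over 18 chromosomes with exponential ~50 kb
gaps; reference panels of 49 (Pietrain) and 38 (German Landrace); 40
experimental animals in four cells — Pietrain-dominant control/IHF of
10/15 and Landrace-dominant control/IHF of 8/7 — with admixture 0.8/0.2
toward Pietrain.

Divergence follows the Balding–Nichols model: ancestral frequencies
Uniform(0.1, 0.9), breed frequencies Beta-distributed around them with a
single parameter $F$ (default 0.1, the middle of the plausible 0.05–0.15
range for commercial pig breeds; the true Pietrain–Landrace differentiation
is unknown here, so $F$ is a scenario parameter, not an estimate). Admixed
animals draw each allele copy from the mixture frequency
$\alpha p_A + (1-\alpha) p_B$ — allele-level admixture with independent
copies, which ignores linkage within blocks. That is adequate because the
ASD statistic is genotype-level, but it means the generator cannot
validate haplotype-phase-sensitive methods, and realized LD is essentially
absent.

Phenotype effects follow the pattern the stratified analysis is designed to
detect: ejection fraction down ~25 points and filling pressures up under
IHF in both backgrounds; per-image fibrosis (baseline 5%, between-animal SD
2, within-animal per-image SD 2, ten images per region) raised 6 percentage
points only in Pietrain-dominant IHF; AERP (SD 20 ms) shortened 40 ms at
every drive cycle length only in Landrace-dominant IHF; qPCR ΔCt shifts of
±1 cycle (±0.4 for sub-significant trends) in the breed-specific gene sets
(FN/JNK1 up in Pietrain-dominant left atrium; MMP2/FSP1/TGFB/JNK1 and
COL1A1/TGFB/JNK1 down in Landrace-dominant left and right atria), with a
per-sample baseline Ct shift shared by target and reference genes that the
ΔΔCt analysis must cancel.

AF induction is intentionally simple: each burst stimulation induces
independently with the cell's per-stimulation rate (defaults 0.32 / 0.30
for the IHF cells, 0.02 / 0.10 for controls), and induced episodes are
recorded at a fixed 15 s — only the > 10 s indicator feeds the endpoints.
An iid-Bernoulli cohort reproduces stimulation-level inducibility by
construction, but with ten stimulations per animal its animal-level
inducibility saturates near 100% in the IHF cells, unlike a real cohort
where responder heterogeneity keeps it far lower. Passing tests therefore
show the endpoint arithmetic and the stimulation-level contrasts are
right; they do not show the generator reproduces animal-level inducibility
heterogeneity, which would need a per-animal susceptibility mixture.

Everything is drawn from one generator seeded once per cohort, so a fixed
seed gives a byte-identical cohort, and the pipeline manifest (MD5 per
artifact) makes end-to-end determinism checkable.

## Numerical and interface choices

- Positions are 1-based inclusive; the BED export converts to 0-based
  half-open. Chromosome labels are opaque strings.
- Missing genotypes are a distinct code, never imputed at I/O time; the
  B allele of a PLINK marker is the lexicographically larger observed
  allele, recorded in the map so coding and files round-trip.
- Distance matrices are written with 15 significant digits so read-back
  agrees to at least 12 decimals.
- Degenerate inputs fail loudly and early: empty panels, animals missing
  from the distance matrix, all markers filtered, unsorted maps, pairs
  without usable blocks. The one deliberate exception is the stratified
  report, where an empty design cell yields an `NA` row (an empty cell is
  a property of the data, not a usage error).
- SNRT/BCL is a ratio expressed in percent and routinely exceeds 100; the
  [0, 100] bound is enforced only for true percentages (ejection fraction,
  fibrosis).

## Problem sizes in the test suite

Unit and property tests run at small sizes chosen to make brute-force
oracles exhaustive: block scans on 1,000 random maps of up to 50 markers
against an independent reference scan; ASD against per-marker hand
computation on up to 6 animals × 3 blocks; MDS on 100 random planar
configurations of up to 20 points (recovery to 1e-8); UPGMA against brute
force on 200 random 6×6 matrices; exact tests against full enumeration for
all group sizes up to 5 and margins up to 12. Recovery experiments use a
2,000-SNP, 20+20-reference cohort at $F = 0.1$ (assignment accuracy ≥ 95%
required; observed 100%), and report calibration/power use 200 replicates
of fibrosis-only cohorts (type-I fraction inside the 95% binomial band
around 0.05; breed-A-only effect of 6 points recovered with the breed-B
contrast null in ≥ 90% of replicates). The full-scale configuration
(46,298 SNPs, 127 animals) is exercised by `scripts/acceptance.R`.

## Known limitations

- The block-level sharing statistic is genotype-level IBS, an approximation
  to haplotype-sharing definitions that require phase; with phased input a
  different sharing kernel could be swapped in behind the same interface.
- Assignment is a two-panel nearest-mean rule; it does not estimate
  admixture proportions (no STRUCTURE/ADMIXTURE-style model) and is only
  meaningful when the two panels bracket the cohort's ancestry.
- Stimulation-level AF tests ignore within-animal clustering (flagged in
  the report).
- The synthetic cohort has no LD, no pedigree structure, and no
  responder-heterogeneity in AF induction; conclusions from passing tests
  transfer to real data only for the properties listed above.
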