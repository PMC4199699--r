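---
title: "Reconstructing mosaic chromosomes and building introgression panels in diploid wheats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing mosaic chromosomes and building introgression panels in diploid wheats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgramap)
```

## The problem

*Triticum monococcum* (einkorn, genome A^m^) and *T. urartu* (genome A^u^)
are diploid wheats that are only marginally cross-compatible: F~1~ hybrids
are almost sterile, yet rare hybrid-derived progenies recover fertility and
recombine the two genomes. Working with such wide crosses poses four linked
analysis problems that this package addresses as one toolkit:

1. **Mosaic-chromosome reconstruction.** Given a selfed population derived
   from a single hybrid founder, genotyped with dominant (AFLP-type)
   presence/absence fragments, infer which chromosomal regions of the
   founder were homozygous A^m^, homozygous A^u^, or heterospecific, and
   where interspecific crossing-over took place.
2. **Introgression-line panels.** Given codominant (SSR-type) fingerprints
   of backcross-derived lines, call the donor chromosome segments each line
   carries, select a nonredundant panel, and report per-linkage-group map
   coverage.
3. **Diversity and species diagnostics.** From multi-accession AFLP
   profiles, compute pairwise distances, principal coordinates, and counts
   of species-specific fragments (present in one species' gene pool and
   absent from the other).
4. **Fertility and trait statistics.** Spikelet-fertility arithmetic and
   distribution summaries, and a pooled-error t-test for transgressive
   phenotypes among introgression lines.

Because raw marker matrices for such historical experiments are rarely
machine-readable, the package ships a forward cross simulator whose outputs
carry exact ground truth; every inference stage is validated against it.

## Data model

Everything anchors to a `linkage_map`: loci with a linkage-group label and a
position in centimorgans (cM). Group length is the span of its loci; the
bundled synthetic backbone (`example_backbone_map()`) has 155 loci over
984 cM in seven groups, one marker per 6.35 cM, emulating the density of a
published einkorn SSR map. Its per-group lengths (128.0, 208.0, 151.4, 75.8,
229.4, 85.0, 106.4 cM) were chosen once from published per-group coverage
arithmetic; positions are evenly spaced and are synthetic.

Dominant fragments live in a `fragment_matrix` (calls 1/0/NA plus a
species-specificity label per fragment); codominant markers in an
`ssr_matrix` with calls RR (recurrent homozygote), DD (donor homozygote),
RD. Simulated individuals are `chrom_painting` objects: per linkage group,
two homologs each tiled by origin segments (A^m^ or A^u^), from which the
diplotype (A^m^/A^m^, A^u^/A^u^, Het) is derived.

## The cross simulator

`simulate_gamete()` draws a Poisson number of crossovers per group with mean
length/100 (no interference) and uniform breakpoint positions, then
alternates between the parental homologs. Two deliberate modelling choices:

* **No crossover interference.** The Kosambi function is used only to
  convert estimated recombination fractions to map distances; the generative
  process is Haldane/Poisson. The asymmetry is intentional and documented —
  no interference model is implied by the analyses themselves.
* **Distortion as gametic selection.** Segregation distortion regions
  (`group`, interval, donor transmission probability *p*) act by rejection
  sampling: a gamete carrying the donor origin at the region midpoint is
  accepted with probability *p*, a non-carrier with 1 − *p*, so transmission
  from a heterozygous parent equals *p* exactly, including complete
  elimination at *p* = 0. Regions where the parent is homozygous are
  skipped (transmission there is forced, and rejection would never
  terminate at *p* = 0).

`simulate_pedigree()` runs crossing, selfing and backcrossing from fully
homozygous founders; expectations follow the textbook recursions (donor
genome fraction 2^−(t+1)^ after t backcrosses; heterozygosity 0.5^g^ after
g selfing generations from F~1~), and the suite checks both. All randomness
flows through R's global generator from a single recorded seed, so runs are
replayable byte for byte.

`genotype_from_painting()` implements the defining property of dominant
markers: an A^m^-specific fragment is present whenever at least one homolog
is A^m^ at its position, so heterozygotes are indistinguishable from
presence homozygotes (the null allele is invisible). Codominant loci report
all three states. The fertility generator is a labelled stand-in (no
quantitative fertility model exists for these crosses): expected fertility
is `clamp(baseline − penalty × het_fraction, 0, 1)` and seeds are binomial
over florets.

## Two-point linkage core

`estimate_rf_codominant()` maximizes the F~2~ two-locus likelihood by EM
over the double-heterozygote phase ambiguity (tolerance 1e-8 on r, max 500
iterations, grid fallback on non-convergence — the tolerances are ours, as
the original analyses used packaged software). `estimate_rf_dominant()`
maximizes the dominant-class likelihood directly in one dimension; in
coupling the class probabilities are (2+(1−r)²)/4, (1−(1−r)²)/4 twice and
(1−r)²/4, in repulsion (1−r)² is replaced by r². With unknown phase both
likelihoods are maximized and the better one is kept; an exact tie reports
phase `unknown` and such pairs are never used for phase calls downstream —
repulsion-phase dominant pairs in F~2~ are weakly informative and must not
force a call. Estimates are clamped to [0, 0.5] and flagged at the
boundary. LOD is log~10~ L(r̂) − log~10~ L(0.5).

`group_loci()` reproduces threshold-stepped grouping: single-linkage
components over edges with r̂ ≤ threshold and LOD ≥ 3, stepping the
threshold from 0.250 down to 0.050. The step size (0.050) is our choice;
only the range is documented in the mapping literature we follow. Grouping
is provably nested across thresholds, and the suite asserts it.

`kosambi_cM()` / `kosambi_inverse()` are d = 25 ln((1+2r)/(1−2r)) and
r = tanh(d/50)/2, exact mutual inverses (checked to 1e-12).

## Mosaic reconstruction

The reconstruction of a hybrid founder from its selfed offspring proceeds
in the four classical steps, implemented as:

1. **Species assignment** (`assign_fragment_species()`): a fragment present
   in at least one A^m^ reference parent and absent in all A^u^ references
   is A^m^-specific, and symmetrically; present in both it is shared.
2. **Per-fragment evidence.** In the offspring population a fragment is
   either monomorphic-present (the founder is homozygous for that
   fragment's species at its site — with 200 offspring the probability that
   a heterozygous site shows no absence is (3/4)^200^, i.e. nil), or
   segregating (the founder is heterospecific there). The monomorphic
   threshold is 98% presence, tolerating rare miscalls. Maximal runs of
   monomorphic-present fragments of one species become homozygous subgroup
   calls. Fragment absence in *all* offspring is deliberately not used as
   evidence: presence is the classical criterion, and with species-balanced
   fragment coverage absence adds nothing.
3. **Linkage subgroups and phase** (`call_subgroups()`): segregating
   fragments are paired within a 15 cM window, r̂ and phase estimated, and
   single-linkage subgroups formed at the final 0.050 threshold with the
   LOD ≥ 3 gate. Subgroups are then refined by backbone contiguity: a
   subgroup interrupted by a monomorphic run is split at the interruption,
   since a linkage subgroup must occupy one map interval. Mixed subgroups
   are classified by two-colouring the phase graph (coupling = same
   haplotype side, repulsion = opposite): if each side is monospecific and
   the sides differ, the region is heterozygous (all A^m^–A^u^ pairs in
   repulsion); any species transition along a side is an interspecific
   crossover — the mosaic-chromosome signature — and each transition plants
   an internal breakpoint midway between the flanking fragments.
   A mixed subgroup needs at least one A^m^–A^u^ pair at LOD ≥ 3 to be
   called; otherwise it is reported unresolved. A single-species
   *segregating* subgroup is also reported unresolved: its fragments prove
   the founder heterospecific at their sites, but without a cross-species
   phase partner the second haplotype cannot be localised, and painting it
   with its composition label would contradict the segregation evidence.
4. **Painting and event counting** (`reconstruct_founder()`): anchored
   subgroup intervals (the hull of their members' backbone positions;
   members anchoring to two groups flag a duplicated-block conflict and the
   subgroup stays unanchored) are laid along each group. Every label change
   between adjacent painted intervals counts one crossover event, placed
   midway between the facing interval ends — events are marked between
   bordering polymorphisms, and the midpoint is the natural convention when
   segments are known only at marker resolution. Mosaic-internal
   breakpoints add their events. Unresolved or unanchored calls are never
   painted, and gaps are excluded from all counts; `anchored_fraction`
   reports how much of the map is painted. Overlapping painted intervals
   with contradictory labels are a hard error listing the intervals —
   conflicts are surfaced, never silently dropped.

At the validation scale used throughout (seven groups, fragments every
2 cM alternating species, 200 offspring, 20 founder replicates) the
pipeline recovers ≥ 95% of planted crossovers within 5 cM with no false
events. The residual misses are founder segments shorter than the fragment
spacing — invisible to any marker-based method at that density. What
passing this does *not* show: robustness to high miscall rates, to sparse
or one-sided fragment coverage (single-species regions then stay
unresolved), or to segregation distortion, all of which degrade real AFLP
data; the simulator's regularity is a best case by construction.

## Panels and coverage

`call_donor_segments()` turns SSR fingerprints into donor segments: maximal
runs of consecutive DD (or RD) calls, boundaries midway between the
outermost donor locus and the flanking RR locus, terminal runs extended to
the group end. Missing calls bridge a run up to 20 cM of silent span
(sparse fingerprinting panels make single missing loci common), beyond
which the run splits. `select_nonredundant()` is greedy maximum coverage
with a 1 cM minimum-gain default (suppressing sub-resolution slivers),
lexicographic tie-breaks, and optional exclusion of multi-segment lines —
the single-introgression panel design. Because unconstrained greedy
coverage keeps adding any line with positive gain, at `min_gain = 0` it
attains the exhaustive-subset optimum, which the suite verifies on
instances of up to 12 lines. `coverage_report()` reports the union length,
fragment count and percent coverage per group (percent to one decimal,
matching how such tables are printed).

## Diversity, colinearity, traits

Distances over dominant profiles use pairwise deletion of missing calls and
default to Jaccard — presence-based, the standard choice for AFLP; the
original distance reference is not recoverable, so the metric is an option
(`dice`, `simple_matching`) with a documented default. `pcoa()` is
classical scaling; negative eigenvalues (non-Euclidean input) are reported
but truncated, with no Lingoes/Cailliez correction — the simplest
defensible convention, flagged in the result. A pair of lines with no
jointly scored fragment gets `NA` and a warning rather than an imputed
value. `count_species_specific()` removes the declared intermediate
accessions *before* counting, so a fragment present only in excluded lines
of the other species still counts as specific.

`compare_maps()` matches loci across two maps by exact name (no fuzzy
matching), classifies each against a declared homeology mapping (identity
by default — the two A genomes share chromosome numbering), and reports
Kendall's tau per homeologous pair as the rank-order concordance.

`fertility_percent()` is 100 × seeds / (florets × spikelets) with two
florets per spikelet by default, reported to one decimal;
`fertility_histogram()` uses 10-point classes with a closed top bin and
reports all tied mode classes (a bimodal distribution yields two).
`transgressive_test()` takes the pooled within-entry mean square from a
one-way ANOVA over all entries and tests each line against the best parent
(the larger parent mean) one-sided on the residual degrees of freedom;
parents are compared two-sided. No multiple-testing correction is applied
by default, matching the classical presentation; Bonferroni is available.
With two replicates per entry and a line planted three pooled SDs above the
best parent the noncentrality is exactly 3, so one-sided power at α = 0.05
is 1 − pt(qt(0.95, df), df, 3) ≈ 0.90 at df = 30 — a ceiling of about 0.91
even at infinite df. The suite checks the empirical power against this
exact value rather than against a round number.

## Reproducibility and problem sizes

`run_pipeline()` executes simulate → mosaic/panel/diversity/traits from one
declarative configuration with a single master seed and writes a manifest
with an MD5 checksum per output; identical configurations replay to
identical checksums. The validation sizes used by the test suite and the
acceptance script — 20 founder replicates × 200 offspring for mosaic
recovery, 1000 random tables for the estimator/oracle comparison, 1000
backcross lines for the BC~6~ expectation, 1000 simulations each for power
and size — were chosen as the smallest sizes at which Monte-Carlo error is
negligible relative to the tolerances being asserted.

## Known limitations

* Multipoint map ordering is out of scope: the backbone map is an input,
  and only two-point estimation and threshold grouping are implemented.
* The mosaic caller assumes an F~2~-type founder selfed once; backcross
  material is handled by the panel module directly from genotype calls.
* Recombination gaps between anchored segments are reported as unpainted
  map, never sized.
* The fertility generator is a stand-in for data generation, not a model of
  the cytoplasmic/epigenetic cross-direction asymmetry seen in real
  reciprocal crosses, which is not simulated.
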