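---
title: "Methods: alignment, shift correction and normalization of T-RF profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment, shift correction and normalization of T-RF profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflptools)
```

# The data and its noise structure

A T-RF profile is the list of peaks called for one capillary
electrophoresis loading of one sample: fragment size estimates in
bases, with peak heights and areas in fluorescence units. Two
properties of this data drive every design decision in the package:

* **Size estimates vary between runs.** Repeated loadings of the same
  restriction digest do not produce identical sizes. The variation has
  two components: a *systematic* shift, in which essentially every T-RF
  of one run is estimated slightly longer or shorter than in another
  run, and residual per-peak jitter. The systematic component is the
  larger of the two (see "Calibration of the simulator" below): this is
  what makes a dedicated correction step worthwhile, because a single
  additive offset per profile removes most of the disagreement.
* **Total fluorescence (TF) varies with loading and concentration.**
  The sum of peak heights (or areas) of a profile tracks the amount of
  DNA injected. Because peak calling uses a fixed height threshold,
  profiles with higher TF show more T-RFs - but the extra T-RFs are
  essentially all of low relative abundance. Comparisons of profiles
  with unequal TF therefore confound community differences with loading
  differences unless the profiles are normalized.

# Detection filtering

`apply_detection_threshold()` keeps peaks with height at or above the
peak detection threshold (PDT) and size inside the analysis range.
Defaults are PDT 50 and range 50-1020 bases; a PDT of 100 is the
stricter option used when false positives (e.g. spectral pull-up peaks,
which stay below ~100 units) are a concern. Both comparisons are
inclusive: the PDT is defined as the *lowest acceptable* peak height, so
a peak exactly at the threshold is kept. The filter is idempotent and
may be applied post hoc to exported tables.

# Moving-average alignment binning

`moving_average_bin()` aligns profiles by the moving-average procedure:

1. The globally shortest unbinned T-RF seeds a new bin.
2. Every unbinned T-RF at most `y` bases longer than the seed joins the
   bin, at most one per profile.
3. The bin mean is computed; unbinned T-RFs at most `z` bases longer
   than the mean are admitted one at a time, the mean being recomputed
   and the window re-searched after every admission.
4. When no T-RF qualifies, the next bin is seeded from the shortest
   remaining T-RF.

Defaults are `y = 1`, `z = 0.5`. The published description leaves three
details open, which the package fixes deterministically:

* When a profile has several candidates inside a window, the candidate
  closest to the current reference (the seed during step 2, the bin
  mean during step 3) wins; ties go to the shorter fragment.
* Exact size ties across profiles are processed in profile input order.
* The seed window runs once; the re-search loop belongs to the
  mean-relative extension phase only.

These choices are covered by a property test that re-executes the
procedure with an independent, deliberately naive implementation on
randomly generated instances (up to 6 peaks over up to 3 profiles,
1000 instances) and requires identical bins.

**Ambiguity classification.** `classify_bins()` flags a bin *ambiguous*
when any of its T-RFs lies within the alignment range (default 1 base,
inclusive) of a T-RF in another bin; the relation is symmetric. For
alignments of exactly two replicates, `resolve_duplicate_ambiguity()`
re-pairs the peaks inside each connected cluster of ambiguous bins so
that the most similar sizes are matched: among order-preserving
matchings with pair differences at most the alignment range it
maximizes the number of pairs and then minimizes the total absolute
difference (a small dynamic program). For more than two profiles this
greedy repair is not well defined, and the systematic shift correction
below is the appropriate tool.

`drop_ambiguous_bins()` removes bins that remain ambiguous. This is the
conservative core of the workflow: information is sacrificed so that
similarities are never driven by uncertain binning.

**Integer binning.** `integer_bin()` implements the round-to-nearest
comparison treatment (halves away from zero, so 99.5 rounds to 100).
Two T-RFs of 134.4 and 134.6 bases land in different bins under this
rule - the standard argument against it - and it has no sub-base
resolution, so it cannot be combined with shift correction.

# Systematic shift correction

`correct_systematic_shift()` assumes the size-estimation error of each
profile is a constant additive offset. Every T-RF that is present in
all profiles and sits in a correct bin is a candidate reference. For a
candidate, the common value is the mean of its observed sizes, each
profile's offset is (common value - that profile's size), and the
candidate is scored by the sum over correct bins of the standard
deviation of offset-corrected member sizes. The minimal-score reference
wins (ties to the smaller bin mean), all sizes are offset, and the
profiles are re-binned and re-classified on the corrected sizes.

Numerical notes:

* Only relative offsets affect the score; the choice of the common
  value (mean) affects reported bin sizes only.
* Corrected sizes live in a separate `size_corrected` column; original
  estimates are never overwritten, because the correction is relative
  to the profile set at hand.
* Scoring uses the *pre-correction* alignment's correct bins during the
  candidate search; re-alignment happens once, after selection. The
  procedure is not iterated to a fixed point - one pass suffices for
  constant offsets, which the model assumes anyway (re-running on
  corrected profiles yields offsets of zero, which is tested).
* For noiseless constant offsets the recovery is exact to machine
  precision. Under per-peak jitter the offset error is on the order of
  one jitter draw (the algorithm anchors on a single reference T-RF;
  the minimization over candidates selects a well-aligned one, but the
  error does not average over bins). Sizes are carried at full
  precision throughout; display rounding to two decimals happens only
  in output files, since the correction works with sub-0.1-base
  differences.
* `detect_pairwise_shift()` reports a pair as shifted only when all
  nonzero per-bin differences agree in sign; zero differences are
  sign-neutral and all-zero pairs are not shifted.

# Normalization

Five procedures are provided via `normalization_config()`:

* **TFN-heights** (`tfn_normalize()`, basis height, threshold = PDT):
  iteratively rescales each profile to the group's minimum TF, removing
  peaks whose scaled height falls below the PDT.
* **TFN-areas** (basis area, threshold = minimum observed area in the
  whole dataset) and **TFN-areas-LT** (threshold = minimum observed
  area among the replicates being normalized).
* **FPT-heights / FPT-areas** (`fpt_normalize()`): single-pass removal
  of T-RFs with relative abundance strictly below a fixed fraction
  (default 1%); survivors are not rescaled and the threshold is not
  re-applied.

The TFN iteration re-evaluates the *original* peak set under the
cumulative scale factor each round, so a removed peak may re-enter.
This is what makes the documented oscillation possible: a peak near the
threshold can be alternately excluded (TF falls below the minimum) and
included (TF rises above it). The iteration detects this two-state
cycle by hashing the retained-peak set and, on a period-2 repeat,
returns the peak-wise average of the two states - a peak absent from
one state contributes zero to its average, and an averaged peak is
retained even if its averaged signal sits below the threshold, since
averaging is the declared terminal step. A destructive-removal mode
(peaks stay removed) is available as a documented alternative.
Convergence is |TF - TFmin| / TFmin below 1e-9, capped at 1000
iterations; the minimum-TF profile is returned untouched.

Group scope matters: `groups = NULL` normalizes all profiles to one
dataset-wide minimum, a per-sample grouping normalizes replicate pairs
to their pairwise minimum. Both are exposed. The dataset-wide scope is
what removes the dependence of T-RF count on pre-treatment TF: every
profile is then cut at the same effective abundance threshold, whereas
pairwise scope cannot remove concentration differences *between*
samples (this distinction is exercised in the test suite).

# Consensus profiles and similarity

`build_consensus()` keeps the alignment bins present in at least
`min_presence` replicates (default: all, normally two) and averages
size, height and area over the members actually present. Averaging over
present members (not over all replicates) follows from keeping only
fragments observed in every replicate in the default workflow.

`build_abundance_matrix()` computes relative abundances over the bins
retained *after* the chosen treatment, renormalized so each profile
column sums to 1 - comparisons proceed on the post-treatment peak set.
`similarity_matrix()` then gives Jaccard (presence/absence: shared
T-RFs over distinct T-RFs) or Bray-Curtis (1 minus half the sum of
absolute abundance differences; equal to the sum of bin-wise minima for
unit-sum vectors, an identity tested to 1e-12). Two empty profiles are
defined as identical (similarity 1, with a warning) rather than an
error, because aggressive filtering can legitimately empty a profile.
`write_similarity_matrix(..., as_distance = TRUE)` exports
1 - similarity for ordination software.

# The treatment registry

`treatment_presets()` encodes nine named stage compositions, from
`PDT50 NoNorm NoAlCorr` (threshold, align, nothing else) to
`PDT100 TFN-H RepNorm` (strict threshold, TFN-heights on replicates
and consensus profiles, shift correction, ambiguous bins dropped). The
three `TRex-*` presets reproduce only the downstream composition of the
corresponding external-tool analyses: their first stage, an external
noise filter, is out of scope here, so they refuse to run unless the
caller asserts the input is already filtered; they average the union
of replicate peaks instead of intersecting, and `TRex-H Round-up` uses
integer binning. `run_treatment()` records the mean T-RF count and mean
TF after every stage; for the intersection-consensus presets the count
trajectory is non-increasing by construction, which the acceptance
suite checks for all six fully self-contained presets.

# The synthetic data generator

`simulate_dataset()` draws datasets with known ground truth for a
factorial design (samples x replicates x loadings, with per-sample
concentrations). The generative model:

* **Community**: `n_fragments` true sizes (default 40), uniform over
  the analysis range with at least 3 bases spacing; base abundances
  follow a geometric rank-abundance series (ratio 0.85). Each sample
  tilts the series by a random power (uniform on 0.5-1.5) and adds
  per-fragment log-normal noise (sd 0.6), giving the between-sample
  compositional variability without which peak count would be a pure
  function of TF.
* **Sizes**: observed size = true size + per-profile systematic shift
  (uniform on +/-0.3 bases) + per-peak jitter (normal, sd 0.0593,
  truncated at +/-0.15).
* **Signals**: height = abundance x base signal (15000) x concentration
  x replicate yield multiplier (log-normal, cv 0.15) x loading
  multiplier; area = height x (1 + 0.002 x size), reflecting peak
  broadening with migration time.
* **Loadings**: the relative TF difference between consecutive loadings
  of one digest is drawn directly from a truncated normal (mean 17%,
  sd 7%, max 33%) with random direction.
* **Artifacts**: Poisson-distributed artifact peaks (rate 5) with
  uniform sizes and heights uniform on 20-100 units, spanning baseline
  noise up to sub-threshold pull-up peaks.

Two calibration choices deserve explanation. First, the loading effect
is modeled as a pairwise difference rather than an independent
multiplier per loading: the observed duplicate TF differences have a
nonzero mode and a small spread relative to their maximum, a shape no
symmetric independent-multiplier model can produce (the difference of
iid draws always has its mode at zero and a heavy tail relative to its
mean). Second, the split of size noise into shift and jitter is fixed
jointly by four duplicate statistics (mean difference 0.21 bases,
spread, maximum below 1, ~90% below 0.5) *and* by the fraction of
profile pairs showing a coherent all-one-sign shift (roughly half): a
jitter-dominated split reproduces the first four but yields almost no
detectable systematic shifts, so the systematic component must
dominate. The defaults give a simulated shifted-pair fraction of about
0.4-0.6 at the 38-profile scale.

What the simulator does *not* emulate: raw electropherogram traces,
restriction-site biology (fragment sizes are arbitrary, not derived
from sequences), PCR amplification bias, size-dependent signal decay
within a profile, and non-constant (size-dependent) shift curves.
Passing tests therefore demonstrate correctness of the data treatment
under the characterized noise model, not performance on any particular
real instrument or community.

`evaluate_recovery()` closes the loop: bin-to-fragment assignment
accuracy, artifact leak counts, abundance RMSE against per-sample
truth, and per-profile shift-recovery error (offsets are relative, so
errors are centered before comparison).

# Problem sizes and tolerances used by the tests

The suite runs the binning oracle on 1000 random instances, similarity
identities on 10<sup>4</sup> random vector pairs, duplicate noise
statistics on 600 simulated pairs (the systematic shift is shared
within a pair, so the pair - not the peak - is the Monte-Carlo unit),
shift recovery on 3-profile, 20-fragment simulations (noiseless exact
to 1e-9; jitter sd 0.05 recovered within 0.05 bases), and full
treatment runs at the 38-sample x 2-replicate scale of a typical
longitudinal dataset. TFN convergence is asserted at 1e-9 relative;
cycle-averaged profiles are within one contested peak's half-signal of
the minimum TF.

# Known limitations

* The shift model is a constant additive offset per profile; smooth
  size-dependent miscalibration is out of scope.
* `resolve_duplicate_ambiguity()` is specific to two profiles.
* The TFN cycle handling covers period-2 oscillations, the only kind
  the rescale/remove dynamics are known to produce; longer cycles, if
  ever encountered, terminate with a diagnostic error rather than a
  silent average.
* The `TRex-*` presets document, but do not implement, the external
  noise filter they depend on.
* NMDS ordination and significance testing are deliberately not
  included; the package exports the matrices those tools consume.
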