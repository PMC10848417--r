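---
title: "Rare-subclone analysis of paired primary and metastatic tumors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-subclone analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rareclone)
```

## The question and the assay

Metastatic recurrences of breast cancer routinely carry mutations that
standard whole-exome sequencing (WES) never saw in the antecedent
primary tumor. Two readings are possible: the mutations arose after
dissemination, or they were present all along in a subclone too rare
for WES (which cannot reliably call variants below roughly half the
tumor cells at ~50x). Ultra-deep sequencing with unique molecular
identifiers (UDS-UMI) collapses reads into molecular tags (MTs), each
representing one pre-amplification DNA molecule, pushing the error
floor low enough to interrogate subclones of a few percent of cells —
provided two artifact sources are controlled: PCR/sequencing errors
(handled by the UMI consensus upstream of this package) and
formalin-fixation (FFPE) cytosine deamination, which masquerades as
low-VAF C>T variants and is enzymatically depleted by uracil-DNA
glycosylase (UDG) before library preparation.

`rareclone` takes the UMI-collapsed per-site variant tables as input
and implements everything downstream: detection power, CCF estimation,
artifact quantification, co-clonality and false-positive inference,
and the driver-versus-passenger likelihood framework. It does not
align reads, build UMI consensus or re-implement the caller.

## Detection power

At a site with `n` effective observations and a caller demanding `m`
alternate observations, the smallest reliably detectable VAF is the
smallest `v` with `P[Binomial(n, v) >= m] >= 0.95`, found by bisection
on the exact binomial tail to an absolute tolerance of 1e-6
(`min_detectable_vaf()`). The CCF equivalent (minCCF~95%~) converts
through the purity/copy-number map at multiplicity s = 1, the
conservative choice; per-s values are available.

The published assay does not print its calling rule, so the defaults
were chosen to reproduce its printed summaries and are exposed in
`tech_model()`:

* **UDS-UMI: 8 variant MTs.** At the printed median MT coverage of
  1160 and typical purity ~0.7 this gives a median minCCF~95%~ of
  ~3.2% of cells (printed: 3.1%), and ~0.9% of cells beyond 4000 MTs
  (printed: 0.9%).
* **WES: depth 50, 5 variant reads.** `min_detectable_vaf(50, 5)` =
  0.174, giving a median minCCF~95%~ of ~0.50 (printed: 0.54) and a
  ~15.4-fold sensitivity gap to UDS-UMI (printed: 17-fold). A
  4-read rule — sometimes quoted for WES pipelines — yields 0.42 and
  ~13-fold, more than 20% from the printed values, so 5 was adopted.
  Both remain configurable.

## CCF estimation with multiplicity uncertainty

With purity `p`, locus total tumor copy number `C_t` (major + minor
from the allele-specific segments, not ploidy-averaged), normal copy
number `C_n = 2` and `s` mutated allele copies,

$$\mathrm{CCF} = \mathrm{VAF}\cdot\frac{p\,C_t + (1-p)\,C_n}{p\,s}.$$

`s` is unknown a priori and bounded by the major copy number;
`ccf_estimate()` reports the value for every feasible `s` (each
exactly the s = 1 value divided by s) and their median as the point
estimate. When the major copy number is 1 the estimate is flagged
unambiguous — the precondition for the pigeonhole test below.

Posterior uncertainty uses a Jeffreys Beta(1/2, 1/2) prior on VAF, so
the posterior is Beta(alt + 1/2, ref + 1/2) mapped through the formula
above. The prior's influence vanishes at UDS depths (hundreds to
thousands of tags); only count uncertainty is modeled — purity and
copy number enter as fixed values, which understates the width of the
violins a fully Bayesian treatment would produce. CCF values above 1
are returned unclamped with a flag: they signal inconsistent
purity/CN/multiplicity inputs, and published per-mutation estimates do
reach ~1.2.

## FFPE burden and UDG depletion

Rare-subclonal variants are defined by VAF strictly below 0.10
(approximately CCF below ~0.2 at full cellularity, ~0.4 at 50%).
`rare_subclonal_burden()` counts called background variants per
(trinucleotide, substitution) class — contexts collapsed to the
pyrimidine strand, 6 substitution types times 16 flanks = 96 classes —
against the covered sites eligible for each class. Classes with no
covered sites report an undefined (NA) rate, never 0.

Deamination is C>T-specific, so a sample's *artifact excess* is its
C>T rare-subclonal per-site rate minus the mean rate of the five other
substitution types (the deamination-free baseline; the source study
does not state its estimator, and this difference isolates the
artifact component testably). For matched UDG-treated/untreated blocks,

$$\mathrm{depletion} = 1 -
  \frac{\mathrm{excess}_{\mathrm{treated}}}{\mathrm{excess}_{\mathrm{untreated}}},$$

with counts pooled across pairs before the ratio (stabler than a mean
of ratios at low counts; per-pair values are also returned). When the
untreated excess is not positive the estimate is returned as NA with
an explicit reason — an artifact burden cannot be demonstrated.
Uncertainty comes from a seeded 1000-iteration parametric bootstrap
that redraws each class's mutated-site count binomially, which is
equivalent to resampling covered sites under within-class
exchangeability.

## Detection status, co-clonality, and sampling bounds

Strata follow the standard definitions: *major* subclone CCF >= 0.50,
*minor* < 0.50, *rare* VAF < 0.10, *undetected* otherwise; sites under
100 MTs are excluded as inadequately covered. When low purity makes a
VAF < 0.10 call exceed CCF 0.50, the VAF-based rare rule wins (the
rare definition is VAF-based and only approximately corresponds to a
CCF band) and a flag records the conflict.

The pigeonhole principle turns CCFs into lineage statements: two
mutations whose CCFs in one sample sum to more than 1 must co-occur in
some cells, and all mutations with CCF > 0.50 belong to one sequential
lineage (`sequential_lineage_set()`, whose size `k` feeds the
evolution framework). `pigeonhole_sum_test()` estimates
P(CCF~a~ + CCF~b~ <= 1) by Monte Carlo over the two posteriors (10^7
draws by default, Wilson interval attached) and analytically from a
Gaussian approximation to the sum; the analytic tail is reported
whenever the Monte-Carlo estimate is exactly 0, since published tails
(~10^-6) sit below practical Monte-Carlo resolution. The test refuses
mutations with ambiguous multiplicity, mirroring its published
precondition.

If every undetected metastasis-specific mutation had really been
sequentially acquired inside the detected ancestral rare subclone, the
nested lineage's CCF could not exceed `min(ancestral CCF, min over
undetected sites of minCCF95)` — otherwise something would have been
seen (`nested_subclone_upper_bound()`).

## Is the detection signal real?

Two orthogonal tests guard against artifact sampling:

1. `prob_false_detections()`: with background per-site rate `q` (from
   the sample's own non-target sites), the number of artifactual
   "detections" among `n` assayed sites is Binomial(n, q) panel-wide,
   or Poisson-binomial over context-specific rates (exact dynamic
   programming). Per-patient tails combine across the cohort by
   Fisher's method (calibrated; the raw likelihood product is also
   reported because the published "combined likelihood" formula is
   unstated). A context class with an observed zero rate legitimately
   yields a zero tail; a combined value of exactly 0 is flagged. At
   panel scale most of the 96 classes have zero observed background,
   so the panel-wide mode is the robust default and the trinucleotide
   mode is reported alongside.
2. `sample_permutation_test()`: reassigns each patient's assayed site
   list to unrelated primaries and recounts detections; sites
   uncovered in a permuted primary are unassayable there and recorded.
   The add-one estimator guarantees P >= 1/(n_perm + 1); small cohorts
   can enumerate all assignments exactly.

Because the tails are discrete, the Fisher combination is conservative
(super-uniform under the null) — verified in the tests via exact-tail
identities, KS-uniformity on randomized tails, and empirical type-I
error at or below nominal on null cohorts. Fisher's method also
dilutes a signal carried by a few patients across many null patients;
on cohort-scale synthetic data the permutation test and the likelihood
product are the sensitive summaries, and all three are reported.

## The sequential-acquisition framework

The probability that a series of `k` mutations, `d` of them drivers
each followed by clonal expansion to a fraction `c` of a tumor of `T`
cells, was acquired within one clonal lineage is

$$P_{\mathrm{sequence}}(k, d) \propto
  \left(1-(1-\mu)^{Tc}\right)^{d}\,\mu^{\,k-d-1}\,
  \left(1-(1-\mu)^{T}\right),$$

evaluated in log space with `log1p`/`expm1` so that exponents down to
10^-266 and far beyond remain finite (`p_sequence()` returns both the
bare probability and its log10). The proportionality constant is never
applied: only relative likelihoods, where it cancels, are interpreted.
`k` and `d` may be fractional because the framework is applied to
cohort averages. Usage of "k = d" for all-driver undetected series
maps to `d = k - 1` here, since the first mutation's factor is
separate and the displayed form requires `d <= k - 1`.

Three parameter regimes matter:

* **Passenger bound.** With `d = 0` the probability is at most
  `mu^(k-1)`; even at a deliberately high exome-wide rate of 0.1
  mutations per cell division this is 10^-3 for 4 mutations and
  10^-4 for 5 (`passenger_upper_bound()`).
* **Passenger-vs-driver ratios.** Under saturated expansion
  (`Tc*mu >> 1`) the ratio collapses to `mu^d`. The published ratios
  (3.2x10^-32 for k = 8, 3.2x10^-266 for k = 60, 10^-90 for k = 60
  with a third drivers) are all consistent with an exome-wide
  `mu = 10^-4.5`, which is therefore the documented default for this
  use — back-derived, configurable, never hard-coded.
* **Bounded expansion.** `p_sequence_bounded()` caps every expansion
  at a CCF ceiling `f` (0.5 for "never a majority clone", 0.03 for
  "beneath the assay's detection floor") by setting `c = f`. Tiny
  bounded probabilities require the sub-saturated regime
  `T f mu ~ 1`, i.e. a per-driver-site rate (~10^-9 per division at
  `T = 10^9`), not the exome-wide rate; `run_full_analysis()`
  defaults to `mu = 1e-9` for this stage. At those values a series
  of 8 undetected drivers kept beneath a 3% floor costs ~10^-11, and
  cohort products collapse by tens of orders of magnitude.

The framework is deliberately minimal: no birth/death rates, no
time-varying mutation rate or tumor size, mutation events treated as
independent. The last assumption is checkable:
`clustered_mutation_fraction()` measures how many mutations fall
within 1 kbp of another (kataegis-style simultaneous events); at the
published ~3% the independence approximation is immaterial.

## The synthetic world

`simulate_cohort()` generates the stated study conditions as defaults:
21 patients; a panel of 204 regions of 11-22 bp; log-normal MT depth
with median 1160 and sdlog 1.1 (matching the printed IQR ~600-2600);
WES resampling at 50x with a 4-read call; block purity uniform on
0.5-0.9 (median ~0.7, the scale at which the printed detection powers
reproduce); ~7.5% of metastasis-specific mutations pre-dissemination
(the study detected 9 of 120 in rare subclones) inside rare ancestral
subclones with CCF log-uniform on 0.02-0.28 (printed detected range
0.019-0.276, median 0.073); a mean of 6 assayed metastasis-specific
mutations per patient, negative-binomially dispersed (printed median
3, IQR 1-8, max 33); untreated FFPE C>T artifact rate 0.01 per covered
C site with UDG efficiency 0.9 (printed bound: >= 88% depleted), with
artifact VAFs uniform on (1/depth, 0.05); context-independent bona
fide background at 0.002 per site (the printed panel-wide example is
~5/2395); and five patients' primary blocks re-sequenced untreated, as
in the study. Subclone CCFs are assigned, not grown — the pipeline
needs controlled CCFs, not growth kinetics, and the evolution module
has its own process-level simulation oracle in the tests.

What a green test therefore establishes: the estimators recover the
parameters of this binomial-sampling world at study scale — detection
calibration within 95% +/- 2%, CCF recovery to < 0.02 median absolute
error at >= 1000 MTs, UDG efficiencies recovered within bootstrap CIs,
permutation and combined tests at or below nominal type-I error. What
it does not establish: robustness to mis-specified purity or copy
number, UMI consensus errors, spatial sampling of real blocks, or
selection-driven clone-size distributions.

## Numerical and interface choices

* Bisection tolerance 1e-6 (absolute, on VAF); detection confidence
  0.95 throughout.
* Thresholds fixed by definition and exposed as arguments: rare VAF
  ceiling 0.10 (strict inequality), major-subclone CCF 0.50, coverage
  floor 100 MTs, co-lineage alpha 0.05.
* Variant positions are 1-based (VCF convention); BED input is
  0-based half-open and converted on read. Contexts always on the
  pyrimidine strand.
* Required variant-table columns: patient_id, sample_id, chrom, pos,
  ref, alt, mt_alt, mt_total, called; extra columns pass through
  untouched, `vaf` is recomputed and cross-checked to 1e-6.
* Zero covered sites in a class: rate NA (undefined), falling back to
  the panel-wide rate inside the artifact model, flagged.
* The interface is the exported functions plus this vignette;
  `run_full_analysis()` orchestrates the stages on an in-memory
  cohort and optionally writes every table as TSV. All randomness is
  seed-controlled; reruns are identical.

## Known limitations

Purity and copy number are treated as known; their uncertainty is not
propagated into CCF posteriors or detection power. The artifact model
assumes background sites are exchangeable with assayed sites after
context stratification. The permutation test conditions on the
observed call sets rather than re-running detection per permutation.
The evolution framework compares models by relative likelihood only —
its absolute values have no calibrated interpretation.
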