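---
title: "Scoring RAD51 foci as a functional HRR biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RAD51 foci as a functional HRR biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad51score)
```

## The assay and its rationale

Homologous recombination repair (HRR) fixes DNA double-strand breaks with
high fidelity; tumors that have lost it — through BRCA1/2 or PALB2
inactivation, among other routes — are selectively killed by PARP
inhibitors. Sequence-based markers are imperfect proxies for the repair
phenotype: they miss non-genetic causes of deficiency and, critically,
they stay positive when resistant tumors *restore* repair. The assay
implemented here reads the phenotype directly. RAD51, the recombinase at
the core of HRR, accumulates into microscopically visible nuclear foci at
break sites; a cell that can form RAD51 foci has a working pathway.

The read-out is a percentage: among tumor cells in S/G2 (marked by
geminin, because HRR operates only when a sister chromatid is available),
what fraction carries five or more RAD51 foci? Samples at or below 10%
are called HRR-deficient. Two quality gates protect the denominator: a
sample needs at least 40 geminin-positive cells, and at least 25% of them
must carry γ-H2AX foci — without endogenous double-strand breaks there is
nothing for RAD51 to respond to, and a low score would be uninterpretable.

## Focus detection

The published protocol counts foci of 0.42–1.15 µm diameter by eye. We
operationalize "diameter" as the **equivalent diameter of the
half-maximum region**: each candidate spot is grown to the connected set
of pixels above background + half its peak height, and
d = 2·√(area/π)·pixel_size. This makes the criterion measurable and
monotone in spot size. Both band edges are inclusive.

Detection proceeds in three steps:

1. **Band-pass enhancement.** A difference-of-Gaussians filter with
   σ_low/σ_high matched to the diameter band. The two σ values are fixed
   when a `foci_params()` object is constructed, so that later edits to
   the band act purely as a post-filter on measured diameters — this is
   what makes "widening the band never decreases counts" a theorem rather
   than a tendency.
2. **Candidates.** Local maxima of the enhanced image above
   `detection_sensitivity` (default 3) robust background standard
   deviations (MAD), de-duplicated at the minimum in-band diameter. A
   second prominence gate at the same multiple of the smoothed channel's
   MAD removes rare noise peaks that would otherwise pass sizing. Both
   thresholds scale with the data, so all outputs are invariant to
   rescaling intensities by a positive constant, and raising the
   sensitivity can only remove candidates (monotonicity).
3. **Sizing.** The half-maximum region is measured on the channel
   smoothed with a σ = 1 px Gaussian; the kernel's width is subtracted in
   quadrature (d = √(d_obs² − FWHM_kernel²)), so on noise-free fields the
   measured diameter equals the rendered one up to pixel quantization. A
   region that touches its measurement window is discarded — it is larger
   than the band allows.

Nucleus segmentation is standard: Otsu threshold on the smoothed nuclear
channel, morphological clean-up, then a distance-transform watershed —
seeds are the local maxima of the smoothed distance map after
minimum-separation suppression (default 4 µm), and the mask is
partitioned around the seeds by seeded propagation with a large
smoothness weight, which splits touching nuclei at the neck. Nuclei under
20 µm² or touching the field border are discarded (border nuclei would
have truncated counts). Geminin positivity is Otsu's threshold on the set
of per-nucleus mean geminin intensities, guarded against degenerate
unimodal inputs by a minimum 1.5-fold contrast between the split groups;
a fixed-threshold policy is available.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `diameter_min`, `diameter_max` | 0.42, 1.15 | µm | the protocol's focus-size band, inclusive |
| `min_foci_per_cell` | 5 | foci | positivity rule behind the score |
| `detection_sensitivity` | 3 | background SDs | candidate threshold; higher = stricter |
| `min_geminin_cells` | 40 | cells | QC gate; fewer is not evaluable |
| `min_gh2ax_score` | 25 | % | damage gate; lower is not evaluable |
| `target_cells` | 100 | cells | scoring denominator target |
| `cutoff` | 10 | % | HRR-deficiency call, inclusive |
| mRECIST bounds | −95, −30, +20 | % | CR/PR/SD edges; PD if day-21 change > +20 |
| pixel size | 0.11 | µm/px | **not from the protocol**: chosen as typical for a 60× oil objective; configurable, and a pixel size too coarse to resolve the band (minimum diameter < 2 px) is flagged in QC metadata |

When a sample has between 40 and 99 geminin-positive cells, all of them
form the denominator: the protocol targets 100 cells but only gates at
40, and discarding evaluable cells would waste information. Cells are
taken in canonical (area, field, nucleus) order so the score does not
depend on record order. The γ-H2AX score is computed over geminin-positive
cells with the same ≥ 5-foci rule as RAD51; the protocol's "25% of
positive cells" phrasing is ambiguous about the reference population and
we chose the geminin-positive one, consistent with every other read-out of
the assay. Too few areas (< 3) is a warning rather than an exclusion by
default — the protocol states it as procedure, not as a QC rule — with a
hard-fail switch. The QC gates are checked in the order geminin count →
γ-H2AX → areas, and the first failure is reported.

## Tumor response

Caliper volumes use V = (π/6)·L·l². The printed form of this formula
("4π/3/L×l×l") is typographically ambiguous; read with semi-axes L/2 and
l/2 it is the standard scalene-ellipsoid formula above, and because
percent change is a ratio the leading constant cannot affect any
classification. "Best response sustained for at least 10 days" is
operationalized as the minimum percent change at time points ≥ 10 days
after treatment start; an alternative reading (value maintained across a
10-day window) is available via `rule = "window"` and is never less
conservative. Day-21 changes match the nearest measurement within ±3 days
(measurements are bi-weekly), earlier on ties. Models with several animals
are classified on the mean percent-change trajectory (each animal
normalized to its own day-1 volume); per-animal classification with a
modal call is exposed as an option.

## Statistics

The ROC AUC is computed by pair counting (the Mann–Whitney statistic:
concordant pairs 1, ties ½, divided by n₁n₂), which equals the
trapezoidal area under the empirical ROC curve — the suite verifies this
against an independent implementation. Score directions are explicit
(`"low"` for RAD51, where low scores indicate responders; `"high"` for
HRD-type scores) to prevent silent AUC flips.

Two AUCs on the same cohort are compared by a stratified paired
bootstrap: models are resampled within responder and non-responder
classes, the AUC difference recomputed per replicate (default 2000), the
CI taken as the 2.5/97.5 percentiles, and the two-sided p from the normal
approximation D/sd(D\*). The percentile interval is widened, if necessary,
to include the observed difference, so the reported triple is always
internally consistent. With identical scores the bootstrap distribution is
degenerate at zero and p = 1 by convention.

For 2×2 tables with a zero cell, plain logistic regression diverges, so
the odds ratio uses the Haldane–Anscombe correction (+0.5 everywhere)
with the Woolf log-scale interval. On the gPALB2 × RAD51-low table
(11, 0, 3, 9) this gives OR = 62.4 with CI ≈ 2.854–1366. A Fisher exact
test (full enumeration of the margin-fixed hypergeometric support) is
provided as the companion significance measure. No multiple-testing
correction is applied anywhere, matching the analysis this package
accompanies.

## What the synthetic data emulates — and what it does not

`synthesize_field()` renders elliptical nuclei (optionally touching, up
to a configurable pairwise overlap cap, default 10% area, to exercise
watershed splitting), a geminin channel elevated ~5× background in a
Bernoulli-sampled S/G2 subpopulation, and marker channels of 2-D Gaussian
spots whose FWHM equals the nominal focus diameter — which is exactly the
quantity the detector's half-maximum sizing measures, closing the loop
between generator and detector. Focus counts are class-conditional
Poisson (focus-forming nuclei λ = 12 in-band foci, non-forming λ = 0.3,
defaults that the ≥ 5-foci rule separates cleanly); γ-H2AX-style channels
use forming fraction 1 and λ = 15 to emulate pervasive damage. Spots are
placed by dart throwing with a diameter-dependent minimum separation
(floor 1.3 µm), because the assay counts *resolvable* puncta; a spot that
cannot be placed is dropped and the ground truth always describes exactly
what was rendered. Noise is additive Gaussian plus per-nucleus intensity
jitter.

Passing tests on these fields show that segmentation, thresholding,
detection and scoring are correct against a known truth. They do not show
robustness to what real FFPE tissue adds: autofluorescence texture,
sectioning artifacts, stain gradients across a slide, strongly aspherical
or overlapping-in-z nuclei, and out-of-focus light. 3-D stacks, optics
and chromatic shift are out of scope by design.

`simulate_cohort()` draws per-model RAD51 and HRD scores from
class-conditional truncated normals. The RAD51 defaults (deficient
N(1.25, 0.5) on [0, 10]; proficient N(66.54, 10) on (10, 100]) mirror the
separation reported for PARPi-sensitive versus -resistant xenograft
cohorts; with disjoint supports the 10% cutoff is perfect by
construction, which is precisely the study condition being reconstructed.
The HRD-score defaults overlap (deficient N(55, 15), proficient
N(28, 15), both on [0, 100]) so that the genomic score is informative but
imperfect, qualitatively matching its reported behavior; per-model HRD
values from the original cohorts are not public, so no quantitative HRD
claim is reconstructed. Class allocation is deterministic (rounded
fraction, then shuffle), giving exact class counts whenever the fraction
divides the cohort evenly. Tumor trajectories are exponential,
V(t) = V₁·e^{k(t−1)}, with log-normal measurement noise (σ = 0.05) and
class-dependent rates: k = ln(0.04)/20 for sensitive models (a −96%
day-21 change, CR) and k = ln(1.3)/20 for resistant ones (+30%, PD).

## Numerical choices and degenerate inputs

- Coordinates are 0-based (row, col) in all user-facing tables; areas are
  pixel counts × pixel_size².
- Blank (zero-variance) nuclear channels segment to zero labels with a
  warning, not an error; a single nucleus or an all-background geminin
  channel yields all-negative geminin calls (there is no bimodality to
  threshold).
- Local maxima use ≥-with-at-least-one-> neighbor comparison, so sampling
  plateaus are kept and then merged by minimum-separation suppression
  (brightest wins).
- MAD-based thresholds carry a 10⁻¹² floor so noise-free images do not
  divide by zero; on such images only true rendered structure survives
  the strict local-maximum test.
- `compare_auc_bootstrap()` restores the caller's RNG state; all
  generator entry points take explicit seeds and are bit-for-bit
  reproducible, which the suite asserts.

## Problem sizes used by the test suite

Detection performance is measured on 50 nuclei at peak SNR 5 (three
512×512 fields), where in-band recall and precision exceed 0.9 against a
2-px matching radius. Bootstrap calibration uses 100 replicate 28-model
cohorts at 500 replicates each. The end-to-end recovery test simulates an
18-model cohort, four 512×512 fields of ~30 nuclei per model, and checks
that every HRR call matches the generating class and that the report's
AUC is 1. These sizes were chosen as the smallest that exercise the
claims convincingly.

## Known limitations

- The detector is tuned to the scoring band; spots far outside it are
  rejected by sizing, not by the enhancement filter, so a pathological
  channel dominated by huge blobs will still spend time measuring them.
- Half-maximum sizing quantizes at the pixel level; diameters within
  ~0.05 µm of a band edge can fall on either side at 0.11 µm/px. The
  protocol's visual criterion has the same soft edge.
- Scoring order (area, field, nucleus) is canonical but arbitrary; a
  different canonical order could select a different 100-cell subset in
  samples with more than 100 geminin-positive cells.
- The Woolf interval after Haldane correction is an approximation to the
  (unspecified) regression interval behind the published OR; it matches
  to ~0.1%.
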