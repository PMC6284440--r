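# rad51score

Functional testing of homologous recombination repair (HRR) from routine
tumor tissue. PARP inhibitors are selectively lethal to HRR-deficient
tumors, but genomic markers (BRCA1/2 status, genomic-scar HRD scores) miss
both non-BRCA causes of deficiency and restored repair in resistant
disease. A direct read-out is the cell's ability to form **RAD51 nuclear
foci**: punctate accumulations of the RAD51 recombinase at double-strand
breaks, visible by immunofluorescence in formalin-fixed tissue.

`rad51score` implements that assay and its companion analyses as a tested
R pipeline:

- **Image quantification** — nucleus segmentation (Otsu +
  distance-transform watershed), geminin positivity calling (geminin marks
  S/G2, the phases in which HRR is active), and band-limited focus
  detection: spots are enhanced with a difference-of-Gaussians filter,
  candidates above a robust noise threshold are grown to their
  half-maximum region, and only foci with equivalent diameter in the
  inclusive band **0.42–1.15 µm** are counted.
- **Scoring** — the RAD51 score of a sample is

  `score = 100 × #(geminin⁺ cells with ≥ 5 RAD51 foci) / #(geminin⁺ cells scored)`

  over the first 100 geminin-positive cells drawn from ≥ 3 representative
  areas. QC gates: < 40 geminin⁺ cells or a γ-H2AX score < 25% (too little
  endogenous damage to read out repair) make a sample *not evaluable*.
  Evaluable samples with score ≤ 10% are called **HRR-deficient**.
- **Tumor response** — caliper volumes V = (π/6)·L·l², percent change
  relative to day 1, best response (minimum change sustained ≥ 10 days),
  and mRECIST classes: CR ≤ −95 < PR ≤ −30 < SD ≤ +20; PD if the day-21
  change exceeds +20%.
- **Discrimination statistics** — pair-counting (Mann–Whitney) ROC AUC,
  sensitivity/specificity at the 10% cutoff, stratified paired bootstrap
  AUC comparison, Haldane–Anscombe-corrected odds ratios with Woolf
  intervals, Fisher exact test, and the usual correlation/group tests.
- **Synthetic data** — `synthesize_field()`, `simulate_cohort()` and
  `simulate_volume_series()` generate microscopy fields, cohorts and
  growth trajectories with exact ground truth, so every stage is testable
  without external data.

## Worked example

```r
library(rad51score)

# an HRR-proficient sample: 3 fields, RAD51 foci in ~60% of nuclei
records <- do.call(rbind, lapply(1:3, function(i) {
  spec <- field_spec(n_nuclei = 30, geminin_fraction = 0.6, seed = i,
                     markers = list(
                       RAD51 = marker_model(forming_fraction = 0.6),
                       gH2AX = marker_model(forming_fraction = 1,
                                            lambda_forming = 15)))
  f <- synthesize_field(spec, field_id = paste0("F", i),
                        area_id = paste0("A", i))$field
  quantify_field(f)
}))
score_sample(records)
#>   sample_id n_geminin_cells n_areas RAD51_score gH2AX_score qc_status   hrr_call
#> 1        S1              61       3    57.37705         100 evaluable proficient
```

57.4% of the 61 geminin-positive cells carry ≥ 5 in-band RAD51 foci and
the γ-H2AX gate passes, so the sample is evaluable and well above the 10%
cutoff: HRR-proficient, hence predicted PARPi-resistant.

Cohort-level discrimination:

```r
co <- simulate_cohort(cohort_spec(n_models = 28, deficient_fraction = 0.25,
                                  seed = 3))
discriminate_report(co, cutoff = 10)
#> Discrimination of rad51_score at cutoff 10 (n = 28, 7 responders)
#>   AUC = 1.000; sensitivity = 100.0%; specificity = 100.0%
#>   2x2 (a,b,c,d) = 7,0,0,21; OR = 645 (95% CI 11.7-3.55e+04); Fisher p = 8.45e-07
```

A full simulate → quantify → score → classify → stats run, with every
intermediate table, a manifest and a Markdown report:

```r
run_pipeline(pipeline_config(seed = 1), "runs/demo")
```

A thin command-line wrapper with the same stages as subcommands lives at
`inst/cli/rad51score-cli.R`.

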