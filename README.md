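# exomeburden

Exome-wide analysis of somatic mutation burden and patient mortality for
small tumor–normal cohorts, as used in studies of metastatic clear cell
renal cell carcinoma: ~10 matched pairs sequenced at depth, a refined set
of high-confidence somatic SNVs, and the question of which genes
accumulate mutations differently in patients who die of their disease.

The package implements the full analysis chain as composable R functions
with classed results:

* **Somatic refinement** — per-sample quality-flag filtering (`badReads`,
  `MQ`, `strandBias`, `SC`, `QD`), merge/joint-genotype/re-filter,
  panel-of-normals germline subtraction (any normal of any patient),
  ≥3-read support, SNV restriction; every stage counted in a filter
  funnel. VCF v4.2 in, TSV/JSON out.
* **Burden association** — per gene, a 2×2 of somatic variant counts
  (gene vs. rest of exome × deceased vs. alive) tested with the
  two-sided Fisher exact test (minimum-likelihood convention), ranked by
  nominal p with no multiple-testing adjustment; QQ data and the
  genomic inflation factor λ = median(χ²)/0.455 as calibration
  diagnostics; an external count-table validation mode.
* **Selection (dN/dS)** — exhaustive opportunity counting per
  trinucleotide context and consequence, synonymous-rate-based expected
  counts, ω = N_obs/E[N] with profile-likelihood tests and intervals,
  exome-wide and per gene, after recurrent-variant exclusion.
* **Mutational signatures** — 96-context spectra (pyrimidine
  convention), constrained maximum-likelihood fitting of a fixed catalog
  by EM with bootstrap intervals, and a two-stage select-and-refit.
* **Gene-set enrichment** — hypergeometric overlap tests against a local
  GMT library with BH adjustment, plus a subsampling sensitivity
  analysis (default 71,000 subsets of 30–100 genes).
* **Synthetic cohorts** — a truth-labelled generator (toy exome, VCF
  emission, planted burden effects, signature mixtures, germline pool,
  caller-flag and homopolymer-indel artifacts) so every stage is
  testable without any external data.

## Worked example

The bundled demo simulates a 10-patient cohort on a 100-gene toy exome
with two planted burden genes (`g042` at 20×, `g057` at 15× in deceased
patients) and runs every stage:

```sh
cd $(mktemp -d)
cp $(Rscript -e 'cat(system.file("extdata", package="exomeburden"))')/demo_* .
Rscript $(Rscript -e 'cat(system.file("cli/exomeburden-pipeline", package="exomeburden"))') \
    run-all --config demo_config.yaml
```

The run report (`demo_out/run_report.json`) from this configuration:

```
filter funnel : 46801 raw calls -> 11482 flagged removed -> 158 joint-flagged
                -> 13620 in-normal -> 396 low-support -> 70 indels
                -> 7192 somatic SNVs
burden        : 100 genes tested, 18 prioritized at p < 0.05,
                top gene g042 (p = 5.9e-77), lambda = 2.12
dN/dS         : 0.981 (95% CI 0.913-1.057), p = 0.63  -> neutral background
signatures    : selected S1, S5, S12 with exposures 0.496/0.297/0.207
                (truth: 0.5/0.3/0.2)
enrichment    : kidney_cancer_dev ranks first (overlap g042,g057 + 2;
                adjusted p = 0.16)
```

Reading it: both planted genes are recovered at ranks 1–2; the planted
signature triple is recovered exactly; the mutational background is
neutral (ω ≈ 1, not rejected) as befits a cohort simulated without
selection; λ > 1 here reflects the genuine planted signal distorting the
complement margins, not miscalibration — under a null simulation λ sits
slightly *below* 1, a known property of median-λ on exact-test p-values
discussed in the methods vignette. At this toy scale a 2-gene overlap is
not significant after adjustment; the subsampling sensitivity output
(`enrichment_sensitivity.tsv`) quantifies exactly that fragility.

The same stages are available as plain functions (`simulate_cohort()`,
`refine_somatic()`, `burden_test()`, `estimate_dnds()`,
`select_and_refit()`, `enrich()`, `subsample_sensitivity()`, ...) — see
the methods vignette in `vignettes/` for the models, conventions and
numerical choices.

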