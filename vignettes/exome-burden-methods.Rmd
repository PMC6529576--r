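---
title: "Methods: somatic burden, selection and signature analysis in small tumor-normal cohorts"
author: "exomeburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic burden, selection and signature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeburden)
```

# Scope

`exomeburden` implements an exome-wide analysis of somatic mutation burden
and patient mortality for small tumor–normal cohorts, of the kind used to
study metastatic clear cell renal cell carcinoma (ccRCC): roughly ten
matched pairs, a somatic SNV load on the order of 10^3 for the cohort, and
a binary vital-status label. The package covers the full chain —
refinement of raw variant calls into a high-confidence somatic set,
consequence annotation, per-gene exact burden tests with inflation
diagnostics, a trinucleotide-context-corrected dN/dS selection estimator,
96-context mutational-signature fitting, overlap-based gene-set enrichment
with a subsampling stability analysis — together with a synthetic cohort
generator that provides truth labels for every stage.

Nothing here calls a variant caller, aligns reads, or queries a web
service: call files (VCF v4.2) are the entry point, and all reference
resources (gene models, signature catalog, gene-set library) are local
files with documented formats.

# Somatic refinement

Raw per-sample calls carry caller quality flags (`badReads`, `MQ`,
`strandBias`, `SC`, `QD`) in FILTER. Refinement runs in a fixed order:

1. **Per-sample flag filter** — any flagged call is discarded.
2. **Merge / joint genotype / re-filter** — the union of surviving variant
   keys is genotyped in every sample (a sample without the call is imputed
   hom-ref with 0 supporting reads; no likelihood recomputation is
   attempted, since the substrate formats carry none). Variants flagged at
   the joint stage (`INFO/JF`) are removed from all samples.
3. **Panel-of-normals subtraction** — a tumor call is removed if its
   (chromosome, position, ref, alt) key occurs in *any* patient's normal
   sample, not only the matched one; with ten patients the cross-patient
   panel is what gives the germline filter its power.
4. **Read support** — somatic candidates need at least 3 supporting reads.
5. **SNV restriction** — surviving indels are reported but excluded from
   the somatic set; at realistic artifact rates for amplicon chemistry,
   essentially all indel calls are homopolymer artifacts anyway.

Variant identity is the exact allele key; no left-alignment or allele
normalisation is performed beyond VCF parsing. That is a documented
limitation for real data (the bundled simulator never emits unnormalised
alleles).

# Per-gene burden test

Burden is the total somatic variant count per gene per patient. For each
gene $g$ the cohort is summarised as a 2×2 table of variant counts,

$$\begin{pmatrix} n_{g,\text{dec}} & n_{g,\text{alive}} \\
 n_{\bar g,\text{dec}} & n_{\bar g,\text{alive}} \end{pmatrix}$$

(in gene vs. elsewhere, by vital status), tested with the two-sided Fisher
exact test under the minimum-likelihood convention (the sum of
hypergeometric probabilities no larger than the observed table's — the
convention of `stats::fisher.test`, which the worked clinical-table
examples pin down). Genes are ranked by nominal p with ties broken by
in-gene count then gene id; **no multiple-testing adjustment is applied**,
deliberately: the ranking feeds a downstream enrichment analysis, and
adjustment would only rescale a monotone quantity. A presence/absence mode
(patients with vs. without a variant in the gene) is available for
sensitivity analysis; with ten patients its smallest attainable p is on
the order of 5×10⁻³, which is why counts, not carriers, are the default.

Calibration is summarised by a QQ plot and the genomic inflation factor
$\lambda = \mathrm{median}(q)/0.4549$, where $q$ are the p-values mapped
to upper-tail 1-df chi-square quantiles. The median method is used — it is
closed-form testable (all p = 0.05 gives λ = 8.44 exactly) — rather than
any regression variant.

**A caveat the package makes explicit:** exact-test p-values are
*super-uniform* (conservative) under the discrete hypergeometric null, so
their median exceeds 0.5 and the median-method λ sits systematically
below 1 even for perfectly calibrated data; simulation at the default
cohort scale puts it near 0.77–0.81, and it falls further as per-gene
counts get sparser. A λ close to 1 should therefore be read as "no
inflation", while values noticeably below 1 reflect test discreteness,
not deflation of real signal. The false-positive rate at p < 0.05
(measured ≈ 4% under the null at default scale) is the sharper
calibration summary for this design.

An external-validation mode applies the identical table construction and
test to per-gene deceased/alive counts supplied as a TSV with a YAML
totals sidecar, mirroring a count extraction from a public cohort.

# dN/dS with trinucleotide-context correction

Opportunities are enumerated exhaustively: every coding base admits 3
substitutions, each classified as synonymous, missense or nonsense by the
standard genetic code (hard-coded NCBI table 1; stop-loss is binned as
missense, a rarity at toy scale) and binned into the 96
pyrimidine-normalised trinucleotide classes. Context-specific rates are
estimated from synonymous counts over synonymous opportunities; the
expected nonsynonymous count is the rate-weighted opportunity sum, and

$$\omega = N_\text{obs} / E[N].$$

Recurrent variants (seen in >1 tumor) are excluded first — shared somatic
keys in a small cohort are germline leakage until proven otherwise, and
they inflate ω.

Two numerical choices deserve note:

* **Sparsity collapse.** When any 96-class has fewer than 5 observed
  synonymous mutations the rate classes collapse to the 6 pyrimidine
  substitution types (deterministically, recorded in the fit). Under
  strongly context-peaked mutational processes a 6-class correction is
  coarser than a 96-class one, and residual context bias of a few percent
  in ω can survive; the threshold is exposed as `min_syn_per_class`.
* **Neutrality inference.** The test of ω = 1 is a profile-likelihood
  ratio test that models synonymous *and* nonsynonymous class counts
  jointly as Poisson with the class rates profiled out. Treating $E[N]$
  as known — the naive plug-in LRT — is badly anticonservative (~25%
  null rejection at n = 2000 in simulation) because $E[N]$ is estimated
  from the same data's synonymous counts; profiling restores ~5%
  rejection. Confidence intervals are profile-likelihood at 95%.

Per-gene estimates use gene-local opportunities with exome-wide rates and
a plain Poisson LRT (a single gene contributes negligibly to the rate
estimates); genes with no observed substitution are reported as
undefined, never 0/0. Missense and truncating ratios are computed
separately and combined. This is intentionally *not* a full
negative-binomial covariate model of gene-level mutation rates: the
questions it serves are exome-wide neutrality and per-gene departures at
toy scale, and those are exactly what the simplified estimator is
verifiable on.

# Mutational signatures

Spectra classify SNVs into 96 categories — substitution type with the
pyrimidine as reference (purine-reference calls are reverse-complemented
together with both flanks) by 5′ and 3′ reference base. Rows are ordered
lexicographically by (substitution, 5′ base, 3′ base) in all files.

Exposures of a fixed catalog (COSMIC v2 layout: 96 rows, one column per
signature; the bundled 30-column catalog is synthetic, generated from
Dirichlet draws, not COSMIC content) are fitted by maximising the
multinomial likelihood over the convex mixture via EM — monotone,
derivative-free, converged when the largest weight update falls below
10⁻⁸ (cap 10⁴ iterations), and testable against a grid-search oracle on
two signatures. Uncertainty comes from ≥1000 nonparametric bootstrap
resamples of the SNV set.

The two-stage procedure fits the full catalog, then *selects* signatures
whose bootstrap lower bound is strictly positive and whose point exposure
reaches a threshold (default 0.05), and refits the selected subset. The
selection rule is an interpretation — "significant activity" has no
unique definition outside a Bayesian fit — and both ingredients are
exposed as arguments. No computational stand-in for biological coherence
is attempted; selection here is purely statistical.

Exposure–covariate association (e.g. signature activity vs. age at
diagnosis) uses Spearman's ρ with the exact permutation null for n ≤ 10
untied samples (verified against full enumeration at n = 6) and the
large-sample approximation otherwise.

# Gene-set enrichment and stability

Enrichment of the prioritized gene list against a local GMT library is
upper-tail hypergeometric per set with Benjamini–Hochberg adjustment
across the library ("adjusted tests" is interpreted as BH). The
background universe defaults to the union of the library's sets; the
recommended setting is an explicit universe file of all genes carrying at
least one somatic variant.

Stability is quantified by re-running the enrichment on many random
subsets of the query (default 71,000 subsets of sizes uniform on 30–100,
clamped to the query; the size distribution is a package choice, as none
is canonical) and reporting, per set, the proportion of subsamples
significant after adjustment, with a per-size breakdown. Subsampling is
deterministic given its seed.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
reference study conditions: 10 tumor–normal pairs, 900 expected somatic
SNVs per tumor (the cohort total of ~9×10³ divided evenly, since no
per-patient distribution is available to emulate), 2000 germline variants
per patient with half drawn from a shared pool, a 40% mortality fraction,
read support from a shifted Poisson with mean 30 and a 5% low-support
(1–2 read) contamination, a 5% per-flag artifact rate, ~30 spurious SNV
calls and ~50 homopolymer-indel artifacts per sample (indels are placed
only inside runs of ≥4 identical bases and truth-labelled artifact), and
signature exposures 0.5/0.3/0.2 on catalog columns 1, 5 and 12 — the
three-active-signatures structure the two-stage fit is meant to recover.
54% of somatic SNVs are placed in coding sequence. Somatic trinucleotide
classes are drawn from the exposure-weighted catalog mixture and matched
to sites without replacement within each (gene, class) stratum, so pooled
spectra track the mixture.

Design points that matter for interpreting tests:

* **Quality flags are site-level within a patient** (tumor and normal
  agree), as caller flags are locus properties. Per-call independent
  flags would let a germline variant flagged only in the normal slip
  through the panel of normals — an artifact of the emulation, not of
  real pipelines.
* **Truth categories occupy disjoint site subsets.** A master-seed
  partition assigns each possible substitution to the germline, somatic
  or artifact pool (25/65/10%). On a 3-Gb genome cross-category key
  collisions are negligible; on a ~100-kb toy exome they would be common
  enough to corrupt the truth structure (a somatic call subtracted as
  another patient's germline) and to make patient streams
  non-independent.
* **One RNG stream per patient**, derived from the master seed by fixed
  offsets: adding a patient leaves earlier patients' calls byte-identical.

What the generator does *not* emulate: read-level data (no FASTQ/BAM, no
base qualities), copy-number or structural variation, per-patient somatic
load heterogeneity, transcript structure (genes are single-exon,
intronless, so "exonic/intergenic" is the whole element vocabulary), or
realistic gene length dispersion (lengths are Poisson around the mean).
Passing tests therefore demonstrate the correctness of the analysis
machinery under the stated statistical structure, not robustness to the
full messiness of FFPE amplicon sequencing data.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately desk-sized
scales, chosen as the package's reference configuration: a 100-gene toy
exome with ~900-bp coding sequences (~10⁵ bases, ~3×10⁵ possible
substitutions), 2,000-SNV draws for selection analyses, 10⁴-SNV spectra
for signature recovery with 10³ bootstrap resamples, and 20-seed
replicates for calibration and power claims. Every stochastic routine
takes an explicit seed and restores the caller's RNG state; identical
inputs and seeds reproduce identical files, reports and JSON artifacts.

# Known limitations

* Allele keys are compared verbatim; unnormalised indel representations
  from external callers would evade the panel-of-normals join.
* The 6-class sparsity collapse can leave residual context bias in ω
  under strongly peaked mutational processes (see above).
* The median-method λ is conservative for exact tests (see the burden
  section); comparisons against λ values computed by regression methods
  on continuous tests are not like-for-like.
* The hypergeometric enrichment treats genes as exchangeable; no
  gene-length or mutability covariate enters the null, which is the main
  reason an explicit variant-bearing universe is recommended.
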