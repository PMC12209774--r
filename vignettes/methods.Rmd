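---
title: "Detecting enhancer hijacking from cohort WGS and RNA-seq: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting enhancer hijacking from cohort WGS and RNA-seq: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hijackr)
```

## The problem

Enhancer hijacking is a noncoding driver mechanism: a structural
rearrangement places an active enhancer inside the topologically associating
domain (TAD) of a proto-oncogene, producing strong, usually monoallelic,
overexpression of a gene that is otherwise silent or weakly expressed in
that tissue. Unlike recurrent fusions, these events are scattered across
many different partner loci, so they must be detected **per sample**, using
the rest of the cohort as the background. hijackr implements such a
detector for cohorts with WGS-derived breakends and RNA-seq expression; it
does no upstream calling (alignment, SV/CNA/SNP/fusion calling, TAD
inference and ROSE enhancer ranking are all inputs, not outputs).

## Model

### Candidate and reference samples

Only genes exceeding 1 TPM in at least one sample are considered (strict
inequality; `min_tpm_expressed`). For a gene, a sample becomes a
**candidate** when any end of any of its breakend pairs falls inside the
gene's search region: every TAD overlapping the gene body, extended by
`tad_extension_bp` (default 80 kb, guarding imprecise TAD boundary calls),
or a ±`fallback_window_bp` window (default 1.5 Mb) when no TAD list is
given. All other samples are **references**. Each junction end is tested
independently; TAD membership is any overlap with the gene body, not
TSS-only, since enhancer contacts can act across the body. Genes need at
least one candidate and `min_reference_samples` (default 5) references to
be scored — with fewer references the background mean and SD are too
unstable to standardize against.

### Score components

*Overexpression.* Expression is corrected for copy number
(TPM × 2/CN) so amplification-driven overexpression cancels, then
log-transformed as ln(0.5 + E). With μ and σ the reference mean and SD,
t = (ln(0.5 + E) − μ)/(σ + `sigma_floor`). The floor (0.3) prevents
runaway t when references are nearly constant — the common case for a
silent gene, where σ ≈ 0. The score is ln(t − 1) for t > 2 and
−2 ln(3 − t) otherwise: continuous at t = 2 (both branches are 0),
strictly increasing, and logarithmically damped on both flanks so neither
one extreme outlier nor one deeply average sample dominates the weighted
sum downstream.

*Allele-specific expression.* Hijacking activates one allele, so candidate
samples should show allelic imbalance at heterozygous SNPs. Each SNP's
reference/alternative counts are scored by the log-likelihood ratio of a
monoallelic model — an equal mixture of beta-binomials with means
`mono_means` (0.02/0.98, allowing leaky expression of the silent allele) —
against a biallelic beta-binomial with mean 0.5. All three components share
one concentration `bb_concentration` (s = 10; α = ps, β = (1−p)s), a
moderate overdispersion consistent with RNA-seq allelic counts; the
symmetric mixture makes the ratio exactly symmetric in (ref, alt). Ratios
are clamped to ±`llr_clamp` (20) so a single ultra-deep SNP has bounded
influence, then combined as Σ llrᵢ/(n + 2): an average with damping, so two
concordant SNPs outscore one. The score is forced to 0 where allelic
balance carries no signal about hijacking: copy number below `ase_cn_low`
(2) or above `ase_cn_high` (4), sex-chromosome genes, imprinted genes, or
no usable SNPs.

*Hijacked enhancers.* Orientation-aware traversal: a breakend pair
contributes when one end lies in the gene's search region with the gene
body on its retained flank (the derivative allele keeps the gene) and the
partner end lies elsewhere. Enhancers on the partner's retained flank are
collected from the junction up to the nearest TAD boundary in that
direction — a proxy for the derivative TAD — capped at
`fallback_window_bp` when no boundary exists. Enhancers inside the gene's
own search regions are excluded (no self-hijack) and each enhancer counts
once even if reached by several junctions. Unknown orientations are tried
both ways and the union kept, conservative toward sensitivity. With
enrichments sorted descending, S_enh = Σ Eᵢ/(i+1); the harmonic weights
encode that one strong enhancer matters more than many weak ones. ROSE
enrichment units are consumed as provided — their scale is dataset-specific
and `w_enhancer` is the knob that balances their influence.
`merge_enhancer_rankings()` averages ROSE scores across ChIP-seq datasets
(matching enhancers by ≥50% reciprocal overlap, absent datasets
contributing 0), since single-experiment rankings are highly variable.

*Deletion penalty.* A rearrangement that hijacks an enhancer should not
delete its target, so candidates with gene CN below
`deletion_cn_threshold` (1.5, covering integer CN ≤ 1 and subclonal
fractional losses) are penalized by 1.

### Combination, aggregation, FDR

S = ω_ovx·S_ovx + ω_ase·S_ase + ω_enh·S_enh − ω_del·1_del with default
weights (4, 2, 1, 1); the gene score aggregates candidates as
S_gene = 5 Σ Sᵢ/(n + 4), the single-sample identity with a mild recurrence
bonus. All candidates contribute, including negative ones — the formula is
applied as stated rather than truncated, so one strong event in a
recurrently rearranged region can be diluted by breakpoint-bearing samples
without expression change (a documented behaviour, not a bug).

The null distribution is resampled: per gene and iteration, 1–3 randomly
chosen reference samples (uniform, mirroring typical observed candidate
counts) are scored as pseudo-candidates — overexpression against the
remaining references, their observed ASE and deletion status, enhancer
score 0 since they carry no qualifying breakend — and aggregated by the
same formula. `niter` (50) iterations give a pooled list of
niter × n_genes null scores; genes enter the null when they retain at
least `min_reference_samples` + 3 references so pseudo-candidate scoring
stays comparable. Empirical p-values use the add-one convention
p = (1 + #{null ≥ obs})/(1 + N) — strictly positive, ties counted — and
are Benjamini–Hochberg adjusted across the tested genes only. The
`fdr_threshold` (0.2) sets a reporting flag and never touches scores.

## Numerical and reproducibility choices

- Natural logarithms everywhere; any other base would only rescale scores
  jointly with the weights, and ln keeps the −2 ln 3 anchor at t = 0.
- Sums written over "n" items run over indices 0…n−1 (n terms).
- Reference σ is the population SD (divisor n); the +0.3 floor makes the
  estimator choice numerically immaterial, but it is fixed for exact
  reproducibility.
- Copy number per gene is that of the maximally overlapping segment (robust
  to segment fragmentation), 2 when uncovered; the 2/CN denominator is
  floored at 1 so homozygous deletions do not blow up the correction.
  Fractional copy numbers are used as-is.
- Coordinates: BED-style intervals are 0-based half-open, breakend and SNP
  positions 1-based; conversion happens once at read time. Chromosome names
  are normalized (leading "chr" stripped, X/Y/MT upper-cased).
- Duplicate SNP rows are collapsed by summing (evidence-preserving);
  zero-coverage rows are dropped with a warning.
- Output ordering is total: FDR, then descending score, then gene_id; reruns
  with identical inputs and seed are byte-identical, including the YAML run
  manifest (which therefore carries no timestamp).
- One master seed (`rng_seed`) drives the null stage; per-iteration
  generator states are derived deterministically from it, and the
  derived-seed stream is itself tested for not biasing the 1–3 draw.
- Cohorts below 10 samples warn prominently but run: the size guidance is a
  recommendation, not a hard precondition.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the statistical structure the detector
assumes, with known ground truth:

- a genome tiled into TADs (~1 Mb, one gene per TAD plus gene-free donor
  TADs), log-normal baseline expression with a silent-gene fraction, and
  log-normal per-sample noise;
- **hijack events**: a silent gene driven to 100–200 TPM in one sample,
  with a gene-retaining junction into a donor TAD containing a strong
  enhancer (enrichment ≥ 5), and monoallelic allelic counts (97% major
  allele — deliberately off the 98% model mean);
- **amplification decoys**: CN 6 segments with 3× expression and balanced
  alleles — overexpression that must cancel under the 2/CN correction.
  They carry no junction of their own, so they also exercise the rule that
  only breakpoint-proximal samples are ever tested;
- **breakpoint decoys**: in-TAD junctions with unchanged expression,
  placed as recurrent loci hitting 1–3 samples (uniform). Real cohorts
  show recurrently rearranged regions, and this recurrence profile is also
  what the resampled null assumes; a cohort of exclusively single-hit genes
  would sit in the null's tail by construction (see Limitations);
- background heterozygous sites at 2 candidate SNPs per gene with per-site
  heterozygosity 0.3, so roughly half of gene-sample pairs have no usable
  ASE information — typical of real allelic-count tables.

All features keep a 100 kb margin from TAD boundaries so the 80 kb
extension cannot create accidental cross-TAD candidates: injected genes are
candidates exactly in their injected samples. The simulator does **not**
emulate read-level noise, chromothripsis-like clustered breakpoints,
fusion transcripts, subclonality, or expression covariates (purity, batch);
passing on simulated cohorts therefore demonstrates the pipeline's
statistical behaviour under its own assumptions, not performance on any
real cohort.

The package's checks use desk-scale problem sizes chosen to keep the full
suite fast while leaving enough genes for distributional assertions: a
recovery cohort of 200 genes × 30 samples with 5 + 5 + 10 injected
events/decoys, and null cohorts of 300 expressed genes × 40 samples with
120 breakpoint-decoy loci (≈120 tested genes, enough for a meaningful
Kolmogorov–Smirnov check of p-value uniformity).

## Known limitations

- **Per-breakpoint independence.** Each junction is traversed
  independently; complex rearrangements that chain several junctions can
  bring an enhancer into the gene's TAD through intermediate segments and
  be missed.
- **Singleton genes under the pooled null.** The null draws 1–3
  pseudo-candidates and pools the aggregated scores. A tested gene whose
  observed candidate count distribution differs from that draw — a single
  candidate with ASE gated (e.g. a high-CN sample), in the extreme — is
  scored against a null that is stochastically more negative, deflating
  its p-value. With many tested genes this is diluted by Benjamini-Hochberg
  ranking; in small cohorts it is the main false-discovery mode.
- **ASE model scale.** The beta-binomial concentration is not identified
  from the data; it is a fixed moderate-overdispersion choice. Cohorts with
  strong reference-mapping bias may need `mono_means` further from 0/1.
- **Enhancer units.** ROSE enrichments are consumed unnormalized; scores
  are comparable within a cohort, not across enhancer catalogues.
- A gene deleted in most of the cohort, or expressed nowhere above 1 TPM,
  is invisible to the method by design.

## Session

```{r}
sessionInfo()
```
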