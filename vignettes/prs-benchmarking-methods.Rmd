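---
title: "Benchmarking polygenic risk scores for Alzheimer's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking polygenic risk scores for Alzheimer's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A polygenic risk score (PRS) summarizes a person's genetic liability to
disease as a weighted sum of risk-allele dosages,
$\mathrm{PRS}_s = \sum_j \hat\beta_j \, g_{sj}$, with weights $\hat\beta_j$
estimated in a discovery genome-wide association study (GWAS). For
Alzheimer's disease (AD) the practical questions are not whether a PRS
associates with case/control status — it does — but *which construction
choices matter*: which discovery GWAS (clinically diagnosed AD versus much
larger proxy-dementia meta-analyses), whether the *APOE* region
(chr19:43.9–46.0 Mb, GRCh38) is scored as part of the PRS, modelled as
explicit ε2/ε4 allele counts, or both; and whether restricting the score to
cell-type-relevant annotation (microglia-selective regulatory regions,
about 3% of variants) retains predictive power. Equally important for
clinical-trial recruitment is whether two defensible PRS pipelines place
the *same individuals* in the high-risk tail.

`prsbench` implements this benchmarking loop as a tested pipeline. Because
the cohorts such analyses run on are access-restricted, the package ships a
simulator with full ground truth; every claim a test makes is checked
against quantities the simulator knows exactly.

# The simulator

## Genotypes

Haplotypes are generated per LD block by thresholding a latent AR(1)
Gaussian: within a block of $m_b$ variants, latent values follow
$z_{k} = \rho z_{k-1} + \sqrt{1-\rho^2}\,\epsilon_k$ and the allele at
variant $k$ is carried when $z_k < \Phi^{-1}(\mathrm{MAF}_k)$. Dosages are
the sum of two independent haplotypes. This gives marginally correct allele
frequencies and a tunable, geometrically decaying LD profile ($r^2$
decreasing with index distance), which is the property clumping needs.
What it does *not* emulate: recombination-map hotspots, population
structure and admixture, imputation uncertainty (INFO scores are
synthesized as a metadata column, not modelled), and long-range LD beyond a
block. Passing tests therefore demonstrate correctness of the pipeline's
logic under a realistic-but-idealized LD regime, not robustness to real
human haplotype structure.

A dedicated block on chromosome 19 carries two designated sites playing the
rs429358 (ε4-defining) and rs7412 (ε2-defining) roles, at their GRCh38
coordinates. The ε2-defining allele is drawn from the *opposite* tail of
the block's latent Gaussian, so ε2 and ε4 alleles live on different
haplotype backgrounds and are negatively associated, as in real *APOE*
haplotypes. A haplotype that would carry both defining alleles (the rare
ε1) is resolved to ε4; consequently per-sample ε2+ε4 counts never exceed 2
and the unphased double heterozygote is the only ambiguous diplotype.

## Liability, ascertainment and covariates

Disease follows the liability-threshold model: liability is the
standardized-genotype genetic component plus $N(0, 1 - h^2 -
\sigma^2_{APOE})$ environmental noise, and a sample is a case when
liability exceeds $\Phi^{-1}(1-K)$. Polygenic effects are i.i.d.
$N(0, h^2/m_c)$ over a causal subset drawn with probability `pi_causal`;
the two ε sites are always causal with per-allele liability effects
`apoe_beta_e4` (default +0.5) and `apoe_beta_e2` (default −0.25), chosen so
the major locus explains roughly 5–7% of liability variance — the order of
magnitude attributed to *APOE* — and produces carrier frequencies around
28% in the population, rising strongly in ascertained cases. Cohorts are
ascertained by rejection sampling until the requested case and control
counts are met (capped at $10^7$ population draws). Age is Gaussian with
cases shifted upward (default +3 years, echoing the age gaps typical of AD
case/control tables); sex is Bernoulli(0.5); neither influences liability
by default — they are pure covariates, exercised by the adjustment step.

The defaults `prevalence = 0.05` and `h2 = 0.2` are configuration choices
in the plausible range for AD, not estimates; no result in this package
depends on their exact values.

## Discovery GWAS

Trait A's per-variant marginal truth is the LD-convolved effect
$R\beta$, using each block's AR(1) correlation $\rho^{|i-j|}$ as the
working LD matrix. The induced *dosage* correlation is slightly attenuated
relative to the latent correlation (threshold dichotomization loses
information), so $R$ should be read as the simulator's own LD bookkeeping;
the GWAS-unbiasedness test is self-consistent under it, and heritability
recovery is unaffected because the LD cross-terms vanish in expectation
over effect draws. Trait B's truth is $r_g A + \sqrt{1-r_g^2}\,C$ with $C$
an independently drawn architecture of equal marginal variance — except at
the two ε sites, whose effects are shared between traits regardless of
$r_g$, since any pair of real AD/dementia GWAS shares the *APOE* signal.
Reported estimates add noise with the standardized-trait large-sample
standard error $SE_j = 1/\sqrt{2p_j(1-p_j)N}$; `N = Inf` gives the
zero-noise limit used by tests that isolate architecture effects from
estimation noise. Defaults are $N_A = 63{,}926$ and $N_B = 487{,}511$
(clinical-AD-sized versus proxy-meta-analysis-sized) with $r_g = 0.8$, a
typical value for the genetic correlation between clinical AD and
proxy-dementia phenotypes.

# The pipeline

## QC

Variant filters follow common post-imputation practice and are applied
with a fixed attribution order (INFO < 0.7, MAF < 0.05, missingness > 5%,
HWE exact $p \le 10^{-6}$) so reports are deterministic. The
Hardy-Weinberg test is the exact conditional test (two-sided: sum of
conditional probabilities not exceeding the observed table's). Relatedness
uses the KING-robust kinship estimator with greedy pruning above 0.125
(the PLINK-style IBD rule $\hat\pi > 0.2$ corresponds to kinship > 0.1;
both thresholds are exposed). Hard calls for HWE, kinship and APOE leave dosages in
(0.4, 0.6) ∪ (1.4, 1.6) missing — an uncertainty guard for imputed data;
the guard band is a declared design decision, since tools differ and no
single convention is canonical. PCA standardizes genotypes at
$2\hat p$, $\sqrt{2\hat p(1-\hat p)}$ and returns unit eigenvectors of the
sample-sample covariance with a deterministic sign convention
(largest-magnitude entry positive).

## Scoring

Harmonization matches on (chrom, pos), keeps effects stated on the
cohort's alt allele, sign-flips effects stated on the ref allele, drops
allele mismatches and (optionally) strand-ambiguous A/T and C/G variants.
Clumping is the standard greedy rule: take the smallest-p unassigned
variant as an index, discard unassigned variants within ±1000 kb with
$r^2 > 0.1$; LD is computed in the target cohort itself (in-sample LD, as
when clumping is run directly on the study genotypes). Ties on p break by
smaller SE then lower position, making the result independent of input row
order. The p-value threshold is inclusive ($p \le p_T$) over the grid
$5\times10^{-8}, 10^{-6}, 10^{-5}, 10^{-3}, 10^{-2}, 0.05, 0.1, 0.5$;
region bounds are inclusive on both ends. Missing dosages are mean-imputed
per variant at scoring. External per-SNP weight files (from
continuous-shrinkage or heritability-model tools, which this package
deliberately does not re-implement) enter through the same harmonization
path, minus thresholding.

One interpretation is worth flagging: when both GWAS are scored, clumping
always uses the p-values of the same GWAS that supplies the weights.

## Risk models and evaluation

Every predictor — each PRS and the ε2/ε4 allele counts — is adjusted for
age, sex and PCs by OLS residualization and then z-scored (n−1
denominator), in that order. The five logistic models are

* M1: AD ~ APOE(ε2 count + ε4 count)
* M2: AD ~ PRS of the APOE region only
* M3: AD ~ whole-genome PRS
* M4: AD ~ PRS excluding the APOE region
* M5: AD ~ M4's PRS + APOE(ε2, ε4 counts)

fitted by IRLS (`glm`-backed, tolerance $10^{-10}$, 100 iterations) with
Wald p-values from the inverse observed information; perfect separation is
reported as a distinct error, detected by coefficient divergence. AUC is
the Mann-Whitney rank statistic with midranks (ties count ½), computed on
the fitted linear predictor — for single-predictor models this equals the
AUC of the predictor itself, and for M1/M5 it is the natural composite.
All models are evaluated on one common analysis set (APOE-callable samples
with complete covariates) so AUCs are comparable across models. The
optimal threshold maximizes M5's AUC (ties to the smaller threshold), and
the microglia analysis selects its own optimal threshold the same way —
these are in-sample selections, as when a benchmark reports per-threshold
supplementary tables. The multiple-testing budget enumerates the full
benchmark grid — 5×2×4 main tests + 1×2×4 ε3ε3 tests + 4×2×4 microglia
tests = 80 — giving a per-test Bonferroni threshold of 0.05/80 = 0.000625.

## Score consistency

Individual-level agreement between two score sets is summarized by the
Pearson correlation and by the overlap of the risk-quintile tails:
samples are ranked (ties broken by sample ID, stable), assigned five
consecutive groups of near-equal size, and the overlap of tail $t$ is
$100\,|T_a \cap T_b|/|T_a|$ with the first assignment's tail as
denominator (both orders coincide when sizes are equal; the denominator
convention is declared, since either choice is defensible). The nominal
per-quintile size is reported as round-half-to-even of $N/5$ — 114 for
$N = 568$ and 153 for $N = 766$.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; only the BED
  boundary converts (0-based half-open on disk). Chromosome labels are
  normalized (no `chr` prefix; `M` → `MT`).
* Only biallelic SNPs are scored; multi-allelic VCF records are hard
  errors with their location, indels are dropped with a count.
* An empty thresholded weight set scores everyone 0 with a warning and
  `n_snps = 0`; the pipeline marks such model cells unusable rather than
  fitting a constant predictor.
* HWE and AUC implementations are each cross-checked against an
  independent enumeration oracle to $10^{-12}$ in the test suite;
  clumping is cross-checked against a brute-force greedy re-implementation
  on instances of up to 12 variants.
* Determinism: a single seed expands into per-stage child seeds through a
  fixed affine map, so any stage re-run in isolation reproduces itself and
  two runs of the same config produce byte-identical output files
  (verified by manifest checksums).

# Problem sizes used by the tests

The shipped tests and the acceptance script run the full pipeline at
reduced scale — hundreds to a few thousand variants in 25–100 LD blocks,
cohorts of 450–2,000 samples (e.g. a 170-case/596-control layout mirroring
a typical clinical cohort), 25 replicates for ordering properties. These
sizes were chosen so the whole suite completes comfortably on a laptop
while keeping Monte-Carlo error well inside each test's stated band; the
statistical properties being checked (null calibration, model ordering,
overlap behaviour under $r_g$) are size-stable.

# Known limitations

* LD is block-diagonal AR(1); there is no background LD between blocks
  and no allele-frequency-dependent LD, so clumping faces an easier
  problem than on real data.
* Discovery GWAS estimates are drawn directly around the true marginals
  rather than computed from a simulated discovery cohort; subtle
  finite-sample phenomena (winner's curse conditional on significance,
  case/control imbalance effects on SE) are not represented.
* In-sample AUC only: no cross-validation or optimism correction, no AUC
  confidence intervals, mirroring benchmark-style reporting.
* The ε1 haplotype is not modelled; the unphased ε2/ε4 double
  heterozygote is flagged ambiguous and counted (1,1).
* Headline numbers from restricted real cohorts are treated as
  qualitative ordering targets for the synthetic benchmark, not as values
  to reproduce: desk-scale synthetic data supports the *ordering* claims
  (M5 ≥ M3 ≥ M4; summary-statistics choice dominating individual-level
  discordance), not the cohort-specific AUC decimals.
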