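---
title: "Mapping isoform-ratio QTL: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping isoform-ratio QTL: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irQTL)
```

## The problem

A gene with several isoforms can be genetically regulated in a way that
gene-level expression QTL (eQTL) analysis cannot see: if a cis variant
pushes the proportions of the gene's isoforms in opposite directions,
the isoform-level effects cancel in the total and the gene looks
genetically inert. irQTL mapping targets exactly this hidden layer. The
phenotype is the *isoform ratio*

$$r_{t,i} = \frac{\mathrm{TPM}_{t,i}}{\sum_{u \in \mathrm{gene}(t)} \mathrm{TPM}_{u,i}},$$

the share of isoform $t$ in its gene's total TPM for sample $i$. Per
gene and sample the ratios sum to 1, so only multi-isoform genes carry
information and one isoform's gain is another's loss.

## Workflow and models

**QC.** Samples are removed when half or more of their genes have zero
total counts (strictly $\geq 0.5$; all genes in the denominator, not
only multi-isoform ones — the package's reading of an ambiguous rule).
Variants are kept when MAF $> 0.05$ strictly; monomorphic variants are
always dropped.

**Covariates and transform.** The genomic relationship matrix is the
VanRaden-type standardized cross-product $K = ZZ'/M$ (missing dosages
mean-imputed here only); its top three eigenvectors are the ancestry
covariates. Each ratio phenotype is first residualized on
\[1, age, sex, PC1..PC3\] by OLS and then mapped through the rank-based
inverse normal transform with Blom offsets,
$z_i = \Phi^{-1}\!\big((\mathrm{rank}_i - 3/8)/(n + 1/4)\big)$, average
ranks for ties. Residualize-then-transform is the order used
throughout; the Blom offset is the common GWAS default. The
transformed phenotypes are reused for every downstream stage.

**Cis scan.** Each phenotype is regressed on each variant inside the
gene body $\pm 1$ Mb (inclusive endpoints, clamped at position 1) with
the closed-form simple-regression solution computed from vectorized
sufficient statistics; missing dosages are handled pairwise per
variant. Because the phenotypes are pre-residualized, each test has the
two-variable simple-regression degrees of freedom $n-2$ rather than the
joint-model $n-2-q$; at the sample sizes involved the difference is
negligible, and the two-stage design matches how large phenotype
batches are scanned in practice. The lead variant of a locus is the
smallest p; ties break by absolute TSS distance (signed along the
direction of transcription), then variant id. p-values below the
smallest positive normal double are floored there, never reported as 0.

**Definition of an irQTL.** One (isoform phenotype, locus) pair with
its lead variant. The final set keeps loci with lead
$p < 5\times 10^{-8}$ *and* gene-level eQTL $p > 0.05$ at that same
lead variant, the strictest reproducible reading of "no eQTL effect";
the locus-minimum eQTL p is available as a configurable alternative.
The gene-level scan applies the identical covariate/INT pipeline to
$\log(\mathrm{gene\ TPM} + 1)$. The scan-wide FDR is the plug-in
expected-false-positive ratio $\alpha\, m / R$ with $m$ tests and $R$
significant records — the only estimator consistent with quoting a
single FDR per tissue at a fixed threshold. Inflation is summarized by
$\lambda_q$, the q-quantile of the observed $\chi^2_1$ statistics over
the matching theoretical quantile.

**Heritability enrichment (S-LDSC).** GWAS summary statistics are
harmonized against the genotype panel (allele matching in either
orientation with sign flips, strand-ambiguous A/T and C/G variants
dropped, configurable exclusion regions such as the MHC). Per-annotation
LD scores $\ell(j,c) = \sum_k a_{kc}\,\tilde r^2_{jk}$ use a symmetric
1 Mb window — the synthetic genome's map is 1 cM/Mb, so this is the
conventional 1 cM window — with the bias-adjusted
$\tilde r^2 = r^2 - (1-r^2)/(n-2)$ and the self-pair fixed at 1. The
regression $E[\chi^2_j] = N \sum_c \tau_c\, \ell(j,c) + b$ keeps a free
intercept and uses the two-step LDSC weights
$1/\max(\ell_{base},1) \times 1/(1 + N\bar h^2 \ell_{base}/M)^2$.
Enrichment is the proportion of $h^2$ over the proportion of SNPs, with
delete-one block-jackknife standard errors.

Two choices here deserve emphasis. First, the one-sided test of
enrichment $> 1$ is carried out on the annotation coefficient $\tau_c$
(jackknife z), not on $(\mathrm{enrichment}-1)/\mathrm{SE}$: for a
binary annotation fitted on top of the all-SNP base — the per-tissue,
one-annotation-per-model configuration used throughout — the two
hypotheses are equivalent, and in calibration runs the ratio statistic
rejected a true null at only 1–2% (its jackknife SE over-covers) while
the $\tau$ statistic sat at the nominal 5%. `enrichmentTestAndFdr`
still provides the ratio-based formula for cross-tissue summary
tables. Second, jackknife blocks must be long relative to the LD decay
length; the package default of 200 contiguous blocks suits genome-scale
data, while the desk-scale analyses here use 40 blocks so each block
(~250 kb) spans ten decay lengths. Comparisons between two gene sets
(e.g. irQTL genes vs other genes) use the delta-method ratio SE under
an independence assumption that is stated in the output.

**Mendelian randomization.** Instruments are LD-clumped
(greedy by p, removing $r^2 \geq 0.001$ companions) genome-wide
significant irQTL variants; exposure and outcome are aligned to a
common effect allele, with sign flips for swapped pairs, mismatched
pairs dropped, and strand-ambiguous variants with MAF > 0.4 removed.
The causal effect is estimated by fixed-effect IVW (a config switch
gives the multiplicative random-effects SE), which reduces to the Wald
ratio for a single instrument; Egger regression (weights $1/se_{out}^2$,
instruments oriented so $b_{exp} \ge 0$, residual scale floored at 1)
requires at least three independent instruments and is refused below
that. Multiplicity across isoform–trait pairs is controlled by BH FDR
at 5%. Reverse causality is probed by reverse-direction IVW — trait as
exposure, isoform ratio as outcome — rather than GSMR, whose HEIDI
outlier machinery needs an external LD-reference workflow; the
substitution is flagged in the output and is a known limitation.

## The synthetic-data generator

The generator exists so every stage above can be verified against known
truth. It emulates:

* **Genotypes.** Haplotype-copying LD: the allele at a variant copies
  its left neighbour with probability $\exp(-d/\text{ld\_decay\_bp})$
  (default decay 25 kb), otherwise it is a fresh Bernoulli draw at the
  variant's base frequency (uniform on the configured MAF range,
  default 0.05–0.5). Inter-variant gaps are exponential with mean 2 kb:
  clustered positions give heterogeneous LD scores, without which the
  LDSC intercept and the base LD score are collinear and the fit is
  unidentifiable. One synthetic chromosome; genetic map 1 cM/Mb.
* **Isoform expression.** Proportions follow a softmax (multinomial
  logit) model $\pi_{k,i} \propto \exp(a_k + b_k x_i + \xi_{k,i})$,
  $\xi \sim N(0, \sigma_\pi^2)$ with $\sigma_\pi = 0.5$; the softmax
  guarantees ratios in $[0,1]$ summing to 1 and is the minimal
  generative model consistent with proportions that shift while totals
  do not. Gene totals are log-normal
  ($\mu = \log 100$, $\sigma_g = 0.5$) with age, sex and ancestry
  effects and *no* genotype term, so opposite-sign $b$ (default
  $\pm 0.8$) moves ratios while total expression stays genetically
  flat — the cancellation mechanism, end to end. Setting `eqtl_beta`
  adds a genotype term to the total, creating positive-control eQTL
  genes that the cross-filter must reject. Age is uniform on 21–70
  years, sex Bernoulli(1/2).
* **Outcome traits.** An independent GWAS cohort (two-sample MR
  setting) with trait
  $y = \sum \gamma\, (b_k x_{causal}) + \sum_j \beta_j \tilde x_j + e$;
  the polygenic $\beta_j$ have per-SNP variance scaled inside a
  configured annotation. The annotation parameter is the target
  *enrichment score* $E$ (the S-LDSC estimand); the per-SNP variance
  fold applied is $E(1-p)/(1-Ep)$ for annotation fraction $p$, so a
  configured enrichment of 5 is what an unbiased fit should return.
  Marginal OLS summary statistics are accumulated blockwise, so memory
  stays flat in the cohort size.
* **MR studies.** `simulateMrStudy` draws independent instruments with
  direct effects on an exposure and an outcome
  $y = \gamma\,g_{exposure} + \alpha' x + e$ in a second cohort —
  the standard two-sample design, with configurable directional
  pleiotropy $\alpha$. The single-causal-variant gene model cannot
  yield three or more independent instruments after $r^2 < 0.001$
  clumping, so multi-instrument MR properties are exercised through
  this generator.

What the generator does **not** emulate: real human LD panels,
read-level quantification noise and isoform-assignment uncertainty,
tissue-sharing across multiple tissues, and population admixture beyond
a single ancestry axis. Passing tests therefore demonstrate the
statistical machinery under the stated generative assumptions, not
performance on real GTEx-scale data.

## Numerical choices and degenerate inputs

* Dosages are hard calls in {0,1,2,NA}; association scans use pairwise
  complete cases, the GRM mean-imputes.
* Zero-variance variants yield NA association records, not errors;
  all-NA loci are dropped with a message.
* A gene with zero TPM in a sample has missing ratios for that sample
  only (per-gene masks), preserving the sample elsewhere.
* The INT requires at least 3 distinct values; identical values are an
  error (ranks undefined).
* Eigenvector signs follow a largest-magnitude-loading-positive
  convention so PCs are reproducible across platforms.
* Odds-ratio CIs apply the Haldane–Anscombe +0.5 correction whenever a
  cell is zero; the reported headline is the CI lower bound.
* All randomness flows from one root seed; identical config + seed
  give byte-identical outputs (the run manifest omits timestamps).

## Problem sizes

The bundled analyses run at desk scale, chosen so each estimator is in
the regime it assumes: null calibration at $10^5$ tests (300 samples
$\times$ 1,000 variants $\times$ 100 phenotypes); cancellation recovery
at $n = 500$ with $|b| = 0.8$; S-LDSC at 5,000 variants with a 10%
annotation of fifty 10-variant gene-region blocks (scattered singleton
annotations are nearly collinear with the base LD score and carry
almost no signal; ~5,000 variants is the minimum meaningful problem
size on this genome); MR with 10 instruments at exposure/outcome
cohorts of $10^5$/5,000 so mean instrument F is in the hundreds —
fixed-effect IVW and Egger assume negligible exposure-estimate noise
and are known to undercover when instruments are weak.

## Known limitations

* Fixed-effect covariate correction only; no mixed-model scan on the
  kinship matrix itself.
* The eQTL cross-filter reuses the package's own gene-level scan; a
  published external eQTL table can be substituted where available.
* GSMR/HEIDI is replaced by reverse IVW (above).
* The enrichment-ratio one-sided test is conservative; the
  $\tau$-based test is exact only for one binary annotation over base,
  which is the supported per-tissue model.
* Trans effects, conditional secondary signals and permutation-based
  gene-level p-values are out of scope.
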