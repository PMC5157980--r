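---
title: "Genomic prediction with snpblup: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with snpblup: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpblup)
```

## The problem

Complex traits such as height or BMI are shaped by thousands of variants of
individually tiny effect. Selecting only genome-wide-significant hits wastes
most of that signal. `snpblup` instead fits **all** array SNPs jointly as
random effects in a mixed linear model, back-solves the per-SNP best linear
unbiased predictions (SNP-BLUP), and uses them as a portable polygenic
scorer. The package covers the full workflow around that core: cohort
quality control, relatedness handling, genomic PCA, a clump-and-threshold
GWAS baseline, and extrapolation of prediction accuracy to larger training
cohorts — all driven by a synthetic cohort generator, so every stage is
testable on a workstation without access to restricted biobank data.

## The model

For individual $i$ with trait value $y_i$, covariates $x_{il}$ (sex and
age by default) and standardised genotypes
$z_{ij} = (s_{ij} - \mu_j^*)/\sigma_j^*$,

$$y_i = \mu + \sum_{l=1}^{L} x_{il}\beta_l + \sum_{j=1}^{M} z_{ij} a_j + e_i,
\qquad a \sim N(0, I\sigma_u^2), \quad e \sim N(0, I\sigma_e^2).$$

$\mu_j^*$ and $\sigma_j^*$ are the mean and SD of the counted-allele dosage
in the **training** population; they travel with the effects in the scoring
file, so a validation cohort is standardised with training statistics. With
$\sigma_g^2 = M\sigma_u^2$ the SNP-heritability is
$h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$. Equivalently, individual
genetic values $g = Za$ follow $N(0, K\sigma_g^2)$ with $K = ZZ'/M$ the
genomic relationship matrix — the GBLUP parameterisation the fitter uses.

Extensions fit several genomic variance components at once: a main/tail
split by GWAS effect size (tail = SNPs whose fixed-effect estimate lies
more than 3 SD from the mean effect), a three-way MAF stratification
(MAF > 0.05; 0.01–0.05; 0.001–0.01, strict boundaries, boundary values left
unassigned with a warning), and a multivariate model in which the per-SNP
effect vectors across traits share a genetic covariance matrix
$\Sigma_g \otimes I$ with residual covariance $\Sigma_e \otimes I$.

Predicted genetic values are scored as
$\hat y_i = \sum_j a_j (s_{ij} - \mu_j^*)/\sigma_j^*$. Note the division by
$\sigma_j^*$: the effects are on the standardised-genotype scale, matching
the model in which $z$ is the standardised genotype. Accuracy is the
Pearson correlation between scores and phenotypes residualised on the
covariates **in the evaluation set**, with 95% confidence intervals from
the Fisher z transform ($\mathrm{SE} = 1/\sqrt{n-3}$); the CI method is a
package choice, made explicit because reports often omit it.

## REML fitting

* **Single component.** One eigendecomposition of $K$ rotates the model to
  a diagonal covariance; the restricted likelihood is then maximised
  exactly by one-dimensional search over $\log(\sigma_g^2/\sigma_e^2)$ on
  $[-12, 12]$, with the boundary values checked explicitly. No iteration,
  no convergence failures. Standard errors come from the inverse
  average-information matrix evaluated at the optimum; the SE of $h^2$ and
  of derived ratios use the delta method.
* **Several components.** Average-information REML. Each AI step is clamped
  at a variance floor of $10^{-8}\,\mathrm{Var}(y)$ and step-halved if it
  would decrease the restricted likelihood; when no AI step helps, an EM
  step (which always moves uphill) substitutes. Components stuck at the
  floor with a negative score are pinned and leave the AI system, which
  avoids the slow multiplicative EM crawl toward zero. Convergence is
  declared at $|\Delta \log L| < 10^{-6}$ (default), with a hard iteration
  cap of 100; a non-converged fit is returned flagged, never silently.
* **Multivariate.** After the same eigen-rotation the observations
  decouple into $T$-vectors with covariance $d_i\Sigma_g + \Sigma_e$, so
  each likelihood evaluation is $O(nT^3)$ with fixed effects profiled out
  by GLS. We maximise directly over Cholesky factors of $\Sigma_g$ and
  $\Sigma_e$ (log-scale diagonals), which enforces positive
  semi-definiteness by construction — a deliberate substitute for
  multivariate AI-REML: for $T \le 3$ at workstation scale the direct
  optimisation (Nelder–Mead polish followed by BFGS) is more robust near
  the $r_g = \pm 1$ boundary and needs no PSD projection heuristics.
  Genetic-correlation SEs come from the numerical Hessian at the optimum
  via the delta method. Samples missing any trait are dropped listwise.

SNP effects are recovered by the dual identity
$\hat a_c = \sigma_{u(c)}^2 Z_c' V^{-1}(y - X\hat\beta)$, which the test
suite pins against the primal ridge solution to $10^{-8}$.

## Quality control

Thresholds follow the published protocol and are the package defaults
(`qc_defaults()`): variants lose on multi-allelism, overall missingness
> 2%, platform-differential missingness (two-sided Fisher exact
$p < 10^{-100}$), MAF not strictly > 0.05, and Hardy–Weinberg exact
$p < 10^{-50}$; MAF and HWE are computed on the designated unrelated
training subset. Samples lose on autosomal missingness > 5%,
heterozygosity beyond ±3 SD (an explicit stand-in for cohort-internal
procedures that are not public), and X-based sex checks with inbreeding
calls at $F > 0.8$ (male) / $F < 0.2$ (female) — thresholds adopted from
common practice since none are published. Phenotypes outside ±3 SD of
their sex mean are set missing, with the stratum statistics computed once
on the input. Ancestry outliers are samples departing more than 3 SD from
their group mean on any of the leading 20 genomic principal components;
groups under 1,000 samples are dropped (both configurable — the packaged
demonstration lowers the group minimum because its groups are small).

Both exact tests run in log space. The HWE test enumerates every
heterozygote count compatible with the observed minor-allele count and
sums the probabilities of configurations no more probable than the
observed one; a chi-square approximation is useless at $p \sim 10^{-50}$.
The Fisher test sums hypergeometric log-masses with a log-sum-exp, so a
$p$ around $10^{-300}$ or below still yields a finite `log10_p` for
comparison against the $10^{-100}$ cut.

The unrelated set is built by greedy maximum-degree removal on the
relatedness graph thresholded at 0.0625 (ties: larger maximum kinship,
then identifier order) — the construction algorithm is unspecified in the
protocol, so greedy removal was chosen for determinism and testability;
its postcondition (no retained pair above threshold) is property-tested on
1,000 random matrices. Removed samples with at least one above-threshold
link into the retained set form the related validation group.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis relies on,
not human genetics per se:

* **Population structure**: ancestral MAFs from a configurable
  distribution; non-reference populations draw SNP-wise from the
  Balding–Nichols beta law with per-population $F_{ST}$, giving tunable
  across-population prediction decay.
* **LD**: haplotypes are thresholded latent AR(1) Gaussians within blocks
  of configurable size; the lag-one latent correlation is the
  `within_block_r` parameter. Thresholding attenuates the genotype-scale
  correlation below the latent target (at 0.9 latent, adjacent genotype
  correlation is roughly 0.75 for common SNPs) — sufficient to exercise
  pruning and clumping. Allele frequencies are drawn per block, which
  makes the degenerate `within_block_r = 1` case produce literally
  identical adjacent SNPs; with block size 1 the model reduces to
  independent SNPs.
* **Relatives**: full-sib pairs by per-SNP Mendelian gamete sampling from
  two parents in the reference pool (expected genomic relationship 0.5;
  transmission ignores within-block phase, which matters for none of the
  relatedness statistics used downstream).
* **Traits**: spike-and-slab effects on the standardised scale — exactly
  zero off the causal set, so the causal count controls the effective
  number of loci in the accuracy law. Mixtures (a large-effect tail or
  MAF-binned variances) and cross-trait effect correlations are
  configurable. Environmental noise is scaled so realized
  $\mathrm{Var}(g) = h^2$ and $\mathrm{Var}(g) + \mathrm{Var}(e) = 1$;
  at $h^2 = 1$ the noise is exactly zero.
* **Platforms**: two platforms with baseline missingness rates and a
  configurable fraction of variants whose platform-2 missingness is
  elevated — the pattern the Fisher filter is designed to catch.
* **Sex**: Bernoulli(1/2), with an optional X-like chromosome on which
  males are coded homozygous, exercising the inbreeding-based sex check.
  Sex and age enter the phenotype as fixed effects; their sizes are
  arbitrary defaults (1.0 and 0.01 per year in the demo) since no
  published values exist — they are estimated, not assumed, downstream.

One seed fixes every draw end to end; the same configuration reproduces
the cohort byte for byte. What the generator does **not** emulate:
coalescent genealogy, realistic LD decay or recombination maps,
imputation error, genotype-calling intensity artefacts. Passing tests
therefore certify the statistical machinery, not performance on real
biobank data.

## Study conditions used by the heavier checks

Problem sizes were chosen once, as the largest a single CPU handles
comfortably: parameter recovery uses $n = 2{,}000$, $M = 1{,}000$ fully
causal SNPs at $h^2 = 0.5$ over 20 cohorts; SE calibration redraws 50
traits on one fixed genotype panel (the coverage statement concerns the
trait distribution given genotypes, and holding genotypes fixed lets one
eigendecomposition serve all replicates); cross-validation uses the same
cohort with 5 folds. The learning-curve check subsamples training sizes
400–1,600 (10 replicates each) against a deliberately small panel of 300
fully causal markers: the inverse-squared-accuracy relation is linear
only near its asymptote ($n h^2 / M_e \gtrsim 1$), and a small panel
puts the sampled sizes in that regime — the same regime biobank-scale
learning-curve fits operate in — so the extrapolated intercept is
stable. The clump-and-threshold comparison runs at $n = 2{,}000$,
$M = 20{,}000$ LD-blocked SNPs under two architectures chosen to span a
documented contrast: an *infinitesimal* trait (every SNP causal,
$h^2 = 0.8$, the heritability of a height-like trait) where joint
estimation should dominate and the profile should peak where all
independent SNPs enter, and a *mixed* trait ($h^2 = 0.5$ with 0.1% of
10,000 causal SNPs carrying a 1,000-fold variance tail) where the optimum
sits at stringent thresholds. On a nine-point threshold grid the top two
points differ by less than holdout noise for infinitesimal traits, so
"boundary optimum" is operationalised as an argmax at 0.5 or 1 and
"interior optimum" as an argmax below 0.01 — regions separated by four
grid points. The packaged end-to-end demonstration (`demo_config()`) uses
~3,100 samples over four ancestry groups, 100 sib pairs, and ~20,000
variants with two correlated traits. Two of its settings deviate from the
published defaults for reasons of scale: the ancestry-group minimum drops
from 1,000 to 100 (the demo groups are small by construction), and the
ancestry filter uses the leading 6 rather than 20 principal components —
at three thousand samples the trailing components of the GRM spectrum are
dominated by the spiked sib pairs and noise, and a 3-SD rule on them
flags most relatives as ancestry outliers, which a 150,000-sample cohort
would never show. Its extrapolation stage can also report a flagged
nonpositive intercept: with ~18,000 effective loci against ~1,600
training samples the accuracies being inverted are small and noisy, and
the fit honestly refuses a ceiling rather than extrapolating garbage.

## Numerical choices and degenerate inputs

* Population (divisor-$n$) SD in standardisation, so standardised columns
  have exactly zero mean; monomorphic training variants are an error that
  names the offending ids. Missing genotypes standardise to 0 (mean
  imputation) everywhere — fitting, scanning, scoring.
* Allele flips between training and target are auto-corrected
  ($s \to 2-s$) when the labels are swapped, or refused when
  `allow_flip = FALSE`; any other allele mismatch is an error.
* Ties in LD pruning (equal MAF) drop the later position; clumping breaks
  p-value ties by position then id — both make variant order irrelevant.
* PCA signs follow a largest-loading-positive convention, so projections
  are reproducible across variant orderings.
* The accuracy of an empty C+T threshold is reported as `NA`, never 0.
* Perfect single-SNP fits (zero residual) report the underflow-guarded
  minimum p-value, not $p = 1$.
* The extrapolation is unweighted OLS of $1/r^2$ on $1/n$ with one point
  per (size, replicate); a nonpositive intercept is flagged and refuses
  projection rather than returning a complex ceiling. Reported percent
  fractions are rounded to the nearest integer.

## Known limitations

In-sample effect-size grouping (the same data pick the tail and refit it)
mirrors the reference analysis design and carries the same overfitting risk, as
does selecting the optimal C+T threshold on the validation set. The OLS
association scan stands in for a mixed-model scan; on the unrelated,
single-ancestry training sets used here the difference is negligible, and
leading principal components can be supplied as covariates for structured
cohorts. Listwise deletion in the multivariate fitter discards partially
phenotyped samples. The delta-method SE on projected accuracies assumes
the OLS coefficient covariance is trustworthy at the target $n$, which is
an extrapolation by construction.
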