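---
title: "Chance-corrected assessment of genotype imputation with iqscore"
author: "iqscore authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Chance-corrected assessment of genotype imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqscore)
```

## The problem

Genotype imputation infers untyped variants from typed ones via haplotype
models, and its output is, per SNP and individual, a posterior probability
triplet over the genotypes (AA, AB, BB). Two practical situations make the
standard quality summaries unreliable:

1. **Low minor allele frequency (MAF).** The usual summary, *imputation
   accuracy* — the proportion of individuals whose best-guess genotype matches
   the truth — is not corrected for chance. A rare SNP can be "imputed" at
   better than 90% accuracy by always calling the major homozygote, so
   accuracy saturates exactly where imputation is hardest.
2. **Cases and controls genotyped on different platforms.** When the two arms
   of a case/control study are imputed from different arrays, imputation error
   is systematically different between arms. A small number of badly imputed
   SNPs then produce extreme association signals — false positives at
   genome-wide significance — while leaving genome-wide summaries such as the
   inflation factor nearly unchanged.

## The statistic

For one SNP over $N$ individuals with known true genotypes, the posterior
probabilities are accumulated into a $3\times 3$ table whose cell $n_{ij}$
holds the posterior mass assigned to imputed genotype $i$ among individuals
with true genotype $j$; cells are generally not integers. With
$P_o = \sum_i n_{ii} / N$ the observed proportion of agreement and
$P_c = \sum_i (n_{i\cdot}/N)(n_{\cdot i}/N)$ the agreement expected under
random calling with the same marginal rates, the imputation quality score is

$$\mathrm{IQS} \;=\; \frac{P_o - P_c}{1 - P_c}.$$

IQS is the probability-mass analogue of Cohen's unweighted $\kappa$: 1 for a
perfect match, 0 for agreement at chance level, negative when imputation does
worse than chance. On integer hard-call tables it *is* $\kappa$, which the
test suite verifies against an independent brute-force implementation. When
the marginals are fully concentrated ($1 - P_c \le 10^{-12}$, e.g. a
monomorphic SNP) the score is reported as undefined (`NA`) rather than forced
to a number; analyses that correlate or average IQS exclude SNPs with
MAF < 0.01 by default, where the vanishing denominator makes the score
unstable.

When the *same* individuals are imputed from two different platforms, neither
posterior set is truth. The table is then built from the summed per-individual
outer products $n_{ij} = \sum_k a_{i,k}\, b_{j,k}$ of the two probability
triplets, and IQS is computed from it unchanged. This pairing requires shared
individuals; for disjoint cohorts `crossPlatformConfusion(..., paired =
FALSE)` falls back to a marginal product $N\,\bar a_i\,\bar b_j$ behind an
explicit warning, because the paired definition is the meaningful one and the
fallback only measures marginal compatibility.

### Companion statistics

The package also implements the statistics IQS is compared against, all
computable without truth from the expected dosage
$e_k = p_{AB,k} + 2 p_{BB,k}$:

* **Variance ratio** (MACH `rsq_hat` style): population variance of the
  dosages divided by $2\hat p(1-\hat p)$, $\hat p = \overline{e}/2$. The
  binomial reference variance is taken on the dosage scale ($2p(1-p)$, not
  $p(1-p)$), the convention that makes the ratio exactly 1 for certain
  genotypes at exact Hardy–Weinberg counts; the numerator uses the population
  (divisor-$N$) variance. Both conventions are recorded as attributes on the
  result because published descriptions are loose on this point and the two
  readings differ by a factor of 2.
* **Information score** (IMPUTE-family):
  $1 - \sum_k (f_k - e_k^2) \,/\, (2N\hat\theta(1-\hat\theta))$ with
  $f_k = p_{AB,k} + 4p_{BB,k}$. Equal to 1 for certain genotypes. Information
  measures based on Newton estimation of the observed information differ
  slightly for uncertain genotypes; outputs are tagged `impute_info` so the
  convention is never ambiguous.
* **MAF difference**: $|\hat q - q_{\mathrm{ref}}|$ against a reference-panel
  frequency table; SNPs missing from the reference pass no MAF-difference
  filter.

### Association testing and filtering

The validation protocol tests each SNP for case/control association with a
1-df score (trend) test on expected dosage,

$$X^2 = \frac{\left[\sum_k (y_k - \bar y)\, e_k\right]^2}
 {\bar y(1-\bar y)\sum_k (e_k - \bar e)^2},$$

which reduces exactly to the Cochran–Armitage trend chi-square on hard calls
(verified against `stats::prop.trend.test`) and is first-order equivalent to
probability-weighted logistic regression near the null — the regime that
matters when the phenotype is a random label and all signal is artifact. A
full logistic likelihood option was considered and left out: at the null it
agrees to first order and the score form is orders of magnitude faster at
desk scale. Genomic inflation $\lambda$ is the median observed statistic over
the $\chi^2_1$ median (0.4549); the mean-based estimator is not reported.
Genome-wide significance is fixed at $p < 5\times 10^{-8}$, strict, with no
multiplicity correction — the protocol counts raw exceedances.

Filters are comparator rules on any metric column (e.g. `iqs > 0.9`,
`accuracy > 0.99`, `maf_difference < 0.01`) with intersection semantics for
composites. An undefined metric value always fails a rule: an unscorable SNP
is never retained.

## What the synthetic cohorts emulate

Real validation of an imputation-quality statistic needs a cohort genotyped
on two platforms; such data are access-controlled. The generator therefore
emulates the *structure* of the problem:

* **Truth**: per SNP, a MAF drawn from a configurable distribution (default
  uniform on [0.01, 0.5]) and i.i.d. genotypes from Hardy–Weinberg
  proportions. SNPs are independent — IQS, accuracy and the trend test are
  all per-SNP statistics, so linkage structure would add cost without adding
  discrimination. This is the main respect in which the synthetic data are
  simpler than real data: passing tests here show the statistics behave as
  designed per SNP, not that any particular real imputation pipeline achieves
  a given IQS distribution, and not how correlated neighbouring SNPs' scores
  would be.
* **Imputation error** (per SNP, rate $\varepsilon$):
  * `soft_blend` mixes the one-hot truth with the SNP's realized genotype
    distribution $\pi$: row $= (1-\varepsilon)\,\mathrm{onehot} +
    \varepsilon\pi$. This model is deterministic and satisfies an exact
    algebraic identity, $\mathrm{IQS} = 1 - \varepsilon$ at every MAF, while
    $P_o = (1-\varepsilon) + \varepsilon\sum_i\pi_i^2$ grows as MAF falls —
    the divergence between chance-corrected and raw agreement as a testable
    statement, and the reason the blend is the default error model.
  * `random_hardcall` keeps the true call with probability $1-\varepsilon$
    and otherwise reports a random genotype from $\pi$ — a noisy hard-caller
    used for the stochastic robustness analyses.
  * `major_bias` moves mass $\beta$ to the major homozygote: row
    $= (1-\beta)\,\mathrm{onehot} + \beta\,\mathrm{onehot(AA)}$. This is the
    simplest mechanism reproducing how hard-to-impute SNPs inherit the
    reference panel's allele frequency: the estimated MAF shrinks by the
    factor $1-\beta$ and IQS drops to
    $(1-\beta)(1-S) / (1 - (1-\beta)S - \beta\pi_1)$ (with $S = \sum\pi_i^2$),
    which for $\beta = 0.6$ stays below 0.9 at every MAF in [0.01, 0.5] —
    so the IQS > 0.9 filter removes every biased SNP by construction, and the
    mapping from $\beta$ to IQS makes filter behaviour exactly predictable.

All generators are pure functions of a `SimConfig` (seed included);
sub-streams for truth, error rates, random draws and the case/control split
are derived deterministically from the one seed.

## The experiment protocols

* **Cross-platform split** (`runSplitExperiment`): the cohort is halved at
  random into "cases" and "controls"; controls keep certain true genotypes;
  cases are re-imputed under the error model with a fraction of SNPs (default
  1%) given `major_bias` at $\beta = 0.6$ and the rest `soft_blend` at
  $\varepsilon = 0.02$ — a caricature of combining a well-imputed platform
  with a systematically mis-imputed one. Because the phenotype is a random
  label, every genome-wide hit is an imputation artifact. The reference
  problem size is 20,000 SNPs by 2,000 individuals, which runs in about a
  minute and 3 GB; at this size roughly 180 of the 200 biased SNPs reach
  $p < 5\times10^{-8}$ unfiltered, $\lambda \approx 1.02$–1.03, and the
  IQS > 0.9 filter removes all of them while retaining 99% of SNPs. Note the
  $\lambda$ diagnostic is deliberately weak here: 1% grossly inflated SNPs
  shift the median-based $\lambda$ by only ~0.024, about 1.5 times its own
  sampling error at 20,000 SNPs — the hit count, not $\lambda$, is the
  sensitive readout, which is exactly the argument for per-SNP filtering.
* **Split-half robustness** (`runSplitHalfRobustness`): the cohort is halved,
  the identical per-SNP error model is applied independently in each half,
  and the per-SNP IQS values of the two halves are correlated over SNPs with
  MAF > 0.01. Under `random_hardcall` with $\varepsilon \sim U(0, 0.5)$,
  10,000 SNPs and 2,000 individuals per half, between-SNP variance in
  $\varepsilon$ (sd ≈ 0.144) dominates within-SNP sampling noise and the
  correlation exceeds 0.95. With a single shared $\varepsilon$ for all SNPs
  the correlation would collapse toward zero — the statistic measures
  *between-SNP* reproducibility, which is what justifies publishing IQS
  databases for reuse.
* **Pure null**: the same split with $\varepsilon = 0$ and no biased SNPs
  gives zero hits and $\lambda$ within sampling error of 1, confirming the
  protocol itself is calibrated.

## Numerical choices and degenerate inputs

* Genotype coding is fixed: columns (AA, AB, BB) with allele A the
  first/reference allele. IQS is invariant to the A/B swap, so the choice is
  benign, but fixing it makes files reproducible.
* The confusion table is oriented rows = imputed, columns = true. $P_o$,
  $P_c$ and IQS are invariant under transposition.
* Individuals with missing truth are dropped per SNP; SNPs with fewer than
  10 scored individuals are flagged `low_confidence` rather than dropped.
* Best-guess calls use argmax with ties broken toward the lower genotype
  index — deterministic, so accuracy is reproducible. The 0.9
  maximum-posterior threshold is used only by efficiency (strict
  inequality).
* IQS undefined iff $1 - P_c \le 10^{-12}$; undefined propagates as `NA`
  through tables, files (`NA` in TSV) and filters (fails every rule).
* GEN triplets are renormalized when their sum is within $10^{-3}$ of 1
  (absorbing 3-decimal files; a warning reports the count), all-zero
  triplets (the GEN missing convention) become uniform rows, and worse sums
  flag the record. After normalization rows must sum to 1 within $10^{-6}$
  — the container's validity invariant.
* Strand-ambiguous A/T and C/G SNPs are excluded from cross-platform
  harmonization with reason `strand-ambiguous`; the swap/flip
  transformations are involutions, which the suite checks.
* Test problem sizes: the reference split experiment runs at its full
  20,000 × 2,000 size; robustness uses 10,000 SNPs × 4,000 individuals;
  calibration checks use 5,000–6,000 SNPs. These sizes keep every stochastic
  acceptance band several standard errors wide of its threshold, except the
  unfiltered-$\lambda$ bound discussed above, which is inherently marginal
  at this design.

## Known limitations

* No linkage disequilibrium, no haplotype/reference-panel simulation, and no
  attempt to reproduce any real cohort's absolute numbers.
* The information score is the direct IMPUTE-style measure; SNPTEST's
  Newton-based variant can differ slightly for very uncertain genotypes.
* The trend test fits no covariates and applies no population-structure
  correction — out of scope for the artifact-detection protocol.
* Sex chromosomes are not handled; the database format stores population
  labels but the package does not model admixture, which makes IQS sensitive
  to the mixing proportions.
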