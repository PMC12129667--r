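---
title: "Methods: drift-covariance selection scans and two-stage association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift-covariance selection scans and two-stage association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divescan)
```

## The scientific setting

divescan implements a two-stage design for finding recent positive selection
in a small, relatively isolated focal population and linking the selected
variants to a quantitative trait. The motivating setting is a diving
population on an island: a focal group (here labelled JEJ), a closely related
mainland sister group (KOR, pairwise F~ST~ on the order of 0.003), and a more
diverged outgroup (CHS). Stage one scans the genome for SNPs whose
focal-population allele frequency has moved more than genome-wide drift can
explain; stage two tests only the handful of top candidates for association
with the phenotype (e.g. maximum diastolic blood pressure during a simulated
dive), shrinking the multiple-testing burden from millions of SNPs to about
ten.

## Stage one: the drift-covariance likelihood-ratio scan

### Model

Let $p_{i}$ be the alternate-allele frequency of population $i$ at a SNP.
With $K = 3$ populations we form the outgroup-rooted contrast vector
$y = (p_\text{focal} - p_\text{out},\; p_\text{sister} - p_\text{out})$,
a full-rank $(K-1)$-dimensional reduction, and the per-SNP scale
$s = \bar p (1 - \bar p)$ with $\bar p$ the unweighted across-population mean.
Under pure drift, $y$ is modelled as Gaussian with mean zero and covariance
$s\,C$, where $C$ is estimated genome-wide as the average of $y y^\top / s$
over all polymorphic SNPs. $C$ absorbs every source of correlated frequency
change shared by all SNPs: drift along each branch, shared history above the
root, and binomial sampling noise from finite samples (which also scales with
$p(1-p)$, which is why no explicit sampling term is added to the diagonal by
default; a config switch can add $\mathrm{diag}(\hat p(1-\hat p)/2n_i)$).

The per-SNP test multiplies the focal diagonal entry $c_{ff}$ of $C$ by a
scalar $\gamma \ge 1$ and estimates $\gamma$ by maximum likelihood:

$$\mathrm{LLR} = 2\left[\max_{\gamma \ge 1} \ell(\gamma) - \ell(1)\right] \ge 0 .$$

A large statistic says the focal frequency moved further than the genome-wide
covariance predicts — the signature of directional selection on that SNP.

### Exact profile optimum

The one-parameter profile likelihood has an analytic optimum. Writing
$z = \big[(C^{-1}y)_f\big]^2 / \big(s\,[C^{-1}]_{ff}\big)$ (a rank-one
Sherman–Morrison reduction), the maximizing scalar and the statistic are

$$\hat\gamma = 1 + \frac{z - 1}{c_{ff}[C^{-1}]_{ff}},\qquad
\mathrm{LLR} = z - 1 - \ln z \quad (z \ge 1;\ \text{else } \hat\gamma = 1,\ \mathrm{LLR} = 0).$$

For diagonal $C$ this reduces to the familiar
$z = y_f^2/(s\,c_{ff})$ form. `scan_genome()` uses this exact closed form by
default (it is vectorized over SNPs and free of optimizer error); a bounded
derivative-free search over $\log\gamma \in [0, \log 10^6]$ is kept as
`method = "numeric"` and the test suite verifies the two routes agree to
$10^{-6}$ on a thousand random instances. When $C$ is near-singular
(reciprocal condition number below $10^{-10}$) a ridge of $10^{-9}$ is added
to its diagonal before inversion, identically in both routes;
well-conditioned models are left untouched so the closed form is exact.

### The exact null, the 50:50 mixture, and zero inflation

The usual chi-bar-square argument for a boundary-constrained one-parameter
test predicts that, under the null, the statistic is a 50:50 mixture of a
point mass at zero and $\chi^2_1$. That argument is an asymptotic one: it
requires the MLE of $\gamma$ to concentrate near 1, which happens only when
each test aggregates many observations. Here each SNP contributes a *single*
draw of $y$, so the asymptotics never engage, and the finite-sample null can
be computed exactly: $\hat\gamma > 1$ iff $z > 1$, and $z$ is exactly
$\chi^2_1$ under the Gaussian null, so

$$\Pr(\mathrm{LLR} = 0) = \Pr(\chi^2_1 \le 1) = 0.683,$$

independent of $C$. Simulations with this package reproduce 0.68 within
Monte-Carlo error; allele-frequency discreteness in sampled genotypes pushes
the realized zero fraction slightly higher (values around 0.70–0.74 are
typical for small samples and skewed frequency spectra). The package reports
the realized `fraction_zero` and deliberately does not force it to 0.5; the
50% figure quoted in asymptotic treatments of this test is, for this design,
an approximation that understates the point mass.

### Calibration

Because of the point mass, median-based genomic control is meaningless.
`calibrate_llrs()` instead discards the lowest half of all statistics and
computes the inflation factor from upper quantiles,

$$\lambda = \frac{P_{99}(\text{retained})}{P_{99}(\chi^2_1)},$$

then divides every statistic by $\lambda$ and assigns mixture p-values:
$p = 1$ when $\mathrm{LLR} = 0$, else
$p = \tfrac12 \Pr(\chi^2_1 > \mathrm{LLR}/\lambda)$. Whether the 99th
percentile is taken over the retained upper half (default) or over all
statistics is exposed via `quantile_base`, since both conventions appear in
practice. When the true zero fraction exceeds one half the retained half
still contains zeros and $\lambda$ falls below 1; the quantile ratio then
acts as a deflation factor, which is the intended behaviour of the
calibration (the tail is matched to $\chi^2_1$ regardless).

## Peak selection

Scan statistics are converted to candidate signals by a fixed rule sequence
(`select_candidates()`): (1) keep SNPs at or above the empirical 99th
percentile of all statistics, zeros included; (2) keep outliers with at least
one other outlier within ±100 kb on the same chromosome (isolated outliers
are noise under unlinked nulls); (3) keep outliers that are the strict
maximum of their ±100 kb window, ties resolved toward the lower position;
(4) chain surviving SNPs within 1 Mb into single peaks so that one wide
low-recombination signal (a centromere-scale peak, for instance) is counted
once, represented by its top SNP; (5) rank peaks by their top statistic with
(chromosome, position) tie-breaks and keep the top 10. All windows are
boundary-inclusive; the 1 Mb chain distance automates what is otherwise a
manual "this is one wide peak" judgement and is config-exposed because no
principled value exists without recombination maps.

## Stage two: candidate association

`run_two_stage()` regresses the untransformed phenotype on the
alternate-allele dosage (additive 0/1/2 coding) of each candidate top SNP,
adjusting for age, height, weight, dive duration, optionally age², and the
first 10 principal components of the post-QC genotypes of the analyzed
samples. Significance is declared at the Bonferroni threshold
$\alpha/m$ over the $m \le 10$ candidates (0.005 at $\alpha = 0.05$ with ten
candidates). `gc_lambda_median()` provides the standard median-based QQ
inflation diagnostic for the association stage (where no point mass exists),
and `ttest_groups()` covers the simple two-group physiological comparisons
(pooled variance by default, Welch by flag). Anti-hypertensive medication is
deliberately absent from the covariate set, mirroring the data situation the
design anticipates. The age non-linearity is implemented as age² (the
conventional blood-pressure-GWAS choice) and recorded in `model_terms`.

## QC

The pipeline order is fixed: biallelic filtering (at VCF import) →
heterozygote-excess exact test (one-sided Levene/Haldane conditional test,
sites with $p \le 10^{-6}$ removed — the semantics of the `ExcHet`
annotation) → allele-flip removal → MAF ≥ 1% across all samples jointly →
relatedness pruning.

Allele flips are detected as exact fixed differences between two merged
panels (one panel fixed for REF where the other is fixed for ALT); the
tolerance around fixation is exposed (`eps`, default 0) because near-fixed
conventions differ between pipelines.

Relatedness uses a composite-likelihood K0: for each pair, the
genotype-pair probabilities at every site are written as a mixture over
identity-by-descent states (0, 1, or 2 alleles shared), with sample allele
frequencies plugged in, and the mixture weights (k0, k1, k2) estimated by
EM. The estimate is deterministic given genotypes and frequencies. A
moment estimator based only on opposite-homozygote counts was considered
and rejected: its information is confined to the $\sum_m 2p_m^2q_m^2$
expected IBS-0 events — a few dozen at a thousand SNPs — giving a standard
error above 0.1, which falsely flags unrelated pairs against a 0.75
threshold. The likelihood uses every genotype pair and is an order of
magnitude more precise at the same SNP count (duplicates and
parent–offspring near 0, unrelated pairs above 0.9 from about a thousand
informative SNPs). Pruning iteratively removes the later-in-input-order
member of each flagged pair until no pair is flagged.
Conventionally *low* K0 means related, so the default flags `k0 < 0.75`;
because published pipelines have stated the opposite inequality for the same
0.75 threshold, the comparator direction is an explicit argument rather than
a hard-wired rule.

## The synthetic-data generator

`simulate_panel()` draws ancestral frequencies from a configurable root law
and evolves each population one Balding–Nichols step: a Beta distribution
with mean $p_0$ and variance $F\,p_0(1-p_0)$, which keeps frequencies
strictly inside (0, 1) with no clipping — so the scan's Gaussian drift model
is a genuine approximation being tested, not baked into the data.
`sample_genotypes()` draws Binomial(2, p) dosages and assigns synthetic
coordinates (3 kb spacing, 100,000 SNPs per chromosome) so windowed rules
operate on realistic densities.

Chosen defaults, fixed once as the emulated study conditions:

* **Sample sizes** 57 / 84 / 50 diploids (focal / sister / outgroup),
  matching a small field cohort plus reference panels.
* **Branch drift** focal 0.004, sister 0.003, outgroup 0.006. Pairwise
  Weir–Cockerham F~ST~ under matched Balding–Nichols branches is close to the
  mean of the two branch F values, so these reproduce the observed scale:
  focal–sister ≈ 0.0035 and sister–outgroup ≈ 0.0045. The outgroup branch is
  the largest, encoding its deeper divergence.
* **Root frequency law** Uniform(0.05, 0.95), i.e. a well-ascertained
  common-variant panel; a Beta option exists for skewed spectra (the QC tests
  use Beta(0.4, 0.4) to generate near-fixed sites).
* **Mutation rate** 1.25×10⁻⁸ per site per generation, generation time
  27 years — the standard values for human East Asian histories, used by
  `ne_from_pi()` and `generations_to_years()`.
* **Phenotype** intercept 60, per-allele effect −10 units, residual SD 8,
  covariates drawn for an aging female cohort (age 65 ± 8 y, height
  157 ± 6 cm, weight 60 ± 8 kg, dive duration 30 ± 12 s).

Selection can be injected two ways. A *variance boost* multiplies the focal
branch F at selected loci (placed in short clusters of consecutive SNPs);
this makes displacements stochastically larger but — because a boosted Beta
draw still has most of its mass near the root — individual boosted loci are
enriched among top statistics rather than guaranteed to top the list. A
*deterministic sweep* (`inject_sweep()`) sets the focal frequency at a causal
SNP to a target (e.g. 0.33 against a 0.07 background) and displaces a few
flanking SNPs by a fraction (default 0.45, four SNPs per side) of the causal
displacement. The footprint emulates hitchhiking: flanking sites shift with
the sweep, far enough to register as supported outliers, while the causal
site carries the cluster maximum. A lone shifted SNP would always be deleted
by the window-support rule — clustered injection is required by the
pipeline's own design, not a convenience.

What the generator does **not** emulate: linkage disequilibrium between
neighbouring genotypes (sweep footprints move marginal frequencies only),
recombination, sequencing/imputation error, and admixture. Passing tests
therefore demonstrate the statistical machinery under the stated drift
model, not robustness to LD structure or data-processing artifacts in real
cohorts.

`inject_artifacts()` plants ground-truthed QC challenges: allele flips
(genotypes of a designated sample subset recoded $2-g$ at monomorphic sites,
creating exact fixed differences between panels) and related pairs (a
sample's genotypes replaced by a Mendelian child of a template: one allele
copied, one drawn from the population frequency, giving K0 ≈ 0).

## Numerical choices and degenerate inputs

* Quantiles use R's default type-7 convention; outlier membership is
  `llr >= threshold`, so ties at the threshold are kept deterministically.
* Monomorphic SNPs ($s = 0$) are skipped with a reason, never scanned;
  all-zero scans raise an explicit "degenerate scan" error in calibration.
* F~ST~ is the ratio of averages $\sum a / \sum(a+b+c)$, never an average of
  per-SNP ratios; sites with zero total variance are flagged undefined and
  excluded from both sums.
* π uses the unbiased per-site estimator $2\hat p(1-\hat p)\,2n/(2n-1)$,
  which equals the pairwise-difference definition in expectation and needs
  no phasing; window coordinates are 1-based inclusive internally, converted
  to 0-based half-open only in BED export.
* PCA standardizes by $\sqrt{2\hat p(1-\hat p)}$, mean-imputes missing calls,
  and drops monomorphic variants; scores are eigenvectors scaled by the
  square root of their eigenvalues, so axes are orthogonal and defined up to
  sign.
* All simulation functions are pure functions of their inputs and an integer
  seed (`withr::with_seed`), giving bit-identical reruns.

## Problem sizes used in the test suite

The shipped tests exercise the pipeline at desk scale, chosen to make
Monte-Carlo error small relative to each assertion: 20,000–50,000 SNPs for
distributional checks (null zero fraction, F~ST~ recovery, covariance
structure), 100 replicates of the full two-stage pipeline at 4,000 SNPs each
for power and family-wise-error checks, and exhaustive enumeration up to
genotype totals of 200 for the exact test. These sizes are the package's
own validation conditions; the same functions run unchanged at
millions-of-SNPs scale.

## Known limitations

* The Gaussian drift model ignores the discreteness of sample frequencies;
  its practical consequence — extra zero statistics — is reported, not
  corrected.
* K0 is a moment estimator: adequate for pruning duplicates and first-degree
  relatives, not for fine relationship classification, and it assumes
  reasonably accurate allele frequencies.
* The candidate-association stage assumes the causal variant itself is
  scanned; without LD modelling, a tag SNP cannot stand in for an unscanned
  causal site.
* Selection-coefficient estimation, trajectory-based tests, admixture-aware
  component inference, and imputation are intentionally out of scope.
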