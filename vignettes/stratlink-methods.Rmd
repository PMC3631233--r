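---
title: "Models and methods in stratlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stratlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stratlink implements a stratified whole-genome pedigree linkage workflow of
the kind used for familial neurological malformations such as Chiari Type I
Malformation (CMI): multiplex families genotyped on a dense SNP array, a
marker/sample QC cascade, parametric and nonparametric linkage under an
affecteds-only model, clinical stratification of families (e.g. by
connective-tissue-disorder comorbidity) with an empirical permutation test,
Monte-Carlo power estimation, and triage of candidate sequence variants
found under linkage peaks. This vignette records the models, the numerical
choices, and the places where the design was genuinely open.

## The disease model and the affecteds-only contract

Parametric linkage assumes a single-locus model: disease allele frequency
$q$ and penetrances $(f_0, f_1, f_2)$ for 0/1/2 disease alleles. The default
`disease_model()` is the rare-dominant affecteds-only model $q = 0.001$,
$(f_0, f_1, f_2) = (0, 0.001, 0.001)$. Under this model affected
individuals must carry the allele (because $f_0 = 0$) but unaffected
individuals are essentially uninformative (because $f_1$ is tiny). The
package goes one step further and hard-codes the *affecteds-only contract*
in every likelihood: affected members contribute the penetrance of their
disease genotype, while unaffected and uncertain members contribute a
factor 1 (their marker genotypes always contribute). This protects against
misclassification of non-penetrant relatives and makes "uncertain" and
"unaffected" deliberately indistinguishable to the engine — the convention
we adopted for how uncertain diagnoses enter the likelihood.

## Two-point engine

`pedigree_likelihood()` computes the exact joint likelihood of phenotypes
and one marker by variable elimination over phased two-locus genotypes:
each person carries an ordered pair of haplotypes, a haplotype being
(disease allele, marker allele), for a 16-state space. Founders get
linkage-equilibrium priors; each child contributes a transmission factor
with recombination fraction $\theta$. Elimination uses a greedy min-degree
order, which is optimal on loop-free pedigrees (looped pedigrees are
rejected at construction). Factor tables are rescaled by their maximum at
every step, so penetrances of $10^{-3}$ per affected cause no underflow.
The elimination schedule and the $\theta$-specific transmission arrays are
cached per pedigree structure, which matters because the permutation and
power stages evaluate the same structures tens of thousands of times.

LOD$(\theta) = \log_{10} L(\theta) - \log_{10} L(0.5)$ summed over
families; the default grid is $\{0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5\}$.
The heterogeneity LOD follows Smith's admixture model,
$\mathrm{HLOD} = \max_{\alpha,\theta} \sum_f \log_{10}(\alpha\,
10^{\mathrm{LOD}_f(\theta)} + 1 - \alpha)$, with $\alpha$ on a grid of step
0.01. When the curve is flat the smallest maximizing $\alpha$ is reported,
so a null cohort returns $\hat\alpha = 0$ by convention. A caution
established by our own simulations: $\hat\alpha$ estimates the linked
proportion *among informative families*; cohorts padded with uninformative
families (homozygous key parents) will show upward-biased $\hat\alpha$.

## Multipoint engine

`lander_green()` runs the inheritance-vector hidden Markov model. One
meiosis is one bit; the chain runs on the full meiosis space of
$2^{2n_{nf}}$ vectors rather than the founder-phase quotient. The quotient
(bits $= 2 n_{nf} - n_f$, which `ped_bits()` reports) would halve the space
per founder, but transition kernels on the quotient under founder flips are
notoriously easy to get subtly wrong; at this package's scale (families of
about ten members after trimming, bit cap configurable, default 16 full
bits) the full space is exact and cheap, so we deliberately traded memory
for correctness. Oversize families are skipped with a warning and recorded,
never silently dropped.

Emissions are founder-allele-graph sums: given the descent pattern implied
by a vector, the probability of the observed genotypes is a sum over
founder-allele assignments. For biallelic SNPs this is vectorized over all
vectors by enumerating assignments of the founder alleles that reach a
typed member; for LD-cluster super-markers a backtracking enumeration over
the constraint graph is used instead. Transitions between positions apply
an independent per-bit flip with the Haldane recombination fraction of the
inter-position distance (the map function is configurable to Kosambi in
`cm_to_theta()`; Haldane is the default since the reference analyses do not
state one).

The multipoint parametric LOD at position $x$ is
$\log_{10} \sum_v P(v \mid \text{markers}) P(\Phi \mid v) -
\log_{10} \sum_v 2^{-B} P(\Phi \mid v)$, where $P(\Phi \mid v)$ drops
disease alleles through the vector. The nonparametric score is
Whittemore–Halpern $S_{all}$, computed per vector by direct enumeration of
one-allele-per-affected picks, standardized by exact null moments over
uniform vectors — no analytic approximation is used, and the family's full
null score distribution is retained.

## Kong–Cox models

`kong_cox()` maximizes the one-parameter ($\delta \ge 0$) likelihood on
per-family Z scores with weights $\gamma_f$ normalized to
$\sum \gamma_f^2 = 1$ (equal weights by default; the reference analyses do
not state a weighting scheme). The linear model uses factors
$1 + \delta \gamma_f Z_f$; $\delta$ is bounded so that every family's
*minimum attainable* standardized score keeps its factor positive when the
engine supplies null laws, otherwise by the observed negative scores with a
documented pragmatic upper bound of 10 when all scores are positive. The
exponential model tilts each family's exact null score distribution:
$\ell(\delta) = \sum_f [\delta \gamma_f Z_f - K_f(\delta\gamma_f)]$ with
$K_f$ the cumulant generating function of the family's enumerated null law
(Gaussian $K(t) = t^2/2$ as fallback). Maximization is by golden-section
(`optimize`) on the bounded interval with explicit boundary comparison at
$\delta = 0$, so all-negative cohorts return LOD 0 exactly (one-sided
test). LOD $= \ell(\hat\delta)/\ln 10$.

## QC cascade

`snp_filter_cascade()` applies, in order: call rate ($\ge$ 0.98),
cross-batch presence (a marker must be called in every declared genotyping
batch — the generalization of "present in only one batch"), Mendelian
errors in more than 4% of scoreable families (scoreable = has a typed
child with a typed parent at that marker; the denominator choice is ours,
the reference is silent), MAF $\ge$ 0.05 and exact Hardy–Weinberg
$p \ge 0.001$ both computed in unaffected founders, identical physical
position (tie-break: higher call rate, then map order), missing genetic
distance, and identical genetic position at two decimal places (first by
bp kept). A marker is attributed to the first filter that removes it; the
reference study's per-filter counts overlap and cannot be reproduced by any
first-hit attribution, so we do not attempt to. Families with any
Mendelian inconsistency at a surviving marker are masked wholesale at that
marker via a ledger the linkage engine consumes. The inbreeding screen is
method-of-moments $F$ with a 4-SD outlier flag.

## Stratification and the conditional permutation test

`stratify()` labels a family positive when any qualifying clinical
condition is flagged (default list: hypermobility, kyphosis, aneurysm,
mitral valve prolapse, pectus excavatum, scoliosis, orthostatic
hypotension, supraventricular tachycardia, heart valve disease, heart
murmur). `stratified_scan()` re-estimates founder allele frequencies per
stratum and runs the six-model battery (parametric HLOD, Kong–Cox linear,
Kong–Cox exponential; two-point and multipoint each).

The permutation test asks whether the stratified maximum is larger than an
arbitrary half of the cohort would give: each repetition splits the
families into random halves ignoring the clinical labels, analyses both
halves under all configured models, and retains per-chromosome and
genome-wide maxima (two draws per repetition; default 500 repetitions =
1000 draws). The empirical p-value uses the add-one estimator
$p = (\#\{draws \ge observed\} + 1)/(N + 1)$; the raw proportion is also
reported since the reference analyses do not state an estimator. Halves
are of size $\lfloor n/2 \rfloor$ even though real strata may be uneven
(34/32 vs 33/33) — we permute at half size as the procedure is described and note
the mismatch. One deliberate optimization: per-family statistics are computed
once on the full cohort (with cohort founder frequencies) and each
repetition merely re-aggregates subsets. Because every statistic is built
from per-family components this is identical to re-running the engine per
half, except that halves do not re-estimate allele frequencies — which
would be statistically dubious anyway. As acknowledged for the original
design, the empirical p-values are approximate because families differ in
size and structure; no correction is implemented.

## Power simulation

`estimate_power()` follows the SIMLINK design: family structures, affection
statuses, and sampling flags are fixed conditioning information. Per
replicate, disease genotypes are drawn *exactly* from
$P(\text{genotypes} \mid \text{phenotypes})$ — implemented by enumerating
phased founder genotypes jointly with inheritance vectors, which is
rejection-free and also yields the segregation indicators needed to drop a
linked marker (MAF 0.30, $\theta = 0.01$ by default) consistently through
the family. The cohort two-point LOD is maximized over the analysis grid;
power is the exceedance fraction at threshold 3 with a Clopper–Pearson
interval, and the LOD at $\theta = 0.01$ is reported alongside. The
reference study's power figure (0.94) depends on its undeposited real
family structures and is *not* a target here; the procedure, not the
number, is reproduced.

## Synthetic cohorts

`generate_cohort()` emulates the statistical shape of a multiplex CMI
linkage cohort: 66 families (nuclear and three-generation mix), at least
two affected sampled members each with affected-per-family mean near 2.77,
a SNP map with 0.31 cM spacing and MAF centred on 0.42 (truncated normal,
SD 0.09), about a quarter of founders ungenotyped, 1% sporadic missing
genotypes, and two genotyping batches. Linked families segregate a dominant
allele introduced through a carrier founder and phenotypes follow
generation penetrances (0.01, 0.8, 0.8); unlinked families draw phenotypes
from a familial background rate of 0.4. Ascertainment is implemented as
whole-family resampling until two affected sampled members exist. The
near-zero analysis penetrances would make resampling non-terminating, so
generation and analysis models differ by design; the affecteds-only
analysis is robust to this mismatch. What a green test on these cohorts
does *not* establish: behaviour under real ascertainment quirks,
population stratification, genotyping-intensity artefacts, or realistic
background LD (LD exists only within explicitly constructed clusters).

`plant_defects()` injects QC defects on disjoint marker sets with exact
bookkeeping: low-call markers are masked to the target rate exactly;
Mendel errors are planted as parent-parent-child impossibilities;
Hardy–Weinberg violations set all founders heterozygous and re-drop
descendants (consistent, so they trip only the HWE filter); rare-MAF
markers are re-dropped at frequency 0.01; duplicate positions copy a
neighbour's bp. The defect ledger is the only truth source tests consult.

## Numerical choices and degenerate inputs

* Likelihood scaling: per-elimination-step max-rescaling; log scale
  throughout; impossible data return $-\infty$ and LOD columns become
  $-\infty$ (handled by HLOD as zero-mass families).
* HWE exact test: probabilities computed in log space, summation tolerance
  $1+10^{-9}$ on "no more probable than observed"; monomorphic markers
  return $p = 1$.
* Support intervals: linear interpolation in cM on both flanks, bp by
  interpolation of the map; flat curves return the whole range with a
  warning; `drop = 0` returns the argmax point.
* Ties: duplicate-position QC keeps higher call rate then map order;
  multipoint thinning keeps higher MAF then lower bp; HLOD ties resolve to
  the smallest $\alpha$.
* EM for cluster haplotypes: tolerance $10^{-8}$, 500 iterations, fallback
  to independent markers with a warning on non-convergence.

## Known limitations

Families beyond the meiosis-bit cap are excluded from multipoint (logged);
X-chromosome models, looped pedigrees, and variance-components linkage are
out of scope. The permutation test's exchangeability argument is
approximate for unequal family structures. LD clustering uses composite
(genotype-correlation) $r^2$ on founders, not haplotype $r^2$.
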