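---
title: "Genetic confounding in population and family-based GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic confounding in population and family-based GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasconfound)
```

# The trait model and what the estimators estimate

`gwasconfound` studies how long-range allelic associations bias effect-size
estimates in genome-wide association studies. The trait model is additive:

\[
Y \;=\; Y^* \;+\; \sum_{l} g_l\,\alpha^d_l
      \;+\; \sum_{l} (g^m_l + g^f_l)\,\alpha^i_l \;+\; \epsilon,
\]

where \(g_l \in \{0,1,2\}\) is the number of focal (trait-increasing) alleles
an individual carries at locus \(l\), \(g^m, g^f\) are the parental dosages,
\(\alpha^d\) and \(\alpha^i\) are direct and indirect per-allele effects, and
\(\epsilon\) is environmental noise. Focal alleles are oriented so that
\(\alpha^d \ge 0\).

Two kinds of allelic association matter and must be kept separate:

* **cis-LD** \(D_{\lambda l}\): covariance of dosages carried on the *same*
  parentally inherited haplotype;
* **trans-LD** \(\tilde D_{\lambda l}\): covariance of a maternal dosage at
  one locus with the paternal dosage at the other.

Both are computed exactly on phased populations (`cis_ld()`, `trans_ld()`),
with denominator \(n\) (population covariance). That convention makes the
in-sample identity \(\mathrm{Cov}(g_\lambda, g_l) = 2(D_{\lambda l} +
\tilde D_{\lambda l})\) exact, so the population-GWAS decomposition

\[
\hat\alpha^{\mathrm{pop}}_\lambda \;=\; \frac{1}{V_\lambda}\Big(
  \sum_l 2\,(D_{\lambda l} + \tilde D_{\lambda l})\,\alpha^d_l
  \;+\; \mathrm{Cov}(g_\lambda, \epsilon)\Big),
\qquad V_\lambda = 2p_\lambda(1-p_\lambda)(1+F_\lambda),
\]

is an algebraic identity for any additively constructed phenotype — the test
suite checks it to \(10^{-10}\) (`decompose_estimate()`). Family designs are
different: the sibling estimator (regression of sibling differences in
phenotype on sibling differences in dosage, no intercept) and the
transmitted/untransmitted difference satisfy, in expectation,

\[
\hat\alpha^{\mathrm{sib}}_\lambda \approx \frac{2}{H_\lambda}\Big(
 \sum_{l \in \text{local}} D'_{\lambda l} \alpha^d_l
 + \sum_{l \notin \text{local}} (1 - 2c_{\lambda l})
   (D'_{\lambda l} - \tilde D'_{\lambda l})\,\alpha^d_l \Big),
\]

with parental LD \(D', \tilde D'\), parental heterozygosity \(H_\lambda\),
and recombination fraction \(c_{\lambda l}\). Only *linked* loci can
confound a family design — the \((1-2c)\) factor kills unlinked pairs — and
the confound is the cis-*excess* \(D' - \tilde D'\), equal to half the
difference between the fractions of coupling and repulsion double
heterozygotes among parents. The regression of the trait on *untransmitted*
alleles, often read as an indirect effect, instead absorbs cis- and trans-LD
and environmental confounds much as a population GWAS does
(`parent_offspring_gwas()` returns all three slopes).

The within-pair ordering of siblings is irrelevant for the no-intercept
difference regression (flipping a pair flips both differences), so the
implementation uses a fixed family ordering rather than randomizing.

# Maps, meiosis and the recombination model

Genetic maps hold cumulative positions in Morgans (`recomb_map`,
`load_genetic_map()`). Meiosis draws a Poisson number of crossovers per
chromosome (mean = genetic length), places them uniformly in map distance,
and starts from a random haplotype per chromosome. This is exactly the
no-interference model whose pairwise recombination fraction is the Haldane
transform \(c = (1 - e^{-2d})/2\), so analytic and simulated recombination
fractions agree by construction. Maps are sex-averaged throughout, matching
the estimator theory.

Two genomes are bundled: a hypothetical single chromosome of 1 Morgan, and a
22-autosome human map built from sex-averaged genetic lengths (total
35.8 M). `place_loci()` allocates loci to chromosomes by largest-remainder
rounding of length-proportional quotas and spaces them evenly in *genetic*
distance; with 1,000 equal-effect loci this yields a harmonic-mean
recombination fraction

```{r cbarh}
harmonic_mean_recomb(place_loci(human_autosome_map(), 1000))
```

The even spacing could alternatively be read in physical distance; the
genetic-distance convention reproduces the published value of
\(\bar c_h \approx 0.464\) within 0.002, so it is the one adopted.

# The synthetic populations

The simulator is the package's data generator: all populations are created
internally. Founders are drawn at linkage equilibrium and Hardy–Weinberg
proportions at user-set allele frequencies (0.5 by default, so every locus
contributes maximal variance). Generations are discrete and non-overlapping
with a monogamous mating structure: every female and male belongs to exactly
one pair, every pair leaves exactly two offspring (full siblings), and brood
sex ratios are fixed at ¼ two daughters / ¼ two sons / ½ one of each (pairs
randomly permuted first), which keeps the sex ratio exactly even without
drift. Population size is therefore constant.

Default sizes are desk-scale: \(N = 2{,}000\) for the assortative-mating
experiments and \(N = 1{,}000\) for the architecture, admixture and
selection experiments, with 100–300 replicates averaged; sampling error is
handled by replicate averaging rather than by large \(N\). These sizes keep
every bundled experiment in the minutes range on one CPU while leaving
replicate-mean Monte-Carlo errors well inside the tolerances the tests
assert.

What the generator deliberately does *not* emulate: mutation, overlapping
generations, sex chromosomes, crossover interference, realistic
allele-frequency spectra, and ascertainment/participation bias. Passing
tests therefore demonstrate the estimator algebra and the population
processes under study, not robustness to the full complexity of human
cohort data.

## Assortative mating

Mates are paired by the iterative rank-perturbation algorithm: rank-match
females and males on their (true) scores; if that maximal correlation
already lies below \(\rho + \varepsilon\), accept. Otherwise perturb each
score with Gaussian noise of SD \(\xi_k\), re-rank, and evaluate the
correlation of true scores under the induced matching; \(\xi\) is doubled
when the correlation is still too high, halved when it overshoots low twice
in a row, and bisected when the last two correlations straddle the target.
Each iteration redraws the perturbation five times and keeps the matching
closest to the target. The tolerance \(\varepsilon = 0.005\), initial
\(\xi_0 = 0.5\,\mathrm{SD}(\text{score})\) and the cap of 50 iterations are
package choices (the pairing literature specifies the five repeats but not
these constants); they are echoed in run metadata, and a run that never
reaches tolerance returns its best matching with the achieved correlation as
a diagnostic rather than failing silently. Cross-trait pairing is
sex-asymmetric (females scored on trait 1, males on trait 2) or symmetric
(the scored trait randomized within each individual).

Closed forms used as oracles: same-trait AM inflates population estimates by
\(h^2\rho/(1-h^2\rho)\) at equilibrium; sex-asymmetric cross-trait AM
produces spurious estimates of \(h^2\rho/2\) (relative to the causal
effect) at the other trait's loci, twice that when symmetric. With unequal
architectures at fixed genic variance, per-locus effects scale as
\(1/\sqrt{L}\) and AM-generated pairwise LD as the product of coupled
effects, so the spurious-to-causal magnitude ratio scales as
\(\sqrt{L_2/L_1}\); `am_architecture_scaling()` implements the square-root
form, and the reduced-scale simulation confirms its monotonicity (a printed
linear form without the root would disagree with that first-order
calculation).

## Population structure and admixture

Per-population founder frequencies come from the Balding–Nichols model,
Beta\((p\frac{1-F_{ST}}{F_{ST}}, (1-p)\frac{1-F_{ST}}{F_{ST}})\), which has
mean \(p\) and variance \(F_{ST}\,p(1-p)\) — drift-like divergence. A pooled
two-population sample has equal cis- and trans-LD
\(w(1-w)\,\Delta p_\lambda \Delta p_l\) (`stratified_ld()`), which inflates
the population GWAS but cancels exactly in family designs. On admixture in
proportions \(A:1-A\), founders carry cis- *and* trans-LD
\(A(1-A)\Delta p_\lambda \Delta p_l\); the first round of random mating
eliminates trans-LD while recombination feeds the founders' trans-LD into
cis, so cis starts at the same initial value and then decays by \((1-c)\)
per generation (`admixture_ld_decay()`; the tests verify the rate against
the first post-admixture generation). Family designs, unconfounded while
the populations were separate, become confounded in the admixed population
through the surviving cis-excess at linked pairs.

## Stabilizing selection and the Bulmer equilibrium

Gaussian stabilizing selection enters the life cycle as fertility selection:
parents are sampled into the mating pool with replacement, with weights
\(\exp(-(Y-\text{opt})^2 / 2V_S)\), separately by sex. (Viability versus
fertility placement is not fixed by the monogamous structure itself;
weighted sampling into the pool is the package's choice and preserves the
exact sex balance the brood scheme needs.)

At equilibrium, selection maintains negative disequilibrium \(d^* < 0\)
among like-effect alleles. With equal effects the fixed point solved by
`bulmer_equilibrium_d()` is

\[
d = \frac{1-\bar c_h}{\bar c_h}\,\delta(d), \qquad
\delta(d) = -\frac{(V_g + d)^2}{V_g + d + V_E + V_S},
\]

iterated with damping 0.5 from \(d = 0\) to \(10^{-12}\) (the map is smooth
and contractive there, so damping guarantees convergence). When selection
strength is supplied as \(V_S/V_P\), \(V_P\) is the *equilibrium*
phenotypic variance \(V_g + d^* + V_E\), solved self-consistently — the
scaling convention is implicit in the usual presentation, and this choice
reproduces the published attenuation values. Population estimates are
attenuated by \(-d^*/V_g\); family estimates by \((1-2\bar c_h)\) times
that, exactly by construction. Naive SNP-heritability estimates scale with
heterozygosity-weighted squared estimates, so a uniform attenuation \(b\)
reduces them by \(1-(1-b)^2\); this reconstruction reproduces all three
printed anchor values (0.5%, ~6% for height, 10%).

## Masking of mate-correlation estimates

Cross-chromosome polygenic-score correlations are a standard estimator of
assortative-mating strength. At the joint AM + selection equilibrium, a
freely recombining locus pair carries (i) AM disequilibrium in cis and
trans, whose per-pair share of the genome-wide total is
\(\rho\,h^2_{\mathrm{eq}} V_A\), and (ii) a selection-generated cis excess
equal to the per-generation increment \(\delta = -V_A^2/(V_P+V_S)\) (for
\(c = 1/2\) the equilibrium excess equals one generation's input). A naive
inversion that attributes all cross-chromosome disequilibrium to AM
therefore returns

\[
\hat\rho \;\approx\; \rho + \frac{\delta}{h^2_{\mathrm{eq}} V_A}
\;=\; \rho - \frac{V_P}{V_P + V_S},
\]

implemented in `masked_mate_correlation()` with equilibrium variances taken
at the Bulmer fixed point. For height parameters it gives ≈ 0.218 from a
true \(\rho = 0.25\). The derivation is a reconstruction from first
principles; its two sanity anchors are the no-selection limit
(\(\hat\rho \to \rho\) as \(V_S \to \infty\)) and the reduced-scale joint
simulation, which agrees within Monte-Carlo error. The simulation-side
estimator (`cross_chrom_pgs_mate_correlation()`) pools cross-chromosome
score covariances, normalises by genic (default) or observed score
variances, inverts the AM-equilibrium relation \(x = \rho_g/(1-\rho_g)\),
and rescales by the assumed PGS heritability. Both a within-individual and
a between-mate convention are exposed; the default is within-individual,
because that is where selection's negative cis-LD enters the estimator —
between-mate cross-chromosome correlations track the phenotypic mate
correlation nearly unmasked.

## Sibling indirect effects and G×E

With reciprocal sibling effects \(\beta\), phenotypes solve a 2×2 linear
system (`sibling_phenotypes_with_indirect()`), giving
\(\hat\alpha^{\mathrm{sib}} = \alpha/(1+\beta)\) and
\(\hat\alpha^{\mathrm{pop}} = (\alpha + \alpha\beta r^{\mathrm{sibs}}_g)/(1-\beta^2)\)
— opposite-signed biases for synergistic versus antagonistic interactions.
Under G×E effect-size heterogeneity (family deviation \(\alpha_f\), mean
zero), the sibling design returns \(\alpha + E[\alpha_f \mid \text{parent
heterozygous}]\) — and the conditional mean is weighted by the number of
heterozygous parents, since each contributes the segregating variance the
regression uses — while the population design conditions on carried copies:
\(\alpha + (1-2p)(1-2F)E[\alpha_f\mid g{=}1] + 2(p + (1-2p)F)E[\alpha_f\mid
g{=}2]\). Both formulas are checked against exhaustive enumeration of
Mendelian transmissions and exact genotype-by-environment tables.

# Numerical and degenerate-input conventions

* LD uses denominator \(n\); the coupling/repulsion identity
  \((H^{\mathrm{coup}} - H^{\mathrm{rep}})/2 = D - \tilde D\) is exact
  whenever maternal and paternal sample frequencies coincide, and otherwise
  holds up to the explicit origin-frequency product term.
* Monomorphic loci (population design) and loci with no segregating sibling
  pair (family design) are flagged `NA`, never an error, and excluded from
  summaries with counts reported.
* The "local" window for decomposition reporting defaults to ±0.01 Morgans
  and is a configuration knob — there is no principled boundary between
  tagged and confounding LD.
* All randomness in a run flows from one seeded global RNG stream;
  experiment replicate \(r\) uses seed \(s + 1009r\), so a fixed seed makes
  reruns bit-identical.
* Degenerate assortative pairing (zero-variance scores) returns an arbitrary
  matching flagged `degenerate` with achieved correlation reported as 0.

# Known limitations

The closed forms are first-order equilibrium approximations (equal effects,
weak per-pair disequilibrium); they degrade under strong selection
(\(V_S/V_P \lesssim 5\)) or strong AM (\(h^2\rho\) near 1). The
masked-correlation formula is a reconstruction whose absolute masking
fraction is modestly uncertain even though its limits and monotonicity are
not. Desk-scale populations drift faster than the large cohorts the theory
envisions, which the tests absorb with replicate averaging and stated
tolerances rather than larger sizes. LD estimation requires phased,
error-free genotypes — the package simulates them and makes no attempt at
statistical phasing.
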