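# gwasconfound

Forward-time simulation and closed-form theory for **genetic confounding in
genome-wide association studies** — for quantitative and statistical
geneticists who want to know when population-based and within-family GWAS
effect-size estimates are biased, by how much, and why.

A population GWAS regresses trait values on per-locus dosages; a sibling
GWAS regresses sibling *differences* on dosage differences; a
parent-offspring design regresses the trait jointly on transmitted and
untransmitted parental alleles. All three absorb long-range allelic
associations, but differently. Writing D and D̃ for cis- and trans-linkage
disequilibrium (covariances of dosages on the same vs. opposite parental
haplotypes), the package implements the decompositions

- population: `α̂_λ = [ Σ_l 2(D_λl + D̃_λl) α_l + Cov(g_λ, ε) ] / V_λ`
- family: `α̂_λ ≈ (2/H_λ) [ Σ_local D′_λl α_l + Σ_nonlocal (1 − 2c_λl)(D′_λl − D̃′_λl) α_l ]`

so population designs are confounded by *sums* of cis- and trans-LD at all
loci, while family designs are confounded only by the cis-*excess* at
*linked* loci (the `(1 − 2c)` factor removes other chromosomes). The package
provides:

- a phase-tracked monogamous forward simulator (Poisson-crossover meiosis on
  genetic maps, assortative mating by iterative rank perturbation, Gaussian
  stabilizing selection, population structure and admixture, sibling
  indirect effects, G×E effect-size heterogeneity);
- exact cis/trans-LD computation and coupling/repulsion double-heterozygote
  accounting on phased populations;
- the GWAS estimators for every design, their LD decompositions, polygenic
  scores, within-family PGS regressions, and cross-chromosome PGS estimates
  of assortative-mating strength;
- closed-form bias predictions: assortative-mating inflation
  `h²ρ/(1 − h²ρ)` and cross-trait spurious effects `h²ρ/2` (sex-asymmetric)
  or `h²ρ` (symmetric); the Bulmer equilibrium disequilibrium `d*` under
  stabilizing selection with attenuations `−d*/V_g` (population) and
  `(1 − 2c̄_h)(−d*/V_g)` (family); SNP-heritability reductions; and the
  masking of mate-correlation estimates by stabilizing selection;
- config-driven, seeded, desk-scale experiments reproducing each of these
  phenomena, with tab-delimited outputs.

## Worked example

Closed-form predictions for a height-like trait (h² = 0.8, mate correlation
ρ = 0.25, stabilizing selection V_S/V_P = 30, harmonic-mean recombination
c̄_h = 0.464):

```r
library(gwasconfound)

harmonic_mean_recomb(place_loci(human_autosome_map(), 1000))
#> [1] 0.4651019

theory_report(h2 = 0.8, rho = 0.25, vs_over_vp = 30, c_bar_h = 0.464)
#>                             quantity    value
#> 1            am_inflation_same_trait 0.250000
#> 2                   am_spurious_asym 0.100000
#> 3                    am_spurious_sym 0.200000
#> 5     stabsel_attenuation_population 0.028782
#> 6         stabsel_attenuation_family 0.002072
#> 7                   snp_h2_reduction 0.056736
#> 8            masked_mate_correlation 0.217742
```

Reading: effect sizes at causal height loci are underestimated by ~2.9% in
a population GWAS but only ~0.21% in a family GWAS; naive SNP-heritability
estimates lose ~5.7%; and a cross-chromosome-PGS estimate of the mate
correlation reads ~0.218 where the truth is 0.25.

The matching simulation — 20 generations of sex-asymmetric cross-trait
assortative mating (ρ = 0.2, heritability 1, 100 equal-effect loci per
trait on a 1-Morgan chromosome, N = 2,000), GWAS on trait 2 evaluated at
the *non-causal* trait-1 loci:

```r
res <- run_experiment("fig2_cross_trait_am", replicates = 20, seed = 1,
                      params = list(record_generations = c(5L, 20L)))
res$extra$spurious_population_final_am   # population GWAS, generation 20
#> [1] 0.08874
res$extra$spurious_sibling_final_am      # sibling GWAS, generation 20
#> [1] -0.01747
```

With 20 replicates the population-GWAS mean spurious effect is already near
the theoretical asymptote h²ρ/2 = 0.1 of the causal effect (200 replicates
tighten it to ~0.097), while the sibling GWAS sits near zero — its small
negative value is the transient from trans-LD still exceeding cis-LD.

A thin command-line wrapper is installed at `exec/gwasconfound`
(subcommands `theory`, `experiment`, `simulate`, `fixtures`), e.g.

```sh
Rscript exec/gwasconfound theory --h2 0.8 --rho 0.25 --vs-over-vp 30
Rscript exec/gwasconfound experiment --id fig5_structure_admixture --seed 1 --out out/
```

## Package layout

- `R/map.R`, `R/population.R` — genetic maps, locus placement, recombination
  fractions, phased founder populations, Balding–Nichols divergence,
  admixture
- `R/mating.R`, `R/meiosis.R` — pairing schemes (random / assortative),
  Poisson-crossover meiosis, stabilizing selection
- `R/phenotype.R` — trait architectures, additive phenotypes, sibling
  indirect effects, G×E deviations
- `R/ld.R` — cis/trans-LD, coupling/repulsion fractions, stratified and
  admixture LD closed forms
- `R/gwas.R`, `R/pgs.R` — the estimators, decompositions, summary metrics,
  polygenic scores and PGS regressions
- `R/theory.R` — closed-form bias calculator
- `R/scenario.R`, `R/experiments.R` — config-driven scenarios and bundled
  experiments; deterministic fixture generators
- `vignettes/confounding-methods.Rmd` — the model, all derivations and
  conventions, and known limitations
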