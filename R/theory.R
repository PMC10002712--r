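# Closed-form and fixed-point predictions for confounding biases. These serve
# both as a user-facing calculator and as the oracle layer for the
# simulation-based tests.

#' Equilibrium inflation of population estimates under same-trait AM
#'
#' Under constant same-trait assortative mating with mate phenotypic
#' correlation rho on a trait of heritability h2, population-GWAS effect-size
#' estimates are inflated at equilibrium by an average proportional factor
#' h2 rho / (1 - h2 rho).
#'
#' @param h2 trait heritability in \[0, 1\].
#' @param rho mate phenotypic correlation.
#' @return proportional inflation (0 means unbiased).
#' @export
am_inflation_same_trait <- function(h2, rho) {
  if (h2 * rho >= 1) stop("h2 * rho must be < 1")
  h2 * rho / (1 - h2 * rho)
}

#' Equilibrium spurious effects under cross-trait AM
#'
#' With cross-trait assortative mating between traits of equal heritability
#' and architecture and disjoint causal sets, the equilibrium spurious
#' effect-size estimate at non-causal loci (loci causal for the other trait)
#' is approximately h2 rho / 2 times the causal-locus effect when mating is
#' sex-asymmetric (the correlation links female trait 1 to male trait 2),
#' and h2 rho times the causal-locus effect when it is sex-symmetric.
#'
#' @inheritParams am_inflation_same_trait
#' @param symmetric logical; sex-symmetric (TRUE) or asymmetric (FALSE,
#'   default).
#' @return spurious effect relative to the causal-locus effect.
#' @export
am_spurious_cross_trait <- function(h2, rho, symmetric = FALSE) {
  if (symmetric) h2 * rho else h2 * rho / 2
}

#' Architecture-density scaling of spurious estimates
#'
#' When trait 1 has a denser architecture (fewer causal loci, larger
#' per-locus effects at fixed genic variance) than trait 2, the
#' assortative-mating LD between the traits' causal sets loads more heavily
#' per-locus onto trait-1 loci. Relative to the equal-architecture baseline,
#' the average magnitude of spurious estimates at trait-1 loci in a trait-2
#' GWAS scales as sqrt(L2 / L1): at fixed genic variance per trait,
#' per-locus effects scale as 1/sqrt(L), AM-generated pairwise LD scales as
#' the product of the coupled effects, and summing over the L2 causal loci
#' of trait 2 leaves a factor sqrt(L2 / L1) relative to the causal
#' trait-2 estimates.
#'
#' @param L1,L2 numbers of causal loci for traits 1 and 2 (>= 1).
#' @return relative magnitude factor (1 when L1 = L2).
#' @export
am_architecture_scaling <- function(L1, L2) {
  if (L1 < 1 || L2 < 1) stop("locus counts must be >= 1")
  sqrt(L2 / L1)
}

#' Equilibrium disequilibrium under Gaussian stabilizing selection
#'
#' Solves the Bulmer-type fixed point for the equilibrium (negative)
#' disequilibrium component d* of the genetic variance under stabilizing
#' selection, for a trait with many loci of equal effect:
#' d = ((1 - c_bar_h) / c_bar_h) * delta(d), with per-generation selection
#' increment delta(d) = -(V_g + d)^2 / (V_g + d + V_E + V_S), where c_bar_h
#' is the harmonic-mean recombination fraction among causal loci. The width
#' V_S may be given directly, or scaled to the phenotypic variance via
#' `vs_over_vp`, in which case V_P is the equilibrium phenotypic variance
#' V_g + d* + V_E, solved self-consistently.
#'
#' @param v_g genic variance (squared trait units).
#' @param v_e environmental variance.
#' @param v_s width of the Gaussian fitness function; ignored when
#'   `vs_over_vp` is given.
#' @param c_bar_h harmonic-mean recombination fraction in (0, 0.5\].
#' @param vs_over_vp optional ratio V_S / V_P (equilibrium phenotypic
#'   variance).
#' @param tol absolute convergence tolerance of the damped iteration.
#' @param max_iter iteration cap.
#' @return d* (<= 0, squared trait units).
#' @examples
#' bulmer_equilibrium_d(v_g = 0.8, v_e = 0.2, vs_over_vp = 30, c_bar_h = 0.464)
#' @export
bulmer_equilibrium_d <- function(v_g, v_e, v_s = NULL, c_bar_h,
                                 vs_over_vp = NULL, tol = 1e-12,
                                 max_iter = 1e5) {
  if (v_g <= 0 || v_e < 0) stop("variances must be positive (v_e may be 0)")
  if (c_bar_h <= 0 || c_bar_h > 0.5) stop("c_bar_h must lie in (0, 0.5]")
  if (is.null(v_s) && is.null(vs_over_vp)) stop("give v_s or vs_over_vp")
  ratio <- (1 - c_bar_h) / c_bar_h
  d <- 0
  for (i in seq_len(max_iter)) {
    va <- v_g + d
    vp <- va + v_e
    vs <- if (is.null(vs_over_vp)) v_s else vs_over_vp * vp
    delta <- -(va^2) / (vp + vs)
    d_new <- 0.5 * d + 0.5 * ratio * delta   # damping factor 0.5
    if (abs(d_new - d) < tol) return(min(d_new, 0))
    d <- d_new
  }
  stop("Bulmer fixed point did not converge")
}

#' Attenuation of effect-size estimates under stabilizing selection
#'
#' The average proportionate downward bias of effect-size estimates at
#' causal loci at the stabilizing-selection equilibrium: -d* / V_g in a
#' population GWAS, and (1 - 2 c_bar_h) times that in a within-family GWAS
#' (only linked loci confound family designs).
#'
#' @inheritParams bulmer_equilibrium_d
#' @param design `"population"` or `"family"`.
#' @return proportional attenuation (e.g. 0.03 for 3 percent).
#' @examples
#' stabsel_attenuation(v_g = 0.8, v_e = 0.2, vs_over_vp = 30,
#'                     c_bar_h = 0.464, design = "population")
#' @export
stabsel_attenuation <- function(v_g, v_e, v_s = NULL, c_bar_h,
                                vs_over_vp = NULL,
                                design = c("population", "family")) {
  design <- match.arg(design)
  d <- bulmer_equilibrium_d(v_g, v_e, v_s, c_bar_h, vs_over_vp)
  b <- -d / v_g
  if (design == "family") (1 - 2 * c_bar_h) * b else b
}

#' Reduction in naive SNP-heritability estimates
#'
#' SNP-heritability estimates scale with heterozygosity-weighted squared
#' effect-size estimates; a uniform proportional attenuation b of the
#' estimates therefore reduces them by 1 - (1 - b)^2 (about 2 b for small b).
#'
#' @param attenuation_b proportional attenuation of effect-size estimates,
#'   in \[0, 1).
#' @return proportional reduction in naive SNP-heritability estimates.
#' @export
snp_h2_reduction <- function(attenuation_b) {
  if (any(attenuation_b < 0 | attenuation_b >= 1)) stop("b must lie in [0, 1)")
  1 - (1 - attenuation_b)^2
}

#' Masked mate-correlation estimate under AM plus stabilizing selection
#'
#' Stabilizing selection generates negative disequilibrium between
#' like-effect alleles that opposes the positive disequilibrium generated by
#' assortative mating, so cross-chromosome-PGS-based estimates of the mate
#' phenotypic correlation are biased downward. At the joint equilibrium,
#' cross-chromosome locus pairs carry an assortative-mating disequilibrium
#' (cis plus trans) proportional to rho h2_eq V_A, plus a
#' selection-generated cis excess equal (for freely recombining pairs) to
#' the per-generation selection increment delta = -V_A^2 / (V_P + V_S).
#' A naive inversion that attributes all observed cross-chromosome
#' disequilibrium to assortative mating therefore returns approximately
#' rho_hat = rho + delta / (h2_eq V_A), with equilibrium variances taken at
#' the Bulmer fixed point.
#'
#' @param rho true mate phenotypic correlation.
#' @param h2 trait heritability (defined at linkage equilibrium: V_g over
#'   V_g + V_E).
#' @param vs_over_vp stabilizing-selection strength V_S / V_P.
#' @param c_bar_h harmonic-mean recombination fraction among causal loci.
#' @return the masked (naive) estimate of the mate phenotypic correlation.
#' @examples
#' masked_mate_correlation(rho = 0.25, h2 = 0.8, vs_over_vp = 30,
#'                         c_bar_h = 0.464)
#' @export
masked_mate_correlation <- function(rho, h2, vs_over_vp, c_bar_h) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  v_g <- h2; v_e <- 1 - h2   # unit linkage-equilibrium phenotypic variance
  d <- bulmer_equilibrium_d(v_g, v_e, c_bar_h = c_bar_h,
                            vs_over_vp = vs_over_vp)
  v_a <- v_g + d
  v_p <- v_a + v_e
  v_s <- vs_over_vp * v_p
  delta <- -(v_a^2) / (v_p + v_s)
  h2_eq <- v_a / v_p
  rho + delta / (h2_eq * v_a)
}

#' Expected sibling-GWAS slope with sibling indirect effects
#'
#' With reciprocal sibling indirect effects of strength beta, the
#' sibling-difference regression returns alpha / (1 + beta): synergistic
#' effects (beta > 0) attenuate, antagonistic effects (beta < 0) inflate.
#'
#' @param alpha true direct effect.
#' @param beta sibling indirect-effect coefficient, |beta| < 1.
#' @return expected sibling-GWAS estimate.
#' @export
sibling_estimate_with_indirect <- function(alpha, beta) {
  if (any(abs(beta) >= 1)) stop("|beta| must be < 1")
  alpha / (1 + beta)
}

#' Expected population-GWAS slope with sibling indirect effects
#'
#' Sampling one sibling per family, the population regression returns
#' (alpha + alpha beta r) / (1 - beta^2), where r is the genotypic
#' correlation between siblings at the locus (1/2 under random mating).
#'
#' @inheritParams sibling_estimate_with_indirect
#' @param r_g_sibs sibling genotypic correlation at the locus, in \[0, 1\].
#' @return expected population-GWAS estimate.
#' @export
population_estimate_with_indirect <- function(alpha, beta, r_g_sibs) {
  if (any(abs(beta) >= 1)) stop("|beta| must be < 1")
  if (any(r_g_sibs < 0 | r_g_sibs > 1)) stop("r_g_sibs must lie in [0, 1]")
  (alpha + alpha * beta * r_g_sibs) / (1 - beta^2)
}

#' Expected GWAS slopes under G x E effect-size heterogeneity
#'
#' When an allele's effect deviates by alpha_f in family f (mean zero over
#' the population), the sibling-difference GWAS returns
#' alpha + E\[alpha_f | parent heterozygous\] (only heterozygous parents
#' contribute segregating variation), while the population GWAS returns
#' approximately alpha + (1 - 2p)(1 - 2F) E\[alpha_f | g = 1\] +
#' 2 (p + (1 - 2p) F) E\[alpha_f | g = 2\] (conditioning on carried copies).
#'
#' @param alpha average causal effect.
#' @param e_f_het mean family deviation conditional on a parent being
#'   heterozygous at the locus.
#' @param e_f_g1,e_f_g2 mean family deviations conditional on the sampled
#'   individual carrying 1 or 2 focal alleles.
#' @param p focal-allele frequency.
#' @param f_coef inbreeding coefficient F at the locus (default 0).
#' @param design `"sibling"` or `"population"`.
#' @return expected slope.
#' @export
gxe_expected_estimates <- function(alpha, e_f_het = 0, e_f_g1 = 0, e_f_g2 = 0,
                                   p = 0.5, f_coef = 0,
                                   design = c("sibling", "population")) {
  design <- match.arg(design)
  if (design == "sibling") {
    alpha + e_f_het
  } else {
    alpha + (1 - 2 * p) * (1 - 2 * f_coef) * e_f_g1 +
      2 * (p + (1 - 2 * p) * f_coef) * e_f_g2
  }
}

#' All closed-form predictions as a table
#'
#' Convenience wrapper used by the command-line calculator: evaluates every
#' closed-form prediction available from a set of scalar theory parameters.
#'
#' @param h2 heritability; @param rho mate correlation;
#' @param vs_over_vp selection strength; @param c_bar_h harmonic-mean
#'   recombination; @param L1,L2 causal-locus counts; @param beta sibling
#'   indirect coefficient; @param r_g_sibs sibling genotypic correlation.
#' @return data frame with columns `quantity` and `value`.
#' @export
theory_report <- function(h2 = 0.8, rho = 0.25, vs_over_vp = 30,
                          c_bar_h = 0.464, L1 = 1000, L2 = 1000,
                          beta = 0, r_g_sibs = 0.5) {
  b_pop <- stabsel_attenuation(h2, 1 - h2, vs_over_vp = vs_over_vp,
                               c_bar_h = c_bar_h, design = "population")
  data.frame(
    quantity = c("am_inflation_same_trait", "am_spurious_asym",
                 "am_spurious_sym", "am_architecture_scaling",
                 "stabsel_attenuation_population", "stabsel_attenuation_family",
                 "snp_h2_reduction", "masked_mate_correlation",
                 "sibling_estimate_with_indirect",
                 "population_estimate_with_indirect"),
    value = c(am_inflation_same_trait(h2, rho),
              am_spurious_cross_trait(h2, rho, symmetric = FALSE),
              am_spurious_cross_trait(h2, rho, symmetric = TRUE),
              am_architecture_scaling(L1, L2),
              b_pop,
              (1 - 2 * c_bar_h) * b_pop,
              snp_h2_reduction(b_pop),
              masked_mate_correlation(rho, h2, vs_over_vp, c_bar_h),
              sibling_estimate_with_indirect(1, beta),
              population_estimate_with_indirect(1, beta, r_g_sibs)))
}
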