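# GWAS estimators across study designs. All regressions are marginal
# (one locus at a time), matching standard single-marker association scans.

gwas_result <- function(design, estimate, pop, extra = NULL) {
  p <- allele_freqs(pop)
  g <- genotypes(pop)
  v <- colMeans(g^2) - colMeans(g)^2
  out <- data.frame(locus = seq_len(n_loci(pop)), design = design,
                    estimate = estimate, p_hat = p, V_lambda = v,
                    n = n_ind(pop))
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Population GWAS
#'
#' Per-locus simple OLS slope (with intercept) of trait values on genotype
#' dosage across all individuals. Monomorphic loci are flagged `NA`, not an
#' error.
#'
#' @param pop a [phased_pop].
#' @param phenotypes trait values aligned with `pop`.
#' @return a `gwas_result` data frame with columns `locus`, `design`,
#'   `estimate`, `p_hat`, `V_lambda`, `n`.
#' @export
population_gwas <- function(pop, phenotypes) {
  if (length(phenotypes) != n_ind(pop)) stop("phenotypes must align with individuals")
  g <- genotypes(pop)
  n <- n_ind(pop)
  sy <- as.vector(crossprod(g, phenotypes)) / n - colMeans(g) * mean(phenotypes)
  v <- colMeans(g^2) - colMeans(g)^2
  est <- ifelse(v > 0, sy / v, NA_real_)
  gwas_result("population", est, pop)
}

#' Sibling-difference GWAS
#'
#' Regresses within-pair differences in trait values on within-pair
#' differences in genotype dosage, without intercept (the no-intercept slope
#' is invariant to the within-pair ordering, since flipping a pair flips both
#' differences). Loci at which no pair differs in genotype are flagged `NA`.
#'
#' @param pop a [phased_pop] grouped into full-sibling pairs by `pop$family`.
#' @param phenotypes trait values aligned with `pop`.
#' @return a `gwas_result` data frame; `H_lambda` is the fraction of parents
#'   heterozygous at the locus, estimated from the transmitted-haplotype
#'   pairs when parent indices are unavailable.
#' @export
sibling_gwas <- function(pop, phenotypes) {
  pr <- sibling_pairs(pop)
  g <- genotypes(pop)
  dg <- g[pr[, 1L], , drop = FALSE] - g[pr[, 2L], , drop = FALSE]
  dy <- phenotypes[pr[, 1L]] - phenotypes[pr[, 2L]]
  ss <- colSums(dg^2)
  est <- ifelse(ss > 0, as.vector(crossprod(dg, dy)) / ss, NA_real_)
  gwas_result("sibling", est, pop)
}

#' Parent-offspring (transmitted / untransmitted) GWAS
#'
#' Joint per-locus OLS (with intercept) of offspring trait values on the
#' transmitted genotype g_T (the offspring's own dosage) and the
#' untransmitted genotype g_U (the sum over both parents of the allele each
#' did not transmit). Transmissions are known exactly because the simulator
#' tracks phase: the untransmitted maternal allele is the mother's dosage
#' minus the offspring's maternal haplotype, and likewise for the father.
#' Returns the two slopes and their difference, the direct-effect estimate.
#'
#' @param pop offspring [phased_pop] with recorded `mother` and `father`.
#' @param parents the parental [phased_pop].
#' @param phenotypes offspring trait values.
#' @return a `gwas_result` data frame with columns `estimate` (= T minus U),
#'   `estimate_T`, `estimate_U`.
#' @export
parent_offspring_gwas <- function(pop, parents, phenotypes) {
  if (is.null(pop$mother) || is.null(pop$father)) {
    stop("offspring population lacks recorded parent indices (phase untracked)")
  }
  gT <- genotypes(pop)
  gp <- genotypes(parents)
  gU <- (gp[pop$mother, , drop = FALSE] - pop$mat) +
        (gp[pop$father, , drop = FALSE] - pop$pat)
  y <- phenotypes
  n <- n_ind(pop)
  sTT <- colMeans(gT^2) - colMeans(gT)^2
  sUU <- colMeans(gU^2) - colMeans(gU)^2
  sTU <- colMeans(gT * gU) - colMeans(gT) * colMeans(gU)
  sTY <- as.vector(crossprod(gT, y)) / n - colMeans(gT) * mean(y)
  sUY <- as.vector(crossprod(gU, y)) / n - colMeans(gU) * mean(y)
  det <- sTT * sUU - sTU^2
  ok <- det > .Machine$double.eps
  bT <- ifelse(ok, (sUU * sTY - sTU * sUY) / det, NA_real_)
  bU <- ifelse(ok, (sTT * sUY - sTU * sTY) / det, NA_real_)
  gwas_result("parent_offspring_TminusU", bT - bU, pop,
              extra = data.frame(estimate_T = bT, estimate_U = bU))
}

#' Predicted effect-size estimates from LD decompositions
#'
#' Evaluates the analytic confound decomposition of each study design from
#' recorded LD, trait architecture, and the pairwise recombination-fraction
#' matrix:
#' \describe{
#'   \item{population}{alpha_hat = \[sum_l 2 (D + Dt) alpha_d + Cov(g, eps)\]
#'     / V_lambda, with sample cis-/trans-LD; an exact in-sample identity for
#'     additively constructed phenotypes. Parental-LD indirect-effect terms
#'     (D' + Dt' + 2 Dt) alpha_i are added when the architecture has indirect
#'     effects and `parents` is supplied.}
#'   \item{sibling}{(2 / H_lambda) \[sum_local D' alpha_d +
#'     sum_nonlocal (1 - 2 c)(D' - Dt') alpha_d\] with LD measured in the
#'     parents; only linked loci confound, and the focal locus itself
#'     contributes its locally tagged effect.}
#'   \item{parent_offspring_U}{(2 / V_lambda) \[sum_l (D' c + Dt' (1 - c) +
#'     Dt) alpha_d + local and distant indirect terms + Cov(g_U, eps) / 2\].}
#' }
#'
#' @param design `"population"`, `"sibling"`, or `"parent_offspring_U"`.
#' @param pop the GWAS sample ([phased_pop]).
#' @param arch a [trait_architecture].
#' @param map a [recomb_map] (needed for family designs).
#' @param parents parental [phased_pop] (needed for family designs and
#'   indirect effects).
#' @param eps optional per-individual environmental deviations used to
#'   evaluate the environmental-confound term exactly.
#' @param local_window half-width (Morgans) of the window around each locus
#'   treated as locally tagged, default 0.01.
#' @param loci loci at which to evaluate the prediction (default all).
#' @return numeric vector of predicted estimates.
#' @export
decompose_estimate <- function(design = c("population", "sibling",
                                          "parent_offspring_U"),
                               pop, arch, map = NULL, parents = NULL,
                               eps = NULL, local_window = 0.01,
                               loci = seq_len(n_loci(pop))) {
  design <- match.arg(design)
  L <- n_loci(pop)
  ad <- full_effect_vector(arch, L, "alpha_d")
  ai <- full_effect_vector(arch, L, "alpha_i")
  has_ind <- any(ai != 0)

  if (design == "population") {
    ld <- ld_matrices(pop)
    g <- genotypes(pop)
    v <- colMeans(g^2) - colMeans(g)^2
    num <- as.vector((2 * (ld$cis + ld$trans)) %*% ad)
    if (has_ind) {
      if (is.null(parents)) stop("indirect-effect terms need the parental population")
      lp <- ld_matrices(parents)
      num <- num + as.vector((lp$cis + lp$trans + 2 * ld$trans) %*% ai)
    }
    if (!is.null(eps)) {
      num <- num + as.vector(crossprod(g, eps)) / n_ind(pop) -
        colMeans(g) * mean(eps)
    }
    return((num / v)[loci])
  }

  if (is.null(parents)) stop("family-design decompositions need the parental population")
  if (is.null(map)) stop("family-design decompositions need the genetic map")
  lp <- ld_matrices(parents)
  cmat <- recomb_matrix(map)
  local <- outer(map$chrom, map$chrom, "==") &
    abs(outer(map$pos, map$pos, "-")) <= local_window

  if (design == "sibling") {
    gp <- genotypes(parents)
    H <- colMeans(gp == 1L)
    dd <- lp$cis - lp$trans
    W <- ifelse(local, lp$cis, (1 - 2 * cmat) * dd)
    num <- 2 * as.vector(W %*% ad)
    return((num / H)[loci])
  }

  # parent_offspring_U (Eq. for the untransmitted-allele regression)
  g <- genotypes(pop)
  v <- colMeans(g^2) - colMeans(g)^2
  Wd <- lp$cis * cmat + lp$trans * (1 - cmat)
  ldo <- ld_matrices(pop)
  num <- 2 * as.vector((Wd + ldo$trans) %*% ad)
  if (has_ind) {
    num <- num + 2 * as.vector(ifelse(local, lp$cis, lp$cis) %*% ai) +
      2 * as.vector((lp$trans + 2 * ldo$trans) %*% ai)
  }
  if (!is.null(eps)) {
    gp <- genotypes(parents)
    gU <- (gp[pop$mother, , drop = FALSE] - pop$mat) +
          (gp[pop$father, , drop = FALSE] - pop$pat)
    num <- num + as.vector(crossprod(gU, eps)) / n_ind(pop) -
      colMeans(gU) * mean(eps)
  }
  (num / v)[loci]
}

#' Summary metrics of a GWAS against the truth
#'
#' Three scalar metrics over a declared locus set: the mean deviation of the
#' estimate from the true effect E\[alpha_hat - alpha\]; the
#' heterozygosity-weighted mean squared estimate E\[2 p (1 - p) alpha_hat^2\]
#' (related to SNP-heritability); and, when a second GWAS is supplied, the
#' heterozygosity-weighted cross product E\[2 p (1 - p) alpha_hat beta_hat\]
#' (related to cross-trait genetic covariance). Loci with `NA` estimates are
#' excluded, with a count reported.
#'
#' @param result a `gwas_result` (e.g. from [population_gwas()]).
#' @param truth true per-locus effects over `loci` (scalar recycled), default
#'   0.
#' @param loci locus indices defining the summary set (default all).
#' @param second optional second `gwas_result` on the same loci.
#' @return a list with `mean_deviation`, `het_weighted_mean_square`,
#'   `het_weighted_cross_product` (NA unless `second` given), `n_loci_used`,
#'   `n_dropped`.
#' @export
summarize_gwas <- function(result, truth = 0, loci = result$locus,
                           second = NULL) {
  i <- match(loci, result$locus)
  if (anyNA(i)) stop("locus sets misaligned")
  est <- result$estimate[i]
  p <- result$p_hat[i]
  truth <- rep_len(truth, length(loci))
  ok <- !is.na(est)
  cross <- NA_real_
  if (!is.null(second)) {
    j <- match(loci, second$locus)
    if (anyNA(j)) stop("locus sets misaligned")
    est2 <- second$estimate[j]
    ok <- ok & !is.na(est2)
    cross <- mean(2 * p[ok] * (1 - p[ok]) * est[ok] * est2[ok])
  }
  list(mean_deviation = mean(est[ok] - truth[ok]),
       het_weighted_mean_square = mean(2 * p[ok] * (1 - p[ok]) * est[ok]^2),
       het_weighted_cross_product = cross,
       n_loci_used = sum(ok), n_dropped = sum(!ok))
}
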