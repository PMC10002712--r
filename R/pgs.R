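# Polygenic scores and within-family PGS regressions.

#' Polygenic-score weights
#'
#' @param loci genotyped locus indices.
#' @param weights per-locus weights (trait units per allele), aligned with
#'   `loci`.
#' @param provenance label recording which GWAS produced the weights.
#' @return an object of class `pgs_weights`.
#' @export
pgs_weights <- function(loci, weights, provenance = "unknown") {
  loci <- as.integer(loci)
  if (length(weights) != length(loci)) stop("weights must align with loci")
  structure(list(loci = loci, weights = as.numeric(weights),
                 provenance = provenance),
            class = "pgs_weights")
}

#' Build polygenic scores
#'
#' score = sum over genotyped loci of dosage x weight.
#'
#' @param pop a [phased_pop].
#' @param weights a [pgs_weights] object.
#' @return numeric vector of per-individual scores.
#' @export
build_pgs <- function(pop, weights) {
  if (any(weights$loci < 1L | weights$loci > n_loci(pop))) {
    stop("weight loci do not match the population's loci")
  }
  as.vector(genotypes(pop)[, weights$loci, drop = FALSE] %*% weights$weights)
}

#' Sibling PGS regression
#'
#' Regresses sibling differences in a second trait on sibling differences in
#' a polygenic score built with fixed weights (typically from a population
#' GWAS of a first trait). The covariance of the differences equals, in
#' expectation, a double sum over score loci and causal loci of
#' 2 (1 - 2 c)(D' - Dt') w beta, so non-zero slopes reflect signed
#' intra-chromosomal LD rather than necessarily pleiotropy.
#'
#' @param pop a [phased_pop] grouped into full-sibling pairs.
#' @param weights a [pgs_weights] object.
#' @param phenotypes trait-2 values aligned with `pop`.
#' @return list with `covariance` (denominator n), `slope` (no-intercept OLS
#'   of the phenotype difference on the score difference) and `n_pairs`.
#' @export
sibling_pgs_regression <- function(pop, weights, phenotypes) {
  pr <- sibling_pairs(pop)
  if (nrow(pr) < 2L) stop("need at least 2 sibling pairs")
  s <- build_pgs(pop, weights)
  ds <- s[pr[, 1L]] - s[pr[, 2L]]
  dy <- phenotypes[pr[, 1L]] - phenotypes[pr[, 2L]]
  list(covariance = mean(ds * dy),
       slope = sum(ds * dy) / sum(ds^2),
       n_pairs = nrow(pr))
}

#' Mate-correlation estimate from cross-chromosome PGS correlations
#'
#' Estimates the strength of assortative mating from the disequilibrium that
#' it leaves between polygenic-score contributions of different chromosomes.
#' Per-chromosome partial scores are formed, all cross-chromosome score
#' covariances pooled, normalised by the product of per-chromosome score
#' variances (genic, from allele frequencies and weights, or observed), and
#' the pooled ratio x inverted through the equilibrium relation
#' x = rho_g / (1 - rho_g) to give the implied mate genetic-score correlation
#' rho_g, which is rescaled by the PGS heritability `h2` to a mate
#' phenotypic correlation.
#'
#' Two conventions are exposed: `"within_individual"` pools the covariances
#' between an individual's own per-chromosome scores (the convention used by
#' cross-chromosome estimators in the literature, and the one through which
#' stabilizing selection masks assortative mating); `"between_mate"` pools
#' the covariances between one mate's score on one chromosome and the other
#' mate's score on another (requires `pairs`).
#'
#' @param pop a [phased_pop].
#' @param weights a [pgs_weights] spanning at least two chromosomes.
#' @param map a [recomb_map] assigning loci to chromosomes.
#' @param h2 assumed PGS heritability used for the rescaling (default 1).
#' @param pairs mating pairs (`mother`, `father`) for the between-mate
#'   convention.
#' @param convention `"within_individual"` (default) or `"between_mate"`.
#' @param normalization `"genic"` (default) or `"observed"` per-chromosome
#'   score variances.
#' @return list with `rho_hat` (implied mate phenotypic correlation),
#'   `rho_g_hat`, `x` (pooled normalised cross-chromosome disequilibrium) and
#'   `n_chrom`.
#' @export
cross_chrom_pgs_mate_correlation <- function(pop, weights, map, h2 = 1,
                                             pairs = NULL,
                                             convention = c("within_individual",
                                                            "between_mate"),
                                             normalization = c("genic",
                                                               "observed")) {
  convention <- match.arg(convention)
  normalization <- match.arg(normalization)
  chrom <- map$chrom[weights$loci]
  chroms <- unique(chrom)
  if (length(chroms) < 2L) stop("cross-chromosome estimator needs loci on >= 2 chromosomes")
  g <- genotypes(pop)
  p <- allele_freqs(pop)
  S <- sapply(chroms, function(ch) {
    sel <- weights$loci[chrom == ch]
    w <- weights$weights[chrom == ch]
    as.vector(g[, sel, drop = FALSE] %*% w)
  })
  vg <- sapply(chroms, function(ch) {
    sel <- weights$loci[chrom == ch]
    w <- weights$weights[chrom == ch]
    sum(2 * p[sel] * (1 - p[sel]) * w^2)
  })
  vnorm <- switch(normalization,
                  genic = vg,
                  observed = apply(S, 2L, function(x) mean(x^2) - mean(x)^2))
  vtot <- sum(vnorm)
  nc <- length(chroms)
  num <- 0; den <- 0
  if (convention == "within_individual") {
    CS <- pcov_mat(S, S)
    for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
      num <- num + 2 * CS[a, b]
      den <- den + 2 * vnorm[a] * vnorm[b] / vtot
    }
  } else {
    if (is.null(pairs)) stop("between-mate convention requires mating pairs")
    Sf <- S[pairs$mother, , drop = FALSE]
    Sm <- S[pairs$father, , drop = FALSE]
    CC <- (pcov_mat(Sf, Sm) + t(pcov_mat(Sm, Sf))) / 2
    for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
      num <- num + CC[a, b] + CC[b, a]
      den <- den + 2 * vnorm[a] * vnorm[b] / vtot
    }
  }
  x <- unname(num / den)
  rho_g <- x / (1 + x)
  list(rho_hat = rho_g / h2, rho_g_hat = rho_g, x = x, n_chrom = nc)
}
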