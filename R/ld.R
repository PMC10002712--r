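# cis- and trans-linkage disequilibrium on phased populations.
#
# All covariances use denominator n (population covariance), so that in-sample
# identities such as Cov(g_i, g_j) = 2(D_cis + D_trans) hold exactly.

pcov <- function(x, y) mean(x * y) - mean(x) * mean(y)

pcov_mat <- function(X, Y) {
  n <- nrow(X)
  crossprod(X, Y) / n - tcrossprod(colMeans(X), colMeans(Y))
}

#' Cis-linkage disequilibrium between two loci
#'
#' The covariance of focal-allele dosages across same-origin haplotypes
#' (maternal with maternal, paternal with paternal), averaged over the two
#' origins: positive cis-LD means that an individual who inherits the focal
#' allele at one locus from a given parent is disproportionately likely to
#' have inherited the focal allele at the other locus from that same parent.
#'
#' @param pop a [phased_pop].
#' @param locus_i,locus_j locus indices.
#' @return dosage covariance in \[-0.25, 0.25\]; 0 at monomorphic loci.
#' @export
cis_ld <- function(pop, locus_i, locus_j) {
  (pcov(pop$mat[, locus_i], pop$mat[, locus_j]) +
   pcov(pop$pat[, locus_i], pop$pat[, locus_j])) / 2
}

#' Trans-linkage disequilibrium between two loci
#'
#' The covariance of the maternal dosage at one locus with the paternal
#' dosage at the other, symmetrised over the two orderings: positive trans-LD
#' means that inheriting the focal allele at one locus from one parent makes
#' inheriting the focal allele at the other locus from the *other* parent
#' disproportionately likely.
#'
#' @inheritParams cis_ld
#' @return dosage covariance in \[-0.25, 0.25\].
#' @export
trans_ld <- function(pop, locus_i, locus_j) {
  (pcov(pop$mat[, locus_i], pop$pat[, locus_j]) +
   pcov(pop$pat[, locus_i], pop$mat[, locus_j])) / 2
}

#' Full cis- and trans-LD matrices
#'
#' @param pop a [phased_pop].
#' @param loci locus indices (default all).
#' @return a list with symmetric matrices `cis` and `trans`. The diagonal of
#'   `cis` is the mean haplotype variance p(1-p); the diagonal of `trans` is
#'   the maternal-paternal same-locus covariance (departure from
#'   Hardy-Weinberg, p(1-p)F).
#' @export
ld_matrices <- function(pop, loci = seq_len(n_loci(pop))) {
  M <- pop$mat[, loci, drop = FALSE]; P <- pop$pat[, loci, drop = FALSE]
  cis <- (pcov_mat(M, M) + pcov_mat(P, P)) / 2
  mp <- pcov_mat(M, P)
  trans <- (mp + t(mp)) / 2
  list(cis = cis, trans = trans)
}

#' Coupling and repulsion double-heterozygote fractions
#'
#' Fractions of individuals heterozygous at both loci carrying the focal
#' alleles on the same haplotype (coupling) or on opposite haplotypes
#' (repulsion). When maternal and paternal sample allele frequencies agree,
#' (H_coup - H_rep) / 2 = D_cis - D_trans exactly; in general the identity
#' holds up to a term (pbar_m,i - pbar_p,i)(pbar_m,j - pbar_p,j) / 2 in the
#' sample frequency differences between haplotype origins.
#'
#' @inheritParams cis_ld
#' @return named numeric vector `c(H_coup, H_rep)`.
#' @export
coupling_repulsion <- function(pop, locus_i, locus_j) {
  mi <- pop$mat[, locus_i]; pi <- pop$pat[, locus_i]
  mj <- pop$mat[, locus_j]; pj <- pop$pat[, locus_j]
  het <- (mi != pi) & (mj != pj)
  c(H_coup = mean(het & (mi == mj)), H_rep = mean(het & (mi != mj)))
}

#' Pairwise LD summary table
#'
#' @param pop a [phased_pop].
#' @param pairs 2-column matrix of locus index pairs; default all unordered
#'   pairs.
#' @return data frame with columns `locus_i`, `locus_j`, `D_cis`, `D_trans`,
#'   `r_cis`, `r_trans`, `H_coup`, `H_rep`.
#' @export
ld_table <- function(pop, pairs = NULL) {
  L <- n_loci(pop)
  if (is.null(pairs)) {
    pairs <- t(combn(L, 2L))
  }
  p <- allele_freqs(pop)
  hv <- p * (1 - p)  # haplotype variance
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    dc <- cis_ld(pop, i, j); dt <- trans_ld(pop, i, j)
    denom <- sqrt(hv[i] * hv[j])
    hh <- coupling_repulsion(pop, i, j)
    data.frame(locus_i = i, locus_j = j, D_cis = dc, D_trans = dt,
               r_cis = if (denom > 0) dc / denom else 0,
               r_trans = if (denom > 0) dt / denom else 0,
               H_coup = hh[["H_coup"]], H_rep = hh[["H_rep"]])
  })
  do.call(rbind, rows)
}

#' Predicted LD in a stratified sample of two populations
#'
#' In a sample mixing two diverged populations in proportions w and 1 - w,
#' allele-frequency differences generate identical cis- and trans-LD:
#' D = w (1 - w) (p1_i - p2_i)(p1_j - p2_j) for every locus pair.
#'
#' @param p1,p2 per-locus focal-allele frequencies in populations 1 and 2.
#' @param weight sampling fraction w of population 1 (default 0.5, equal
#'   weights).
#' @return a list with matrices `D_cis` and `D_trans` (equal), of dimension
#'   `length(p1)` squared.
#' @export
stratified_ld <- function(p1, p2, weight = 0.5) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) stop("frequencies must lie in [0, 1]")
  D <- weight * (1 - weight) * outer(p1 - p2, p1 - p2)
  list(D_cis = D, D_trans = D)
}

#' Decay of admixture cis-LD under random mating
#'
#' After admixture, the initial cis-LD D0 between a locus pair decays by a
#' factor (1 - c) per generation, where c is the pairwise recombination
#' fraction; the trans-LD is zero in every generation because mating is
#' random with respect to ancestry.
#'
#' @param D0 initial cis-LD (scalar or vector).
#' @param c recombination fraction in \[0, 0.5\].
#' @param t generations since admixture (>= 0).
#' @return a list with `D_cis = D0 (1 - c)^t` and `D_trans = 0`.
#' @export
admixture_ld_decay <- function(D0, c, t) {
  if (any(c < 0 | c > 0.5)) stop("c must lie in [0, 0.5]")
  if (any(t < 0)) stop("t must be >= 0")
  list(D_cis = D0 * (1 - c)^t, D_trans = D0 * 0)
}
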