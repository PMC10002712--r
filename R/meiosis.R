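# Poisson-crossover meiosis on a genetic map. Crossover counts per chromosome
# are Poisson(length in Morgans), positions uniform in map distance, starting
# haplotype random per chromosome: this matches the Haldane map function used
# for analytic recombination fractions, with no crossover interference.

# 0/1 matrix (n_meioses x L): 1 means "copy from the second haplotype"
crossover_patterns <- function(n, map) {
  L <- nrow(map)
  pat <- matrix(0L, n, L)
  lens <- chrom_lengths(map)
  for (ch in names(lens)) {
    cols <- which(map$chrom == ch)
    m <- length(cols)
    if (m == 0L) next
    len <- lens[[ch]]
    start <- sample.int(2L, n, replace = TRUE) - 1L
    if (len <= 0) {
      pat[, cols] <- start
      next
    }
    k <- rpois(n, len)
    K <- sum(k)
    if (K == 0L) {
      pat[, cols] <- start
      next
    }
    p <- map$pos[cols]
    u <- runif(K) * len
    id <- rep.int(seq_len(n), k)
    b <- findInterval(u, p)              # 0..m; crossovers at b flip loci > b
    keep <- b < m
    cb <- matrix(tabulate(id[keep] + n * b[keep], nbins = n * m), n, m)
    if (m > 1L) for (j in 2:m) cb[, j] <- cb[, j] + cb[, j - 1L]
    pat[, cols] <- (start + cb) %% 2L
  }
  pat
}

# transmitted haplotypes for a set of meioses: rows of hapA/hapB are the
# parents' two haplotypes, one row per meiosis
transmit <- function(hapA, hapB, map) {
  pat <- crossover_patterns(nrow(hapA), map)
  sel <- pat == 1L
  gam <- hapA
  gam[sel] <- hapB[sel]
  gam
}

#' Produce offspring by monogamous meiosis
#'
#' Each mating pair produces exactly two offspring (full siblings), so the
#' population size is preserved. Each parent transmits one recombinant
#' haplotype per offspring, formed by Poisson crossovers on the genetic map.
#' Brood sex ratios follow the even-sex-ratio scheme: after randomly
#' permuting pairs, a quarter of pairs produce two daughters, a quarter two
#' sons, and half one of each.
#'
#' @param pairs data frame with columns `mother`, `father` (row indices into
#'   `pop`), e.g. from [pair_random()] or [pair_assortative()].
#' @param pop the parental [phased_pop].
#' @param map a [recomb_map] covering all loci of `pop`.
#' @param seed optional integer seed.
#' @return a [phased_pop] of `2 * nrow(pairs)` offspring with recorded
#'   `mother`, `father` and `family` (one family per pair).
#' @export
meiosis_offspring <- function(pairs, pop, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(c("mother", "father") %in% names(pairs))) {
    stop("pairs must have columns 'mother' and 'father'")
  }
  if (nrow(map) != n_loci(pop)) stop("map does not cover the population's loci")
  np <- nrow(pairs)
  n_off <- 2L * np
  mo <- rep(pairs$mother, each = 2L)
  fa <- rep(pairs$father, each = 2L)
  mat <- transmit(pop$mat[mo, , drop = FALSE], pop$pat[mo, , drop = FALSE], map)
  pat <- transmit(pop$mat[fa, , drop = FALSE], pop$pat[fa, , drop = FALSE], map)
  # brood sex ratios: 1/4 FF, 1/4 MM, 1/2 FM among randomly permuted pairs
  broods <- c(rep("FF", np %/% 4L), rep("MM", np %/% 4L))
  broods <- c(broods, rep("FM", np - length(broods)))
  broods <- broods[sample.int(np)]
  sexmat <- rbind(FF = c("F", "F"), MM = c("M", "M"), FM = c("F", "M"))
  sex <- as.vector(t(sexmat[broods, , drop = FALSE]))
  new_phased_pop(mat, pat, sex, mother = mo, father = fa,
             family = rep(seq_len(np), each = 2L),
             generation = pop$generation + 1L)
}

#' Selection schemes
#'
#' @param kind `"none"` or `"stabilizing"` (Gaussian selection against
#'   deviations from an optimum).
#' @param optimum optimal trait value.
#' @param v_s width of the Gaussian fitness function, in squared trait units;
#'   smaller values mean stronger selection.
#' @return an object of class `selection_scheme`.
#' @export
selection_scheme <- function(kind = c("none", "stabilizing"), optimum = 0,
                             v_s = Inf) {
  kind <- match.arg(kind)
  if (kind == "stabilizing" && !(v_s > 0)) stop("V_S must be > 0")
  structure(list(kind = kind, optimum = optimum, v_s = v_s),
            class = "selection_scheme")
}

#' Sample parents under Gaussian stabilizing selection
#'
#' Individuals enter the mating pool with probability proportional to
#' exp(-(Y - optimum)^2 / (2 V_S)), sampled with replacement separately by
#' sex so that the sex balance needed for monogamous pairing is preserved.
#'
#' @param pop a [phased_pop].
#' @param phenotypes trait values aligned with `pop`.
#' @param scheme a [selection_scheme] with `kind = "stabilizing"`.
#' @param n_out size of the returned mating pool (default `n_ind(pop)`,
#'   half female and half male).
#' @param seed optional integer seed.
#' @return a [phased_pop] of selected (possibly repeated) individuals.
#' @export
select_parents_stabilizing <- function(pop, phenotypes, scheme,
                                       n_out = n_ind(pop), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (scheme$kind != "stabilizing") stop("scheme must be stabilizing")
  if (n_out %% 2L != 0L) stop("n_out must be even")
  # subtract the max log-weight per sex for numerical stability
  lw <- -(phenotypes - scheme$optimum)^2 / (2 * scheme$v_s)
  idx <- integer(0)
  for (s in c("F", "M")) {
    who <- which(pop$sex == s)
    w <- exp(lw[who] - max(lw[who]))
    if (!any(w > 0)) stop("all fitness weights underflowed to zero")
    idx <- c(idx, sample(who, n_out %/% 2L, replace = TRUE, prob = w))
  }
  out <- subset_pop(pop, idx)
  attr(out, "index") <- idx   # rows of `pop` drawn into the mating pool
  out
}
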