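# Independent oracles and tiny fixture builders used across the test files.
# Oracles are deliberately written as naive loops / enumerations, independent
# of the vectorised implementation paths they check.

# population (denominator n) covariance of two vectors
pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)

# brute-force cis-LD: explicit loop over individuals and haplotype origins
brute_cis_ld <- function(pop, i, j) {
  n <- n_ind(pop)
  sm <- 0; sp <- 0
  mi <- pop$mat[, i]; mj <- pop$mat[, j]
  pi <- pop$pat[, i]; pj <- pop$pat[, j]
  for (k in seq_len(n)) {
    sm <- sm + mi[k] * mj[k]
    sp <- sp + pi[k] * pj[k]
  }
  ((sm / n - mean(mi) * mean(mj)) + (sp / n - mean(pi) * mean(pj))) / 2
}

brute_trans_ld <- function(pop, i, j) {
  n <- n_ind(pop)
  s1 <- 0; s2 <- 0
  mi <- pop$mat[, i]; pj <- pop$pat[, j]
  pi <- pop$pat[, i]; mj <- pop$mat[, j]
  for (k in seq_len(n)) {
    s1 <- s1 + mi[k] * pj[k]
    s2 <- s2 + pi[k] * mj[k]
  }
  ((s1 / n - mean(mi) * mean(pj)) + (s2 / n - mean(pi) * mean(mj))) / 2
}

# brute-force harmonic mean over an explicit double loop
brute_harmonic_mean_c <- function(map) {
  L <- nrow(map)
  s <- 0; np <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    s <- s + 1 / recomb_fraction(map, i, j)
    np <- np + 1
  }
  np / s
}

# random phased population with arbitrary haplotype frequencies (no HWE/LE
# structure imposed), for property tests
random_pop <- function(n = 60, L = 4, seed = 1) {
  set.seed(seed)
  phased_pop(matrix(rbinom(n * L, 1, runif(L)[rep(1:L, each = n)]), n, L),
             matrix(rbinom(n * L, 1, runif(L)[rep(1:L, each = n)]), n, L),
             sex = rep(c("F", "M"), length.out = n))
}

# a population built from explicit haplotype rows: hap_m and hap_p are
# matrices with one row per individual
pop_from_haps <- function(hap_m, hap_p, ...) {
  n <- nrow(hap_m)
  phased_pop(hap_m, hap_p, sex = rep(c("F", "M"), length.out = n), ...)
}

# exhaustive enumeration of sibling-pair transmissions for a single locus:
# returns the expected sibling-difference regression slope under the G x E
# family-deviation model (effect alpha + dev per family), by enumerating all
# offspring-pair transmission outcomes of each family with equal probability
enum_sibling_slope_gxe <- function(families, alpha) {
  num <- 0; den <- 0
  for (f in families) {
    gm <- f$mother; gf <- f$father   # parental dosages 0/1/2
    a_f <- alpha + f$dev
    tm <- if (gm == 1L) c(0L, 1L) else gm / 2L   # transmissible alleles
    tf <- if (gf == 1L) c(0L, 1L) else gf / 2L
    for (g1m in tm) for (g1f in tf) for (g2m in tm) for (g2f in tf) {
      w <- 1 / (length(tm)^2 * length(tf)^2)
      dg <- (g1m + g1f) - (g2m + g2f)
      dy <- a_f * dg     # noise-free
      num <- num + w * dy * dg
      den <- den + w * dg^2
    }
  }
  num / den
}
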