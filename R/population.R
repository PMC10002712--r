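#' Phased populations
#'
#' A phased population stores, for every individual, the maternal and paternal
#' haplotype dosage (0 or 1) at every locus, the individual's sex, and —
#' when the population was produced by the simulator — the row indices of its
#' mother and father in the parental population and a family label shared by
#' full siblings. The focal allele at every locus is, by convention, the
#' allele that directly increases the trait value.
#'
#' @param mat,pat integer matrices (individuals x loci) of maternal and
#'   paternal haplotype dosages, entries 0 or 1.
#' @param sex character vector, `"F"` or `"M"`, one per individual.
#' @param mother,father optional integer vectors of parental row indices.
#' @param family optional integer vector; full siblings share a value.
#' @param generation integer generation counter.
#' @return an object of class `phased_pop`.
#' @export
phased_pop <- function(mat, pat, sex, mother = NULL, father = NULL,
                       family = NULL, generation = 0L) {
  mat <- as.matrix(mat); pat <- as.matrix(pat)
  storage.mode(mat) <- "integer"; storage.mode(pat) <- "integer"
  if (!identical(dim(mat), dim(pat))) stop("mat and pat must have identical dimensions")
  if (nrow(mat) != length(sex)) stop("sex must have one entry per individual")
  if (any(mat < 0L | mat > 1L) || any(pat < 0L | pat > 1L)) {
    stop("haplotype dosages must be 0 or 1")
  }
  if (!all(sex %in% c("F", "M"))) stop('sex entries must be "F" or "M"')
  new_phased_pop(mat, pat, as.character(sex), mother, father, family,
                 as.integer(generation))
}

# fast internal constructor: callers guarantee valid 0/1 integer matrices
new_phased_pop <- function(mat, pat, sex, mother = NULL, father = NULL,
                           family = NULL, generation = 0L) {
  structure(list(mat = mat, pat = pat, sex = sex,
                 mother = mother, father = father, family = family,
                 generation = generation),
            class = "phased_pop")
}

#' @export
print.phased_pop <- function(x, ...) {
  cat(sprintf("<phased_pop> %d individuals (%d F / %d M) x %d loci, generation %d\n",
              n_ind(x), sum(x$sex == "F"), sum(x$sex == "M"), n_loci(x),
              x$generation))
  invisible(x)
}

#' @rdname phased_pop
#' @param pop a `phased_pop`.
#' @export
n_ind <- function(pop) nrow(pop$mat)

#' @rdname phased_pop
#' @export
n_loci <- function(pop) ncol(pop$mat)

#' Genotype dosage matrix (0/1/2)
#' @param pop a [phased_pop].
#' @return integer matrix individuals x loci.
#' @export
genotypes <- function(pop) pop$mat + pop$pat

#' Focal-allele frequencies
#' @param pop a [phased_pop].
#' @return numeric vector of per-locus allele frequencies.
#' @export
allele_freqs <- function(pop) (colMeans(pop$mat) + colMeans(pop$pat)) / 2

#' Subset a phased population by individual
#'
#' Parental indices are kept as-is (they refer to the previous generation).
#' Individuals may be repeated, e.g. when sampling with replacement under
#' selection.
#'
#' @param pop a [phased_pop].
#' @param idx integer vector of individuals to keep.
#' @return a `phased_pop`.
#' @export
subset_pop <- function(pop, idx) {
  new_phased_pop(pop$mat[idx, , drop = FALSE], pop$pat[idx, , drop = FALSE],
             pop$sex[idx],
             mother = pop$mother[idx], father = pop$father[idx],
             family = pop$family[idx], generation = pop$generation)
}

#' Initialise a founding population at linkage equilibrium
#'
#' Haplotype dosages are drawn independently per haplotype per locus at the
#' supplied focal-allele frequencies, so founders are at linkage equilibrium
#' and Hardy-Weinberg proportions. Sexes are assigned half female, half male.
#'
#' @param n number of individuals (must be even, for monogamous pairing).
#' @param allele_freqs per-locus focal-allele frequencies in \[0, 1\]
#'   (recycled to the number of loci if scalar).
#' @param n_loci number of loci; defaults to `length(allele_freqs)`.
#' @param seed optional integer seed (sets the global RNG).
#' @return a [phased_pop].
#' @export
init_population <- function(n, allele_freqs, n_loci = length(allele_freqs),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n %% 2L != 0L) stop("n must be even (monogamous pairing requires equal sex counts)")
  if (any(allele_freqs < 0 | allele_freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  p <- rep_len(allele_freqs, n_loci)
  draw <- function() matrix(rbinom(n * n_loci, 1L, rep(p, each = n)), n, n_loci)
  sex <- rep(c("F", "M"), each = n %/% 2L)
  phased_pop(draw(), draw(), sex = sex, generation = 0L)
}

#' Balding-Nichols per-population allele frequencies
#'
#' Draws per-population focal-allele frequencies independently from
#' Beta(p (1 - F_ST) / F_ST, (1 - p)(1 - F_ST) / F_ST) around ancestral
#' frequencies p, so that E\[p_k\] = p and Var\[p_k\] = F_ST p (1 - p).
#' Mimics allele-frequency divergence accumulated by drift.
#'
#' @param ancestral_freqs ancestral frequencies in (0, 1).
#' @param f_st Wright's fixation index in (0, 1).
#' @param n_pops number of descendant populations.
#' @param seed optional integer seed.
#' @return matrix of dimension `n_pops` x `length(ancestral_freqs)`.
#' @export
balding_nichols_freqs <- function(ancestral_freqs, f_st, n_pops = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (f_st <= 0 || f_st >= 1) stop("F_ST must lie strictly in (0, 1)")
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1)) {
    stop("ancestral frequencies must lie strictly in (0, 1)")
  }
  k <- (1 - f_st) / f_st
  L <- length(ancestral_freqs)
  out <- matrix(rbeta(n_pops * L,
                      shape1 = rep(ancestral_freqs * k, each = n_pops),
                      shape2 = rep((1 - ancestral_freqs) * k, each = n_pops)),
                n_pops, L)
  out
}

#' Admix two populations
#'
#' Founders of the admixed generation are drawn (with replacement) from
#' population 1 with probability `A` and from population 2 with probability
#' `1 - A`; mating is subsequently random with respect to ancestry. The
#' initial cis-LD between loci that had diverged in frequency is
#' A (1 - A) (p1 - p2)(q1 - q2), and decays at the pairwise recombination
#' fraction per generation (see [admixture_ld_decay()]).
#'
#' @param pop1,pop2 [phased_pop] objects with identical loci.
#' @param A admixture proportion of population 1, in (0, 1).
#' @param n_out number of admixed founders (even); default `n_ind(pop1)`.
#' @param seed optional integer seed.
#' @return a [phased_pop] of admixed founders.
#' @export
admix_populations <- function(pop1, pop2, A, n_out = n_ind(pop1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (A <= 0 || A >= 1) stop("A must lie strictly in (0, 1)")
  if (n_loci(pop1) != n_loci(pop2)) stop("populations must share the same loci")
  if (n_out %% 2L != 0L) stop("n_out must be even")
  from1 <- runif(n_out) < A
  i1 <- sample.int(n_ind(pop1), n_out, replace = TRUE)
  i2 <- sample.int(n_ind(pop2), n_out, replace = TRUE)
  mat <- matrix(0L, n_out, n_loci(pop1)); pat <- mat
  mat[from1, ] <- pop1$mat[i1[from1], , drop = FALSE]
  pat[from1, ] <- pop1$pat[i1[from1], , drop = FALSE]
  mat[!from1, ] <- pop2$mat[i2[!from1], , drop = FALSE]
  pat[!from1, ] <- pop2$pat[i2[!from1], , drop = FALSE]
  sex <- sample(rep(c("F", "M"), each = n_out %/% 2L))
  phased_pop(mat, pat, sex, generation = 0L)
}
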