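#' Trait architectures
#'
#' An additive trait architecture: a set of causal loci with per-locus direct
#' effects (trait units per focal-allele copy), optional indirect (parental)
#' effects acting through the family environment, a baseline value, and
#' environmental noise variance. By the focal-allele convention, direct
#' effects are non-negative.
#'
#' @param loci integer indices of causal loci.
#' @param alpha_d direct per-allele effects (recycled to `length(loci)`).
#' @param alpha_i indirect per-allele effects of parental genotypes
#'   (maternal and paternal effects assumed equal), default 0.
#' @param y_star baseline trait value: the expected value for offspring of
#'   parents carrying only trait-decreasing alleles.
#' @param v_e environmental noise variance.
#' @return an object of class `trait_arch`.
#' @export
trait_architecture <- function(loci, alpha_d, alpha_i = 0, y_star = 0, v_e = 0) {
  loci <- as.integer(loci)
  alpha_d <- rep_len(alpha_d, length(loci))
  alpha_i <- rep_len(alpha_i, length(loci))
  if (any(alpha_d < 0)) stop("direct effects must be >= 0 (focal-allele orientation)")
  if (v_e < 0) stop("v_e must be >= 0")
  structure(list(loci = loci, alpha_d = alpha_d, alpha_i = alpha_i,
                 y_star = y_star, v_e = v_e),
            class = "trait_arch")
}

#' Genic variance of an architecture at given allele frequencies
#'
#' Sum over causal loci of 2 p (1 - p) alpha_d^2: the additive genetic
#' variance expected at linkage equilibrium.
#'
#' @param arch a [trait_architecture].
#' @param p per-locus allele frequencies for the whole population (length
#'   `n_loci`), or for the causal loci only (length `length(arch$loci)`).
#' @return numeric scalar.
#' @export
genic_variance <- function(arch, p) {
  pc <- if (length(p) == length(arch$loci)) p else p[arch$loci]
  sum(2 * pc * (1 - pc) * arch$alpha_d^2)
}

full_effect_vector <- function(arch, L, what = c("alpha_d", "alpha_i")) {
  what <- match.arg(what)
  a <- numeric(L)
  a[arch$loci] <- arch[[what]]
  a
}

#' Compute additive phenotypes
#'
#' Y = Y* + sum_l g_l alpha_d_l + sum_l (g_l^m + g_l^f) alpha_i_l + eps,
#' where g is the individual's dosage and g^m, g^f the parental dosages.
#' Environmental noise is drawn fresh on each call.
#'
#' Gene-by-environment interaction can be injected through per-family and
#' per-individual effect-size deviations: the direct effect at every causal
#' locus becomes alpha_d + alpha_f(family) + alpha_ind(individual). Both
#' deviation rules should be mean-zero in the population when the
#' unconditional trait model is intended.
#'
#' @param pop a [phased_pop].
#' @param arch a [trait_architecture].
#' @param parents the parental [phased_pop]; required when the architecture
#'   has non-zero indirect effects.
#' @param gxe_family_dev per-family effect deviations: a numeric vector
#'   indexed by `pop$family`, or a function `f(n_families)` generating one
#'   deviation per family.
#' @param gxe_individual_sd standard deviation of per-individual effect
#'   deviations (independent of genotype).
#' @param env optional vector of group labels per individual, used with
#'   `env_confound`.
#' @param env_confound named numeric: environmental mean added per `env`
#'   group (induces gene-environment correlation if groups differ
#'   genetically).
#' @param seed optional integer seed.
#' @return numeric vector of trait values.
#' @export
compute_phenotypes <- function(pop, arch, parents = NULL,
                               gxe_family_dev = NULL, gxe_individual_sd = 0,
                               env = NULL, env_confound = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_ind(pop); L <- n_loci(pop)
  g <- genotypes(pop)
  ad <- full_effect_vector(arch, L, "alpha_d")
  y <- arch$y_star + as.vector(g %*% ad)
  if (any(arch$alpha_i != 0)) {
    if (is.null(parents)) stop("indirect effects require the parental population")
    if (is.null(pop$mother) || is.null(pop$father)) {
      stop("indirect effects require recorded parent indices")
    }
    ai <- full_effect_vector(arch, L, "alpha_i")
    gp <- genotypes(parents)
    y <- y + as.vector((gp[pop$mother, , drop = FALSE] +
                        gp[pop$father, , drop = FALSE]) %*% ai)
  }
  if (!is.null(gxe_family_dev) || gxe_individual_sd > 0) {
    gc_tot <- rowSums(g[, arch$loci, drop = FALSE])
    dev <- numeric(n)
    if (!is.null(gxe_family_dev)) {
      if (is.null(pop$family)) stop("G x E family deviations require family labels")
      fam <- pop$family
      if (is.function(gxe_family_dev)) {
        ufam <- sort(unique(fam))
        af <- gxe_family_dev(length(ufam))
        dev <- dev + af[match(fam, ufam)]
      } else {
        dev <- dev + gxe_family_dev[fam]
      }
    }
    if (gxe_individual_sd > 0) dev <- dev + rnorm(n, 0, gxe_individual_sd)
    y <- y + dev * gc_tot
  }
  if (!is.null(env_confound)) {
    if (is.null(env)) stop("env_confound requires per-individual env labels")
    y <- y + env_confound[as.character(env)]
  }
  if (arch$v_e > 0) y <- y + rnorm(n, 0, sqrt(arch$v_e))
  unname(y)
}

#' Sibling phenotypes with reciprocal indirect effects
#'
#' Each sibling's phenotype feeds back on the other with coefficient `beta`:
#' Y_i = Y* + a_i + beta Y_j + eps_i (and symmetrically), where a = alpha' g
#' is the additive genetic value. The simultaneous solution is
#' Y_i = (Y** + a_i + beta a_j + eps_i + beta eps_j) / (1 - beta^2) with
#' Y** = (1 + beta) Y*. Requires |beta| < 1, else the feedback diverges.
#'
#' @param pop a [phased_pop] whose individuals are grouped into full-sibling
#'   pairs by `pop$family` (exactly two per family).
#' @param arch a [trait_architecture] (its `v_e` is the per-sibling noise
#'   variance).
#' @param beta sibling indirect-effect coefficient, |beta| < 1.
#' @param seed optional integer seed.
#' @return numeric vector of trait values aligned with `pop`.
#' @export
sibling_phenotypes_with_indirect <- function(pop, arch, beta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(beta) >= 1) stop("|beta| must be < 1 (sibling feedback diverges)")
  pairs <- sibling_pairs(pop)
  a <- as.vector(genotypes(pop) %*% full_effect_vector(arch, n_loci(pop), "alpha_d"))
  eps <- if (arch$v_e > 0) rnorm(n_ind(pop), 0, sqrt(arch$v_e)) else numeric(n_ind(pop))
  ystar2 <- (1 + beta) * arch$y_star
  y <- numeric(n_ind(pop))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  y[i] <- (ystar2 + a[i] + beta * a[j] + eps[i] + beta * eps[j]) / (1 - beta^2)
  y[j] <- (ystar2 + a[j] + beta * a[i] + eps[j] + beta * eps[i]) / (1 - beta^2)
  y
}

#' @keywords internal
sibling_pairs <- function(pop) {
  if (is.null(pop$family)) stop("population has no family labels")
  ord <- order(pop$family)
  fam <- pop$family[ord]
  if (length(fam) %% 2L != 0L || any(fam[c(TRUE, FALSE)] != fam[c(FALSE, TRUE)])) {
    stop("individuals must be grouped into full-sibling pairs")
  }
  cbind(ord[c(TRUE, FALSE)], ord[c(FALSE, TRUE)])
}
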