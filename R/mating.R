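#' Mating schemes
#'
#' Describes how mating pairs are formed: at random, or assortatively on one
#' trait (same-trait) or on two different traits (cross-trait), the latter
#' either sex-asymmetric (females scored on trait 1, males on trait 2) or
#' symmetric (the scored trait assigned at random within each pair).
#'
#' @param kind one of `"random"`, `"same_trait_am"`, `"cross_trait_am_asym"`,
#'   `"cross_trait_am_sym"`.
#' @param rho target correlation among mates of the relevant scores.
#' @param epsilon acceptance tolerance on the achieved correlation.
#' @param xi0 initial perturbation SD in score units; default half the SD of
#'   the scores (resolved at pairing time when `NULL`).
#' @param max_iter maximum perturbation-size updates per generation.
#' @param retries_per_iter perturbation draws per iteration; the matching with
#'   correlation closest to `rho` is kept.
#' @return an object of class `mating_scheme`.
#' @export
mating_scheme <- function(kind = c("random", "same_trait_am",
                                   "cross_trait_am_asym", "cross_trait_am_sym"),
                          rho = 0, epsilon = 0.005, xi0 = NULL,
                          max_iter = 50L, retries_per_iter = 5L) {
  kind <- match.arg(kind)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (!is.null(xi0) && xi0 <= 0) stop("xi0 must be > 0")
  structure(list(kind = kind, rho = rho, epsilon = epsilon, xi0 = xi0,
                 max_iter = as.integer(max_iter),
                 retries_per_iter = as.integer(retries_per_iter)),
            class = "mating_scheme")
}

#' Random monogamous pairing
#'
#' Matches every female with exactly one male, uniformly at random.
#'
#' @param pop a [phased_pop] with equal numbers of females and males.
#' @param seed optional integer seed.
#' @return a data frame with columns `mother`, `father` (row indices into
#'   `pop`) and attribute `achieved_rho = NA`.
#' @export
pair_random <- function(pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- which(pop$sex == "F"); m <- which(pop$sex == "M")
  if (length(f) != length(m)) stop("unequal numbers of females and males")
  out <- data.frame(mother = f, father = sample(m))
  attr(out, "achieved_rho") <- NA_real_
  out
}

#' Assortative monogamous pairing by iterative rank perturbation
#'
#' Forms mating pairs whose scores (e.g. polygenic scores or phenotypes) are
#' correlated at a target value `rho`. Females and males are first matched by
#' score rank; if the resulting correlation rho_0 already falls below
#' `rho + epsilon` the rank matching is accepted. Otherwise scores are
#' perturbed with independent Gaussian noise of SD xi_k, mates matched on the
#' perturbed ranks, and the correlation of the *true* scores evaluated; the
#' perturbation SD is then doubled (correlation still too high), halved
#' (overshot low twice), or bisected (the last two correlations straddle the
#' target), and each iteration the perturbation is redrawn
#' `retries_per_iter` times, keeping the matching closest to the target.
#' The first matching within `epsilon` of `rho` is returned; if the tolerance
#' is never met, the best matching found is returned with its achieved
#' correlation as a diagnostic (never silently).
#'
#' @param pop a [phased_pop] with equal sex counts.
#' @param female_scores,male_scores numeric vectors aligned with `pop`
#'   individuals (entries for the other sex are ignored).
#' @param scheme a [mating_scheme] giving `rho`, `epsilon`, `xi0`,
#'   `max_iter`, `retries_per_iter`.
#' @param seed optional integer seed.
#' @return a data frame with columns `mother`, `father`, and attributes
#'   `achieved_rho`, `iterations`, `converged`, `degenerate`.
#' @export
pair_assortative <- function(pop, female_scores, male_scores, scheme,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- which(pop$sex == "F"); m <- which(pop$sex == "M")
  if (length(f) != length(m)) stop("unequal numbers of females and males")
  sf <- female_scores[f]; sm <- male_scores[m]
  if (any(!is.finite(sf)) || any(!is.finite(sm))) stop("scores must be finite")
  rho <- scheme$rho; eps <- scheme$epsilon

  finish <- function(of, om, achieved, iters, converged, degenerate = FALSE) {
    out <- data.frame(mother = f[of], father = m[om])
    attr(out, "achieved_rho") <- achieved
    attr(out, "iterations") <- iters
    attr(out, "converged") <- converged
    attr(out, "degenerate") <- degenerate
    out
  }

  if (sd(sf) == 0 || sd(sm) == 0) {
    # degenerate scores: any matching has undefined correlation
    return(finish(sample(length(f)), sample(length(m)), 0, 0L, TRUE, TRUE))
  }

  of0 <- order(sf, decreasing = TRUE); om0 <- order(sm, decreasing = TRUE)
  rho0 <- cor(sf[of0], sm[om0])
  if (rho0 < rho + eps) return(finish(of0, om0, rho0, 0L, TRUE))

  xi0 <- if (is.null(scheme$xi0)) 0.5 * sd(sf) else scheme$xi0
  try_xi <- function(xi) {
    best <- NULL
    for (r in seq_len(scheme$retries_per_iter)) {
      of <- order(sf + rnorm(length(sf), 0, xi), decreasing = TRUE)
      om <- order(sm + rnorm(length(sm), 0, xi), decreasing = TRUE)
      rk <- cor(sf[of], sm[om])
      if (is.null(best) || abs(rk - rho) < abs(best$rho - rho)) {
        best <- list(of = of, om = om, rho = rk)
      }
    }
    best
  }

  xi_prev <- xi0
  cand <- try_xi(xi_prev)
  rho_prev <- cand$rho
  best <- cand
  if (abs(cand$rho - rho) < eps) {
    return(finish(cand$of, cand$om, cand$rho, 1L, TRUE))
  }
  xi_cur <- 2 * xi0
  for (k in seq_len(scheme$max_iter)) {
    cand <- try_xi(xi_cur)
    if (abs(cand$rho - rho) < abs(best$rho - rho)) best <- cand
    if (abs(cand$rho - rho) < eps) {
      return(finish(cand$of, cand$om, cand$rho, k + 1L, TRUE))
    }
    if (rho_prev > rho && cand$rho > rho) {
      xi_next <- 2 * xi_cur
    } else if (rho_prev < rho && cand$rho < rho) {
      xi_next <- xi_cur / 2
    } else {
      xi_next <- (xi_prev + xi_cur) / 2
    }
    xi_prev <- xi_cur; rho_prev <- cand$rho; xi_cur <- xi_next
  }
  warning(sprintf("assortative pairing did not reach |rho - %.3g| < %.3g; best achieved %.4f",
                  rho, eps, best$rho))
  finish(best$of, best$om, best$rho, scheme$max_iter + 1L, FALSE)
}
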