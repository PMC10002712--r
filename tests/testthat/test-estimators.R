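# GWAS estimators, decompositions, summaries, PGS regressions.

test_that("population GWAS recovers identity regressions and its decomposition is exact", {
  pop <- random_pop(n = 100, L = 6, seed = 1)
  g <- genotypes(pop)

  res <- population_gwas(pop, g[, 3])
  expect_equal(res$estimate[3], 1, tolerance = 1e-12)

  # additive phenotype with noise: decomposition equals OLS slope exactly
  arch <- trait_architecture(c(2L, 5L), alpha_d = c(0.7, 1.3))
  set.seed(2)
  eps <- rnorm(100, 0, 0.5)
  y <- compute_phenotypes(pop, arch) + eps
  slopes <- population_gwas(pop, y)$estimate
  pred <- decompose_estimate("population", pop, arch, eps = eps)
  expect_equal(pred, slopes, tolerance = 1e-10)

  # environmental confound: slope shift at a null locus is Cov(g, eps) / V
  arch0 <- trait_architecture(2L, 0)
  eps_conf <- g[, 1] * 0.5
  y2 <- compute_phenotypes(pop, arch0) + eps_conf
  s2 <- population_gwas(pop, y2)$estimate[1]
  v1 <- mean(g[, 1]^2) - mean(g[, 1])^2
  expect_equal(s2, pop_cov(g[, 1], eps_conf) / v1, tolerance = 1e-10)

  # monomorphic locus flagged NA
  popm <- pop_from_haps(cbind(1L, c(1L, 0L)), cbind(1L, c(0L, 1L)))
  expect_true(is.na(population_gwas(popm, c(1, 2))$estimate[1]))
})

test_that("sibling GWAS regresses differences on differences", {
  pop <- random_pop(n = 40, L = 3, seed = 3)
  pop$family <- rep(1:20, each = 2)
  g <- genotypes(pop)
  res <- sibling_gwas(pop, g[, 2])
  expect_equal(res$estimate[2], 1, tolerance = 1e-12)
  # locus with no segregating pair flagged NA
  popc <- pop_from_haps(cbind(1L, c(1L, 0L)), cbind(1L, c(0L, 1L)))
  popc$family <- c(1L, 1L)
  expect_true(is.na(sibling_gwas(popc, c(0, 1))$estimate[1]))
})

test_that("unlinked confounders shift population but not sibling estimates", {
  # locus 1 (chrom a, non-causal) in perfect coupling LD with locus 2
  # (chrom b, causal) among the parents
  map <- recomb_map(c("a", "b"), c(0, 0), chrom_length = c(0, 0))
  reps <- 40L
  set.seed(4)
  est <- replicate(reps, {
    hap <- matrix(rbinom(400, 1, 0.5), 200, 2)[, c(1, 1)]  # identical alleles
    hap2 <- matrix(rbinom(400, 1, 0.5), 200, 2)[, c(1, 1)]
    parents <- pop_from_haps(hap, hap2)
    off <- meiosis_offspring(pair_random(parents), parents, map)
    y <- compute_phenotypes(off, trait_architecture(2L, 1))
    c(pop = population_gwas(off, y)$estimate[1],
      sib = sibling_gwas(off, y)$estimate[1])
  })
  expect_lt(abs(mean(est["sib", ])), 0.06)   # family design immune (c = 1/2)
  expect_gt(mean(est["pop", ]), 0.4)         # population design confounded
})

test_that("linked confounders shift sibling estimates per the parental-LD prediction", {
  cc <- 0.05
  d <- -log(1 - 2 * cc) / 2
  map <- recomb_map(c("a", "a"), c(0, d))
  arch <- trait_architecture(2L, 1)
  reps <- 60L
  set.seed(5)
  out <- replicate(reps, {
    hap <- matrix(rbinom(300, 1, 0.5), 150, 2)[, c(1, 1)]   # coupling cis-LD
    hap2 <- matrix(rbinom(300, 1, 0.5), 150, 2)
    parents <- pop_from_haps(hap, hap2)
    off <- meiosis_offspring(pair_random(parents), parents, map)
    y <- compute_phenotypes(off, arch)
    c(sib = sibling_gwas(off, y)$estimate[1],
      pred = decompose_estimate("sibling", off, arch, map = map,
                                parents = parents, local_window = 1e-6)[1])
  })
  expect_gt(mean(out["pred", ]), 0.2)  # a real confound, not a null check
  expect_lt(abs(mean(out["sib", ]) - mean(out["pred", ])), 0.05)
})

test_that("parent-offspring regression separates transmitted and untransmitted", {
  parents <- random_pop(n = 60, L = 3, seed = 6)
  map <- recomb_map(c("a", "b", "c"), c(0, 0, 0))
  off <- meiosis_offspring(pair_random(parents, seed = 1), parents, map, seed = 2)
  gT <- genotypes(off)
  res <- parent_offspring_gwas(off, parents, gT[, 2])
  expect_equal(res$estimate_T[2], 1, tolerance = 1e-10)
  expect_equal(res$estimate_U[2], 0, tolerance = 1e-10)
  expect_equal(res$estimate[2], 1, tolerance = 1e-10)

  # null: untransmitted slope centred on zero; with an indirect effect it
  # centres on alpha_i
  arch_null <- trait_architecture(2L, 1, v_e = 0.5)
  arch_ind <- trait_architecture(2L, 1, alpha_i = 0.6, v_e = 0.5)
  set.seed(7)
  us <- replicate(50, {
    parents <- init_population(300, 0.5, n_loci = 3)
    off <- meiosis_offspring(pair_random(parents), parents, map)
    y0 <- compute_phenotypes(off, arch_null)
    y1 <- compute_phenotypes(off, arch_ind, parents = parents)
    r0 <- parent_offspring_gwas(off, parents, y0)
    r1 <- parent_offspring_gwas(off, parents, y1)
    c(null = r0$estimate_U[2], ind = r1$estimate_U[2], indT = r1$estimate_T[2])
  })
  expect_equal(mean(us["null", ]), 0, tolerance = 0.03)
  expect_equal(mean(us["ind", ]), 0.6, tolerance = 0.05)
  expect_equal(mean(us["indT", ]), 1 + 0.6, tolerance = 0.05)

  off$mother <- NULL
  expect_error(parent_offspring_gwas(off, parents, rnorm(n_ind(off))), "parent")
})

test_that("summary metrics compute the declared means", {
  pop <- init_population(500, 0.5, n_loci = 4, seed = 8)
  res <- population_gwas(pop, rnorm(500))
  res$estimate <- c(2, 2, 2, 2)
  res$p_hat <- rep(0.5, 4)
  s <- summarize_gwas(res, truth = 2)
  expect_equal(s$mean_deviation, 0)
  expect_equal(s$het_weighted_mean_square, 2 * 0.25 * 4)   # = 2

  # independent null GWASs have ~zero cross product
  set.seed(9)
  r1 <- population_gwas(pop, rnorm(500))
  r2 <- population_gwas(pop, rnorm(500))
  s2 <- summarize_gwas(r1, second = r2)
  expect_lt(abs(s2$het_weighted_cross_product), 0.01)
  expect_error(summarize_gwas(r1, loci = 99), "misaligned")
})

test_that("polygenic scores sum weighted dosages", {
  pop <- random_pop(n = 50, L = 4, seed = 10)
  w1 <- pgs_weights(2L, 1)
  expect_equal(build_pgs(pop, w1), as.numeric(genotypes(pop)[, 2]))
  expect_equal(build_pgs(pop, pgs_weights(1:4, rep(0, 4))), rep(0, 50))

  founders <- init_population(4000, 0.5, n_loci = 10, seed = 11)
  w <- pgs_weights(1:10, seq(0.1, 1, by = 0.1))
  v <- var(build_pgs(founders, w))
  expect_equal(v, sum(2 * 0.5 * 0.5 * w$weights^2), tolerance = 0.05)
  expect_error(build_pgs(pop, pgs_weights(9L, 1)), "loci")
})

test_that("sibling PGS regression matches the intra-chromosomal LD prediction", {
  # 5 generations of cross-trait AM build signed LD; mating then randomises,
  # so the offspring cohort's confound is the parents' cis-trans excess
  L <- 40L
  map <- onechrom_map(L)
  ar <- interleaved_two_trait_arch(L, 1)
  w <- pgs_weights(ar$arch1$loci, rep(1, length(ar$arch1$loci)))
  beta_full <- rep(0, L); beta_full[ar$arch2$loci] <- 1
  cmat <- recomb_matrix(map)
  reps <- 40L
  sims <- vapply(seq_len(reps), function(r) {
    cfg <- scenario_config(n = 600, map = map, arch1 = ar$arch1,
                           arch2 = ar$arch2,
                           phases = list(
                             list(generations = 5L,
                                  mating = mating_scheme("cross_trait_am_asym",
                                                         rho = 0.5)),
                             list(generations = 1L,
                                  mating = mating_scheme("random"))),
                           record = character(0), seed = 100 + r)
    run <- run_scenario(cfg)
    lp <- ld_matrices(run$parents)
    dd <- (lp$cis - lp$trans)[ar$arch1$loci, ar$arch2$loci]
    cm <- cmat[ar$arch1$loci, ar$arch2$loci]
    pred <- 2 * sum((1 - 2 * cm) * dd)
    y2 <- compute_phenotypes(run$pop, ar$arch2)
    obs <- sibling_pgs_regression(run$pop, w, y2)$covariance
    c(obs, pred)
  }, numeric(2))
  obs <- mean(sims[1, ]); pred <- mean(sims[2, ])
  expect_gt(abs(pred), 0.05)            # cross-trait AM leaves a real signal
  expect_lt(abs(obs - pred), 0.3 * abs(pred))

  # null: weights unrelated to trait-2 loci under random mating
  set.seed(12)
  nullcov <- replicate(20, {
    pop <- init_population(400, 0.5, n_loci = L)
    off <- meiosis_offspring(pair_random(pop), pop, map)
    y2 <- compute_phenotypes(off, ar$arch2)
    sibling_pgs_regression(off, w, y2)$covariance
  })
  expect_lt(abs(mean(nullcov)), 3 * sd(nullcov) / sqrt(20))
})

test_that("maternal and paternal sibling-difference transmissions are uncorrelated", {
  pop <- init_population(2000, 0.5, n_loci = 8, seed = 13)
  off <- meiosis_offspring(pair_random(pop, seed = 1), pop, onechrom_map(8), seed = 2)
  fam <- matrix(order(off$family), ncol = 2, byrow = TRUE)
  dm <- off$mat[fam[, 1], ] - off$mat[fam[, 2], ]
  dp <- off$pat[fam[, 1], ] - off$pat[fam[, 2], ]
  r <- cor(as.vector(dm), as.vector(dp))
  expect_lt(abs(r), 0.03)
})

test_that("all designs recover true effects in the unconfounded null", {
  L <- 10L
  map <- recomb_map(rep(c("a", "b"), each = 5), rep(seq(0, 1, length.out = 5), 2))
  alpha <- 0.4
  arch <- trait_architecture(seq_len(L), alpha, v_e = 1)
  set.seed(14)
  ests <- replicate(8, {
    pop <- init_population(2000, 0.5, n_loci = L)
    off <- meiosis_offspring(pair_random(pop), pop, map)
    y <- compute_phenotypes(off, arch)
    c(pop = mean(population_gwas(off, y)$estimate),
      sib = mean(sibling_gwas(off, y)$estimate),
      tu = mean(parent_offspring_gwas(off, pop, y)$estimate))
  })
  expect_lt(abs(mean(ests["pop", ]) - alpha), 0.03)
  expect_lt(abs(mean(ests["sib", ]) - alpha), 0.03)
  expect_lt(abs(mean(ests["tu", ]) - alpha), 0.03)
})

test_that("cross-chromosome PGS correlations recover the mate correlation under AM", {
  expect_error(
    cross_chrom_pgs_mate_correlation(random_pop(20, 4, 1),
                                     pgs_weights(1:4, rep(1, 4)),
                                     onechrom_map(4)),
    ">= 2 chromosomes")

  # same-trait AM at h2 = 1, near equilibrium: estimate ~ rho
  L <- 60L
  map <- place_loci(recomb_map(paste0("c", 1:6), rep(0, 6),
                               chrom_length = rep(1, 6)), L)
  arch <- trait_architecture(seq_len(L), 1)
  w <- pgs_weights(seq_len(L), rep(1, L))
  set.seed(15)
  est <- replicate(8, {
    cfg <- scenario_config(n = 1000, map = map, arch1 = arch,
                           phases = list(list(generations = 12L,
                                              mating = mating_scheme("same_trait_am",
                                                                     rho = 0.3))),
                           record = character(0),
                           seed = sample.int(1e6, 1))
    run <- run_scenario(cfg)
    cross_chrom_pgs_mate_correlation(run$pop, w, map, h2 = 1)$rho_hat
  })
  expect_lt(abs(mean(est) - 0.3), 0.05)
})
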