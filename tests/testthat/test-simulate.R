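# Phenotypes, mating, meiosis, selection, admixture, scenarios.

test_that("phenotypes follow the additive model with indirect effects", {
  pop <- pop_from_haps(rbind(c(0L, 0L)), rbind(c(0L, 0L)))
  arch <- trait_architecture(1:2, alpha_d = 1, y_star = 3)
  expect_equal(compute_phenotypes(pop, arch), 3)

  het <- pop_from_haps(rbind(c(1L, 0L)), rbind(c(0L, 0L)))
  expect_equal(compute_phenotypes(het, trait_architecture(1L, 1, y_star = 3)), 4)

  # indirect effect: both parents heterozygous adds (1 + 1) * 0.5 = 1
  parents <- pop_from_haps(rbind(c(1L, 0L), c(1L, 0L)), rbind(c(0L, 0L), c(0L, 0L)))
  off <- phased_pop(rbind(c(0L, 0L)), rbind(c(0L, 0L)), sex = "F",
                    mother = 1L, father = 2L)
  archi <- trait_architecture(1L, alpha_d = 0, alpha_i = 0.5)
  expect_equal(compute_phenotypes(off, archi, parents = parents), 1)
  expect_error(compute_phenotypes(off, archi), "parental")
})

test_that("sibling indirect-effect phenotypes solve the coupled system", {
  pop <- pop_from_haps(rbind(c(1L), c(0L)), rbind(c(0L), c(0L)))
  pop$family <- c(1L, 1L)
  arch <- trait_architecture(1L, 1)
  y <- sibling_phenotypes_with_indirect(pop, arch, beta = 0.5)
  expect_equal(y, c(1 / 0.75, 0.5 / 0.75))

  y0 <- sibling_phenotypes_with_indirect(pop, arch, beta = 0)
  expect_equal(y0, c(1, 0))
  expect_error(sibling_phenotypes_with_indirect(pop, arch, beta = 1), "beta")

  # noise-only variance: Var(Y) = (1 + beta^2) V_E / (1 - beta^2)^2
  n <- 20000L
  popn <- phased_pop(matrix(0L, n, 1), matrix(0L, n, 1),
                     sex = rep(c("F", "M"), n / 2),
                     family = rep(seq_len(n / 2), each = 2L))
  archn <- trait_architecture(1L, 0, v_e = 1)
  yn <- sibling_phenotypes_with_indirect(popn, archn, beta = 0.5, seed = 4)
  expect_equal(var(yn), (1 + 0.25) * 1 / (1 - 0.25)^2, tolerance = 0.05)
})

test_that("random pairing is a uniform perfect matching", {
  pop <- init_population(8, 0.5, n_loci = 2, seed = 1)
  pr <- pair_random(pop, seed = 2)
  expect_equal(nrow(pr), 4L)
  expect_setequal(c(pr$mother, pr$father), 1:8)

  # 2 females x 2 males: both matchings near 50/50 over many seeds
  p4 <- init_population(4, 0.5, n_loci = 1, seed = 1)
  hits <- vapply(1:400, function(s) pair_random(p4, seed = s)$father[1], 0)
  tab <- table(factor(hits, levels = c(3, 4)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("assortative pairing reaches the target correlation", {
  pop <- init_population(2000, 0.5, n_loci = 50, seed = 3)
  score <- as.vector(genotypes(pop) %*% rep(1, 50))
  # acceptance branch: maximal rank matching cannot exceed rho = 1
  pr1 <- pair_assortative(pop, score, score, mating_scheme("same_trait_am", rho = 1),
                          seed = 1)
  expect_equal(attr(pr1, "iterations"), 0L)

  pr <- pair_assortative(pop, score, score,
                         mating_scheme("same_trait_am", rho = 0.2, epsilon = 0.01),
                         seed = 2)
  expect_lt(abs(attr(pr, "achieved_rho") - 0.2), 0.01)
  expect_setequal(c(pr$mother, pr$father), 1:2000)

  # degenerate: identical scores
  prd <- pair_assortative(pop, rep(1, 2000), rep(1, 2000),
                          mating_scheme("same_trait_am", rho = 0.2), seed = 3)
  expect_true(attr(prd, "degenerate"))
  expect_equal(attr(prd, "achieved_rho"), 0)

  expect_error(pair_assortative(pop, rep(NA_real_, 2000), score,
                                mating_scheme("same_trait_am", rho = 0.2)),
               "finite")
})

test_that("meiosis transmits intact haplotypes on a zero-length chromosome", {
  map <- recomb_map(chrom = c("a", "a", "a"), pos = c(0, 0, 0))
  pop <- phased_pop(rbind(c(1L, 1L, 1L), c(0L, 0L, 0L)),
                    rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)),
                    sex = c("F", "M"))
  off <- meiosis_offspring(data.frame(mother = 1L, father = 2L), pop, map,
                           seed = 1)
  # each transmitted haplotype is one of the parent's two, intact
  for (r in 1:2) {
    expect_true(all(off$mat[r, ] == 1L) || all(off$mat[r, ] == 0L))
    expect_true(all(off$pat[r, ] == 1L) || all(off$pat[r, ] == 0L))
  }
  expect_equal(off$family, c(1L, 1L))
  expect_equal(off$mother, c(1L, 1L))
})

test_that("recombinant fraction matches the Haldane closed form at 1 Morgan", {
  map <- recomb_map(chrom = c("a", "a"), pos = c(0, 1))
  n <- 4000L
  pop <- phased_pop(matrix(1L, n, 2), matrix(0L, n, 2),
                    sex = rep(c("F", "M"), each = n / 2))
  pairs <- data.frame(mother = 1:(n / 2), father = (n / 2 + 1):n)
  set.seed(7)
  off <- meiosis_offspring(pairs, pop, map)
  rec <- mean(off$mat[, 1] != off$mat[, 2])
  expect_lt(abs(rec - (1 - exp(-2)) / 2), 0.03)
  expect_true(all(off$mat %in% 0:1) && all(off$pat %in% 0:1))
})

test_that("allele frequencies are conserved in expectation under neutrality", {
  map <- onechrom_map(10)
  set.seed(11)
  freqs <- replicate(40, {
    pop <- init_population(200, 0.5, n_loci = 10)
    off <- meiosis_offspring(pair_random(pop), pop, map)
    mean(allele_freqs(off))
  })
  expect_lt(abs(mean(freqs) - 0.5), 3 * sd(freqs) / sqrt(40))
})

test_that("stabilizing selection reweights parents as Gaussian fitness dictates", {
  pop <- init_population(2000, 0.5, n_loci = 2, seed = 5)
  set.seed(5)
  y <- rnorm(2000)
  # V_S -> infinity: neutral limit, sampling is uniform
  pool <- select_parents_stabilizing(pop, y, selection_scheme("stabilizing", v_s = 1e12),
                                     seed = 1)
  expect_equal(n_ind(pool), 2000L)
  expect_equal(sum(pool$sex == "F"), 1000L)
  expect_equal(mean(y[attr(pool, "index")]), mean(y), tolerance = 0.1)

  # two females at the optimum and one sigma away: odds exp(sigma^2 / (2 V_S))
  v_s <- 2
  p2 <- phased_pop(matrix(0L, 4, 1), matrix(0L, 4, 1), sex = c("F", "F", "M", "M"))
  y2 <- c(0, 1, 0, 0)
  pool2 <- select_parents_stabilizing(p2, y2, selection_scheme("stabilizing", v_s = v_s),
                                      n_out = 40000, seed = 9)
  fem <- attr(pool2, "index")[seq_len(20000)]
  odds <- sum(fem == 1L) / sum(fem == 2L)
  expect_lt(abs(odds - exp(1 / (2 * v_s))), 0.07)

  # post-selection phenotypic variance ~ V_P V_S / (V_P + V_S) for Gaussian Y
  pool3 <- select_parents_stabilizing(pop, y, selection_scheme("stabilizing", v_s = 1),
                                      n_out = 20000, seed = 13)
  ysel <- y[attr(pool3, "index")]
  expect_lt(abs(var(ysel) - var(y) * 1 / (var(y) + 1)), 0.04)

  expect_error(select_parents_stabilizing(pop, y, selection_scheme("none")),
               "stabilizing")
})

test_that("admixture mixes founders in the right proportions", {
  fx <- make_fixture("two_pop", seed = 1)
  adm <- admix_populations(fx$pop1, fx$pop2, A = 0.7, n_out = 400, seed = 2)
  expect_lt(abs(mean(allele_freqs(adm)) - (0.7 * 0.9 + 0.3 * 0.1)), 0.05)
  bad <- init_population(10, 0.5, n_loci = 5)
  expect_error(admix_populations(fx$pop1, bad, 0.5), "loci")
})

test_that("scenarios run phases, record diagnostics, and honour null models", {
  map <- onechrom_map(4)
  arch <- trait_architecture(1:4, alpha_d = 0, y_star = 2, v_e = 0)
  cfg <- scenario_config(n = 40, map = map, arch1 = arch,
                         phases = list(list(generations = 0L)), seed = 1)
  run0 <- run_scenario(cfg)
  expect_equal(run0$pop$generation, 0L)   # founders only
  expect_null(run0$history)

  cfg2 <- scenario_config(n = 40, map = map, arch1 = arch,
                          phases = list(list(generations = 3L,
                                             mating = mating_scheme("random"))),
                          record = character(0), seed = 2)
  run2 <- run_scenario(cfg2)
  expect_equal(run2$pop$generation, 3L)
  expect_equal(compute_phenotypes(run2$pop, arch), rep(2, 40))

  # same-trait AM: achieved mate correlation tracks the target each generation
  archh <- trait_architecture(1:30, 1)
  cfg3 <- scenario_config(n = 600, map = onechrom_map(30), arch1 = archh,
                          phases = list(list(generations = 3L,
                                             mating = mating_scheme("same_trait_am",
                                                                    rho = 0.3))),
                          record = character(0), seed = 3)
  run3 <- run_scenario(cfg3)
  expect_true(all(abs(run3$mate_rho$achieved_rho - 0.3) < 0.02))
})
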