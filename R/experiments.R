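# Desk-scale reproductions of the study's simulation experiments, plus
# deterministic fixture generators for tests.

#' Default parameters of the bundled experiments
#'
#' @param experiment experiment id.
#' @return named list of parameters.
#' @export
experiment_defaults <- function(experiment = c("fig2_cross_trait_am",
                                               "fig3_same_trait_am",
                                               "fig4_architectures",
                                               "fig5_structure_admixture",
                                               "fig6_stabilizing_selection")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    fig2_cross_trait_am = list(n = 2000L, loci_per_trait = 100L, rho = 0.2,
                               am_generations = 20L, random_generations = 0L,
                               alpha = 1, founder_freq = 0.5,
                               record_generations = NULL),
    fig3_same_trait_am = list(n = 2000L, n_loci = 100L, rho = 0.2,
                              am_generations = 20L, random_generations = 10L,
                              alpha = 1, founder_freq = 0.5),
    fig4_architectures = list(n = 2000L, L1 = 10L, L2 = 100L, rho = 0.2,
                              am_generations = 20L, v_g = 1,
                              founder_freq = 0.5),
    fig5_structure_admixture = list(n = 1000L, n_loci = 50L, n_chrom = 5L,
                                    f_st = 0.2, generations_after = 10L,
                                    alpha = 1, ancestral_freq = 0.5,
                                    admix_A = 0.5),
    fig6_stabilizing_selection = list(n = 1000L, n_loci = 100L,
                                      n_chrom = 10L, vs_over_vp = 30,
                                      h2 = 0.8, rho = 0, generations = 25L,
                                      v_g = 1))
}

replicate_seed <- function(seed, r) (as.integer(seed) + 1009L * as.integer(r)) %% .Machine$integer.max

interleaved_two_trait_arch <- function(n_loci_total, alpha, v_e = 0) {
  odd <- seq(1L, n_loci_total, by = 2L)
  even <- seq(2L, n_loci_total, by = 2L)
  list(arch1 = trait_architecture(odd, alpha, v_e = v_e),
       arch2 = trait_architecture(even, alpha, v_e = v_e))
}

#' Run a bundled experiment
#'
#' Config-driven reproduction of each simulation experiment at desk scale.
#' Summaries are averaged over replicates; a fixed seed makes reruns
#' bit-identical. When `out_dir` is given, per-generation tables are written
#' tab-delimited together with a YAML metadata file echoing the
#' configuration and achieved mate correlations.
#'
#' @param experiment experiment id (see [experiment_defaults()]), or
#'   `"custom"` with a full [scenario_config] in `params$config`.
#' @param replicates number of replicate simulations to average.
#' @param seed integer seed; replicate r runs with `seed + 1009 r`.
#' @param params named list overriding [experiment_defaults()].
#' @param out_dir optional output directory.
#' @return a list with `history` (replicate-averaged per-generation
#'   summaries), experiment-specific `extra` results, and `params`.
#' @export
run_experiment <- function(experiment, replicates = 20L, seed = 1L,
                           params = list(), out_dir = NULL) {
  if (identical(experiment, "custom")) {
    if (is.null(params$config)) stop("custom experiment requires params$config")
    runs <- lapply(seq_len(replicates), function(r) {
      cfg <- params$config
      cfg$seed <- replicate_seed(seed, r)
      run_scenario(cfg)
    })
    out <- list(history = average_histories(lapply(runs, `[[`, "history")),
                extra = NULL, params = params)
    return(write_experiment(out, runs, experiment, seed, out_dir))
  }
  p <- utils::modifyList(experiment_defaults(experiment), params)
  out <- switch(experiment,
    fig2_cross_trait_am = exp_fig2(p, replicates, seed),
    fig3_same_trait_am = exp_fig3(p, replicates, seed),
    fig4_architectures = exp_fig4(p, replicates, seed),
    fig5_structure_admixture = exp_fig5(p, replicates, seed),
    fig6_stabilizing_selection = exp_fig6(p, replicates, seed),
    stop("unknown experiment id: ", experiment))
  out$params <- p
  write_experiment(out, NULL, experiment, seed, out_dir)
}

average_histories <- function(hists) {
  all <- do.call(rbind, hists)
  if (is.null(all)) return(NULL)
  agg <- aggregate(cbind(mean_estimate, het_weighted_mean_square) ~
                     generation + design + class, data = all, FUN = mean)
  agg[order(agg$generation, agg$design, agg$class), ]
}

write_experiment <- function(out, runs, experiment, seed, out_dir) {
  if (is.null(out_dir)) return(invisible(out))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$history)) {
    utils::write.table(out$history,
                       file.path(out_dir, paste0(experiment, "_history.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(experiment = experiment, seed = seed,
               params = out$params[!vapply(out$params, is.object, TRUE)],
               extra = out$extra)
  yaml::write_yaml(meta, file.path(out_dir, paste0(experiment, "_metadata.yaml")))
  invisible(out)
}

# cross-trait sex-asymmetric AM on a 1-Morgan chromosome; GWAS on trait 2
exp_fig2 <- function(p, replicates, seed) {
  L <- 2L * p$loci_per_trait
  map <- onechrom_map(L)
  ar <- interleaved_two_trait_arch(L, p$alpha)
  phases <- list(list(generations = p$am_generations,
                      mating = mating_scheme("cross_trait_am_asym", rho = p$rho)))
  if (p$random_generations > 0L) {
    phases <- c(phases, list(list(generations = p$random_generations,
                                  mating = mating_scheme("random"))))
  }
  runs <- lapply(seq_len(replicates), function(r) {
    cfg <- scenario_config(n = p$n, map = map, arch1 = ar$arch1,
                           arch2 = ar$arch2, founder_freq = p$founder_freq,
                           phases = phases, gwas_trait = 2L,
                           record_generations = p$record_generations,
                           seed = replicate_seed(seed, r))
    run_scenario(cfg)
  })
  hist <- average_histories(lapply(runs, `[[`, "history"))
  final_gen <- max(hist$generation)
  pick <- function(design, cl, gen) {
    hist$mean_estimate[hist$design == design & hist$class == cl &
                         hist$generation == gen]
  }
  list(history = hist,
       extra = list(
         spurious_population_final_am =
           pick("population", "causal1", p$am_generations) / p$alpha,
         spurious_sibling_final_am =
           pick("sibling", "causal1", p$am_generations) / p$alpha,
         causal_population_final_am =
           pick("population", "causal2", p$am_generations) / p$alpha,
         mean_achieved_rho = mean(vapply(runs, function(x)
           mean(x$mate_rho$achieved_rho[seq_len(p$am_generations)]), 0)),
         final_generation = final_gen))
}

# same-trait AM: inflation of estimates and het-weighted mean square
exp_fig3 <- function(p, replicates, seed) {
  map <- onechrom_map(p$n_loci)
  arch <- trait_architecture(seq_len(p$n_loci), p$alpha)
  phases <- list(list(generations = p$am_generations,
                      mating = mating_scheme("same_trait_am", rho = p$rho)))
  if (p$random_generations > 0L) {
    phases <- c(phases, list(list(generations = p$random_generations,
                                  mating = mating_scheme("random"))))
  }
  runs <- lapply(seq_len(replicates), function(r) {
    cfg <- scenario_config(n = p$n, map = map, arch1 = arch,
                           founder_freq = p$founder_freq, phases = phases,
                           gwas_trait = 1L, seed = replicate_seed(seed, r))
    run_scenario(cfg)
  })
  hist <- average_histories(lapply(runs, `[[`, "history"))
  list(history = hist,
       extra = list(
         inflation_population_final_am =
           hist$mean_estimate[hist$design == "population" &
                              hist$generation == p$am_generations] / p$alpha - 1))
}

# unequal architectures: spurious magnitudes at trait-1 loci in a trait-2 GWAS
exp_fig4 <- function(p, replicates, seed) {
  L <- p$L1 + p$L2
  map <- onechrom_map(L)
  loci1 <- seq_len(p$L1) * (L %/% p$L1) - (L %/% p$L1 - 1L)  # spread trait-1 loci
  loci2 <- setdiff(seq_len(L), loci1)[seq_len(p$L2)]
  a1 <- sqrt(p$v_g / (2 * 0.5 * 0.5 * p$L1))
  a2 <- sqrt(p$v_g / (2 * 0.5 * 0.5 * p$L2))
  arch1 <- trait_architecture(loci1, a1)
  arch2 <- trait_architecture(loci2, a2)
  one <- function(r, am) {
    phases <- list(list(generations = p$am_generations,
                        mating = if (am)
                          mating_scheme("cross_trait_am_asym", rho = p$rho)
                        else mating_scheme("random")))
    cfg <- scenario_config(n = p$n, map = map, arch1 = arch1, arch2 = arch2,
                           founder_freq = p$founder_freq, phases = phases,
                           gwas_trait = 2L, record = character(0),
                           seed = replicate_seed(seed, r))
    run <- run_scenario(cfg)
    y2 <- compute_phenotypes(run$pop, arch2)
    est <- population_gwas(run$pop, y2)$estimate
    c(spur = mean(abs(est[loci1]), na.rm = TRUE),
      causal = mean(abs(est[loci2]), na.rm = TRUE))
  }
  am <- rowMeans(sapply(seq_len(replicates), one, am = TRUE))
  rm_ <- rowMeans(sapply(seq_len(replicates), one, am = FALSE))
  list(history = NULL,
       extra = list(spurious_mag_am = am[["spur"]],
                    causal_mag_am = am[["causal"]],
                    spurious_mag_random = rm_[["spur"]],
                    causal_mag_random = rm_[["causal"]],
                    alpha1 = a1, alpha2 = a2))
}

# two diverged populations admix; het-weighted mean squares by design
exp_fig5 <- function(p, replicates, seed) {
  map <- place_loci(recomb_map(chrom = paste0("chr", seq_len(p$n_chrom)),
                               pos = rep(0, p$n_chrom),
                               chrom_length = rep(1, p$n_chrom)),
                    p$n_loci)
  arch <- trait_architecture(seq_len(p$n_loci), p$alpha)
  one <- function(r) {
    set.seed(replicate_seed(seed, r))
    fr <- balding_nichols_freqs(rep(p$ancestral_freq, p$n_loci), p$f_st, 2L)
    pop1 <- init_population(p$n, fr[1L, ], n_loci = p$n_loci)
    pop2 <- init_population(p$n, fr[2L, ], n_loci = p$n_loci)
    adm <- admix_populations(pop1, pop2, p$admix_A, n_out = p$n)
    pop <- adm
    hist <- list()
    y0 <- compute_phenotypes(adm, arch)
    s0 <- summarize_gwas(population_gwas(adm, y0), loci = arch$loci)
    hist[["g0"]] <- data.frame(
      generation = 0L, design = "population", class = "causal1",
      mean_estimate = s0$mean_deviation,
      het_weighted_mean_square = s0$het_weighted_mean_square)
    for (g in seq_len(p$generations_after)) {
      pairs <- pair_random(pop)
      pop <- meiosis_offspring(pairs, pop, map)
      y <- compute_phenotypes(pop, arch)
      sp <- summarize_gwas(population_gwas(pop, y), loci = arch$loci)
      ss <- summarize_gwas(sibling_gwas(pop, y), loci = arch$loci)
      hist[[length(hist) + 1L]] <- data.frame(
        generation = g,
        design = c("population", "sibling"), class = "causal1",
        mean_estimate = c(sp$mean_deviation, ss$mean_deviation),
        het_weighted_mean_square = c(sp$het_weighted_mean_square,
                                     ss$het_weighted_mean_square))
    }
    do.call(rbind, hist)
  }
  hist <- average_histories(lapply(seq_len(replicates), one))
  hwms <- function(design, gen) {
    hist$het_weighted_mean_square[hist$design == design &
                                    hist$generation == gen]
  }
  gmax <- max(hist$generation)
  list(history = hist,
       extra = list(pop_over_family_gen1 = hwms("population", 1L) / hwms("sibling", 1L),
                    pop_over_family_final = hwms("population", gmax) / hwms("sibling", gmax)))
}

# stabilizing selection (optionally joint with same-trait AM): attenuation of
# estimates and the cross-chromosome PGS view of the mate correlation
exp_fig6 <- function(p, replicates, seed) {
  map <- place_loci(recomb_map(chrom = paste0("chr", seq_len(p$n_chrom)),
                               pos = rep(0, p$n_chrom),
                               chrom_length = rep(1, p$n_chrom)),
                    p$n_loci)
  alpha <- sqrt(p$v_g / (2 * 0.5 * 0.5 * p$n_loci))
  v_e <- p$v_g * (1 - p$h2) / p$h2
  arch <- trait_architecture(seq_len(p$n_loci), alpha, v_e = v_e)
  one <- function(r) {
    set.seed(replicate_seed(seed, r))
    pop <- init_population(p$n, 0.5, n_loci = p$n_loci)
    vs <- p$vs_over_vp * (p$v_g + v_e)  # width from founder phenotypic variance
    sel <- selection_scheme("stabilizing", optimum = 2 * sum(arch$alpha_d) * 0.5,
                            v_s = vs)
    for (g in seq_len(p$generations)) {
      y <- compute_phenotypes(pop, arch)
      pool <- select_parents_stabilizing(pop, y, sel)
      if (p$rho > 0) {
        yp <- compute_phenotypes(pool, arch)
        pairs <- pair_assortative(pool, yp, yp,
                                  mating_scheme("same_trait_am", rho = p$rho))
      } else {
        pairs <- pair_random(pool)
      }
      pop <- meiosis_offspring(pairs, pool, map)
    }
    y <- compute_phenotypes(pop, arch)
    est <- population_gwas(pop, y)$estimate
    esib <- sibling_gwas(pop, y)$estimate
    pfr <- allele_freqs(pop)
    vg_hat <- genic_variance(arch, pfr)
    g <- genotypes(pop)
    va_hat <- {
      gv <- as.vector(g %*% full_effect_vector(arch, p$n_loci, "alpha_d"))
      mean(gv^2) - mean(gv)^2
    }
    w <- pgs_weights(arch$loci, arch$alpha_d, provenance = "true_effects")
    xc <- cross_chrom_pgs_mate_correlation(pop, w, map, h2 = p$h2)
    c(atten_pop = 1 - mean(est / alpha, na.rm = TRUE),
      atten_sib = 1 - mean(esib / alpha, na.rm = TRUE),
      disequilibrium = va_hat - vg_hat,
      rho_hat_xchrom = xc$rho_hat)
  }
  res <- rowMeans(sapply(seq_len(replicates), one))
  list(history = NULL, extra = as.list(res))
}

#' Deterministic test fixtures
#'
#' Builds tiny phased populations with exactly known LD, pedigrees, or
#' genotype-by-environment composition, for unit tests and worked examples.
#' All fixtures are generated in code; `path` optionally writes a
#' tab-delimited copy.
#'
#' @param kind one of `"two_locus"` (two individuals whose haplotypes give
#'   D_cis = 0.25, D_trans = -0.25 exactly), `"small_pedigree"` (4 mating
#'   pairs and 8 offspring with recorded transmissions), `"two_pop"` (two
#'   populations with fixed divergent allele frequencies 0.9 / 0.1), or
#'   `"gxe_table"` (families with declared parental genotypes and
#'   environment labels).
#' @param seed integer seed.
#' @param path optional file path for a tab-delimited copy.
#' @return the fixture object (a [phased_pop] or a list).
#' @export
make_fixture <- function(kind = c("two_locus", "small_pedigree", "two_pop",
                                  "gxe_table"),
                         seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- switch(kind,
    two_locus = phased_pop(mat = rbind(c(1L, 1L), c(0L, 0L)),
                           pat = rbind(c(0L, 0L), c(1L, 1L)),
                           sex = c("F", "M")),
    small_pedigree = {
      parents <- init_population(8L, 0.5, n_loci = 4L)
      map <- recomb_map(rep("chr1", 4L), c(0, 0.1, 0.2, 0.3))
      pairs <- pair_random(parents)
      list(parents = parents, pairs = pairs,
           offspring = meiosis_offspring(pairs, parents, map), map = map)
    },
    two_pop = list(pop1 = init_population(200L, 0.9, n_loci = 2L),
                   pop2 = init_population(200L, 0.1, n_loci = 2L)),
    gxe_table = {
      # 2 environments x parental genotype classes at one locus
      par_geno <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L), c(1L, 1L))
      env <- c("amplifying", "neutral", "neutral", "amplifying")
      fams <- lapply(seq_len(nrow(par_geno)), function(f) {
        mm <- par_geno[f, 1L]; ff <- par_geno[f, 2L]
        list(mother = c(mat = mm %/% 1L %% 2L, pat = as.integer(mm == 2L)),
             father = c(mat = ff %/% 1L %% 2L, pat = as.integer(ff == 2L)),
             env = env[f])
      })
      list(families = fams, env = env,
           dev = c(amplifying = 0.5, neutral = 0))
    })
  if (!is.null(path) && inherits(out, "phased_pop")) {
    df <- data.frame(id = seq_len(n_ind(out)), sex = out$sex)
    df <- cbind(df, setNames(as.data.frame(out$mat),
                             paste0("mat_", seq_len(n_loci(out)))),
                setNames(as.data.frame(out$pat),
                         paste0("pat_", seq_len(n_loci(out)))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
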