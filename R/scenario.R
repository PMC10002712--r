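# Config-driven forward-time scenarios: burn-in / assortative-mating /
# selection phases with per-generation GWAS and LD summaries.

#' Build a scenario configuration
#'
#' @param n population size (even).
#' @param map a [recomb_map] with placed loci.
#' @param arch1 [trait_architecture] of trait 1.
#' @param arch2 optional architecture of trait 2 (cross-trait scenarios).
#' @param founder_freq founder focal-allele frequency (scalar or per-locus).
#' @param phases list of phases, each a list with `generations` and optional
#'   `mating` (a [mating_scheme]) and `selection` (a [selection_scheme]).
#' @param gwas_trait which trait's phenotype the recorded GWASs regress
#'   (1 or 2).
#' @param selection_trait which trait stabilizing selection acts on.
#' @param record which summaries to record each generation: any of
#'   `"gwas"`, `"sib_gwas"`, `"ld"`.
#' @param record_generations generations at which to record (default `NULL`,
#'   all); recording only the generations needed speeds long runs.
#' @param seed integer seed for the whole run (one global RNG stream).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n, map, arch1, arch2 = NULL, founder_freq = 0.5,
                            phases = list(list(generations = 1L,
                                               mating = mating_scheme("random"))),
                            gwas_trait = 1L, selection_trait = 1L,
                            record = c("gwas", "sib_gwas"),
                            record_generations = NULL, seed = 1L) {
  if (n %% 2L != 0L) stop("n must be even")
  gens <- vapply(phases, function(ph) as.integer(ph$generations), 1L)
  if (any(is.na(gens) | gens < 0L)) stop("invalid phase schedule: non-negative generation counts required")
  structure(list(n = as.integer(n), map = map, arch1 = arch1, arch2 = arch2,
                 founder_freq = founder_freq, phases = phases,
                 gwas_trait = as.integer(gwas_trait),
                 selection_trait = as.integer(selection_trait),
                 record = record,
                 record_generations = record_generations,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' Maps a structured-text description (population size, generations, phases,
#' mating, selection, architecture, seed) onto a [scenario_config]. The map
#' is given either as `map: onechrom` with `n_loci`, `map: human` with
#' `n_loci`, or `map_file:` pointing to a 3-column genetic map.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  map <- if (!is.null(y$map_file)) {
    place_loci(load_genetic_map(y$map_file), y$n_loci)
  } else if (identical(y$map, "human")) {
    place_loci(human_autosome_map(), y$n_loci)
  } else {
    onechrom_map(y$n_loci)
  }
  mk_arch <- function(a) trait_architecture(
    loci = as.integer(a$loci), alpha_d = a$alpha_d,
    alpha_i = if (is.null(a$alpha_i)) 0 else a$alpha_i,
    y_star = if (is.null(a$y_star)) 0 else a$y_star,
    v_e = if (is.null(a$v_e)) 0 else a$v_e)
  mk_phase <- function(ph) {
    out <- list(generations = ph$generations)
    if (!is.null(ph$mating)) {
      out$mating <- mating_scheme(kind = ph$mating,
                                  rho = if (is.null(ph$rho)) 0 else ph$rho)
    }
    if (!is.null(ph$selection)) {
      out$selection <- selection_scheme(kind = ph$selection,
                                        v_s = if (is.null(ph$v_s)) Inf else ph$v_s)
    }
    out
  }
  scenario_config(n = y$n, map = map, arch1 = mk_arch(y$arch1),
                  arch2 = if (is.null(y$arch2)) NULL else mk_arch(y$arch2),
                  founder_freq = if (is.null(y$founder_freq)) 0.5 else y$founder_freq,
                  phases = lapply(y$phases, mk_phase),
                  gwas_trait = if (is.null(y$gwas_trait)) 1L else y$gwas_trait,
                  selection_trait = if (is.null(y$selection_trait)) 1L else y$selection_trait,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

scenario_scores <- function(pop, cfg, y1, y2, kind) {
  n <- n_ind(pop)
  switch(kind,
         same_trait_am = list(f = y1, m = y1),
         cross_trait_am_asym = list(f = y1, m = y2),
         cross_trait_am_sym = {
           pick1 <- runif(n) < 0.5
           s <- ifelse(pick1, y1, y2)
           list(f = s, m = s)
         },
         stop("unknown mating kind: ", kind))
}

#' Run a forward-time scenario
#'
#' Executes the phase schedule of a [scenario_config]: each generation the
#' current cohort's phenotypes are computed (fresh environmental noise),
#' stabilizing selection (if active) samples the mating pool, mates are
#' paired (randomly or assortatively on the phase's scheme), and each pair
#' produces two offspring by Poisson-crossover meiosis. Per-generation GWAS
#' and LD summaries are recorded on each offspring cohort.
#'
#' @param config a [scenario_config].
#' @return a list with `history` (per-generation summary data frame),
#'   `mate_rho` (achieved mate-score correlations), `pop` (final cohort),
#'   `parents` (its parental mating pool), and `config`.
#' @export
run_scenario <- function(config) {
  set.seed(config$seed)
  L <- nrow(config$map)
  pop <- init_population(config$n, config$founder_freq, n_loci = L)
  parents <- NULL
  history <- list()
  rho_log <- list()
  gen <- 0L

  classes <- list(causal1 = config$arch1$loci)
  if (!is.null(config$arch2)) classes$causal2 <- config$arch2$loci

  record_gen <- function(pop, parents, gen) {
    arch_y <- if (config$gwas_trait == 2L) config$arch2 else config$arch1
    y <- compute_phenotypes(pop, arch_y)
    rows <- list()
    designs <- list()
    if ("gwas" %in% config$record) designs$population <- population_gwas(pop, y)
    if ("sib_gwas" %in% config$record) designs$sibling <- sibling_gwas(pop, y)
    for (dn in names(designs)) {
      res <- designs[[dn]]
      for (cl in names(classes)) {
        s <- summarize_gwas(res, loci = classes[[cl]])
        rows[[length(rows) + 1L]] <- data.frame(
          generation = gen, design = dn, class = cl,
          mean_estimate = s$mean_deviation,  # truth 0; deviation = estimate
          het_weighted_mean_square = s$het_weighted_mean_square)
      }
    }
    if ("ld" %in% config$record && !is.null(config$arch2)) {
      idx <- cbind(rep(config$arch1$loci, length.out = 200L),
                   rep(config$arch2$loci, length.out = 200L))
      dc <- mean(vapply(seq_len(nrow(idx)), function(k)
        cis_ld(pop, idx[k, 1L], idx[k, 2L]), 0))
      dt <- mean(vapply(seq_len(nrow(idx)), function(k)
        trans_ld(pop, idx[k, 1L], idx[k, 2L]), 0))
      rows[[length(rows) + 1L]] <- data.frame(
        generation = gen, design = "ld_cross_trait", class = "mean",
        mean_estimate = dc, het_weighted_mean_square = dt)
    }
    do.call(rbind, rows)
  }

  for (ph in config$phases) {
    for (g in seq_len(ph$generations)) {
      y1 <- compute_phenotypes(pop, config$arch1)
      y2 <- if (!is.null(config$arch2)) compute_phenotypes(pop, config$arch2) else NULL
      pool <- pop
      if (!is.null(ph$selection) && ph$selection$kind == "stabilizing") {
        ysel <- if (config$selection_trait == 2L) y2 else y1
        pool <- select_parents_stabilizing(pop, ysel, ph$selection)
        y1 <- compute_phenotypes(pool, config$arch1)
        y2 <- if (!is.null(config$arch2)) compute_phenotypes(pool, config$arch2) else NULL
      }
      scheme <- if (is.null(ph$mating)) mating_scheme("random") else ph$mating
      if (scheme$kind == "random") {
        pairs <- pair_random(pool)
      } else {
        sc <- scenario_scores(pool, config, y1, y2, scheme$kind)
        pairs <- pair_assortative(pool, sc$f, sc$m, scheme)
      }
      offspring <- meiosis_offspring(pairs, pool, config$map)
      gen <- gen + 1L
      offspring$generation <- gen
      rho_log[[gen]] <- data.frame(generation = gen,
                                   achieved_rho = attr(pairs, "achieved_rho"))
      if (length(config$record) &&
          (is.null(config$record_generations) ||
           gen %in% config$record_generations)) {
        history[[length(history) + 1L]] <- record_gen(offspring, pool, gen)
      }
      parents <- pool
      pop <- offspring
    }
  }
  list(history = if (length(history)) do.call(rbind, history) else NULL,
       mate_rho = if (length(rho_log)) do.call(rbind, rho_log) else NULL,
       pop = pop, parents = parents, config = config)
}
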