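#' Found a population from a haplotype panel
#'
#' Samples `2 * N` haplotypes with replacement from the panel and pairs them
#' into N diploid individuals (generation 1 of the experiment).
#'
#' @param panel a [haplotype_panel()].
#' @param N diploid population size.
#' @param seed optional integer seed.
#' @return a `population`: list with haplotype matrices `A`, `B`
#'   (N x n_loci), the map, and `generation = 1`.
#' @export
found_population <- function(panel, N, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), N >= 2)
  maybe_set_seed(seed)
  idx <- sample.int(nrow(panel$alleles), 2L * N, replace = TRUE)
  structure(
    list(A = panel$alleles[idx[seq_len(N)], , drop = FALSE],
         B = panel$alleles[idx[N + seq_len(N)], , drop = FALSE],
         map = panel$map, generation = 1L),
    class = "population"
  )
}

#' Genotypic values of a population
#'
#' Additive-with-dominance locus contributions: genotypes 0 / 1 / 2 copies
#' contribute 0 / `2 * d * effect` / `2 * effect`, so d = 0.5 gives the
#' additive 0 / effect / 2 * effect scale. For a `module_architecture` the
#' model is purely additive and a matrix of per-trait values is returned.
#'
#' @param pop a [found_population()] object.
#' @param arch a [trait_architecture()] or `module_architecture`.
#' @return numeric vector of length N (single trait) or N x n_traits matrix
#'   (module).
#' @export
genotypic_value <- function(pop, arch) {
  stopifnot(inherits(pop, "population"))
  n_loci <- ncol(pop$A)
  if (any(arch$loci < 1) || any(arch$loci > n_loci)) {
    stop("architecture locus index out of range for this population")
  }
  G <- pop$A[, arch$loci, drop = FALSE] + pop$B[, arch$loci, drop = FALSE]
  if (inherits(arch, "module_architecture")) {
    return(G %*% arch$effect_matrix)
  }
  if (all(arch$dominance == 0.5)) {
    return(drop(G %*% arch$effect))
  }
  het <- G == 1L
  hom <- G == 2L
  drop(het %*% (2 * arch$dominance * arch$effect) + hom %*% (2 * arch$effect))
}

#' Phenotypes from genotypic values
#'
#' Adds independent zero-mean Gaussian environmental noise of variance
#' `sigmaE2` to each genotypic value. For module values (a matrix), `sigmaE2`
#' is recycled per trait.
#'
#' @param values vector or matrix of genotypic values.
#' @param sigmaE2 environmental variance(s) (>= 0).
#' @param seed optional integer seed.
#' @return phenotypes with the same shape as `values`.
#' @export
phenotype <- function(values, sigmaE2, seed = NULL) {
  if (any(sigmaE2 < 0)) stop("'sigmaE2' must be non-negative")
  maybe_set_seed(seed)
  if (is.matrix(values)) {
    sigmaE2 <- rep_len(sigmaE2, ncol(values))
    noise <- matrix(rnorm(length(values)), nrow(values), ncol(values))
    values + sweep(noise, 2, sqrt(sigmaE2), "*")
  } else {
    values + rnorm(length(values), 0, sqrt(sigmaE2))
  }
}

# Fitness-proportional parent sampling via the inverse CDF; scaling all
# fitness values by a positive constant cannot change the outcome (for
# power-of-two constants, bit-identically so).
sample_parents <- function(w, n) {
  if (is.null(w)) return(sample.int(n, 2L * n, replace = TRUE))
  if (any(w < 0) || anyNA(w)) stop("fitness values must be non-negative")
  cw <- cumsum(as.numeric(w))
  tot <- cw[length(cw)]
  if (tot <= 0) stop("all-zero fitness: population extinct under this regime")
  findInterval(runif(2L * n) * tot, cw) + 1L
}

#' Advance a population by one generation
#'
#' Draws each offspring's two parents independently with probability
#' proportional to fitness (monoecious random mating, selfing allowed),
#' forms each gamete by Poisson-crossover recombination of the parent's two
#' haplotypes along the genetic map, and returns N offspring. No new
#' mutations are introduced.
#'
#' @param pop a `population`.
#' @param fitness per-individual non-negative fitness, or `NULL` for
#'   neutrality (all parents equally likely).
#' @param seed optional integer seed.
#' @param layout precomputed internal map layout (for repeated calls).
#' @return the next-generation `population`.
#' @export
next_generation <- function(pop, fitness = NULL, seed = NULL, layout = NULL) {
  stopifnot(inherits(pop, "population"))
  maybe_set_seed(seed)
  N <- nrow(pop$A)
  if (is.null(layout)) layout <- map_layout(pop$map)
  parents <- sample_parents(fitness, N)
  gam <- make_gametes_cpp(pop$A, pop$B, parents, layout$chrom_start,
                          layout$pos)
  pop$A <- gam[seq_len(N), , drop = FALSE]
  pop$B <- gam[N + seq_len(N), , drop = FALSE]
  pop$generation <- pop$generation + 1L
  pop
}

#' Simulate trait evolution forward in time
#'
#' Founds N individuals from the panel, captures the ancestral phenotypic
#' mean and genetic variance at generation 1, anchors the fitness regime to
#' them, and iterates Wright-Fisher reproduction with selection on the
#' phenotype. The phenotypic mean and variance of all N individuals are
#' recorded at the scheduled generations; the variance-change statistic
#' `F = sigma_x^2 / sigma_1^2` uses the generation-1 phenotypic variance of
#' the founded population as baseline.
#'
#' If the architecture carries no preset environmental variance, it is
#' assigned at founding as `V_anc * (1 - h2) / h2` from the realized
#' ancestral genetic variance, so the trait's heritability at generation 1
#' equals `h2` exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param arch a [trait_architecture()] or `module_architecture`.
#' @param regime a [fitness_regime()].
#' @param N diploid population size (e.g. 300 or 1200).
#' @param generations final generation (>= 1); generation 1 is the founded
#'   population, so `generations - 1` rounds of reproduction are simulated.
#' @param record generations at which to record the trajectory (default:
#'   every generation).
#' @param keep_phenotypes generations whose full phenotype vectors (or
#'   matrices, for modules) should be returned for later resampling.
#' @param return_population return the final population as an attribute.
#' @param seed optional integer seed.
#' @return a `trait_trajectory`: data frame with columns `generation`,
#'   `trait_id`, `pheno_mean`, `pheno_var`, `geno_var`, `F`, with metadata in
#'   `attr(, "meta")` and kept phenotypes in `attr(, "phenotypes")`.
#' @examples
#' p <- generate_founder_haplotypes(189, 50, seed = 1)
#' a <- trait_architecture(p, M = 5, h2 = 0.6, seed = 2)
#' tr <- evolve(p, a, fitness_regime("single_trait", a = 1, b = 3.6),
#'              N = 100, generations = 20, seed = 3)
#' tail(tr)
#' @export
evolve <- function(panel, arch, regime = fitness_regime("neutral"),
                   N = 300, generations = 100,
                   record = seq_len(generations),
                   keep_phenotypes = integer(0),
                   return_population = FALSE, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(regime, "fitness_regime"),
            generations >= 1)
  is_module <- inherits(arch, "module_architecture")
  if (!is_module) stopifnot(inherits(arch, "trait_architecture"))
  if (regime$kind == "module" && !is_module) {
    stop("module fitness regime requires a module_architecture")
  }
  maybe_set_seed(seed)
  record <- sort(unique(as.integer(record)))
  if (!1L %in% record) record <- c(1L, record)
  if (any(record < 1L | record > generations)) {
    stop("'record' generations must lie in [1, generations]")
  }
  keep_phenotypes <- sort(unique(as.integer(keep_phenotypes)))

  # Only the causal loci influence the trait, and each trait evolves in its
  # own run, so the simulated population is restricted to the architecture's
  # loci (their map positions, hence linkage, are preserved).
  if (length(arch$loci) < ncol(panel$alleles)) {
    panel <- subset_panel(panel, arch$loci)
    arch$loci <- seq_along(arch$loci)
  }
  layout <- map_layout(panel$map)

  pop <- found_population(panel, N)
  values <- genotypic_value(pop, arch)
  if (is_module) {
    mean_anc <- colMeans(values)
    V_anc <- col_vars(values)
  } else {
    mean_anc <- mean(values)
    V_anc <- var(values)
  }
  sigmaE2 <- arch$sigmaE2
  if (is.null(sigmaE2)) {
    sigmaE2 <- assign_environmental_variance(pmax(V_anc, .Machine$double.eps),
                                             arch$h2)
  }
  regime <- finalize_regime(regime, mean_anc, V_anc)
  selective <- regime$kind != "neutral"

  n_traits <- if (is_module) arch$n_traits else 1L
  recs <- vector("list", length(record))
  phenos <- list()
  base_var <- NULL
  ri <- 1L

  for (t in seq_len(generations)) {
    need_values <- selective || t %in% record || t %in% keep_phenotypes
    if (t > 1L && need_values) values <- genotypic_value(pop, arch)
    if (need_values) {
      z <- phenotype(values, sigmaE2)
      if (t %in% keep_phenotypes) phenos[[as.character(t)]] <- z
      if (t %in% record) {
        if (is_module) {
          pv <- col_vars(z)
          recs[[ri]] <- data.frame(
            generation = t, trait_id = seq_len(n_traits),
            pheno_mean = colMeans(z), pheno_var = pv,
            geno_var = col_vars(values)
          )
        } else {
          pv <- var(z)
          recs[[ri]] <- data.frame(
            generation = t, trait_id = 1L, pheno_mean = mean(z),
            pheno_var = pv, geno_var = var(values)
          )
        }
        if (t == 1L) base_var <- pv
        ri <- ri + 1L
      }
    }
    if (t < generations) {
      w <- if (!selective) NULL
           else if (regime$kind == "module") module_fitness(z, regime)
           else gaussian_fitness(z, regime)
      pop <- next_generation(pop, w, layout = layout)
    }
  }

  traj <- do.call(rbind, recs)
  traj$F <- traj$pheno_var / base_var[traj$trait_id]
  rownames(traj) <- NULL
  class(traj) <- c("trait_trajectory", "data.frame")
  attr(traj, "meta") <- list(
    N = N, generations = generations, kind = regime$kind,
    a = regime$a, b = regime$b, mean_anc = mean_anc, V_anc = V_anc,
    sigmaE2 = sigmaE2, h2 = arch$h2,
    M = if (is_module) length(arch$loci) else arch$M,
    shape = if (is_module) NA_real_ else arch$shape,
    z0 = regime$z0, width = regime$width, seed = seed
  )
  attr(traj, "phenotypes") <- phenos
  if (return_population) attr(traj, "population") <- pop
  traj
}

#' Simulate an ensemble of independently evolving traits
#'
#' Runs [evolve()] once per trait, each with a freshly drawn architecture
#' (its own loci, effect sizes and heritability) over the same founder
#' panel, mirroring a transcriptome of independently controlled expression
#' traits. Heritabilities are drawn per trait from `h2_sampler`.
#'
#' @param panel a [haplotype_panel()].
#' @param n_traits number of independent traits to simulate.
#' @param M,shape,rho_freq_effect,dominance passed to [trait_architecture()].
#' @param regime a [fitness_regime()].
#' @param N,generations,record,keep_phenotypes passed to [evolve()].
#' @param h2_sampler function(n) returning heritabilities (default
#'   [sample_heritability()]).
#' @param seed optional integer master seed; per-trait sub-seeds are drawn
#'   from it.
#' @return list of `trait_trajectory` objects.
#' @export
simulate_trait_ensemble <- function(panel, n_traits, M = 5, shape = 2.5,
                                    rho_freq_effect = -0.7, dominance = 0.5,
                                    regime = fitness_regime("neutral"),
                                    N = 300, generations = 100,
                                    record = c(1L, generations),
                                    keep_phenotypes = integer(0),
                                    h2_sampler = sample_heritability,
                                    seed = NULL) {
  maybe_set_seed(seed)
  seeds <- draw_seeds(n_traits)
  h2s <- h2_sampler(n_traits)
  lapply(seq_len(n_traits), function(i) {
    set.seed(seeds[i])
    arch <- trait_architecture(panel, M = M, shape = shape,
                               rho_freq_effect = rho_freq_effect,
                               h2 = h2s[i], dominance = dominance)
    evolve(panel, arch, regime, N = N, generations = generations,
           record = record, keep_phenotypes = keep_phenotypes)
  })
}
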