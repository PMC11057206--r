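#' Neutral Wright-Fisher burn-in
#'
#' Evolves a diploid population of `pop_size` individuals neutrally for
#' `generations` generations with recurrent biallelic mutation (allele state
#' flips at `mutation_rate` per locus per gamete per generation) and
#' Poisson-crossover recombination along `map`. Used to build an ancestral
#' population at mutation-drift-recombination balance for the modular
#' scenario; the reference configuration (N = 10,000, 20,000 generations,
#' 5,000 loci at r = 0.001) is accepted, while the package defaults are
#' scaled down for desk-scale runtimes.
#'
#' @param pop_size diploid population size (>= 2).
#' @param n_loci number of loci.
#' @param mutation_rate per-locus, per-gamete flip probability.
#' @param map optional `genetic_map`; defaults to weak linkage
#'   (`per_interval`, r = 0.001).
#' @param generations number of generations (>= 0).
#' @param init `"monomorphic"` (all ancestral) or `"random"` (each locus
#'   initialized at a uniform random frequency).
#' @param seed optional integer seed.
#' @return a [haplotype_panel()] of `2 * pop_size` haplotypes; sample rows
#'   from it (e.g. 300 individuals = 600 haplotypes) to seed an experiment.
#' @export
neutral_burnin <- function(pop_size = 1000, n_loci = 5000,
                           mutation_rate = 1e-5, map = NULL,
                           generations = 10 * pop_size,
                           init = c("monomorphic", "random"),
                           seed = NULL) {
  stopifnot(pop_size >= 2, n_loci >= 1, generations >= 0,
            mutation_rate >= 0, mutation_rate <= 1)
  init <- match.arg(init)
  maybe_set_seed(seed)
  if (is.null(map)) {
    map <- generate_genetic_map(n_loci, "per_interval", rate = 0.001)
  }
  stopifnot(nrow(map) == n_loci)
  layout <- map_layout(map)
  N <- as.integer(pop_size)
  make_mat <- function() {
    if (init == "monomorphic") {
      matrix(0L, N, n_loci)
    } else {
      p <- runif(n_loci)
      matrix(rbinom(N * n_loci, 1L, rep(p, each = N)), N, n_loci)
    }
  }
  A <- make_mat(); B <- make_mat()
  ncell <- 2L * N * n_loci
  for (t in seq_len(generations)) {
    parents <- sample.int(N, 2L * N, replace = TRUE)
    gam <- make_gametes_cpp(A, B, parents, layout$chrom_start, layout$pos)
    nmut <- rbinom(1L, ncell, mutation_rate)
    if (nmut > 0) {
      at <- sample.int(ncell, nmut)
      gam[at] <- 1L - gam[at]
    }
    A <- gam[seq_len(N), , drop = FALSE]
    B <- gam[N + seq_len(N), , drop = FALSE]
  }
  haplotype_panel(rbind(A, B), map)
}
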