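#' Sample gamma-distributed effect sizes standardized to mean 1/M
#'
#' Effect sizes of the M loci contributing to a trait are drawn from a gamma
#' distribution with the given shape; the draws are rescaled so their sample
#' mean is exactly 1/M. Small shapes (0.5) give highly unequal effects, large
#' shapes (100) nearly equal ones (CV = 1/sqrt(shape)).
#'
#' @param M number of contributing loci (>= 1).
#' @param shape gamma shape parameter (> 0); study grid uses 0.5, 2.5, 100.
#' @param seed optional integer seed.
#' @return numeric vector of M positive effects with `mean(effect) == 1/M`.
#' @examples
#' e <- sample_effect_sizes(5, 2.5, seed = 1)
#' mean(e)  # exactly 0.2
#' @export
sample_effect_sizes <- function(M, shape, seed = NULL) {
  if (M < 1) stop("'M' must be at least 1")
  if (shape <= 0) stop("'shape' must be positive")
  maybe_set_seed(seed)
  x <- rgamma(M, shape = shape, rate = shape * M)
  x * (1 / M) / mean(x)
}

#' Impose a target frequency-effect rank correlation
#'
#' Reorders a vector of effect sizes against allele frequencies so that the
#' Spearman correlation between them approaches `rho` (default -0.7: rare
#' alleles tend to carry large effects). The effects themselves are only
#' permuted, so their marginal distribution is untouched. A Gaussian-copula
#' construction is used: effects are ranked against a latent variable that
#' correlates with the normal scores of the frequency ranks; the latent
#' correlation is 2*sin(pi*rho/6) so the achieved Spearman correlation
#' matches `rho` in expectation.
#'
#' @param freq per-locus allele frequencies (length M).
#' @param effect effect sizes (length M, typically positive magnitudes).
#' @param rho target Spearman correlation in \[-1, 1\].
#' @param seed optional integer seed.
#' @return a permutation of `effect`.
#' @export
impose_frequency_effect_correlation <- function(freq, effect, rho = -0.7,
                                                seed = NULL) {
  M <- length(freq)
  if (length(effect) != M) stop("'freq' and 'effect' must have equal length")
  if (abs(rho) > 1) stop("'rho' must be in [-1, 1]")
  maybe_set_seed(seed)
  if (M == 1) return(effect)
  if (rho == 1) return(sort(effect)[rank(freq, ties.method = "random")])
  if (rho == -1) return(sort(effect, decreasing = TRUE)[rank(freq, ties.method = "random")])
  rl <- 2 * sin(pi * rho / 6)
  u <- qnorm(rank(freq, ties.method = "random") / (M + 1))
  y <- rl * u + sqrt(1 - rl^2) * rnorm(M)
  sort(effect)[rank(y, ties.method = "first")]
}

#' Environmental variance from heritability
#'
#' Given the ancestral genetic variance of a trait and its narrow-sense
#' heritability, returns the environmental/technical variance
#' `sigmaE2 = V_anc * (1 - h2) / h2`, so that at generation 1 the realized
#' heritability of the simulated phenotype equals `h2`.
#'
#' @param V_anc ancestral genetic variance (>= 0).
#' @param h2 narrow-sense heritability in (0, 1\].
#' @return environmental variance (trait units squared).
#' @export
assign_environmental_variance <- function(V_anc, h2) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("'h2' must be in (0, 1]")
  if (any(V_anc < 0)) stop("'V_anc' must be non-negative")
  V_anc * (1 - h2) / h2
}

#' Sample expression-trait heritabilities
#'
#' Default heritability distribution for simulated expression traits:
#' Beta(3.2, 1.7), mean about 0.65. With this distribution the expected
#' neutral variance ratio after 100 generations at N = 300,
#' `1 - mean(h2) * (1 - (1 - 1/(2N))^100)`, is about 0.9. Supply your own
#' sampler (or an empirical table of heritabilities) to
#' [trait_architecture()] to override it.
#'
#' @param n number of draws.
#' @param shape1,shape2 Beta parameters.
#' @param seed optional integer seed.
#' @return numeric vector of heritabilities in (0, 1).
#' @export
sample_heritability <- function(n, shape1 = 3.2, shape2 = 1.7, seed = NULL) {
  maybe_set_seed(seed)
  rbeta(n, shape1, shape2)
}

#' Construct a single-trait genetic architecture
#'
#' Chooses `M` distinct segregating loci from a founder panel, samples gamma
#' effect-size magnitudes standardized to mean 1/M, imposes the target
#' frequency-effect correlation on the magnitudes, and optionally flips signs
#' with probability `sign_flip_prob` (default 0.5) so the trait has no
#' built-in direction. Dominance defaults to additive (d = 0.5).
#'
#' The environmental variance is not fixed here: it is derived from `h2` and
#' the realized ancestral genetic variance when the population is founded in
#' [evolve()] (or can be preset via `sigmaE2`).
#'
#' @param panel a [haplotype_panel()].
#' @param M number of contributing loci.
#' @param shape gamma shape for effect-size magnitudes.
#' @param rho_freq_effect target Spearman frequency-effect correlation.
#' @param h2 heritability; a single value, or `NULL` to draw one from
#'   [sample_heritability()].
#' @param dominance per-locus dominance coefficient(s) in \[0, 1\]
#'   (0.5 = additive).
#' @param sign_flip_prob probability of flipping each effect's sign.
#' @param sigmaE2 optional preset environmental variance (otherwise assigned
#'   at founding from `h2`).
#' @param seed optional integer seed.
#' @return a `trait_architecture`: list with `loci`, `effect`, `dominance`,
#'   `h2`, `sigmaE2`, `M`, `shape`, `rho_freq_effect`.
#' @export
trait_architecture <- function(panel, M, shape = 2.5, rho_freq_effect = -0.7,
                               h2 = NULL, dominance = 0.5,
                               sign_flip_prob = 0.5, sigmaE2 = NULL,
                               seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  maybe_set_seed(seed)
  seg <- which(!panel$monomorphic)
  if (length(seg) < M) stop("panel has fewer than M segregating loci")
  loci <- sort(sample(seg, M))
  eff <- sample_effect_sizes(M, shape)
  eff <- impose_frequency_effect_correlation(panel$freq[loci], eff,
                                             rho_freq_effect)
  if (sign_flip_prob > 0) {
    flip <- runif(M) < sign_flip_prob
    eff[flip] <- -eff[flip]
  }
  if (is.null(h2)) h2 <- sample_heritability(1)
  stopifnot(h2 > 0, h2 <= 1)
  dominance <- rep_len(dominance, M)
  stopifnot(all(dominance >= 0), all(dominance <= 1))
  structure(
    list(loci = loci, effect = eff, dominance = dominance, h2 = h2,
         sigmaE2 = sigmaE2, M = M, shape = shape,
         rho_freq_effect = rho_freq_effect),
    class = "trait_architecture"
  )
}

#' Construct a modular (multi-trait) genetic architecture
#'
#' For a module of `n_traits` coregulated expression traits, every causal
#' locus receives one effect per trait, drawn from a multivariate normal with
#' unit variances and constant pairwise correlation `rho` (0 / 0.1 / 0.5 /
#' 0.8 = random / weak / moderate / strong coregulation). Either all
#' segregating loci are causal (polygenic) or a fraction (e.g. 5%,
#' oligogenic).
#'
#' @param panel a [haplotype_panel()].
#' @param n_traits traits per module (default 20).
#' @param rho pairwise effect correlation in \[0, 1).
#' @param fraction_causal proportion of segregating loci with effects.
#' @param h2 per-trait heritabilities (recycled); `NULL` draws them from
#'   [sample_heritability()].
#' @param seed optional integer seed.
#' @return a `module_architecture`: list with `loci`, `effect_matrix`
#'   (loci x traits), `n_traits`, `rho`, `fraction_causal`, `h2`.
#' @export
build_module_architecture <- function(panel, n_traits = 20, rho = 0,
                                      fraction_causal = 1, h2 = NULL,
                                      seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (fraction_causal <= 0 || fraction_causal > 1) {
    stop("'fraction_causal' must be in (0, 1]")
  }
  maybe_set_seed(seed)
  seg <- which(!panel$monomorphic)
  n_causal <- max(1L, round(fraction_causal * length(seg)))
  loci <- sort(sample(seg, n_causal))
  sigma <- matrix(rho, n_traits, n_traits)
  diag(sigma) <- 1
  effect <- matrix(rnorm(n_causal * n_traits), n_causal, n_traits) %*%
    chol(sigma)
  if (is.null(h2)) h2 <- sample_heritability(n_traits)
  h2 <- rep_len(h2, n_traits)
  stopifnot(all(h2 > 0), all(h2 <= 1))
  structure(
    list(loci = loci, effect_matrix = effect, n_traits = n_traits,
         rho = rho, fraction_causal = fraction_causal, h2 = h2),
    class = "module_architecture"
  )
}

#' Read / write a trait architecture
#'
#' TSV with columns `locus_id`, `locus_index`, `effect`, `dominance`, plus
#' header comment lines carrying M, shape, correlation target and h2.
#'
#' @param arch a [trait_architecture()].
#' @param file output path.
#' @export
write_trait_architecture <- function(arch, file) {
  stopifnot(inherits(arch, "trait_architecture"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# M=%d shape=%g rho_freq_effect=%g h2=%.10g",
                     arch$M, arch$shape, arch$rho_freq_effect, arch$h2), con)
  df <- data.frame(locus_index = arch$loci, effect = arch$effect,
                   dominance = arch$dominance)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
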