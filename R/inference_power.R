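#' Single-trait variance F-test against the neutral expectation
#'
#' Tests whether a trait lost significantly more phenotypic variance than
#' expected under neutrality. The statistic `(sx_sq / s1_sq) / F_neutral` is
#' referred to the F distribution with (n - 1, n - 1) degrees of freedom,
#' one-sided lower tail; `F_neutral` is the mean neutral ensemble variance
#' ratio at the tested generation (about 0.9 at generation 100 for N = 300).
#'
#' @param s1_sq sample variance at generation 1 (vectorized).
#' @param sx_sq sample variance at the tested generation.
#' @param n number of individuals behind each variance estimate.
#' @param F_neutral expected neutral variance ratio (> 0).
#' @param alpha significance level.
#' @return data frame with `statistic`, `p_value`, `significant`.
#' @export
single_trait_variance_test <- function(s1_sq, sx_sq, n, F_neutral = 0.9,
                                       alpha = 0.05) {
  if (n < 2) stop("'n' must be at least 2")
  if (F_neutral <= 0) stop("'F_neutral' must be positive")
  if (any(s1_sq <= 0)) stop("ancestral sample variance must be positive")
  stat <- (sx_sq / s1_sq) / F_neutral
  p <- pf(stat, n - 1, n - 1)
  data.frame(statistic = stat, p_value = p, significant = p < alpha)
}

#' Group-level test of variance-change distributions
#'
#' Welch two-sample t-test comparing the F distributions of a group of
#' (putatively) selected traits against a group of neutral traits. Returns a
#' non-significant result (p = 1) when both groups are degenerate and
#' identical.
#'
#' @param F_selected,F_neutral vectors of per-trait variance ratios
#'   (length >= 2 each).
#' @param alpha significance level.
#' @return list with `p_value`, `significant`, `estimate` (group means).
#' @export
group_variance_test <- function(F_selected, F_neutral, alpha = 0.05) {
  if (length(F_selected) < 2 || length(F_neutral) < 2) {
    stop("both groups need at least 2 traits")
  }
  if (sd(F_selected) == 0 && sd(F_neutral) == 0) {
    return(list(p_value = 1, significant = FALSE,
                estimate = c(mean(F_selected), mean(F_neutral))))
  }
  tt <- t.test(F_selected, F_neutral)
  p <- tt$p.value
  if (is.na(p)) p <- 1
  list(p_value = p, significant = p < alpha,
       estimate = unname(tt$estimate))
}

# Pull kept phenotype vectors at two generations out of a trajectory
# ensemble into traits x N matrices.
ensemble_phenotypes <- function(ensemble, gens) {
  lapply(as.character(gens), function(g) {
    m <- t(vapply(ensemble, function(tr) {
      ph <- attr(tr, "phenotypes")[[g]]
      if (is.null(ph)) stop("phenotypes at generation ", g, " were not kept")
      as.numeric(ph)
    }, numeric(length(attr(ensemble[[1]], "phenotypes")[[g]]))))
    m
  })
}

#' Simulation-based power of the variance-change tests
#'
#' Estimates, by resampling, how often a significant difference in variance
#' change is detected. In `"group"` mode each iteration samples n individuals
#' per trait (independently at the two time points), computes per-trait
#' F-hats for the selected and neutral ensembles and applies
#' [group_variance_test()]; power is the fraction of iterations with
#' p < alpha. In `"single"` mode each selected trait is tested with
#' [single_trait_variance_test()] against `F_neutral` and power is the
#' fraction of (trait, iteration) tests that reject. When `n` equals the
#' population size the full census is used once (no resampling).
#'
#' @param selected,neutral trajectory ensembles from
#'   [simulate_trait_ensemble()] with phenotypes kept at `gens`.
#' @param gens the two generations to contrast, e.g. `c(1, 100)`.
#' @param n sample size per time point.
#' @param iterations resampling iterations (study default 100).
#' @param mode `"group"` or `"single"`.
#' @param F_neutral neutral expectation for `"single"` mode.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return a one-row data frame (a power result): `mode`, `n`, `generation`,
#'   `iterations`, `power`.
#' @export
estimate_power <- function(selected, neutral = NULL, gens = c(1, 100),
                           n = 20, iterations = 100,
                           mode = c("group", "single"),
                           F_neutral = 0.9, alpha = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(gens) == 2)
  maybe_set_seed(seed)
  sel <- ensemble_phenotypes(selected, gens)
  N <- ncol(sel[[1]])
  if (n > N) stop("'n' exceeds the phenotyped population size")
  census <- n == N
  if (census) iterations <- 1L

  subsample_F <- function(ph) {
    # ph: list of two traits x N matrices; returns per-trait F-hats
    if (census) {
      s1 <- row_vars(ph[[1]]); sx <- row_vars(ph[[2]])
    } else {
      k <- nrow(ph[[1]])
      i1 <- ph[[1]][cbind(rep(seq_len(k), each = n),
                          as.vector(replicate(k, sample.int(N, n))))]
      ix <- ph[[2]][cbind(rep(seq_len(k), each = n),
                          as.vector(replicate(k, sample.int(N, n))))]
      s1 <- col_vars(matrix(i1, nrow = n))
      sx <- col_vars(matrix(ix, nrow = n))
    }
    list(s1 = s1, sx = sx, F = sx / s1)
  }

  if (mode == "group") {
    if (is.null(neutral)) stop("'group' mode needs a neutral ensemble")
    neu <- ensemble_phenotypes(neutral, gens)
    hits <- vapply(seq_len(iterations), function(i) {
      Fs <- subsample_F(sel)$F
      Fn <- subsample_F(neu)$F
      group_variance_test(Fs, Fn, alpha)$significant
    }, logical(1))
    power <- mean(hits)
  } else {
    rates <- vapply(seq_len(iterations), function(i) {
      ss <- subsample_F(sel)
      mean(single_trait_variance_test(ss$s1, ss$sx, n, F_neutral,
                                      alpha)$significant)
    }, numeric(1))
    power <- mean(rates)
  }
  data.frame(mode = mode, n = n, generation = gens[2],
             iterations = iterations, power = power)
}

#' Power over a grid of scenarios
#'
#' Applies [estimate_power()] to a list of scenarios (each a list with
#' elements `selected`, `neutral` and any metadata columns such as `M`,
#' `shape`, `a`, `b`, `N`), crossed with the requested sample sizes.
#'
#' @param scenarios named list of scenario lists.
#' @param n sample sizes to evaluate.
#' @param gens two generations to contrast.
#' @param iterations resampling iterations.
#' @param mode,F_neutral,alpha passed to [estimate_power()].
#' @param seed optional integer seed.
#' @return data frame of power results, one row per scenario x sample size,
#'   with scenario metadata carried through.
#' @export
power_grid <- function(scenarios, n = 20, gens = c(1, 100), iterations = 100,
                       mode = "group", F_neutral = 0.9, alpha = 0.05,
                       seed = NULL) {
  maybe_set_seed(seed)
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    meta <- sc[setdiff(names(sc), c("selected", "neutral"))]
    for (ni in n) {
      pr <- estimate_power(sc$selected, sc$neutral, gens = gens, n = ni,
                           iterations = iterations, mode = mode,
                           F_neutral = F_neutral, alpha = alpha)
      pr$scenario <- nm
      for (f in names(meta)) pr[[f]] <- meta[[f]]
      rows[[length(rows) + 1L]] <- pr
    }
  }
  do.call(rbind, rows)
}

#' Lower bound on the number of contributing loci
#'
#' The largest number of loci M for which a significant difference between
#' selected traits and the neutral expectation is found across all simulated
#' parameter combinations. Observing no significant variance change then
#' excludes architectures with up to this many loci.
#'
#' @param results data frame with a column `M` and either a logical
#'   `significant` or a numeric `power` column (one row per parameter
#'   combination and M).
#' @param power_threshold power required to call a combination significant
#'   when only `power` is supplied.
#' @return the qualifying M (integer), or `NA` when no M qualifies.
#' @export
lower_bound_loci <- function(results, power_threshold = 0.8) {
  if (!nrow(results) || !"M" %in% names(results)) {
    stop("'results' must be a non-empty data frame with an 'M' column")
  }
  sig <- if ("significant" %in% names(results)) results$significant
         else if ("power" %in% names(results)) results$power >= power_threshold
         else stop("'results' needs a 'significant' or 'power' column")
  ok <- tapply(sig, results$M, all)
  qual <- as.integer(names(ok))[ok]
  if (!length(qual)) NA_integer_ else max(qual)
}

#' Permutation test for replicate correlation of variance changes
#'
#' Compares the correlation of per-gene variance-change F between two
#' evolution replicates for DE genes against a null distribution built by
#' repeatedly drawing the same number of random non-DE genes. A small p-value
#' indicates that variance changes of DE genes are more strongly correlated
#' across replicates than those of non-DE genes.
#'
#' @param F_rep1,F_rep2 per-gene F in replicate 1 and 2 (aligned).
#' @param de_label per-gene logical, TRUE for DE genes.
#' @param n_perm number of permutation draws (>= 100 to resolve p < 0.01).
#' @param method correlation type, `"pearson"` or `"spearman"`.
#' @param seed optional integer seed.
#' @return list with `r_de`, `r_nonde`, `p_value`, `null` (the permutation
#'   correlations).
#' @export
replicate_correlation_test <- function(F_rep1, F_rep2, de_label,
                                       n_perm = 1000,
                                       method = c("pearson", "spearman"),
                                       seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(F_rep1) == length(F_rep2),
            length(de_label) == length(F_rep1))
  if (!any(de_label) || all(de_label)) {
    stop("both DE and non-DE classes must be non-empty")
  }
  n_de <- sum(de_label)
  nonde <- which(!de_label)
  if (n_de > length(nonde)) {
    stop("more DE genes than non-DE genes; cannot match class sizes")
  }
  maybe_set_seed(seed)
  r_de <- cor(F_rep1[de_label], F_rep2[de_label], method = method)
  r_nonde <- cor(F_rep1[nonde], F_rep2[nonde], method = method)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(nonde, n_de)
    cor(F_rep1[idx], F_rep2[idx], method = method)
  }, numeric(1))
  # include the observed statistic in the null ensemble (the usual finite-
  # permutation correction) so the test stays valid under the null
  list(r_de = r_de, r_nonde = r_nonde,
       p_value = (1 + sum(null >= r_de)) / (n_perm + 1),
       null = null)
}
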