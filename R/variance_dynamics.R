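#' Variance-change statistic from a trajectory
#'
#' `F = sigma_x^2 / sigma_1^2`: the ratio of the phenotypic variance at
#' generation x to the ancestral (generation-1) phenotypic variance. F stays
#' near the neutral expectation for polygenic traits and drops sharply when
#' few loci control an adapting trait.
#'
#' @param traj a `trait_trajectory` from [evolve()].
#' @param x generation at which to evaluate F (must be recorded).
#' @param trait_id trait within a module trajectory (default 1).
#' @return a one-row data frame with `generation`, `trait_id`, `F`.
#' @export
variance_ratio <- function(traj, x, trait_id = 1L) {
  stopifnot(inherits(traj, "trait_trajectory"))
  i1 <- which(traj$generation == 1L & traj$trait_id == trait_id)
  ix <- which(traj$generation == x & traj$trait_id == trait_id)
  if (!length(i1) || !length(ix)) {
    stop("generations 1 and x must both be recorded for this trait")
  }
  s1 <- traj$pheno_var[i1]
  if (s1 == 0) stop("ancestral variance is zero; F undefined")
  data.frame(generation = x, trait_id = trait_id,
             F = traj$pheno_var[ix] / s1)
}

#' Sampling distribution of the variance ratio at finite sample size
#'
#' Emulates phenotyping only n of the N individuals: at each iteration, n
#' individuals are drawn without replacement, independently at each of the
#' two time points, and the ratio of unbiased sample variances
#' `F_hat = s2_tx / s2_t1` is computed. The study default is 100 iterations
#' of sampling 20 individuals.
#'
#' @param pheno_t1 phenotypes of the full population at the first time point.
#' @param pheno_tx phenotypes at the later time point.
#' @param n sample size (2 <= n <= population size).
#' @param iterations number of resampling iterations.
#' @param seed optional integer seed.
#' @return numeric vector of `iterations` F estimates.
#' @export
sample_variance_ratio <- function(pheno_t1, pheno_tx, n = 20,
                                  iterations = 100, seed = NULL) {
  if (n < 2) stop("'n' must be at least 2")
  if (n > length(pheno_t1) || n > length(pheno_tx)) {
    stop("'n' exceeds the population size")
  }
  maybe_set_seed(seed)
  vapply(seq_len(iterations), function(i) {
    var(pheno_tx[sample.int(length(pheno_tx), n)]) /
      var(pheno_t1[sample.int(length(pheno_t1), n)])
  }, numeric(1))
}

#' Mean F curve and 95% band over a trajectory ensemble
#'
#' Summarizes many independently simulated traits: for every recorded
#' generation, the mean F across traits and the 2.5%/97.5% quantiles.
#' Module trajectories contribute one curve per trait.
#'
#' @param ensemble list of `trait_trajectory` objects sharing one recording
#'   schedule.
#' @return data frame with `generation`, `mean_F`, `q2.5`, `q97.5`,
#'   `n_traits`.
#' @export
trajectory_band <- function(ensemble) {
  if (length(ensemble) < 2 && !(length(ensemble) == 1 &&
        length(unique(ensemble[[1]]$trait_id)) >= 2)) {
    stop("need at least 2 trait curves")
  }
  gens <- lapply(ensemble, function(tr) sort(unique(tr$generation)))
  if (length(unique(vapply(gens, paste, "", collapse = ","))) != 1) {
    stop("trajectories have ragged recording schedules")
  }
  Fm <- do.call(cbind, lapply(ensemble, function(tr) {
    sp <- split(tr$F, tr$trait_id)
    g <- split(tr$generation, tr$trait_id)[[1]]
    m <- do.call(cbind, sp)
    m[order(g), , drop = FALSE]
  }))
  g <- sort(unique(ensemble[[1]]$generation))
  data.frame(
    generation = g,
    mean_F = rowMeans(Fm),
    q2.5 = apply(Fm, 1, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(Fm, 1, quantile, probs = 0.975, names = FALSE),
    n_traits = ncol(Fm)
  )
}

#' Plot a variance-trajectory band
#'
#' Mean F against generation with a translucent 95% band, one curve per
#' summarized ensemble.
#'
#' @param ... named [trajectory_band()] data frames.
#' @return a ggplot object.
#' @export
plot_trajectory_band <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_trajectory_band() needs the ggplot2 package")
  }
  bands <- list(...)
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    names(bands) <- paste0("ensemble", seq_along(bands))
  }
  df <- do.call(rbind, Map(function(b, nm) cbind(b, ensemble = nm),
                           bands, names(bands)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$mean_F,
                                   colour = .data$ensemble,
                                   fill = .data$ensemble)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = expression(F == sigma[x]^2 / sigma[1]^2)) +
    ggplot2::theme_minimal()
}

#' Write a trajectory-band summary
#'
#' @param band a [trajectory_band()] data frame.
#' @param file output TSV path.
#' @export
write_trajectory_band <- function(band, file) {
  write.table(band, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write one or more trait trajectories to TSV
#'
#' Columns: run_id, generation, trait_id, pheno_mean, pheno_var, geno_var, F.
#'
#' @param trajs a `trait_trajectory` or list of them.
#' @param file output TSV path.
#' @export
write_trait_trajectory <- function(trajs, file) {
  if (inherits(trajs, "trait_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, Map(function(tr, i) {
    cbind(run_id = i, as.data.frame(tr))
  }, trajs, seq_along(trajs)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
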