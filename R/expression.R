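#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors relative to a reference library
#' (the library whose 75th-percentile count is most typical), with log-ratio
#' trimming of 30%, absolute-expression trimming of 5% and precision
#' weighting, normalized so the factors have geometric mean 1. Computed with
#' edgeR's implementation.
#'
#' @param cm a `count_matrix` or a genes x individuals count matrix.
#' @return named numeric vector of per-individual scaling factors.
#' @export
tmm_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) < 2) stop("TMM needs at least 2 libraries")
  if (any(colSums(counts) == 0)) stop("a library has zero total count")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  setNames(f, colnames(counts))
}

#' Natural-log counts per million
#'
#' `ln((count + pseudocount) / (library_size * factor) * 1e6)`. The natural
#' (not base-2) log is used so that downstream variances are on the natural
#' log scale. The pseudocount (default 0.5) guards against zeros.
#'
#' @param cm a `count_matrix` or counts matrix.
#' @param factors per-library scaling factors (default [tmm_factors()]).
#' @param pseudocount added to every count before the log.
#' @return genes x individuals matrix of natural-log CPM.
#' @export
log_cpm <- function(cm, factors = NULL, pseudocount = 0.5) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (any(factors <= 0)) stop("scaling factors must be positive")
  eff <- colSums(counts) * factors
  log(sweep(counts + pseudocount, 2, eff, "/") * 1e6)
}

# same-lot (ancestral, evolved) population pairs from a sample sheet
default_pairs <- function(samples) {
  anc <- unique(samples$population[startsWith(samples$population, "anc")])
  evo <- unique(samples$population[startsWith(samples$population, "evo")])
  lot_of <- function(p) unique(samples$batch[samples$population == p])
  pairs <- list()
  for (e in evo) {
    cand <- anc[vapply(anc, function(a) identical(lot_of(a), lot_of(e)),
                       logical(1))]
    if (length(cand)) pairs[[length(pairs) + 1L]] <- c(cand[1], e)
  }
  if (!length(pairs)) stop("no same-lot ancestral/evolved pair found")
  pairs
}

#' Per-gene variance change between ancestral and evolved populations
#'
#' For each (ancestral, evolved) population pair sharing a library-
#' preparation lot, computes unbiased per-gene sample variances of log-CPM
#' within each population and the variance-change statistic
#' `F = var_evolved / var_ancestral`. Individuals from different lots are
#' never pooled into one contrast. Genes with zero ancestral variance get
#' `F = NA` and are flagged.
#'
#' @param logcpm genes x individuals matrix from [log_cpm()].
#' @param samples sample sheet with `individual_id`, `population`, `batch`.
#' @param pairing list of `c(ancestral, evolved)` population pairs; derived
#'   from the lot structure when `NULL`.
#' @return list with `stats` (per gene x population mean/var/n), `F`
#'   (genes x pairs matrix), `pairs`.
#' @export
per_gene_variance_change <- function(logcpm, samples, pairing = NULL) {
  stopifnot(ncol(logcpm) == nrow(samples))
  if (is.null(pairing)) pairing <- default_pairs(samples)
  pops <- unique(samples$population)
  stats <- do.call(rbind, lapply(pops, function(p) {
    idx <- samples$population == p
    if (sum(idx) < 2) stop("population ", p, " has fewer than 2 individuals")
    data.frame(gene_id = rownames(logcpm), population = p,
               n = sum(idx), mean_logcpm = rowMeans(logcpm[, idx, drop = FALSE]),
               var_logcpm = row_vars(logcpm[, idx, drop = FALSE]),
               row.names = NULL)
  }))
  Fm <- vapply(pairing, function(pr) {
    va <- stats$var_logcpm[stats$population == pr[1]]
    ve <- stats$var_logcpm[stats$population == pr[2]]
    ifelse(va > 0, ve / va, NA_real_)
  }, numeric(nrow(logcpm)))
  colnames(Fm) <- vapply(pairing, paste, "", collapse = "_vs_")
  rownames(Fm) <- rownames(logcpm)
  list(stats = stats, F = Fm, pairs = pairing)
}

#' Jackknife confidence interval for a sample variance
#'
#' Leave-one-out pseudovalue jackknife: with `theta` the unbiased sample
#' variance and `theta_(-i)` its leave-one-out versions, the pseudovalues
#' `n * theta - (n - 1) * theta_(-i)` yield the interval
#' `mean(p) +/- t_{level, n-1} * sd(p) / sqrt(n)`. Because a variance is
#' positive and its sampling distribution right-skewed, the pseudovalues are
#' by default formed on the log scale and the interval back-transformed,
#' which brings small-sample coverage close to the nominal level;
#' `log_scale = FALSE` gives the plain raw-scale jackknife.
#'
#' @param values per-individual measurements (n >= 3).
#' @param level confidence level.
#' @param log_scale jackknife the log of the variance (default) rather than
#'   the variance itself.
#' @return list with `estimate` (the unbiased sample variance), `lower`,
#'   `upper`, `se` (standard error of the jackknifed statistic, on the log
#'   scale when `log_scale`).
#' @export
jackknife_ci <- function(values, level = 0.95, log_scale = TRUE) {
  n <- length(values)
  if (n < 3) stop("jackknife needs at least 3 values")
  theta <- var(values)
  if (theta == 0) {
    return(list(estimate = 0, lower = 0, upper = 0, se = 0))
  }
  loo <- vapply(seq_len(n), function(i) var(values[-i]), numeric(1))
  if (log_scale && any(loo <= 0)) log_scale <- FALSE
  tq <- qt(1 - (1 - level) / 2, n - 1)
  if (log_scale) {
    pseudo <- n * log(theta) - (n - 1) * log(loo)
    se <- sd(pseudo) / sqrt(n)
    ctr <- mean(pseudo)
    list(estimate = theta, lower = exp(ctr - tq * se),
         upper = exp(ctr + tq * se), se = se)
  } else {
    pseudo <- n * theta - (n - 1) * loo
    est <- mean(pseudo)
    se <- sd(pseudo) / sqrt(n)
    list(estimate = est, lower = est - tq * se, upper = est + tq * se,
         se = se)
  }
}

#' Partition the squared coefficient of variation of expression
#'
#' For every gene within each population, the total squared coefficient of
#' variation of depth-normalized counts is split as
#' `total CV^2 = technical CV^2 + biological CV^2`: technical noise is the
#' Poisson read-sampling component `1 / mean(normalized count)` and the
#' biological component (squared BCV) is the non-negative remainder.
#' Optionally the biological component is shrunk toward a smooth
#' mean-dispersion trend (lowess of the raw biological CV^2 against log
#' mean), with `shrink = 0` disabling shrinkage. All-zero gene rows are
#' flagged and not partitioned.
#'
#' @param cm a `count_matrix` or counts matrix.
#' @param samples sample sheet (taken from `cm` when omitted).
#' @param factors normalization factors (default [tmm_factors()]).
#' @param shrink shrinkage weight toward the trend, in \[0, 1\] (default
#'   0.2, mild).
#' @return data frame, one row per gene x population: `gene_id`,
#'   `population`, `mean_ncount`, `total_cv2`, `technical_cv2`,
#'   `biological_cv2`, `flagged`.
#' @export
cv_partition <- function(cm, samples = NULL, factors = NULL, shrink = 0.2) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(samples) && inherits(cm, "count_matrix")) samples <- cm$samples
  stopifnot(!is.null(samples), ncol(counts) == nrow(samples))
  if (shrink < 0 || shrink > 1) stop("'shrink' must be in [0, 1]")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  ncount <- sweep(counts, 2, mean(eff) / eff, "*")
  out <- lapply(unique(samples$population), function(p) {
    idx <- samples$population == p
    if (sum(idx) < 2) stop("population ", p, " has fewer than 2 individuals")
    x <- ncount[, idx, drop = FALSE]
    mu <- rowMeans(x)
    flagged <- mu == 0
    total <- ifelse(flagged, NA_real_, row_vars(x) / mu^2)
    tech <- ifelse(flagged, NA_real_, 1 / mu)
    bio <- pmax(0, total - tech)
    if (shrink > 0 && sum(!flagged) > 10) {
      ok <- !flagged
      tr <- lowess(log(mu[ok]), bio[ok], f = 0.5)
      trend <- approx(tr$x, tr$y, xout = log(mu[ok]), rule = 2)$y
      bio[ok] <- pmax(0, (1 - shrink) * bio[ok] + shrink * trend)
    }
    data.frame(gene_id = rownames(counts), population = p, mean_ncount = mu,
               total_cv2 = total, technical_cv2 = tech,
               biological_cv2 = bio, flagged = flagged, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Compare variance changes of DE and non-DE genes
#'
#' Welch t-test of the per-gene variance-change F between genes with and
#' without a significant change in mean expression, with per-class medians.
#' A non-significant difference indicates that selection on mean expression
#' did not measurably alter expression variance, as expected under a
#' polygenic architecture.
#'
#' @param F_values per-gene variance-change statistics (one replicate
#'   contrast).
#' @param de_label per-gene logical.
#' @param alpha significance level.
#' @return list with `median_F_de`, `median_F_nonde`, `t_p_value`,
#'   `significant`, `n_de`, `n_nonde`.
#' @export
compare_de_vs_nonde <- function(F_values, de_label, alpha = 0.05) {
  stopifnot(length(F_values) == length(de_label))
  keep <- is.finite(F_values)
  F_values <- F_values[keep]
  de_label <- de_label[keep]
  if (!any(de_label) || all(de_label)) {
    stop("both DE and non-DE classes must be non-empty")
  }
  fd <- F_values[de_label]
  fn <- F_values[!de_label]
  p <- if (sd(fd) == 0 && sd(fn) == 0) 1 else {
    pv <- t.test(fd, fn)$p.value
    if (is.na(pv)) 1 else pv
  }
  list(median_F_de = median(fd), median_F_nonde = median(fn),
       t_p_value = p, significant = p < alpha,
       n_de = length(fd), n_nonde = length(fn))
}

#' Stand-in differential-expression calls
#'
#' Per-gene Welch t-test of mean log-CPM between all ancestral and all
#' evolved individuals with Benjamini-Hochberg FDR control. This is a simple
#' stand-in for externally supplied DE labels (e.g. from a dedicated
#' count-based DE analysis); user-supplied labels should be preferred when
#' available.
#'
#' @param logcpm genes x individuals matrix.
#' @param samples sample sheet with a `population` column (anc*/evo*).
#' @param fdr false-discovery-rate level.
#' @return logical vector, TRUE for genes called DE.
#' @export
de_call_standin <- function(logcpm, samples, fdr = 0.05) {
  stopifnot(ncol(logcpm) == nrow(samples))
  anc <- startsWith(samples$population, "anc")
  evo <- startsWith(samples$population, "evo")
  if (sum(anc) < 2 || sum(evo) < 2) {
    stop("need at least 2 ancestral and 2 evolved individuals")
  }
  xa <- logcpm[, anc, drop = FALSE]
  xe <- logcpm[, evo, drop = FALSE]
  na <- ncol(xa); ne <- ncol(xe)
  va <- row_vars(xa) / na
  ve <- row_vars(xe) / ne
  tstat <- (rowMeans(xe) - rowMeans(xa)) / sqrt(va + ve)
  df <- (va + ve)^2 / (va^2 / (na - 1) + ve^2 / (ne - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  p.adjust(p, method = "BH") < fdr
}

#' Run the full expression-variance pipeline
#'
#' TMM normalization, natural-log CPM, same-lot per-gene variance-change F,
#' DE labels (supplied or stand-in calls), the DE vs non-DE comparison per
#' replicate contrast, and the CV^2 partition.
#'
#' @param cm a `count_matrix` (see [simulate_expression_counts()] /
#'   [read_count_matrix()]).
#' @param de_label optional per-gene logical; when `NULL`, labels from `cm`
#'   are used if present, else [de_call_standin()] is applied.
#' @param fdr FDR level for stand-in DE calls.
#' @param pseudocount for [log_cpm()].
#' @param shrink for [cv_partition()].
#' @return list with `factors`, `logcpm`, `variance` (from
#'   [per_gene_variance_change()]), `de_label`, `comparison` (one
#'   [compare_de_vs_nonde()] result per replicate contrast), `cv` (the CV^2
#'   partition).
#' @export
analyze_expression <- function(cm, de_label = NULL, fdr = 0.05,
                               pseudocount = 0.5, shrink = 0.2) {
  stopifnot(inherits(cm, "count_matrix"))
  factors <- tmm_factors(cm)
  lc <- log_cpm(cm, factors, pseudocount)
  vc <- per_gene_variance_change(lc, cm$samples)
  if (is.null(de_label)) de_label <- cm$de_label
  if (is.null(de_label)) de_label <- de_call_standin(lc, cm$samples, fdr)
  cmp <- lapply(seq_len(ncol(vc$F)), function(k) {
    compare_de_vs_nonde(vc$F[, k], de_label)
  })
  names(cmp) <- colnames(vc$F)
  list(factors = factors, logcpm = lc, variance = vc, de_label = de_label,
       comparison = cmp, cv = cv_partition(cm, factors = factors,
                                           shrink = shrink))
}
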