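#' Dispersion specifications for the count generator
#'
#' Per-gene biological dispersion (squared biological coefficient of
#' variation) models: a constant value for every gene, or log-normally
#' distributed across genes. The default log-normal (median 0.09, i.e. BCV
#' 0.3, sdlog 0.4) reflects across-individual expression variability typical
#' of outbred insect populations.
#'
#' @param phi dispersion (> 0).
#' @param meanlog,sdlog log-normal parameters for per-gene dispersions.
#' @return a `disp_spec` consumed by [simulate_expression_counts()].
#' @export
disp_constant <- function(phi = 0.09) {
  if (phi <= 0) stop("dispersion must be positive")
  structure(list(kind = "constant", phi = phi), class = "disp_spec")
}

#' @rdname disp_constant
#' @export
disp_lognormal <- function(meanlog = log(0.09), sdlog = 0.4) {
  if (sdlog < 0) stop("'sdlog' must be non-negative")
  structure(list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "disp_spec")
}

sample_dispersion <- function(spec, n) {
  stopifnot(inherits(spec, "disp_spec"))
  switch(spec$kind,
    constant = rep(spec$phi, n),
    lognormal = exp(rnorm(n, spec$meanlog, spec$sdlog))
  )
}

#' Simulate an RNA-seq count matrix for the 2 + 2 population design
#'
#' Generates negative-binomial read counts for a study layout of two
#' reconstituted ancestral and two independently evolved populations with
#' 19-22 individuals each. Gene baselines are log-normal; library sizes vary
#' log-normally around a target depth; library-preparation lots add additive
#' log-scale offsets shared by the populations prepared together (by default
#' anc1/evo1 in one lot, anc2/evo2 in the other, so each evolved population
#' has a same-lot ancestral contrast).
#'
#' A fraction of genes is flagged DE: their log-mean in the evolved
#' populations is shifted by `mean_shift_sd` ancestral log-scale standard
#' deviations (the ancestral SD of a gene is `sqrt(phi + 1/mu)`, biological
#' plus Poisson sampling variance on the log scale), with random sign.
#' Evolved-population biological dispersion is multiplied by
#' `variance_factor` for the chosen gene subset. All generating parameters
#' are recorded for parameter-recovery checks.
#'
#' @param n_genes number of genes.
#' @param design named integer vector of individuals per population; names
#'   define populations, and names starting with "evo" are treated as
#'   evolved.
#' @param de_fraction proportion of genes flagged DE.
#' @param mean_shift_sd DE mean shift in ancestral-SD units.
#' @param variance_factor multiplier on evolved biological dispersion
#'   (> 0) for `var_factor_genes`.
#' @param var_factor_genes `"de"`, `"all"`, or an integer vector of gene
#'   indices.
#' @param dispersion_model a [disp_constant()] / [disp_lognormal()] spec.
#' @param batch_effect list with `sd` (log-scale SD of per-gene lot offsets)
#'   and `batches` (named character vector population -> lot).
#' @param library_sizes list with `mean` (target depth) and `sdlog`.
#' @param baseline_sdlog SD of log relative expression across genes.
#' @param seed optional integer seed.
#' @return a `count_matrix`: list with `counts` (genes x individuals),
#'   `samples` (individual_id, population, batch), `de_label`,
#'   `true_params`, `params`.
#' @examples
#' cm <- simulate_expression_counts(n_genes = 200, seed = 1)
#' cm$counts[1:3, 1:4]
#' @export
simulate_expression_counts <- function(
    n_genes = 5000,
    design = c(anc1 = 20L, anc2 = 22L, evo1 = 19L, evo2 = 21L),
    de_fraction = 0.05,
    mean_shift_sd = 1,
    variance_factor = 1,
    var_factor_genes = "de",
    dispersion_model = disp_lognormal(),
    batch_effect = list(sd = 0.1,
                        batches = c(anc1 = "lot1", evo1 = "lot1",
                                    anc2 = "lot2", evo2 = "lot2")),
    library_sizes = list(mean = 2e6, sdlog = 0.15),
    baseline_sdlog = 1.5,
    seed = NULL) {
  if (de_fraction < 0 || de_fraction > 1) stop("'de_fraction' must be in [0, 1]")
  if (variance_factor <= 0) stop("'variance_factor' must be positive")
  if (is.null(names(design)) || any(!nzchar(names(design)))) {
    stop("'design' must be a named vector of per-population sample sizes")
  }
  if (!is.null(library_sizes$mean) && library_sizes$mean <= 0) {
    stop("library size must be positive")
  }
  maybe_set_seed(seed)

  pops <- names(design)
  n_ind <- sum(design)
  population <- rep(pops, design)
  evolved <- startsWith(population, "evo")
  batches <- batch_effect$batches
  if (is.null(batches)) batches <- setNames(rep("lot1", length(pops)), pops)
  batch <- unname(batches[population])
  ind_id <- paste0(population, "_", unlist(lapply(design, seq_len)))

  # gene baselines: relative expression, then per-individual expected counts
  q <- exp(rnorm(n_genes, 0, baseline_sdlog))
  q <- q / sum(q)
  libsize <- exp(rnorm(n_ind, log(library_sizes$mean), library_sizes$sdlog))
  phi <- sample_dispersion(dispersion_model, n_genes)

  n_de <- round(de_fraction * n_genes)
  de <- rep(FALSE, n_genes)
  if (n_de > 0) de[sample.int(n_genes, n_de)] <- TRUE

  vf_idx <- switch(as.character(var_factor_genes[1]),
                   de = which(de),
                   all = seq_len(n_genes),
                   as.integer(var_factor_genes))

  mu_base <- q * library_sizes$mean          # per-gene mean at target depth
  sd_anc <- sqrt(phi + 1 / pmax(mu_base, 1e-8))
  shift <- numeric(n_genes)
  if (n_de > 0) {
    shift[de] <- mean_shift_sd * sd_anc[de] * sample(c(-1, 1), n_de,
                                                     replace = TRUE)
  }

  # per-gene x batch log-scale offsets
  lots <- unique(batch)
  boff <- matrix(rnorm(n_genes * length(lots), 0, batch_effect$sd %||% 0),
                 n_genes, length(lots), dimnames = list(NULL, lots))

  counts <- matrix(0L, n_genes, n_ind)
  phi_evo <- phi
  phi_evo[vf_idx] <- phi_evo[vf_idx] * variance_factor
  for (j in seq_len(n_ind)) {
    ph <- if (evolved[j]) phi_evo else phi
    lmu <- log(q) + log(libsize[j]) + boff[, batch[j]]
    if (evolved[j]) lmu <- lmu + shift
    mu <- exp(lmu)
    counts[, j] <- as.integer(rnbinom(n_genes, mu = mu, size = 1 / ph))
  }
  dimnames(counts) <- list(paste0("g", seq_len(n_genes)), ind_id)

  structure(
    list(
      counts = counts,
      samples = data.frame(individual_id = ind_id, population = population,
                           batch = batch),
      de_label = de,
      true_params = data.frame(
        gene_id = rownames(counts), mu = mu_base, dispersion = phi,
        de = de, shift_sd = shift / sd_anc, shift_log = shift,
        sd_anc_log = sd_anc,
        variance_factor = ifelse(seq_len(n_genes) %in% vf_idx,
                                 variance_factor, 1)
      ),
      params = list(design = design, de_fraction = de_fraction,
                    mean_shift_sd = mean_shift_sd,
                    variance_factor = variance_factor, seed = seed)
    ),
    class = "count_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d individuals (%s); %d DE genes\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s=%d", names(table(x$samples$population)),
                  table(x$samples$population)), collapse = ", "),
    sum(x$de_label)
  ))
  invisible(x)
}

#' Read / write a count matrix
#'
#' Counts as a genes x individuals TSV (first column `gene_id`), a sidecar
#' sample sheet (individual_id, population, batch) and an optional gene
#' label file (gene_id, de_status).
#'
#' @param cm a `count_matrix`.
#' @param counts_file,samples_file,labels_file file paths; `labels_file`
#'   may be `NULL`.
#' @return `read_count_matrix()` returns a `count_matrix` (without
#'   generating parameters).
#' @export
write_count_matrix <- function(cm, counts_file, samples_file,
                               labels_file = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, samples_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(labels_file)) {
    write.table(data.frame(gene_id = rownames(cm$counts),
                           de_status = cm$de_label),
                labels_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_file)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, samples_file,
                              labels_file = NULL) {
  df <- read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  samples <- read.delim(samples_file, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "population", "batch") %in% names(samples))) {
    stop("sample sheet needs individual_id, population, batch columns")
  }
  if (!identical(colnames(counts), samples$individual_id)) {
    stop("sample sheet does not match count columns")
  }
  de <- NULL
  if (!is.null(labels_file)) {
    lab <- read.delim(labels_file, stringsAsFactors = FALSE)
    de <- as.logical(lab$de_status[match(rownames(counts), lab$gene_id)])
  }
  structure(list(counts = counts, samples = samples, de_label = de,
                 true_params = NULL, params = NULL),
            class = "count_matrix")
}
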