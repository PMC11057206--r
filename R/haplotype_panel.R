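#' Founder haplotype panel
#'
#' A `haplotype_panel` holds the founder chromosomes that seed every
#' simulation: a binary allele matrix (haplotypes x loci), the per-locus
#' derived-allele frequency, and a genetic map. No new mutations arise during
#' the simulated experiment, so the panel fixes the raw material available to
#' selection and drift.
#'
#' @param alleles binary matrix, rows = haplotypes, columns = loci.
#' @param map a [generate_genetic_map()] object with one row per locus;
#'   generated with defaults when omitted.
#' @return a `haplotype_panel`: list with elements `alleles`, `freq`,
#'   `map`, `monomorphic` (logical per locus).
#' @export
haplotype_panel <- function(alleles, map = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 2) stop("a panel needs at least 2 haplotypes")
  if (ncol(alleles) < 1) stop("a panel needs at least 1 locus")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
  if (is.null(map)) map <- generate_genetic_map(ncol(alleles))
  stopifnot(inherits(map, "genetic_map"))
  if (nrow(map) != ncol(alleles)) {
    stop("map must have one row per locus")
  }
  freq <- colMeans(alleles)
  structure(
    list(alleles = alleles, freq = freq, map = map,
         monomorphic = freq == 0 | freq == 1),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes x %d loci (%d monomorphic), %s chromosomes, %.3g M total\n",
    nrow(x$alleles), ncol(x$alleles), sum(x$monomorphic),
    length(unique(x$map$chromosome)),
    sum(tapply(x$map$pos_morgans, x$map$chromosome, function(p) diff(range(p))))
  ))
  invisible(x)
}

#' Frequency-spectrum specifications for founder panels
#'
#' Describe the distribution from which per-locus derived-allele frequencies
#' are drawn before being realized by binomial sampling of haplotypes.
#' `sfs_uniform` draws uniformly on \[f_min, f_max\]; `sfs_beta` from a Beta
#' distribution (the default Beta(1, 3) panel skews toward low frequencies as
#' expected for variants segregating in a natural founder population);
#' `sfs_neutral` from the neutral site-frequency spectrum, density
#' proportional to 1/f, truncated to \[f_min, f_max\].
#'
#' @param f_min,f_max frequency bounds in (0, 1).
#' @param shape1,shape2 Beta parameters (> 0).
#' @return an `sfs_spec` list consumed by [generate_founder_haplotypes()].
#' @export
sfs_uniform <- function(f_min = 0.05, f_max = 0.95) {
  stopifnot(f_min > 0, f_max < 1, f_min <= f_max)
  structure(list(kind = "uniform", f_min = f_min, f_max = f_max),
            class = "sfs_spec")
}

#' @rdname sfs_uniform
#' @export
sfs_beta <- function(shape1 = 1, shape2 = 3) {
  if (shape1 <= 0 || shape2 <= 0) stop("Beta shape parameters must be > 0")
  structure(list(kind = "beta", shape1 = shape1, shape2 = shape2),
            class = "sfs_spec")
}

#' @rdname sfs_uniform
#' @export
sfs_neutral <- function(f_min = 0.01, f_max = 0.99) {
  stopifnot(f_min > 0, f_max < 1, f_min < f_max)
  structure(list(kind = "neutral", f_min = f_min, f_max = f_max),
            class = "sfs_spec")
}

sample_sfs <- function(sfs, n) {
  stopifnot(inherits(sfs, "sfs_spec"))
  switch(sfs$kind,
    uniform = runif(n, sfs$f_min, sfs$f_max),
    beta = rbeta(n, sfs$shape1, sfs$shape2),
    neutral = {
      # inverse-CDF sampling of density 1/f on [f_min, f_max]
      u <- runif(n)
      sfs$f_min * (sfs$f_max / sfs$f_min)^u
    }
  )
}

#' Generate founder haplotypes
#'
#' Draws per-locus allele frequencies from a frequency-spectrum specification
#' and realizes them by independent binomial sampling of haplotype alleles
#' (loci are in linkage equilibrium in the panel). Columns that come out
#' monomorphic are redrawn a bounded number of times; any that remain
#' monomorphic are flagged in the returned panel.
#'
#' @param n_haplotypes number of founder haplotypes (>= 2); 189 matches a
#'   typical Drosophila experimental-evolution founder panel.
#' @param n_loci number of loci (>= 1).
#' @param sfs an [sfs_beta()]-style spec; default Beta(1, 3).
#' @param map optional [generate_genetic_map()] map (defaults to 5 Morgans
#'   over 5 chromosome arms).
#' @param seed optional integer seed.
#' @param max_retries resampling attempts per monomorphic column.
#' @return a [haplotype_panel()].
#' @examples
#' p <- generate_founder_haplotypes(189, 100, seed = 1)
#' p
#' @export
generate_founder_haplotypes <- function(n_haplotypes, n_loci,
                                        sfs = sfs_beta(1, 3),
                                        map = NULL, seed = NULL,
                                        max_retries = 20) {
  if (n_loci < 1) stop("'n_loci' must be at least 1")
  if (n_haplotypes < 2) stop("'n_haplotypes' must be at least 2")
  maybe_set_seed(seed)
  p <- sample_sfs(sfs, n_loci)
  alleles <- matrix(rbinom(n_haplotypes * n_loci, 1L, rep(p, each = n_haplotypes)),
                    nrow = n_haplotypes, ncol = n_loci)
  for (i in seq_len(max_retries)) {
    cm <- colMeans(alleles)
    mono <- which(cm == 0 | cm == 1)
    if (!length(mono)) break
    p2 <- sample_sfs(sfs, length(mono))
    alleles[, mono] <- rbinom(n_haplotypes * length(mono), 1L,
                              rep(p2, each = n_haplotypes))
  }
  haplotype_panel(alleles, map)
}

#' Restrict a panel to a subset of loci
#'
#' Keeps the given loci (columns) and their map rows; genetic positions are
#' unchanged, so linkage between the retained loci is preserved.
#'
#' @param panel a [haplotype_panel()].
#' @param loci increasing integer locus indices.
#' @return a [haplotype_panel()] over the selected loci.
#' @export
subset_panel <- function(panel, loci) {
  stopifnot(inherits(panel, "haplotype_panel"), !is.unsorted(loci))
  map <- panel$map[loci, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  haplotype_panel(panel$alleles[, loci, drop = FALSE], map)
}

#' Read / write a haplotype panel
#'
#' The panel is stored as a plain TSV of 0/1 alleles (rows = haplotypes,
#' columns = loci, header = locus ids) with the map in a separate
#' [write_genetic_map()] file.
#'
#' @param panel a [haplotype_panel()].
#' @param file path for the allele TSV.
#' @param map_file path for the map TSV.
#' @return `read_haplotype_panel()` returns a `haplotype_panel`.
#' @export
write_haplotype_panel <- function(panel, file, map_file) {
  stopifnot(inherits(panel, "haplotype_panel"))
  al <- as.data.frame(panel$alleles)
  names(al) <- panel$map$locus_id
  write.table(al, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write_genetic_map(panel$map, map_file)
  invisible(file)
}

#' @rdname write_haplotype_panel
#' @export
read_haplotype_panel <- function(file, map_file) {
  al <- as.matrix(read.delim(file, check.names = FALSE))
  map <- read_genetic_map(map_file)
  haplotype_panel(al, map)
}

#' Read a phased VCF into a haplotype panel
#'
#' Minimal reader for phased diploid VCFs (GT fields like `0|1`): each sample
#' contributes two haplotypes. Genetic positions are taken from a supplied
#' map, or default to physical position times a constant Morgan/bp rate.
#'
#' @param file path to an uncompressed VCF.
#' @param map optional `genetic_map` with one row per VCF record.
#' @param morgans_per_bp used to synthesize a map when none is given.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_panel_vcf <- function(file, map = NULL, morgans_per_bp = 2e-8) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) {
    stop("not a VCF: missing #CHROM header")
  }
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns")
  rec <- strsplit(lines[-1], "\t", fixed = TRUE)
  chrom <- vapply(rec, `[[`, "", 1)
  pos <- as.numeric(vapply(rec, `[[`, "", 2))
  ids <- vapply(rec, `[[`, "", 3)
  gt_cols <- lapply(rec, function(r) r[10:length(r)])
  gt <- vapply(gt_cols, function(g) {
    g <- sub(":.*", "", g)
    parts <- strsplit(g, "|", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("VCF genotypes must be phased ('|')")
    as.integer(unlist(parts))
  }, integer(2 * (length(hdr) - 9)))
  # gt: (2 * n_samples) x n_loci
  if (is.null(map)) {
    map <- data.frame(
      chromosome = chrom,
      locus_id = ifelse(ids == ".", paste0(chrom, ":", pos), ids),
      pos_morgans = ave(pos * morgans_per_bp, chrom, FUN = function(x) x - min(x)),
      pos_physical = pos
    )
    class(map) <- c("genetic_map", "data.frame")
  }
  haplotype_panel(gt, map)
}
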