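#' Generate a synthetic genetic map
#'
#' Builds a genetic map for `n_loci` loci under one of two models:
#' \describe{
#'   \item{`"uniform"`}{loci evenly spaced over `n_chromosomes` chromosome
#'     arms of equal genetic length, totalling `total_morgans` Morgans. The
#'     default (5 Morgans over 5 arms) is a synthetic stand-in for a
#'     Drosophila-like linkage map.}
#'   \item{`"per_interval"`}{a single chromosome on which every pair of
#'     adjacent loci recombines with fraction `rate`; locus spacing is the
#'     Haldane inverse of `rate`, so the Poisson-crossover gamete model
#'     reproduces `rate` exactly in expectation. This is the layout used for
#'     weakly linked loci in the modular scenario (r = 0.001).}
#' }
#'
#' Recombination fractions between adjacent loci follow the Haldane map
#' function; loci on different chromosomes assort independently (r = 0.5).
#'
#' @param n_loci number of loci (>= 1).
#' @param model `"uniform"` or `"per_interval"`.
#' @param total_morgans total map length in Morgans (uniform model). May be 0
#'   for complete linkage.
#' @param n_chromosomes number of chromosome arms (uniform model).
#' @param rate adjacent-locus recombination fraction (per-interval model),
#'   in \[0, 0.5).
#' @return a `genetic_map`: data frame with columns `chromosome`, `locus_id`,
#'   `pos_morgans`, `pos_physical`.
#' @examples
#' m <- generate_genetic_map(100)
#' head(rec_fractions(m))
#' @export
generate_genetic_map <- function(n_loci,
                                 model = c("uniform", "per_interval"),
                                 total_morgans = 5,
                                 n_chromosomes = 5,
                                 rate = 0.001) {
  model <- match.arg(model)
  stopifnot(n_loci >= 1)
  if (model == "uniform") {
    if (total_morgans < 0) stop("'total_morgans' must be non-negative")
    stopifnot(n_chromosomes >= 1)
    chrom <- sort(rep_len(seq_len(n_chromosomes), n_loci))
    arm_len <- total_morgans / n_chromosomes
    pos <- unlist(lapply(split(seq_len(n_loci), chrom), function(idx) {
      k <- length(idx)
      if (k == 1) 0 else seq(0, arm_len, length.out = k)
    }), use.names = FALSE)
    map <- data.frame(
      chromosome = paste0("chr", chrom),
      locus_id = paste0("L", seq_len(n_loci)),
      pos_morgans = pos,
      pos_physical = seq_len(n_loci)
    )
  } else {
    if (rate < 0) stop("'rate' must be non-negative")
    if (rate >= 0.5) stop("'rate' must be below 0.5 for linked loci")
    d <- haldane_inverse(rate)
    map <- data.frame(
      chromosome = "chr1",
      locus_id = paste0("L", seq_len(n_loci)),
      pos_morgans = (seq_len(n_loci) - 1) * d,
      pos_physical = seq_len(n_loci)
    )
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Recombination fractions between adjacent loci
#'
#' @param map a `genetic_map`.
#' @return numeric vector of length `nrow(map) - 1`; within a chromosome the
#'   Haldane transform of the inter-locus distance, 0.5 across chromosome
#'   boundaries.
#' @export
rec_fractions <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  if (nrow(map) < 2) return(numeric(0))
  d <- diff(map$pos_morgans)
  r <- haldane(pmax(d, 0))
  boundary <- map$chromosome[-1] != map$chromosome[-nrow(map)]
  r[boundary] <- 0.5
  r
}

# Internal layout used by the C++ gamete sampler: 0-based chromosome block
# offsets (with sentinel) and cumulative positions.
map_layout <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- map$chromosome
  if (is.unsorted(match(chrom, unique(chrom)))) {
    stop("map loci must be grouped by chromosome")
  }
  starts <- c(0L, cumsum(table(factor(chrom, levels = unique(chrom)))))
  list(chrom_start = as.integer(starts), pos = as.numeric(map$pos_morgans))
}

#' Read / write a genetic map
#'
#' Plain TSV with columns chromosome, locus_id, genetic position in Morgans
#' and physical position (PLINK `.map`-like).
#'
#' @param map a `genetic_map`.
#' @param file path to a tab-separated file.
#' @return `read_genetic_map()` returns a `genetic_map`.
#' @export
write_genetic_map <- function(map, file) {
  stopifnot(inherits(map, "genetic_map"))
  write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(file) {
  map <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("chromosome", "locus_id", "pos_morgans", "pos_physical")
  if (!all(need %in% names(map))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  map <- map[need]
  bad <- unlist(lapply(split(map$pos_morgans, map$chromosome), is.unsorted))
  if (any(bad)) stop("map positions must be non-decreasing within chromosome")
  class(map) <- c("genetic_map", "data.frame")
  map
}
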