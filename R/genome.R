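#' Genome specification for the cross simulator
#'
#' Describes the chromosomes of the simulated genome, a uniform genetic map,
#' and (optionally) a set of intervals treated as coding sequence, from which
#' the causal SNP is drawn.
#'
#' @param chromosomes A data.frame with columns `name` and `length` (bp), or
#'   a named numeric vector of chromosome lengths.
#' @param recomb_rate Recombination rate in cM/Mb, applied uniformly along
#'   every chromosome. The default, 4 cM/Mb, is a rice-like genome-wide
#'   average.
#' @param gene_intervals Optional data.frame with columns `chrom`, `start`,
#'   `end` (1-based, inclusive) marking CDS intervals available for
#'   causal-SNP placement and for simulated gene models.
#' @return An object of class `genome_spec`.
#' @seealso [default_genome()], [simulate_gene_models()]
#' @export
genome_spec <- function(chromosomes, recomb_rate = 4, gene_intervals = NULL) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(unname(chromosomes)),
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "length") %in% names(chromosomes))) {
    stop("`chromosomes` must be a data.frame with columns name, length")
  }
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1 || recomb_rate < 0) {
    stop("`recomb_rate` must be a single value >= 0 (cM/Mb)")
  }
  if (!is.null(gene_intervals)) {
    if (!all(c("chrom", "start", "end") %in% names(gene_intervals))) {
      stop("`gene_intervals` must have columns chrom, start, end")
    }
    len <- chromosomes$length[match(gene_intervals$chrom, chromosomes$name)]
    bad <- is.na(len) | gene_intervals$start < 1 |
      gene_intervals$end > len | gene_intervals$end < gene_intervals$start
    if (any(bad)) {
      stop("gene_intervals rows outside chromosome bounds: ",
           paste(which(bad), collapse = ", "))
    }
    gene_intervals <- gene_intervals[order(gene_intervals$chrom,
                                           gene_intervals$start), ,
                                     drop = FALSE]
    rownames(gene_intervals) <- NULL
  }
  structure(list(chromosomes = chromosomes,
                 recomb_rate = recomb_rate,
                 gene_intervals = gene_intervals),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x$chromosomes), " chromosome(s), ",
      x$recomb_rate, " cM/Mb, ",
      if (is.null(x$gene_intervals)) 0 else nrow(x$gene_intervals),
      " CDS interval(s)\n", sep = "")
  invisible(x)
}

#' Default simulated genome
#'
#' One 30 Mb chromosome (named `chr12`, so that candidate positions on the
#' scale of the 23-27 Mb mapping interval are representable) carrying 20
#' single-exon CDS intervals of 900 bp spread evenly along its length.
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of evenly spaced CDS intervals.
#' @param recomb_rate Recombination rate in cM/Mb.
#' @return A [genome_spec()].
#' @export
default_genome <- function(chrom_length = 30e6, n_genes = 20, recomb_rate = 4) {
  starts <- round(seq(chrom_length * 0.04, chrom_length * 0.96,
                      length.out = n_genes))
  gi <- data.frame(chrom = "chr12", start = starts, end = starts + 899L)
  genome_spec(data.frame(name = "chr12", length = chrom_length),
              recomb_rate = recomb_rate, gene_intervals = gi)
}

# Map position in Morgans for bp positions on one chromosome.
morgan_pos <- function(genome, pos_bp) {
  pos_bp / 1e6 * genome$recomb_rate / 100
}

# Genetic length of a chromosome in Morgans.
morgan_length <- function(genome, chrom) {
  len <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
  if (any(is.na(len))) stop("unknown chromosome: ", chrom)
  morgan_pos(genome, len)
}

#' Haldane map function
#'
#' Recombination fraction between two loci separated by `d` Morgans under a
#' no-interference (Poisson) crossover model: `(1 - exp(-2 d)) / 2`.
#' The inverse converts a recombination fraction back to map distance.
#'
#' @param d Map distance in Morgans.
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Recombination fraction (`haldane_r`) or map distance in Morgans
#'   (`haldane_d`).
#' @export
haldane_r <- function(d) (1 - exp(-2 * d)) / 2

#' @rdname haldane_r
#' @export
haldane_d <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  -log(1 - 2 * r) / 2
}
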