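# Readers and writers for the formats the pipeline exchanges: a simplified
# two-sample VCF (FORMAT AD), flat TSV allele-count tables, BED regions, and
# the packaged worked-example fixture of ten chromosome-12 SNPs.

#' Write an allele-count table
#'
#' `dialect = "tsv"` writes the eight declared columns as tab-separated
#' text. `dialect = "vcf"` writes a simplified VCF v4.2 with two sample
#' columns, `WP_BULK` and `MP_BULK`, carrying `AD` (ref,alt depths).
#'
#' @param counts Allele-count table.
#' @param path Output path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    utils::write.table(
      counts[, c("chrom", "pos", "ref", "alt",
                 "wp_ref", "wp_alt", "mp_ref", "mp_alt")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=mutmapr",
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
             "Description=\"Allelic depths (ref,alt)\">"),
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "WP_BULK", "MP_BULK", sep = "\t"))
    body <- paste(counts$chrom, counts$pos, ".", counts$ref, counts$alt,
                  ".", ".", ".", "AD",
                  paste0(counts$wp_ref, ",", counts$wp_alt),
                  paste0(counts$mp_ref, ",", counts$mp_alt), sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read an allele-count table from simplified VCF or TSV
#'
#' VCF input must carry two samples with an `AD` FORMAT field (the first
#' sample is taken as the WP bulk, the second as the MP bulk) and be
#' biallelic; TSV input must have the eight declared columns with
#' non-negative integer counts. Malformed rows are reported with their line
#' numbers. The returned table is validated and sorted by (chrom, pos).
#'
#' @param path Input path.
#' @param dialect `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return Allele-count table data.frame.
#' @export
read_counts <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  tab <- if (dialect == "vcf") read_counts_vcf(path) else read_counts_tsv(path)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("non-biallelic VCF records at row(s): ",
         paste(which(multi), collapse = ", "))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || ncol(ad) < 2) {
    stop("VCF must carry an AD field for two bulk samples")
  }
  if (any(is.na(ad))) {
    stop("missing AD at VCF record(s): ",
         paste(which(rowSums(is.na(ad)) > 0), collapse = ", "))
  }
  split_ad <- function(col) {
    parts <- strsplit(ad[, col], ",", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) {
      stop("AD is not ref,alt at VCF record(s): ",
           paste(which(bad), collapse = ", "))
    }
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    m
  }
  wp <- split_ad(1)
  mp <- split_ad(2)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             wp_ref = wp[, 1], wp_alt = wp[, 2],
             mp_ref = mp[, 1], mp_alt = mp[, 2])
}

read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt",
            "wp_ref", "wp_alt", "mp_ref", "mp_alt")
  if (!all(need %in% names(tab))) {
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  }
  counts <- as.matrix(tab[, c("wp_ref", "wp_alt", "mp_ref", "mp_alt")])
  bad <- rowSums(is.na(counts) | counts < 0 | counts != floor(counts)) > 0
  if (any(bad)) {
    stop("negative or non-integer counts at TSV line(s): ",
         paste(which(bad) + 1L, collapse = ", "))  # +1 for the header line
  }
  tab[, need]
}

#' Coordinate conversions between 1-based positions and BED intervals
#'
#' VCF/GFF3 positions are 1-based inclusive; BED intervals are 0-based
#' half-open. A single base at position `p` is the BED interval
#' `[p - 1, p)`.
#'
#' @param pos 1-based position(s).
#' @param start,end BED interval bounds (0-based half-open).
#' @return `pos_to_bed`: data.frame with `start`, `end`; `bed_to_pos`:
#'   data.frame with 1-based `first`, `last` positions covered.
#' @export
pos_to_bed <- function(pos) data.frame(start = pos - 1, end = pos)

#' @rdname pos_to_bed
#' @export
bed_to_pos <- function(start, end) {
  if (any(end <= start)) stop("empty BED interval")
  data.frame(first = start + 1, last = end)
}

#' Write candidate regions as BED
#'
#' Region starts/ends from [detect_candidate_regions()] are already 0-based
#' half-open and are written unchanged.
#'
#' @param regions data.frame with chrom, start, end (and optionally
#'   peak_index used as the score column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  score <- if ("peak_index" %in% names(regions)) {
    regions$peak_index
  } else {
    rep(".", nrow(regions))
  }
  lines <- paste(regions$chrom, format(regions$start, scientific = FALSE,
                                       trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 paste0("region", seq_len(nrow(regions))), score,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' The packaged ten-SNP worked example
#'
#' Ten SNPs on chromosome 12 with the WP- and MP-bulk SNP indices, region
#' classes, candidate ORF labels and S/NS mutation types reported for the
#' floral-organ mutant mapping: every MP index is 1, six SNPs fall in the
#' 23-27 Mb candidate region, two are nonsynonymous, and the causative one
#' at 26,056,055 has WP index 0.35.
#'
#' @return data.frame with columns chrom, pos, ref, alt, wp_index,
#'   mp_index, region_class, orf, mutation_type.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_chr12.tsv", package = "mutmapr",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "")
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  stopifnot(nrow(tab) == 10,
            all(tab$mp_index == 1),
            sum(tab$mutation_type == "NS") == 2,
            sum(tab$pos >= 23e6 & tab$pos <= 27e6) == 6)
  tab
}
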