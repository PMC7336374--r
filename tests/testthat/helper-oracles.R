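# Independent oracles and small builders shared across the suite.

# Expected mutant-allele frequency at a locus with recombination fraction r
# from the causal SNP, conditional on the phenotype class, by brute-force
# enumeration of the 4 x 4 ordered gamete pairs of the F2.
bulk_freq_oracle <- function(r, class = c("mp", "wp")) {
  class <- match.arg(class)
  g <- expand.grid(a1 = 0:1, b1 = 0:1, a2 = 0:1, b2 = 0:1)
  hap_p <- function(a, b) ifelse(a == b, (1 - r) / 2, r / 2)
  w <- hap_p(g$a1, g$b1) * hap_p(g$a2, g$b2)
  mutant <- g$a1 + g$a2 == 2
  sel <- if (class == "mp") mutant else !mutant
  sum(w[sel] * (g$b1 + g$b2)[sel]) / (2 * sum(w[sel]))
}

# Naive O(n * windows) recomputation of the sliding-window means.
naive_window_means <- function(records, chrom, chrom_length,
                               window_bp, step_bp) {
  r <- records[records$chrom == chrom, , drop = FALSE]
  starts <- if (chrom_length > window_bp) {
    seq(0, chrom_length - window_bp, by = step_bp)
  } else {
    0
  }
  do.call(rbind, lapply(starts, function(s) {
    inw <- r$pos - 1 >= s & r$pos - 1 < s + window_bp
    mean_of <- function(x) {
      x <- x[inw & !is.na(x)]
      if (length(x)) mean(x) else NA_real_
    }
    data.frame(start = s, n_snps = sum(inw),
               wp_mean = mean_of(r$wp_index),
               mp_mean = mean_of(r$mp_index))
  }))
}

# Hand-built variant set: a causal locus plus one linked locus at
# recombination fraction r (r = 0 via a zero-recombination chromosome,
# r = 0.5 via independent chromosomes, otherwise Haldane distance on a
# 4 cM/Mb chromosome).
two_locus_setup <- function(r) {
  if (r == 0.5) {
    genome <- genome_spec(c(chrA = 3e6, chrB = 3e6), recomb_rate = 4,
                          gene_intervals = data.frame(chrom = "chrA",
                                                      start = 1e6,
                                                      end = 1e6 + 899))
    v <- data.frame(chrom = c("chrA", "chrB"), pos = c(1e6, 1e6),
                    ref = "C", alt = "T", ems = TRUE)
  } else if (r == 0) {
    genome <- genome_spec(c(chrA = 3e6), recomb_rate = 0,
                          gene_intervals = data.frame(chrom = "chrA",
                                                      start = 1e6,
                                                      end = 1e6 + 899))
    v <- data.frame(chrom = "chrA", pos = c(1e6, 2e6),
                    ref = "C", alt = "T", ems = TRUE)
  } else {
    delta_bp <- haldane_d(r) * 100 / 4 * 1e6  # 4 cM/Mb map
    genome <- genome_spec(c(chrA = 1e6 + delta_bp + 1e6), recomb_rate = 4,
                          gene_intervals = data.frame(chrom = "chrA",
                                                      start = 1e6,
                                                      end = 1e6 + 899))
    v <- data.frame(chrom = "chrA", pos = c(1e6, 1e6 + delta_bp),
                    ref = "C", alt = "T", ems = TRUE)
  }
  variants <- structure(list(variants = v, causal_index = 1L,
                             spectrum_fraction = 1),
                        class = "ems_variant_set")
  list(genome = genome, variants = variants)
}

# A small genome with one 900 bp CDS interval, for simulator tests.
toy_genome <- function(len = 5e6, rate = 4) {
  genome_spec(c(chrA = len), recomb_rate = rate,
              gene_intervals = data.frame(chrom = "chrA", start = 10000,
                                          end = 10899))
}

# A complete toy CDS: ATG + fixed interior codons + TAA (600 nt, 200 codons),
# deterministic so positions of interest are stable across the suite.
toy_cds <- function(n_codons = 200) {
  set.seed(4242)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# Whole-CDS re-translation via Biostrings, the independent route for
# coding-effect checks. no.init.codon keeps the plain standard code (no
# alternative-initiator M at codon 1), matching the per-codon convention.
translate_oracle <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}
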