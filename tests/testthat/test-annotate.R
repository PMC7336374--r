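test_that("gene models validate their intervals and sequence", {
  expect_error(gene_model("g", "c", "+",
                          data.frame(start = c(1, 50), end = c(60, 99))),
               "overlap")
  expect_error(gene_model("g", "c", "+", data.frame(start = 10, end = 5)),
               "end < start")
  expect_error(gene_model("g", "c", "+", data.frame(start = 1, end = 10),
                          cds_seq = "ATGAAATAA"), "length")
  expect_error(gene_model("g", "c", "+", data.frame(start = 1, end = 10),
                          cds_seq = "ATGAAAATAA"), "divisible")
  expect_error(gene_model("g", "c", "+", data.frame(start = 1, end = 9),
                          cds_seq = "AAAAAATAA", complete = TRUE),
               "start with ATG")
  m <- gene_model("g", "c", "+", data.frame(start = 1, end = 9),
                  cds_seq = "ATGAAATAA", complete = TRUE)
  expect_s3_class(m, "gene_model")
})

test_that("region classes are exhaustive, exclusive, and precedence-ordered", {
  # plus-strand gene: UTR5 100-129, CDS 130-189 and 250-309, UTR3 310-339
  gp <- gene_model("plus", "c", "+",
                   cds = data.frame(start = c(130, 250), end = c(189, 309)),
                   utr5 = data.frame(start = 100, end = 129),
                   utr3 = data.frame(start = 310, end = 339))
  gm <- gene_model("minus", "c", "-",
                   cds = data.frame(start = 5000, end = 5059))
  models <- list(gp, gm)
  expect_identical(locate_variant("c", 150, models)$class, "exonic")
  expect_identical(locate_variant("c", 200, models)$class, "intronic")
  expect_identical(locate_variant("c", 110, models)$class, "UTR5")
  expect_identical(locate_variant("c", 320, models)$class, "UTR3")
  expect_identical(locate_variant("c", 90, models)$class, "upstream")
  expect_identical(locate_variant("c", 400, models)$class, "downstream")
  # minus strand: flank beyond the genomic-left end is downstream
  expect_identical(locate_variant("c", 4990, models)$class, "downstream")
  expect_identical(locate_variant("c", 5100, models)$class, "upstream")
  expect_identical(locate_variant("c", 2500, models)$class, "intergenic")
  expect_error(locate_variant("chrX", 1, models), "unknown chromosome")

  # exhaustive scan: exactly one class per position, always defined
  classes <- vapply(1:6100, function(p) locate_variant("c", p, models)$class,
                    character(1))
  expect_true(all(classes %in% c("exonic", "UTR5", "UTR3", "intronic",
                                 "upstream", "downstream", "intergenic")))
  expect_identical(sum(classes == "exonic"), 120L + 60L)
  expect_identical(sum(classes == "intronic"), 60L)
})

test_that("CDS coordinates splice correctly on both strands", {
  single <- gene_model("s", "c", "+", data.frame(start = 101, end = 1000),
                       cds_seq = toy_cds(300))
  expect_identical(cds_position("c", 101, single), 1L)
  expect_identical(cds_position("c", 845, single), 745L)
  expect_error(cds_position("c", 50, single), "not in the CDS")

  two <- gene_model("t", "c", "+",
                    data.frame(start = c(100, 201), end = c(150, 250)))
  # hand-spliced: exon1 has 51 bases, genomic 201 is the 52nd CDS base
  expect_identical(cds_position("c", 201, two), 52L)
  expect_identical(cds_position("c", 150, two), 51L)

  minus <- gene_model("m", "c", "-",
                      data.frame(start = c(100, 201), end = c(150, 250)))
  # transcript 5' end is the highest genomic coordinate
  expect_identical(cds_position("c", 250, minus), 1L)
  expect_identical(cds_position("c", 201, minus), 50L)
  expect_identical(cds_position("c", 150, minus), 51L)
  expect_identical(cds_position("c", 100, minus), 101L)

  # genomic_position inverts cds_position everywhere
  for (m in list(two, minus)) {
    for (cp in 1:101) {
      gp <- mutmapr:::genomic_position(m, cp)
      expect_identical(cds_position("c", gp, m), cp)
    }
  }
})

test_that("codon arithmetic follows the 1-based CDS convention", {
  expect_identical(codon_index(745), 249L)
  expect_identical(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_identical(codon_index(326), 109L)
  expect_identical(codon_index(170), 57L)
  expect_error(codon_index(0), ">= 1")
})

test_that("substitution effects agree with whole-CDS re-translation", {
  # worked examples under the standard code
  seq <- paste0("ATG", "CTC", "CTG", "TGG", "TAA")
  e1 <- classify_substitution(seq, 4, "C", "T")  # CTC -> TTC
  expect_identical(e1$category, "nonsynonymous")
  expect_identical(c(e1$ref_aa, e1$alt_aa), c("L", "F"))
  expect_identical(e1$codon_index, 2L)
  e2 <- classify_substitution(seq, 9, "G", "A")  # CTG -> CTA
  expect_identical(e2$category, "synonymous")
  expect_identical(e2$ref_aa, "L")
  e3 <- classify_substitution(seq, 12, "G", "A")  # TGG -> TGA
  expect_identical(e3$category, "stop_gain")
  expect_error(classify_substitution(seq, 4, "G", "T"), "mismatch")

  # 200 random draws against the Biostrings translation oracle
  set.seed(91)
  cds <- toy_cds(80)
  ref_prot <- translate_oracle(cds)
  for (i in 1:200) {
    pos <- sample.int(nchar(cds), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- classify_substitution(cds, pos, ref, alt)
    mut <- cds
    substr(mut, pos, pos) <- alt
    mut_prot <- translate_oracle(mut)
    diff_at <- which(strsplit(ref_prot, "")[[1]] !=
                       strsplit(mut_prot, "")[[1]])
    if (eff$category == "synonymous") {
      expect_identical(mut_prot, ref_prot)
    } else {
      expect_identical(diff_at, eff$codon_index)
      expect_identical(substr(mut_prot, diff_at, diff_at),
                       sub("\\*", "*", eff$alt_aa))
      if (eff$category == "stop_gain") {
        expect_identical(substr(mut_prot, diff_at, diff_at), "*")
      }
    }
  }
})

test_that("indel effects are verified by full re-translation", {
  cds <- toy_cds(150)
  ref_prot <- translate_oracle(cds)

  # in-frame deletion of one codon at a boundary: no frameshift
  infr <- classify_indel(cds, 10, delete_len = 3)
  expect_identical(infr$category, "inframe_indel")
  expect_identical(nchar(infr$mutated_protein), nchar(ref_prot) - 1L)

  # single-base insertion after CDS position 170: frameshift in codon 57
  fs <- classify_indel(cds, 170, insert = "C")
  expect_identical(fs$category, "frameshift")
  expect_identical(fs$edit_codon, 57L)
  mut <- paste0(substr(cds, 1, 170), "C", substr(cds, 171, nchar(cds)))
  mut_prot <- translate_oracle(substr(mut, 1, (nchar(mut) %/% 3) * 3))
  k <- min(nchar(ref_prot), nchar(mut_prot))
  oracle_shift <- which(strsplit(substr(ref_prot, 1, k), "")[[1]] !=
                          strsplit(substr(mut_prot, 1, k), "")[[1]])[1]
  expect_identical(fs$first_shifted_codon, oracle_shift)
  oracle_stop <- regexpr("*", mut_prot, fixed = TRUE)
  if (oracle_stop > 0 && oracle_stop < nchar(ref_prot)) {
    expect_identical(fs$premature_stop, as.integer(oracle_stop))
  }

  # single-base deletion: premature stop matches the translation scan
  del <- classify_indel(cds, 256, delete_len = 1)
  expect_identical(del$category, "frameshift")
  mutd <- paste0(substr(cds, 1, 255), substr(cds, 257, nchar(cds)))
  protd <- translate_oracle(substr(mutd, 1, (nchar(mutd) %/% 3) * 3))
  stopd <- regexpr("*", protd, fixed = TRUE)
  if (stopd > 0 && stopd < regexpr("*", ref_prot, fixed = TRUE)) {
    expect_identical(del$premature_stop, as.integer(stopd))
  } else {
    expect_true(is.na(del$premature_stop))
  }
  expect_error(classify_indel(cds, nchar(cds), delete_len = 5), "bounds")
  expect_error(classify_indel(cds, 10), "exactly one")
})

test_that("minus-strand annotation equals the reverse-complement mirror", {
  set.seed(95)
  seq <- toy_cds(60)  # 180 nt
  L <- 1000
  start <- 301
  end <- start + nchar(seq) - 1
  minus <- gene_model("gm", "c", "-", data.frame(start = start, end = end),
                      cds_seq = seq)
  # mirror chromosome of length L: position p maps to L - p + 1
  plus <- gene_model("gm", "c", "+",
                     data.frame(start = L - end + 1, end = L - start + 1),
                     cds_seq = seq)
  for (i in 1:50) {
    pos <- sample(start:end, 1)
    ref <- mutmapr:::model_ref_base(minus, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a_minus <- annotate_variants(
      data.frame(chrom = "c", pos = pos, ref = ref, alt = alt),
      list(minus))
    comp <- function(b) chartr("ACGT", "TGCA", b)
    a_plus <- annotate_variants(
      data.frame(chrom = "c", pos = L - pos + 1, ref = comp(ref),
                 alt = comp(alt)),
      list(plus))
    expect_identical(a_minus$mutation_type, a_plus$mutation_type)
    expect_identical(a_minus$codon_index, a_plus$codon_index)
    expect_identical(a_minus$ref_aa, a_plus$ref_aa)
    expect_identical(a_minus$alt_aa, a_plus$alt_aa)
  }
})

test_that("gene models survive a GFF3 + FASTA round trip", {
  set.seed(97)
  chrom_seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                     collapse = "")
  plus <- gene_model("gplus", "toy", "+",
                     data.frame(start = c(201, 401), end = c(290, 460)),
                     utr5 = data.frame(start = 150, end = 200))
  minus <- gene_model("gminus", "toy", "-",
                      data.frame(start = c(1001, 1201),
                                 end = c(1090, 1260)))
  splice <- function(m) {
    pieces <- substring(chrom_seq, m$cds$start, m$cds$end)
    s <- paste(pieces, collapse = "")
    if (m$strand == "-") mutmapr:::reverse_complement(s) else s
  }
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_gene_models_gff3(list(plus, minus), gff)
  write_fasta(c(toy = chrom_seq), fa)
  back <- read_gene_models(gff, fa)
  ids <- vapply(back, `[[`, character(1), "gene_id")
  bp <- back[[which(ids == "gplus")]]
  bm <- back[[which(ids == "gminus")]]
  expect_equal(bp$cds, plus$cds)
  expect_identical(bp$strand, "+")
  expect_equal(bp$utr5, plus$utr5)
  expect_identical(bp$cds_seq, splice(plus))
  expect_equal(bm$cds, minus$cds)
  expect_identical(bm$strand, "-")
  expect_identical(bm$cds_seq, splice(minus))
})
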