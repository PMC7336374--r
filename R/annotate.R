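# Variant classification against gene models and coding-effect computation:
# region classes (exonic/intronic/UTR/up-downstream/intergenic), CDS
# coordinate mapping on either strand, and synonymous/nonsynonymous/
# stop-gain/frameshift calls under the standard genetic code.

#' Construct a gene model
#'
#' A strand-aware spliced CDS with genomic intervals, optionally carrying the
#' transcript-oriented CDS nucleotide sequence used for coding-effect calls.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with columns `start`, `end` (genomic, 1-based,
#'   inclusive), non-overlapping.
#' @param utr5,utr3 Optional UTR interval data.frames (same columns).
#' @param cds_seq Optional transcript-oriented CDS sequence (character or
#'   `DNAString`); its length must equal the summed CDS widths and be a
#'   multiple of 3.
#' @param complete If `TRUE`, require the sequence to begin with ATG and end
#'   with a stop codon.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, utr5 = NULL, utr3 = NULL,
                       cds_seq = NULL, complete = FALSE) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  if (any(cds$end < cds$start)) stop("CDS interval with end < start")
  if (nrow(cds) > 1 &&
      any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stop("CDS intervals overlap")
  }
  if (!is.null(cds_seq)) {
    cds_seq <- toupper(as.character(cds_seq))
    total <- sum(cds$end - cds$start + 1)
    if (nchar(cds_seq) != total) {
      stop("cds_seq length (", nchar(cds_seq),
           ") != summed CDS width (", total, ")")
    }
    if (nchar(cds_seq) %% 3 != 0) stop("CDS length not divisible by 3")
    if (complete) {
      if (substr(cds_seq, 1, 3) != "ATG") stop("CDS does not start with ATG")
      last <- substr(cds_seq, nchar(cds_seq) - 2, nchar(cds_seq))
      if (!last %in% c("TAA", "TAG", "TGA")) {
        stop("CDS does not end with a stop codon")
      }
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, utr5 = utr5, utr3 = utr3, cds_seq = cds_seq),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " ", x$chrom, ":", min(x$cds$start), "-",
      max(x$cds$end), " (", x$strand, "), ", nrow(x$cds), " CDS exon(s)",
      if (!is.null(x$cds_seq)) paste0(", ", nchar(x$cds_seq), " nt"), "\n",
      sep = "")
  invisible(x)
}

dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

gene_span <- function(model) {
  ivs <- rbind(model$cds[, c("start", "end")],
               if (!is.null(model$utr5)) model$utr5[, c("start", "end")],
               if (!is.null(model$utr3)) model$utr3[, c("start", "end")])
  c(min(ivs$start), max(ivs$end))
}

in_intervals <- function(pos, ivs) {
  !is.null(ivs) && nrow(ivs) > 0 && any(pos >= ivs$start & pos <= ivs$end)
}

#' Classify a genomic position against a set of gene models
#'
#' Assigns exactly one region class per position under the precedence
#' exonic > UTR > intronic > upstream/downstream (within `flank_bp` of the
#' gene span, strand-aware) > intergenic. Ties across genes are resolved to
#' the class of highest precedence, then to the gene whose transcription
#' start is nearest, then lexicographically by gene id.
#'
#' @param chrom,pos Genomic position (1-based).
#' @param gene_models List of [gene_model()]s.
#' @param flank_bp Width of the upstream/downstream flanks (default 1000 bp).
#' @return List with `class` (one of `exonic`, `UTR5`, `UTR3`, `intronic`,
#'   `upstream`, `downstream`, `intergenic`) and `gene_id` (`NA` for
#'   intergenic).
#' @export
locate_variant <- function(chrom, pos, gene_models, flank_bp = 1000) {
  chroms <- vapply(gene_models, function(m) m$chrom, character(1))
  if (!chrom %in% chroms) {
    stop("unknown chromosome for gene models: ", chrom)
  }
  prec <- c(exonic = 1, UTR5 = 2, UTR3 = 2, intronic = 3,
            upstream = 4, downstream = 4, intergenic = 5)
  best <- NULL
  for (m in gene_models[chroms == chrom]) {
    span <- gene_span(m)
    cls <- if (in_intervals(pos, m$cds)) {
      "exonic"
    } else if (in_intervals(pos, m$utr5)) {
      "UTR5"
    } else if (in_intervals(pos, m$utr3)) {
      "UTR3"
    } else if (pos >= span[1] && pos <= span[2]) {
      "intronic"
    } else {
      before <- pos < span[1] && pos >= span[1] - flank_bp
      after <- pos > span[2] && pos <= span[2] + flank_bp
      if (before) {
        if (m$strand == "+") "upstream" else "downstream"
      } else if (after) {
        if (m$strand == "+") "downstream" else "upstream"
      } else {
        next
      }
    }
    tss <- if (m$strand == "+") span[1] else span[2]
    hit <- list(class = cls, gene_id = m$gene_id, dist = abs(pos - tss))
    if (is.null(best) ||
        prec[[cls]] < prec[[best$class]] ||
        (prec[[cls]] == prec[[best$class]] &&
         (hit$dist < best$dist ||
          (hit$dist == best$dist && hit$gene_id < best$gene_id)))) {
      best <- hit
    }
  }
  if (is.null(best)) {
    list(class = "intergenic", gene_id = NA_character_)
  } else {
    best[c("class", "gene_id")]
  }
}

#' Map a genomic position into spliced CDS coordinates
#'
#' Returns the 1-based offset of a genomic position into the spliced CDS in
#' transcript orientation: for minus-strand genes the count starts from the
#' transcript 5' end (the highest genomic coordinate).
#'
#' @param chrom,pos Genomic position (1-based); must lie in a CDS interval.
#' @param model A [gene_model()].
#' @return Integer CDS coordinate.
#' @export
cds_position <- function(chrom, pos, model) {
  if (chrom != model$chrom || !in_intervals(pos, model$cds)) {
    stop("position ", chrom, ":", pos, " is not in the CDS of ",
         model$gene_id)
  }
  w <- model$cds$end - model$cds$start + 1L
  i <- which(pos >= model$cds$start & pos <= model$cds$end)
  if (model$strand == "+") {
    before <- if (i > 1) sum(w[seq_len(i - 1L)]) else 0L
    as.integer(before + (pos - model$cds$start[i] + 1L))
  } else {
    k <- nrow(model$cds)
    after <- if (i < k) sum(w[seq(i + 1L, k)]) else 0L
    as.integer(after + (model$cds$end[i] - pos + 1L))
  }
}

# Inverse of cds_position: genomic coordinate of a CDS offset.
genomic_position <- function(model, cds_pos) {
  w <- model$cds$end - model$cds$start + 1L
  if (cds_pos < 1 || cds_pos > sum(w)) stop("cds_pos outside CDS")
  if (model$strand == "+") {
    cum <- cumsum(w)
    i <- which(cds_pos <= cum)[1]
    before <- if (i > 1) cum[i - 1L] else 0L
    as.integer(model$cds$start[i] + (cds_pos - before) - 1L)
  } else {
    wr <- rev(w)
    cum <- cumsum(wr)
    j <- which(cds_pos <= cum)[1]
    before <- if (j > 1) cum[j - 1L] else 0L
    i <- nrow(model$cds) - j + 1L
    as.integer(model$cds$end[i] - (cds_pos - before) + 1L)
  }
}

# Genomic-strand reference base at a genomic position inside the CDS.
model_ref_base <- function(model, pos) {
  cp <- cds_position(model$chrom, pos, model)
  b <- substr(model$cds_seq, cp, cp)
  if (model$strand == "-") dna_complement(b) else b
}

#' Codon index of a CDS position
#'
#' `floor((cds_pos - 1) / 3) + 1`: CDS position 745 lies in codon 249.
#'
#' @param cds_pos 1-based position in the spliced CDS.
#' @return Integer codon index.
#' @export
codon_index <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("cds_pos must be >= 1")
  as.integer((cds_pos - 1) %/% 3 + 1)
}

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Coding effect of a single-base substitution
#'
#' Extracts the containing codon, applies the substitution, and translates
#' both codons under the standard genetic code. `ref` and `alt` are
#' transcript-oriented.
#'
#' @param cds_seq Transcript-oriented CDS sequence.
#' @param cds_pos 1-based CDS position of the substituted base.
#' @param ref,alt Reference and alternate bases (transcript strand).
#' @return List of class `coding_effect`: `cds_pos`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, and `category` in
#'   `{synonymous, nonsynonymous, stop_gain}` (stop-loss substitutions are
#'   reported as nonsynonymous).
#' @export
classify_substitution <- function(cds_seq, cds_pos, ref, alt) {
  cds_seq <- toupper(as.character(cds_seq))
  if (cds_pos < 1 || cds_pos > nchar(cds_seq)) stop("cds_pos out of bounds")
  have <- substr(cds_seq, cds_pos, cds_pos)
  if (have != toupper(ref)) {
    stop("reference mismatch at CDS ", cds_pos, ": sequence has ", have,
         ", variant says ", ref, " (coordinate or strand error)")
  }
  ci <- codon_index(cds_pos)
  off <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- toupper(alt)
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  category <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "stop_gain"
  } else {
    "nonsynonymous"
  }
  structure(list(cds_pos = as.integer(cds_pos), codon_index = ci,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, category = category),
            class = "coding_effect")
}

#' Coding effect of a small insertion or deletion in the CDS
#'
#' Builds the mutated CDS (`insert` places bases immediately after
#' `cds_pos`; `delete_len` removes bases starting at `cds_pos`), re-translates
#' from codon 1, and reports the codon containing the edit point, the first
#' codon whose amino acid differs from the reference protein, and the codon
#' index of the first stop in the mutated frame when it arrives earlier than
#' the reference stop.
#'
#' @param cds_seq Transcript-oriented CDS sequence.
#' @param cds_pos 1-based CDS anchor position of the edit.
#' @param insert Bases to insert after `cds_pos` (exclusive with
#'   `delete_len`).
#' @param delete_len Number of bases to delete starting at `cds_pos`.
#' @return List of class `coding_effect` with `category` (`frameshift` or
#'   `inframe_indel`), `edit_codon`, `first_shifted_codon` (`NA` if the
#'   protein is unchanged up to the shorter length) and `premature_stop`
#'   (`NA` if the mutated frame stops no earlier than the reference).
#' @export
classify_indel <- function(cds_seq, cds_pos, insert = NULL,
                           delete_len = NULL) {
  cds_seq <- toupper(as.character(cds_seq))
  n <- nchar(cds_seq)
  if (is.null(insert) == is.null(delete_len)) {
    stop("give exactly one of `insert`, `delete_len`")
  }
  if (!is.null(insert)) {
    if (cds_pos < 0 || cds_pos > n) stop("insertion point out of bounds")
    insert <- toupper(as.character(insert))
    mut <- paste0(substr(cds_seq, 1, cds_pos), insert,
                  substr(cds_seq, cds_pos + 1, n))
    len <- nchar(insert)
  } else {
    if (cds_pos < 1 || cds_pos + delete_len - 1 > n) {
      stop("deletion out of CDS bounds")
    }
    mut <- paste0(substr(cds_seq, 1, cds_pos - 1),
                  substr(cds_seq, cds_pos + delete_len, n))
    len <- delete_len
  }
  ref_aa <- translate_codons(cds_seq)
  mut_aa <- translate_codons(mut)
  k <- min(length(ref_aa), length(mut_aa))
  diff <- which(ref_aa[seq_len(k)] != mut_aa[seq_len(k)])
  first_shifted <- if (length(diff)) diff[1] else NA_integer_
  ref_stop <- which(ref_aa == "*")
  mut_stop <- which(mut_aa == "*")
  premature <- if (length(mut_stop) &&
                   (!length(ref_stop) || mut_stop[1] < ref_stop[1])) {
    mut_stop[1]
  } else {
    NA_integer_
  }
  structure(list(cds_pos = as.integer(cds_pos),
                 edit_codon = codon_index(max(cds_pos, 1L)),
                 category = if (len %% 3 == 0) "inframe_indel" else
                   "frameshift",
                 first_shifted_codon = first_shifted,
                 premature_stop = premature,
                 mutated_protein = paste(mut_aa, collapse = "")),
            class = "coding_effect")
}

#' @export
print.coding_effect <- function(x, ...) {
  if (!is.null(x$ref_codon)) {
    cat("<coding_effect> ", x$category, ": codon ", x$codon_index, " ",
        x$ref_codon, ">", x$alt_codon, " (", x$ref_aa, ">", x$alt_aa, ")\n",
        sep = "")
  } else {
    cat("<coding_effect> ", x$category, " at CDS ", x$cds_pos,
        " (edit codon ", x$edit_codon, ", first shifted ",
        x$first_shifted_codon, ", premature stop ", x$premature_stop, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Annotate variants for region class and coding effect
#'
#' For every variant row, [locate_variant()] assigns the region class; for
#' exonic variants of a model carrying its CDS sequence the substitution is
#' classified with [classify_substitution()] (alleles are complemented for
#' minus-strand genes). Mutation types are reported as `"S"`
#' (synonymous), `"NS"` (nonsynonymous) or `"stop_gain"`.
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param gene_models List of [gene_model()]s.
#' @param flank_bp Flank width for up/downstream classification.
#' @return data.frame with columns chrom, pos, ref, alt, region_class,
#'   gene_id, cds_pos, codon_index, ref_aa, alt_aa, mutation_type.
#' @export
annotate_variants <- function(variants, gene_models, flank_bp = 1000) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  by_id <- stats::setNames(gene_models,
                           vapply(gene_models, `[[`, character(1), "gene_id"))
  n <- nrow(variants)
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    region_class = NA_character_, gene_id = NA_character_,
                    cds_pos = NA_integer_, codon_index = NA_integer_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    mutation_type = NA_character_)
  for (i in seq_len(n)) {
    loc <- locate_variant(variants$chrom[i], variants$pos[i], gene_models,
                          flank_bp = flank_bp)
    out$region_class[i] <- loc$class
    out$gene_id[i] <- loc$gene_id
    if (loc$class == "exonic") {
      m <- by_id[[loc$gene_id]]
      if (!is.null(m$cds_seq)) {
        cp <- cds_position(variants$chrom[i], variants$pos[i], m)
        ref_t <- variants$ref[i]
        alt_t <- variants$alt[i]
        if (m$strand == "-") {
          ref_t <- dna_complement(ref_t)
          alt_t <- dna_complement(alt_t)
        }
        eff <- classify_substitution(m$cds_seq, cp, ref_t, alt_t)
        out$cds_pos[i] <- eff$cds_pos
        out$codon_index[i] <- eff$codon_index
        out$ref_aa[i] <- eff$ref_aa
        out$alt_aa[i] <- eff$alt_aa
        out$mutation_type[i] <- switch(eff$category,
                                       synonymous = "S",
                                       nonsynonymous = "NS",
                                       stop_gain = "stop_gain")
      }
    }
  }
  out
}

#' Read gene models from GFF3 (and optionally attach CDS sequence)
#'
#' CDS features are grouped by their `Parent` (falling back to `ID` or
#' `gene_id`); `five_prime_UTR`/`three_prime_UTR` features become UTR
#' intervals. When a FASTA file is given, the spliced transcript-oriented CDS
#' sequence is extracted and attached.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Optional path to the genome FASTA.
#' @return List of [gene_model()]s.
#' @export
read_gene_models <- function(gff_path, fasta_path = NULL) {
  gr <- rtracklayer::import(gff_path)
  md <- S4Vectors::mcols(gr)
  parent_of <- function(i) {
    p <- if ("Parent" %in% names(md)) unlist(md$Parent[i]) else NULL
    if (length(p)) as.character(p[1])
    else if ("ID" %in% names(md) && !is.na(md$ID[i])) as.character(md$ID[i])
    else "gene1"
  }
  seqs <- if (!is.null(fasta_path)) {
    Biostrings::readDNAStringSet(fasta_path)
  } else {
    NULL
  }
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  types <- as.character(md$type)
  take <- function(type) which(types == type)
  groups <- list()
  for (i in c(take("CDS"), take("five_prime_UTR"), take("three_prime_UTR"))) {
    pid <- parent_of(i)
    groups[[pid]] <- c(groups[[pid]], i)
  }
  lapply(names(groups), function(pid) {
    idx <- groups[[pid]]
    sub <- gr[idx]
    st <- as.character(BiocGenerics::strand(sub))
    strand <- if (any(st == "-")) "-" else "+"
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    iv <- function(type) {
      sel <- types[idx] == type
      if (!any(sel)) return(NULL)
      data.frame(start = BiocGenerics::start(sub)[sel],
                 end = BiocGenerics::end(sub)[sel])
    }
    cds <- iv("CDS")
    if (is.null(cds)) stop("no CDS features for ", pid)
    cds <- cds[order(cds$start), , drop = FALSE]
    cds_seq <- NULL
    if (!is.null(seqs) && chrom %in% names(seqs)) {
      pieces <- substring(as.character(seqs[[chrom]]), cds$start, cds$end)
      cds_seq <- paste(pieces, collapse = "")
      if (strand == "-") cds_seq <- reverse_complement(cds_seq)
    }
    gene_model(gene_id = pid, chrom = chrom, strand = strand, cds = cds,
               utr5 = iv("five_prime_UTR"), utr3 = iv("three_prime_UTR"),
               cds_seq = cds_seq)
  })
}

#' Write gene models as GFF3
#'
#' @param models List of [gene_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- gene_span(m)
    lines <- c(lines,
               paste(m$chrom, "mutmapr", "gene", span[1], span[2], ".",
                     m$strand, ".", paste0("ID=", m$gene_id), sep = "\t"))
    feat <- function(type, ivs) {
      if (is.null(ivs) || nrow(ivs) == 0) return(character(0))
      paste(m$chrom, "mutmapr", type, ivs$start, ivs$end, ".", m$strand,
            if (type == "CDS") "0" else ".",
            paste0("Parent=", m$gene_id), sep = "\t")
    }
    lines <- c(lines, feat("five_prime_UTR", m$utr5), feat("CDS", m$cds),
               feat("three_prime_UTR", m$utr3))
  }
  writeLines(lines, path)
  invisible(path)
}
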