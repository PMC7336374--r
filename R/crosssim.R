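# Forward simulator: EMS mutagenesis, mutant x WT F2 cross, phenotype bulks,
# and bulk read counts. All randomness flows through R's RNG so a single
# set.seed() makes every artifact byte-reproducible.

EMS_ALT <- c(G = "A", C = "T")
DNA_BASES <- c("A", "C", "G", "T")

#' Simulate gene models over the genome's CDS intervals
#'
#' Each CDS interval of the [genome_spec()] becomes one single-exon gene with
#' a random coding sequence (ATG, interior codons drawn from the 61 non-stop
#' codons, TAA), on alternating strands. These models supply reference bases
#' for variants falling inside coding sequence and are the substrate for
#' coding-effect annotation.
#'
#' @param genome A [genome_spec()] with non-empty `gene_intervals`.
#' @param seed Optional integer seed.
#' @return A list of [gene_model()] objects.
#' @export
simulate_gene_models <- function(genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gi <- genome$gene_intervals
  if (is.null(gi) || nrow(gi) == 0) {
    stop("genome has no gene_intervals to build gene models from")
  }
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  lapply(seq_len(nrow(gi)), function(i) {
    width <- gi$end[i] - gi$start[i] + 1L
    n_codon <- width %/% 3L
    if (n_codon < 3L) stop("gene interval ", i, " too short for a CDS")
    end <- gi$start[i] + n_codon * 3L - 1L
    seq <- paste0("ATG",
                  paste(sample(sense, n_codon - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    gene_model(gene_id = sprintf("GENE%03d", i),
               chrom = gi$chrom[i],
               strand = if (i %% 2L == 1L) "+" else "-",
               cds = data.frame(start = gi$start[i], end = end),
               cds_seq = seq, complete = TRUE)
  })
}

#' Simulate a set of homozygous EMS-induced variants in the mutant line
#'
#' Draws `n_variants` SNPs private to the mutant parent. A configurable
#' fraction follows the EMS mutational spectrum (G>A / C>T transitions on the
#' genomic strand); exactly one variant is flagged causal and placed inside a
#' CDS interval. When `models` are supplied the causal site is chosen so that
#' its EMS transition is a nonsynonymous substitution, and reference bases of
#' all variants falling in coding sequence agree with the model sequences.
#'
#' @param genome A [genome_spec()] with at least one CDS interval.
#' @param n_variants Number of variants (>= 1).
#' @param spectrum_fraction Fraction of variants drawn from the EMS
#'   G:C->A:T spectrum (default 1, matching EMS chemistry).
#' @param seed Optional integer seed.
#' @param models Optional list of [gene_model()]s (e.g. from
#'   [simulate_gene_models()]).
#' @return An object of class `ems_variant_set`: list with `variants`
#'   (data.frame chrom, pos, ref, alt, ems), `causal_index`, and
#'   `spectrum_fraction`.
#' @export
simulate_ems_variants <- function(genome, n_variants, spectrum_fraction = 1,
                                  seed = NULL, models = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_variants >= 1,
            spectrum_fraction >= 0, spectrum_fraction <= 1)
  gi <- genome$gene_intervals
  if (is.null(gi) || nrow(gi) == 0) {
    stop("genome has no CDS interval: cannot place a coding causal SNP")
  }

  causal <- draw_causal_site(gi, models)

  n_bg <- n_variants - 1L
  bg <- if (n_bg > 0) {
    draw_background_variants(genome, n_bg, spectrum_fraction, models,
                             exclude = causal)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), ems = logical())
  }

  v <- rbind(bg,
             data.frame(chrom = causal$chrom, pos = causal$pos,
                        ref = causal$ref, alt = causal$alt, ems = TRUE))
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v,
                 causal_index = which(v$chrom == causal$chrom &
                                        v$pos == causal$pos),
                 spectrum_fraction = spectrum_fraction),
            class = "ems_variant_set")
}

#' @export
print.ems_variant_set <- function(x, ...) {
  ca <- x$variants[x$causal_index, ]
  cat("<ems_variant_set> ", nrow(x$variants), " variants; causal ",
      ca$chrom, ":", ca$pos, " ", ca$ref, ">", ca$alt, "\n", sep = "")
  invisible(x)
}

# Pick the causal site: an EMS-compatible CDS position whose transition is
# nonsynonymous when model sequences are available.
draw_causal_site <- function(gi, models) {
  if (!is.null(models)) {
    cand <- do.call(rbind, lapply(models, function(m) {
      s <- strsplit(m$cds_seq, "")[[1]]
      n <- length(s)
      idx <- which(s %in% c("C", "G"))
      if (length(idx) == 0) return(NULL)
      alt_t <- unname(EMS_ALT[s[idx]])
      ci <- (idx - 1L) %/% 3L + 1L
      off <- (idx - 1L) %% 3L + 1L
      ref_codon <- substring(m$cds_seq, (ci - 1L) * 3L + 1L, ci * 3L)
      alt_codon <- ref_codon
      substr(alt_codon, off, off) <- alt_t
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      keep <- ref_aa != alt_aa & ref_aa != "*" & alt_aa != "*"
      if (!any(keep)) return(NULL)
      idx <- idx[keep]
      gpos <- vapply(idx, function(p) genomic_position(m, p), integer(1))
      ref_g <- s[idx]
      alt_g <- unname(EMS_ALT[ref_g])
      if (m$strand == "-") {
        ref_g <- dna_complement(ref_g)
        alt_g <- dna_complement(alt_g)
      }
      data.frame(chrom = m$chrom, pos = gpos, ref = ref_g, alt = alt_g)
    }))
    if (is.null(cand) || nrow(cand) == 0) {
      stop("no CDS site admits a nonsynonymous EMS transition; ",
           "genome/gene models are misconfigured")
    }
    cand[sample.int(nrow(cand), 1L), , drop = FALSE]
  } else {
    i <- sample.int(nrow(gi), 1L, prob = gi$end - gi$start + 1)
    pos <- gi$start[i] + sample.int(gi$end[i] - gi$start[i] + 1L, 1L) - 1L
    ref <- sample(c("C", "G"), 1L)
    data.frame(chrom = gi$chrom[i], pos = pos, ref = ref,
               alt = unname(EMS_ALT[ref]))
  }
}

# Genome-wide background variants; rejection sampling keeps CDS-overlapping
# variants consistent with model reference bases and the per-variant
# mutation type (EMS transition vs other substitution).
draw_background_variants <- function(genome, n, spectrum_fraction, models,
                                     exclude) {
  chroms <- genome$chromosomes
  is_ems <- stats::runif(n) < spectrum_fraction
  taken <- paste0(exclude$chrom, ":", exclude$pos)
  out <- vector("list", n)
  filled <- 0L
  tries <- 0L
  while (filled < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop("could not place background variants")
    ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
    chrom <- chroms$name[ci]
    pos <- sample.int(chroms$length[ci], 1L)
    key <- paste0(chrom, ":", pos)
    if (key %in% taken) next
    ems <- is_ems[filled + 1L]
    m <- model_at(models, chrom, pos)
    if (!is.null(m)) {
      ref <- model_ref_base(m, pos)
      if (ems) {
        if (!ref %in% c("C", "G")) next
        alt <- unname(EMS_ALT[ref])
      } else {
        alt <- sample(non_ems_alts(ref), 1L)
      }
    } else {
      if (ems) {
        ref <- sample(c("C", "G"), 1L)
        alt <- unname(EMS_ALT[ref])
      } else {
        ref <- sample(DNA_BASES, 1L)
        alt <- sample(non_ems_alts(ref), 1L)
      }
    }
    filled <- filled + 1L
    taken <- c(taken, key)
    out[[filled]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = alt, ems = ems)
  }
  do.call(rbind, out)
}

# Alternate alleles that are NOT the EMS transition for this ref base.
non_ems_alts <- function(ref) {
  alts <- setdiff(DNA_BASES, ref)
  if (ref %in% names(EMS_ALT)) alts <- setdiff(alts, EMS_ALT[[ref]])
  alts
}

model_at <- function(models, chrom, pos) {
  if (is.null(models)) return(NULL)
  for (m in models) {
    if (m$chrom == chrom && any(pos >= m$cds$start & pos <= m$cds$end)) {
      return(m)
    }
  }
  NULL
}

#' Simulate F1 gametes under a Poisson (no-interference) crossover model
#'
#' Each gamete inherits, per chromosome, a random parental haplotype that
#' switches at crossover points; the crossover count is Poisson with mean
#' equal to the chromosome's genetic length in Morgans, so the recombination
#' fraction between two loci at map distance `d` follows Haldane's map
#' function `(1 - exp(-2d))/2` in expectation.
#'
#' @param variants An `ems_variant_set` (or its `variants` data.frame).
#' @param genome The [genome_spec()].
#' @param n Number of gametes.
#' @return Integer matrix `n x n_variants`; 1 = mutant-line allele.
#' @export
simulate_gametes <- function(variants, genome, n) {
  v <- variant_frame(variants)
  chroms <- unique(v$chrom)
  idx <- lapply(chroms, function(ch) which(v$chrom == ch))
  d <- lapply(chroms, function(ch) morgan_pos(genome, v$pos[v$chrom == ch]))
  L <- vapply(chroms, function(ch) morgan_length(genome, ch), numeric(1))
  out <- matrix(0L, nrow = n, ncol = nrow(v))
  for (g in seq_len(n)) {
    for (ci in seq_along(chroms)) {
      k <- stats::rpois(1L, L[ci])
      xo <- if (k > 0) sort(stats::runif(k, 0, L[ci])) else numeric(0)
      start <- stats::rbinom(1L, 1L, 0.5)
      out[g, idx[[ci]]] <- (start + findInterval(d[[ci]], xo)) %% 2L
    }
  }
  out
}

variant_frame <- function(variants) {
  if (inherits(variants, "ems_variant_set")) variants$variants else variants
}

#' Simulate an F2 population from the mutant x wild-type cross
#'
#' The F1 is heterozygous at every mutant-line variant; each F2 individual is
#' the sum of two independent gametes drawn by [simulate_gametes()].
#' Phenotypes follow the fully penetrant recessive rule at the causal SNP
#' (mutant iff homozygous for the mutant allele), with an optional
#' misclassification probability.
#'
#' @param variants An `ems_variant_set`.
#' @param genome The [genome_spec()].
#' @param n Population size.
#' @param seed Optional integer seed.
#' @param misclass_rate Probability a phenotype is recorded wrongly
#'   (default 0).
#' @return An object of class `f2_population`: list with `genotypes`
#'   (integer matrix, mutant-allele dosage 0/1/2), `phenotype`
#'   (`"mutant"`/`"wild_type"`), `variants`, `genome`.
#' @export
simulate_f2_population <- function(variants, genome, n, seed = NULL,
                                   misclass_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_gametes(variants, genome, n) +
    simulate_gametes(variants, genome, n)
  ph <- assign_phenotype(geno[, variants$causal_index], misclass_rate)
  structure(list(genotypes = geno, phenotype = ph, variants = variants,
                 genome = genome),
            class = "f2_population")
}

#' Assign phenotypes by the recessive rule at the causal locus
#'
#' @param causal_genotype Integer vector of mutant-allele dosages (0/1/2) at
#'   the causal SNP.
#' @param misclass_rate Probability of recording the opposite phenotype.
#' @return Character vector, `"mutant"` or `"wild_type"`.
#' @export
assign_phenotype <- function(causal_genotype, misclass_rate = 0) {
  if (any(is.na(causal_genotype)) ||
      !all(causal_genotype %in% 0:2)) {
    stop("causal genotypes must be 0, 1 or 2")
  }
  ph <- ifelse(causal_genotype == 2L, "mutant", "wild_type")
  if (misclass_rate > 0) {
    flip <- stats::runif(length(ph)) < misclass_rate
    ph[flip] <- ifelse(ph[flip] == "mutant", "wild_type", "mutant")
  }
  ph
}

#' Sample phenotype-selected bulks from an F2 population
#'
#' Draws, without replacement, `n_mp` mutant-phenotype and `n_wp`
#' wild-type-phenotype individuals (default 30 each, the bulk size used for
#' whole-genome sequencing of the cross).
#'
#' @param population An `f2_population`.
#' @param n_mp,n_wp Bulk sizes.
#' @return List with integer member indices `mp` and `wp`.
#' @export
sample_bulks <- function(population, n_mp = 30, n_wp = 30) {
  stopifnot(n_mp >= 1, n_wp >= 1)
  mut <- which(population$phenotype == "mutant")
  wt <- which(population$phenotype == "wild_type")
  if (length(mut) < n_mp) {
    stop("mutant-phenotype class has only ", length(mut),
         " individuals; need ", n_mp)
  }
  if (length(wt) < n_wp) {
    stop("wild-type-phenotype class has only ", length(wt),
         " individuals; need ", n_wp)
  }
  list(mp = sort(mut[sample.int(length(mut), n_mp)]),
       wp = sort(wt[sample.int(length(wt), n_wp)]))
}

#' Simulate bulk sequencing read counts at every variant
#'
#' Per site and bulk, total depth is Poisson(`mean_depth`) and each read
#' carries the mutant allele with probability `q (1 - e) + (1 - q) e`, where
#' `q` is the bulk mutant-allele frequency and `e` the per-read miscall rate.
#' Zero-depth sites are emitted with zero counts; the depth filter downstream
#' is the single place coverage decisions happen.
#'
#' @param population An `f2_population`.
#' @param bulks Member lists from [sample_bulks()].
#' @param mean_depth Poisson mean reads per site per bulk.
#' @param error_rate Per-read miscall probability in `[0, 0.5)`.
#' @return Allele-count table: data.frame with columns chrom, pos, ref, alt,
#'   wp_ref, wp_alt, mp_ref, mp_alt, sorted by (chrom, pos).
#' @export
simulate_allele_counts <- function(population, bulks, mean_depth = 30,
                                   error_rate = 0.005) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  v <- variant_frame(population$variants)
  bulk_counts <- function(members) {
    g <- population$genotypes[members, , drop = FALSE]
    q <- colSums(g) / (2 * length(members))
    depth <- stats::rpois(nrow(v), mean_depth)
    p <- q * (1 - error_rate) + (1 - q) * error_rate
    alt <- stats::rbinom(nrow(v), depth, p)
    list(ref = depth - alt, alt = alt)
  }
  wp <- bulk_counts(bulks$wp)
  mp <- bulk_counts(bulks$mp)
  out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    wp_ref = wp$ref, wp_alt = wp$alt,
                    mp_ref = mp$ref, mp_alt = mp$alt)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Run the full cross simulation
#'
#' EMS variants -> F2 population -> phenotype bulks -> bulk read counts,
#' with ground truth recorded for validation. The default population size is
#' 208 with phenotype counts drawn by 3:1 segregation; `match_paper = TRUE`
#' instead fixes the composition at 164 wild-type : 44 mutant. If a random
#' draw leaves a phenotype class smaller than its bulk, additional F2
#' individuals are simulated until both bulks can be filled.
#'
#' @param genome A [genome_spec()]; defaults to [default_genome()].
#' @param n_variants Number of EMS SNPs.
#' @param spectrum_fraction Fraction of variants on the G:C->A:T spectrum.
#' @param pop_size F2 population size.
#' @param n_mp,n_wp Bulk sizes.
#' @param mean_depth,error_rate Sequencing model, see
#'   [simulate_allele_counts()].
#' @param misclass_rate Phenotyping error probability.
#' @param match_paper Fix the population at 164 wild-type and 44 mutant
#'   individuals rather than drawing the composition by segregation.
#' @param models Gene models; built by [simulate_gene_models()] when `NULL`.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return Object of class `mutmap_sim`: list with `counts` (allele-count
#'   table), `truth` (causal site, genotype matrix, phenotypes, bulk
#'   members, seed), `variants`, `models`, `population`.
#' @export
simulate_cross <- function(genome = default_genome(), n_variants = 300,
                           spectrum_fraction = 1, pop_size = 208,
                           n_mp = 30, n_wp = 30, mean_depth = 30,
                           error_rate = 0.005, misclass_rate = 0,
                           match_paper = FALSE, models = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(models)) models <- simulate_gene_models(genome)
  variants <- simulate_ems_variants(genome, n_variants, spectrum_fraction,
                                    models = models)
  pop <- simulate_f2_population(variants, genome, pop_size,
                                misclass_rate = misclass_rate)
  need <- function(p) {
    sum(p$phenotype == "mutant") < max(n_mp, if (match_paper) 44 else 0) ||
      sum(p$phenotype == "wild_type") < max(n_wp, if (match_paper) 164 else 0)
  }
  grown <- 0L
  while (need(pop)) {
    grown <- grown + 32L
    if (grown > 200L * pop_size) stop("population failed to fill both bulks")
    extra <- simulate_f2_population(variants, genome, 32L,
                                    misclass_rate = misclass_rate)
    pop$genotypes <- rbind(pop$genotypes, extra$genotypes)
    pop$phenotype <- c(pop$phenotype, extra$phenotype)
  }
  if (match_paper) {
    keep <- c(which(pop$phenotype == "wild_type")[1:164],
              which(pop$phenotype == "mutant")[1:44])
    keep <- sort(keep)
    pop$genotypes <- pop$genotypes[keep, , drop = FALSE]
    pop$phenotype <- pop$phenotype[keep]
  }
  bulks <- sample_bulks(pop, n_mp = n_mp, n_wp = n_wp)
  counts <- simulate_allele_counts(pop, bulks, mean_depth = mean_depth,
                                   error_rate = error_rate)
  ca <- variant_frame(variants)[variants$causal_index, ]
  truth <- list(causal = list(chrom = ca$chrom, pos = ca$pos),
                causal_index = variants$causal_index,
                genotypes = pop$genotypes,
                phenotype = pop$phenotype,
                mp_members = bulks$mp, wp_members = bulks$wp,
                seed = seed)
  structure(list(counts = counts, truth = truth, variants = variants,
                 models = models, population = pop,
                 params = list(n_variants = n_variants,
                               spectrum_fraction = spectrum_fraction,
                               pop_size = pop_size, n_mp = n_mp, n_wp = n_wp,
                               mean_depth = mean_depth,
                               error_rate = error_rate,
                               misclass_rate = misclass_rate,
                               match_paper = match_paper, seed = seed)),
            class = "mutmap_sim")
}

#' @export
print.mutmap_sim <- function(x, ...) {
  cat("<mutmap_sim> ", nrow(x$counts), " variants, ",
      length(x$truth$phenotype), " F2 individuals (",
      sum(x$truth$phenotype == "mutant"), " mutant); causal ",
      x$truth$causal$chrom, ":", x$truth$causal$pos, "\n", sep = "")
  invisible(x)
}
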