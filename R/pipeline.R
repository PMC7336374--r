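# Orchestration: one resolved configuration object, the end-to-end pipeline
# (simulate/ingest -> index -> windows -> regions -> candidates -> annotate),
# and the packaged worked-example demo.

#' Pipeline configuration
#'
#' Collects every tunable of the simulator, the SNP-index statistics and the
#' candidate filter in one validated object. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return List of class `mutmap_config`.
#' @details Defaults: `window_bp = 1e6`, `step_bp = 1e3` (the sliding
#'   window); `index_threshold = 0.9`, `min_windows = 1` (region
#'   detection); `mp_min_index = 1`, `mp_tolerance = 0.1`,
#'   `wp_band = c(1/6, 1/2)`, `alpha = 0.05`, `min_depth = 10`,
#'   `require_nonsynonymous = TRUE`, `region = NULL` (candidate filter);
#'   `flank_bp = 1000` (annotation); `n_variants = 300`,
#'   `spectrum_fraction = 1`, `pop_size = 208`, `n_mp = 30`, `n_wp = 30`,
#'   `mean_depth = 30`, `error_rate = 0.005`, `misclass_rate = 0`,
#'   `recomb_rate = 4`, `match_paper = FALSE` (simulator); `seed = 1`.
#' @export
mutmap_config <- function(...) {
  defaults <- list(
    window_bp = 1e6, step_bp = 1e3,
    index_threshold = 0.9, min_windows = 1,
    mp_min_index = 1, mp_tolerance = 0.1,
    wp_band = c(1 / 6, 1 / 2), alpha = 0.05, min_depth = 10,
    require_nonsynonymous = TRUE, region = NULL,
    flank_bp = 1000,
    n_variants = 300, spectrum_fraction = 1, pop_size = 208,
    n_mp = 30, n_wp = 30, mean_depth = 30, error_rate = 0.005,
    misclass_rate = 0, recomb_rate = 4, match_paper = FALSE,
    seed = 1)
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == ""))) {
    stop("all configuration values must be named")
  }
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)
  structure(cfg, class = "mutmap_config")
}

#' Read a pipeline configuration from a key = value text file
#'
#' Blank lines and `#` comments are ignored; values are parsed as logicals,
#' numbers, comma-separated numeric vectors, or strings. Unknown keys are
#' rejected by [mutmap_config()].
#'
#' @param path Path to the configuration file.
#' @param ... Overrides taking precedence over the file.
#' @return A `mutmap_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  parse_val <- function(s) {
    s <- trimws(s)
    if (toupper(s) %in% c("TRUE", "FALSE")) return(as.logical(toupper(s)))
    if (grepl(",", s) && !grepl(":", s)) {
      v <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
      if (!anyNA(v)) return(v)
    }
    n <- suppressWarnings(as.numeric(s))
    if (!is.na(n)) return(n)
    s
  }
  vals <- stats::setNames(lapply(kv, function(m) parse_val(m[3])),
                          vapply(kv, `[`, character(1), 2))
  vals <- utils::modifyList(vals, list(...), keep.null = TRUE)
  do.call(mutmap_config, vals)
}

format_config <- function(cfg) {
  vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ",
           if (is.null(v)) "NULL" else paste(format(v, digits = 10),
                                             collapse = ","))
  }, character(1))
}

#' Run the MutMap pipeline end to end
#'
#' Simulates a cross (or ingests a supplied allele-count table), computes
#' per-SNP indices for both bulks, applies the depth filter, smooths the
#' MP-bulk index with the sliding window, detects the candidate region, and
#' applies the dual-bulk causal filter with coding-effect annotation. When
#' no `region` is configured, the top detected region becomes the
#' restriction.
#'
#' @param config A [mutmap_config()].
#' @param counts Optional allele-count table; when `NULL`, a cross is
#'   simulated with the configured parameters.
#' @param models Gene models for annotation; taken from the simulation when
#'   counts are simulated.
#' @param genome A [genome_spec()]; defaults to [default_genome()] with the
#'   configured recombination rate.
#' @param out_dir Optional directory; when given, all artifacts are written
#'   (per-SNP index TSV, window series TSV, region BED, candidate report
#'   TSV, counts as simplified VCF and TSV, ground truth TSV, and a run log
#'   embedding the fully resolved configuration and seed).
#' @return Object of class `mutmap_run`: list with `counts`, `index`,
#'   `windows`, `regions`, `candidates`, `truth` (NULL for ingested
#'   counts), `config`, `log`.
#' @export
run_pipeline <- function(config = mutmap_config(), counts = NULL,
                         models = NULL, genome = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "mutmap_config"))
  if (is.null(genome)) {
    genome <- default_genome(recomb_rate = config$recomb_rate)
  }
  truth <- NULL
  sim <- NULL
  if (is.null(counts)) {
    sim <- simulate_cross(genome = genome,
                          n_variants = config$n_variants,
                          spectrum_fraction = config$spectrum_fraction,
                          pop_size = config$pop_size,
                          n_mp = config$n_mp, n_wp = config$n_wp,
                          mean_depth = config$mean_depth,
                          error_rate = config$error_rate,
                          misclass_rate = config$misclass_rate,
                          match_paper = config$match_paper,
                          models = models, seed = config$seed)
    counts <- sim$counts
    models <- sim$models
    truth <- sim$truth
  }
  idx <- compute_index_table(counts)
  filt <- suppressMessages(filter_sites(idx, min_depth = config$min_depth))
  chrom_len <- function(ch) {
    genome$chromosomes$length[match(ch, genome$chromosomes$name)]
  }
  windows <- do.call(rbind, lapply(unique(filt$chrom), function(ch) {
    sliding_window_mean(filt, ch, chrom_length = chrom_len(ch),
                        window_bp = config$window_bp,
                        step_bp = config$step_bp)
  }))
  regions <- detect_candidate_regions(windows, bulk = "mp",
                                      index_threshold = config$index_threshold,
                                      min_windows = config$min_windows)
  region <- config$region
  if (is.null(region) && nrow(regions) > 0) {
    region <- list(chrom = regions$chrom[1],
                   start = regions$start[1] + 1,  # BED-style to 1-based
                   end = regions$end[1])
  }
  ann <- if (!is.null(models)) {
    annotate_variants(filt[, c("chrom", "pos", "ref", "alt")], models,
                      flank_bp = config$flank_bp)
  } else {
    NULL
  }
  fcfg <- candidate_filter_config(
    mp_min_index = config$mp_min_index, mp_tolerance = config$mp_tolerance,
    wp_band = config$wp_band, alpha = config$alpha,
    min_depth = config$min_depth,
    require_nonsynonymous = config$require_nonsynonymous, region = region)
  candidates <- candidate_snp_filter(filt, ann, fcfg)
  log <- c(paste0("mutmapr run, seed = ", format(config$seed)),
           paste0("stage counts: input=", nrow(idx),
                  " depth_filtered=", nrow(filt),
                  " regions=", nrow(regions),
                  " candidates=", sum(candidates$candidate)),
           if (!is.null(region)) {
             paste0("region restriction: ", region$chrom, ":",
                    format(region$start, scientific = FALSE), "-",
                    format(region$end, scientific = FALSE))
           },
           "resolved configuration:",
           paste0("  ", format_config(config)))
  run <- structure(list(counts = counts, index = idx, windows = windows,
                        regions = regions, candidates = candidates,
                        truth = truth, config = config, log = log),
                   class = "mutmap_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_counts(counts, p("counts.tsv"), "tsv")
    write_counts(counts, p("counts.vcf"), "vcf")
    utils::write.table(idx, p("snp_index.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(windows, p("window_series.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(regions) > 0) write_bed(regions, p("regions.bed"))
    utils::write.table(candidates, p("candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) {
      tv <- data.frame(individual = seq_along(truth$phenotype),
                       phenotype = truth$phenotype,
                       causal_genotype = truth$genotypes[, truth$causal_index],
                       in_mp_bulk = seq_along(truth$phenotype) %in%
                         truth$mp_members,
                       in_wp_bulk = seq_along(truth$phenotype) %in%
                         truth$wp_members)
      utils::write.table(tv, p("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    writeLines(log, p("run_log.txt"))
  }
  run
}

#' @export
print.mutmap_run <- function(x, ...) {
  cat("<mutmap_run> ", nrow(x$index), " sites, ", nrow(x$regions),
      " candidate region(s), ", sum(x$candidates$candidate),
      " candidate SNP(s)\n", sep = "")
  top <- x$candidates[!is.na(x$candidates$rank) & x$candidates$rank == 1, ]
  if (nrow(top) == 1) {
    cat("top candidate: ", top$chrom, ":", top$pos, " ", top$ref, ">",
        top$alt, "  wp_index=", signif(top$wp_index, 3),
        " mp_index=", signif(top$mp_index, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Worked example: the ten-SNP candidate cascade
#'
#' Runs the dual-bulk candidate filter on the packaged ten-SNP fixture
#' ([load_table1()]) and reports the narrative cascade: ten SNPs with
#' MP-bulk index 1, six inside the 23-27 Mb candidate region, two
#' nonsynonymous, and one surviving the full dual-bulk criterion.
#'
#' @param region Candidate-region restriction (default
#'   `"chr12:23000000-27000000"`).
#' @return List with `report` (the fixture with filter verdicts and
#'   ranks), `cascade` (named counts `index1`, `in_region`,
#'   `nonsynonymous`, `final`), and `top` (the surviving record).
#' @export
table1_demo <- function(region = "chr12:23000000-27000000") {
  tb <- load_table1()
  cfg <- candidate_filter_config(region = region)
  report <- candidate_snp_filter(tb, annotations = NULL, config = cfg)
  cascade <- c(index1 = sum(report$pass_mp),
               in_region = sum(report$pass_mp & report$pass_region),
               nonsynonymous = sum(report$pass_mp & report$pass_effect),
               final = sum(report$candidate))
  list(report = report, cascade = cascade,
       top = report[!is.na(report$rank) & report$rank == 1, , drop = FALSE])
}
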