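# Per-SNP and sliding-window SNP indices, candidate-region detection, and
# the dual-bulk causal filter (MP index = 1, WP index about 1/3).

#' SNP index of one site
#'
#' The fraction of reads carrying the non-reference (mutant-line) allele:
#' `alt / (ref + alt)`. With zero total depth the index is undefined and
#' `NA` is returned; that is the only way an `NA` index arises.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorized).
#' @return Numeric in `[0, 1]`, or `NA` at zero depth.
#' @export
compute_snp_index <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0) || any(alt_reads < 0)) {
    stop("read counts must be non-negative")
  }
  total <- ref_reads + alt_reads
  ifelse(total == 0, NA_real_, alt_reads / total)
}

assert_sorted <- function(chrom, pos, what = "input") {
  o <- order(chrom, pos)
  if (!identical(o, seq_along(pos))) {
    stop(what, " is not sorted by (chrom, pos); upstream file is malformed")
  }
}

#' Per-SNP index table for both bulks
#'
#' One record per allele-count row, with the WP (wild-type phenotype) and MP
#' (mutant phenotype) bulk SNP indices and depths.
#'
#' @param counts Allele-count table (columns chrom, pos, ref, alt, wp_ref,
#'   wp_alt, mp_ref, mp_alt), sorted by (chrom, pos).
#' @return data.frame with columns chrom, pos, ref, alt, wp_index, mp_index,
#'   wp_depth, mp_depth.
#' @export
compute_index_table <- function(counts) {
  need <- c("chrom", "pos", "ref", "alt",
            "wp_ref", "wp_alt", "mp_ref", "mp_alt")
  if (!all(need %in% names(counts))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  }
  assert_sorted(counts$chrom, counts$pos, "allele-count table")
  data.frame(chrom = counts$chrom, pos = counts$pos,
             ref = counts$ref, alt = counts$alt,
             wp_index = compute_snp_index(counts$wp_ref, counts$wp_alt),
             mp_index = compute_snp_index(counts$mp_ref, counts$mp_alt),
             wp_depth = counts$wp_ref + counts$wp_alt,
             mp_depth = counts$mp_ref + counts$mp_alt)
}

#' Drop low-coverage sites
#'
#' Keeps records whose depth in both bulks is at least `min_depth`; order is
#' preserved and the number of removed records is reported via `message()`.
#'
#' @param records SNP-index table from [compute_index_table()].
#' @param min_depth Minimum per-bulk depth (default 10).
#' @return Filtered records.
#' @export
filter_sites <- function(records, min_depth = 10) {
  stopifnot(min_depth >= 0)
  keep <- records$wp_depth >= min_depth & records$mp_depth >= min_depth
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " site(s) removed below depth ", min_depth)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window mean SNP index along one chromosome
#'
#' Windows of `window_bp` advanced by `step_bp`, anchored at 0 and half-open:
#' a SNP at 1-based position `p` belongs to window `[s, s + W)` iff
#' `s <= p - 1 < s + W`. Each window carries the arithmetic mean of the
#' defined member indices per bulk (`NA` when no member has a defined
#' index). Computed in O(n + windows) with cumulative sums; equal to naive
#' per-window recomputation.
#'
#' @param records SNP-index table, sorted by position.
#' @param chrom Chromosome to window.
#' @param chrom_length Chromosome length in bp (defaults to the last SNP
#'   position).
#' @param window_bp Window size (default 1 Mb).
#' @param step_bp Step size (default 1 kb).
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   midpoint, n_snps, wp_mean, mp_mean; attributes `window_bp`, `step_bp`.
#' @export
sliding_window_mean <- function(records, chrom, chrom_length = NULL,
                                window_bp = 1e6, step_bp = 1e3) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  r <- records[records$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) stop("no records on chromosome ", chrom)
  if (is.unsorted(r$pos)) stop("records not sorted by position")
  if (is.null(chrom_length)) chrom_length <- max(r$pos)
  starts <- if (chrom_length > window_bp) {
    seq(0, chrom_length - window_bp, by = step_bp)
  } else {
    0
  }
  p0 <- r$pos - 1  # windows are 0-based half-open
  cum <- function(x) c(0, cumsum(ifelse(is.na(x), 0, x)))
  cnt <- function(x) c(0, cumsum(!is.na(x)))
  cs_wp <- cum(r$wp_index); cn_wp <- cnt(r$wp_index)
  cs_mp <- cum(r$mp_index); cn_mp <- cnt(r$mp_index)
  lo <- findInterval(starts - 0.5, p0)          # members with p0 <  start
  hi <- findInterval(starts + window_bp - 0.5, p0)  # p0 <= start + W - 1
  n_wp <- cn_wp[hi + 1] - cn_wp[lo + 1]
  n_mp <- cn_mp[hi + 1] - cn_mp[lo + 1]
  out <- data.frame(chrom = chrom, start = starts, end = starts + window_bp,
                    midpoint = starts + window_bp / 2,
                    n_snps = hi - lo,
                    wp_mean = ifelse(n_wp == 0, NA_real_,
                                     (cs_wp[hi + 1] - cs_wp[lo + 1]) / n_wp),
                    mp_mean = ifelse(n_mp == 0, NA_real_,
                                     (cs_mp[hi + 1] - cs_mp[lo + 1]) / n_mp))
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  out
}

#' Detect candidate regions from a window series
#'
#' Maximal runs of at least `min_windows` consecutive windows whose mean
#' index is defined and at or above `index_threshold` ("SNP index of 1 or
#' approximation"), merged into genomic intervals. Regions are returned
#' sorted by peak mean (descending), ties broken by genomic order.
#'
#' @param series Window series from [sliding_window_mean()].
#' @param bulk Which bulk's mean to threshold (default `"mp"`).
#' @param index_threshold Minimum window mean (default 0.9).
#' @param min_windows Minimum run length (default 1).
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   peak_index, n_windows.
#' @export
detect_candidate_regions <- function(series, bulk = c("mp", "wp"),
                                     index_threshold = 0.9,
                                     min_windows = 1) {
  bulk <- match.arg(bulk)
  stopifnot(index_threshold > 0, index_threshold <= 1)
  x <- series[[paste0(bulk, "_mean")]]
  ok <- !is.na(x) & x >= index_threshold
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values & runs$lengths >= min_windows)
  if (length(sel) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_index = numeric(),
                      n_windows = integer()))
  }
  out <- do.call(rbind, lapply(sel, function(i) {
    w <- starts[i]:ends[i]
    data.frame(chrom = series$chrom[w[1]],
               start = series$start[w[1]],
               end = series$end[w[length(w)]],
               peak_index = max(x[w]),
               n_windows = length(w))
  }))
  out <- out[order(-out$peak_index, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected bulk SNP index from a genotype-class composition
#'
#' Computes the expected mutant-allele read fraction of a bulk as the
#' mutant-allele dosage of its genotype classes over total allele copies.
#' The phenotypically wild-type F2 class of a monogenic recessive segregates
#' AA : Aa = 1 : 2, giving `(0*1 + 1*2) / (2*(1+2)) = 1/3` — the value the
#' dual-bulk filter centres on. The mutant class (aa only) gives 1; an
#' AA-only class gives 0.
#'
#' @param class_counts Named numeric vector of relative class frequencies
#'   with names among `AA`, `Aa`, `aa`. Default: the wild-type phenotype
#'   class of an F2.
#' @return Expected SNP index (exact fraction).
#' @export
expected_wp_index <- function(class_counts = c(AA = 1, Aa = 2, aa = 0)) {
  dosage <- c(AA = 0, Aa = 1, aa = 2)
  if (!all(names(class_counts) %in% names(dosage))) {
    stop("class names must be among AA, Aa, aa")
  }
  total <- sum(class_counts)
  if (total <= 0) stop("class counts must sum to > 0")
  sum(dosage[names(class_counts)] * class_counts) / (2 * total)
}

#' Exact two-sided binomial consistency test for the WP index
#'
#' Probability, under `Binomial(depth, p0)`, of an outcome no more probable
#' than the observed alternate-read count (the minimum-likelihood two-sided
#' convention), computed by direct summation over 0..depth. Used to judge
#' whether a WP-bulk index is consistent with the recessive expectation
#' `p0 = 1/3`.
#'
#' @param alt_reads Observed alternate reads (0..depth).
#' @param depth Total reads (> 0).
#' @param p0 Null allele fraction (default 1/3).
#' @return p-value in (0, 1].
#' @export
wp_consistency_pvalue <- function(alt_reads, depth, p0 = 1 / 3) {
  if (length(alt_reads) > 1 || length(depth) > 1) {
    return(mapply(wp_consistency_pvalue, alt_reads, depth,
                  MoreArgs = list(p0 = p0)))
  }
  if (depth <= 0) stop("depth must be > 0")
  if (alt_reads < 0 || alt_reads > depth) stop("alt_reads outside 0..depth")
  d <- stats::dbinom(0:depth, depth, p0)
  p_obs <- d[alt_reads + 1]
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

#' Candidate filter configuration
#'
#' Tunables of the dual-bulk causal-SNP filter.
#'
#' @param mp_min_index Minimum MP-bulk index (default 1).
#' @param mp_tolerance Tolerance subtracted from `mp_min_index` before
#'   comparison (default 0.1, mirroring the 0.9 window threshold that
#'   operationalizes "index of 1 or approximation" under sequencing error).
#' @param wp_target Centre of the WP criterion (default 1/3, the recessive
#'   expectation).
#' @param wp_band Closed-open interval `[lo, hi)` of admissible WP indices
#'   (default `[1/6, 1/2)`, separating the causal expectation 1/3 from
#'   fixed-background 1 and unlinked 1/2).
#' @param alpha Significance level of the exact binomial consistency test
#'   (default 0.05); applied only when read depths are available.
#' @param min_depth Minimum per-bulk depth (default 10); applied only when
#'   depths are available.
#' @param require_nonsynonymous Require an exonic nonsynonymous (or
#'   stop-gain) call (default TRUE).
#' @param region Optional restriction, either `list(chrom, start, end)`
#'   (1-based, inclusive) or a string `"chr:START-END"`.
#' @return List of class `candidate_filter_config`.
#' @export
candidate_filter_config <- function(mp_min_index = 1, mp_tolerance = 0.1,
                                    wp_target = 1 / 3,
                                    wp_band = c(1 / 6, 1 / 2),
                                    alpha = 0.05, min_depth = 10,
                                    require_nonsynonymous = TRUE,
                                    region = NULL) {
  stopifnot(mp_min_index >= 0, mp_min_index <= 1,
            wp_band[1] >= 0, wp_band[2] <= 1, wp_band[1] < wp_band[2],
            alpha >= 0, alpha <= 1)
  if (wp_target < wp_band[1] || wp_target >= wp_band[2]) {
    warning("wp_band excludes wp_target; no WP index can satisfy both ",
            "the band and the consistency test")
  }
  if (is.character(region)) region <- parse_region(region)
  structure(list(mp_min_index = mp_min_index, mp_tolerance = mp_tolerance,
                 wp_target = wp_target, wp_band = wp_band, alpha = alpha,
                 min_depth = min_depth,
                 require_nonsynonymous = require_nonsynonymous,
                 region = region),
            class = "candidate_filter_config")
}

parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop("region must look like 'chr:START-END'")
  num <- function(s) as.numeric(gsub(",", "", s))
  list(chrom = m[2], start = num(m[3]), end = num(m[4]))
}

#' Dual-bulk causal-SNP filter
#'
#' Applies, as one conjunction (so the result is independent of filter
#' order), the criteria that single out the causative SNP of a monogenic
#' recessive: MP-bulk index at (or near) 1, position inside the candidate
#' region, WP-bulk index inside the band around 1/3 and consistent with 1/3
#' by the exact binomial test, adequate depth, and a nonsynonymous exonic
#' annotation. Every record keeps its per-criterion verdicts; survivors are
#' ranked by `|wp_index - 1/3|` ascending, ties broken by genomic
#' coordinate.
#'
#' @param records SNP-index table; may already carry `region_class` /
#'   `mutation_type` columns.
#' @param annotations Optional annotation data.frame (from
#'   [annotate_variants()] or equivalent) joined by (chrom, pos).
#' @param config A [candidate_filter_config()].
#' @return `records` augmented with logical verdict columns (`pass_depth`,
#'   `pass_region`, `pass_mp`, `pass_wp_band`, `pass_wp_test`,
#'   `pass_effect`), `wp_pvalue`, `candidate` and `rank` (`NA` for
#'   non-candidates), ordered with ranked candidates first.
#' @export
candidate_snp_filter <- function(records, annotations = NULL,
                                 config = candidate_filter_config()) {
  r <- records
  if (!is.null(annotations)) {
    ann_cols <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))
    key <- paste(r$chrom, r$pos)
    akey <- paste(annotations$chrom, annotations$pos)
    idx <- match(key, akey)
    for (col in ann_cols) r[[col]] <- annotations[[col]][idx]
  }
  have_depth <- all(c("wp_depth", "mp_depth") %in% names(r))

  pass_depth <- if (have_depth) {
    !is.na(r$wp_depth) & !is.na(r$mp_depth) &
      r$wp_depth >= config$min_depth & r$mp_depth >= config$min_depth
  } else {
    rep(TRUE, nrow(r))
  }
  pass_region <- if (is.null(config$region)) {
    rep(TRUE, nrow(r))
  } else {
    r$chrom == config$region$chrom &
      r$pos >= config$region$start & r$pos <= config$region$end
  }
  pass_mp <- !is.na(r$mp_index) &
    r$mp_index >= config$mp_min_index - config$mp_tolerance
  pass_wp_band <- !is.na(r$wp_index) &
    r$wp_index >= config$wp_band[1] & r$wp_index < config$wp_band[2]
  wp_pvalue <- rep(NA_real_, nrow(r))
  if (have_depth) {
    ok <- !is.na(r$wp_index) & !is.na(r$wp_depth) & r$wp_depth > 0
    if (any(ok)) {
      wp_pvalue[ok] <- wp_consistency_pvalue(
        round(r$wp_index[ok] * r$wp_depth[ok]), r$wp_depth[ok],
        p0 = config$wp_target)
    }
  }
  pass_wp_test <- is.na(wp_pvalue) | wp_pvalue >= config$alpha
  pass_effect <- if (config$require_nonsynonymous) {
    if (!"mutation_type" %in% names(r)) {
      stop("nonsynonymous filtering requested but no mutation_type ",
           "annotation is joined to the records")
    }
    mt <- r$mutation_type
    if (any(is.na(mt) & pass_depth & pass_region & pass_mp & pass_wp_band &
            pass_wp_test &
            (!"region_class" %in% names(r) |
               r$region_class %in% c("exonic", "Exonic")))) {
      stop("annotation missing for a record surviving all other filters ",
           "(broken annotation join)")
    }
    !is.na(mt) & mt %in% c("NS", "nonsynonymous", "stop_gain")
  } else {
    rep(TRUE, nrow(r))
  }

  r$pass_depth <- pass_depth
  r$pass_region <- pass_region
  r$pass_mp <- pass_mp
  r$pass_wp_band <- pass_wp_band
  r$wp_pvalue <- wp_pvalue
  r$pass_wp_test <- pass_wp_test
  r$pass_effect <- pass_effect
  r$candidate <- pass_depth & pass_region & pass_mp & pass_wp_band &
    pass_wp_test & pass_effect
  r$rank <- NA_integer_
  if (any(r$candidate)) {
    ci <- which(r$candidate)
    o <- order(abs(r$wp_index[ci] - config$wp_target), r$chrom[ci],
               r$pos[ci])
    r$rank[ci[o]] <- seq_along(ci)
  }
  r <- r[order(!r$candidate, r$rank, r$chrom, r$pos), , drop = FALSE]
  rownames(r) <- NULL
  r
}
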