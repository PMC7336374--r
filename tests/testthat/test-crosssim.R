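test_that("EMS spectrum fraction forces the substitution types", {
  g <- toy_genome()
  ems_pairs <- c(G = "A", C = "T")
  v1 <- simulate_ems_variants(g, 100, spectrum_fraction = 1, seed = 11)
  is_ems <- function(v) {
    v$ref %in% names(ems_pairs) & v$alt == unname(ems_pairs[v$ref])
  }
  expect_true(all(is_ems(v1$variants)))
  v0 <- simulate_ems_variants(g, 100, spectrum_fraction = 0, seed = 11)
  bg <- v0$variants[-v0$causal_index, ]
  expect_false(any(is_ems(bg)))
  # the causal variant is always an EMS transition
  expect_true(is_ems(v0$variants[v0$causal_index, ]))
})

test_that("variant positions are unique, sorted, and seed-reproducible", {
  g <- toy_genome()
  a <- simulate_ems_variants(g, 80, seed = 3)
  b <- simulate_ems_variants(g, 80, seed = 3)
  expect_identical(a, b)
  v <- a$variants
  expect_false(any(duplicated(paste(v$chrom, v$pos))))
  expect_true(all(diff(v$pos[v$chrom == "chrA"]) > 0))
  expect_true(all(v$ref != v$alt))
})

test_that("causal placement needs a CDS interval and is nonsynonymous", {
  bare <- genome_spec(c(chrA = 1e6))
  expect_error(simulate_ems_variants(bare, 10, seed = 1), "CDS interval")
  g <- toy_genome()
  models <- simulate_gene_models(g, seed = 5)
  v <- simulate_ems_variants(g, 20, seed = 5, models = models)
  ca <- v$variants[v$causal_index, ]
  gi <- g$gene_intervals
  expect_true(any(ca$pos >= gi$start & ca$pos <= gi$end))
  ann <- annotate_variants(ca[, c("chrom", "pos", "ref", "alt")], models)
  expect_identical(ann$region_class, "exonic")
  expect_identical(ann$mutation_type, "NS")
})

test_that("gamete recombination follows Haldane's map function", {
  # map distance 0: alleles perfectly co-inherited within every gamete
  s0 <- two_locus_setup(0)
  set.seed(21)
  gam0 <- simulate_gametes(s0$variants, s0$genome, 2000)
  expect_true(all(gam0[, 1] == gam0[, 2]))

  # d = 0.1 Morgan: empirical r near (1 - exp(-0.2)) / 2
  s1 <- two_locus_setup(haldane_r(0.1))
  set.seed(22)
  gam1 <- simulate_gametes(s1$variants, s1$genome, 10000)
  r_emp <- mean(gam1[, 1] != gam1[, 2])
  r_exp <- haldane_r(0.1)
  se <- sqrt(r_exp * (1 - r_exp) / nrow(gam1))
  expect_lt(abs(r_emp - r_exp), 3 * se)

  # different chromosomes: independent assortment, r near 1/2
  s5 <- two_locus_setup(0.5)
  set.seed(23)
  gam5 <- simulate_gametes(s5$variants, s5$genome, 10000)
  r5 <- mean(gam5[, 1] != gam5[, 2])
  expect_lt(abs(r5 - 0.5), 3 * sqrt(0.25 / nrow(gam5)))
})

test_that("phenotype is the recessive readout of the causal genotype", {
  s <- two_locus_setup(0.25)
  pop <- simulate_f2_population(s$variants, s$genome, 3000, seed = 31)
  causal_geno <- pop$genotypes[, s$variants$causal_index]
  expect_identical(pop$phenotype == "mutant", causal_geno == 2L)
  expect_identical(assign_phenotype(2L), "mutant")
  expect_identical(assign_phenotype(1L), "wild_type")
  expect_identical(assign_phenotype(0L), "wild_type")
  expect_error(assign_phenotype(3L), "0, 1 or 2")
  # 3:1 segregation: mutant fraction near 1/4
  p <- mean(causal_geno == 2L)
  expect_lt(abs(p - 0.25), 3 * sqrt(0.25 * 0.75 / 3000))
})

test_that("conditional allele frequencies match the enumeration oracle", {
  # oracle sanity at the closed-form points
  expect_equal(bulk_freq_oracle(0, "mp"), 1)
  expect_equal(bulk_freq_oracle(0, "wp"), 1 / 3)
  expect_equal(bulk_freq_oracle(0.5, "wp"), 1 / 2)
  grid <- seq(0, 0.5, by = 0.05)
  wp_curve <- vapply(grid, bulk_freq_oracle, numeric(1), class = "wp")
  expect_true(all(diff(wp_curve) >= 0))  # monotone nondecreasing
  expect_equal(vapply(grid, bulk_freq_oracle, numeric(1), class = "mp"),
               1 - grid)

  for (r in c(0, 0.25)) {
    s <- two_locus_setup(r)
    pop <- simulate_f2_population(s$variants, s$genome, 4000,
                                  seed = 100 + round(100 * r))
    other <- 3 - s$variants$causal_index
    mp <- pop$genotypes[pop$phenotype == "mutant", other]
    wp <- pop$genotypes[pop$phenotype == "wild_type", other]
    for (case in list(list(x = mp, e = bulk_freq_oracle(r, "mp")),
                      list(x = wp, e = bulk_freq_oracle(r, "wp")))) {
      emp <- mean(case$x) / 2
      se <- sqrt(case$e * (1 - case$e) / (2 * length(case$x)))
      expect_lt(abs(emp - case$e), 3 * se + 1e-12)
    }
  }
})

test_that("bulk sampling is without replacement and fails on short classes", {
  s <- two_locus_setup(0.25)
  pop <- simulate_f2_population(s$variants, s$genome, 208, seed = 41)
  n_mut <- sum(pop$phenotype == "mutant")
  set.seed(42)
  bulks <- sample_bulks(pop, n_mp = min(30, n_mut), n_wp = 30)
  expect_false(any(duplicated(bulks$mp)))
  expect_true(all(pop$phenotype[bulks$mp] == "mutant"))
  expect_true(all(pop$phenotype[bulks$wp] == "wild_type"))
  # a bulk equal to the whole class is the class itself
  full <- sample_bulks(pop, n_mp = n_mut, n_wp = 30)
  expect_setequal(full$mp, which(pop$phenotype == "mutant"))
  expect_error(sample_bulks(pop, n_mp = n_mut + 1),
               "mutant-phenotype class")
  expect_error(sample_bulks(pop, n_wp = length(pop$phenotype)),
               "wild-type-phenotype class")
  set.seed(7); b1 <- sample_bulks(pop)
  set.seed(7); b2 <- sample_bulks(pop)
  expect_identical(b1, b2)
})

test_that("bulk read counts follow the sampling model", {
  # q = 1/2 at every site: pooled mutant-read fraction near 1/2
  n_sites <- 10000
  v <- data.frame(chrom = "chrA", pos = seq_len(n_sites), ref = "C",
                  alt = "T", ems = TRUE)
  pop <- structure(list(
    genotypes = matrix(1L, nrow = 4, ncol = n_sites),
    phenotype = rep("wild_type", 4),
    variants = structure(list(variants = v, causal_index = 1L,
                              spectrum_fraction = 1),
                         class = "ems_variant_set")),
    class = "f2_population")
  set.seed(51)
  counts <- simulate_allele_counts(pop, list(mp = 1:2, wp = 3:4),
                                   mean_depth = 20, error_rate = 0)
  frac <- sum(counts$mp_alt) / sum(counts$mp_ref + counts$mp_alt)
  expect_lt(abs(frac - 0.5),
            3 * sqrt(0.25 / sum(counts$mp_ref + counts$mp_alt)))
  # q = 0 with no error: zero mutant reads everywhere
  pop$genotypes[] <- 0L
  set.seed(52)
  c0 <- simulate_allele_counts(pop, list(mp = 1:2, wp = 3:4),
                               mean_depth = 3, error_rate = 0)
  expect_true(all(c0$mp_alt == 0) && all(c0$wp_alt == 0))
  expect_true(any(c0$mp_ref + c0$mp_alt == 0))  # zero-depth sites emitted
})

test_that("the full cross simulation is byte-identical under a fixed seed", {
  a <- simulate_cross(genome = toy_genome(), n_variants = 40, pop_size = 120,
                      n_mp = 15, n_wp = 15, seed = 61)
  b <- simulate_cross(genome = toy_genome(), n_variants = 40, pop_size = 120,
                      n_mp = 15, n_wp = 15, seed = 61)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  # match_paper fixes the phenotype composition at 164:44
  m <- simulate_cross(genome = toy_genome(), n_variants = 10,
                      match_paper = TRUE, seed = 62)
  expect_identical(sum(m$truth$phenotype == "wild_type"), 164L)
  expect_identical(sum(m$truth$phenotype == "mutant"), 44L)
})

test_that("replicate WP index at the causal site centres on 1/3", {
  s <- two_locus_setup(0.5)  # second locus unlinked
  wp_at_causal <- mp_unlinked <- wp_unlinked <- numeric(200)
  set.seed(71)
  for (i in 1:200) {
    pop <- simulate_f2_population(s$variants, s$genome, 120)
    bulks <- sample_bulks(pop, n_mp = 10, n_wp = 10)
    counts <- simulate_allele_counts(pop, bulks, mean_depth = 30,
                                     error_rate = 0)
    idx <- compute_index_table(counts)
    ci <- s$variants$causal_index
    wp_at_causal[i] <- idx$wp_index[ci]
    mp_unlinked[i] <- idx$mp_index[3 - ci]
    wp_unlinked[i] <- idx$wp_index[3 - ci]
  }
  within3se <- function(x, target) {
    abs(mean(x, na.rm = TRUE) - target) <
      3 * stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  }
  expect_true(within3se(wp_at_causal, 1 / 3))
  expect_true(within3se(mp_unlinked, 1 / 2))
  expect_true(within3se(wp_unlinked, 1 / 2))
})
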