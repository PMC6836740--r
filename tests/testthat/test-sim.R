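test_that("config validation names the offending field", {
  expect_error(sim_config(het_rate = 1.5), "het_rate")
  expect_error(sim_config(coverage_range = c(0.8, 0.5)), "coverage_range")
  expect_error(sim_config(co_rate = -1), "co_rate")
  expect_error(sim_config(fragment_length_range = c(300000, 400000)),
               "fragment_length_range")
})

test_that("zero heterozygosity gives identical haplotypes and no SNPs", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5000, het_rate = 0,
                    fragment_length_range = c(500, 2000), seed = 3)
  g <- simulate_diploid_genome(cfg)
  expect_identical(g$hapA, g$hapB)
  expect_equal(nrow(g$snps), 0L)
})

test_that("SNP count follows the binomial expectation", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100000,
                    het_rate = 0.0102, seed = 5)
  g <- simulate_diploid_genome(cfg)
  mu <- 100000 * 0.0102
  sdv <- sqrt(100000 * 0.0102 * (1 - 0.0102))
  expect_lt(abs(nrow(g$snps) - mu), 3 * sdv)
  # haplotypes differ exactly at the SNP sites, with differing alleles
  a <- strsplit(g$hapA[[1]], "")[[1]]
  b <- strsplit(g$hapB[[1]], "")[[1]]
  expect_identical(which(a != b) - 1L, g$snps$pos)
  expect_true(all(g$snps$alleleA != g$snps$alleleB))
})

test_that("the simulator is deterministic for a fixed seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000,
                    n_fragments = 20, seed = 9)
  run <- function() {
    g <- simulate_diploid_genome(cfg)
    gam <- simulate_gametes(g, cfg)
    list(g = g, gam = gam,
         calls = simulate_pollen_calls(g, gam, cfg),
         bacs = simulate_bacs(g, cfg))
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("gametes partition each chromosome into alternating segments", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 50000, seed = 21)
  g <- simulate_diploid_genome(cfg)
  gam <- simulate_gametes(g, cfg)
  for (cell in names(gam)) {
    for (ch in names(gam[[cell]])) {
      x <- gam[[cell]][[ch]]
      expect_true(all(diff(x$breakpoints) > 0))
      expect_true(all(x$breakpoints > 0 & x$breakpoints < 50000))
      expect_equal(length(x$sources), length(x$breakpoints) + 1L)
      if (length(x$sources) > 1L)
        expect_true(all(x$sources[-1] != x$sources[-length(x$sources)]))
    }
  }
})

test_that("co_rate zero gives single-segment gametes", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 10000, co_rate = 0,
                    fragment_length_range = c(500, 2000), seed = 2)
  g <- simulate_diploid_genome(cfg)
  gam <- simulate_gametes(g, cfg)
  for (cell in names(gam))
    expect_length(gam[[cell]]$chr01$breakpoints, 0)
})

test_that("mean crossover count converges to co_rate", {
  counts <- integer(0)
  for (s in 1:25) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length = 50000, co_rate = 1.3,
                      seed = 1000 + s)
    g <- simulate_diploid_genome(cfg)
    gam <- simulate_gametes(g, cfg)
    counts <- c(counts, unlist(lapply(gam, function(cell)
      vapply(cell, function(x) length(x$breakpoints), integer(1)))))
  }
  se <- sqrt(1.3 / length(counts))
  expect_lt(abs(mean(counts) - 1.3), 3 * se)
})

test_that("end-biased crossovers concentrate in the terminal 20%", {
  rel <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length = 100000, co_rate = 2,
                      end_bias = 0.5, seed = 2000 + s)
    g <- simulate_diploid_genome(cfg)
    gam <- simulate_gametes(g, cfg)
    rel <- c(rel, unlist(lapply(gam, function(cell)
      lapply(cell, function(x) x$breakpoints / 100000))))
  }
  # Beta(0.5, 0.5) puts ~0.59 of its mass in the outer 20% of each end
  expect_gt(mean(rel <= 0.2 | rel >= 0.8), 0.4)
})

test_that("noise-free full-coverage calls reproduce the gamete alleles", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000,
                    coverage_range = c(1, 1), genotype_error_rate = 0,
                    seed = 13)
  g <- simulate_diploid_genome(cfg)
  gam <- simulate_gametes(g, cfg)
  calls <- simulate_pollen_calls(g, gam, cfg)
  expect_equal(nrow(calls), nrow(g$snps) * cfg$n_cells)
  for (cell in unique(calls$cell)) {
    sub <- calls[calls$cell == cell, ]
    src <- gamete_source(gam[[cell]]$chr01, sub$pos)
    truth <- ifelse(src == "A",
                    g$snps$alleleA[match(sub$pos, g$snps$pos)],
                    g$snps$alleleB[match(sub$pos, g$snps$pos)])
    expect_identical(sub$base, truth)
  }
  expect_false(any(calls$is_error))
})

test_that("per-cell coverage calibrates to the configured range", {
  fractions <- numeric(0)
  for (s in 1:20) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 50000,
                      coverage_range = c(0.50, 0.78), seed = 3000 + s)
    g <- simulate_diploid_genome(cfg)
    gam <- simulate_gametes(g, cfg)
    calls <- simulate_pollen_calls(g, gam, cfg)
    fractions <- c(fractions,
                   as.vector(table(factor(calls$cell, levels = names(gam)))) /
                     nrow(g$snps))
  }
  target <- mean(c(0.50, 0.78))
  expect_lt(abs(mean(fractions) - target),
            2 * sd(fractions) / sqrt(length(fractions)))
  # fixed coverage reproduces the study's median per-cell breadth
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 50000,
                    coverage_range = c(0.66, 0.66), seed = 77)
  g <- simulate_diploid_genome(cfg)
  gam <- simulate_gametes(g, cfg)
  calls <- simulate_pollen_calls(g, gam, cfg)
  frac <- as.vector(table(factor(calls$cell, levels = names(gam)))) / nrow(g$snps)
  expect_true(all(abs(frac - 0.66) < 0.05))
  # with 12 cells at p = 0.66 nearly every site is seen in >= 2 cells
  tab <- table(factor(calls$pos, levels = g$snps$pos))
  closed_form <- 1 - (1 - 0.66)^12 - 12 * 0.66 * (1 - 0.66)^11
  expect_gt(closed_form, 0.999)
  expect_gt(mean(tab >= 2), 0.999)
})

test_that("genotype errors are injected and flagged at the configured rate", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100000, het_rate = 0.02,
                    coverage_range = c(1, 1), genotype_error_rate = 0.1,
                    n_cells = 5, seed = 31)
  g <- simulate_diploid_genome(cfg)
  gam <- simulate_gametes(g, cfg)
  calls <- simulate_pollen_calls(g, gam, cfg)
  n <- nrow(calls)
  expected <- n * 0.1
  sdv <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(sum(calls$is_error) - expected), 4 * sdv)
  # flagged calls carry the opposite allele
  sub <- calls[calls$is_error, ]
  src <- gamete_source(gam[[sub$cell[1]]]$chr01, sub$pos[1])
  m <- match(sub$pos[1], g$snps$pos)
  truth <- if (src == "A") g$snps$alleleA[m] else g$snps$alleleB[m]
  expect_false(sub$base[1] == truth)
})

test_that("fragments are haplotype-pure copies with a balanced A:B ratio", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 60000,
                    n_fragments = 400, fragment_length_range = c(1000, 5000),
                    seed = 17)
  g <- simulate_diploid_genome(cfg)
  b <- simulate_bacs(g, cfg)
  expect_equal(nrow(b$records), 400)
  r <- b$records
  expect_true(all(r$start >= 0 & r$start < r$end & r$end <= 60000))
  hapseq <- ifelse(r$haplotype == "A", g$hapA[r$chrom], g$hapB[r$chrom])
  expect_identical(unname(b$sequences),
                   unname(substring(hapseq, r$start + 1, r$end)))
  ratio <- mean(r$haplotype == "A")
  expect_lt(abs(ratio - 0.5), 3 * sqrt(0.25 / 400))
  # zero fragments is a valid request
  cfg0 <- sim_config(n_fragments = 0, seed = 1)
  expect_equal(nrow(simulate_bacs(g, cfg0)$records), 0L)
})
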