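test_that("alignment projects haplotypes onto reference coordinates", {
  a <- align_to_ref("ACGTACGT", "ACGTACGT")
  expect_equal(a$map, strsplit("ACGTACGT", "")[[1]])
  expect_equal(a$score, 8)
  # single substitution
  b <- align_to_ref("ACGTACGT", "ACGTTCGT")
  expect_equal(sum(b$map != strsplit("ACGTACGT", "")[[1]]), 1L)
  expect_equal(b$score, 7 - 1)
  # 3 bp deletion maps three reference positions to gaps
  ref <- "ACGTTGCATGCA"
  hap <- "ACGTGCA"  # drop TGCAT? construct: ref minus positions 5-9? use explicit
  d <- align_to_ref("AAACCCGGGTTT", "AAACCCTTT")
  expect_equal(sum(d$map == "-"), 3L)
  expect_equal(d$score, 9 - (4 + 3))
  expect_error(align_to_ref("", "ACGT"), "empty")
})

test_that("alignment scores equal the exhaustive DP oracle on short pairs", {
  set.seed(8)
  for (i in 1:120) {
    n <- sample(1:20, 1); m <- sample(1:20, 1)
    a <- random_dna(n); b <- random_dna(m)
    expect_equal(align_to_ref(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  # include near-identical pairs where gaps compete with mismatches
  for (i in 1:30) {
    a <- random_dna(15)
    b <- paste0(substr(a, 1, 7), substr(a, 9, 15))  # 1 bp deletion
    expect_equal(align_to_ref(a, b)$score, oracle_align_score(a, b))
  }
})

# build a triplet with known diagnostic sites: hapA and hapB differ at
# given positions (1-based), ref copies A or B per position
make_triplet <- function(len = 60, diff_pos, ref_from, exons = NULL) {
  base <- strsplit(paste0(rep("ACGT", len / 4 + 1), collapse = ""), "")[[1]][1:len]
  hapA <- base
  hapB <- base
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  third <- c(A = "G", C = "A", G = "T", T = "C")
  hapB[diff_pos] <- flip[base[diff_pos]]
  ref <- hapA
  for (i in seq_along(diff_pos)) {
    p <- diff_pos[i]
    ref[p] <- switch(ref_from[i], A = hapA[p], B = hapB[p], N = third[base[p]])
  }
  list(ref = paste0(ref, collapse = ""), hapA = paste0(hapA, collapse = ""),
       hapB = paste0(hapB, collapse = ""), exons = exons)
}

test_that("diagnostic sites classify reference bases against each haplotype", {
  # identical haplotypes -> no diagnostic sites
  t0 <- make_triplet(40, integer(0), character(0))
  expect_equal(nrow(diagnostic_sites(t0$ref, t0$hapA, t0$hapB)), 0L)
  # 4 sites matching A and 4 matching B, as in a split mosaic gene
  t1 <- make_triplet(80, c(5, 15, 25, 35, 45, 55, 65, 75),
                     c(rep("A", 4), rep("B", 4)))
  s1 <- diagnostic_sites(t1$ref, t1$hapA, t1$hapB)
  expect_equal(sum(s1$state == "MATCHES_A"), 4L)
  expect_equal(sum(s1$state == "MATCHES_B"), 4L)
  expect_equal(s1$pos, c(5, 15, 25, 35, 45, 55, 65, 75) - 1L)
  # a third allele in the reference is NEITHER
  t2 <- make_triplet(40, c(10, 20), c("A", "N"))
  s2 <- diagnostic_sites(t2$ref, t2$hapA, t2$hapB)
  expect_equal(sort(s2$state), c("MATCHES_A", "NEITHER"))
})

test_that("gene classification applies the mosaic rules", {
  mk_sites <- function(states, in_exon = rep(FALSE, length(states))) {
    data.frame(pos = seq_along(states) * 10, state = states, in_exon = in_exon,
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_gene(mk_sites(character(0)))$class, "identical_AB")
  expect_equal(classify_gene(mk_sites(rep("MATCHES_A", 10)))$class, "consistent_A")
  expect_equal(classify_gene(mk_sites(rep("MATCHES_B", 3)))$class, "consistent_B")
  # 8 A + 2 B: B is the minority; class follows where the B sites fall
  st <- c(rep("MATCHES_A", 8), rep("MATCHES_B", 2))
  expect_equal(classify_gene(mk_sites(st))$class, "mosaic_intron")
  ex <- c(rep(FALSE, 8), TRUE, FALSE)
  expect_equal(classify_gene(mk_sites(st, ex))$class, "mosaic_exon")
  # NEITHER-dominated genes are unresolved
  stn <- c("MATCHES_A", rep("NEITHER", 3))
  expect_equal(classify_gene(mk_sites(stn))$class, "unresolved")
  # 5 + 5 tie: the minority is the segment after the first switch
  tie <- c(rep("MATCHES_A", 5), rep("MATCHES_B", 5))
  ex_late <- c(rep(FALSE, 5), TRUE, rep(FALSE, 4))  # exonic site in B segment
  expect_equal(classify_gene(mk_sites(tie, ex_late))$class, "mosaic_exon")
  ex_early <- c(TRUE, rep(FALSE, 9))                # exonic site in A segment
  expect_equal(classify_gene(mk_sites(tie, ex_early))$class, "mosaic_intron")
})

test_that("spliced mosaic genes are detected with a localized switch", {
  set.seed(12)
  for (i in 1:10) {
    diffs <- sort(sample(5:115, 8))
    cut <- 4  # first 4 sites from A, rest from B
    t1 <- make_triplet(120, diffs, c(rep("A", cut), rep("B", 8 - cut)))
    call <- classify_triplet("g", t1$ref, t1$hapA, t1$hapB)
    expect_true(call$class %in% c("mosaic_exon", "mosaic_intron"))
    sw <- as.integer(strsplit(call$switch_positions, ",")[[1]])
    expect_length(sw, 1L)
    expect_gt(sw, diffs[cut] - 1L)
    expect_lte(sw, diffs[cut + 1] - 1L)
  }
})

test_that("swapping the A and B inputs swaps the matched states symmetrically", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    diffs <- sort(sample(5:95, n))
    origin <- sample(c("A", "B"), n, replace = TRUE)
    t1 <- make_triplet(100, diffs, origin)
    s_ab <- diagnostic_sites(t1$ref, t1$hapA, t1$hapB)
    s_ba <- diagnostic_sites(t1$ref, t1$hapB, t1$hapA)
    expect_equal(s_ab$state == "MATCHES_A", s_ba$state == "MATCHES_B")
    c_ab <- classify_gene(s_ab)
    c_ba <- classify_gene(s_ba)
    swap <- c(consistent_A = "consistent_B", consistent_B = "consistent_A",
              identical_AB = "identical_AB", mosaic_exon = "mosaic_exon",
              mosaic_intron = "mosaic_intron", unresolved = "unresolved")
    if (sum(origin == "A") != sum(origin == "B"))  # non-tied inputs
      expect_equal(c_ba$class, unname(swap[c_ab$class]))
  }
})

test_that("the report tallies classes and the mosaic percentage", {
  calls <- data.frame(
    gene = sprintf("g%d", 1:50),
    class = c("mosaic_exon", rep("consistent_A", 25), rep("consistent_B", 24)),
    n_A = 1, n_B = 1, n_neither = 0, switch_positions = "",
    stringsAsFactors = FALSE)
  rep1 <- mosaic_report(calls)
  expect_equal(rep1$n_mosaic, 1L)
  expect_equal(rep1$mosaic_pct, 2.00)
  # exon + intron mosaics sum to the total mosaic count
  calls2 <- data.frame(gene = sprintf("g%d", 1:3479),
                       class = c(rep("mosaic_exon", 2332),
                                 rep("mosaic_intron", 1147)),
                       n_A = 1, n_B = 1, n_neither = 0, switch_positions = "",
                       stringsAsFactors = FALSE)
  rep2 <- mosaic_report(calls2)
  expect_equal(rep2$n_mosaic, 3479L)
  expect_equal(unname(rep2$counts["mosaic_exon"]), 2332L)
  expect_equal(unname(rep2$counts["mosaic_intron"]), 1147L)
  expect_equal(mosaic_report(calls[0, ])$total, 0L)
})

test_that("the triplet simulator's mosaic genes are recovered", {
  trips <- simulate_gene_triplets(n_genes = 40, gene_length = 800,
                                  mosaic_fraction = 0.3, seed = 5)
  calls <- do.call(rbind, lapply(trips, function(t)
    classify_triplet(t$gene, t$ref, t$hapA, t$hapB, t$exons)))
  truth <- vapply(trips, `[[`, logical(1), "truth_mosaic")
  got_mosaic <- calls$class %in% c("mosaic_exon", "mosaic_intron")
  expect_equal(got_mosaic, unname(truth))
})
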