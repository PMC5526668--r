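test_that("planted repeats are found with correct coordinates and filters", {
  withr::local_seed(21)
  pl <- plant_repeat(5000, 250, 3, 1000)
  r <- find_direct_repeats(pl$seq)
  expect_equal(nrow(r), 1L)
  # the report covers the planted pair (maximal extension may add a few bp)
  expect_lte(r$start1, pl$start1); expect_gte(r$end1, pl$start1 + 250)
  expect_lte(r$start2, pl$start2)
  expect_gte(r$repeat_length, 250)
  expect_gte(r$hamming, 3)
  # unplanted random sequence has no qualifying repeats
  expect_equal(nrow(find_direct_repeats(random_seq(5000))), 0L)
  # identical 200-mers with gap below min_gap are excluded, not trimmed
  tandem <- plant_repeat(3000, 200, 0, 150)
  expect_equal(nrow(find_direct_repeats(tandem$seq)), 0L)
  expect_equal(nrow(find_direct_repeats(tandem$seq, min_gap = 100)), 1L)
  # too-short sequences give an empty result
  expect_equal(nrow(find_direct_repeats(random_seq(500))), 0L)
  expect_error(find_direct_repeats("ACGTN"), "A/C/G/T")
})

test_that("seeded scan is equivalent to the exhaustive oracle", {
  withr::local_seed(22)
  for (i in 1:12) {
    n <- sample(2500:5000, 1)
    L <- sample(200:320, 1)
    h <- sample(0:8, 1)
    gap <- sample(c(150, 201, 400, 1200), 1)
    pl <- plant_repeat(n, L, h, gap)
    for (mm in c(5, 8)) {
      a <- find_direct_repeats(pl$seq, 200, mm, 1e5, 200)
      b <- find_direct_repeats(pl$seq, 200, mm, 1e5, 200, method = "exhaustive")
      expect_identical(a, b)
    }
  }
})

test_that("circular mode finds repeats across the origin", {
  withr::local_seed(23)
  g <- sample(BASES, 4000, replace = TRUE)
  seg <- g[1001:1250]
  g[c(3901:4000, 1:150)] <- seg   # copy wrapping the origin
  g[2001:2250] <- seg
  s <- paste(g, collapse = "")
  rc <- find_direct_repeats(s, 200, 8, 1e5, 200, circular = TRUE)
  rl <- find_direct_repeats(s, 200, 8, 1e5, 200, circular = FALSE)
  expect_equal(nrow(rl), 1L)   # only the non-wrapping pair
  expect_equal(nrow(rc), 3L)   # all three pairs of the three copies
})

test_that("genes_between_repeats uses full containment", {
  reps <- structure(data.frame(start1 = 100, end1 = 300, start2 = 2000,
                               end2 = 2200, repeat_length = 200, hamming = 0,
                               gap = 1700, region_start = 300,
                               region_end = 2000),
                    class = c("repeat_region", "data.frame"))
  genes <- data.frame(id = c("inside", "straddle", "outside"),
                      start = c(500L, 250L, 2500L), end = c(900L, 600L, 2900L),
                      strand = "+", essential = FALSE)
  expect_equal(genes_between_repeats(reps, genes), "inside")
  expect_equal(genes_between_repeats(reps, genes, exclude = "inside"),
               character(0))
  expect_equal(genes_between_repeats(reps, genes, min_region_span = 5000),
               character(0))
})

test_that("closest upstream terminator is strand-aware and wraps", {
  term <- data.frame(pos = c(400L, 800L, 1900L),
                     strand = c("+", "+", "-"),
                     mode = c("intrinsic", "rho", "rho"))
  gplus <- data.frame(id = "g", start = 1000L, end = 1500L, strand = "+",
                      essential = FALSE)
  got <- closest_upstream_terminator(gplus, term, 5000, circular = FALSE)
  expect_equal(got$pos, 800L)       # nearest of the two co-oriented ones
  # minus-strand gene scans toward higher coordinates
  gminus <- gplus; gminus$strand <- "-"
  got <- closest_upstream_terminator(gminus, term, 5000, circular = FALSE)
  expect_equal(got$pos, 1900L)
  # circular wrap: only co-oriented terminator lies behind the origin
  g2 <- data.frame(id = "g2", start = 50L, end = 500L, strand = "+",
                   essential = FALSE)
  t2 <- data.frame(pos = 4900L, strand = "+", mode = "rho")
  expect_null(closest_upstream_terminator(g2, t2, 5000, circular = FALSE))
  expect_equal(closest_upstream_terminator(g2, t2, 5000, circular = TRUE)$pos,
               4900L)
  expect_null(closest_upstream_terminator(gplus, term[3, ], 5000, TRUE))
})

test_that("toy-genome construction truth is recovered exactly", {
  for (seed in c(7, 31)) {
    toy <- make_toy_annotation(seed)
    res <- classify_genes(toy$ann)
    m <- merge(res$membership, toy$truth, by = "gene_id",
               suffixes = c("", ".truth"))
    expect_equal(m$tier, m$tier.truth)
    expect_equal(m$in_rho_set, m$in_rho_set.truth)
    expect_equal(m$in_deletion_set, m$in_deletion_set.truth)
    expect_equal(m$in_duplicate_set, m$in_duplicate_set.truth)
    expect_equal(sum(res$venn_counts), nrow(res$membership))
    # planted repeat found
    reps <- find_direct_repeats(toy$ann$sequence, circular = TRUE)
    pr <- toy$planted_repeat
    expect_true(any(reps$start1 <= pr$start1 & reps$end1 >= pr$end1 &
                      reps$start2 <= pr$start2))
  }
  # no planted features: no repeats, everything tier low
  bare <- make_toy_annotation(5, plant_loci = FALSE)
  res <- classify_genes(bare$ann)
  expect_true(all(res$membership$tier == "low"))
  expect_equal(unname(res$venn_counts[["outside"]]), nrow(res$membership))
})

test_that("set membership is invariant under reverse complement", {
  toy <- make_toy_annotation(9)
  ann <- toy$ann
  L <- ann$genome_length
  rc <- annotation_bundle(
    L,
    genes = data.frame(id = ann$genes$id,
                       start = L - ann$genes$end, end = L - ann$genes$start,
                       strand = ifelse(ann$genes$strand == "+", "-", "+"),
                       essential = ann$genes$essential),
    promoters = data.frame(pos = L - 1L - ann$promoters$pos,
                           strand = ifelse(ann$promoters$strand == "+", "-", "+"),
                           primary = ann$promoters$primary),
    terminators = data.frame(pos = L - 1L - ann$terminators$pos,
                             strand = ifelse(ann$terminators$strand == "+", "-", "+"),
                             mode = ann$terminators$mode),
    circular = TRUE)
  expect_setequal(rho_terminated_set(rc), rho_terminated_set(ann))
  expect_setequal(deletion_cooption_set(rc), deletion_cooption_set(ann))
})
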