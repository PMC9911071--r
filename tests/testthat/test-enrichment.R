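# Breakpoint enrichment: window geometry, null draws, permutation test
# behaviour, and the depletion-symmetry identity.

test_that("window overlap follows interval geometry", {
  lens <- c(chr1 = 100000L)
  track <- data.frame(chrom = "chr1", start = 10000L, end = 12000L)
  inside <- data.frame(chrom = "chr1", pos = 11000L)
  nearby <- data.frame(chrom = "chr1", pos = 12600L) # 600 bp from the interval
  expect_identical(window_overlap(inside, track, 10, lens), 1)
  expect_identical(window_overlap(nearby, track, 1000, lens), 0)
  expect_identical(window_overlap(nearby, track, 10000, lens), 1)
  empty <- track[0, ]
  expect_identical(window_overlap(inside, empty, 1000, lens), 0)
})

test_that("pseudo-breakpoint draws are seeded and respect constraints", {
  g <- make_genome(2, c(1e6, 3e6) / 100 * 100, seed = 401) # 1 Mb + 3 Mb
  reg <- region("chr1:1-500000")
  a <- draw_pseudo_breakpoints(498, g, "within_region", reg, seed = 5)
  b <- draw_pseudo_breakpoints(498, g, "within_region", reg, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$chrom == "chr1" & a$pos >= 1 & a$pos <= 500000))
  d <- draw_pseudo_breakpoints(10000, g, "genome_wide", seed = 6)
  # chromosome choice proportional to length: 25%/75% within 3 binomial SD
  expect_lt(abs(mean(d$chrom == "chr1") - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("a track covering everything gives ratio 1 and p 1", {
  g <- make_genome(1, 1e5, seed = 402)
  full <- data.frame(chrom = "chr1", start = 1L, end = 100000L)
  bp <- draw_pseudo_breakpoints(50, g, seed = 7)
  r <- enrichment_test(bp, full, 1000, n_perm = 200, genome = g, seed = 8)
  expect_identical(r$enrichment_ratio, 1)
  expect_identical(r$p_value, 1)
})

test_that("planted enrichment approaches the inverse covered fraction", {
  g <- make_genome(1, 1e6, seed = 403)
  tr <- make_tracks(g, list(x = list(fraction = 0.25, mean_len = 5000)),
                    seed = 404)$x
  # all breakpoints inside the track, vanishing window
  set.seed(405)
  idx <- sample(nrow(tr), 200, replace = TRUE)
  bp <- data.frame(chrom = "chr1",
                   pos = as.integer((tr$start[idx] + tr$end[idx]) / 2))
  r <- enrichment_test(bp, tr, 2, n_perm = 2000, genome = g, seed = 406)
  expect_lt(abs(r$enrichment_ratio - 1 / 0.25) / 4, 0.1)
  expect_lt(r$p_value, 0.01)
})

test_that("complement track obeys the depletion-symmetry identity", {
  g <- make_genome(1, 1e6, seed = 407)
  tr <- make_tracks(g, list(x = list(fraction = 0.3, mean_len = 4000)),
                    seed = 408)$x
  e <- sum(tr$end - tr$start + 1) / 1e6
  # complement intervals
  ir <- IRanges::gaps(IRanges::IRanges(tr$start, tr$end), start = 1, end = 1e6)
  comp <- data.frame(chrom = "chr1", start = IRanges::start(ir),
                     end = IRanges::end(ir))
  bp <- draw_pseudo_breakpoints(300, g, "within_region",
                                region("chr1:1-1000000"), seed = 409)
  r1 <- enrichment_test(bp, tr, 2, n_perm = 3000, genome = g, seed = 410)
  r2 <- enrichment_test(bp, comp, 2, n_perm = 3000, genome = g, seed = 411)
  pred <- (1 - r1$enrichment_ratio * e) / (1 - e)
  expect_lt(abs(r2$enrichment_ratio - pred), 0.05)
})

test_that("ratios are invariant under chromosome relabeling", {
  g <- make_genome(1, 2e5, seed = 412)
  tr <- make_tracks(g, list(x = list(fraction = 0.2, mean_len = 2000)),
                    seed = 413)$x
  bp <- draw_pseudo_breakpoints(80, g, seed = 414)
  r1 <- enrichment_test(bp, tr, 1000, n_perm = 500, genome = g, seed = 415)
  lens2 <- c(chrZ = 200000L)
  tr2 <- transform(tr, chrom = "chrZ")
  bp2 <- transform(bp, chrom = "chrZ")
  r2 <- enrichment_test(bp2, tr2, 1000, n_perm = 500, genome = lens2, seed = 415)
  expect_equal(r1$enrichment_ratio, r2$enrichment_ratio)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the enrichment table covers tracks x windows with BH column", {
  g <- make_genome(1, 2e5, seed = 416)
  trs <- make_tracks(g, list(gene = list(fraction = 0.3, mean_len = 2000),
                             te = list(fraction = 0.1, mean_len = 3000)),
                     seed = 417)
  bp <- draw_pseudo_breakpoints(60, g, seed = 418)
  tab <- enrich_tracks(bp, trs, windows = c(1000, 10000), n_perm = 200,
                       genome = g, seed = 419)
  expect_identical(nrow(tab), 4L)
  expect_true(all(c("track", "window", "enrichment_ratio", "p_value",
                    "p_adj_BH") %in% names(tab)))
  expect_true(all(tab$p_value >= 1 / 201 & tab$p_value <= 1))
})
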