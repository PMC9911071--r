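# Parental allele dosage: pileups, diagnostic SNPs, binned frequencies,
# expected states, and meiotic-stage inference.

test_that("diagnostic SNP selection applies fixation and depth rules", {
  mkp <- function(A, C, G, T) {
    data.frame(chrom = "chr1", pos = seq_along(A), A = A, C = C, G = G, T = T,
               depth = A + C + G + T)
  }
  # pos 1: A fixed T / B fixed C -> diagnostic
  # pos 2: both parents T -> excluded
  # pos 3: parent A 10xT 5xC (minor 0.33) -> excluded
  pa <- mkp(A = c(0, 0, 0), C = c(0, 0, 5), G = c(0, 0, 0), T = c(20, 15, 10))
  pb <- mkp(A = c(0, 0, 0), C = c(18, 0, 20), G = c(0, 0, 0), T = c(0, 12, 0))
  snps <- select_diagnostic_snps(pa, pb, min_depth = 10, max_minor = 0.1)
  expect_identical(snps$pos, 1L)
  expect_identical(snps$alleleA, "T")
  expect_identical(snps$alleleB, "C")
})

test_that("binned frequency pools reads, not SNPs, and masks thin bins", {
  lens <- c(chr1 = 20000L)
  counts <- data.frame(chrom = "chr1", pos = c(2000L, 4000L, 12000L),
                       alleleA = "T", alleleB = "C",
                       nA = c(20L, 10L, 3L), nB = c(20L, 10L, 2L))
  fb <- binned_allele_freq(counts, lens, bin_size = 10000, floor = 20)
  expect_identical(fb$n_snps, c(2L, 1L))
  expect_equal(fb$freq_B[1], 30 / 60)
  expect_true(fb$masked[2]) # 5 informative reads < floor
  expect_true(is.na(fb$freq_B[2]))
  # read-weighted pooling: 20 B of 60 -> 1/3 even though per-SNP mean differs
  counts2 <- data.frame(chrom = "chr1", pos = c(2000L, 4000L),
                        alleleA = "T", alleleB = "C",
                        nA = c(38L, 2L), nB = c(12L, 8L))
  fb2 <- binned_allele_freq(counts2, lens, bin_size = 10000, floor = 20)
  expect_equal(fb2$freq_B[1], 20 / 60)
})

test_that("expected allele frequency is the exact copy fraction and scale-free", {
  expect_identical(expected_allele_frequency(c("A", "B")), 1 / 2)
  expect_identical(expected_allele_frequency(c("A", "A", "B")), 1 / 3)
  expect_identical(expected_allele_frequency(c("A", "B", "B")), 2 / 3)
  expect_identical(expected_allele_frequency(c("A", "A")), 0)
  expect_identical(expected_allele_frequency(rep(c("A", "A", "B"), 4)), 1 / 3)
  expect_error(expected_allele_frequency(character(0)), "copy")
})

test_that("bins classify to the nearest state within tolerance", {
  fb <- data.frame(chrom = "chr1", start = 1, end = 10000,
                   freq_B = c(0.34, 0.42, 0.51, 0.65, 0.02),
                   masked = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cl <- classify_bins(fb, tol = 0.05)
  expect_identical(cl$state_label, c("1/3", "other", "1/2", "2/3", NA))
  expect_error(classify_bins(fb, tol = 0.2), "tol")
})

test_that("stage inference follows the allele-dosage logic", {
  mk <- function(labels) {
    n <- length(labels)
    data.frame(chrom = "chr1", start = seq(1, by = 10000, length.out = n),
               end = seq(10000, by = 10000, length.out = n),
               freq_B = NA, masked = FALSE,
               state = NA, state_label = labels)
  }
  reg <- region("chr1:1-200000")
  expect_identical(infer_stage(mk(rep(c("1/3", "1/2"), 10)), reg)$verdict,
                   "meiosis_I")
  expect_identical(infer_stage(mk(rep("2/3", 20)), reg)$verdict, "meiosis_II")
  expect_identical(infer_stage(mk(rep("0", 20)), reg)$verdict, "meiosis_II")
  expect_identical(infer_stage(mk(rep("1/2", 20)), reg)$verdict, "balanced")
  expect_identical(infer_stage(mk(rep("other", 20)), reg)$verdict, "inconclusive")
  # pericentromeric subregion dominates when populated
  lab <- c(rep("1/2", 10), rep("2/3", 10))
  peri <- region("chr1:100001-200000")
  expect_identical(infer_stage(mk(lab), reg, peri)$verdict, "meiosis_II")
})

test_that("read-level allele frequencies recover the karyotype dosage", {
  fx <- fx_detect()
  sc <- snp_allele_counts(fx$reads$aln, fx$haps$snps)
  fb <- binned_allele_freq(sc, fx$genome, bin_size = 10000, floor = 20)
  # trisomic {A,A,B} arm: 1/3; disomic remainder: 1/2 (meiosis-I offspring,
  # intact maternal B, shattered extra copy A, no fragment loss)
  arm <- fb$start >= 1 & fb$end <= 150000 & !fb$masked
  rest <- fb$start > 160000 & !fb$masked
  expect_lt(abs(mean(fb$freq_B[arm]) - 1 / 3), 0.02)
  expect_lt(abs(mean(fb$freq_B[rest]) - 1 / 2), 0.02)
  # genome-wide pooled parent-A fraction at least 1/2 for this offspring
  expect_gte(sum(sc$nA) / sum(sc$nA + sc$nB), 0.5)
})

test_that("paternal parent-A contribution bounds karyotype allele fractions", {
  g <- make_genome(1, 5e4, seed = 301)
  h <- derive_haplotypes(g, 0.002, seed = 302)
  sh <- shatter(g, region("chr1:10001-40000"), 4, loss_fraction = 0, seed = 303)
  grid <- offspring_karyotype_grid(sh$genome, h, sh$event)
  for (k in grid) {
    # the paternal copy is always haplotype A
    expect_true(any(vapply(k$chromatids, function(ch)
      startsWith(ch$label, "paternal_A"), logical(1))))
    # disomic loci always carry at least one parent-A copy
    expect_gte(parentA_disomic_floor(k), 0.5)
  }
  # pooled genome-wide fraction respects the floor for balanced and
  # extra-copy-A karyotypes
  expect_gte(karyotype_parentA_fraction(grid$balanced_mB), 0.5)
  expect_gte(karyotype_parentA_fraction(grid$meiosis_I_mB), 0.5)
})

test_that("stage recovery from reads works across all three origins", {
  g <- fixture("stage_genome", make_genome(1, 3e5, seed = 310))
  reg <- region("chr1:50001-250000")
  peri <- region("chr1:120001-180000")
  verdicts <- vapply(c("balanced", "meiosis_I", "meiosis_II"), function(stage) {
    sh <- shatter(g, reg, n_fragments = 6, loss_fraction = 0.15, seed = 311)
    h <- derive_haplotypes(sh$genome, 0.003, seed = 312)
    k <- make_offspring(sh$genome, h, if (stage == "balanced") NULL else sh$event,
                        stage, maternal_hap = "B")
    rs <- simulate_reads(k, depth = 30, seed = 313)
    sc <- snp_allele_counts(rs$aln, h$snps)
    cl <- classify_bins(binned_allele_freq(sc, sh$genome, 10000, 20))
    infer_stage(cl, reg, peri)$verdict
  }, character(1))
  expect_identical(unname(verdicts), c("balanced", "meiosis_I", "meiosis_II"))
})
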