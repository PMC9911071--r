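# Synthetic-data generator: determinism, composition, shatter ground truth,
# offspring karyotypes, read dosage, and annotation tracks.

test_that("genomes are reproducible from their seed and hit the GC target", {
  g1 <- make_genome(1, 1e5, gc = 0.36, seed = 7)
  g2 <- make_genome(1, 1e5, gc = 0.36, seed = 7)
  expect_identical(g1$chroms, g2$chroms)
  expect_true(all(strsplit(g1$chroms[[1]], "")[[1]] %in% c("A", "C", "G", "T")))
  gc <- sum(strsplit(g1$chroms[[1]], "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - 0.36), 0.02)
  expect_error(make_genome(1, 0), "10 kb")
  expect_error(make_genome(1, 1e5, gc = 1.2), "gc")
})

test_that("haplotype SNP counts follow the requested rate and alleles differ", {
  g <- make_genome(1, 1e6, seed = 1)
  h <- derive_haplotypes(g, snp_rate = 0.001, seed = 2)
  # binomial(1e6, 1e-3): mean 1000, sd ~31.6
  expect_lt(abs(nrow(h$snps) - 1000), 3 * sqrt(1000 * 0.999))
  expect_true(all(h$snps$alleleA != h$snps$alleleB))
  expect_true(all(diff(h$snps$pos) > 0))
  ref <- substring(g$chroms[[1]], h$snps$pos, h$snps$pos)
  expect_identical(h$snps$alleleA, ref)
  expect_identical(nrow(derive_haplotypes(g, 0, seed = 3)$snps), 0L)
  expect_error(derive_haplotypes(g, 0.5), "snp_rate")
})

test_that("shatter round-trips: the event reconstructs the derivative exactly", {
  g <- make_genome(1, 1e5, seed = 5)
  for (s in c(11, 12, 13)) {
    sh <- shatter(g, region("chr1:20001-80000"), n_fragments = 6,
                  loss_fraction = 0.2, seed = s)
    expect_identical(derivative_sequence(sh$event, sh$genome), sh$derivative)
    # sequence outside the region untouched
    expect_identical(substring(sh$genome$chroms[[1]], 1, 20000),
                     substring(g$chroms[[1]], 1, 20000))
    expect_identical(substring(sh$genome$chroms[[1]], 80001, 1e5),
                     substring(g$chroms[[1]], 80001, 1e5))
    # truth junction count = retained fragments - 1
    expect_identical(nrow(sh$event$junctions), nrow(sh$event$fragments) - 1L)
    # fragments + lost fragments partition the region
    all_fr <- rbind(sh$event$fragments[, c("ref_start", "ref_end")],
                    sh$event$lost_fragments[, c("ref_start", "ref_end")])
    all_fr <- all_fr[order(all_fr$ref_start), ]
    expect_identical(all_fr$ref_start[1], 20001L)
    expect_identical(all_fr$ref_end[nrow(all_fr)], 80000L)
    expect_true(all(diff(all_fr$ref_start) == utils::head(all_fr$ref_end + 1L, -1) -
                      utils::head(all_fr$ref_start, -1)))
  }
})

test_that("shatter honours the repair mix and stated length ranges", {
  g <- make_genome(1, 2e5, seed = 6)
  sh <- shatter(g, region("chr1:1-150000"), n_fragments = 14, loss_fraction = 0,
                repair_mix = c(microhomology = 1, perfect = 0, insertion = 0),
                seed = 21)
  expect_identical(nrow(sh$event$junctions), 13L) # 14 fragments, no loss
  novel <- sh$event$junctions[sh$event$junctions$novel, ]
  expect_true(all(novel$repair_class == "microhomology"))
  expect_true(all(novel$mh_len >= 1 & novel$mh_len <= 29))
  sh2 <- shatter(g, region("chr1:1-150000"), n_fragments = 10, loss_fraction = 0,
                 repair_mix = c(microhomology = 0, perfect = 0, insertion = 1),
                 seed = 22)
  novel2 <- sh2$event$junctions[sh2$event$junctions$novel, ]
  expect_true(all(novel2$repair_class == "insertion"))
  expect_true(all(nchar(novel2$ins_seq) >= 1 & nchar(novel2$ins_seq) <= 80))
  expect_error(shatter(g, region("chr1:1-300000"), 5), "bounds")
  expect_error(shatter(g, region("chr1:1-1000"), 50), "n_fragments")
})

test_that("an identity arrangement leaves the region sequence unchanged", {
  g <- make_genome(1, 5e4, seed = 8)
  # search a seed whose permutation is the identity with all-plus orientation
  found <- FALSE
  for (s in 1:200) {
    sh <- shatter(g, region("chr1:10001-30000"), n_fragments = 2,
                  loss_fraction = 0, seed = s,
                  repair_mix = c(microhomology = 0, perfect = 1, insertion = 0))
    fr <- sh$event$fragments
    if (all(fr$orient == "+") && !is.unsorted(fr$ref_start)) {
      expect_identical(sh$derivative, substring(g$chroms[[1]], 10001, 30000))
      expect_false(any(sh$event$junctions$novel))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # derange never yields the identity
  for (s in 1:20) {
    sh <- shatter(g, region("chr1:10001-30000"), n_fragments = 2,
                  loss_fraction = 0, seed = s, derange = TRUE)
    fr <- sh$event$fragments
    expect_true(any(fr$orient == "-") || is.unsorted(fr$ref_start))
  }
})

test_that("offspring karyotypes carry the stage-specific haplotype multisets", {
  g <- make_genome(1, 5e4, seed = 9)
  h <- derive_haplotypes(g, 0.002, seed = 10)
  sh <- shatter(g, region("chr1:10001-40000"), 4, loss_fraction = 0, seed = 11)
  pos <- c(15000L, 25000L, 45000L)

  bal <- make_offspring(sh$genome, h, NULL, "balanced", maternal_hap = "B")
  hc <- haplotype_copies(bal, "chr1", pos)
  expect_true(all(hc$copies_A + hc$copies_B == 2L))
  expect_true(all(hc$copies_A == 1L))

  m1 <- make_offspring(sh$genome, h, sh$event, "meiosis_I", maternal_hap = "B")
  hc1 <- haplotype_copies(m1, "chr1", pos)
  # shattered extra copy differs from the intact maternal copy (A vs B)
  expect_identical(hc1$copies_A[1:2], c(2L, 2L)) # region: {A,A,B}
  expect_identical(hc1$copies_B[1:2], c(1L, 1L))
  expect_identical(hc1$copies_A[3] + hc1$copies_B[3], 2L) # outside the arm

  m2 <- make_offspring(sh$genome, h, sh$event, "meiosis_II", maternal_hap = "B")
  hc2 <- haplotype_copies(m2, "chr1", pos)
  expect_identical(hc2$copies_B[1:2], c(2L, 2L)) # region: {A,B,B}
  expect_identical(hc2$copies_A[1:2], c(1L, 1L))
  # paternal copy is always haplotype A
  expect_true(any(vapply(m2$chromatids, function(ch)
    startsWith(ch$label, "paternal_A"), logical(1))))
})

test_that("read dosage scales linearly with copy number", {
  fx <- fx_detect()
  sb <- bin_counts(fx$reads$aln, fx$genome, bin_size = 5000)
  # per-bin expected count is proportional to copy number; regress
  mid <- (sb$start + sb$end) / 2
  cn <- copy_number(fx$kary, "chr1", as.integer(mid))
  keep <- sb$start > 2000 & sb$end < 398000 # drop chromosome-end ramps
  fit <- stats::lm(sb$count[keep] ~ 0 + cn[keep])
  per_copy <- unname(stats::coef(fit)[1]) / 5000
  # depth 30, 100-bp reads: two mates per pair, so the per-copy per-base
  # record-start rate is depth / (2 * read_len) = 0.15
  expect_lt(abs(per_copy - 30 / 200) / (30 / 200), 0.05)
  # trisomic retained fragments vs disomic remainder
  expect_gt(mean(sb$count[keep & cn == 3]) / mean(sb$count[keep & cn == 2]), 1.40)
})

test_that("idealized alignments report junction-spanning pairs at both loci", {
  fx <- fx_detect()
  rec <- find_distant_pairs(fx$reads$aln, 2000)
  truth <- detectable_truth(fx$event)
  # every detectable truth junction is supported by distant pairs near its
  # breakpoints
  for (i in seq_len(nrow(truth))) {
    hit <- (abs(rec$pos1 - truth$left_bp[i]) < 600 &
              abs(rec$pos2 - truth$right_bp[i]) < 600) |
      (abs(rec$pos1 - truth$right_bp[i]) < 600 &
         abs(rec$pos2 - truth$left_bp[i]) < 600)
    expect_gt(sum(hit), 2)
  }
  # identical seeds give identical read sets
  r2 <- simulate_reads(fx$kary, depth = 30, seed = 74)
  expect_identical(fx$reads$pairs, r2$pairs)
  expect_identical(fx$reads$aln, r2$aln)
})

test_that("track generator hits target fractions; state tracks partition", {
  g <- make_genome(1, 2e5, seed = 30)
  tr <- make_tracks(g, list(gene = list(fraction = 0.25, mean_len = 2000),
                            none = list(fraction = 0, mean_len = 500)),
                    seed = 31)
  cov <- sum(tr$gene$end - tr$gene$start + 1) / 2e5
  expect_lt(abs(cov - 0.25) / 0.25, 0.1)
  expect_identical(nrow(tr$none), 0L)
  ir <- IRanges::IRanges(tr$gene$start, tr$gene$end)
  expect_identical(length(IRanges::findOverlaps(ir, ir)), length(ir)) # disjoint
  expect_error(make_tracks(g, list(x = list(fraction = 1.5, mean_len = 100))),
               "fraction")

  st <- make_state_tracks(g, n_states = 9, mean_len = 3000, seed = 32)
  expect_length(st, 9L)
  allint <- do.call(rbind, st)
  expect_identical(sum(allint$end - allint$start + 1L), 200000L) # union = genome
  ir2 <- IRanges::IRanges(allint$start, allint$end)
  expect_identical(length(IRanges::findOverlaps(ir2, ir2)), length(ir2))
})

test_that("segment deletion produces a copy-number-1 region", {
  g <- make_genome(1, 5e4, seed = 33)
  h <- derive_haplotypes(g, 0.001, seed = 34)
  k <- make_offspring(g, h, NULL, "balanced")
  kd <- delete_segment(k, region("chr1:20001-30000"))
  expect_identical(copy_number(kd, "chr1", c(15000L, 25000L, 35000L)),
                   c(2L, 1L, 2L))
})
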