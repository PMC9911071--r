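# Junction discovery: distant pairs, clustering, control logic, support
# threshold, assembly, anchoring, repair classification, spacing.

test_that("distant-pair extraction applies the distance-or-chromosome rule", {
  aln <- rbind(mk_pair("a", "chr1", 100000, "chr1", 150000),
               mk_pair("b", "chr1", 10000, "chr1", 11500),
               mk_pair("c", "chr1", 5000, "chr2", 100))
  rec <- find_distant_pairs(aln, 2000)
  expect_setequal(rec$qname, c("a", "c")) # 50 kb apart kept, 1.5 kb dropped
  expect_identical(rec$chrom2[rec$qname == "c"], "chr2")
  expect_error(find_distant_pairs(mk_aln("solo", "chr1", 1)), "unpaired")
})

test_that("pair clustering merges nearby records and splits distant ones", {
  rec <- find_distant_pairs(do.call(rbind, lapply(1:5, function(i)
    mk_pair(paste0("p", i), "chr1", 10000 + i * 50, "chr1", 90000 + i * 40))))
  ev <- cluster_pairs(rec, radius = 300)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$support, 5L)
  # two pairs 10 kb apart on side 1 form two clusters
  rec2 <- find_distant_pairs(rbind(mk_pair("x", "chr1", 10000, "chr1", 90000),
                                   mk_pair("y", "chr1", 20000, "chr1", 90000)))
  expect_identical(nrow(cluster_pairs(rec2, 500)), 2L)
  expect_error(cluster_pairs(rec, radius = 0), "radius")
})

test_that("control subtraction removes shared artifacts and is idempotent", {
  mkev <- function(p1, p2) cluster_pairs(find_distant_pairs(
    do.call(rbind, lapply(1:4, function(i)
      mk_pair(paste0("q", i, p1), "chr1", p1 + i * 10, "chr1", p2 + i * 10)))))
  target <- rbind(mkev(10000, 90000), mkev(30000, 120000))
  target$cluster <- seq_len(nrow(target))
  ctrl <- mkev(10020, 90020) # matches the first target cluster
  kept <- subtract_controls(target, ctrl, radius = 500)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$pos1, target$pos1[2])
  expect_identical(subtract_controls(kept, ctrl, radius = 500), kept)
  # absent from controls: kept untouched
  expect_identical(nrow(subtract_controls(target, target[0, ], radius = 500)), 2L)
})

test_that("support threshold follows max(3, ceil(mu + 3*sqrt(mu)))", {
  expect_identical(support_threshold_model(list())$min_support, 3L)
  ev4 <- data.frame(support = c(4L, 4L))
  expect_identical(support_threshold_model(list(ev4))$min_support, 10L)
  ev <- data.frame(support = c(1L, 5L))
  filt <- support_filter(ev, support_threshold_model(list()))
  expect_identical(filt$support, 5L)
})

test_that("repair classification reads constructed junctions correctly", {
  # reference with two well-separated unique segments
  g <- make_genome(1, 30000, seed = 101)
  refc <- g$chroms[[1]]
  leftf <- substring(refc, 4901, 5000)   # left flank, ends at bp1 = 5000
  rightf <- substring(refc, 20001, 20100) # right flank, starts at bp2 = 20001

  # microhomology of 4: make the 4 bases after bp2 equal the last 4 of left
  g2 <- g
  v <- strsplit(refc, "")[[1]]
  v[20001:20004] <- strsplit(substring(leftf, 97, 100), "")[[1]]
  # stop extension on both sides
  if (v[20005] == v[5001]) v[20005] <- setdiff(c("A","C","G","T"), v[5001])[1]
  if (v[4996] == v[20000]) v[4996] <- setdiff(c("A","C","G","T"), v[20000])[1]
  g2$chroms[[1]] <- paste0(v, collapse = "")
  contig_mh <- paste0(substring(g2$chroms[[1]], 4901, 5000),
                      substring(g2$chroms[[1]], 20005, 20100))
  loc <- locate_breakpoints(contig_mh, g2)
  expect_identical(loc$status, "ok")
  expect_identical(c(loc$bp1, loc$bp2), c(5000L, 20001L))
  expect_identical(loc$orientation_class, "tail_head")
  rep <- classify_repair(contig_mh, loc)
  expect_identical(rep$repair_class, "microhomology")
  expect_identical(rep$mh_len, 4L)

  # perfect join and 5-bp insertion on the unedited genome
  mk_loc <- function(contig) locate_breakpoints(contig, g)
  if (substring(refc, 20001, 20001) != substring(refc, 5001, 5001) &&
      substring(refc, 5000, 5000) != substring(refc, 20000, 20000)) {
    locp <- mk_loc(paste0(leftf, rightf))
    expect_identical(classify_repair(paste0(leftf, rightf), locp)$repair_class,
                     "perfect")
  }
  ins <- "TTTTG"
  contig_ins <- paste0(leftf, ins, rightf)
  loci <- mk_loc(contig_ins)
  repi <- classify_repair(contig_ins, loci)
  expect_identical(repi$repair_class, "insertion")
  expect_identical(nchar(repi$ins_seq), 5L)

  # anti-symmetric stability: the reverse complement classifies identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig_mh)))
  locr <- locate_breakpoints(rc, g2)
  repr <- classify_repair(rc, locr)
  expect_identical(repr$repair_class, "microhomology")
  expect_identical(repr$mh_len, 4L)
  expect_setequal(c(locr$bp1, locr$bp2), c(5000L, 20001L))
})

test_that("a flank present twice in the reference is flagged multi-mapping", {
  g <- make_genome(1, 30000, seed = 102)
  refc <- g$chroms[[1]]
  # plant an exact 120-bp duplicate of the left-flank region elsewhere
  dup <- substring(refc, 4881, 5000)
  v <- strsplit(refc, "")[[1]]
  v[25001:25120] <- strsplit(dup, "")[[1]]
  g$chroms[[1]] <- paste0(v, collapse = "")
  contig <- paste0(substring(g$chroms[[1]], 4901, 5000), "TTTTG",
                   substring(g$chroms[[1]], 20001, 20100))
  loc <- locate_breakpoints(contig, g)
  expect_identical(loc$status, "ok")
  expect_false(loc$unique_mapping)
})

test_that("assembly reports branches and insufficient input instead of guessing", {
  expect_identical(assemble_contig(data.frame(seq = "ACGTACGTACGT",
                                              member = TRUE))$status,
                   "insufficient")
  # two incompatible junction continuations with comparable member support:
  # the seed ends at the shared flank, and the pool continues into two
  # different distal sequences
  g <- make_genome(1, 30000, seed = 103)
  refc <- g$chroms[[1]]
  left <- substring(refc, 1001, 1100)
  contA <- substring(refc, 5001, 5100)
  contB <- substring(refc, 9001, 9100)
  reads <- data.frame(
    seq = c(substring(left, 41, 100), # seed: pure shared flank
            paste0(substring(left, 21, 100), substring(contA, 1, 20)),
            paste0(substring(left, 31, 100), substring(contA, 1, 30)),
            paste0(substring(left, 21, 100), substring(contB, 1, 20)),
            paste0(substring(left, 31, 100), substring(contB, 1, 30))),
    member = TRUE)
  asm <- assemble_contig(reads, k = 31, seed_idx = 1L)
  expect_identical(asm$status, "branched")
})

test_that("the full caller recovers simulated junctions with exact chemistry", {
  fx <- fx_detect()
  calls <- fx$jc$calls
  truth <- detectable_truth(fx$event)
  m <- match_calls(calls, truth)
  # recall over detectable truth and precision over calls
  expect_gte(mean(!is.na(m$truth_match)), 0.9)
  expect_gte(mean(!is.na(m$call_match)), 0.95)
  # chemistry recovered exactly on matched calls
  for (i in which(!is.na(m$truth_match))) {
    j <- m$truth_match[i]
    expect_identical(calls$repair_class[j], truth$repair_class[i])
    if (truth$repair_class[i] == "microhomology")
      expect_identical(calls$mh_len[j], truth$mh_len[i])
    if (truth$repair_class[i] == "insertion") {
      ok <- identical(calls$ins_seq[j], truth$ins_seq[i]) ||
        identical(calls$ins_seq[j],
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(truth$ins_seq[i]))))
      expect_true(ok)
    }
  }
  # every reported call satisfies the output contract
  expect_true(all(calls$support >= fx$jc$support_model$min_support))
  expect_true(all(calls$unique_mapping))
})

test_that("breakpoint spacing arithmetic matches the worked example", {
  # 249 junctions with both ends inside a 16.1-Mb region -> 498 breakpoints
  set.seed(7)
  bp <- data.frame(chrom = "chr1", pos = sample.int(16100000, 498))
  sp <- breakpoint_density(bp, region("chr1:1-16100000"))
  expect_identical(round(sp), 32)
  expect_identical(breakpoint_density(data.frame(chrom = "chr1", pos = 5e5),
                                      region("chr1:1-1000000")), 1000)
  expect_error(breakpoint_density(data.frame(chrom = character(0), pos = integer(0)),
                                  region("chr1:1-1000000")), "undefined")
})
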