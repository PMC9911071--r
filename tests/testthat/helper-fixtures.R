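# Shared fixtures, built once per test run and memoized (several suites walk
# the same simulated scenario).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Minimal alignment-table row builder for constructed unit tests.
mk_aln <- function(qname, rname, pos, strand = "+", seq = strrep("A", 100),
                   mate = 1L) {
  flag <- 1L + (if (mate == 1L) 64L else 128L) + (if (strand == "-") 16L else 0L)
  data.frame(qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
             mapq = 60L, cigar = paste0(nchar(seq), "M"), rnext = "*",
             pnext = 0L, tlen = 0L, seq = seq, stringsAsFactors = FALSE)
}

mk_pair <- function(qname, rname1, pos1, rname2, pos2, strand1 = "+",
                    strand2 = "-", seq = strrep("A", 100)) {
  rbind(mk_aln(qname, rname1, pos1, strand1, seq, mate = 1L),
        mk_aln(qname, rname2, pos2, strand2, seq, mate = 2L))
}

# A mid-size shattered-line scenario used by the junction, reconstruction and
# coverage suites: 400-kb chromosome, 150-kb shattered arm (a minority of the
# genome, as in the study), no fragment loss.
fx_detect <- function() fixture("detect", {
  g <- make_genome(1, 4e5, 0.36, seed = 71)
  sh <- shatter(g, region("chr1:1-150000"), n_fragments = 8, loss_fraction = 0,
                seed = 72)
  genome <- sh$genome
  haps <- derive_haplotypes(genome, 0.002, seed = 73)
  kary <- make_offspring(genome, haps, sh$event, "meiosis_I")
  reads <- simulate_reads(kary, depth = 30, seed = 74)
  ctrl <- lapply(c(75, 76), function(s)
    simulate_reads(make_offspring(genome, haps, NULL, "balanced"),
                   depth = 30, seed = s))
  jc <- call_junctions(reads$aln, lapply(ctrl, `[[`, "aln"), genome)
  list(genome = genome, event = sh$event, haps = haps, kary = kary,
       reads = reads, ctrl = ctrl, jc = jc,
       region = region("chr1:1-150000"))
})

# Match detected calls against truth junctions (unordered breakpoint pairs,
# orientation class respected; tolerance in bp). Returns per-truth and
# per-call match indices.
match_calls <- function(calls, truth, tol = 2) {
  truth_match <- rep(NA_integer_, nrow(truth))
  call_match <- rep(NA_integer_, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      same <- function(b1, b2) abs(b1 - b2) <= tol
      fwd <- same(calls$bp1[j], truth$left_bp[i]) &&
        same(calls$bp2[j], truth$right_bp[i])
      rev <- same(calls$bp1[j], truth$right_bp[i]) &&
        same(calls$bp2[j], truth$left_bp[i])
      if ((fwd || rev) && calls$orientation_class[j] == truth$orientation_class[i]) {
        truth_match[i] <- j
        call_match[j] <- i
        attr(truth_match, "flipped") <- c(attr(truth_match, "flipped"),
                                          stats::setNames(rev && !fwd, i))
        break
      }
    }
  }
  list(truth_match = truth_match, call_match = call_match)
}

# Cut positions implied by a junction table (a tail side at p cuts at p, a
# head side at p cuts at p-1).
junction_cuts <- function(j) {
  unique(c(ifelse(j$side1 == "tail", j$left_bp, j$left_bp - 1L),
           ifelse(j$side2 == "tail", j$right_bp, j$right_bp - 1L)))
}

# Junction indices whose removal leaves every one of their cuts implied by a
# remaining junction: for these, deleting the call splits its chain into
# exactly two (removing others can merge segments across a chain terminus and
# close a cycle instead).
deletable_junctions <- function(truth) {
  which(vapply(seq_len(nrow(truth)), function(i)
    all(junction_cuts(truth[i, , drop = FALSE]) %in%
          junction_cuts(truth[-i, , drop = FALSE])), logical(1)))
}

# Truth junctions detectable by the distant-pair rule: novel, with
# breakpoints further apart than min_distance.
detectable_truth <- function(event, min_distance = 2000) {
  j <- event$junctions
  j[j$novel & abs(j$right_bp - j$left_bp) > min_distance, , drop = FALSE]
}
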