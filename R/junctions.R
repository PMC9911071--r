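# Novel-DNA-junction discovery: distant-mate read pairs are clustered into
# junction evidence, filtered against controls and a support threshold, then
# resolved to exact breakpoints by local greedy assembly of a junction-
# spanning contig and maximal exact-match anchoring of its two flanks to the
# reference, which also reads off the repair chemistry (microhomology /
# perfect / insertion) at the join.

#' Extract distant-mate pair records from an alignment table
#'
#' Keeps read pairs whose mates map more than `min_distance` bp apart or to
#' different chromosomes. Sides are canonicalized so side 1 is the
#' lexicographically lower (chrom, pos) locus.
#'
#' @param aln Alignment table with both mates present for every read name.
#' @param min_distance Minimum inter-mate distance in bp (same chromosome).
#' @return Data frame: qname, chrom1, pos1, strand1, chrom2, pos2, strand2.
#' @export
find_distant_pairs <- function(aln, min_distance = 2000L) {
  aln <- aln[order(aln$qname), , drop = FALSE]
  cnt <- table(aln$qname)
  if (any(cnt != 2L)) stopf("unpaired input: %d read name(s) lack exactly 2 records",
                            sum(cnt != 2L))
  i1 <- seq(1L, nrow(aln), by = 2L); i2 <- i1 + 1L
  str <- aln_strand(aln)
  swap <- aln$rname[i1] > aln$rname[i2] |
    (aln$rname[i1] == aln$rname[i2] & aln$pos[i1] > aln$pos[i2])
  a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
  rec <- data.frame(qname = aln$qname[a],
                    chrom1 = aln$rname[a], pos1 = aln$pos[a], strand1 = str[a],
                    chrom2 = aln$rname[b], pos2 = aln$pos[b], strand2 = str[b],
                    stringsAsFactors = FALSE)
  keep <- rec$chrom1 != rec$chrom2 | (rec$pos2 - rec$pos1) > min_distance
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Cluster distant-pair records into junction evidence
#'
#' Records agreeing in strand on both sides and lying within `radius` bp of
#' each other on both sides are merged; support is the member count.
#'
#' @param records Output of [find_distant_pairs()].
#' @param radius Clustering radius in bp (> 0).
#' @return Evidence data frame: cluster, chrom1, pos1, strand1, chrom2, pos2,
#'   strand2, support, qnames (comma-separated member read names).
#' @export
cluster_pairs <- function(records, radius = 500L) {
  if (radius <= 0) stopf("radius must be > 0")
  empty <- data.frame(cluster = integer(), chrom1 = character(), pos1 = integer(),
                      strand1 = character(), chrom2 = character(), pos2 = integer(),
                      strand2 = character(), support = integer(),
                      qnames = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  key <- paste(records$chrom1, records$strand1, records$chrom2, records$strand2)
  out <- list()
  for (k in unique(key)) {
    d <- records[key == k, , drop = FALSE]
    d <- d[order(d$pos1), , drop = FALSE]
    g1 <- cumsum(c(1L, as.integer(diff(d$pos1) > radius)))
    for (g in unique(g1)) {
      e <- d[g1 == g, , drop = FALSE]
      e <- e[order(e$pos2), , drop = FALSE]
      g2 <- cumsum(c(1L, as.integer(diff(e$pos2) > radius)))
      for (h in unique(g2)) {
        f <- e[g2 == h, , drop = FALSE]
        out[[length(out) + 1]] <- data.frame(
          chrom1 = f$chrom1[1], pos1 = as.integer(round(stats::median(f$pos1))),
          strand1 = f$strand1[1],
          chrom2 = f$chrom2[1], pos2 = as.integer(round(stats::median(f$pos2))),
          strand2 = f$strand2[1],
          support = nrow(f), qnames = paste(f$qname, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$support), , drop = FALSE]
  res <- cbind(cluster = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

# Does evidence row x match evidence row y within radius (same strands)?
evidence_match <- function(x, y, radius) {
  x$chrom1 == y$chrom1 & x$chrom2 == y$chrom2 &
    x$strand1 == y$strand1 & x$strand2 == y$strand2 &
    abs(x$pos1 - y$pos1) <= radius & abs(x$pos2 - y$pos2) <= radius
}

#' Remove junction evidence shared with control samples
#'
#' A target cluster is dropped when any control cluster matches both of its
#' sides within `radius` bp with agreeing strands; the survivors are the
#' junctions unique to the target line. Idempotent.
#'
#' @param evidence Target evidence from [cluster_pairs()].
#' @param ... One or more control evidence tables computed with the same
#'   parameters.
#' @param radius Matching radius in bp.
#' @return Filtered target evidence.
#' @export
subtract_controls <- function(evidence, ..., radius = 500L) {
  ctrl <- list(...)
  if (nrow(evidence) == 0 || length(ctrl) == 0) return(evidence)
  drop <- logical(nrow(evidence))
  for (cv in ctrl) {
    if (is.null(cv) || nrow(cv) == 0) next
    for (i in seq_len(nrow(evidence))) {
      if (drop[i]) next
      if (any(evidence_match(evidence[i, ], cv, radius))) drop[i] <- TRUE
    }
  }
  out <- evidence[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Support-threshold model from control distant-pair density
#'
#' The minimum cluster support is `max(3, ceiling(mu + 3 * sqrt(mu)))`, where
#' `mu` is the expected artifact support per locus estimated from pooled
#' controls (mean support of control distant-pair clusters, scaled by
#' `depth_ratio` when target and control depths differ).
#'
#' @param control_evidence List of control evidence tables (may be empty).
#' @param depth_ratio Target depth divided by pooled-control depth.
#' @return A `support_model`: list with `mu` and `min_support`.
#' @export
support_threshold_model <- function(control_evidence = list(), depth_ratio = 1) {
  sup <- unlist(lapply(control_evidence, function(e) e$support))
  mu <- if (length(sup) == 0) 0 else mean(sup) * depth_ratio
  structure(list(mu = mu, min_support = max(3L, as.integer(ceiling(mu + 3 * sqrt(mu))))),
            class = "support_model")
}

#' Filter junction evidence by minimum support
#'
#' @param evidence Evidence table.
#' @param model A [support_threshold_model()].
#' @return Evidence with `support >= model$min_support`.
#' @export
support_filter <- function(evidence, model) {
  out <- evidence[evidence$support >= model$min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Local assembly

# Mismatch count of each alignment record against the reference (positional,
# cigar is all-M). Used to pick junction-spanning seed reads.
count_ref_mismatches <- function(aln, genome) {
  n <- integer(nrow(aln))
  for (chrom in unique(aln$rname)) {
    idx <- which(aln$rname == chrom)
    refc <- genome$chroms[[chrom]]
    sub <- substring(refc, aln$pos[idx], aln$pos[idx] + nchar(aln$seq[idx]) - 1L)
    n[idx] <- mapply(function(a, b) {
      ra <- charToRaw(a); rb <- charToRaw(b)
      m <- min(length(ra), length(rb))
      sum(ra[seq_len(m)] != rb[seq_len(m)]) + abs(length(ra) - length(rb))
    }, aln$seq[idx], sub, USE.NAMES = FALSE)
  }
  n
}

# Reads relevant to one evidence cluster: all mates of member pairs plus any
# read mapped within `window` bp of either side locus.
collect_junction_reads <- function(aln, ev, window = 400L) {
  members <- strsplit(ev$qnames, ",")[[1]]
  near <- (aln$rname == ev$chrom1 & abs(aln$pos - ev$pos1) <= window) |
          (aln$rname == ev$chrom2 & abs(aln$pos - ev$pos2) <= window)
  sel <- aln[near | aln$qname %in% members, , drop = FALSE]
  sel$member <- sel$qname %in% members
  sel
}

# Candidate extensions of `contig` to the right using pool reads (both
# orientations). Returns per-candidate extension string and member flag.
right_extension_candidates <- function(contig, seqs, member, k) {
  Lc <- nchar(contig)
  if (Lc < k) k <- Lc
  S <- substring(contig, Lc - k + 1L, Lc)
  ext <- character(0); mem <- logical(0)
  all_seq <- c(seqs, revcomp(seqs))
  all_mem <- c(member, member)
  p <- regexpr(S, all_seq, fixed = TRUE)
  hit <- which(p > 0)
  for (i in hit) {
    r <- all_seq[i]; pp <- p[i]
    # the part of the read overlapping the contig left of the seed must agree
    # (any read bases extending past the contig start are ignored here)
    if (pp > 1L) {
      take <- min(pp - 1L, Lc - k)
      if (take > 0L &&
          substring(r, pp - take, pp - 1L) !=
            substring(contig, Lc - k - take + 1L, Lc - k))
        next
    }
    e <- substring(r, pp + k)
    if (nchar(e) > 0) { ext <- c(ext, e); mem <- c(mem, all_mem[i]) }
  }
  list(ext = ext, member = mem)
}

# Build the extension by per-column majority consensus over the candidate
# reads. Columns where the cluster's own member reads disagree comparably
# signal a true branch (two junctions mixed); near-ties among non-member
# reads only truncate the extension at that column, so isolated disagreements
# (e.g. a heterozygous variant on a non-rearranged copy at 2:1 dosage) are
# outvoted rather than mistaken for junction sequence.
choose_extension <- function(cand) {
  if (length(cand$ext) == 0) return(list(ext = NULL, branched = FALSE))
  maxlen <- max(nchar(cand$ext))
  cons <- character(0)
  for (col in seq_len(maxlen)) {
    covers <- nchar(cand$ext) >= col
    b <- substring(cand$ext[covers], col, col)
    mem <- cand$member[covers]
    tab <- sort(table(b[mem]), decreasing = TRUE)
    if (length(tab) >= 2L && tab[2] >= 0.9 * tab[1])
      return(list(ext = NULL, branched = TRUE))
    if (length(tab) == 0L) {
      # no member evidence: require two covering reads before committing a
      # base, so a lone read cannot lock a variant allele into the contig
      if (length(b) < 2L) break
      tab <- sort(table(b), decreasing = TRUE)
      if (length(tab) >= 2L && tab[2] >= 0.9 * tab[1]) break
    }
    cons <- c(cons, names(tab)[1])
  }
  if (length(cons) == 0) return(list(ext = NULL, branched = FALSE))
  list(ext = paste0(cons, collapse = ""), branched = FALSE)
}

#' Assemble a junction-spanning contig by greedy exact-overlap extension
#'
#' Seeds on a read that disagrees with the reference (a junction-spanning
#' read), then extends in both directions with pool reads (either
#' orientation) sharing an exact `k`-mer overlap consistent with the growing
#' contig. When two incompatible extensions have comparable support from
#' junction-member reads the assembly is reported as branched rather than
#' guessed.
#'
#' @param reads Data frame with columns `seq`, `member` (junction-pair
#'   membership), and optionally `n_mismatch` used to rank seeds.
#' @param k Overlap seed length.
#' @param max_rounds Maximum extension steps per direction.
#' @param max_len Contig length cap in bp.
#' @param seed_idx Optional explicit seed-read row.
#' @return List with `contig` (or `NA`), and `status` in
#'   `{"ok","branched","insufficient"}`.
#' @export
assemble_contig <- function(reads, k = 31L, max_rounds = 100L, max_len = 2000L,
                            seed_idx = NULL) {
  if (nrow(reads) < 2L)
    return(list(contig = NA_character_, status = "insufficient"))
  if (is.null(seed_idx)) {
    rank <- if ("n_mismatch" %in% names(reads)) -reads$n_mismatch else
      -as.integer(reads$member)
    seed_idx <- order(rank)[1]
  }
  contig <- reads$seq[seed_idx]
  branched <- FALSE
  for (dir in 1:2) {
    if (dir == 2) contig <- revcomp(contig)
    for (round in seq_len(max_rounds)) {
      if (nchar(contig) >= max_len) break
      cand <- right_extension_candidates(contig, reads$seq, reads$member, k)
      ch <- choose_extension(cand)
      if (ch$branched) { branched <- TRUE; break }
      if (is.null(ch$ext)) break
      contig <- paste0(contig, ch$ext)
    }
    if (branched) break
  }
  if (branched) return(list(contig = NA_character_, status = "branched"))
  list(contig = revcomp(contig), status = "ok") # undo the direction-2 flip
}

# ---------------------------------------------------------------------------
# Anchoring and classification

# Maximal exact-match anchoring of the first bases of `contig` against the
# reference, on either strand. Returns the best (longest) anchor; ties at
# the same length across loci mark the flank as multiply mapping.
anchor_left_flank <- function(contig, genome, k = 20L) {
  seed <- substring(contig, 1L, k)
  if (nchar(seed) < k) return(NULL)
  best <- NULL; best_len <- 0L; ties <- 0L
  for (chrom in names(genome$chroms)) {
    refc <- genome$chroms[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seed else revcomp(seed)
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(refc))
      for (h in seq_along(m)) {
        s <- Biostrings::start(m)[h]; e <- Biostrings::end(m)[h]
        # extend the match along the contig past the seed
        rest <- substring(contig, k + 1L)
        avail <- if (strand == "+") nchar(refc) - e else s - 1L
        n <- min(nchar(rest), avail)
        ext <- 0L
        if (n > 0) {
          refpart <- if (strand == "+") substring(refc, e + 1L, e + n)
                     else revcomp(substring(refc, s - n, s - 1L))
          ra <- charToRaw(substring(rest, 1L, n)); rb <- charToRaw(refpart)
          d <- which(ra != rb)
          ext <- if (length(d) == 0) n else d[1] - 1L
        }
        len <- k + ext
        bp <- if (strand == "+") s + len - 1L else e - len + 1L
        if (len > best_len) {
          best_len <- len; ties <- 0L
          best <- list(chrom = chrom, bp = bp, strand = strand, len = len)
        } else if (len == best_len && !(identical(best$chrom, chrom) && best$bp == bp)) {
          ties <- ties + 1L
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$unique <- ties == 0L
  best
}

#' Locate the two breakpoints of a junction contig on the reference
#'
#' Anchors the left and right contig flanks by maximal exact match (seed
#' `k`-mer, then extension), requiring at least `min_flank` matched bases per
#' flank. Side labels follow segment-end usage: a flank matching the forward
#' strand enters the junction through the reference segment's 3' end (tail)
#' on the left and 5' end (head) on the right; reverse-strand flanks swap
#' the label. A flank whose best match length is achieved at more than one
#' locus sets `unique_mapping = FALSE`.
#'
#' @param contig Assembled junction contig (>= 60 bp).
#' @param genome Reference genome object.
#' @param k Anchor seed length.
#' @param min_flank Minimum matched flank length per side.
#' @return List with `chrom1, bp1, side1, chrom2, bp2, side2`,
#'   `orientation_class`, `unique_mapping`, contig anchor extents `a`
#'   (left flank end) and `b` (right flank start), and `status`
#'   (`"ok"` or `"unresolved"`).
#' @export
locate_breakpoints <- function(contig, genome, k = 20L, min_flank = 30L) {
  unresolved <- list(status = "unresolved")
  if (is.na(contig) || nchar(contig) < 60L) return(unresolved)
  left <- anchor_left_flank(contig, genome, k)
  rc <- revcomp(contig)
  right_rc <- anchor_left_flank(rc, genome, k)
  if (is.null(left) || is.null(right_rc)) return(unresolved)
  L <- nchar(contig)
  a <- left$len                      # contig[1..a] matches at the left locus
  b <- L - right_rc$len + 1L         # contig[b..L] matches at the right locus
  if (a < min_flank || right_rc$len < min_flank) return(unresolved)
  if (a >= L || b <= 1L) return(unresolved)          # one flank swallows all
  if (b - a - 1L > 200L) return(unresolved)          # anchors never meet
  s1 <- left$strand
  s2 <- if (right_rc$strand == "+") "-" else "+"     # flip back to contig frame
  ocls <- switch(paste0(s1, s2), "++" = "tail_head", "--" = "tail_head",
                 "+-" = "tail_tail", "-+" = "head_head")
  list(chrom1 = left$chrom, bp1 = left$bp,
       side1 = if (s1 == "+") "tail" else "head",
       chrom2 = right_rc$chrom, bp2 = right_rc$bp,
       side2 = if (s2 == "+") "head" else "tail",
       strand1 = s1, strand2 = s2,
       orientation_class = ocls,
       unique_mapping = left$unique && right_rc$unique,
       a = a, b = b, status = "ok")
}

#' Classify the repair chemistry of a located junction
#'
#' With maximal flank anchors ending at contig position `a` (left) and
#' starting at `b` (right): an overlap (`b <= a`) is a microhomology of
#' length `a - b + 1`, present once at the junction; a gap is an insertion
#' whose sequence matches neither flank; direct abutment is a perfect join.
#' Microhomologies longer than `mh_max` are reported but flagged
#' out-of-range rather than truncated.
#'
#' @param contig Junction contig.
#' @param anchors Output of [locate_breakpoints()].
#' @param mh_max Upper bound of the expected microhomology range.
#' @return List with `repair_class`, `mh_len`, `ins_seq`, `mh_out_of_range`.
#' @export
classify_repair <- function(contig, anchors, mh_max = 29L) {
  if (anchors$status != "ok") stopf("breakpoints not located")
  a <- anchors$a; b <- anchors$b
  if (b <= a) {
    m <- a - b + 1L
    list(repair_class = "microhomology", mh_len = m, ins_seq = NA_character_,
         mh_out_of_range = m > mh_max)
  } else if (b == a + 1L) {
    list(repair_class = "perfect", mh_len = NA_integer_, ins_seq = NA_character_,
         mh_out_of_range = FALSE)
  } else {
    list(repair_class = "insertion", mh_len = NA_integer_,
         ins_seq = substring(contig, a + 1L, b - 1L), mh_out_of_range = FALSE)
  }
}

#' Call novel DNA junctions from a sample against controls
#'
#' Runs the full discovery chain: distant-pair extraction (target and
#' controls), clustering, control subtraction, support filtering against a
#' control-derived threshold, local assembly, breakpoint anchoring, and
#' repair classification. Only resolved, uniquely mapping calls are
#' reported.
#'
#' @param sample_aln Target alignment table (or SAM path).
#' @param control_alns List of control alignment tables (or SAM paths).
#' @param genome Reference genome object.
#' @param min_distance Distant-pair distance threshold in bp.
#' @param radius Cluster/matching radius in bp.
#' @param window Read-collection window around each side in bp.
#' @param k_overlap Assembly overlap seed length.
#' @param k_anchor Anchoring seed length.
#' @param min_flank Minimum anchored flank per side.
#' @return List with `calls` (junction table: breakpoints 1-based,
#'   orientation class, repair class, mh/ins, support, contig),
#'   `evidence` (post-filter evidence), `unresolved` (evidence rows that
#'   failed assembly/anchoring with their status), and `support_model`.
#' @export
call_junctions <- function(sample_aln, control_alns = list(), genome,
                           min_distance = 2000L, radius = 500L, window = 400L,
                           k_overlap = 31L, k_anchor = 20L, min_flank = 30L) {
  if (is.character(sample_aln)) sample_aln <- read_sam(sample_aln)
  control_alns <- lapply(control_alns, function(a)
    if (is.character(a)) read_sam(a) else a)
  rec <- find_distant_pairs(sample_aln, min_distance)
  ev <- cluster_pairs(rec, radius)
  ctrl_ev <- lapply(control_alns, function(a)
    cluster_pairs(find_distant_pairs(a, min_distance), radius))
  if (length(ctrl_ev) > 0)
    ev <- do.call(subtract_controls, c(list(ev), ctrl_ev, list(radius = radius)))
  model <- support_threshold_model(ctrl_ev)
  ev <- support_filter(ev, model)

  calls <- list(); unres <- list()
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    pool <- collect_junction_reads(sample_aln, e, window)
    pool$n_mismatch <- count_ref_mismatches(pool, genome)
    asm <- NULL
    # seed on junction-spanning reads (they disagree with the reference),
    # member pairs of this cluster first
    seeds <- order(-as.integer(pool$member), -pool$n_mismatch)
    seeds <- seeds[pool$n_mismatch[seeds] > 0]
    status <- "no_spanning_read"
    loc_tol <- radius + window + 100L
    for (sidx in utils::head(seeds, 8L)) {
      asm <- assemble_contig(pool, k = k_overlap, seed_idx = sidx)
      status <- asm$status
      if (asm$status != "ok") next
      loc <- locate_breakpoints(asm$contig, genome, k_anchor, min_flank)
      if (loc$status != "ok") { status <- "unresolved"; next }
      # the located junction must be the one this evidence cluster describes
      near <- function(c1, p1, c2, p2)
        c1 == e$chrom1 && abs(p1 - e$pos1) <= loc_tol &&
        c2 == e$chrom2 && abs(p2 - e$pos2) <= loc_tol
      if (!near(loc$chrom1, loc$bp1, loc$chrom2, loc$bp2) &&
          !near(loc$chrom2, loc$bp2, loc$chrom1, loc$bp1)) {
        status <- "locus_mismatch"; next
      }
      rep <- classify_repair(asm$contig, loc)
      calls[[length(calls) + 1]] <- data.frame(
        cluster = e$cluster, chrom1 = loc$chrom1, bp1 = loc$bp1,
        side1 = loc$side1, chrom2 = loc$chrom2, bp2 = loc$bp2,
        side2 = loc$side2, orientation_class = loc$orientation_class,
        repair_class = rep$repair_class, mh_len = rep$mh_len,
        ins_seq = rep$ins_seq, mh_out_of_range = rep$mh_out_of_range,
        support = e$support, unique_mapping = loc$unique_mapping,
        contig = asm$contig, stringsAsFactors = FALSE)
      status <- "called"
      break
    }
    if (status != "called")
      unres[[length(unres) + 1]] <- cbind(e, status = status)
  }
  calls <- if (length(calls) > 0) do.call(rbind, calls) else NULL
  if (!is.null(calls)) {
    calls <- calls[calls$unique_mapping, , drop = FALSE]
    # one call per distinct junction: the same junction is typically seen as
    # two mirror-strand evidence clusters whose supports are pooled here
    swap <- calls$chrom1 > calls$chrom2 |
      (calls$chrom1 == calls$chrom2 & calls$bp1 > calls$bp2)
    key <- ifelse(swap,
                  paste(calls$chrom2, calls$bp2, calls$chrom1, calls$bp1),
                  paste(calls$chrom1, calls$bp1, calls$chrom2, calls$bp2))
    key <- paste(key, calls$orientation_class)
    supp <- tapply(calls$support, key, sum)
    calls <- calls[!duplicated(key), , drop = FALSE]
    calls$support <- as.integer(supp[key[!duplicated(key)]])
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(cluster = integer(), chrom1 = character(), bp1 = integer(),
                        side1 = character(), chrom2 = character(), bp2 = integer(),
                        side2 = character(), orientation_class = character(),
                        repair_class = character(), mh_len = integer(),
                        ins_seq = character(), mh_out_of_range = logical(),
                        support = integer(), unique_mapping = logical(),
                        contig = character(), stringsAsFactors = FALSE)
  }
  list(calls = calls, evidence = ev,
       unresolved = if (length(unres) > 0) do.call(rbind, unres) else NULL,
       support_model = model)
}

# Normalize a junction table (calls or simulator truth) to one breakpoint
# per row.
junction_breakpoints <- function(x) {
  if (all(c("chrom1", "bp1") %in% names(x))) {
    data.frame(chrom = c(x$chrom1, x$chrom2), pos = c(x$bp1, x$bp2),
               stringsAsFactors = FALSE)
  } else if (all(c("left_bp", "right_bp") %in% names(x))) {
    data.frame(chrom = rep(x$chrom, 2), pos = c(x$left_bp, x$right_bp),
               stringsAsFactors = FALSE)
  } else stopf("unrecognized junction table")
}

#' Mean breakpoint spacing over a region
#'
#' Counts breakpoints individually (two per junction when both fall inside
#' the region) and returns `region length / count` in kb.
#'
#' @param calls Junction table (calls or truth) or a data.frame with
#'   chrom/pos breakpoints.
#' @param region A [region()].
#' @return Mean spacing in kb.
#' @export
breakpoint_density <- function(calls, region) {
  bp <- if (all(c("chrom", "pos") %in% names(calls))) calls
        else junction_breakpoints(calls)
  n <- sum(bp$chrom == region$chrom & bp$pos >= region$start & bp$pos <= region$end)
  if (n == 0) stopf("no breakpoints in region; spacing undefined")
  (region_len(region) / n) / 1000
}

#' Write junction calls as BEDPE
#' @param calls Junction call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  df <- data.frame(calls$chrom1, calls$bp1 - 1L, calls$bp1,
                   calls$chrom2, calls$bp2 - 1L, calls$bp2,
                   paste0("junction_", seq_len(nrow(calls))),
                   calls$support,
                   ifelse(calls$side1 == "tail", "+", "-"),
                   ifelse(calls$side2 == "head", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
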