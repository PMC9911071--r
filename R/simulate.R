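# Synthetic-data generator: genomes, parental haplotypes, shattered
# chromosomes, offspring karyotypes, paired reads with idealized alignments,
# and annotation tracks -- all seeded, all with ground truth attached.
#
# The scenario emulated is a cross between a parent-A/parent-B hybrid female
# and a parent-A male, in which one maternal chromosome (or chromosome arm)
# shatters and reassembles in random order and orientation, joined by
# microhomology, perfect, or small-insertion junctions, and is co-transmitted
# with an intact homolog after meiosis-I or meiosis-II nondisjunction.

#' Genomic region constructor
#'
#' @param chrom Chromosome name, or a single string `"chr1:100-200"`
#'   (1-based inclusive).
#' @param start,end 1-based inclusive bounds (ignored when `chrom` carries them).
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
region <- function(chrom, start = NULL, end = NULL) {
  if (is.null(start) && grepl(":", chrom)) {
    m <- regmatches(chrom, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", chrom))[[1]]
    if (length(m) != 4) stopf("cannot parse region string '%s'", chrom)
    chrom <- m[2]
    start <- as.numeric(gsub(",", "", m[3]))
    end <- as.numeric(gsub(",", "", m[4]))
  }
  if (is.null(start) || is.null(end) || end < start)
    stopf("invalid region bounds")
  list(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

region_len <- function(r) r$end - r$start + 1L

#' Generate a random reference genome
#'
#' @param n_chroms Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chroms`); each must
#'   be at least 10 kb.
#' @param gc Target G+C fraction in (0, 1).
#' @param seed Integer seed; the genome is reproducible from it.
#' @return A `synthetic_genome` object: list with `chroms` (named character
#'   vector of sequences) and `seed`.
#' @export
make_genome <- function(n_chroms = 1L, lengths = 1e6, gc = 0.36, seed = NULL) {
  lengths <- as.integer(rep_len(lengths, n_chroms))
  if (any(lengths < 10000L)) stopf("chromosome lengths must be >= 10 kb")
  if (gc <= 0 || gc >= 1) stopf("gc must be in (0, 1)")
  chroms <- with_seed(seed, {
    out <- vapply(lengths, function(L) paste0(sample_bases(L, gc), collapse = ""),
                  character(1))
    names(out) <- paste0("chr", seq_len(n_chroms))
    out
  })
  structure(list(chroms = chroms, gc = gc, seed = seed),
            class = "synthetic_genome")
}

#' Chromosome lengths of a genome
#' @param genome Genome object or named character vector.
#' @return Named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.numeric(genome)) return(genome) # already a named length vector
  seqs <- if (inherits(genome, "synthetic_genome")) genome$chroms else genome
  out <- nchar(seqs)
  names(out) <- names(seqs)
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  lens <- genome_lengths(x)
  cat(sprintf("synthetic genome: %d chromosome(s), %.2f Mb total\n",
              length(lens), sum(lens) / 1e6))
  invisible(x)
}

#' Derive a pair of parental haplotypes over a genome
#'
#' Parent A is the reference haplotype (its allele equals the reference base);
#' parent B carries substitutions at SNP sites drawn per base at `snp_rate`.
#'
#' @param genome A [make_genome()] genome.
#' @param snp_rate Per-bp SNP probability in `[0, 0.1)`.
#' @param seed Integer seed.
#' @param exclude Optional track data.frame (chrom/start/end) of regions to
#'   keep free of SNPs.
#' @return A `haplotype_pair`: labels and a data.frame `snps` with
#'   chrom, pos (1-based), alleleA, alleleB.
#' @export
derive_haplotypes <- function(genome, snp_rate = 0.002, seed = NULL,
                              exclude = NULL) {
  if (snp_rate < 0 || snp_rate >= 0.1) stopf("snp_rate must be in [0, 0.1)")
  snps <- with_seed(seed, {
    res <- lapply(names(genome$chroms), function(chrom) {
      L <- nchar(genome$chroms[[chrom]])
      pos <- which(stats::runif(L) < snp_rate)
      if (!is.null(exclude)) {
        ex <- exclude[exclude$chrom == chrom, , drop = FALSE]
        if (nrow(ex) > 0) {
          hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos),
                                      IRanges::IRanges(ex$start, ex$end))
          pos <- pos[!hit]
        }
      }
      if (length(pos) == 0) return(NULL)
      a <- substring(genome$chroms[[chrom]], pos, pos)
      data.frame(chrom = chrom, pos = pos, alleleA = a,
                 alleleB = random_base_avoiding(a), stringsAsFactors = FALSE)
    })
    do.call(rbind, res) %||% data.frame(chrom = character(), pos = integer(),
                                        alleleA = character(), alleleB = character())
  })
  rownames(snps) <- NULL
  structure(list(parentA_label = "parentA", parentB_label = "parentB",
                 snps = snps, snp_rate = snp_rate, seed = seed),
            class = "haplotype_pair")
}

# ---------------------------------------------------------------------------
# Shattering

# Oriented accessors used when planting junction chemistry. A fragment's
# "oriented" sequence is the reference slice for '+' and its reverse
# complement for '-'; oriented offset i is converted to a reference
# coordinate, and bases written through these helpers are complemented as
# needed.
oriented_ref_pos <- function(start, end, strand, i) {
  if (strand == "+") start + i - 1L else end - i + 1L
}

get_base <- function(seq, pos, strand = "+") {
  b <- substring(seq, pos, pos)
  if (strand == "-") comp_base(b) else b
}

set_base <- function(seq, pos, base, strand = "+") {
  if (strand == "-") base <- comp_base(base)
  substring(seq, pos, pos) <- base
  seq
}

#' Shatter a region of a chromosome and reassemble it at random
#'
#' Cuts `region` into `n_fragments` pieces (each at least `min_fragment` bp),
#' drops each piece with probability `loss_fraction`, permutes and flips the
#' survivors uniformly at random, and joins consecutive pieces with a repair
#' class drawn from `repair_mix`: `microhomology` (a 1-29 bp identical
#' sequence on both sides, present once at the junction), `perfect` (direct
#' abutment), or `insertion` (1-80 bp of novel sequence between the ends).
#'
#' Microhomology is planted by editing the reference inside the region so
#' that the bases entering the junction from both sides are identical; the
#' bases immediately beyond every junction are adjusted so that maximal
#' exact-match anchoring recovers exactly the planned repair chemistry.
#' The function therefore returns the (lightly edited) genome along with the
#' event, and all sequence outside `region` is unchanged.
#'
#' @param genome A [make_genome()] genome.
#' @param region A [region()] within one chromosome.
#' @param n_fragments Number of pieces (>= 2).
#' @param loss_fraction Per-fragment loss probability (micronucleus losses).
#' @param repair_mix Named numeric vector over
#'   `c("microhomology","perfect","insertion")`; must sum to 1.
#' @param mh_len_range,ins_len_range Inclusive length ranges for planted
#'   microhomologies and insertions.
#' @param min_fragment Minimum fragment length in bp (keeps junction zones
#'   disjoint; must be > 2 * max microhomology + 2).
#' @param derange If `TRUE`, redraw until the arrangement is not the identity
#'   (some fragment moved or flipped).
#' @param seed Integer seed.
#' @return A list with `event` (a `shatter_event` holding fragments in
#'   derivative order, lost fragments, and the truth junction table),
#'   `genome` (the edited genome -- use this downstream), and `derivative`
#'   (the rearranged sequence of the region).
#' @export
shatter <- function(genome, region, n_fragments,
                    loss_fraction = 0.1,
                    repair_mix = c(microhomology = 0.638, perfect = 0.112,
                                   insertion = 0.25),
                    mh_len_range = c(1L, 29L), ins_len_range = c(1L, 80L),
                    min_fragment = 200L, derange = FALSE, seed = NULL) {
  chrom <- region$chrom
  if (!chrom %in% names(genome$chroms)) stopf("unknown chromosome '%s'", chrom)
  L_chr <- nchar(genome$chroms[[chrom]])
  if (region$start < 1 || region$end > L_chr)
    stopf("region exceeds chromosome bounds")
  L <- region_len(region)
  if (n_fragments < 2) stopf("n_fragments must be >= 2")
  if (n_fragments * min_fragment > L)
    stopf("n_fragments too large for region (need >= %d bp each)", min_fragment)
  if (abs(sum(repair_mix) - 1) > 1e-6) stopf("repair_mix must sum to 1")
  repair_mix <- repair_mix[c("microhomology", "perfect", "insertion")]
  repair_mix[is.na(repair_mix)] <- 0

  with_seed(seed, {
    # fragment lengths: minimum plus a uniform split of the slack
    slack <- as.integer(L - n_fragments * min_fragment)
    cuts <- sort(sample.int(slack + 1L, n_fragments - 1L, replace = TRUE) - 1L)
    lens <- as.integer(diff(c(0L, cuts, slack)) + min_fragment)
    starts <- as.integer(region$start + c(0L, cumsum(lens))[seq_len(n_fragments)])
    frags <- data.frame(id = seq_len(n_fragments), ref_start = starts,
                        ref_end = starts + lens - 1L)

    # losses; keep at least two survivors so a junction exists
    repeat {
      lost <- stats::runif(n_fragments) < loss_fraction
      if (sum(!lost) >= 2) break
    }
    ret <- frags[!lost, , drop = FALSE]

    # random order and orientation
    repeat {
      ord <- sample.int(nrow(ret))
      orient <- sample(c("+", "-"), nrow(ret), replace = TRUE)
      if (!derange) break
      if (any(ord != seq_len(nrow(ret))) || any(orient == "-")) break
    }
    ret <- ret[ord, , drop = FALSE]
    ret$orient <- orient
    rownames(ret) <- NULL

    n_j <- nrow(ret) - 1L
    cls <- sample(names(repair_mix), n_j, replace = TRUE, prob = repair_mix)
    mh_len <- ifelse(cls == "microhomology",
                     sample(seq(mh_len_range[1], mh_len_range[2]), n_j, replace = TRUE),
                     NA_integer_)
    ins_len <- ifelse(cls == "insertion",
                      sample(seq(ins_len_range[1], ins_len_range[2]), n_j, replace = TRUE),
                      NA_integer_)

    seqc <- genome$chroms[[chrom]]

    # junction geometry in derivative order
    jd <- lapply(seq_len(n_j), function(j) {
      Lf <- ret[j, ]; Rf <- ret[j + 1L, ]
      lenL <- Lf$ref_end - Lf$ref_start + 1L
      bp1 <- if (Lf$orient == "+") Lf$ref_end else Lf$ref_start
      bp2 <- if (Rf$orient == "+") Rf$ref_start else Rf$ref_end
      ref_adj <- (Lf$orient == "+" && Rf$orient == "+" && Rf$ref_start == Lf$ref_end + 1L) ||
                 (Lf$orient == "-" && Rf$orient == "-" && Lf$ref_start == Rf$ref_end + 1L)
      list(Lf = Lf, Rf = Rf, lenL = lenL,
           lenR = Rf$ref_end - Rf$ref_start + 1L,
           bp1 = bp1, bp2 = bp2, ref_adjacent = ref_adj)
    })
    for (j in seq_len(n_j)) {
      if (jd[[j]]$ref_adjacent) {
        # identity-style adjacency: the join restores reference sequence, so a
        # zero-modification perfect join is forced and nothing is planted
        cls[j] <- "perfect"; mh_len[j] <- NA_integer_; ins_len[j] <- NA_integer_
      }
      m <- mh_len[j]
      if (!is.na(m) && m >= min(jd[[j]]$lenL, jd[[j]]$lenR) - 30L)
        mh_len[j] <- m <- 1L # degenerate guard; unreachable at default sizes
    }

    # phase 1: plant microhomologies (copy the left end's last m oriented
    # bases onto the right fragment's first m oriented bases)
    for (j in seq_len(n_j)) {
      if (cls[j] != "microhomology" || jd[[j]]$ref_adjacent) next
      g <- jd[[j]]; m <- mh_len[j]
      for (i in seq_len(m)) {
        src <- oriented_ref_pos(g$Lf$ref_start, g$Lf$ref_end, g$Lf$orient,
                                g$lenL - m + i)
        dst <- oriented_ref_pos(g$Rf$ref_start, g$Rf$ref_end, g$Rf$orient, i)
        b <- get_base(seqc, src, g$Lf$orient)
        seqc <- set_base(seqc, dst, b, g$Rf$orient)
      }
    }

    # insertion sequences (constraint-checked against junction context below)
    ins_seq <- rep(NA_character_, n_j)
    for (j in seq_len(n_j)) {
      if (cls[j] == "insertion") ins_seq[j] <- paste0(sample_bases(ins_len[j], 0.5),
                                                      collapse = "")
    }

    # phase 2: enforce anchor-stop conditions to a fixed point so maximal
    # exact anchoring reads back exactly the planned chemistry.  For each
    # junction the base that would extend the left flank past bp1 must differ
    # from the next contig base, and symmetrically on the right.
    ctx_base <- function(pos, strand) {
      if (pos < 1 || pos > nchar(seqc)) return(NA_character_)
      get_base(seqc, pos, strand)
    }
    for (pass in seq_len(50L)) {
      dirty <- FALSE
      for (j in seq_len(n_j)) {
        g <- jd[[j]]
        if (g$ref_adjacent) next
        oL <- g$Lf$orient; oR <- g$Rf$orient
        # reference continuation beyond the left end, in left-oriented reading
        nL <- ctx_base(if (oL == "+") g$bp1 + 1L else g$bp1 - 1L, oL)
        # reference base preceding the right end, in right-oriented reading
        pR <- ctx_base(if (oR == "+") g$bp2 - 1L else g$bp2 + 1L, oR)
        m <- if (cls[j] == "microhomology") mh_len[j] else 0L
        if (cls[j] == "insertion") {
          s <- ins_seq[j]
          b1 <- substring(s, 1, 1); bn <- substring(s, nchar(s), nchar(s))
          if (!is.na(nL) && b1 == nL) {
            substring(s, 1, 1) <- random_base_avoiding(nL); dirty <- TRUE
          }
          if (!is.na(pR) && nchar(s) >= 1) {
            bn <- substring(s, nchar(s), nchar(s))
            if (bn == pR && !(nchar(s) == 1 && substring(s, 1, 1) != pR)) {
              # avoid clobbering the first-base fix on length-1 inserts
              repl <- random_base_avoiding(pR, if (nchar(s) == 1) nL else NULL)
              substring(s, nchar(s), nchar(s)) <- repl; dirty <- TRUE
            }
          }
          ins_seq[j] <- s
        } else {
          # contig base following the left flank: first unplanted right base
          posA <- oriented_ref_pos(g$Rf$ref_start, g$Rf$ref_end, oR, m + 1L)
          if (!is.na(nL) && get_base(seqc, posA, oR) == nL) {
            seqc <- set_base(seqc, posA, random_base_avoiding(nL), oR)
            dirty <- TRUE
          }
          # contig base preceding the right flank: left base just before any MH
          posB <- oriented_ref_pos(g$Lf$ref_start, g$Lf$ref_end, oL, g$lenL - m)
          if (!is.na(pR) && get_base(seqc, posB, oL) == pR) {
            seqc <- set_base(seqc, posB, random_base_avoiding(pR), oL)
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
      if (pass == 50L) stopf("junction constraint planting did not converge")
    }
    genome$chroms[[chrom]] <- seqc

    side1 <- ifelse(ret$orient[-nrow(ret)] == "+", "tail", "head")
    side2 <- ifelse(ret$orient[-1L] == "+", "head", "tail")
    ocls <- character(n_j)
    for (j in seq_len(n_j)) {
      oo <- paste0(ret$orient[j], ret$orient[j + 1L])
      ocls[j] <- switch(oo, "++" = "tail_head", "--" = "tail_head",
                        "+-" = "tail_tail", "-+" = "head_head")
    }
    junctions <- data.frame(
      junction = seq_len(n_j), chrom = chrom,
      left_bp = as.integer(vapply(jd, function(g) g$bp1, numeric(1))),
      side1 = side1,
      right_bp = as.integer(vapply(jd, function(g) g$bp2, numeric(1))),
      side2 = side2,
      orientation_class = ocls, repair_class = cls,
      mh_len = mh_len,
      ins_seq = ins_seq,
      novel = !vapply(jd, function(g) g$ref_adjacent, logical(1)),
      stringsAsFactors = FALSE)

    event <- structure(list(
      chrom = chrom, start = region$start, end = region$end,
      fragments = ret, lost_fragments = frags[lost, c("id", "ref_start", "ref_end")],
      junctions = junctions, min_fragment = min_fragment, seed = seed),
      class = "shatter_event")

    list(event = event, genome = genome,
         derivative = derivative_sequence(event, genome))
  })
}

#' Rebuild the derivative (rearranged) sequence from a shatter event
#'
#' Concatenates the retained fragments in derivative order and orientation,
#' dropping one copy of each microhomology and interposing each insertion.
#' Applying this to the genome returned by [shatter()] reproduces the
#' emitted derivative byte-identically.
#'
#' @param event A `shatter_event`.
#' @param genome The genome returned by [shatter()].
#' @return A character string: the rearranged sequence of the region.
#' @export
derivative_sequence <- function(event, genome) {
  seqc <- genome$chroms[[event$chrom]]
  fr <- event$fragments
  parts <- character(0)
  for (i in seq_len(nrow(fr))) {
    s <- substring(seqc, fr$ref_start[i], fr$ref_end[i])
    if (fr$orient[i] == "-") s <- revcomp(s)
    if (i > 1) {
      j <- event$junctions[i - 1L, ]
      if (j$repair_class == "microhomology") s <- substring(s, j$mh_len + 1L)
      if (j$repair_class == "insertion") s <- paste0(j$ins_seq, s)
    }
    parts <- c(parts, s)
  }
  paste0(parts, collapse = "")
}

#' @export
print.shatter_event <- function(x, ...) {
  cat(sprintf("shatter event %s:%d-%d\n", x$chrom, x$start, x$end))
  cat(sprintf("  %d fragments retained, %d lost, %d truth junctions (%d novel)\n",
              nrow(x$fragments), nrow(x$lost_fragments), nrow(x$junctions),
              sum(x$junctions$novel)))
  tb <- table(x$junctions$repair_class)
  cat("  repair classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Offspring karyotypes

# A chromatid is a list(label, pieces) where pieces has columns
# type ("ref"/"ins"), chrom, start, end, strand, hap, ins_seq.
ref_piece <- function(chrom, start, end, strand = "+", hap = "A") {
  data.frame(type = "ref", chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, hap = hap,
             ins_seq = NA_character_, stringsAsFactors = FALSE)
}

ins_piece <- function(seq) {
  data.frame(type = "ins", chrom = NA_character_, start = NA_integer_,
             end = NA_integer_, strand = "+", hap = NA_character_,
             ins_seq = seq, stringsAsFactors = FALSE)
}

# Pieces of a full (possibly recombinant) copy of every chromosome.
full_copy_pieces <- function(genome, hap, crossover = NULL) {
  out <- lapply(names(genome$chroms), function(chrom) {
    L <- nchar(genome$chroms[[chrom]])
    if (!is.null(crossover) && identical(crossover$chrom, chrom) &&
        crossover$pos > 1 && crossover$pos < L) {
      rbind(ref_piece(chrom, 1L, crossover$pos, "+", hap),
            ref_piece(chrom, crossover$pos + 1L, L, "+",
                      if (hap == "A") "B" else "A"))
    } else {
      ref_piece(chrom, 1L, L, "+", hap)
    }
  })
  do.call(rbind, out)
}

# Pieces of the shattered arm chromatid implied by a shatter event.
shattered_pieces <- function(event, hap) {
  fr <- event$fragments
  out <- list()
  for (i in seq_len(nrow(fr))) {
    st <- fr$ref_start[i]; en <- fr$ref_end[i]; o <- fr$orient[i]
    if (i > 1) {
      j <- event$junctions[i - 1L, ]
      if (j$repair_class == "microhomology") {
        # the junction keeps a single copy of the homology; trim the leading
        # oriented bases of the right fragment
        if (o == "+") st <- st + j$mh_len else en <- en - j$mh_len
      }
      if (j$repair_class == "insertion") out <- c(out, list(ins_piece(j$ins_seq)))
    }
    out <- c(out, list(ref_piece(event$chrom, st, en, o, hap)))
  }
  do.call(rbind, out)
}

#' Build an offspring karyotype of the hybrid-female x parent-A-male cross
#'
#' The paternal gamete always contributes one full parent-A copy of every
#' chromosome. The maternal gamete depends on `stage`:
#' \describe{
#'   \item{balanced}{one full maternal copy (`maternal_hap`).}
#'   \item{meiosis_I}{both homologs of the shattered chromosome are
#'     transmitted; the shattered copy carries the haplotype that differs
#'     from the intact maternal copy, and only its rearranged arm survives.}
#'   \item{meiosis_II}{two sister chromatids of the same haplotype are
#'     transmitted; the shattered arm carries the same haplotype as the
#'     intact maternal copy.}
#' }
#'
#' @param genome Genome returned by [shatter()] (or [make_genome()] when no
#'   event is supplied).
#' @param haplotypes A [derive_haplotypes()] pair.
#' @param shatter_event A `shatter_event`, or `NULL` for a karyotype without
#'   rearrangement (the extra copy, if any, is then the intact arm).
#' @param stage One of `"balanced"`, `"meiosis_I"`, `"meiosis_II"`.
#' @param maternal_hap Haplotype of the intact maternal copy, `"A"` or `"B"`
#'   (default `"B"`, the study-like configuration).
#' @param crossover Optional `list(chrom, pos)`: the intact maternal copy is
#'   recombinant, switching haplotype after `pos`.
#' @param seed Integer seed (used only for optional random choices).
#' @return A `karyotype` object.
#' @export
make_offspring <- function(genome, haplotypes, shatter_event = NULL,
                           stage = c("balanced", "meiosis_I", "meiosis_II"),
                           maternal_hap = "B", crossover = NULL, seed = NULL) {
  stage <- match.arg(stage)
  if (!maternal_hap %in% c("A", "B")) stopf("maternal_hap must be 'A' or 'B'")
  if (sum(genome_lengths(genome)) == 0) stopf("zero-length genome")
  # one chromatid per chromosome per copy (reads never cross chromosomes)
  per_chrom <- function(label, pieces) {
    lapply(unique(pieces$chrom), function(ch)
      list(label = paste0(label, "_", ch),
           pieces = pieces[pieces$chrom == ch, , drop = FALSE]))
  }
  chromatids <- c(
    per_chrom("paternal_A", full_copy_pieces(genome, "A")),
    per_chrom(paste0("maternal_", maternal_hap),
              full_copy_pieces(genome, maternal_hap, crossover)))
  if (stage != "balanced") {
    extra_hap <- if (stage == "meiosis_I") {
      if (maternal_hap == "A") "B" else "A" # homolog: the other haplotype
    } else maternal_hap                     # sister chromatid: same haplotype
    pieces <- if (!is.null(shatter_event)) shattered_pieces(shatter_event, extra_hap)
              else NULL
    if (is.null(pieces)) {
      # no event supplied: the extra copy is an intact chromosome
      ch <- names(genome$chroms)[1]
      pieces <- ref_piece(ch, 1L, nchar(genome$chroms[[ch]]), "+", extra_hap)
    }
    chromatids <- c(chromatids,
                    list(list(label = paste0("extra_", extra_hap, "_shattered"),
                              pieces = pieces)))
  }
  structure(list(chromatids = chromatids,
                 meiosis_origin = switch(stage, balanced = "balanced",
                                         meiosis_I = "meiosis_I_nondisjunction",
                                         meiosis_II = "meiosis_II_nondisjunction"),
                 genome = genome, haplotypes = haplotypes,
                 event = shatter_event, seed = seed),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("karyotype (%s): %d chromatids\n", x$meiosis_origin,
              length(x$chromatids)))
  for (ch in x$chromatids)
    cat(sprintf("  %-24s %d piece(s), %.2f Mb\n", ch$label, nrow(ch$pieces),
                sum(ch$pieces$end - ch$pieces$start + 1, na.rm = TRUE) / 1e6 +
                  sum(nchar(ch$pieces$ins_seq), na.rm = TRUE) / 1e6))
  invisible(x)
}

#' Copy number of a karyotype at given positions
#'
#' @param karyotype A `karyotype`.
#' @param chrom Chromosome name.
#' @param pos Vector of 1-based positions.
#' @return Integer vector: number of chromatid copies covering each position.
#' @export
copy_number <- function(karyotype, chrom, pos) {
  out <- integer(length(pos))
  q <- IRanges::IRanges(pos, pos)
  for (ch in karyotype$chromatids) {
    p <- ch$pieces[ch$pieces$type == "ref" & ch$pieces$chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0) next
    out <- out + IRanges::countOverlaps(q, IRanges::IRanges(p$start, p$end))
  }
  out
}

#' Haplotype copy multiset of a karyotype at given positions
#'
#' @inheritParams copy_number
#' @return Data frame with columns `copies_A`, `copies_B` per position.
#' @export
haplotype_copies <- function(karyotype, chrom, pos) {
  a <- integer(length(pos)); b <- integer(length(pos))
  q <- IRanges::IRanges(pos, pos)
  for (ch in karyotype$chromatids) {
    p <- ch$pieces[ch$pieces$type == "ref" & ch$pieces$chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0) next
    for (h in c("A", "B")) {
      ph <- p[p$hap == h, , drop = FALSE]
      if (nrow(ph) == 0) next
      n <- IRanges::countOverlaps(q, IRanges::IRanges(ph$start, ph$end))
      if (h == "A") a <- a + n else b <- b + n
    }
  }
  data.frame(copies_A = a, copies_B = b)
}

#' Genome-wide pooled parent-A base fraction of a karyotype
#'
#' Total parent-A-labelled bases over total bases across all chromatids
#' (insertion pieces excluded).
#'
#' @param karyotype A `karyotype`.
#' @return A fraction in `[0, 1]`.
#' @export
karyotype_parentA_fraction <- function(karyotype) {
  a <- 0; tot <- 0
  for (ch in karyotype$chromatids) {
    p <- ch$pieces[ch$pieces$type == "ref", , drop = FALSE]
    w <- p$end - p$start + 1
    tot <- tot + sum(w)
    a <- a + sum(w[p$hap == "A"])
  }
  a / tot
}

#' Per-locus parent-A fraction floor over disomic loci
#'
#' The cross design (paternal gamete always parent-A) guarantees every
#' disomic locus carries at least one parent-A copy, so this floor is the
#' quantity the cross fixes at 50%.
#'
#' @param karyotype A `karyotype`.
#' @return Minimum over disomic loci of the per-locus parent-A copy fraction,
#'   or `NA` if no locus is disomic.
#' @export
parentA_disomic_floor <- function(karyotype) {
  floors <- c()
  for (chrom in names(karyotype$genome$chroms)) {
    L <- nchar(karyotype$genome$chroms[[chrom]])
    # breakpoints of the piecewise-constant copy profile
    cuts <- sort(unique(c(1L, L)))
    for (ch in karyotype$chromatids) {
      p <- ch$pieces[ch$pieces$type == "ref" & ch$pieces$chrom == chrom, , drop = FALSE]
      cuts <- sort(unique(c(cuts, p$start, pmin(p$end + 1L, L))))
    }
    hc <- haplotype_copies(karyotype, chrom, cuts)
    tot <- hc$copies_A + hc$copies_B
    dis <- tot == 2L
    if (any(dis)) floors <- c(floors, min(hc$copies_A[dis] / 2))
  }
  if (length(floors) == 0) NA_real_ else min(floors)
}

#' Enumerate the offspring karyotypes of the cross design
#'
#' Builds one karyotype per combination of meiotic stage, intact maternal
#' haplotype, and presence of a maternal crossover, always with the paternal
#' gamete contributing parent-A.
#'
#' @param genome,haplotypes,shatter_event As for [make_offspring()].
#' @param crossover_pos Position used for the "with crossover" variants.
#' @return Named list of `karyotype` objects.
#' @export
offspring_karyotype_grid <- function(genome, haplotypes, shatter_event = NULL,
                                     crossover_pos = NULL) {
  ch1 <- names(genome$chroms)[1]
  if (is.null(crossover_pos)) crossover_pos <- nchar(genome$chroms[[ch1]]) %/% 2L
  out <- list()
  for (stage in c("balanced", "meiosis_I", "meiosis_II")) {
    for (mh in c("A", "B")) {
      for (co in c(FALSE, TRUE)) {
        nm <- sprintf("%s_m%s%s", stage, mh, if (co) "_co" else "")
        out[[nm]] <- make_offspring(genome, haplotypes, shatter_event, stage,
                                    maternal_hap = mh,
                                    crossover = if (co) list(chrom = ch1, pos = crossover_pos))
      }
    }
  }
  out
}

#' Delete a segment from one chromatid of a karyotype
#'
#' Produces a heterozygous (copy-number 1) deletion over `region` by removing
#' it from the pieces of one chromatid (by default the last chromatid
#' covering the region, i.e. the maternal copy).
#'
#' @param karyotype A `karyotype`.
#' @param region A [region()].
#' @param label Optional chromatid label prefix to target.
#' @return The modified `karyotype`.
#' @export
delete_segment <- function(karyotype, region, label = NULL) {
  covers <- vapply(karyotype$chromatids, function(ch) {
    p <- ch$pieces
    any(p$type == "ref" & p$chrom == region$chrom &
          p$start <= region$end & p$end >= region$start) &&
      (is.null(label) || startsWith(ch$label, label))
  }, logical(1))
  if (!any(covers)) stopf("no chromatid covers the region")
  i <- max(which(covers))
  p <- karyotype$chromatids[[i]]$pieces
  out <- list()
  for (r in seq_len(nrow(p))) {
    row <- p[r, , drop = FALSE]
    if (row$type != "ref" || row$chrom != region$chrom ||
        row$end < region$start || row$start > region$end) {
      out[[length(out) + 1]] <- row; next
    }
    if (row$start < region$start) {
      a <- row; a$end <- region$start - 1L; out[[length(out) + 1]] <- a
    }
    if (row$end > region$end) {
      b <- row; b$start <- region$end + 1L; out[[length(out) + 1]] <- b
    }
  }
  karyotype$chromatids[[i]]$pieces <- do.call(rbind, out)
  karyotype$chromatids[[i]]$label <- paste0(karyotype$chromatids[[i]]$label, "_del")
  karyotype
}

# ---------------------------------------------------------------------------
# Reads and idealized alignments

# Materialize a chromatid: its physical sequence (haplotype substitutions and
# orientation applied) plus a piece map from sample to reference coordinates.
build_chromatid <- function(chromatid, genome, haplotypes) {
  p <- chromatid$pieces
  chunks <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (p$type[i] == "ins") { chunks[i] <- p$ins_seq[i]; next }
    s <- substring(genome$chroms[[p$chrom[i]]], p$start[i], p$end[i])
    if (identical(p$hap[i], "B") && nrow(haplotypes$snps) > 0) {
      sn <- haplotypes$snps
      sn <- sn[sn$chrom == p$chrom[i] & sn$pos >= p$start[i] & sn$pos <= p$end[i], ,
               drop = FALSE]
      if (nrow(sn) > 0) {
        v <- strsplit(s, "", fixed = TRUE)[[1]]
        v[sn$pos - p$start[i] + 1L] <- sn$alleleB
        s <- paste0(v, collapse = "")
      }
    }
    if (p$strand[i] == "-") s <- revcomp(s)
    chunks[i] <- s
  }
  w <- nchar(chunks)
  map <- cbind(p, samp_start = cumsum(c(1L, w))[seq_len(nrow(p))],
               samp_end = cumsum(w))
  list(seq = paste0(chunks, collapse = ""), map = map, label = chromatid$label)
}

# Reference coordinate of sample position s within ref piece row m.
map_ref_pos <- function(m, s) {
  if (m$strand == "+") m$start + (s - m$samp_start) else m$end - (s - m$samp_start)
}

#' Simulate paired reads and idealized alignments from a karyotype
#'
#' Insert positions are drawn uniformly across the karyotype's physical
#' sequence, so a segment present in `c` copies has expected per-base
#' coverage `depth * c / 2`. Each mate is assigned an idealized alignment at
#' the reference locus of the piece holding the majority of its bases; a pair
#' whose mates derive from opposite sides of a junction is therefore reported
#' at the junction's two reference loci. Alignments carry no sequencing error
#' unless `error_rate > 0`.
#'
#' @param karyotype A [make_offspring()] karyotype.
#' @param depth Mean fold coverage on the diploid scale (> 0).
#' @param read_len Read length (>= 30).
#' @param insert_mean,insert_sd Insert-size distribution (truncated normal,
#'   minimum `read_len`).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Integer seed.
#' @return A `read_set`: list with `pairs` (name, seq1, seq2 and true origin
#'   coordinates) and `aln` (alignment table, two records per pair).
#' @export
simulate_reads <- function(karyotype, depth = 30, read_len = 100L,
                           insert_mean = 300, insert_sd = 50,
                           error_rate = 0, seed = NULL) {
  if (depth <= 0) stopf("depth must be > 0")
  if (read_len < 30) stopf("read_len must be >= 30")
  built <- lapply(karyotype$chromatids, build_chromatid,
                  genome = karyotype$genome, haplotypes = karyotype$haplotypes)
  lens <- vapply(built, function(b) nchar(b$seq), numeric(1))
  if (sum(lens) == 0) stopf("zero-length karyotype")
  n_pairs <- max(1L, round(depth / 2 * sum(lens) / (2 * read_len)))

  with_seed(seed, {
    cid <- sample.int(length(built), n_pairs, replace = TRUE, prob = lens)
    ins <- pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                read_len)
    ins <- pmin(ins, lens[cid])
    start <- floor(stats::runif(n_pairs) * (lens[cid] - ins + 1)) + 1L

    qname <- sprintf("rp%07d", seq_len(n_pairs))
    seq1 <- character(n_pairs); seq2 <- character(n_pairs)
    rec <- vector("list", length(built))
    for (b in seq_along(built)) {
      sel <- which(cid == b)
      if (length(sel) == 0) next
      s <- start[sel]; e <- s + ins[sel] - 1L
      seq1[sel] <- substring(built[[b]]$seq, s, s + read_len - 1L)
      seq2[sel] <- revcomp(substring(built[[b]]$seq, e - read_len + 1L, e))
    }
    if (error_rate > 0) {
      seq1 <- add_substitution_errors(seq1, error_rate)
      seq2 <- add_substitution_errors(seq2, error_rate)
    }

    aln <- idealized_alignments(built, cid, start, ins, read_len, qname,
                                insert_mean, insert_sd)
    labels <- vapply(built, function(b) b$label, character(1))
    structure(list(
      pairs = data.frame(name = qname, seq1 = seq1, seq2 = seq2,
                         chromatid = labels[cid], samp_start = start,
                         insert = ins, stringsAsFactors = FALSE),
      aln = aln, depth = depth, read_len = read_len,
      insert_mean = insert_mean, insert_sd = insert_sd, seed = seed),
      class = "read_set")
  })
}

add_substitution_errors <- function(seqs, rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    p <- sample.int(nchar(seqs[i]), n_err[i])
    for (k in p) {
      b <- substring(seqs[i], k, k)
      substring(seqs[i], k, k) <- random_base_avoiding(b)
    }
  }
  seqs
}

# Compute idealized alignment records for all mates (vectorized over the
# common case of a mate falling inside a single reference piece).
idealized_alignments <- function(built, cid, start, ins, read_len, qname,
                                 insert_mean, insert_sd) {
  n <- length(cid)
  # mate sample intervals
  m1s <- start; m1e <- start + read_len - 1L
  m2s <- start + ins - read_len; m2e <- start + ins - 1L

  res <- list()
  for (b in seq_along(built)) {
    sel <- which(cid == b)
    if (length(sel) == 0) next
    map <- built[[b]]$map
    for (mate in 1:2) {
      xs <- if (mate == 1) m1s[sel] else m2s[sel]
      xe <- if (mate == 1) m1e[sel] else m2e[sel]
      i1 <- findInterval(xs, map$samp_start)
      i2 <- findInterval(xe, map$samp_start)
      pidx <- i1
      span <- which(i1 != i2 | map$type[i1] == "ins")
      for (k in span) { # few reads straddle pieces; pick the majority ref piece
        cand <- seq(i1[k], i2[k])
        cand <- cand[map$type[cand] == "ref"]
        if (length(cand) == 0) { pidx[k] <- NA_integer_; next }
        ov <- pmin(xe[k], map$samp_end[cand]) - pmax(xs[k], map$samp_start[cand]) + 1
        pidx[k] <- cand[which.max(ov)]
      }
      ok <- !is.na(pidx)
      mp <- map[pidx[ok], , drop = FALSE]
      oxs <- pmax(xs[ok], mp$samp_start); oxe <- pmin(xe[ok], mp$samp_end)
      pos <- ifelse(mp$strand == "+",
                    mp$start + (oxs - mp$samp_start) - (oxs - xs[ok]),
                    mp$end - (oxe - mp$samp_start) - (xe[ok] - oxe))
      pos <- pmax(pos, 1L)
      # reference-forward stored sequence
      sampfwd <- substring(built[[b]]$seq, xs[ok], xe[ok])
      stored <- ifelse(mp$strand == "-", revcomp(sampfwd), sampfwd)
      # mate1 reads sample-forward, mate2 sample-reverse
      refstrand <- if (mate == 1) mp$strand else ifelse(mp$strand == "+", "-", "+")
      res[[length(res) + 1]] <- data.frame(
        qname = qname[sel][ok], mate = mate, rname = mp$chrom,
        pos = as.integer(pos), strand = refstrand, seq = stored,
        stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, res)
  # assemble SAM fields; drop pairs that lost a mate (ins-majority mates)
  recs <- recs[order(recs$qname, recs$mate), , drop = FALSE]
  cnt <- table(recs$qname)
  keep <- recs$qname %in% names(cnt)[cnt == 2L]
  recs <- recs[keep, , drop = FALSE]
  i1 <- which(recs$mate == 1); i2 <- which(recs$mate == 2)
  same <- recs$rname[i1] == recs$rname[i2]
  lo <- pmin(recs$pos[i1], recs$pos[i2])
  hi <- pmax(recs$pos[i1] + nchar(recs$seq[i1]), recs$pos[i2] + nchar(recs$seq[i2])) - 1L
  span <- hi - lo + 1L
  proper <- same & span <= (insert_mean + 10 * insert_sd) &
    recs$strand[i1] != recs$strand[i2]
  flag1 <- 1L + 64L + ifelse(recs$strand[i1] == "-", 16L, 0L) +
    ifelse(recs$strand[i2] == "-", 32L, 0L) + ifelse(proper, 2L, 0L)
  flag2 <- 1L + 128L + ifelse(recs$strand[i2] == "-", 16L, 0L) +
    ifelse(recs$strand[i1] == "-", 32L, 0L) + ifelse(proper, 2L, 0L)
  tl1 <- ifelse(same, ifelse(recs$pos[i1] <= recs$pos[i2], span, -span), 0L)
  aln <- data.frame(
    qname = c(recs$qname[i1], recs$qname[i2]),
    flag = c(flag1, flag2),
    rname = c(recs$rname[i1], recs$rname[i2]),
    pos = c(recs$pos[i1], recs$pos[i2]),
    mapq = 60L,
    cigar = paste0(nchar(c(recs$seq[i1], recs$seq[i2])), "M"),
    rnext = c(ifelse(same, "=", recs$rname[i2]), ifelse(same, "=", recs$rname[i1])),
    pnext = c(recs$pos[i2], recs$pos[i1]),
    tlen = c(tl1, -tl1),
    seq = c(recs$seq[i1], recs$seq[i2]),
    stringsAsFactors = FALSE)
  aln[order(aln$rname, aln$pos), , drop = FALSE]
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d pairs, %d bp reads, insert %g +/- %g, depth %gx\n",
              nrow(x$pairs), x$read_len, x$insert_mean, x$insert_sd, x$depth))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Annotation tracks

#' Generate random non-overlapping annotation tracks
#'
#' Each spec asks for a target covered genome fraction and a mean feature
#' length; features are placed uniformly with rejection of overlaps until the
#' target is met (realized fraction within ~10% relative for fractions of at
#' least 0.05).
#'
#' @param genome A genome object.
#' @param track_specs Named list; each element is `list(fraction=, mean_len=)`.
#' @param seed Integer seed.
#' @return Named list of track data.frames (chrom, start, end; 1-based
#'   inclusive, sorted, non-overlapping).
#' @export
make_tracks <- function(genome, track_specs, seed = NULL) {
  lens <- genome_lengths(genome)
  G <- sum(lens)
  with_seed(seed, {
    out <- lapply(names(track_specs), function(nm) {
      sp <- track_specs[[nm]]
      if (sp$fraction > 1 || sp$fraction < 0) stopf("track fraction must be in [0, 1]")
      if (sp$fraction == 0)
        return(data.frame(chrom = character(), start = integer(), end = integer()))
      target <- sp$fraction * G
      got <- 0
      rows <- list()
      occupied <- lapply(lens, function(...) IRanges::IRanges())
      attempts <- 0L
      while (got < target && attempts < 200000L) {
        attempts <- attempts + 1L
        w <- max(20L, as.integer(stats::rgeom(1, 1 / sp$mean_len)))
        ci <- sample.int(length(lens), 1L, prob = lens)
        if (w >= lens[ci]) next
        st <- sample.int(lens[ci] - w, 1L)
        ir <- IRanges::IRanges(st, st + w - 1L)
        if (length(IRanges::findOverlaps(ir, occupied[[ci]])) > 0) next
        if (got + w > target * 1.02) w <- max(20L, as.integer(target - got))
        occupied[[ci]] <- c(occupied[[ci]], IRanges::IRanges(st, st + w - 1L))
        rows[[length(rows) + 1]] <- data.frame(chrom = names(lens)[ci],
                                               start = st, end = st + w - 1L)
        got <- got + w
      }
      df <- do.call(rbind, rows)
      df[order(df$chrom, df$start), , drop = FALSE]
    })
    names(out) <- names(track_specs)
    out
  })
}

#' Partition a genome into disjoint state tracks
#'
#' Segments every chromosome into runs with exponentially distributed lengths
#' and assigns each run one of `n_states` labels, producing tracks that are
#' pairwise disjoint and jointly cover the genome (like chromatin-state
#' annotations).
#'
#' @param genome A genome object.
#' @param n_states Number of states.
#' @param mean_len Mean segment length in bp.
#' @param weights State probabilities (default uniform).
#' @param seed Integer seed.
#' @return Named list (`state_1` ... `state_n`) of track data.frames.
#' @export
make_state_tracks <- function(genome, n_states = 9L, mean_len = 5000,
                              weights = NULL, seed = NULL) {
  lens <- genome_lengths(genome)
  if (is.null(weights)) weights <- rep(1, n_states)
  with_seed(seed, {
    segs <- lapply(names(lens), function(chrom) {
      L <- lens[[chrom]]
      w <- integer(0)
      while (sum(w) < L) w <- c(w, max(50L, round(stats::rexp(1, 1 / mean_len))))
      w[length(w)] <- w[length(w)] - (sum(w) - L)
      en <- as.integer(cumsum(w))
      data.frame(chrom = chrom, start = c(1L, utils::head(en, -1) + 1L), end = en,
                 state = sample.int(n_states, length(w), replace = TRUE,
                                    prob = weights))
    })
    segs <- do.call(rbind, segs)
    out <- lapply(seq_len(n_states), function(s) {
      d <- segs[segs$state == s, c("chrom", "start", "end"), drop = FALSE]
      rownames(d) <- NULL
      d
    })
    names(out) <- paste0("state_", seq_len(n_states))
    out
  })
}
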