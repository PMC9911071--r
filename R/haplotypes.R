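# Parental-haplotype dosage: pileup allele counts at parent-diagnostic SNPs,
# binned parent-B allele frequency, and inference of the meiotic origin of a
# trisomic (shattered) region. On the study's cross design the paternal
# gamete always carries parent A, so a disomic locus sits at 50% parent-B,
# a meiosis-I trisomy oscillates between 33% (shattered copy present) and
# 50% (fragment lost), and a meiosis-II trisomy shows 0% or 67%.

#' Per-position allele counts from an alignment table
#'
#' Positional pileup over the requested positions (alignments are all-M, so
#' base `i` of a stored read covers reference position `pos + i - 1`).
#'
#' @param aln Alignment table (or SAM path).
#' @param positions Data frame with chrom, pos (1-based). Default: every
#'   position of every chromosome in `genome` (small genomes only).
#' @param genome Genome object (required when `positions` is `NULL` or when
#'   reference bases are wanted).
#' @return Data frame: chrom, pos, ref (if genome given), A, C, G, T, depth.
#' @export
pileup_table <- function(aln, positions = NULL, genome = NULL) {
  if (is.character(aln)) aln <- read_sam(aln)
  if (is.null(positions)) {
    if (is.null(genome)) stopf("positions or genome must be supplied")
    lens <- genome_lengths(genome)
    positions <- do.call(rbind, lapply(names(lens), function(chrom)
      data.frame(chrom = chrom, pos = seq_len(lens[[chrom]]))))
  }
  counts <- matrix(0L, nrow(positions), 4L,
                   dimnames = list(NULL, BASES))
  for (chrom in unique(positions$chrom)) {
    qi <- which(positions$chrom == chrom)
    ri <- which(aln$rname == chrom)
    if (length(ri) == 0) next
    q <- IRanges::IRanges(positions$pos[qi], positions$pos[qi])
    r <- IRanges::IRanges(aln$pos[ri], aln$pos[ri] + nchar(aln$seq[ri]) - 1L)
    ov <- IRanges::findOverlaps(q, r)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    off <- positions$pos[qi][qh] - aln$pos[ri][sh] + 1L
    b <- substring(aln$seq[ri][sh], off, off)
    bi <- match(b, BASES)
    ok <- !is.na(bi)
    idx <- (qh[ok] - 1L) * 4L + bi[ok]
    tb <- tabulate(idx, nbins = length(qi) * 4L)
    counts[qi, ] <- counts[qi, ] + matrix(tb, ncol = 4L, byrow = TRUE)
  }
  out <- cbind(positions, as.data.frame(counts))
  if (!is.null(genome))
    out$ref <- substring(genome$chroms[out$chrom], out$pos, out$pos)
  out$depth <- rowSums(counts)
  rownames(out) <- NULL
  out
}

#' Select parent-diagnostic SNPs from two parental pileups
#'
#' Keeps positions where each (homozygous) parent is near-fixed for a
#' different allele: depth at least `min_depth` in both parents and minor
#' allele fraction at most `max_minor` in each.
#'
#' @param pileupA,pileupB [pileup_table()] outputs for the two parents over
#'   the same positions.
#' @param min_depth Minimum parental depth.
#' @param max_minor Maximum minor-allele fraction per parent.
#' @return SNP table: chrom, pos, alleleA, alleleB.
#' @export
select_diagnostic_snps <- function(pileupA, pileupB, min_depth = 10L,
                                   max_minor = 0.1) {
  key <- function(p) paste(p$chrom, p$pos)
  common <- intersect(key(pileupA), key(pileupB))
  a <- pileupA[match(common, key(pileupA)), , drop = FALSE]
  b <- pileupB[match(common, key(pileupB)), , drop = FALSE]
  major <- function(p) BASES[max.col(as.matrix(p[, BASES]), ties.method = "first")]
  minor_frac <- function(p) {
    m <- as.matrix(p[, BASES])
    1 - apply(m, 1, max) / pmax(rowSums(m), 1)
  }
  majA <- major(a); majB <- major(b)
  keep <- a$depth >= min_depth & b$depth >= min_depth &
    minor_frac(a) <= max_minor & minor_frac(b) <= max_minor & majA != majB
  data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
             alleleA = majA[keep], alleleB = majB[keep],
             stringsAsFactors = FALSE)
}

#' Allele counts of a sample at diagnostic SNPs
#'
#' @param aln Sample alignment table (or SAM path).
#' @param snps SNP table (chrom, pos, alleleA, alleleB).
#' @return `snps` with added `nA`, `nB` read counts.
#' @export
snp_allele_counts <- function(aln, snps) {
  p <- pileup_table(aln, positions = snps[, c("chrom", "pos")])
  m <- as.matrix(p[, BASES])
  snps$nA <- m[cbind(seq_len(nrow(snps)), match(snps$alleleA, BASES))]
  snps$nB <- m[cbind(seq_len(nrow(snps)), match(snps$alleleB, BASES))]
  snps
}

#' Binned parent-B allele frequency
#'
#' Pools read counts across the SNPs of each bin (read-weighted, not
#' SNP-averaged, since depth varies with the CNV landscape):
#' `freq_B = sum(nB) / sum(nA + nB)`. Bins with fewer informative reads than
#' `floor` are masked.
#'
#' @param snp_counts Output of [snp_allele_counts()].
#' @param genome Genome object (defines the bin grid).
#' @param bin_size Bin width in bp.
#' @param floor Minimum informative reads per unmasked bin.
#' @return Data frame: chrom, start, end, n_snps, reads_B, reads_total,
#'   freq_B, masked.
#' @export
binned_allele_freq <- function(snp_counts, genome, bin_size = 10000L,
                               floor = 20L) {
  lens <- genome_lengths(genome)
  out <- lapply(names(lens), function(chrom) {
    st <- as.integer(seq.int(1L, lens[[chrom]], by = bin_size))
    d <- data.frame(chrom = chrom, start = st,
                    end = as.integer(pmin(st + bin_size - 1L, lens[[chrom]])))
    s <- snp_counts[snp_counts$chrom == chrom, , drop = FALSE]
    bi <- (s$pos - 1L) %/% bin_size + 1L
    d$n_snps <- tabulate(bi, nbins = nrow(d))
    d$reads_B <- as.integer(rowsum_by(s$nB, bi, nrow(d)))
    d$reads_total <- as.integer(rowsum_by(s$nA + s$nB, bi, nrow(d)))
    d
  })
  out <- do.call(rbind, out)
  out$freq_B <- ifelse(out$reads_total > 0, out$reads_B / out$reads_total, NA_real_)
  out$masked <- out$reads_total < floor
  out$freq_B[out$masked] <- NA_real_
  rownames(out) <- NULL
  out
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x) > 0) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Expected parent-B allele frequency of a copy multiset
#'
#' @param copies Character vector of haplotype labels, e.g. `c("A","A","B")`.
#' @return Fraction of parent-B copies (exact ratio as numeric).
#' @export
expected_allele_frequency <- function(copies) {
  if (length(copies) == 0) stopf("at least one copy required")
  if (!all(copies %in% c("A", "B"))) stopf("copies must be 'A' or 'B'")
  sum(copies == "B") / length(copies)
}

#' Classify allele-frequency bins to the nearest dosage state
#'
#' @param freq_bins Output of [binned_allele_freq()].
#' @param states Candidate frequency states (defaults: 0, 1/3, 1/2, 2/3).
#' @param tol Assignment tolerance; must be below half the minimal state gap
#'   (1/12 for the defaults).
#' @return `freq_bins` with `state` (numeric or NA) and `state_label`
#'   (fraction string or "other"; NA when masked).
#' @export
classify_bins <- function(freq_bins, states = c(0, 1/3, 1/2, 2/3), tol = 0.06) {
  gaps <- diff(sort(states))
  if (tol >= min(gaps) / 2) stopf("tol must be < half the minimal state gap")
  lab <- c("0", "1/3", "1/2", "2/3")[match(sort(states), c(0, 1/3, 1/2, 2/3))]
  lab[is.na(lab)] <- format(sort(states)[is.na(lab)], digits = 3)
  st <- sort(states)
  idx <- apply(abs(outer(freq_bins$freq_B, st, "-")), 1, which.min)
  near <- abs(freq_bins$freq_B - st[idx]) <= tol
  freq_bins$state <- ifelse(!freq_bins$masked & near, st[idx], NA_real_)
  freq_bins$state_label <- ifelse(freq_bins$masked, NA_character_,
                                  ifelse(near, lab[idx], "other"))
  freq_bins
}

#' Infer the meiotic origin of a trisomic region
#'
#' Decision logic on the classified allele-frequency states within the
#' trisomic region, with the pericentromeric subregion weighted decisively
#' when it holds enough bins (crossovers rarely alter its haplotype, so it
#' is most indicative of mis-segregation timing):
#' coexistence of the 1/2 and 1/3 states means two different maternal
#' haplotypes were co-inherited (meiosis I); dominance of the 2/3 or 0
#' states means two identical maternal haplotypes (meiosis II); a uniform
#' 1/2 state is a balanced region.
#'
#' @param classified Output of [classify_bins()].
#' @param trisomic_region A [region()] (e.g. the top CNV cluster).
#' @param pericentromere Optional [region()] inside the trisomic region.
#' @param min_state_fraction Minimum fraction of classified bins for a state
#'   to count as present.
#' @param min_bins Minimum classified bins needed in the pericentromeric
#'   subregion before it overrides the whole region.
#' @return A `meiosis_call`: verdict in
#'   `{"meiosis_I","meiosis_II","balanced","inconclusive"}` plus evidence.
#' @export
infer_stage <- function(classified, trisomic_region, pericentromere = NULL,
                        min_state_fraction = 0.05, min_bins = 5L) {
  pick <- function(r) {
    d <- classified[classified$chrom == r$chrom &
                      classified$start >= r$start & classified$end <= r$end, ,
                    drop = FALSE]
    d[!is.na(d$state_label), , drop = FALSE]
  }
  used <- "trisomic_region"
  d <- pick(trisomic_region)
  if (!is.null(pericentromere)) {
    dp <- pick(pericentromere)
    if (nrow(dp) >= min_bins) { d <- dp; used <- "pericentromere" }
  }
  if (nrow(d) == 0) {
    verdict <- "inconclusive"
    fr <- c(`0` = NA_real_, `1/3` = NA_real_, `1/2` = NA_real_, `2/3` = NA_real_)
  } else {
    fr <- vapply(c("0", "1/3", "1/2", "2/3"),
                 function(s) mean(d$state_label == s), numeric(1))
    th <- min_state_fraction
    verdict <- if ((fr["2/3"] >= th || fr["0"] >= th) && fr["1/3"] < th) {
      "meiosis_II"
    } else if (fr["1/3"] >= th && fr["1/2"] >= th) {
      "meiosis_I"
    } else if (fr["1/2"] >= 0.9) {
      "balanced"
    } else if (fr["1/3"] >= th) {
      # trisomic 1/3 with no lost-fragment 1/2 bins still implies two
      # different maternal haplotypes in the region
      "meiosis_I"
    } else "inconclusive"
  }
  structure(list(verdict = verdict, region = trisomic_region,
                 pericentromere = pericentromere, evaluated = used,
                 state_fractions = fr, n_bins = nrow(d)),
            class = "meiosis_call")
}

#' @export
print.meiosis_call <- function(x, ...) {
  cat(sprintf("meiosis call: %s (%d classified bins in %s)\n", x$verdict,
              x$n_bins, x$evaluated))
  fr <- x$state_fractions
  cat("  state fractions:",
      paste(sprintf("%s=%.2f", names(fr), fr), collapse = "  "), "\n")
  invisible(x)
}

#' Plot binned parent-B allele frequency along a chromosome
#'
#' @param freq_bins Output of [binned_allele_freq()].
#' @param chrom Chromosome (default first).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data.
#' @export
plot_allele_freq <- function(freq_bins, chrom = NULL, ...) {
  chrom <- chrom %||% freq_bins$chrom[1]
  d <- freq_bins[freq_bins$chrom == chrom & !freq_bins$masked, , drop = FALSE]
  graphics::plot((d$start + d$end) / 2 / 1e6, 100 * d$freq_B, pch = 16,
                 cex = 0.4, col = "grey30", ylim = c(0, 100),
                 xlab = sprintf("%s position (Mb)", chrom),
                 ylab = "parent-B allele frequency (%)", ...)
  graphics::abline(h = 100 * c(0, 1/3, 1/2, 2/3), lty = 3, col = "steelblue")
  invisible(d)
}
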