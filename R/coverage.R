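# Binned read dosage: raw counts, control normalization onto the
# diploid-equals-2 scale, CNV bin states, and dense-CNV cluster detection.

#' Count reads in non-overlapping genomic bins
#'
#' Each mapped primary read is assigned to exactly one bin by its leftmost
#' mapped coordinate; bins tile every chromosome, the terminal bin being
#' shorter where the length is not a multiple of `bin_size`.
#'
#' @param aln Alignment table (or path to a SAM file).
#' @param genome Genome object or named vector of chromosome lengths.
#' @param bin_size Bin width in bp (>= 1000).
#' @return Data frame with chrom, start, end (1-based inclusive), count.
#' @export
bin_counts <- function(aln, genome, bin_size = 5000L) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_sam(aln)
  if (bin_size < 1000) stopf("bin_size must be >= 1 kb")
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  bad <- setdiff(unique(aln$rname), names(lens))
  if (length(bad) > 0)
    stopf("alignment chromosome(s) not in genome table: %s",
          paste(bad, collapse = ", "))
  grid <- lapply(names(lens), function(chrom) {
    st <- as.integer(seq.int(1L, lens[[chrom]], by = bin_size))
    data.frame(chrom = chrom, start = st,
               end = as.integer(pmin(st + bin_size - 1L, lens[[chrom]])))
  })
  grid <- do.call(rbind, grid)
  grid$count <- 0L
  for (chrom in names(lens)) {
    p <- aln$pos[aln$rname == chrom]
    if (length(p) == 0) next
    nb <- sum(grid$chrom == chrom)
    tb <- tabulate((p - 1L) %/% bin_size + 1L, nbins = nb)
    grid$count[grid$chrom == chrom] <- tb
  }
  rownames(grid) <- NULL
  grid
}

#' Pool congruent bin-count tables by summing counts
#'
#' Mirrors pooling of low-coverage wild-type control libraries before
#' normalization.
#'
#' @param ... Two or more congruent [bin_counts()] tables.
#' @return A single bin-count table with summed counts.
#' @export
pool_bins <- function(...) {
  tabs <- list(...)
  out <- tabs[[1]]
  for (t2 in tabs[-1]) {
    check_congruent(out, t2)
    out$count <- out$count + t2$count
  }
  out
}

check_congruent <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) || !all(a$start == b$start))
    stopf("bin grids are not congruent")
  invisible(TRUE)
}

#' Normalize sample bin counts against a diploid control
#'
#' Per bin, `relative_coverage = 2 * (sample/sample_total) /
#' (control/control_total)`, so a diploid sample reads close to 2 and values
#' near 1 and 3 indicate heterozygous deletion and duplication. Bins whose
#' control count is below `control_floor` are masked rather than divided.
#'
#' Totals-based scaling alone leaves the diploid baseline displaced when an
#' aneuploid segment is a non-negligible fraction of the genome (the extra
#' copy inflates the sample total), so by default the ratios are recentered
#' so that the genome-wide median unmasked bin sits at exactly 2 -- the
#' robust assumption that most of the genome is diploid.
#'
#' @param sample_bins,control_bins Congruent [bin_counts()] tables. Pass
#'   pooled controls (see [pool_bins()]) for multiple control samples.
#' @param control_floor Minimum control raw count for an unmasked bin.
#' @param center `"median"` (default) recenters the genome-wide median to 2;
#'   `"none"` keeps the plain totals-based ratio.
#' @return Data frame of relative-coverage bins: chrom, start, end,
#'   raw_count, relative_coverage, masked.
#' @export
normalize_bins <- function(sample_bins, control_bins, control_floor = 10L,
                           center = c("median", "none")) {
  center <- match.arg(center)
  check_congruent(sample_bins, control_bins)
  st <- sum(sample_bins$count); ct <- sum(control_bins$count)
  if (st == 0 || ct == 0) stopf("empty sample or control")
  masked <- control_bins$count < control_floor
  rel <- rep(NA_real_, nrow(sample_bins))
  rel[!masked] <- 2 * (sample_bins$count[!masked] / st) /
    (control_bins$count[!masked] / ct)
  if (center == "median" && any(!masked)) {
    # two passes: the plain median is pulled off the diploid baseline when a
    # sizable genome fraction is aneuploid, so recenter again on the bins
    # that look neutral after the first pass
    rel <- rel * 2 / stats::median(rel[!masked])
    neutral <- !masked & rel > 1.5 & rel < 2.5
    if (sum(neutral) >= 10) rel <- rel * 2 / stats::median(rel[neutral])
  }
  data.frame(chrom = sample_bins$chrom, start = sample_bins$start,
             end = sample_bins$end, raw_count = sample_bins$count,
             relative_coverage = rel, masked = masked,
             stringsAsFactors = FALSE)
}

#' Call per-bin copy-number state
#'
#' Thresholds sit between the integer dosage anchors (1 = loss, 2 = neutral,
#' 3 = gain on the diploid scale). Masked bins get state `NA`.
#'
#' @param rel_bins Output of [normalize_bins()].
#' @param low,high State thresholds (`loss` below `low`, `gain` above `high`).
#' @return `rel_bins` with a `state` column in `{"loss","neutral","gain", NA}`.
#' @export
call_cnv_bins <- function(rel_bins, low = 1.5, high = 2.5) {
  if (low >= high) stopf("thresholds must satisfy low < high")
  st <- rep(NA_character_, nrow(rel_bins))
  ok <- !rel_bins$masked
  st[ok] <- "neutral"
  st[ok & rel_bins$relative_coverage < low] <- "loss"
  st[ok & rel_bins$relative_coverage > high] <- "gain"
  rel_bins$state <- st
  rel_bins
}

#' Find dense CNV clusters
#'
#' Scans each chromosome with a sliding window of `min_span` bp and reports
#' maximal runs of bins in which some covering window holds at least
#' `min_fraction` CNV (loss or gain) bins -- the signature of a shattered
#' region.
#'
#' @param cnv_bins Output of [call_cnv_bins()].
#' @param min_span Window span in bp.
#' @param min_fraction Minimum CNV-bin fraction within a window.
#' @return Data frame of clusters (chrom, start, end, n_cnv_bins,
#'   fraction_cnv_bins), sorted by decreasing span.
#' @export
find_cnv_cluster <- function(cnv_bins, min_span = 5e5, min_fraction = 0.2) {
  out <- list()
  for (chrom in unique(cnv_bins$chrom)) {
    d <- cnv_bins[cnv_bins$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    is_cnv <- !is.na(d$state) & d$state != "neutral"
    n <- nrow(d)
    bw <- max(d$end[1] - d$start[1] + 1L, 1L)
    w <- max(1L, min(n, as.integer(ceiling(min_span / bw))))
    if (!any(is_cnv)) next
    cs <- cumsum(c(0L, is_cnv))
    nwin <- n - w + 1L
    frac <- (cs[(w + 1):(w + nwin)] - cs[1:nwin]) / w
    hit <- frac >= min_fraction
    if (!any(hit)) next
    covered <- logical(n)
    for (i in which(hit)) covered[i:(i + w - 1L)] <- TRUE
    r <- rle(covered)
    endi <- cumsum(r$lengths); starti <- endi - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starti[k]; i1 <- endi[k]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = d$start[i0], end = d$end[i1],
        n_cnv_bins = sum(is_cnv[i0:i1]),
        fraction_cnv_bins = mean(is_cnv[i0:i1]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cnv_bins = integer(), fraction_cnv_bins = numeric()))
  res <- do.call(rbind, out)
  res[order(-(res$end - res$start)), , drop = FALSE]
}

#' Plot relative coverage along a chromosome
#'
#' @param rel_bins Output of [normalize_bins()] (optionally with states).
#' @param chrom Chromosome to plot (default: first present).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data.
#' @export
plot_dosage <- function(rel_bins, chrom = NULL, ...) {
  chrom <- chrom %||% rel_bins$chrom[1]
  d <- rel_bins[rel_bins$chrom == chrom & !rel_bins$masked, , drop = FALSE]
  graphics::plot((d$start + d$end) / 2 / 1e6, d$relative_coverage,
                 pch = 16, cex = 0.4, col = "grey30",
                 xlab = sprintf("%s position (Mb)", chrom),
                 ylab = "relative coverage (diploid = 2)",
                 ylim = c(0, max(4, d$relative_coverage, na.rm = TRUE)), ...)
  graphics::abline(h = c(1, 2, 3), lty = 3, col = "steelblue")
  invisible(d)
}
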