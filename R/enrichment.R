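# Breakpoint feature enrichment: the fraction of breakpoints whose centered
# window touches a track is compared with the same statistic for randomly
# placed pseudo-breakpoints, giving an observed/expected enrichment ratio
# and an empirical permutation p-value.

#' Fraction of breakpoints whose window overlaps a track
#'
#' Each breakpoint contributes a binary hit: whether its centered window
#' (+/- window/2, clipped at chromosome ends) intersects at least one track
#' interval.
#'
#' @param breakpoints Data frame with chrom, pos.
#' @param track Track data.frame (chrom, start, end; merged internally).
#' @param window Window size in bp (> 0).
#' @param genome Genome object or named lengths (for clipping).
#' @return Overlap fraction in `[0, 1]`.
#' @export
window_overlap <- function(breakpoints, track, window, genome) {
  if (window <= 0) stopf("window must be > 0")
  mean(window_hits(breakpoints, track, window, genome))
}

# Binary per-breakpoint window hits; vectorized via findInterval on the
# merged track.
window_hits <- function(breakpoints, track, window, genome) {
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  track <- merge_intervals(track)
  hits <- logical(nrow(breakpoints))
  half <- window / 2
  for (chrom in unique(breakpoints$chrom)) {
    bi <- which(breakpoints$chrom == chrom)
    tr <- track[track$chrom == chrom, , drop = FALSE]
    if (nrow(tr) == 0) next
    ws <- pmax(1, floor(breakpoints$pos[bi] - half))
    we <- pmin(lens[[chrom]], ceiling(breakpoints$pos[bi] + half))
    idx <- findInterval(we, tr$start)
    hits[bi] <- idx >= 1L & tr$end[pmax(idx, 1L)] >= ws
  }
  hits
}

#' Draw pseudo-breakpoints uniformly at random
#'
#' @param n Number of positions (>= 1).
#' @param genome Genome object or named lengths.
#' @param constraint `"genome_wide"` (uniform over all chromosomes,
#'   weighted by length) or `"within_region"`.
#' @param region Required for `"within_region"`.
#' @param seed Integer seed (same seed, same draws).
#' @return Data frame with chrom, pos.
#' @export
draw_pseudo_breakpoints <- function(n, genome,
                                    constraint = c("genome_wide", "within_region"),
                                    region = NULL, seed = NULL) {
  constraint <- match.arg(constraint)
  if (n < 1) stopf("n must be >= 1")
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  with_seed(seed, {
    if (constraint == "within_region") {
      if (is.null(region)) stopf("region required for within_region")
      data.frame(chrom = region$chrom,
                 pos = region$start + floor(stats::runif(n) * region_len(region)),
                 stringsAsFactors = FALSE)
    } else {
      ci <- sample.int(length(lens), n, replace = TRUE, prob = lens)
      data.frame(chrom = names(lens)[ci],
                 pos = floor(stats::runif(n) * lens[ci]) + 1L,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Permutation enrichment test of breakpoints against a track
#'
#' The expected overlap fraction is the mean of [window_overlap()] over
#' `n_perm` pseudo-breakpoint sets of equal size; the enrichment ratio is
#' observed/expected and the two-sided empirical p-value counts
#' permutations whose statistic deviates from the permutation mean at least
#' as much as the observed one, with the +1 correction.
#'
#' @param breakpoints Data frame with chrom, pos.
#' @param track Track data.frame.
#' @param window Window size in bp.
#' @param n_perm Number of permutations (>= 1000 recommended; hard floor 100).
#' @param constraint,region Null model (see [draw_pseudo_breakpoints()]).
#' @param genome Genome object or named lengths.
#' @param seed Integer seed.
#' @return One-row data.frame: track (if named), window, observed, expected,
#'   enrichment_ratio, p_value, n_perm.
#' @export
enrichment_test <- function(breakpoints, track, window, n_perm = 10000L,
                            constraint = c("genome_wide", "within_region"),
                            region = NULL, genome, seed = NULL) {
  constraint <- match.arg(constraint)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  n <- nrow(breakpoints)
  obs <- window_overlap(breakpoints, track, window, genome)
  f_perm <- with_seed(seed, {
    draws <- draw_pseudo_breakpoints(n * n_perm, genome, constraint, region)
    h <- window_hits(draws, track, window, genome)
    as.numeric(rowsum(as.numeric(h), rep(seq_len(n_perm), each = n))) / n
  })
  expected <- mean(f_perm)
  ratio <- if (expected == 0) { if (obs > 0) Inf else NA_real_ } else obs / expected
  eps <- 1e-12
  p <- (1 + sum(abs(f_perm - expected) >= abs(obs - expected) - eps)) / (n_perm + 1)
  data.frame(window = window, observed = obs, expected = expected,
             enrichment_ratio = ratio, p_value = p, n_perm = n_perm)
}

#' Enrichment table over several tracks and window sizes
#'
#' @param breakpoints Data frame with chrom, pos.
#' @param tracks Named list of track data.frames.
#' @param windows Window sizes in bp.
#' @param ... Passed to [enrichment_test()].
#' @param adjust Add Benjamini-Hochberg adjusted p-values (extension column).
#' @return Data frame shaped like a feature-enrichment table: track, window,
#'   observed, expected, enrichment_ratio, p_value (and p_adj_BH).
#' @export
enrich_tracks <- function(breakpoints, tracks, windows = c(1000L, 10000L),
                          ..., adjust = TRUE) {
  rows <- list()
  for (nm in names(tracks)) {
    for (w in windows) {
      r <- enrichment_test(breakpoints, tracks[[nm]], w, ...)
      rows[[length(rows) + 1]] <- cbind(track = nm, r)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj_BH <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
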