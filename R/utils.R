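# Small shared helpers. All coordinates handled here are 1-based inclusive;
# conversion to/from 0-based half-open happens only at the BED boundary.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions do
#' not perturb the caller's random stream. A `NULL` seed evaluates the
#' expression with the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage tag, keeping the result a
# valid 32-bit integer. Deterministic and order-free across stages.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(as.integer(charToRaw(as.character(tag))) * seq_along(charToRaw(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

BASES <- c("A", "C", "G", "T")

# Reverse complement of a character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorized single-base complement.
comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

# Sample n bases with a given GC content.
sample_bases <- function(n, gc = 0.36) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

# Pick, for each element of `avoid`, a random base different from it (and from
# `also_avoid` where given).
random_base_avoiding <- function(avoid, also_avoid = NULL) {
  vapply(seq_along(avoid), function(i) {
    cand <- setdiff(BASES, c(avoid[i], if (!is.null(also_avoid)) also_avoid[i]))
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Merge possibly-overlapping intervals (1-based inclusive) into a sorted,
# disjoint set. `df` needs chrom/start/end columns.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir), end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
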