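# Reconstruction of rearranged fragments: junction calls are turned into a
# graph over the reference segments delimited by their breakpoints, and
# maximal simple paths through that graph are the reconstructed runs of
# ordered, oriented segments.

#' Build the segment graph implied by junction calls over a region
#'
#' Breakpoints cut the region into segments; each junction becomes an edge
#' attaching the specific segment ends implied by its side labels (a `tail`
#' side uses the 3' end of the segment ending at the breakpoint, a `head`
#' side the 5' end of the segment starting there). Junctions with a
#' breakpoint outside the region are ignored with a message.
#'
#' @param calls Junction table (detector calls or simulator truth junctions).
#' @param region A [region()] containing the breakpoints.
#' @return List with `segments` (id, chrom, start, end), `edges`
#'   (junction, seg1, end1, seg2, end2, support), and `region`.
#' @export
build_segment_graph <- function(calls, region) {
  j <- normalize_junctions(calls)
  inside <- j$chrom1 == region$chrom & j$bp1 >= region$start & j$bp1 <= region$end &
            j$chrom2 == region$chrom & j$bp2 >= region$start & j$bp2 <= region$end
  if (any(!inside))
    message(sprintf("ignoring %d junction(s) with breakpoints outside the region",
                    sum(!inside)))
  j <- j[inside, , drop = FALSE]
  # a tail side at p implies a cut after p; a head side at p a cut after p-1
  cutpos <- function(bp, side) ifelse(side == "tail", bp, bp - 1L)
  cuts <- sort(unique(c(cutpos(j$bp1, j$side1), cutpos(j$bp2, j$side2))))
  cuts <- cuts[cuts >= region$start & cuts < region$end]
  starts <- c(region$start, cuts + 1L)
  ends <- c(cuts, region$end)
  segments <- data.frame(id = seq_along(starts), chrom = region$chrom,
                         start = starts, end = ends)
  find_end <- function(bp, side) {
    if (side == "tail") segments$id[match(bp, segments$end)]
    else segments$id[match(bp, segments$start)]
  }
  edges <- NULL
  if (nrow(j) > 0) {
    edges <- data.frame(
      junction = j$junction,
      seg1 = mapply(find_end, j$bp1, j$side1), end1 = j$side1,
      seg2 = mapply(find_end, j$bp2, j$side2), end2 = j$side2,
      support = j$support, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(junction = integer(), seg1 = integer(), end1 = character(),
                        seg2 = integer(), end2 = character(), support = integer())
  }
  list(segments = segments, edges = edges, region = region)
}

# Accept either detector call tables or simulator truth junction tables.
normalize_junctions <- function(calls) {
  if (all(c("chrom1", "bp1", "side1") %in% names(calls))) {
    data.frame(junction = seq_len(nrow(calls)),
               chrom1 = calls$chrom1, bp1 = calls$bp1, side1 = calls$side1,
               chrom2 = calls$chrom2, bp2 = calls$bp2, side2 = calls$side2,
               support = if ("support" %in% names(calls)) calls$support else 1L,
               stringsAsFactors = FALSE)
  } else if (all(c("left_bp", "side1") %in% names(calls))) {
    data.frame(junction = seq_len(nrow(calls)),
               chrom1 = calls$chrom, bp1 = calls$left_bp, side1 = calls$side1,
               chrom2 = calls$chrom, bp2 = calls$right_bp, side2 = calls$side2,
               support = 1L, stringsAsFactors = FALSE)
  } else stopf("unrecognized junction table")
}

#' Chain the segment graph into reconstructed fragments
#'
#' Walks maximal simple paths under the constraint that every segment end is
#' used by at most one junction. Ends claimed by several edges keep the
#' highest-support edge (losers are reported); cycles are broken at their
#' lowest-support edge. Chains are normalized so the leftmost reference
#' segment appears in '+' orientation, and ordered by leftmost coordinate
#' then length.
#'
#' @param graph Output of [build_segment_graph()].
#' @param drop_singletons Drop chains consisting of a single segment with no
#'   junction (default `FALSE`).
#' @return List with `chains` (long data.frame: chain, order, seg id, chrom,
#'   start, end, orient, junction to the next entry), `summary` (chain,
#'   n_segments, n_junctions), and `dropped_edges`.
#' @export
chain_fragments <- function(graph, drop_singletons = FALSE) {
  seg <- graph$segments
  ed <- graph$edges
  dropped <- NULL
  if (nrow(ed) > 0) {
    # conflict resolution: each (segment, end) may carry one edge
    keyA <- paste(ed$seg1, ed$end1); keyB <- paste(ed$seg2, ed$end2)
    ord <- order(-ed$support)
    used <- character(0); keep <- logical(nrow(ed))
    for (i in ord) {
      if (keyA[i] %in% used || keyB[i] %in% used) next
      keep[i] <- TRUE
      used <- c(used, keyA[i], keyB[i])
    }
    dropped <- ed[!keep, , drop = FALSE]
    ed <- ed[keep, , drop = FALSE]
  }

  # endpoint -> edge lookup
  epkey <- function(s, e) paste(s, e)
  edge_at <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ed))) {
    assign(epkey(ed$seg1[i], ed$end1[i]), i, envir = edge_at)
    assign(epkey(ed$seg2[i], ed$end2[i]), i, envir = edge_at)
  }
  has_edge <- function(s, e) exists(epkey(s, e), envir = edge_at)

  visited <- logical(nrow(seg))
  edge_used <- logical(nrow(ed))
  chains <- list()

  walk <- function(start_seg, enter_end) {
    path <- list()
    s <- start_seg; ent <- enter_end
    repeat {
      visited[s] <<- TRUE
      orient <- if (ent == "head") "+" else "-"
      exit_end <- if (ent == "head") "tail" else "head"
      nxt_j <- NA_integer_
      if (has_edge(s, exit_end)) {
        i <- get(epkey(s, exit_end), envir = edge_at)
        if (!edge_used[i]) {
          edge_used[i] <<- TRUE
          nxt_j <- ed$junction[i]
          other_seg <- if (ed$seg1[i] == s && ed$end1[i] == exit_end) ed$seg2[i] else ed$seg1[i]
          other_end <- if (ed$seg1[i] == s && ed$end1[i] == exit_end) ed$end2[i] else ed$end1[i]
          path[[length(path) + 1]] <- list(seg = s, orient = orient, junction = nxt_j)
          s <- other_seg; ent <- other_end
          next
        }
      }
      path[[length(path) + 1]] <- list(seg = s, orient = orient, junction = NA_integer_)
      break
    }
    path
  }

  # start at free ends
  for (s in seg$id) {
    if (visited[s]) next
    free_head <- !has_edge(s, "head")
    free_tail <- !has_edge(s, "tail")
    if (free_head && free_tail && !drop_singletons) {
      chains[[length(chains) + 1]] <- walk(s, "head")
    } else if (free_head) {
      chains[[length(chains) + 1]] <- walk(s, "head")
    } else if (free_tail) {
      chains[[length(chains) + 1]] <- walk(s, "tail")
    }
  }
  # remaining components are cycles: break at the lowest-support unused edge
  repeat {
    left <- which(!visited)
    left <- left[vapply(left, function(s) has_edge(s, "head") || has_edge(s, "tail"),
                        logical(1))]
    if (length(left) == 0) break
    cyc_edges <- which(!edge_used & (ed$seg1 %in% left | ed$seg2 %in% left))
    br <- cyc_edges[which.min(ed$support[cyc_edges])]
    edge_used[br] <- TRUE # sever
    dropped <- rbind(dropped, ed[br, , drop = FALSE])
    # enter through the freed end so the walk traverses the rest of the cycle
    chains[[length(chains) + 1]] <- walk(ed$seg1[br], ed$end1[br])
  }
  if (!drop_singletons) {
    for (s in seg$id[!visited]) chains[[length(chains) + 1]] <- walk(s, "head")
  }

  rows <- list()
  for (ci in seq_along(chains)) {
    p <- chains[[ci]]
    d <- data.frame(chain = ci, order = seq_along(p),
                    seg = vapply(p, `[[`, integer(1), "seg"),
                    orient = vapply(p, `[[`, character(1), "orient"),
                    junction = vapply(p, `[[`, integer(1), "junction"))
    d$chrom <- seg$chrom[d$seg]; d$start <- seg$start[d$seg]; d$end <- seg$end[d$seg]
    # normalize: leftmost segment in '+' orientation
    lm <- which.min(d$start)
    if (d$orient[lm] == "-") {
      d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
      d$orient <- ifelse(d$orient == "+", "-", "+")
      d$junction <- c(d$junction[-1], NA_integer_)
      d$order <- seq_len(nrow(d))
    }
    rows[[ci]] <- d
  }
  key <- vapply(rows, function(d) min(d$start), numeric(1))
  len <- vapply(rows, nrow, integer(1))
  ord <- order(key, -len)
  long <- do.call(rbind, lapply(seq_along(ord), function(i) {
    d <- rows[[ord[i]]]; d$chain <- i; d
  }))
  rownames(long) <- NULL
  summary <- do.call(rbind, lapply(split(long, long$chain), function(d)
    data.frame(chain = d$chain[1], n_segments = nrow(d),
               n_junctions = sum(!is.na(d$junction)))))
  rownames(summary) <- NULL
  list(chains = long, summary = summary, dropped_edges = dropped)
}

#' Reconstruct rearranged fragments from junction calls
#'
#' Convenience wrapper: [build_segment_graph()] then [chain_fragments()].
#'
#' @inheritParams build_segment_graph
#' @inheritParams chain_fragments
#' @return As [chain_fragments()].
#' @export
reconstruct_fragments <- function(calls, region, drop_singletons = FALSE) {
  chain_fragments(build_segment_graph(calls, region), drop_singletons)
}

#' Derivative-order chain implied by a shatter event
#'
#' Ground-truth counterpart of a reconstructed chain: the retained fragments
#' in derivative order with orientations, normalized like
#' [chain_fragments()] output.
#'
#' @param event A `shatter_event`.
#' @return Data frame with start, end, orient in derivative order.
#' @export
event_chain <- function(event) {
  d <- data.frame(start = event$fragments$ref_start,
                  end = event$fragments$ref_end,
                  orient = event$fragments$orient)
  lm <- which.min(d$start)
  if (d$orient[lm] == "-") {
    d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    d$orient <- ifelse(d$orient == "+", "-", "+")
  }
  rownames(d) <- NULL
  d
}

#' Test whether two chains describe the same reconstruction
#'
#' Chains are compared as ordered (start, end, orient) runs, accepting
#' whole-chain reversal with flipped orientations.
#'
#' @param a,b Data frames with start, end, orient.
#' @return `TRUE` or `FALSE`.
#' @export
chains_equivalent <- function(a, b) {
  sig <- function(d) paste(d$start, d$end, d$orient, collapse = ";")
  flip <- function(d) {
    d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    d$orient <- ifelse(d$orient == "+", "-", "+")
    d
  }
  sig(a) == sig(b) || sig(flip(a)) == sig(b)
}
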