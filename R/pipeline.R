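# End-to-end orchestration: simulate (or load) -> coverage -> junctions ->
# reconstruct -> haplotypes -> enrichment, with a census-style summary
# report whose every number is recomputable from the stage outputs.

#' Default run configuration
#'
#' Returns the full configuration list for [run_shatterscan()]; any element
#' can be overridden through `...` (nested lists are replaced wholesale).
#' The defaults describe a study-like scenario scaled to desk size: a
#' two-chromosome genome whose first chromosome carries a shattered arm,
#' transmitted trisomically after meiosis-I nondisjunction alongside an
#' intact parent-B homolog, sequenced at 30x with two diploid controls.
#'
#' @param ... Named overrides.
#' @return Configuration list.
#' @export
shatterscan_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(n_chroms = 2L, lengths = c(1200000L, 400000L), gc = 0.36),
    snp_rate = 0.002,
    shatter = list(chrom = "chr1", start = 1L, end = 600000L,
                   n_fragments = 12L, loss_fraction = 0.1,
                   repair_mix = c(microhomology = 0.638, perfect = 0.112,
                                  insertion = 0.25)),
    stage = "meiosis_I", maternal_hap = "B",
    depth = 30, control_depth = 30, read_len = 100L,
    insert_mean = 300, insert_sd = 50,
    bin_size = 5000L, control_floor = 10L,
    cnv = list(low = 1.5, high = 2.5, min_span = 100000L, min_fraction = 0.2),
    junctions = list(min_distance = 2000L, radius = 500L, window = 400L),
    hap = list(bin_size = 10000L, floor = 20L, tol = 0.06),
    pericentromere = NULL, # default: middle third of the top CNV cluster
    tracks = list(gene = list(fraction = 0.3, mean_len = 2000),
                  transposable_element = list(fraction = 0.15, mean_len = 3000)),
    enrichment = list(windows = c(1000L, 10000L), n_perm = 1000L,
                      constraint = "within_region"),
    outdir = NULL, write_alignments = FALSE)
  utils::modifyList(cfg, list(...))
}

#' Run the full chromoanagenesis characterization pipeline
#'
#' Simulates the configured scenario (genome, shattered arm, offspring
#' karyotype, reads for the target and two pooled controls, annotation
#' tracks), then runs dosage analysis, junction calling, fragment
#' reconstruction, haplotype staging, and breakpoint enrichment, and
#' assembles a summary report. Rerunning with the same configuration gives
#' identical results.
#'
#' @param config A [shatterscan_config()] list.
#' @return A `shatterscan_run` object with stage outputs, ground truth, and
#'   `report`.
#' @export
run_shatterscan <- function(config = shatterscan_config()) {
  seed <- config$seed
  # --- simulate -----------------------------------------------------------
  genome0 <- make_genome(config$genome$n_chroms, config$genome$lengths,
                         config$genome$gc, seed = derive_seed(seed, "genome"))
  sh <- shatter(genome0,
                region(config$shatter$chrom, config$shatter$start, config$shatter$end),
                n_fragments = config$shatter$n_fragments,
                loss_fraction = config$shatter$loss_fraction,
                repair_mix = config$shatter$repair_mix,
                seed = derive_seed(seed, "shatter"))
  genome <- sh$genome
  haps <- derive_haplotypes(genome, config$snp_rate,
                            seed = derive_seed(seed, "haplotypes"))
  kary <- make_offspring(genome, haps, sh$event, config$stage,
                         maternal_hap = config$maternal_hap)
  reads <- simulate_reads(kary, depth = config$depth, read_len = config$read_len,
                          insert_mean = config$insert_mean,
                          insert_sd = config$insert_sd,
                          seed = derive_seed(seed, "reads"))
  controls <- lapply(1:2, function(i) {
    k <- make_offspring(genome, haps, NULL, "balanced",
                        maternal_hap = config$maternal_hap)
    simulate_reads(k, depth = config$control_depth, read_len = config$read_len,
                   insert_mean = config$insert_mean, insert_sd = config$insert_sd,
                   seed = derive_seed(seed, paste0("control", i)))
  })
  tracks <- make_tracks(genome, config$tracks, seed = derive_seed(seed, "tracks"))

  # --- coverage -----------------------------------------------------------
  sb <- bin_counts(reads$aln, genome, config$bin_size)
  cb <- pool_bins(bin_counts(controls[[1]]$aln, genome, config$bin_size),
                  bin_counts(controls[[2]]$aln, genome, config$bin_size))
  rel <- normalize_bins(sb, cb, config$control_floor)
  cnv <- call_cnv_bins(rel, config$cnv$low, config$cnv$high)
  clusters <- find_cnv_cluster(cnv, config$cnv$min_span, config$cnv$min_fraction)
  cluster_region <- if (nrow(clusters) > 0)
    region(clusters$chrom[1], clusters$start[1], clusters$end[1])
  else region(config$shatter$chrom, config$shatter$start, config$shatter$end)

  # --- junctions ----------------------------------------------------------
  jc <- call_junctions(reads$aln, lapply(controls, `[[`, "aln"), genome,
                       min_distance = config$junctions$min_distance,
                       radius = config$junctions$radius,
                       window = config$junctions$window)
  calls <- jc$calls

  # --- reconstruct --------------------------------------------------------
  calls_in <- calls[calls$chrom1 == cluster_region$chrom &
                      calls$bp1 >= cluster_region$start & calls$bp1 <= cluster_region$end &
                      calls$chrom2 == cluster_region$chrom &
                      calls$bp2 >= cluster_region$start & calls$bp2 <= cluster_region$end, ,
                    drop = FALSE]
  recon <- if (nrow(calls_in) > 0)
    reconstruct_fragments(calls_in, cluster_region) else NULL

  # --- haplotypes ---------------------------------------------------------
  sc <- snp_allele_counts(reads$aln, haps$snps)
  freq <- binned_allele_freq(sc, genome, config$hap$bin_size, config$hap$floor)
  classified <- classify_bins(freq, tol = config$hap$tol)
  peri <- config$pericentromere %||% {
    w <- region_len(cluster_region) %/% 3L
    region(cluster_region$chrom, cluster_region$start + w,
           cluster_region$end - w)
  }
  stage_call <- infer_stage(classified, cluster_region, peri)

  # --- enrichment ---------------------------------------------------------
  bp <- junction_breakpoints(calls)
  enr <- if (nrow(bp) >= 5) {
    enrich_tracks(bp, tracks, windows = config$enrichment$windows,
                  n_perm = config$enrichment$n_perm,
                  constraint = config$enrichment$constraint,
                  region = cluster_region, genome = genome,
                  seed = derive_seed(seed, "enrichment"))
  } else NULL

  report <- build_report(calls, cluster_region, tracks$gene, recon, stage_call, enr)
  run <- structure(list(
    config = config, genome = genome, haplotypes = haps, event = sh$event,
    karyotype = kary, reads = reads, controls = controls, tracks = tracks,
    bins = rel, cnv = cnv, clusters = clusters, cluster_region = cluster_region,
    junctions = jc, calls = calls, reconstruction = recon,
    allele_freq = classified, stage_call = stage_call, enrichment = enr,
    report = report), class = "shatterscan_run")
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

# Report arithmetic is pure: every field is recomputed from the stage tables.
build_report <- function(calls, cluster_region, gene_track, recon, stage_call,
                         enr) {
  fr <- report_fractions(calls, cluster_region, gene_track)
  spacing <- if (fr$n_breakpoints_in_cluster > 0)
    breakpoint_density(calls, cluster_region) else NA_real_
  rc <- if (nrow(calls) > 0) {
    tb <- table(factor(calls$repair_class,
                       levels = c("microhomology", "perfect", "insertion")))
    100 * as.numeric(tb) / nrow(calls)
  } else rep(NA_real_, 3)
  names(rc) <- c("microhomology", "perfect", "insertion")
  inverted <- if (nrow(calls) > 0)
    100 * mean(calls$orientation_class %in% c("head_head", "tail_tail")) else NA_real_
  list(n_junctions = nrow(calls),
       pct_junctions_in_cluster = fr$pct_junctions_in_cluster,
       breakpoint_spacing_kb = spacing,
       n_chains = if (!is.null(recon)) nrow(recon$summary) else 0L,
       longest_chain_junctions = if (!is.null(recon) && nrow(recon$summary) > 0)
         max(recon$summary$n_junctions) else 0L,
       repair_pct = rc, pct_inverted = inverted,
       pct_breakpoints_in_genes = fr$pct_breakpoints_in_genes,
       meiosis_verdict = stage_call$verdict,
       enrichment = enr)
}

#' Census fractions of a junction table
#'
#' Computes the report's ratio fields: the percentage of junctions with both
#' breakpoints inside the cluster region, and the percentage of individual
#' breakpoints (two per junction) falling within gene-track intervals.
#' An empty junction table yields `NA` percentages.
#'
#' @param calls Junction call table.
#' @param cluster_region A [region()].
#' @param gene_track Gene track data.frame (or `NULL`).
#' @return List with counts and percentages.
#' @export
report_fractions <- function(calls, cluster_region, gene_track = NULL) {
  n <- nrow(calls)
  if (n == 0) {
    return(list(n_junctions = 0L, n_in_cluster = 0L,
                pct_junctions_in_cluster = NA_real_,
                n_breakpoints = 0L, n_breakpoints_in_cluster = 0L,
                n_breakpoints_in_genes = NA_integer_,
                pct_breakpoints_in_genes = NA_real_))
  }
  inside <- function(chrom, pos) chrom == cluster_region$chrom &
    pos >= cluster_region$start & pos <= cluster_region$end
  both <- inside(calls$chrom1, calls$bp1) & inside(calls$chrom2, calls$bp2)
  bp <- junction_breakpoints(calls)
  ing <- if (!is.null(gene_track) && nrow(gene_track) > 0) {
    hit <- logical(nrow(bp))
    for (chrom in unique(bp$chrom)) {
      tr <- gene_track[gene_track$chrom == chrom, , drop = FALSE]
      bi <- which(bp$chrom == chrom)
      if (nrow(tr) == 0) next
      idx <- findInterval(bp$pos[bi], tr$start)
      hit[bi] <- idx >= 1L & tr$end[pmax(idx, 1L)] >= bp$pos[bi]
    }
    hit
  } else NULL
  list(n_junctions = n, n_in_cluster = sum(both),
       pct_junctions_in_cluster = 100 * sum(both) / n,
       n_breakpoints = nrow(bp),
       n_breakpoints_in_cluster = sum(inside(bp$chrom, bp$pos)),
       n_breakpoints_in_genes = if (!is.null(ing)) sum(ing) else NA_integer_,
       pct_breakpoints_in_genes = if (!is.null(ing)) 100 * mean(ing) else NA_real_)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(run$genome, file.path(outdir, "reference.fa"))
  write_tsv(run$bins, file.path(outdir, "relative_coverage.tsv"))
  write_tsv(run$cnv[, c("chrom", "start", "end", "raw_count",
                        "relative_coverage", "state")],
            file.path(outdir, "cnv_bins.tsv"))
  if (nrow(run$clusters) > 0)
    write_tsv(run$clusters, file.path(outdir, "cnv_clusters.tsv"))
  write_tsv(run$calls[, setdiff(names(run$calls), "contig")],
            file.path(outdir, "junctions.tsv"))
  if (nrow(run$calls) > 0) write_bedpe(run$calls, file.path(outdir, "junctions.bedpe"))
  if (!is.null(run$reconstruction))
    write_tsv(run$reconstruction$chains, file.path(outdir, "chains.tsv"))
  write_tsv(run$allele_freq, file.path(outdir, "allele_freq_bins.tsv"))
  write_tsv(run$event$junctions, file.path(outdir, "truth_junctions.tsv"))
  write_tsv(run$event$fragments, file.path(outdir, "truth_fragments.tsv"))
  for (nm in names(run$tracks))
    write_bed(run$tracks[[nm]], file.path(outdir, paste0("track_", nm, ".bed")))
  if (!is.null(run$enrichment))
    write_tsv(run$enrichment, file.path(outdir, "enrichment.tsv"))
  if (isTRUE(run$config$write_alignments)) {
    write_sam(run$reads$aln, run$genome, file.path(outdir, "sample.sam"))
    for (i in seq_along(run$controls))
      write_sam(run$controls[[i]]$aln, run$genome,
                file.path(outdir, sprintf("control%d.sam", i)))
    write_fastq(run$reads, file.path(outdir, "sample"))
  }
  cfg <- run$config
  cfg$shatter$repair_mix <- as.list(cfg$shatter$repair_mix)
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(outdir)
}

#' @export
print.shatterscan_run <- function(x, ...) {
  r <- x$report
  cat("shatterscan run\n")
  cat(sprintf("  CNV cluster: %s:%d-%d\n", x$cluster_region$chrom,
              x$cluster_region$start, x$cluster_region$end))
  cat(sprintf("  novel junctions called: %d (truth: %d novel)\n",
              r$n_junctions, sum(x$event$junctions$novel)))
  if (!is.na(r$pct_junctions_in_cluster))
    cat(sprintf("  both breakpoints in cluster: %.1f%%\n",
                r$pct_junctions_in_cluster))
  if (!is.na(r$breakpoint_spacing_kb))
    cat(sprintf("  mean breakpoint spacing: %.0f kb\n", r$breakpoint_spacing_kb))
  if (!all(is.na(r$repair_pct)))
    cat(sprintf("  repair classes: microhomology %.1f%%, perfect %.1f%%, insertion %.1f%%\n",
                r$repair_pct[1], r$repair_pct[2], r$repair_pct[3]))
  if (!is.na(r$pct_inverted))
    cat(sprintf("  inverted-configuration junctions: %.1f%%\n", r$pct_inverted))
  cat(sprintf("  reconstructed chains: %d (longest: %d junctions)\n",
              r$n_chains, r$longest_chain_junctions))
  if (!is.na(r$pct_breakpoints_in_genes))
    cat(sprintf("  breakpoints in genes: %.1f%%\n", r$pct_breakpoints_in_genes))
  cat(sprintf("  meiosis verdict: %s\n", r$meiosis_verdict))
  invisible(x)
}

#' @export
#' @method summary shatterscan_run
summary.shatterscan_run <- function(object, ...) object$report

#' @export
#' @method plot shatterscan_run
plot.shatterscan_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot_dosage(x$bins, x$cluster_region$chrom)
  plot_allele_freq(x$allele_freq, x$cluster_region$chrom)
  invisible(x)
}

#' Run a small bundled end-to-end demonstration
#'
#' A reduced configuration (smaller genome, fewer fragments) that completes
#' in well under a minute on one CPU.
#'
#' @param outdir Optional output directory for artifacts.
#' @param seed Integer seed.
#' @return A `shatterscan_run`.
#' @export
shatterscan_demo <- function(outdir = NULL, seed = 1L) {
  cfg <- shatterscan_config(
    seed = seed,
    genome = list(n_chroms = 2L, lengths = c(600000L, 200000L), gc = 0.36),
    shatter = list(chrom = "chr1", start = 1L, end = 300000L,
                   n_fragments = 8L, loss_fraction = 0.1,
                   repair_mix = c(microhomology = 0.638, perfect = 0.112,
                                  insertion = 0.25)),
    enrichment = list(windows = c(1000L, 10000L), n_perm = 500L,
                      constraint = "within_region"),
    outdir = outdir)
  run_shatterscan(cfg)
}
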