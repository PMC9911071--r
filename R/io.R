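# File-format plumbing. Alignments travel through the package as a plain
# data.frame ("alignment table") with the SAM mandatory columns:
# qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq.
# SAM text is the on-disk interchange; reading goes through Rsamtools.

#' Write an alignment table as SAM
#'
#' Emits a minimal, `samtools`-compatible SAM file with `@HD`/`@SQ` headers
#' taken from the genome.
#'
#' @param aln Alignment table (see [simulate_reads()]).
#' @param genome A [make_genome()] genome (supplies `@SQ` lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  qual <- strrep("I", nchar(aln$seq))
  rec <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
               aln$rnext, aln$pnext, aln$tlen, aln$seq, qual, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Converts through BAM with Rsamtools and returns the package's alignment
#' data.frame. Unmapped records are dropped.
#'
#' @param path Path to a SAM file with `@SQ` headers.
#' @return Alignment table.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq",
                                        "cigar", "mrnm", "mpos", "isize", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  data.frame(qname = x$qname[keep], flag = x$flag[keep],
             rname = as.character(x$rname[keep]), pos = x$pos[keep],
             mapq = x$mapq[keep], cigar = x$cigar[keep],
             rnext = ifelse(is.na(x$mrnm[keep]), "*", as.character(x$mrnm[keep])),
             pnext = ifelse(is.na(x$mpos[keep]), 0L, x$mpos[keep]),
             tlen = ifelse(is.na(x$isize[keep]), 0L, x$isize[keep]),
             seq = as.character(x$seq[keep]), stringsAsFactors = FALSE)
}

# Strand of each record as "+"/"-" from the 0x10 flag bit.
aln_strand <- function(aln) ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")

# Aligned reference width (cigar is always <len>M here).
aln_width <- function(aln) nchar(aln$seq)

#' Write a genome as FASTA
#' @param genome A genome object or named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$chroms else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write paired reads as a pair of FASTQ files
#' @param reads Read set from [simulate_reads()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  s1 <- Biostrings::DNAStringSet(reads$pairs$seq1)
  s2 <- Biostrings::DNAStringSet(reads$pairs$seq2)
  names(s1) <- names(s2) <- reads$pairs$name
  q1 <- Biostrings::BStringSet(strrep("I", nchar(reads$pairs$seq1)))
  q2 <- Biostrings::BStringSet(strrep("I", nchar(reads$pairs$seq2)))
  Biostrings::writeXStringSet(s1, p1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(s2, p2, format = "fastq", qualities = q2)
  invisible(c(p1, p2))
}

#' Write an annotation track as BED
#'
#' Internal track tables are 1-based inclusive; BED on disk is 0-based
#' half-open, converted here via rtracklayer.
#'
#' @param track Data frame with chrom/start/end (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$start, track$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as a 1-based inclusive track table
#' @param path Path to a BED file.
#' @return Data frame with chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
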