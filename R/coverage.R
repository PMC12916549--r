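# Per-Mb-bin read counting and normalization. Each read is assigned to
# exactly one bin by its start position (150-bp reads against 1-Mb bins make
# overlap splitting immaterial); normalized values scale raw counts so a
# fully present euploid bin centres near 1.

new_bin_coverage <- function(ref, raw_count, normalized = NA_real_,
                             norm_constant = NA_real_) {
  cov <- ref$bins
  cov$raw_count <- as.integer(raw_count)
  cov$normalized <- normalized
  structure(cov, class = c("bin_coverage", "data.frame"),
            reference = ref, norm_constant = norm_constant)
}

#' Read mapped-read placements from BED-like text
#'
#' Three leading tab-separated columns `chrom`, `start_bp`, `end_bp`
#' (0-based half-open); extra columns and `#` lines are ignored.
#'
#' @param path file path.
#' @return placements data.frame.
#' @export
read_placements_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expected at least 3 columns (chrom, start, end)")
  data.frame(chrom = as.character(tab[[1]]), start_bp = as.numeric(tab[[2]]),
             end_bp = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
}

#' Read mapped-read placements from SAM text
#'
#' Extracts (reference name, 0-based start) from mapped records, keeping
#' alignments with MAPQ at or above `min_mapq` and without the unmapped
#' flag (0x4). Header lines (`@`) are skipped. The end coordinate is taken
#' as start + sequence length (CIGAR is not interpreted; bin assignment
#' uses the start only).
#'
#' @param path SAM text file path.
#' @param min_mapq minimum mapping quality (default 20).
#' @return placements data.frame.
#' @export
read_placements_sam <- function(path, min_mapq = 20L) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  rname <- vapply(fields, function(f) f[3], character(1))
  pos <- vapply(fields, function(f) as.numeric(f[4]), numeric(1))
  mapq <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  seqlen <- vapply(fields, function(f) {
    if (length(f) >= 10L && f[10] != "*") nchar(f[10]) else 0L
  }, integer(1))
  keep <- bitwAnd(flag, 4L) == 0L & mapq >= min_mapq & rname != "*"
  data.frame(chrom = rname[keep], start_bp = pos[keep] - 1,
             end_bp = pos[keep] - 1 + seqlen[keep], stringsAsFactors = FALSE)
}

#' Count reads per bin
#'
#' Assigns each placement to the bin containing its start position and
#' tallies. Totals are conserved: the counts sum to the number of placements.
#'
#' @param placements data.frame with `chrom`, `start_bp` (`end_bp` ignored).
#' @param ref hybrid reference supplying the bin grid.
#' @return `bin_coverage` with raw counts.
#' @export
count_reads <- function(placements, ref) {
  bins <- ref$bins
  ci <- match(placements$chrom, ref$chromosomes$name)
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop(sprintf("placement record %d on unknown chromosome '%s'",
                 bad, placements$chrom[bad]))
  }
  len_bp <- ref$chromosomes$length_mb[ci] * 1e6
  if (any(placements$start_bp < 0 | placements$start_bp >= len_bp)) {
    bad <- which(placements$start_bp < 0 | placements$start_bp >= len_bp)[1]
    stop(sprintf("placement record %d at %s:%s outside chromosome length",
                 bad, placements$chrom[bad],
                 format(placements$start_bp[bad], scientific = FALSE)))
  }
  bin_in_chrom <- floor(placements$start_bp / (ref$bin_size_mb * 1e6))
  key_bins <- paste0(bins$chrom, ":", bins$bin_index)
  key_reads <- paste0(placements$chrom, ":", bin_in_chrom)
  counts <- tabulate(match(key_reads, key_bins), nbins = nrow(bins))
  new_bin_coverage(ref, counts)
}

#' Normalize bin counts
#'
#' Fills the `normalized` column as `raw_count / (M * len_frac)` where the
#' normalization constant `M` is, by default, the median raw count over bins
#' with nonzero counts -- robust to large absent fractions and centring
#' fully present euploid bins near 1. The alternative `"mean_top_half"`
#' uses the mean of the upper half of nonzero counts.
#'
#' @param cov `bin_coverage` with raw counts.
#' @param method `"median_nonzero"` (default) or `"mean_top_half"`.
#' @return `bin_coverage` with `normalized` filled and the constant attached
#'   as attribute `norm_constant`.
#' @export
normalize_coverage <- function(cov, method = c("median_nonzero",
                                               "mean_top_half")) {
  method <- match.arg(method)
  nz <- cov$raw_count[cov$raw_count > 0]
  if (length(nz) == 0L) stop("no informative bins (all counts are zero)")
  m <- switch(method,
              median_nonzero = stats::median(nz),
              mean_top_half = mean(sort(nz, decreasing = TRUE)[
                seq_len(ceiling(length(nz) / 2))]))
  out <- cov
  out$normalized <- cov$raw_count / (m * cov$len_frac)
  attr(out, "norm_constant") <- m
  out
}

#' Mean normalized coverage of one chromosome
#'
#' @param cov normalized `bin_coverage`.
#' @param chrom chromosome name.
#' @return arithmetic mean of the chromosome's normalized bin values.
#' @export
chromosome_mean <- function(cov, chrom) {
  ref <- attr(cov, "reference")
  chrom_row(ref, chrom)
  mean(cov$normalized[cov$chrom == chrom])
}

#' Sequencing run summary
#'
#' Totals read number and sequenced length and reports average coverage as
#' their ratio to the reference length, the usual depth statement for
#' low-pass genome skimming.
#'
#' @param reference_length_bp reference length in bp (> 0).
#' @param read_lengths_bp vector of read lengths in bp, or
#' @param placements placements data.frame (lengths taken as end - start), or
#' @param n_reads,sum_length_bp precomputed totals.
#' @return list with `n_reads`, `sum_length_bp`, `average_coverage`.
#' @export
sequencing_summary <- function(reference_length_bp, read_lengths_bp = NULL,
                               placements = NULL, n_reads = NULL,
                               sum_length_bp = NULL) {
  if (reference_length_bp <= 0) stop("reference_length_bp must be > 0")
  if (!is.null(placements)) {
    read_lengths_bp <- placements$end_bp - placements$start_bp
  }
  if (!is.null(read_lengths_bp)) {
    n_reads <- length(read_lengths_bp)
    sum_length_bp <- sum(read_lengths_bp)
  }
  if (is.null(n_reads) || is.null(sum_length_bp)) {
    stop("provide read_lengths_bp, placements, or n_reads + sum_length_bp")
  }
  list(n_reads = n_reads, sum_length_bp = sum_length_bp,
       average_coverage = sum_length_bp / reference_length_bp)
}

#' Write / read a bin coverage table as TSV
#'
#' Columns `chrom`, `bin_start_mb`, `bin_end_mb`, `raw_count`, `normalized`,
#' in reference order.
#'
#' @param cov `bin_coverage`.
#' @param path file path.
#' @export
write_bin_table <- function(cov, path) {
  out <- data.frame(chrom = cov$chrom, bin_start_mb = cov$start_mb,
                    bin_end_mb = cov$end_mb, raw_count = cov$raw_count,
                    normalized = cov$normalized, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_table
#' @param ref the hybrid reference the table was computed on.
#' @export
read_bin_table <- function(path, ref) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  key_ref <- paste0(ref$bins$chrom, ":", ref$bins$start_mb)
  key_tab <- paste0(tab$chrom, ":", tab$bin_start_mb)
  idx <- match(key_ref, key_tab)
  if (anyNA(idx)) stop("bin table does not tile the given reference")
  new_bin_coverage(ref, tab$raw_count[idx], normalized = tab$normalized[idx])
}
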