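# Present/absent segmentation of normalized bin coverage: two-threshold
# classification with flank-based resolution of intermediate bins, short-run
# smoothing, and merging into maximal segments. Deterministic and auditable;
# adequate at the signal-to-noise of low-pass skim data where present and
# absent bins are separated by more than an order of magnitude.

#' Classify bins present/absent from normalized coverage
#'
#' Bins at or below `tau_absent` are absent, at or above `tau_present`
#' present. Bins strictly between are intermediate and are resolved to the
#' state of the nearer resolved flanking bin on the same chromosome (ties
#' broken toward the flanking run whose mean normalized value is closer to
#' the bin's own value); an intermediate run touching a chromosome end takes
#' its single flank's state. A chromosome that is entirely intermediate
#' falls back to comparing each bin against the threshold midpoint.
#'
#' @param cov normalized `bin_coverage`.
#' @param tau_absent,tau_present thresholds, `0 <= tau_absent < tau_present`.
#' @return character vector, one of `"present"`/`"absent"` per bin, in
#'   reference order.
#' @export
classify_bins <- function(cov, tau_absent = 0.15, tau_present = 0.4) {
  if (tau_absent < 0 || tau_absent >= tau_present) {
    stop("thresholds must satisfy 0 <= tau_absent < tau_present")
  }
  x <- cov$normalized
  if (anyNA(x)) stop("coverage must be normalized before classification")
  state <- ifelse(x <= tau_absent, "absent",
                  ifelse(x >= tau_present, "present", NA_character_))
  for (ch in unique(cov$chrom)) {
    sel <- which(cov$chrom == ch)
    state[sel] <- resolve_intermediate(state[sel], x[sel],
                                       (tau_absent + tau_present) / 2)
  }
  state
}

resolve_intermediate <- function(s, x, midpoint) {
  if (!anyNA(s)) return(s)
  if (all(is.na(s))) return(ifelse(x >= midpoint, "present", "absent"))
  resolved <- which(!is.na(s))
  runs <- rle(is.na(s))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    left <- if (starts[k] > 1L) starts[k] - 1L else NA_integer_
    right <- if (ends[k] < length(s)) ends[k] + 1L else NA_integer_
    for (i in starts[k]:ends[k]) {
      if (is.na(left)) {
        s[i] <- s[right]
      } else if (is.na(right)) {
        s[i] <- s[left]
      } else {
        dl <- i - left
        dr <- right - i
        if (dl < dr) {
          s[i] <- s[left]
        } else if (dr < dl) {
          s[i] <- s[right]
        } else {
          # equidistant: side whose flanking-run mean is closer to this bin
          lrun <- run_mean(s, x, left, -1L)
          rrun <- run_mean(s, x, right, +1L)
          s[i] <- if (abs(x[i] - lrun) <= abs(x[i] - rrun)) s[left] else s[right]
        }
      }
    }
  }
  s
}

# mean normalized value of the maximal same-state resolved run starting at
# index i and extending in direction dir
run_mean <- function(s, x, i, dir) {
  st <- s[i]
  j <- i
  while (j + dir >= 1L && j + dir <= length(s) &&
         !is.na(s[j + dir]) && s[j + dir] == st) {
    j <- j + dir
  }
  mean(x[seq(min(i, j), max(i, j))])
}

#' Smooth a bin-state vector by absorbing short runs
#'
#' Iteratively flips any maximal run shorter than `min_run` whose two
#' flanking runs share a state into that state, repeating to a fixpoint.
#' Runs touching a chromosome end are never flipped. Operates per
#' chromosome.
#'
#' @param states character state vector (`"present"`/`"absent"`).
#' @param chrom chromosome label per bin (single chromosome if omitted).
#' @param min_run minimum run length to survive, in bins (default 3).
#' @return smoothed state vector.
#' @export
smooth_states <- function(states, chrom = NULL, min_run = 3L) {
  if (min_run < 1L) stop("min_run must be >= 1")
  if (is.null(chrom)) chrom <- rep("chr", length(states))
  out <- states
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    out[sel] <- smooth_one(out[sel], min_run)
  }
  out
}

smooth_one <- function(s, min_run) {
  repeat {
    r <- rle(s)
    if (length(r$lengths) < 3L) return(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- 2:(length(r$lengths) - 1L)
    flip <- interior[r$lengths[interior] < min_run &
                     r$values[interior - 1L] == r$values[interior + 1L]]
    if (length(flip) == 0L) return(s)
    k <- flip[1]  # flip shortest-first would also work; leftmost is stable
    s[starts[k]:ends[k]] <- r$values[k - 1L]
  }
}

#' Segment one chromosome into maximal present/absent runs
#'
#' Classifies, smooths, then merges adjacent equal-state bins. The output
#' segments tile the chromosome, alternate in state, and carry the mean
#' normalized coverage of their bins.
#'
#' @param cov normalized `bin_coverage`.
#' @param chrom chromosome name.
#' @param tau_absent,tau_present classification thresholds.
#' @param min_run smoothing window in bins.
#' @return data.frame of class `segment_calls`: `chrom`, `start_mb`,
#'   `end_mb` (0-based half-open Mb), `state`, `length_mb`,
#'   `mean_normalized`, `label` (1-based inclusive Mb, the field's reporting
#'   convention).
#' @export
segment_chromosome <- function(cov, chrom, tau_absent = 0.15,
                               tau_present = 0.4, min_run = 3L) {
  ref <- attr(cov, "reference")
  chrom_row(ref, chrom)
  seg <- segment_coverage(cov, tau_absent = tau_absent,
                          tau_present = tau_present, min_run = min_run)
  out <- seg[seg$chrom == chrom, ]
  rownames(out) <- NULL
  out
}

#' Segment every chromosome of a coverage table
#'
#' @inheritParams segment_chromosome
#' @return `segment_calls` data.frame over all chromosomes, reference order.
#' @export
segment_coverage <- function(cov, tau_absent = 0.15, tau_present = 0.4,
                             min_run = 3L) {
  states <- classify_bins(cov, tau_absent, tau_present)
  states <- smooth_states(states, cov$chrom, min_run)
  merge_states(cov, states)
}

merge_states <- function(cov, states) {
  ref <- attr(cov, "reference")
  segs <- do.call(rbind, lapply(unique(cov$chrom), function(ch) {
    sel <- which(cov$chrom == ch)
    r <- rle(states[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(
      chrom = ch,
      start_mb = cov$start_mb[sel][starts],
      end_mb = cov$end_mb[sel][ends],
      state = r$values,
      mean_normalized = vapply(seq_along(starts), function(k) {
        mean(cov$normalized[sel][starts[k]:ends[k]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(segs) <- NULL
  segs$length_mb <- segs$end_mb - segs$start_mb
  segs$label <- segment_label(segs)
  structure(segs, class = c("segment_calls", "data.frame"), reference = ref)
}

#' 1-based inclusive Mb label of a segment
#'
#' Converts internal 0-based half-open Mb coordinates to the printed
#' "start+1-end" convention, e.g. `[0,217)` is labelled `"1-217 Mb"`.
#'
#' @param seg `segment_calls` (or any data.frame with `start_mb`, `end_mb`).
#' @return character vector of labels.
#' @export
segment_label <- function(seg) {
  sprintf("%d-%d Mb", as.integer(seg$start_mb) + 1L, as.integer(seg$end_mb))
}

#' Write segment calls as BED and TSV
#'
#' The BED twin uses 0-based half-open bp with the state in the name column
#' and mean normalized coverage in the score column; the TSV twin keeps Mb
#' coordinates and the 1-based labels.
#'
#' @param segments `segment_calls`.
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom,
                    start_bp = format(segments$start_mb * 1e6, scientific = FALSE, trim = TRUE),
                    end_bp = format(segments$end_mb * 1e6, scientific = FALSE, trim = TRUE),
                    name = segments$state,
                    score = signif(segments$mean_normalized, 4),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
write_segments_tsv <- function(segments, path) {
  out <- as.data.frame(segments)[, c("chrom", "start_mb", "end_mb", "state",
                                     "length_mb", "mean_normalized", "label")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @param ref hybrid reference the segments refer to.
#' @export
read_segments_tsv <- function(path, ref) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(tab, class = c("segment_calls", "data.frame"), reference = ref)
}
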