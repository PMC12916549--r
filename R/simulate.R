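# Seeded gamma-Poisson simulator of low-pass GBS bin counts over a karyotype.
# Present bins draw counts around depth_per_bin * cn/2; absent bins receive a
# flat cross-mapping background (homoeologous reads mis-assigned between the
# two subgenomes of the concatenated reference).

#' Simulation parameters
#'
#' @param depth_per_bin expected raw count for a copy-number-2 bin of full
#'   width (default 30).
#' @param mappability_dispersion variance of the unit-mean gamma mappability
#'   factor multiplying each bin's rate; 0 disables it (default 0.005,
#'   a mild bin-to-bin mappability wobble on top of counting noise).
#' @param cross_map_to_barley fraction of `depth_per_bin` leaking onto barley
#'   bins regardless of copy number (default 0.011, the midpoint of the
#'   0.009-0.013 background a wheat line shows on barley chromosomes).
#' @param cross_map_to_wheat same for wheat bins (default 0.004, midpoint of
#'   0.002-0.006).
#' @param seed integer RNG seed; mandatory, every draw flows from it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(depth_per_bin = 30, mappability_dispersion = 0.005,
                       cross_map_to_barley = 0.011,
                       cross_map_to_wheat = 0.004, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  if (depth_per_bin < 0) stop("depth_per_bin must be >= 0")
  if (mappability_dispersion < 0) stop("mappability_dispersion must be >= 0")
  if (cross_map_to_barley < 0 || cross_map_to_barley >= 1 ||
      cross_map_to_wheat < 0 || cross_map_to_wheat >= 1) {
    stop("cross-mapping rates must lie in [0, 1)")
  }
  structure(list(depth_per_bin = depth_per_bin,
                 mappability_dispersion = mappability_dispersion,
                 cross_map_to_barley = cross_map_to_barley,
                 cross_map_to_wheat = cross_map_to_wheat,
                 seed = as.integer(seed)),
            class = "sim_params")
}

with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

bin_rates <- function(karyotype, params) {
  bins <- as.data.frame(karyotype)
  cross <- ifelse(bins$subgenome == "barley",
                  params$cross_map_to_barley, params$cross_map_to_wheat)
  params$depth_per_bin * (bins$copy_number / 2 + cross) * bins$len_frac
}

draw_counts <- function(karyotype, params) {
  lambda <- bin_rates(karyotype, params)
  n <- length(lambda)
  m <- if (params$mappability_dispersion > 0) {
    shape <- 1 / params$mappability_dispersion
    stats::rgamma(n, shape = shape, rate = shape)
  } else rep(1, n)
  stats::rpois(n, lambda * m)
}

#' Simulate per-bin raw read counts
#'
#' For each bin, `count ~ Poisson(lambda * m)` with
#' `lambda = depth_per_bin * (copy_number/2 + cross_map_rate) * len_frac`
#' and `m` a unit-mean gamma mappability factor (a gamma-Poisson mixture,
#' i.e. negative-binomial-like marginal). Bins are consumed in reference
#' order from a single seeded stream, so an identical (karyotype, params)
#' pair reproduces identical counts.
#'
#' @param karyotype a `karyotype`.
#' @param params a `sim_params`.
#' @return `bin_coverage` data.frame (bin table plus `raw_count`; the
#'   `normalized` column is filled by [normalize_coverage()]).
#' @export
simulate_bin_counts <- function(karyotype, params) {
  stopifnot(inherits(params, "sim_params"))
  counts <- with_sim_seed(params$seed, draw_counts(karyotype, params))
  new_bin_coverage(attr(karyotype, "reference"), counts)
}

#' Simulate individual read placements
#'
#' Draws the same per-bin multiplicities as [simulate_bin_counts()] (same
#' seed, same stream order), then scatters that many fixed-length reads
#' uniformly within each bin. Counting the result with [count_reads()]
#' reproduces the simulated count table exactly.
#'
#' @param karyotype a `karyotype`.
#' @param params a `sim_params`.
#' @param read_length_bp emitted read length (default 150).
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`.
#' @export
simulate_read_positions <- function(karyotype, params, read_length_bp = 150L) {
  stopifnot(inherits(params, "sim_params"))
  bins <- as.data.frame(karyotype)
  with_sim_seed(params$seed, {
    counts <- draw_counts(karyotype, params)
    total <- sum(counts)
    if (total == 0L) {
      data.frame(chrom = character(), start_bp = numeric(),
                 end_bp = numeric(), stringsAsFactors = FALSE)
    } else {
      idx <- rep.int(seq_along(counts), counts)
      span_bp <- (bins$end_mb[idx] - bins$start_mb[idx]) * 1e6
      offs <- floor(stats::runif(total) * pmax(span_bp - read_length_bp, 1))
      start <- as.numeric(bins$start_mb[idx] * 1e6 + offs)
      data.frame(chrom = bins$chrom[idx],
                 start_bp = start,
                 end_bp = start + read_length_bp,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Write / read read placements as 3-column BED-like text
#'
#' @param placements data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param path file path.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements[, c("chrom", "start_bp", "end_bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
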