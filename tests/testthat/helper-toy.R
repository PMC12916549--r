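# Small references and profiles built in code; no fixture files.

toy_specs <- function(name, subgenome, length_mb, centromere_mb, group = 1L) {
  data.frame(name = name, subgenome = subgenome, length_mb = length_mb,
             centromere_mb = centromere_mb, group = group,
             stringsAsFactors = FALSE)
}

# one wheat (10 Mb, cen 5) + one barley (8 Mb, cen 4) chromosome
toy_ref <- function(bin_size_mb = 1L) {
  build_hybrid_reference(
    toy_specs("1W", "wheat", 10L, 5L),
    toy_specs("1Hb", "barley", 8L, 4L),
    bin_size_mb = bin_size_mb
  )
}

# random valid chromosome spec tables for property-style loops
random_specs <- function(n, subgenome, prefix) {
  len <- sample(2:40, n, replace = TRUE)
  cen <- pmax(1L, pmin(len - 1L, round(len * stats::runif(n, 0.2, 0.8))))
  toy_specs(paste0(prefix, seq_len(n)), subgenome, len, as.integer(cen),
            group = rep_len(1:7, n))
}

# coverage object with prescribed normalized values on a single-chromosome
# reference (one bin per value)
profile_coverage <- function(values, centromere_mb = NULL, name = "1W",
                             subgenome = "wheat") {
  len <- length(values)
  cen <- if (is.null(centromere_mb)) max(1L, len %/% 2L) else centromere_mb
  specs <- toy_specs(name, subgenome, len, cen)
  ref <- if (subgenome == "wheat") {
    build_hybrid_reference(specs, NULL)
  } else {
    build_hybrid_reference(toy_specs("0W", "wheat", 2L, 1L), specs)
  }
  cov <- count_reads(
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), stringsAsFactors = FALSE), ref)
  cov$raw_count <- rep(0L, nrow(cov))
  full <- rep(0, nrow(cov))
  full[cov$chrom == name] <- values
  cov$normalized <- full
  cov
}

# noiseless normalized profile over the full default wheat+barley reference:
# present bins at `hi`, absent at `lo`, from a karyotype
karyotype_profile <- function(karyotype, hi = 1.0, lo = 0.01) {
  ref <- attr(karyotype, "reference")
  cov <- count_reads(
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), stringsAsFactors = FALSE), ref)
  cov$normalized <- ifelse(karyotype$copy_number > 0, hi, lo)
  cov
}
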