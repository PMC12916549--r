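# Coordinate geometry of the concatenated "in silico hybrid" reference:
# two parental chromosome sets on a shared 1-Mb bin grid. The reference is
# purely positional -- no sequence is ever touched.

#' Validate a chromosome specification table
#'
#' A chromosome specification table describes one parental genome (or both):
#' one row per chromosome with its label, subgenome of origin, length and
#' centromere position in Mb, and homoeologous group.
#'
#' @param specs data.frame with columns `name`, `subgenome` (`"wheat"` or
#'   `"barley"`), `length_mb`, `centromere_mb`, `group` (integer 1-7).
#' @return The validated data.frame (invisibly usable downstream).
#' @export
as_chromosome_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  required <- c("name", "subgenome", "length_mb", "centromere_mb", "group")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0L) {
    stop("chromosome spec table lacks column(s): ", paste(missing, collapse = ", "))
  }
  specs$name <- as.character(specs$name)
  specs$subgenome <- as.character(specs$subgenome)
  if (!all(specs$subgenome %in% c("wheat", "barley"))) {
    stop("subgenome must be 'wheat' or 'barley'")
  }
  if (anyDuplicated(specs$name)) {
    dup <- unique(specs$name[duplicated(specs$name)])
    stop("duplicate chromosome name(s): ", paste(dup, collapse = ", "))
  }
  if (any(specs$length_mb < 1)) {
    stop("chromosome length_mb must be >= 1 (offending: ",
         paste(specs$name[specs$length_mb < 1], collapse = ", "), ")")
  }
  bad_cen <- specs$centromere_mb <= 0 | specs$centromere_mb >= specs$length_mb
  if (any(bad_cen)) {
    stop("centromere_mb must satisfy 0 < centromere < length (offending: ",
         paste(specs$name[bad_cen], collapse = ", "), ")")
  }
  if (!all(specs$group %in% 1:7)) stop("homoeologous group must be in 1..7")
  specs[required]
}

#' Read a chromosome specification file
#'
#' Tab-delimited text with columns `name`, `subgenome`, `length_mb`,
#' `centromere_mb`, `group`; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return validated chromosome spec data.frame.
#' @export
read_chromosome_specs <- function(path) {
  specs <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  as_chromosome_specs(specs)
}

#' Write a chromosome specification file
#'
#' @param specs chromosome spec data.frame.
#' @param path output path.
#' @export
write_chromosome_specs <- function(specs, path) {
  specs <- as_chromosome_specs(specs)
  utils::write.table(specs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default wheat + barley chromosome table
#'
#' Assembly-scale chromosome lengths and centromere positions for the 21
#' bread-wheat chromosomes (CS RefSeq scale) and the 7 barley chromosomes
#' (Morex scale), in Mb. Chromosomes that carry the packaged translocation
#' scenarios use the coordinates those scenarios require (6B 731 Mb with
#' centromere 345; 6H 560 Mb with centromere 253; 3B 851 Mb; 2D 665 Mb;
#' 4B 673 Mb with centromere 317; 4H 647 Mb with centromere 312); the
#' remaining entries are representative defaults at realistic scale.
#'
#' @param subgenome optionally restrict to `"wheat"` or `"barley"`.
#' @return chromosome spec data.frame (28 rows by default).
#' @export
wheat_barley_specs <- function(subgenome = c("both", "wheat", "barley")) {
  subgenome <- match.arg(subgenome)
  wheat <- data.frame(
    name = c("1A", "1B", "1D", "2A", "2B", "2D", "3A", "3B", "3D",
             "4A", "4B", "4D", "5A", "5B", "5D", "6A", "6B", "6D",
             "7A", "7B", "7D"),
    subgenome = "wheat",
    length_mb = c(598L, 700L, 498L, 787L, 812L, 665L, 754L, 851L, 631L,
                  754L, 673L, 525L, 713L, 714L, 566L, 622L, 731L, 495L,
                  744L, 764L, 642L),
    centromere_mb = c(213L, 240L, 168L, 326L, 348L, 268L, 317L, 354L, 241L,
                      265L, 317L, 185L, 253L, 200L, 186L, 286L, 345L, 214L,
                      363L, 310L, 339L),
    group = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L,
              5L, 5L, 5L, 6L, 6L, 6L, 7L, 7L, 7L),
    stringsAsFactors = FALSE
  )
  barley <- data.frame(
    name = c("1H", "2H", "3H", "4H", "5H", "6H", "7H"),
    subgenome = "barley",
    length_mb = c(522L, 665L, 622L, 647L, 597L, 560L, 657L),
    centromere_mb = c(205L, 305L, 271L, 312L, 217L, 253L, 329L),
    group = 1:7,
    stringsAsFactors = FALSE
  )
  out <- switch(subgenome,
                both = rbind(wheat, barley),
                wheat = wheat,
                barley = barley)
  as_chromosome_specs(out)
}

#' Build the concatenated hybrid reference and its bin grid
#'
#' Concatenates the two parental chromosome sets (first genome first, mirroring
#' an aligner's view of a combined assembly) and tiles every chromosome with
#' half-open bins `[i*bin, (i+1)*bin)` in Mb. A trailing partial bin shorter
#' than `bin_size_mb` is kept as its own bin; its fractional length is stored
#' so normalization can rescale it.
#'
#' @param wheat_specs chromosome specs for the recipient genome.
#' @param barley_specs chromosome specs for the donor genome (may be empty,
#'   i.e. a zero-row data.frame or `NULL`).
#' @param bin_size_mb bin width in Mb (integer >= 1; default 1).
#' @return object of class `hybrid_reference`: list with `chromosomes`
#'   (spec table in concatenation order), `bin_size_mb`, and `bins`, a
#'   data.frame with one row per bin (`chrom`, `bin_index` 0-based within
#'   chromosome, `start_mb`, `end_mb`, `subgenome`, `group`, `arm`,
#'   `len_frac`).
#' @examples
#' ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
#'                               wheat_barley_specs("barley"))
#' nrow(ref$chromosomes)  # 28
#' @export
build_hybrid_reference <- function(wheat_specs, barley_specs = NULL,
                                   bin_size_mb = 1L) {
  if (!is.numeric(bin_size_mb) || bin_size_mb < 1) {
    stop("bin_size_mb must be an integer >= 1")
  }
  bin_size_mb <- as.integer(bin_size_mb)
  wheat_specs <- as_chromosome_specs(wheat_specs)
  if (!all(wheat_specs$subgenome == "wheat")) {
    stop("wheat_specs must have subgenome 'wheat'")
  }
  if (is.null(barley_specs) || nrow(as.data.frame(barley_specs)) == 0L) {
    chroms <- wheat_specs
  } else {
    barley_specs <- as_chromosome_specs(barley_specs)
    if (!all(barley_specs$subgenome == "barley")) {
      stop("barley_specs must have subgenome 'barley'")
    }
    chroms <- rbind(wheat_specs, barley_specs)
    if (anyDuplicated(chroms$name)) {
      dup <- unique(chroms$name[duplicated(chroms$name)])
      stop("duplicate chromosome name(s) across genomes: ",
           paste(dup, collapse = ", "))
    }
  }

  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length_mb[i]
    n_bins <- as.integer(ceiling(len / bin_size_mb))
    start <- (seq_len(n_bins) - 1L) * bin_size_mb
    end <- pmin(start + bin_size_mb, len)
    data.frame(
      chrom = chroms$name[i],
      bin_index = seq_len(n_bins) - 1L,
      start_mb = start,
      end_mb = end,
      subgenome = chroms$subgenome[i],
      group = chroms$group[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(bins) <- NULL
  bins$len_frac <- (bins$end_mb - bins$start_mb) / bin_size_mb

  ref <- structure(
    list(chromosomes = chroms, bin_size_mb = bin_size_mb, bins = bins),
    class = "hybrid_reference"
  )
  ref$bins$arm <- assign_arms(ref)
  ref
}

# S/L arm label per bin: S strictly before the centromere, L at/after; the
# bin containing the centromere goes to the arm holding the larger share,
# ties to S.
assign_arms <- function(ref) {
  cen <- ref$chromosomes$centromere_mb[match(ref$bins$chrom,
                                             ref$chromosomes$name)]
  s_share <- pmax(0, pmin(ref$bins$end_mb, cen) - ref$bins$start_mb)
  l_share <- (ref$bins$end_mb - ref$bins$start_mb) - s_share
  ifelse(s_share >= l_share & s_share > 0, "S",
         ifelse(ref$bins$end_mb <= cen, "S", "L"))
}

#' @export
print.hybrid_reference <- function(x, ...) {
  cat(sprintf(
    "hybrid_reference: %d chromosomes (%d wheat, %d barley), %d bins of %d Mb\n",
    nrow(x$chromosomes),
    sum(x$chromosomes$subgenome == "wheat"),
    sum(x$chromosomes$subgenome == "barley"),
    nrow(x$bins), x$bin_size_mb))
  invisible(x)
}

chrom_row <- function(ref, chrom) {
  i <- match(chrom, ref$chromosomes$name)
  if (is.na(i)) {
    stop("unknown chromosome '", chrom, "' (reference has: ",
         paste(ref$chromosomes$name, collapse = ", "), ")")
  }
  ref$chromosomes[i, ]
}

#' Arm label of a bin
#'
#' @param ref hybrid reference.
#' @param chrom chromosome name.
#' @param bin_index 0-based bin index within the chromosome.
#' @return `"S"` or `"L"` per bin. A bin lying entirely before the centromere
#'   is `S`, entirely at/after is `L`; the centromere-containing bin goes to
#'   the arm holding its larger share (ties to `S`).
#' @export
arm_of <- function(ref, chrom, bin_index) {
  chrom_row(ref, chrom)  # validates name
  sel <- ref$bins$chrom == chrom
  idx <- match(bin_index, ref$bins$bin_index[sel])
  if (anyNA(idx)) {
    stop("bin index out of range for chromosome ", chrom)
  }
  ref$bins$arm[sel][idx]
}

#' Locate the bin containing a position
#'
#' @param ref hybrid reference.
#' @param chrom chromosome name.
#' @param position_mb position in Mb, `0 <= position < length_mb`.
#' @return 0-based bin index `i` with `i*bin <= position < (i+1)*bin`.
#' @export
locate_bin <- function(ref, chrom, position_mb) {
  row <- chrom_row(ref, chrom)
  if (any(position_mb < 0 | position_mb >= row$length_mb)) {
    stop(sprintf("position %s Mb out of range on %s (length %d Mb)",
                 paste(position_mb[position_mb < 0 |
                                   position_mb >= row$length_mb][1]),
                 chrom, row$length_mb))
  }
  as.integer(floor(position_mb / ref$bin_size_mb))
}

n_bins <- function(ref) nrow(ref$bins)

reference_length_mb <- function(ref, subgenome = NULL) {
  chroms <- ref$chromosomes
  if (!is.null(subgenome)) chroms <- chroms[chroms$subgenome == subgenome, ]
  sum(chroms$length_mb)
}
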