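# Interpretation of segment calls: arm-level presence, compensating centric
# fusion nomenclature (short arm first, e.g. T6BS.6HL), deletion calls,
# introgression summaries, and pericentric-inversion inference from two
# complementary carrier lines of the same chromosome.

check_tiling <- function(segments, ref, chrom) {
  row <- chrom_row(ref, chrom)
  seg <- segments[segments$chrom == chrom, ]
  if (nrow(seg) == 0L) stop("no segments for chromosome ", chrom)
  seg <- seg[order(seg$start_mb), ]
  ok <- seg$start_mb[1] == 0 &&
    seg$end_mb[nrow(seg)] == row$length_mb &&
    (nrow(seg) == 1L || all(seg$start_mb[-1] == seg$end_mb[-nrow(seg)]))
  if (!ok) stop("segments do not tile chromosome ", chrom)
  seg
}

#' Arm-level presence status of one chromosome
#'
#' For each arm, the fraction of its span covered by present segments;
#' status is `present` at fraction >= 0.9, `absent` at <= 0.1, else
#' `partial`.
#'
#' @param segments `segment_calls` tiling the chromosome.
#' @param ref hybrid reference.
#' @param chrom chromosome name.
#' @return data.frame with one row per arm: `chrom`, `arm`,
#'   `fraction_present`, `status`.
#' @export
arm_status <- function(segments, ref, chrom) {
  seg <- check_tiling(segments, ref, chrom)
  row <- chrom_row(ref, chrom)
  cen <- row$centromere_mb
  arm_frac <- function(lo, hi) {
    pres <- seg[seg$state == "present", , drop = FALSE]
    if (nrow(pres) == 0L) return(0)
    overlap <- pmax(0, pmin(pres$end_mb, hi) - pmax(pres$start_mb, lo))
    sum(overlap) / (hi - lo)
  }
  fr <- c(S = arm_frac(0, cen), L = arm_frac(cen, row$length_mb))
  data.frame(
    chrom = chrom, arm = names(fr), fraction_present = unname(fr),
    status = ifelse(fr >= 0.9, "present", ifelse(fr <= 0.1, "absent", "partial")),
    stringsAsFactors = FALSE
  )
}

#' Arm statuses for every chromosome of a segment table
#'
#' @param segments genome-wide `segment_calls`.
#' @param ref hybrid reference.
#' @return data.frame of arm statuses with `subgenome` and `group` attached.
#' @export
arm_status_table <- function(segments, ref) {
  out <- do.call(rbind, lapply(unique(segments$chrom), function(ch) {
    arm_status(segments, ref, ch)
  }))
  i <- match(out$chrom, ref$chromosomes$name)
  out$subgenome <- ref$chromosomes$subgenome[i]
  out$group <- ref$chromosomes$group[i]
  rownames(out) <- NULL
  out
}

#' Call compensating centric fusions (Robertsonian translocations)
#'
#' Within each homoeologous group, a fusion is called when exactly one wheat
#' chromosome has one arm absent and the other present, while the barley
#' chromosome of the group shows the complementary pattern: the opposite
#' arm present and the same arm absent. The wheat side uses the strict
#' 0.9/0.1 arm thresholds; on the barley side a fraction >= 0.75 counts as
#' present and <= 0.25 as absent, tolerating block boundaries shifted
#' across the centromere by a pericentric inversion. Names put the short
#' arm first (`T6BS.6HL`). A wheat chromosome with both arms absent is
#' reported as a whole-chromosome loss, not a fusion.
#'
#' @param statuses arm-status table from [arm_status_table()].
#' @return list with `translocations` (data.frame: `name`, `wheat_arm`,
#'   `barley_arm`, `homoeologous_group`) and `whole_losses` (chromosome
#'   names).
#' @export
call_centric_fusions <- function(statuses) {
  calls <- list()
  losses <- character()
  for (g in sort(unique(statuses$group))) {
    gs <- statuses[statuses$group == g, ]
    wheat <- gs[gs$subgenome == "wheat", ]
    barley <- gs[gs$subgenome == "barley", ]
    for (wc in unique(wheat$chrom)) {
      ws <- wheat[wheat$chrom == wc, ]
      s_stat <- ws$status[ws$arm == "S"]
      l_stat <- ws$status[ws$arm == "L"]
      if (s_stat == "absent" && l_stat == "absent") {
        losses <- c(losses, wc)
        next
      }
      lost_arm <- if (s_stat == "absent" && l_stat == "present") "S"
        else if (l_stat == "absent" && s_stat == "present") "L"
        else next
      kept_arm <- setdiff(c("S", "L"), lost_arm)
      for (bc in unique(barley$chrom)) {
        bs <- barley[barley$chrom == bc, ]
        b_lost <- bs$fraction_present[bs$arm == lost_arm]
        b_kept <- bs$fraction_present[bs$arm == kept_arm]
        if (b_lost >= 0.75 && b_kept <= 0.25) {
          wheat_arm <- paste0(wc, kept_arm)
          barley_arm <- paste0(bc, lost_arm)
          arms <- c(wheat_arm, barley_arm)
          short_first <- arms[order(substr(arms, nchar(arms), nchar(arms)),
                                    decreasing = TRUE)]  # "S" before "L"
          calls[[length(calls) + 1L]] <- data.frame(
            name = paste0("T", short_first[1], ".", short_first[2]),
            wheat_arm = wheat_arm, barley_arm = barley_arm,
            homoeologous_group = g, stringsAsFactors = FALSE)
        }
      }
    }
  }
  translocations <- if (length(calls)) do.call(rbind, calls) else
    data.frame(name = character(), wheat_arm = character(),
               barley_arm = character(), homoeologous_group = integer(),
               stringsAsFactors = FALSE)
  list(translocations = translocations, whole_losses = losses)
}

#' Parse a fusion name back into its arms
#'
#' @param name translocation name like `"T6BS.6HL"`.
#' @return list with `arm1`, `arm2` (chromosome + arm letter).
#' @export
parse_fusion_name <- function(name) {
  m <- regmatches(name, regexec("^T([0-9][A-Z]+[SL])\\.([0-9][A-Z]+[SL])$", name))[[1]]
  if (length(m) != 3L) stop("malformed translocation name: ", name)
  list(arm1 = m[2], arm2 = m[3])
}

#' Call deletions on majority-present chromosomes
#'
#' Each absent segment on a chromosome whose bins are majority-present
#' becomes a deletion call: `terminal` if it touches either chromosome end,
#' else `interstitial`. Chromosomes that are not majority-present, or that
#' have a whole arm absent (the lost arm of a centric fusion), are skipped
#' -- their absence is interpreted by the fusion/whole-loss caller, not as
#' deletion. By default only recipient (wheat) chromosomes are scanned:
#' absent stretches on a donor chromosome delimit the introgression, they
#' are not deletions in the genetic background.
#'
#' @param segments genome-wide `segment_calls`.
#' @param ref hybrid reference.
#' @param min_length_mb smallest reportable deletion (default 5 Mb, below
#'   which absent runs are more plausibly smoothing artefacts).
#' @param subgenomes which subgenomes to scan (default `"wheat"`).
#' @return data.frame: `chrom`, `start_mb`, `end_mb`, `kind`, `length_mb`.
#' @export
call_deletions <- function(segments, ref, min_length_mb = 5,
                           subgenomes = "wheat") {
  scan <- ref$chromosomes$name[ref$chromosomes$subgenome %in% subgenomes]
  out <- list()
  for (ch in intersect(unique(segments$chrom), scan)) {
    seg <- check_tiling(segments, ref, ch)
    len <- chrom_row(ref, ch)$length_mb
    present_mb <- sum(seg$length_mb[seg$state == "present"])
    if (present_mb <= len / 2) next
    if (any(arm_status(segments, ref, ch)$status == "absent")) next
    abs_seg <- seg[seg$state == "absent" & seg$length_mb >= min_length_mb, ,
                   drop = FALSE]
    if (nrow(abs_seg) == 0L) next
    abs_seg$kind <- ifelse(abs_seg$start_mb == 0 | abs_seg$end_mb == len,
                           "terminal", "interstitial")
    out[[ch]] <- abs_seg[, c("chrom", "start_mb", "end_mb", "kind",
                             "length_mb")]
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start_mb = numeric(),
                      end_mb = numeric(), kind = character(),
                      length_mb = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

present_runs <- function(segments, chrom) {
  seg <- segments[segments$chrom == chrom & segments$state == "present", ,
                  drop = FALSE]
  seg[order(seg$start_mb), c("start_mb", "end_mb")]
}

#' Infer a pericentric inversion from two complementary carrier lines
#'
#' Given the segment calls of the two lines that carry, respectively, the
#' short-arm and long-arm chromatin of the same donor chromosome, tests
#' whether their present sets interleave as `[0,p)+[q,r)` versus
#' `[p,q)+[r,L)` with the centromere inside `[p,r)`. That crossover is the
#' signature of a pericentric inversion that swapped two pericentromeric
#' blocks before the centric fission: each carrier holds one block from the
#' "wrong" side of the centromere. A clean single split point is a plain
#' centric fission and yields no call; more fragmented patterns yield a
#' diagnostic instead of a call.
#'
#' @param segments_s_carrier,segments_l_carrier `segment_calls` of the two
#'   lines (order does not matter; the roles are inferred from which line
#'   holds position 0).
#' @param ref hybrid reference.
#' @param chrom the donor chromosome to compare.
#' @param max_overlap_frac complementarity gate: reject when the carriers'
#'   present bins overlap by more than this fraction (default 0.05) or when
#'   their union leaves more than 5% of the chromosome uncovered.
#' @return an `inversion_call` list (`chrom`, `start_mb`, `end_mb`,
#'   `block_a`, `block_b`, `length_mb`, `spans_centromere`), or an
#'   `inversion_nocall` carrying a `diagnostic` message when no call is
#'   made.
#' @export
infer_pericentric_inversion <- function(segments_s_carrier,
                                        segments_l_carrier, ref, chrom,
                                        max_overlap_frac = 0.05) {
  row <- chrom_row(ref, chrom)
  len <- row$length_mb
  a <- present_runs(segments_s_carrier, chrom)
  b <- present_runs(segments_l_carrier, chrom)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("each carrier must have at least one present segment on ", chrom)
  }
  # complementarity gate on Mb totals
  overlap <- 0
  for (i in seq_len(nrow(a))) {
    overlap <- overlap + sum(pmax(0, pmin(a$end_mb[i], b$end_mb) -
                                     pmax(a$start_mb[i], b$start_mb)))
  }
  covered <- sum(a$end_mb - a$start_mb) + sum(b$end_mb - b$start_mb) - overlap
  if (overlap > max_overlap_frac * len) {
    stop(sprintf(
      "carriers are not complementary on %s: present sets overlap by %g Mb",
      chrom, overlap))
  }
  if (covered < 0.95 * len) {
    stop(sprintf(
      "carriers are not complementary on %s: union covers only %g of %d Mb",
      chrom, covered, len))
  }
  # identify which carrier holds the chromosome start
  if (a$start_mb[1] != 0 && b$start_mb[1] == 0) {
    tmp <- a; a <- b; b <- tmp
  }
  no_call <- function(msg) {
    structure(list(diagnostic = msg), class = "inversion_nocall")
  }
  if (nrow(a) == 1L && nrow(b) == 1L) {
    return(no_call("single boundary: clean centric fission, no inversion"))
  }
  if (nrow(a) != 2L || nrow(b) != 2L) {
    return(no_call(sprintf(
      "present runs too fragmented for inversion inference (%d and %d runs)",
      nrow(a), nrow(b))))
  }
  # expected crossover: a = [0,p)+[q,r), b = [p,q)+[r,len)
  p <- a$end_mb[1]; q <- a$start_mb[2]; r <- a$end_mb[2]
  pattern_ok <- a$start_mb[1] == 0 &&
    b$start_mb[1] == p && b$end_mb[1] == q &&
    b$start_mb[2] == r && b$end_mb[2] == len
  if (!pattern_ok) {
    return(no_call("present runs do not form the 2x2 crossover pattern"))
  }
  spans <- row$centromere_mb > p && row$centromere_mb < r
  if (!spans) {
    return(no_call("crossover interval does not span the centromere"))
  }
  structure(list(chrom = chrom, start_mb = p, end_mb = r,
                 block_a = c(p, q), block_b = c(q, r),
                 length_mb = r - p,
                 block_a_mb = q - p, block_b_mb = r - q,
                 spans_centromere = TRUE),
            class = "inversion_call")
}

#' Summarize introgressed chromatin on one chromosome
#'
#' @param segments `segment_calls` tiling the chromosome.
#' @param ref hybrid reference.
#' @param chrom chromosome name.
#' @return list: `chrom`, `total_present_mb`, `percent_of_chromosome`
#'   (rounded to integer), `segments` (the present segments).
#' @export
summarize_introgression <- function(segments, ref, chrom) {
  seg <- check_tiling(segments, ref, chrom)
  len <- chrom_row(ref, chrom)$length_mb
  pres <- seg[seg$state == "present", , drop = FALSE]
  total <- sum(pres$length_mb)
  list(chrom = chrom, total_present_mb = total,
       percent_of_chromosome = round(100 * total / len),
       segments = pres)
}

#' Carrier frequency among screened plants
#'
#' @param n_carriers number of carriers observed.
#' @param n_screened number of plants screened (> 0).
#' @return percentage, rounded to one decimal.
#' @export
carrier_frequency <- function(n_carriers, n_screened) {
  if (n_screened <= 0) stop("n_screened must be > 0")
  if (n_carriers < 0 || n_carriers > n_screened) {
    stop("n_carriers must lie in [0, n_screened]")
  }
  round(100 * n_carriers / n_screened, 1)
}
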