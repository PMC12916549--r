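# Karyotypes as per-bin copy-number functions over the hybrid reference,
# produced by applying typed structural events to the euploid background
# (wheat bins at copy number 2, barley bins at 0).
#
# A pericentric inversion does not change copy number on its own chromosome;
# what it changes is which physical blocks travel with each arm when a later
# centric fusion transfers an arm. The karyotype therefore tracks, per bin,
# a "traveling arm" label that inversions re-tag and arm replacements consume.

#' Construct a structural event
#'
#' @param kind one of `"arm_replacement"` (compensating centric fusion:
#'   a wheat arm is lost and the homoeologous barley arm takes its place),
#'   `"terminal_loss"`, `"interstitial_deletion"`, `"pericentric_inversion"`,
#'   `"whole_addition"`, `"whole_loss"`.
#' @param chrom chromosome the event acts on (for `arm_replacement`, the
#'   wheat chromosome).
#' @param start_mb,end_mb half-open interval in Mb, for deletion/loss and
#'   inversion kinds.
#' @param partner for `arm_replacement`: the barley chromosome (same
#'   homoeologous group) whose arm replaces the wheat arm.
#' @param arm for `arm_replacement`: `"S"` or `"L"`, the arm being swapped.
#' @param copy_number_change for `whole_addition`: copies added (1 or 2).
#' @return object of class `structural_event`.
#' @export
structural_event <- function(kind, chrom, start_mb = NA_real_, end_mb = NA_real_,
                             partner = NA_character_, arm = NA_character_,
                             copy_number_change = NA_integer_) {
  kinds <- c("arm_replacement", "terminal_loss", "interstitial_deletion",
             "pericentric_inversion", "whole_addition", "whole_loss")
  if (!kind %in% kinds) {
    stop("unknown event kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  if (kind == "arm_replacement") {
    if (is.na(partner) || !arm %in% c("S", "L")) {
      stop("arm_replacement needs a partner chromosome and arm 'S' or 'L'")
    }
  }
  if (kind %in% c("terminal_loss", "interstitial_deletion",
                  "pericentric_inversion")) {
    if (is.na(start_mb) || is.na(end_mb) || start_mb >= end_mb) {
      stop(kind, " needs start_mb < end_mb")
    }
  }
  structure(list(kind = kind, chrom = chrom, start_mb = start_mb,
                 end_mb = end_mb, partner = partner, arm = arm,
                 copy_number_change = copy_number_change),
            class = "structural_event")
}

check_interval <- function(ref, ev) {
  row <- chrom_row(ref, ev$chrom)
  if (ev$start_mb < 0 || ev$end_mb > row$length_mb) {
    stop(sprintf("%s interval [%g,%g) outside chromosome %s (length %d Mb)",
                 ev$kind, ev$start_mb, ev$end_mb, ev$chrom, row$length_mb))
  }
}

#' Apply structural events to build a karyotype
#'
#' Starts from the euploid wheat background (wheat bins at copy number 2,
#' barley bins at 0) and applies the events in order. Order matters only for
#' `pericentric_inversion` relative to an `arm_replacement` on the same
#' chromosome pair: an inversion listed first re-tags which blocks each arm
#' carries before the fusion transfers them (matching the biology, where the
#' inversion precedes the centric breakage-and-fusion).
#'
#' @param ref hybrid reference.
#' @param events list of `structural_event` objects (possibly empty).
#' @return object of class `karyotype`: the reference's bin table with an
#'   integer `copy_number` column and the (possibly inversion-permuted)
#'   `travel_arm` column; the reference is attached as an attribute.
#' @export
apply_events <- function(ref, events = list()) {
  if (inherits(events, "structural_event")) events <- list(events)
  bins <- ref$bins
  bins$copy_number <- ifelse(bins$subgenome == "wheat", 2L, 0L)
  bins$travel_arm <- bins$arm

  for (ev in events) {
    stopifnot(inherits(ev, "structural_event"))
    switch(ev$kind,
      pericentric_inversion = {
        check_interval(ref, ev)
        cen <- chrom_row(ref, ev$chrom)$centromere_mb
        if (ev$start_mb >= cen || ev$end_mb <= cen) {
          stop("pericentric_inversion interval [", ev$start_mb, ",",
               ev$end_mb, ") must span the centromere (", cen, " Mb) of ",
               ev$chrom)
        }
        sel <- bins$chrom == ev$chrom &
          bins$start_mb >= ev$start_mb & bins$end_mb <= ev$end_mb
        # material before the centromere now travels with the other arm
        bins$travel_arm[sel] <- ifelse(bins$end_mb[sel] <= cen, "L", "S")
      },
      arm_replacement = {
        wheat_row <- chrom_row(ref, ev$chrom)
        barley_row <- chrom_row(ref, ev$partner)
        if (wheat_row$subgenome != "wheat" || barley_row$subgenome != "barley") {
          stop("arm_replacement must name a wheat chromosome and a barley partner")
        }
        if (wheat_row$group != barley_row$group) {
          stop(sprintf(
            "arm_replacement across homoeologous groups (%s is group %d, %s is group %d)",
            ev$chrom, wheat_row$group, ev$partner, barley_row$group))
        }
        lost <- bins$chrom == ev$chrom & bins$travel_arm == ev$arm
        gained <- bins$chrom == ev$partner & bins$travel_arm == ev$arm
        bins$copy_number[lost] <- 0L
        bins$copy_number[gained] <- 2L
      },
      terminal_loss = {
        check_interval(ref, ev)
        len <- chrom_row(ref, ev$chrom)$length_mb
        if (ev$start_mb > 0 && ev$end_mb < len) {
          stop("terminal_loss interval must reach a chromosome end")
        }
        sel <- bins$chrom == ev$chrom &
          bins$start_mb >= ev$start_mb & bins$end_mb <= ev$end_mb
        bins$copy_number[sel] <- 0L
      },
      interstitial_deletion = {
        check_interval(ref, ev)
        sel <- bins$chrom == ev$chrom &
          bins$start_mb >= ev$start_mb & bins$end_mb <= ev$end_mb
        bins$copy_number[sel] <- 0L
      },
      whole_addition = {
        chrom_row(ref, ev$chrom)
        add <- if (is.na(ev$copy_number_change)) 2L else
          as.integer(ev$copy_number_change)
        sel <- bins$chrom == ev$chrom
        bins$copy_number[sel] <- pmin(bins$copy_number[sel] + add, 2L)
      },
      whole_loss = {
        chrom_row(ref, ev$chrom)
        bins$copy_number[bins$chrom == ev$chrom] <- 0L
      }
    )
  }
  structure(bins, class = c("karyotype", "data.frame"), reference = ref)
}

#' Packaged translocation-line scenarios
#'
#' Event lists reproducing the karyotypes of three wheat-barley centric
#' fusion lines on the default chromosome table:
#' \describe{
#'   \item{T6HS.6BL}{6BS lost, replaced by the 6HS-traveling barley chromatin;
#'     a 64-Mb pericentric inversion on 6H means the short-arm carrier holds
#'     blocks `[0,217)` and `[253,281)` Mb (245 Mb in total).}
#'   \item{T6BS.6HL}{the complementary line: 6BL lost, 6HL-traveling chromatin
#'     present as `[217,253)` and `[281,560)` Mb (315 Mb).}
#'   \item{T4BS.4HL}{4BL (last 356 Mb of 4B) lost, 4HL (last 335 Mb of 4H)
#'     gained, plus two collateral wheat deletions: interstitial 49 Mb on 2D
#'     (`[573,622)`) and terminal 127 Mb on 3B (`[724,851)`).}
#' }
#'
#' @param name scenario name; `NULL` lists all scenarios.
#' @return for a single name, a list with `events` (list of
#'   `structural_event`) and `specs` (the chromosome table the coordinates
#'   assume); with `name = NULL`, the named list of all scenarios.
#' @export
translocation_scenarios <- function(name = NULL) {
  specs <- wheat_barley_specs()
  inv_6h <- structural_event("pericentric_inversion", "6H",
                             start_mb = 217, end_mb = 281)
  all <- list(
    T6HS.6BL = list(
      events = list(inv_6h,
                    structural_event("arm_replacement", "6B",
                                     partner = "6H", arm = "S")),
      specs = specs),
    T6BS.6HL = list(
      events = list(inv_6h,
                    structural_event("arm_replacement", "6B",
                                     partner = "6H", arm = "L")),
      specs = specs),
    T4BS.4HL = list(
      events = list(structural_event("arm_replacement", "4B",
                                     partner = "4H", arm = "L"),
                    structural_event("interstitial_deletion", "2D",
                                     start_mb = 573, end_mb = 622),
                    structural_event("terminal_loss", "3B",
                                     start_mb = 724, end_mb = 851)),
      specs = specs)
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  all[[name]]
}

#' Build the karyotype of a packaged scenario
#'
#' @param name scenario name (see [translocation_scenarios()]).
#' @param bin_size_mb bin width in Mb.
#' @return `karyotype` over the scenario's reference.
#' @export
scenario_karyotype <- function(name, bin_size_mb = 1L) {
  sc <- translocation_scenarios(name)
  ref <- build_hybrid_reference(sc$specs[sc$specs$subgenome == "wheat", ],
                                sc$specs[sc$specs$subgenome == "barley", ],
                                bin_size_mb = bin_size_mb)
  apply_events(ref, sc$events)
}

#' Write the non-default copy-number intervals of a karyotype as BED
#'
#' Emits 0-based half-open bp intervals for every maximal run of bins whose
#' copy number differs from the euploid background (wheat 2, barley 0), with
#' the copy number in the score column. Useful as simulation truth.
#'
#' @param karyotype a `karyotype`.
#' @param path output path.
#' @export
write_truth_bed <- function(karyotype, path) {
  bins <- as.data.frame(karyotype)
  bg <- ifelse(bins$subgenome == "wheat", 2L, 0L)
  runs <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
    b <- bins[bins$chrom == ch, ]
    dev <- b$copy_number != ifelse(b$subgenome == "wheat", 2L, 0L)
    if (!any(dev)) return(NULL)
    r <- rle(paste0(dev, "_", b$copy_number))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- grepl("^TRUE", r$values)
    data.frame(chrom = ch,
               start_bp = b$start_mb[starts[keep]] * 1e6,
               end_bp = b$end_mb[ends[keep]] * 1e6,
               name = "cn",
               score = b$copy_number[starts[keep]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(runs)) runs <- data.frame()
  utils::write.table(runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a scenario event table
#'
#' Plain tab-delimited event files with columns `kind`, `chrom`, `start_mb`,
#' `end_mb`, `partner`, `arm`, `copy_number_change`; `.` marks an unused
#' field and `#` lines are comments.
#'
#' @param path file path.
#' @return `read_events`: list of `structural_event`.
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = ".")
  lapply(seq_len(nrow(tab)), function(i) {
    structural_event(
      kind = tab$kind[i], chrom = tab$chrom[i],
      start_mb = if ("start_mb" %in% names(tab)) tab$start_mb[i] else NA_real_,
      end_mb = if ("end_mb" %in% names(tab)) tab$end_mb[i] else NA_real_,
      partner = if ("partner" %in% names(tab)) tab$partner[i] else NA_character_,
      arm = if ("arm" %in% names(tab)) tab$arm[i] else NA_character_,
      copy_number_change = if ("copy_number_change" %in% names(tab))
        as.integer(tab$copy_number_change[i]) else NA_integer_)
  })
}

#' @rdname read_events
#' @param events list of `structural_event`.
#' @export
write_events <- function(events, path) {
  tab <- do.call(rbind, lapply(events, function(ev) {
    data.frame(kind = ev$kind, chrom = ev$chrom, start_mb = ev$start_mb,
               end_mb = ev$end_mb, partner = ev$partner, arm = ev$arm,
               copy_number_change = ev$copy_number_change,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
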