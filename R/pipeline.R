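# End-to-end orchestration: simulate (or load) -> count -> normalize ->
# segment -> call -> report. Pure plumbing over the module functions; every
# number in a report is recomputable by calling those functions directly.

#' Pipeline run configuration
#'
#' Exactly one input mode must be chosen: a packaged simulation scenario,
#' a placements file (BED-like or SAM text), or a precomputed bin-count
#' table.
#'
#' @param mode `"simulate"`, `"placements"` or `"counts"`.
#' @param scenario scenario name for simulate mode (see
#'   [translocation_scenarios()]).
#' @param placements_path,counts_path input paths for the other modes.
#' @param placements_format `"bed"` or `"sam"`.
#' @param reference a `hybrid_reference`, or path to a chromosome spec file;
#'   `NULL` uses the default wheat + barley table.
#' @param seed RNG seed (simulate mode).
#' @param depth_per_bin,mappability_dispersion,cross_map_to_barley,cross_map_to_wheat
#'   simulator settings, see [sim_params()].
#' @param tau_absent,tau_present,min_run segmentation settings.
#' @param min_deletion_mb smallest reportable deletion.
#' @param bin_size_mb bin width in Mb.
#' @param out_dir output directory (`NULL` for no files).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "placements", "counts"),
                       scenario = NULL, placements_path = NULL,
                       counts_path = NULL, placements_format = c("bed", "sam"),
                       reference = NULL, seed = 1L, depth_per_bin = 30,
                       mappability_dispersion = 0.005,
                       cross_map_to_barley = 0.011, cross_map_to_wheat = 0.004,
                       tau_absent = 0.15, tau_present = 0.4, min_run = 3L,
                       min_deletion_mb = 5, bin_size_mb = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  placements_format <- match.arg(placements_format)
  if (mode == "simulate" && is.null(scenario)) {
    stop("simulate mode needs a scenario name")
  }
  if (mode == "placements" && is.null(placements_path)) {
    stop("placements mode needs placements_path")
  }
  if (mode == "counts" && is.null(counts_path)) {
    stop("counts mode needs counts_path")
  }
  structure(list(
    mode = mode, scenario = scenario, placements_path = placements_path,
    counts_path = counts_path, placements_format = placements_format,
    reference = reference, seed = as.integer(seed),
    depth_per_bin = depth_per_bin,
    mappability_dispersion = mappability_dispersion,
    cross_map_to_barley = cross_map_to_barley,
    cross_map_to_wheat = cross_map_to_wheat,
    tau_absent = tau_absent, tau_present = tau_present,
    min_run = as.integer(min_run), min_deletion_mb = min_deletion_mb,
    bin_size_mb = as.integer(bin_size_mb), out_dir = out_dir
  ), class = "run_config")
}

resolve_reference <- function(config) {
  ref <- config$reference
  if (inherits(ref, "hybrid_reference")) return(ref)
  specs <- if (is.null(ref)) wheat_barley_specs() else
    read_chromosome_specs(ref)
  build_hybrid_reference(specs[specs$subgenome == "wheat", ],
                         specs[specs$subgenome == "barley", ],
                         bin_size_mb = config$bin_size_mb)
}

#' Run the full coverage-analysis pipeline
#'
#' Executes simulate/load -> count -> normalize -> segment -> call and
#' assembles an event report. With `out_dir` set, writes `bins.tsv`,
#' `segments.bed`, `segments.tsv` and `report.json` there.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return list of class `pipeline_result`: `reference`, `coverage`,
#'   `segments`, `report` (JSON-ready list).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  if (config$mode == "simulate") {
    say("simulating scenario ", config$scenario)
    kar <- scenario_karyotype(config$scenario, config$bin_size_mb)
    ref <- attr(kar, "reference")
    params <- sim_params(depth_per_bin = config$depth_per_bin,
                         mappability_dispersion = config$mappability_dispersion,
                         cross_map_to_barley = config$cross_map_to_barley,
                         cross_map_to_wheat = config$cross_map_to_wheat,
                         seed = config$seed)
    cov <- simulate_bin_counts(kar, params)
  } else {
    ref <- resolve_reference(config)
    if (config$mode == "placements") {
      say("counting placements from ", config$placements_path)
      placements <- if (config$placements_format == "sam") {
        read_placements_sam(config$placements_path)
      } else {
        read_placements_bed(config$placements_path)
      }
      cov <- count_reads(placements, ref)
    } else {
      say("loading counts from ", config$counts_path)
      cov <- read_bin_table(config$counts_path, ref)
    }
  }

  say("normalizing and segmenting")
  cov <- normalize_coverage(cov)
  segments <- segment_coverage(cov, tau_absent = config$tau_absent,
                               tau_present = config$tau_present,
                               min_run = config$min_run)

  say("calling events")
  statuses <- arm_status_table(segments, ref)
  fusions <- call_centric_fusions(statuses)
  deletions <- call_deletions(segments, ref,
                              min_length_mb = config$min_deletion_mb)
  barley_chroms <- ref$chromosomes$name[ref$chromosomes$subgenome == "barley"]
  summaries <- lapply(barley_chroms, function(ch) {
    s <- summarize_introgression(segments, ref, ch)
    if (s$total_present_mb == 0) return(NULL)
    list(chrom = s$chrom, total_present_mb = s$total_present_mb,
         percent_of_chromosome = s$percent_of_chromosome)
  })
  summaries <- Filter(Negate(is.null), summaries)

  report <- list(
    schema = 1L,
    translocations = fusions$translocations,
    whole_losses = fusions$whole_losses,
    deletions = deletions,
    introgression_summaries = summaries,
    parameters = list(
      tau_absent = config$tau_absent, tau_present = config$tau_present,
      min_run = config$min_run, min_deletion_mb = config$min_deletion_mb,
      bin_size_mb = config$bin_size_mb,
      norm_constant = attr(cov, "norm_constant")
    ),
    provenance = list(
      mode = config$mode,
      scenario = config$scenario,
      input = config$placements_path %||% config$counts_path,
      seed = if (config$mode == "simulate") config$seed else NULL
    )
  )

  result <- structure(list(reference = ref, coverage = cov,
                           segments = segments, report = report),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bin_table(cov, file.path(config$out_dir, "bins.tsv"))
    write_segments_bed(segments, file.path(config$out_dir, "segments.bed"))
    write_segments_tsv(segments, file.path(config$out_dir, "segments.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two complementary carrier lines on one chromosome
#'
#' Runs the pericentric-inversion inference on the segment calls of two
#' pipeline runs and tabulates their present/absent states side by side.
#'
#' @param result_a,result_b `pipeline_result` objects computed on the same
#'   reference.
#' @param chrom donor chromosome to compare.
#' @return list: `inversion` (an `inversion_call` or `NULL`), `diagnostic`
#'   (message when no call), `table` (per-segment side-by-side comparison).
#' @export
compare_lines <- function(result_a, result_b, chrom) {
  ref_a <- result_a$reference
  ref_b <- result_b$reference
  if (!identical(ref_a$chromosomes, ref_b$chromosomes) ||
      ref_a$bin_size_mb != ref_b$bin_size_mb) {
    stop("the two runs were not computed on the same reference")
  }
  inv <- infer_pericentric_inversion(result_a$segments, result_b$segments,
                                     ref_a, chrom)
  diagnostic <- NULL
  if (inherits(inv, "inversion_nocall")) {
    diagnostic <- inv$diagnostic
    inv <- NULL
  }
  seg_a <- result_a$segments[result_a$segments$chrom == chrom, ]
  seg_b <- result_b$segments[result_b$segments$chrom == chrom, ]
  bounds <- sort(unique(c(seg_a$start_mb, seg_a$end_mb,
                          seg_b$start_mb, seg_b$end_mb)))
  state_at <- function(seg, pos) {
    seg$state[seg$start_mb <= pos & seg$end_mb > pos][1]
  }
  mids <- utils::head(bounds, -1)
  tab <- data.frame(
    start_mb = mids, end_mb = bounds[-1],
    state_a = vapply(mids, function(p) state_at(seg_a, p), character(1)),
    state_b = vapply(mids, function(p) state_at(seg_b, p), character(1)),
    stringsAsFactors = FALSE
  )
  list(inversion = inv, diagnostic = diagnostic, table = tab)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  tr <- x$report$translocations
  cat("  translocations:",
      if (nrow(tr)) paste(tr$name, collapse = ", ") else "none", "\n")
  cat("  deletions:", nrow(x$report$deletions), "\n")
  for (s in x$report$introgression_summaries) {
    cat(sprintf("  introgression %s: %g Mb (%d%% of chromosome)\n",
                s$chrom, s$total_present_mb, s$percent_of_chromosome))
  }
  invisible(x)
}
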