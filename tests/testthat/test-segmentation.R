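test_that("two-threshold classification separates present and absent bins", {
  cov <- profile_coverage(c(1.0, 0.01))
  expect_equal(classify_bins(cov), c("present", "absent"))

  all0 <- profile_coverage(c(0, 0, 0))
  expect_equal(classify_bins(all0), rep("absent", 3))

  expect_error(classify_bins(cov, tau_absent = 0.5, tau_present = 0.4),
               "thresholds")
})

test_that("intermediate bins resolve to the nearer flank, ties by value", {
  # middle bin 0.3 sits between the thresholds; flanks are 1 bin away on
  # each side, so the closer-mean rule decides: 0.3 is nearer 0.01 than 1.0
  cov <- profile_coverage(c(1.0, 0.3, 0.01))
  expect_equal(classify_bins(cov), c("present", "absent", "absent"))
  # with an intermediate value close to the present flank's mean it goes
  # present on a tie
  cov2 <- profile_coverage(c(0.45, 0.39, 0.01))
  expect_equal(classify_bins(cov2), c("present", "present", "absent"))
  # off-centre intermediate bins take the nearer flank regardless of value
  cov3 <- profile_coverage(c(1.0, 0.39, 0.39, 0.39, 0.39, 0.01))
  expect_equal(classify_bins(cov3),
               c("present", "present", "present", "absent", "absent",
                 "absent"))
  # an intermediate run touching the chromosome end takes its single flank
  cov4 <- profile_coverage(c(0.3, 0.3, 1.0))
  expect_equal(classify_bins(cov4), rep("present", 3))
})

test_that("smoothing absorbs short runs and reaches a fixpoint", {
  expect_equal(
    smooth_states(c("present", "present", "absent", "present", "present"),
                  min_run = 3L),
    rep("present", 5))
  # a run exactly min_run long survives
  unchanged <- c("present", "absent", "absent", "absent", "present")
  expect_equal(smooth_states(unchanged, min_run = 3L), unchanged)
  # runs at chromosome ends are never flipped
  edge <- c("absent", "present", "present", "present", "present")
  expect_equal(smooth_states(edge, min_run = 3L), edge)
  expect_error(smooth_states(edge, min_run = 0L), "min_run")
})

test_that("smoothing is idempotent on random state vectors", {
  set.seed(123)
  for (i in 1:20) {
    s <- sample(c("present", "absent"), 50, replace = TRUE)
    once <- smooth_states(s, min_run = 3L)
    expect_equal(smooth_states(once, min_run = 3L), once)
    # fixpoint property: no interior run shorter than min_run is left with
    # equal-state flanks (with two states, flanks of any interior run are
    # always equal, so every interior run must reach min_run)
    r <- rle(once)
    if (length(r$lengths) > 2) {
      expect_true(all(r$lengths[2:(length(r$lengths) - 1L)] >= 3L))
    }
  }
})

test_that("noiseless profiles segment into the published blocks", {
  # 6H of the short-arm carrier: 217 present / 36 absent / 28 present /
  # 279 absent
  vals <- rep(c(1.0, 0.01, 1.0, 0.01), c(217, 36, 28, 279))
  cov <- profile_coverage(vals, centromere_mb = 253L, name = "6H",
                          subgenome = "barley")
  seg <- segment_chromosome(cov, "6H")
  expect_equal(seg$length_mb, c(217, 36, 28, 279))
  expect_equal(seg$state, c("present", "absent", "present", "absent"))

  # uniform coverage gives a single present segment
  uni <- profile_coverage(rep(1, 40))
  segu <- segment_chromosome(uni, "1W")
  expect_equal(nrow(segu), 1L)
  expect_equal(segu$state, "present")
  expect_equal(segu$length_mb, 40)

  # 4B of the group-4 fusion line: present then a 356-Mb terminal absence
  v4b <- rep(c(1.0, 0.01), c(317, 356))
  cov4b <- profile_coverage(v4b, centromere_mb = 317L, name = "4B")
  seg4b <- segment_chromosome(cov4b, "4B")
  expect_equal(seg4b$state, c("present", "absent"))
  expect_equal(seg4b$length_mb, c(317, 356))
  expect_equal(seg4b$end_mb[2], 673)
})

test_that("segments tile each chromosome and alternate states", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:80, 1)
    vals <- ifelse(runif(n) < 0.5, rpois(n, 30) / 30, rpois(n, 0.3) / 30)
    cov <- profile_coverage(vals)
    seg <- segment_chromosome(cov, "1W")
    expect_equal(seg$start_mb[1], 0)
    expect_equal(seg$end_mb[nrow(seg)], n)
    if (nrow(seg) > 1) {
      expect_equal(seg$start_mb[-1], seg$end_mb[-nrow(seg)])
      expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
    }
    expect_equal(sum(seg$length_mb), n)
  }
})

test_that("segmentation is idempotent on its own piecewise profile", {
  vals <- rep(c(1.0, 0.01, 1.0), c(10, 6, 14))
  seg <- segment_chromosome(profile_coverage(vals), "1W")
  rebuilt <- rep(ifelse(seg$state == "present", 1.0, 0.01), seg$length_mb)
  seg2 <- segment_chromosome(profile_coverage(rebuilt), "1W")
  expect_equal(seg2$start_mb, seg$start_mb)
  expect_equal(seg2$end_mb, seg$end_mb)
  expect_equal(seg2$state, seg$state)
})

test_that("merging matches a brute-force run scan on small chromosomes", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    vals <- sample(c(1.0, 0.01), n, replace = TRUE)
    cov <- profile_coverage(vals)
    seg <- segment_chromosome(cov, "1W", min_run = 1L)  # no smoothing
    # oracle: enumerate maximal equal-state runs directly
    states <- ifelse(vals >= 0.4, "present", "absent")
    breaks <- c(0, which(states[-1] != states[-n]), n)
    expect_equal(seg$start_mb, breaks[-length(breaks)])
    expect_equal(seg$end_mb, breaks[-1])
    expect_equal(seg$state, states[breaks[-length(breaks)] + 1])
  }
})

test_that("segment labels use the 1-based inclusive convention", {
  seg <- data.frame(start_mb = c(217, 0, 281), end_mb = c(253, 217, 560))
  expect_equal(segment_label(seg),
               c("218-253 Mb", "1-217 Mb", "282-560 Mb"))
})

test_that("true block boundaries are recovered across seeds", {
  # simulated short-arm carrier at default depth and noise: every 6H
  # boundary within +/- 1 bin in at least 95% of cases over 20 seeds
  kar <- scenario_karyotype("T6HS.6BL")
  truth <- c(217, 253, 281)
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    cov <- normalize_coverage(simulate_bin_counts(
      kar, sim_params(depth_per_bin = 30, seed = seed)))
    seg <- segment_chromosome(cov, "6H")
    found <- setdiff(unique(c(seg$start_mb, seg$end_mb)), c(0, 560))
    for (b in truth) {
      total <- total + 1L
      if (any(abs(found - b) <= 1)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("segment calls round-trip through BED and TSV writers", {
  vals <- rep(c(1.0, 0.01), c(12, 8))
  seg <- segment_chromosome(profile_coverage(vals), "1W")
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_segments_bed(seg, bed)
  write_segments_tsv(seg, tsv)
  bed_tab <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed_tab$V2, c(0, 12e6))
  expect_equal(bed_tab$V3, c(12e6, 20e6))
  back <- read_segments_tsv(tsv, attr(seg, "reference"))
  expect_equal(back$start_mb, seg$start_mb)
  expect_equal(back$state, seg$state)
})
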