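# noiseless segment calls straight from a karyotype, via the helper profile
scenario_segments <- function(name) {
  kar <- scenario_karyotype(name)
  segment_coverage(karyotype_profile(kar))
}

test_that("arm status reflects per-arm present fractions", {
  ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
                                wheat_barley_specs("barley"))
  seg <- scenario_segments("T6HS.6BL")

  st6b <- arm_status(seg, ref, "6B")
  expect_equal(st6b$status, c("absent", "present"))
  expect_equal(st6b$fraction_present, c(0, 1))

  # fully present chromosome: both arms present
  st2a <- arm_status(seg, ref, "2A")
  expect_equal(st2a$status, c("present", "present"))

  # the short-arm carrier's 6H: 217 of the 253-Mb short arm -> partial
  st6h <- arm_status(seg, ref, "6H")
  expect_equal(st6h$fraction_present[st6h$arm == "S"], 217 / 253)
  expect_equal(st6h$status[st6h$arm == "S"], "partial")
  expect_equal(st6h$status[st6h$arm == "L"], "absent")

  # non-tiling input is rejected
  broken <- seg[!(seg$chrom == "6B" & seg$start_mb == 0), ]
  expect_error(arm_status(broken, ref, "6B"), "tile")
})

test_that("compensating fusions are named with the short arm first", {
  ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
                                wheat_barley_specs("barley"))
  for (case in list(
    list(scen = "T6HS.6BL", name = "T6HS.6BL", wheat = "6BL", barley = "6HS"),
    list(scen = "T6BS.6HL", name = "T6BS.6HL", wheat = "6BS", barley = "6HL"),
    list(scen = "T4BS.4HL", name = "T4BS.4HL", wheat = "4BS", barley = "4HL"))) {
    calls <- call_centric_fusions(
      arm_status_table(scenario_segments(case$scen), ref))
    expect_equal(nrow(calls$translocations), 1L)
    expect_equal(calls$translocations$name, case$name)
    expect_equal(calls$translocations$wheat_arm, case$wheat)
    expect_equal(calls$translocations$barley_arm, case$barley)
  }

  # euploid line: no calls
  eu <- segment_coverage(karyotype_profile(apply_events(ref, list())))
  expect_equal(nrow(call_centric_fusions(arm_status_table(eu, ref))$translocations),
               0L)

  # both wheat arms absent is a whole-chromosome loss, not a fusion
  lost <- apply_events(ref, structural_event("whole_loss", "6B"))
  res <- call_centric_fusions(
    arm_status_table(segment_coverage(karyotype_profile(lost)), ref))
  expect_equal(res$whole_losses, "6B")
  expect_equal(nrow(res$translocations), 0L)
})

test_that("fusion names round-trip through the parser", {
  for (nm in c("T6HS.6BL", "T6BS.6HL", "T4BS.4HL", "T1AS.1HL")) {
    parts <- parse_fusion_name(nm)
    rebuilt <- paste0("T", parts$arm1, ".", parts$arm2)
    expect_equal(rebuilt, nm)
  }
  expect_error(parse_fusion_name("6BS.6HL"), "malformed")
})

test_that("deletions are typed interstitial or terminal and arm losses skipped", {
  ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
                                wheat_barley_specs("barley"))
  seg <- scenario_segments("T4BS.4HL")
  dels <- call_deletions(seg, ref)
  expect_equal(nrow(dels), 2L)
  d2 <- dels[dels$chrom == "2D", ]
  expect_equal(d2$kind, "interstitial")
  expect_equal(d2$length_mb, 49)
  expect_equal(c(d2$start_mb, d2$end_mb), c(573, 622))
  d3 <- dels[dels$chrom == "3B", ]
  expect_equal(d3$kind, "terminal")
  expect_equal(d3$length_mb, 127)
  # the lost 4BL arm and the absent 4HS region are fusion geometry, not
  # deletions
  expect_false(any(dels$chrom %in% c("4B", "4H")))

  # donor-chromosome absences delimit the introgression, they are not
  # background deletions: the long-arm carrier's 6H has a 217-Mb and a
  # 28-Mb absent stretch yet majority-present bins
  seg_l <- scenario_segments("T6BS.6HL")
  expect_equal(nrow(call_deletions(seg_l, ref)), 0L)
  expect_equal(nrow(call_deletions(seg_l, ref,
                                   subgenomes = c("wheat", "barley"))), 2L)

  eu <- segment_coverage(karyotype_profile(apply_events(ref, list())))
  expect_equal(nrow(call_deletions(eu, ref)), 0L)

  # short absences below the reporting floor are ignored
  small <- apply_events(ref, structural_event("interstitial_deletion", "1A",
                                              start_mb = 100, end_mb = 104))
  seg_small <- segment_coverage(karyotype_profile(small))
  expect_equal(nrow(call_deletions(seg_small, ref)), 0L)
  expect_equal(nrow(call_deletions(seg_small, ref, min_length_mb = 3)), 1L)
})

test_that("the complementary-carrier crossover yields an inversion call", {
  ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
                                wheat_barley_specs("barley"))
  seg_s <- scenario_segments("T6HS.6BL")
  seg_l <- scenario_segments("T6BS.6HL")
  inv <- infer_pericentric_inversion(seg_s, seg_l, ref, "6H")
  expect_s3_class(inv, "inversion_call")
  expect_equal(c(inv$start_mb, inv$end_mb), c(217, 281))
  expect_equal(inv$length_mb, 64)
  expect_equal(inv$block_a_mb, 36)
  expect_equal(inv$block_b_mb, 28)
  expect_true(inv$spans_centromere)

  # symmetric in the argument order
  inv2 <- infer_pericentric_inversion(seg_l, seg_s, ref, "6H")
  expect_equal(inv2$start_mb, inv$start_mb)
  expect_equal(inv2$end_mb, inv$end_mb)

  # clean fission on 6B: single boundary, no call
  no <- infer_pericentric_inversion(seg_s, seg_l, ref, "6B")
  expect_s3_class(no, "inversion_nocall")
  expect_match(no$diagnostic, "fission")

  # non-complementary inputs are rejected
  expect_error(infer_pericentric_inversion(seg_s, seg_s, ref, "6H"),
               "not complementary")
})

test_that("the inversion rule applies on a toy chromosome", {
  ref <- build_hybrid_reference(
    toy_specs("1W", "wheat", 10L, 5L),
    toy_specs("1Hb", "barley", 10L, 5L))
  inv_ev <- structural_event("pericentric_inversion", "1Hb",
                             start_mb = 3, end_mb = 7)
  # blocks of 2 bins: segment without smoothing so they survive
  seg_s <- segment_coverage(karyotype_profile(apply_events(ref, list(
    inv_ev,
    structural_event("arm_replacement", "1W", partner = "1Hb", arm = "S")))),
    min_run = 1L)
  seg_l <- segment_coverage(karyotype_profile(apply_events(ref, list(
    inv_ev,
    structural_event("arm_replacement", "1W", partner = "1Hb", arm = "L")))),
    min_run = 1L)
  inv <- infer_pericentric_inversion(seg_s, seg_l, ref, "1Hb")
  expect_equal(c(inv$start_mb, inv$end_mb), c(3, 7))
  expect_equal(inv$block_a, c(3, 5))
  expect_equal(inv$block_b, c(5, 7))
})

test_that("introgression summaries total present chromatin and conserve length", {
  ref <- build_hybrid_reference(wheat_barley_specs("wheat"),
                                wheat_barley_specs("barley"))
  s <- summarize_introgression(scenario_segments("T6HS.6BL"), ref, "6H")
  expect_equal(s$total_present_mb, 245)
  expect_equal(s$percent_of_chromosome, 44)

  l <- summarize_introgression(scenario_segments("T6BS.6HL"), ref, "6H")
  expect_equal(l$total_present_mb, 315)
  expect_equal(l$percent_of_chromosome, 56)

  # empty present set
  eu <- segment_coverage(karyotype_profile(apply_events(ref, list())))
  e <- summarize_introgression(eu, ref, "6H")
  expect_equal(e$total_present_mb, 0)
  expect_equal(e$percent_of_chromosome, 0)

  # conservation: present + absent = chromosome length, on every chromosome
  seg <- scenario_segments("T4BS.4HL")
  for (ch in unique(seg$chrom)) {
    tot <- sum(seg$length_mb[seg$chrom == ch])
    expect_equal(tot, ref$chromosomes$length_mb[
      ref$chromosomes$name == ch])
  }
})

test_that("carrier frequencies follow the screened proportions", {
  expect_equal(carrier_frequency(3, 40), 7.5)
  expect_equal(carrier_frequency(6, 50), 12.0)
  expect_equal(carrier_frequency(0, 10), 0.0)
  expect_error(carrier_frequency(1, 0), "n_screened")
  expect_error(carrier_frequency(5, 3), "n_carriers")
})
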