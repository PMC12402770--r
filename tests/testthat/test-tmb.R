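test_that("MNVs decompose positionally and redundant calls deduplicate", {
  mnv <- make_variant(pos = 100L, ref = "CG", alt = "AT")
  out <- prepare_snv_input(mnv)
  expect_equal(out$pos, c(100L, 101L))
  expect_equal(out$ref, c("C", "G"))
  expect_equal(out$alt, c("A", "T"))
  # a matching base inside the MNV is not a variant
  part <- prepare_snv_input(make_variant(pos = 200L, ref = "CAG", alt = "AAT"))
  expect_equal(part$pos, c(200L, 202L))
  # decomposed SNV identical to an existing SNV collapses to one record
  dup <- dplyr::bind_rows(mnv, make_variant(pos = 100L, ref = "C", alt = "A"))
  expect_equal(nrow(prepare_snv_input(dup)), 2)
  snv_only <- make_variant()
  expect_equal(nrow(prepare_snv_input(snv_only)), 1)
})

test_that("TMB arithmetic: numerator classes, denominators, scale", {
  surveyed <- genome_intervals("chr1", 0, 5e6)
  maf <- purrr::map_dfr(1:10, function(i) make_variant(pos = i * 1000L))
  out <- calculate_tmb(maf, surveyed, strategy = "WGS")
  expect_equal(out$tmb_all, 2.0)
  expect_equal(out$n_all, 10L)
  expect_equal(out$denom_all_bp, 5e6)

  silent <- dplyr::bind_rows(maf,
    make_variant(pos = 999000L, variant_classification = "Silent"))
  expect_equal(calculate_tmb(silent, surveyed, strategy = "WGS")$n_all, 10L)

  empty <- calculate_tmb(maf[0, ], surveyed, strategy = "WGS",
                         samples = "BS_1")
  expect_equal(empty$tmb_all, 0)
})

test_that("coding TMB restricts numerator and denominator to CDS intersection", {
  surveyed <- genome_intervals("chr1", 0, 2e6)
  cds <- genome_intervals("chr1", 0, 1e6)
  maf <- dplyr::bind_rows(
    make_variant(pos = 100L), make_variant(pos = 200L),
    make_variant(pos = 1500000L))   # outside CDS
  out <- calculate_tmb(maf, surveyed, cds, "WGS")
  expect_equal(out$n_coding, 2L)
  expect_equal(out$denom_coding_bp, 1e6)
  expect_equal(out$tmb_coding, 2.0)
  expect_true(out$n_coding <= out$n_all)
  disjoint <- genome_intervals("chr2", 0, 1000)
  expect_error(calculate_tmb(maf, surveyed, disjoint, "WGS"), "zero-length")
})

test_that("WGS denominator is the intersection of all surveyed sets", {
  surveyed <- list(genome_intervals("chr1", 0, 1000),
                   genome_intervals("chr1", 200, 1500),
                   genome_intervals("chr1", 0, 900))
  out <- calculate_tmb(make_variant(pos = 500L), surveyed, strategy = "WGS")
  expect_equal(out$denom_all_bp, 700)  # [200, 900)
})

test_that("the alternate consequence-class list is selectable", {
  cfg <- rule_config()
  expect_length(select_nonsyn_filter("default", cfg), 9)
  expect_true("Splice_Region" %in% select_nonsyn_filter("focr", cfg))
  expect_error(select_nonsyn_filter("bogus", cfg))
})

test_that("TMB is linear in the scale factor", {
  surveyed <- genome_intervals("chr1", 0, 1e6)
  maf <- purrr::map_dfr(1:7, function(i) make_variant(pos = i * 100L))
  t1 <- calculate_tmb(maf, surveyed, strategy = "WGS")
  t2 <- calculate_tmb(maf, surveyed, strategy = "WGS",
                      cfg = rule_config(tmb_scale = 2e6))
  expect_equal(t2$tmb_all, 2 * t1$tmb_all)
})

test_that("planted coding mutations give exactly m/L x 1e6 in the noiseless cohort", {
  co <- generate_cohort(cohort_spec(n_participants = 4, seed = 7,
                                    caller_agreement = 1, hotspot_fraction = 0))
  cons <- consensus_snv(co$maf_by_caller)
  tmb <- calculate_tmb(cons, co$genome$surveyed, co$genome$cds, "WGS")
  joined <- dplyr::left_join(tmb, co$manifest$tmb, by = "sample_id")
  expect_equal(joined$tmb_coding, joined$expected_tmb_coding)
  expect_equal(joined$tmb_all, joined$expected_tmb_all)
  expect_equal(joined$denom_coding_bp, rep(co$genome$cds_length_bp, 4))
})
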