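test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- generate_cohort(cohort_spec(n_participants = 5, seed = 4))
  b <- generate_cohort(cohort_spec(n_participants = 5, seed = 4))
  expect_identical(a$maf_by_caller, b$maf_by_caller)
  expect_identical(a$seg_by_caller, b$seg_by_caller)
  expect_identical(a$manifest, b$manifest)
  c2 <- generate_cohort(cohort_spec(n_participants = 5, seed = 5))
  expect_false(identical(a$maf_by_caller, c2$maf_by_caller))
})

test_that("generation does not disturb the caller's RNG stream", {
  withr::with_seed(1, {
    invisible(generate_cohort(cohort_spec(n_participants = 2, seed = 99)))
    x <- runif(1)
  })
  withr::with_seed(1, y <- runif(1))
  expect_identical(x, y)
})

test_that("noiseless cohorts place every planted variant in every caller", {
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 2,
                                    caller_agreement = 1))
  counts <- vapply(co$maf_by_caller, nrow, integer(1))
  expect_true(all(counts == counts[1]))
  cons <- consensus_snv(co$maf_by_caller)
  expect_equal(nrow(cons), nrow(co$manifest$expected_consensus))
})

test_that("the manifest consensus is reproduced by the pipeline under noise", {
  co <- generate_cohort(cohort_spec(n_participants = 6, seed = 8,
                                    caller_agreement = 0.7))
  cons <- consensus_snv(co$maf_by_caller)
  got <- sort(paste(cons$sample_id, cons$chrom, cons$pos, cons$ref, cons$alt))
  want <- with(co$manifest$expected_consensus,
               sort(paste(sample_id, chrom, pos, ref, alt)))
  expect_identical(got, want)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(histology_mix = c(MB = 0.5, HGG = 0.2)), "sum to 1")
  expect_error(cohort_spec(caller_agreement = 1.5), "0, 1")
})

test_that("cohort files round-trip through the standard formats", {
  co <- generate_cohort(cohort_spec(n_participants = 2, seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  maf <- read_maf(file.path(dir, "strelka2.maf"))
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "t_depth",
            "t_alt_count", "n_depth", "hotspot", "variant_classification")
  expect_equal(as.data.frame(maf[cols]),
               as.data.frame(co$maf_by_caller$strelka2[cols]))
  seg <- read_seg(file.path(dir, "controlfreec.seg"))
  expect_equal(as.data.frame(seg), as.data.frame(co$seg_by_caller$controlfreec))
  expect_equal(interval_length(read_bed(file.path(dir, "cds.bed"))),
               co$genome$cds_length_bp)
})

test_that("the printed-table fixture is constant with the published marginals", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 150)
  expect_identical(fx, table1_fixture())
  counts <- dplyr::count(fx, methylation_subclass, rna_group)
  expect_equal(counts$n[counts$methylation_subclass == "MB_G34_VII"], 30)
  expect_equal(counts$n[counts$methylation_subclass == "MB_WNT"], 18)
  expect_equal(sum(counts$n[counts$rna_group == "SHH"]), 24)
})

test_that("the toy genome honours its stated arithmetic", {
  g <- toy_genome()
  expect_equal(interval_length(g$cds), g$cds_length_bp)
  expect_equal(interval_length(Reduce(interval_intersect, g$surveyed)),
               g$surveyed_intersection_bp)
  # every coding interval lies inside every caller's surveyed region
  for (sv in g$surveyed) {
    expect_equal(interval_length(interval_intersect(g$cds, sv)),
                 g$cds_length_bp)
  }
})
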