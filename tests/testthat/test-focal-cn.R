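gene_one <- tibble::tibble(gene = "GENE1", chrom = "chr1",
                           start = 1000L, end = 1999L)

mk_region <- function(start, end, direction = "gain", cn = 4L,
                      sample_id = "BS_1") {
  tibble::tibble(sample_id = sample_id, chrom = "chr1", start = start,
                 end = end, direction = direction,
                 supporting_callers = "cnvkit,controlfreec", copy_number = cn,
                 status = cn_status(cn))
}

test_that("non-neutral calls outrank neutral regardless of overlap size", {
  regions <- dplyr::bind_rows(
    mk_region(1000L, 1599L, cn = 2L),               # neutral, 60% of gene
    mk_region(1600L, 1999L, direction = "loss", cn = 1L))  # loss, 40%
  out <- assign_gene_status(regions, gene_one)
  expect_equal(out$status, "loss")
})

test_that("amplification and deep deletion beat gain and loss on overlap ties", {
  regions <- dplyr::bind_rows(
    mk_region(1000L, 1499L, cn = 3L),   # gain, 50%
    mk_region(1500L, 1999L, cn = 6L))   # amplification, 50%
  expect_equal(assign_gene_status(regions, gene_one)$status, "amplification")
  del <- dplyr::bind_rows(
    mk_region(1000L, 1499L, direction = "loss", cn = 1L),
    mk_region(1500L, 1999L, direction = "loss", cn = 0L))
  expect_equal(assign_gene_status(del, gene_one)$status, "deep_deletion")
})

test_that("genes without overlapping regions are neutral", {
  out <- assign_gene_status(mk_region(900000L, 950000L), gene_one)
  expect_equal(out$status, "neutral")
  expect_equal(out$overlap_fraction, 0)
})

test_that("resolution yields exactly one row per gene and sample under conflicts", {
  withr::with_seed(13, {
    genes <- tibble::tibble(gene = paste0("G", 1:10), chrom = "chr1",
                            start = seq(1000L, 91000L, 10000L),
                            end = seq(6000L, 96000L, 10000L))
    regions <- purrr::map_dfr(1:30, function(i) {
      s <- sample(seq(1L, 90000L, 500L), 1)
      mk_region(s, s + sample(3000:20000, 1),
                direction = sample(c("gain", "loss"), 1),
                cn = sample(c(0L, 1L, 2L, 4L, 6L), 1),
                sample_id = sample(c("BS_1", "BS_2"), 1))
    })
    out <- assign_gene_status(regions, genes, samples = c("BS_1", "BS_2"))
    expect_equal(anyDuplicated(paste(out$gene, out$sample_id)), 0)
    expect_equal(nrow(out), 20)
    # order invariance
    out2 <- assign_gene_status(regions[sample.int(nrow(regions)), ], genes,
                               samples = c("BS_1", "BS_2"))
    expect_identical(out, out2)
  })
})

test_that("fully contained genes take the status of a single covering segment", {
  genes <- tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                          start = c(2000L, 5000L), end = c(2999L, 5999L))
  out <- assign_gene_status(mk_region(1000L, 8000L, cn = 6L), genes)
  expect_true(all(out$status == "amplification"))
  expect_true(all(out$overlap_fraction == 1))
})

test_that("arm status reflects covered fraction against a per-base oracle", {
  arms <- tibble::tibble(arm = "17p", chrom = "chr1", start = 1L, end = 100000L)
  loss60 <- mk_region(1L, 60000L, direction = "loss", cn = 1L)
  out <- arm_status(loss60, arms)
  expect_equal(out$status, "loss")
  expect_equal(out$covered_fraction,
               brute_interval_length(
                 tibble::tibble(chrom = "chr1", start = 0L, end = 60000L)) / 1e5)
  expect_equal(arm_status(mk_region(1L, 10000L, direction = "loss"), arms)$status,
               "neutral")
  empty <- arm_status(mk_region(1L, 10L)[0, ], arms, samples = "BS_1")
  expect_equal(empty$status, "neutral")
})
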