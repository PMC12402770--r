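test_that("noisy caller files are dropped wholesale at the segment-count cutoff", {
  mk <- function(n, caller) {
    dplyr::mutate(
      purrr::map_dfr(seq_len(n), function(i) {
        make_segment(start = i * 10L, end = i * 10L + 5L)
      }), caller = caller)
  }
  over <- mk(2501, "controlfreec")
  at <- mk(2500, "cnvkit")
  expect_equal(nrow(denoise_caller_set(over)), 0)
  expect_equal(nrow(denoise_caller_set(at)), 2500)
  expect_equal(nrow(denoise_caller_set(at[0, ])), 0)
  # only the offending (sample, caller) pair is removed from a pooled table
  both <- dplyr::bind_rows(over, at)
  kept <- denoise_caller_set(both)
  expect_equal(unique(kept$caller), "cnvkit")
})

test_that("reciprocal overlap fractions match per-base counting", {
  a <- list(chrom = "chr1", start = 1001, end = 2000)
  b <- list(chrom = "chr1", start = 1501, end = 2500)
  expect_equal(unname(reciprocal_overlap(a, b)), c(0.5, 0.5))
  expect_equal(unname(reciprocal_overlap(a, a)), c(1, 1))
  expect_equal(unname(reciprocal_overlap(a, list(chrom = "chr1", start = 5000,
                                                 end = 6000))), c(0, 0))
  expect_error(reciprocal_overlap(a, list(chrom = "chr2", start = 1, end = 10)),
               "different chromosomes")
})

test_that("pairwise consensus emits intersected spans and containment spans", {
  by_caller <- list(
    controlfreec = make_segment(start = 1001L, end = 2000L),
    cnvkit = make_segment(start = 1501L, end = 2500L))
  out <- consensus_regions(by_caller)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1501L, 2000L))
  expect_equal(out$supporting_callers, "cnvkit,controlfreec")

  contained <- list(
    controlfreec = make_segment(start = 1001L, end = 1200L),
    cnvkit = make_segment(start = 1L, end = 10000L))
  out2 <- consensus_regions(contained)
  # the small segment's own span is emitted (coverage 1.0 >= 0.9)
  expect_true(any(out2$start == 1001 & out2$end == 1200))

  opposed <- list(
    controlfreec = make_segment(start = 1001L, end = 2000L, status = "gain"),
    cnvkit = make_segment(start = 1001L, end = 2000L, copy_number = 1L,
                          status = "loss"))
  expect_equal(nrow(consensus_regions(opposed)), 0)
})

test_that("single caller set yields an empty consensus with a warning", {
  expect_warning(
    out <- consensus_regions(list(controlfreec = make_segment())),
    "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("adjacent same-direction regions merge across gaps up to 10 kb", {
  regions <- tibble::tibble(
    sample_id = "BS_1", chrom = "chr1",
    start = c(1L, 6001L), end = c(1000L, 9000L), direction = "gain",
    supporting_callers = c("cnvkit,controlfreec", "cnvkit,gatk"),
    copy_number = c(4L, 4L))
  merged <- merge_adjacent(regions)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(1L, 9000L))
  expect_equal(merged$supporting_callers, "cnvkit,controlfreec,gatk")
  expect_identical(merge_adjacent(merged), merged)  # idempotent

  mixed <- dplyr::mutate(regions, direction = c("gain", "loss"))
  expect_equal(nrow(merge_adjacent(mixed)), 2)

  far <- dplyr::mutate(regions, start = c(1L, 11002L), end = c(1000L, 19000L))
  expect_equal(nrow(merge_adjacent(far)), 2)  # gap 10001 > 10000
})

test_that("length and blacklist filters use the printed boundaries", {
  bl <- genome_intervals("chr1", 10000, 15000)
  mk_region <- function(start, end) {
    tibble::tibble(sample_id = "BS_1", chrom = "chr1", start = start,
                   end = end, direction = "gain",
                   supporting_callers = "cnvkit,controlfreec",
                   copy_number = 4L)
  }
  expect_equal(nrow(filter_regions(mk_region(1L, 2999L), bl)), 0)   # < 3 kb
  expect_equal(nrow(filter_regions(mk_region(1L, 3000L), bl)), 1)
  # 10 kb region with exactly 50% blacklist overlap -> removed
  expect_equal(nrow(filter_regions(mk_region(10001L, 20000L), bl)), 0)
  # 4.9 kb of 10 kb inside blacklist -> kept
  expect_equal(nrow(filter_regions(mk_region(10101L, 20100L), bl)), 1)
})

test_that("MantaSV substitutes for GATK only when no panel of normals exists", {
  sets <- list(controlfreec = make_segment(), cnvkit = make_segment(),
               gatk = make_segment(), mantasv = make_segment())
  expect_named(apply_manta_fallback(sets, TRUE),
               c("controlfreec", "cnvkit", "gatk"))
  expect_named(apply_manta_fallback(sets, FALSE),
               c("controlfreec", "cnvkit", "mantasv"))
  expect_error(apply_manta_fallback(sets[c("controlfreec", "cnvkit")], FALSE),
               "mantasv")
})

test_that("full consensus matches the per-base voting oracle on toy genomes", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      mk_set <- function() {
        n <- sample(4:7, 1)
        start <- sample(seq.int(1L, 800000L, by = 500L), n)
        len <- sample(seq.int(2000L, 120000L, by = 500L), n, replace = TRUE)
        cn <- sample(c(1L, 4L), n, replace = TRUE)
        tibble::tibble(sample_id = "BS_1", chrom = "chr1", start = start,
                       end = pmin(start + len - 1L, 1000000L),
                       copy_number = cn, status = cn_status(cn))
      }
      by_caller <- list(controlfreec = mk_set(), cnvkit = mk_set(),
                        gatk = mk_set())
      bl <- genome_intervals("chr1", c(0, 500000), c(20000, 530000))
      got <- consensus_cnv(by_caller, bl, has_gatk_pon = TRUE)
      want <- oracle_cnv_regions(by_caller, bl)
      got_spans <- got[c("sample_id", "chrom", "start", "end", "direction")]
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(as.data.frame(got_spans), want, ignore_attr = TRUE)
      }
    }
  })
})

test_that("merged output regions never overlap within a sample and direction", {
  withr::with_seed(31, {
    mk_set <- function() {
      start <- sample(seq.int(1L, 900000L, by = 1000L), 6)
      tibble::tibble(sample_id = "BS_1", chrom = "chr1", start = start,
                     end = start + sample(seq.int(5000L, 90000L, 1000L), 6, TRUE),
                     copy_number = 4L, status = "gain")
    }
    out <- consensus_regions(list(a = mk_set(), b = mk_set())) |>
      merge_adjacent()
    by_dir <- split(out, out$direction)
    for (d in by_dir) {
      d <- dplyr::arrange(d, start)
      if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  })
})

test_that("WXS single-caller segments are appended unchanged", {
  wgs <- list(controlfreec = make_segment(start = 1001L, end = 5000L),
              cnvkit = make_segment(start = 1001L, end = 5000L),
              gatk = make_segment(start = 1001L, end = 5000L))
  wxs <- make_segment(sample_id = "BS_WXS", start = 50001L, end = 60000L)
  out <- consensus_cnv(wgs, genome_intervals("chr1", 0, 1),
                       has_gatk_pon = TRUE, wxs_segments = wxs)
  app <- dplyr::filter(out, sample_id == "BS_WXS")
  expect_equal(nrow(app), 1)
  expect_equal(c(app$start, app$end), c(50001L, 60000L))
  expect_equal(app$supporting_callers, "cnvkit")
})
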