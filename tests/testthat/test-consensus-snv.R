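test_that("consecutive SNVs matching an MNP template are collapsed", {
  s <- dplyr::bind_rows(
    make_variant(pos = 100L, ref = "C", alt = "A"),
    make_variant(pos = 101L, ref = "G", alt = "T"),
    make_variant(pos = 500L, ref = "T", alt = "G"))
  m <- make_variant(pos = 100L, ref = "CG", alt = "AT")
  out <- reconstruct_mnps(s, m)
  expect_equal(nrow(out), 2)
  mnp <- dplyr::filter(out, pos == 100)
  expect_equal(mnp$ref, "CG")
  expect_equal(mnp$alt, "AT")
  expect_true(mnp$mnp_reconstructed)
  expect_false(dplyr::filter(out, pos == 500)$mnp_reconstructed)
})

test_that("MNP reconstruction requires full, allele-consistent SNV runs", {
  s <- make_variant(pos = 100L, ref = "C", alt = "A")
  expect_identical(
    dplyr::select(reconstruct_mnps(s, s[0, ]), -mnp_reconstructed),
    s)
  # non-adjacent SNVs spanning the template positions: no merge
  s2 <- dplyr::bind_rows(make_variant(pos = 100L, ref = "C", alt = "A"),
                         make_variant(pos = 102L, ref = "G", alt = "T"))
  m2 <- make_variant(pos = 100L, ref = "CAG", alt = "AGT")
  expect_warning(out <- reconstruct_mnps(s2, m2), "inconsistent")
  expect_equal(sort(out$pos), c(100L, 102L))
  expect_false(any(out$mnp_reconstructed))
})

test_that("consensus keeps 2-caller and hotspot variants, drops singletons", {
  v <- make_variant()
  calls <- list(
    strelka2 = v,
    mutect2 = dplyr::bind_rows(v, make_variant(pos = 900L, ref = "A", alt = "G")),
    lancet = make_variant(pos = 300L, ref = "T", alt = "C", hotspot = TRUE),
    vardict = v[0, ])
  cons <- call_consensus(calls)
  expect_equal(nrow(cons), 2)
  two <- dplyr::filter(cons, pos == 100)
  expect_equal(two$caller_support, "mutect2,strelka2")
  expect_false(two$hotspot_rescued)
  rescued <- dplyr::filter(cons, pos == 300)
  expect_true(rescued$hotspot_rescued)
  expect_false(900 %in% cons$pos)
})

test_that("germline filter needs BOTH shallow normal and population frequency", {
  cases <- tibble::tribble(
    ~n_depth, ~gnomad_af, ~hotspot, ~kept,
    7L,  0.002, FALSE, FALSE,   # both conditions met -> removed
    10L, 0.002, FALSE, TRUE,    # deep normal -> kept
    7L,  0.001, FALSE, TRUE,    # AF not above threshold -> kept
    8L,  0.0005, FALSE, TRUE,
    3L,  0.05,  TRUE,  TRUE,    # hotspot never removed
    7L,  NA,    FALSE, TRUE     # missing AF treated as 0
  )
  for (i in seq_len(nrow(cases))) {
    cons <- make_variant(n_depth = cases$n_depth[i],
                         gnomad_af = cases$gnomad_af[i],
                         hotspot = cases$hotspot[i])
    expect_equal(nrow(filter_germline(cons)) == 1, cases$kept[i],
                 info = paste("case", i))
  }
})

test_that("tumor-only depth filter applies the printed inequalities exactly", {
  cases <- tibble::tribble(
    ~t_alt_count, ~t_depth, ~kept,
    0L,  100L, FALSE,  # no alt reads
    3L,  4L,   TRUE,   # boundary: 4 is not < 4
    2L,  3L,   FALSE,  # below minimum depth
    1L,  50L,  TRUE
  )
  calls <- purrr::pmap_dfr(cases[1:2], function(t_alt_count, t_depth) {
    make_variant(pos = sample.int(1e6, 1), t_alt_count = t_alt_count,
                 t_depth = t_depth)
  })
  kept <- filter_tumor_only(calls)
  expect_equal(calls$t_depth %in% kept$t_depth &
                 calls$t_alt_count %in% kept$t_alt_count, cases$kept)
})

test_that("consensus equals the set-based oracle on a random multi-caller input", {
  withr::with_seed(11, {
    mk <- function(n) {
      purrr::map_dfr(seq_len(n), function(i) {
        make_variant(sample_id = sample(c("BS_1", "BS_2"), 1),
                     pos = sample.int(2000, 1),
                     ref = sample(c("A", "C"), 1), alt = sample(c("G", "T"), 1),
                     n_depth = sample(c(3L, 7L, 20L), 1),
                     gnomad_af = sample(c(NA, 0.0005, 0.01), 1),
                     hotspot = runif(1) < 0.05)
      }) |> dplyr::distinct(sample_id, chrom, pos, ref, alt, .keep_all = TRUE)
    }
    calls <- list(strelka2 = mk(120), mutect2 = mk(120),
                  lancet = mk(120), vardict = mk(120))
    got <- consensus_snv(calls)
    got_keys <- sort(paste(got$sample_id, got$chrom, got$pos, got$ref, got$alt))
    expect_identical(got_keys, oracle_consensus_keys(calls))
  })
})

test_that("filtering commutes with restriction to a sample", {
  withr::with_seed(5, {
    pool <- purrr::map_dfr(1:60, function(i) {
      make_variant(sample_id = sample(c("BS_1", "BS_2", "BS_3"), 1),
                   pos = sample.int(5000, 1),
                   n_depth = sample(c(3L, 10L), 1),
                   gnomad_af = sample(c(NA, 0.01), 1))
    })
    whole <- filter_germline(pool)
    per_sample <- dplyr::bind_rows(lapply(split(pool, pool$sample_id),
                                          filter_germline))
    expect_equal(dplyr::arrange(whole, sample_id, pos),
                 dplyr::arrange(per_sample, sample_id, pos))
  })
})

test_that("consensus output ordering is deterministic under input shuffling", {
  withr::with_seed(9, {
    v <- purrr::map_dfr(1:40, function(i) {
      make_variant(pos = sample.int(1e5, 1), ref = sample(c("A", "C", "G"), 1))
    }) |> dplyr::distinct(pos, .keep_all = TRUE)
    calls <- list(strelka2 = v, mutect2 = v[sample.int(nrow(v)), ])
    a <- call_consensus(calls)
    b <- call_consensus(lapply(calls, function(x) x[sample.int(nrow(x)), ]))
    expect_identical(a, b)
  })
})
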