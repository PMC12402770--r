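mk_fusion <- function(fusion_name = "KIAA1549::BRAF",
                      callers = "arriba,starfusion", sample_id = "BS_1",
                      cancer_group = "LGG") {
  parts <- strsplit(fusion_name, "::", fixed = TRUE)[[1]]
  tibble::tibble(fusion_name = fusion_name, gene5 = parts[1], gene3 = parts[2],
                 callers = callers, sample_id = sample_id,
                 cancer_group = cancer_group, annotations = NA_character_)
}

gene_lists <- list(kinase = c("BRAF", "ALK"), oncogene = "MYC",
                   tsg = "TP53", tf = "FOXR2", cosmic_cgc = "EWSR1",
                   tcga_observed = "FGFR3")

test_that("oncogenic annotation checks both partners against every list", {
  expect_true(annotate_oncogenic(mk_fusion(), gene_lists)$putative_oncogenic)
  expect_false(annotate_oncogenic(mk_fusion("GENEX::GENEY"),
                                  gene_lists)$putative_oncogenic)
  expect_true(annotate_oncogenic(mk_fusion("GENEX::FGFR3"),
                                 gene_lists)$putative_oncogenic)
})

test_that("retention requires one of the four criteria, with reasons recorded", {
  fus <- dplyr::bind_rows(
    mk_fusion("AAA::BBB"),                                    # both callers
    mk_fusion("CCC::BRAF", callers = "arriba"),               # oncogenic
    mk_fusion("DDD::EEE", callers = "starfusion",
              sample_id = "BS_2", cancer_group = "HGG"),      # specific only
    mk_fusion("DDD::EEE", callers = "starfusion",
              sample_id = "BS_3", cancer_group = "LGG")       # now 2 groups
  ) |> annotate_oncogenic(gene_lists)
  out <- retain_fusions(fus)
  expect_true(grepl("both_callers",
                    out$retained_reason[out$fusion_name == "AAA::BBB"]))
  expect_true(grepl("oncogenic",
                    out$retained_reason[out$fusion_name == "CCC::BRAF"]))
  # DDD::EEE: single caller, 1 patient per group, 2 groups -> dropped
  expect_false("DDD::EEE" %in% out$fusion_name)
})

test_that("recurrent fusions are kept at the independent-patient threshold", {
  rec <- purrr::map_dfr(1:3, function(i) {
    mk_fusion("RRR::SSS", callers = "arriba", sample_id = paste0("BS_", i),
              cancer_group = c("HGG", "LGG")[1 + i %% 2])
  }) |> annotate_oncogenic(gene_lists)
  # 2 patients in HGG, 1 in LGG: below threshold in every group, 2 groups
  expect_equal(nrow(retain_fusions(rec)), 0)
  rec3 <- dplyr::mutate(rec, cancer_group = "HGG")
  out <- retain_fusions(rec3)
  expect_equal(nrow(out), 3)
  expect_true(all(grepl("recurrent", out$retained_reason)))
})

test_that("growing a gene list never drops a previously retained fusion", {
  withr::with_seed(17, {
    fus <- purrr::map_dfr(1:20, function(i) {
      mk_fusion(paste0("G", i, "::H", i),
                callers = sample(c("arriba", "starfusion",
                                   "arriba,starfusion"), 1),
                sample_id = paste0("BS_", sample.int(5, 1)),
                cancer_group = sample(c("HGG", "LGG"), 1))
    })
    before <- retain_fusions(annotate_oncogenic(fus, gene_lists))
    bigger <- c(gene_lists, list(extra = c("G1", "G7", "H13")))
    after <- retain_fusions(annotate_oncogenic(fus, bigger))
    expect_true(all(before$fusion_name %in% after$fusion_name))
  })
})

test_that("fusion-panel calls pass through regardless of other criteria", {
  dgd <- annotate_oncogenic(
    mk_fusion("PANEL::ONLY", callers = "dgd_panel"), gene_lists)
  out <- retain_fusions(dgd)
  expect_equal(nrow(out), 1)
  expect_true(grepl("dgd_panel", out$retained_reason))
})
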