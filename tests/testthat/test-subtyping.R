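test_that("high-confidence methylation selection enforces the 0.8 boundary", {
  m <- tibble::tibble(subclass = "ATRT_MYC", score = 0.85)
  expect_equal(nrow(high_conf_methyl(m, "ATRT_MYC")), 1)
  expect_equal(nrow(high_conf_methyl(dplyr::mutate(m, score = 0.79), "ATRT_MYC")), 0)
  expect_equal(nrow(high_conf_methyl(dplyr::mutate(m, score = 0.8), "ATRT_MYC")), 1)
  expect_equal(nrow(high_conf_methyl(dplyr::mutate(m, subclass = "OTHER"),
                                     "ATRT_MYC")), 0)
  expect_equal(nrow(high_conf_methyl(m, function(s) grepl("^ATRT", s))), 1)
})

test_that("the engine recovers every planted rule branch exactly", {
  pl <- plant_subtype_evidence()
  calls <- run_subtyping(pl$evidence)
  joined <- dplyr::left_join(pl$truth, calls, by = "tumor_event_id")
  expect_false(any(is.na(joined$molecular_subtype)))
  mism <- dplyr::filter(joined, molecular_subtype != expected_label)
  expect_equal(nrow(mism), 0, info = paste(mism$branch, collapse = ", "))
})

test_that("every emitted label belongs to the closed vocabulary", {
  pl <- plant_subtype_evidence()
  calls <- run_subtyping(pl$evidence)
  expect_true(all(calls$molecular_subtype %in% subtype_labels()$molecular_subtype))
})

test_that("PXA needs the full conjunction of text/methylation, BRAF and CDKN2A/B", {
  full <- plant_subtype_evidence("hgg_pxa")
  expect_equal(run_subtyping(full$evidence)$molecular_subtype, "PXA")
  partial <- plant_subtype_evidence("hgg_pxa_negative")
  expect_equal(run_subtyping(partial$evidence)$molecular_subtype,
               "HGG, To be classified")
})

test_that("neuroblastoma RNA fallback applies the exact TPM boundary", {
  ids <- c("a", "b", "c")
  evs <- plant_subtype_evidence(c("nbl_rna_amp", "nbl_rna_nonamp", "nbl_tbc"),
                                ids = ids)
  calls <- run_subtyping(evs$evidence)
  expect_equal(calls$molecular_subtype[match(ids, calls$tumor_event_id)],
               c("NBL, MYCN amplified", "NBL, MYCN non-amplified",
                 "NBL, To be classified"))
  # exact boundary: 140.83 is amplified
  ev <- cohort_evidence(
    histologies = tibble::tibble(tumor_event_id = "t",
                                 pathology_diagnosis = "Neuroblastoma"),
    expression = tibble::tibble(tumor_event_id = "t", gene = "MYCN",
                                tpm = 140.83, z = NA_real_))
  expect_equal(run_subtyping(ev)$molecular_subtype, "NBL, MYCN amplified")
})

test_that("ependymoma rules respect their printed order", {
  # an event carrying both ZFTA fusion and PF A evidence resolves to ST ZFTA
  ev <- cohort_evidence(
    histologies = tibble::tibble(tumor_event_id = "t",
                                 pathology_diagnosis = "Ependymoma"),
    fusions = tibble::tibble(tumor_event_id = "t",
                             fusion_name = "ZFTA::RELA",
                             gene5 = "ZFTA", gene3 = "RELA"),
    expression = tibble::tibble(tumor_event_id = "t", gene = "EZHIP",
                                tpm = NA_real_, z = 3))
  expect_equal(run_subtyping(ev)$molecular_subtype, "EPN, ST ZFTA")
})

test_that("methylation high-confidence calls dominate other evidence channels", {
  # MB group from methylation wins over a contradictory RNA classifier label
  ev <- cohort_evidence(
    histologies = tibble::tibble(tumor_event_id = "t",
                                 pathology_diagnosis = "Medulloblastoma",
                                 rna_mb_class = "Group4"),
    methylation = tibble::tibble(tumor_event_id = "t", classifier = "dkfz_v12",
                                 subclass = "MB_WNT", score = 0.95))
  expect_equal(run_subtyping(ev)$molecular_subtype, "MB, WNT")
  # stripping the non-methylation evidence leaves the call unchanged
  ev2 <- cohort_evidence(
    histologies = tibble::tibble(tumor_event_id = "t",
                                 pathology_diagnosis = "Medulloblastoma"),
    methylation = tibble::tibble(tumor_event_id = "t", classifier = "dkfz_v12",
                                 subclass = "MB_WNT", score = 0.95))
  expect_equal(run_subtyping(ev2)$molecular_subtype, "MB, WNT")
})

test_that("MB SHH subgroup disambiguation: 2p-gain-only goes to gamma", {
  mk <- function(arms) {
    cohort_evidence(
      histologies = tibble::tibble(tumor_event_id = "t",
                                   pathology_diagnosis = "Medulloblastoma",
                                   age_at_diagnosis_years = 3,
                                   rna_mb_class = "SHH"),
      arm_cn = tibble::tibble(tumor_event_id = "t", arm = arms,
                              status = "gain"))
  }
  expect_equal(run_subtyping(mk("2p"))$molecular_subtype, "MB, SHH gamma")
  expect_equal(run_subtyping(mk(c("2p", "2q")))$molecular_subtype, "MB, SHH beta")
})

test_that("subtyping is deterministic and invariant to cohort permutation", {
  pl <- plant_subtype_evidence()
  a <- run_subtyping(pl$evidence)
  shuffled <- pl$evidence
  withr::with_seed(3, {
    for (nm in names(shuffled)) {
      shuffled[[nm]] <- shuffled[[nm]][sample.int(nrow(shuffled[[nm]])), ]
    }
  })
  b <- run_subtyping(shuffled)
  expect_identical(a, b)
})

test_that("unmatched histologies produce no call", {
  ev <- cohort_evidence(
    histologies = tibble::tibble(tumor_event_id = "t",
                                 pathology_diagnosis = "Osteosarcoma"))
  expect_equal(nrow(run_subtyping(ev)), 0)
})

test_that("concordance marginals conserve the input label counts", {
  fx <- table1_fixture()
  cc <- concordance_table(fx$methylation_subclass, fx$rna_group)
  expect_equal(cc$n_pairs, nrow(fx))
  td <- tidy(cc)
  expect_equal(sum(td$n), nrow(fx))
  by_meth <- dplyr::count(fx, methylation_subclass)
  got <- dplyr::count(cc$pairs, methylation_subclass)
  expect_equal(got, by_meth)
  expect_equal(concordance_table(c("MB_WNT", "MB_WNT"),
                                 c("WNT", "WNT"))$n_mismatch, 0)
})

test_that("tidiers and plots expose the concordance result", {
  fx <- table1_fixture()
  cc <- concordance_table(fx$methylation_subclass, fx$rna_group)
  g <- glance(cc)
  expect_equal(g$n_pairs, 150)
  expect_s3_class(autoplot(cc), "ggplot")
  pl <- plant_subtype_evidence(c("mb_wnt", "atrt_shh"))
  expect_s3_class(plot_subtype_counts(run_subtyping(pl$evidence)), "ggplot")
})
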