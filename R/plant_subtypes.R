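# Builders planting exactly the evidence one subtyping rule needs, so
# engine recovery can be checked branch by branch against known labels.

p_hist <- function(id, dx, free_text = NA_character_, age = 8,
                   cns = NA_character_, germline = NA_character_,
                   rna_mb = NA_character_) {
  tibble(tumor_event_id = id, participant_id = paste0("PT_", id),
         pathology_diagnosis = dx, pathology_free_text_diagnosis = free_text,
         age_at_diagnosis_years = age, tumor_descriptor = "Initial CNS Tumor",
         cns_region = cns, germline_pathogenic = germline,
         rna_mb_class = rna_mb)
}
p_meth <- function(id, subclass, score = 0.9) {
  tibble(tumor_event_id = id, classifier = "dkfz_v12",
         subclass = subclass, score = score)
}
p_var <- function(id, gene, hgvsp = NA_character_,
                  class = "Missense_Mutation", hotspot = FALSE,
                  origin = "somatic") {
  tibble(tumor_event_id = id, hugo_symbol = gene, hgvsp_short = hgvsp,
         variant_classification = class, hotspot = hotspot, origin = origin)
}
p_gcn <- function(id, gene, status) {
  tibble(tumor_event_id = id, gene = gene, status = status)
}
p_arm <- function(id, arm, status) {
  tibble(tumor_event_id = id, arm = arm, status = status)
}
p_fus <- function(id, name) {
  parts <- strsplit(name, "::", fixed = TRUE)[[1]]
  tibble(tumor_event_id = id, fusion_name = name,
         gene5 = parts[1], gene3 = parts[2])
}
p_exp <- function(id, gene, z = NA_real_, tpm = NA_real_) {
  tibble(tumor_event_id = id, gene = gene, tpm = tpm, z = z)
}
p_flag <- function(id, ...) {
  tibble(tumor_event_id = id, ...)
}

branch_builders <- function() {
  hgg <- "High-grade glioma"
  mb <- "Medulloblastoma"
  list(
    # --- high-grade glioma ---------------------------------------------
    hgg_dmg_variant = list("HGG", "DMG, H3 K28", function(id) list(
      hist = p_hist(id, hgg),
      variants = p_var(id, "H3F3A", "p.K28M"))),
    hgg_dmg_methyl = list("HGG", "DMG, H3 K28", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "DMG_K27"))),
    hgg_o_idh = list("HGG", "Oligodendroglioma, IDH-mutant", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "O_IDH"))),
    hgg_oligosarc = list("HGG", "Oligosarcoma, IDH-mutant", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "OLIGOSARC_IDH"))),
    hgg_pxa = list("HGG", "PXA", function(id) list(
      hist = p_hist(id, hgg, free_text = "pxa"),
      variants = p_var(id, "BRAF", "p.V600E"),
      gene_cn = p_gcn(id, "CDKN2A", "deep_deletion"))),
    hgg_pxa_negative = list("HGG", "HGG, To be classified", function(id) list(
      hist = p_hist(id, hgg, free_text = "pxa"),
      variants = p_var(id, "BRAF", "p.V600E"),
      gene_cn = p_gcn(id, "CDKN2A", "neutral"))),
    hgg_dhg = list("HGG", "DHG, H3 G35", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "DHG_G34"))),
    hgg_idh = list("HGG", "HGG, IDH", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "GBM_IDH"))),
    hgg_h3wt = list("HGG", "HGG, H3 wild-type", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "GBM_MES_TYP"))),
    hgg_tbc = list("HGG", "HGG, To be classified", function(id) list(
      hist = p_hist(id, hgg))),
    # --- infant-type hemispheric glioma --------------------------------
    ihg_alk = list("HGG", "IHG, ALK-altered", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "IHG"),
      fusions = p_fus(id, "EML4::ALK"))),
    ihg_ntrk = list("HGG", "IHG, NTRK-altered", function(id) list(
      hist = p_hist(id, hgg, free_text = "infant type hemispheric glioma"),
      fusions = p_fus(id, "ETV6::NTRK3"))),
    ihg_ros1 = list("HGG", "IHG, ROS1-altered", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "IHG"),
      fusions = p_fus(id, "GOPC::ROS1"))),
    ihg_met = list("HGG", "IHG, MET-altered", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "IHG"),
      fusions = p_fus(id, "CAPZA2::MET"))),
    ihg_tbc = list("HGG", "IHG, To be classified", function(id) list(
      hist = p_hist(id, hgg), methylation = p_meth(id, "IHG"))),
    # --- ATRT ----------------------------------------------------------
    atrt_myc = list("ATRT", "ATRT, MYC", function(id) list(
      hist = p_hist(id, "Atypical teratoid rhabdoid tumor"),
      methylation = p_meth(id, "ATRT_MYC", 0.85))),
    atrt_shh = list("ATRT", "ATRT, SHH", function(id) list(
      hist = p_hist(id, "Atypical teratoid rhabdoid tumor"),
      methylation = p_meth(id, "ATRT_SHH", 0.9))),
    atrt_tyr = list("ATRT", "ATRT, TYR", function(id) list(
      hist = p_hist(id, "Atypical teratoid rhabdoid tumor"),
      methylation = p_meth(id, "ATRT_TYR", 0.95))),
    atrt_tbc = list("ATRT", "ATRT, To be classified", function(id) list(
      hist = p_hist(id, "Atypical teratoid rhabdoid tumor"),
      methylation = p_meth(id, "ATRT_SHH", 0.5))),
    # --- neuroblastoma -------------------------------------------------
    nbl_cn_amp = list("NBL", "NBL, MYCN amplified", function(id) list(
      hist = p_hist(id, "Neuroblastoma"),
      gene_cn = p_gcn(id, "MYCN", "amplification"))),
    nbl_rna_amp = list("NBL", "NBL, MYCN amplified", function(id) list(
      hist = p_hist(id, "Neuroblastoma"),
      expression = p_exp(id, "MYCN", tpm = 150))),
    nbl_rna_nonamp = list("NBL", "NBL, MYCN non-amplified", function(id) list(
      hist = p_hist(id, "Neuroblastoma"),
      expression = p_exp(id, "MYCN", tpm = 140.82))),
    nbl_conflict = list("NBL", "NBL, MYCN amplified", function(id) list(
      hist = p_hist(id, "Neuroblastoma", free_text = "nbl, mycn amplified"),
      gene_cn = p_gcn(id, "MYCN", "neutral"),
      expression = p_exp(id, "MYCN", tpm = 200))),
    nbl_nonamp = list("NBL", "NBL, MYCN non-amplified", function(id) list(
      hist = p_hist(id, "Ganglioneuroblastoma"),
      gene_cn = p_gcn(id, "MYCN", "neutral"))),
    nbl_tbc = list("NBL", "NBL, To be classified", function(id) list(
      hist = p_hist(id, "Neuroblastoma"))),
    # --- craniopharyngioma ---------------------------------------------
    cranio_pap = list("CRANIO", "CRANIO, PAP", function(id) list(
      hist = p_hist(id, "Craniopharyngioma"),
      methylation = p_meth(id, "CPH_PAP"))),
    cranio_adam = list("CRANIO", "CRANIO, ADAM", function(id) list(
      hist = p_hist(id, "Craniopharyngioma"),
      methylation = p_meth(id, "CPH_ADM", 0.95))),
    cranio_tbc = list("CRANIO", "CRANIO, To be classified", function(id) list(
      hist = p_hist(id, "Craniopharyngioma"),
      methylation = p_meth(id, "CPH_PAP", 0.6))),
    # --- ependymoma ----------------------------------------------------
    epn_spmycn = list("EPN", "EPN, SP-MYCN", function(id) list(
      hist = p_hist(id, "Ependymoma", cns = "spinal"),
      gene_cn = p_gcn(id, "MYCN", "amplification"))),
    epn_spmycn_methyl = list("EPN", "EPN, SP-MYCN", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      methylation = p_meth(id, "EPN, SP-MYCN"))),
    epn_yap1 = list("EPN", "EPN, ST YAP1", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      fusions = p_fus(id, "YAP1::MAMLD1"))),
    epn_zfta = list("EPN", "EPN, ST ZFTA", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      fusions = p_fus(id, "ZFTA::RELA"))),
    epn_pfa_1q = list("EPN", "EPN, PF A", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      arm_cn = p_arm(id, "1q", "gain"),
      expression = p_exp(id, "TKTL1", z = 2.5))),
    epn_pfa_ezhip = list("EPN", "EPN, PF A", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      expression = p_exp(id, "EZHIP", z = 3))),
    epn_pfa_h3 = list("EPN", "EPN, PF A", function(id) list(
      hist = p_hist(id, "Ependymoma", cns = "posterior fossa"),
      variants = p_var(id, "HIST1H3B", "p.K28M"))),
    epn_pfa_methyl = list("EPN", "EPN, PF A", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      methylation = p_meth(id, "EPN, PF A"))),
    epn_pfb = list("EPN", "EPN, PF B", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      arm_cn = p_arm(id, "6q", "loss"),
      expression = p_exp(id, "GPBP1", z = 2.2))),
    epn_pfb_methyl = list("EPN", "EPN, PF B", function(id) list(
      hist = p_hist(id, "Ependymoma"),
      methylation = p_meth(id, "EPN, PF B"))),
    epn_mpe = list("EPN", "EPN, MPE", function(id) list(
      hist = p_hist(id, "Ependymoma"), methylation = p_meth(id, "EPN, MPE"))),
    epn_pfse = list("EPN", "EPN, PF SE", function(id) list(
      hist = p_hist(id, "Ependymoma"), methylation = p_meth(id, "EPN, PF SE"))),
    epn_spse = list("EPN", "EPN, SP SE", function(id) list(
      hist = p_hist(id, "Ependymoma"), methylation = p_meth(id, "EPN, SP SE"))),
    epn_sp = list("EPN", "EPN, SP", function(id) list(
      hist = p_hist(id, "Ependymoma"), methylation = p_meth(id, "EPN, SP"))),
    epn_tbc = list("EPN", "EPN, To be classified", function(id) list(
      hist = p_hist(id, "Ependymoma"))),
    # --- low-grade glioma ----------------------------------------------
    lgg_pa_mid = list("LGG", "LGG, other MAPK-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"), methylation = p_meth(id, "PA_MID"))),
    lgg_plnty = list("LGG", "LGG, other MAPK-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"), methylation = p_meth(id, "PLNTY"))),
    lgg_fgfr = list("LGG", "LGG, FGFR-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"),
      methylation = p_meth(id, "PA_INF_FGFR"))),
    lgg_idh = list("LGG", "LGG, IDH-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"), methylation = p_meth(id, "A_IDH_LG"))),
    lgg_myb = list("LGG", "LGG, MYB/MYBL1 fusion", function(id) list(
      hist = p_hist(id, "Low-grade glioma"), methylation = p_meth(id, "AG_MYB"))),
    lgg_mapk = list("LGG", "LGG, MAPK-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"), methylation = p_meth(id, "LGG, MAPK"))),
    lgg_braf_mapk = list("LGG", "LGG, BRAF- and MAPK-altered", function(id) list(
      hist = p_hist(id, "Low-grade glioma"),
      methylation = p_meth(id, "LGG, BRAF/MAPK"))),
    lgg_sega = list("LGG", "SEGA, To be classified", function(id) list(
      hist = p_hist(id, "Low-grade glioma"),
      methylation = p_meth(id, "SEGA, To be classified"))),
    lgg_tbc = list("LGG", "LGG, To be classified", function(id) list(
      hist = p_hist(id, "Low-grade glioma"))),
    # --- medulloblastoma -----------------------------------------------
    mb_wnt = list("MB", "MB, WNT", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_WNT"))),
    mb_group3 = list("MB", "MB, Group3", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_G34_II"))),
    mb_group4 = list("MB", "MB, Group4", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_G34_VII"))),
    mb_myo = list("MB", "MB, MYO", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_MYO"))),
    mb_rna = list("MB", "MB, Group4", function(id) list(
      hist = p_hist(id, mb, rna_mb = "Group4"))),
    mb_tbc = list("MB", "MB, To be classified", function(id) list(
      hist = p_hist(id, mb))),
    shh_alpha_methyl = list("MB", "MB, SHH alpha", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_SHH_3"))),
    shh_beta_methyl = list("MB", "MB, SHH beta", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_SHH_1"))),
    shh_gamma_methyl = list("MB", "MB, SHH gamma", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_SHH_2"))),
    shh_delta_methyl = list("MB", "MB, SHH delta", function(id) list(
      hist = p_hist(id, mb), methylation = p_meth(id, "MB_SHH_4"))),
    shh_alpha_gli2 = list("MB", "MB, SHH alpha", function(id) list(
      hist = p_hist(id, mb, age = 4, rna_mb = "SHH"),
      gene_cn = p_gcn(id, "GLI2", "amplification"))),
    shh_alpha_germline = list("MB", "MB, SHH alpha", function(id) list(
      hist = p_hist(id, mb, age = 6, rna_mb = "SHH", germline = "TP53"))),
    shh_alpha_17p = list("MB", "MB, SHH alpha", function(id) list(
      hist = p_hist(id, mb, age = 3, rna_mb = "SHH"),
      arm_cn = p_arm(id, "17p", "loss"))),
    shh_beta_kmt2d = list("MB", "MB, SHH beta", function(id) list(
      hist = p_hist(id, mb, age = 3, rna_mb = "SHH"),
      variants = p_var(id, "KMT2D", class = "Nonsense_Mutation"))),
    shh_beta_pten = list("MB", "MB, SHH beta", function(id) list(
      hist = p_hist(id, mb, age = 2, rna_mb = "SHH"),
      gene_cn = p_gcn(id, "PTEN", "deep_deletion"))),
    shh_gamma_2p = list("MB", "MB, SHH gamma", function(id) list(
      hist = p_hist(id, mb, age = 3, rna_mb = "SHH"),
      arm_cn = p_arm(id, "2p", "gain"))),
    shh_delta_ddx3x = list("MB", "MB, SHH delta", function(id) list(
      hist = p_hist(id, mb, age = 12, rna_mb = "SHH"),
      variants = p_var(id, "DDX3X", class = "Nonsense_Mutation"))),
    shh_delta_u1 = list("MB", "MB, SHH delta", function(id) list(
      hist = p_hist(id, mb, age = 15, rna_mb = "SHH"),
      flags = p_flag(id, u1_snrna_hotspot = TRUE))),
    shh_delta_14q = list("MB", "MB, SHH delta", function(id) list(
      hist = p_hist(id, mb, age = 11, rna_mb = "SHH"),
      arm_cn = p_arm(id, "14q", "loss"))),
    shh_unsub = list("MB", "MB, SHH", function(id) list(
      hist = p_hist(id, mb, age = 7, rna_mb = "SHH"))),
    # --- pineoblastoma -------------------------------------------------
    pb_foxr2 = list("PB", "PB, MYC/FOXR2-activated", function(id) list(
      hist = p_hist(id, "Pineoblastoma"), methylation = p_meth(id, "PB_FOXR2"))),
    pb_rb1 = list("PB", "PB, RB1-altered", function(id) list(
      hist = p_hist(id, "Pineoblastoma"), methylation = p_meth(id, "PB_RB1"))),
    pb_grp1 = list("PB", "PB, Group 1", function(id) list(
      hist = p_hist(id, "Pineoblastoma"), methylation = p_meth(id, "PB_GRP1B"))),
    pb_grp2 = list("PB", "PB, Group 2", function(id) list(
      hist = p_hist(id, "Pineoblastoma"), methylation = p_meth(id, "PB_GRP2"))),
    pb_tbc = list("PB", "PB, To be classified", function(id) list(
      hist = p_hist(id, "Pineoblastoma"),
      methylation = p_meth(id, "PB_RB1", 0.7))),
    # --- embryonal tumor with multilayered rosettes --------------------
    etmr_methyl = list("ETMR", "ETMR, C19MC-altered", function(id) list(
      hist = p_hist(id, "Embryonal tumor with multilayered rosettes"),
      methylation = p_meth(id, "ETMR_C19MC"))),
    etmr_ttyh1_lin28a = list("ETMR", "ETMR, C19MC-altered", function(id) list(
      hist = p_hist(id, "Embryonal tumor with multilayered rosettes"),
      fusions = p_fus(id, "TTYH1::C19MC"),
      expression = p_exp(id, "LIN28A", z = 3))),
    etmr_ttyh1_chr19 = list("ETMR", "ETMR, C19MC-altered", function(id) list(
      hist = p_hist(id, "Embryonal tumor with multilayered rosettes"),
      fusions = p_fus(id, "TTYH1::C19MC"),
      flags = p_flag(id, chr19_amplified = TRUE))),
    etmr_nos = list("ETMR", "ETMR, NOS", function(id) list(
      hist = p_hist(id, "Embryonal tumor with multilayered rosettes"),
      expression = p_exp(id, "LIN28A", z = 3)))
  )
}

#' Catalog of planted subtyping rule branches
#'
#' One row per rule branch the synthetic cohorts can plant, with the
#' histology group it belongs to and the label the engine is expected to
#' emit when exactly that branch's antecedents are present.
#'
#' @return Tibble `branch`, `histology_group`, `expected_label`.
#' @export
subtype_rule_catalog <- function() {
  b <- branch_builders()
  tibble(branch = names(b),
         histology_group = map_chr(b, 1),
         expected_label = map_chr(b, 2))
}

#' Plant per-branch subtyping evidence with known expected labels
#'
#' Builds a [cohort_evidence()] bundle in which each tumor event carries
#' exactly the antecedents of one subtyping rule branch, together with the
#' label the engine must recover.
#'
#' @param branches Character vector of branch names (see
#'   [subtype_rule_catalog()]); defaults to every branch once.
#' @param ids Optional tumor event ids (recycled names get a numeric
#'   suffix when a branch is planted more than once).
#' @return List with `evidence` (a `pedcan_evidence`) and `truth`
#'   (tibble `tumor_event_id`, `branch`, `histology_group`,
#'   `expected_label`).
#' @export
plant_subtype_evidence <- function(branches = NULL, ids = NULL) {
  b <- branch_builders()
  branches <- branches %||% names(b)
  bad <- setdiff(branches, names(b))
  if (length(bad)) abort(paste0("unknown branch(es): ", paste(bad, collapse = ", ")))
  ids <- ids %||% sprintf("TE_%03d", seq_along(branches))
  stopifnot(length(ids) == length(branches), !anyDuplicated(ids))
  frags <- purrr::map2(branches, ids, function(br, id) b[[br]][[3]](id))
  collect <- function(field) {
    rows <- compact(map(frags, ~ .x[[field]]))
    if (length(rows) == 0) NULL else bind_rows(rows)
  }
  ev <- cohort_evidence(
    histologies = bind_rows(map(frags, "hist")),
    variants = collect("variants"), gene_cn = collect("gene_cn"),
    arm_cn = collect("arm_cn"), fusions = collect("fusions"),
    expression = collect("expression"), methylation = collect("methylation"),
    flags = collect("flags")
  )
  list(evidence = ev,
       truth = tibble(tumor_event_id = ids, branch = branches,
                      histology_group = map_chr(b[branches], 1),
                      expected_label = map_chr(b[branches], 2)))
}
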