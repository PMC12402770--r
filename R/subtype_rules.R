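st_call <- function(e, label, evidence, basis) {
  tibble(tumor_event_id = e$tumor_event_id, molecular_subtype = label,
         evidence_used = paste(evidence, collapse = ","),
         confidence_basis = basis)
}

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "pedcan", mustWork = TRUE)
}

read_label_map <- function(file) {
  readr::read_tsv(pkg_extdata(file), col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

h3_k28_genes <- c("H3F3A", "HIST1H3B", "HIST1H3C", "HIST2H3C")

#' High-grade glioma subtyping
#'
#' Ordered first-match rules: H3 K28-altered diffuse midline glioma
#' (p.K28M/p.K28I in an H3 gene, or high-confidence DMG methylation
#' class); oligodendroglioma / oligosarcoma IDH-mutant (methylation
#' "O_IDH" / "OLIGOSARC_IDH"); pleomorphic xanthoastrocytoma (PXA
#' methylation or free-text diagnosis, **and** BRAF V600E **and**
#' CDKN2A/B deep deletion); diffuse hemispheric glioma H3 G35
#' ("DHG_G34"/"GBM_G34"); HGG IDH ("A_IDH_HG"/"GBM_IDH"); H3 wild-type
#' (methylation containing GBM_MES/GBM_RTK/HGG_/HGAP/AAP/ped_); otherwise
#' "HGG, To be classified".
#'
#' @param e Per-event evidence (from `event_evidence()`); callers normally
#'   go through [run_subtyping()].
#' @param cfg A [rule_config()].
#' @return One-row subtype call tibble.
#' @export
subtype_hgg <- function(e, cfg = rule_config()) {
  if (ev_variant(e, genes = h3_k28_genes, hgvsp = c("p.K28M", "p.K28I")))
    return(st_call(e, "DMG, H3 K28", "h3_k28_variant", "molecular"))
  if (nrow(high_conf_methyl(e$methylation, function(s) grepl("DMG", s), cfg)))
    return(st_call(e, "DMG, H3 K28", "methylation_dmg", "methylation_high_conf"))
  if (nrow(high_conf_methyl(e$methylation, "O_IDH", cfg)))
    return(st_call(e, "Oligodendroglioma, IDH-mutant", "methylation_o_idh",
                   "methylation_high_conf"))
  if (nrow(high_conf_methyl(e$methylation, "OLIGOSARC_IDH", cfg)))
    return(st_call(e, "Oligosarcoma, IDH-mutant", "methylation_oligosarc",
                   "methylation_high_conf"))
  pxa_path <- nrow(high_conf_methyl(e$methylation, "PXA", cfg)) > 0 ||
    grepl("pleomorphic xanthoastrocytoma|pxa", e$free_text)
  if (pxa_path &&
      ev_variant(e, genes = "BRAF", hgvsp = "p.V600E") &&
      (ev_gene_status(e, "CDKN2A") == "deep_deletion" ||
       ev_gene_status(e, "CDKN2B") == "deep_deletion")) {
    return(st_call(e, "PXA", c("pxa_evidence", "braf_v600e", "cdkn2ab_deletion"),
                   "molecular"))
  }
  if (nrow(high_conf_methyl(e$methylation, c("DHG_G34", "GBM_G34"), cfg)))
    return(st_call(e, "DHG, H3 G35", "methylation_g34", "methylation_high_conf"))
  if (nrow(high_conf_methyl(e$methylation, c("A_IDH_HG", "GBM_IDH"), cfg)))
    return(st_call(e, "HGG, IDH", "methylation_idh", "methylation_high_conf"))
  wt <- function(s) grepl("GBM_MES|GBM_RTK|HGG_|HGAP|AAP|ped_", s)
  if (nrow(high_conf_methyl(e$methylation, wt, cfg)))
    return(st_call(e, "HGG, H3 wild-type", "methylation_h3_wt",
                   "methylation_high_conf"))
  st_call(e, "HGG, To be classified", "", "fallback")
}

ihg_eligible <- function(e, cfg) {
  nrow(high_conf_methyl(e$methylation, function(s) grepl("IHG", s), cfg)) > 0 ||
    grepl("infant[ -]type hemispheric glioma", e$free_text)
}

#' Infant-type hemispheric glioma subtyping
#'
#' Events eligible as IHG (methylation class "IHG" or a matching free-text
#' diagnosis) are labeled by their receptor tyrosine kinase fusion partner
#' (ALK, NTRK1/2/3, ROS1, MET); with no RTK fusion the label is
#' "IHG, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble, or `NULL` when not IHG-eligible.
#' @export
subtype_ihg <- function(e, cfg = rule_config()) {
  if (!ihg_eligible(e, cfg)) return(NULL)
  rtk <- list(
    c(gene = "ALK", label = "IHG, ALK-altered"),
    c(gene = "NTRK", label = "IHG, NTRK-altered"),
    c(gene = "ROS1", label = "IHG, ROS1-altered"),
    c(gene = "MET", label = "IHG, MET-altered")
  )
  partners <- unique(c(e$fusions$gene5, e$fusions$gene3))
  for (r in rtk) {
    genes <- if (r[["gene"]] == "NTRK") c("NTRK1", "NTRK2", "NTRK3") else r[["gene"]]
    if (any(partners %in% genes)) {
      return(st_call(e, r[["label"]], paste0("fusion_", tolower(r[["gene"]])),
                     "molecular"))
    }
  }
  st_call(e, "IHG, To be classified", "ihg_no_rtk_fusion", "fallback")
}

#' Atypical teratoid rhabdoid tumor subtyping
#'
#' Based solely on DNA methylation: a high-confidence ATRT_MYC / ATRT_SHH /
#' ATRT_TYR subclass assigns the subtype; anything else is
#' "ATRT, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_atrt <- function(e, cfg = rule_config()) {
  for (sub in c("MYC", "SHH", "TYR")) {
    if (nrow(high_conf_methyl(e$methylation, paste0("ATRT_", sub), cfg))) {
      return(st_call(e, paste0("ATRT, ", sub), "methylation_atrt",
                     "methylation_high_conf"))
    }
  }
  st_call(e, "ATRT, To be classified", "", "fallback")
}

#' Neuroblastoma MYCN subtyping
#'
#' MYCN copy-number amplification dominates; free-text/genomic conflicts
#' resolve in favor of genomic amplification. When the free text claims
#' amplification but genomics says non-amplified, or when no DNA evidence
#' exists, the MYCN RNA expression level decides (TPM at or above
#' `cfg$mycn_tpm_cutoff`, 140.83, is amplified). With no usable evidence
#' the label is "NBL, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_nbl <- function(e, cfg = rule_config()) {
  mycn_cn <- ev_gene_status(e, "MYCN")
  tpm <- ev_tpm(e, "MYCN")
  by_tpm <- function(reason) {
    if (is.na(tpm)) return(st_call(e, "NBL, To be classified", reason, "fallback"))
    if (tpm >= cfg$mycn_tpm_cutoff)
      st_call(e, "NBL, MYCN amplified", c(reason, "mycn_tpm"), "molecular")
    else
      st_call(e, "NBL, MYCN non-amplified", c(reason, "mycn_tpm"), "molecular")
  }
  if (mycn_cn == "amplification")
    return(st_call(e, "NBL, MYCN amplified", "mycn_cn_amplified", "molecular"))
  text_amp <- grepl("amplified", e$free_text) & !grepl("non-?\\s?amplified", e$free_text)
  if (!e$has_dna) return(by_tpm("no_dna"))
  if (text_amp) return(by_tpm("free_text_conflict"))
  st_call(e, "NBL, MYCN non-amplified", "mycn_cn_non_amplified", "molecular")
}

#' Craniopharyngioma subtyping
#'
#' High-confidence methylation subclass containing "CPH_PAP" yields
#' papillary (CRANIO, PAP) and "CPH_ADM" adamantinomatous (CRANIO, ADAM);
#' otherwise "CRANIO, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_cranio <- function(e, cfg = rule_config()) {
  if (nrow(high_conf_methyl(e$methylation, function(s) grepl("CPH_PAP", s), cfg)))
    return(st_call(e, "CRANIO, PAP", "methylation_cph_pap", "methylation_high_conf"))
  if (nrow(high_conf_methyl(e$methylation, function(s) grepl("CPH_ADM", s), cfg)))
    return(st_call(e, "CRANIO, ADAM", "methylation_cph_adm", "methylation_high_conf"))
  st_call(e, "CRANIO, To be classified", "", "fallback")
}

#' Ependymoma subtyping
#'
#' Ordered first-match rules: (1) spinal location with MYCN amplification
#' or "EPN, SP-MYCN" methylation; (2) YAP1 fusions
#' (YAP1::MAMLD1/MAML2/FAM118B) or "EPN, ST YAP1" methylation; (3) ZFTA
#' fusions (ZFTA::RELA/MAML2) or "EPN, ST ZFTA" methylation; (4) PF A —
#' 1q gain with TKTL1 over-expression, or EZHIP over-expression, or
#' posterior fossa location with an H3 K28 mutation, or "EPN, PF A"
#' methylation; (5) PF B — 6p/6q loss with GPBP1 or IFT46 over-expression,
#' or "EPN, PF B" methylation; (6)-(9) high-confidence "EPN, MPE" /
#' "EPN, PF SE" / "EPN, SP SE" / "EPN, SP" methylation; otherwise
#' "EPN, To be classified". Over-expression means a cohort z-score of at
#' least `cfg$expr_z_high`.
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_epn <- function(e, cfg = rule_config()) {
  hc <- function(lbl) nrow(high_conf_methyl(e$methylation, lbl, cfg)) > 0
  spinal <- grepl("spinal", e$cns_region)
  pf <- grepl("posterior fossa", e$cns_region)
  if ((spinal && ev_gene_status(e, "MYCN") == "amplification") || hc("EPN, SP-MYCN"))
    return(st_call(e, "EPN, SP-MYCN", "spinal_mycn", "molecular"))
  if (ev_fusion(e, names = c("YAP1::MAMLD1", "YAP1::MAML2", "YAP1::FAM118B")) ||
      hc("EPN, ST YAP1"))
    return(st_call(e, "EPN, ST YAP1", "yap1_fusion", "molecular"))
  if (ev_fusion(e, names = c("ZFTA::RELA", "ZFTA::MAML2")) || hc("EPN, ST ZFTA"))
    return(st_call(e, "EPN, ST ZFTA", "zfta_fusion", "molecular"))
  pfa <- (ev_arm_is(e, "1q", "gain") && ev_overexpressed(e, "TKTL1", cfg)) ||
    ev_overexpressed(e, "EZHIP", cfg) ||
    (pf && ev_variant(e, genes = h3_k28_genes, hgvsp = c("p.K28M", "p.K28I"))) ||
    hc("EPN, PF A")
  if (pfa) return(st_call(e, "EPN, PF A", "pfa_evidence", "molecular"))
  pfb <- (ev_arm_is(e, c("6p", "6q"), "loss") &&
            (ev_overexpressed(e, "GPBP1", cfg) || ev_overexpressed(e, "IFT46", cfg))) ||
    hc("EPN, PF B")
  if (pfb) return(st_call(e, "EPN, PF B", "pfb_evidence", "molecular"))
  for (lbl in c("EPN, MPE", "EPN, PF SE", "EPN, SP SE", "EPN, SP")) {
    if (hc(lbl)) return(st_call(e, lbl, "methylation_epn", "methylation_high_conf"))
  }
  st_call(e, "EPN, To be classified", "", "fallback")
}

#' Low-grade glioma subtyping from methylation classes
#'
#' Applies the methylation subclass-to-label mapping shipped in
#' `extdata/lgg_methyl_map.tsv` (e.g. PA_MID/PLNTY to "LGG, other
#' MAPK-altered", PA_INF_FGFR to "LGG, FGFR-altered"); with no
#' high-confidence mapped subclass the label is "LGG, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_lgg_methyl <- function(e, cfg = rule_config()) {
  map <- read_label_map("lgg_methyl_map.tsv")
  hit <- high_conf_methyl(e$methylation, map$subclass, cfg)
  if (nrow(hit)) {
    lbl <- map$label[match(hit$subclass, map$subclass)]
    return(st_call(e, lbl, "methylation_lgg", "methylation_high_conf"))
  }
  st_call(e, "LGG, To be classified", "", "fallback")
}

#' Map a medulloblastoma methylation subclass to its consensus group
#'
#' MB_SHH_* subclasses map to SHH; MB_G34_I-IV to Group3; MB_G34_V-VIII to
#' Group4; MB_WNT to WNT; MB_MYO to MYO (mapping shipped in
#' `extdata/mb_methyl_map.tsv`).
#'
#' @param subclass Character vector of methylation subclass labels.
#' @return Character vector of group labels (`NA` for unmapped).
#' @examples
#' mb_methyl_group(c("MB_G34_VII", "MB_WNT", "MB_SHH_1"))
#' @export
mb_methyl_group <- function(subclass) {
  map <- read_label_map("mb_methyl_map.tsv")
  out <- map$group[match(subclass, map$subclass)]
  ifelse(is.na(out) & grepl("^MB_SHH", subclass), "SHH", out)
}

#' Medulloblastoma group subtyping
#'
#' A high-confidence methylation classification decides the group via
#' [mb_methyl_group()]; absent usable methylation, the external RNA
#' classifier label (`rna_mb_class`: WNT/SHH/Group3/Group4) is used.
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_mb <- function(e, cfg = rule_config()) {
  hit <- high_conf_methyl(e$methylation, function(s) grepl("^MB_", s), cfg)
  if (nrow(hit)) {
    grp <- mb_methyl_group(hit$subclass)
    if (!is.na(grp)) {
      return(st_call(e, paste0("MB, ", grp), "methylation_mb",
                     "methylation_high_conf"))
    }
  }
  if (!is.na(e$rna_mb_class) &&
      e$rna_mb_class %in% c("WNT", "SHH", "Group3", "Group4")) {
    return(st_call(e, paste0("MB, ", e$rna_mb_class), "rna_mb_classifier",
                   "molecular"))
  }
  st_call(e, "MB, To be classified", "", "fallback")
}

#' SHH-activated medulloblastoma subgroup assignment
#'
#' For events already labeled "MB, SHH": a high-confidence MB_SHH_3 / 1 /
#' 2 / 4 methylation class assigns alpha / beta / gamma / delta directly.
#' Otherwise age and molecular features decide: alpha at age >= 2 with
#' MYCN/GLI2/CCND2 amplification or over-expression, a pathogenic
#' germline ELP1 or TP53 variant, a somatic TP53 hotspot, 9p gain or 17p
#' loss; beta at age < 5 with a KMT2D loss-of-function variant, PTEN
#' loss/deep deletion or under-expression, or 2q gain; gamma at age < 5
#' with 2p gain; delta at age >= 10 with DDX3X or SMO loss-of-function, a
#' TERT or U1 snRNA hotspot, or 14q loss. Events matching no subgroup stay
#' "MB, SHH". 2p gain is listed among both beta and gamma features: a
#' 2p-gain-only event goes to gamma, beta requires a beta-specific
#' feature.
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_mb_shh <- function(e, cfg = rule_config()) {
  hc <- function(lbl) nrow(high_conf_methyl(e$methylation, lbl, cfg)) > 0
  if (hc("MB_SHH_3")) return(st_call(e, "MB, SHH alpha", "methylation_shh3", "methylation_high_conf"))
  if (hc("MB_SHH_1")) return(st_call(e, "MB, SHH beta", "methylation_shh1", "methylation_high_conf"))
  if (hc("MB_SHH_2")) return(st_call(e, "MB, SHH gamma", "methylation_shh2", "methylation_high_conf"))
  if (hc("MB_SHH_4")) return(st_call(e, "MB, SHH delta", "methylation_shh4", "methylation_high_conf"))
  age <- e$age
  amp_or_over <- function(g) {
    ev_gene_status(e, g) == "amplification" || ev_overexpressed(e, g, cfg)
  }
  if (!is.na(age) && age >= cfg$shh_alpha_min_age) {
    alpha <- any(vapply(c("MYCN", "GLI2", "CCND2"), amp_or_over, logical(1))) ||
      any(c("ELP1", "TP53") %in% e$germline) ||
      ev_variant(e, genes = "TP53", hotspot = TRUE) ||
      ev_arm_is(e, "9p", "gain") || ev_arm_is(e, "17p", "loss")
    if (alpha) return(st_call(e, "MB, SHH alpha", "alpha_features", "molecular"))
  }
  if (!is.na(age) && age < cfg$shh_beta_gamma_max_age) {
    pten_z <- ev_z(e, "PTEN")
    beta <- ev_lof(e, "KMT2D", cfg) ||
      ev_gene_status(e, "PTEN") %in% c("loss", "deep_deletion") ||
      (!is.na(pten_z) && pten_z < cfg$expr_z_low) ||
      ev_arm_is(e, "2q", "gain")
    if (beta) return(st_call(e, "MB, SHH beta", "beta_features", "molecular"))
    if (ev_arm_is(e, "2p", "gain"))
      return(st_call(e, "MB, SHH gamma", "gamma_2p_gain", "molecular"))
  }
  if (!is.na(age) && age >= cfg$shh_delta_min_age) {
    delta <- ev_lof(e, c("DDX3X", "SMO"), cfg) ||
      ev_variant(e, genes = "TERT", hotspot = TRUE) || e$u1_snrna_hotspot ||
      ev_arm_is(e, "14q", "loss")
    if (delta) return(st_call(e, "MB, SHH delta", "delta_features", "molecular"))
  }
  st_call(e, "MB, SHH", "shh_unsubgrouped", "fallback")
}

#' Pineoblastoma subtyping
#'
#' High-confidence methylation classes map through
#' `extdata/pb_methyl_map.tsv` (PB_FOXR2, PB_RB1, PB_GRP1A/B, PB_GRP2);
#' otherwise "PB, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble.
#' @export
subtype_pb <- function(e, cfg = rule_config()) {
  map <- read_label_map("pb_methyl_map.tsv")
  hit <- high_conf_methyl(e$methylation, map$subclass, cfg)
  if (nrow(hit)) {
    lbl <- map$label[match(hit$subclass, map$subclass)]
    return(st_call(e, lbl, "methylation_pb", "methylation_high_conf"))
  }
  st_call(e, "PB, To be classified", "", "fallback")
}

#' Embryonal tumor with multilayered rosettes subtyping
#'
#' "ETMR, C19MC-altered" on a high-confidence ETMR_C19MC methylation
#' class, or a TTYH1 fusion together with chromosome 19 amplification or
#' LIN28A over-expression; "ETMR, NOS" on LIN28A over-expression without a
#' TTYH1 fusion; otherwise no ETMR call (`NULL`).
#'
#' @inheritParams subtype_hgg
#' @return One-row subtype call tibble or `NULL`.
#' @export
subtype_etmr <- function(e, cfg = rule_config()) {
  ttyh1 <- ev_fusion(e, partner = "TTYH1")
  chr19_amp <- e$chr19_amplified || ev_arm_is(e, c("19p", "19q"), "gain")
  lin28a <- ev_overexpressed(e, "LIN28A", cfg)
  if (nrow(high_conf_methyl(e$methylation, "ETMR_C19MC", cfg)) ||
      (ttyh1 && (chr19_amp || lin28a))) {
    return(st_call(e, "ETMR, C19MC-altered", "c19mc_evidence", "molecular"))
  }
  if (lin28a && !ttyh1) {
    return(st_call(e, "ETMR, NOS", "lin28a_no_ttyh1", "molecular"))
  }
  NULL
}
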