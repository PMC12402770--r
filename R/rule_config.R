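#' Pipeline rule configuration
#'
#' Every numeric threshold and label list used across the pipeline lives in
#' one versioned configuration object, so that the calling rules are
#' auditable and overridable in a single place. Defaults reflect the
#' OpenPedCan-style consensus and subtyping conventions:
#'
#' * consensus SNV: a variant is retained when called by at least
#'   `min_callers_consensus` callers, or flagged as a hotspot allele;
#'   non-hotspot likely-germline calls with normal depth <= 7 **and**
#'   gnomAD allele frequency > 0.001 are removed; tumor-only calls need
#'   `t_alt_count > 0` and `t_depth >= 4`.
#' * consensus CNV: per-sample caller files with more than 2,500 segments
#'   are dropped as noise; segment pairs need >= 50% reciprocal overlap (or
#'   >= 90% containment); same-direction regions within 10 kb are merged;
#'   regions shorter than 3 kb or >= 50% inside blacklist regions are
#'   filtered.
#' * methylation classifier calls are "high confidence" at score >= 0.8;
#'   MYCN RNA over-expression calls use TPM >= 140.83; TP53 inactivation
#'   classifier calls use score > 0.5; "over-expressed" means a cohort
#'   z-score of log2(TPM+1) >= 2.
#'
#' @param ... Named overrides for any default field.
#'
#' @return A list of class `pedcan_config`.
#' @examples
#' cfg <- rule_config()
#' cfg$min_callers_consensus
#' rule_config(cnv_merge_gap_bp = 5000)$cnv_merge_gap_bp
#' @export
rule_config <- function(...) {
  cfg <- list(
    # consensus SNV
    min_callers_consensus = 2L,
    germline_max_n_depth  = 7L,
    germline_min_gnomad_af = 0.001,
    tumor_only_min_t_depth = 4L,
    caller_precedence = c("strelka2", "mutect2", "lancet", "vardict"),
    # consensus CNV
    cnv_denoise_max       = 2500L,
    cnv_reciprocal_min    = 0.50,
    cnv_containment_min   = 0.90,
    cnv_merge_gap_bp      = 10000L,
    cnv_min_len_bp        = 3000L,
    cnv_blacklist_overlap = 0.50,
    # focal CN
    ploidy                = 2L,
    amplification_gain_over_ploidy = 3L,  # CN >= ploidy + 3 -> amplification
    arm_coverage_min      = 0.5,
    # subtyping / classifier thresholds
    methyl_high_confidence = 0.8,
    mycn_tpm_cutoff        = 140.83,
    tp53_classifier_cutoff = 0.5,
    expr_z_high            = 2.0,
    expr_z_low             = -2.0,
    shh_alpha_min_age      = 2,
    shh_beta_gamma_max_age = 5,
    shh_delta_min_age      = 10,
    # fusion prioritization
    fusion_recurrent_min   = 3L,
    rna_fusion_callers     = c("arriba", "starfusion"),
    # TMB
    tmb_scale = 1e6,
    nonsyn_classes = c(
      "Missense_Mutation", "Frame_Shift_Del", "In_Frame_Ins",
      "Frame_Shift_Ins", "Splice_Site", "Nonsense_Mutation",
      "In_Frame_Del", "Nonstop_Mutation", "Translation_Start_Site"
    ),
    nonsynfilter_focr = c(
      "Missense_Mutation", "Frame_Shift_Del", "In_Frame_Ins",
      "Frame_Shift_Ins", "Splice_Site", "Nonsense_Mutation",
      "In_Frame_Del", "Nonstop_Mutation", "Translation_Start_Site",
      "Splice_Region"
    ),
    lof_classes = c(
      "Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del",
      "Splice_Site", "Translation_Start_Site"
    )
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown or unnamed config field(s): ",
                   paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  stopifnot(
    cfg$min_callers_consensus >= 1, cfg$cnv_denoise_max > 0,
    cfg$cnv_reciprocal_min > 0, cfg$cnv_containment_min > 0,
    cfg$cnv_merge_gap_bp >= 0, cfg$cnv_min_len_bp > 0,
    cfg$tmb_scale > 0, length(cfg$nonsyn_classes) > 0
  )
  structure(cfg, class = c("pedcan_config", "list"))
}

#' Map integer copy number to a categorical CNV status
#'
#' The callers report integer copy number; category boundaries are not part
#' of the upstream file formats, so they are an explicit configuration
#' choice: CN 0 is a deep deletion, CN below ploidy a loss, CN equal to
#' ploidy neutral, CN above ploidy but below ploidy + 3 a gain, and CN at
#' or above ploidy + 3 an amplification.
#'
#' @param copy_number Integer vector (NA allowed).
#' @param cfg A [rule_config()] object (fields `ploidy`,
#'   `amplification_gain_over_ploidy`).
#' @return Character vector of statuses in
#'   `c("deep_deletion", "loss", "neutral", "gain", "amplification")`,
#'   NA where `copy_number` is NA.
#' @examples
#' cn_status(c(0, 1, 2, 3, 5, NA))
#' @export
cn_status <- function(copy_number, cfg = rule_config()) {
  p <- cfg$ploidy
  amp <- p + cfg$amplification_gain_over_ploidy
  dplyr::case_when(
    is.na(copy_number) ~ NA_character_,
    copy_number == 0 ~ "deep_deletion",
    copy_number < p ~ "loss",
    copy_number == p ~ "neutral",
    copy_number >= amp ~ "amplification",
    TRUE ~ "gain"
  )
}

#' @export
print.pedcan_config <- function(x, ...) {
  cat("<pedcan_config> ", length(x), " fields\n", sep = "")
  scalars <- x[vapply(x, function(v) length(v) == 1 && !is.list(v), logical(1))]
  for (nm in names(scalars)) cat("  ", nm, ": ", format(scalars[[nm]]), "\n", sep = "")
  invisible(x)
}
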