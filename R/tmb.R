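#' Prepare a consensus MAF for TMB calculation
#'
#' Multinucleotide variants are decomposed into their constituent SNVs
#' (positions where the ref and alt base coincide are skipped), merged back
#' with the SNV subset, and sample-level redundant calls — identical
#' (chrom, pos, ref, alt) within a sample — are removed.
#'
#' @param consensus Consensus variant tibble.
#' @return Variant tibble of unique per-sample SNVs.
#' @examples
#' prepare_snv_input(tibble::tibble(
#'   sample_id = "BS_1", chrom = "chr1", pos = 100L, ref = "CG", alt = "AT",
#'   variant_classification = "Missense_Mutation"))
#' @export
prepare_snv_input <- function(consensus) {
  mnv <- filter(consensus, is_mnp(.data$ref, .data$alt))
  snv <- filter(consensus, !is_mnp(.data$ref, .data$alt))
  if (nrow(mnv) > 0) {
    split_rows <- map_dfr(seq_len(nrow(mnv)), function(i) {
      m <- mnv[i, ]
      refs <- strsplit(m$ref, "")[[1]]
      alts <- strsplit(m$alt, "")[[1]]
      keep <- refs != alts
      if (!any(keep)) return(NULL)
      out <- m[rep(1, sum(keep)), ]
      out$pos <- m$pos + which(keep) - 1L
      out$ref <- refs[keep]
      out$alt <- alts[keep]
      out
    })
    snv <- bind_rows(snv, split_rows)
  }
  snv |>
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Active nonsynonymous consequence-class list
#'
#' `"default"` returns the nine high/moderate-consequence classes counted
#' in the TMB numerator; `"focr"` returns the alternate list following the
#' TMB harmonization convention (`cfg$nonsynfilter_focr`).
#'
#' @param mode `"default"` or `"focr"`.
#' @param cfg A [rule_config()].
#' @return Character vector of variant classifications.
#' @export
select_nonsyn_filter <- function(mode = c("default", "focr"),
                                 cfg = rule_config()) {
  mode <- match.arg(mode)
  if (mode == "default") cfg$nonsyn_classes else cfg$nonsynfilter_focr
}

tmb_denominator <- function(surveyed, strategy) {
  if (is.data.frame(surveyed)) surveyed <- list(surveyed)
  if (length(surveyed) == 0) abort("tmb: no surveyed region sets supplied")
  if (strategy == "WGS" && length(surveyed) > 1) {
    Reduce(interval_intersect, surveyed)
  } else {
    # WXS: the capture BED itself (a single set is expected)
    normalize_intervals(surveyed[[1]])
  }
}

#' Tumor mutation burden (all-mutation and coding-only)
#'
#' For each sample, the all-mutation TMB is the number of nonsynonymous
#' consensus mutations divided by the effectively surveyed genome size:
#' for WGS the intersection of the supplied per-caller surveyed-region
#' files, for WXS the capture BED. The coding-only TMB restricts both the
#' numerator (mutations inside the coding sequence intersected with the
#' surveyed region) and the denominator (the length of that intersection).
#' Both are scaled by `cfg$tmb_scale` (per-megabase by default).
#'
#' @param consensus Consensus variant tibble, already passed through
#'   [prepare_snv_input()] (applied internally otherwise).
#' @param surveyed Interval tibble or list of interval tibbles: per-caller
#'   effectively-surveyed regions (WGS) or the capture BED (WXS).
#' @param cds Interval tibble of coding sequence regions; `NULL` skips the
#'   coding-only computation.
#' @param strategy `"WGS"` or `"WXS"`.
#' @param nonsyn_mode Passed to [select_nonsyn_filter()].
#' @param cfg A [rule_config()].
#' @param samples Optional sample ids to report (zero counts included);
#'   defaults to samples present in `consensus`.
#' @return Tibble with one row per sample: `sample_id`, `strategy`,
#'   `n_all`, `denom_all_bp`, `tmb_all`, and when `cds` is given
#'   `n_coding`, `denom_coding_bp`, `tmb_coding`.
#' @examples
#' maf <- tibble::tibble(sample_id = "BS_1", chrom = "chr1",
#'   pos = c(100L, 200L), ref = "C", alt = "T",
#'   variant_classification = "Missense_Mutation")
#' calculate_tmb(maf, genome_intervals("chr1", 0, 1e6), strategy = "WGS")
#' @export
calculate_tmb <- function(consensus, surveyed, cds = NULL,
                          strategy = c("WGS", "WXS"),
                          nonsyn_mode = "default", cfg = rule_config(),
                          samples = NULL) {
  strategy <- match.arg(strategy)
  consensus <- prepare_snv_input(consensus)
  classes <- select_nonsyn_filter(nonsyn_mode, cfg)
  samples <- samples %||% sort(unique(consensus$sample_id))
  denom_all <- tmb_denominator(surveyed, strategy)
  L_all <- interval_length(denom_all)
  if (L_all <= 0) abort("tmb: zero-length surveyed region denominator")
  nonsyn <- filter(consensus, .data$variant_classification %in% classes)
  out <- tibble(sample_id = samples, strategy = strategy) |>
    left_join(count(nonsyn, .data$sample_id, name = "n_all"),
              by = "sample_id") |>
    mutate(n_all = dplyr::coalesce(.data$n_all, 0L),
           denom_all_bp = L_all,
           tmb_all = .data$n_all / .data$denom_all_bp * cfg$tmb_scale)
  if (!is.null(cds)) {
    denom_coding <- interval_intersect(denom_all, cds)
    L_cod <- interval_length(denom_coding)
    if (L_cod <= 0) abort("tmb: zero-length coding denominator (CDS disjoint from surveyed regions)")
    coding <- nonsyn[in_intervals(nonsyn$chrom, nonsyn$pos, denom_coding), ]
    out <- out |>
      left_join(count(coding, .data$sample_id, name = "n_coding"),
                by = "sample_id") |>
      mutate(n_coding = dplyr::coalesce(.data$n_coding, 0L),
             denom_coding_bp = L_cod,
             tmb_coding = .data$n_coding / .data$denom_coding_bp * cfg$tmb_scale)
  }
  out
}
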