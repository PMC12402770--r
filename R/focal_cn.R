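region_status <- function(regions, cfg) {
  # derive a categorical status for a consensus region: copy number when
  # known, otherwise the direction label
  if ("status" %in% names(regions)) return(regions$status)
  ifelse(is.na(regions$copy_number), regions$direction,
         cn_status(regions$copy_number, cfg))
}

#' Gene-level copy-number status from consensus regions
#'
#' Projects consensus CNV regions onto gene models and resolves conflicting
#' per-gene calls to exactly one status per (gene, sample): (i) non-neutral
#' calls take precedence over neutral ones; (ii) among those, the dominant
#' segment is the one with the largest base-pair overlap with the gene;
#' (iii) when the overlap ties, amplification beats gain and deep deletion
#' beats loss, then the longer segment, then the leftmost start. Genes
#' overlapped by no region are neutral.
#'
#' @param regions Consensus region tibble (1-based inclusive) with either a
#'   `status` column or `direction`/`copy_number` to derive one.
#' @param gene_models Tibble `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive spans).
#' @param samples Optional character vector of sample ids for which a full
#'   gene matrix (including all-neutral samples) is wanted; defaults to the
#'   samples present in `regions`.
#' @param cfg A [rule_config()].
#' @return Tibble `gene`, `sample_id`, `status`, `overlap_fraction` with
#'   exactly one row per (gene, sample).
#' @export
assign_gene_status <- function(regions, gene_models, samples = NULL,
                               cfg = rule_config()) {
  if (nrow(gene_models) == 0) abort("assign_gene_status: empty gene models")
  samples <- samples %||% unique(regions$sample_id)
  base <- tidyr::expand_grid(gene = gene_models$gene, sample_id = samples) |>
    left_join(gene_models, by = "gene")
  if (nrow(regions) > 0) {
    regions <- mutate(regions, .status = region_status(regions, cfg),
                      .seg_len = seg_len(.data$start, .data$end))
    hits <- inner_join(
      base,
      select(regions, "sample_id", seg_chrom = "chrom", seg_start = "start",
             seg_end = "end", ".status", ".seg_len"),
      by = "sample_id", relationship = "many-to-many"
    ) |>
      filter(.data$chrom == .data$seg_chrom) |>
      mutate(overlap = pmax(0, pmin(.data$end, .data$seg_end) -
                              pmax(.data$start, .data$seg_start) + 1)) |>
      filter(.data$overlap > 0)
  } else {
    hits <- tibble(gene = character(), sample_id = character())
  }
  rank_status <- c(amplification = 1, deep_deletion = 1, gain = 2, loss = 2,
                   neutral = 3)
  resolved <- if (nrow(hits) > 0) {
    hits |>
      group_by(.data$gene, .data$sample_id) |>
      group_modify(function(df, key) {
        nn <- filter(df, .data$.status != "neutral")
        cand <- if (nrow(nn) > 0) nn else df
        cand <- arrange(cand, desc(.data$overlap), rank_status[.data$.status],
                        desc(.data$.seg_len), .data$seg_start)
        tibble(status = cand$.status[1],
               overlap_fraction = cand$overlap[1] /
                 seg_len(df$start[1], df$end[1]))
      }) |>
      ungroup()
  } else {
    tibble(gene = character(), sample_id = character(),
           status = character(), overlap_fraction = numeric())
  }
  base |>
    select("gene", "sample_id") |>
    left_join(resolved, by = c("gene", "sample_id")) |>
    mutate(status = dplyr::coalesce(.data$status, "neutral"),
           overlap_fraction = dplyr::coalesce(.data$overlap_fraction, 0)) |>
    arrange(.data$gene, .data$sample_id)
}

#' Chromosome-arm copy-number status
#'
#' An arm is labeled gained (lost) when same-direction consensus regions
#' cover at least `cfg$arm_coverage_min` (default 0.5) of its span; when
#' both directions reach the threshold the larger coverage wins and an
#' exact tie is neutral.
#'
#' @param regions Consensus region tibble with a `direction` column.
#' @param arm_models Tibble `arm`, `chrom`, `start`, `end` (1-based
#'   inclusive spans, e.g. from a cytoband table).
#' @param samples Optional sample ids for a complete matrix.
#' @param cfg A [rule_config()].
#' @return Tibble `sample_id`, `arm`, `status`, `covered_fraction`.
#' @export
arm_status <- function(regions, arm_models, samples = NULL,
                       cfg = rule_config()) {
  samples <- samples %||% unique(regions$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, arm = arm_models$arm) |>
    left_join(arm_models, by = "arm")
  cover <- function(s, ch, a0, a1, dir) {
    r <- filter(regions, .data$sample_id == s, .data$chrom == ch,
                .data$direction == dir)
    if (nrow(r) == 0) return(0)
    ov <- interval_intersect(
      tibble(chrom = ch, start = r$start - 1L, end = r$end),
      tibble(chrom = ch, start = a0 - 1L, end = a1))
    interval_length(ov) / seg_len(a0, a1)
  }
  grid |>
    rowwise() |>
    mutate(gain_frac = cover(.data$sample_id, .data$chrom, .data$start,
                             .data$end, "gain"),
           loss_frac = cover(.data$sample_id, .data$chrom, .data$start,
                             .data$end, "loss")) |>
    ungroup() |>
    mutate(
      status = dplyr::case_when(
        gain_frac >= cfg$arm_coverage_min & gain_frac > loss_frac ~ "gain",
        loss_frac >= cfg$arm_coverage_min & loss_frac > gain_frac ~ "loss",
        TRUE ~ "neutral"
      ),
      covered_fraction = pmax(.data$gain_frac, .data$loss_frac)
    ) |>
    select("sample_id", "arm", "status", "covered_fraction") |>
    arrange(.data$sample_id, .data$arm)
}
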