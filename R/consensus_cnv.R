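seg_len <- function(start, end) end - start + 1

seg_direction <- function(status) {
  dplyr::case_when(
    status %in% c("gain", "amplification") ~ "gain",
    status %in% c("loss", "deep_deletion") ~ "loss",
    TRUE ~ NA_character_
  )
}

#' Drop noisy per-caller CNV segment sets
#'
#' A caller's segment file for a sample carrying more than
#' `cfg$cnv_denoise_max` (2,500) CNVs is treated as noise and removed
#' wholesale; at or below the threshold it passes unchanged.
#'
#' @param segments Segment tibble for one (sample, caller) pair, or a
#'   pooled tibble with `sample_id` and `caller` columns (each pair is
#'   assessed independently).
#' @param cfg A [rule_config()].
#' @return Segment tibble with noisy (sample, caller) sets removed.
#' @export
denoise_caller_set <- function(segments, cfg = rule_config()) {
  if (nrow(segments) == 0) return(segments)
  grp <- if (all(c("sample_id", "caller") %in% names(segments))) {
    paste(segments$sample_id, segments$caller)
  } else rep("all", nrow(segments))
  counts <- table(grp)
  keep <- grp %in% names(counts)[counts <= cfg$cnv_denoise_max]
  segments[keep, , drop = FALSE]
}

#' Reciprocal overlap between two segments
#'
#' Overlap length divided by each segment's own length; both fractions
#' must reach the consensus threshold for a reciprocal-overlap match.
#' Coordinates are 1-based inclusive.
#'
#' @param a,b Single-row segment tibbles (or lists) with `chrom`, `start`,
#'   `end` on the same chromosome.
#' @return Named numeric vector `c(frac_a, frac_b)`; both 0 when disjoint.
#' @examples
#' reciprocal_overlap(list(chrom = "chr1", start = 1001, end = 2000),
#'                    list(chrom = "chr1", start = 1501, end = 2500))
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) abort("reciprocal_overlap: segments on different chromosomes")
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
  c(frac_a = ov / seg_len(a$start, a$end), frac_b = ov / seg_len(b$start, b$end))
}

pool_union_regions <- function(regions) {
  # union overlapping same-direction spans, union their supporters
  if (nrow(regions) == 0) return(regions)
  regions |>
    group_by(.data$sample_id, .data$chrom, .data$direction) |>
    group_modify(function(df, key) {
      ir <- IRanges::IRanges(df$start, df$end)
      red <- IRanges::reduce(ir, with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      tibble(
        start = IRanges::start(red), end = IRanges::end(red),
        supporting_callers = vapply(seq_along(red), function(i) {
          paste(sort(unique(unlist(strsplit(
            df$supporting_callers[revmap[[i]]], ",")))), collapse = ",")
        }, character(1)),
        copy_number = vapply(seq_along(red), function(i) {
          cns <- df$copy_number[revmap[[i]]]
          if (anyNA(cns) || length(unique(cns)) != 1) NA_integer_ else cns[1]
        }, integer(1))
      )
    }) |>
    ungroup()
}

#' Consensus CNV regions from multiple callers
#'
#' For each sample, a region enters the consensus when (i) two segments
#' from different callers with the same direction (gain or loss) overlap
#' reciprocally by at least `cfg$cnv_reciprocal_min` (50%) — the
#' intersected span is emitted — or (ii) a segment is covered for at least
#' `cfg$cnv_containment_min` (90%) of its length by another caller's
#' same-direction segments — the contained segment's own span is emitted.
#' Pair-wise matches across all caller pairs are pooled and overlapping
#' same-direction spans are unioned. The consensus copy number is the
#' callers' agreed value, `NA` when the supporters disagree or any
#' underlying call is neutral.
#'
#' @param by_caller Named list of segment tibbles (one per caller) for one
#'   or more samples.
#' @param cfg A [rule_config()].
#' @return Tibble of consensus regions: `sample_id`, `chrom`, `start`,
#'   `end`, `direction`, `supporting_callers`, `copy_number`.
#' @export
consensus_regions <- function(by_caller, cfg = rule_config()) {
  empty <- tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), direction = character(),
                  supporting_callers = character(), copy_number = integer())
  by_caller <- by_caller[vapply(by_caller, nrow, integer(1)) > 0]
  if (length(by_caller) < 2) {
    warn("consensus_regions: fewer than 2 caller sets available; empty consensus")
    return(empty)
  }
  pooled <- bind_rows(lapply(names(by_caller), function(cl) {
    mutate(as_tibble(by_caller[[cl]]), caller = cl,
           direction = seg_direction(.data$status))
  }))
  directed <- filter(pooled, !is.na(.data$direction))
  if (nrow(directed) == 0) return(empty)

  hits <- directed |>
    group_by(.data$sample_id, .data$chrom, .data$direction) |>
    group_modify(function(df, key) {
      callers <- unique(df$caller)
      if (length(callers) < 2) return(tibble())
      res <- list()
      # rule (i): pairwise reciprocal overlap >= threshold -> intersected span
      for (i in seq_len(nrow(df) - 1)) {
        for (j in seq((i + 1), nrow(df))) {
          if (df$caller[i] == df$caller[j]) next
          a <- df[i, ]; b <- df[j, ]
          ov <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
          ro <- c(ov / seg_len(a$start, a$end), ov / seg_len(b$start, b$end))
          if (all(ro >= cfg$cnv_reciprocal_min)) {
            cns <- c(a$copy_number, b$copy_number)
            neutral <- any(c(a$status, b$status) == "neutral")
            res[[length(res) + 1]] <- tibble(
              start = max(a$start, b$start), end = min(a$end, b$end),
              supporting_callers = paste(sort(c(a$caller, b$caller)), collapse = ","),
              copy_number = if (anyNA(cns) || neutral ||
                                length(unique(cns)) != 1) NA_integer_ else cns[1]
            )
          }
        }
      }
      # rule (ii): segment >= containment threshold covered by another
      # caller's same-direction segments -> the contained segment's span
      for (i in seq_len(nrow(df))) {
        a <- df[i, ]
        ir_a <- IRanges::IRanges(a$start, a$end)
        for (other in setdiff(callers, a$caller)) {
          cover <- df[df$caller == other, , drop = FALSE]
          if (nrow(cover) == 0) next
          ir_o <- IRanges::reduce(IRanges::IRanges(cover$start, cover$end))
          covered <- sum(IRanges::width(IRanges::intersect(ir_a, ir_o)))
          if (covered / seg_len(a$start, a$end) >= cfg$cnv_containment_min) {
            res[[length(res) + 1]] <- tibble(
              start = a$start, end = a$end,
              supporting_callers = paste(sort(c(a$caller, other)), collapse = ","),
              copy_number = if (is.na(a$copy_number) || a$status == "neutral")
                NA_integer_ else a$copy_number
            )
          }
        }
      }
      bind_rows(res)
    }) |>
    ungroup()
  if (nrow(hits) == 0) return(empty)
  pool_union_regions(hits) |>
    select("sample_id", "chrom", "start", "end", "direction",
           "supporting_callers", "copy_number") |>
    arrange(.data$sample_id, .data$chrom, .data$start, .data$direction)
}

#' Merge nearby same-direction consensus regions
#'
#' Consensus regions on the same chromosome with the same direction of
#' gain or loss lying within `cfg$cnv_merge_gap_bp` (10,000 bp) of each
#' other are merged into one spanning region; supporter sets are unioned
#' and disagreeing copy numbers become `NA`. Idempotent.
#'
#' @param regions Consensus region tibble.
#' @param cfg A [rule_config()].
#' @return Merged region tibble.
#' @export
merge_adjacent <- function(regions, cfg = rule_config()) {
  if (nrow(regions) == 0) return(regions)
  regions |>
    group_by(.data$sample_id, .data$chrom, .data$direction) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$start, .data$end)
      # widen by gap/2-ish trick is off-by-one prone; chain explicitly
      grp <- cumsum(c(1, (df$start[-1] - cummax(df$end[-nrow(df)]) - 1) >
                         cfg$cnv_merge_gap_bp))
      df |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(
          start = min(.data$start), end = max(.data$end),
          supporting_callers = paste(sort(unique(unlist(
            strsplit(.data$supporting_callers, ",")))), collapse = ","),
          copy_number = if (anyNA(.data$copy_number) ||
                            length(unique(.data$copy_number)) != 1)
            NA_integer_ else .data$copy_number[1],
          .groups = "drop"
        ) |>
        select(-any_of(".grp"))
    }) |>
    ungroup() |>
    select("sample_id", "chrom", "start", "end", "direction",
           "supporting_callers", "copy_number") |>
    arrange(.data$sample_id, .data$chrom, .data$start, .data$direction)
}

#' Filter consensus regions against a blacklist and a minimum length
#'
#' Regions shorter than `cfg$cnv_min_len_bp` (3,000 bp), or overlapping
#' blacklist intervals (immunoglobulin, telomeric, centromeric, segmental
#' duplication) for at least `cfg$cnv_blacklist_overlap` (50%) of their
#' length, are removed.
#'
#' @param regions Consensus region tibble (1-based inclusive).
#' @param blacklist Interval tibble (0-based half-open; see [read_bed()]).
#' @param cfg A [rule_config()].
#' @return Filtered region tibble.
#' @export
filter_regions <- function(regions, blacklist, cfg = rule_config()) {
  if (nrow(regions) == 0) return(regions)
  keep_len <- seg_len(regions$start, regions$end) >= cfg$cnv_min_len_bp
  bl_frac <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    ov <- interval_intersect(
      tibble(chrom = r$chrom, start = r$start - 1L, end = r$end),
      blacklist)
    interval_length(ov) / seg_len(r$start, r$end)
  }, numeric(1))
  regions[keep_len & bl_frac < cfg$cnv_blacklist_overlap, , drop = FALSE]
}

#' Select the caller trio entering CNV consensus
#'
#' The consensus runs on Control-FREEC, CNVkit and GATK when a GATK panel
#' of normals could be built (>= 30 male and 30 female normals on the same
#' platform); otherwise structural-variant-derived MantaSV calls stand in
#' for GATK.
#'
#' @param by_caller Named list of segment tibbles, possibly including
#'   `gatk` and/or `mantasv`.
#' @param has_gatk_pon Logical; is a GATK panel of normals available?
#' @return `by_caller` restricted to the active trio.
#' @export
apply_manta_fallback <- function(by_caller, has_gatk_pon) {
  want <- if (has_gatk_pon) c("controlfreec", "cnvkit", "gatk")
          else c("controlfreec", "cnvkit", "mantasv")
  missing_callers <- setdiff(want, names(by_caller))
  if (length(missing_callers)) {
    abort(paste0("caller set(s) unavailable for CNV consensus: ",
                 paste(missing_callers, collapse = ", ")))
  }
  by_caller[want]
}

#' End-to-end consensus CNV pipeline
#'
#' Chains denoising, caller-trio selection, pairwise consensus, adjacent
#' merging and blacklist/length filtering. Segments from WXS samples
#' (single-caller CNVkit) bypass the consensus and are appended unchanged.
#'
#' @param by_caller Named list of per-caller WGS segment tibbles.
#' @param blacklist Interval tibble of excluded regions.
#' @param has_gatk_pon Logical, see [apply_manta_fallback()].
#' @param wxs_segments Optional CNVkit segment tibble for WXS samples,
#'   appended as-is (with `supporting_callers = "cnvkit"`).
#' @param cfg A [rule_config()].
#' @return Consensus region tibble.
#' @export
consensus_cnv <- function(by_caller, blacklist, has_gatk_pon = TRUE,
                          wxs_segments = NULL, cfg = rule_config()) {
  trio <- apply_manta_fallback(by_caller, has_gatk_pon)
  trio <- lapply(names(trio), function(cl) {
    denoise_caller_set(mutate(trio[[cl]], caller = cl), cfg) |> select(-"caller")
  }) |> setNames(names(trio))
  out <- consensus_regions(trio, cfg) |>
    merge_adjacent(cfg) |>
    filter_regions(blacklist, cfg)
  if (!is.null(wxs_segments) && nrow(wxs_segments) > 0) {
    wxs <- wxs_segments |>
      mutate(direction = seg_direction(.data$status),
             supporting_callers = "cnvkit") |>
      filter(!is.na(.data$direction)) |>
      select("sample_id", "chrom", "start", "end", "direction",
             "supporting_callers", "copy_number")
    out <- bind_rows(out, wxs)
  }
  arrange(out, .data$sample_id, .data$chrom, .data$start, .data$direction)
}
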