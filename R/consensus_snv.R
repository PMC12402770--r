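variant_key <- function(x) {
  paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt, sep = "\r")
}

is_mnp <- function(ref, alt) {
  nchar(ref) == nchar(alt) & nchar(ref) > 1L &
    !grepl("-", ref, fixed = TRUE) & !grepl("-", alt, fixed = TRUE)
}

#' Reconstruct multinucleotide variants in a caller's SNV-only output
#'
#' Some callers report a multinucleotide polymorphism (MNP) as a run of
#' consecutive SNVs. To preserve the predicted protein change, MNP records
#' from the other callers are used as templates: wherever another caller
#' reports an MNP at positions `p..p+k` and the SNV-only caller reports
#' single-base substitutions at exactly those positions whose concatenated
#' ref/alt alleles equal the MNP alleles, those SNVs are collapsed into one
#' MNP record (flagged `mnp_reconstructed`). Overlapping but
#' allele-inconsistent evidence is left untouched with a warning. All other
#' records pass through unchanged.
#'
#' @param snv_calls Variant tibble (the SNV-only caller, e.g. Strelka2).
#' @param other_calls Variant tibble(s) from callers that emit MNPs.
#' @return The `snv_calls` tibble with matching runs collapsed and a
#'   logical `mnp_reconstructed` column.
#' @examples
#' s <- tibble::tibble(sample_id = "BS_1", chrom = "chr1",
#'   pos = c(100L, 101L), ref = c("C", "G"), alt = c("A", "T"),
#'   hugo_symbol = "X", t_depth = 50L, t_alt_count = 20L,
#'   n_depth = 40L, gnomad_af = NA_real_, hotspot = FALSE,
#'   variant_classification = "Missense_Mutation", hgvsp_short = NA_character_)
#' m <- dplyr::mutate(s[1, ], ref = "CG", alt = "AT")
#' reconstruct_mnps(s, m)
#' @export
reconstruct_mnps <- function(snv_calls, other_calls) {
  out <- mutate(snv_calls, mnp_reconstructed = FALSE)
  mnps <- filter(other_calls, is_mnp(.data$ref, .data$alt)) |>
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .keep_all = TRUE)
  if (nrow(mnps) == 0 || nrow(out) == 0) return(out)
  drop <- logical(nrow(out))
  add <- list()
  snv_idx <- which(nchar(out$ref) == 1L & nchar(out$alt) == 1L)
  lookup <- setNames(snv_idx, variant_key(out[snv_idx, , drop = FALSE]))
  for (i in seq_len(nrow(mnps))) {
    m <- mnps[i, ]
    k <- nchar(m$ref)
    want <- paste(m$sample_id, m$chrom, m$pos + seq_len(k) - 1L,
                  strsplit(m$ref, "")[[1]], strsplit(m$alt, "")[[1]], sep = "\r")
    idx <- lookup[want]
    if (all(!is.na(idx))) {
      if (any(drop[idx])) next  # already consumed by another template
      drop[idx] <- TRUE
      rec <- out[idx[1], ]
      rec$ref <- m$ref; rec$alt <- m$alt; rec$mnp_reconstructed <- TRUE
      add[[length(add) + 1]] <- rec
    } else if (any(!is.na(idx))) {
      # some positions have SNV evidence at this locus but alleles don't
      # concatenate to the template: inconsistent, leave unmerged
      here <- filter(out[snv_idx, , drop = FALSE],
                     .data$sample_id == m$sample_id, .data$chrom == m$chrom,
                     .data$pos >= m$pos, .data$pos < m$pos + k)
      if (nrow(here) > 0) {
        warn(paste0("MNP evidence at ", m$chrom, ":", m$pos,
                    " is allele-inconsistent with SNV calls; not merged"))
      }
    }
  }
  bind_rows(out[!drop, , drop = FALSE], bind_rows(add)) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Multi-caller consensus somatic SNV calling
#'
#' A variant (keyed by sample, chromosome, position, ref, alt) is retained
#' when it is detected by at least `cfg$min_callers_consensus` callers
#' (default 2 of the 4: Strelka2, Mutect2, Lancet, VarDict) or is flagged
#' as a hotspot allele by any caller; hotspot-only calls are marked
#' `hotspot_rescued`. Numeric fields of the consensus record are taken
#' from the highest-precedence reporting caller
#' (`cfg$caller_precedence`). Output is sorted by sample, chromosome,
#' position and alternate allele so repeated runs are byte-identical.
#'
#' @param calls_by_caller Named list of variant tibbles, one per caller, or
#'   a single tibble with a `caller` column. MNP reconstruction
#'   ([reconstruct_mnps()]) is assumed to have been applied already.
#' @param cfg A [rule_config()].
#' @return A consensus tibble with `caller_support` (comma-separated),
#'   `n_callers` and `hotspot_rescued` columns.
#' @export
call_consensus <- function(calls_by_caller, cfg = rule_config()) {
  if (is.data.frame(calls_by_caller)) {
    pooled <- as_tibble(calls_by_caller)
    if (!"caller" %in% names(pooled)) abort("single-table input needs a caller column")
  } else {
    pooled <- bind_rows(lapply(names(calls_by_caller), function(cl) {
      mutate(as_tibble(calls_by_caller[[cl]]), caller = cl)
    }))
  }
  if (nrow(pooled) == 0) {
    return(mutate(pooled, caller_support = character(), n_callers = integer(),
                  hotspot_rescued = logical()))
  }
  prec <- match(pooled$caller, cfg$caller_precedence)
  prec[is.na(prec)] <- length(cfg$caller_precedence) + 1L
  pooled$.prec <- prec
  pooled |>
    group_by(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$.prec, .by_group = TRUE) |>
    summarise(
      caller_support = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = n_distinct(.data$caller),
      hotspot = any(.data$hotspot, na.rm = TRUE),
      across(any_of(c("hugo_symbol", "t_depth", "t_alt_count", "n_depth",
                      "gnomad_af", "variant_classification", "hgvsp_short",
                      "mnp_reconstructed")),
             ~ .x[1]),
      .groups = "drop"
    ) |>
    filter(.data$n_callers >= cfg$min_callers_consensus | .data$hotspot) |>
    mutate(hotspot_rescued = .data$hotspot &
             .data$n_callers < cfg$min_callers_consensus) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

#' Remove likely-germline variants from a consensus set
#'
#' Non-hotspot calls with normal depth <= `cfg$germline_max_n_depth` (7)
#' **and** gnomAD allele frequency > `cfg$germline_min_gnomad_af` (0.001)
#' are removed: shallow normal coverage cannot rule out a germline origin
#' and a non-negligible population frequency makes one likely. Both
#' conditions must hold. A missing gnomAD frequency is treated as 0 (the
#' variant is kept); hotspot calls are never removed here.
#'
#' @param consensus Consensus tibble from [call_consensus()].
#' @param cfg A [rule_config()].
#' @return Filtered consensus tibble.
#' @export
filter_germline <- function(consensus, cfg = rule_config()) {
  af <- dplyr::coalesce(consensus$gnomad_af, 0)
  germline <- !consensus$hotspot &
    !is.na(consensus$n_depth) & consensus$n_depth <= cfg$germline_max_n_depth &
    af > cfg$germline_min_gnomad_af
  consensus[!germline, , drop = FALSE]
}

#' Depth filter for tumor-only variant calls
#'
#' Without a matched normal, calls with no supporting alternate reads
#' (`t_alt_count == 0`) or total depth below
#' `cfg$tumor_only_min_t_depth` (4) are removed.
#'
#' @param calls Variant tibble of tumor-only records.
#' @param cfg A [rule_config()].
#' @return Filtered tibble.
#' @export
filter_tumor_only <- function(calls, cfg = rule_config()) {
  bad <- dplyr::coalesce(calls$t_alt_count, 0L) == 0L |
    dplyr::coalesce(calls$t_depth, 0L) < cfg$tumor_only_min_t_depth
  calls[!bad, , drop = FALSE]
}

#' End-to-end consensus SNV pipeline for matched tumor/normal cohorts
#'
#' Convenience wrapper chaining MNP reconstruction on the SNV-only caller,
#' multi-caller consensus, and the germline filter.
#'
#' @param calls_by_caller Named list of per-caller variant tibbles; the
#'   `strelka2` element (if present) undergoes MNP reconstruction against
#'   the other callers first.
#' @param cfg A [rule_config()].
#' @return Consensus tibble.
#' @export
consensus_snv <- function(calls_by_caller, cfg = rule_config()) {
  if ("strelka2" %in% names(calls_by_caller)) {
    others <- bind_rows(calls_by_caller[setdiff(names(calls_by_caller), "strelka2")])
    calls_by_caller$strelka2 <-
      reconstruct_mnps(calls_by_caller$strelka2, others)
  }
  call_consensus(calls_by_caller, cfg) |> filter_germline(cfg)
}
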