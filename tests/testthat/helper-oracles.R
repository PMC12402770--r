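# Brute-force oracles, deliberately independent of the package internals:
# per-base counting for interval arithmetic, set arithmetic for consensus
# calling, and a per-base voting implementation of the CNV consensus rules.

# per-base length of a 0-based half-open interval set (coords < 1e6)
brute_interval_length <- function(x) {
  total <- 0
  for (ch in unique(x$chrom)) {
    xi <- x[x$chrom == ch, ]
    covered <- logical(max(xi$end))
    for (i in seq_len(nrow(xi))) covered[(xi$start[i] + 1):xi$end[i]] <- TRUE
    total <- total + sum(covered)
  }
  total
}

# per-base length of the intersection of two 0-based half-open sets
brute_intersect_length <- function(x, y) {
  total <- 0
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- x[x$chrom == ch, ]; yi <- y[y$chrom == ch, ]
    n <- max(xi$end, yi$end)
    cx <- logical(n); cy <- logical(n)
    for (i in seq_len(nrow(xi))) cx[(xi$start[i] + 1):xi$end[i]] <- TRUE
    for (i in seq_len(nrow(yi))) cy[(yi$start[i] + 1):yi$end[i]] <- TRUE
    total <- total + sum(cx & cy)
  }
  total
}

# set-based consensus SNV oracle: >= 2 distinct callers or any hotspot,
# then the non-hotspot germline removal (n_depth <= 7 AND gnomAD AF > 0.001)
oracle_consensus_keys <- function(calls_by_caller) {
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  pooled <- do.call(rbind, lapply(names(calls_by_caller), function(cl) {
    df <- as.data.frame(calls_by_caller[[cl]])
    df$caller <- cl
    df
  }))
  pooled$k <- key(pooled)
  supp <- tapply(pooled$caller, pooled$k, function(v) length(unique(v)))
  hot <- tapply(pooled$hotspot, pooled$k, any)
  keep <- names(supp)[supp >= 2 | hot[names(supp)]]
  # germline removal using fields from the highest-precedence caller
  prec <- c("strelka2", "mutect2", "lancet", "vardict")
  out <- character()
  for (k in keep) {
    rows <- pooled[pooled$k == k, ]
    rows <- rows[order(match(rows$caller, prec)), ]
    nd <- rows$n_depth[1]
    af <- rows$gnomad_af[1]
    if (is.na(af)) af <- 0
    hotk <- any(rows$hotspot)
    if (!hotk && !is.na(nd) && nd <= 7 && af > 0.001) next
    out <- c(out, k)
  }
  sort(out)
}

# per-base voting oracle for the CNV consensus rules (50% reciprocal
# overlap, 90% containment, 10 kb same-direction merge, 3 kb minimum
# length, 50% blacklist removal); 1-based inclusive segments, contigs <= 1e6
oracle_cnv_regions <- function(by_caller, blacklist, contig_len = 1e6) {
  dir_of <- function(s) {
    if (s %in% c("gain", "amplification")) "gain"
    else if (s %in% c("loss", "deep_deletion")) "loss"
    else NA_character_
  }
  pooled <- do.call(rbind, lapply(names(by_caller), function(cl) {
    df <- as.data.frame(by_caller[[cl]])
    df$caller <- cl
    df
  }))
  pooled$direction <- vapply(pooled$status, dir_of, character(1))
  pooled <- pooled[!is.na(pooled$direction), ]
  out <- NULL
  for (s in unique(pooled$sample_id)) {
    for (ch in unique(pooled$chrom[pooled$sample_id == s])) {
      bl <- logical(contig_len)
      bli <- blacklist[blacklist$chrom == ch, ]
      for (i in seq_len(nrow(bli))) bl[(bli$start[i] + 1):bli$end[i]] <- TRUE
      for (d in c("gain", "loss")) {
        segs <- pooled[pooled$sample_id == s & pooled$chrom == ch &
                         pooled$direction == d, ]
        if (nrow(segs) < 2) next
        mask <- logical(contig_len)
        vecs <- lapply(seq_len(nrow(segs)), function(i) {
          v <- logical(contig_len); v[segs$start[i]:segs$end[i]] <- TRUE; v
        })
        for (i in seq_len(nrow(segs))) {
          for (j in seq_len(nrow(segs))) {
            if (i >= j || segs$caller[i] == segs$caller[j]) next
            ov <- sum(vecs[[i]] & vecs[[j]])
            if (ov / sum(vecs[[i]]) >= 0.5 && ov / sum(vecs[[j]]) >= 0.5) {
              mask <- mask | (vecs[[i]] & vecs[[j]])
            }
          }
          # containment: union of every other caller's segments
          for (other in setdiff(unique(segs$caller), segs$caller[i])) {
            vo <- Reduce(`|`, vecs[segs$caller == other], logical(contig_len))
            if (sum(vecs[[i]] & vo) / sum(vecs[[i]]) >= 0.9) {
              mask <- mask | vecs[[i]]
            }
          }
        }
        if (!any(mask)) next
        r <- rle(mask)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        runs <- data.frame(start = starts[r$values], end = ends[r$values])
        # merge runs separated by <= 10 kb
        merged <- runs[1, ]
        for (i in seq_len(nrow(runs))[-1]) {
          if (runs$start[i] - merged$end[nrow(merged)] - 1 <= 10000) {
            merged$end[nrow(merged)] <- runs$end[i]
          } else merged <- rbind(merged, runs[i, ])
        }
        merged$len <- merged$end - merged$start + 1
        keep <- vapply(seq_len(nrow(merged)), function(i) {
          if (merged$len[i] < 3000) return(FALSE)
          sum(bl[merged$start[i]:merged$end[i]]) / merged$len[i] < 0.5
        }, logical(1))
        merged <- merged[keep, , drop = FALSE]
        if (nrow(merged) > 0) {
          out <- rbind(out, data.frame(sample_id = s, chrom = ch,
                                       start = merged$start, end = merged$end,
                                       direction = d))
        }
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$sample_id, out$chrom, out$start, out$direction), ]
}

# a minimal fully-populated variant row for building fixtures
make_variant <- function(sample_id = "BS_1", chrom = "chr1", pos = 100L,
                         ref = "C", alt = "A", t_depth = 80L,
                         t_alt_count = 30L, n_depth = 40L,
                         gnomad_af = NA_real_, hotspot = FALSE,
                         variant_classification = "Missense_Mutation",
                         hugo_symbol = "GENE", hgvsp_short = NA_character_) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, t_depth = as.integer(t_depth),
                 t_alt_count = as.integer(t_alt_count),
                 n_depth = as.integer(n_depth), gnomad_af = gnomad_af,
                 hotspot = hotspot,
                 variant_classification = variant_classification,
                 hugo_symbol = hugo_symbol, hgvsp_short = hgvsp_short)
}

make_segment <- function(sample_id = "BS_1", chrom = "chr1", start = 1L,
                         end = 1000L, copy_number = 4L, status = "gain") {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 copy_number = as.integer(copy_number), status = status)
}
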