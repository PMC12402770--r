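#' Genome interval sets
#'
#' Interval sets (surveyed regions, coding sequence, blacklists) are plain
#' tibbles with columns `chrom`, `start`, `end` in the BED convention:
#' 0-based, half-open, so a record `(chr1, 0, 100)` covers the first 100
#' bases. Variant and segment coordinates elsewhere in the package are
#' 1-based inclusive (MAF/SEG convention); conversion between the two
#' happens only at these boundaries.
#'
#' `genome_intervals()` validates and normalizes the chromosome naming;
#' `normalize_intervals()` additionally sorts and fuses overlapping or
#' abutting records so the set is canonical (the operation is idempotent).
#'
#' @param chrom Character chromosome names, with or without a "chr" prefix
#'   (normalized to the prefixed form).
#' @param start,end Integer 0-based half-open bounds, `0 <= start < end`.
#' @param name Optional label for the set.
#' @return A tibble with columns `chrom`, `start`, `end` (and attribute
#'   `name`).
#' @examples
#' genome_intervals("1", 0, 100)
#' interval_length(genome_intervals(c("chr1", "chr1"), c(0, 100), c(100, 200)))
#' @export
genome_intervals <- function(chrom, start, end, name = NULL) {
  x <- tibble(chrom = normalize_chrom(chrom),
              start = as.integer(start), end = as.integer(end))
  if (any(is.na(x$start) | is.na(x$end))) abort("non-integer interval bounds")
  if (any(x$start < 0)) abort("negative interval coordinates")
  if (any(x$end <= x$start)) abort("interval end must exceed start (0-based half-open)")
  if (!is.null(name)) attr(x, "name") <- name
  x
}

#' Normalize chromosome names to the "chr"-prefixed form
#' @param chrom Character vector.
#' @return Character vector with a "chr" prefix on every name.
#' @examples normalize_chrom(c("1", "chrX"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}

as_iranges_list <- function(x) {
  # 0-based half-open -> IRanges 1-based inclusive
  S4Vectors::split(
    IRanges::IRanges(start = x$start + 1L, end = x$end),
    factor(x$chrom, levels = unique(x$chrom))
  )
}

from_iranges_list <- function(rl) {
  chroms <- rep(names(rl), vapply(rl, length, integer(1)))
  flat <- do.call(c, unname(rl))
  tibble(chrom = chroms,
         start = IRanges::start(flat) - 1L,
         end   = IRanges::end(flat))
}

#' @rdname genome_intervals
#' @param x,y Interval tibbles as returned by [genome_intervals()].
#' @export
normalize_intervals <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  x <- genome_intervals(x$chrom, x$start, x$end)
  out <- from_iranges_list(lapply(as_iranges_list(x), IRanges::reduce))
  arrange(out, .data$chrom, .data$start)
}

#' @rdname genome_intervals
#' @export
interval_length <- function(x) {
  x <- normalize_intervals(x)
  sum(as.numeric(x$end - x$start))
}

#' @rdname genome_intervals
#' @export
interval_intersect <- function(x, y) {
  x <- normalize_intervals(x); y <- normalize_intervals(y)
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  chroms <- intersect(unique(x$chrom), unique(y$chrom))
  out <- map_dfr(chroms, function(ch) {
    xi <- as_iranges_list(filter(x, .data$chrom == ch))[[1]]
    yi <- as_iranges_list(filter(y, .data$chrom == ch))[[1]]
    hit <- IRanges::intersect(xi, yi)
    if (length(hit) == 0) return(NULL)
    tibble(chrom = ch, start = IRanges::start(hit) - 1L, end = IRanges::end(hit))
  })
  if (nrow(out) == 0) tibble(chrom = character(), start = integer(), end = integer())
  else arrange(out, .data$chrom, .data$start)
}

#' Test 1-based positions for membership in an interval set
#'
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions (the MAF convention).
#' @param intervals Interval tibble (0-based half-open).
#' @return Logical vector.
#' @examples
#' in_intervals("chr1", c(1, 100, 101), genome_intervals("chr1", 0, 100))
#' @export
in_intervals <- function(chrom, pos, intervals) {
  intervals <- normalize_intervals(intervals)
  chrom <- normalize_chrom(chrom)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- filter(intervals, .data$chrom == ch)
    idx <- which(chrom == ch)
    if (nrow(iv) == 0) next
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    out[idx] <- IRanges::countOverlaps(
      IRanges::IRanges(start = pos[idx], width = 1L), ir) > 0
  }
  out
}
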