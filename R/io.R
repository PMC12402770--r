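#' Read and write somatic variant tables (MAF)
#'
#' MAF files are tab-separated with `#`-prefixed comment lines and v2.4-style
#' column names. Internally the package uses snake-case column names and
#' 1-based positions: `hugo_symbol`, `chrom`, `pos`, `ref`, `alt`,
#' `t_depth`, `t_alt_count`, `n_depth`, `gnomad_af`, `hotspot`,
#' `variant_classification`, `hgvsp_short`, `sample_id`. Missing numeric
#' fields parse to `NA`, never to zero: an absent normal depth means "no
#' matched normal", which downstream filters must not confuse with depth 0.
#'
#' @param path File path.
#' @return `read_maf()`: a tibble of variant calls.
#' @examples
#' tf <- tempfile(fileext = ".maf")
#' write_maf(tibble::tibble(
#'   hugo_symbol = "TP53", chrom = "chr17", pos = 7675088L,
#'   ref = "C", alt = "T", t_depth = 100L, t_alt_count = 40L,
#'   n_depth = 60L, gnomad_af = NA_real_, hotspot = TRUE,
#'   variant_classification = "Missense_Mutation",
#'   hgvsp_short = "p.R273C", sample_id = "BS_1"), tf)
#' read_maf(tf)
#' @export
read_maf <- function(path) {
  maf_cols <- c(
    Hugo_Symbol = "hugo_symbol", Chromosome = "chrom",
    Start_Position = "pos", Reference_Allele = "ref",
    Tumor_Seq_Allele2 = "alt", t_depth = "t_depth",
    t_alt_count = "t_alt_count", n_depth = "n_depth",
    gnomAD_AF = "gnomad_af", HotSpotAllele = "hotspot",
    Variant_Classification = "variant_classification",
    HGVSp_Short = "hgvsp_short", Tumor_Sample_Barcode = "sample_id"
  )
  required <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2", "t_depth",
                "t_alt_count", "Variant_Classification",
                "Tumor_Sample_Barcode")
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         na = c("", "NA", "."), progress = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("MAF format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  present <- intersect(names(maf_cols), names(raw))
  out <- raw[present]
  names(out) <- maf_cols[present]
  for (nm in setdiff(unname(maf_cols), names(out))) out[[nm]] <- NA_character_
  out <- as_tibble(out)[unname(maf_cols)]
  parse_int <- function(v, col) {
    r <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(r))
    if (length(bad)) abort(paste0("MAF format error in column ", col,
                                  ": malformed value at data row ", bad[1]))
    r
  }
  out$pos <- parse_int(out$pos, "Start_Position")
  out$t_depth <- parse_int(out$t_depth, "t_depth")
  out$t_alt_count <- parse_int(out$t_alt_count, "t_alt_count")
  out$n_depth <- parse_int(out$n_depth, "n_depth")
  out$gnomad_af <- suppressWarnings(as.numeric(out$gnomad_af))
  out$hotspot <- !is.na(out$hotspot) & out$hotspot %in% c("TRUE", "True", "1", "Yes", "yes")
  out$chrom <- normalize_chrom(out$chrom)
  if (any(out$pos < 1, na.rm = TRUE)) abort("MAF format error: position < 1")
  bad_depth <- which(!is.na(out$t_depth) & !is.na(out$t_alt_count) &
                       out$t_depth < out$t_alt_count)
  if (length(bad_depth)) {
    abort(paste0("MAF format error: t_alt_count exceeds t_depth at data row ",
                 bad_depth[1]))
  }
  if (any(!is.na(out$gnomad_af) & (out$gnomad_af < 0 | out$gnomad_af > 1))) {
    abort("MAF format error: gnomad_af outside [0, 1]")
  }
  out
}

#' @rdname read_maf
#' @param x Tibble of variant calls with the internal column names.
#' @return `write_maf()`: `path`, invisibly.
#' @export
write_maf <- function(x, path) {
  out <- tibble(
    Hugo_Symbol = x$hugo_symbol, Chromosome = x$chrom,
    Start_Position = x$pos, Reference_Allele = x$ref,
    Tumor_Seq_Allele2 = x$alt, t_depth = x$t_depth,
    t_alt_count = x$t_alt_count, n_depth = x$n_depth,
    gnomAD_AF = x$gnomad_af, HotSpotAllele = x$hotspot,
    Variant_Classification = x$variant_classification,
    HGVSp_Short = x$hgvsp_short, Tumor_Sample_Barcode = x$sample_id
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write copy-number segment tables (SEG)
#'
#' SEG-style TSV with columns `ID`, `chrom`, `loc.start`, `loc.end` and a
#' copy number and/or status column. Coordinates are 1-based inclusive,
#' both in the file and internally. When the file carries copy numbers but
#' no status column, statuses are derived through the configured
#' copy-number mapping ([cn_status()]).
#'
#' @param path File path.
#' @param cfg A [rule_config()]; used only to derive missing statuses.
#' @return `read_seg()`: a tibble with `sample_id`, `chrom`, `start`,
#'   `end`, `copy_number`, `status`.
#' @examples
#' tf <- tempfile(fileext = ".seg")
#' write_seg(tibble::tibble(
#'   sample_id = "BS_1", chrom = "chr1", start = 1000L, end = 5000L,
#'   copy_number = 0L, status = "deep_deletion"), tf)
#' read_seg(tf)
#' @export
read_seg <- function(path, cfg = rule_config()) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  required <- c("ID", "chrom", "loc.start", "loc.end")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("SEG format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    sample_id = raw$ID,
    chrom = normalize_chrom(raw$chrom),
    start = as.integer(raw$`loc.start`),
    end = as.integer(raw$`loc.end`),
    copy_number = if ("copy.num" %in% names(raw))
      suppressWarnings(as.integer(raw$`copy.num`)) else NA_integer_,
    status = if ("status" %in% names(raw)) raw$status else NA_character_
  )
  bad <- which(out$start > out$end)
  if (length(bad)) abort(paste0("SEG format error: start > end at data row ", bad[1]))
  derive <- is.na(out$status) & !is.na(out$copy_number)
  out$status[derive] <- cn_status(out$copy_number[derive], cfg)
  out
}

#' @rdname read_seg
#' @param x Segment tibble with the internal column names.
#' @return `write_seg()`: `path`, invisibly.
#' @export
write_seg <- function(x, path) {
  out <- tibble(ID = x$sample_id, chrom = x$chrom,
                `loc.start` = x$start, `loc.end` = x$end,
                `copy.num` = x$copy_number, status = x$status)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open and headerless; columns beyond the third
#' (a name/category label) are preserved in a `name` column when present.
#'
#' @param path File path.
#' @return `read_bed()`: an interval tibble (see [genome_intervals()]).
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' write_bed(genome_intervals("chr1", 0, 100), tf)
#' interval_length(read_bed(tf))
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(raw) < 3) abort("BED format error: fewer than 3 columns")
  start <- suppressWarnings(as.integer(raw$X2))
  end <- suppressWarnings(as.integer(raw$X3))
  if (any(is.na(start) | is.na(end))) abort("BED format error: non-integer coordinates")
  if (any(start < 0 | end < 0)) abort("BED format error: negative coordinates")
  x <- genome_intervals(raw$X1, start, end)
  if (ncol(raw) >= 4) x$name <- raw$X4
  x
}

#' @rdname read_bed
#' @param x Interval tibble.
#' @return `write_bed()`: `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- x[c("chrom", "start", "end")]
  if ("name" %in% names(x)) out$name <- x$name
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write fusion call tables
#'
#' Tab-separated with columns `FusionName` (`GENE5::GENE3`), `Gene1A`,
#' `Gene1B`, `Caller` (comma-separated caller set), `Sample`,
#' `cancer_group`, and `annots` (comma-separated annotation set).
#'
#' @param path File path.
#' @return `read_fusions()`: a tibble with `fusion_name`, `gene5`, `gene3`,
#'   `callers`, `sample_id`, `cancer_group`, `annotations`.
#' @export
read_fusions <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  required <- c("FusionName", "Gene1A", "Gene1B", "Caller", "Sample")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("fusion format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    fusion_name = raw$FusionName, gene5 = raw$Gene1A, gene3 = raw$Gene1B,
    callers = raw$Caller, sample_id = raw$Sample,
    cancer_group = if ("cancer_group" %in% names(raw)) raw$cancer_group else NA_character_,
    annotations = if ("annots" %in% names(raw)) raw$annots else NA_character_
  )
  if (any(is.na(out$callers) | out$callers == "")) {
    abort("fusion format error: empty caller set")
  }
  if (any(is.na(out$gene5) | is.na(out$gene3))) {
    abort("fusion format error: empty partner gene symbol")
  }
  out
}

#' @rdname read_fusions
#' @param x Fusion tibble.
#' @return `write_fusions()`: `path`, invisibly.
#' @export
write_fusions <- function(x, path) {
  out <- tibble(FusionName = x$fusion_name, Gene1A = x$gene5, Gene1B = x$gene3,
                Caller = x$callers, Sample = x$sample_id,
                cancer_group = x$cancer_group, annots = x$annotations)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write methylation classifier call tables
#'
#' Wide per-specimen TSV using the classifier-specific field names
#' (`dkfz_v12_methylation_subclass`, `dkfz_v12_methylation_subclass_score`,
#' `dkfz_v12_methylation_mgmt_status`, `dkfz_v12_methylation_mgmt_estimated`,
#' `NIH_v2_methylation_Class`, `NIH_v2_methylation_Class_mean_score`).
#' Internally calls are long, one row per (specimen, classifier).
#'
#' @param path File path.
#' @return `read_methylation()`: a tibble with `sample_id`, `classifier`
#'   (`"dkfz_v12"` or `"nih_v2"`), `subclass`, `score`, `mgmt_status`,
#'   `mgmt_estimated`.
#' @export
read_methylation <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (!"Kids_First_Biospecimen_ID" %in% names(raw)) {
    abort("methylation format error: missing required column(s): Kids_First_Biospecimen_ID")
  }
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
  dkfz <- tibble(
    sample_id = raw$Kids_First_Biospecimen_ID, classifier = "dkfz_v12",
    subclass = grab("dkfz_v12_methylation_subclass"),
    score = suppressWarnings(as.numeric(grab("dkfz_v12_methylation_subclass_score"))),
    mgmt_status = grab("dkfz_v12_methylation_mgmt_status"),
    mgmt_estimated = suppressWarnings(as.numeric(grab("dkfz_v12_methylation_mgmt_estimated")))
  )
  nih <- tibble(
    sample_id = raw$Kids_First_Biospecimen_ID, classifier = "nih_v2",
    subclass = grab("NIH_v2_methylation_Class"),
    score = suppressWarnings(as.numeric(grab("NIH_v2_methylation_Class_mean_score"))),
    mgmt_status = NA_character_, mgmt_estimated = NA_real_
  )
  out <- bind_rows(dkfz, nih) |> filter(!is.na(.data$subclass))
  if (any(!is.na(out$score) & (out$score < 0 | out$score > 1))) {
    abort("methylation format error: classifier score outside [0, 1]")
  }
  out
}

#' @rdname read_methylation
#' @param x Long methylation tibble.
#' @return `write_methylation()`: `path`, invisibly.
#' @export
write_methylation <- function(x, path) {
  wide_d <- x |> filter(.data$classifier == "dkfz_v12") |>
    select(Kids_First_Biospecimen_ID = "sample_id",
           dkfz_v12_methylation_subclass = "subclass",
           dkfz_v12_methylation_subclass_score = "score",
           dkfz_v12_methylation_mgmt_status = "mgmt_status",
           dkfz_v12_methylation_mgmt_estimated = "mgmt_estimated")
  wide_n <- x |> filter(.data$classifier == "nih_v2") |>
    select(Kids_First_Biospecimen_ID = "sample_id",
           NIH_v2_methylation_Class = "subclass",
           NIH_v2_methylation_Class_mean_score = "score")
  out <- full_join(wide_d, wide_n, by = "Kids_First_Biospecimen_ID")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write histology (clinical metadata) tables
#'
#' Kids First data model fields, one row per biospecimen. Required:
#' `Kids_First_Participant_ID`, `Kids_First_Biospecimen_ID`. Recognized:
#' `tumor_event_id`, `pathology_diagnosis`,
#' `pathology_free_text_diagnosis`, `age_at_diagnosis_years`,
#' `tumor_descriptor`, `CNS_region`, `experimental_strategy`,
#' `composition`, `germline_pathogenic` (comma-separated gene symbols).
#'
#' @param path File path.
#' @return `read_histologies()`: a tibble with snake-case internal names
#'   (`participant_id`, `biospecimen_id`, ...).
#' @export
read_histologies <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  required <- c("Kids_First_Participant_ID", "Kids_First_Biospecimen_ID")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("histology format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
  out <- tibble(
    participant_id = raw$Kids_First_Participant_ID,
    biospecimen_id = raw$Kids_First_Biospecimen_ID,
    tumor_event_id = grab("tumor_event_id"),
    pathology_diagnosis = grab("pathology_diagnosis"),
    pathology_free_text_diagnosis = grab("pathology_free_text_diagnosis"),
    age_at_diagnosis_years = suppressWarnings(as.numeric(grab("age_at_diagnosis_years"))),
    tumor_descriptor = grab("tumor_descriptor"),
    cns_region = grab("CNS_region"),
    experimental_strategy = grab("experimental_strategy"),
    composition = grab("composition"),
    germline_pathogenic = grab("germline_pathogenic")
  )
  if (any(is.na(out$participant_id) | is.na(out$biospecimen_id))) {
    abort("histology format error: empty identifier")
  }
  if (any(!is.na(out$age_at_diagnosis_years) & out$age_at_diagnosis_years < 0)) {
    abort("histology format error: negative age at diagnosis")
  }
  out
}

#' @rdname read_histologies
#' @param x Histology tibble with internal column names.
#' @return `write_histologies()`: `path`, invisibly.
#' @export
write_histologies <- function(x, path) {
  out <- tibble(
    Kids_First_Participant_ID = x$participant_id,
    Kids_First_Biospecimen_ID = x$biospecimen_id,
    tumor_event_id = x$tumor_event_id,
    pathology_diagnosis = x$pathology_diagnosis,
    pathology_free_text_diagnosis = x$pathology_free_text_diagnosis,
    age_at_diagnosis_years = x$age_at_diagnosis_years,
    tumor_descriptor = x$tumor_descriptor,
    CNS_region = x$cns_region,
    experimental_strategy = x$experimental_strategy,
    composition = x$composition,
    germline_pathogenic = x$germline_pathogenic
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read and write gene-by-sample expression matrices
#'
#' TSV with leading `ensembl_id` and `symbol` columns followed by one
#' numeric column per sample (TPM, FPKM, or expected counts).
#'
#' @param path File path.
#' @return `read_expression()`: a tibble, genes in rows.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    ensembl_id = "c", symbol = "c", .default = "d"), progress = FALSE)
  missing_cols <- setdiff(c("ensembl_id", "symbol"), names(raw))
  if (length(missing_cols)) {
    abort(paste0("expression format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  vals <- as.matrix(raw[setdiff(names(raw), c("ensembl_id", "symbol"))])
  if (any(vals < 0, na.rm = TRUE)) abort("expression format error: negative values")
  if (anyDuplicated(setdiff(names(raw), c("ensembl_id", "symbol")))) {
    abort("expression format error: duplicate sample columns")
  }
  raw
}

#' @rdname read_expression
#' @param x Expression tibble.
#' @return `write_expression()`: `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}
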