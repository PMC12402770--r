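# Seeded synthetic cohorts with planted ground truth. The generator's
# defaults define the study conditions every stage is tested under; all
# randomness flows from one seed so identical seeds give identical cohorts.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Miniature two-contig genome used by the synthetic cohorts
#'
#' Two 1-Mb contigs with per-caller surveyed regions, a coding-sequence
#' model of 80 non-overlapping 1-kb exons (all inside every caller's
#' surveyed region, so the coding denominator is exactly 80,000 bp), a
#' blacklist (telomeric / centromeric / segmental-duplication stand-ins),
#' gene spans and chromosome-arm spans. Interval tables are 0-based
#' half-open; gene and arm spans are 1-based inclusive.
#'
#' @return Named list of tibbles: `surveyed` (list per caller), `cds`,
#'   `blacklist`, `gene_models`, `arm_models`, plus `cds_length_bp` and
#'   `surveyed_intersection_bp` computed by plain arithmetic on the
#'   definitions.
#' @export
toy_genome <- function() {
  surveyed <- list(
    strelka2 = genome_intervals(c("chr1", "chr2"), c(0, 0), c(900000, 900000)),
    mutect2  = genome_intervals(c("chr1", "chr2"), c(50000, 0), c(950000, 850000)),
    vardict  = genome_intervals(c("chr1", "chr2"), c(0, 100000), c(1000000, 900000))
  )
  cds <- genome_intervals(
    chrom = c(rep("chr1", 50), rep("chr2", 30)),
    start = c(100000 + (0:49) * 10000, 200000 + (0:29) * 10000),
    end   = c(100000 + (0:49) * 10000 + 1000, 200000 + (0:29) * 10000 + 1000)
  )
  blacklist <- genome_intervals(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(950000, 600000, 0),
    end   = c(1000000, 610000, 50000))
  blacklist$name <- c("telomeric", "segmental_duplication", "centromeric")
  gene_models <- tibble(
    gene = c("MYCN", "CDKN2A", "CDKN2B", "TP53", "PTEN", "GLI2", "BRAF"),
    chrom = c("chr2", "chr1", "chr1", "chr1", "chr2", "chr2", "chr1"),
    start = c(210001L, 120001L, 125001L, 300001L, 400001L, 500001L, 700001L),
    end   = c(215000L, 123000L, 128000L, 320000L, 410000L, 510000L, 705000L)
  )
  arm_models <- tibble(
    arm = c("1p", "1q", "2p", "2q"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(1L, 500001L, 1L, 500001L),
    end = c(500000L, 1000000L, 500000L, 1000000L)
  )
  # lengths by plain arithmetic on the definitions above
  list(surveyed = surveyed, cds = cds, blacklist = blacklist,
       gene_models = gene_models, arm_models = arm_models,
       cds_length_bp = 80 * 1000,
       surveyed_intersection_bp = (900000 - 50000) + (850000 - 100000))
}

#' Specification for a synthetic cohort
#'
#' @param n_participants Number of participants (one tumor event each).
#' @param histology_mix Named proportions over the subtyped histology
#'   groups; must sum to 1.
#' @param caller_agreement Probability that each SNV caller independently
#'   reports a true variant (1 = noiseless).
#' @param breakpoint_jitter_sd Standard deviation (bp) of per-caller CNV
#'   breakpoint jitter (0 = noiseless).
#' @param n_coding_variants,n_noncoding_variants Planted somatic variants
#'   per sample inside (nonsynonymous, missense) and outside (silent) the
#'   coding model.
#' @param hotspot_fraction Fraction of planted coding variants flagged as
#'   hotspot alleles.
#' @param n_cnv_per_sample Planted true CNV regions per sample.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `pedcan_cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 24,
                        histology_mix = c(HGG = 0.2, ATRT = 0.1, NBL = 0.1,
                                          EPN = 0.15, LGG = 0.1, MB = 0.2,
                                          CRANIO = 0.05, PB = 0.05,
                                          ETMR = 0.05),
                        caller_agreement = 1.0,
                        breakpoint_jitter_sd = 0,
                        n_coding_variants = 10L,
                        n_noncoding_variants = 5L,
                        hotspot_fraction = 0.1,
                        n_cnv_per_sample = 4L,
                        seed = 1L) {
  if (abs(sum(histology_mix) - 1) > 1e-8) abort("histology_mix must sum to 1")
  if (caller_agreement < 0 || caller_agreement > 1) {
    abort("caller_agreement must lie in [0, 1]")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         histology_mix = histology_mix,
         caller_agreement = caller_agreement,
         breakpoint_jitter_sd = breakpoint_jitter_sd,
         n_coding_variants = as.integer(n_coding_variants),
         n_noncoding_variants = as.integer(n_noncoding_variants),
         hotspot_fraction = hotspot_fraction,
         n_cnv_per_sample = as.integer(n_cnv_per_sample),
         seed = as.integer(seed)),
    class = c("pedcan_cohort_spec", "list"))
}

snv_callers <- c("strelka2", "mutect2", "lancet", "vardict")

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

plant_snvs <- function(sample_id, spec, genome) {
  cds_pos <- unlist(lapply(seq_len(nrow(genome$cds)), function(i) {
    g <- genome$cds[i, ]
    seq.int(g$start + 1L, g$end)  # 1-based positions inside the exon
  }))
  cds_chrom <- rep(genome$cds$chrom, genome$cds$end - genome$cds$start)
  pick <- sample.int(length(cds_pos), spec$n_coding_variants)
  coding <- tibble(
    sample_id = sample_id, chrom = cds_chrom[pick], pos = cds_pos[pick],
    variant_classification = "Missense_Mutation")
  # silent calls scattered outside the coding model but inside chr1 surveyed
  nc_pos <- sample(seq.int(700001L, 890000L), spec$n_noncoding_variants)
  noncoding <- tibble(
    sample_id = sample_id, chrom = "chr1", pos = nc_pos,
    variant_classification = "Silent")
  truth <- bind_rows(coding, noncoding) |>
    distinct(.data$sample_id, .data$chrom, .data$pos, .keep_all = TRUE) |>
    mutate(
      ref = random_bases(n()),
      alt = map_chr(.data$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1)),
      t_depth = sample(60:120, n(), replace = TRUE),
      t_alt_count = pmin(.data$t_depth, 10L + rpois(n(), 20)),
      n_depth = sample(30:60, n(), replace = TRUE),
      gnomad_af = NA_real_,
      hotspot = runif(n()) < spec$hotspot_fraction &
        .data$variant_classification == "Missense_Mutation",
      hugo_symbol = "SYNGENE", hgvsp_short = NA_character_
    )
  incl <- matrix(runif(nrow(truth) * 4) < spec$caller_agreement,
                 nrow = nrow(truth), dimnames = list(NULL, snv_callers))
  # a hotspot allele unseen by every caller cannot exist in any input file;
  # force one caller so the planted rescue is observable
  orphan <- truth$hotspot & rowSums(incl) == 0
  if (any(orphan)) incl[cbind(which(orphan), sample.int(4, sum(orphan), replace = TRUE))] <- TRUE
  list(truth = truth, inclusion = incl)
}

plant_cnvs <- function(sample_id, spec) {
  n <- spec$n_cnv_per_sample
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample(seq.int(10001L, 700000L, by = 1000L), n)
  len <- sample(seq.int(30000L, 80000L, by = 1000L), n, replace = TRUE)
  cn <- sample(c(1L, 4L), n, replace = TRUE)
  tibble(sample_id = sample_id, chrom = chrom, start = start,
         end = start + len - 1L, copy_number = cn,
         status = cn_status(cn))
}

jitter_segments <- function(truth, sd) {
  if (sd == 0) return(truth)
  mutate(truth,
         start = pmax(1L, as.integer(round(.data$start + rnorm(n(), 0, sd)))),
         end = as.integer(round(.data$end + rnorm(n(), 0, sd))),
         end = pmax(.data$end, .data$start))
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Emits per-caller somatic variant tables (each true variant included
#' independently per caller with the configured agreement probability,
#' hotspot alleles flagged), per-caller copy-number segments with jittered
#' breakpoints, fusion calls, a TPM expression matrix, methylation
#' classifier calls, a histology table, the assembled
#' [cohort_evidence()] bundle, and a ground-truth manifest: the expected
#' consensus variant keys (set arithmetic over the generator's own
#' inclusion draws), expected noiseless TMB values, the true CNV regions,
#' and the planted subtype label per tumor event.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `pedcan_cohort`: `maf_by_caller`,
#'   `seg_by_caller`, `fusions`, `expression`, `methylation`,
#'   `histologies`, `evidence`, `manifest`, `genome`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "pedcan_cohort_spec"))
  restore <- local_seed(spec$seed); on.exit(restore())
  genome <- toy_genome()
  ids <- sprintf("PT_%03d", seq_len(spec$n_participants))

  # ---- subtype channel: sample a planted rule branch per participant ----
  groups <- sample(names(spec$histology_mix), spec$n_participants,
                   replace = TRUE, prob = spec$histology_mix)
  catalog <- subtype_rule_catalog()
  branches <- vapply(groups, function(g) {
    sample(catalog$branch[catalog$histology_group == g], 1)
  }, character(1))
  planted <- plant_subtype_evidence(branches, ids = ids)

  # ---- SNV channel ----
  snv <- lapply(ids, function(s) plant_snvs(paste0("BS_", s), spec, genome))
  names(snv) <- ids
  maf_by_caller <- lapply(snv_callers, function(cl) {
    map_dfr(snv, function(x) x$truth[x$inclusion[, cl], , drop = FALSE])
  }) |> setNames(snv_callers)
  n_support <- map_dfr(snv, function(x) {
    mutate(x$truth, n_callers_true = rowSums(x$inclusion))
  })
  expected_consensus <- n_support |>
    filter(.data$n_callers_true >= 2 |
             (.data$hotspot & .data$n_callers_true >= 1)) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "hotspot")

  # ---- CNV channel ----
  cnv_truth <- map_dfr(ids, function(s) plant_cnvs(paste0("BS_", s), spec))
  seg_by_caller <- lapply(c("controlfreec", "cnvkit", "gatk"), function(cl) {
    jitter_segments(cnv_truth, spec$breakpoint_jitter_sd)
  }) |> setNames(c("controlfreec", "cnvkit", "gatk"))

  # ---- expression matrix (for symbol collapse / liftover testing) ----
  symbols <- c(genome$gene_models$gene, "DUPGENE", "DUPGENE", "ZEROGENE",
               "LIN28A", "EZHIP", "TKTL1")
  ens <- sprintf("ENSG%011d", seq_along(symbols))
  tpm <- matrix(round(stats::rlnorm(length(symbols) * length(ids), 2, 1), 3),
                nrow = length(symbols),
                dimnames = list(NULL, paste0("BS_", ids)))
  tpm[symbols == "ZEROGENE", ] <- 0
  expression <- bind_cols(tibble(ensembl_id = ens, symbol = symbols),
                          as_tibble(tpm))

  # ---- noiseless TMB expectation from the planted truth ----
  tmb_expected <- n_support |>
    group_by(.data$sample_id) |>
    summarise(n_coding_true = sum(.data$variant_classification ==
                                    "Missense_Mutation"), .groups = "drop") |>
    mutate(
      expected_tmb_coding = .data$n_coding_true / genome$cds_length_bp * 1e6,
      expected_tmb_all = .data$n_coding_true / genome$surveyed_intersection_bp * 1e6
    )

  structure(list(
    spec = spec, genome = genome,
    maf_by_caller = maf_by_caller,
    seg_by_caller = seg_by_caller,
    fusions = planted$evidence$fusions,
    expression = expression,
    methylation = planted$evidence$methylation,
    histologies = planted$evidence$histologies,
    evidence = planted$evidence,
    manifest = list(
      subtypes = planted$truth,
      expected_consensus = expected_consensus,
      tmb = tmb_expected,
      cnv_truth = cnv_truth,
      caller_agreement = spec$caller_agreement
    )
  ), class = c("pedcan_cohort", "list"))
}

#' Write a synthetic cohort to disk in the standard file formats
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(cohort$maf_by_caller)) {
    write_maf(cohort$maf_by_caller[[cl]], file.path(dir, paste0(cl, ".maf")))
  }
  for (cl in names(cohort$seg_by_caller)) {
    write_seg(cohort$seg_by_caller[[cl]], file.path(dir, paste0(cl, ".seg")))
  }
  write_bed(cohort$genome$blacklist, file.path(dir, "blacklist.bed"))
  write_bed(cohort$genome$cds, file.path(dir, "cds.bed"))
  write_expression(cohort$expression, file.path(dir, "expression_tpm.tsv"))
  readr::write_tsv(cohort$manifest$subtypes, file.path(dir, "manifest_subtypes.tsv"))
  invisible(dir)
}

#' Paired methylation/RNA medulloblastoma labels from the printed
#' concordance table
#'
#' Expands the published methylation-subclass by RNA-group contingency
#' cells into the multiset of 150 per-sample label pairs used to validate
#' the concordance computation. Constant across calls.
#'
#' @return Tibble `methylation_subclass`, `rna_group`, one row per sample.
#' @export
table1_fixture <- function() {
  cells <- tibble::tribble(
    ~methylation_subclass, ~rna_group, ~n,
    "MB_G34_II",   "Group3", 8L,
    "MB_G34_III",  "Group3", 17L,
    "MB_G34_IV",   "Group3", 8L,
    "MB_G34_V",    "Group4", 6L,
    "MB_G34_VI",   "Group4", 4L,
    "MB_G34_VII",  "Group4", 30L,
    "MB_G34_VIII", "Group4", 34L,
    "MB_MYO",      "Group3", 1L,
    "MB_SHH_1",    "SHH",    11L,
    "MB_SHH_2",    "SHH",    4L,
    "MB_SHH_3",    "SHH",    2L,
    "MB_SHH_4",    "SHH",    7L,
    "MB_WNT",      "WNT",    18L
  )
  tidyr::uncount(cells, weights = .data$n)
}
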