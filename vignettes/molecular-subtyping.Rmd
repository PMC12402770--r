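---
title: "Consensus calling, mutation burden, and molecular subtyping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus calling, mutation burden, and molecular subtyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcan)
library(dplyr)
```

# Scope and model

`pedcan` implements the downstream computational core of a pediatric CNS
tumor cohort analysis: it consumes the outputs of upstream callers
(somatic small-variant callers, copy-number callers, RNA fusion callers,
DNA methylation classifiers) and clinical metadata, and produces
consensus somatic call sets, tumor mutation burden (TMB), prioritized
fusions, TP53 status, and WHO-2021-aligned molecular subtype labels per
tumor event. The callers themselves, read alignment, and variant
annotation are out of scope; the package starts from annotated tabular
files (MAF, SEG, BED, TSV).

Every numeric threshold lives in one configuration object,
`rule_config()`, so the rules are auditable and overridable in one place.

# Consensus somatic SNVs

Four callers (Strelka2, Mutect2, Lancet, VarDict semantics) are combined
by variant identity `(sample, chrom, pos, ref, alt)`. A variant is
retained when at least 2 callers report it, or when any caller flags it
as a hotspot allele. Because one caller emits multinucleotide variants
(MNVs) as runs of consecutive SNVs, MNP records from the other callers
serve as templates: a run of SNVs whose positions and concatenated
alleles exactly reproduce a template MNP is collapsed into a single MNP
record before support counting, so the reconstructed record and its
template count as two supporters of the same allele. Runs that overlap a
template but disagree in alleles are left unmerged with a warning.

Two filters follow:

* **Likely germline** (matched tumor/normal): non-hotspot calls with
  normal depth ≤ 7 *and* gnomAD allele frequency > 0.001 are removed.
  The conjunction matters — shallow normal coverage alone, or population
  frequency alone, does not remove a call. A missing gnomAD frequency is
  treated as 0 (kept), matching the filter's intent of removing
  common-population variants only when frequency evidence exists.
* **Tumor-only depth**: calls with no alternate reads or total depth
  < 4 are removed. The boundaries are strict as printed: depth 4 is
  kept, depth 3 is not.

Consensus record numerics (depths) come from a fixed caller precedence
(strelka2 > mutect2 > lancet > vardict) purely for reproducibility; the
upstream sources do not specify a rule. Output ordering is fully sorted,
so repeated runs are byte-identical.

# Consensus CNVs

Per-sample caller segment files with more than 2,500 CNVs are dropped
wholesale as noise. The consensus then admits, per sample and per
direction (gain/loss):

1. the **intersected span** of two segments from different callers with
   reciprocal overlap ≥ 50%, and
2. the **own span** of a segment covered ≥ 90% by another caller's
   same-direction segments.

The emitted span for rule (1) is the intersection — the conservative
choice, guaranteeing every supporter covers the whole emitted span; the
union is the other defensible reading and is not taken. For rule (2) the
contained segment's own coordinates are emitted. Pairwise matches across
all caller pairs are pooled and overlapping same-direction spans are
unioned, which reproduces "at least 2 callers" semantics without
triple-wise enumeration. Same-direction regions within 10 kb are merged;
regions shorter than 3 kb or ≥ 50% inside blacklist intervals
(immunoglobulin/telomeric/centromeric/segmental-duplication stand-ins)
are removed. Consensus copy number is the callers' agreed value and `NA`
whenever supporters disagree or any underlying call is neutral.

The caller trio is Control-FREEC + CNVkit + GATK when a GATK panel of
normals exists (≥ 30 male and 30 female normals), otherwise
structural-variant-derived MantaSV calls substitute for GATK. WXS
samples bypass consensus entirely: their single-caller CNVkit segments
are appended unchanged.

Interval arithmetic (merge, intersect, length) is delegated to IRanges
behind a tibble-based surface; variants and segments are 1-based
inclusive (MAF/SEG convention), interval sets 0-based half-open (BED
convention), with conversion only at type boundaries.

# Focal copy number

Consensus regions are projected onto gene spans. Conflicting statuses
per (gene, sample) resolve by: non-neutral over neutral, then the
dominant segment (largest base-pair overlap with the gene), then
amplification over gain / deep deletion over loss, then the longer
segment, then the leftmost start. The final two tie-breaks are this
package's choice — the source criterion names the dominant-segment rule
but no tie-break. Resolution leaves exactly one row per (gene, sample),
asserted as zero duplicates on engineered conflicts (strictly stronger
than the upstream project's ">99% resolved" statement). Copy-number
categories derive from integer copy number through an explicit config
mapping (CN 0 deep deletion, below-ploidy loss, at-ploidy neutral,
ploidy+1..2 gain, ≥ ploidy+3 amplification) because the upstream file
formats carry no category boundaries; ploidy defaults to 2 and the
mapping is overridable.

Arm status is a coverage call: an arm is gained/lost when same-direction
regions cover ≥ 50% of its span (configurable; the source uses arm
events without defining the computation). When both directions pass, the
larger coverage wins and exact ties are neutral.

# Tumor mutation burden

MNVs are decomposed into constituent SNVs (skipping positions where ref
and alt agree), merged with the SNV subset, and per-sample duplicates
removed. The numerator counts nine high/moderate-consequence classes
(missense, frameshift ins/del, in-frame ins/del, splice site, nonsense,
nonstop, translation start site); an alternate class list following the
TMB-harmonization convention is selectable. Denominators: for WGS the
intersection of all supplied per-caller surveyed-region files — the set
of files is an input, so either the two-caller or three-caller
intersection is reachable — and for WXS the capture BED. Coding-only TMB
restricts the numerator to mutations inside surveyed ∩ CDS and uses that
intersection's length as denominator. Results are scaled per megabase
(`tmb_scale = 1e6`); the literal unscaled ratio is available by setting
the scale to 1. A zero-length denominator is an error, never a silent 0.

# Fusion prioritization and TP53 status

A fusion is putative oncogenic when either partner is a known kinase,
oncogene, tumor suppressor, curated transcription factor, COSMIC Cancer
Gene Census member, or TCGA-observed. Retention requires any of: called
by both RNA callers; recurrent in a cancer group (≥ 3 independent
patients — a convention default, not a published constant, and
configurable); specific to exactly one cancer group; or putative
oncogenic. Panel (DGD) fusions pass through untouched. Artifact flags
(read-through, low support) are accepted on input; recomputing caller QC
is out of scope.

TP53 status evaluates activation before loss: gain-of-function variants
p.R273C/p.R248W give *activated*; otherwise *lost* on a
hotspot-database mutation, on ≥ 2 distinct alterations among SNVs, CNV
deletion and SV disruption (biallelic inactivation), on a somatic
variant together with an LFS-associated pathogenic germline variant, or
on an LFS germline variant with an RNA inactivation-classifier score
strictly above 0.5. We read the third loss condition as a conjunction
(somatic variant *and* LFS germline variant): the disjunctive reading
would let any single somatic TP53 variant imply loss, collapsing the
hotspot and biallelic conditions into dead code. A sample meeting both
activation and loss criteria is labeled activated (rule order decides;
the conflict is otherwise unspecified). The RNA classifier itself is
consumed as a precomputed score.

# The subtyping engine

Each tumor event is routed by `pathology_diagnosis` through a
case-insensitive dispatch table to one histology rule set (HGG incl.
DMG/IHG/PXA, ATRT, NBL, CRANIO, EPN, LGG, MB with SHH subgroups, PB,
ETMR). Within a rule set, rules evaluate in their printed order and the
first match wins (explicit for ependymoma; adopted globally). A
methylation classifier call is usable only at score ≥ 0.8
("high confidence"); such calls dominate other evidence wherever a rule
has a methylation clause.

Design choices worth flagging:

* **Rules as code, mappings as data.** The methylation
  subclass-to-label mappings and the closed label vocabulary ship as
  TSV files under `inst/extdata/` and are read at runtime, keeping the
  label catalog auditable and editable. The boolean rule logic
  (conjunctions over fusions, CNV, age, expression) is ordinary R code:
  a condition-DSL interpreter would be a larger correctness surface
  than the ~40 rules it would encode.
* **MB SHH beta vs gamma.** Both subgroups can fire at age < 5 with
  chromosome 2p gain. Methylation decides when present; otherwise beta
  requires a beta-specific feature (KMT2D loss-of-function, PTEN
  loss/under-expression, or 2q gain) and a 2p-gain-only event goes to
  gamma. This is a package decision, not a published tie-break.
* **Over-expression** (TKTL1, EZHIP, GPBP1, IFT46, LIN28A, and the SHH
  driver genes) means a cohort z-score of log2(TPM+1) ≥ 2, computed
  within RNA library-type strata upstream; the threshold is
  configurable (`expr_z_high`). MYCN in neuroblastoma instead uses an
  absolute cutoff, TPM ≥ 140.83, as established upstream by inspection
  of CNV-stratified expression.
* **Loss-of-function** means classification in {nonsense, frameshift
  ins/del, splice site, translation start site}; configurable.
* **Neuroblastoma conflicts.** Genomic MYCN amplification always wins.
  When free text claims amplification but genomics disagrees, RNA
  decides; with no RNA either, the event is "NBL, To be classified"
  rather than trusting free text.
* **Spinal/posterior-fossa location** for ependymoma comes from the
  harmonized `cns_region` field, not free text.
* **U1 snRNA hotspot** mutations have no natural MAF representation and
  are accepted as a per-event boolean flag.
* Two garbled subclass names in the source prose (`MB_G334_IV`,
  `MB_G334_VIII`) are treated as `MB_G34_*`, consistent with the
  published concordance table.

The medulloblastoma methylation-vs-RNA concordance operation maps each
methylation subclass to its consensus group (`mb_methyl_group()`) and
counts disagreements with the RNA label; on the 150 published pairs it
reproduces the single discordant sample (MB_MYO, called Group3 by RNA):

```{r concordance}
fx <- table1_fixture()
cc <- concordance_table(fx$methylation_subclass, fx$rna_group)
glance(cc)
```

# Synthetic cohorts and what they show

`generate_cohort()` emits every input the pipeline consumes — four
per-caller variant tables, three per-caller segment tables, fusion,
expression, methylation and histology tables — on a miniature
two-contig (2 × 1 Mb) genome with an 80-exon coding model, caller
surveyed regions, a blacklist, gene spans and arm spans. All randomness
derives from one seed; identical seeds give identical cohorts and the
caller's RNG stream is left untouched.

Planted ground truth makes expectations computable without running the
pipeline: the expected consensus set is set arithmetic over the
generator's own per-caller inclusion draws (a variant survives when ≥ 2
callers drew it, or a hotspot was drawn at least once); with agreement
probability 1 and m planted coding mutations in a coding model of
length L, coding TMB is exactly m/L × 10⁶; with agreement 0.6 the
expected recall is the closed form 1 − 0.4⁴ − 4·0.6·0.4³ = 0.8208,
checked within its binomial 95% interval at 500 variants. Subtype
recovery uses `plant_subtype_evidence()`, which builds one tumor event
per rule branch (81 branches, including a dedicated negative case for
every "To be classified" fallback) carrying exactly that branch's
antecedents.

Defaults model the noiseless study condition (agreement 1, jitter 0);
noise parameters exist to exercise the consensus machinery, not to
emulate real error processes. The generator does not model realistic
mutational spectra, read-level evidence, caller-specific artifact
modes, correlated caller errors, or borderline methylation scores — so
passing tests demonstrate the *rules* are implemented faithfully, not
that the pipeline is robust to every real-data pathology.

Problem sizes used by the test suite — 10³ variants for the consensus
oracle comparison, 500 variants for the recall check, ≤ 10⁶ bp toy
genomes for the per-base CNV voting oracle, 81 planted subtype events —
were chosen so each check runs in seconds while leaving the oracles
brute-force and independent of the implementation.

# Known limitations

* Subtype labels outside the shipped vocabulary require editing the
  extdata tables; the engine will not invent labels.
* The germline filter cannot act on tumor-only samples (no normal
  depth); those rely on the depth filter alone, as upstream.
* Arm-level calls are coverage-threshold approximations; no
  allele-specific or ploidy-adjusted arm model is attempted.
* `concordance_table()` is specific to the medulloblastoma group
  mapping; other histologies have no published RNA counterpart here.
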