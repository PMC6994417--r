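#' @import methods
#' @importFrom stats median pchisq runif setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

## Effect vocabulary used throughout. "Nonsynonymous" in the sense of a
## protein-altering call: missense, stop-gain, splice-site, and indels in
## coding sequence.
.EFFECTS <- c("missense", "stop_gain", "splicing", "frameshift_indel",
              "inframe_indel", "synonymous", "intronic", "other")
.NONSYN_EFFECTS <- c("missense", "stop_gain", "splicing",
                     "frameshift_indel", "inframe_indel")
.SAMPLE_ROLES <- c("tumor_discovery", "tumor_extension", "matched_normal",
                   "pon_normal", "hyperplastic_control")
.PRED_COLS <- paste0("pred_", 1:9)

## The nine structure/homology-based predictors behind pred_1..pred_9.
## Their calls are consumed as annotation, never computed here.
.PREDICTOR_NAMES <- c("Polyphen2", "Polyphen2_HVAR", "Polyphen2_HDIV",
                      "LRT_pred", "MutationTaster_pred", "FATHMM_pred",
                      "RadialSVM_pred", "LR_pred", "MutationAssessor")

#' CohortProfile: published cohort structure driving the synthetic generator
#'
#' A `CohortProfile` encodes every cohort-level quantity the generator
#' emulates: sample counts and roles, the gene panel and per-gene
#' mutated-sample counts, the per-patient mutation burden of the discovery
#' set, the transition/transversion ratio and G/C targeting bias of the
#' substitution spectrum, contamination rates, and the clinical follow-up
#' structure (group medians, fixed-time survival, follow-up range).
#'
#' @slot nDiscovery,nExtension number of discovery / extension tumors.
#' @slot nMatchedDiscovery,nMatchedExtension tumors with a matched saliva
#'   normal in each panel.
#' @slot nPon unmatched healthy-volunteer saliva normals (panel of normals).
#' @slot nHyperplastic reactive hyperplastic lymph-node controls.
#' @slot nRna discovery tumors with RNA-seq evidence.
#' @slot exomeMb effective exome size in megabases for per-Mb burden rates.
#' @slot wesGenes,litGenes gene symbols entering the targeted panel from the
#'   exome screen and from the literature (disjoint).
#' @slot geneFreqs named integer vector; number of tumors carrying a planted
#'   somatic variant per gene.
#' @slot perSampleBurden integer vector (length `nDiscovery`) of planted
#'   nonsynonymous mutations per discovery patient.
#' @slot titvRatio target transition/transversion ratio of planted SNVs.
#' @slot gcBias probability that a planted SNV has a G or C reference base.
#' @slot nBackground number of background (off-panel) gene intervals on the
#'   toy reference that receive discovery burden variants.
#' @slot contamination list: `germline_per_tumor`, `artifact_per_tumor`,
#'   `germline_pool`, `artifact_pool`, `artifact_dup`.
#' @slot survivalSpec list: `n_clinical`, `gene`, `median_mutated`,
#'   `median_wildtype`, `survival_at_36m`, `followup_range`.
#' @slot seed default generator seed.
#' @seealso [referenceProfile()], [readCohortProfile()], [generateCohort()]
#' @exportClass CohortProfile
setClass("CohortProfile",
  representation(
    nDiscovery = "integer", nExtension = "integer",
    nMatchedDiscovery = "integer", nMatchedExtension = "integer",
    nPon = "integer", nHyperplastic = "integer", nRna = "integer",
    exomeMb = "numeric",
    wesGenes = "character", litGenes = "character",
    geneFreqs = "integer",
    perSampleBurden = "integer",
    titvRatio = "numeric", gcBias = "numeric",
    nBackground = "integer",
    contamination = "list",
    survivalSpec = "list",
    seed = "integer"))

setValidity("CohortProfile", function(object) {
  msg <- character()
  cnt <- c(object@nDiscovery, object@nExtension, object@nMatchedDiscovery,
           object@nMatchedExtension, object@nPon, object@nHyperplastic,
           object@nRna, object@nBackground)
  if (any(is.na(cnt)) || any(cnt < 0L))
    msg <- c(msg, "all sample counts must be nonnegative integers")
  nTum <- object@nDiscovery + object@nExtension
  if (object@nMatchedDiscovery + object@nMatchedExtension > nTum)
    msg <- c(msg, "matched pairs exceed total tumors")
  if (object@nMatchedDiscovery > object@nDiscovery)
    msg <- c(msg, "matched discovery pairs exceed discovery tumors")
  if (object@nRna > object@nDiscovery)
    msg <- c(msg, "RNA-seq samples exceed discovery tumors")
  if (length(object@exomeMb) != 1L || object@exomeMb <= 0)
    msg <- c(msg, "exomeMb must be a single positive number")
  if (anyDuplicated(c(object@wesGenes, object@litGenes)))
    msg <- c(msg, "wesGenes and litGenes must be disjoint and duplicate-free")
  if (is.null(names(object@geneFreqs)) ||
      !all(names(object@geneFreqs) %in%
           c(object@wesGenes, object@litGenes)))
    msg <- c(msg, "geneFreqs must be named by panel genes")
  if (any(object@geneFreqs < 0L) || any(object@geneFreqs > nTum))
    msg <- c(msg, sprintf(
      "gene frequencies must lie in [0, %d] (the cohort size)", nTum))
  if (length(object@perSampleBurden) != object@nDiscovery)
    msg <- c(msg, "perSampleBurden must have one entry per discovery tumor")
  if (any(object@perSampleBurden < 0L))
    msg <- c(msg, "perSampleBurden entries must be nonnegative")
  if (object@titvRatio <= 0)
    msg <- c(msg, "titvRatio must be positive")
  if (object@gcBias < 0 || object@gcBias > 1)
    msg <- c(msg, "gcBias must lie in [0, 1]")
  ss <- object@survivalSpec
  need <- c("n_clinical", "gene", "median_mutated", "median_wildtype",
            "survival_at_36m", "followup_range")
  if (!all(need %in% names(ss)))
    msg <- c(msg, paste("survivalSpec must contain:",
                        paste(need, collapse = ", ")))
  else {
    if (ss$n_clinical > nTum)
      msg <- c(msg, "n_clinical exceeds total tumors")
    if (ss$survival_at_36m < 0 || ss$survival_at_36m > 1)
      msg <- c(msg, "survival_at_36m must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated tumor/normal cohort bundle with ground truth
#'
#' Holds every table the filtering, statistics and survival layers consume,
#' plus the planted truth used by the recovery tests: per-sample exome and
#' targeted variant tables, matched-normal site evidence, panel-of-normals
#' and hyperplastic-control tables, RNA evidence, the cohort-wide annotation
#' table, the clinical table, the toy reference sequence and gene map.
#'
#' @slot samples data.frame of sample metadata (id, role, paired, has_rna,
#'   tumor_fraction, frac_reads_ge_q30).
#' @slot wes named list of exome variant tables (discovery tumors).
#' @slot wesMatchedNormals named list (by tumor id) of matched-normal site
#'   evidence tables for the paired discovery tumors.
#' @slot targeted named list of targeted-panel variant tables (all tumors).
#' @slot saliva named list (by tumor id) of matched-saliva targeted tables.
#' @slot pon named list of panel-of-normals variant tables.
#' @slot hyperplastic named list of hyperplastic-control variant tables.
#' @slot rna named list (by tumor id) of RNA evidence tables (key, reads).
#' @slot annotations cohort-wide annotation table, one row per variant key.
#' @slot clinical data.frame: patient_id, os_months, event, group.
#' @slot truth list: `classes` (data.frame key/class), `perSampleSomatic`
#'   (list of planted somatic keys per tumor), `geneSamples` (list of planted
#'   mutated-sample ids per gene).
#' @slot reference toy reference chromosome ([Biostrings::DNAString]).
#' @slot geneMap [GenomicRanges::GRanges] of gene intervals on the reference.
#' @slot profile the [CohortProfile] that produced the bundle.
#' @slot seed seed actually used.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    samples = "data.frame",
    wes = "list", wesMatchedNormals = "list",
    targeted = "list", saliva = "list",
    pon = "list", hyperplastic = "list", rna = "list",
    annotations = "data.frame",
    clinical = "data.frame",
    truth = "list",
    reference = "ANY",
    geneMap = "ANY",
    profile = "CohortProfile",
    seed = "integer"))

#' PanelOfNormals: variant keys observed in normal samples
#'
#' Set of variant identity keys (`chrom:pos:ref:alt`) carried by any member
#' normal with at least `minReads` supporting reads, with per-key provenance.
#'
#' @slot keys character vector of member keys (unique).
#' @slot provenance data.frame (key, sample_id), one row per supporting
#'   normal observation.
#' @slot minReads read-support threshold used for membership.
#' @seealso [buildPon()]
#' @exportClass PanelOfNormals
setClass("PanelOfNormals",
  representation(keys = "character", provenance = "data.frame",
                 minReads = "integer"))

setValidity("PanelOfNormals", function(object) {
  if (!setequal(object@keys, unique(object@provenance$key)))
    return("keys must equal the union of provenance keys")
  if (anyDuplicated(object@keys))
    return("keys must be unique")
  TRUE
})

#' FilterResult: verdicts and full per-gate trace of a filtering cascade
#'
#' @slot calls the adjudicated calls joined with their annotation, plus
#'   `verdict` ("retained"/"rejected") and `rejecting_gate` (first failed
#'   gate, NA when retained).
#' @slot trace long data.frame, one row per (variant, gate): sample_id, key,
#'   gate, passed, observed.
#' @slot cascade "wes" or "targeted".
#' @slot gates gate names in cascade order.
#' @seealso [wesDiscoveryFilter()], [targetedFilter()], [retainedCalls()]
#' @exportClass FilterResult
setClass("FilterResult",
  representation(calls = "data.frame", trace = "data.frame",
                 cascade = "character", gates = "character"))

#' SpectrumSummary: transition/transversion and six-class substitution summary
#'
#' @slot tiCount,tvCount transition / transversion counts.
#' @slot ratio Ti/Tv (NaN when no transversions, see `tvZero`).
#' @slot ratioTruncated Ti/Tv truncated to one decimal (reporting rendering).
#' @slot tvZero TRUE when the ratio is undefined (zero transversions).
#' @slot sixClass named integer vector of pyrimidine-collapsed substitution
#'   classes (C>A, C>G, C>T, T>A, T>C, T>G).
#' @slot gcTargetedFraction fraction of SNVs with a G or C reference base.
#' @seealso [spectrumSummary()]
#' @exportClass SpectrumSummary
setClass("SpectrumSummary",
  representation(tiCount = "integer", tvCount = "integer",
                 ratio = "numeric", ratioTruncated = "numeric",
                 tvZero = "logical", sixClass = "integer",
                 gcTargetedFraction = "numeric"))

#' RecurrenceMatrix: sample-collapsed gene-by-sample mutation matrix
#'
#' Binary genes x samples matrix; a cell is 1 when the sample carries at
#' least one retained variant in the gene, regardless of how many.
#'
#' @slot mat binary matrix (genes x samples).
#' @slot counts named integer vector of mutated-sample counts per gene.
#' @slot minSamples recurrence threshold used by [recurrentGenes()].
#' @exportClass RecurrenceMatrix
setClass("RecurrenceMatrix",
  representation(mat = "matrix", counts = "integer", minSamples = "integer"))

setValidity("RecurrenceMatrix", function(object) {
  if (length(object@counts) != nrow(object@mat))
    return("one count per gene row required")
  if (!all(object@counts == rowSums(object@mat > 0)))
    return("counts must equal row sums of the binary matrix")
  TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' Distinct event times with numbers at risk, event counts and the survival
#' estimate S(t); right-continuous and non-increasing with S(0-) = 1.
#' Censored observations tied with an event time are counted at risk at that
#' time (events before censorings).
#'
#' @slot time distinct event times (only times with >= 1 event).
#' @slot nRisk,nEvent numbers at risk / events at each event time.
#' @slot surv product-limit estimate at each event time.
#' @slot censTimes censoring times (for marks/diagnostics).
#' @slot n number of subjects.
#' @seealso [kmEstimate()], [kmMedian()], [survivalAt()]
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", nRisk = "numeric", nEvent = "numeric",
                 surv = "numeric", censTimes = "numeric", n = "integer"))

setValidity("KMCurve", function(object) {
  if (is.unsorted(object@time, strictly = TRUE))
    return("event times must be strictly increasing")
  if (length(object@surv) && any(diff(object@surv) > 1e-12))
    return("survival estimate must be non-increasing")
  if (length(object@surv) && (any(object@surv < -1e-12) ||
                              any(object@surv > 1 + 1e-12)))
    return("survival estimate must lie in [0, 1]")
  TRUE
})

#' LogRankResult: Mantel-Cox log-rank comparison of two survival curves
#'
#' @slot groups the two group labels.
#' @slot observed,expected observed and expected event counts per group
#'   (expected counts sum to the total number of events).
#' @slot variance summed hypergeometric variance of the group-1 event count.
#' @slot chisq chi-square statistic (1 df).
#' @slot pValue two-sided p-value.
#' @seealso [logrankTest()]
#' @exportClass LogRankResult
setClass("LogRankResult",
  representation(groups = "character", observed = "numeric",
                 expected = "numeric", variance = "numeric",
                 chisq = "numeric", pValue = "numeric"))

setValidity("LogRankResult", function(object) {
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-6)
    return("expected counts must sum to total events")
  if (object@chisq < 0) return("statistic must be nonnegative")
  TRUE
})
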