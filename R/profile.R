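#' Construct a CohortProfile
#'
#' Builds and validates a [CohortProfile-class]. Fields not supplied fall
#' back to documented defaults: contamination of 50 germline and 20 artifact
#' variants per tumor drawn from cohort-wide pools of 300 and 100 keys (10
#' artifact keys sitting in duplicated-context regions), 200 background gene
#' intervals, a G/C targeting bias of 0.6 and a transition/transversion
#' ratio of 1676/857.
#'
#' @param nDiscovery,nExtension tumor counts in the discovery / extension
#'   panels.
#' @param nMatchedDiscovery,nMatchedExtension tumors with matched saliva.
#' @param nPon,nHyperplastic,nRna unmatched normals, hyperplastic controls,
#'   RNA-sequenced discovery tumors.
#' @param exomeMb effective exome size (Mb) used for burden rates.
#' @param wesGenes,litGenes panel gene symbols (exome-derived / literature).
#' @param geneFreqs named vector: tumors mutated per gene.
#' @param perSampleBurden planted nonsynonymous mutations per discovery
#'   patient.
#' @param titvRatio,gcBias substitution-spectrum parameters.
#' @param nBackground background gene intervals on the toy reference.
#' @param contamination,survivalSpec,seed see [CohortProfile-class].
#' @return a validated [CohortProfile-class].
#' @export
newCohortProfile <- function(nDiscovery, nExtension,
                             nMatchedDiscovery = 0L, nMatchedExtension = 0L,
                             nPon = 0L, nHyperplastic = 0L, nRna = 0L,
                             exomeMb = 54, wesGenes, litGenes = character(),
                             geneFreqs, perSampleBurden,
                             titvRatio = 1676 / 857, gcBias = 0.6,
                             nBackground = 200L,
                             contamination = list(),
                             survivalSpec = list(), seed = 42L) {
  cdef <- list(germline_per_tumor = 50L, artifact_per_tumor = 20L,
               germline_pool = 300L, artifact_pool = 100L,
               artifact_dup = 10L)
  contamination <- utils::modifyList(cdef, contamination)
  gf <- setNames(as.integer(geneFreqs), names(geneFreqs))
  new("CohortProfile",
      nDiscovery = as.integer(nDiscovery),
      nExtension = as.integer(nExtension),
      nMatchedDiscovery = as.integer(nMatchedDiscovery),
      nMatchedExtension = as.integer(nMatchedExtension),
      nPon = as.integer(nPon), nHyperplastic = as.integer(nHyperplastic),
      nRna = as.integer(nRna), exomeMb = as.numeric(exomeMb),
      wesGenes = as.character(wesGenes), litGenes = as.character(litGenes),
      geneFreqs = gf,
      perSampleBurden = as.integer(perSampleBurden),
      titvRatio = as.numeric(titvRatio), gcBias = as.numeric(gcBias),
      nBackground = as.integer(nBackground),
      contamination = contamination,
      survivalSpec = survivalSpec, seed = as.integer(seed))
}

#' Read or write a cohort profile (YAML)
#'
#' The on-disk profile mirrors the [CohortProfile-class] slots; see the
#' packaged `reference_profile.yaml` for the full schema. Missing optional
#' fields are filled with the [newCohortProfile()] defaults; invariant
#' violations (e.g. a gene frequency exceeding the cohort size) are
#' rejected.
#'
#' @param path YAML file.
#' @param profile a [CohortProfile-class] to serialise.
#' @return `readCohortProfile`: a validated [CohortProfile-class].
#' @export
readCohortProfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  co <- y$cohort
  if (is.null(co)) stop(path, ": missing 'cohort' block", call. = FALSE)
  titv <- if (!is.null(y[["titv"]])) y[["titv"]]$ti / y[["titv"]]$tv
          else if (!is.null(y[["titv_ratio"]])) y[["titv_ratio"]]
          else 1676 / 857
  args <- list(
    nDiscovery = co$n_discovery, nExtension = co$n_extension,
    nMatchedDiscovery = co$n_matched_discovery %||% 0L,
    nMatchedExtension = co$n_matched_extension %||% 0L,
    nPon = co$n_pon %||% 0L, nHyperplastic = co$n_hyperplastic %||% 0L,
    nRna = co$n_rna %||% 0L,
    exomeMb = y$exome_mb %||% 54,
    wesGenes = unlist(y$genes$wes),
    litGenes = unlist(y$genes$literature) %||% character(),
    geneFreqs = unlist(y$gene_freqs),
    perSampleBurden = unlist(y$per_sample_burden),
    titvRatio = titv, gcBias = y$gc_bias %||% 0.6,
    nBackground = y$n_background_genes %||% 200L,
    contamination = y$contamination %||% list(),
    survivalSpec = y$survival %||% list(),
    seed = y$seed %||% 42L)
  do.call(newCohortProfile, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readCohortProfile
#' @export
writeCohortProfile <- function(profile, path) {
  stopifnot(is(profile, "CohortProfile"))
  y <- list(
    cohort = list(
      n_discovery = profile@nDiscovery, n_extension = profile@nExtension,
      n_matched_discovery = profile@nMatchedDiscovery,
      n_matched_extension = profile@nMatchedExtension,
      n_pon = profile@nPon, n_hyperplastic = profile@nHyperplastic,
      n_rna = profile@nRna),
    exome_mb = profile@exomeMb,
    titv_ratio = profile@titvRatio, gc_bias = profile@gcBias,
    genes = list(wes = as.list(profile@wesGenes),
                 literature = as.list(profile@litGenes)),
    gene_freqs = as.list(profile@geneFreqs),
    per_sample_burden = as.list(profile@perSampleBurden),
    n_background_genes = profile@nBackground,
    contamination = profile@contamination,
    survival = profile@survivalSpec,
    seed = profile@seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The packaged reference cohort profile
#'
#' Encodes the published cohort this package emulates: 71 tumors (21
#' discovery + 50 extension, 12 with matched saliva: 4 discovery and 8
#' extension), 20 panel-of-normals saliva samples, 8 hyperplastic
#' lymph-node controls, 18 RNA-sequenced discovery tumors; a 137-gene panel
#' (92 exome-derived + 45 literature genes); per-gene mutated-tumor counts
#' (FAT1 28, KMT2C 23, TET2/KMT2D/NOTCH1 16, NOTCH2 14, CREBBP/ATM 11, TP63
#' 9, KMT2A 8, SETD2 7, DNMT3A/ASXL3 6, CHD1/MBD4/JAK3/TP53 5, STK3 4,
#' LATS1 3, STAT6 2, plus filler genes so exactly 52 genes reach two or more
#' mutated tumors); a discovery burden list with median 135 and range 6-204
#' over a 54 Mb exome; Ti/Tv 1676/857; and a 61-patient clinical layer with
#' group medians 11 and 26 months, 24% 3-year survival and 1-78 month
#' follow-up.
#'
#' @return a [CohortProfile-class].
#' @examples
#' p <- referenceProfile()
#' nTumors(p)            # 71
#' geneFreqs(p)[["FAT1"]] # 28
#' @export
referenceProfile <- function() {
  readCohortProfile(system.file("extdata", "reference_profile.yaml",
                                package = "SomaticScreen", mustWork = TRUE))
}
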