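#' Classify a base substitution as transition or transversion
#'
#' Purine-purine and pyrimidine-pyrimidine exchanges (A<->G, C<->T) are
#' transitions; all other single-base exchanges are transversions;
#' multi-base alleles (indels) are `not_snv`.
#'
#' @param ref,alt allele vectors.
#' @return character vector in `{"transition", "transversion", "not_snv"}`.
#' @examples
#' classifySubstitution("C", "T")  # transition
#' classifySubstitution("C", "A")  # transversion
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ifelse(!snv, "not_snv", ifelse(ti, "transition", "transversion"))
}

#' Mutation-spectrum summary (Ti/Tv and six substitution classes)
#'
#' Summarises SNVs into transition/transversion counts, the Ti/Tv ratio
#' (also truncated to one decimal, the conventional rendering), the six
#' pyrimidine-collapsed substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G; purine-reference substitutions are mapped through the reverse
#' complement), and the fraction of SNVs with a G or C reference base
#' (the "G/C targeting" statistic). Non-SNV records are ignored.
#'
#' @param ref,alt allele vectors, or a data.frame with `ref`/`alt` columns
#'   as the first argument.
#' @return a [SpectrumSummary-class]. With zero transversions the ratio is
#'   undefined and flagged (`tvZero`).
#' @examples
#' spectrumSummary(c("C", "C", "G"), c("T", "A", "A"))
#' @export
spectrumSummary <- function(ref, alt = NULL) {
  if (is.data.frame(ref)) { alt <- ref$alt; ref <- ref$ref }
  cls <- classifySubstitution(ref, alt)
  snv <- cls != "not_snv"
  if (!any(snv))
    stop("no single-nucleotide variants to summarise", call. = FALSE)
  ref <- toupper(ref[snv]); alt <- toupper(alt[snv]); cls <- cls[snv]
  ti <- sum(cls == "transition"); tv <- sum(cls == "transversion")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyrRef <- ifelse(ref %in% c("A", "G"), comp[ref], ref)
  pyrAlt <- ifelse(ref %in% c("A", "G"), comp[alt], alt)
  lvls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  six <- table(factor(paste0(pyrRef, ">", pyrAlt), levels = lvls))
  ratio <- if (tv == 0L) NaN else ti / tv
  new("SpectrumSummary",
      tiCount = as.integer(ti), tvCount = as.integer(tv),
      ratio = ratio,
      ratioTruncated = if (tv == 0L) NaN else floor(ratio * 10) / 10,
      tvZero = tv == 0L,
      sixClass = setNames(as.integer(six), lvls),
      gcTargetedFraction = mean(ref %in% c("G", "C")))
}

#' Per-sample mutation burden and per-megabase rates
#'
#' Counts retained nonsynonymous variants per sample and divides by the
#' effective exome size to obtain mutations/Mb; reports the per-sample
#' table plus cohort median and range of both scales. Samples listed in
#' `samples` but absent from the calls contribute zero counts.
#'
#' @param calls data.frame of retained calls with `sample_id` and (unless
#'   `nonsynOnly = FALSE`) an `effect` column.
#' @param exomeMb effective exome size in megabases (> 0).
#' @param samples optional character vector fixing the sample universe.
#' @param nonsynOnly restrict to nonsynonymous effects (default TRUE).
#' @return list: `perSample` (data.frame sample_id, count, rate_per_mb),
#'   `medianCount`, `rangeCount`, `medianRate`, `rangeRate`.
#' @export
mutationBurden <- function(calls, exomeMb, samples = NULL,
                           nonsynOnly = TRUE) {
  if (!is.numeric(exomeMb) || exomeMb <= 0)
    stop("exomeMb must be positive", call. = FALSE)
  if (nonsynOnly && !is.null(calls$effect))
    calls <- calls[isNonsynonymous(calls$effect), , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (length(samples) == 0L)
    stop("empty cohort: no samples to summarise", call. = FALSE)
  counts <- table(factor(calls$sample_id, levels = samples))
  per <- data.frame(sample_id = samples,
                    count = as.integer(counts),
                    rate_per_mb = as.integer(counts) / exomeMb)
  list(perSample = per,
       medianCount = median(per$count),
       rangeCount = range(per$count),
       medianRate = median(per$rate_per_mb),
       rangeRate = range(per$rate_per_mb))
}

#' Sample-collapsed gene recurrence matrix
#'
#' Builds the binary genes x samples matrix in which a cell is 1 when the
#' sample carries at least one retained variant in the gene — multiple
#' variants of a gene in one sample count once. Row sums therefore give
#' mutated-sample (not variant) counts.
#'
#' @param calls data.frame of retained calls with `gene` and `sample_id`.
#' @param samples optional sample universe (columns); defaults to samples
#'   observed in `calls`.
#' @param genes optional gene universe (rows).
#' @param minSamples recurrence threshold stored for [recurrentGenes()].
#' @return a [RecurrenceMatrix-class] (empty input gives a 0 x 0 matrix).
#' @export
recurrenceMatrix <- function(calls, samples = NULL, genes = NULL,
                             minSamples = 2L) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(calls)) {
    keep <- calls$gene %in% genes & calls$sample_id %in% samples
    tab <- unique(calls[keep, c("gene", "sample_id")])
    mat[cbind(tab$gene, tab$sample_id)] <- 1L
  }
  new("RecurrenceMatrix", mat = mat,
      counts = setNames(as.integer(rowSums(mat)), genes),
      minSamples = as.integer(minSamples))
}

#' Assemble a targeted sequencing panel
#'
#' Combines the exome-derived genes with literature genes into one panel.
#' The literature set must be disjoint from the exome set (it exists to add
#' genes \emph{not} recorded in the discovery screen); any overlap is an
#' error naming the offending genes.
#'
#' @param wesGenes,litGenes character vectors of gene symbols.
#' @return sorted character vector of length
#'   `length(wesGenes) + length(litGenes)`.
#' @examples
#' length(buildPanel(paste0("G", 1:92), paste0("L", 1:45)))  # 137
#' @export
buildPanel <- function(wesGenes, litGenes) {
  overlap <- intersect(wesGenes, litGenes)
  if (length(overlap))
    stop("literature genes already in the exome set: ",
         paste(sort(overlap), collapse = ", "), call. = FALSE)
  if (anyDuplicated(wesGenes) || anyDuplicated(litGenes))
    stop("duplicated gene symbols within a set", call. = FALSE)
  sort(c(wesGenes, litGenes))
}

#' Immunohistochemical H-score
#'
#' Product of the percentage of positive cells (0-100) and the staining
#' intensity (0-3), range 0-300.
#'
#' @param percentPositive numeric in \[0, 100\].
#' @param intensity numeric in \[0, 3\].
#' @return numeric H-score in \[0, 300\].
#' @examples
#' hScore(50, 2)  # 100
#' @export
hScore <- function(percentPositive, intensity) {
  if (any(percentPositive < 0 | percentPositive > 100))
    stop("percentPositive must lie in [0, 100]", call. = FALSE)
  if (any(intensity < 0 | intensity > 3))
    stop("intensity must lie in [0, 3]", call. = FALSE)
  percentPositive * intensity
}
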