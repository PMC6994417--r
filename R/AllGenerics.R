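#' Accessors for SomaticScreen classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x,object a SomaticScreen S4 object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTumors", function(x) standardGeneric("nTumors"))

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname accessors
#' @export
setGeneric("geneFreqs", function(x) standardGeneric("geneFreqs"))

#' @rdname accessors
#' @export
setGeneric("perSampleBurden", function(x) standardGeneric("perSampleBurden"))

#' @rdname accessors
#' @export
setGeneric("profileSeed", function(x) standardGeneric("profileSeed"))

#' @rdname accessors
#' @export
setGeneric("survivalSpec", function(x) standardGeneric("survivalSpec"))

#' @rdname accessors
#' @export
setGeneric("ponKeys", function(x) standardGeneric("ponKeys"))

#' @rdname accessors
#' @export
setGeneric("retainedCalls", function(x) standardGeneric("retainedCalls"))

#' @rdname accessors
#' @export
setGeneric("filterTrace", function(x) standardGeneric("filterTrace"))

#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' Kaplan-Meier median survival time
#'
#' Smallest time `t` with `S(t) <= 0.5`; `NA` when the curve never reaches
#' 0.5. When the curve sits exactly at 0.5 over a plateau, the plateau start
#' (the event time where 0.5 is first attained) is returned.
#'
#' @param x a [KMCurve-class].
#' @return median time in the curve's time unit, or `NA_real_`.
#' @export
setGeneric("kmMedian", function(x) standardGeneric("kmMedian"))

#' Survival probability at a fixed time
#'
#' Evaluates the product-limit estimate `S(t)` with right continuity.
#'
#' @param x a [KMCurve-class].
#' @param t time(s) at which to evaluate, same unit as the curve.
#' @return numeric vector of survival probabilities.
#' @export
setGeneric("survivalAt", function(x, t) standardGeneric("survivalAt"))

#' Recurrently mutated genes
#'
#' Genes whose mutated-sample count reaches the recurrence threshold, sorted
#' by count (decreasing) then gene name.
#'
#' @param x a [RecurrenceMatrix-class].
#' @param minSamples recurrence threshold; defaults to the one stored in `x`.
#' @return data.frame with columns `gene` and `n_samples`.
#' @export
setGeneric("recurrentGenes",
           function(x, minSamples = NULL) standardGeneric("recurrentGenes"))

## ---- CohortProfile accessors ----

#' @rdname accessors
#' @export
setMethod("nTumors", "CohortProfile",
          function(x) x@nDiscovery + x@nExtension)

#' @rdname accessors
#' @export
setMethod("panelGenes", "CohortProfile",
          function(x) sort(c(x@wesGenes, x@litGenes)))

#' @rdname accessors
#' @export
setMethod("geneFreqs", "CohortProfile", function(x) x@geneFreqs)

#' @rdname accessors
#' @export
setMethod("perSampleBurden", "CohortProfile", function(x) x@perSampleBurden)

#' @rdname accessors
#' @export
setMethod("profileSeed", "CohortProfile", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("survivalSpec", "CohortProfile", function(x) x@survivalSpec)

setMethod("show", "CohortProfile", function(object) {
  cat("CohortProfile\n")
  cat(sprintf("  tumors: %d (%d discovery + %d extension), %d matched pairs\n",
              nTumors(object), object@nDiscovery, object@nExtension,
              object@nMatchedDiscovery + object@nMatchedExtension))
  cat(sprintf("  normals: %d PoN saliva, %d hyperplastic controls, %d RNA-seq\n",
              object@nPon, object@nHyperplastic, object@nRna))
  cat(sprintf("  panel: %d genes (%d exome + %d literature), %d with planted variants\n",
              length(object@wesGenes) + length(object@litGenes),
              length(object@wesGenes), length(object@litGenes),
              sum(object@geneFreqs > 0L)))
  cat(sprintf("  burden: median %s per discovery patient; exome %.1f Mb\n",
              format(median(object@perSampleBurden)), object@exomeMb))
  cat(sprintf("  spectrum: Ti/Tv %.4f, G/C bias %.2f; seed %d\n",
              object@titvRatio, object@gcBias, object@seed))
})

## ---- SyntheticCohort ----

setMethod("show", "SyntheticCohort", function(object) {
  roles <- table(object@samples$role)
  cat("SyntheticCohort\n")
  cat("  samples:",
      paste(sprintf("%s=%d", names(roles), as.integer(roles)),
            collapse = ", "), "\n")
  cat(sprintf("  planted keys: %d (%s)\n", nrow(object@truth$classes),
              paste(sprintf("%s=%d",
                            names(table(object@truth$classes$class)),
                            as.integer(table(object@truth$classes$class))),
                    collapse = ", ")))
  cat(sprintf("  annotation rows: %d; clinical records: %d; seed %d\n",
              nrow(object@annotations), nrow(object@clinical), object@seed))
})

## ---- PanelOfNormals ----

#' @rdname accessors
#' @export
setMethod("ponKeys", "PanelOfNormals", function(x) x@keys)

setMethod("show", "PanelOfNormals", function(object) {
  cat(sprintf(
    "PanelOfNormals: %d keys from %d normal samples (>= %d reads)\n",
    length(object@keys), length(unique(object@provenance$sample_id)),
    object@minReads))
})

#' @describeIn accessors number of member keys in a panel of normals.
#' @export
setMethod("length", "PanelOfNormals", function(x) length(x@keys))

## ---- FilterResult ----

#' @rdname accessors
#' @export
setMethod("retainedCalls", "FilterResult",
          function(x) x@calls[x@calls$verdict == "retained", , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("filterTrace", "FilterResult", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("verdicts", "FilterResult", function(x)
  x@calls[, c("sample_id", "key", "verdict", "rejecting_gate")])

setMethod("show", "FilterResult", function(object) {
  cat(sprintf("FilterResult (%s cascade): %d calls, %d retained\n",
              object@cascade, nrow(object@calls),
              sum(object@calls$verdict == "retained")))
  rej <- table(object@calls$rejecting_gate)
  if (length(rej))
    cat("  rejections:",
        paste(sprintf("%s=%d", names(rej), as.integer(rej)),
              collapse = ", "), "\n")
})

## ---- SpectrumSummary ----

setMethod("show", "SpectrumSummary", function(object) {
  cat(sprintf("SpectrumSummary: %d Ti, %d Tv; Ti/Tv = %s (%.4f)\n",
              object@tiCount, object@tvCount,
              if (object@tvZero) "undefined" else
                format(object@ratioTruncated, nsmall = 1),
              object@ratio))
  cat("  classes:",
      paste(sprintf("%s=%d", names(object@sixClass),
                    as.integer(object@sixClass)), collapse = ", "), "\n")
  cat(sprintf("  G/C-targeted fraction: %.3f\n", object@gcTargetedFraction))
})

## ---- RecurrenceMatrix ----

#' @rdname recurrentGenes
#' @export
setMethod("recurrentGenes", "RecurrenceMatrix",
  function(x, minSamples = NULL) {
    if (is.null(minSamples)) minSamples <- x@minSamples
    keep <- x@counts >= minSamples
    out <- data.frame(gene = names(x@counts)[keep],
                      n_samples = as.integer(x@counts[keep]))
    out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  })

setMethod("show", "RecurrenceMatrix", function(object) {
  cat(sprintf("RecurrenceMatrix: %d genes x %d samples; %d genes in >= %d samples\n",
              nrow(object@mat), ncol(object@mat),
              sum(object@counts >= object@minSamples), object@minSamples))
})

#' @describeIn accessors genes x samples dimension of a recurrence matrix.
#' @export
setMethod("dim", "RecurrenceMatrix", function(x) dim(x@mat))

## ---- KMCurve ----

setMethod("show", "KMCurve", function(object) {
  med <- kmMedian(object)
  cat(sprintf("KMCurve: n = %d, %d events at %d distinct times, %d censored\n",
              object@n, sum(object@nEvent), length(object@time),
              length(object@censTimes)))
  cat(sprintf("  median: %s\n",
              if (is.na(med)) "not reached" else format(med)))
})

## ---- LogRankResult ----

setMethod("show", "LogRankResult", function(object) {
  cat("Mantel-Cox log-rank test\n")
  for (i in 1:2)
    cat(sprintf("  %s: observed %g, expected %.2f\n",
                object@groups[i], object@observed[i], object@expected[i]))
  cat(sprintf("  chisq = %.4f (1 df), p = %.4g\n",
              object@chisq, object@pValue))
})
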