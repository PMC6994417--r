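#' Consensus damaging-prediction vote
#'
#' A missense variant is called functionally consequential when at least
#' `minDamaging` of the nine structure/homology-based predictors
#' (PolyPhen-2, PolyPhen-2 HVAR/HDIV, LRT, MutationTaster, FATHMM,
#' RadialSVM, LR, MutationAssessor) call it damaging. A missing predictor
#' output (`"."`) counts against the vote (conservative).
#'
#' @param calls predictor calls: a character vector of length 9, or a
#'   matrix/data.frame with 9 columns (`pred_1..pred_9`), values `"D"`
#'   (damaging), `"T"` (tolerated) or `"."` (missing).
#' @param minDamaging votes required (default 4).
#' @return logical vector, one element per variant. The vote is monotone:
#'   adding a damaging call never flips `TRUE` to `FALSE`.
#' @examples
#' damagingVote(c("D", "D", "D", "D", "T", "T", "T", "T", "."))  # TRUE
#' @export
damagingVote <- function(calls, minDamaging = 4L) {
  if (is.null(dim(calls))) {
    if (length(calls) != 9L)
      stop("exactly 9 predictor calls are required", call. = FALSE)
    calls <- matrix(as.character(calls), nrow = 1L)
  } else {
    calls <- as.matrix(calls)
    if (ncol(calls) != 9L)
      stop("exactly 9 predictor slots are required", call. = FALSE)
  }
  bad <- !(calls %in% c("D", "T", "."))
  if (any(bad))
    stop("predictor calls must be D, T or .", call. = FALSE)
  unname(rowSums(calls == "D") >= minDamaging)
}

#' Protein-stability classification from predicted folding free energy
#'
#' A missense variant is destabilizing when its predicted folding
#' free-energy change is below -0.5 kcal/mol (strict inequality: a variant
#' at exactly the threshold is non-destabilizing). `NA` (non-missense or
#' unscored) yields `"not_applicable"`.
#'
#' @param ddg numeric vector of free-energy changes (kcal/mol), `NA`
#'   allowed.
#' @param threshold destabilisation threshold (default -0.5).
#' @return character vector in `{"destabilizing", "non_destabilizing",
#'   "not_applicable"}`.
#' @examples
#' classifyStability(c(-1.2, -0.5, NA))
#' @export
classifyStability <- function(ddg, threshold = -0.5) {
  ifelse(is.na(ddg), "not_applicable",
         ifelse(ddg < threshold, "destabilizing", "non_destabilizing"))
}

#' Destabilizing fraction of a gene's missense variants
#'
#' Counts destabilizing calls (`k`) among the applicable (scored missense)
#' calls (`n`). Given a data.frame of annotated retained calls the input is
#' first restricted to missense variants of `gene`.
#'
#' @param x numeric ddG vector, or a data.frame with `gene`, `effect` and
#'   `ddg` columns.
#' @param gene gene symbol (required for data.frame input).
#' @param threshold see [classifyStability()].
#' @return integer vector `c(k, n)` with `k <= n`.
#' @examples
#' destabilizingFraction(c(-1, -0.6, 0.2))   # k = 2, n = 3
#' @export
destabilizingFraction <- function(x, gene = NULL, threshold = -0.5) {
  if (is.data.frame(x)) {
    if (is.null(gene))
      stop("gene must be given for data.frame input", call. = FALSE)
    x <- x$ddg[x$gene == gene & x$effect == "missense"]
  }
  lab <- classifyStability(x, threshold)
  c(k = sum(lab == "destabilizing"),
    n = sum(lab != "not_applicable"))
}

#' Consequence step of the targeted pipeline
#'
#' Restricts retained calls to those with predicted functional consequence:
#' missense variants must win the [damagingVote()]; protein-truncating and
#' splice-site classes (stop-gain, frameshift, splicing) pass by class, as
#' structure/homology predictors only score amino-acid substitutions.
#' Synonymous/intronic calls (normally removed upstream) are dropped.
#'
#' @param calls data.frame of retained, annotated calls (must carry
#'   `effect` and `pred_1..pred_9`).
#' @param minDamaging votes required for missense variants.
#' @return the filtered data.frame.
#' @export
consequenceFilter <- function(calls, minDamaging = 4L) {
  if (nrow(calls) == 0L) return(calls)
  keep <- isNonsynonymous(calls$effect) &
    (calls$effect != "missense" |
       damagingVote(calls[, .PRED_COLS], minDamaging))
  calls[keep, , drop = FALSE]
}
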