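## Native Kaplan-Meier product-limit estimation and Mantel-Cox log-rank
## testing. These are implemented in the package (not delegated) because
## the exact tie and median conventions are part of the pipeline's
## contract; the survival package serves as an independent cross-check in
## the test suite only.

.survivalInput <- function(x, event = NULL) {
  if (is.data.frame(x)) {
    time <- x$os_months; event <- x$event
  } else { time <- x }
  if (length(time) == 0L)
    stop("at least one survival record is required", call. = FALSE)
  if (any(is.na(time)) || any(time < 0))
    stop("survival times must be nonnegative", call. = FALSE)
  list(time = as.numeric(time), event = as.logical(event))
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times
#' `t_i`, with `d_i` events among `n_i` at risk. Observations censored at
#' an event time are counted at risk at that time (events before
#' censorings, the standard convention).
#'
#' @param x data.frame with `os_months` and `event` columns (e.g. a
#'   clinical table), or a numeric time vector.
#' @param event logical/0-1 event vector (death = TRUE) when `x` is a
#'   vector.
#' @return a [KMCurve-class].
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
#' survivalAt(km, 2)   # 0.5
#' kmMedian(km)        # 2
#' @export
kmEstimate <- function(x, event = NULL) {
  inp <- .survivalInput(x, event)
  time <- inp$time; ev <- inp$event
  evTimes <- sort(unique(time[ev]))
  nRisk <- vapply(evTimes, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(evTimes, function(t) sum(ev & time == t), numeric(1))
  nCens <- vapply(evTimes, function(t) sum(!ev & time == t), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  new("KMCurve", time = evTimes, nRisk = nRisk, nEvent = nEvent,
      surv = surv, censTimes = sort(time[!ev]), n = length(time))
}

#' @rdname survivalAt
#' @export
setMethod("survivalAt", "KMCurve", function(x, t) {
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  s <- c(1, x@surv)
  s[findInterval(t, x@time) + 1L]
})

#' @rdname kmMedian
#' @export
setMethod("kmMedian", "KMCurve", function(x) {
  i <- which(x@surv <= 0.5 + 1e-12)
  if (length(i) == 0L) return(NA_real_)
  x@time[i[1L]]
})

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct pooled event time the expected group-1 events are the
#' hypergeometric mean `d_j * n_1j / n_j` with variance
#' `d_j (n_1j/n_j)(n_2j/n_j)(n_j - d_j)/(n_j - 1)`; the statistic is
#' `(O_1 - E_1)^2 / V` on 1 df (the summed-variance Mantel-Cox form, not
#' the pooled `(O-E)^2/E` approximation). The statistic is invariant under
#' swapping the group labels.
#'
#' @param groupA,groupB data.frames with `os_months` and `event` columns.
#' @param labels group labels for reporting.
#' @return a [LogRankResult-class].
#' @export
logrankTest <- function(groupA, groupB,
                        labels = c("groupA", "groupB")) {
  a <- .survivalInput(groupA); b <- .survivalInput(groupB)
  time <- c(a$time, b$time); ev <- c(a$event, b$event)
  g1 <- c(rep(TRUE, length(a$time)), rep(FALSE, length(b$time)))
  if (!any(ev))
    stop("no events in either group; log-rank test undefined",
         call. = FALSE)
  evTimes <- sort(unique(time[ev]))
  e1 <- v <- 0
  o1 <- sum(ev & g1); o2 <- sum(ev & !g1)
  e2 <- 0
  for (t in evTimes) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(ev & time == t)
    e1 <- e1 + d * n1 / n
    e2 <- e2 + d * (n - n1) / n
    if (n > 1L)
      v <- v + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  new("LogRankResult", groups = labels,
      observed = c(o1, o2), expected = c(e1, e2), variance = v,
      chisq = chisq, pValue = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Stratify clinical records by gene mutation status
#'
#' Partitions the clinical table into patients carrying at least one
#' retained nonsynonymous variant of `gene` versus wild-type patients. The
#' partition is exhaustive and disjoint over the clinical records; mutated
#' patients lacking a clinical record are dropped (with a message).
#'
#' @param calls data.frame of retained calls (`sample_id`, `gene`,
#'   `effect`).
#' @param clinical data.frame with `patient_id`, `os_months`, `event`.
#' @param gene gene symbol to stratify by.
#' @param knownGenes gene universe used to validate `gene`; defaults to
#'   the genes observed in `calls`.
#' @return list with data.frames `mutated` and `wildtype`, each carrying a
#'   `group` column.
#' @export
stratifyByGene <- function(calls, clinical, gene,
                           knownGenes = unique(calls$gene)) {
  if (!(gene %in% knownGenes))
    stop("unknown gene: ", gene, call. = FALSE)
  hit <- calls$gene == gene & isNonsynonymous(calls$effect)
  mutSamples <- unique(calls$sample_id[hit])
  missing <- setdiff(mutSamples, clinical$patient_id)
  if (length(missing))
    message(length(missing),
            " mutated patient(s) without clinical record excluded: ",
            paste(missing, collapse = ", "))
  isMut <- clinical$patient_id %in% mutSamples
  mut <- clinical[isMut, , drop = FALSE]
  wt <- clinical[!isMut, , drop = FALSE]
  mut$group <- "mutated"; wt$group <- "wildtype"
  rownames(mut) <- rownames(wt) <- NULL
  list(mutated = mut, wildtype = wt)
}
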