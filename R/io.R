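## Readers and writers for the native interchange formats.
##
## Native variant TSV (column order fixed):
##   sample_id chrom pos ref alt depth alt_reads [vaf] [quality_ok]
## vaf defaults to alt_reads/depth, quality_ok to TRUE when absent.
##
## Annotation TSV (one row per variant key):
##   chrom pos ref alt gene effect dist_to_cds in_dbsnp dbsnp_pathogenic
##   kg_af in_cosmic pred_1..pred_9 ddg context41
## Predictor calls are D (damaging), T (tolerated) or "." (missing);
## ddg and context41 use "." when absent.

.ANNOT_COLS <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                 "dist_to_cds", "in_dbsnp", "dbsnp_pathogenic", "kg_af",
                 "in_cosmic", .PRED_COLS, "ddg", "context41")

#' Read a variant table
#'
#' Reads per-sample variant calls either from the package's native TSV
#' dialect or from a VCF 4.x file. VCF fields map to the dialect as:
#' `FORMAT/DP` to `depth`, the alt entry of `FORMAT/AD` to `alt_reads`,
#' and `FILTER` in `PASS`/`.` to `quality_ok`. Multi-allelic VCF records are
#' split into one record per alternate allele; one record is emitted per
#' (sample, site, alt allele).
#'
#' @param path file to read.
#' @param dialect `"tsv"` (native, default) or `"vcf"`.
#' @param sample_id sample name to use for VCF input without genotype
#'   samples, or to override the VCF sample names.
#' @return data.frame in the native dialect with the identity `key` column;
#'   zero rows for a header-only file.
#' @seealso [writeMafLike()], [validateVariantTable()]
#' @export
readVariantTable <- function(path, dialect = c("tsv", "vcf"),
                             sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    ## read everything as character first: allele columns like "T" must
    ## not be parsed as logicals
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, colClasses = "character")
    for (cc in intersect(c("pos", "depth", "alt_reads"), names(df)))
      df[[cc]] <- as.integer(df[[cc]])
    if (!is.null(df$vaf)) df$vaf <- as.numeric(df$vaf)
    if (!is.null(df$quality_ok))
      df$quality_ok <- df$quality_ok %in% c("TRUE", "T", "1")
    return(validateVariantTable(df, where = path))
  }
  .readVcfTable(path, sample_id = sample_id)
}

.readVcfTable <- function(path, sample_id = NULL) {
  for (pkg in c("VariantAnnotation", "SummarizedExperiment"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("reading VCF requires the ", pkg, " package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  ex <- VariantAnnotation::expand(vcf)       # one row per alt allele
  rr <- SummarizedExperiment::rowRanges(ex)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(ex))
  alt <- as.character(VariantAnnotation::alt(ex))
  filt <- VariantAnnotation::filt(ex)
  qok <- is.na(filt) | filt %in% c("PASS", ".")
  gt <- VariantAnnotation::geno(ex)
  samples <- colnames(ex)
  if (length(samples) == 0L)
    stop(path, ": VCF has no genotype samples; supply per-sample calls",
         call. = FALSE)
  takeAlt <- function(x) {       # alt entry of an (expanded) AD field
    x <- unlist(x, use.names = FALSE)
    if (length(x) == 0L || all(is.na(x))) NA_integer_
    else as.integer(x[length(x)])
  }
  out <- lapply(seq_along(samples), function(j) {
    ad <- if ("AD" %in% names(gt)) {
      if (length(dim(gt$AD)) == 3L) as.integer(gt$AD[, j, 2L])
      else {
        adj <- gt$AD[, j]
        if (is.list(adj)) vapply(adj, takeAlt, integer(1))
        else as.integer(adj)
      }
    } else rep(NA_integer_, length(pos))
    dp <- if ("DP" %in% names(gt)) as.integer(gt$DP[, j])
          else rep(NA_integer_, length(pos))
    dp[is.na(dp)] <- ad[is.na(dp)]
    ad[is.na(ad)] <- 0L
    makeVariantTable(
      sample_id = if (is.null(sample_id)) samples[j] else sample_id,
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      depth = pmax(dp, ad), alt_reads = ad, quality_ok = qok)
  })
  do.call(rbind, out)
}

#' Write retained variants as a MAF-like TSV
#'
#' One row per call with gene, effect, read evidence, the verdict and the
#' attributed rejecting gate. All written fields round-trip losslessly
#' through [readMafLike()]; the VAF is printed at full double precision.
#'
#' @param x a [FilterResult-class] (all adjudicated calls are written) or a
#'   data.frame carrying the MAF-like columns.
#' @param path output file.
#' @param retainedOnly write only retained calls (default TRUE for a
#'   `FilterResult`).
#' @return `path`, invisibly.
#' @export
writeMafLike <- function(x, path, retainedOnly = TRUE) {
  if (is(x, "FilterResult"))
    x <- if (retainedOnly) retainedCalls(x) else x@calls
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
            "depth", "alt_reads", "vaf", "verdict", "rejecting_gate")
  for (cc in setdiff(cols, names(x))) x[[cc]] <- NA
  out <- x[, cols, drop = FALSE]
  out$vaf <- .fmtNum(out$vaf)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname writeMafLike
#' @export
readMafLike <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  chrom = "character", ref = "character",
                                  alt = "character"))
  df
}

#' Read and write annotation tables
#'
#' The annotation table carries, per variant key: gene symbol, effect class,
#' distance to the coding sequence (0 for exonic), dbSNP membership and
#' pathogenicity flag, 1000 Genomes allele frequency, COSMIC membership, the
#' nine predictor calls (`pred_1..pred_9`, values `D`/`T`/`.`), the predicted
#' protein-stability change `ddg` (kcal/mol, `.` for non-missense) and the
#' 41-base flanking context (`.` when absent).
#'
#' @param path file to read or write.
#' @param df annotation data.frame.
#' @return `readAnnotationTable`: validated data.frame with `key` column.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  charCols <- c("chrom", "ref", "alt", "gene", "effect", "context41",
                .PRED_COLS)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA",
                   colClasses = setNames(rep("character",
                                             length(charCols)), charCols))
  df$ddg <- as.numeric(ifelse(df$ddg == ".", NA, df$ddg))
  df$context41[df$context41 == "."] <- NA_character_
  validateAnnotationTable(df, where = path)
}

#' @rdname readAnnotationTable
#' @export
writeAnnotationTable <- function(df, path) {
  df <- validateAnnotationTable(df)
  out <- df[, .ANNOT_COLS]
  out$ddg <- ifelse(is.na(out$ddg), ".", .fmtNum(out$ddg))
  out$context41[is.na(out$context41)] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readAnnotationTable
#' @param where label for error messages.
#' @export
validateAnnotationTable <- function(df, where = "annotation table") {
  miss <- setdiff(.ANNOT_COLS, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(df$effect %in% .EFFECTS))
    stop(where, ": unknown effect class: ",
         paste(setdiff(unique(df$effect), .EFFECTS), collapse = ", "),
         call. = FALSE)
  predOk <- vapply(df[.PRED_COLS],
                   function(p) all(p %in% c("D", "T", ".")), logical(1))
  if (!all(predOk))
    stop(where, ": predictor calls must be D, T or .", call. = FALSE)
  ctx <- df$context41[!is.na(df$context41)]
  if (any(nchar(ctx) != 41L))
    stop(where, ": context41 must be 41 bases when present", call. = FALSE)
  df$key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key))
    stop(where, ": duplicated variant keys", call. = FALSE)
  df
}

#' Read and write clinical tables
#'
#' Clinical TSV: `patient_id`, `os_months` (overall survival from diagnosis
#' to death or last follow-up), `event` (1 = death, 0 = censored).
#'
#' @param path file to read or write.
#' @param df clinical data.frame.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(patient_id = "character"))
  need <- c("patient_id", "os_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$os_months < 0))
    stop(path, ": os_months must be nonnegative", call. = FALSE)
  df$event <- as.logical(df$event)
  df[, need]
}

#' @rdname readClinicalTable
#' @export
writeClinicalTable <- function(df, path) {
  out <- df[, c("patient_id", "os_months", "event")]
  out$event <- as.integer(out$event)
  out$os_months <- .fmtNum(out$os_months)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
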