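#' Variant identity key
#'
#' All set operations (panel-of-normals membership, control subtraction,
#' RNA concordance, truth bookkeeping) key variants by
#' `chrom:pos:ref:alt`, sample-agnostic. Coordinates are 1-based VCF-style;
#' indels are normalised with [normalizeVariant()] before keying so that a
#' given allele always maps to one key.
#'
#' @param chrom,pos,ref,alt vectors describing the variants.
#' @param normalize normalise indel representation first (default TRUE).
#' @return character vector of keys.
#' @examples
#' variantKey("chr4", 187518852, "C", "T")
#' @export
variantKey <- function(chrom, pos, ref, alt, normalize = TRUE) {
  if (normalize) {
    nv <- normalizeVariant(chrom, pos, ref, alt)
    chrom <- nv$chrom; pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Minimal left-aligned variant representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing the
#' position), yielding the minimal representation used for identity keys.
#' SNVs are untouched.
#'
#' @inheritParams variantKey
#' @return list with components `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalizeVariant("chr1", 100, "CTT", "CT")  # -> ref "CT", alt "C"
#' @export
normalizeVariant <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  n <- length(ref)
  fix <- which(nchar(ref) > 1L & nchar(alt) > 1L & ref != alt)
  for (i in fix) {
    r <- strsplit(ref[i], "")[[1]]; a <- strsplit(alt[i], "")[[1]]
    # shared suffix (keep at least one base each)
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]; a <- a[-1L]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

## Required columns of the native variant-table dialect, in file order.
.VARIANT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt",
                   "depth", "alt_reads", "vaf", "quality_ok")

#' Construct and validate a variant table
#'
#' Builds a variant table in the native dialect from per-call vectors. The
#' variant allele fraction is defined as `alt_reads / depth` at the site
#' (0 when depth is 0) and is recomputed from the counts.
#'
#' @param sample_id,chrom,pos,ref,alt,depth,alt_reads call fields.
#' @param quality_ok logical caller-quality flag (default TRUE).
#' @return validated data.frame with the native columns, including `key`.
#' @export
makeVariantTable <- function(sample_id, chrom, pos, ref, alt, depth,
                             alt_reads, quality_ok = TRUE) {
  n <- length(pos)
  sample_id <- rep(as.character(sample_id), length.out = n)
  quality_ok <- rep(as.logical(quality_ok), length.out = n)
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   depth = as.integer(depth),
                   alt_reads = as.integer(alt_reads),
                   quality_ok = as.logical(quality_ok))
  df$vaf <- ifelse(df$depth > 0L, df$alt_reads / df$depth, 0)
  df <- df[, .VARIANT_COLS]
  validateVariantTable(df)
}

#' Validate a variant table against the dialect invariants
#'
#' Checks: required columns present; positions >= 1; ref != alt; alt-read
#' counts bounded by depth; stored VAF equal to `alt_reads/depth` within
#' 1e-9 (0 at zero depth). Adds the identity `key` column.
#'
#' @param df data.frame to check.
#' @param where label used in error messages (e.g. a file name).
#' @return the table, with `key` attached.
#' @export
validateVariantTable <- function(df, where = "variant table") {
  miss <- setdiff(setdiff(.VARIANT_COLS, c("vaf", "quality_ok")), names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(df$vaf))
    df$vaf <- ifelse(df$depth > 0L, df$alt_reads / df$depth, 0)
  if (is.null(df$quality_ok)) df$quality_ok <- TRUE
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s: %s at line %s", where, what,
                   paste(i + 1L, collapse = ", ")), call. = FALSE)
  }
  bad(is.na(df$pos) | df$pos < 1L, "position must be >= 1")
  bad(!nzchar(df$chrom), "empty chromosome name")
  bad(df$ref == df$alt, "ref and alt alleles are identical")
  bad(!nzchar(df$ref) | !nzchar(df$alt), "empty allele")
  bad(is.na(df$depth) | df$depth < 0L | is.na(df$alt_reads) |
        df$alt_reads < 0L, "negative or missing read count")
  bad(df$alt_reads > df$depth, "alt_reads exceeds depth")
  expected <- ifelse(df$depth > 0L, df$alt_reads / df$depth, 0)
  bad(abs(df$vaf - expected) > 1e-9,
      "vaf inconsistent with alt_reads/depth")
  df$key <- variantKey(df$chrom, df$pos, df$ref, df$alt)
  df
}

## Derive a 31-bit child seed from a user seed and a stage tag, so that every
## stage of a run draws from an independent, reproducible stream.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Nonsynonymous (protein-altering) effect predicate.
isNonsynonymous <- function(effect) effect %in% .NONSYN_EFFECTS

## Format a numeric so it survives a text round trip bit-exactly.
.fmtNum <- function(x) sprintf("%.17g", x)
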