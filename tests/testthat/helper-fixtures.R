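# Shared fixtures: a down-scaled cohort profile for fast tests, and small
# constructors for annotation rows and variant calls.

smallProfile <- function(seed = 7L) {
  newCohortProfile(
    nDiscovery = 4L, nExtension = 6L,
    nMatchedDiscovery = 2L, nMatchedExtension = 2L,
    nPon = 4L, nHyperplastic = 2L, nRna = 3L,
    exomeMb = 10,
    wesGenes = c("FAT1", "TET2", "TP53", "GENEA", "GENEB"),
    litGenes = c("LITA", "LITB"),
    geneFreqs = c(FAT1 = 3L, TET2 = 2L, TP53 = 2L, GENEA = 1L),
    perSampleBurden = c(5L, 8L, 10L, 12L),
    titvRatio = 2, gcBias = 0.5,
    nBackground = 30L,
    contamination = list(germline_per_tumor = 8L, artifact_per_tumor = 4L,
                         germline_pool = 30L, artifact_pool = 10L,
                         artifact_dup = 2L),
    survivalSpec = list(n_clinical = 9L, gene = "FAT1",
                        median_mutated = 5, median_wildtype = 10,
                        survival_at_36m = 0.25,
                        followup_range = c(1, 40)),
    seed = seed)
}

# cached small bundle (generated once per test file)
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateCohort(smallProfile(), seed = 7)
    cache
  }
})

# one annotation row with overridable fields; defaults describe a clean
# COSMIC-listed somatic missense call with a unanimous damaging vote
annotRow <- function(pos, chrom = "chr1", ref = "C", alt = "T",
                     gene = "FAT1", effect = "missense", dist_to_cds = 0L,
                     in_dbsnp = FALSE, dbsnp_pathogenic = FALSE,
                     kg_af = 0, in_cosmic = TRUE,
                     preds = rep("D", 9), ddg = NA_real_,
                     context41 = NA_character_) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, gene = gene, effect = effect,
                   dist_to_cds = as.integer(dist_to_cds),
                   in_dbsnp = in_dbsnp, dbsnp_pathogenic = dbsnp_pathogenic,
                   kg_af = kg_af, in_cosmic = in_cosmic)
  pm <- matrix(preds, nrow = 1,
               dimnames = list(NULL, paste0("pred_", 1:9)))
  cbind(df, as.data.frame(pm), ddg = ddg, context41 = context41)
}

callRow <- function(pos, sample_id = "S1", chrom = "chr1", ref = "C",
                    alt = "T", depth = 100L, alt_reads = 30L,
                    quality_ok = TRUE) {
  makeVariantTable(sample_id, chrom, pos, ref, alt, depth, alt_reads,
                   quality_ok)
}

# brute-force panel-of-normals oracle: plain loop over every table/row
bruteForcePon <- function(tables, minReads) {
  keys <- character()
  for (tb in tables)
    for (i in seq_len(nrow(tb)))
      if (tb$alt_reads[i] >= minReads)
        keys <- union(keys, variantKey(tb$chrom[i], tb$pos[i],
                                       tb$ref[i], tb$alt[i]))
  sort(keys)
}

# brute-force context-uniqueness oracle: character scan counting forward
# and reverse-complement exact matches, overlaps included
bruteForceContextUnique <- function(context, refStr) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  countHits <- function(pat) {
    n <- 0L
    for (i in seq_len(nchar(refStr) - nchar(pat) + 1L))
      if (substring(refStr, i, i + nchar(pat) - 1L) == pat) n <- n + 1L
    n
  }
  (countHits(context) + countHits(rc(context))) == 1L
}
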