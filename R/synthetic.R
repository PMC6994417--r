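## Synthetic cohort generator.
##
## The generator plants three classes of variants with known truth labels:
##   somatic  - survive both filtering cascades by construction (deep
##              coverage, VAF > 0.25, >= 3 alt reads, COSMIC members, zero
##              population frequency, absent from every normal, unique
##              flanking context, nonsynonymous effect);
##   germline - dbSNP members with 1000 Genomes AF > 0.01, present at ~50%
##              VAF in the tumor and (where one exists) the matched normal,
##              and scattered through the normal panels;
##   artifact - recurrent technical calls present with >= 2 supporting reads
##              in panel-of-normals and hyperplastic-control samples; a
##              configurable subset sits in duplicated-context regions of
##              the toy reference (pseudogene-style multi-mapping mimics).
## Running the filtering cascades on a generated bundle must recover exactly
## the planted somatic set; that full-recovery property is the backbone of
## the package's validation suite.

## sample() that never falls into the length-1 integer trap
.resample <- function(x, size, replace = FALSE)
  x[sample.int(length(x), size, replace = replace)]

#' Draw substitution (ref, alt) pairs with a fixed Ti/Tv ratio and G/C bias
#'
#' The reference base is G or C with probability `gcBias` (uniform within
#' the class); the substitution is a transition with probability
#' `titvRatio / (1 + titvRatio)`, so the empirical Ti/Tv ratio of many draws
#' converges to `titvRatio`. Transversion partners are chosen uniformly.
#'
#' @param titvRatio target transition/transversion ratio (> 0; `Inf` gives
#'   transitions only).
#' @param gcBias probability of a G/C reference base, in \[0, 1\].
#' @param n number of draws.
#' @return data.frame with columns `ref` and `alt`.
#' @examples
#' set.seed(1)
#' table(classifySubstitution(sampleSubstitution(2, 0.5, 100)$ref,
#'                            sampleSubstitution(2, 0.5, 100)$alt))
#' @export
sampleSubstitution <- function(titvRatio, gcBias, n = 1L) {
  if (!is.numeric(titvRatio) || length(titvRatio) != 1L || titvRatio <= 0)
    stop("titvRatio must be a single positive number", call. = FALSE)
  if (!is.numeric(gcBias) || length(gcBias) != 1L ||
      gcBias < 0 || gcBias > 1)
    stop("gcBias must lie in [0, 1]", call. = FALSE)
  gc <- runif(n) < gcBias
  ref <- ifelse(gc, .resample(c("G", "C"), n, replace = TRUE),
                    .resample(c("A", "T"), n, replace = TRUE))
  data.frame(ref = ref, alt = .altGivenRef(ref, titvRatio))
}

## alt allele for fixed reference bases at a given Ti/Tv ratio
.altGivenRef <- function(ref, titvRatio) {
  pTi <- if (is.infinite(titvRatio)) 1 else titvRatio / (1 + titvRatio)
  tiPartner <- c(A = "G", G = "A", C = "T", T = "C")
  tvPartner <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
  isTi <- runif(length(ref)) < pTi
  alt <- tiPartner[ref]
  tv <- which(!isTi)
  alt[tv] <- vapply(ref[tv], function(b) .resample(tvPartner[[b]], 1L), "")
  unname(alt)
}

## ---- toy reference layout ------------------------------------------------

## Deterministic coordinate layout on one toy chromosome: panel genes first
## (2 kb each, 1 kb gaps), then background gene intervals that absorb the
## discovery burden variants, then duplicated-context blocks (each source
## block is copied verbatim elsewhere so any 41-mer inside occurs twice).
.cohortLayout <- function(profile) {
  genes <- panelGenes(profile)
  gw <- 2000L; gap <- 1000L
  panelStart <- 1001L
  gStart <- panelStart + (seq_along(genes) - 1L) * (gw + gap)
  panel <- data.frame(gene = genes, start = gStart, end = gStart + gw - 1L)
  bgN <- profile@nBackground
  bgw <- 2000L; bggap <- 500L
  bgStart0 <- max(panel$end) + 2000L
  bgStart <- bgStart0 + (seq_len(bgN) - 1L) * (bgw + bggap)
  bg <- data.frame(gene = sprintf("BKG%03d", seq_len(bgN)),
                   start = bgStart, end = bgStart + bgw - 1L)
  nDupKeys <- profile@contamination$artifact_dup
  nBlocks <- if (nDupKeys > 0L) max(1L, ceiling(nDupKeys / 4L)) else 0L
  bw <- 200L
  dupBase <- if (bgN > 0L) max(bg$end) + 2000L else max(panel$end) + 2000L
  src <- dupBase + (seq_len(nBlocks) - 1L) * (bw + 200L)
  cpyBase <- if (nBlocks > 0L) max(src) + bw + 2000L else dupBase
  cpy <- cpyBase + (seq_len(nBlocks) - 1L) * (bw + 200L)
  refLength <- (if (nBlocks > 0L) max(cpy) + bw else dupBase) + 1000L
  list(chrom = "chrT", panel = panel, bg = bg,
       dupSrc = src, dupCpy = cpy, dupWidth = bw,
       refLength = as.integer(refLength))
}

## Random toy reference with the layout's duplicated blocks stamped in.
.makeToyReference <- function(layout) {
  chars <- .resample(c("A", "C", "G", "T"), layout$refLength,
                     replace = TRUE)
  for (i in seq_along(layout$dupSrc)) {
    s <- layout$dupSrc[i]; d <- layout$dupCpy[i]; w <- layout$dupWidth
    chars[d:(d + w - 1L)] <- chars[s:(s + w - 1L)]
  }
  chars
}

#' Gene map of the toy reference
#'
#' @param profile a [CohortProfile-class].
#' @return [GenomicRanges::GRanges] with one interval per panel gene and per
#'   background gene (`type` metadata column distinguishes them).
#' @export
toyGeneMap <- function(profile) {
  lay <- .cohortLayout(profile)
  df <- rbind(cbind(lay$panel, type = "panel"),
              cbind(lay$bg, type = "background"))
  GenomicRanges::GRanges(
    seqnames = lay$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    gene = df$gene, type = df$type)
}

## per-gene / background position pools keyed by reference base, consumed
## without replacement so variant keys never collide
.posPools <- function(chars, layout) {
  env <- new.env(parent = emptyenv())
  env$pools <- list()
  mkPool <- function(idx) {
    sp <- split(idx, chars[idx])
    lapply(sp, function(v) .resample(v, length(v)))
  }
  env$get <- function(region) {
    if (is.null(env$pools[[region]])) {
      idx <- if (region == ".bg") {
        unlist(lapply(seq_len(nrow(layout$bg)), function(i)
          layout$bg$start[i]:layout$bg$end[i]), use.names = FALSE)
      } else {
        r <- layout$panel[layout$panel$gene == region, ]
        r$start:r$end
      }
      env$pools[[region]] <- mkPool(idx)
    }
    env$pools[[region]]
  }
  env$take <- function(region, base) {
    p <- env$get(region)
    avail <- p[[base]]
    if (length(avail) == 0L)
      stop("position pool exhausted for ", region, "/", base,
           call. = FALSE)
    pos <- avail[1L]
    env$pools[[region]][[base]] <- avail[-1L]
    pos
  }
  env$takeMany <- function(region, bases) {
    vapply(bases, function(b) env$take(region, b), integer(1))
  }
  env
}

## ---- effect / predictor design -------------------------------------------

## Missense/destabilising structure for the tumor-suppressor genes whose
## published destabilising fractions the bundle reproduces; remaining
## mutated tumors of each gene receive stop-gain variants.
.TSG_PLAN <- list(
  FAT1  = list(missense = 20L, destab = 12L),
  LATS1 = list(missense = 3L,  destab = 2L),
  STK3  = list(missense = 4L,  destab = 3L),
  TP53  = list(missense = 3L,  destab = 2L),
  TP63  = list(missense = 5L,  destab = 3L),
  ATM   = list(missense = 9L,  destab = 5L))

.designEffects <- function(gene, freq) {
  plan <- .TSG_PLAN[[gene]]
  if (!is.null(plan) && plan$missense <= freq) {
    nMis <- plan$missense; nStop <- freq - nMis
    ddg <- c(runif(plan$destab, -2.5, -0.6),
             runif(nMis - plan$destab, -0.45, 0.9),
             rep(NA_real_, nStop))
    effect <- c(rep("missense", nMis), rep("stop_gain", nStop))
  } else {
    effect <- .resample(c("missense", "stop_gain", "splicing"), freq,
                        replace = TRUE)
    ## weight toward missense, the dominant class in the published spectrum
    effect[runif(freq) < 0.6] <- "missense"
    ddg <- ifelse(effect == "missense", runif(freq, -2.5, 1), NA_real_)
  }
  ord <- .resample(seq_len(freq), freq)
  data.frame(effect = effect[ord], ddg = ddg[ord])
}

## predictor-call matrix; damaging votes >= minD when damaging = TRUE,
## otherwise a 0..9 mixture
.predMatrix <- function(n, damaging, minD = 4L) {
  m <- matrix(".", nrow = n, ncol = 9L,
              dimnames = list(NULL, .PRED_COLS))
  if (n == 0L) return(m)
  k <- if (damaging) .resample(minD:9L, n, replace = TRUE)
       else .resample(0:9L, n, replace = TRUE)
  for (i in seq_len(n)) {
    slots <- .resample(1:9L, k[i])
    m[i, slots] <- "D"
    rest <- setdiff(1:9L, slots)
    m[i, rest] <- .resample(c("T", "."), length(rest), replace = TRUE)
  }
  m
}

## ---- evidence draws ------------------------------------------------------

.evidence <- function(n, class, assay = c("wes", "targeted")) {
  assay <- match.arg(assay)
  depth <- switch(assay,
    wes = switch(class,
      somatic  = .resample(40:200, n, replace = TRUE),
      germline = .resample(30:120, n, replace = TRUE),
      artifact = .resample(30:80, n, replace = TRUE)),
    targeted = .resample(300:1500, n, replace = TRUE))
  vaf <- switch(class,
    somatic  = runif(n, 0.30, 0.60),
    germline = runif(n, 0.45, 0.55),
    artifact = {
      v <- runif(n, 0.10, 0.25)
      low <- runif(n) < 0.15          # some sub-threshold artifact calls
      v[low] <- runif(sum(low), 0.03, 0.09)
      v
    })
  alt <- pmax(as.integer(round(depth * vaf)), 3L)
  quality <- if (class == "artifact") runif(n) >= 0.10 else rep(TRUE, n)
  data.frame(depth = as.integer(depth), alt_reads = alt,
             quality_ok = quality)
}

.callRows <- function(defs, idx, sample_id, class, assay) {
  n <- length(idx)
  if (n == 0L)
    return(makeVariantTable(character(), character(), integer(),
                            character(), character(), integer(), integer()))
  ev <- .evidence(n, class, assay)
  makeVariantTable(sample_id = rep(sample_id, n),
                   chrom = defs$chrom[idx], pos = defs$pos[idx],
                   ref = defs$ref[idx], alt = defs$alt[idx],
                   depth = ev$depth, alt_reads = ev$alt_reads,
                   quality_ok = ev$quality_ok)
}

## normal-side site evidence (alt = 0) at given keys
.normalSiteRows <- function(defs, idx, sample_id, depthRange) {
  n <- length(idx)
  makeVariantTable(sample_id = rep(sample_id, n),
                   chrom = defs$chrom[idx], pos = defs$pos[idx],
                   ref = defs$ref[idx], alt = defs$alt[idx],
                   depth = .resample(depthRange, n, replace = TRUE),
                   alt_reads = rep(0L, n))
}

.hetRows <- function(defs, idx, sample_id, depthRange) {
  n <- length(idx)
  depth <- .resample(depthRange, n, replace = TRUE)
  alt <- pmax(as.integer(round(depth * runif(n, 0.45, 0.55))), 2L)
  makeVariantTable(sample_id = rep(sample_id, n),
                   chrom = defs$chrom[idx], pos = defs$pos[idx],
                   ref = defs$ref[idx], alt = defs$alt[idx],
                   depth = depth, alt_reads = alt)
}

.lowSupportRows <- function(defs, idx, sample_id, depthRange) {
  n <- length(idx)
  depth <- .resample(depthRange, n, replace = TRUE)
  alt <- .resample(2:6, n, replace = TRUE)
  makeVariantTable(sample_id = rep(sample_id, n),
                   chrom = defs$chrom[idx], pos = defs$pos[idx],
                   ref = defs$ref[idx], alt = defs$alt[idx],
                   depth = pmax(depth, alt), alt_reads = alt)
}

## ---- the generator -------------------------------------------------------

.tumorIds <- function(profile)
  c(sprintf("PTCL_D%02d", seq_len(profile@nDiscovery)),
    sprintf("PTCL_E%02d", seq_len(profile@nExtension)))

#' Generate a full synthetic tumor/normal cohort with planted ground truth
#'
#' Produces, deterministically for a given `(profile, seed)`: exome variant
#' tables for the discovery tumors, targeted-panel tables for all tumors,
#' matched-normal site evidence, matched-saliva / panel-of-normals /
#' hyperplastic-control tables, RNA-seq evidence tables, a cohort-wide
#' annotation table, a clinical table, the toy reference and gene map, and
#' the planted truth. For every gene `g`, exactly `geneFreqs(profile)[g]`
#' tumors carry a planted somatic nonsynonymous variant in `g` that survives
#' the filtering cascades by construction; each discovery tumor carries
#' exactly its profiled burden of planted nonsynonymous variants.
#'
#' @param profile a [CohortProfile-class].
#' @param seed integer seed; defaults to the profile's.
#' @return a [SyntheticCohort-class].
#' @examples
#' \donttest{
#' bundle <- generateCohort(referenceProfile(), seed = 42)
#' bundle
#' }
#' @export
generateCohort <- function(profile, seed = profileSeed(profile)) {
  validObject(profile)
  seed <- as.integer(as.numeric(seed) %% 2147483647)
  set.seed(seed)
  lay <- .cohortLayout(profile)
  chars <- .makeToyReference(lay)
  refStr <- paste(chars, collapse = "")
  pools <- .posPools(chars, lay)
  ctxAt <- function(pos) substring(refStr, pos - 20L, pos + 20L)

  nD <- profile@nDiscovery; nE <- profile@nExtension
  tumors <- .tumorIds(profile)
  discovery <- tumors[seq_len(nD)]
  pairedTumors <- c(discovery[seq_len(profile@nMatchedDiscovery)],
                    tumors[nD + seq_len(profile@nMatchedExtension)])
  rnaSamples <- discovery[seq_len(profile@nRna)]
  ponIds <- sprintf("NORM_P%02d", seq_len(profile@nPon))
  hypIds <- sprintf("HYP_%02d", seq_len(profile@nHyperplastic))

  samples <- data.frame(
    sample_id = c(tumors, paste0("SAL_", pairedTumors), ponIds, hypIds),
    role = c(rep("tumor_discovery", nD), rep("tumor_extension", nE),
             rep("matched_normal", length(pairedTumors)),
             rep("pon_normal", length(ponIds)),
             rep("hyperplastic_control", length(hypIds))),
    paired = c(tumors %in% pairedTumors,
               rep(FALSE, length(pairedTumors) + length(ponIds) +
                     length(hypIds))),
    has_rna = c(tumors %in% rnaSamples,
                rep(FALSE, length(pairedTumors) + length(ponIds) +
                      length(hypIds))))
  isTumor <- samples$role %in% c("tumor_discovery", "tumor_extension")
  samples$tumor_fraction <- ifelse(isTumor,
                                   runif(nrow(samples), 0.76, 0.95), NA)
  samples$frac_reads_ge_q30 <- runif(nrow(samples), 0.71, 0.95)

  ## -- assign mutated tumors per panel gene, respecting burden capacity --
  burden <- setNames(perSampleBurden(profile), discovery)
  gf <- geneFreqs(profile)
  gf <- gf[gf > 0L]
  gf <- gf[order(-gf, names(gf))]
  assigned <- setNames(integer(length(tumors)), tumors)
  capacity <- setNames(c(burden, rep(Inf, nE)), tumors)
  geneSamples <- list()
  for (g in names(gf)) {
    eligible <- tumors[assigned < capacity]
    if (length(eligible) < gf[[g]])
      stop("infeasible profile: cannot place ", gf[[g]],
           " mutated tumors for gene ", g, call. = FALSE)
    sel <- .resample(eligible, gf[[g]])
    geneSamples[[g]] <- sort(sel)
    assigned[sel] <- assigned[sel] + 1L
  }
  if (any(assigned[discovery] > burden))
    stop("infeasible profile: panel assignment exceeds burden", call. = FALSE)

  ## -- plant panel somatic variants --
  defs <- list()
  for (g in names(gf)) {
    f <- gf[[g]]
    sub <- sampleSubstitution(profile@titvRatio, profile@gcBias, f)
    pos <- pools$takeMany(g, sub$ref)
    des <- .designEffects(g, f)
    defs[[g]] <- data.frame(
      class = "somatic", subclass = "panel",
      owner = geneSamples[[g]],
      chrom = lay$chrom, pos = pos, ref = sub$ref, alt = sub$alt,
      gene = g, effect = des$effect,
      dist_to_cds = ifelse(des$effect == "splicing",
                           .resample(1:2, f, replace = TRUE), 0L),
      in_dbsnp = FALSE, dbsnp_pathogenic = FALSE, kg_af = 0,
      in_cosmic = TRUE, ddg = des$ddg)
  }
  panelDefs <- do.call(rbind, defs)
  panelPred <- .predMatrix(nrow(panelDefs), damaging = TRUE)
  ## non-missense planted variants carry no structure-based predictions
  panelPred[panelDefs$effect != "missense", ] <- "."

  ## -- discovery burden filler in background genes --
  fillerN <- burden - assigned[discovery]
  totFill <- sum(fillerN)
  fillDefs <- NULL; fillPred <- NULL
  if (totFill > 0L) {
    sub <- sampleSubstitution(profile@titvRatio, profile@gcBias, totFill)
    pos <- pools$takeMany(".bg", sub$ref)
    bgGene <- lay$bg$gene[findInterval(pos, lay$bg$start)]
    effect <- .resample(c("missense", "stop_gain", "splicing"), totFill,
                        replace = TRUE)
    effect[runif(totFill) < 0.7] <- "missense"
    fillDefs <- data.frame(
      class = "somatic", subclass = "filler",
      owner = rep(discovery, fillerN),
      chrom = lay$chrom, pos = pos, ref = sub$ref, alt = sub$alt,
      gene = bgGene, effect = effect,
      dist_to_cds = ifelse(effect == "splicing",
                           .resample(1:2, totFill, replace = TRUE), 0L),
      in_dbsnp = FALSE, dbsnp_pathogenic = FALSE, kg_af = 0,
      in_cosmic = TRUE,
      ddg = ifelse(effect == "missense", runif(totFill, -2.5, 1),
                   NA_real_))
    fillPred <- .predMatrix(totFill, damaging = FALSE)
    fillPred[fillDefs$effect != "missense", ] <- "."
  }

  ## -- germline contaminant pool --
  ct <- profile@contamination
  nGerm <- ct$germline_pool
  germGene <- .resample(lay$panel$gene, nGerm, replace = TRUE)
  gsub <- sampleSubstitution(profile@titvRatio, profile@gcBias, nGerm)
  gpos <- vapply(seq_len(nGerm),
                 function(i) pools$take(germGene[i], gsub$ref[i]),
                 integer(1))
  geff <- .resample(c("missense", "synonymous", "intronic"), nGerm,
                    replace = TRUE)
  germDefs <- data.frame(
    class = "germline", subclass = "pool", owner = NA_character_,
    chrom = lay$chrom, pos = gpos, ref = gsub$ref, alt = gsub$alt,
    gene = germGene, effect = geff,
    dist_to_cds = ifelse(geff == "intronic",
                         .resample(3:10, nGerm, replace = TRUE), 0L),
    in_dbsnp = TRUE, dbsnp_pathogenic = FALSE,
    kg_af = runif(nGerm, 0.02, 0.40), in_cosmic = FALSE,
    ddg = ifelse(geff == "missense", runif(nGerm, -1.5, 1.5), NA_real_))
  germPred <- .predMatrix(nGerm, damaging = FALSE)
  germPred[germDefs$effect != "missense", ] <- "."

  ## -- artifact pool --
  nArt <- ct$artifact_pool
  nDup <- min(ct$artifact_dup, nArt)
  nStd <- nArt - nDup
  artGene <- .resample(lay$panel$gene, nArt, replace = TRUE)
  stdSub <- sampleSubstitution(profile@titvRatio, profile@gcBias, nStd)
  stdPos <- vapply(seq_len(nStd),
                   function(i) pools$take(artGene[i], stdSub$ref[i]),
                   integer(1))
  dupPos <- integer(0); dupRef <- character(0)
  if (nDup > 0L) {
    cand <- unlist(lapply(seq_along(lay$dupSrc), function(i)
      (lay$dupSrc[i] + 20L):(lay$dupSrc[i] + lay$dupWidth - 21L)),
      use.names = FALSE)
    dupPos <- .resample(cand, nDup)
    dupRef <- chars[dupPos]
  }
  artDefs <- data.frame(
    class = "artifact",
    subclass = c(rep("standard", nStd), rep("dup_context", nDup)),
    owner = NA_character_,
    chrom = lay$chrom,
    pos = c(stdPos, dupPos),
    ref = c(stdSub$ref, dupRef),
    alt = c(stdSub$alt, .altGivenRef(dupRef, profile@titvRatio)),
    gene = artGene, effect = "missense", dist_to_cds = 0L,
    in_dbsnp = FALSE, dbsnp_pathogenic = FALSE, kg_af = 0,
    ## duplicated-context artifacts mimic COSMIC-listed pseudogene calls
    in_cosmic = c(runif(nStd) < 0.30, rep(TRUE, nDup)),
    ddg = runif(nArt, -1.5, 1.5))
  artPred <- .predMatrix(nArt, damaging = FALSE)

  allDefs <- rbind(panelDefs,
                   if (!is.null(fillDefs)) fillDefs,
                   germDefs, artDefs)
  allPred <- rbind(panelPred,
                   if (!is.null(fillPred)) fillPred,
                   germPred, artPred)
  allDefs$key <- variantKey(allDefs$chrom, allDefs$pos, allDefs$ref,
                            allDefs$alt)
  if (anyDuplicated(allDefs$key))
    stop("internal error: planted variant keys collide", call. = FALSE)
  allDefs$context41 <- ctxAt(allDefs$pos)
  rownames(allDefs) <- NULL

  annotations <- cbind(
    allDefs[, c("chrom", "pos", "ref", "alt", "gene", "effect",
                "dist_to_cds", "in_dbsnp", "dbsnp_pathogenic", "kg_af",
                "in_cosmic")],
    as.data.frame(allPred, stringsAsFactors = FALSE),
    allDefs[, c("ddg", "context41", "key")])

  germIdxAll <- which(allDefs$class == "germline")
  artIdxAll <- which(allDefs$class == "artifact")

  ## per-tumor contaminant draws
  gpt <- min(ct$germline_per_tumor, length(germIdxAll))
  apt <- min(ct$artifact_per_tumor, length(artIdxAll))
  germBy <- setNames(lapply(tumors, function(s)
    .resample(germIdxAll, gpt)), tumors)
  artBy <- setNames(lapply(tumors, function(s)
    .resample(artIdxAll, apt)), tumors)

  ## artifact carriers among the normal panels (>= 1 PoN normal and >= 1
  ## hyperplastic control each, so both cascades can subtract them)
  ponCarry <- setNames(lapply(ponIds, function(x) integer(0)), ponIds)
  hypCarry <- setNames(lapply(hypIds, function(x) integer(0)), hypIds)
  for (i in artIdxAll) {
    if (length(ponIds)) {
      for (p in .resample(ponIds, .resample(seq_len(min(3L,
                                             length(ponIds))), 1L)))
        ponCarry[[p]] <- c(ponCarry[[p]], i)
    }
    if (length(hypIds)) {
      for (h in .resample(hypIds, .resample(seq_len(min(2L,
                                             length(hypIds))), 1L)))
        hypCarry[[h]] <- c(hypCarry[[h]], i)
    }
  }

  somaticBy <- setNames(lapply(tumors, function(s)
    which(allDefs$class == "somatic" & allDefs$owner == s)), tumors)
  panelBy <- setNames(lapply(tumors, function(s)
    which(allDefs$class == "somatic" & allDefs$subclass == "panel" &
            allDefs$owner == s)), tumors)

  ## -- assemble per-sample tables --
  wes <- list(); targeted <- list(); wesMatched <- list(); saliva <- list()
  for (s in tumors) {
    isDisc <- s %in% discovery
    if (isDisc) {
      wes[[s]] <- rbind(
        .callRows(allDefs, somaticBy[[s]], s, "somatic", "wes"),
        .callRows(allDefs, germBy[[s]], s, "germline", "wes"),
        .callRows(allDefs, artBy[[s]], s, "artifact", "wes"))
    }
    targeted[[s]] <- rbind(
      .callRows(allDefs, panelBy[[s]], s, "somatic", "targeted"),
      .callRows(allDefs, germBy[[s]], s, "germline", "targeted"),
      .callRows(allDefs, artBy[[s]], s, "artifact", "targeted"))
    if (s %in% pairedTumors) {
      sid <- paste0("SAL_", s)
      if (isDisc) {
        nonGerm <- c(somaticBy[[s]], artBy[[s]])
        wesMatched[[s]] <- rbind(
          .normalSiteRows(allDefs, nonGerm, sid, 40:120),
          .hetRows(allDefs, germBy[[s]], sid, 40:120))
      }
      saliva[[s]] <- .hetRows(allDefs, germBy[[s]], sid, 300:1500)
    }
  }
  pon <- setNames(lapply(ponIds, function(p) {
    rbind(.hetRows(allDefs, .resample(germIdxAll, gpt), p, 30:80),
          .lowSupportRows(allDefs, unique(ponCarry[[p]]), p, 30:80))
  }), ponIds)
  hyper <- setNames(lapply(hypIds, function(h) {
    rbind(.hetRows(allDefs, .resample(germIdxAll, gpt), h, 300:1500),
          .lowSupportRows(allDefs, unique(hypCarry[[h]]), h, 200:800))
  }), hypIds)

  rna <- setNames(lapply(rnaSamples, function(s) {
    idx <- somaticBy[[s]]
    data.frame(sample_id = s, key = allDefs$key[idx],
               reads = .resample(3:30, length(idx), replace = TRUE))
  }), rnaSamples)

  truth <- list(
    classes = data.frame(key = allDefs$key, class = allDefs$class,
                         subclass = allDefs$subclass,
                         gene = allDefs$gene, effect = allDefs$effect),
    perSampleSomatic = setNames(lapply(tumors, function(s)
      allDefs$key[somaticBy[[s]]]), tumors),
    perSamplePanel = setNames(lapply(tumors, function(s)
      allDefs$key[panelBy[[s]]]), tumors),
    geneSamples = geneSamples)

  clinical <- generateSurvival(profile, truth, seed = NULL)

  new("SyntheticCohort",
      samples = samples, wes = wes, wesMatchedNormals = wesMatched,
      targeted = targeted, saliva = saliva, pon = pon,
      hyperplastic = hyper, rna = rna,
      annotations = annotations, clinical = clinical, truth = truth,
      reference = Biostrings::DNAString(refStr),
      geneMap = toyGeneMap(profile),
      profile = profile, seed = seed)
}

## ---- clinical layer ------------------------------------------------------

#' Generate the clinical follow-up table with exact survival landmarks
#'
#' Constructs `n_clinical` overall-survival records whose Kaplan-Meier
#' summaries hit the profiled landmarks exactly: the mutated-group and
#' wild-type-group medians are planted as uncensored event times at the
#' median-defining rank, and the pooled 36-month survival equals
#' `survival_at_36m` exactly. To make the fixed-time estimate attainable as
#' a product of integer ratios, a computed number of patients is censored at
#' the follow-up minimum (before the first event), bringing the at-risk set
#' to the largest size whose product with `survival_at_36m` is an integer;
#' between that initial censoring and month 36 every removal is a death. All times lie
#' within the profiled follow-up range.
#'
#' @param profile a [CohortProfile-class] with a complete `survivalSpec`.
#' @param truth planted truth (from [generateCohort()]) identifying the
#'   mutated tumors for the stratification gene.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return data.frame: `patient_id`, `os_months`, `event`, `group`.
#' @export
generateSurvival <- function(profile, truth, seed = profileSeed(profile)) {
  if (!is.null(seed)) set.seed(deriveSeed(seed, "survival"))
  ss <- survivalSpec(profile)
  n <- as.integer(ss$n_clinical)
  s36 <- ss$survival_at_36m
  medM <- ss$median_mutated; medW <- ss$median_wildtype
  fmin <- ss$followup_range[[1]]; fmax <- ss$followup_range[[2]]
  landmark <- 36
  if (medM <= fmin || medW <= fmin || medM >= landmark ||
      medW >= landmark || fmax <= landmark)
    stop("survival constraints jointly infeasible: medians must lie ",
         "strictly between the follow-up minimum and the 36-month ",
         "landmark, and follow-up must extend past it", call. = FALSE)

  tumors <- .tumorIds(profile)
  mutAll <- truth$geneSamples[[ss$gene]]
  if (is.null(mutAll))
    stop("no planted mutated tumors for survival gene ", ss$gene,
         call. = FALSE)
  nExcl <- length(tumors) - n
  if (nExcl < 0)
    stop("n_clinical exceeds the cohort size", call. = FALSE)

  ## candidate at-risk sizes r with r * s36 integral
  rCand <- n:2
  rCand <- rCand[abs(rCand * s36 - round(rCand * s36)) < 1e-8]
  kPref <- round(nExcl * length(mutAll) / length(tumors))
  kCand <- unique(c(kPref, 0:min(nExcl, length(mutAll))))
  kCand <- kCand[kCand >= max(0, nExcl - (length(tumors) - length(mutAll))) &
                   kCand <= min(nExcl, length(mutAll))]

  sol <- NULL
  for (k in kCand) {
    mClin <- length(mutAll) - k
    wClin <- n - mClin
    if (mClin < 2L || wClin < 2L) next
    for (r in rCand) {
      cInit <- n - r
      surv <- round(r * s36)
      e2 <- r - surv
      cPref <- round(cInit * mClin / n)
      for (cM in order(abs(0:cInit - cPref)) - 1L) {
        cW <- cInit - cM
        rM <- mClin - cM; rW <- wClin - cW
        if (rM < 2L || rW < 2L || rM %% 2L || rW %% 2L) next
        dM <- rM %/% 2L; dW <- rW %/% 2L
        extra <- e2 - dM - dW
        if (extra < 0L) next
        mExtra <- min(extra, rM - dM)
        wExtra <- extra - mExtra
        if (wExtra > rW - dW) next
        sol <- list(k = k, mClin = mClin, wClin = wClin, cM = cM, cW = cW,
                    rM = rM, rW = rW, dM = dM, dW = dW,
                    mExtra = mExtra, wExtra = wExtra, surv = surv)
        break
      }
      if (!is.null(sol)) break
    }
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("survival constraints jointly infeasible at n = ", n,
         " (no attainable configuration reproduces survival_at_36m = ",
         s36, " with the configured medians)", call. = FALSE)

  exclMut <- .resample(mutAll, sol$k)
  wtAll <- setdiff(tumors, mutAll)
  exclWt <- .resample(wtAll, nExcl - sol$k)
  mutClin <- .resample(setdiff(mutAll, exclMut),
                       length(setdiff(mutAll, exclMut)))
  wtClin <- .resample(setdiff(wtAll, exclWt),
                      length(setdiff(wtAll, exclWt)))

  spread <- function(from, to, k)
    if (k > 0L) from + (to - from) * seq_len(k) / k else numeric(0)
  mutTimes <- c(rep(fmin, sol$cM),                       # early censored
                spread(fmin, medM, sol$dM),              # deaths to median
                spread(medM, landmark, sol$mExtra),      # later deaths
                spread(landmark + 0.5, fmax,
                       sol$rM - sol$dM - sol$mExtra))    # late censored
  mutEvent <- c(rep(FALSE, sol$cM), rep(TRUE, sol$dM + sol$mExtra),
                rep(FALSE, sol$rM - sol$dM - sol$mExtra))
  wtTimes <- c(rep(fmin, sol$cW),
               spread(fmin, medW, sol$dW),
               spread(medW, landmark - 0.5, sol$wExtra),
               spread(landmark + 0.5, fmax,
                      sol$rW - sol$dW - sol$wExtra))
  wtEvent <- c(rep(FALSE, sol$cW), rep(TRUE, sol$dW + sol$wExtra),
               rep(FALSE, sol$rW - sol$dW - sol$wExtra))

  out <- data.frame(
    patient_id = c(mutClin, wtClin),
    os_months = c(mutTimes, wtTimes),
    event = c(mutEvent, wtEvent),
    group = c(rep("mutated", sol$mClin), rep("wildtype", sol$wClin)))
  out <- out[order(out$patient_id), ]
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits the native TSV dialect per sample plus `annotations.tsv`,
#' `clinical.tsv`, `truth.json`, `reference.fasta` and `gene_map.tsv`.
#'
#' @param bundle a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wv <- function(tbl, path)
    write.table(transform(tbl[, .VARIANT_COLS], vaf = .fmtNum(vaf)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  for (grp in c("wes", "wesMatchedNormals", "targeted", "saliva", "pon",
                "hyperplastic")) {
    sub <- file.path(dir, grp)
    dir.create(sub, showWarnings = FALSE)
    tbls <- slot(bundle, grp)
    for (nm in names(tbls))
      wv(tbls[[nm]], file.path(sub, paste0(nm, ".tsv")))
  }
  dir.create(file.path(dir, "rna"), showWarnings = FALSE)
  for (nm in names(bundle@rna))
    write.table(bundle@rna[[nm]], file.path(dir, "rna",
                                            paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeAnnotationTable(bundle@annotations,
                       file.path(dir, "annotations.tsv"))
  writeClinicalTable(bundle@clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(bundle@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  ref <- Biostrings::DNAStringSet(bundle@reference)
  names(ref) <- "chrT"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  gm <- as.data.frame(bundle@geneMap)
  write.table(gm, file.path(dir, "gene_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
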