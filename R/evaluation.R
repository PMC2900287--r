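# Permutation testing, FDR curves, region calling, classification against
# gene annotation, enrichment, and commonality summaries.

#' Assign sites to permutation bins
#'
#' Sites are partitioned into (up to) 5 levels by the number of individuals
#' in which they are heterozygous and 5 levels by their mean expression
#' across individuals (quantile splits, so levels stay populated), giving
#' at most 25 bins.  Permuting sites only within a bin preserves the
#' heterozygosity and expression structure of the genome, so that the only
#' freely swapped signal is the allelic ratio.
#'
#' @param x an \linkS4class{AIData} object.
#' @param nLevels levels per factor (default 5, for up to 25 bins).
#' @return integer vector of bin ids (one per site), with attributes
#'   \code{hetLevel} and \code{eLevel}.
#' @export
assignPermutationBins <- function(x, nLevels = 5L) {
  hetCount <- rowSums(isHet(x))
  meanE <- rowMeans(exprValues(x), na.rm = TRUE)
  hl <- quantileLevels(hetCount, nLevels)
  el <- quantileLevels(meanE, nLevels)
  bin <- (hl - 1L) * nLevels + el
  structure(as.integer(factor(bin)), hetLevel = hl, eLevel = el)
}

#' Permute sites within bins
#'
#' Draws a uniform random permutation within every bin and relocates each
#' site's full data column (genotype, E and R of all individuals jointly),
#' preserving the correspondence between sites in different individuals.
#' Site positions and metadata stay in place; only the measurements move.
#'
#' @param x an \linkS4class{AIData} object.
#' @param bins bin ids from [assignPermutationBins()] (recomputed when
#'   omitted).
#' @param seed integer seed; the same seed reproduces the permutation.
#' @return a permuted \linkS4class{AIData} with attribute \code{perm}
#'   (the site index each row's data came from).
#' @export
permuteWithinBins <- function(x, bins = NULL, seed = NULL) {
  if (is.null(bins)) bins <- assignPermutationBins(x)
  perm <- seq_len(nrow(x))
  withSeed(seed, {
    for (b in unique(bins)) {
      i <- which(bins == b)
      if (length(i) > 1L) perm[i] <- i[sample.int(length(i))]
    }
  })
  out <- x
  assay(out, "geno", withDimnames = FALSE) <-
    genoCalls(x)[perm, , drop = FALSE]
  assay(out, "E", withDimnames = FALSE) <-
    exprValues(x)[perm, , drop = FALSE]
  assay(out, "R", withDimnames = FALSE) <-
    ratioValues(x)[perm, , drop = FALSE]
  attr(out, "perm") <- perm
  out
}

#' Call score-threshold regions
#'
#' Maximal runs of consecutive scored sites (missing scores are
#' transparent, mirroring the het-site windows of the detectors) with
#' \code{S >= t} (positive regions) or \code{S <= -t} (negative regions);
#' a sign flip terminates a region.  Runs shorter than \code{minSnps} are
#' dropped.  A region over sites at 1-based positions p1..pn spans the
#' half-open interval [p1-1, pn) in 0-based bp, i.e. the 1-based closed
#' range [p1, pn] reported here.
#'
#' @param track sites x individuals score matrix.
#' @param sites the matching site \code{GRanges} (or an
#'   \linkS4class{AIData}).
#' @param threshold positive score threshold \code{t}.
#' @param minSnps minimum sites per region.
#' @return a \code{GRanges} with metadata columns \code{individual},
#'   \code{sign}, \code{meanScore}, \code{nSnps}; strand encodes the sign.
#' @export
callRegions <- function(track, sites, threshold, minSnps = 1L) {
  stopifnot(threshold > 0)
  if (is(sites, "AIData")) sites <- rowRanges(sites)
  stopifnot(length(sites) == nrow(track))
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  ids <- colnames(track)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(track)))
  res <- list()
  for (chr in unique(chrom)) {
    ci <- which(chrom == chr)
    for (j in seq_len(ncol(track))) {
      si <- ci[!is.na(track[ci, j])]
      if (!length(si)) next
      s <- track[si, j]
      f <- integer(length(s))
      f[s >= threshold] <- 1L
      f[s <= -threshold] <- -1L
      r <- rle(f)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values != 0L & r$lengths >= minSnps
      if (!any(keep)) next
      cs <- c(0, cumsum(s))
      res[[length(res) + 1L]] <- data.frame(
        chrom = chr,
        start = pos[si[starts[keep]]], end = pos[si[ends[keep]]],
        individual = ids[j], sign = r$values[keep],
        meanScore = (cs[ends[keep] + 1L] - cs[starts[keep]]) /
          r$lengths[keep],
        nSnps = r$lengths[keep])
    }
  }
  if (!length(res))
    return(GRanges(individual = character(0), sign = integer(0),
                   meanScore = numeric(0), nSnps = integer(0)))
  df <- do.call(rbind, res)
  GRanges(df$chrom, IRanges(df$start, df$end),
          strand = ifelse(df$sign > 0, "+", "-"),
          individual = df$individual, sign = df$sign,
          meanScore = df$meanScore, nSnps = df$nSnps)
}

## pooled region (or site) count above a threshold
countCalls <- function(track, sites, threshold, minSnps, unit) {
  reg <- callRegions(track, sites, threshold, minSnps)
  if (unit == "region") length(reg) else sum(mcols(reg)$nSnps)
}

#' Permutation-based FDR curve
#'
#' For each threshold \code{t}, the number of called regions (pooled over
#' individuals) in the real track, the average count over permuted tracks,
#' and the estimated false-discovery rate \code{FDR(t) = N_perm / N_real}.
#' Thresholds with no real calls report a missing FDR (0/0 is undefined).
#'
#' @param realTrack score matrix on the real data.
#' @param permTracks a single score matrix or list of score matrices on
#'   permuted data.
#' @param sites matching site \code{GRanges} (or \linkS4class{AIData}).
#' @param thresholds vector of positive thresholds.
#' @param minSnps minimum sites per region.
#' @param unit count \code{"region"}s (default) or \code{"snp"}s (sites
#'   inside called regions).
#' @return data.frame with columns \code{threshold}, \code{nReal},
#'   \code{nPerm}, \code{fdr}.
#' @export
fdrCurve <- function(realTrack, permTracks, sites, thresholds,
                     minSnps = 1L, unit = c("region", "snp")) {
  unit <- match.arg(unit)
  if (is.matrix(permTracks)) permTracks <- list(permTracks)
  nReal <- vapply(thresholds, function(t)
    countCalls(realTrack, sites, t, minSnps, unit), 1)
  permCounts <- vapply(permTracks, function(p)
    vapply(thresholds, function(t) countCalls(p, sites, t, minSnps, unit),
           1), numeric(length(thresholds)))
  nPerm <- rowMeans(matrix(permCounts, nrow = length(thresholds)))
  data.frame(threshold = thresholds, nReal = nReal, nPerm = nPerm,
             fdr = ifelse(nReal > 0, nPerm / nReal, NA_real_))
}

#' Detections at a target FDR
#'
#' The smallest threshold whose estimated FDR is at or below \code{level}
#' (maximizing the number of detections at that error rate) and the real
#' region count there.
#'
#' @param curve a data.frame from [fdrCurve()].
#' @param level target FDR (default 0.05).
#' @return list with \code{threshold} and \code{nReal}; \code{threshold}
#'   is \code{Inf} and \code{nReal} 0 when no threshold qualifies.
#' @export
fdrThreshold <- function(curve, level = 0.05) {
  ok <- which(!is.na(curve$fdr) & curve$fdr <= level)
  if (!length(ok)) return(list(threshold = Inf, nReal = 0))
  i <- ok[which.min(curve$threshold[ok])]
  list(threshold = curve$threshold[i], nReal = curve$nReal[i])
}

#' Fold enrichment of predictions in an annotation
#'
#' \code{fold = (|pred & annot| / |pred|) / (|annot| / |universe|)}: the
#' ratio of the observed overlap to the overlap expected if predictions
#' were drawn uniformly from the universe.
#'
#' @param pred,annot,universe vectors of site identifiers; \code{pred} and
#'   \code{annot} must be subsets of \code{universe}.
#' @return a single number.
#' @export
enrichmentFold <- function(pred, annot, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(annot)) stop("empty annotation set")
  if (!length(pred)) stop("empty prediction set")
  if (!all(pred %in% universe) || !all(annot %in% universe))
    stop("pred and annot must be subsets of the universe")
  (length(intersect(pred, annot)) / length(pred)) /
    (length(unique(annot)) / length(unique(universe)))
}

#' Classify AI regions against annotated genes
#'
#' Each region is assigned to one of eight categories by a rule cascade
#' that tolerates a margin of \code{delta} bp (default 20 kb) in the region
#' boundaries: \emph{intergenic} (less than 10 percent of the region
#' overlaps genes), \emph{multiple transcripts} (at least two genes each
#' overlap at least 20 percent of the region), \emph{exact transcript}
#' (both region boundaries match the principal gene's boundaries within
#' \code{delta}), \emph{extended 5'/3'} (the region runs past a gene
#' boundary by more than \code{delta}), \emph{5'/3' end} (one boundary
#' matches a gene end, the rest of the region is inside the gene), and
#' \emph{intronic} (inside the gene, away from both boundaries).  The
#' 5'/3' designation follows the gene's strand.
#'
#' @param regions a \code{GRanges} of AI regions.
#' @param genes a stranded \code{GRanges} of gene bodies.
#' @param delta boundary tolerance in bp.
#' @return character vector of categories, one per region.
#' @export
classifyRegion <- function(regions, genes, delta = 20000) {
  stopifnot(length(genes) > 0, all(width(genes) > 0))
  out <- character(length(regions))
  ov <- findOverlaps(regions, genes, ignore.strand = TRUE)
  for (i in seq_along(regions)) {
    r <- regions[i]
    gIdx <- subjectHits(ov)[queryHits(ov) == i]
    g <- genes[gIdx]
    covFrac <- if (length(g))
      sum(width(intersect(ranges(r), reduce(ranges(g))))) / width(r) else 0
    if (covFrac < 0.1) { out[i] <- "intergenic"; next }
    ovw <- width(pintersect(rep(ranges(r), length(g)), ranges(g)))
    if (sum(ovw / width(r) >= 0.2) >= 2) {
      out[i] <- "multiple transcripts"; next
    }
    main <- g[which.max(ovw)]
    fwd <- as.character(strand(main)) != "-"
    dStart <- start(r) - start(main)   # <0: region extends left of gene
    dEnd <- end(r) - end(main)         # >0: region extends right of gene
    matchStart <- abs(dStart) <= delta
    matchEnd <- abs(dEnd) <= delta
    if (matchStart && matchEnd) { out[i] <- "exact transcript"; next }
    extLeft <- dStart < -delta
    extRight <- dEnd > delta
    if (extLeft || extRight) {
      left <- if (extLeft && extRight) -dStart >= dEnd else extLeft
      out[i] <- if (left == fwd) "extended 5'" else "extended 3'"
      next
    }
    ## region is inside the gene (within tolerance) and not exact
    if (xor(matchStart, matchEnd)) {
      out[i] <- if (matchStart == fwd) "5' end" else "3' end"
      next
    }
    out[i] <- "intronic"
  }
  out
}

#' Commonality of AI calls across individuals
#'
#' For every site called imbalanced in at least one individual, counts in
#' how many individuals it is called, and tabulates the number of SNPs per
#' commonality level.
#'
#' @param calls logical sites x individuals matrix of AI calls (e.g. from
#'   [aiCalls()]).
#' @return data.frame with columns \code{nIndividuals} (1..ncol) and
#'   \code{nSnps}; levels with no sites are omitted, so a dataset with no
#'   calls yields zero rows.
#' @export
commonalityCounts <- function(calls) {
  cnt <- rowSums(calls, na.rm = TRUE)
  tab <- table(factor(cnt[cnt > 0], levels = seq_len(ncol(calls))))
  df <- data.frame(nIndividuals = as.integer(names(tab)),
                   nSnps = as.integer(tab))
  df[df$nSnps > 0, , drop = FALSE]
}
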