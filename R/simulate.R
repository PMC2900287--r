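# Synthetic allelic-expression data with ground truth.  The generator
# emulates the structure of HapMap-scale array data: a gene/intergenic
# segment layout with SNP densities of one site per 3.5 kb (genic) and
# 4.5 kb (intergenic); Hardy-Weinberg genotypes from per-site allele
# frequencies; a bimodal total-expression distribution (half of genes and a
# tenth of intergenic segments expressed); planted AI regions with varying
# population sharing; and allelic-ratio noise that grows as expression
# shrinks, calibrated so technical replicates reproduce the observed
# replicate correlations of E and R.

#' Simulation configuration
#'
#' All tunables of [simulateDataset()], with defaults matching the study
#' conditions the package targets (53 individuals, genic/intergenic SNP
#' densities of 1/3.5 kb and 1/4.5 kb, 50 percent of genes and 10 percent
#' of intergenic segments expressed) and a noise model calibrated so that
#' simulated technical replicates give Pearson correlations of about 0.864
#' for E and 0.632 for R.
#'
#' @param nIndividuals number of individuals.
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param genicGap,intergenicGap mean inter-SNP gap (bp) inside and outside
#'   genes.
#' @param meanTranscriptLength,meanIntergenicLength mean segment lengths
#'   (bp) of the alternating gene / intergenic layout (exponential laws).
#' @param pGenicExpressed,pIntergenicExpressed probability that a gene /
#'   an intergenic segment is expressed.
#' @param mafRange allele-frequency law: uniform on this interval.
#' @param missingRate per-call genotype missingness.
#' @param exprMean,exprSd,nonExprMean,nonExprSd normal components of the
#'   bimodal E mixture (log2 units).
#' @param eNoiseSd per-replicate technical noise sd of E (calibrated).
#' @param noiseA,noiseB,noiseC,eMin allelic-ratio noise law, see
#'   [noiseSd()].
#' @param rShareRho fraction of the ratio-noise variance shared between
#'   technical replicates (site-specific residual probe effects;
#'   calibrated).
#' @param replicateNoiseScale multiplier on the per-replicate (independent)
#'   noise components; 0 makes replicates identical.
#' @param nAIRegions number of randomly placed AI regions.
#' @param pCommon probability an AI region is population-common; common
#'   regions draw their carrier frequency from \code{commonFreqRange},
#'   rare ones affect 1..\code{rareMax} individuals.
#' @param commonFreqRange,rareMax see \code{pCommon}.
#' @param magnitudeRange uniform law of the per-region |log-ratio|.
#' @param alignProbs probabilities of the region/transcript alignment
#'   types: exact, 5'-partial, 3'-partial, extended, intergenic.
#' @param extendFrac extension length of "extended" regions, as a fraction
#'   of the transcript length.
#' @param aiRegionSpec optional data.frame with columns \code{nSites},
#'   \code{nCarriers}, \code{magnitude} (and optionally \code{sign}):
#'   plants exactly these regions in expressed genes instead of the random
#'   law above.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nIndividuals = 53L,
                      chromLengths = c(chr1 = 10e6),
                      genicGap = 3500, intergenicGap = 4500,
                      meanTranscriptLength = 5e4,
                      meanIntergenicLength = 6e4,
                      pGenicExpressed = 0.5, pIntergenicExpressed = 0.1,
                      mafRange = c(0.05, 0.5), missingRate = 0.01,
                      exprMean = 1.5, exprSd = 1.0,
                      nonExprMean = -1.5, nonExprSd = 0.6,
                      eNoiseSd = 0.624,
                      noiseA = 0.25, noiseB = 20, noiseC = 1, eMin = -4,
                      rShareRho = 0.631, replicateNoiseScale = 1,
                      nAIRegions = 30L, pCommon = 0.5,
                      commonFreqRange = c(0.2, 0.9), rareMax = 5L,
                      magnitudeRange = c(0.5, 2.5),
                      alignProbs = c(exact = 0.5, partial5 = 0.15,
                                     partial3 = 0.15, extended = 0.1,
                                     intergenic = 0.1),
                      extendFrac = 0.5,
                      aiRegionSpec = NULL) {
  cfg <- as.list(environment())
  stopifnot(nIndividuals >= 1, all(chromLengths > 0),
            genicGap > 0, intergenicGap > 0,
            pGenicExpressed >= 0, pGenicExpressed <= 1,
            pIntergenicExpressed >= 0, pIntergenicExpressed <= 1,
            missingRate >= 0, missingRate < 1,
            noiseB >= 0, noiseC >= 0,
            rShareRho >= 0, rShareRho <= 1, replicateNoiseScale >= 0)
  structure(cfg, class = "SimConfig")
}

#' Expression-dependent allelic-ratio noise
#'
#' \code{sigma(E) = a + b exp(-c (E - eMin))}: the standard deviation of
#' the measured log-ratio decays toward the floor \code{a} as expression
#' grows, and blows up at non-expressed levels where the ratio is estimated
#' from background signal.  Strictly decreasing in E whenever b, c > 0.
#'
#' @param E total expression value(s).
#' @param a asymptotic noise floor at high expression.
#' @param b,c amplitude and decay rate of the low-expression term.
#' @param eMin reference expression level.
#' @return sigma, same shape as \code{E}.
#' @export
noiseSd <- function(E, a = 0.25, b = 20, c = 1, eMin = -4) {
  stopifnot(b >= 0, c >= 0)
  a + b * exp(-c * (E - eMin))
}

## alternating intergenic/genic segment layout of one chromosome
simLayout <- function(chrom, len, cfg) {
  segs <- list()
  at <- 1
  genic <- FALSE  # start intergenic
  while (at < len) {
    m <- if (genic) cfg$meanTranscriptLength else cfg$meanIntergenicLength
    sl <- max(ceiling(rexp(1, 1 / m)), 1000)
    end <- min(at + sl - 1, len)
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = chrom, start = at, end = end, genic = genic,
      strand = if (genic) sample(c("+", "-"), 1) else "*",
      expressed = runif(1) < if (genic) cfg$pGenicExpressed
                             else cfg$pIntergenicExpressed)
    at <- end + 1
    genic <- !genic
  }
  do.call(rbind, segs)
}

## SNP positions within one segment (exponential gaps)
simSegSites <- function(seg, cfg) {
  gapMean <- if (seg$genic) cfg$genicGap else cfg$intergenicGap
  len <- seg$end - seg$start + 1
  nDraw <- ceiling(len / gapMean * 2) + 10L
  gaps <- pmax(ceiling(rexp(nDraw, 1 / gapMean)), 1)
  pos <- seg$start - 1 + cumsum(gaps)
  pos[pos <= seg$end]
}

## choose carriers of one AI region
drawCarriers <- function(cfg) {
  if (runif(1) < cfg$pCommon) {
    f <- runif(1, cfg$commonFreqRange[1], cfg$commonFreqRange[2])
    carriers <- which(runif(cfg$nIndividuals) < f)
    if (!length(carriers)) carriers <- sample.int(cfg$nIndividuals, 1)
  } else {
    k <- sample.int(min(cfg$rareMax, cfg$nIndividuals), 1)
    carriers <- sample.int(cfg$nIndividuals, k)
  }
  carriers
}

#' Simulate an allelic-expression dataset with ground truth
#'
#' See [simConfig()] for the generative model.  The same seed reproduces
#' the dataset exactly.
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed.
#' @return list with elements \code{data} (an \linkS4class{AIData}),
#'   and \code{truth}, a \code{AIGroundTruth} list holding the site-level
#'   \code{expressed} flags, the sites x individuals \code{trueRatio}
#'   matrix (0 outside AI regions), the \code{aiRegions} table with
#'   carrier sets, the \code{transcripts} GRanges, the latent expression
#'   levels \code{E0} and shared noise components \code{u} (needed by
#'   [simulateReplicates()]), and the \code{config}.
#' @export
simulateDataset <- function(config = simConfig(), seed = NULL) {
  cfg <- config
  withSeed(seed, {
    segsL <- list(); sitesL <- list(); segIdL <- list()
    for (ci in seq_along(cfg$chromLengths)) {
      chrom <- names(cfg$chromLengths)[ci]
      if (is.null(chrom)) chrom <- paste0("chr", ci)
      segs <- simLayout(chrom, cfg$chromLengths[ci], cfg)
      segs$id <- seq_len(nrow(segs)) + sum(vapply(segsL, nrow, 1L))
      for (k in seq_len(nrow(segs))) {
        pos <- simSegSites(segs[k, ], cfg)
        if (!length(pos)) next
        sitesL[[length(sitesL) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, genic = segs$genic[k])
        segIdL[[length(segIdL) + 1L]] <- rep(segs$id[k], length(pos))
      }
      segsL[[length(segsL) + 1L]] <- segs
    }
    segs <- do.call(rbind, segsL)
    sites <- do.call(rbind, sitesL)
    segId <- unlist(segIdL)
    n <- nrow(sites)
    nI <- cfg$nIndividuals
    if (n < 2) stop("configuration yields fewer than two sites")

    expressed <- segs$expressed[match(segId, segs$id)]

    ## genotypes under Hardy-Weinberg from per-site allele frequencies
    maf <- runif(n, cfg$mafRange[1], cfg$mafRange[2])
    pHet <- 2 * maf * (1 - maf)
    geno <- matrix("hom", n, nI)
    geno[matrix(runif(n * nI), n, nI) < pHet] <- "het"
    geno[matrix(runif(n * nI), n, nI) < cfg$missingRate] <- "missing"

    ## planted AI regions
    trueRatio <- matrix(0, n, nI)
    regionRows <- list()
    usedSeg <- integer(0)
    plant <- function(siteIdx, carriers, mag, signs) {
      trueRatio[siteIdx, carriers] <<-
        rep(signs * mag, each = length(siteIdx))
      regionRows[[length(regionRows) + 1L]] <<- data.frame(
        chrom = sites$chrom[siteIdx[1]],
        start = sites$pos[siteIdx[1]], end = sites$pos[max(siteIdx)],
        firstSite = siteIdx[1], lastSite = max(siteIdx),
        nSites = length(siteIdx), magnitude = mag,
        nCarriers = length(carriers),
        carriers = I(list(carriers)), signs = I(list(signs)))
    }
    if (!is.null(cfg$aiRegionSpec)) {
      spec <- cfg$aiRegionSpec
      for (k in seq_len(nrow(spec))) {
        nS <- spec$nSites[k]
        cand <- setdiff(segs$id[segs$genic & segs$expressed], usedSeg)
        cand <- cand[vapply(cand, function(s) sum(segId == s), 1L) >= nS]
        if (!length(cand))
          stop("no expressed gene large enough for a planted region of ",
               nS, " sites; enlarge the chromosome")
        sg <- if (length(cand) == 1L) cand else sample(cand, 1)
        usedSeg <- c(usedSeg, sg)
        inSeg <- which(segId == sg)
        at <- sample.int(length(inSeg) - nS + 1L, 1)
        siteIdx <- inSeg[at:(at + nS - 1L)]
        carriers <- sample.int(nI, spec$nCarriers[k])
        signs <- if (!is.null(spec$sign))
          rep(spec$sign[k], length(carriers))
          else sample(c(-1, 1), length(carriers), replace = TRUE)
        plant(siteIdx, carriers, spec$magnitude[k], signs)
      }
    }
    if (cfg$nAIRegions > 0) {
      for (k in seq_len(cfg$nAIRegions)) {
        type <- sample(names(cfg$alignProbs), 1, prob = cfg$alignProbs)
        pool <- if (type == "intergenic")
          segs$id[!segs$genic & segs$expressed]
          else segs$id[segs$genic & segs$expressed]
        pool <- setdiff(pool, usedSeg)
        pool <- pool[pool %in% segId]
        if (!length(pool)) next
        sg <- if (length(pool) == 1L) pool else sample(pool, 1)
        usedSeg <- c(usedSeg, sg)
        inSeg <- which(segId == sg)
        fwd <- segs$strand[segs$id == sg] != "-"
        siteIdx <- switch(type,
          exact = , intergenic = inSeg,
          partial5 = if (fwd) head(inSeg, ceiling(length(inSeg) / 2))
                     else tail(inSeg, ceiling(length(inSeg) / 2)),
          partial3 = if (fwd) tail(inSeg, ceiling(length(inSeg) / 2))
                     else head(inSeg, ceiling(length(inSeg) / 2)),
          extended = {
            ext <- (segs$end[segs$id == sg] - segs$start[segs$id == sg]) *
              cfg$extendFrac
            lo <- sites$pos[inSeg[1]] - ext
            hi <- sites$pos[max(inSeg)] + ext
            which(sites$chrom == sites$chrom[inSeg[1]] &
                  sites$pos >= lo & sites$pos <= hi)
          })
        if (length(siteIdx) < 1L) next
        expressed[siteIdx] <- TRUE  # extension = unannotated transcription
        carriers <- drawCarriers(cfg)
        mag <- runif(1, cfg$magnitudeRange[1], cfg$magnitudeRange[2])
        plant(siteIdx, carriers, mag,
              sample(c(-1, 1), length(carriers), replace = TRUE))
      }
    }

    ## latent expression level (shared between technical replicates)
    E0 <- matrix(rnorm(n * nI,
                       ifelse(expressed, cfg$exprMean, cfg$nonExprMean),
                       ifelse(expressed, cfg$exprSd, cfg$nonExprSd)),
                 n, nI)
    sigma0 <- noiseSd(E0, cfg$noiseA, cfg$noiseB, cfg$noiseC, cfg$eMin)
    u <- matrix(rnorm(n * nI), n, nI)  # shared ratio-noise component

    E <- E0 + cfg$replicateNoiseScale * cfg$eNoiseSd * rnorm(n * nI)
    R <- trueRatio + sigma0 * (sqrt(cfg$rShareRho) * u +
         sqrt(1 - cfg$rShareRho) * cfg$replicateNoiseScale * rnorm(n * nI))
    E[geno == "missing"] <- NA_real_
    R[geno != "het"] <- NA_real_

    ids <- sprintf("NA%05d", seq_len(nI))
    colnames(geno) <- colnames(E) <- colnames(R) <- ids
    gr <- GRanges(factor(sites$chrom, levels = unique(sites$chrom)),
                  IRanges(sites$pos, width = 1L),
                  snp_id = sprintf("rs%07d", seq_len(n)),
                  alleleA = "A", alleleB = "B", genic = sites$genic)
    data <- AIData(gr, geno, E, R, individuals = ids)
    gseg <- segs[segs$genic, , drop = FALSE]
    transcripts <- GRanges(gseg$chrom, IRanges(gseg$start, gseg$end),
                           strand = gseg$strand, expressed = gseg$expressed)
    truth <- structure(list(
      expressed = expressed, trueRatio = trueRatio,
      aiRegions = if (length(regionRows)) do.call(rbind, regionRows)
                  else NULL,
      transcripts = transcripts, E0 = E0, u = u, config = cfg),
      class = "AIGroundTruth")
    list(data = data, truth = truth)
  })
}

#' Simulate a technical replicate
#'
#' Re-measures the same underlying sample: the latent expression levels,
#' the true log-ratios and the shared (site-specific) component of the
#' ratio noise are retained from the original draw; only the independent
#' per-replicate noise is redrawn.  With \code{replicateNoiseScale = 0}
#' the replicate is identical to the original.
#'
#' @param x the \linkS4class{AIData} returned by [simulateDataset()].
#' @param truth the matching \code{AIGroundTruth}.
#' @param config the simulation configuration (defaults to the one stored
#'   in \code{truth}).
#' @param seed integer seed for the fresh noise draws.
#' @return an \linkS4class{AIData} replicate.
#' @export
simulateReplicates <- function(x, truth, config = truth$config,
                               seed = NULL) {
  cfg <- config
  n <- nrow(truth$E0); nI <- ncol(truth$E0)
  geno <- genoCalls(x)
  withSeed(seed, {
    sigma0 <- noiseSd(truth$E0, cfg$noiseA, cfg$noiseB, cfg$noiseC,
                      cfg$eMin)
    E <- truth$E0 + cfg$replicateNoiseScale * cfg$eNoiseSd * rnorm(n * nI)
    R <- truth$trueRatio + sigma0 * (sqrt(cfg$rShareRho) * truth$u +
         sqrt(1 - cfg$rShareRho) * cfg$replicateNoiseScale * rnorm(n * nI))
    E[geno == "missing"] <- NA_real_
    R[geno != "het"] <- NA_real_
    colnames(E) <- colnames(R) <- colnames(geno)
    AIData(rowRanges(x), geno, E, R, individuals = individuals(x))
  })
}

#' Configuration for the shared weak-imbalance benchmark
#'
#' A scenario in which a set of moderate AI regions is shared by a large
#' fraction of the population: \code{nRegions} regions of \code{nSites}
#' consecutive sites (about 10 heterozygous sites per carrier at the
#' default allele-frequency law), each carried by \code{nCarriers} of the
#' \code{nIndividuals} individuals with |log-ratio| \code{magnitude}.
#' This is the regime where borrowing strength across individuals pays
#' off, used to compare the detectors at matched permutation FDR.
#'
#' @param nRegions,nSites,nCarriers,magnitude see above.
#' @param nIndividuals,chromLength population and chromosome size.
#' @param ... further overrides passed to [simConfig()].
#' @return a \code{SimConfig}.
#' @export
sharedScenarioConfig <- function(nRegions = 15L, nSites = 27L,
                                 nCarriers = 40L, magnitude = 0.5,
                                 nIndividuals = 53L, chromLength = 30e6,
                                 ...) {
  simConfig(nIndividuals = nIndividuals,
            chromLengths = c(chr1 = chromLength),
            meanTranscriptLength = 1e5,
            aiRegionSpec = data.frame(nSites = rep(nSites, nRegions),
                                      nCarriers = nCarriers,
                                      magnitude = magnitude),
            ...)
}
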