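# The two single-sample non-HMM detectors: simple smoothing of the allelic
# log-ratio, and the expression-binned Z-score approach with greedy
# non-overlapping window selection.  Homozygous sites are transparent:
# windows run over consecutive heterozygous sites, skipping intervening hom
# sites, and never cross a chromosome boundary.

#' Smooth allelic log-ratios over neighbouring heterozygous sites
#'
#' Each heterozygous site is scored with the mean of its own log-ratio and
#' that of up to \code{k} heterozygous neighbours on each side (windows are
#' truncated at chromosome ends so every het site gets a score).  With
#' \code{k = 0} the score equals the raw ratio.
#'
#' @param x an \linkS4class{AIData} object.
#' @param k window half-width in het sites.
#' @return a sites x individuals score matrix (NA at non-het sites) with
#'   attribute \code{method = "smooth"}.
#' @export
scoreSmooth <- function(x, k = 2L) {
  stopifnot(k >= 0)
  R <- ratioValues(x)
  S <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  for (idx in chromIndex(x)) {
    for (j in seq_len(ncol(R))) {
      het <- idx[!is.na(R[idx, j])]
      if (!length(het)) next
      S[het, j] <- smoothVector(R[het, j], k)
    }
  }
  structure(S, method = "smooth")
}

## truncated running mean over <= 2k+1 neighbours
smoothVector <- function(r, k) {
  n <- length(r)
  cs <- c(0, cumsum(r))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fit expression-level bins for Z-score standardization
#'
#' The range of E at heterozygous sites is split into \code{nBins}
#' equal-width bins and the mean and standard deviation of R are estimated
#' per bin, capturing the strong growth of ratio noise at low expression.
#' Bins holding fewer than \code{minBinN} sites are merged with the nearest
#' populated bin; standard deviations are floored at \code{sigmaFloor}.
#'
#' @param E,R numeric vectors or matrices of expression and log-ratio.
#' @param geno optional genotype matrix; when given, only het entries are
#'   used (otherwise all non-NA R values are taken as het).
#' @param nBins number of equal-width expression bins.
#' @param minBinN minimum sites per bin before merging.
#' @param sigmaFloor lower bound on the per-bin standard deviation.
#' @return an object of class \code{BinStats}: list with \code{breaks},
#'   \code{group} (bin to merged-group map), \code{mu}, \code{sigma}.
#' @export
fitExpressionBins <- function(E, R, geno = NULL, nBins = 100L,
                              minBinN = 50L, sigmaFloor = 1e-3) {
  het <- if (is.null(geno)) !is.na(R) else geno == "het"
  e <- as.numeric(E[het]); r <- as.numeric(R[het])
  keep <- is.finite(e) & is.finite(r)
  e <- e[keep]; r <- r[keep]
  if (!length(e)) stop("no heterozygous sites to fit expression bins")
  rg <- range(e)
  if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
  breaks <- seq(rg[1], rg[2], length.out = nBins + 1L)
  bin <- findInterval(e, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  populated <- which(counts >= minBinN)
  if (!length(populated)) populated <- which(counts == max(counts))[1]
  ## map every bin to its nearest populated bin (ties toward lower index)
  group <- vapply(seq_len(nBins), function(b)
    populated[which.min(abs(populated - b))], 1L)
  g <- group[bin]
  mu <- tapply(r, factor(g, levels = populated), mean)
  sg <- tapply(r, factor(g, levels = populated), sd)
  mu[is.na(mu)] <- 0
  sg[is.na(sg)] <- 0
  sg <- pmax(sg, sigmaFloor)
  muFull <- setNames(rep(NA_real_, nBins), NULL)
  sgFull <- muFull
  muFull[populated] <- as.numeric(mu)
  sgFull[populated] <- as.numeric(sg)
  structure(list(breaks = breaks, group = group, mu = muFull,
                 sigma = sgFull, counts = counts),
            class = "BinStats")
}

#' Site-specific Z-score
#'
#' Standardizes the log-ratio of a heterozygous site by the mean and
#' standard deviation of its expression bin: \code{z = (R - mu_b)/sigma_b}.
#'
#' @param R,E values at heterozygous sites (vectors of equal length).
#' @param stats a \code{BinStats} object from [fitExpressionBins()].
#' @param geno optional genotype vector; any non-het entry is an error
#'   (hom sites carry no ratio information).
#' @return numeric vector of z-scores.
#' @export
siteZ <- function(R, E, stats, geno = NULL) {
  stopifnot(inherits(stats, "BinStats"))
  if (!is.null(geno) && any(geno != "het"))
    stop("siteZ is defined only at heterozygous sites")
  if (any(is.na(R)))
    stop("siteZ is defined only at heterozygous sites (NA ratio)")
  bin <- findInterval(E, stats$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  g <- stats$group[bin]
  (R - stats$mu[g]) / stats$sigma[g]
}

#' Regional Z-score of a run of consecutive heterozygous sites
#'
#' \code{Z = sum(z)/sqrt(k)} for \code{k} site scores; under the null of no
#' imbalance (independent standardized sites) it follows Normal(0,1) for a
#' fixed window.  Note that the score assigned by the greedy maximization
#' in [greedyWindowAssignment()] is a maximum over windows and does not
#' retain this null distribution.
#'
#' @param z numeric vector of site z-scores (nonempty).
#' @return a single number.
#' @export
regionalZ <- function(z) {
  stopifnot(length(z) >= 1L)
  sum(z) / sqrt(length(z))
}

#' Greedy assignment of regional Z-scores to heterozygous sites
#'
#' Regional Z-scores are computed for every window of 1..\code{wMax}
#' consecutive het sites.  The window with the highest |Z| is selected and
#' its Z assigned to all its sites; the window is then masked out and the
#' next highest-|Z| window containing only unassigned sites is selected,
#' until every site is assigned.  Ties are broken toward the leftmost, then
#' shortest window, making the assignment deterministic.
#'
#' @param z site z-scores of consecutive het sites (one chromosome, one
#'   individual).
#' @param wMax maximum window length.
#' @return numeric vector of assigned regional Z-scores, one per site, with
#'   attribute \code{window} giving the id of the selected window each site
#'   belongs to.
#' @export
greedyWindowAssignment <- function(z, wMax = 25L) {
  stopifnot(wMax >= 1L)
  n <- length(z)
  if (n == 0L) return(numeric(0))
  cs <- c(0, cumsum(z))
  starts <- integer(0); lens <- integer(0); Z <- numeric(0)
  for (len in seq_len(min(wMax, n))) {
    st <- seq_len(n - len + 1L)
    starts <- c(starts, st)
    lens <- c(lens, rep.int(len, length(st)))
    Z <- c(Z, (cs[st + len] - cs[st]) / sqrt(len))
  }
  ord <- order(-abs(Z), starts, lens)
  assigned <- .greedy_accept(starts[ord], lens[ord], n)
  out <- Z[ord][assigned]
  attr(out, "window") <- assigned
  out
}

#' Z-score track for a dataset
#'
#' Fits expression bins on all heterozygous sites pooled across individuals,
#' standardizes each het site, and runs the greedy window assignment per
#' individual and chromosome.
#'
#' @param x an \linkS4class{AIData} object.
#' @param nBins,minBinN,sigmaFloor passed to [fitExpressionBins()].
#' @param wMax maximum window length, passed to [greedyWindowAssignment()].
#' @return a sites x individuals score matrix (NA at non-het sites) with
#'   attribute \code{method = "zscore"}.
#' @export
scoreZ <- function(x, nBins = 100L, wMax = 25L, minBinN = 50L,
                   sigmaFloor = 1e-3) {
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  stats <- fitExpressionBins(E, R, geno, nBins = nBins, minBinN = minBinN,
                             sigmaFloor = sigmaFloor)
  S <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  for (idx in chromIndex(x)) {
    for (j in seq_len(ncol(R))) {
      het <- idx[geno[idx, j] == "het"]
      if (!length(het)) next
      zz <- siteZ(R[het, j], E[het, j], stats)
      S[het, j] <- as.numeric(greedyWindowAssignment(zz, wMax = wMax))
    }
  }
  structure(S, method = "zscore", binStats = stats)
}
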