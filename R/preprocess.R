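# Derivation of the (E, R) observables from raw four-channel probe
# intensities, deconvolution of the expression distribution, and masking of
# duplication-prone sites.

#' Derive total expression and allelic log-ratio from probe intensities
#'
#' Given the four channel intensities at each site x individual -- cDNA
#' allele A/B and genomic DNA allele A/B -- computes the DNA-normalized
#' observables
#' \deqn{E = \log_2\frac{cA + cB + \epsilon}{gA + gB + \epsilon}, \qquad
#'       R = \log_2\frac{(cA+\epsilon)/(cB+\epsilon)}
#'                      {(gA+\epsilon)/(gB+\epsilon)}.}
#' The genomic DNA of a heterozygous site is known to carry the two alleles
#' in equal copy, so dividing by the gDNA ratio cancels probe sensitivity
#' bias; with \code{eps = 0} both values are invariant to rescaling all four
#' channels.  \code{R} is set missing at non-heterozygous sites (where the
#' allelic ratio is uninformative), and both values are missing where all
#' four intensities are zero.
#'
#' @param cdnaA,cdnaB,gdnaA,gdnaB nonnegative intensity matrices (or
#'   vectors) of identical shape.
#' @param geno optional genotype call matrix (\code{"het"}/\code{"hom"}/
#'   \code{"missing"}); when supplied, R is kept only at het sites.
#' @param eps pseudocount added to every channel (intensity units) to guard
#'   zero channels.
#' @return list with elements \code{E} and \code{R}.
#' @export
computeExpressionRatio <- function(cdnaA, cdnaB, gdnaA, gdnaB, geno = NULL,
                                   eps = 1) {
  stopifnot(all(cdnaA >= 0, na.rm = TRUE), all(cdnaB >= 0, na.rm = TRUE),
            all(gdnaA >= 0, na.rm = TRUE), all(gdnaB >= 0, na.rm = TRUE))
  E <- log2((cdnaA + cdnaB + eps) / (gdnaA + gdnaB + eps))
  R <- log2(((cdnaA + eps) / (cdnaB + eps)) /
            ((gdnaA + eps) / (gdnaB + eps)))
  dead <- (cdnaA + cdnaB + gdnaA + gdnaB) == 0
  E[dead] <- NA_real_
  R[dead] <- NA_real_
  if (!is.null(geno)) R[geno != "het"] <- NA_real_
  list(E = E, R = R)
}

#' Expression histogram over fixed breaks
#'
#' @param x finite numeric values.
#' @param nBins number of equal-width bins.
#' @param breaks optional explicit break points (overrides \code{nBins}).
#' @return list with \code{breaks} (length nBins+1) and \code{mass}
#'   (sums to 1).
#' @export
expressionHistogram <- function(x, nBins = 200L, breaks = NULL) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values to histogram")
  if (is.null(breaks)) {
    rg <- range(x)
    if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
    breaks <- seq(rg[1], rg[2], length.out = nBins + 1L)
  }
  b <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- tabulate(b, nbins = length(breaks) - 1L)
  list(breaks = breaks, mass = mass / sum(mass))
}

#' Genic and intergenic expression histograms of a dataset
#'
#' Histograms of all finite E values at genic and at intergenic sites, over
#' shared bin edges spanning the observed E range; the inputs to
#' [deconvolveExpression()].
#'
#' @param x an \linkS4class{AIData} object.
#' @param nBins number of equal-width bins.
#' @return list with elements \code{genic} and \code{intergenic}.
#' @export
expressionHistograms <- function(x, nBins = 200L) {
  E <- exprValues(x)
  genic <- mcols(rowRanges(x))$genic
  all <- E[is.finite(E)]
  rg <- range(all)
  if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
  breaks <- seq(rg[1], rg[2], length.out = nBins + 1L)
  list(genic = expressionHistogram(E[genic, ], breaks = breaks),
       intergenic = expressionHistogram(E[!genic, ], breaks = breaks))
}

#' Deconvolve genic/intergenic expression histograms into expressed and
#' non-expressed components
#'
#' The observed genic and intergenic E distributions are modelled as
#' two-component mixtures of a shared expressed and non-expressed
#' distribution, with known mixing proportions (by default 50% of genic and
#' 10% of intergenic sites expressed).  Per-bin linear unmixing gives
#' \deqn{f_{expr} = \frac{(1-q) f_{gen} - (1-p) f_{int}}{p - q}, \qquad
#'       f_{non} = \frac{p f_{int} - q f_{gen}}{p - q}}
#' with \eqn{p} = \code{pGenic}, \eqn{q} = \code{pIntergenic}.  Negative
#' bin masses (sampling noise) are clipped to zero and each component is
#' renormalized so the results are valid distributions, usable as HMM
#' expression emissions; the raw (unclipped) solutions are also returned.
#'
#' @param genic,intergenic histograms over shared breaks (lists with
#'   \code{breaks}, \code{mass}).
#' @param pGenic,pIntergenic assumed expressed fractions; must differ.
#' @return list with \code{expressed}, \code{nonExpressed} (clipped,
#'   renormalized) and \code{expressedRaw}, \code{nonExpressedRaw}.
#' @export
deconvolveExpression <- function(genic, intergenic, pGenic = 0.5,
                                 pIntergenic = 0.1) {
  if (!isTRUE(all.equal(genic$breaks, intergenic$breaks)))
    stop("histograms must share bin edges")
  p <- pGenic; q <- pIntergenic
  if (p == q) stop("pGenic and pIntergenic must differ (singular unmixing)")
  fg <- genic$mass; fi <- intergenic$mass
  fe <- ((1 - q) * fg - (1 - p) * fi) / (p - q)
  fn <- (p * fi - q * fg) / (p - q)
  clipNorm <- function(m) {
    m <- pmax(m, 0)
    s <- sum(m)
    if (s <= 0) stop("deconvolved component has no mass")
    m / s
  }
  list(expressed = list(breaks = genic$breaks, mass = clipNorm(fe)),
       nonExpressed = list(breaks = genic$breaks, mass = clipNorm(fn)),
       expressedRaw = list(breaks = genic$breaks, mass = fe),
       nonExpressedRaw = list(breaks = genic$breaks, mass = fn))
}

#' Remove sites falling in duplication-prone intervals
#'
#' Sites inside recent segmental duplications cross-hybridize with their
#' paralogous copy and show spurious imbalance; they are removed before
#' analysis.  Intervals are 0-based half-open (BED); a 1-based site at
#' position p is removed when an interval \code{[a, b)} satisfies
#' \code{a <= p <= b}, i.e. boundary-touching sites on either side are
#' masked.
#'
#' @param x an \linkS4class{AIData} object.
#' @param dup duplication intervals: a \code{GRanges} (1-based, as returned
#'   by [readBed()]) or a data.frame with \code{chrom}, \code{start},
#'   \code{end} in 0-based half-open coordinates.
#' @return the filtered \linkS4class{AIData}; the number of removed sites
#'   is reported via \code{message}.
#' @export
maskDuplications <- function(x, dup) {
  if (is.data.frame(dup)) {
    dup <- GRanges(dup$chrom, IRanges(dup$start + 1L, dup$end))
  }
  if (!length(dup)) return(x)
  ## widen by one base on the left so that a site touching the 0-based
  ## interval start is masked too (see contract above)
  wide <- GRanges(seqnames(dup),
                  IRanges(pmax(start(dup) - 1L, 1L), end(dup)))
  hits <- overlapsAny(rowRanges(x), wide, ignore.strand = TRUE)
  message(sum(hits), " site(s) removed by duplication mask")
  x[!hits, ]
}
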