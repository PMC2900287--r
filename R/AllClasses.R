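#' @include aiscan-package.R
NULL

#' AIData: site-by-sample allelic expression data
#'
#' An extension of \linkS4class{RangedSummarizedExperiment} holding, for a
#' set of biallelic polymorphic sites (rows) and individuals (columns), the
#' genotype call (\code{"het"}, \code{"hom"} or \code{"missing"}), the total
#' expression value \code{E} (log2 of the DNA-normalized combined abundance
#' of the two alleles) and the allelic log-ratio \code{R} (log2 fold
#' difference between the two alleles, normalized by the genomic-DNA ratio,
#' defined only at heterozygous sites).  Row ranges carry the site metadata:
#' \code{snp_id}, \code{alleleA}, \code{alleleB} and the \code{genic} flag.
#'
#' Sites are strictly sorted by (chromosome, position) with unique positions
#' per chromosome; \code{R} is non-missing exactly at heterozygous sites and
#' \code{E} is finite wherever the genotype is not missing.
#'
#' @export
setClass("AIData", contains = "RangedSummarizedExperiment")

setValidity("AIData", function(object) {
  msg <- character(0)
  an <- assayNames(object)
  if (!all(c("geno", "E", "R") %in% an))
    return("assays 'geno', 'E' and 'R' are required")
  rr <- rowRanges(object)
  need <- c("snp_id", "alleleA", "alleleB", "genic")
  if (!all(need %in% names(mcols(rr))))
    return(paste("row ranges need metadata columns:",
                 paste(need, collapse = ", ")))
  ord <- order(as.factor(seqnames(rr)), start(rr))
  if (!identical(ord, seq_along(rr)))
    msg <- c(msg, "sites must be sorted by (chromosome, position)")
  if (anyDuplicated(paste(seqnames(rr), start(rr))))
    msg <- c(msg, "duplicate positions on a chromosome")
  geno <- assay(object, "geno")
  if (!all(geno %in% c("het", "hom", "missing")))
    msg <- c(msg, "genotype calls must be 'het', 'hom' or 'missing'")
  R <- assay(object, "R")
  badHom <- !is.na(R) & geno != "het"
  if (any(badHom)) {
    i <- which(badHom, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf("R present at non-het site %s (individual %s)",
                          mcols(rr)$snp_id[i[1]],
                          colnames(object)[i[2]]))
  }
  if (any(is.na(R) & geno == "het"))
    msg <- c(msg, "R missing at a heterozygous site")
  E <- assay(object, "E")
  if (any(!is.finite(E) & geno != "missing"))
    msg <- c(msg, "E must be finite wherever the genotype is not missing")
  if (length(msg)) msg else TRUE
})

#' ErgodicModel: single-sample ergodic hidden Markov model
#'
#' The 2m+2-state ergodic HMM over allelic expression observations.  States
#' are \code{N} (non-expressed), \code{Mm..M1} (negative imbalance),
#' \code{B} (balanced) and \code{P1..Pm} (positive imbalance).  Each
#' expressed state emits \code{E} from a shared expressed-expression
#' histogram and \code{R} from a state-specific normal; state \code{N} emits
#' \code{E} from the non-expressed histogram and \code{R} from a fixed
#' broad zero-mean normal, so its classification is driven by expression.
#' Expression emissions stay fixed during training; the normal means and
#' standard deviations, the homogeneous transition matrix and the initial
#' distribution are trained by Baum-Welch.
#'
#' @slot states character vector of state labels, \code{N} first, expressed
#'   states in increasing order of mean log-ratio.
#' @slot mu,sigma named per-state normal parameters for \code{R}; by
#'   convention \code{mu["N"] == 0} and \code{sigma["N"]} is fixed.
#' @slot trans row-stochastic homogeneous transition matrix.
#' @slot pi initial state distribution.
#' @slot meanGap mean inter-SNP distance D (bp) used for the unit kernel.
#' @slot exprHist,nonExprHist expression histograms (\code{breaks}/\code{mass}
#'   lists) for expressed states and for \code{N}.
#' @slot m number of positive (and negative) imbalance levels.
#' @slot fit list of training diagnostics (log-likelihood trace, iterations,
#'   convergence flag).
#' @export
setClass("ErgodicModel",
  representation(states = "character", mu = "numeric", sigma = "numeric",
                 trans = "matrix", pi = "numeric", meanGap = "numeric",
                 exprHist = "list", nonExprHist = "list", m = "integer",
                 fit = "list"))

setValidity("ErgodicModel", function(object) {
  msg <- character(0)
  S <- length(object@states)
  if (S != 2L * object@m + 2L)
    msg <- c(msg, "state count must be 2m+2")
  if (anyDuplicated(object@states)) msg <- c(msg, "state labels not unique")
  if (object@states[1] != "N") msg <- c(msg, "state 'N' must come first")
  if (length(object@mu) != S || length(object@sigma) != S)
    msg <- c(msg, "mu and sigma must have one entry per state")
  if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
  if (!isTRUE(all.equal(unname(object@mu["N"]), 0)))
    msg <- c(msg, "mu['N'] must be 0")
  expressed <- object@states[-1]
  if (is.unsorted(object@mu[expressed]))
    msg <- c(msg, "expressed-state means must be non-decreasing")
  if (!all(dim(object@trans) == c(S, S)))
    msg <- c(msg, "transition matrix has wrong dimensions")
  if (any(object@trans < -1e-9) ||
      any(abs(rowSums(object@trans) - 1) > 1e-6))
    msg <- c(msg, "transition matrix must be row-stochastic")
  if (length(object@pi) != S || abs(sum(object@pi) - 1) > 1e-6)
    msg <- c(msg, "pi must be a distribution over states")
  for (h in list(object@exprHist, object@nonExprHist)) {
    if (!all(c("breaks", "mass") %in% names(h)) ||
        length(h$breaks) != length(h$mass) + 1L ||
        any(h$mass < 0) || abs(sum(h$mass) - 1) > 1e-6) {
      msg <- c(msg, "expression histograms must be valid distributions")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' TransitionKernel: distance-dependent transition matrices
#'
#' Cached eigendecomposition of a trained homogeneous transition matrix
#' \code{T} together with the mean inter-SNP gap \code{D}, from which the
#' per-base-pair unit matrix \code{T^(1/D)} and the matrix \code{T(d) =
#' T^(d/D)} for an arbitrary gap of \code{d} bp are computed via fractional
#' matrix powers (principal branch).
#'
#' @slot trans the trained row-stochastic matrix T.
#' @slot D mean inter-SNP gap in base pairs.
#' @slot lambda,V,Vinv eigendecomposition \code{T = V diag(lambda) V^-1}
#'   (complex).
#' @export
setClass("TransitionKernel",
  representation(trans = "matrix", D = "numeric", lambda = "complex",
                 V = "matrix", Vinv = "matrix"))

#' LTRModel: multi-sample left-to-right hidden Markov model
#'
#' A left-to-right HMM in which every site carries its own copy of the state
#' set of a reference \linkS4class{ErgodicModel} and transitions occur only
#' between states at neighbouring sites.  Emissions are shared across all
#' copies of a state and fixed from the ergodic fit; the per-gap transition
#' matrices are trained jointly on all individuals with the
#' distance-corrected ergodic transitions as a pseudocount prior of weight
#' \code{w}.
#'
#' @slot ergodic the stage-1 \linkS4class{ErgodicModel}.
#' @slot transList named list (per chromosome) of S x S x (n_sites-1)
#'   arrays of per-gap transition matrices.
#' @slot gapList named list (per chromosome) of gap distances in bp.
#' @slot positions named list (per chromosome) of site positions, used to
#'   check alignment of data to the model.
#' @slot pi initial state distribution (taken from the ergodic fit).
#' @slot w pseudocount weight of the ergodic prior.
#' @slot fit training diagnostics.
#' @export
setClass("LTRModel",
  representation(ergodic = "ErgodicModel", transList = "list",
                 gapList = "list", positions = "list", pi = "numeric",
                 w = "numeric", fit = "list"))

setValidity("LTRModel", function(object) {
  msg <- character(0)
  if (object@w < 0) msg <- c(msg, "pseudocount weight w must be >= 0")
  if (!identical(names(object@transList), names(object@positions)))
    msg <- c(msg, "transList and positions must cover the same chromosomes")
  for (chr in names(object@transList)) {
    a <- object@transList[[chr]]
    n <- length(object@positions[[chr]])
    if (n > 1L && dim(a)[3] != n - 1L) {
      msg <- c(msg, sprintf("chromosome %s needs one matrix per gap", chr))
      next
    }
    if (dim(a)[3] > 0) {
      rs <- apply(a, 3, rowSums)
      if (any(abs(rs - 1) > 1e-6))
        msg <- c(msg, sprintf("non-stochastic gap matrix on %s", chr))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ErgodicModel", function(object) {
  cat(sprintf("ErgodicModel: %d states (m = %d), mean gap D = %.1f bp\n",
              length(object@states), object@m, object@meanGap))
  cat("  mu:   ", paste(sprintf("%s=%.3f", object@states, object@mu),
                        collapse = "  "), "\n")
  cat("  sigma:", paste(sprintf("%s=%.3f", object@states, object@sigma),
                        collapse = "  "), "\n")
  if (length(object@fit))
    cat(sprintf("  trained: %d iterations, logLik %.2f, converged: %s\n",
                length(object@fit$logliks),
                tail(object@fit$logliks, 1), object@fit$converged))
})

setMethod("show", "LTRModel", function(object) {
  ns <- vapply(object@positions, length, 1L)
  cat(sprintf(
    "LTRModel: %d chromosome(s), %d sites, w = %g (ergodic prior)\n",
    length(ns), sum(ns), object@w))
  if (length(object@fit))
    cat(sprintf("  trained: %d iterations, joint logLik %.2f\n",
                length(object@fit$logliks), tail(object@fit$logliks, 1)))
})
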