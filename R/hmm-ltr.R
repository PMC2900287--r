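# Multi-sample left-to-right HMM.  Every site carries a copy of the ergodic
# state set; transitions occur only between neighbouring sites, with one
# transition matrix per gap shared across individuals.  Training is a
# two-stage process: stage 1 fits the ergodic model on all individuals;
# stage 2 re-estimates only the per-gap transition matrices by EM, treating
# each individual's data as an independent run of the HMM, with the
# distance-corrected ergodic transitions P_i = T^(d_i/D) as a pseudocount
# prior of weight w:
#   A_i(s,t) = (sum_j xi_{j,i}(s,t) + w P_i(s,t)) /
#              (sum_j gamma_{j,i}(s) + w).

#' Distance-corrected prior transition matrices for each gap
#'
#' \code{P_i = T^(d_i/D)} for every consecutive-site gap \code{d_i},
#' computed from the trained ergodic matrix via the fractional-power
#' kernel.
#'
#' @param ergodic a trained \linkS4class{ErgodicModel}.
#' @param gaps vector of positive gap distances in bp (duplicate positions
#'   would give a non-positive gap and are an error).
#' @return an S x S x length(gaps) array.
#' @export
buildGapPriors <- function(ergodic, gaps) {
  if (length(gaps) && any(gaps <= 0))
    stop("non-positive inter-site gap (duplicate positions?)")
  kernel <- transitionKernel(ergodic@trans, ergodic@meanGap)
  gapTransArray(kernel, gaps)
}

#' Train the left-to-right model
#'
#' Stage-2 EM: emissions and the initial distribution are fixed from the
#' ergodic fit; only the per-gap transition matrices are re-estimated,
#' jointly over all individuals, with the ergodic prior pseudocount of
#' weight \code{w}.  Matrices are initialized at the prior.  Chromosomes
#' are processed independently.  The joint log-likelihood (sum over
#' individuals) must be non-decreasing; convergence uses the same rule as
#' [trainErgodic()] applied to the transition entries.
#'
#' @param x an \linkS4class{AIData} object (all individuals share the site
#'   list).
#' @param ergodic the stage-1 \linkS4class{ErgodicModel}.
#' @param w pseudocount weight (>= 0); \code{w = Inf}-like large values pin
#'   every matrix at its prior, recovering the distance-corrected ergodic
#'   decoder.
#' @param maxIter,absTol,relTol EM control, as in [trainErgodic()].
#' @param verbose print the joint log-likelihood each iteration.
#' @return an \linkS4class{LTRModel}.
#' @export
trainLTR <- function(x, ergodic, w = 10, maxIter = 200L, absTol = 1e-4,
                     relTol = 0.01, verbose = FALSE) {
  stopifnot(w >= 0)
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  S <- length(ergodic@states)
  nInd <- ncol(E)
  cidx <- chromIndex(x)
  transList <- list(); gapList <- list(); positions <- list()
  logliks <- NULL
  for (chr in names(cidx)) {
    idx <- cidx[[chr]]
    n <- length(idx)
    gaps <- siteGaps(start(rowRanges(x))[idx])
    P <- buildGapPriors(ergodic, gaps)
    A <- P
    S <- length(ergodic@states)
    ## emissions are fixed throughout stage 2
    logemCube <- array(0, dim = c(n, S, nInd))
    for (j in seq_len(nInd))
      logemCube[, , j] <- emissionLogLik(ergodic, E[idx, j], R[idx, j],
                                         geno[idx, j])
    lls <- numeric(0)
    for (iter in seq_len(maxIter)) {
      ## xi slices are normalized per-gap posteriors summed over
      ## individuals; rows of slice i sum to the pooled gamma at the left
      ## site of gap i
      es <- .ltr_estep(logemCube, A, ergodic@pi)
      ll <- es$loglik
      if (length(lls) &&
          ll < tail(lls, 1) - 1e-6 * (1 + abs(tail(lls, 1))))
        stop(sprintf(
          "LTR EM log-likelihood decreased (%.8g -> %.8g) at iteration %d",
          tail(lls, 1), ll, iter))
      lls <- c(lls, ll)
      if (verbose) message(sprintf("[%s] iter %d logLik %.4f", chr, iter, ll))
      if (n <= 1L) break
      rs <- colSums(aperm(es$xiAcc, c(2, 1, 3)))     # pooled gamma, S x n-1
      denom <- aperm(array(rs + w, dim = c(S, n - 1L, S)), c(1, 3, 2))
      Anew <- (es$xiAcc + w * P) / denom
      done <- all(abs(Anew - A) <= pmax(absTol, relTol * abs(A)))
      A <- Anew
      if (done) break
    }
    transList[[chr]] <- A
    gapList[[chr]] <- gaps
    positions[[chr]] <- start(rowRanges(x))[idx]
    logliks <- if (is.null(logliks)) lls else {
      len <- max(length(logliks), length(lls))
      pad <- function(v) c(v, rep(tail(v, 1), len - length(v)))
      pad(logliks) + pad(lls)
    }
  }
  obj <- new("LTRModel", ergodic = ergodic, transList = transList,
             gapList = gapList, positions = positions, pi = ergodic@pi,
             w = as.numeric(w),
             fit = list(logliks = logliks, iterations = length(logliks)))
  validObject(obj)
  obj
}

## check that the data's sites match the model's site list
checkAlignment <- function(x, model) {
  cidx <- chromIndex(x)
  if (!setequal(names(cidx), names(model@positions)))
    stop("data and LTR model cover different chromosomes")
  for (chr in names(cidx)) {
    if (!identical(start(rowRanges(x))[cidx[[chr]]],
                   model@positions[[chr]]))
      stop("data sites on ", chr, " do not match the LTR model's site list")
  }
  cidx
}

#' Score a dataset with the left-to-right model
#'
#' Forward-backward decoding of each individual with the trained per-gap
#' transition matrices; returns the posterior expected allelic log-ratio.
#'
#' @param x an \linkS4class{AIData} aligned to the model's site list.
#' @param model an \linkS4class{LTRModel}.
#' @return a sites x individuals score matrix with attribute
#'   \code{method = "ltr"}.
#' @export
scoreLTR <- function(x, model) {
  cidx <- checkAlignment(x, model)
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  S <- matrix(NA_real_, nrow(E), ncol(E), dimnames = dimnames(E))
  erg <- model@ergodic
  for (chr in names(cidx)) {
    idx <- cidx[[chr]]
    A <- model@transList[[chr]]
    trans <- if (length(idx) > 1L) A else erg@trans
    for (j in seq_len(ncol(E))) {
      em <- emissionLogLik(erg, E[idx, j], R[idx, j], geno[idx, j])
      fb <- forwardBackward(em, trans, model@pi)
      S[idx, j] <- posteriorExpectedRatio(fb$gamma, erg)
    }
  }
  structure(S, method = "ltr")
}

#' Viterbi state labels under the left-to-right model
#'
#' @inheritParams scoreLTR
#' @return a sites x individuals character matrix of state labels.
#' @export
viterbiStatesLTR <- function(x, model) {
  cidx <- checkAlignment(x, model)
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  out <- matrix(NA_character_, nrow(E), ncol(E), dimnames = dimnames(E))
  erg <- model@ergodic
  for (chr in names(cidx)) {
    idx <- cidx[[chr]]
    trans <- if (length(idx) > 1L) model@transList[[chr]] else erg@trans
    for (j in seq_len(ncol(E))) {
      em <- emissionLogLik(erg, E[idx, j], R[idx, j], geno[idx, j])
      vit <- viterbiPath(em, trans, model@pi)
      out[idx, j] <- erg@states[vit$path]
    }
  }
  out
}
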