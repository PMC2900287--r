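# Single-sample ergodic HMM.  Observations at each site are the pair (E, R);
# expression emissions are fixed histograms (the deconvolved expressed /
# non-expressed distributions), R emissions are state-specific normals.
# Baum-Welch trains the R-normal parameters of the expressed states, the
# homogeneous transition matrix and the initial distribution, pooling the
# sequences (one per chromosome and individual) of all individuals.

## log-density lookup in a (smoothed) histogram; values outside the support
## are clamped to the end bins
ehistLogDensity <- function(h, E) {
  nb <- length(h$mass)
  width <- diff(h$breaks)
  out <- rep(0, length(E))
  ok <- is.finite(E)
  if (any(ok)) {
    clamped <- sum(E[ok] < h$breaks[1] | E[ok] > h$breaks[nb + 1L])
    if (clamped > 0)
      message(clamped, " E value(s) outside histogram support; ",
              "clamped to end bins")
    b <- findInterval(E[ok], h$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    out[ok] <- log(h$mass[b]) - log(width[b])
  }
  out[!ok] <- 0  # uninformative (missing genotype)
  out
}

## add a small floor so empty bins keep nonzero emission probability
smoothHist <- function(h, floor = 1e-6) {
  m <- h$mass + floor
  list(breaks = h$breaks, mass = m / sum(m))
}

#' Create an untrained ergodic model
#'
#' Builds the 2m+2-state model with its fixed expression emissions and the
#' initial parameter values from which Baum-Welch starts: expressed-state
#' means on a symmetric grid (\code{0, +/-muLevels}), a common initial
#' standard deviation, a sticky transition matrix and a uniform initial
#' distribution.  The R emission of the non-expressed state \code{N} is a
#' fixed broad zero-mean normal (sd \code{nSd}) so that classification of
#' non-expressed sites is driven by the expression value.
#'
#' @param exprHist,nonExprHist expression histograms for expressed states
#'   and for \code{N} (e.g. from [deconvolveExpression()]).
#' @param meanGap mean inter-SNP distance D in bp.
#' @param m number of positive (and negative) imbalance levels.
#' @param muLevels positive imbalance means of the initial grid (length m).
#' @param sigmaInit initial R standard deviation of expressed states.
#' @param nSd fixed R standard deviation of state \code{N}.
#' @param selfProb initial self-transition probability.
#' @return an \linkS4class{ErgodicModel}.
#' @export
newErgodicModel <- function(exprHist, nonExprHist, meanGap, m = 3L,
                            muLevels = NULL, sigmaInit = 0.5, nSd = 2,
                            selfProb = 0.95) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (is.null(muLevels))
    muLevels <- if (m == 3L) c(0.5, 1, 2) else seq(0.5, 2, length.out = m)
  stopifnot(length(muLevels) == m, all(muLevels > 0),
            !is.unsorted(muLevels))
  states <- c("N", paste0("M", m:1), "B", paste0("P", 1:m))
  S <- 2L * m + 2L
  mu <- setNames(c(0, -rev(muLevels), 0, muLevels), states)
  sigma <- setNames(c(nSd, rep(sigmaInit, S - 1L)), states)
  trans <- matrix((1 - selfProb) / (S - 1), S, S,
                  dimnames = list(states, states))
  diag(trans) <- selfProb
  new("ErgodicModel", states = states, mu = mu, sigma = sigma,
      trans = trans, pi = setNames(rep(1 / S, S), states),
      meanGap = as.numeric(meanGap),
      exprHist = smoothHist(exprHist), nonExprHist = smoothHist(nonExprHist),
      m = m, fit = list())
}

#' Per-state emission log-likelihoods
#'
#' For a heterozygous site the emission is P(E|state) * Normal(R; mu_s,
#' sigma_s); at homozygous (and missing-genotype) sites the ratio is
#' unobserved and contributes equally to every state, so only the
#' expression term differs (and a fully missing site is uninformative).
#'
#' @param model an \linkS4class{ErgodicModel}.
#' @param E,R,geno observation vectors for one sequence.
#' @param Eterm optional precomputed expression term (sites x states), as
#'   returned with \code{attr(..., "Eterm")}; the expression emissions are
#'   fixed, so callers that re-evaluate emissions during training can reuse
#'   it.
#' @return a sites x states matrix of log-likelihoods.
#' @export
emissionLogLik <- function(model, E, R, geno, Eterm = NULL) {
  S <- length(model@states)
  n <- length(E)
  if (is.null(Eterm)) {
    Eterm <- matrix(0, n, S, dimnames = list(NULL, model@states))
    nonMissing <- geno != "missing"
    eExpr <- ehistLogDensity(model@exprHist, E)
    eNon <- ehistLogDensity(model@nonExprHist, E)
    Eterm[nonMissing, 1L] <- eNon[nonMissing]
    for (s in 2:S) Eterm[nonMissing, s] <- eExpr[nonMissing]
  }
  out <- Eterm
  het <- which(geno == "het")
  if (length(het)) {
    for (s in seq_len(S))
      out[het, s] <- out[het, s] +
        dnorm(R[het], model@mu[s], model@sigma[s], log = TRUE)
  }
  attr(out, "Eterm") <- Eterm
  out
}

#' Forward-backward algorithm
#'
#' Posterior state probabilities, pairwise transition posteriors and the
#' sequence log-likelihood, computed with per-site scaling.
#'
#' @param logem sites x states matrix of emission log-likelihoods.
#' @param trans a single row-stochastic matrix (homogeneous chain) or an
#'   S x S x (n-1) array of per-gap matrices.
#' @param pi initial state distribution.
#' @param xiByGap return \code{xi} as an S x S x (n-1) array of per-gap
#'   posteriors instead of their sum over gaps.
#' @return list with \code{gamma} (sites x states, rows sum to 1),
#'   \code{xi} and \code{loglik}.
#' @export
forwardBackward <- function(logem, trans, pi, xiByGap = FALSE) {
  logem <- as.matrix(logem)
  S <- ncol(logem)
  homog <- is.matrix(trans)
  cube <- if (homog) array(trans, dim = c(S, S, 1L)) else trans
  .hmm_fb(logem, cube, as.numeric(pi), homog, xiByGap)
}

#' Viterbi algorithm
#'
#' Maximum-joint-probability state path; ties are broken toward the lower
#' state index.
#'
#' @inheritParams forwardBackward
#' @return list with \code{path} (1-based state indices) and
#'   \code{logprob}.
#' @export
viterbiPath <- function(logem, trans, pi) {
  logem <- as.matrix(logem)
  S <- ncol(logem)
  homog <- is.matrix(trans)
  cube <- if (homog) array(log(trans), dim = c(S, S, 1L)) else log(trans)
  .hmm_viterbi(logem, cube, log(as.numeric(pi)), homog)
}

## build the per-sequence observation list (one sequence per chromosome and
## individual) with cached fixed expression terms
ergodicSequences <- function(x, model) {
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  seqs <- list()
  for (idx in chromIndex(x)) {
    for (j in seq_len(ncol(E))) {
      em <- emissionLogLik(model, E[idx, j], R[idx, j], geno[idx, j])
      seqs[[length(seqs) + 1L]] <- list(
        idx = idx, ind = j, R = R[idx, j], het = geno[idx, j] == "het",
        Eterm = attr(em, "Eterm"))
    }
  }
  seqs
}

## R-normal part of the emissions, recomputed as mu/sigma evolve
addRterm <- function(Eterm, model, R, het) {
  out <- Eterm
  if (any(het)) {
    for (s in seq_along(model@states))
      out[het, s] <- out[het, s] +
        dnorm(R[het], model@mu[s], model@sigma[s], log = TRUE)
  }
  out
}

#' Baum-Welch training of the ergodic model
#'
#' Trains the R-emission parameters of the expressed states, the
#' homogeneous transition matrix and the initial distribution on the pooled
#' sequences of all individuals; expression emissions stay fixed.  After
#' every M-step the expressed states are re-sorted by mean (the transition
#' matrix and initial distribution are permuted along), which prevents
#' label switching.  Iteration stops when no parameter changes by more than
#' \code{absTol} or 1 percent of its value (\code{relTol}), or after
#' \code{maxIter} iterations.  The log-likelihood must be non-decreasing
#' across iterations; a decrease beyond numerical tolerance is an error.
#'
#' @param x an \linkS4class{AIData} object.
#' @param model an \linkS4class{ErgodicModel} (initial values).
#' @param maxIter maximum EM iterations.
#' @param absTol absolute convergence tolerance.
#' @param relTol relative convergence tolerance (default 1 percent).
#' @param sigmaFloor lower bound on trained standard deviations.
#' @param verbose print the log-likelihood each iteration.
#' @return the trained \linkS4class{ErgodicModel}; slot \code{fit} holds
#'   the log-likelihood trace, iteration count and convergence flag.
#' @export
trainErgodic <- function(x, model, maxIter = 200L, absTol = 1e-4,
                         relTol = 0.01, sigmaFloor = 1e-2,
                         verbose = FALSE) {
  seqs <- ergodicSequences(x, model)
  S <- length(model@states)
  expressed <- 2:S
  logliks <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    ll <- 0
    xiTot <- matrix(0, S, S)
    pi1 <- numeric(S)
    Sw <- SwR <- SwR2 <- numeric(S)
    for (sq in seqs) {
      logem <- addRterm(sq$Eterm, model, sq$R, sq$het)
      fb <- forwardBackward(logem, model@trans, model@pi)
      ll <- ll + fb$loglik
      xiTot <- xiTot + fb$xi
      pi1 <- pi1 + fb$gamma[1L, ]
      if (any(sq$het)) {
        gh <- fb$gamma[sq$het, , drop = FALSE]
        r <- sq$R[sq$het]
        Sw <- Sw + colSums(gh)
        SwR <- SwR + colSums(gh * r)
        SwR2 <- SwR2 + colSums(gh * r * r)
      }
    }
    if (length(logliks) &&
        ll < tail(logliks, 1) - 1e-6 * (1 + abs(tail(logliks, 1))))
      stop(sprintf(
        "EM log-likelihood decreased (%.8g -> %.8g) at iteration %d",
        tail(logliks, 1), ll, iter))
    logliks <- c(logliks, ll)
    if (verbose) message(sprintf("iter %d logLik %.4f", iter, ll))

    old <- c(model@mu[expressed], model@sigma[expressed],
             as.vector(model@trans), model@pi)
    mu <- model@mu; sigma <- model@sigma
    for (s in expressed) {
      if (Sw[s] > 1e-8) {
        mu[s] <- SwR[s] / Sw[s]
        sigma[s] <- max(sqrt(max(SwR2[s] / Sw[s] - mu[s]^2, 0)), sigmaFloor)
      }
    }
    ## update only rows with expected-count mass; a state never visited
    ## keeps its previous (sticky) row, which also keeps the matrix well
    ## inside the cone of matrices with a real fractional power
    trans <- model@trans
    rs <- rowSums(xiTot)
    upd <- rs > 1e-8
    trans[upd, ] <- xiTot[upd, , drop = FALSE] / rs[upd]
    piNew <- pi1 / length(seqs)
    ## keep state labels meaningful: expressed states ordered by mean
    perm <- c(1L, 1L + order(mu[expressed]))
    mu <- setNames(mu[perm], model@states)
    sigma <- setNames(sigma[perm], model@states)
    trans <- trans[perm, perm, drop = FALSE]
    dimnames(trans) <- list(model@states, model@states)
    piNew <- setNames(piNew[perm], model@states)
    model@mu <- mu; model@sigma <- sigma
    model@trans <- trans; model@pi <- piNew

    new <- c(mu[expressed], sigma[expressed], as.vector(trans), piNew)
    if (all(abs(new - old) <= pmax(absTol, relTol * abs(old)))) {
      converged <- TRUE
      break
    }
  }
  model@fit <- list(logliks = logliks, iterations = length(logliks),
                    converged = converged)
  validObject(model)
  model
}

#' Fit the ergodic model to a dataset
#'
#' Convenience wrapper: builds the genic/intergenic expression histograms,
#' deconvolves them into the expressed / non-expressed emissions, creates
#' the initial model with the dataset's mean inter-SNP gap and runs
#' [trainErgodic()].
#'
#' @param x an \linkS4class{AIData} object.
#' @param m imbalance levels (8 states for the default \code{m = 3}).
#' @param nBins expression histogram bins.
#' @param pGenic,pIntergenic assumed expressed fractions for the
#'   deconvolution.
#' @param ... passed to [trainErgodic()].
#' @return a trained \linkS4class{ErgodicModel}.
#' @export
fitErgodic <- function(x, m = 3L, nBins = 200L, pGenic = 0.5,
                       pIntergenic = 0.1, ...) {
  hh <- expressionHistograms(x, nBins = nBins)
  dec <- deconvolveExpression(hh$genic, hh$intergenic, pGenic, pIntergenic)
  model <- newErgodicModel(dec$expressed, dec$nonExpressed,
                           meanGap = meanGap(x), m = m)
  trainErgodic(x, model, ...)
}

#' Posterior expected allelic log-ratio
#'
#' The per-site summary score \code{S_i = sum_s gamma_i(s) mu_s}, with
#' \code{mu_N = 0} by convention (no expression means no measurable
#' imbalance).  Bounded by the range of the state means.
#'
#' @param gamma sites x states posterior matrix.
#' @param model the model providing the state means.
#' @return numeric vector of scores.
#' @export
posteriorExpectedRatio <- function(gamma, model) {
  as.numeric(gamma %*% model@mu)
}

#' Score a dataset with the ergodic model
#'
#' Decodes every chromosome of every individual with the forward-backward
#' algorithm, using the distance-corrected transition matrix
#' \code{T(d) = T^(d/D)} for each inter-SNP gap \code{d}, and returns the
#' posterior expected allelic log-ratio at every site.
#'
#' @param x an \linkS4class{AIData} object.
#' @param model a trained \linkS4class{ErgodicModel}.
#' @param distanceCorrect use per-gap \code{T(d)} (otherwise the trained
#'   homogeneous matrix is used for every gap).
#' @return a sites x individuals score matrix with attribute
#'   \code{method = "ergodic"}.
#' @export
scoreErgodic <- function(x, model, distanceCorrect = TRUE) {
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  S <- matrix(NA_real_, nrow(E), ncol(E), dimnames = dimnames(E))
  kernel <- if (distanceCorrect) transitionKernel(model@trans, model@meanGap)
  for (idx in chromIndex(x)) {
    gaps <- siteGaps(start(rowRanges(x))[idx])
    trans <- if (distanceCorrect && length(gaps)) gapTransArray(kernel, gaps)
             else model@trans
    for (j in seq_len(ncol(E))) {
      em <- emissionLogLik(model, E[idx, j], R[idx, j], geno[idx, j])
      fb <- forwardBackward(em, trans, model@pi)
      S[idx, j] <- posteriorExpectedRatio(fb$gamma, model)
    }
  }
  structure(S, method = "ergodic")
}

#' Viterbi state labels for a dataset
#'
#' @inheritParams scoreErgodic
#' @return a sites x individuals character matrix of state labels.
#' @export
viterbiStates <- function(x, model, distanceCorrect = TRUE) {
  E <- exprValues(x); R <- ratioValues(x); geno <- genoCalls(x)
  out <- matrix(NA_character_, nrow(E), ncol(E), dimnames = dimnames(E))
  kernel <- if (distanceCorrect) transitionKernel(model@trans, model@meanGap)
  for (idx in chromIndex(x)) {
    gaps <- siteGaps(start(rowRanges(x))[idx])
    trans <- if (distanceCorrect && length(gaps)) gapTransArray(kernel, gaps)
             else model@trans
    for (j in seq_len(ncol(E))) {
      em <- emissionLogLik(model, E[idx, j], R[idx, j], geno[idx, j])
      vit <- viterbiPath(em, trans, model@pi)
      out[idx, j] <- model@states[vit$path]
    }
  }
  out
}

#' Allelic-imbalance calls from Viterbi state labels
#'
#' A site is called imbalanced when its Viterbi state is one of the
#' positive or negative imbalance states (not \code{N} or \code{B}).
#'
#' @param states character matrix from [viterbiStates()] (ergodic or
#'   left-to-right).
#' @return a logical matrix of the same shape.
#' @export
aiCalls <- function(states) {
  states != "N" & states != "B"
}
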