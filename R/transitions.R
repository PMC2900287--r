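# Distance-dependent transition matrices.  The homogeneous matrix T trained
# at the mean inter-SNP gap D is converted to a per-base-pair kernel
# T1 = T^(1/D) through its eigendecomposition (principal branch of the
# fractional power); the matrix used for a pair of sites d bp apart is then
# T(d) = T^(d/D).  Fractional powers of a stochastic matrix need not be
# exactly stochastic, so results are projected back (negative entries
# clipped, rows renormalized) before use in an HMM.

#' Build a distance-dependent transition kernel
#'
#' @param trans a row-stochastic transition matrix trained at the mean gap.
#' @param D mean inter-SNP distance in base pairs (> 0).
#' @return a \linkS4class{TransitionKernel}.
#' @export
transitionKernel <- function(trans, D) {
  stopifnot(is.matrix(trans), nrow(trans) == ncol(trans), D > 0)
  if (any(abs(rowSums(trans) - 1) > 1e-6))
    stop("transition matrix must be row-stochastic")
  eg <- eigen(trans)
  V <- matrix(as.complex(eg$vectors), nrow(trans), ncol(trans))
  Vinv <- tryCatch(solve(V), error = function(e)
    stop("transition matrix is not diagonalizable; ",
         "perturb it with a small jitter and retry"))
  recon <- Re(V %*% (as.complex(eg$values) * Vinv))
  if (max(abs(recon - trans)) > 1e-8)
    stop("transition matrix is not diagonalizable; ",
         "perturb it with a small jitter and retry")
  new("TransitionKernel", trans = trans, D = as.numeric(D),
      lambda = as.complex(eg$values), V = V, Vinv = Vinv)
}

#' Transition matrix at a given genomic distance
#'
#' Computes \code{T(d) = V diag(lambda^(d/D)) V^-1} from the cached
#' eigendecomposition.  With \code{project = TRUE} (the default) the result
#' is projected to a stochastic matrix; \code{project = FALSE} returns the
#' raw real part (useful for checking the semigroup property
#' \code{T(d1+d2) = T(d1) T(d2)}, which holds before projection).
#' An imaginary residue above \code{imagTol} is an error.
#'
#' @param kernel a \linkS4class{TransitionKernel}.
#' @param d distance in base pairs (>= 0); \code{d = 0} gives the identity,
#'   \code{d = D} recovers the trained matrix.
#' @param project project the result back to a stochastic matrix.
#' @param imagTol largest tolerated imaginary residue.
#' @return a square numeric matrix.
#' @export
transitionAtDistance <- function(kernel, d, project = TRUE,
                                 imagTol = 1e-8) {
  stopifnot(is(kernel, "TransitionKernel"), d >= 0)
  S <- nrow(kernel@trans)
  if (d == 0) return(diag(S))
  pw <- d / kernel@D
  lam <- kernel@lambda
  lp <- complex(length.out = length(lam))
  nz <- Mod(lam) > 0
  lp[nz] <- exp(pw * log(lam[nz]))  # principal branch
  M <- kernel@V %*% (lp * kernel@Vinv)
  if (max(abs(Im(M))) > imagTol)
    stop("fractional matrix power has imaginary residue ",
         format(max(abs(Im(M)))), "; the matrix likely has negative real ",
         "eigenvalues and no real fractional power")
  M <- Re(M)
  if (project) {
    M <- pmax(M, 0)
    M <- rowNormalize(M)
  }
  M
}

#' Unit (per-base-pair) transition matrix
#'
#' The D-th root of the trained matrix, \code{T1 = T^(1/D)}.
#'
#' @param trans trained row-stochastic matrix, or a
#'   \linkS4class{TransitionKernel}.
#' @param D mean inter-SNP gap (ignored when a kernel is given).
#' @param ... passed to [transitionAtDistance()].
#' @return a square numeric matrix.
#' @export
unitTransition <- function(trans, D, ...) {
  kernel <- if (is(trans, "TransitionKernel")) trans
            else transitionKernel(trans, D)
  transitionAtDistance(kernel, 1, ...)
}

## S x S x (n-1) array of projected T(d) for a vector of gaps.  Decoding
## tolerates any imaginary residue, unlike the exported primitive: a
## trained matrix can carry negative eigenvalues (oscillating state
## patterns fitted on sparse data) whose principal fractional powers are
## complex; dropping the imaginary part and projecting to a stochastic
## matrix gives the standard real interpolation used by array-CNV HMMs.
gapTransArray <- function(kernel, gaps, imagTol = Inf) {
  S <- nrow(kernel@trans)
  out <- array(0, dim = c(S, S, length(gaps)))
  for (i in seq_along(gaps))
    out[, , i] <- transitionAtDistance(kernel, gaps[i], imagTol = imagTol)
  out
}
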