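# Shared internal helpers.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package functions do
#' not disturb the caller's RNG stream.  A \code{NULL} seed evaluates the
#' expression under the current stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## row-normalize a nonnegative matrix; zero rows become uniform
rowNormalize <- function(x) {
  rs <- rowSums(x)
  zero <- rs <= 0
  if (any(zero)) {
    x[zero, ] <- 1 / ncol(x)
    rs[zero] <- 1
  }
  x / rs
}

## quantile-based level assignment used by the permutation binning; ties in
## the quantiles collapse levels, NA values fall in level 1
quantileLevels <- function(x, nLevels = 5L) {
  xx <- x[is.finite(x)]
  if (length(xx) == 0L) return(rep(1L, length(x)))
  br <- unique(quantile(xx, probs = seq(0, 1, length.out = nLevels + 1L),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  lev <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  lev[is.na(lev)] <- 1L
  as.integer(lev)
}

## consecutive gap distances (bp) between sites of one chromosome
siteGaps <- function(pos) {
  if (length(pos) < 2L) return(numeric(0))
  diff(pos)
}
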