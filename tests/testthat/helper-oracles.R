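# Independent brute-force oracles and small fixture builders used across
# the test files.  Everything here is deliberately naive: exhaustive path
# enumeration for HMM quantities and a literal re-enumeration loop for the
# greedy window assignment.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## enumerate all S^n state paths; returns gamma, xi (summed), loglik and the
## best path (ties toward lower state indices, matching viterbiPath)
enumHMM <- function(logem, trans, pi) {
  n <- nrow(logem); S <- ncol(logem)
  transAt <- function(t) if (is.matrix(trans)) trans else trans[, , t]
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))[, n:1, drop = FALSE]
  ## expand.grid varies the first factor fastest; reversed so column 1 is
  ## the first site and enumeration order is lexicographic in the path
  logp <- apply(paths, 1, function(p) {
    lp <- log(pi[p[1]]) + logem[1, p[1]]
    if (n > 1) for (t in 2:n)
      lp <- lp + log(transAt(t - 1)[p[t - 1], p[t]]) + logem[t, p[t]]
    lp
  })
  w <- exp(logp - max(logp))
  lik <- sum(w)
  gamma <- matrix(0, n, S)
  xi <- matrix(0, S, S)
  for (k in seq_len(nrow(paths))) {
    for (t in seq_len(n)) gamma[t, paths[k, t]] <- gamma[t, paths[k, t]] + w[k]
    if (n > 1) for (t in 2:n)
      xi[paths[k, t - 1], paths[k, t]] <- xi[paths[k, t - 1], paths[k, t]] + w[k]
  }
  best <- which.max(logp)  # first max = lexicographically smallest path
  list(gamma = gamma / lik, xi = xi / lik,
       loglik = log(lik) + max(logp), path = unname(paths[best, ]))
}

## random row-stochastic matrix (Dirichlet rows)
randomStochastic <- function(S, concentration = 1) {
  m <- matrix(rgamma(S * S, concentration), S, S)
  m / rowSums(m)
}

## random sticky stochastic matrix, as arises for genomic segment models
randomSticky <- function(S, self = 0.9) {
  m <- matrix(runif(S * S), S, S)
  diag(m) <- 0
  m <- (1 - self) * m / rowSums(m)
  diag(m) <- self
  m
}

## random HMM instance for oracle comparisons
randomInstance <- function(n, S, perGap = FALSE) {
  logem <- matrix(log(runif(n * S, 0.05, 1)), n, S)
  pi <- rgamma(S, 1); pi <- pi / sum(pi)
  trans <- if (perGap && n > 1) {
    a <- array(0, c(S, S, n - 1))
    for (t in seq_len(n - 1)) a[, , t] <- randomStochastic(S)
    a
  } else randomStochastic(S)
  list(logem = logem, trans = trans, pi = pi)
}

## literal greedy loop: recompute the candidate set each round
greedyOracle <- function(z, wMax) {
  n <- length(z)
  assigned <- rep(NA_real_, n)
  taken <- rep(FALSE, n)
  while (any(!taken)) {
    best <- NULL
    for (start in seq_len(n)) {
      for (len in seq_len(min(wMax, n - start + 1))) {
        idx <- start:(start + len - 1)
        if (any(taken[idx])) next
        Z <- sum(z[idx]) / sqrt(len)
        ## ties: leftmost then shortest -- enumeration order guarantees it
        if (is.null(best) || abs(Z) > best$a) {
          best <- list(idx = idx, Z = Z, a = abs(Z))
        }
      }
    }
    assigned[best$idx] <- best$Z
    taken[best$idx] <- TRUE
  }
  assigned
}

## small AIData built by hand
makeAIData <- function(pos = c(100, 500, 900), chrom = "chr1",
                       geno = NULL, E = NULL, R = NULL, nInd = 2,
                       genic = TRUE) {
  n <- length(pos)
  if (is.null(geno)) geno <- matrix("het", n, nInd)
  if (is.null(E)) E <- matrix(1, n, nInd)
  if (is.null(R)) { R <- matrix(0.5, n, nInd); R[geno != "het"] <- NA }
  colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  gr <- GRanges(chrom, IRanges(pos, width = 1),
                snp_id = paste0("rs", seq_len(n)),
                alleleA = "A", alleleB = "B",
                genic = rep(genic, length.out = n))
  AIData(gr, geno, E, R)
}

## tiny ergodic model with simple two-bin expression histograms
makeTinyModel <- function(m = 1L, meanGap = 1000) {
  hi <- list(breaks = c(-4, 0, 4), mass = c(0.1, 0.9))   # expressed
  lo <- list(breaks = c(-4, 0, 4), mass = c(0.9, 0.1))   # non-expressed
  newErgodicModel(hi, lo, meanGap = meanGap, m = m)
}
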