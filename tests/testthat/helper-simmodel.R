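# Simulate observations directly from a known ergodic model (used by the
# parameter-recovery checks): a homogeneous Markov chain over the states,
# expression values drawn from the state-appropriate histogram, ratios from
# the state normals at heterozygous sites.

## discretized normal histogram on shared breaks
normalHist <- function(mean, sd, breaks = seq(-6, 6, length.out = 201)) {
  p <- diff(pnorm(breaks, mean, sd))
  list(breaks = breaks, mass = p / sum(p))
}

## sample n values from a histogram (uniform within the drawn bin)
sampleHist <- function(h, n) {
  b <- sample.int(length(h$mass), n, replace = TRUE, prob = h$mass)
  runif(n, h$breaks[b], h$breaks[b + 1])
}

simulateFromModel <- function(model, n, pHet = 0.7, gap = 3500,
                              seed = NULL) {
  withSeed(seed, {
    S <- length(model@states)
    states <- integer(n)
    states[1] <- sample.int(S, 1, prob = model@pi)
    for (t in 2:n)
      states[t] <- sample.int(S, 1, prob = model@trans[states[t - 1], ])
    expressed <- states != 1L
    E <- numeric(n)
    E[expressed] <- sampleHist(model@exprHist, sum(expressed))
    E[!expressed] <- sampleHist(model@nonExprHist, sum(!expressed))
    geno <- ifelse(runif(n) < pHet, "het", "hom")
    R <- rep(NA_real_, n)
    het <- geno == "het"
    R[het] <- rnorm(sum(het), model@mu[states[het]],
                    model@sigma[states[het]])
    x <- makeAIData(pos = seq(gap, by = gap, length.out = n),
                    geno = matrix(geno, n, 1),
                    E = matrix(E, n, 1), R = matrix(R, n, 1))
    list(data = x, states = states)
  })
}

## the "true" model the recovery experiment starts from
recoveryTruthModel <- function(self = 0.97) {
  eh <- normalHist(1.5, 1.0)
  nh <- normalHist(-1.5, 0.6)
  m <- newErgodicModel(eh, nh, meanGap = 3500, m = 3L, selfProb = self)
  m@mu[] <- c(0, -2.4, -1.2, -0.55, 0, 0.55, 1.2, 2.4)
  m@sigma[] <- c(2, rep(0.35, 7))
  m
}
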