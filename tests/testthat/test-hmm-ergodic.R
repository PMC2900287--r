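test_that("emission log-likelihoods respect the observation model", {
  model <- makeTinyModel(m = 3L)

  ## hom site: the ratio is unobserved, so all expressed states share the
  ## same value (they share the expression histogram)
  em <- emissionLogLik(model, E = 1, R = NA, geno = "hom")
  expect_equal(length(unique(round(em[1, -1], 12))), 1L)

  ## het site at R = mu_B: B is maximal among the equal-sigma expressed
  ## states
  em <- emissionLogLik(model, E = 1, R = model@mu["B"], geno = "het")
  expressed <- em[1, -1]
  expect_equal(names(which.max(expressed)), "B")

  ## lowest-bin E: N exceeds expressed states by the histogram log-ratio
  em <- emissionLogLik(model, E = -2, R = NA, geno = "hom")
  expect_equal(unname(em[1, "N"] - em[1, "B"]),
               log(model@nonExprHist$mass[1]) - log(model@exprHist$mass[1]))

  ## missing genotype is uninformative
  em <- emissionLogLik(model, E = NA, R = NA, geno = "missing")
  expect_true(all(em == 0))
})

test_that("forward-backward and Viterbi match exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    S <- sample(2:4, 1)
    inst <- randomInstance(n, S, perGap = (rep %% 2 == 0))
    fb <- forwardBackward(inst$logem, inst$trans, inst$pi)
    ref <- enumHMM(inst$logem, inst$trans, inst$pi)
    expect_equal(fb$loglik, ref$loglik, tolerance = 1e-9)
    expect_equal(fb$gamma, ref$gamma, tolerance = 1e-9)
    expect_equal(fb$xi, ref$xi, tolerance = 1e-9)
    vit <- viterbiPath(inst$logem, inst$trans, inst$pi)
    expect_equal(vit$path, ref$path)
  }

  ## single site: gamma proportional to pi * emission
  inst <- randomInstance(1, 3)
  fb <- forwardBackward(inst$logem, inst$trans, inst$pi)
  g <- inst$pi * exp(inst$logem[1, ])
  expect_equal(fb$gamma[1, ], g / sum(g), tolerance = 1e-12)

  ## uniform emissions: gamma equals the Markov-chain marginals
  S <- 3; n <- 6
  trans <- randomSticky(S, 0.7)
  pi <- c(0.5, 0.3, 0.2)
  logem <- matrix(0, n, S)
  fb <- forwardBackward(logem, trans, pi)
  marg <- pi
  for (t in seq_len(n)) {
    expect_equal(fb$gamma[t, ], as.numeric(marg), tolerance = 1e-12)
    marg <- marg %*% trans
  }

  ## symmetric two-state tie resolves to the lower state index
  logem <- matrix(0, 4, 2)
  trans <- matrix(0.5, 2, 2)
  vit <- viterbiPath(logem, trans, c(0.5, 0.5))
  expect_equal(vit$path, rep(1L, 4))

  ## an all-zero-emission site is reported by position
  logem <- matrix(0, 3, 2)
  logem[2, ] <- -Inf
  expect_error(forwardBackward(logem, trans, c(0.5, 0.5)), "site 2")
})

test_that("transition kernel algebra holds", {
  set.seed(33)
  ## T = I is its own root
  kI <- transitionKernel(diag(3), D = 10)
  expect_equal(transitionAtDistance(kI, 1), diag(3), tolerance = 1e-12)
  ## D = 1: the unit matrix is T itself
  Tm <- randomSticky(4, 0.85)
  expect_equal(unitTransition(Tm, D = 1), Tm, tolerance = 1e-9)
  ## root-power inverse: (T^(1/D))^D reproduces T
  D <- 1000
  k <- transitionKernel(Tm, D)
  T1 <- transitionAtDistance(k, 1, project = FALSE)
  acc <- diag(4)
  P2 <- T1
  ## fast exponentiation to the 1000th power
  e <- D
  while (e > 0) {
    if (e %% 2 == 1) acc <- acc %*% P2
    P2 <- P2 %*% P2
    e <- e %/% 2
  }
  expect_equal(acc, Tm, tolerance = 1e-6)
  ## d = 0 and d = D are the identity and the trained matrix
  expect_equal(transitionAtDistance(k, 0), diag(4))
  expect_equal(transitionAtDistance(k, D), Tm, tolerance = 1e-6)
  ## semigroup property before projection
  A <- transitionAtDistance(k, 300, project = FALSE)
  B <- transitionAtDistance(k, 450, project = FALSE)
  AB <- transitionAtDistance(k, 750, project = FALSE)
  expect_equal(A %*% B, AB, tolerance = 1e-8)
  ## projected rows are stochastic
  for (d in c(1, 17, 300, 5000)) {
    M <- transitionAtDistance(k, d)
    expect_true(all(M >= 0))
    expect_equal(rowSums(M), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("Baum-Welch improves the likelihood and stays at optima", {
  ## small training run: log-likelihood trace is non-decreasing
  sim <- simulateDataset(simConfig(nIndividuals = 3,
                                   chromLengths = c(chr1 = 2e6),
                                   nAIRegions = 4), seed = 9)
  suppressMessages({
    model <- fitErgodic(sim$data)
  })
  ll <- model@fit$logliks
  expect_true(all(diff(ll) >= -1e-6 * (1 + abs(ll[-length(ll)]))))
  ## mu stays ordered after training
  expect_false(is.unsorted(model@mu[-1]))

  ## a converged model is a fixed point: one more EM pass moves nothing
  suppressMessages({
    again <- trainErgodic(sim$data, model, maxIter = 1)
  })
  expect_equal(again@mu, model@mu, tolerance = 0.02)
  expect_equal(again@trans, model@trans, tolerance = 0.02)
})

test_that("posterior expected log-ratio follows the state means", {
  model <- makeTinyModel(m = 1L)  # states N, M1, B, P1
  model@mu[] <- c(0, -2, 0, 2)
  g1 <- matrix(c(0, 0, 0, 1), 1)  # all mass on P1 (mu = 2)
  expect_equal(posteriorExpectedRatio(g1, model), 2)
  g2 <- matrix(c(1, 0, 0, 0), 1)  # all mass on N: 0 by convention
  expect_equal(posteriorExpectedRatio(g2, model), 0)
  g3 <- matrix(c(0, 0.5, 0, 0.5), 1)  # symmetric +/-2
  expect_equal(posteriorExpectedRatio(g3, model), 0)
  ## bounded by the range of state means
  set.seed(3)
  g <- matrix(rgamma(40, 1), 10); g <- g / rowSums(g)
  s <- posteriorExpectedRatio(g, model)
  expect_true(all(s >= min(model@mu) & s <= max(model@mu)))
})
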