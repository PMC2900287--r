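test_that("smoothing averages het neighbours with truncated edges", {
  ## k = 0 is the identity on het sites
  R <- matrix(c(0.3, NA, -1, 2), 4, 1)
  geno <- matrix(c("het", "hom", "het", "het"), 4, 1)
  x <- makeAIData(pos = c(10, 20, 30, 40), geno = geno,
                  E = matrix(1, 4, 1), R = R)
  s0 <- scoreSmooth(x, k = 0)
  expect_equal(s0[, 1], R[, 1])

  ## 3-site mean, hom sites transparent
  s1 <- scoreSmooth(x, k = 1)
  expect_equal(unname(s1[3, 1]), mean(c(0.3, -1, 2)))  # hom site 2 skipped
  expect_true(is.na(s1[2, 1]))

  ## truncated edge windows: first of [0,3,0] with k=1 averages 2 sites
  x2 <- makeAIData(pos = c(10, 20, 30),
                   R = matrix(c(0, 3, 0), 3, 1), nInd = 1)
  s <- scoreSmooth(x2, k = 1)
  expect_equal(s[, 1], c(1.5, 1, 1.5))

  ## spec'd edge case: first site of [2, 4, ...] with k=1 is 3
  x3 <- makeAIData(pos = c(10, 20, 30),
                   R = matrix(c(2, 4, 6), 3, 1), nInd = 1)
  expect_equal(unname(scoreSmooth(x3, k = 1)[1, 1]), 3)
})

test_that("expression bins standardize by the local noise level", {
  ## all E identical: a single populated bin holds every het site
  st <- fitExpressionBins(rep(1, 60), rnorm(60), minBinN = 10)
  expect_equal(length(unique(st$group)), 1L)

  ## constant R in a bin hits the sigma floor, not zero
  st <- fitExpressionBins(rep(1, 60), rep(0.7, 60), minBinN = 10,
                          sigmaFloor = 1e-3)
  g <- unique(st$group)
  expect_equal(unname(st$sigma[g]), 1e-3)

  ## recovered sigma decreases with E when the generating noise does
  set.seed(31)
  E <- runif(20000, -2, 2)
  s <- 1.5 * exp(-E)  # decreasing in E
  R <- rnorm(20000, 0, s)
  st <- fitExpressionBins(E, R, nBins = 10, minBinN = 100)
  sig <- st$sigma[!is.na(st$sigma)]  # bins in increasing E order
  expect_true(all(diff(sig) < 0))

  ## site z formula
  stats <- structure(list(breaks = c(0, 1), group = 1L, mu = 0.1,
                          sigma = 0.5, counts = 10L), class = "BinStats")
  expect_equal(siteZ(1.1, 0.5, stats), 2)
  expect_equal(siteZ(0.1, 0.5, stats), 0)
  expect_equal(siteZ(0.6, 0.5, stats), 1)
  expect_error(siteZ(c(0.5, NA), c(0.5, 0.5), stats), "het")
  expect_error(siteZ(0.5, 0.5, stats, geno = "hom"), "het")

  ## no het sites at all
  expect_error(fitExpressionBins(numeric(0), numeric(0)), "het")
})

test_that("regional Z is the normalized window sum", {
  expect_equal(regionalZ(c(1, 1, 1, 1)), 2)
  expect_equal(regionalZ(0.37), 0.37)
  ## null calibration: fixed non-overlapping windows of standardized
  ## independent scores have mean ~0 and variance ~1
  set.seed(7)
  z <- rnorm(50000)
  z <- (z - mean(z)) / sd(z)  # empirical standardization, as site_z does
  Z <- vapply(split(z, rep(1:5000, each = 10)), regionalZ, 1)
  expect_lt(abs(mean(Z)), 0.05)
  expect_gt(var(Z), 0.93)
  expect_lt(var(Z), 1.07)
})

test_that("greedy window assignment matches the re-enumeration oracle", {
  ## all-zero scores stay zero
  expect_equal(as.numeric(greedyWindowAssignment(rep(0, 5), 3)), rep(0, 5))

  ## dominant window is picked first and scores its sites
  z <- c(0, 0, 5, 5, 0)
  s <- greedyWindowAssignment(z, wMax = 2)
  expect_equal(s[3], 10 / sqrt(2))
  expect_equal(s[4], 10 / sqrt(2))

  ## randomized equivalence with the brute-force loop
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    wMax <- sample(1:3, 1)
    z <- rnorm(n)
    expect_equal(as.numeric(greedyWindowAssignment(z, wMax)),
                 greedyOracle(z, wMax))
  }

  ## every het site is assigned exactly once (partition property)
  set.seed(12)
  z <- rnorm(200)
  s <- greedyWindowAssignment(z, 25)
  expect_false(any(is.na(s)))
  win <- attr(s, "window")
  expect_true(all(tapply(seq_along(z), win, function(i)
    all(diff(i) == 1))))  # windows are contiguous site runs
})

test_that("scoreZ assigns a score to every het site and only het sites", {
  sim <- simulateDataset(simConfig(nIndividuals = 3,
                                   chromLengths = c(chr1 = 2e6),
                                   nAIRegions = 2), seed = 4)
  S <- scoreZ(sim$data, minBinN = 20)
  het <- isHet(sim$data)
  expect_true(all(is.na(S[!het])))
  expect_false(any(is.na(S[het])))
})
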