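test_that("simulation is reproducible from the seed", {
  cfg <- simConfig(nIndividuals = 3, chromLengths = c(chr1 = 2e6),
                   nAIRegions = 3)
  a <- simulateDataset(cfg, seed = 99)
  b <- simulateDataset(cfg, seed = 99)
  expect_identical(exprValues(a$data), exprValues(b$data))
  expect_identical(ratioValues(a$data), ratioValues(b$data))
  expect_identical(genoCalls(a$data), genoCalls(b$data))
  expect_identical(a$truth$trueRatio, b$truth$trueRatio)
  c <- simulateDataset(cfg, seed = 100)
  expect_false(identical(exprValues(a$data), exprValues(c$data)))
})

test_that("genotypes follow Hardy-Weinberg at the configured frequency", {
  cfg <- simConfig(nIndividuals = 4, chromLengths = c(chr1 = 10e6),
                   mafRange = c(0.5, 0.5), missingRate = 0,
                   nAIRegions = 0)
  sim <- simulateDataset(cfg, seed = 21)
  het <- mean(isHet(sim$data))
  n <- length(genoCalls(sim$data))
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / n))
})

test_that("expressed fractions and SNP densities match the configuration", {
  cfg <- simConfig(nIndividuals = 2, chromLengths = c(chr1 = 60e6),
                   nAIRegions = 0)
  sim <- simulateDataset(cfg, seed = 31)
  genic <- mcols(siteInfo(sim$data))$genic
  tr <- sim$truth$transcripts
  ## per-transcript expressed flags: se on the 0.5 fraction scales with
  ## the transcript count
  fGenic <- mean(sim$truth$expressed[genic])
  expect_lt(abs(fGenic - 0.5), 3 * sqrt(0.25 / length(tr)) + 0.02)
  fInter <- mean(sim$truth$expressed[!genic])
  expect_lt(abs(fInter - 0.1), 0.06)
  ## SNP density: one site per ~3.5 kb of gene, ~4.5 kb of intergenic
  genicBp <- sum(width(tr))
  interBp <- sum(cfg$chromLengths) - genicBp
  expect_lt(abs(sum(genic) / (genicBp / 3500) - 1), 0.1)
  expect_lt(abs(sum(!genic) / (interBp / 4500) - 1), 0.1)
})

test_that("expression at genic sites is bimodal", {
  cfg <- simConfig(nIndividuals = 2, chromLengths = c(chr1 = 40e6),
                   nAIRegions = 0)
  sim <- simulateDataset(cfg, seed = 41)
  genic <- mcols(siteInfo(sim$data))$genic
  E <- exprValues(sim$data)[genic, ]
  E <- E[is.finite(E)]
  suppressPackageStartupMessages(library(mclust))
  fit <- Mclust(as.numeric(E), G = 2, verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  ## two well-separated components near the configured means
  expect_lt(abs(mu[1] - cfg$nonExprMean), 0.5)
  expect_lt(abs(mu[2] - cfg$exprMean), 0.5)
  expect_gt(diff(mu), 2)
})

test_that("noise law decays with expression and drives the planted data", {
  ## constant when b = 0; asymptote a as E grows
  expect_equal(noiseSd(c(-3, 0, 3), a = 0.3, b = 0), rep(0.3, 3))
  expect_lt(noiseSd(30, a = 0.3, b = 20, c = 1) - 0.3, 1e-10)
  e <- seq(-4, 4, 0.5)
  s <- noiseSd(e)
  expect_true(all(diff(s) < 0))

  ## planted regions carry their true ratio: the observed het-site R mean
  ## inside a region matches the truth within the noise-predicted se
  cfg <- simConfig(nIndividuals = 10, chromLengths = c(chr1 = 20e6),
                   nAIRegions = 0,
                   aiRegionSpec = data.frame(nSites = 40, nCarriers = 10,
                                             magnitude = 1.2, sign = 1))
  sim <- simulateDataset(cfg, seed = 51)
  regs <- sim$truth$aiRegions
  idx <- regs$firstSite:regs$lastSite
  R <- ratioValues(sim$data)[idx, ]
  tr <- sim$truth$trueRatio[idx, ]
  het <- !is.na(R)
  sig <- noiseSd(sim$truth$E0[idx, ], cfg$noiseA, cfg$noiseB, cfg$noiseC,
                 cfg$eMin)
  resid <- (R - tr)[het]
  se <- sqrt(mean(sig[het]^2) / sum(het))
  expect_lt(abs(mean(resid)), 4 * se)
})

test_that("technical replicates share signal but not noise", {
  cfg <- simConfig(nIndividuals = 2, chromLengths = c(chr1 = 30e6),
                   nAIRegions = 10)
  sim <- simulateDataset(cfg, seed = 61)
  rep1 <- simulateReplicates(sim$data, sim$truth, seed = 62)
  ## E more reproducible than R (the ordering of the calibrated targets)
  E1 <- exprValues(sim$data); E2 <- exprValues(rep1)
  ok <- is.finite(E1) & is.finite(E2)
  R1 <- ratioValues(sim$data); R2 <- ratioValues(rep1)
  okr <- !is.na(R1) & !is.na(R2)
  rE <- cor(E1[ok], E2[ok])
  rR <- cor(R1[okr], R2[okr])
  expect_gt(rE, rR)
  ## zero replicate noise: replicate identical to original
  cfg0 <- simConfig(nIndividuals = 2, chromLengths = c(chr1 = 2e6),
                    replicateNoiseScale = 0, nAIRegions = 2)
  sim0 <- simulateDataset(cfg0, seed = 63)
  rep0 <- simulateReplicates(sim0$data, sim0$truth, seed = 64)
  expect_equal(exprValues(rep0), exprValues(sim0$data))
  expect_equal(ratioValues(rep0), ratioValues(sim0$data))
})

test_that("ground truth is internally consistent", {
  cfg <- simConfig(nIndividuals = 5, chromLengths = c(chr1 = 10e6))
  sim <- simulateDataset(cfg, seed = 71)
  tr <- sim$truth
  ## nonzero true ratios only at expressed sites
  expect_true(all(tr$trueRatio[!tr$expressed, ] == 0))
  ## and only inside the recorded regions
  inRegion <- rep(FALSE, nrow(sim$data))
  if (!is.null(tr$aiRegions))
    for (k in seq_len(nrow(tr$aiRegions)))
      inRegion[tr$aiRegions$firstSite[k]:tr$aiRegions$lastSite[k]] <- TRUE
  expect_true(all(tr$trueRatio[!inRegion, ] == 0))
  ## genic flags agree with the transcript layout
  genic <- mcols(siteInfo(sim$data))$genic
  ov <- overlapsAny(siteInfo(sim$data), tr$transcripts, ignore.strand = TRUE)
  expect_equal(genic, ov)
})
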