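test_that("permutation bins cross het-frequency and expression levels", {
  ## identical sites collapse into one bin
  x <- makeAIData(pos = c(10, 20, 30), nInd = 2)
  b <- assignPermutationBins(x)
  expect_equal(length(unique(b)), 1L)

  ## never more than 25 bins; quantile splits balance the marginals
  sim <- simulateDataset(simConfig(nIndividuals = 8,
                                   chromLengths = c(chr1 = 8e6),
                                   nAIRegions = 0), seed = 2)
  b <- assignPermutationBins(sim$data)
  expect_lte(length(unique(b)), 25L)
  el <- attr(b, "eLevel")
  expect_lte(max(table(el)) / min(table(el)), 2.5)
})

test_that("within-bin permutation is reproducible and structure-preserving", {
  sim <- simulateDataset(simConfig(nIndividuals = 5,
                                   chromLengths = c(chr1 = 5e6),
                                   nAIRegions = 5), seed = 8)
  x <- sim$data
  bins <- assignPermutationBins(x)
  p1 <- permuteWithinBins(x, bins, seed = 123)
  p2 <- permuteWithinBins(x, bins, seed = 123)
  p3 <- permuteWithinBins(x, bins, seed = 124)
  expect_identical(attr(p1, "perm"), attr(p2, "perm"))
  expect_false(identical(attr(p1, "perm"), attr(p3, "perm")))
  perm <- attr(p1, "perm")
  ## a bijection that respects bins
  expect_true(all(sort(perm) == seq_len(nrow(x))))
  expect_true(all(bins[perm] == bins))
  ## site columns move intact: het counts and E relocate together
  expect_identical(genoCalls(p1), genoCalls(x)[perm, ])
  expect_identical(exprValues(p1), exprValues(x)[perm, ])
  ## marginal distributions are exactly preserved
  expect_identical(sort(rowSums(isHet(p1))), sort(rowSums(isHet(x))))
  ## bins of size 1 stay put
  singles <- which(bins %in% names(which(table(bins) == 1)))
  expect_true(all(perm[singles] == singles))
})

test_that("region calling splits runs by sign and respects minSnps", {
  x <- makeAIData(pos = c(100, 200, 300, 400), nInd = 1)
  S <- matrix(c(0, 2, 2, 0), 4, 1)
  reg <- callRegions(S, x, threshold = 1)
  expect_length(reg, 1L)
  expect_equal(start(reg), 200)
  expect_equal(end(reg), 300)
  expect_equal(reg$sign, 1L)
  expect_equal(reg$nSnps, 2L)
  expect_equal(reg$meanScore, 2)

  ## opposite signs split
  x2 <- makeAIData(pos = c(100, 200), nInd = 1)
  reg <- callRegions(matrix(c(2, -2), 2, 1), x2, threshold = 1)
  expect_length(reg, 2L)
  expect_equal(sort(reg$sign), c(-1L, 1L))

  ## nothing above threshold
  expect_length(callRegions(matrix(c(0.5, -0.5), 2, 1), x2, 1), 0L)

  ## minSnps filters short runs
  reg <- callRegions(S, x, threshold = 1, minSnps = 3)
  expect_length(reg, 0L)

  ## NA (unscored) sites are transparent
  S3 <- matrix(c(2, NA, 2, 0), 4, 1)
  reg <- callRegions(S3, x, threshold = 1)
  expect_length(reg, 1L)
  expect_equal(reg$nSnps, 2L)

  ## mirror symmetry: reversing the track mirrors the calls
  set.seed(9)
  pos <- sort(sample.int(1e5, 30))
  xm <- makeAIData(pos = pos, nInd = 1)
  s <- matrix(rnorm(30), 30, 1)
  fwd <- callRegions(s, xm, 0.8)
  xr <- makeAIData(pos = sort(1e5 + 1 - rev(pos)), nInd = 1)
  rev <- callRegions(s[30:1, , drop = FALSE], xr, 0.8)
  expect_equal(length(fwd), length(rev))
  expect_equal(sort(width(fwd)), sort(width(rev)))

  ## nesting: every region at a higher threshold sits inside one at a
  ## lower threshold
  hi <- callRegions(s, xm, 1.5)
  if (length(hi) && length(fwd))
    expect_true(all(overlapsAny(hi, fwd, type = "within")))
})

test_that("FDR curve is the permuted/real count ratio", {
  x <- makeAIData(pos = seq(100, 1000, by = 100), nInd = 1)
  real <- matrix(c(rep(2, 5), rep(0, 5)), 10, 1)
  perm <- matrix(c(rep(0, 8), 2, 2), 10, 1)
  fc <- fdrCurve(real, perm, x, thresholds = c(1, 3))
  expect_equal(fc$nReal, c(1, 0))
  expect_equal(fc$nPerm, c(1, 0))
  expect_equal(fc$fdr[1], 1)
  expect_true(is.na(fc$fdr[2]))  # 0/0 reported missing
  ## snp-level counting counts sites inside called regions
  fs <- fdrCurve(real, perm, x, thresholds = 1, unit = "snp")
  expect_equal(fs$nReal, 5)
  expect_equal(fs$nPerm, 2)
  ## averaged over multiple permutations
  fm <- fdrCurve(real, list(perm, real), x, thresholds = 1)
  expect_equal(fm$nPerm, 1)
  th <- fdrThreshold(fm, level = 1)
  expect_equal(th$threshold, 1)
  expect_equal(th$nReal, 1)
})

test_that("enrichment compares overlap to the random expectation", {
  u <- 1:1000
  expect_equal(enrichmentFold(u, 1:100, u), 1)
  expect_equal(enrichmentFold(1:50, 1:100, u), 10)
  expect_error(enrichmentFold(integer(0), 1:100, u), "empty")
  expect_error(enrichmentFold(1:50, integer(0), u), "empty")
  expect_error(enrichmentFold(1:50, 2000, u), "subset")
  ## random predictions have fold ~= 1
  set.seed(17)
  folds <- replicate(200, enrichmentFold(sample(u, 100), 1:200, u))
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("region classification follows the rule cascade", {
  genes <- GRanges("chr1",
                   IRanges(c(100e3, 300e3, 500e3), c(200e3, 400e3, 560e3)),
                   strand = c("+", "-", "+"))
  mk <- function(s, e) GRanges("chr1", IRanges(s, e))
  ## boundaries within 20 kb of one gene
  expect_equal(classifyRegion(mk(95e3, 210e3), genes), "exact transcript")
  ## little or no overlap with genes
  expect_equal(classifyRegion(mk(230e3, 290e3), genes), "intergenic")
  ## inside the gene, away from both boundaries
  expect_equal(classifyRegion(mk(125e3, 175e3), genes), "intronic")
  ## one matched boundary, strand-aware 5'/3'
  expect_equal(classifyRegion(mk(100e3, 150e3), genes), "5' end")
  expect_equal(classifyRegion(mk(150e3, 200e3), genes), "3' end")
  ## minus-strand gene flips the ends
  expect_equal(classifyRegion(mk(300e3, 350e3), genes), "3' end")
  expect_equal(classifyRegion(mk(350e3, 400e3), genes), "5' end")
  ## extension beyond a boundary
  expect_equal(classifyRegion(mk(40e3, 200e3), genes), "extended 5'")
  expect_equal(classifyRegion(mk(100e3, 260e3), genes), "extended 3'")
  expect_equal(classifyRegion(mk(450e3, 560e3), genes), "extended 5'")
  ## two genes covered
  expect_equal(classifyRegion(mk(90e3, 410e3), genes),
               "multiple transcripts")
  ## vectorized over regions
  out <- classifyRegion(c(mk(95e3, 210e3), mk(230e3, 290e3)), genes)
  expect_equal(out, c("exact transcript", "intergenic"))
})

test_that("commonality counts tally individuals sharing a call", {
  calls <- matrix(FALSE, 5, 4)
  expect_equal(nrow(commonalityCounts(calls)), 0L)  # no AI anywhere
  calls[1, ] <- TRUE                       # shared by all 4
  calls[2, 1:2] <- TRUE                    # shared by 2
  calls[3, 3] <- TRUE                      # unique
  cc <- commonalityCounts(calls)
  expect_equal(cc$nSnps[cc$nIndividuals == 4], 1L)
  expect_equal(cc$nSnps[cc$nIndividuals == 2], 1L)
  expect_equal(cc$nSnps[cc$nIndividuals == 1], 1L)
})
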