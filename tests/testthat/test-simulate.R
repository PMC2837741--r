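test_that("simulation is a pure function of its config", {
  cfg <- simConfig(nIndividuals = 50, nSnps = 20, seed = 7,
                   errorModel = "random_hardcall", epsilon = 0.2)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assays(a)[["pAA"]],
                   SummarizedExperiment::assays(b)[["pAA"]])
  expect_identical(trueGenotypes(a), trueGenotypes(b))

  cfg2 <- simConfig(nIndividuals = 50, nSnps = 20, seed = 8,
                    errorModel = "random_hardcall", epsilon = 0.2)
  expect_false(identical(trueGenotypes(a),
                         trueGenotypes(simulateCohort(cfg2))))
})

test_that("truth genotypes follow Hardy-Weinberg proportions", {
  # MAF 0: everyone is the AA homozygote
  tr <- simulateTruth(simConfig(nIndividuals = 100, nSnps = 5, seed = 1,
                                maf = 0))
  expect_true(all(tr$truth == 0L))

  # MAF 0.5 at large n: genotype frequencies near (0.25, 0.5, 0.25)
  tr <- simulateTruth(simConfig(nIndividuals = 100000, nSnps = 1, seed = 2,
                                maf = 0.5))
  freqs <- vapply(0:2, function(g) mean(tr$truth == g), numeric(1))
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.01)
})

test_that("zero-error emulation returns certain truth with IQS 1", {
  cfg <- simConfig(nIndividuals = 300, nSnps = 10, seed = 3,
                   maf = list(dist = "uniform", min = 0.1, max = 0.5),
                   errorModel = "soft_blend", epsilon = 0)
  ig <- simulateCohort(cfg)
  expect_equal(max(abs(expectedDosage(ig) - trueGenotypes(ig))), 0)
  m <- snpMetrics(ig)
  expect_true(all(m$iqs == 1))
  expect_true(all(m$accuracy == 1))
})

test_that("soft blend produces the exact IQS = 1 - eps identity downstream", {
  cfg <- simConfig(nIndividuals = 400, nSnps = 30, seed = 4,
                   maf = list(dist = "uniform", min = 0.05, max = 0.5),
                   errorModel = "soft_blend", epsilon = 0.3)
  m <- snpMetrics(simulateCohort(cfg))
  expect_equal(m$iqs, rep(0.7, 30), tolerance = 1e-9)
  # accuracy stays near 1 because argmax still recovers the truth
  expect_true(all(m$accuracy == 1))
})

test_that("major-homozygote bias shrinks the estimated MAF", {
  cfg <- simConfig(nIndividuals = 1000, nSnps = 10, seed = 5, maf = 0.3,
                   errorModel = "major_bias", biasBeta = 0.5)
  ig <- simulateCohort(cfg)
  m <- snpMetrics(ig)
  trueMaf <- vapply(seq_len(10), function(i)
    mean(trueGenotypes(ig)[i, ]) / 2, numeric(1))
  expect_true(all(m$maf < trueMaf))
  # beta = 0.5 halves the dosage: estimated frequency is half the realized
  expect_equal(m$maf, trueMaf / 2, tolerance = 1e-9)
})

test_that("biased SNP subset gets the major-bias model on top of the base model", {
  cfg <- simConfig(nIndividuals = 200, nSnps = 100, seed = 6,
                   maf = list(dist = "uniform", min = 0.1, max = 0.5),
                   errorModel = "soft_blend", epsilon = 0.02,
                   biasFraction = 0.2, biasBeta = 0.6)
  ig <- simulateCohort(cfg)
  rd <- SummarizedExperiment::rowData(ig)
  expect_equal(sum(rd$biased), 20)
  m <- snpMetrics(ig)
  # blend identity for clean SNPs; heavily depressed IQS for biased ones
  expect_equal(m$iqs[!rd$biased], rep(0.98, 80), tolerance = 1e-9)
  expect_true(all(m$iqs[rd$biased] < 0.9))
})

test_that("mean IQS recovers 1 - E[eps] under random hard-calling", {
  cfg <- simConfig(nIndividuals = 1000, nSnps = 1000, seed = 7,
                   maf = list(dist = "uniform", min = 0.05, max = 0.5),
                   errorModel = "random_hardcall",
                   epsilon = list(dist = "uniform", min = 0, max = 0.5))
  m <- snpMetrics(simulateCohort(cfg))
  expect_equal(mean(m$iqs, na.rm = TRUE), 0.75, tolerance = 0.02)
})

test_that("accuracy rises while IQS stays flat as MAF falls (fixed error)", {
  grid <- c(0.005, 0.01, 0.05, 0.1, 0.3, 0.5)
  cfg <- simConfig(nIndividuals = 50000, nSnps = length(grid), seed = 8,
                   maf = list(dist = "fixed", values = grid),
                   errorModel = "random_hardcall", epsilon = 0.3)
  m <- snpMetrics(simulateCohort(cfg))
  # accuracy strictly increases toward low MAF ...
  expect_true(all(diff(m$accuracy) < 0))
  # ... while chance-corrected IQS stays near 1 - eps across the whole range
  expect_true(all(abs(m$iqs - 0.7) < 0.05))
  expect_lt(max(m$iqs) - min(m$iqs), 0.1)
})

test_that("a pure-null split experiment is calibrated", {
  cfg <- simConfig(nIndividuals = 500, nSnps = 6000, seed = 9,
                   maf = list(dist = "uniform", min = 0.01, max = 0.5),
                   errorModel = "soft_blend", epsilon = 0, biasFraction = 0)
  exp <- runSplitExperiment(cfg)
  expect_equal(exp$hits_before, 0)
  expect_gt(exp$lambda_before, 0.9)
  expect_lt(exp$lambda_before, 1.1)
})

test_that("split-half IQS correlation is 1 under the deterministic blend", {
  cfg <- simConfig(nIndividuals = 400, nSnps = 200, seed = 10,
                   maf = list(dist = "uniform", min = 0.05, max = 0.5),
                   errorModel = "soft_blend",
                   epsilon = list(dist = "uniform", min = 0, max = 0.5))
  rob <- runSplitHalfRobustness(cfg)
  expect_equal(rob$correlation, 1, tolerance = 1e-9)
  expect_equal(rob$per_snp$iqs_half1, rob$per_snp$iqs_half2,
               tolerance = 1e-9)
  expect_error(runSplitHalfRobustness(
    simConfig(nIndividuals = 100, nSnps = 10, seed = 1)), "at least 200")
})

test_that("certain posteriors wrap hard calls losslessly", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  ig <- certainPosteriors(truth, c("a", "b"))
  expect_equal(expectedDosage(ig), truth, ignore_attr = TRUE)
  expect_equal(trueGenotypes(ig), truth, ignore_attr = TRUE)
  m <- snpMetrics(ig, minN = 1)
  expect_true(all(m$accuracy == 1))
})
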