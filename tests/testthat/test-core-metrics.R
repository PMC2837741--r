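test_that("confusion tabulation accumulates posterior mass by true genotype", {
  # certain, correct posteriors give a diagonal table
  ct <- confusionTable(c(0, 0, 1), onehotProbs(c(0L, 0L, 1L)))
  expect_equal(as.matrix(ct), diag(c(2, 1, 0)), ignore_attr = TRUE)
  expect_equal(totalN(ct), 3)

  # fractional mass lands in the (imputed, true) cell
  ct <- confusionTable(c(0, 1), rbind(c(0.8, 0.2, 0), c(0.1, 0.6, 0.3)))
  expect_equal(as.matrix(ct),
               rbind(c(0.8, 0.1, 0), c(0.2, 0.6, 0), c(0.0, 0.3, 0)),
               ignore_attr = TRUE)
  expect_equal(totalN(ct), 2)
  expect_equal(rowMarginals(ct), c(0.9, 0.8, 0.3), ignore_attr = TRUE)
  expect_equal(colMarginals(ct), c(1, 1, 0), ignore_attr = TRUE)

  # individuals with missing truth are excluded
  ct <- confusionTable(c(0, NA), rbind(c(1, 0, 0), c(0.5, 0.5, 0)))
  expect_equal(totalN(ct), 1)
  expect_equal(as.matrix(ct)[1, 1], 1)
  expect_equal(sum(as.matrix(ct)[-1]), 0)
})

test_that("confusion tabulation rejects invalid input", {
  expect_error(confusionTable(c(0, 1, 2), onehotProbs(c(0L, 1L))),
               "differ in length")
  expect_error(confusionTable(c(NA, NA), onehotProbs(c(0L, 1L))),
               "all true genotypes are missing")
  expect_error(confusionTable(c(0, 3), onehotProbs(c(0L, 1L))),
               "outside")
  expect_error(confusionTable(c(0, 1), rbind(c(0.5, 0.2, 0.1),
                                             c(0, 1, 0))),
               "sum to 1")
})

test_that("observed and chance agreement match hand arithmetic", {
  tab <- rbind(c(45, 5, 0), c(5, 25, 0), c(0, 0, 20))
  ct <- tableToConfusion(tab)
  expect_equal(observedAgreement(ct), 0.90)
  expect_equal(chanceAgreement(ct), 0.5 * 0.5 + 0.3 * 0.3 + 0.2 * 0.2)

  # perfect diagonal
  expect_equal(observedAgreement(tableToConfusion(diag(c(50, 30, 20)))), 1)

  # uniform table: both agreements are 1/3 by symmetry
  u <- tableToConfusion(matrix(3, 3, 3))
  expect_equal(observedAgreement(u), 1 / 3)
  expect_equal(chanceAgreement(u), 1 / 3)

  # all mass in one cell: chance agreement is 1
  mono <- tableToConfusion(matrix(c(9, rep(0, 8)), 3, 3))
  expect_equal(chanceAgreement(mono), 1)
})

test_that("IQS is the chance-corrected agreement with a degeneracy guard", {
  # perfect match
  expect_equal(iqs(tableToConfusion(diag(c(50, 30, 20)))), 1)

  # worked fractional example
  ct <- tableToConfusion(rbind(c(45, 5, 0), c(5, 25, 0), c(0, 0, 20)))
  expect_equal(iqs(ct), (0.90 - 0.38) / 0.62)

  # independence table has IQS exactly 0 for any marginal distribution
  for (pi in list(c(0.2, 0.3, 0.5), c(0.9, 0.09, 0.01), c(1, 2, 3) / 6)) {
    ind <- 600 * tcrossprod(pi, pi)
    ct <- iqscore:::.newConfusion(ind)
    expect_equal(iqs(ct), 0, tolerance = 1e-12)
  }

  # monomorphic table: undefined, not an error
  expect_true(is.na(iqs(tableToConfusion(matrix(c(9, rep(0, 8)), 3, 3)))))
})

test_that("IQS equals brute-force Cohen's kappa on integer tables", {
  set.seed(11)
  for (k in 1:200) {
    tab <- randomIntTable()
    expect_equal(iqs(tableToConfusion(tab)), bruteKappa(tab),
                 tolerance = 1e-12)
  }
})

test_that("probability mass is conserved and IQS is label-symmetric", {
  set.seed(21)
  for (k in 1:25) {
    n <- sample(5:60, 1)
    truth <- sample(c(0:2, NA), n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
    if (all(is.na(truth))) truth[1] <- 0
    p <- matrix(runif(3 * n), n, 3)
    p <- p / rowSums(p)
    ct <- confusionTable(truth, p)
    expect_equal(totalN(ct), sum(!is.na(truth)),
                 tolerance = 1e-9 * max(1, sum(!is.na(truth))))

    # simultaneous relabeling of the genotype categories
    perm <- sample(1:3)
    truthP <- ifelse(is.na(truth), NA, perm[truth + 1] - 1)
    pP <- p
    pP[, perm] <- p
    ctP <- confusionTable(truthP, pP)
    expect_equal(observedAgreement(ctP), observedAgreement(ct))
    expect_equal(chanceAgreement(ctP), chanceAgreement(ct))
    expect_equal(iqs(ctP), iqs(ct))
  }
})

test_that("IQS is 1 exactly when all off-diagonal mass vanishes", {
  set.seed(31)
  for (k in 1:20) {
    diagTab <- diag(runif(3, 0.5, 20))
    expect_equal(iqs(iqscore:::.newConfusion(diagTab)), 1)
    # perturb one off-diagonal cell: IQS must drop strictly below 1
    pert <- diagTab
    pert[1, 2] <- 0.5
    expect_lt(iqs(iqscore:::.newConfusion(pert)), 1)
  }
})

test_that("cross-platform tabulation is the summed per-individual outer product", {
  # identical certain calls: diagonal table, IQS 1
  p <- onehotProbs(c(0L, 1L, 2L, 1L))
  ct <- crossPlatformConfusion(p, p)
  expect_equal(as.matrix(ct), diag(c(1, 2, 1)), ignore_attr = TRUE)
  expect_equal(iqs(ct), 1)

  # uninformative second platform: agreement equals chance, IQS 0
  b <- matrix(1 / 3, 4, 3)
  ct <- crossPlatformConfusion(p, b)
  expect_equal(observedAgreement(ct), 1 / 3)
  expect_equal(chanceAgreement(ct), 1 / 3)
  expect_equal(iqs(ct), 0, tolerance = 1e-12)

  # hand outer-product oracle on two individuals
  a <- rbind(c(0.9, 0.1, 0), c(0.2, 0.7, 0.1))
  b <- rbind(c(0.8, 0.2, 0), c(0.1, 0.8, 0.1))
  expected <- outer(a[1, ], b[1, ]) + outer(a[2, ], b[2, ])
  expect_equal(as.matrix(crossPlatformConfusion(a, b)), expected,
               ignore_attr = TRUE)

  expect_error(crossPlatformConfusion(a, b[1, , drop = FALSE]),
               "equal cohort sizes")
  expect_warning(res <- crossPlatformConfusion(a, b, paired = FALSE),
                 "marginal")
  expect_equal(totalN(res), 2, tolerance = 1e-9)
})

test_that("accuracy counts best-guess matches with deterministic ties", {
  expect_equal(imputationAccuracy(c(0, 1, 2), onehotProbs(c(0L, 1L, 2L))), 1)
  # argmax calls (0, 1, 0) against truth (0, 1, 2)
  p <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.5, 0.3, 0.2))
  expect_equal(imputationAccuracy(c(0, 1, 2), p), 2 / 3)
  # exact tie goes to the lower genotype index
  expect_equal(bestGuessCalls(matrix(c(0.5, 0.5, 0), 1)), 0L)
  expect_equal(bestGuessCalls(matrix(c(0.2, 0.4, 0.4), 1)), 1L)
})

test_that("always-major calling achieves p^2 accuracy at low MAF", {
  # truth from HWE at MAF 0.05; imputation always calls AA
  set.seed(41)
  n <- 200000
  truth <- rbinom(n, 2, 0.05)
  p <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  acc <- imputationAccuracy(truth, p)
  expect_equal(acc, 0.95^2, tolerance = 0.005)
  # while the same calls have IQS exactly 0 at independence-like structure:
  # all imputed mass in one category makes agreement equal chance
  ct <- confusionTable(truth, p)
  expect_equal(iqs(ct), 0, tolerance = 1e-9)
})

test_that("efficiency is the fraction of confidently imputed genotypes", {
  p <- rbind(c(0.95, 0.05, 0), c(0.85, 0.1, 0.05), c(0.04, 0.05, 0.91))
  expect_equal(imputationEfficiency(p), 2 / 3)
  expect_equal(imputationEfficiency(onehotProbs(c(0L, 1L, 2L))), 1)
  expect_equal(imputationEfficiency(matrix(1 / 3, 5, 3)), 0)
  # strict inequality at the threshold
  expect_equal(imputationEfficiency(rbind(c(0.9, 0.1, 0))), 0)
})

test_that("estimated MAF folds the dosage-implied allele-B frequency", {
  expect_equal(estimatedMAF(onehotProbs(rep(0L, 4))), 0)
  expect_equal(estimatedMAF(onehotProbs(rep(1L, 4))), 0.5)
  expect_equal(estimatedMAF(onehotProbs(c(0L, 1L, 2L))), 0.5)
  expect_equal(estimatedMAF(onehotProbs(rep(2L, 4))), 0)
  expect_equal(estimatedMAF(onehotProbs(rep(2L, 4)), fold = FALSE), 1)
})

test_that("soft-blend posteriors give IQS = 1 - eps independent of MAF", {
  set.seed(51)
  for (maf in c(0.02, 0.1, 0.3, 0.5)) {
    truth <- rbinom(400, 2, maf)
    if (length(unique(truth)) < 2) next
    for (eps in seq(0, 0.9, by = 0.1)) {
      p <- softBlendProbs(truth, eps)
      ct <- confusionTable(truth, p)
      expect_equal(iqs(ct), 1 - eps, tolerance = 1e-9)
      pi2 <- sum(vapply(0:2, function(g) mean(truth == g)^2, numeric(1)))
      expect_equal(observedAgreement(ct), (1 - eps) + eps * pi2,
                   tolerance = 1e-9)
    }
  }
})

test_that("random marginal hard-calling has mean IQS near zero", {
  cfg <- simConfig(nIndividuals = 1000, nSnps = 1000, seed = 61,
                   maf = list(dist = "uniform", min = 0.05, max = 0.5),
                   errorModel = "random_hardcall", epsilon = 1)
  m <- snpMetrics(simulateCohort(cfg))
  expect_lt(abs(mean(m$iqs, na.rm = TRUE)), 0.02)
})
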