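test_that("dosage trend test agrees with the Cochran-Armitage oracle", {
  set.seed(101)
  for (k in 1:50) {
    tab <- randomTrendTable()
    ind <- expandTrendTable(tab)
    mine <- dosageTrendTest(matrix(ind$dosage, 1), ind$y)
    oracle <- suppressWarnings(
      prop.trend.test(tab[2, ], colSums(tab), score = 0:2))
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, unname(oracle$p.value), tolerance = 1e-9)
  }
})

test_that("trend statistic on printed allele-count example matches the oracle", {
  # cases: 120 B alleles of 200; controls: 80 of 200 — as genotype counts
  # cases 40/40/20 (AA/AB/BB), controls 60/40/0? use exact homozygote split:
  cases <- c(50, 20, 30)    # 20 + 60 = 80... recompute: B alleles = 20+2*30
  controls <- c(60, 40, 0)  # B alleles = 40
  tab <- rbind(controls, cases)
  ind <- expandTrendTable(tab)
  mine <- dosageTrendTest(matrix(ind$dosage, 1), ind$y)
  oracle <- prop.trend.test(tab[2, ], colSums(tab), score = 0:2)
  expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-9)
})

test_that("balanced dosage distributions give statistic 0 and p 1", {
  d <- matrix(c(0, 1, 2, 0, 1, 2), 1)
  res <- dosageTrendTest(d, c(1, 1, 1, 0, 0, 0))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("complete separation yields the maximal score statistic n", {
  d <- matrix(rep(c(2, 0), each = 50), 1)
  res <- dosageTrendTest(d, rep(c(1, 0), each = 50))
  expect_equal(res$statistic, 100, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-8)
})

test_that("zero dosage variance is flagged, not an error", {
  d <- matrix(1, 1, 10)
  res <- dosageTrendTest(d, rep(c(1, 0), each = 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$flag, "zero_variance")
})

test_that("phenotype validation catches bad input", {
  d <- matrix(0:3, 1)
  expect_error(dosageTrendTest(d, c(1, 1, 1, 1)), "at least one case")
  expect_error(dosageTrendTest(d, c("case", "x", "control", "case")),
               "labels")
  expect_error(dosageTrendTest(d, c(1, 0)), "does not match")
})

test_that("genomic lambda is 1 on exact null quantiles and scale-equivariant", {
  m <- 2000
  stats <- qchisq((seq_len(m) - 0.5) / m, df = 1)
  expect_equal(genomicLambda(stats), 1, tolerance = 1e-6)
  expect_equal(genomicLambda(stats * 1.5), 1.5, tolerance = 1e-6)
  expect_warning(genomicLambda(stats[1:50]), "unstable")
  expect_error(genomicLambda(numeric(0)), "lambda undefined")
})

test_that("QQ coordinates pair sorted p-values with uniform expectations", {
  qq <- qqPoints(1)
  expect_equal(qq$expected, -log10(0.5))
  expect_equal(qq$observed, 0)

  # p-values placed exactly at their expected uniform ranks line up
  m <- 9
  qq <- qqPoints((seq_len(m) - 0.5) / m)
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)

  p <- seq(0.1, 0.9, by = 0.1)
  qq <- qqPoints(p)
  expect_equal(nrow(qq), length(p))
  expect_true(all(diff(qq$expected) >= 0))
  # a decimal grid deviates by at most its own resolution on the log scale
  expect_lt(max(abs(qq$observed - qq$expected)), log10(2))
})

test_that("genome-wide hit counting uses a strict threshold", {
  expect_equal(countGenomewideHits(rep(0.5, 10)), 0)
  expect_equal(countGenomewideHits(c(1e-9, 5e-8, 1e-7)), 1)
  expect_equal(countGenomewideHits(c(1e-9, 5e-8, 1e-7), alpha = 1e-6), 3)
})

test_that("filter rules retain by comparator with NA failing", {
  df <- data.frame(snp_id = paste0("s", 1:10),
                   iqs = c(0.95, 0.99, 0.91, rep(0.5, 3), 0.92, 0.93,
                           0.94, 0.96),
                   maf = rep(0.005, 10),
                   info_score = c(NA, rep(0.8, 9)))
  res <- applyFilter(df, "iqs>0.9")
  expect_equal(res$n_retained, 7)
  expect_equal(res$retention, 0.7)

  expect_equal(applyFilter(df, "maf>0.01")$n_retained, 0)

  # intersection semantics for composite rules
  both <- applyFilter(df, c("iqs>0.9", "info_score>0.5"))
  expect_setequal(both$snp_id,
                  intersect(applyFilter(df, "iqs>0.9")$snp_id,
                            applyFilter(df, "info_score>0.5")$snp_id))
  # the NA info_score SNP fails despite passing the IQS rule
  expect_false("s1" %in% both$snp_id)

  expect_error(applyFilter(df, "accuracy>0.99"), "not present")
  expect_error(parseFilterRule("bogus>1"), "unknown metric")
  expect_error(filterRule("maf", ">", 0.7), "outside range")
})

test_that("filtering can only reduce the genome-wide hit count", {
  set.seed(121)
  p <- c(runif(500), runif(20, 0, 1e-9))
  df <- data.frame(snp_id = paste0("s", seq_along(p)), p_value = p,
                   iqs = runif(length(p)))
  before <- countGenomewideHits(df)
  for (thr in c(0.1, 0.5, 0.9)) {
    keep <- applyFilter(df, sprintf("iqs>%g", thr))$snp_id
    after <- countGenomewideHits(df[df$snp_id %in% keep, ])
    expect_lte(after, before)
  }
})
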