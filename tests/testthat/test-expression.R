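fourVsFour <- function() {
  sampleDesign(data.frame(
    sample_id = sprintf("s%d", 1:8),
    line = rep(c("AM", "OWA"), each = 4),
    environment = rep(c("AM", "OWA"), each = 4),
    generation = "F1", replicate = rep(1:4, 2)))
}

test_that("low-expression filter applies the >90%-below-10 rule", {
  n <- 48L
  counts <- rbind(
    zero = rep(0L, n),                      # removed
    kept = c(rep(12L, 6), rep(3L, n - 6)),  # 87.5% low -> kept
    gone = c(rep(12L, 4), rep(3L, n - 4)))  # 91.7% low -> removed
  x <- expressionCounts(counts, fullSampleDesign())
  out <- filterLowExpression(x)
  expect_identical(rownames(out), "kept")
})

test_that("median-of-ratios size factors match the closed form", {
  d <- sampleDesign(data.frame(sample_id = c("a", "b"), line = "AM",
                               environment = "AM", generation = "F1",
                               replicate = 1:2))
  counts <- cbind(a = c(10L, 100L, 40L), b = c(20L, 200L, 80L))
  x <- normalizeAndTransform(expressionCounts(counts, d))
  sf <- SummarizedExperiment::colData(x)$sizeFactor
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- normalizeAndTransform(
    expressionCounts(cbind(a = c(5L, 9L), b = c(5L, 9L)), d))
  expect_equal(unname(SummarizedExperiment::colData(same)$sizeFactor),
               c(1, 1))
  expect_equal(SummarizedExperiment::assay(same, "logcounts")[, 1],
               log2(c(5, 9) + 1), ignore_attr = TRUE)

  zero <- expressionCounts(cbind(a = c(5L, 1L), b = c(0L, 0L)), d)
  expect_error(normalizeAndTransform(zero), "all-zero")
})

test_that("identical cells give zero fold change and p near 1", {
  # every gene constant across samples: size factors are exactly 1 and
  # each contrast compares identical cells
  counts <- matrix(rep(seq(20L, 218L, by = 2L), 8), 100, 8)
  x <- normalizeAndTransform(expressionCounts(counts, fourVsFour()))
  expect_equal(unname(SummarizedExperiment::colData(x)$sizeFactor),
               rep(1, 8))
  res <- deTest(x, "F1", c("AM_AM", "OWA_OWA"))
  expect_true(all(abs(res$lfc) < 1e-6))
  expect_true(all(res$p > 0.95))
})

test_that("the NB Wald test is calibrated on a null simulation", {
  set.seed(17)
  counts <- matrix(rnbinom(1000 * 8, mu = 100, size = 5), 1000, 8)
  x <- normalizeAndTransform(expressionCounts(counts, fourVsFour()))
  res <- deTest(x, "F1", c("AM_AM", "OWA_OWA"))
  expect_lte(mean(res$padj < 0.05, na.rm = TRUE), 0.05)
  ks <- suppressWarnings(stats::ks.test(res$p[res$converged], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted fold changes are detected with high power", {
  set.seed(19)
  mu <- matrix(100, 600, 8)
  mu[1:60, 5:8] <- 400  # LFC = 2 in the second cell
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 5), nrow(mu))
  x <- normalizeAndTransform(expressionCounts(counts, fourVsFour()))
  res <- deTest(x, "F1", c("AM_AM", "OWA_OWA"))
  expect_gt(mean(res$p[1:60] < 0.05, na.rm = TRUE), 0.9)
  expect_lt(abs(median(res$lfc[1:60], na.rm = TRUE) - 2), 0.3)
  # BH adjustment is monotone in raw p order
  ord <- order(res$p[res$converged])
  expect_true(all(diff(res$padj[res$converged][ord]) >= -1e-12))

  # an eightfold change survives the BH correction nearly always
  set.seed(19)
  mu[1:60, 5:8] <- 800
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 5), nrow(mu))
  x <- normalizeAndTransform(expressionCounts(counts, fourVsFour()))
  res <- deTest(x, "F1", c("AM_AM", "OWA_OWA"))
  expect_gt(mean(res$padj[1:60] < 0.05, na.rm = TRUE), 0.9)
})

test_that("plastic set sizes and ratio come from the within-line contrasts", {
  flags <- data.frame(gene_id = sprintf("g%d", 1:10),
                      eligible = rep(c(TRUE, FALSE), 5),
                      plastic = c(rep(TRUE, 4), rep(FALSE, 6)),
                      transdest = FALSE)
  ct <- fakeContrasts(flags)
  ps <- plasticGeneSets(ct)
  expect_setequal(ps$am, sprintf("g%d", 1:4))
  expect_equal(ps$ratio, 1)  # both within-line tables share the flags here
  # empty OWA set flags an infinite ratio
  ct$OWA_OWA_vs_OWA_AM$padj[] <- 0.9
  ps2 <- plasticGeneSets(ct)
  expect_true(ps2$infinite)
  expect_equal(ps2$ratio, Inf)
})

test_that("PO/GC classification matches the definitions on all 8 combos", {
  combos <- expand.grid(eligible = c(TRUE, FALSE), plastic = c(TRUE, FALSE),
                        transdest = c(TRUE, FALSE))
  combos$gene_id <- sprintf("g%d", seq_len(nrow(combos)))
  for (dir in c("forward", "reverse")) {
    cls <- classifyPoGc(fakeContrasts(combos), dir)
    # only eligible genes are classified at all
    expect_setequal(cls$gene_id, combos$gene_id[combos$eligible])
    for (i in which(combos$eligible)) {
      expected <- if (combos$transdest[i]) "GC"
        else if (combos$plastic[i]) "PO" else "unclassified"
      expect_equal(cls$class[cls$gene_id == combos$gene_id[i]], expected)
    }
    # mutual exclusion and containment in the eligible set
    expect_equal(sum(cls$class == "PO" & cls$class == "GC"), 0L)
  }
  expect_error(classifyPoGc(fakeContrasts(combos)[-1], "forward"),
               "missing contrast")
})

test_that("fold-change slope recovers known relationships", {
  x <- seq(-3, 3, length.out = 500)
  expect_equal(lfcSlope(x, x)$slope, 1)
  expect_equal(lfcSlope(x, -x)$slope, -1)
  set.seed(23)
  y <- 0.37 * x + rnorm(500, 0, 0.1)
  expect_lt(abs(lfcSlope(x, y)$slope - 0.37), 0.02)
  expect_error(lfcSlope(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(lfcSlope(x, x, mask = 1:2), "at least 3")
})
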