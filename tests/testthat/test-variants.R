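eightSampleDesign <- function() {
  sampleDesign(data.frame(
    sample_id = sprintf("s%d", 1:8),
    line = rep(c("AM", "OWA"), each = 4),
    environment = rep(c("AM", "OWA"), each = 4),
    generation = "F1", replicate = rep(1:4, 2)))
}

test_that("the filter cascade matches a hand-enumerated 5-site toy", {
  # A: 60x everywhere, MAF 0.1 in 4 samples            -> kept
  # B: one sample at 30x                               -> rule 1
  # C: MAF exactly 0.025 in exactly 4 samples (80x)    -> kept (inclusive)
  # D: variable in only 3 samples                      -> rule 3
  # E: depth 250x > 3 x dataset median (60x)           -> rule 2
  ref <- rbind(A = c(rep(54, 4), rep(60, 4)),
               B = c(30, rep(60, 7)),
               C = c(rep(78, 4), rep(80, 4)),
               D = c(rep(54, 3), rep(60, 5)),
               E = rep(225, 8))
  alt <- rbind(A = c(rep(6, 4), rep(0, 4)),
               B = rep(0, 8),
               C = c(rep(2, 4), rep(0, 4)),
               D = c(rep(6, 3), rep(0, 5)),
               E = rep(25, 8))
  sites <- data.frame(contig = "sc1", position = 1:5 * 10,
                      ref_allele = "A", alt_allele = "C")
  x <- alleleCounts(ref, alt, sites, eightSampleDesign())
  out <- filterVariants(x)
  expect_equal(nrow(out$counts), 2L)
  expect_setequal(GenomicRanges::start(
    SummarizedExperiment::rowRanges(out$counts)), c(10L, 30L))
  expect_equal(unname(out$rejections), c(1L, 1L, 1L))
  expect_equal(sum(out$rejections), nrow(x) - nrow(out$counts))
})

test_that("degenerate filter settings behave as identity / empty", {
  sim <- smallExperiment()
  idAll <- filterVariants(sim$allele,
                          filterRules(minVariableSamples = 0L,
                                      minSampleMaf = 0,
                                      maxDepthFactor = 1e9,
                                      minSampleCoverage = 0L))
  expect_equal(nrow(idAll$counts), nrow(sim$allele))
  # monomorphic sites all fail the variable-sample rule
  ref <- matrix(100L, 3, 8); alt <- matrix(0L, 3, 8)
  sites <- data.frame(contig = "sc1", position = 1:3 * 10,
                      ref_allele = "A", alt_allele = "G")
  x <- alleleCounts(ref, alt, sites, eightSampleDesign())
  expect_warning(out <- filterVariants(x), "all sites")
  expect_true(out$empty)
  expect_error(filterVariants(x[0, ]), "empty")
})

test_that("the CMH statistic reproduces hand-formula values", {
  null4 <- cmhTest(rep(10, 4), rep(10, 4), rep(10, 4), rep(10, 4))
  expect_equal(null4$statistic, 0)
  expect_equal(null4$p.value, 1)

  one <- cmhTest(8, 2, 2, 8)
  expect_equal(one$statistic, 9 / (10 * 10 * 10 * 10 / (400 * 19)),
               tolerance = 1e-12)
  expect_equal(round(one$statistic, 2), 6.84)
  expect_equal(one$p.value, 0.0089, tolerance = 0.01)

  two <- cmhTest(c(8, 8), c(2, 2), c(2, 2), c(8, 8))
  expect_equal(two$statistic, 36 / (2 * 10 * 10 * 10 * 10 / (400 * 19)),
               tolerance = 1e-12)
  expect_equal(round(two$statistic, 2), 13.68)
})

test_that("CMH agrees with the reference stratified test", {
  set.seed(7)
  for (i in 1:20) {
    R <- sample(2:4, 1)
    a <- rpois(R, 40) + 2; b <- rpois(R, 30) + 2
    cc <- rpois(R, 25) + 2; d <- rpois(R, 45) + 2
    ours <- cmhTest(a, b, cc, d)
    arr <- array(rbind(a, cc, b, d), dim = c(2, 2, R))
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("zero-margin strata are skipped, fully degenerate input gives p 1", {
  base <- cmhTest(8, 2, 2, 8)
  with0 <- cmhTest(c(8, 0), c(2, 0), c(2, 5), c(8, 5))
  expect_equal(with0$statistic, base$statistic)
  allDegenerate <- cmhTest(c(5, 3), c(0, 0), c(5, 2), c(0, 0))
  expect_equal(allDegenerate$p.value, 1)
})

test_that("chi-square p tracks the exact permutation oracle within 2x", {
  tables <- list(c(8, 2, 2, 8), c(5, 5, 5, 5), c(3, 7, 6, 4),
                 c(10, 5, 4, 11), c(2, 4, 4, 2), c(12, 3, 5, 10),
                 c(6, 9, 9, 6), c(4, 4, 8, 3))
  for (tb in tables) {
    for (R in 1:3) {
      m <- matrix(rep(tb, R), nrow = R, byrow = TRUE)
      pc <- cmhTest(m[, 1], m[, 2], m[, 3], m[, 4])$p.value
      pe <- exactCmhMidP(m[, 1], m[, 2], m[, 3], m[, 4])
      expect_gt(pc / pe, 0.5)
      expect_lt(pc / pe, 2)
    }
  }
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroniThreshold(322595, 3, 0.05), 3), 5.17e-08)
  expect_equal(bonferroniThreshold(10, 1, 0.05), 0.005)
  expect_equal(bonferroniThreshold(1, 1, 0.05), 0.05)
  expect_error(bonferroniThreshold(0, 3, 0.05), "positive")
})

test_that("adaptive set is the order-preserving intersection", {
  expect_equal(adaptiveLociIntersection(list(c(1, 2, 3), c(2, 3),
                                             c(2, 3, 4))), c(2, 3))
  expect_equal(adaptiveLociIntersection(list(c(1, 2), integer())),
               integer())
  expect_equal(adaptiveLociIntersection(list(c(3, 1, 2))), c(3, 1, 2))
  expect_error(adaptiveLociIntersection(list()), "at least one")
})

test_that("selected loci are recovered and drift alone is not called", {
  sim <- smallExperiment()
  flt <- filterVariants(sim$allele)
  res <- adaptiveLoci(flt$counts, runConfig())
  selKeys <- rownames(sim$allele)[sim$truth$selected_loci]
  selIdx <- which(rownames(flt$counts) %in% selKeys)
  expect_gt(mean(selIdx %in% res$adaptive), 0.8)
  falsePos <- setdiff(res$adaptive, selIdx)
  expect_lt(length(falsePos) / nrow(flt$counts), 0.02)
  # degenerate alpha = 1: every tested locus is adaptive
  resAll <- adaptiveLoci(flt$counts, runConfig(alpha = 1))
  expect_equal(resAll$adaptive, seq_len(nrow(flt$counts)))
})

test_that("allelic-vs-expression QC computes a sign-blind R squared", {
  p <- 10^-runif(100, 0.1, 6)
  expect_equal(alleleExpressionQC(p, p)$r.squared, 1)
  anti <- 10^(-(6.2 - (-log10(p))))
  expect_equal(alleleExpressionQC(p, anti)$r.squared, 1)
  expect_lt(alleleExpressionQC(p, anti)$slope, 0)
  set.seed(11)
  qc <- alleleExpressionQC(runif(10000), runif(10000))
  expect_lt(qc$r.squared, 0.01)
  expect_true(is.na(alleleExpressionQC(rep(0.5, 10), runif(10))$r.squared))
})
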