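test_that("neutral Wright-Fisher drift matches the one-generation variance", {
  # var(p1) = p0 (1 - p0) / (2 ne) for one generation of binomial drift
  set.seed(101)
  ne <- 100L; p0 <- 0.5
  p1 <- rbinom(10000L, 2L * ne, p0) / (2 * ne)
  expected <- p0 * (1 - p0) / (2 * ne)
  cfg <- simulationConfig(nLoci = 10000L, propSelected = 0, ne = ne,
                          nBurninGens = 1L, nTransplantGens = 1L, seed = 5L)
  traj <- simulateAlleleTrajectories(cfg, p0 = rep(p0, 10000L),
                                     nReplicates = 1L)
  observed <- var(traj$truth$burnin_final[, 1L, "AM"])
  expect_lt(abs(observed - expected) / expected, 0.10)
  # sanity: the independent direct simulation agrees too
  expect_lt(abs(var(p1) - expected) / expected, 0.10)
})

test_that("large-N neutral trajectories barely move", {
  cfg <- simulationConfig(nLoci = 200L, propSelected = 0, ne = 1000000L,
                          nBurninGens = 1L, nTransplantGens = 1L, seed = 9L)
  p0 <- rep(0.4, 200L)
  traj <- simulateAlleleTrajectories(cfg, p0 = p0, nReplicates = 1L)
  dp <- abs(traj$truth$burnin_final[, 1L, "AM"] - p0)
  expect_true(all(dp < 3 * sqrt(0.4 * 0.6 / (2 * 1e6)) * 3))
})

test_that("strong selection drives frequencies near fixation", {
  # deterministic logistic oracle: p' = p(1+s)/(1+ps) iterated 20 times
  oracle <- function(p, s, g) { for (i in seq_len(g)) p <- p * (1 + s) / (1 + p * s); p }
  expect_gt(oracle(0.5, 0.5, 20L), 0.95)
  cfg <- simulationConfig(nLoci = 100L, propSelected = 1, sSelected = 0.5,
                          ne = 10000L, seed = 3L)
  traj <- simulateAlleleTrajectories(cfg, p0 = rep(0.5, 100L),
                                     nReplicates = 2L)
  expect_gt(mean(traj$truth$burnin_final[, , "OWA"]), 0.95)
  # AM line is neutral through burn-in: stays near p0
  expect_lt(abs(mean(traj$truth$burnin_final[, , "AM"]) - 0.5), 0.05)
})

test_that("pool count sampling recovers frequencies without bias", {
  design <- sampleDesign(data.frame(sample_id = "s1", line = "AM",
                                    environment = "AM", generation = "F1",
                                    replicate = 1))
  cfg <- simulationConfig(nLoci = 10000L, seed = 21L)
  freq <- matrix(0.5, 10000L, 1L)
  ac <- simulatePoolCounts(freq, cfg, design)
  refm <- SummarizedExperiment::assay(ac, "ref")
  altm <- SummarizedExperiment::assay(ac, "alt")
  frac <- sum(altm) / sum(refm + altm)
  expect_lt(abs(frac - 0.5), 0.01)
  expect_lt(abs(mean(refm + altm) - cfg$meanCoverage) / cfg$meanCoverage,
            0.05)
  # boundary: frequency 0 yields no alternate reads at any depth
  ac0 <- simulatePoolCounts(matrix(0, 100L, 1L), cfg, design,
                            sites = poolSeqER:::defaultSites(100L),
                            stage = "zero")
  expect_true(all(SummarizedExperiment::assay(ac0, "alt") == 0L))
})

test_that("expression generator hits its plastic log2 effect", {
  cfg <- simulationConfig(nGenes = 4000L, propPlastic = 1, propGenetic = 0,
                          propPlasticAlsoGenetic = 0,
                          propPlasticLostInOwa = 0, effectPlastic = 2,
                          nbDispersion = 20, seed = 31L)
  sim <- simulateExpression(cfg)
  counts <- SummarizedExperiment::assay(sim$expression, "counts")
  d <- as.data.frame(SummarizedExperiment::colData(sim$expression))
  am <- d$line == "AM"
  lfc <- log2(rowMeans(counts[, am & d$environment == "OWA"]) /
                rowMeans(counts[, am & d$environment == "AM"]))
  expect_lt(abs(mean(lfc) - 2), 0.1)
})

test_that("total plasticity loss silences the OWA-line response", {
  cfg <- simulationConfig(nGenes = 2000L, propPlastic = 1, propGenetic = 0,
                          propPlasticAlsoGenetic = 0,
                          propPlasticLostInOwa = 1, effectPlastic = 2,
                          nbDispersion = 20, seed = 32L)
  sim <- simulateExpression(cfg)
  counts <- SummarizedExperiment::assay(sim$expression, "counts")
  d <- as.data.frame(SummarizedExperiment::colData(sim$expression))
  owa <- d$line == "OWA"
  lfc <- log2(rowMeans(counts[, owa & d$environment == "OWA"]) /
                rowMeans(counts[, owa & d$environment == "AM"]))
  expect_lt(abs(mean(lfc)), 0.1)
  expect_length(sim$truth$plastic_genes_owa, 0L)
})

test_that("life-history chains match binomial and Poisson expectations", {
  cfg <- simulationConfig(seed = 41L)
  rates <- poolSeqER:::defaultLifeHistoryRates()
  rates <- rates[rates$treatment == "AM_AM" & rates$food == "replete", ]
  rates$daily_survival <- 0.9
  lh <- simulateLifeHistory(cfg, rates = rates, nBeakers = 1000L,
                            nPairs = 1000L, nDays = 10L)
  finals <- lh$survivorship$alive[lh$survivorship$day == 10L]
  expect_lt(abs(mean(finals) - 25 * 0.9^10), 0.3)
  epr <- (lh$matepairs$e_unhatched + lh$matepairs$e_hatched) /
    lh$matepairs$days
  expect_lt(abs(mean(epr) - rates$epr_mean), 0.5)
  # survival 1 keeps every individual
  rates$daily_survival <- 1
  lh1 <- simulateLifeHistory(cfg, rates = rates, nBeakers = 3L,
                             nPairs = 1L, nDays = 6L)
  expect_true(all(lh1$survivorship$alive == 25L))
})

test_that("a fixed seed reproduces every matrix bit-exactly", {
  cfg <- simulationConfig(nLoci = 50L, nGenes = 40L, seed = 77L)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(SummarizedExperiment::assay(a$allele, "alt"),
                   SummarizedExperiment::assay(b$allele, "alt"))
  expect_identical(SummarizedExperiment::assay(a$expression, "counts"),
                   SummarizedExperiment::assay(b$expression, "counts"))
  expect_identical(a$lifeHistory, b$lifeHistory)
  expect_identical(a$truth$selected_loci, b$truth$selected_loci)
})

test_that("child seeds differ across stages but are deterministic", {
  expect_identical(childSeed(1L, "cmh"), childSeed(1L, "cmh"))
  expect_false(childSeed(1L, "cmh") == childSeed(1L, "pi"))
  expect_false(childSeed(1L, "cmh") == childSeed(2L, "cmh"))
  expect_true(childSeed(123456L, "shift_expression_F3") < 2^31)
})
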