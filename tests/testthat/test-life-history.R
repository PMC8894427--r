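test_that("EPR and HS formulas and exclusion rules", {
  r <- eprAndHs(6, 24, 3)
  expect_equal(r$epr, 10)
  expect_equal(r$hs, 0.8)

  zero <- eprAndHs(0, 0, 3)
  expect_equal(zero$epr, 0)
  expect_false(zero$hsValid)
  expect_true(is.na(zero$hs))

  deadMale <- eprAndHs(3, 9, 3, maleAlive = FALSE)
  expect_equal(deadMale$epr, 4)
  expect_false(deadMale$hsValid)

  deadFemale <- eprAndHs(3, 9, 3, femaleAlive = FALSE)
  expect_false(deadFemale$eprValid)
  expect_false(deadFemale$hsValid)

  expect_error(eprAndHs(-1, 5, 3), "negative")
  expect_error(eprAndHs(1, 5, 0), "positive")
})

test_that("survivorship probabilities follow l_x / l_{x-1} with P_1 = 1", {
  expect_equal(survivorshipProbabilities(c(25, 20, 20)), c(1, 0.8, 1))
  expect_equal(survivorshipProbabilities(c(25, 0, 0)), c(1, 0, 0))
  expect_equal(survivorshipProbabilities(c(25, 25, 25)), c(1, 1, 1))
  expect_error(survivorshipProbabilities(c(10, 12)), "non-increasing")
})

test_that("Leslie assembly places survival and scaled fecundity", {
  M <- assembleLeslie(Px = c(1, 0.5), epr = 5, hs = 0.8, nFemales = 5,
                      nMales = 5, maturityDay = 2L)
  expect_equal(M, matrix(c(0, 0.5, 2, 0), 2))
  M1 <- assembleLeslie(c(1, 0.5, 0.9), 5, 0.8, 5, 5, maturityDay = 1L)
  expect_true(all(M1[1, ] == 2))
  expect_error(assembleLeslie(c(1, 0.5), 5, 0.8, 0, 0, 2L), "no sexed")
  expect_error(assembleLeslie(c(1, 0.5), 5, 0.8, 2, 2, 5L), "outside")
  # raw female:male ratio mode doubles the proportion-female scaling at 1:1
  Mr <- assembleLeslie(c(1, 0.5), 5, 0.8, 5, 5, 2L, rawRatio = TRUE)
  expect_equal(Mr[1, 2], 4)
})

test_that("dominant eigenvalue matches closed forms and power iteration", {
  expect_equal(dominantEigenvalue(matrix(c(0, 0.5, 2, 0), 2)), 1)
  expect_equal(dominantEigenvalue(matrix(c(1, 0.5, 1, 0), 2)),
               (1 + sqrt(3)) / 2)
  expect_equal(dominantEigenvalue(matrix(c(0, 0.5, 0, 0), 2)), 0)
  # lambda^d = F P^(d-1) for fecundity only at the terminal day d
  for (d in c(3L, 5L, 8L)) {
    P <- 0.8; F_ <- 4
    M <- matrix(0, d, d)
    M[1, d] <- F_
    M[cbind(2:d, 1:(d - 1))] <- P
    expect_equal(dominantEigenvalue(M), (F_ * P^(d - 1))^(1 / d),
                 tolerance = 1e-9)
  }
  # power-iteration oracle on random non-negative matrices
  set.seed(61)
  for (i in 1:10) {
    n <- sample(3:7, 1)
    M <- matrix(0, n, n)
    M[1, ] <- runif(n, 0, 5)
    M[cbind(2:n, 1:(n - 1))] <- runif(n - 1)
    v <- rep(1, n)
    for (k in 1:2000) { v <- M %*% v; v <- v / sqrt(sum(v^2)) }
    lamPI <- drop(crossprod(v, M %*% v))
    expect_equal(dominantEigenvalue(M), lamPI, tolerance = 1e-9)
  }
})

test_that("lambda is monotone in survival and fecundity entries", {
  set.seed(63)
  for (i in 1:10) {
    n <- 5L
    M <- matrix(0, n, n)
    M[1, 3:n] <- runif(n - 2, 0.5, 4)
    M[cbind(2:n, 1:(n - 1))] <- runif(n - 1, 0.3, 0.95)
    lam <- dominantEigenvalue(M)
    Mp <- M
    idx <- which(M > 0)[sample(sum(M > 0), 1)]
    Mp[idx] <- Mp[idx] * 1.2
    expect_gte(dominantEigenvalue(Mp), lam - 1e-12)
  }
})

lhFixture <- function(nBeakers = 4L, nPairs = 12L, deadFemales = 0L) {
  sv <- do.call(rbind, lapply(seq_len(nBeakers), function(b) data.frame(
    beaker_id = paste0("b", b), treatment = "T", food = "replete",
    day = 0:6, alive = c(25, 24, 22, 21, 20, 20, 19),
    n_females = 8L, n_males = 9L, first_adult_day = 4L)))
  mp <- data.frame(pair_id = sprintf("p%d", seq_len(nPairs)),
                   treatment = "T", food = "replete",
                   e_unhatched = 6L, e_hatched = 24L, days = 3L,
                   male_alive = TRUE,
                   female_alive = rep(c(FALSE, TRUE),
                                      c(deadFemales, nPairs - deadFemales)))
  list(sv = sv, mp = mp)
}

test_that("the lambda ensemble crosses beakers with eligible pairs", {
  f <- lhFixture()
  res <- lambdaEnsemble(f$sv, f$mp)
  expect_equal(res$n, 48L)
  expect_false(res$empty)
  expect_true(res$ci_low <= res$lambda_mean &&
                res$lambda_mean <= res$ci_high)
  # six dead-female pairs excluded: 4 beakers x 6 pairs = 24
  f6 <- lhFixture(deadFemales = 6L)
  expect_equal(lambdaEnsemble(f6$sv, f6$mp)$n, 24L)
  # single beaker x single pair: the interval collapses to the point
  f1 <- lhFixture(nBeakers = 1L, nPairs = 1L)
  res1 <- lambdaEnsemble(f1$sv, f1$mp)
  expect_equal(res1$n, 1L)
  expect_equal(res1$ci_low, res1$lambda_mean)
  # a cell with no eligible pairs is flagged empty
  fAll <- lhFixture(deadFemales = 12L)
  expect_true(lambdaEnsemble(fAll$sv, fAll$mp)$empty)
})

test_that("the log-rank test matches its formula and the reference", {
  same <- data.frame(day = 0:5, alive = c(25, 22, 20, 18, 18, 17))
  r0 <- logrankTest(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  g1 <- data.frame(day = 0:10, alive = c(25, rep(0, 10)))
  g2 <- data.frame(day = 0:10, alive = rep(25, 11))
  expect_lt(logrankTest(g1, g2)$p.value, 0.001)

  # cross-check against the survival package on individual-level data
  s1 <- data.frame(day = 0:4, alive = c(20, 16, 13, 11, 10))
  s2 <- data.frame(day = 0:4, alive = c(20, 19, 17, 16, 15))
  ours <- logrankTest(s1, s2)
  expand <- function(s, grp) {
    deaths <- -diff(s$alive)
    time <- rep(s$day[-1], deaths)
    data.frame(time = c(time, rep(max(s$day), s$alive[nrow(s)])),
               status = c(rep(1, length(time)),
                          rep(0, s$alive[nrow(s)])), grp = grp)
  }
  df <- rbind(expand(s1, 1), expand(s2, 2))
  ref <- survival::survdiff(survival::Surv(time, status) ~ grp, df)
  expect_equal(ours$statistic, ref$chisq, tolerance = 1e-8)

  expect_error(logrankTest(s1[0, ], s2), "empty")
})
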