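#' Egg production rate and hatching success for one mate pair
#'
#' EPR = (E_u + E_h)/t eggs per day; HS = E_h/(E_u + E_h).  Pairs with a
#' dead female are excluded from both measures; pairs with a dead male
#' contribute EPR only; zero-egg pairs have HS undefined (flagged).
#'
#' @param eUnhatched,eHatched unhatched and hatched egg counts.
#' @param days egg-laying days (3 in the assay design).
#' @param maleAlive,femaleAlive adult survival flags at assessment.
#' @return list with `epr`, `hs`, `eprValid`, `hsValid`.
#' @examples
#' eprAndHs(6, 24, 3)  # EPR 10, HS 0.8
#' @export
eprAndHs <- function(eUnhatched, eHatched, days = 3L, maleAlive = TRUE,
                     femaleAlive = TRUE) {
  if (eUnhatched < 0 || eHatched < 0) stop("negative egg counts")
  if (days <= 0) stop("egg-laying time must be positive")
  total <- eUnhatched + eHatched
  eprValid <- isTRUE(femaleAlive)
  hsValid <- isTRUE(femaleAlive) && isTRUE(maleAlive) && total > 0
  list(epr = if (eprValid) total / days else NA_real_,
       hs = if (hsValid) eHatched / total else NA_real_,
       eprValid = eprValid, hsValid = hsValid)
}

#' Day-specific survivorship probabilities P_x = l_x / l_{x-1}
#'
#' Survival on the first observation day is assumed 100%; once the count
#' reaches zero all later probabilities are zero.
#'
#' @param lx individuals alive at each observation day (non-increasing,
#'   first element the starting count).
#' @return vector of survival probabilities, same length as `lx`.
#' @examples
#' survivorshipProbabilities(c(25, 20, 20))  # 1, 0.8, 1
#' @export
survivorshipProbabilities <- function(lx) {
  if (any(diff(lx) > 0)) stop("l_x must be non-increasing")
  if (lx[1L] <= 0) stop("starting count must be positive")
  P <- rep(0, length(lx))
  P[1L] <- 1
  if (length(lx) > 1L)
    for (x in 2:length(lx))
      P[x] <- if (lx[x - 1L] > 0) lx[x] / lx[x - 1L] else 0
  P
}

#' Assemble a day-structured Leslie matrix
#'
#' Square matrix over the observation days: the subdiagonal carries the
#' day-specific survival probabilities P_2..P_n and the first row the
#' female-scaled fecundity EPR x HS x (females / (females + males)),
#' assigned to all days from the first-matured-adult day onward (a
#' strict-after mode assigns them from the following day).
#'
#' @param Px survival probabilities from [survivorshipProbabilities()].
#' @param epr per-capita egg production rate (eggs/day).
#' @param hs hatching success fraction.
#' @param nFemales,nMales sexed adults in the beaker.
#' @param maturityDay index (1-based, on the observation grid) of the
#'   first observed adult.
#' @param strictAfter assign fecundity strictly after the maturity day.
#' @param rawRatio scale by females/males instead of proportion female.
#' @return the Leslie matrix.
#' @export
assembleLeslie <- function(Px, epr, hs, nFemales, nMales, maturityDay,
                           strictAfter = FALSE, rawRatio = FALSE) {
  n <- length(Px)
  if (maturityDay < 1L || maturityDay > n)
    stop("maturity day outside the observation series")
  if (nFemales + nMales <= 0) stop("no sexed adults")
  scale <- if (rawRatio) {
    if (nMales == 0) stop("raw female:male ratio undefined with no males")
    nFemales / nMales
  } else nFemales / (nFemales + nMales)
  F_ <- epr * hs * scale
  M <- matrix(0, n, n)
  from <- if (strictAfter) maturityDay + 1L else maturityDay
  if (from <= n) M[1L, from:n] <- F_
  if (n > 1L) M[cbind(2:n, 1:(n - 1L))] <- Px[2:n]
  M
}

#' Dominant eigenvalue (net reproductive rate lambda)
#'
#' The Perron root of a non-negative projection matrix; lambda > 1
#' signals positive population growth.
#'
#' @param M a Leslie (or any non-negative) matrix.
#' @return the largest-modulus eigenvalue's magnitude.
#' @examples
#' dominantEigenvalue(matrix(c(0, 0.5, 2, 0), 2))  # 1
#' @export
dominantEigenvalue <- function(M) {
  if (any(M < 0)) stop("matrix must be non-negative")
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Lambda ensemble over beakers x mate pairs
#'
#' Every eligible survivorship beaker is paired with every eligible mate
#' pair of its treatment x food cell (maximum 4 x 12 = 48 matrices); each
#' pairing yields one Leslie matrix and one lambda.  The cell estimate is
#' the mean with a 95% confidence interval xbar +/- 1.960 SD/sqrt(n).
#'
#' @param survivorship long data.frame (beaker_id, treatment, food, day,
#'   alive, n_females, n_males, first_adult_day), as produced by
#'   [simulateLifeHistory()].
#' @param matepairs data.frame (pair_id, treatment, food, e_unhatched,
#'   e_hatched, days, male_alive, female_alive).
#' @param zScore normal quantile for the interval (1.960).
#' @return data.frame per treatment x food: lambda_mean, sd, n, ci_low,
#'   ci_high, empty flag (TRUE when a cell has no eligible beaker/pair,
#'   e.g. starved food).
#' @export
lambdaEnsemble <- function(survivorship, matepairs, zScore = 1.960) {
  cells <- unique(rbind(survivorship[, c("treatment", "food")],
                        matepairs[, c("treatment", "food")]))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    tr <- cells$treatment[i]; fd <- cells$food[i]
    sv <- survivorship[survivorship$treatment == tr &
                         survivorship$food == fd, ]
    mp <- matepairs[matepairs$treatment == tr & matepairs$food == fd, ]
    lam <- numeric()
    for (bk in unique(sv$beaker_id)) {
      b <- sv[sv$beaker_id == bk, ]
      b <- b[order(b$day), ]
      if (b$alive[1L] <= 0) next
      sexed <- b$n_females[1L] + b$n_males[1L]
      if (sexed <= 0) next  # no adults matured in this beaker
      Px <- survivorshipProbabilities(b$alive)
      matIdx <- which(b$day >= b$first_adult_day[1L])[1L]
      if (is.na(matIdx)) next
      for (j in seq_len(nrow(mp))) {
        eh <- eprAndHs(mp$e_unhatched[j], mp$e_hatched[j], mp$days[j],
                       mp$male_alive[j], mp$female_alive[j])
        if (!eh$eprValid || !eh$hsValid) next
        M <- assembleLeslie(Px, eh$epr, eh$hs, b$n_females[1L],
                            b$n_males[1L], matIdx)
        lam <- c(lam, dominantEigenvalue(M))
      }
    }
    n <- length(lam)
    if (n == 0L) {
      out[[i]] <- data.frame(treatment = tr, food = fd,
                             lambda_mean = NA_real_, sd = NA_real_,
                             n = 0L, ci_low = NA_real_,
                             ci_high = NA_real_, empty = TRUE)
    } else {
      m <- mean(lam); s <- if (n > 1L) stats::sd(lam) else 0
      half <- zScore * s / sqrt(n)
      out[[i]] <- data.frame(treatment = tr, food = fd, lambda_mean = m,
                             sd = s, n = n, ci_low = m - half,
                             ci_high = m + half, empty = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-group log-rank test on survivorship series
#'
#' Death counts per day are derived from the decrements of the l_x
#' series (individuals alive at the last day are censored there).  The
#' statistic is the classic X^2 = (sum(O1 - E1))^2 / sum(V) over distinct
#' death days, with p from a 1-df chi-square.
#'
#' @param series1,series2 data.frames with columns day and alive (one or
#'   more beakers summed per group: pass aggregated counts).
#' @return list with `statistic`, `p.value`, `observed1`, `expected1`.
#' @export
logrankTest <- function(series1, series2) {
  if (!NROW(series1) || !NROW(series2)) stop("empty survivorship group")
  prep <- function(s) {
    s <- stats::aggregate(alive ~ day, s, sum)
    s[order(s$day), ]
  }
  s1 <- prep(series1); s2 <- prep(series2)
  days <- sort(unique(c(s1$day, s2$day)))
  atRisk <- function(s, d) s$alive[max(which(s$day <= d))]
  O1 <- E1 <- V <- 0; totalDeaths <- 0
  for (k in seq_along(days)[-1L]) {
    d0 <- days[k - 1L]; d1 <- days[k]
    n1 <- atRisk(s1, d0); n2 <- atRisk(s2, d0)
    d1n <- n1 - atRisk(s1, d1); d2n <- n2 - atRisk(s2, d1)
    dd <- d1n + d2n; nn <- n1 + n2
    totalDeaths <- totalDeaths + dd
    if (dd == 0 || nn <= 1 || n1 == 0 || n2 == 0) next
    O1 <- O1 + d1n
    E1 <- E1 + dd * n1 / nn
    V <- V + dd * (n1 / nn) * (n2 / nn) * (nn - dd) / (nn - 1)
  }
  if (totalDeaths == 0 || V <= 0)
    return(list(statistic = 0, p.value = 1, observed1 = O1,
                expected1 = E1))
  stat <- (O1 - E1)^2 / V
  list(statistic = stat,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       observed1 = O1, expected1 = E1)
}
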