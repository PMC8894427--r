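#' Fit a two-group discriminant-space model on home-line samples
#'
#' PCA of the centred feature matrix followed by a one-axis linear
#' discriminant between the two groups on the retained PC scores: the
#' axis is proportional to the pooled within-group covariance inverse
#' times the group-mean difference (a ridge of 1e-8 is added when the
#' within-group covariance is singular).  The axis is unit-normalised in
#' PC space.
#'
#' @param features samples x features numeric matrix (e.g. `logcounts`
#'   columns of the home samples, transposed, or per-sample alternate
#'   allele frequencies).
#' @param groups length-nrow factor/character with exactly 2 levels.
#' @param nPcs number of principal components to retain (4 is typical for
#'   expression, 3 for allele frequencies).
#' @param varThreshold when non-NULL, retain the smallest number of PCs
#'   reaching this fraction of total variance instead of `nPcs`.
#' @return a [DAPCModel-class].
#' @export
fitDapc <- function(features, groups, nPcs = 4L, varThreshold = NULL) {
  features <- as.matrix(features)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  center <- colMeans(features)
  xc <- sweep(features, 2L, center)
  pca <- stats::prcomp(xc, center = FALSE)
  totVar <- sum(pca$sdev^2)
  avail <- sum(pca$sdev > 1e-10)
  if (!is.null(varThreshold)) {
    cum <- cumsum(pca$sdev^2) / totVar
    nPcs <- which(cum >= varThreshold)[1L]
  }
  if (nPcs > avail)
    stop("nPcs = ", nPcs, " exceeds available components (", avail, ")")
  rot <- pca$rotation[, seq_len(nPcs), drop = FALSE]
  scores <- xc %*% rot
  varFraction <- sum(pca$sdev[seq_len(nPcs)]^2) / totVar
  g1 <- groups == levels(groups)[1L]
  m1 <- colMeans(scores[g1, , drop = FALSE])
  m2 <- colMeans(scores[!g1, , drop = FALSE])
  W <- (crossprod(sweep(scores[g1, , drop = FALSE], 2L, m1)) +
          crossprod(sweep(scores[!g1, , drop = FALSE], 2L, m2))) /
    (nrow(scores) - 2L)
  axis <- tryCatch(solve(W, m2 - m1), error = function(e) {
    message("singular within-group covariance; adding ridge 1e-8")
    solve(W + diag(1e-8, nPcs), m2 - m1)
  })
  nrm <- sqrt(sum(axis^2))
  separable <- TRUE
  if (nrm < 1e-12) {
    separable <- FALSE
    axis <- rep(1 / sqrt(nPcs), nPcs)
  } else axis <- axis / nrm
  coord <- drop(scores %*% axis)
  means <- c(mean(coord[g1]), mean(coord[!g1]))
  names(means) <- levels(groups)
  withinSD <- sqrt((sum((coord[g1] - means[1L])^2) +
                      sum((coord[!g1] - means[2L])^2)) /
                     (length(coord) - 2L))
  if (abs(diff(means)) < 1e-8 * (1 + withinSD)) separable <- FALSE
  new("DAPCModel", center = center, rotation = rot,
      varFraction = varFraction, loadings = as.numeric(axis),
      groupMeans = means, withinSD = withinSD,
      groups = levels(groups), separable = separable)
}

#' Project samples onto a fitted discriminant axis
#'
#' coordinate = ((x - center) . rotation) . loadings; projecting the home
#' samples reproduces the stored group means.
#'
#' @param model a [DAPCModel-class].
#' @param features samples x features matrix with the model's feature
#'   dimension.
#' @return numeric vector of discriminant coordinates.
#' @export
projectSamples <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model@center))
    stop("feature dimension (", ncol(features), ") does not match model (",
         length(model@center), ")")
  drop((sweep(features, 2L, model@center) %*% model@rotation) %*%
         model@loadings)
}

#' Per-sample alternate-allele frequencies as DAPC features
#'
#' @param x an [AlleleCounts-class] (typically filtered).
#' @return samples x sites matrix of alt/(ref+alt); sites with zero depth
#'   in a sample get that sample's mean frequency at covered sites.
#' @export
alleleFrequencyFeatures <- function(x) {
  refm <- assay(x, "ref"); altm <- assay(x, "alt")
  depth <- refm + altm
  f <- altm / ifelse(depth > 0L, depth, NA_real_)
  f[is.na(f)] <- mean(f, na.rm = TRUE)
  t(f)
}

#' Fit-and-project DAPC for one generation
#'
#' Builds the discriminant function from the non-transplanted lines
#' (AM_AM and OWA_OWA) of one generation and projects all of that
#' generation's samples onto it.
#'
#' @param features all-sample feature matrix (samples x features, rows
#'   named by sample id).
#' @param design sample design covering the feature rows.
#' @param generation generation label.
#' @param nPcs retained principal components.
#' @param varThreshold see [fitDapc()].
#' @return list with `model` and `coordinates` (data.frame sample_id,
#'   line, environment, replicate, transplanted, coordinate).
#' @export
dapcGeneration <- function(features, design, generation, nPcs = 4L,
                           varThreshold = NULL) {
  d <- as.data.frame(design)
  inGen <- which(d$generation == generation)
  home <- inGen[d$line[inGen] == as.character(d$environment[inGen])]
  model <- fitDapc(features[home, , drop = FALSE], d$line[home],
                   nPcs = nPcs, varThreshold = varThreshold)
  coord <- projectSamples(model, features[inGen, , drop = FALSE])
  list(model = model,
       coordinates = data.frame(
         sample_id = d$sample_id[inGen], line = d$line[inGen],
         environment = d$environment[inGen],
         replicate = d$replicate[inGen],
         transplanted = d$line[inGen] != as.character(d$environment[inGen]),
         coordinate = coord, generation = generation, row.names = NULL))
}

#' Bayesian inference on transplant shifts in discriminant space
#'
#' Gaussian linear model coordinate = intercept + line effect +
#' line-specific transplant effect, with a replicate-culture random
#' intercept, fitted by a Gibbs sampler with conjugate
#' normal/inverse-gamma priors.  For each effect P_MCMC = 2 min(Pr(draw >
#' 0), Pr(draw < 0)), floored at 1/nDraws (reported at the floor when no
#' draw crosses zero, the "< 1/nDraws" convention).  The between-line
#' comparison is the posterior of |transplant effect AM| - |transplant
#' effect OWA|.
#'
#' @param coordinates data.frame from [dapcGeneration()] (one generation:
#'   2 lines x 2 environments x replicates).
#' @param nDraws retained posterior draws (2500).
#' @param seed RNG seed.
#' @param burnin discarded initial draws.
#' @return list with `perLine` (data.frame line, mean, ci_low, ci_high,
#'   p_mcmc), `magnitude` (list mean, ci_low, ci_high, p_mcmc for
#'   |AM| - |OWA|), `nDraws`, `rhat`, `converged`.
#' @export
shiftInference <- function(coordinates, nDraws = 2500L, seed = 1L,
                           burnin = 500L) {
  cellN <- table(paste(coordinates$line, coordinates$environment))
  if (length(cellN) < 4L || min(cellN) < 2L)
    stop("need >= 2 replicates per line x environment cell")
  y0 <- coordinates$coordinate
  scl <- stats::sd(y0); if (!is.finite(scl) || scl == 0) scl <- 1
  ctr <- mean(y0)
  y <- (y0 - ctr) / scl
  n <- length(y)
  X <- cbind(intercept = 1,
             lineOWA = as.numeric(coordinates$line == "OWA"),
             shiftAM = as.numeric(coordinates$line == "AM" &
                                    coordinates$transplanted),
             shiftOWA = as.numeric(coordinates$line == "OWA" &
                                     coordinates$transplanted))
  repId <- factor(coordinates$replicate)
  Zidx <- as.integer(repId); R <- nlevels(repId)
  p <- ncol(X)
  tauBeta <- 100  # vague prior variance on standardised scale
  a0 <- b0 <- 0.001
  total <- burnin + nDraws
  beta <- rep(0, p); u <- rep(0, R); sige <- 1; sigu <- 0.5
  draws <- matrix(NA_real_, nDraws, p,
                  dimnames = list(NULL, colnames(X)))
  XtX <- crossprod(X)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (it in seq_len(total)) {
    resid <- y - u[Zidx]
    V <- solve(XtX / sige + diag(1 / tauBeta, p))
    mb <- V %*% crossprod(X, resid) / sige
    beta <- drop(mb + t(chol(V)) %*% stats::rnorm(p))
    r2 <- y - drop(X %*% beta)
    for (r in seq_len(R)) {
      idx <- Zidx == r
      vr <- 1 / (sum(idx) / sige + 1 / sigu)
      u[r] <- stats::rnorm(1L, vr * sum(r2[idx]) / sige, sqrt(vr))
    }
    res <- r2 - u[Zidx]
    sige <- 1 / stats::rgamma(1L, a0 + n / 2, b0 + sum(res^2) / 2)
    sigu <- 1 / stats::rgamma(1L, a0 + R / 2, b0 + sum(u^2) / 2)
    if (it > burnin) draws[it - burnin, ] <- beta
  }
  floorP <- 1 / nDraws
  pSign <- function(v) max(2 * min(mean(v > 0), mean(v < 0)), floorP)
  splitRhat <- function(v) {
    m <- length(v) %/% 2L
    ch <- list(v[seq_len(m)], v[m + seq_len(m)])
    W <- mean(vapply(ch, stats::var, 0))
    B <- m * stats::var(vapply(ch, mean, 0))
    sqrt(((m - 1) / m * W + B / m) / W)
  }
  eff <- list(AM = draws[, "shiftAM"] * scl, OWA = draws[, "shiftOWA"] * scl)
  perLine <- do.call(rbind, lapply(names(eff), function(ln) {
    v <- eff[[ln]]
    data.frame(line = ln, mean = mean(v),
               ci_low = unname(stats::quantile(v, 0.025)),
               ci_high = unname(stats::quantile(v, 0.975)),
               p_mcmc = pSign(v), row.names = NULL)
  }))
  magDiff <- abs(eff$AM) - abs(eff$OWA)
  rhat <- max(splitRhat(eff$AM), splitRhat(eff$OWA))
  if (rhat > 1.1)
    warning("split-chain Rhat ", round(rhat, 3), " > 1.1: chain may not ",
            "have converged")
  list(perLine = perLine,
       magnitude = list(mean = mean(magDiff),
                        ci_low = unname(stats::quantile(magDiff, 0.025)),
                        ci_high = unname(stats::quantile(magDiff, 0.975)),
                        p_mcmc = pSign(magDiff)),
       nDraws = as.integer(nDraws), rhat = rhat, converged = rhat <= 1.1)
}
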