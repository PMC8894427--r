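#' Remove genes with uniformly low expression
#'
#' A gene is kept iff the fraction of samples with fewer than `minCount`
#' reads is at most `maxLowFraction` (default: drop genes with fewer than
#' 10 counts in more than 90% of the samples).
#'
#' @param x an [ExpressionCounts-class] object.
#' @param minCount count threshold defining "low" in a sample.
#' @param maxLowFraction maximum tolerated fraction of low samples.
#' @return the filtered [ExpressionCounts-class] object.
#' @export
filterLowExpression <- function(x, minCount = 10L, maxLowFraction = 0.9) {
  counts <- assay(x, "counts")
  lowFrac <- rowMeans(counts < minCount)
  x[lowFrac <= maxLowFraction, ]
}

#' Median-of-ratios normalisation and log transform
#'
#' Size factors are the per-sample median of count ratios to a
#' geometric-mean reference built from genes with all-positive counts.
#' The transformed assay is log2(count / sizeFactor + 1), a variance-
#' flattening transform feeding the PCA/discriminant geometry.
#'
#' @param x an [ExpressionCounts-class] object.
#' @return `x` with a `logcounts` assay and a `sizeFactor` column in
#'   `colData`.
#' @export
normalizeAndTransform <- function(x) {
  counts <- assay(x, "counts")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  allPos <- rowSums(counts == 0) == 0L
  if (!any(allPos)) stop("cannot form reference: no gene with all-positive counts")
  logRef <- rowMeans(log(counts[allPos, , drop = FALSE]))
  sf <- apply(counts[allPos, , drop = FALSE], 2L,
              function(cnt) exp(stats::median(log(cnt) - logRef)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor")
  colData(x)$sizeFactor <- sf
  assay(x, "logcounts") <- log2(sweep(counts, 2L, sf, "/") + 1)
  validObject(x)
  x
}

#' @noRd
cellLabel <- function(design)
  paste(design$line, design$environment, sep = "_")

## Per-gene NB dispersion: method of moments on normalised counts within
## design cells, floored, then shrunk 50% (geometric) toward the fitted
## mean-dispersion trend alpha(mu) = a0 + a1/mu.  Returns the estimates
## with the pooled within-cell degrees of freedom as an attribute (used
## as the reference df of the Wald statistic).
#' @noRd
dispersionEstimates <- function(normCounts, cellFactor, floor = 1e-8) {
  cellFactor <- droplevels(factor(cellFactor))
  G <- nrow(normCounts)
  m <- rowMeans(normCounts)
  withinVar <- rep(0, G); df <- 0L
  for (lev in levels(cellFactor)) {
    idx <- which(cellFactor == lev)
    if (length(idx) < 2L) next
    sub <- normCounts[, idx, drop = FALSE]
    withinVar <- withinVar + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(idx) - 1L
  }
  v <- withinVar / max(df, 1L)
  alpha <- pmax((v - m) / pmax(m, 1e-8)^2, floor)
  usable <- m > 0 & is.finite(alpha)
  if (sum(usable) >= 3L && stats::var(m[usable]) > 0) {
    fit <- stats::lm(alpha[usable] ~ I(1 / m[usable]))
    trend <- pmax(stats::fitted(fit), floor)
    alpha[usable] <- exp(0.5 * log(alpha[usable]) + 0.5 * log(trend))
  }
  structure(pmax(alpha, floor), df = max(df, 1L))
}

#' Negative-binomial Wald test between two design cells
#'
#' For each gene a negative-binomial log-linear model is fitted by
#' iteratively reweighted least squares (fixed per-gene dispersion from a
#' method-of-moments estimate shrunk 50% toward the fitted
#' mean-dispersion trend, floored at 1e-8), with the log size factor as
#' offset.  The reported log2 fold change and Wald statistic refer to
#' cell B relative to cell A; because the dispersion is estimated from
#' few residual degrees of freedom, the Wald statistic is referred to a
#' moderated t distribution whose df is the dispersion-estimation
#' residual df plus an equal prior df contributed by the trend
#' shrinkage (a z reference is anti-conservative at this design size).
#' P-values are BH-adjusted
#' across genes; genes whose fit does not converge are flagged and
#' excluded from the BH denominator.
#'
#' @param x a normalised [ExpressionCounts-class] (see
#'   [normalizeAndTransform()]).
#' @param generation generation to analyse ("F1", "F2", "F3").
#' @param contrast character 2-vector of cell labels `line_environment`,
#'   e.g. `c("AM_AM", "AM_OWA")` (A, B).
#' @param dispersions optional precomputed per-gene dispersion vector for
#'   this generation.
#' @return data.frame: gene_id, baseMean, lfc, p, padj, converged,
#'   contrast, generation.
#' @export
deTest <- function(x, generation, contrast, dispersions = NULL) {
  stopifnot(length(contrast) == 2L)
  d <- as.data.frame(colData(x))
  if (is.null(d$sizeFactor)) stop("run normalizeAndTransform() first")
  inGen <- d$generation == generation
  cells <- cellLabel(d)
  idxA <- which(inGen & cells == contrast[1L])
  idxB <- which(inGen & cells == contrast[2L])
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("need >= 2 samples per contrasted cell (", contrast[1L], ": ",
         length(idxA), ", ", contrast[2L], ": ", length(idxB), ")")
  counts <- assay(x, "counts")
  sf <- d$sizeFactor
  if (is.null(dispersions)) {
    norm <- sweep(counts[, inGen, drop = FALSE], 2L, sf[inGen], "/")
    dispersions <- dispersionEstimates(norm, cells[inGen])
  }
  dispDf <- attr(dispersions, "df")
  if (is.null(dispDf)) dispDf <- length(idxA) + length(idxB) - 2L
  idx <- c(idxA, idxB)
  grp <- factor(rep(c("A", "B"), c(length(idxA), length(idxB))),
                levels = c("A", "B"))
  off <- log(sf[idx])
  G <- nrow(counts)
  lfc <- p <- base <- rep(NA_real_, G)
  conv <- rep(FALSE, G)
  for (g in seq_len(G)) {
    y <- counts[g, idx]
    base[g] <- mean(y / sf[idx])
    if (all(y == 0)) { lfc[g] <- 0; p[g] <- 1; conv[g] <- TRUE; next }
    theta <- 1 / dispersions[g]
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ grp + offset(off),
                                  family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    ## dispersion = 1: the NB variance is carried by theta, so the Wald
    ## z uses the model-based information, not a quasi-likelihood scale
    co <- summary(fit, dispersion = 1)$coefficients
    if (!"grpB" %in% rownames(co)) next
    est <- co["grpB", "Estimate"]; se <- co["grpB", "Std. Error"]
    if (!is.finite(est) || !is.finite(se) || se <= 0) next
    lfc[g] <- est / log(2)
    ## moderated df: the 50% equal-weight shrinkage toward the trend acts
    ## as a prior worth the residual df, so the reference is t with
    ## residual + prior df (a plain z reference is anti-conservative)
    p[g] <- 2 * stats::pt(-abs(est / se), df = 2L * dispDf)
    conv[g] <- TRUE
  }
  padj <- rep(NA_real_, G)
  padj[conv] <- stats::p.adjust(p[conv], method = "BH")
  data.frame(gene_id = rownames(counts), baseMean = base, lfc = lfc,
             p = p, padj = padj, converged = conv,
             contrast = paste(contrast, collapse = "_vs_"),
             generation = generation, row.names = NULL)
}

#' The five design contrasts used by the plasticity analysis
#'
#' Runs [deTest()] for one generation on: the two within-line plastic
#' contrasts (AM_AM vs AM_OWA; OWA_OWA vs OWA_AM), the home-line
#' divergence contrast (AM_AM vs OWA_OWA), and the two
#' transplant-vs-destination contrasts (AM_OWA vs OWA_OWA; OWA_AM vs
#' AM_AM).
#'
#' @param x normalised [ExpressionCounts-class].
#' @param generation generation label.
#' @return named list of [deTest()] data.frames keyed by contrast label.
#' @export
plasticityContrasts <- function(x, generation) {
  d <- as.data.frame(colData(x))
  inGen <- d$generation == generation
  cells <- cellLabel(d)
  norm <- sweep(assay(x, "counts")[, inGen, drop = FALSE], 2L,
                d$sizeFactor[inGen], "/")
  disp <- dispersionEstimates(norm, cells[inGen])
  specs <- list(c("AM_AM", "AM_OWA"), c("OWA_OWA", "OWA_AM"),
                c("AM_AM", "OWA_OWA"), c("AM_OWA", "OWA_OWA"),
                c("OWA_AM", "AM_AM"))
  out <- lapply(specs, function(ct) deTest(x, generation, ct,
                                           dispersions = disp))
  names(out) <- vapply(specs, paste, "", collapse = "_vs_")
  out
}

#' Per-line plastic gene sets and their size ratio
#'
#' Plastic genes of a line are those differentially expressed between its
#' home and transplant environments.  The ratio of AM to OWA set sizes
#' summarises the asymmetry in plasticity (12.7-fold in the study at F1);
#' when the OWA set is empty the ratio is reported as `Inf` with
#' `infinite = TRUE`.
#'
#' @param contrasts output of [plasticityContrasts()].
#' @param deAlpha adjusted-p threshold.
#' @return list with `am`, `owa` (gene-id vectors), `ratio`, `infinite`.
#' @export
plasticGeneSets <- function(contrasts, deAlpha = 0.05) {
  sig <- function(tab) tab$gene_id[!is.na(tab$padj) & tab$padj < deAlpha]
  am <- sig(contrasts[["AM_AM_vs_AM_OWA"]])
  owa <- sig(contrasts[["OWA_OWA_vs_OWA_AM"]])
  list(am = am, owa = owa,
       ratio = if (length(owa)) length(am) / length(owa) else Inf,
       infinite = length(owa) == 0L)
}

#' Partition adaptively diverged genes into plasticity-only vs
#' genetic-change
#'
#' Over genes differentially expressed between the two home lines (AM_AM
#' vs OWA_OWA), forward adaptation (AM to OWA) classifies a gene as
#' genetic change (GC) when the transplanted line still differs from its
#' destination home line (AM_OWA vs OWA_OWA significant), and as
#' plasticity only (PO) when the gene is significantly plastic within the
#' source line (AM_AM vs AM_OWA) and shows no such residual difference.
#' The two classes are mutually exclusive; genes that are neither remain
#' unclassified, which is why PO + GC can be fewer than the eligible set.
#' The reverse direction (OWA to AM) mirrors the definitions with OWA
#' labels.
#'
#' @param contrasts output of [plasticityContrasts()].
#' @param direction "forward" (AM to OWA) or "reverse" (OWA to AM).
#' @param deAlpha adjusted-p threshold.
#' @return data.frame gene_id, class (PO / GC / unclassified), direction,
#'   generation, over the eligible genes.
#' @export
classifyPoGc <- function(contrasts, direction = c("forward", "reverse"),
                         deAlpha = 0.05) {
  direction <- match.arg(direction)
  need <- c("AM_AM_vs_OWA_OWA",
            if (direction == "forward") c("AM_AM_vs_AM_OWA",
                                          "AM_OWA_vs_OWA_OWA")
            else c("OWA_OWA_vs_OWA_AM", "OWA_AM_vs_AM_AM"))
  miss <- setdiff(need, names(contrasts))
  if (length(miss)) stop("missing contrast(s): ", paste(miss, collapse = ", "))
  sig <- function(tab) !is.na(tab$padj) & tab$padj < deAlpha
  home <- contrasts[["AM_AM_vs_OWA_OWA"]]
  eligible <- home$gene_id[sig(home)]
  plasticTab <- contrasts[[if (direction == "forward") "AM_AM_vs_AM_OWA"
                           else "OWA_OWA_vs_OWA_AM"]]
  transTab <- contrasts[[if (direction == "forward") "AM_OWA_vs_OWA_OWA"
                         else "OWA_AM_vs_AM_AM"]]
  plasticSet <- plasticTab$gene_id[sig(plasticTab)]
  transSet <- transTab$gene_id[sig(transTab)]
  cls <- ifelse(eligible %in% transSet, "GC",
                ifelse(eligible %in% plasticSet, "PO", "unclassified"))
  data.frame(gene_id = eligible, class = cls,
             direction = rep(direction, length(eligible)),
             generation = rep(home$generation[1L], length(eligible)),
             row.names = NULL)
}

#' Slope of one line's plastic response on the other's
#'
#' Ordinary least-squares slope of line-2 log2 fold changes on line-1
#' log2 fold changes over a gene mask (genes differentially expressed in
#' one or both lines).  A slope of 1 means equal plasticity; negative
#' slopes arise when the lines respond to transplant in opposite
#' directions relative to their home states.
#'
#' @param lfc1,lfc2 per-gene log2 fold changes (same order).
#' @param mask logical or integer gene selector.
#' @return list with `slope`, `intercept`, `n`.
#' @export
lfcSlope <- function(lfc1, lfc2, mask = seq_along(lfc1)) {
  x <- lfc1[mask]; y <- lfc2[mask]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 genes in the mask")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), n = length(x))
}
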