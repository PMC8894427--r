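#' Variant filter rules
#'
#' Defaults mirror a stringent pooled RNA-seq cascade: no missing data,
#' at least four samples variable with within-sample minor-allele
#' frequency >= 0.025 (one heterozygote in a pool of 20 diploids = 1/40
#' chromosomes), site depth no more than 3x the dataset-wide median, and
#' at least 50 reads in every sample (2.5 reads per diploid).
#'
#' @param minVariableSamples minimum samples with MAF above the threshold.
#' @param minSampleMaf within-sample minor-allele-frequency threshold.
#' @param maxDepthFactor maximum site depth as a multiple of the
#'   dataset-wide median site depth.
#' @param minSampleCoverage minimum total reads per sample at a site.
#' @param requireNoMissing drop sites with any zero-depth sample (implied
#'   by `minSampleCoverage` > 0).
#' @return a validated list of filter rules.
#' @export
filterRules <- function(minVariableSamples = 4L, minSampleMaf = 0.025,
                        maxDepthFactor = 3, minSampleCoverage = 50L,
                        requireNoMissing = TRUE) {
  if (minSampleMaf < 0 || minSampleMaf >= 0.5)
    stop("minSampleMaf must lie in [0, 0.5)")
  if (minVariableSamples < 0L || maxDepthFactor <= 0 ||
      minSampleCoverage < 0L)
    stop("filter rule values must be non-negative")
  list(minVariableSamples = as.integer(minVariableSamples),
       minSampleMaf = minSampleMaf, maxDepthFactor = maxDepthFactor,
       minSampleCoverage = as.integer(minSampleCoverage),
       requireNoMissing = isTRUE(requireNoMissing))
}

#' Apply the variant filter cascade
#'
#' Rules are applied in order: (1) minimum per-sample coverage (zero-depth
#' samples, i.e. missing data, fall here too); (2) site depth (median
#' across samples) at most `maxDepthFactor` times the dataset-wide median
#' site depth, computed on the input table; (3) at least
#' `minVariableSamples` samples with within-sample minor-allele frequency
#' (min(ref,alt)/depth, from read counts) of at least `minSampleMaf`.
#' The rejection ledger sums to input minus output.
#'
#' @param x an [AlleleCounts-class] object.
#' @param rules a [filterRules()] list.
#' @return list with `counts` (filtered [AlleleCounts-class]),
#'   `rejections` (named integer vector per rule), and `empty` flag set
#'   when no site survives.
#' @export
filterVariants <- function(x, rules = filterRules()) {
  if (nrow(x) == 0L) stop("empty allele count table")
  refm <- assay(x, "ref"); altm <- assay(x, "alt")
  depth <- refm + altm
  keep <- rep(TRUE, nrow(x))
  rej <- c(coverage = 0L, depth = 0L, maf = 0L)

  failCov <- apply(depth < rules$minSampleCoverage, 1L, any)
  rej["coverage"] <- sum(failCov)
  keep <- !failCov

  siteDepth <- apply(depth, 1L, stats::median)
  datasetMedian <- stats::median(siteDepth)
  failDepth <- keep & (siteDepth > rules$maxDepthFactor * datasetMedian)
  rej["depth"] <- sum(failDepth)
  keep <- keep & !failDepth

  maf <- pmin(refm, altm) / pmax(depth, 1L)
  nVariable <- rowSums(maf >= rules$minSampleMaf & depth > 0L)
  failMaf <- keep & (nVariable < rules$minVariableSamples)
  rej["maf"] <- sum(failMaf)
  keep <- keep & !failMaf

  out <- x[keep, ]
  if (!any(keep))
    warning("filter cascade removed all sites")
  list(counts = out, rejections = rej, empty = !any(keep))
}

#' Cochran-Mantel-Haenszel test for replicate-stratified 2x2 tables
#'
#' Classic CMH chi-square without continuity correction over R strata of
#' alleles x lines tables: X^2 = (sum_r (a_r - E_r))^2 / sum_r V_r with
#' E_r = row1_r col1_r / n_r and V_r = row1_r row2_r col1_r col2_r /
#' (n_r^2 (n_r - 1)); p from a 1-df chi-square.  Strata with a zero
#' margin contribute zero to both sums; when every stratum is degenerate
#' p = 1.
#'
#' @param a,b,c,d vectors (one element per stratum) of the 2x2 cell
#'   counts: a, b = line-1 ref/alt reads; c, d = line-2 ref/alt reads.
#' @return list with `statistic` and `p.value`.
#' @examples
#' cmhTest(8, 2, 2, 8)  # X^2 = 6.84, p ~ 0.0089
#' @export
cmhTest <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  n <- a + b + c + d
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d
  ok <- row1 > 0 & row2 > 0 & col1 > 0 & col2 > 0 & n > 1
  if (!any(ok)) return(list(statistic = 0, p.value = 1))
  E <- row1[ok] * col1[ok] / n[ok]
  V <- row1[ok] * row2[ok] * col1[ok] * col2[ok] / (n[ok]^2 * (n[ok] - 1))
  num <- sum(a[ok] - E)^2
  den <- sum(V)
  if (den <= 0) return(list(statistic = 0, p.value = 1))
  stat <- num / den
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Per-generation CMH scan of home-line divergence
#'
#' For each site, builds one 2x2 table per replicate stratum (reads of
#' ref/alt alleles in the two non-transplanted lines, AM_AM vs OWA_OWA)
#' and computes the CMH statistic, p-value and the mean allele-frequency
#' difference across strata.
#'
#' @param x an [AlleleCounts-class] object (typically filtered).
#' @param generation one of "F1", "F2", "F3".
#' @return data.frame with site, contig, position, statistic, p.value and
#'   mean_afd (mean across strata of alt-frequency difference, line2 -
#'   line1).
#' @export
cmhScan <- function(x, generation) {
  d <- as.data.frame(colData(x))
  home1 <- which(d$line == "AM" & d$environment == "AM" &
                   d$generation == generation)
  home2 <- which(d$line == "OWA" & d$environment == "OWA" &
                   d$generation == generation)
  if (!length(home1) || !length(home2))
    stop("no home-line samples for generation ", generation)
  reps <- sort(intersect(d$replicate[home1], d$replicate[home2]))
  refm <- assay(x, "ref"); altm <- assay(x, "alt")
  nS <- nrow(x)
  sumNum <- sumDen <- afd <- nStrata <- numeric(nS)
  for (r in reps) {
    i1 <- home1[d$replicate[home1] == r]
    i2 <- home2[d$replicate[home2] == r]
    a <- rowSums(refm[, i1, drop = FALSE]); b <- rowSums(altm[, i1, drop = FALSE])
    cc <- rowSums(refm[, i2, drop = FALSE]); dd <- rowSums(altm[, i2, drop = FALSE])
    n <- a + b + cc + dd
    row1 <- a + b; row2 <- cc + dd; col1 <- a + cc; col2 <- b + dd
    ok <- row1 > 0 & row2 > 0 & col1 > 0 & col2 > 0 & n > 1
    E <- ifelse(ok, row1 * col1 / n, 0)
    V <- ifelse(ok, row1 * row2 * col1 * col2 / (n^2 * pmax(n - 1, 1)), 0)
    sumNum <- sumNum + ifelse(ok, a - E, 0)
    sumDen <- sumDen + V
    f1 <- ifelse(row1 > 0, b / row1, NA_real_)
    f2 <- ifelse(row2 > 0, dd / row2, NA_real_)
    afd <- afd + ifelse(ok, f2 - f1, 0)
    nStrata <- nStrata + ok
  }
  stat <- ifelse(sumDen > 0, sumNum^2 / sumDen, 0)
  p <- ifelse(sumDen > 0,
              stats::pchisq(stat, 1L, lower.tail = FALSE), 1)
  rr <- rowRanges(x)
  data.frame(site = seq_len(nS),
             contig = as.character(GenomicRanges::seqnames(rr)),
             position = GenomicRanges::start(rr),
             statistic = stat, p.value = p,
             mean_afd = ifelse(nStrata > 0, afd / nStrata, NA_real_),
             generation = generation)
}

#' Bonferroni significance threshold for the CMH scans
#'
#' alpha divided by (number of SNPs x tests per SNP).  With the study-scale
#' inputs (322,595 SNPs, 3 generations, alpha 0.05) this gives 5.17e-08.
#'
#' @param nSnps number of SNPs tested.
#' @param nTestsPerSnp tests per SNP (generations).
#' @param alpha family-wise level.
#' @return the p-value threshold.
#' @export
bonferroniThreshold <- function(nSnps, nTestsPerSnp, alpha = 0.05) {
  if (nSnps < 1L || nTestsPerSnp < 1L)
    stop("nSnps and nTestsPerSnp must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  alpha / (nSnps * nTestsPerSnp)
}

#' Intersect per-generation significant locus sets into the adaptive set
#'
#' Loci significant in every tested generation are considered adaptive.
#'
#' @param sets list of integer vectors of site indices.
#' @return the intersection, ordered as in the first set.
#' @export
adaptiveLociIntersection <- function(sets) {
  if (!length(sets)) stop("need at least one set")
  Reduce(intersect, sets)
}

#' Adaptive-locus detection across generations
#'
#' Runs [cmhScan()] for each generation, applies the Bonferroni threshold
#' (alpha / (nSites x generations)) and intersects the significant sets.
#'
#' @param x filtered [AlleleCounts-class].
#' @param config a [RunConfig-class].
#' @param generations generations to test.
#' @return list with `tests` (rbind of per-generation scans),
#'   `threshold`, and `adaptive` (site indices significant in all tested
#'   generations).
#' @export
adaptiveLoci <- function(x, config = runConfig(),
                         generations = c("F1", "F2", "F3")) {
  scans <- lapply(generations, function(g) cmhScan(x, g))
  ## alpha >= 1 is the degenerate everything-significant setting
  thr <- if (config@alpha >= 1) Inf else
    bonferroniThreshold(nrow(x), length(generations), config@alpha)
  sets <- lapply(scans, function(s) s$site[s$p.value < thr])
  list(tests = do.call(rbind, scans), threshold = thr,
       adaptive = adaptiveLociIntersection(sets))
}

#' Correlation QC of allelic vs expression signals
#'
#' Ordinary least-squares R^2 between -log10 allelic p-values and -log10
#' expression p-values over genes carrying both.  Near-zero R^2 indicates
#' allele-frequency estimates are not driven by expression differences.
#'
#' @param cmhP per-gene allelic p-values (min p over the gene's SNPs).
#' @param deP per-gene differential-expression p-values, same order.
#' @return list with `r.squared` (NA when either vector is constant),
#'   `slope` and `n`.
#' @export
alleleExpressionQC <- function(cmhP, deP) {
  ok <- is.finite(cmhP) & is.finite(deP) & cmhP > 0 & deP > 0
  x <- -log10(cmhP[ok]); y <- -log10(deP[ok])
  if (length(x) < 3L) stop("need at least 3 genes with both p-values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r.squared = NA_real_, slope = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  smry <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(r.squared = smry$r.squared,
       slope = unname(stats::coef(fit)[2L]), n = length(x))
}
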