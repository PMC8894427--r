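#' Per-site pooled heterozygosity from read counts
#'
#' pi-hat = 2 ref alt / (C (C-1)) with C = ref + alt: the unbiased
#' probability that two reads drawn without replacement differ.  Sites
#' with C < 2 are returned as NA (skipped).  The optional pool-size
#' correction multiplies by n/(n-1) with n chromosomes in the pool.
#'
#' @param ref,alt read counts (vectorised).
#' @param poolCorrection apply the n/(n-1) pool-size correction.
#' @param nChromosomes chromosomes in the pool (2 x pool size).
#' @return per-site heterozygosity; NA where total reads < 2.
#' @examples
#' sitePi(5, 5)   # 0.5556
#' sitePi(10, 0)  # 0
#' @export
sitePi <- function(ref, alt, poolCorrection = FALSE, nChromosomes = 40L) {
  C <- ref + alt
  pi <- ifelse(C >= 2L, 2 * ref * alt / (C * (C - 1)), NA_real_)
  if (poolCorrection) pi <- pi * nChromosomes / (nChromosomes - 1)
  pi
}

#' Windowed nucleotide diversity per sample
#'
#' Windows tile each contig in non-overlapping `windowSize`-bp blocks
#' [0,100), [100,200), ... (0-based half-open; 1-based site positions).
#' Window pi is the sum of per-site heterozygosity over usable variant
#' sites divided by the full window size (invariant and uncovered
#' positions contribute 0); windows with no usable site report pi = 0.
#'
#' @param x an [AlleleCounts-class] object.
#' @param windowSize window width in bp (100).
#' @param adaptiveSet site indices (rows of `x`) defining adaptive
#'   windows: a window is flagged when it contains at least one adaptive
#'   site.
#' @param poolCorrection,nChromosomes see [sitePi()].
#' @param minCoveredFraction minimum fraction of window positions covered
#'   by usable sites for the window to be reported (default 0, i.e. all
#'   windows kept).
#' @return long data.frame: contig, start, end, sample_id, line,
#'   environment, generation, replicate, pi, n_variant_sites,
#'   adaptive_flag.
#' @export
windowPi <- function(x, windowSize = 100L, adaptiveSet = integer(),
                     poolCorrection = FALSE, nChromosomes = 40L,
                     minCoveredFraction = 0) {
  rr <- rowRanges(x)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  winIdx <- (pos - 1L) %/% windowSize
  key <- paste(contig, winIdx, sep = "\r")
  refm <- assay(x, "ref"); altm <- assay(x, "alt")
  piMat <- sitePi(refm, altm, poolCorrection, nChromosomes)
  usable <- !is.na(piMat)
  variant <- usable & piMat > 0
  piMat[!usable] <- 0
  ukeys <- unique(key)
  grp <- match(key, ukeys)
  sumPi <- rowsum(piMat, grp)
  nVar <- rowsum(variant + 0L, grp)
  nUsable <- rowsum(usable + 0L, grp)
  adaptive <- tabulate(grp[seq_len(nrow(x)) %in% adaptiveSet],
                       nbins = length(ukeys)) > 0L
  first <- match(ukeys, key)
  d <- as.data.frame(colData(x))
  out <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
    data.frame(contig = contig[first], start = winIdx[first] * windowSize,
               end = (winIdx[first] + 1L) * windowSize,
               sample_id = d$sample_id[j], line = d$line[j],
               environment = d$environment[j],
               generation = d$generation[j], replicate = d$replicate[j],
               pi = sumPi[, j] / windowSize,
               n_variant_sites = nVar[, j],
               adaptive_flag = adaptive, row.names = NULL)
  }))
  if (minCoveredFraction > 0) {
    frac <- rep(rowMeans(nUsable) / windowSize, ncol(x))
    out <- out[frac >= minCoveredFraction, ]
  }
  out
}

#' @noRd
cldLetters <- function(groups, sigPairs) {
  ## compact letter display: groups not significantly different share a
  ## letter (greedy insert-absorb over mean order)
  sets <- list(groups)
  for (pp in sigPairs) {
    newSets <- list()
    for (s in sets) {
      if (all(pp %in% s)) {
        newSets <- c(newSets, list(setdiff(s, pp[1L])),
                     list(setdiff(s, pp[2L])))
      } else newSets <- c(newSets, list(s))
    }
    keep <- rep(TRUE, length(newSets))
    for (i in seq_along(newSets)) for (j in seq_along(newSets))
      if (i != j && keep[j] && all(newSets[[i]] %in% newSets[[j]]) &&
          length(newSets[[i]]) < length(newSets[[j]])) keep[i] <- FALSE
    sets <- unique(newSets[keep])
  }
  letters_ <- letters[seq_along(sets)]
  vapply(groups, function(g)
    paste(letters_[vapply(sets, function(s) g %in% s, TRUE)],
          collapse = ""), "")
}

#' ANOVA with Tukey post hoc on per-replicate median pi
#'
#' One-way ANOVA over treatment x generation cells of the per-replicate
#' median window pi, followed by Tukey HSD pairwise comparisons and a
#' compact letter display.
#'
#' @param windows output of [windowPi()] (all samples).
#' @return list with `medians` (per replicate x cell), `anova` (F, p),
#'   `tukey` (pairwise table) and `letters`.
#' @export
medianPiTests <- function(windows) {
  windows$cell <- paste(windows$line, windows$environment,
                        windows$generation, sep = "_")
  med <- stats::aggregate(pi ~ cell + replicate, windows, stats::median)
  if (length(unique(med$cell)) < 2L) stop("need >= 2 groups")
  if (min(table(med$cell)) < 2L) stop("need >= 2 replicates per group")
  if (all(stats::aggregate(pi ~ cell, med, stats::var)$pi == 0))
    stop("zero within-group variance everywhere")
  med$cell <- factor(med$cell)
  fit <- stats::aov(pi ~ cell, data = med)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$cell
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  sig <- pairs[tk[, "p adj"] < 0.05]
  groups <- levels(med$cell)
  list(medians = med,
       anova = list(F = an[1L, "F value"], p = an[1L, "Pr(>F)"]),
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       letters = data.frame(cell = groups,
                            letters = cldLetters(groups, sig),
                            row.names = NULL))
}

#' Change in window pi by adaptive class, with rank-sum tests
#'
#' Delta pi of a window in a treatment x generation cell is the
#' replicate-mean pi minus the window's replicate-mean pi in the baseline
#' cell (AM_AM at F1).  Per tested cell, a two-sided Wilcoxon rank-sum
#' test compares adaptive-window delta pi against non-adaptive-window
#' delta pi; p-values are Bonferroni-corrected across the tested cells.
#'
#' @param windows output of [windowPi()] with `adaptive_flag` set.
#' @param baselineLine,baselineEnv,baselineGeneration the reference cell.
#' @param cells data.frame(line, environment, generation) of cells to
#'   test; default all non-baseline cells present.
#' @return list with `delta` (long data.frame window x cell) and `tests`
#'   (per cell: mean delta by class, W, p, p_bonferroni, skipped flag).
#' @export
deltaPiByClass <- function(windows, baselineLine = "AM",
                           baselineEnv = "AM",
                           baselineGeneration = "F1", cells = NULL) {
  windows$window <- paste(windows$contig, windows$start, sep = ":")
  cellOf <- function(w) paste(w$line, w$environment, w$generation,
                              sep = "_")
  windows$cell <- cellOf(windows)
  baseCell <- paste(baselineLine, baselineEnv, baselineGeneration,
                    sep = "_")
  meanPi <- stats::aggregate(pi ~ window + cell + adaptive_flag, windows,
                             mean)
  base <- meanPi[meanPi$cell == baseCell, ]
  if (!nrow(base)) stop("baseline cell ", baseCell, " absent")
  baseMap <- stats::setNames(base$pi, base$window)
  if (is.null(cells)) {
    u <- unique(windows[, c("line", "environment", "generation")])
    cells <- u[paste(u$line, u$environment, u$generation, sep = "_") !=
                 baseCell, ]
  }
  delta <- list(); tests <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- paste(cells$line[i], cells$environment[i], cells$generation[i],
                sep = "_")
    m <- meanPi[meanPi$cell == cl, ]
    m <- m[m$window %in% names(baseMap), ]
    m$delta_pi <- m$pi - baseMap[m$window]
    delta[[cl]] <- data.frame(cell = cl, window = m$window,
                              adaptive_flag = m$adaptive_flag,
                              delta_pi = m$delta_pi, row.names = NULL)
    ad <- m$delta_pi[m$adaptive_flag]
    na <- m$delta_pi[!m$adaptive_flag]
    if (length(ad) < 2L || length(na) < 2L) {
      tests[[cl]] <- data.frame(cell = cl, mean_delta_adaptive = NA,
                                mean_delta_nonadaptive = NA, W = NA,
                                p = NA, skipped = TRUE)
    } else {
      wt <- stats::wilcox.test(ad, na, exact = FALSE)
      tests[[cl]] <- data.frame(cell = cl,
                                mean_delta_adaptive = mean(ad),
                                mean_delta_nonadaptive = mean(na),
                                W = unname(wt$statistic), p = wt$p.value,
                                skipped = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_bonferroni <- pmin(tests$p * sum(!tests$skipped), 1)
  list(delta = do.call(rbind, delta), tests = tests)
}
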