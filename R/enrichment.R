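#' Collapse per-SNP p-values to gene-level statistics
#'
#' The gene statistic is the minimum p-value over the gene's SNPs,
#' reported as -log10; genes with no SNP are absent from the table.
#'
#' @param snpP per-SNP p-values.
#' @param snpGene per-SNP gene id (same length; NA for unassigned SNPs).
#' @return data.frame gene_id, statistic (-log10 min p), n_snps.
#' @export
collapseSnpStats <- function(snpP, snpGene) {
  stopifnot(length(snpP) == length(snpGene))
  ok <- !is.na(snpGene) & is.finite(snpP)
  minP <- tapply(snpP[ok], snpGene[ok], min)
  nSnp <- tapply(snpP[ok], snpGene[ok], length)
  data.frame(gene_id = names(minP),
             statistic = -log10(pmax(as.numeric(minP), 1e-300)),
             n_snps = as.integer(nSnp), row.names = NULL)
}

## one-sided Mann-Whitney with midranks; exact enumeration of rank-sum
## placements when both groups are small, otherwise normal approximation
## with tie-corrected variance and continuity correction
#' @noRd
mwuOneSided <- function(stat, inCat, direction, exactMaxSize = 8L) {
  n1 <- sum(inCat); n2 <- sum(!inCat); N <- n1 + n2
  rk <- rank(stat)  # midranks
  R1 <- sum(rk[inCat])
  if (n1 <= exactMaxSize && n2 <= exactMaxSize) {
    combos <- utils::combn(N, n1)
    sums <- colSums(matrix(rk[combos], nrow = n1))
    tol <- 1e-9
    p <- if (direction == "low") mean(sums <= R1 + tol)
         else mean(sums >= R1 - tol)
    return(list(U = R1 - n1 * (n1 + 1) / 2, p = p, exact = TRUE))
  }
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tieCorr)
  if (v <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- if (direction == "low") (U + 0.5 - mu) / sqrt(v)
       else (U - 0.5 - mu) / sqrt(v)
  p <- if (direction == "low") stats::pnorm(z) else
    stats::pnorm(z, lower.tail = FALSE)
  list(U = U, p = p, exact = FALSE)
}

#' Rank-based (Mann-Whitney) functional-category enrichment
#'
#' Threshold-free enrichment: for every category, a one-sided
#' Mann-Whitney U test compares the gene statistics of in-category genes
#' against all other genes, asking whether the category falls toward the
#' chosen tail of the distribution.  Ties are handled by midranks with a
#' tie-corrected variance; when both groups have at most `exactMaxSize`
#' genes the null is enumerated exactly over all rank placements.
#' Categories are tested flat (no ontology-graph propagation or merging).
#'
#' @param geneStats data.frame with columns gene_id, statistic.
#' @param categoryMap data.frame with columns gene_id, category_id.
#' @param direction "low" (disproportionately low values, e.g. loss of
#'   diversity or small p-values on the -log scale reversed) or "high".
#' @param minCategorySize smallest tested category (genes present in
#'   `geneStats`).
#' @param exactMaxSize exact-enumeration size limit per group.
#' @return data.frame category_id, n_genes, U, p, padj (BH), direction,
#'   exact; categories spanning all genes are excluded.
#' @export
goMwuTest <- function(geneStats, categoryMap,
                      direction = c("low", "high"),
                      minCategorySize = 5L, exactMaxSize = 8L) {
  direction <- match.arg(direction)
  stat <- geneStats$statistic
  names(stat) <- geneStats$gene_id
  categoryMap <- categoryMap[categoryMap$gene_id %in% names(stat), ]
  cats <- split(categoryMap$gene_id, categoryMap$category_id)
  cats <- cats[vapply(cats, function(g) {
    n <- length(unique(g))
    n >= minCategorySize && n < length(stat)
  }, TRUE)]
  if (length(cats) < 2L)
    stop("need >= 2 categories after the size filter")
  rows <- lapply(names(cats), function(cid) {
    inCat <- names(stat) %in% cats[[cid]]
    r <- mwuOneSided(stat, inCat, direction, exactMaxSize)
    data.frame(category_id = cid, n_genes = sum(inCat), U = r$U, p = r$p,
               direction = direction, exact = r$exact, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
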