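#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData colData<- rowRanges
NULL

DESIGN_LEVELS <- list(
  line        = c("AM", "OWA"),
  environment = c("AM", "OWA"),
  generation  = c("F1", "F2", "F3")
)

#' Validate and normalise a sample-design table
#'
#' The design describes the factorial layout of a two-line reciprocal
#' transplant: selection line (AM = ambient, OWA = warming/acidification),
#' assay environment, transplant generation and replicate culture.  The full
#' design has 2 lines x 2 environments x 3 generations x 4 replicates = 48
#' samples.
#'
#' @param design a data.frame or DataFrame with columns `sample_id`, `line`,
#'   `environment`, `generation`, `replicate`.
#' @param requireFull require the complete 48-sample layout.
#' @return a validated [S4Vectors::DataFrame] with factor-coded columns.
#' @examples
#' d <- fullSampleDesign()
#' nrow(d)  # 48
#' @export
sampleDesign <- function(design, requireFull = FALSE) {
  req <- c("sample_id", "line", "environment", "generation", "replicate")
  missing <- setdiff(req, colnames(design))
  if (length(missing))
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  d <- DataFrame(
    sample_id   = as.character(design$sample_id),
    line        = factor(as.character(design$line), DESIGN_LEVELS$line),
    environment = factor(as.character(design$environment),
                         DESIGN_LEVELS$environment),
    generation  = factor(as.character(design$generation),
                         DESIGN_LEVELS$generation),
    replicate   = as.integer(design$replicate)
  )
  if (anyNA(d$line) || anyNA(d$environment) || anyNA(d$generation))
    stop("design has values outside {AM,OWA} x {AM,OWA} x {F1,F2,F3}")
  if (any(d$replicate < 1L))
    stop("replicate must be a positive integer")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design")
  key <- paste(d$line, d$environment, d$generation, d$replicate)
  if (anyDuplicated(key))
    stop("duplicate (line, environment, generation, replicate) combination")
  if (requireFull) {
    if (nrow(d) != 48L)
      stop("full design must have 48 rows, got ", nrow(d))
    cells <- with(as.data.frame(d),
                  table(line, environment, generation))
    if (any(cells != 4L))
      stop("full design requires every line x environment cell in every ",
           "generation to have 4 replicates")
  }
  rownames(d) <- d$sample_id
  d
}

#' The complete 48-sample reciprocal-transplant design
#'
#' @return a [S4Vectors::DataFrame] with 48 rows covering 2 lines x 2
#'   environments x 3 generations x 4 replicates.  Sample ids follow the
#'   line_environment subscript convention, e.g. `OWA_AM_F2_r3` is the
#'   OWA-evolved line assayed in ambient conditions, generation F2,
#'   replicate 3.
#' @export
fullSampleDesign <- function() {
  g <- expand.grid(
    replicate   = 1:4,
    environment = DESIGN_LEVELS$environment,
    line        = DESIGN_LEVELS$line,
    generation  = DESIGN_LEVELS$generation,
    stringsAsFactors = FALSE
  )
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$line, g$environment,
                         g$generation, g$replicate)
  sampleDesign(g[, c("sample_id", "line", "environment",
                     "generation", "replicate")],
               requireFull = TRUE)
}

#' AlleleCounts: pooled biallelic read counts at variant sites
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with two integer
#' assays, `ref` and `alt`, one row per biallelic site and one column per
#' pooled sample.  Row ranges carry the site coordinates (1-based) and the
#' reference/alternate alleles in `ref_allele` / `alt_allele` metadata
#' columns; `colData` is the sample design.
#'
#' @aliases AlleleCounts-class
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

setValidity("AlleleCounts", function(object) {
  msg <- character()
  if (!all(c("ref", "alt") %in% names(assays(object))))
    msg <- c(msg, "assays must contain 'ref' and 'alt'")
  md <- colnames(S4Vectors::mcols(rowRanges(object)))
  if (!all(c("ref_allele", "alt_allele") %in% md))
    msg <- c(msg, "rowRanges must carry 'ref_allele' and 'alt_allele'")
  else {
    ra <- S4Vectors::mcols(rowRanges(object))$ref_allele
    aa <- S4Vectors::mcols(rowRanges(object))$alt_allele
    if (any(ra == aa))
      msg <- c(msg, "ref_allele must differ from alt_allele at every site")
    if (!all(c(ra, aa) %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be A, C, G or T")
  }
  if (length(assays(object)) &&
      (any(assay(object, "ref") < 0) || any(assay(object, "alt") < 0)))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleCounts object
#'
#' @param ref,alt integer matrices (sites x samples) of reference and
#'   alternate allele read counts.
#' @param sites data.frame with columns `contig`, `position` (1-based),
#'   `ref_allele`, `alt_allele`; positions must be strictly increasing
#'   within each contig.
#' @param design sample design (see [sampleDesign()]); rows must match the
#'   count columns.
#' @return an `AlleleCounts` object.
#' @export
alleleCounts <- function(ref, alt, sites, design) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt count matrices must have identical dimensions")
  if (nrow(ref) != nrow(sites))
    stop("count matrix rows (", nrow(ref), ") do not match sites (",
         nrow(sites), ")")
  design <- sampleDesign(design)
  if (ncol(ref) != nrow(design))
    stop("count matrix columns (", ncol(ref), ") do not match design rows (",
         nrow(design), ")")
  ord <- order(sites$contig, sites$position)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    ref <- ref[ord, , drop = FALSE]; alt <- alt[ord, , drop = FALSE]
  }
  pos <- as.integer(sites$position)
  dup <- unlist(tapply(pos, sites$contig, function(p) duplicated(p)))
  if (any(dup))
    stop("positions must be strictly increasing within contig")
  rr <- GRanges(sites$contig, IRanges(pos, width = 1L),
                ref_allele = as.character(sites$ref_allele),
                alt_allele = as.character(sites$alt_allele))
  names(rr) <- sprintf("%s:%d", sites$contig, pos)
  colnames(ref) <- colnames(alt) <- design$sample_id
  rownames(ref) <- rownames(alt) <- names(rr)
  se <- SummarizedExperiment(
    assays = SimpleList(ref = ref, alt = alt),
    rowRanges = rr, colData = design)
  new("AlleleCounts", se)
}

#' ExpressionCounts: gene-level integer counts for the transplant design
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#' (genes x samples, non-negative integers); after
#' [normalizeAndTransform()] a `logcounts` assay and a `sizeFactor`
#' column in `colData` are added.
#'
#' @aliases ExpressionCounts-class
#' @exportClass ExpressionCounts
setClass("ExpressionCounts", contains = "SummarizedExperiment")

setValidity("ExpressionCounts", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assays must contain 'counts'")
  else if (any(assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  if ("sizeFactor" %in% colnames(colData(object)) &&
      any(colData(object)$sizeFactor <= 0))
    msg <- c(msg, "size factors must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCounts object
#'
#' @param counts gene x sample matrix of non-negative integers, with gene
#'   ids as rownames.
#' @param design sample design matching the columns (see [sampleDesign()]).
#' @return an `ExpressionCounts` object.
#' @export
expressionCounts <- function(counts, design) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no genes in expression matrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  design <- sampleDesign(design)
  if (ncol(counts) != nrow(design))
    stop("count columns do not match design rows")
  colnames(counts) <- design$sample_id
  new("ExpressionCounts",
      SummarizedExperiment(assays = SimpleList(counts = counts),
                           colData = design))
}

#' Run configuration for the end-to-end pipeline
#'
#' @slot alpha family-wise significance level for the CMH Bonferroni
#'   threshold (default 0.05).
#' @slot nGenerationsTested number of transplant generations whose CMH tests
#'   enter the Bonferroni correction and the adaptive intersection
#'   (default 3).
#' @slot windowSize nucleotide-diversity window size in bp (default 100).
#' @slot poolSize diploid individuals per RNA pool (default 20).
#' @slot deAlpha BH-adjusted p-value threshold for differential expression
#'   (default 0.05).
#' @slot mcmcDraws retained posterior draws for discriminant-shift inference
#'   (default 2500).
#' @slot seed top-level seed; every stochastic stage derives a child seed
#'   from (seed, stage name).
#' @aliases RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig", representation(
  alpha = "numeric", nGenerationsTested = "integer",
  windowSize = "integer", poolSize = "integer",
  deAlpha = "numeric", mcmcDraws = "integer", seed = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha > 1 ||
      object@deAlpha <= 0 || object@deAlpha >= 1)
    msg <- c(msg, "alpha must lie in (0,1] and deAlpha in (0,1)")
  if (object@windowSize < 1L) msg <- c(msg, "windowSize must be >= 1")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (object@mcmcDraws < 1L) msg <- c(msg, "mcmcDraws must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param alpha,nGenerationsTested,windowSize,poolSize,deAlpha,mcmcDraws,seed
#'   see the class slots.
#' @return a `RunConfig` object.
#' @rdname RunConfig-class
#' @export
runConfig <- function(alpha = 0.05, nGenerationsTested = 3L,
                      windowSize = 100L, poolSize = 20L, deAlpha = 0.05,
                      mcmcDraws = 2500L, seed = 1L) {
  new("RunConfig", alpha = alpha,
      nGenerationsTested = as.integer(nGenerationsTested),
      windowSize = as.integer(windowSize), poolSize = as.integer(poolSize),
      deAlpha = deAlpha, mcmcDraws = as.integer(mcmcDraws),
      seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: alpha=", object@alpha,
      ", generations tested=", object@nGenerationsTested,
      ", window=", object@windowSize, "bp, pool=", object@poolSize,
      " diploids, deAlpha=", object@deAlpha,
      ", mcmcDraws=", object@mcmcDraws, ", seed=", object@seed, "\n",
      sep = "")
})

#' Fitted discriminant-space model for two home lines
#'
#' PCA of centred features followed by a one-axis linear discriminant
#' between the two non-transplanted (home) groups.  Transplanted samples
#' are projected onto the stored axis with [projectSamples()].
#'
#' @slot center feature means used for centring.
#' @slot rotation feature x nPcs PCA rotation matrix.
#' @slot varFraction fraction of total variance retained by the PCs.
#' @slot loadings discriminant axis in PC space (unit norm).
#' @slot groupMeans named length-2 vector: home-group means on the axis.
#' @slot withinSD pooled within-group SD on the axis.
#' @slot groups group labels (home lines).
#' @slot separable FALSE when the groups could not be separated.
#' @aliases DAPCModel-class
#' @exportClass DAPCModel
setClass("DAPCModel", representation(
  center = "numeric", rotation = "matrix", varFraction = "numeric",
  loadings = "numeric", groupMeans = "numeric", withinSD = "numeric",
  groups = "character", separable = "logical"))

setMethod("show", "DAPCModel", function(object) {
  cat("DAPCModel: ", ncol(object@rotation), " PCs (",
      round(100 * object@varFraction, 1), "% variance), groups ",
      paste(object@groups, collapse = " vs "), "\n  axis means: ",
      paste(sprintf("%s=%.3f", names(object@groupMeans), object@groupMeans),
            collapse = ", "),
      ", within-group SD ", signif(object@withinSD, 4),
      if (!object@separable) "  [non-separable]", "\n", sep = "")
})
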