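#' Parse one sync-style record of pooled base counts
#'
#' The sync dialect is the standard pooled-count interchange format:
#' `contig<TAB>position<TAB>ref_base<TAB>A:T:C:G:N:del` with one count
#' field per sample and 1-based positions.  Biallelic reduction is *not*
#' performed here; it happens in [readSync()] across all samples.
#'
#' @param lineText one tab-separated sync record.
#' @param sampleCount expected number of per-sample count fields.
#' @return a list with `contig`, `position`, `ref_base` and `counts`, a
#'   sampleCount x 4 integer matrix with columns A, T, C, G (N and
#'   deletion counts are dropped).
#' @examples
#' parseSyncLine("sc1\t100\tA\t10:0:5:0:0:0", 1L)
#' @export
parseSyncLine <- function(lineText, sampleCount) {
  fields <- strsplit(lineText, "\t", fixed = TRUE)[[1L]]
  if (length(fields) != 3L + sampleCount)
    stop("malformed sync record (expected ", 3L + sampleCount,
         " fields, got ", length(fields), "): ", lineText)
  pos <- suppressWarnings(as.integer(fields[2L]))
  if (is.na(pos) || pos < 1L)
    stop("invalid position in sync record: ", lineText)
  counts <- matrix(0L, sampleCount, 4L,
                   dimnames = list(NULL, c("A", "T", "C", "G")))
  for (i in seq_len(sampleCount)) {
    parts <- strsplit(fields[3L + i], ":", fixed = TRUE)[[1L]]
    if (length(parts) != 6L)
      stop("malformed count field '", fields[3L + i], "' in: ", lineText)
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v) || any(v < 0) || any(v != floor(v)))
      stop("negative or non-integer count in: ", lineText)
    counts[i, ] <- as.integer(v[1:4])
  }
  list(contig = fields[1L], position = pos, ref_base = fields[3L],
       counts = counts)
}

#' Read a sync file of pooled allele counts into an AlleleCounts object
#'
#' Applies biallelic reduction per site: the two bases with the highest
#' total count across all samples are retained (ties broken in base order
#' A < C < G < T); the reference allele is the sync reference base when it
#' is one of the two, otherwise the higher-count base.
#'
#' @param path sync file (no header).
#' @param design sample design; its row order defines the sample order of
#'   the count columns.
#' @return an [AlleleCounts-class] object.
#' @export
readSync <- function(path, design) {
  design <- sampleDesign(design)
  n <- nrow(design)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sync file: ", path)
  recs <- lapply(lines, parseSyncLine, sampleCount = n)
  baseOrder <- c("A", "C", "G", "T")
  ref <- alt <- matrix(0L, length(recs), n)
  sites <- data.frame(contig = character(length(recs)),
                      position = integer(length(recs)),
                      ref_allele = character(length(recs)),
                      alt_allele = character(length(recs)))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    totals <- colSums(r$counts)[baseOrder]
    top2 <- baseOrder[order(-totals, seq_along(totals))][1:2]
    if (r$ref_base %in% top2) {
      refBase <- r$ref_base; altBase <- setdiff(top2, refBase)
    } else {
      refBase <- top2[1L]; altBase <- top2[2L]
    }
    sites$contig[i] <- r$contig; sites$position[i] <- r$position
    sites$ref_allele[i] <- refBase; sites$alt_allele[i] <- altBase
    ref[i, ] <- r$counts[, refBase]
    alt[i, ] <- r$counts[, altBase]
  }
  key <- sprintf("%s:%d", sites$contig, sites$position)
  if (anyDuplicated(key))
    stop("duplicate site keys in sync file: ",
         paste(utils::head(key[duplicated(key)], 5L), collapse = ", "))
  alleleCounts(ref, alt, sites, design)
}

#' Write an AlleleCounts object as a sync file
#'
#' @param x an [AlleleCounts-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSync <- function(x, path) {
  rr <- rowRanges(x)
  md <- S4Vectors::mcols(rr)
  refm <- assay(x, "ref"); altm <- assay(x, "alt")
  baseIdx <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    v <- matrix(0L, ncol(x), 6L)
    v[, baseIdx[[md$ref_allele[i]]]] <- refm[i, ]
    v[, baseIdx[[md$alt_allele[i]]]] <- altm[i, ]
    fields <- apply(v, 1L, paste, collapse = ":")
    writeLines(paste(c(as.character(GenomicRanges::seqnames(rr)[i]),
                       GenomicRanges::start(rr)[i], md$ref_allele[i],
                       fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-design TSV
#'
#' @param path TSV with columns sample_id, line, environment, generation,
#'   replicate.
#' @param requireFull require the 48-sample layout.
#' @return validated design DataFrame.
#' @export
readDesign <- function(path, requireFull = FALSE) {
  sampleDesign(readTsv(path), requireFull = requireFull)
}

#' Read a gene x sample count matrix TSV
#'
#' First column `gene_id`, one column per sample.
#' @param path TSV file.
#' @param design sample design used to order and validate the columns.
#' @return an [ExpressionCounts-class] object.
#' @export
readExpression <- function(path, design) {
  design <- sampleDesign(design)
  df <- readTsv(path)
  if (!nrow(df)) stop("no genes in expression file: ", path)
  if (colnames(df)[1L] != "gene_id")
    stop("expression file must start with a gene_id column")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  missing <- setdiff(design$sample_id, colnames(df))
  if (length(missing))
    stop("expression file is missing sample column(s): ",
         paste(missing, collapse = ", "))
  counts <- as.matrix(df[, design$sample_id, drop = FALSE])
  rownames(counts) <- df$gene_id
  expressionCounts(counts, design)
}

#' Write an ExpressionCounts counts assay as TSV
#' @param x an [ExpressionCounts-class] object.
#' @param path output file.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), assay(x, "counts"),
                   check.names = FALSE)
  writeTsv(df, path)
}

#' Read a two-column gene-to-category map
#' @param path TSV with columns gene_id, category_id (one row per pair).
#' @return data.frame with columns gene_id, category_id.
#' @export
readCategoryMap <- function(path) {
  df <- readTsv(path)
  if (!all(c("gene_id", "category_id") %in% colnames(df)))
    stop("category map needs columns gene_id and category_id")
  df[, c("gene_id", "category_id")]
}

#' Load a full experiment from disk
#'
#' Reads the sync allele counts, the expression matrix and the sample
#' design, harmonising sample order to the design and cross-validating
#' sample ids.
#'
#' @param countsPath sync file of pooled allele counts.
#' @param expressionPath gene x sample TSV.
#' @param designPath design TSV.
#' @param config a [RunConfig-class] (defaults used when missing).
#' @return a list with elements `allele`, `expression`, `design`, `config`.
#' @export
loadExperiment <- function(countsPath, expressionPath, designPath,
                           config = runConfig()) {
  design <- readDesign(designPath)
  allele <- readSync(countsPath, design)
  expr <- readExpression(expressionPath, design)
  list(allele = allele, expression = expr, design = design, config = config)
}
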