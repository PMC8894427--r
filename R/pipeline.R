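#' Run the full analysis pipeline on a fixture directory
#'
#' Orchestrates every stage in the order of the analysis: variant
#' filtering, per-generation CMH scans and the adaptive-locus
#' intersection, differential expression with plastic sets and
#' plasticity-only/genetic-change partitions, discriminant-space shifts
#' for expression and allele frequencies, windowed nucleotide diversity
#' with erosion tests, rank-based enrichment, life-history lambda, and
#' the allelic-vs-expression correlation QC.  Each stage writes its
#' result tables to `outputDir`; a manifest lists every file with its
#' row count.  Any stage failure aborts with the stage name and cause.
#'
#' @param inputDir directory with counts.sync, expression.tsv,
#'   design.tsv and optionally go_map.tsv, snp_gene_map.tsv,
#'   survivorship.tsv, matepairs.tsv (see [simulateExperiment()]).
#' @param outputDir output directory (created).
#' @param config a [RunConfig-class].
#' @return invisibly, a list with `manifest` (data.frame file, rows) and
#'   `results` (the in-memory stage outputs).
#' @export
runPipeline <- function(inputDir, outputDir, config = runConfig()) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(); rowsOf <- integer()
  emit <- function(df, name) {
    path <- file.path(outputDir, name)
    writeTsv(df, path)
    files <<- c(files, name); rowsOf <<- c(rowsOf, nrow(df))
    path
  }
  gens <- paste0("F", seq_len(config@nGenerationsTested))

  exp_ <- stage("load", loadExperiment(
    file.path(inputDir, "counts.sync"),
    file.path(inputDir, "expression.tsv"),
    file.path(inputDir, "design.tsv"), config))

  flt <- stage("filter_variants", filterVariants(exp_$allele))
  emit(data.frame(rule = names(flt$rejections),
                  rejected = as.integer(flt$rejections)),
       "filter_ledger.tsv")
  rr <- rowRanges(flt$counts)
  emit(data.frame(site_key = rownames(flt$counts),
                  contig = as.character(GenomicRanges::seqnames(rr)),
                  position = GenomicRanges::start(rr)),
       "filtered_variants.tsv")

  cmh <- stage("cmh", adaptiveLoci(flt$counts, config, gens))
  emit(cmh$tests, "cmh_tests.tsv")
  emit(data.frame(site = cmh$adaptive,
                  site_key = rownames(flt$counts)[cmh$adaptive]),
       "adaptive_loci.tsv")

  expr <- stage("expression_normalize", {
    x <- filterLowExpression(exp_$expression)
    normalizeAndTransform(x)
  })
  contrasts <- list(); plastic <- list(); pogc <- list(); slopes <- list()
  for (g in gens) {
    ct <- stage(paste0("de_", g), plasticityContrasts(expr, g))
    contrasts[[g]] <- ct
    emit(do.call(rbind, ct), paste0("de_tests_", g, ".tsv"))
    ps <- plasticGeneSets(ct, config@deAlpha)
    plastic[[g]] <- ps
    emit(data.frame(line = c("AM", "OWA"),
                    n_plastic = c(length(ps$am), length(ps$owa)),
                    ratio = ps$ratio, generation = g),
         paste0("plastic_sets_", g, ".tsv"))
    cls <- rbind(classifyPoGc(ct, "forward", config@deAlpha),
                 classifyPoGc(ct, "reverse", config@deAlpha))
    pogc[[g]] <- cls
    emit(cls, paste0("po_gc_", g, ".tsv"))
    amTab <- ct[["AM_AM_vs_AM_OWA"]]; owaTab <- ct[["OWA_OWA_vs_OWA_AM"]]
    mask <- (!is.na(amTab$padj) & amTab$padj < config@deAlpha) |
      (!is.na(owaTab$padj) & owaTab$padj < config@deAlpha)
    slopes[[g]] <- if (sum(mask) >= 3L)
      stage(paste0("lfc_slope_", g),
            lfcSlope(amTab$lfc, -owaTab$lfc, mask)) else
      list(slope = NA_real_, intercept = NA_real_, n = sum(mask))
  }
  emit(data.frame(generation = gens,
                  slope = vapply(slopes, function(s) s$slope, 0),
                  n = vapply(slopes, function(s) s$n, 0L)),
       "lfc_slopes.tsv")

  dapcRows <- list(); shiftRows <- list()
  lcFeat <- t(assay(expr, "logcounts"))
  afFeat <- alleleFrequencyFeatures(flt$counts)
  for (g in gens) {
    for (kind in c("expression", "allele_freq")) {
      feat <- if (kind == "expression") lcFeat else afFeat
      nPcs <- if (kind == "expression") 4L else 3L
      dg <- stage(paste0("dapc_", kind, "_", g),
                  dapcGeneration(feat, exp_$design, g, nPcs = nPcs))
      co <- dg$coordinates; co$data_type <- kind
      dapcRows[[paste(kind, g)]] <- co
      sh <- stage(paste0("shift_", kind, "_", g),
                  shiftInference(co, nDraws = config@mcmcDraws,
                                 seed = childSeed(config@seed,
                                                  paste0("shift_", kind,
                                                         "_", g))))
      sr <- sh$perLine
      sr$generation <- g; sr$data_type <- kind
      sr <- rbind(sr, data.frame(line = "AMvsOWA",
                                 mean = sh$magnitude$mean,
                                 ci_low = sh$magnitude$ci_low,
                                 ci_high = sh$magnitude$ci_high,
                                 p_mcmc = sh$magnitude$p_mcmc,
                                 generation = g, data_type = kind))
      shiftRows[[paste(kind, g)]] <- sr
    }
  }
  emit(do.call(rbind, dapcRows), "dapc_coordinates.tsv")
  shifts <- do.call(rbind, shiftRows)
  emit(shifts, "dapc_shift_tests.tsv")

  windows <- stage("pi_windows",
                   windowPi(flt$counts, config@windowSize,
                            adaptiveSet = cmh$adaptive))
  emit(windows, "pi_windows.tsv")
  piMed <- stage("pi_median_tests", medianPiTests(windows))
  emit(piMed$tukey, "pi_tukey.tsv")
  dpi <- stage("delta_pi", deltaPiByClass(windows))
  emit(dpi$tests, "delta_pi_tests.tsv")

  results <- list(filter = flt, cmh = cmh, expression = expr,
                  contrasts = contrasts, plastic = plastic, pogc = pogc,
                  slopes = slopes, shifts = shifts, windows = windows,
                  piMedian = piMed, deltaPi = dpi)

  mapPath <- file.path(inputDir, "snp_gene_map.tsv")
  goPath <- file.path(inputDir, "go_map.tsv")
  if (file.exists(mapPath) && file.exists(goPath)) {
    snpGene <- readTsv(mapPath)
    goMap <- readCategoryMap(goPath)
    f1 <- cmh$tests[cmh$tests$generation == "F1", ]
    geneKey <- snpGene$gene_id[match(rownames(flt$counts)[f1$site],
                                     snpGene$site_key)]
    alleleStats <- stage("collapse_snp",
                         collapseSnpStats(f1$p.value, geneKey))
    enr <- stage("enrich_allele",
                 goMwuTest(alleleStats, goMap, direction = "high"))
    emit(enr, "enrichment_allele_F1.tsv")
    home <- contrasts[["F1"]][["AM_AM_vs_OWA_OWA"]]
    deStats <- data.frame(gene_id = home$gene_id,
                          statistic = -log10(pmax(home$p, 1e-300)))
    deStats <- deStats[is.finite(deStats$statistic), ]
    enrDe <- stage("enrich_expression",
                   goMwuTest(deStats, goMap, direction = "high"))
    emit(enrDe, "enrichment_expression_F1.tsv")
    qcGenes <- merge(alleleStats, stats::setNames(
      home[, c("gene_id", "p")], c("gene_id", "de_p")), by = "gene_id")
    qc <- stage("allele_expression_qc",
                alleleExpressionQC(10^(-qcGenes$statistic), qcGenes$de_p))
    emit(data.frame(generation = "F1", r_squared = qc$r.squared,
                    slope = qc$slope, n = qc$n),
         "allele_expression_qc.tsv")
    results$enrichment <- list(allele = enr, expression = enrDe)
    results$qc <- qc
  }

  svPath <- file.path(inputDir, "survivorship.tsv")
  mpPath <- file.path(inputDir, "matepairs.tsv")
  if (file.exists(svPath) && file.exists(mpPath)) {
    sv <- readTsv(svPath); mp <- readTsv(mpPath)
    lam <- stage("lambda", lambdaEnsemble(sv, mp))
    emit(lam, "lambda.tsv")
    lr <- list()
    for (fd in unique(sv$food)) {
      s <- sv[sv$food == fd, ]
      for (tr in setdiff(unique(s$treatment), "AM_AM")) {
        t0 <- logrankTest(s[s$treatment == "AM_AM", ],
                          s[s$treatment == tr, ])
        lr[[paste(fd, tr)]] <- data.frame(
          food = fd, comparison = paste("AM_AM vs", tr),
          statistic = t0$statistic, p = t0$p.value)
      }
    }
    emit(do.call(rbind, lr), "logrank.tsv")
    results$lambda <- lam
  }

  manifest <- data.frame(file = files, rows = rowsOf)
  writeTsv(manifest, file.path(outputDir, "manifest.tsv"))
  invisible(list(manifest = manifest, results = results))
}
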