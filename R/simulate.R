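#' Configuration for the synthetic experiment generator
#'
#' The generator emulates the structure of a 20-generation
#' evolve-and-resequence experiment in replicated copepod cultures followed
#' by a three-generation reciprocal transplant: 2 selection lines (AM
#' ambient, OWA warming/acidification) x 2 assay environments x 4 replicate
#' cultures x 3 generations = 48 pooled RNA samples, pools of 20 diploids,
#' and read depths around the study's 174x mean coverage.
#'
#' @param nLoci number of biallelic loci.
#' @param propSelected fraction of loci under selection in the OWA line.
#' @param sSelected per-generation selection coefficient at selected loci.
#' @param sTransplant selection coefficient during the transplant phase
#'   (reverse-direction for lines returned to ambient); defaults to
#'   `sSelected`.
#' @param ne effective pool size (diploids) for Wright-Fisher drift.
#' @param nBurninGens selection generations before transplant (20).
#' @param nTransplantGens transplant generations sampled (3).
#' @param poolSize diploids per RNA pool (20).
#' @param meanCoverage mean read depth per site per sample (174).
#' @param coverageDispersion negative-binomial size of per-site depth.
#' @param nGenes number of genes in the expression matrix.
#' @param nbDispersion negative-binomial size of expression counts.
#' @param effectGenetic constitutive line effect, log2 units.
#' @param effectPlastic environmental (plastic) effect, log2 units.
#' @param propGenetic fraction of genes with a constitutive line effect.
#' @param propPlastic fraction of genes with a plastic effect.
#' @param propPlasticAlsoGenetic fraction of plastic genes whose plastic
#'   response is aligned with a constitutive shift in the OWA line
#'   (adaptive plasticity that became assimilated).
#' @param propPlasticLostInOwa fraction of plastic genes whose plastic
#'   response is absent in the OWA line (plasticity loss).
#' @param alleleBias allele-biased expression knob (log2 shift of the
#'   alternate allele's read sampling odds); default 0, i.e. none.
#' @param seed top-level generator seed.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(nLoci = 2000L, propSelected = 0.05,
                             sSelected = 0.3, sTransplant = sSelected,
                             ne = 1000L, nBurninGens = 20L,
                             nTransplantGens = 3L, poolSize = 20L,
                             meanCoverage = 174, coverageDispersion = 10,
                             nGenes = 2000L, nbDispersion = 5,
                             effectGenetic = 2, effectPlastic = 2,
                             propGenetic = 0.05, propPlastic = 0.15,
                             propPlasticAlsoGenetic = 0.5,
                             propPlasticLostInOwa = 0.9,
                             alleleBias = 0, seed = 1L) {
  cfg <- list(nLoci = as.integer(nLoci), propSelected = propSelected,
              sSelected = sSelected, sTransplant = sTransplant,
              ne = as.integer(ne), nBurninGens = as.integer(nBurninGens),
              nTransplantGens = as.integer(nTransplantGens),
              poolSize = as.integer(poolSize), meanCoverage = meanCoverage,
              coverageDispersion = coverageDispersion,
              nGenes = as.integer(nGenes), nbDispersion = nbDispersion,
              effectGenetic = effectGenetic, effectPlastic = effectPlastic,
              propGenetic = propGenetic, propPlastic = propPlastic,
              propPlasticAlsoGenetic = propPlasticAlsoGenetic,
              propPlasticLostInOwa = propPlasticLostInOwa,
              alleleBias = alleleBias, seed = as.integer(seed))
  fr <- c("propSelected", "propGenetic", "propPlastic",
          "propPlasticAlsoGenetic", "propPlasticLostInOwa")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must lie in [0,1]")
  if (cfg$sSelected < 0 || cfg$sTransplant < 0)
    stop("selection coefficients must be >= 0")
  if (cfg$ne < 1L || cfg$poolSize < 1L) stop("ne and poolSize must be >= 1")
  if (cfg$meanCoverage < 0 || cfg$nLoci < 1L || cfg$nGenes < 1L)
    stop("coverage and sizes must be non-negative")
  class(cfg) <- "SimulationConfig"
  cfg
}

## deterministic one-generation selection update, multiplicative fitness
## (1 + s) for the focal allele
selectionUpdate <- function(p, s) p * (1 + s) / (1 + p * s)

## one generation of Wright-Fisher drift: 2*ne gametes
driftUpdate <- function(p, ne) stats::rbinom(length(p), 2L * ne, p) / (2 * ne)

#' Simulate Wright-Fisher allele-frequency trajectories
#'
#' Replicate cultures of both lines are founded at shared initial
#' frequencies and evolve through `nBurninGens` generations of binomial
#' drift (2 ne gametes per generation); loci in the selected subset receive
#' the deterministic update p(1+s)/(1+ps) before drift in the OWA line.
#' Each replicate is then split and run `nTransplantGens` further
#' generations in both environments: selection at selected loci continues
#' forward in the OWA environment and is reversed (favouring the ancestral
#' allele) in the ambient environment for the OWA-evolved line; the
#' non-transplanted ambient line stays neutral.
#'
#' @param config a [simulationConfig()].
#' @param p0 optional initial frequencies (length nLoci); default drawn
#'   uniform on [0.05, 0.95].
#' @param nReplicates replicate cultures per line (4).
#' @return a list with `freq`, a 4-d array loci x replicate x cell x
#'   generation where cell is line_environment ("AM_AM", "AM_OWA",
#'   "OWA_AM", "OWA_OWA") and generation is F1..F3, and `truth`
#'   (selected-locus indices, initial and burn-in-final frequencies).
#' @export
simulateAlleleTrajectories <- function(config, p0 = NULL,
                                       nReplicates = 4L) {
  withChildSeed(config$seed, "allele_trajectories", {
    L <- config$nLoci
    if (is.null(p0)) p0 <- stats::runif(L, 0.05, 0.95)
    stopifnot(length(p0) == L, all(p0 >= 0 & p0 <= 1))
    nSel <- round(config$propSelected * L)
    selected <- if (nSel > 0) sort(sample.int(L, nSel)) else integer()
    isSel <- seq_len(L) %in% selected
    cells <- c("AM_AM", "AM_OWA", "OWA_AM", "OWA_OWA")
    gens <- paste0("F", seq_len(config$nTransplantGens))
    freq <- array(NA_real_, c(L, nReplicates, length(cells), length(gens)),
                  dimnames = list(NULL, NULL, cells, gens))
    burninFinal <- array(NA_real_, c(L, nReplicates, 2L),
                         dimnames = list(NULL, NULL, c("AM", "OWA")))
    for (r in seq_len(nReplicates)) {
      pAM <- p0; pOWA <- p0
      for (g in seq_len(config$nBurninGens)) {
        pAM <- driftUpdate(pAM, config$ne)
        pOWA[isSel] <- selectionUpdate(pOWA[isSel], config$sSelected)
        pOWA <- driftUpdate(pOWA, config$ne)
      }
      burninFinal[, r, "AM"] <- pAM; burninFinal[, r, "OWA"] <- pOWA
      p <- list(AM_AM = pAM, AM_OWA = pAM, OWA_AM = pOWA, OWA_OWA = pOWA)
      for (g in seq_along(gens)) {
        ## OWA environment: forward selection; AM environment: reverse
        ## selection for the OWA-evolved line, neutrality for AM_AM
        p$AM_OWA[isSel] <- selectionUpdate(p$AM_OWA[isSel],
                                           config$sTransplant)
        p$OWA_OWA[isSel] <- selectionUpdate(p$OWA_OWA[isSel],
                                            config$sSelected)
        q <- 1 - p$OWA_AM[isSel]
        p$OWA_AM[isSel] <- 1 - selectionUpdate(q, config$sTransplant)
        for (cell in cells) {
          p[[cell]] <- driftUpdate(p[[cell]], config$ne)
          if (any(!is.finite(p[[cell]])))
            stop("internal error: non-finite allele frequency")
          freq[, r, cell, g] <- p[[cell]]
        }
      }
    }
    list(freq = freq,
         truth = list(selected_loci = selected, p0 = p0,
                      burnin_final = burninFinal))
  })
}

#' @noRd
defaultSites <- function(nLoci, sitesPerContig = 500L, spacing = 40L) {
  contig <- sprintf("sc%d", (seq_len(nLoci) - 1L) %/% sitesPerContig + 1L)
  offset <- (seq_len(nLoci) - 1L) %% sitesPerContig
  bases <- c("A", "C", "G", "T")
  data.frame(contig = contig, position = as.integer(offset * spacing + 7L),
             ref_allele = bases[offset %% 4L + 1L],
             alt_allele = bases[(offset + 1L) %% 4L + 1L])
}

#' Sample pooled read counts from true allele frequencies
#'
#' Per site and sample: 2 x poolSize chromosomes are drawn binomially from
#' the true frequency (the pooling step), read depth is drawn
#' negative-binomially around `meanCoverage`, and the alternate-allele
#' read count binomially at the pool frequency.  A non-zero `alleleBias`
#' tilts the read-sampling odds of the alternate allele by 2^alleleBias
#' (default off).
#'
#' @param trueFreq loci x sample matrix of true population frequencies.
#' @param config a [simulationConfig()].
#' @param design sample design for the columns.
#' @param sites optional site table; a default contig/position layout
#'   (one site every 40 bp, 500 sites per contig) is generated otherwise.
#' @param stage RNG stage label.
#' @return an [AlleleCounts-class] object.
#' @export
simulatePoolCounts <- function(trueFreq, config, design,
                               sites = NULL, stage = "pool_counts") {
  trueFreq <- as.matrix(trueFreq)
  stopifnot(all(trueFreq >= 0 & trueFreq <= 1))
  if (is.null(sites)) sites <- defaultSites(nrow(trueFreq))
  withChildSeed(config$seed, stage, {
    n <- length(trueFreq)
    chrom <- 2L * config$poolSize
    poolFreq <- stats::rbinom(n, chrom, trueFreq) / chrom
    if (config$alleleBias != 0) {
      w <- 2^config$alleleBias
      poolFreq <- w * poolFreq / (w * poolFreq + (1 - poolFreq))
    }
    depth <- stats::rnbinom(n, size = config$coverageDispersion,
                            mu = config$meanCoverage)
    alt <- stats::rbinom(n, depth, poolFreq)
    dim(alt) <- dim(depth) <- dim(trueFreq)
    alleleCounts(depth - alt, alt, sites, design)
  })
}

#' @noRd
sampledCellFrequencies <- function(traj, design) {
  freq <- matrix(NA_real_, dim(traj$freq)[1L], nrow(design))
  d <- as.data.frame(design)
  for (j in seq_len(nrow(d))) {
    cell <- paste(d$line[j], d$environment[j], sep = "_")
    freq[, j] <- traj$freq[, d$replicate[j], cell, as.character(d$generation[j])]
  }
  colnames(freq) <- d$sample_id
  freq
}

#' Simulate negative-binomial expression counts for the transplant design
#'
#' Per-gene log-mean model: baseline + genetic effect for the OWA line
#' (constitutive, "genetic" genes) + plastic effect in the OWA environment
#' ("plastic" genes).  For the OWA line the plastic effect is multiplied by
#' (1 - loss), with loss = 1 for the `propPlasticLostInOwa` subset of
#' plastic genes -- emulating loss of plasticity after 20 generations of
#' selection.  A fraction `propPlasticAlsoGenetic` of plastic genes also
#' carry the aligned constitutive shift, emulating genetic assimilation of
#' an initially plastic response.  Counts are negative-binomial around the
#' model mean times a per-sample depth factor.
#'
#' @param config a [simulationConfig()].
#' @param design sample design (48-sample layout by default).
#' @return list with `expression` ([ExpressionCounts-class]) and `truth`
#'   (index sets: genetic_genes, plastic_genes_am, plastic_genes_owa,
#'   lost_plastic_genes).
#' @export
simulateExpression <- function(config, design = fullSampleDesign()) {
  design <- sampleDesign(design)
  withChildSeed(config$seed, "expression", {
    G <- config$nGenes
    nPl <- round(config$propPlastic * G)
    plastic <- if (nPl) sort(sample.int(G, nPl)) else integer()
    nPlG <- round(config$propPlasticAlsoGenetic * nPl)
    plasticGenetic <- if (nPlG) sort(sample(plastic, nPlG)) else integer()
    nGen <- round(config$propGenetic * G)
    pureGenetic <- if (nGen) sort(sample(setdiff(seq_len(G), plastic),
                                         nGen)) else integer()
    genetic <- sort(c(pureGenetic, plasticGenetic))
    nLost <- round(config$propPlasticLostInOwa * nPl)
    lost <- if (nLost) sort(sample(plastic, nLost)) else integer()
    baseline <- log(stats::rlnorm(G, meanlog = log(100), sdlog = 1))
    bGen <- bPl <- numeric(G)
    bGen[genetic] <- config$effectGenetic * log(2)
    bPl[plastic] <- config$effectPlastic * log(2)
    lossFac <- rep(1, G); lossFac[lost] <- 0
    depthFac <- stats::runif(nrow(design), 0.7, 1.3)
    d <- as.data.frame(design)
    counts <- matrix(0L, G, nrow(d))
    for (j in seq_len(nrow(d))) {
      isOwaLine <- d$line[j] == "OWA"
      isOwaEnv <- d$environment[j] == "OWA"
      mu <- baseline +
        (if (isOwaLine) bGen else 0) +
        (if (isOwaEnv) bPl * (if (isOwaLine) lossFac else 1) else 0)
      counts[, j] <- stats::rnbinom(G, size = config$nbDispersion,
                                    mu = exp(mu) * depthFac[j])
    }
    rownames(counts) <- sprintf("gene%05d", seq_len(G))
    list(expression = expressionCounts(counts, design),
         truth = list(genetic_genes = genetic,
                      plastic_genes_am = plastic,
                      plastic_genes_owa = sort(setdiff(plastic, lost)),
                      lost_plastic_genes = lost))
  })
}

#' @noRd
defaultLifeHistoryRates <- function() {
  cells <- expand.grid(treatment = c("AM_AM", "AM_OWA", "OWA_AM", "OWA_OWA"),
                       food = c("replete", "limited", "starved"),
                       stringsAsFactors = FALSE)
  surv <- c(replete = 0.97, limited = 0.93, starved = 0.60)
  epr <- c(replete = 12, limited = 6, starved = 0)
  hs <- c(replete = 0.8, limited = 0.6, starved = 0)
  cells$daily_survival <- surv[cells$food]
  cells$epr_mean <- epr[cells$food]
  cells$hs_mean <- hs[cells$food]
  ## transplant stress penalty, strongest for OWA returned to ambient
  pen <- c(AM_AM = 1, AM_OWA = 0.9, OWA_AM = 0.75, OWA_OWA = 1)
  cells$epr_mean <- cells$epr_mean * pen[cells$treatment]
  cells$female_death_prob <- ifelse(cells$treatment == "OWA_AM" &
                                      cells$food == "limited", 0.45, 0.1)
  cells$male_death_prob <- 0.1
  cells$maturity_day <- ifelse(cells$food == "replete", 12L, 15L)
  cells$prop_female <- 0.5
  cells
}

#' Simulate life-history assays (survivorship beakers and mate pairs)
#'
#' Survivorship beakers start with 25 N1 nauplii and follow a binomial
#' chain l_x ~ Binomial(l_{x-1}, daily survival), observed daily to day
#' 18; surviving adults are sexed at maturity.  Mate pairs lay eggs for 3
#' days (Poisson per pair), hatching binomially; adult deaths are recorded
#' so that the exclusion rules of the fecundity assay apply downstream.
#'
#' @param config a [simulationConfig()].
#' @param rates per-treatment x food rate table; see
#'   `poolSeqER:::defaultLifeHistoryRates` for the default (replete /
#'   limited / starved food, transplant penalty on egg production, no
#'   starved survival to maturity).
#' @param nBeakers beakers per treatment x food (4).
#' @param nPairs mate pairs per treatment x food (12).
#' @param nDays observation days (18).
#' @param nStart individuals per beaker (25).
#' @return list with data.frames `survivorship` (beaker_id, treatment,
#'   food, day, alive, n_females, n_males, first_adult_day) and
#'   `matepairs` (pair_id, treatment, food, e_unhatched, e_hatched, days,
#'   male_alive, female_alive).
#' @export
simulateLifeHistory <- function(config, rates = defaultLifeHistoryRates(),
                                nBeakers = 4L, nPairs = 12L, nDays = 18L,
                                nStart = 25L) {
  withChildSeed(config$seed, "life_history", {
    sv <- list(); mp <- list()
    for (i in seq_len(nrow(rates))) {
      rr <- rates[i, ]
      for (b in seq_len(nBeakers)) {
        alive <- integer(nDays + 1L); alive[1L] <- nStart
        for (d in seq_len(nDays))
          alive[d + 1L] <- stats::rbinom(1L, alive[d], rr$daily_survival)
        matDay <- min(rr$maturity_day, nDays)
        matured <- alive[matDay + 1L]
        nf <- stats::rbinom(1L, matured, rr$prop_female)
        sv[[length(sv) + 1L]] <- data.frame(
          beaker_id = sprintf("%s_%s_b%d", rr$treatment, rr$food, b),
          treatment = rr$treatment, food = rr$food, day = 0:nDays,
          alive = alive, n_females = nf, n_males = matured - nf,
          first_adult_day = matDay)
      }
      for (p in seq_len(nPairs)) {
        femaleAlive <- stats::runif(1) > rr$female_death_prob
        maleAlive <- stats::runif(1) > rr$male_death_prob
        eggs <- stats::rpois(1L, rr$epr_mean * 3)
        hatched <- stats::rbinom(1L, eggs, rr$hs_mean)
        mp[[length(mp) + 1L]] <- data.frame(
          pair_id = sprintf("%s_%s_p%d", rr$treatment, rr$food, p),
          treatment = rr$treatment, food = rr$food,
          e_unhatched = eggs - hatched, e_hatched = hatched, days = 3L,
          male_alive = maleAlive, female_alive = femaleAlive)
      }
    }
    list(survivorship = do.call(rbind, sv), matepairs = do.call(rbind, mp))
  })
}

#' @noRd
simulateCategoryMap <- function(config, truth, nCategories = 25L,
                                meanSize = 40L) {
  withChildSeed(config$seed, "category_map", {
    G <- config$nGenes
    ids <- sprintf("gene%05d", seq_len(G))
    rows <- list()
    for (k in seq_len(nCategories)) {
      size <- max(5L, stats::rpois(1L, meanSize))
      rows[[k]] <- data.frame(
        gene_id = ids[sample.int(G, min(size, G))],
        category_id = sprintf("CAT:%04d", k))
    }
    ## planted categories concentrated in true effect genes
    plant <- function(idx, label, size = 30L) {
      take <- idx[sample.int(length(idx), min(size, length(idx)))]
      data.frame(gene_id = ids[take], category_id = label)
    }
    if (length(truth$genetic_genes) >= 5L)
      rows[[length(rows) + 1L]] <- plant(truth$genetic_genes,
                                         "CAT:GENETIC")
    if (length(truth$plastic_genes_am) >= 5L)
      rows[[length(rows) + 1L]] <- plant(truth$plastic_genes_am,
                                         "CAT:PLASTIC")
    unique(do.call(rbind, rows))
  })
}

#' Generate a complete synthetic experiment
#'
#' Runs every generator stage under one seed and (optionally) writes the
#' full fixture directory: sync allele counts, expression TSV, design TSV,
#' gene-to-category map with planted enriched categories, life-history
#' tables and truth tables.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory; when NULL nothing is written.
#' @return a list with `allele`, `expression`, `design`, `categoryMap`,
#'   `lifeHistory`, `truth` and (when written) `files`.
#' @export
simulateExperiment <- function(config = simulationConfig(), dir = NULL) {
  design <- fullSampleDesign()
  traj <- simulateAlleleTrajectories(config)
  freq <- sampledCellFrequencies(traj, design)
  allele <- simulatePoolCounts(freq, config, design)
  expr <- simulateExpression(config, design)
  lh <- simulateLifeHistory(config)
  truth <- c(traj$truth, expr$truth, list(true_freq = freq))
  goMap <- simulateCategoryMap(config, expr$truth)
  ## site-to-gene annotation: loci are assigned round-robin to genes
  snpGeneMap <- data.frame(
    site_key = rownames(allele),
    gene_id = rownames(expr$expression)[(seq_len(nrow(allele)) - 1L) %%
                                          config$nGenes + 1L])
  out <- list(allele = allele, expression = expr$expression,
              design = design, categoryMap = goMap, lifeHistory = lh,
              snpGeneMap = snpGeneMap, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      counts = writeSync(allele, file.path(dir, "counts.sync")),
      expression = writeExpression(expr$expression,
                                   file.path(dir, "expression.tsv")),
      design = writeTsv(as.data.frame(design), file.path(dir, "design.tsv")),
      go_map = writeTsv(goMap, file.path(dir, "go_map.tsv")),
      snp_gene_map = writeTsv(snpGeneMap,
                              file.path(dir, "snp_gene_map.tsv")),
      survivorship = writeTsv(lh$survivorship,
                              file.path(dir, "survivorship.tsv")),
      matepairs = writeTsv(lh$matepairs, file.path(dir, "matepairs.tsv")),
      truth_selected = writeTsv(
        data.frame(selected_locus = truth$selected_loci),
        file.path(dir, "truth_selected_loci.tsv")),
      truth_genes = writeTsv(
        data.frame(
          gene_id = rownames(expr$expression),
          genetic = seq_len(config$nGenes) %in% truth$genetic_genes,
          plastic_am = seq_len(config$nGenes) %in% truth$plastic_genes_am,
          plastic_owa = seq_len(config$nGenes) %in% truth$plastic_genes_owa),
        file.path(dir, "truth_gene_classes.tsv")))
    out$files <- files
  }
  out
}
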