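# Independent oracles and shared fixtures for the suite.

# Exact conditional permutation oracle for the CMH statistic: enumerate
# every stratum table with the observed margins, weight by the product of
# hypergeometric probabilities, and report the mid-p of the CMH statistic
# (P(T > obs) + 0.5 P(T = obs)).  Independent of the implementation's
# chi-square path.
exactCmhMidP <- function(a, b, c, d) {
  supp <- lapply(seq_along(a), function(r) {
    n1 <- a[r] + b[r]; col1 <- a[r] + c[r]
    lo <- max(0L, col1 - (c[r] + d[r])); hi <- min(n1, col1)
    k <- lo:hi
    list(k = k, pr = stats::dhyper(k, n1, c[r] + d[r], col1))
  })
  grid <- expand.grid(lapply(supp, function(s) seq_along(s$k)))
  statOf <- function(av)
    cmhTest(av, (a + b) - av, (a + c) - av, (c + d) - ((a + c) - av))$statistic
  obs <- statOf(a)
  tot <- 0; eq <- 0
  for (i in seq_len(nrow(grid))) {
    av <- mapply(function(s, j) s$k[j], supp, as.integer(grid[i, ]))
    pr <- prod(mapply(function(s, j) s$pr[j], supp, as.integer(grid[i, ])))
    st <- statOf(av)
    if (st > obs + 1e-9) tot <- tot + pr
    else if (st > obs - 1e-9) eq <- eq + pr
  }
  tot + eq / 2
}

# Small synthetic experiment reused across test files (one build per run).
.fixtureEnv <- new.env(parent = emptyenv())
smallExperiment <- function() {
  if (is.null(.fixtureEnv$sim)) {
    cfg <- simulationConfig(nLoci = 400L, nGenes = 300L, seed = 42L)
    .fixtureEnv$sim <- simulateExperiment(cfg)
    .fixtureEnv$cfg <- cfg
  }
  .fixtureEnv$sim
}
smallConfig <- function() { smallExperiment(); .fixtureEnv$cfg }

# Build a minimal contrast list with controlled significance flags, for
# exercising the PO/GC classification logic without fitting models.
fakeContrasts <- function(flags, generation = "F1") {
  # flags: data.frame gene_id, eligible, plastic, transdest (logical),
  # direction-specific labels handled by the caller's choice of contrasts
  tab <- function(sig) data.frame(
    gene_id = flags$gene_id, baseMean = 10, lfc = 1,
    p = ifelse(sig, 1e-6, 0.9), padj = ifelse(sig, 1e-5, 0.95),
    converged = TRUE, contrast = "x", generation = generation)
  list(AM_AM_vs_OWA_OWA = tab(flags$eligible),
       AM_AM_vs_AM_OWA = tab(flags$plastic),
       AM_OWA_vs_OWA_OWA = tab(flags$transdest),
       OWA_OWA_vs_OWA_AM = tab(flags$plastic),
       OWA_AM_vs_AM_AM = tab(flags$transdest))
}
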