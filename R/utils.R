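#' Derive a deterministic child seed for a named pipeline stage
#'
#' Every stochastic stage seeds its RNG with a value derived from the
#' top-level seed and the stage name, so a run is bit-reproducible while
#' stages remain independent.
#'
#' @param seed top-level integer seed.
#' @param stage stage name (character scalar).
#' @return an integer seed in [0, 2^31 - 1).
#' @export
childSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 2147480009
  as.integer((as.double(seed) * 2654435 + h) %% 2147480009)
}

#' @noRd
withChildSeed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(childSeed(seed, stage))
  expr
}

#' @noRd
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
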