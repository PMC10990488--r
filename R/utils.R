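#' @importFrom stats median rnbinom rnorm runif rbinom cor pt pf phyper
#'   p.adjust model.matrix setNames complete.cases quantile
#' @importFrom utils head write.table read.table
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
rm_log <- function(..., verbose = getOption("retromark.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[retromark] ", ...)
  invisible(NULL)
}

#' Geometric mean on the log scale
#' @keywords internal
geomean <- function(x) exp(mean(log(x)))

#' Write a data frame as a headered TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV into a data.frame
#' @param path input file.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
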