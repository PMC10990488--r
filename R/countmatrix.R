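#' Construct a count matrix
#'
#' A light container for non-negative integer feature-by-sample counts with
#' a feature table (class label and length in bp).
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param feature_class single string or per-feature character vector; one
#'   of gene, intron, transposon, readthrough, readin.
#' @param feature_length numeric vector of feature lengths in bp.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, feature_class, feature_length) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(feature_class) == 1L) {
    feature_class <- rep(feature_class, nrow(counts))
  }
  stopifnot(length(feature_class) == nrow(counts),
            length(feature_length) == nrow(counts),
            all(feature_length > 0))
  out <- list(
    counts = counts,
    features = data.frame(feature_id = rownames(counts),
                          class = feature_class,
                          length = as.numeric(feature_length),
                          stringsAsFactors = FALSE)
  )
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples; classes:",
      paste(unique(x$features$class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a feature set
#' @param cm count_matrix.
#' @param feature_ids character vector of feature ids to keep.
#' @export
subset_features <- function(cm, feature_ids) {
  keep <- cm$features$feature_id %in% feature_ids
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$features$class[keep], cm$features$length[keep])
}

#' Count read-interval overlaps over a feature set
#'
#' A read increments a feature when they overlap by at least 1 bp (and, in
#' `sense`/`antisense` mode, when the read strand matches/opposes the
#' feature strand). A read overlapping k features of the set increments all
#' k, but never the same feature twice; feature sets (genes, introns,
#' readthrough bins, transposons) are quantified independently.
#'
#' @param reads named list of GRanges, one per sample (as from
#'   [read_sample_beds()]).
#' @param features GRanges with unique names (feature ids).
#' @param feature_class class label for the resulting matrix.
#' @param strand_mode one of `"unstranded"` (default, all strands pooled),
#'   `"sense"`, `"antisense"`.
#' @return a `count_matrix`.
#' @export
count_overlaps_matrix <- function(reads, features,
                                  feature_class = "gene",
                                  strand_mode = c("unstranded", "sense",
                                                  "antisense")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.list(reads), !is.null(names(reads)),
            !is.null(names(features)))
  counts <- vapply(reads, function(r) {
    if (strand_mode == "antisense") {
      GenomicRanges::strand(r) <- ifelse(
        as.character(GenomicRanges::strand(r)) == "+", "-",
        ifelse(as.character(GenomicRanges::strand(r)) == "-", "+", "*"))
    }
    GenomicRanges::countOverlaps(
      features, r, minoverlap = 1L,
      ignore.strand = (strand_mode == "unstranded"))
  }, integer(length(features)))
  counts <- matrix(counts, nrow = length(features),
                   dimnames = list(names(features), names(reads)))
  count_matrix(counts, feature_class, GenomicRanges::width(features))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across features of the ratio between the
#' sample's count and the feature's geometric mean, computed over features
#' with nonzero counts in all samples; factors are renormalized to
#' geometric mean 1. When no feature is nonzero in every sample, falls back
#' to total-count factors.
#'
#' @param cm a `count_matrix` of genes (or any reference feature set).
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(cm) {
  m <- cm$counts
  logm <- log(m)
  loggeo <- rowMeans(logm)
  use <- is.finite(loggeo)
  if (!any(use)) {
    rm_log("no feature nonzero in all samples; using total-count factors")
    sf <- colSums(m)
    if (any(sf == 0)) stop("sample with zero total counts")
  } else {
    sf <- apply(logm[use, , drop = FALSE], 2,
                function(lc) exp(stats::median(lc - loggeo[use])))
  }
  sf / geomean(sf)
}

#' Low-count feature filter
#'
#' Keeps features with raw count >= `min_count` in at least `min_prop` of
#' samples ("expressed" features); everything downstream of differential
#' expression and enrichment uses this filtered universe.
#'
#' @param cm a `count_matrix`.
#' @param min_count minimum count (default 5).
#' @param min_prop minimum fraction of samples (default 0.25).
#' @return filtered `count_matrix`.
#' @export
filter_low_counts <- function(cm, min_count = 5, min_prop = 0.25) {
  keep <- rowMeans(cm$counts >= min_count) >= min_prop
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$features$class[keep], cm$features$length[keep])
}

#' Write / read a count matrix as TSV
#'
#' Layout: feature_id, class, length, then one column per sample.
#' @param cm count_matrix.
#' @param path file path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- cbind(cm$features, as.data.frame(cm$counts))
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("feature_id", "class", "length")
  stopifnot(all(meta_cols %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(m) <- df$feature_id
  count_matrix(m, df$class, df$length)
}
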