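#' Read a BED6 file as a GRanges
#'
#' BED is 0-based half-open on disk; the returned GRanges uses the usual
#' 1-based closed convention. Names are taken from the BED name column.
#'
#' @param path path to a BED file (3--6 columns, no header).
#' @return GRanges with `name` carried as names and `score` as a
#'   metadata column when present.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED file must have at least 3 columns: ", path)
  chrom <- as.character(dt[[1]])
  start0 <- as.numeric(dt[[2]])
  end0 <- as.numeric(dt[[3]])
  bad <- which(start0 >= end0)
  if (length(bad)) {
    warning(length(bad), " record(s) with start >= end skipped in ", path)
    keep <- setdiff(seq_along(chrom), bad)
    dt <- dt[keep, ]
    chrom <- chrom[keep]; start0 <- start0[keep]; end0 <- end0[keep]
  }
  strand <- if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6]])
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  if (ncol(dt) >= 4L) names(gr) <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) gr$score <- suppressWarnings(as.numeric(dt[[5]]))
  gr
}

#' Write a GRanges as BED6
#'
#' @param gr GRanges; names become the BED name column (ids generated when
#'   absent), score column is 0.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  nm <- names(gr)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    score = rep(0L, length(gr)),
    strand = st
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path two-column TSV (chromosome name, length in bp), no header.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(chrom = names(sizes), size = as.integer(sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-sample aligned-read intervals from BED files
#'
#' One BED6 file per sample; the sample name is the file stem unless a
#' manifest maps paths to names.
#'
#' @param paths character vector of BED paths.
#' @param sample_names optional character vector overriding file stems.
#' @return named list of GRanges, one per sample.
#' @export
read_sample_beds <- function(paths, sample_names = NULL) {
  if (is.null(sample_names)) {
    sample_names <- sub("\\.bed$", "", basename(paths))
  }
  stopifnot(length(sample_names) == length(paths))
  out <- lapply(paths, read_bed)
  names(out) <- sample_names
  out
}
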