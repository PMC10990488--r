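#' Build downstream readthrough or upstream read-in regions
#'
#' For each gene, lays `n_bins` strand-aware bins of `bin_size` bp past the
#' 3' end of the longest transcript (`direction = "readthrough"`) or before
#' its 5' end (`direction = "readin"`). Bin k covers
#' `[k * bin_size, (k+1) * bin_size)` past the anchor. A bin is valid only
#' if (a) the nearest neighboring gene on the relevant side is at least
#' `isolation_bp` away from the gene, and (b) the bin overlaps no gene
#' interval. Bins truncated at a chromosome edge are clipped and marked
#' invalid. Bin 1 (10--20 kb with defaults) is the headline readthrough
#' statistic; all bins feed the decay profile.
#'
#' @param models a `gene_models` object.
#' @param direction `"readthrough"` or `"readin"`.
#' @param bin_size bin width in bp (default 10,000).
#' @param n_bins number of bins (default 10, covering 0--100 kb).
#' @param isolation_bp required gap to the nearest neighboring gene on the
#'   relevant side (default 20,000).
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, bins running off a chromosome end are clipped and invalidated.
#' @return GRanges with `region_id`, `gene_id`, `bin_index` (0-based),
#'   `direction` and `valid` columns.
#' @export
build_flank_regions <- function(models,
                                direction = c("readthrough", "readin"),
                                bin_size = 10000, n_bins = 10,
                                isolation_bp = 20000,
                                chrom_sizes = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(models, "gene_models"), isolation_bp >= 0)
  genes <- models$genes
  tx <- models$transcripts
  ltx <- tx[match(models$longest_tx[names(genes)], tx$transcript_id), ]

  st <- as.character(GenomicRanges::strand(genes))
  st[st == "*"] <- "+"
  gaps <- neighbor_gaps(genes)
  # the relevant genomic side: readthrough leaves the 3' end, read-in the 5'
  going_right <- if (direction == "readthrough") st == "+" else st == "-"
  side_gap <- ifelse(going_right, gaps$right, gaps$left)
  anchor <- ifelse(going_right, ltx$end, ltx$start)

  n_genes <- length(genes)
  k <- rep(0:(n_bins - 1L), times = n_genes)
  gi <- rep(seq_len(n_genes), each = n_bins)
  gr_right <- going_right[gi]
  a <- anchor[gi]
  start <- ifelse(gr_right, a + k * bin_size + 1, a - (k + 1) * bin_size)
  end <- ifelse(gr_right, a + (k + 1) * bin_size, a - k * bin_size - 1)
  chrom <- as.character(GenomicRanges::seqnames(genes))[gi]

  truncated <- start < 1
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[chrom]
    truncated <- truncated | end > sz
    end <- pmin(end, sz)
  }
  start <- pmax(start, 1)
  bad <- start > end
  start[bad] <- 1; end[bad] <- 1; truncated[bad] <- TRUE

  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                strand = st[gi])
  out$gene_id <- names(genes)[gi]
  out$bin_index <- k
  out$direction <- direction
  genes_u <- genes
  GenomicRanges::strand(genes_u) <- "*"
  overlaps_gene <- GenomicRanges::countOverlaps(out, genes_u,
                                                ignore.strand = TRUE) > 0
  out$valid <- !truncated & !overlaps_gene &
    (side_gap[gi] >= isolation_bp)
  out$region_id <- paste0(out$gene_id, "_", direction, "_bin", k)
  names(out) <- out$region_id
  out
}

#' Gap to the nearest gene on each genomic side
#' @keywords internal
neighbor_gaps <- function(genes) {
  n <- length(genes)
  left <- rep(Inf, n); right <- rep(Inf, n)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  s <- GenomicRanges::start(genes); e <- GenomicRanges::end(genes)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 2L) next
    for (a in i) {
      others <- setdiff(i, a)
      ov <- others[s[others] <= e[a] & e[others] >= s[a]]
      if (length(ov)) { left[a] <- 0; right[a] <- 0; next }
      rr <- others[s[others] > e[a]]
      if (length(rr)) right[a] <- min(s[rr] - e[a] - 1)
      ll <- others[e[others] < s[a]]
      if (length(ll)) left[a] <- min(s[a] - e[ll] - 1)
    }
  }
  list(left = left, right = right)
}

#' Randomly re-place loci on the genome
#'
#' Each locus is re-placed uniformly at random: a chromosome is chosen with
#' probability proportional to its length (among chromosomes long enough to
#' hold the locus) and a start position uniformly such that the locus fits.
#' Length and strand are preserved; the result is deterministic for a fixed
#' seed. Used as the permutation control for distance-to-gene analyses.
#'
#' @param loci GRanges.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param seed integer seed.
#' @param exclude optional GRanges; placements overlapping it are resampled
#'   (up to `max_iter` rounds).
#' @param max_iter resampling rounds for the exclude list.
#' @return GRanges of identical lengths and strands at random positions.
#' @export
shuffle_loci <- function(loci, chrom_sizes, seed, exclude = NULL,
                         max_iter = 1000L) {
  w <- GenomicRanges::width(loci)
  if (any(max(chrom_sizes) < w)) {
    stop("some loci are longer than every chromosome")
  }
  with_seed(seed, {
    n <- length(loci)
    chroms <- names(chrom_sizes)
    place <- function(idx) {
      wi <- w[idx]
      ch <- vapply(wi, function(len) {
        ok <- chrom_sizes >= len
        sample(chroms[ok], 1L, prob = chrom_sizes[ok])
      }, character(1))
      start <- floor(runif(length(idx), min = 1,
                           max = chrom_sizes[ch] - wi + 1 + 1))
      GenomicRanges::GRanges(ch, IRanges::IRanges(start, width = wi),
                             strand = GenomicRanges::strand(loci)[idx])
    }
    out <- place(seq_len(n))
    if (!is.null(exclude)) {
      for (it in seq_len(max_iter)) {
        bad <- which(GenomicRanges::countOverlaps(out, exclude,
                                                  ignore.strand = TRUE) > 0)
        if (!length(bad)) break
        out[bad] <- place(bad)
      }
    }
    names(out) <- names(loci)
    S4Vectors::mcols(out) <- S4Vectors::mcols(loci)
    out
  })
}
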