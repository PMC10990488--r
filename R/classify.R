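#' Classify transposon loci by genomic context
#'
#' Assigns each transposon locus one of seven context labels relative to the
#' gene annotation: `genic` (>= 1 bp overlap with a gene), `intronic`
#' (genic, with at least `intronic_frac` of the transposon's length inside a
#' single intron), `ds5kb`/`us5kb` (within `near_bp` of the nearest gene,
#' downstream/upstream of its 3'/5' end), `ds100kb`/`us100kb` (within
#' `far_bp`), otherwise `intergenic`. Downstream/upstream is judged against
#' the nearest gene's strand; unstranded genes are treated as `+`. The
#' nearest gene is the one at minimal edge-to-edge distance, ties broken by
#' lexicographically smallest `gene_id`; a transposon overlapping several
#' genes is assigned the gene with the greatest overlap.
#'
#' @param te GRanges of transposon loci (names used as ids).
#' @param models a `gene_models` object.
#' @param introns optional GRanges from [derive_introns()]; derived on the
#'   fly when `NULL`.
#' @param intronic_frac minimum fraction of the transposon length inside a
#'   single intron to call it intronic (default 0.5).
#' @param near_bp,far_bp distance cutoffs in bp (defaults 5,000 / 100,000).
#' @return data.frame with one row per locus: `te_id`, `context`,
#'   `nearest_gene_id`, `signed_distance` (bp; 0 when overlapping, positive
#'   downstream of the nearest gene, negative upstream).
#' @export
classify_transposon <- function(te, models, introns = NULL,
                                intronic_frac = 0.5,
                                near_bp = 5000, far_bp = 100000) {
  stopifnot(inherits(models, "gene_models"))
  genes <- models$genes
  if (is.null(introns)) introns <- derive_introns(models)
  ids <- names(te)
  if (is.null(ids)) ids <- paste0("te_", seq_along(te))
  n <- length(te)
  context <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  signed_distance <- rep(NA_real_, n)

  te_u <- te
  GenomicRanges::strand(te_u) <- "*"
  genes_u <- genes
  GenomicRanges::strand(genes_u) <- "*"

  # loci on chromosomes absent from the annotation stay intergenic
  known <- as.character(GenomicRanges::seqnames(te_u)) %in%
    as.character(unique(GenomicRanges::seqnames(genes_u)))
  if (any(!known)) {
    missing_chroms <- unique(as.character(GenomicRanges::seqnames(te_u))[!known])
    rm_log("chromosome(s) absent from gene annotation: ",
           paste(missing_chroms, collapse = ", "))
  }

  # genic: any overlap; pick the gene with greatest overlap, ties by id
  # (suppressWarnings: queries on chromosomes the annotation lacks)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(te_u, genes_u, minoverlap = 1L))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(te_u[qh], genes_u[sh]))
    od <- data.frame(q = qh, gene = genes$gene_id[sh], w = ow,
                     stringsAsFactors = FALSE)
    od <- od[order(od$q, -od$w, od$gene), ]
    od <- od[!duplicated(od$q), ]
    context[od$q] <- "genic"
    nearest_gene[od$q] <- od$gene
    signed_distance[od$q] <- 0
  }

  # intronic: >= intronic_frac of the locus inside one intron
  if (length(introns)) {
    iov <- suppressWarnings(
      GenomicRanges::findOverlaps(te_u, introns, ignore.strand = TRUE))
    if (length(iov)) {
      qh <- S4Vectors::queryHits(iov)
      sh <- S4Vectors::subjectHits(iov)
      ow <- GenomicRanges::width(GenomicRanges::pintersect(
        te_u[qh], GenomicRanges::granges(introns)[sh] ))
      frac <- ow / GenomicRanges::width(te_u)[qh]
      hit <- unique(qh[frac >= intronic_frac])
      hit <- hit[context[hit] == "genic"]  # intronic implies genic
      context[hit] <- "intronic"
    }
  }

  # extragenic: nearest gene by edge-to-edge distance, ties by gene_id
  extra <- which(context == "intergenic" & known)
  if (length(extra)) {
    dn <- suppressWarnings(
      GenomicRanges::distanceToNearest(te_u[extra], genes_u,
                                       select = "all"))
    if (length(dn)) {
      dd <- data.frame(
        q = extra[S4Vectors::queryHits(dn)],
        gene = genes$gene_id[S4Vectors::subjectHits(dn)],
        sidx = S4Vectors::subjectHits(dn),
        d = S4Vectors::mcols(dn)$distance,
        stringsAsFactors = FALSE
      )
      dd <- dd[order(dd$q, dd$d, dd$gene), ]
      dd <- dd[!duplicated(dd$q), ]
      g_st <- as.character(GenomicRanges::strand(genes))[dd$sidx]
      g_st[g_st == "*"] <- "+"
      te_start <- GenomicRanges::start(te_u)[dd$q]
      gene_end <- GenomicRanges::end(genes_u)[dd$sidx]
      right_of <- te_start > gene_end
      downstream <- (g_st == "+") == right_of
      sd <- ifelse(downstream, dd$d, -dd$d)
      ctx <- ifelse(dd$d <= near_bp, ifelse(downstream, "ds5kb", "us5kb"),
             ifelse(dd$d <= far_bp, ifelse(downstream, "ds100kb", "us100kb"),
                    "intergenic"))
      context[dd$q] <- ctx
      nearest_gene[dd$q] <- dd$gene
      signed_distance[dd$q] <- sd
    }
  }

  data.frame(te_id = ids, context = context,
             nearest_gene_id = nearest_gene,
             signed_distance = signed_distance,
             stringsAsFactors = FALSE)
}

#' Summarize context fractions over a set of classified transposons
#'
#' Reports the fraction of loci that are genic (intronic counted as genic),
#' intronic, within 5 kb downstream/upstream, within 100 kb
#' downstream/upstream, and intergenic, plus the total count. Genic and
#' intronic are not mutually exclusive; the remaining labels partition the
#' extragenic loci.
#'
#' @param classified data.frame from [classify_transposon()].
#' @return one-row data.frame: `genic`, `intronic`, `ds5kb`, `us5kb`,
#'   `ds100kb`, `us100kb`, `intergenic`, `n`.
#' @export
summarize_context_fractions <- function(classified) {
  if (!nrow(classified)) stop("no classified loci supplied")
  ctx <- classified$context
  n <- length(ctx)
  data.frame(
    genic = mean(ctx %in% c("genic", "intronic")),
    intronic = mean(ctx == "intronic"),
    ds5kb = mean(ctx == "ds5kb"),
    us5kb = mean(ctx == "us5kb"),
    ds100kb = mean(ctx == "ds100kb"),
    us100kb = mean(ctx == "us100kb"),
    intergenic = mean(ctx == "intergenic"),
    n = n
  )
}

#' Histogram of extragenic transposons by signed distance to nearest gene
#'
#' Genic/intronic loci are excluded; downstream distances are positive.
#'
#' @param classified data.frame from [classify_transposon()].
#' @param window_bp half-width of the histogram window (default 100,000).
#' @param bin_bp bin width in bp (default 10,000).
#' @return data.frame with `bin_start`, `bin_end` (signed bp) and `count`.
#' @export
distance_histogram <- function(classified, window_bp = 100000,
                               bin_bp = 10000) {
  d <- classified$signed_distance[
    !classified$context %in% c("genic", "intronic") &
      !is.na(classified$signed_distance)]
  breaks <- seq(-window_bp, window_bp, by = bin_bp)
  d <- d[d >= -window_bp & d < window_bp]
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)],
             bin_end = breaks[-1],
             count = counts)
}

#' Transposon density around splice junctions
#'
#' For each intron, windows of `flank_bp` on both sides of the 5' (donor)
#' and 3' (acceptor) junctions are cut into `bin_bp` bins; the transposon
#' base-pair coverage of each bin, summed over introns, is divided by the
#' total bin length. Offsets are strand-aware: positive offsets point into
#' the intron, negative offsets into the flanking exon.
#'
#' @param te GRanges of transposon loci.
#' @param introns GRanges from [derive_introns()].
#' @param flank_bp window half-width; must be a multiple of `bin_bp`.
#' @param bin_bp bin width in bp.
#' @return list with `profile` (data.frame: junction, offset_start, density)
#'   and `per_intron` (data.frame: intron_id, te_bp, width, density).
#' @export
junction_density_profile <- function(te, introns, flank_bp = 2000,
                                     bin_bp = 250) {
  if (flank_bp %% bin_bp != 0) {
    stop("flank_bp must be a multiple of bin_bp")
  }
  te_red <- GenomicRanges::reduce(GenomicRanges::granges(te),
                                  ignore.strand = TRUE)
  offs <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  st <- as.character(GenomicRanges::strand(introns))
  st[st == "*"] <- "+"
  plus <- st == "+"
  # junction anchor coordinates (1-based first intronic base / last base)
  j5 <- ifelse(plus, GenomicRanges::start(introns),
               GenomicRanges::end(introns))
  j3 <- ifelse(plus, GenomicRanges::end(introns),
               GenomicRanges::start(introns))
  prof <- lapply(c("5p", "3p"), function(junc) {
    anchor <- if (junc == "5p") j5 else j3
    # direction into the intron: +1 on plus-strand 5p and minus-strand 3p
    dir <- if (junc == "5p") ifelse(plus, 1, -1) else ifelse(plus, -1, 1)
    dens <- vapply(offs, function(o) {
      lo <- ifelse(dir > 0, anchor + o, anchor - o - bin_bp + 1)
      bins <- GenomicRanges::GRanges(GenomicRanges::seqnames(introns),
                                     IRanges::IRanges(pmax(lo, 1),
                                                      width = bin_bp))
      hits <- GenomicRanges::findOverlaps(bins, te_red)
      ov <- GenomicRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                                      te_red[S4Vectors::subjectHits(hits)])
      sum(GenomicRanges::width(ov)) / sum(GenomicRanges::width(bins))
    }, numeric(1))
    data.frame(junction = junc, offset_start = offs, density = dens)
  })
  hits <- GenomicRanges::findOverlaps(introns, te_red, ignore.strand = TRUE)
  te_bp <- rep(0, length(introns))
  if (length(hits)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(introns)[S4Vectors::queryHits(hits)],
      te_red[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    te_bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  per_intron <- data.frame(
    intron_id = if (!is.null(introns$intron_id)) introns$intron_id
                else paste0("intron_", seq_along(introns)),
    te_bp = te_bp,
    width = GenomicRanges::width(introns),
    density = te_bp / GenomicRanges::width(introns)
  )
  list(profile = do.call(rbind, prof), per_intron = per_intron)
}
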