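#' Load a GTF gene annotation into a gene-model set
#'
#' Parses a GENCODE-dialect GTF (gene/transcript/exon features with
#' `gene_id` and `transcript_id` attributes) and builds one model per gene:
#' the gene interval, its exon chains per transcript, and the transcript of
#' maximal genomic span (used downstream as the reference 3' end for
#' readthrough regions, so that differential 3'-UTR usage does not move the
#' region).
#'
#' @param gtf_path path to a GTF file.
#' @return an object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{GRanges named by `gene_id`, one per gene}
#'     \item{exons}{GRanges with `gene_id` and `transcript_id` columns}
#'     \item{transcripts}{data.frame of transcript spans}
#'     \item{longest_tx}{named character: gene_id -> transcript_id of the
#'       transcript maximizing genomic span (ties to the lexicographically
#'       smallest transcript_id)}
#'   }
#' @export
load_annotation <- function(gtf_path) {
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("malformed GTF '", gtf_path, "': ",
                             conditionMessage(e))
  )
  if (!all(c("type", "gene_id") %in% names(S4Vectors::mcols(gr)))) {
    stop("GTF must carry 'type' and 'gene_id' attributes: ", gtf_path)
  }
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0L) stop("no exon features in ", gtf_path)
  if (is.null(exons$transcript_id) || anyNA(exons$transcript_id)) {
    stop("exon features missing transcript_id in ", gtf_path)
  }

  # transcript spans from explicit transcript rows when present, else from
  # the range of each transcript's exons
  tx_rows <- gr[gr$type == "transcript"]
  ex_by_tx <- S4Vectors::split(exons, exons$transcript_id)
  ex_span <- unlist(range(ex_by_tx))
  if (length(tx_rows)) {
    tx_span <- tx_rows
    names(tx_span) <- tx_rows$transcript_id
    common <- intersect(names(ex_span), names(tx_span))
    viol <- common[GenomicRanges::start(ex_span[common]) <
                     GenomicRanges::start(tx_span[common]) |
                   GenomicRanges::end(ex_span[common]) >
                     GenomicRanges::end(tx_span[common])]
    if (length(viol)) {
      stop("exon outside its transcript span for transcript(s): ",
           paste(head(viol, 5), collapse = ", "))
    }
  } else {
    tx_span <- ex_span
  }

  tx2gene <- vapply(S4Vectors::split(exons$gene_id, exons$transcript_id),
                    function(g) g[[1]], character(1))
  tx_df <- data.frame(
    transcript_id = names(ex_span),
    gene_id = tx2gene[names(ex_span)],
    chrom = as.character(GenomicRanges::seqnames(ex_span)),
    start = GenomicRanges::start(ex_span),
    end = GenomicRanges::end(ex_span),
    strand = as.character(GenomicRanges::strand(ex_span)),
    span = GenomicRanges::width(ex_span),
    stringsAsFactors = FALSE
  )

  gene_rows <- gr[gr$type == "gene"]
  if (length(gene_rows)) {
    genes <- gene_rows
    names(genes) <- gene_rows$gene_id
  } else {
    by_gene <- S4Vectors::split(exons, exons$gene_id)
    genes <- unlist(range(by_gene))
  }
  S4Vectors::mcols(genes) <- NULL
  genes$gene_id <- names(genes)
  genes <- genes[order(names(genes))]

  longest_tx <- vapply(split(tx_df, tx_df$gene_id), function(d) {
    d <- d[order(-d$span, d$transcript_id), ]
    d$transcript_id[1]
  }, character(1))

  out <- list(genes = genes, exons = exons, transcripts = tx_df,
              longest_tx = longest_tx)
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", length(x$exons), "exons\n")
  invisible(x)
}

#' Derive introns from gene models
#'
#' For each transcript with n exons, emits the n-1 gaps between consecutive
#' exons; abutting exons (zero-length gap) emit nothing. Introns sharing
#' exact coordinates across transcripts of one gene are de-duplicated.
#'
#' @param models a `gene_models` object.
#' @return GRanges of introns with `intron_id`, `gene_id`, `transcript_id`
#'   and `index` (ordinal within the transcript, 5' to 3' in genome order).
#' @export
derive_introns <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  ord <- order(ex$transcript_id, GenomicRanges::start(ex))
  ex <- ex[ord]
  txs <- ex$transcript_id
  n <- length(ex)
  if (n < 2L) return(empty_intron_granges())
  # candidate gaps between consecutive rows of the same transcript
  same <- txs[-n] == txs[-1]
  gap_start <- GenomicRanges::end(ex)[-n] + 1L
  gap_end <- GenomicRanges::start(ex)[-1] - 1L
  keep <- same & gap_start <= gap_end
  if (!any(keep)) return(empty_intron_granges())
  idx <- which(keep)
  introns <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex)[idx],
    ranges = IRanges::IRanges(gap_start[idx], gap_end[idx]),
    strand = GenomicRanges::strand(ex)[idx]
  )
  introns$gene_id <- ex$gene_id[idx]
  introns$transcript_id <- txs[idx]
  ord_in_tx <- stats::ave(seq_along(idx), introns$transcript_id,
                          FUN = seq_along)
  introns$index <- as.integer(ord_in_tx)
  # de-duplicate identical coordinates within a gene
  key <- paste(introns$gene_id,
               GenomicRanges::seqnames(introns),
               GenomicRanges::start(introns),
               GenomicRanges::end(introns))
  introns <- introns[!duplicated(key)]
  introns$intron_id <- paste0(introns$gene_id, "_intron_",
                              stats::ave(seq_along(introns), introns$gene_id,
                                         FUN = seq_along))
  names(introns) <- introns$intron_id
  introns
}

#' @keywords internal
empty_intron_granges <- function() {
  gr <- GenomicRanges::GRanges()
  gr$gene_id <- character(0)
  gr$transcript_id <- character(0)
  gr$index <- integer(0)
  gr$intron_id <- character(0)
  gr
}

#' Write gene models to GTF
#'
#' Emits gene, transcript and exon rows in GENCODE-style attribute layout.
#'
#' @param models a `gene_models` object.
#' @param path output GTF path.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  fmt_row <- function(chrom, src, type, start, end, strand, attrs) {
    strand <- ifelse(strand %in% c("+", "-"), strand, ".")
    paste(chrom, src, type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  lines <- character(0)
  g <- models$genes
  lines <- c(lines, fmt_row(
    as.character(GenomicRanges::seqnames(g)), "retromark", "gene",
    GenomicRanges::start(g), GenomicRanges::end(g),
    as.character(GenomicRanges::strand(g)),
    sprintf("gene_id \"%s\";", g$gene_id)))
  tx <- models$transcripts
  lines <- c(lines, fmt_row(
    tx$chrom, "retromark", "transcript", tx$start, tx$end, tx$strand,
    sprintf("gene_id \"%s\"; transcript_id \"%s\";",
            tx$gene_id, tx$transcript_id)))
  ex <- models$exons
  lines <- c(lines, fmt_row(
    as.character(GenomicRanges::seqnames(ex)), "retromark", "exon",
    GenomicRanges::start(ex), GenomicRanges::end(ex),
    as.character(GenomicRanges::strand(ex)),
    sprintf("gene_id \"%s\"; transcript_id \"%s\";",
            ex$gene_id, ex$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
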