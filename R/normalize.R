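#' Nearest-gene normalization of element counts
#'
#' Divides each element's size-factor-scaled counts by those of its nearest
#' gene, with a pseudocount guarding sparse elements:
#' `value = (element + pseudocount) / (gene + pseudocount)`. This removes
#' the co-expression component so that intronic/downstream elements are
#' compared against the transcriptional activity of their host.
#'
#' @param element_cm `count_matrix` of elements (transposons, introns, ...).
#' @param gene_cm `count_matrix` of genes covering all mapped genes.
#' @param mapping data.frame with columns `element_id`, `gene_id`.
#' @param pseudocount added to numerator and denominator (default 1).
#' @param sf optional named per-sample size factors (computed from
#'   `gene_cm` when `NULL`); both matrices are scaled before the ratio.
#' @return numeric matrix (mapped elements x samples) of normalized values.
#' @export
nearest_gene_normalize <- function(element_cm, gene_cm, mapping,
                                   pseudocount = 1, sf = NULL) {
  stopifnot(all(c("element_id", "gene_id") %in% names(mapping)))
  if (is.null(sf)) sf <- size_factors(gene_cm)
  stopifnot(identical(colnames(element_cm$counts), colnames(gene_cm$counts)))
  mapping <- mapping[!is.na(mapping$gene_id), , drop = FALSE]
  ok <- mapping$element_id %in% rownames(element_cm$counts) &
    mapping$gene_id %in% rownames(gene_cm$counts)
  if (any(!ok)) {
    rm_log(sum(!ok), " element(s) without a mapped gene excluded")
  }
  mapping <- mapping[ok, , drop = FALSE]
  if (!nrow(mapping)) stop("no element maps to a gene in the count matrix")
  el <- t(t(element_cm$counts[mapping$element_id, , drop = FALSE]) / sf)
  ge <- t(t(gene_cm$counts[mapping$gene_id, , drop = FALSE]) / sf)
  out <- (el + pseudocount) / (ge + pseudocount)
  rownames(out) <- mapping$element_id
  out
}

#' Per-sample mean-log expression score
#'
#' The single per-sample summary of an element class: the mean over a
#' chosen element subset of log2 nearest-gene-normalized expression.
#'
#' @param normalized matrix from [nearest_gene_normalize()].
#' @param subset element ids to average over (typically a top-N set from
#'   differential expression); defaults to all rows.
#' @param element_class label recorded in the output.
#' @return data.frame: `sample_id`, `element_class`, `value`, `n_elements`.
#' @export
per_sample_score <- function(normalized, subset = NULL,
                             element_class = "transposon") {
  if (is.null(subset)) subset <- rownames(normalized)
  subset <- intersect(subset, rownames(normalized))
  if (!length(subset)) stop("element subset is empty")
  m <- normalized[subset, , drop = FALSE]
  if (any(m <= 0)) {
    stop("nonpositive normalized values; use pseudocount > 0")
  }
  data.frame(sample_id = colnames(m),
             element_class = element_class,
             value = colMeans(log2(m)),
             n_elements = length(subset),
             row.names = NULL)
}

#' Per-sample log2 readthrough-to-gene ratio
#'
#' Counts are converted to densities (counts per kb of feature length,
#' after size-factor scaling), summed over the isolation-filtered gene set,
#' and the per-sample statistic is
#' `log2((sum rt density + eps) / (sum gene density + eps))`. Per-gene
#' log2 ratios are also returned for locus-level analyses.
#'
#' @param rt_cm `count_matrix` of readthrough regions (typically the
#'   valid 10--20 kb bins), with `gene_id` given by `region_gene`.
#' @param gene_cm `count_matrix` of genes.
#' @param region_gene character vector mapping each `rt_cm` feature to its
#'   gene id (same order as `rt_cm` features).
#' @param sf per-sample size factors (from gene counts when `NULL`).
#' @param eps ratio guard (default 1e-6).
#' @return list with `per_sample` (data.frame sample_id, element_class,
#'   value, n_elements) and `per_gene` (matrix of log2 per-gene ratios).
#' @export
readthrough_ratio <- function(rt_cm, gene_cm, region_gene, sf = NULL,
                              eps = 1e-6) {
  if (!nrow(rt_cm$counts)) stop("no valid readthrough regions")
  stopifnot(length(region_gene) == nrow(rt_cm$counts))
  if (is.null(sf)) sf <- size_factors(gene_cm)
  keep <- region_gene %in% rownames(gene_cm$counts)
  rtc <- rt_cm$counts[keep, , drop = FALSE]
  rtl <- rt_cm$features$length[keep]
  gid <- region_gene[keep]
  if (!nrow(rtc)) stop("no readthrough region maps to a quantified gene")
  rt_dens <- t(t(rtc) / sf) / (rtl / 1000)
  g_dens <- t(t(gene_cm$counts[gid, , drop = FALSE]) / sf) /
    (gene_cm$features$length[match(gid, gene_cm$features$feature_id)] / 1000)
  per_sample <- log2((colSums(rt_dens) + eps) / (colSums(g_dens) + eps))
  per_gene <- log2((rt_dens + eps) / (g_dens + eps))
  rownames(per_gene) <- rownames(rtc)
  list(
    per_sample = data.frame(sample_id = colnames(rtc),
                            element_class = "readthrough",
                            value = per_sample,
                            n_elements = nrow(rtc),
                            row.names = NULL),
    per_gene = per_gene
  )
}

#' Binned flank decay profile
#'
#' Applies the readthrough-ratio statistic bin by bin over the 0--100 kb
#' window, yielding the per-sample decay profile; works for any feature
#' class binned by distance (readthrough bins, read-in bins, transposons
#' grouped by distance bin).
#'
#' @param cm `count_matrix` over all bins, features carrying `bin_index`
#'   via `bin_index` argument.
#' @param gene_cm `count_matrix` of genes.
#' @param region_gene gene id per `cm` feature.
#' @param bin_index integer bin index (0-based) per `cm` feature.
#' @param sf size factors.
#' @param eps ratio guard.
#' @return data.frame: `bin_index`, `sample_id`, `value`, `n_regions`.
#' @export
flank_profile <- function(cm, gene_cm, region_gene, bin_index, sf = NULL,
                          eps = 1e-6) {
  stopifnot(length(bin_index) == nrow(cm$counts))
  if (is.null(sf)) sf <- size_factors(gene_cm)
  out <- lapply(sort(unique(bin_index)), function(k) {
    sel <- bin_index == k
    sub <- count_matrix(cm$counts[sel, , drop = FALSE],
                        cm$features$class[sel], cm$features$length[sel])
    rr <- readthrough_ratio(sub, gene_cm, region_gene[sel], sf = sf,
                            eps = eps)
    data.frame(bin_index = k,
               sample_id = rr$per_sample$sample_id,
               value = rr$per_sample$value,
               n_regions = rr$per_sample$n_elements)
  })
  do.call(rbind, out)
}

#' Partition reads by strand agreement with their container gene
#'
#' Each read overlapping a gene is assigned to its first overlapping gene
#' and counted as sense (strands agree), antisense (strands oppose) or
#' unknown (read strand missing).
#'
#' @param reads named list of GRanges per sample.
#' @param genes GRanges of genes (strand-aware).
#' @return data.frame per sample: `sample_id`, `sense`, `antisense`,
#'   `unknown`, `frac_sense`.
#' @export
strand_partition <- function(reads, genes) {
  out <- lapply(names(reads), function(s) {
    r <- reads[[s]]
    hits <- GenomicRanges::findOverlaps(r, genes, ignore.strand = TRUE,
                                        select = "first")
    has <- !is.na(hits)
    rs <- as.character(GenomicRanges::strand(r))[has]
    gs <- as.character(GenomicRanges::strand(genes))[hits[has]]
    unknown <- rs == "*"
    sense <- !unknown & rs == gs
    anti <- !unknown & rs != gs
    data.frame(sample_id = s, sense = sum(sense), antisense = sum(anti),
               unknown = sum(unknown),
               frac_sense = if (sum(sense) + sum(anti) > 0)
                 sum(sense) / (sum(sense) + sum(anti)) else NA_real_)
  })
  do.call(rbind, out)
}
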