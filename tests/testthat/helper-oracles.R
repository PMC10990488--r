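# Shared fixtures and independent oracles used across test files.

# Build gene models by writing a GTF and loading it through the parser.
# exons: data.frame(chrom, start, end, strand, gene_id, transcript_id),
# 1-based closed coordinates.
toy_models <- function(exons) {
  path <- tempfile(fileext = ".gtf")
  lines <- sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, exons$start, exons$end, exons$strand, exons$gene_id,
    exons$transcript_id)
  writeLines(lines, path)
  load_annotation(path)
}

toy_granges <- function(chrom, start, end, strand = "*", ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  if (!is.null(ids)) names(gr) <- ids
  gr
}

# Independent ORF oracle: scan every position for ATG, walk codons to the
# first stop in that frame, and keep only the first ATG after each stop
# (maximal, non-nested per frame).
brute_force_orfs <- function(seq, min_nt = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (f in 0:2) {
    p <- f + 1L
    blocked_until <- 0L   # 1-based end of the last reported ORF
    while (p + 2 <= n) {
      if (p > blocked_until && substr(seq, p, p + 2) == "ATG") {
        j <- p
        prot <- character(0)
        has_stop <- FALSE
        while (j + 2 <= n) {
          aa <- code[substr(seq, j, j + 2)]
          if (is.na(aa)) aa <- "X"
          if (aa == "*") { has_stop <- TRUE; break }
          prot <- c(prot, aa)
          j <- j + 3
        }
        nt_end <- if (has_stop) j + 2L else j - 1L
        nt_len <- nt_end - p + 1L
        if (nt_len >= min_nt) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f, nt_start = p - 1L, nt_end = nt_end,
            nt_length = nt_len, has_stop = has_stop,
            protein = paste(prot, collapse = ""))
        }
        blocked_until <- nt_end
      }
      p <- p + 3L
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), nt_length = integer(0),
                      has_stop = logical(0), protein = character(0)))
  }
  do.call(rbind, out)
}

random_dna_str <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n, seed) {
  set.seed(seed)
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# deterministic back-translation (first codon per amino acid)
bt_simple <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- vapply(split(names(code), unname(code)), `[`, character(1), 1)
  paste(by_aa[strsplit(protein, "")[[1]]], collapse = "")
}
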