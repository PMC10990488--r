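#' Find open reading frames in a nucleotide sequence
#'
#' Scans all three frames on the given strand(s) for maximal ATG-to-stop
#' ORFs: within each frame, the segment between two stop codons yields at
#' most one ORF, starting at the first ATG of the segment and ending at the
#' stop codon (included in `nt_length`) or at the element end (no stop).
#' Codons containing N (or any non-ACGT base) are never starts or stops and
#' translate to X.
#'
#' @param seq a nucleotide string (or DNAString) over A/C/G/T/N.
#' @param min_nt minimum ORF length in nt, stop included (default 300).
#' @param both_strands also scan the reverse complement; LINE-1 ORFs are
#'   sense-strand, so the default scans only the annotated strand.
#' @return data.frame: `frame` (0--2), `strand`, `nt_start`, `nt_end`
#'   (0-based half-open, element-relative on the scanned strand),
#'   `nt_length`, `has_stop`, `protein`.
#' @export
find_orfs <- function(seq, min_nt = 300, both_strands = FALSE) {
  if (min_nt < 3) stop("min_nt must be >= 3")
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) return(empty_orf_df())
  out <- orf_scan_one(seq, "+", min_nt)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    out <- rbind(out, orf_scan_one(rc, "-", min_nt))
  }
  out
}

#' @keywords internal
empty_orf_df <- function() {
  data.frame(frame = integer(0), strand = character(0),
             nt_start = integer(0), nt_end = integer(0),
             nt_length = integer(0), has_stop = logical(0),
             protein = character(0), stringsAsFactors = FALSE)
}

#' @keywords internal
orf_scan_one <- function(seq, strand, min_nt) {
  n <- nchar(seq)
  code <- Biostrings::GENETIC_CODE
  rows <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    codons <- substring(seq, f + 3 * (seq_len(ncod) - 1) + 1,
                        f + 3 * seq_len(ncod))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"                      # codons containing N etc.
    is_stop <- aa == "*"
    is_start <- codons == "ATG"
    # segment id increments after each stop
    seg <- cumsum(c(FALSE, utils::head(is_stop, -1)))
    for (sg in unique(seg)) {
      idx <- which(seg == sg)
      starts <- idx[is_start[idx]]
      if (!length(starts)) next
      s0 <- starts[1]
      stop_at <- idx[is_stop[idx]]
      if (length(stop_at)) {
        e0 <- stop_at[1]
        has_stop <- TRUE
        prot <- paste(aa[s0:(e0 - 1)], collapse = "")
        if (e0 == s0) prot <- ""              # ATG cannot be a stop; unreachable
      } else {
        e0 <- idx[length(idx)]
        has_stop <- FALSE
        prot <- paste(aa[s0:e0], collapse = "")
      }
      nt_start <- f + 3 * (s0 - 1)
      nt_end <- f + 3 * e0
      nt_length <- nt_end - nt_start
      if (nt_length < min_nt) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, strand = strand, nt_start = nt_start, nt_end = nt_end,
        nt_length = nt_length, has_stop = has_stop, protein = prot,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_orf_df())
  do.call(rbind, rows)
}

#' Global protein alignment with a permutation null
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' Biostrings), scored in substitution-matrix units. Significance is
#' assessed against composition-preserving shuffles of the query:
#' `p = (1 + #\{shuffle score >= observed\}) / (n_shuffles + 1)`, so
#' `p >= 1 / (n_shuffles + 1)` always.
#'
#' @param query,reference amino-acid strings (standard alphabet plus X).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 / 1).
#' @param n_shuffles permutation count (default 200).
#' @param seed integer seed for the shuffles.
#' @return list of class `alignment_result`: `score`, `p`, `n_shuffles`,
#'   `matrix_name`, `gap_open`, `gap_extend`.
#' @export
align_protein <- function(query, reference, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          n_shuffles = 200, seed = 1L) {
  query <- as.character(query); reference <- as.character(reference)
  if (!nchar(query) || !nchar(reference)) stop("empty sequence")
  qx <- strsplit(query, "")[[1]]
  if (mean(qx == "X") > 0.5) stop("query is > 50% X; uninformative")
  submat <- get_submatrix(matrix)
  sc <- function(q) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(reference),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global", scoreOnly = TRUE)
  }
  observed <- sc(query)
  shuffle_scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) sc(paste(sample(qx), collapse = "")), numeric(1))
  })
  p <- (1 + sum(shuffle_scores >= observed)) / (n_shuffles + 1)
  structure(list(score = observed, p = p, n_shuffles = n_shuffles,
                 matrix_name = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_result")
}

#' @keywords internal
get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: score %.1f (%s, gap %g/%g), p = %.4g (%d shuffles)\n",
              x$score, x$matrix_name, x$gap_open, x$gap_extend, x$p,
              x$n_shuffles))
  invisible(x)
}

#' Classify a LINE-1 element as ORF1p / ORF2p coding
#'
#' An element is ORF1p-coding when it carries an ORF longer than
#' `orf1_min_nt` whose translation aligns to the ORF1p reference with
#' permutation p below `p_threshold`; ORF2p-coding analogously with
#' `orf2_min_nt`. The two flags are independent. Only the
#' `max_candidates` longest ORFs passing each length gate are aligned.
#'
#' @param seq element nucleotide sequence.
#' @param orf1_ref,orf2_ref reference protein sequences (ORF1p: UniProt
#'   Q9UN81; ORF2p: O00370 -- or synthetic stand-ins for testing).
#' @param orf1_min_nt,orf2_min_nt strict length gates in nt (defaults 900 /
#'   3400).
#' @param p_threshold alignment significance gate (default 0.05).
#' @param n_shuffles,seed permutation-null parameters.
#' @param both_strands passed to [find_orfs()].
#' @param max_candidates longest ORFs aligned per gate (default 3).
#' @return list: `orf1_coding`, `orf2_coding`, and `detail` data.frame of
#'   the aligned candidates.
#' @export
classify_line1 <- function(seq, orf1_ref, orf2_ref,
                           orf1_min_nt = 900, orf2_min_nt = 3400,
                           p_threshold = 0.05, n_shuffles = 200,
                           seed = 1L, both_strands = FALSE,
                           max_candidates = 3L) {
  orfs <- find_orfs(seq, min_nt = 3, both_strands = both_strands)
  detail <- list()
  flag_for <- function(min_nt, ref, which_orf) {
    cand <- orfs[orfs$nt_length > min_nt, , drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    # try candidates closest in length to the reference first
    prox <- abs(cand$nt_length / 3 - nchar(ref))
    cand <- utils::head(cand[order(prox), , drop = FALSE], max_candidates)
    hit <- FALSE
    for (i in seq_len(nrow(cand))) {
      al <- align_protein(cand$protein[i], ref, n_shuffles = n_shuffles,
                          seed = seed)
      detail[[length(detail) + 1L]] <<- data.frame(
        orf = which_orf, nt_start = cand$nt_start[i],
        nt_length = cand$nt_length[i], score = al$score, p = al$p)
      if (al$p < p_threshold) { hit <- TRUE; break }
    }
    hit
  }
  orf1 <- flag_for(orf1_min_nt, orf1_ref, "orf1")
  orf2 <- flag_for(orf2_min_nt, orf2_ref, "orf2")
  list(orf1_coding = orf1, orf2_coding = orf2,
       detail = if (length(detail)) do.call(rbind, detail) else NULL)
}

#' Annotate a set of LINE-1 elements from FASTA
#'
#' Runs [classify_line1()] on every sequence and returns a per-element
#' table of the best candidate per ORF and the coding flags.
#'
#' @param elements DNAStringSet (names = element ids) or path to a FASTA.
#' @param orf1_ref,orf2_ref protein references (AAString/character or a
#'   FASTA path containing both, named orf1p/orf2p).
#' @param ... passed to [classify_line1()].
#' @return data.frame: element_id, orf1_length, orf1_score, orf1_p,
#'   orf2_length, orf2_score, orf2_p, orf1_coding, orf2_coding.
#' @export
annotate_line1_set <- function(elements, orf1_ref, orf2_ref, ...) {
  if (is.character(elements) && length(elements) == 1L &&
      file.exists(elements)) {
    elements <- Biostrings::readDNAStringSet(elements)
  }
  orf1_ref <- as.character(orf1_ref); orf2_ref <- as.character(orf2_ref)
  rows <- lapply(names(elements), function(id) {
    cl <- classify_line1(as.character(elements[[id]]), orf1_ref, orf2_ref,
                         ...)
    best <- function(which_orf) {
      d <- cl$detail
      if (is.null(d)) return(c(NA_real_, NA_real_, NA_real_))
      d <- d[d$orf == which_orf, , drop = FALSE]
      if (!nrow(d)) return(c(NA_real_, NA_real_, NA_real_))
      d <- d[order(d$p, -d$score), ][1, ]
      c(d$nt_length, d$score, d$p)
    }
    b1 <- best("orf1"); b2 <- best("orf2")
    data.frame(element_id = id,
               orf1_length = b1[1], orf1_score = b1[2], orf1_p = b1[3],
               orf2_length = b2[1], orf2_score = b2[2], orf2_p = b2[3],
               orf1_coding = cl$orf1_coding, orf2_coding = cl$orf2_coding,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge promoter-activity flags onto transposon loci
#'
#' Flags a locus as having an active promoter when it reciprocally
#' overlaps an interval of the user-supplied active list by at least
#' `min_frac` of both lengths.
#'
#' @param loci GRanges of transposon loci (names = ids).
#' @param active_bed GRanges or path to a BED of active loci.
#' @param min_frac reciprocal-overlap fraction (default 0.5).
#' @return logical vector along `loci`.
#' @export
merge_active_flags <- function(loci, active_bed, min_frac = 0.5) {
  if (is.character(active_bed)) active_bed <- read_bed(active_bed)
  flags <- rep(FALSE, length(loci))
  hits <- GenomicRanges::findOverlaps(loci, active_bed,
                                      ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(loci)[qh],
      GenomicRanges::granges(active_bed)[sh]))
    good <- ov >= min_frac * GenomicRanges::width(loci)[qh] &
      ov >= min_frac * GenomicRanges::width(active_bed)[sh]
    flags[unique(qh[good])] <- TRUE
  }
  flags
}
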