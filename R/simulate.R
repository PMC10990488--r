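#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: gene layout,
#' transposon context mixture, sample design and the injected effects
#' (intron-retention fraction, distance-decaying readthrough fraction,
#' autonomous LINE-1 expression). Two presets: `"aging"` (continuous
#' condition, age 0--96 scaled to [0,1], no read-in effect) and
#' `"senescence"` (two groups, stronger readthrough and a nonzero read-in
#' effect).
#'
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @param preset `"aging"` or `"senescence"`.
#' @param n_chroms,n_genes genome layout; genes are laid out in
#'   `slot_bp`-wide slots so that context bands up to 100 kb never collide
#'   with a neighboring gene.
#' @param slot_bp per-gene slot width (default 300,000).
#' @param exons_per_gene,exon_bp,intron_bp ranges (min, max) for gene
#'   structure.
#' @param n_transposons number of transposon loci.
#' @param context_mixture named proportions over genic, ds5kb, us5kb,
#'   ds100kb, us100kb, intergenic; must sum to 1.
#' @param intronic_within_genic fraction of genic placements that are
#'   intronic (default 0.8, mirroring "most of them intronic").
#' @param te_bp transposon width (default 300 bp; full-length LINE-1s are
#'   6 kb).
#' @param junction_exclusion intronic placements keep this margin from both
#'   splice junctions (default 500 bp).
#' @param n_full_length_l1 number of full-length (6 kb) LINE-1s placed in
#'   roomy contexts.
#' @param n_coding_l1 of these, how many carry a planted ORF1p coding
#'   sequence (every second one also ORF2p).
#' @param active_l1_fraction fraction of full-length LINE-1s flagged as
#'   promoter-active (coding ones always are); active elements receive the
#'   autonomous expression term.
#' @param fraction_isolated fraction of genes with no close downstream
#'   neighbor; the rest get a blocker gene 10 kb past their 3' end so the
#'   isolation filter has something to reject.
#' @param n_samples sample count (aging default 60; senescence halves into
#'   two groups).
#' @param mu_meanlog,mu_sdlog log-normal gene expression baseline.
#' @param dispersion negative-binomial dispersion phi (default 0.1).
#' @param rho_ir,beta_ir intron-retention baseline fraction and effect per
#'   unit condition (log scale).
#' @param rho_rt,lambda,beta_rt readthrough baseline fraction, per-bin decay
#'   rate and effect.
#' @param rho_ri,beta_ri read-in baseline and effect.
#' @param sigma_ir_sample,sigma_rt_sample SD of the per-sample random
#'   effects on intron retention and readthrough (log scale); these model
#'   sample-to-sample variability in splicing fidelity and termination
#'   beyond the condition, and are shared between a defect and the
#'   transposons it carries.
#' @param mu_autonomous,beta_l1 autonomous LINE-1 mean count and effect.
#' @param bg_mu,bg_sdlog per-element background expression (pervasive
#'   transcription / mapping noise): element background means are drawn
#'   log-normal with median `bg_mu` and log-SD `bg_sdlog`, so most
#'   elements are near-silent while a tail is weakly expressed.
#' @param libsize_sdlog per-sample depth variation (log scale).
#' @param sense_fraction strand specificity of generated read intervals.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       preset = c("aging", "senescence"),
                       n_chroms = 2L, n_genes = 60L, slot_bp = 300000L,
                       exons_per_gene = c(4L, 7L),
                       exon_bp = c(150L, 400L),
                       intron_bp = c(1500L, 4000L),
                       n_transposons = 2000L,
                       context_mixture = c(genic = 0.6, ds5kb = 0.05,
                                           us5kb = 0.05, ds100kb = 0.10,
                                           us100kb = 0.10,
                                           intergenic = 0.10),
                       intronic_within_genic = 0.8,
                       te_bp = 300L, junction_exclusion = 500L,
                       n_full_length_l1 = 40L, n_coding_l1 = 12L,
                       active_l1_fraction = 0.6,
                       fraction_isolated = 0.9,
                       n_samples = NULL,
                       mu_meanlog = 5, mu_sdlog = 2,
                       dispersion = 0.1,
                       rho_ir = 0.05, beta_ir = NULL,
                       rho_rt = 0.03, lambda = 0.5, beta_rt = NULL,
                       rho_ri = 0.02, beta_ri = NULL,
                       mu_autonomous = 30, beta_l1 = NULL,
                       sigma_ir_sample = 0.25, sigma_rt_sample = 0.25,
                       bg_mu = 0.2, bg_sdlog = 1.5, libsize_sdlog = 0.2,
                       sense_fraction = 0.9) {
  preset <- match.arg(preset)
  if (is.null(n_samples)) n_samples <- if (preset == "aging") 60L else 24L
  if (is.null(beta_ir)) beta_ir <- 1.5
  if (is.null(beta_rt)) beta_rt <- if (preset == "aging") 1.75 else 2
  if (is.null(beta_ri)) beta_ri <- if (preset == "aging") 0 else 0.5
  if (is.null(beta_l1)) beta_l1 <- if (preset == "aging") 0 else 2
  mix <- context_mixture
  need <- c("genic", "ds5kb", "us5kb", "ds100kb", "us100kb", "intergenic")
  stopifnot(setequal(names(mix), need), abs(sum(mix) - 1) < 1e-8,
            all(mix >= 0), intronic_within_genic >= 0,
            intronic_within_genic <= 1, lambda > 0,
            rho_ir >= 0, rho_ir <= 1, rho_rt >= 0, rho_rt <= 1)
  cfg <- as.list(environment())
  cfg$context_mixture <- mix[need]
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic annotation with ground-truth labels
#'
#' Builds gene models (two transcripts per gene; the full exon chain is the
#' longest), places transposons per the context mixture with enforced
#' geometry so that intended labels are exact ground truth, plants ORF1p /
#' ORF2p coding sequences into a subset of full-length LINE-1 elements, and
#' assigns promoter-activity flags. Intronic placements respect a
#' junction-exclusion zone, emulating the observed transposon depletion at
#' splice junctions. All randomness derives from `cfg$seed`.
#'
#' @param cfg a [sim_config()] object.
#' @param dir optional directory; when given, writes `genes.gtf`,
#'   `transposons.bed`, `chrom.sizes`, `l1_elements_synthetic.fasta`,
#'   `orf_refs_synthetic.fasta`, `active_l1.bed` and `truth.tsv`.
#' @return list: `models` (gene_models), `introns`, `te` (GRanges with
#'   family/subfamily), `truth` (data.frame), `chrom_sizes`,
#'   `l1_sequences` (DNAStringSet), `refs` (orf1p/orf2p character),
#'   `active` (GRanges), `blocker_ids`.
#' @export
generate_annotation <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, generate_annotation_impl(cfg, dir))
}

#' @keywords internal
generate_annotation_impl <- function(cfg, dir) {
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  chrom_len <- (genes_per_chrom + 1L) * cfg$slot_bp
  chrom_sizes <- stats::setNames(rep(chrom_len, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))

  # --- gene structures -----------------------------------------------------
  ex_rows <- list(); gene_rows <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    for (si in seq_len(genes_per_chrom)) {
      gid <- gid + 1L
      if (gid > cfg$n_genes) break
      n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
      exw <- sample(cfg$exon_bp[1]:cfg$exon_bp[2], n_ex, replace = TRUE)
      inw <- sample(cfg$intron_bp[1]:cfg$intron_bp[2],
                    max(n_ex - 1, 0), replace = TRUE)
      glen <- sum(exw) + sum(inw)
      slot_start <- (si - 1L) * cfg$slot_bp + cfg$slot_bp %/% 2L
      gstart <- slot_start + (cfg$slot_bp %/% 2L - glen) %/% 2L
      strand <- sample(c("+", "-"), 1)
      pos <- gstart
      estarts <- integer(n_ex); eends <- integer(n_ex)
      for (j in seq_len(n_ex)) {
        estarts[j] <- pos
        eends[j] <- pos + exw[j] - 1L
        pos <- eends[j] + 1L + if (j < n_ex) inw[j] else 0L
      }
      gene_id <- sprintf("gene%03d", gid)
      gene_rows[[gid]] <- data.frame(
        gene_id = gene_id, chrom = names(chrom_sizes)[ci],
        start = estarts[1], end = eends[n_ex], strand = strand,
        n_exons = n_ex)
      tx1 <- paste0(gene_id, "_tx1")
      df1 <- data.frame(chrom = names(chrom_sizes)[ci], start = estarts,
                        end = eends, strand = strand, gene_id = gene_id,
                        transcript_id = tx1)
      ex_rows[[length(ex_rows) + 1L]] <- df1
      if (n_ex >= 3) {      # a shorter second isoform
        df2 <- df1[seq_len(n_ex - 1L), ]
        df2$transcript_id <- paste0(gene_id, "_tx2")
        ex_rows[[length(ex_rows) + 1L]] <- df2
      }
    }
  }
  genes_df <- do.call(rbind, gene_rows)

  # blocker genes break the isolation filter for a fraction of genes
  n_block <- round((1 - cfg$fraction_isolated) * nrow(genes_df))
  blocker_ids <- character(0)
  if (n_block > 0) {
    victims <- sample(seq_len(nrow(genes_df)), n_block)
    for (v in victims) {
      g <- genes_df[v, ]
      bid <- paste0("blocker_", g$gene_id)
      if (g$strand == "+") {
        bs <- g$end + 10000L + 1L
      } else {
        bs <- g$start - 10000L - 2000L
      }
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = bs, end = bs + 1999L, strand = "+",
        gene_id = bid, transcript_id = paste0(bid, "_tx1"))
      blocker_ids <- c(blocker_ids, bid)
    }
  }
  ex_all <- do.call(rbind, ex_rows)
  exons <- GenomicRanges::GRanges(ex_all$chrom,
                                  IRanges::IRanges(ex_all$start, ex_all$end),
                                  strand = ex_all$strand)
  exons$gene_id <- ex_all$gene_id
  exons$transcript_id <- ex_all$transcript_id
  models <- models_from_exons(exons)
  introns <- derive_introns(models)

  # --- transposon placement ------------------------------------------------
  primary <- setdiff(names(models$genes), blocker_ids)
  isolated <- primary[!primary %in% sub("^blocker_", "", blocker_ids)]
  all_genes <- models$genes
  ctx_draw <- sample(names(cfg$context_mixture), cfg$n_transposons,
                     replace = TRUE, prob = cfg$context_mixture)
  # full-length L1s need roomy contexts
  roomy <- which(ctx_draw %in% c("ds100kb", "us100kb", "intergenic"))
  n_fl <- min(cfg$n_full_length_l1, length(roomy))
  fl_idx <- sort(sample(roomy, n_fl))
  widths <- rep(cfg$te_bp, cfg$n_transposons)
  widths[fl_idx] <- 6000L

  gaps <- intergenic_gaps(all_genes, chrom_sizes, margin = 100000L + 5000L)
  te_list <- vector("list", cfg$n_transposons)
  truth_ctx <- character(cfg$n_transposons)
  truth_gene <- rep(NA_character_, cfg$n_transposons)
  truth_dist <- rep(NA_real_, cfg$n_transposons)
  gmap <- stats::setNames(seq_len(nrow(genes_df)), genes_df$gene_id)
  introns_by_gene <- split(seq_along(introns), introns$gene_id)

  for (i in seq_len(cfg$n_transposons)) {
    ctx <- ctx_draw[i]; w <- widths[i]
    if (ctx == "genic") {
      repeat {
        g <- sample(isolated, 1)
        if (runif(1) < cfg$intronic_within_genic &&
            !is.null(introns_by_gene[[g]])) {
          ii <- introns_by_gene[[g]]
          iw <- GenomicRanges::width(introns)[ii]
          ok <- ii[iw >= 2 * cfg$junction_exclusion + w + 2]
          if (!length(ok)) next
          pick <- if (length(ok) == 1L) ok else sample(ok, 1)
          lo <- GenomicRanges::start(introns)[pick] + cfg$junction_exclusion
          hi <- GenomicRanges::end(introns)[pick] - cfg$junction_exclusion -
            w + 1L
          s <- floor(runif(1, lo, hi + 1))
          truth_ctx[i] <- "intronic"
        } else {
          gi <- gmap[[g]]
          ge <- models$exons[models$exons$gene_id == g]
          pick <- sample(seq_along(ge), 1)
          mid <- (GenomicRanges::start(ge)[pick] +
                    GenomicRanges::end(ge)[pick]) %/% 2L
          s <- mid - w %/% 2L
          truth_ctx[i] <- "genic"
        }
        chrom <- genes_df$chrom[gmap[[g]]]
        truth_gene[i] <- g; truth_dist[i] <- 0
        break
      }
    } else if (ctx %in% c("ds5kb", "us5kb", "ds100kb", "us100kb")) {
      g <- sample(isolated, 1)
      gi <- gmap[[g]]
      chrom <- genes_df$chrom[gi]
      st <- genes_df$strand[gi]
      d_rng <- if (ctx %in% c("ds5kb", "us5kb")) c(1, 5000) else
        c(5001, 100000)
      d <- floor(runif(1, d_rng[1], d_rng[2] + 1))
      downstream <- startsWith(ctx, "ds")
      to_right <- (st == "+") == downstream
      if (to_right) {
        s <- genes_df$end[gi] + d + 1L
      } else {
        s <- genes_df$start[gi] - d - w
      }
      truth_ctx[i] <- ctx
      truth_gene[i] <- g
      truth_dist[i] <- if (downstream) d else -d
    } else {
      pick <- sample(nrow(gaps), 1, prob = gaps$avail)
      s <- floor(runif(1, gaps$lo[pick], gaps$hi[pick] - w + 2))
      chrom <- gaps$chrom[pick]
      truth_ctx[i] <- "intergenic"
    }
    te_list[[i]] <- data.frame(chrom = chrom, start = s,
                               end = s + w - 1L)
  }
  te_df <- do.call(rbind, te_list)
  fams <- sample(c("LINE", "SINE", "LTR", "DNA"), cfg$n_transposons,
                 replace = TRUE, prob = c(0.3, 0.35, 0.2, 0.15))
  fams[fl_idx] <- "LINE"
  te <- GenomicRanges::GRanges(te_df$chrom,
                               IRanges::IRanges(te_df$start, te_df$end),
                               strand = sample(c("+", "-"),
                                               cfg$n_transposons,
                                               replace = TRUE))
  names(te) <- sprintf("te%05d", seq_len(cfg$n_transposons))
  te$family <- fams
  te$subfamily <- ifelse(fams == "LINE", "L1", paste0(fams, "_generic"))
  te$full_length <- seq_len(cfg$n_transposons) %in% fl_idx

  # --- planted coding sequences and promoter flags -------------------------
  refs <- list(orf1p = random_protein(338), orf2p = random_protein(1275))
  n_cod <- min(cfg$n_coding_l1, n_fl)
  coding_idx <- if (n_cod > 0) fl_idx[seq_len(n_cod)] else integer(0)
  orf2_idx <- coding_idx[seq_along(coding_idx) %% 2 == 1]
  l1_idx <- which(te$subfamily == "L1")
  seqs <- lapply(l1_idx, function(i) random_dna(GenomicRanges::width(te)[i]))
  names(seqs) <- names(te)[l1_idx]
  for (i in coding_idx) {
    s <- seqs[[names(te)[i]]]
    ins <- back_translate(refs$orf1p)
    if (i %in% orf2_idx) {
      ins <- paste0(ins, "TAA", back_translate(refs$orf2p))
    }
    ins <- paste0("TAA", ins, "TAA")
    off <- 30L + (sample(0:2, 1))
    substr(s, off + 1L, off + nchar(ins)) <- ins
    seqs[[names(te)[i]]] <- s
  }
  l1_sequences <- Biostrings::DNAStringSet(unlist(seqs))

  fl_all <- which(te$full_length)
  n_active <- round(cfg$active_l1_fraction * length(fl_all))
  active_idx <- unique(c(coding_idx,
                         sample(fl_all, min(n_active, length(fl_all)))))
  te$active_promoter <- seq_along(te) %in% active_idx
  te$orf1_planted <- seq_along(te) %in% coding_idx
  te$orf2_planted <- seq_along(te) %in% orf2_idx
  active <- GenomicRanges::granges(te[active_idx])
  names(active) <- names(te)[active_idx]

  truth <- data.frame(te_id = names(te), context = truth_ctx,
                      nearest_gene_id = truth_gene,
                      signed_distance = truth_dist,
                      family = te$family, subfamily = te$subfamily,
                      full_length = te$full_length,
                      active_promoter = te$active_promoter,
                      orf1_planted = te$orf1_planted,
                      orf2_planted = te$orf2_planted,
                      stringsAsFactors = FALSE)

  ann <- list(models = models, introns = introns, te = te, truth = truth,
              chrom_sizes = chrom_sizes, l1_sequences = l1_sequences,
              refs = refs, active = active, blocker_ids = blocker_ids)
  if (!is.null(dir)) write_annotation_files(ann, dir)
  ann
}

#' @keywords internal
models_from_exons <- function(exons) {
  ex_by_tx <- S4Vectors::split(exons, exons$transcript_id)
  ex_span <- unlist(range(ex_by_tx))
  tx2gene <- vapply(S4Vectors::split(exons$gene_id, exons$transcript_id),
                    function(g) g[[1]], character(1))
  tx_df <- data.frame(
    transcript_id = names(ex_span), gene_id = tx2gene[names(ex_span)],
    chrom = as.character(GenomicRanges::seqnames(ex_span)),
    start = GenomicRanges::start(ex_span),
    end = GenomicRanges::end(ex_span),
    strand = as.character(GenomicRanges::strand(ex_span)),
    span = GenomicRanges::width(ex_span), stringsAsFactors = FALSE)
  by_gene <- S4Vectors::split(exons, exons$gene_id)
  genes <- unlist(range(by_gene))
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

#' @keywords internal
intergenic_gaps <- function(genes, chrom_sizes, margin) {
  rows <- list()
  chrom <- as.character(GenomicRanges::seqnames(genes))
  for (ch in names(chrom_sizes)) {
    i <- which(chrom == ch)
    s <- sort(GenomicRanges::start(genes)[i])
    e <- sort(GenomicRanges::end(genes)[i])
    bounds <- c(0, e)
    nexts <- c(s, chrom_sizes[[ch]] + 1)
    for (k in seq_along(bounds)) {
      lo <- bounds[k] + margin + 1
      hi <- nexts[k] - margin - 1
      if (hi - lo > 1000) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, lo = lo, hi = hi, avail = hi - lo)
      }
    }
  }
  do.call(rbind, rows)
}

#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
random_protein <- function(n) {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  paste(c("M", sample(aas, n - 1, replace = TRUE)), collapse = "")
}

#' Back-translate a protein to a coding sequence (random synonymous codons)
#' @keywords internal
back_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- by_aa[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1)
  }, character(1)), collapse = "")
}

#' @keywords internal
write_annotation_files <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(ann$models, file.path(dir, "genes.gtf"))
  write_bed(ann$te, file.path(dir, "transposons.bed"))
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom.sizes"))
  Biostrings::writeXStringSet(
    ann$l1_sequences, file.path(dir, "l1_elements_synthetic.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(orf1p_synthetic = ann$refs$orf1p,
                              orf2p_synthetic = ann$refs$orf2p)),
    file.path(dir, "orf_refs_synthetic.fasta"))
  write_bed(ann$active, file.path(dir, "active_l1.bed"))
  write_tsv(ann$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Simulate count matrices over a synthetic annotation
#'
#' Draws negative-binomial counts whose intron, readthrough and transposon
#' components are driven by gene expression plus the configured condition
#' effects: gene counts ~ NB(mu_g * L_s), intron counts ~
#' NB(mu_g * rho_IR * exp(beta_IR c_s) * L_s), readthrough bin k ~
#' NB(mu_g * rho_RT * exp(-lambda k) * exp(beta_RT c_s) * L_s), read-in
#' mirrored with its own effect, and transposon counts as the host-driven
#' share (proportional to overlap length over host length) plus a
#' background term and, for promoter-active LINE-1s, an autonomous term
#' NB(mu_aut * exp(beta_L1 c_s) * L_s).
#'
#' @param cfg a [sim_config()].
#' @param ann output of [generate_annotation()].
#' @return list: `metadata` (sample_id, age/group, condition, sex),
#'   `genes`, `introns`, `readthrough`, `readin`, `transposons` (all
#'   `count_matrix`), `rt_regions`, `ri_regions` (GRanges),
#'   `expected` (per-feature base means), `lib_factors`.
#' @export
simulate_counts <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1000000L, simulate_counts_impl(cfg, ann))
}

#' @keywords internal
simulate_counts_impl <- function(cfg, ann) {
  n <- cfg$n_samples
  sample_id <- sprintf("s%03d", seq_len(n))
  if (cfg$preset == "aging") {
    age <- round(runif(n, 0, 96), 1)
    cond <- age / 96
    metadata <- data.frame(sample_id = sample_id, age = age,
                           condition = cond,
                           sex = sample(c("F", "M"), n, replace = TRUE))
  } else {
    group <- rep(c("control", "senescent"), length.out = n)
    cond <- as.numeric(group == "senescent")
    metadata <- data.frame(sample_id = sample_id, group = group,
                           condition = cond,
                           sex = sample(c("F", "M"), n, replace = TRUE))
  }
  L <- exp(rnorm(n, 0, cfg$libsize_sdlog))
  # per-sample defect levels: condition effect plus a sample random effect
  # shared between each defect and the transposons it carries
  f_ir <- exp(cfg$beta_ir * cond + rnorm(n, 0, cfg$sigma_ir_sample))
  f_rt <- exp(cfg$beta_rt * cond + rnorm(n, 0, cfg$sigma_rt_sample))
  f_ri <- exp(cfg$beta_ri * cond + rnorm(n, 0, cfg$sigma_rt_sample))
  f_l1 <- exp(cfg$beta_l1 * cond)
  phi <- cfg$dispersion
  nb <- function(mu) {
    matrix(rnbinom(length(mu), mu = pmax(as.vector(mu), 1e-8),
                   size = 1 / phi),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }
  genes <- ann$models$genes
  genes <- genes[!names(genes) %in% ann$blocker_ids]
  G <- length(genes)
  mu_g <- stats::rlnorm(G, cfg$mu_meanlog, cfg$mu_sdlog)
  names(mu_g) <- names(genes)

  base <- function(mu_vec) outer(mu_vec, L)   # features x samples

  gene_mu <- base(mu_g)
  colnames(gene_mu) <- sample_id
  gene_cm <- count_matrix(nb(gene_mu), "gene", GenomicRanges::width(genes))

  introns <- ann$introns[ann$introns$gene_id %in% names(genes)]
  int_mu <- base(mu_g[introns$gene_id] * cfg$rho_ir) *
    rep(f_ir, each = length(introns))
  rownames(int_mu) <- introns$intron_id; colnames(int_mu) <- sample_id
  intron_cm <- count_matrix(nb(int_mu), "intron",
                            GenomicRanges::width(introns))

  pr_models <- models_subset(ann$models, names(genes))
  rt_regions <- build_flank_regions(pr_models, "readthrough",
                                    chrom_sizes = ann$chrom_sizes)
  # neighbor gaps must see blockers: recompute validity on the full model
  rt_regions$valid <- flank_validity(rt_regions, ann$models$genes)
  ri_regions <- build_flank_regions(pr_models, "readin",
                                    chrom_sizes = ann$chrom_sizes)
  ri_regions$valid <- flank_validity(ri_regions, ann$models$genes)

  flank_mu <- function(regions, rho, f_cond) {
    m <- base(mu_g[regions$gene_id] * rho *
                exp(-cfg$lambda * regions$bin_index)) *
      rep(f_cond, each = length(regions))
    rownames(m) <- regions$region_id; colnames(m) <- sample_id
    m
  }
  rt_mu <- flank_mu(rt_regions, cfg$rho_rt, f_rt)
  ri_mu <- flank_mu(ri_regions, cfg$rho_ri, f_ri)
  rt_cm <- count_matrix(nb(rt_mu), "readthrough",
                        GenomicRanges::width(rt_regions))
  ri_cm <- count_matrix(nb(ri_mu), "readin",
                        GenomicRanges::width(ri_regions))

  # transposons: host-driven share + background + autonomous term
  tr <- ann$truth
  w <- GenomicRanges::width(ann$te)
  host_mu <- matrix(0, nrow = nrow(tr), ncol = n)
  iw <- stats::setNames(GenomicRanges::width(introns), introns$intron_id)
  gene_len <- stats::setNames(GenomicRanges::width(genes), names(genes))
  # map intronic transposons to their host intron (containment)
  host_intron <- rep(NA_character_, nrow(tr))
  ov <- GenomicRanges::findOverlaps(ann$te, introns, type = "within",
                                    ignore.strand = TRUE)
  host_intron[S4Vectors::queryHits(ov)] <-
    introns$intron_id[S4Vectors::subjectHits(ov)]
  for (i in seq_len(nrow(tr))) {
    g <- tr$nearest_gene_id[i]
    if (is.na(g) || !g %in% names(mu_g)) next
    share <- switch(
      tr$context[i],
      genic = mu_g[[g]] * (w[i] / gene_len[[g]]) %o% L,
      intronic = if (!is.na(host_intron[i])) {
        (mu_g[[g]] * cfg$rho_ir * (w[i] / iw[[host_intron[i]]])) %o%
          (L * f_ir)
      } else NULL,
      ds5kb = ,
      ds100kb = {
        k <- min(abs(tr$signed_distance[i]) %/% 10000, 9)
        (mu_g[[g]] * cfg$rho_rt * exp(-cfg$lambda * k) * (w[i] / 10000)) %o%
          (L * f_rt)
      },
      us5kb = ,
      us100kb = {
        k <- min(abs(tr$signed_distance[i]) %/% 10000, 9)
        (mu_g[[g]] * cfg$rho_ri * exp(-cfg$lambda * k) * (w[i] / 10000)) %o%
          (L * f_ri)
      },
      NULL)
    if (!is.null(share)) host_mu[i, ] <- share
  }
  bg_i <- stats::rlnorm(nrow(tr), log(cfg$bg_mu), cfg$bg_sdlog)
  te_mu <- host_mu + bg_i %o% L
  aut <- tr$active_promoter
  if (any(aut)) {
    te_mu[aut, ] <- te_mu[aut, ] +
      (cfg$mu_autonomous * rep(1, sum(aut))) %o% (L * f_l1)
  }
  rownames(te_mu) <- tr$te_id; colnames(te_mu) <- sample_id
  te_cm <- count_matrix(nb(te_mu), "transposon", w)

  list(metadata = metadata, genes = gene_cm, introns = intron_cm,
       readthrough = rt_cm, readin = ri_cm, transposons = te_cm,
       rt_regions = rt_regions, ri_regions = ri_regions,
       host_intron = host_intron,
       expected = list(gene_mu = mu_g), lib_factors = L)
}

#' @keywords internal
models_subset <- function(models, gene_ids) {
  out <- list(
    genes = models$genes[names(models$genes) %in% gene_ids],
    exons = models$exons[models$exons$gene_id %in% gene_ids],
    transcripts = models$transcripts[
      models$transcripts$gene_id %in% gene_ids, ],
    longest_tx = models$longest_tx[names(models$longest_tx) %in% gene_ids])
  class(out) <- "gene_models"
  out
}

#' Recompute flank-region validity against a (possibly larger) gene set
#' @keywords internal
flank_validity <- function(regions, genes, isolation_bp = 20000) {
  genes_u <- genes
  GenomicRanges::strand(genes_u) <- "*"
  overlaps_gene <- GenomicRanges::countOverlaps(regions, genes_u,
                                                ignore.strand = TRUE) > 0
  gaps <- neighbor_gaps(genes)
  gidx <- match(regions$gene_id, names(genes))
  st <- as.character(GenomicRanges::strand(genes))[gidx]
  st[st == "*"] <- "+"
  going_right <- if (unique(regions$direction) == "readthrough") {
    st == "+"
  } else {
    st == "-"
  }
  side_gap <- ifelse(going_right, gaps$right[gidx], gaps$left[gidx])
  regions$valid & !overlaps_gene & side_gap >= isolation_bp
}

#' Generate per-sample read intervals realizing a count matrix
#'
#' For each feature and sample, draws `count` read intervals of `read_bp`
#' uniformly within the feature (clipped to its width). Read strand equals
#' the feature strand with probability `sense_fraction`. Intended for
#' small fixtures exercising the interval counter.
#'
#' @param features GRanges with names matching `cm` features.
#' @param cm a `count_matrix`.
#' @param read_bp read length (default 100).
#' @param sense_fraction probability a read is sense (default 0.9).
#' @param seed integer seed.
#' @return named list of GRanges, one per sample.
#' @export
reads_from_counts <- function(features, cm, read_bp = 100,
                              sense_fraction = 0.9, seed = 1L) {
  stopifnot(all(rownames(cm$counts) %in% names(features)))
  features <- features[rownames(cm$counts)]
  with_seed(seed, {
    lapply(stats::setNames(nm = colnames(cm$counts)), function(s) {
      counts <- cm$counts[, s]
      idx <- rep(seq_along(features), counts)
      if (!length(idx)) return(GenomicRanges::GRanges())
      fw <- GenomicRanges::width(features)[idx]
      rl <- pmin(read_bp, fw)
      off <- floor(runif(length(idx)) * (fw - rl + 1))
      st0 <- as.character(GenomicRanges::strand(features))[idx]
      st0[st0 == "*"] <- "+"
      flip <- runif(length(idx)) > sense_fraction
      st <- ifelse(flip, ifelse(st0 == "+", "-", "+"), st0)
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(features)[idx],
        IRanges::IRanges(GenomicRanges::start(features)[idx] + off,
                         width = rl),
        strand = st)
    })
  })
}
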