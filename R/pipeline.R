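#' Default pipeline configuration
#'
#' Returns the full configuration template; user configs may override any
#' subset of these keys (unknown keys are rejected). `mode = "simulate"`
#' generates synthetic inputs from `simulate`; `mode = "files"` reads the
#' annotation and count tables named under `input`.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    simulate = list(preset = "aging"),
    input = list(gtf = NULL, te_bed = NULL, metadata = NULL,
                 condition = "condition", covariates = character(0),
                 gene_counts = NULL, te_counts = NULL,
                 intron_counts = NULL, readthrough_counts = NULL,
                 l1_fasta = NULL, refs_fasta = NULL, active_bed = NULL),
    params = list(pseudocount = 1, top_n = 1000L, outlier_n = 250L,
                  isolation_bp = 20000L, bin_size = 10000L, n_bins = 10L,
                  min_count = 5, min_prop = 0.25, rt_min_mean = 1,
                  eps = 1e-6, p_threshold = 0.05, intronic_frac = 0.5,
                  orf1_min_nt = 900L, orf2_min_nt = 3400L,
                  n_shuffles = 200L),
    stages = list(classify = TRUE, quantify = TRUE, de = TRUE,
                  correlate = TRUE, line1 = TRUE, enrichment = TRUE)
  )
}

#' @keywords internal
merge_config <- function(user, template = default_config(),
                         path = "config") {
  if (is.null(user)) return(template)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        k != "simulate") {
      template[[k]] <- merge_config(user[[k]], template[[k]],
                                    paste0(path, "$", k))
    } else {
      template[[k]] <- user[[k]]
    }
  }
  template
}

#' Run the full analysis pipeline
#'
#' Executes classify -> quantify -> differential expression -> per-sample
#' scores -> correlations -> LINE-1 annotation -> enrichment, and writes
#' report tables (context fractions, sample scores, correlation and
#' model-comparison tables, distance histogram, flank decay profile,
#' enrichment summary, LINE-1 ORF table) plus a run manifest to `outdir`.
#' Identical config and inputs give identical outputs.
#'
#' @param config a nested list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @param outdir output directory (created).
#' @return invisibly, a list with all intermediate objects and a `files`
#'   vector of written reports.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    rm_log(...)
  }
  yaml::write_yaml(cfg, file.path(outdir, "config_used.yaml"))
  res <- list(config = cfg)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  P <- cfg$params

  # ---- inputs -------------------------------------------------------------
  if (cfg$mode == "simulate") {
    say("stage simulate")
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    ann <- generate_annotation(scfg)
    sim <- simulate_counts(scfg, ann)
    models <- ann$models
    te <- ann$te
    metadata <- sim$metadata
    condition <- "condition"
    covariates <- character(0)
    gene_cm <- sim$genes; te_cm <- sim$transposons
    intron_cm <- sim$introns; rt_cm <- sim$readthrough
    rt_regions <- sim$rt_regions
    res$ann <- ann; res$sim <- sim
  } else if (cfg$mode == "files") {
    say("stage load")
    inp <- cfg$input
    for (need in c("gtf", "te_bed", "metadata", "gene_counts",
                   "te_counts")) {
      if (is.null(inp[[need]])) stop("input$", need, " is required")
    }
    models <- load_annotation(inp$gtf)
    te <- read_bed(inp$te_bed)
    metadata <- read_tsv(inp$metadata)
    condition <- inp$condition
    covariates <- inp$covariates
    gene_cm <- read_count_matrix(inp$gene_counts)
    te_cm <- read_count_matrix(inp$te_counts)
    intron_cm <- if (!is.null(inp$intron_counts)) {
      read_count_matrix(inp$intron_counts)
    }
    rt_cm <- if (!is.null(inp$readthrough_counts)) {
      read_count_matrix(inp$readthrough_counts)
    }
    rt_regions <- build_flank_regions(models, "readthrough",
                                      bin_size = P$bin_size,
                                      n_bins = P$n_bins,
                                      isolation_bp = P$isolation_bp)
    ann <- NULL; sim <- NULL
  } else {
    stop("mode must be 'simulate' or 'files'")
  }

  # ---- classify -----------------------------------------------------------
  if (isTRUE(cfg$stages$classify)) {
    say("stage classify")
    cls <- classify_transposon(te, models,
                               intronic_frac = P$intronic_frac)
    res$classification <- cls
    emit(summarize_context_fractions(cls), "context_fractions.tsv")
    emit(distance_histogram(cls), "distance_histogram.tsv")
  } else {
    cls <- classify_transposon(te, models,
                               intronic_frac = P$intronic_frac)
    res$classification <- cls
  }
  te_gene_map <- data.frame(element_id = cls$te_id,
                            gene_id = cls$nearest_gene_id)

  # ---- quantify: filters, size factors, scores ----------------------------
  say("stage quantify")
  gene_f <- filter_low_counts(gene_cm, P$min_count, P$min_prop)
  te_f <- filter_low_counts(te_cm, P$min_count, P$min_prop)
  sf <- size_factors(gene_f)
  res$size_factors <- sf

  # ---- differential expression --------------------------------------------
  de <- list()
  if (isTRUE(cfg$stages$de)) {
    say("stage de")
    de$gene <- differential_expression(gene_f, metadata, condition,
                                       covariates, sf = sf)
    de$transposon <- differential_expression(te_f, metadata, condition,
                                             covariates, sf = sf)
    if (!is.null(intron_cm)) {
      intron_f <- filter_low_counts(intron_cm, P$min_count, P$min_prop)
      de$intron <- differential_expression(intron_f, metadata, condition,
                                           covariates, sf = sf)
    }
    res$de <- de
    emit(do.call(rbind, de), "de_results.tsv")
  }

  # ---- per-sample scores --------------------------------------------------
  scores <- list()
  if (isTRUE(cfg$stages$quantify) && length(de)) {
    top_te <- select_top(de$transposon, P$top_n, overexpressed = TRUE)
    te_norm <- nearest_gene_normalize(te_f, gene_cm, te_gene_map,
                                      pseudocount = P$pseudocount,
                                      sf = sf)
    scores$transposon <- per_sample_score(
      te_norm, intersect(top_te$feature_id, rownames(te_norm)),
      "transposon")
    if (!is.null(de$intron)) {
      imap <- data.frame(element_id = de$intron$feature_id,
                         gene_id = sub("_intron_\\d+$", "",
                                       de$intron$feature_id))
      top_ir <- select_top(de$intron, P$top_n, overexpressed = TRUE)
      ir_norm <- nearest_gene_normalize(
        subset_features(intron_cm, de$intron$feature_id), gene_cm, imap,
        pseudocount = P$pseudocount, sf = sf)
      scores$intron <- per_sample_score(
        ir_norm, intersect(top_ir$feature_id, rownames(ir_norm)),
        "intron")
    }
    if (!is.null(rt_cm)) {
      bin1 <- rt_regions[rt_regions$bin_index == 1 & rt_regions$valid]
      keep <- rownames(rt_cm$counts) %in% bin1$region_id &
        rowMeans(rt_cm$counts) >= P$rt_min_mean
      rt1 <- count_matrix(rt_cm$counts[keep, , drop = FALSE],
                          "readthrough", rt_cm$features$length[keep])
      rg <- rt_regions$gene_id[match(rownames(rt1$counts),
                                     rt_regions$region_id)]
      rr <- readthrough_ratio(rt1, gene_f, rg, sf = sf, eps = P$eps)
      scores$readthrough <- rr$per_sample
      res$rt_per_gene <- rr$per_gene
      # whole-window decay profile over valid regions
      keep_all <- rownames(rt_cm$counts) %in%
        rt_regions$region_id[rt_regions$valid]
      rt_all <- count_matrix(rt_cm$counts[keep_all, , drop = FALSE],
                             "readthrough",
                             rt_cm$features$length[keep_all])
      idx <- match(rownames(rt_all$counts), rt_regions$region_id)
      prof <- flank_profile(rt_all, gene_f, rt_regions$gene_id[idx],
                            rt_regions$bin_index[idx], sf = sf,
                            eps = P$eps)
      emit(prof, "flank_profile.tsv")
    }
    res$scores <- scores
    emit(do.call(rbind, scores), "sample_scores.tsv")
  }

  # ---- correlations -------------------------------------------------------
  if (isTRUE(cfg$stages$correlate) && length(scores) >= 2) {
    say("stage correlate")
    cors <- list()
    cond_vec <- stats::setNames(
      as.numeric(metadata[[condition]][
        match(scores$transposon$sample_id, metadata$sample_id)]),
      scores$transposon$sample_id)
    if (!is.null(scores$intron)) {
      cors$te_ir <- sample_correlation(scores$transposon, scores$intron,
                                       x_name = "transposon",
                                       y_name = "intron")
    }
    if (!is.null(scores$readthrough)) {
      cors$te_rt <- sample_correlation(scores$transposon,
                                       scores$readthrough,
                                       x_name = "transposon",
                                       y_name = "readthrough")
      cors$rt_cond <- sample_correlation(scores$readthrough, cond_vec,
                                         x_name = "readthrough",
                                         y_name = "condition")
    }
    cors$te_cond <- sample_correlation(scores$transposon, cond_vec,
                                       x_name = "transposon",
                                       y_name = "condition")
    res$correlations <- do.call(rbind, cors)
    emit(res$correlations, "correlations.tsv")
    if (!is.null(scores$intron) && !is.null(scores$readthrough)) {
      res$partial <- partial_correlation(scores$transposon,
                                         scores$readthrough,
                                         scores$intron)
      res$nested <- nested_model_test(scores$transposon, scores$intron,
                                      scores$readthrough)
      emit(cbind(res$nested,
                 partial_r = res$partial$r, partial_p = res$partial$p),
           "model_comparison.tsv")
    }
  }

  # ---- LINE-1 annotation --------------------------------------------------
  active_flags <- NULL
  if (isTRUE(cfg$stages$line1)) {
    say("stage line1")
    l1_seqs <- if (cfg$mode == "simulate") ann$l1_sequences else {
      if (!is.null(cfg$input$l1_fasta)) {
        Biostrings::readDNAStringSet(cfg$input$l1_fasta)
      }
    }
    refs <- if (cfg$mode == "simulate") ann$refs else {
      if (!is.null(cfg$input$refs_fasta)) {
        rf <- Biostrings::readAAStringSet(cfg$input$refs_fasta)
        list(orf1p = as.character(rf[[1]]), orf2p = as.character(rf[[2]]))
      }
    }
    if (!is.null(l1_seqs) && !is.null(refs)) {
      res$line1 <- annotate_line1_set(
        l1_seqs, refs$orf1p, refs$orf2p,
        orf1_min_nt = P$orf1_min_nt, orf2_min_nt = P$orf2_min_nt,
        p_threshold = P$p_threshold, n_shuffles = P$n_shuffles,
        seed = cfg$seed)
      emit(res$line1, "line1_orf.tsv")
    }
    active_src <- if (cfg$mode == "simulate") ann$active else {
      if (!is.null(cfg$input$active_bed)) read_bed(cfg$input$active_bed)
    }
    if (!is.null(active_src)) {
      active_flags <- stats::setNames(merge_active_flags(te, active_src),
                                      names(te))
    }
  }

  # ---- enrichment ---------------------------------------------------------
  if (isTRUE(cfg$stages$enrichment) && length(de) &&
      !is.null(active_flags)) {
    say("stage enrichment")
    is_l1 <- te$subfamily == "L1"
    l1_ids <- names(te)[is_l1]
    expressed <- intersect(de$transposon$feature_id, l1_ids)
    sig_all <- de$transposon$feature_id[de$transposon$p < P$p_threshold]
    out <- outlier_selection(de$transposon, de$gene, te_gene_map,
                             n = P$outlier_n,
                             p_threshold = P$p_threshold)
    res$outliers <- out
    if (length(expressed) >= 3) {
      res$enrichment <- enrichment_summary(
        intersect(out$feature_id, expressed),
        intersect(sig_all, expressed),
        expressed, active_flags)
      emit(res$enrichment, "enrichment.tsv")
    }
  }

  say("done")
  manifest <- list(
    package_version = as.character(utils::packageVersion("retromark")),
    r_version = as.character(getRversion()),
    seed = cfg$seed, mode = cfg$mode, params = cfg$params,
    stages = cfg$stages, outputs = basename(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$files <- files
  invisible(res)
}
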