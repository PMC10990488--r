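#' Simplified differential expression by OLS on log2 normalized counts
#'
#' Fits ordinary least squares of `y = log2(count / size factor + 1)` on a
#' design with one condition term plus optional categorical covariates, for
#' every feature at once. The condition may be a two-level factor
#' (senescent vs control; the log2 fold change is the group coefficient) or
#' continuous (age; centered and scaled, so the reported fold change is per
#' 1 SD of the condition). P-values come from the coefficient t-statistic;
#' adjustment is Benjamini-Hochberg within each feature class. This is a
#' deliberately simple, dependency-free statistic: absolute p-values differ
#' from a negative-binomial engine, but ranking and correlation structure
#' are preserved.
#'
#' @param cm a `count_matrix` (any mix of classes).
#' @param metadata data.frame with `sample_id` plus condition/covariates;
#'   rows matched to `cm` columns by `sample_id`.
#' @param condition name of the condition column in `metadata`.
#' @param covariates character vector of covariate column names.
#' @param sf per-sample size factors (total-count-free median-of-ratios
#'   from `cm`'s gene rows when `NULL`; pass gene-derived factors when `cm`
#'   has no genes).
#' @return data.frame per feature: `feature_id`, `feature_class`, `lfc`,
#'   `p`, `padj`, `mean_norm_count`.
#' @export
differential_expression <- function(cm, metadata, condition,
                                    covariates = character(0), sf = NULL) {
  stopifnot("sample_id" %in% names(metadata))
  md <- metadata[match(colnames(cm$counts), metadata$sample_id), ,
                 drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing some samples")
  cond <- md[[condition]]
  if (is.numeric(cond)) {
    cond <- as.numeric(scale(cond))
  } else {
    cond <- factor(cond)
    if (nlevels(cond) != 2L) {
      stop("categorical condition must have exactly 2 levels")
    }
  }
  df <- data.frame(.cond = cond)
  for (cv in covariates) df[[cv]] <- md[[cv]]
  X <- stats::model.matrix(
    stats::as.formula(paste("~ .cond +",
                            paste(c("1", covariates), collapse = " + "))),
    data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  if (is.null(sf)) {
    gsel <- cm$features$class == "gene"
    ref <- if (any(gsel)) {
      count_matrix(cm$counts[gsel, , drop = FALSE], "gene",
                   cm$features$length[gsel])
    } else cm
    sf <- size_factors(ref)
  }
  norm <- t(t(cm$counts) / sf)
  Y <- t(log2(norm + 1))                      # samples x features
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("not enough samples for the design")
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- solve(crossprod(X))
  ci <- which(colnames(X) %in% c(".cond", ".cond2") |
                startsWith(colnames(X), ".cond"))[1]
  se <- sqrt(sigma2 * XtXinv[ci, ci])
  tval <- beta[ci, ] / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  # numerically perfect fits: p collapses to 0 or 1 by the coefficient
  degen <- sigma2 <= 1e-16
  pval[degen] <- ifelse(abs(beta[ci, degen]) < 1e-8, 1, 0)
  out <- data.frame(
    feature_id = cm$features$feature_id,
    feature_class = cm$features$class,
    lfc = as.numeric(beta[ci, ]),
    p = as.numeric(pval),
    mean_norm_count = rowMeans(norm),
    stringsAsFactors = FALSE
  )
  out$padj <- stats::ave(out$p, out$feature_class,
                         FUN = function(x) stats::p.adjust(x, "BH"))
  out[, c("feature_id", "feature_class", "lfc", "p", "padj",
          "mean_norm_count")]
}

#' Select the top-N features per class
#'
#' Within each feature class, ranks by adjusted p ascending, then by
#' absolute fold change descending, then by feature id, and returns the
#' first `n`. With `overexpressed = TRUE` only positive fold changes are
#' eligible (the selection used before nearest-gene normalization).
#'
#' @param results data.frame from [differential_expression()].
#' @param n number per class (default 1000).
#' @param overexpressed restrict to `lfc > 0` first.
#' @return data.frame subset of `results`, ranked.
#' @export
select_top <- function(results, n = 1000, overexpressed = FALSE) {
  if (!nrow(results)) stop("empty results")
  pick <- lapply(split(results, results$feature_class), function(d) {
    if (overexpressed) d <- d[d$lfc > 0, , drop = FALSE]
    d <- d[order(d$padj, -abs(d$lfc), d$feature_id), , drop = FALSE]
    utils::head(d, n)
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}

#' Transposons with higher-than-expected expression changes
#'
#' Restricts to transposons significant at `p_threshold`, regresses their
#' log2 fold change on the fold change of the nearest gene (OLS with
#' intercept) and returns the `n` loci with the largest positive residuals
#' -- the candidates whose expression change is not explained by the
#' neighboring gene.
#'
#' @param tx_results DE results for transposons.
#' @param gene_results DE results for genes.
#' @param mapping data.frame `element_id`, `gene_id` (nearest gene).
#' @param n outlier count (default 250).
#' @param p_threshold unadjusted significance gate (default 0.05).
#' @return data.frame of selected transposons with `residual`, ranked
#'   descending.
#' @export
outlier_selection <- function(tx_results, gene_results, mapping, n = 250,
                              p_threshold = 0.05) {
  sig <- tx_results[tx_results$p < p_threshold, , drop = FALSE]
  m <- mapping[match(sig$feature_id, mapping$element_id), ]
  g <- gene_results[match(m$gene_id, gene_results$feature_id), ]
  ok <- !is.na(g$lfc)
  sig <- sig[ok, , drop = FALSE]; g <- g[ok, , drop = FALSE]
  if (!nrow(sig)) stop("no significant transposons with a mapped gene")
  x <- g$lfc; y <- sig$lfc
  if (stats::var(x) == 0) {
    resid <- y - mean(y)
  } else {
    fit <- stats::lm.fit(cbind(1, x), y)
    resid <- fit$residuals
  }
  sig$nearest_gene_lfc <- x
  sig$residual <- resid
  sig <- sig[order(-sig$residual, sig$feature_id), , drop = FALSE]
  if (nrow(sig) < n) {
    rm_log("only ", nrow(sig), " significant transposons; returning all")
  }
  out <- utils::head(sig, n)
  rownames(out) <- NULL
  out
}

#' Enrichment of flagged (active/coding) elements in a target set
#'
#' One-sided Fisher exact test (alternative "greater") on the 2x2 table of
#' active vs inactive by in-set vs out-of-set, with the background being
#' the "all expressed" universe.
#'
#' @param target_set character vector of element ids (subset of background).
#' @param background_set character vector of element ids.
#' @param active_flags named logical vector over (at least) the background.
#' @param set_name label for the output row.
#' @return data.frame: `set_name`, `k_active`, `n_set`,
#'   `K_active_background`, `N_background`, `pct_active`, `odds_ratio`, `p`.
#' @export
enrichment_test <- function(target_set, background_set, active_flags,
                            set_name = "target") {
  if (!length(target_set)) stop("empty target set")
  stopifnot(all(target_set %in% background_set))
  fl <- active_flags[background_set]
  stopifnot(!anyNA(fl))
  in_set <- background_set %in% target_set
  k <- sum(fl & in_set); n <- sum(in_set)
  K <- sum(fl); N <- length(background_set)
  tab <- matrix(c(k, n - k, K - k, (N - K) - (n - k)), nrow = 2,
                byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "greater")
  data.frame(set_name = set_name, k_active = k, n_set = n,
             K_active_background = K, N_background = N,
             pct_active = 100 * k / n,
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             stringsAsFactors = FALSE)
}

#' Three-row enrichment summary (outliers / significant / all expressed)
#'
#' @param outliers,significant,expressed character vectors of element ids,
#'   nested or not; `expressed` is the background.
#' @param active_flags named logical over `expressed`.
#' @return data.frame with one row per set; p-values compare each set with
#'   the expressed background.
#' @export
enrichment_summary <- function(outliers, significant, expressed,
                               active_flags) {
  rbind(
    enrichment_test(intersect(outliers, expressed), expressed,
                    active_flags, "outliers"),
    enrichment_test(intersect(significant, expressed), expressed,
                    active_flags, "significant"),
    enrichment_test(expressed, expressed, active_flags, "all_expressed")
  )
}
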