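#' Correlate two per-sample score vectors
#'
#' Pearson (default) or Spearman correlation between two per-sample
#' statistics (e.g. transposon score vs intron-retention score), with a
#' two-sided p-value from the t transform.
#'
#' @param x,y data.frames with `sample_id` and `value` (as returned by
#'   [per_sample_score()] / [readthrough_ratio()]), or plain named numeric
#'   vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @param x_name,y_name labels for the output.
#' @return data.frame: `x_name`, `y_name`, `method`, `r`, `p`, `n`.
#' @export
sample_correlation <- function(x, y, method = c("pearson", "spearman"),
                               x_name = "x", y_name = "y") {
  method <- match.arg(method)
  xv <- score_vector(x); yv <- score_vector(y)
  common <- intersect(names(xv), names(yv))
  if (length(common) < 3L) stop("need at least 3 matched samples")
  xv <- xv[common]; yv <- yv[common]
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop("zero variance in one of the inputs")
  }
  ct <- stats::cor.test(xv, yv, method = method, exact = FALSE)
  data.frame(x_name = x_name, y_name = y_name, method = method,
             r = unname(ct$estimate), p = ct$p.value, n = length(common),
             stringsAsFactors = FALSE)
}

#' @keywords internal
score_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample_id", "value") %in% names(x)))
    stats::setNames(x$value, x$sample_id)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Correlate element and container log2 fold changes locus by locus
#'
#' Pairs each element (e.g. an intronic transposon) with its container
#' (host intron or downstream readthrough region) through `mapping` and
#' correlates the paired fold changes. `scope = "shuffled"` permutes the
#' pairing with a fixed seed as a negative control.
#'
#' @param element_results,container_results DE result data.frames.
#' @param mapping data.frame `element_id`, `container_id`.
#' @param scope `"matched"` (default) or `"shuffled"`.
#' @param seed seed for the shuffled control.
#' @param method correlation estimator.
#' @return data.frame as in [sample_correlation()].
#' @export
locus_lfc_correlation <- function(element_results, container_results,
                                  mapping, scope = c("matched", "shuffled"),
                                  seed = 1L,
                                  method = c("pearson", "spearman")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  el <- element_results$lfc[match(mapping$element_id,
                                  element_results$feature_id)]
  co <- container_results$lfc[match(mapping$container_id,
                                    container_results$feature_id)]
  ok <- !is.na(el) & !is.na(co)
  el <- el[ok]; co <- co[ok]
  if (length(el) < 3L) stop("need at least 3 mapped pairs")
  if (scope == "shuffled") {
    co <- with_seed(seed, sample(co))
  }
  ct <- stats::cor.test(el, co, method = method, exact = FALSE)
  data.frame(x_name = "element_lfc", y_name = paste0("container_lfc_",
                                                     scope),
             method = method, r = unname(ct$estimate), p = ct$p.value,
             n = length(el), stringsAsFactors = FALSE)
}

#' Within-sample correlation of element and container counts
#'
#' For each sample, correlates element counts with mapped container counts
#' across loci; reports one r per sample.
#'
#' @param element_cm,container_cm `count_matrix` objects on the same
#'   samples.
#' @param mapping data.frame `element_id`, `container_id`.
#' @param method correlation estimator.
#' @param shuffled permute the mapping (seeded) as a negative control.
#' @param seed seed for the shuffled control.
#' @return data.frame: `sample_id`, `r`, `p`, `n`.
#' @export
per_sample_count_correlation <- function(element_cm, container_cm, mapping,
                                         method = c("pearson", "spearman"),
                                         shuffled = FALSE, seed = 1L) {
  method <- match.arg(method)
  stopifnot(identical(colnames(element_cm$counts),
                      colnames(container_cm$counts)))
  el_id <- mapping$element_id[mapping$element_id %in%
                                rownames(element_cm$counts) &
                              mapping$container_id %in%
                                rownames(container_cm$counts)]
  co_id <- mapping$container_id[match(el_id, mapping$element_id)]
  if (length(el_id) < 3L) stop("need at least 3 mapped pairs")
  if (shuffled) co_id <- with_seed(seed, sample(co_id))
  el <- element_cm$counts[el_id, , drop = FALSE]
  co <- container_cm$counts[co_id, , drop = FALSE]
  out <- lapply(colnames(el), function(s) {
    if (stats::var(el[, s]) == 0 || stats::var(co[, s]) == 0) {
      return(data.frame(sample_id = s, r = NA_real_, p = NA_real_,
                        n = nrow(el)))
    }
    ct <- stats::cor.test(el[, s], co[, s], method = method, exact = FALSE)
    data.frame(sample_id = s, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(el))
  })
  do.call(rbind, out)
}

#' First-order partial correlation
#'
#' Correlation between x and y controlling for z:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided p from the t transform on n - 3 degrees of freedom.
#'
#' @param x,y,z per-sample score data.frames or named numeric vectors.
#' @return data.frame: `r`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  xv <- score_vector(x); yv <- score_vector(y); zv <- score_vector(z)
  common <- Reduce(intersect, list(names(xv), names(yv), names(zv)))
  if (length(common) < 4L) stop("need at least 4 matched samples")
  xv <- xv[common]; yv <- yv[common]; zv <- zv[common]
  r_xy <- stats::cor(xv, yv)
  r_xz <- stats::cor(xv, zv)
  r_yz <- stats::cor(yv, zv)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("z fully explains one of the variables")
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  n <- length(common)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  data.frame(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 3), n = n)
}

#' Nested linear-model comparison (F-test)
#'
#' Compares OLS of y on [1, x1] against y on [1, x1, x2]:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 3))` with p from
#' F(1, n - 3). Used to ask whether readthrough adds predictive value for
#' transposon expression beyond intron retention.
#'
#' @param y,x1,x2 per-sample score data.frames or named numeric vectors.
#' @return data.frame: `rss_reduced`, `rss_full`, `df_reduced`, `df_full`,
#'   `F`, `p`, `n`.
#' @export
nested_model_test <- function(y, x1, x2) {
  yv <- score_vector(y); x1v <- score_vector(x1); x2v <- score_vector(x2)
  common <- Reduce(intersect, list(names(yv), names(x1v), names(x2v)))
  n <- length(common)
  if (n <= 3L) stop("need more than 3 matched samples")
  yv <- yv[common]; x1v <- x1v[common]; x2v <- x2v[common]
  if (abs(stats::cor(x1v, x2v)) > 0.999) {
    stop("x2 is collinear with x1")
  }
  rss <- function(X) {
    fit <- stats::lm.fit(X, yv)
    sum(fit$residuals^2)
  }
  rss_r <- rss(cbind(1, x1v))
  rss_f <- rss(cbind(1, x1v, x2v))
  Fstat <- (rss_r - rss_f) / (rss_f / (n - 3))
  data.frame(rss_reduced = rss_r, rss_full = rss_f,
             df_reduced = n - 2, df_full = n - 3,
             F = Fstat, p = stats::pf(Fstat, 1, n - 3, lower.tail = FALSE),
             n = n)
}
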