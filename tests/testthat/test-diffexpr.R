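two_group_cm <- function(mat) {
  count_matrix(mat, "gene", rep(1000, nrow(mat)))
}

test_that("two-group OLS recovers the exact log2 fold change", {
  # normalized means 20 vs 10, zero within-group variance -> lfc 1, p -> 0
  m <- rbind(gA = c(10, 10, 10, 20, 20, 20),
             gB = c(7, 7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:6)
  md <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("ctrl", "sen"), each = 3))
  de <- differential_expression(two_group_cm(m), md, "group",
                                sf = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_equal(de$lfc[de$feature_id == "gA"], log2(21) - log2(11),
               tolerance = 1e-10)
  expect_lt(de$p[de$feature_id == "gA"], 1e-12)
  # identical groups -> lfc 0, p = 1
  expect_equal(de$lfc[de$feature_id == "gB"], 0)
  expect_equal(de$p[de$feature_id == "gB"], 1)
  expect_true(all(de$padj >= de$p))
})

test_that("continuous condition is centered and scaled; covariates enter
           the design; collinearity is reported", {
  set.seed(2)
  n <- 24
  md <- data.frame(sample_id = paste0("s", 1:n),
                   age = seq(0, 92, length.out = n),
                   sex = rep(c("F", "M"), n / 2))
  z <- as.numeric(scale(md$age))
  y <- 2^(5 + 0.8 * z)           # exact slope on the log2 scale
  m <- matrix(round(y * 50), 1, n,
              dimnames = list("gA", md$sample_id))
  de <- differential_expression(
    count_matrix(m, "gene", 1000), md, "age", covariates = "sex",
    sf = setNames(rep(1, n), md$sample_id))
  expect_equal(de$lfc, 0.8, tolerance = 0.02)
  md$age2 <- md$age * 2
  expect_error(differential_expression(
    count_matrix(m, "gene", 1000), md, "age", covariates = "age2",
    sf = setNames(rep(1, n), md$sample_id)), "collinear")
})

test_that("null features give calibrated, roughly uniform p-values", {
  set.seed(77)
  n <- 40
  md <- data.frame(sample_id = paste0("s", 1:n),
                   group = rep(c("a", "b"), each = n / 2))
  m <- matrix(rnbinom(500 * n, mu = 50, size = 10), 500, n,
              dimnames = list(paste0("f", 1:500), md$sample_id))
  de <- differential_expression(count_matrix(m, "gene", rep(1, 500)), md,
                                "group",
                                sf = setNames(rep(1, n), md$sample_id))
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("top-N selection ranks by padj, |lfc|, then id", {
  res <- data.frame(
    feature_id = paste0("f", 1:10),
    feature_class = "transposon",
    lfc = c(2, 1, -3, 0.5, 2, 1, -1, 0.2, 4, 0.1),
    p = rep(0.01, 10),
    padj = c(0.5, 0.5, 0.01, 0.2, 0.01, 0.3, 0.01, 0.9, 0.05, 0.05),
    mean_norm_count = 1)
  top3 <- select_top(res, 3)
  # brute-force oracle
  oracle <- res[order(res$padj, -abs(res$lfc), res$feature_id), ][1:3, ]
  expect_equal(top3$feature_id, oracle$feature_id)
  # overexpressed variant drops negative lfc first
  topo <- select_top(res, 3, overexpressed = TRUE)
  expect_false("f3" %in% topo$feature_id)
  expect_true(all(topo$lfc > 0))
  # small inputs come back whole
  expect_equal(nrow(select_top(res[1:3, ], 1000)), 3)
})

test_that("outlier selection ranks by regression residual and is shift
           invariant", {
  set.seed(12)
  g_lfc <- rnorm(20)
  t_lfc <- 0.6 * g_lfc + rnorm(20, sd = 0.05)
  t_lfc[7] <- t_lfc[7] + 2      # planted outlier
  tx <- data.frame(feature_id = paste0("te", 1:20),
                   feature_class = "transposon", lfc = t_lfc,
                   p = 0.001, padj = 0.01, mean_norm_count = 1)
  ge <- data.frame(feature_id = paste0("g", 1:20),
                   feature_class = "gene", lfc = g_lfc,
                   p = 0.001, padj = 0.01, mean_norm_count = 1)
  map <- data.frame(element_id = paste0("te", 1:20),
                    gene_id = paste0("g", 1:20))
  out <- outlier_selection(tx, ge, map, n = 5)
  expect_equal(out$feature_id[1], "te7")
  # brute-force residual check
  fit <- lm(t_lfc ~ g_lfc)
  oracle <- paste0("te", order(-resid(fit)))[1:5]
  expect_equal(out$feature_id, oracle)
  # adding a constant to all transposon lfcs changes nothing
  tx2 <- tx; tx2$lfc <- tx2$lfc + 5
  expect_equal(outlier_selection(tx2, ge, map, n = 5)$feature_id,
               out$feature_id)
  # degenerate gene lfc: ranking equals transposon lfc ranking
  ge0 <- ge; ge0$lfc <- 0
  out0 <- outlier_selection(tx, ge0, map, n = 5)
  expect_equal(out0$feature_id,
               paste0("te", order(-t_lfc))[1:5])
})

test_that("enrichment equals the hypergeometric tail and flags extremes", {
  bg <- paste0("e", 1:10000)
  flags <- setNames(c(rep(TRUE, 10), rep(FALSE, 240), rep(TRUE, 90),
                      rep(FALSE, 9660)), bg)
  r <- enrichment_test(paste0("e", 1:250), bg, flags)
  expect_equal(r$p, phyper(9, 100, 9900, 250, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$k_active, 10)
  # equal fractions -> odds ratio near 1, p > 0.5
  bg2 <- paste0("x", 1:200)
  flags2 <- setNames(rep(c(TRUE, FALSE), 100), bg2)
  r2 <- enrichment_test(bg2[1:50], bg2, flags2)
  expect_gt(r2$p, 0.5)
  expect_lt(abs(log(r2$odds_ratio)), 0.5)
  # all active elements inside the target: minimal attainable p
  flags3 <- setNames(c(rep(TRUE, 5), rep(FALSE, 45)), paste0("y", 1:50))
  r3 <- enrichment_test(paste0("y", 1:5), paste0("y", 1:50), flags3)
  expect_equal(r3$p, 1 / choose(50, 5), tolerance = 1e-9)
  expect_error(enrichment_test(character(0), bg, flags), "empty")
})

test_that("enrichment matches a Monte-Carlo permutation test on small
           tables", {
  set.seed(31)
  bg <- paste0("e", 1:40)
  flags <- setNames(sample(c(rep(TRUE, 8), rep(FALSE, 32))), bg)
  target <- sample(bg, 12)
  r <- enrichment_test(target, bg, flags)
  k_obs <- sum(flags[target])
  perm <- replicate(20000, sum(sample(flags, 12)) >= k_obs)
  p_mc <- mean(perm)
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(r$p - p_mc), max(4 * se, 0.01))
})
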