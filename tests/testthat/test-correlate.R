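score_df <- function(v, ids = paste0("s", seq_along(v))) {
  data.frame(sample_id = ids, value = v)
}

test_that("sample correlation handles exact and toy cases", {
  x <- score_df(c(1, 2, 3, 4, 5))
  expect_equal(sample_correlation(x, score_df(2 * x$value + 1))$r, 1)
  # 5-point toy against the covariance formula
  set.seed(6)
  a <- rnorm(5); b <- rnorm(5)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(sample_correlation(score_df(a), score_df(b))$r, r_hand,
               tolerance = 1e-12)
  expect_error(sample_correlation(score_df(c(1, 1, 1)), score_df(a[1:3])),
               "variance")
  expect_error(sample_correlation(score_df(1:2), score_df(1:2)),
               "3 matched")
})

test_that("locus-level lfc correlation is exact when copied and near zero
           when shuffled", {
  n <- 1000
  set.seed(10)
  lfc <- rnorm(n)
  el <- data.frame(feature_id = paste0("e", 1:n), lfc = lfc)
  co <- data.frame(feature_id = paste0("c", 1:n), lfc = lfc)
  map <- data.frame(element_id = el$feature_id,
                    container_id = co$feature_id)
  expect_equal(locus_lfc_correlation(el, co, map)$r, 1)
  co_ind <- data.frame(feature_id = paste0("c", 1:n), lfc = rnorm(n))
  r_sh <- locus_lfc_correlation(el, co_ind, map, scope = "shuffled",
                                seed = 2)$r
  expect_lt(abs(r_sh), 0.1)
})

test_that("within-sample count correlation finds proportional loci", {
  set.seed(4)
  base <- matrix(rpois(5 * 2, 50), 5, 2,
                 dimnames = list(paste0("e", 1:5), c("s1", "s2")))
  el <- count_matrix(base, "transposon", rep(100, 5))
  co <- count_matrix(base * 3,  "intron", rep(100, 5))
  rownames(co$counts) <- paste0("c", 1:5)
  co <- count_matrix(co$counts, "intron", rep(100, 5))
  map <- data.frame(element_id = paste0("e", 1:5),
                    container_id = paste0("c", 1:5))
  pc <- per_sample_count_correlation(el, co, map)
  expect_equal(pc$r, c(1, 1))
  # hand-checked toy
  el2 <- count_matrix(matrix(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), 5, 2,
                             dimnames = list(paste0("e", 1:5),
                                             c("s1", "s2"))),
                      "transposon", rep(100, 5))
  co2 <- count_matrix(matrix(c(2, 4, 5, 8, 10, 1, 2, 3, 4, 5), 5, 2,
                             dimnames = list(paste0("c", 1:5),
                                             c("s1", "s2"))),
                      "intron", rep(100, 5))
  pc2 <- per_sample_count_correlation(el2, co2, map)
  expect_equal(pc2$r[1], cor(c(1, 2, 3, 4, 5), c(2, 4, 5, 8, 10)))
  expect_equal(pc2$r[2], cor(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5)))
})

test_that("partial correlation matches its closed form and guards
           degeneracy", {
  # closed form on correlations (0.8, 0.5, 0.5) -> 0.7333
  set.seed(9)
  n <- 2000
  z <- rnorm(n)
  # construct x, y with known pairwise correlations via latent factors
  x <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  ids <- paste0("s", 1:n)
  pc <- partial_correlation(score_df(x, ids), score_df(y, ids),
                            score_df(z, ids))
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(pc$r, closed, tolerance = 1e-12)
  # orthogonal z leaves the correlation untouched
  x4 <- c(1, 2, 3, 4); y4 <- c(1.2, 1.9, 3.3, 3.9)
  z4 <- c(1, -1, -1, 1)  # orthogonal to the linear trend
  pc4 <- partial_correlation(score_df(x4), score_df(y4), score_df(z4))
  r4 <- cor(x4, y4)
  expect_equal(pc4$r, (r4 - cor(x4, z4) * cor(y4, z4)) /
                 sqrt((1 - cor(x4, z4)^2) * (1 - cor(y4, z4)^2)),
               tolerance = 1e-12)
  expect_error(partial_correlation(score_df(x4), score_df(y4),
                                   score_df(y4)), "fully explains")
})

test_that("the nested F-test matches brute-force RSS arithmetic and the
           squared-t identity", {
  set.seed(21)
  for (i in 1:5) {
    n <- 10
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1 + 0.5 * x1 + 0.8 * x2 + rnorm(n, sd = 0.3)
    ids <- paste0("s", 1:n)
    nm <- nested_model_test(score_df(y, ids), score_df(x1, ids),
                            score_df(x2, ids))
    rss_r <- sum(resid(lm(y ~ x1))^2)
    rss_f <- sum(resid(lm(y ~ x1 + x2))^2)
    F_hand <- (rss_r - rss_f) / (rss_f / (n - 3))
    expect_equal(nm$F, F_hand, tolerance = 1e-10)
    expect_lte(nm$rss_full, nm$rss_reduced)
    # identity: F p-value equals squared-t p-value of x2's coefficient
    p_t <- summary(lm(y ~ x1 + x2))$coefficients["x2", "Pr(>|t|)"]
    expect_equal(nm$p, p_t, tolerance = 1e-10)
  }
})

test_that("the nested test is decisive when x2 generates y and null when
           it is noise", {
  set.seed(22)
  n <- 30
  x1 <- rnorm(n); x2 <- rnorm(n)
  ids <- paste0("s", 1:n)
  nm <- nested_model_test(score_df(x2 + 0, ids), score_df(x1, ids),
                          score_df(x2, ids))
  expect_lt(nm$p, 1e-12)
  expect_lt(nm$rss_full, 1e-12)
  # x2 pure noise: F has mean about one over replications
  Fs <- replicate(300, {
    y <- 1 + x1 + rnorm(n)
    nested_model_test(score_df(y, ids), score_df(x1, ids),
                      score_df(rnorm(n), ids))$F
  })
  # exact null mean of F(1, n-3) is (n-3)/(n-5)
  expect_lt(abs(mean(Fs) - 27 / 25), 0.35)
  expect_error(nested_model_test(score_df(x2, ids), score_df(x1, ids),
                                 score_df(x1 * 2, ids)), "collinear")
})
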