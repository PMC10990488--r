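test_that("overlap counting follows the 1-bp and strand rules", {
  feats <- toy_granges("chr1", c(1, 101), c(100, 200), strand = "+",
                       ids = c("fA", "fB"))
  reads <- list(
    s1 = toy_granges("chr1", c(96, 10), c(105, 50),
                     strand = c("-", "+")))
  cm <- count_overlaps_matrix(reads, feats, strand_mode = "unstranded")
  # read spanning the boundary increments both features
  expect_equal(unname(cm$counts[, "s1"]), c(2, 1))
  # sense mode: the minus-strand read no longer counts
  cm_s <- count_overlaps_matrix(reads, feats, strand_mode = "sense")
  expect_equal(unname(cm_s$counts[, "s1"]), c(1, 0))
  # antisense mode is the complement for stranded reads
  cm_a <- count_overlaps_matrix(reads, feats, strand_mode = "antisense")
  expect_equal(unname(cm_a$counts[, "s1"]), c(1, 1))
})

test_that("counting is additive over concatenated read sets", {
  feats <- toy_granges("chr1", c(1, 500), c(400, 900),
                       ids = c("fA", "fB"))
  set.seed(3)
  mk <- function(n) {
    st <- sample(1:850, n, replace = TRUE)
    toy_granges("chr1", st, st + 49)
  }
  r1 <- list(s = mk(50)); r2 <- list(s = mk(70))
  both <- list(s = c(r1$s, r2$s))
  expect_equal(count_overlaps_matrix(both, feats)$counts,
               count_overlaps_matrix(r1, feats)$counts +
                 count_overlaps_matrix(r2, feats)$counts)
})

test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 30,
                20, 40, 60,
                30, 60, 90), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  cm <- count_matrix(m, "gene", rep(100, 3))
  sf <- size_factors(cm)
  # columns are exact multiples: factors proportional to 1, 2, 3
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[3] / sf[1]), 3)
  expect_equal(geomean <- exp(mean(log(sf))), 1)
  # identical samples -> all factors one
  m2 <- matrix(rep(c(5, 9, 14), 3), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(count_matrix(m2, "gene", rep(1, 3)))),
               rep(1, 3))
})

test_that("size factors agree with the external median-of-ratios
           implementation up to rescaling", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rnbinom(200, mu = 80, size = 5), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  sf <- size_factors(count_matrix(m, "gene", rep(1, 40)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ratio <- sf / ref
  expect_lt(max(ratio) - min(ratio), 1e-12)
})

test_that("nearest-gene normalization applies the pseudocount ratio", {
  el <- count_matrix(matrix(c(10, 0), 2, 1,
                            dimnames = list(c("e1", "e2"), "s1")),
                     "transposon", c(100, 100))
  ge <- count_matrix(matrix(c(100, 0), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     "gene", c(1000, 1000))
  mapping <- data.frame(element_id = c("e1", "e2"),
                        gene_id = c("g1", "g2"))
  v0 <- nearest_gene_normalize(el, ge, mapping, pseudocount = 0,
                               sf = c(s1 = 1))
  expect_equal(unname(v0["e1", "s1"]), 0.1)
  v1 <- nearest_gene_normalize(el, ge, mapping, pseudocount = 1,
                               sf = c(s1 = 1))
  expect_equal(unname(v1["e2", "s1"]), 1.0)
})

test_that("per-sample score is the mean log2 normalized value", {
  nm <- matrix(c(0.1, 0.01), 2, 1,
               dimnames = list(c("a", "b"), "s1"))
  expect_equal(per_sample_score(nm)$value, -4.9829, tolerance = 1e-4)
  ones <- matrix(1, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(per_sample_score(ones)$value, c(0, 0))
  # doubling every element adds exactly one
  expect_equal(per_sample_score(nm * 2)$value,
               per_sample_score(nm)$value + 1)
  expect_error(per_sample_score(nm * 0), "pseudocount")
})

test_that("readthrough ratio reproduces the density log2 ratio", {
  # rt density 1/kb over 10 kb, gene density 100/kb over 2 kb, 5 genes
  rt <- count_matrix(matrix(10, 5, 2, dimnames = list(
    paste0("g", 1:5, "_rt"), c("s1", "s2"))), "readthrough",
    rep(10000, 5))
  ge <- count_matrix(matrix(200, 5, 2, dimnames = list(
    paste0("g", 1:5), c("s1", "s2"))), "gene", rep(2000, 5))
  rr <- readthrough_ratio(rt, ge, paste0("g", 1:5), sf = c(s1 = 1, s2 = 1))
  expect_equal(rr$per_sample$value, c(-6.6439, -6.6439), tolerance = 1e-4)
  # equal densities -> 0; doubling rt adds one
  rt2 <- count_matrix(matrix(20, 5, 2, dimnames = dimnames(rt$counts)),
                      "readthrough", rep(10000, 5))
  expect_equal(readthrough_ratio(rt2, ge, paste0("g", 1:5),
                                 sf = c(s1 = 1, s2 = 1))$per_sample$value,
               rr$per_sample$value + 1, tolerance = 1e-6)
})

test_that("scores are invariant to global library scaling", {
  set.seed(5)
  m <- matrix(rnbinom(60, mu = 50, size = 10), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  m[, 2] <- m[, 1] * 4   # deeper library, same composition
  cm <- count_matrix(m, "gene", rep(1000, 20))
  sf <- size_factors(cm)
  norm <- t(t(cm$counts) / sf)
  expect_equal(unname(norm[, 1]), unname(norm[, 2]))
})

test_that("flank profile decays when the signal decays", {
  bins <- 0:9
  ids <- paste0("g1_rt_bin", bins)
  counts <- matrix(round(1000 * exp(-0.5 * bins)), 10, 2,
                   dimnames = list(ids, c("s1", "s2")))
  cm <- count_matrix(counts, "readthrough", rep(10000, 10))
  ge <- count_matrix(matrix(500, 1, 2, dimnames = list("g1",
                                                       c("s1", "s2"))),
                     "gene", 2000)
  prof <- flank_profile(cm, ge, rep("g1", 10), bins,
                        sf = c(s1 = 1, s2 = 1))
  v <- prof$value[prof$sample_id == "s1"]
  expect_true(all(diff(v) < 0))
  # uniform signal -> flat profile
  cmu <- count_matrix(matrix(100, 10, 2, dimnames = dimnames(counts)),
                      "readthrough", rep(10000, 10))
  pu <- flank_profile(cmu, ge, rep("g1", 10), bins,
                      sf = c(s1 = 1, s2 = 1))
  expect_lt(diff(range(pu$value)), 1e-9)
})

test_that("strand partition splits reads by host-gene agreement", {
  genes <- toy_granges("chr1", c(1, 1000), c(500, 1500),
                       strand = c("+", "-"), ids = c("gA", "gB"))
  reads <- list(s1 = toy_granges(
    "chr1", c(10, 20, 30, 1100, 1200, 1300),
    c(60, 70, 80, 1150, 1250, 1350),
    strand = c("+", "+", "-", "-", "+", "*")))
  sp <- strand_partition(reads, genes)
  expect_equal(sp$sense, 3)      # two + in gA, one - in gB
  expect_equal(sp$antisense, 2)
  expect_equal(sp$unknown, 1)
  expect_equal(sp$frac_sense, 0.6)
})
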