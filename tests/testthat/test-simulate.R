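small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_genes = 16, n_transposons = 300,
             n_full_length_l1 = 6, n_coding_l1 = 2, n_samples = 12, ...)
}

test_that("generation is deterministic and files round-trip", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_annotation(small_cfg(), d1)
  generate_annotation(small_cfg(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # outputs parse with the package's own readers, without errors
  m <- load_annotation(file.path(d1, "genes.gtf"))
  te <- read_bed(file.path(d1, "transposons.bed"))
  sizes <- read_chrom_sizes(file.path(d1, "chrom.sizes"))
  expect_gt(length(m$genes), 16 - 1)   # primary genes plus blockers
  expect_length(te, 300)
  expect_length(sizes, 2)
  truth <- read_tsv(file.path(d1, "truth.tsv"))
  expect_equal(truth$te_id, names(te))
})

test_that("realized context fractions track the configured mixture", {
  cfg <- sim_config(seed = 2, n_genes = 40, n_transposons = 3000,
                    n_full_length_l1 = 10, n_coding_l1 = 0)
  ann <- generate_annotation(cfg)
  fr <- summarize_context_fractions(
    data.frame(te_id = ann$truth$te_id, context = ann$truth$context,
               nearest_gene_id = ann$truth$nearest_gene_id,
               signed_distance = ann$truth$signed_distance))
  mix <- cfg$context_mixture
  tol <- 3 * sqrt(0.6 * 0.4 / 3000) + 0.01
  expect_lt(abs(fr$genic - mix[["genic"]]), tol)
  expect_lt(abs(fr$ds5kb - mix[["ds5kb"]]), tol)
  expect_lt(abs(fr$intergenic - mix[["intergenic"]]), tol)
})

test_that("intronic placements avoid the junction-exclusion zone", {
  cfg <- sim_config(seed = 3, n_genes = 30, n_transposons = 1500,
                    n_full_length_l1 = 0, n_coding_l1 = 0)
  ann <- generate_annotation(cfg)
  intronic <- ann$te[ann$truth$context == "intronic"]
  hits <- GenomicRanges::findOverlaps(intronic, ann$introns,
                                      type = "within",
                                      ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(hits))),
               length(intronic))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  d5 <- GenomicRanges::start(intronic)[q] -
    GenomicRanges::start(ann$introns)[s]
  d3 <- GenomicRanges::end(ann$introns)[s] -
    GenomicRanges::end(intronic)[q]
  expect_true(all(d5 >= 500))
  expect_true(all(d3 >= 500))
})

test_that("fraction_isolated = 1 keeps every flank region eligible", {
  cfg <- small_cfg(fraction_isolated = 1)
  ann <- generate_annotation(cfg)
  rt <- build_flank_regions(ann$models, "readthrough",
                            chrom_sizes = ann$chrom_sizes)
  expect_true(all(rt$valid))
  expect_length(ann$blocker_ids, 0)
})

test_that("simulated counts are deterministic, labelled, and depth
           invariant after size factoring", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  s1 <- simulate_counts(cfg, ann)
  s2 <- simulate_counts(cfg, ann)
  expect_identical(s1$genes$counts, s2$genes$counts)
  expect_identical(s1$transposons$counts, s2$transposons$counts)
  expect_equal(ncol(s1$genes$counts), 12)
  expect_setequal(unique(s1$transposons$features$class), "transposon")
  # deepening one library is absorbed by its size factor: normalized
  # counts change only by a single global rescaling
  sf <- size_factors(s1$genes)
  norm <- t(t(s1$genes$counts) / sf)
  deeper <- s1$genes$counts
  deeper[, 1] <- deeper[, 1] * 2
  sf2 <- size_factors(count_matrix(deeper, "gene",
                                   s1$genes$features$length))
  norm2 <- t(t(deeper) / sf2)
  ratio <- norm2 / norm
  ratio <- ratio[is.finite(ratio)]
  expect_lt(max(ratio) - min(ratio), 1e-8)
})

test_that("host-driven transposons track their intron counts within a
           sample", {
  # no condition effects, no autonomous term: intronic transposons are a
  # fixed share of their host intron signal
  cfg <- sim_config(seed = 6, n_genes = 40, n_transposons = 800,
                    beta_ir = 0, beta_rt = 0, beta_ri = 0, beta_l1 = 0,
                    mu_autonomous = 0, bg_mu = 0,
                    sigma_ir_sample = 0, sigma_rt_sample = 0,
                    n_samples = 6, n_full_length_l1 = 0, n_coding_l1 = 0)
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  ok <- !is.na(sim$host_intron)
  map <- data.frame(element_id = ann$truth$te_id[ok],
                    container_id = sim$host_intron[ok])
  pc <- per_sample_count_correlation(sim$transposons, sim$introns, map)
  expect_gt(mean(pc$r, na.rm = TRUE), 0.5)
  # randomized mapping control collapses the correlation
  pc_sh <- per_sample_count_correlation(sim$transposons, sim$introns,
                                        map, shuffled = TRUE, seed = 3)
  expect_lt(mean(abs(pc_sh$r), na.rm = TRUE),
            mean(pc$r, na.rm = TRUE) / 2)
})

test_that("generated read intervals reproduce their source counts", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  genes <- ann$models$genes[!names(ann$models$genes) %in%
                              ann$blocker_ids]
  sub <- count_matrix(sim$genes$counts[, 1:2], "gene",
                      sim$genes$features$length)
  reads <- reads_from_counts(genes, sub, seed = 2)
  back <- count_overlaps_matrix(reads, genes, "gene", "unstranded")
  expect_equal(back$counts, sub$counts)
  # strandedness: with sense_fraction 0.9 most reads match gene strand
  sp <- strand_partition(reads, genes)
  expect_gt(min(sp$frac_sense), 0.8)
})
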