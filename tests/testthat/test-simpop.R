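test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(divergence_F = 0), "divergence_F")
  expect_error(sim_config(divergence_F = 1), "divergence_F")
  expect_error(sim_config(dirichlet_alpha = c(0.3, 0, 0.3), K_true = 3),
               "dirichlet_alpha")
  expect_error(sim_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(telomere_enrichment = 0.5), "telomere")
})

test_that("simulated maps are sorted, unique and 1-based", {
  cfg <- sim_config(n_lines = 2, n_loci = 30, n_chromosomes = 3,
                    chrom_length_bp = 1e6, K_true = 2, seed = 4)
  map <- plant_map(cfg)
  expect_equal(nrow(map), 30)
  for (ch in unique(map$chrom)) {
    pos <- map$pos[map$chrom == ch]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1 & pos <= 1e6))
  }
  expect_error(plant_map(sim_config(n_loci = 20, n_chromosomes = 1,
                                    chrom_length_bp = 10)),
               "more loci")
})

test_that("uniform maps pass a KS test against uniform, enriched maps do not",
{
  pvals <- vapply(1:5, function(s) {
    cfg <- sim_config(n_lines = 2, n_loci = 1000, n_chromosomes = 1,
                      chrom_length_bp = 1e7, telomere_enrichment = 1,
                      seed = s)
    suppressWarnings(ks.test(plant_map(cfg)$pos / 1e7, "punif")$p.value)
  }, 0)
  expect_gt(max(pvals), 0.01)  # not systematically rejected
  expect_gt(mean(pvals > 0.01), 0.5)
})

test_that("telomere enrichment skews outer vs middle density as configured", {
  ratio <- vapply(1:20, function(s) {
    cfg <- sim_config(n_lines = 2, n_loci = 10000, n_chromosomes = 1,
                      chrom_length_bp = 1e7, telomere_enrichment = 5,
                      seed = s)
    x <- plant_map(cfg)$pos / 1e7
    (mean(x <= 0.1 | x >= 0.9) / 0.2) / (mean(x > 0.45 & x < 0.55) / 0.1)
  }, 0)
  expect_gt(mean(ratio), 3)
  expect_lt(mean(ratio), 8)
})

test_that("fixed seed gives identical panels; rates are respected", {
  cfg <- sim_config(n_lines = 50, n_loci = 400, n_chromosomes = 2,
                    K_true = 2, divergence_F = 0.2, pure_fraction = 1,
                    residual_het_rate = 0.02, missing_rate = 0.1, seed = 9)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$truth$true_Q, p2$truth$true_Q)
  # empirical missing rate within 3 binomial SE
  n <- length(p1$genotypes)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(is.na(p1$genotypes)) - 0.1), 3 * se)
  # Q rows sum to one
  expect_equal(unname(rowSums(p1$truth$true_Q)), rep(1, 50),
               tolerance = 1e-9)
})

test_that("zero residual heterozygosity gives homozygous-only calls", {
  p <- simulate_panel(sim_config(n_lines = 30, n_loci = 200,
                                 n_chromosomes = 1, K_true = 2,
                                 residual_het_rate = 0, pure_fraction = 1,
                                 seed = 2))
  v <- p$genotypes[!is.na(p$genotypes)]
  expect_true(all(v %in% c(0L, 2L)))
})

test_that("pure-group empirical frequencies converge to the true P", {
  p <- simulate_panel(sim_config(n_lines = 400, n_loci = 1000,
                                 n_chromosomes = 2, K_true = 2,
                                 divergence_F = 0.2, pure_fraction = 1,
                                 residual_het_rate = 0, missing_rate = 0,
                                 seed = 3))
  g1 <- p$truth$true_Q[, 1] == 1
  mae <- mean(abs(colMeans(p$genotypes[g1, ]) / 2 - p$truth$true_P[1, ]))
  expect_lt(mae, 0.05)
})

test_that("between-group differentiation tracks the drift parameter", {
  hudson <- function(p) {
    g1 <- p$truth$true_Q[, 1] == 1
    p1 <- colMeans(p$genotypes[g1, ]) / 2
    p2 <- colMeans(p$genotypes[!g1, ]) / 2
    n1 <- sum(g1); n2 <- sum(!g1)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    sum(num) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  # near-zero divergence collapses Fst
  p0 <- simulate_panel(sim_config(n_lines = 200, n_loci = 2000,
                                  n_chromosomes = 5, K_true = 2,
                                  divergence_F = 0.001, pure_fraction = 1,
                                  residual_het_rate = 0, missing_rate = 0,
                                  seed = 1))
  g1 <- p0$truth$true_Q[, 1] == 1
  expect_lt(fst_pairwise(colMeans(p0$genotypes[g1, ]) / 2,
                         colMeans(p0$genotypes[!g1, ]) / 2), 0.01)
  # F = 0.2 puts the Hudson-style estimate near 0.2
  est <- vapply(1:3, function(s) {
    hudson(simulate_panel(sim_config(n_lines = 200, n_loci = 5000,
                                     n_chromosomes = 10, K_true = 2,
                                     divergence_F = 0.2, pure_fraction = 1,
                                     residual_het_rate = 0,
                                     missing_rate = 0, seed = s)))
  }, 0)
  expect_true(all(est > 0.15 & est < 0.25))
})

test_that("block-copy panels carry the declared block structure", {
  bp <- simulate_block_panel(n_lines = 20, n_blocks = 3,
                             loci_per_block = 4, seed = 5)
  expect_equal(dim(bp$genotypes), c(20, 12))
  expect_true(all(bp$genotypes %in% c(0L, 2L)))
  # loci within a block are perfectly associated with two founders
  for (b in 1:3) {
    idx <- bp$truth$block_bounds$start_idx[b]:bp$truth$block_bounds$end_idx[b]
    cors <- abs(cor(bp$genotypes[, idx]))
    expect_equal(unname(cors), matrix(1, 4, 4), tolerance = 1e-12)
  }
})

test_that("panels round-trip through the on-disk formats", {
  p <- simulate_panel(sim_config(n_lines = 20, n_loci = 50,
                                 n_chromosomes = 2, K_true = 2, seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_sim_panel(p, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_vcf(paths[["vcf"]])
  expect_equal(unname(rt$genotypes), unname(p$genotypes))
  Q <- read_q_matrix(paths[["q"]])
  expect_equal(Q, unname(p$truth$true_Q), tolerance = 1e-5)
})
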