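mk_assign <- function(lines, groups) {
  data.frame(line = lines, adjusted_id = groups, base_group = groups,
             stringsAsFactors = FALSE)
}

test_that("group frequencies count alt copies over het-masked calls", {
  G <- rbind(matrix(2L, 10, 3), matrix(0L, 10, 3))
  G[11:15, 2] <- 2L                 # locus 2: 15 alt lines of 20
  G[1, 3] <- 1L                     # one het at locus 3, masked
  rownames(G) <- paste0("L", 1:20)
  colnames(G) <- paste0("S1_", 1:3 * 100L)
  asg <- mk_assign(rownames(G), rep("A", 20))
  gf <- group_freqs(G, asg, "A")
  expect_equal(unname(gf$freqs["A", 1]), 0.5)
  expect_equal(unname(gf$freqs["A", 2]), 0.75)
  # locus 3: het masked -> 9 alt of 19 called lines
  expect_equal(unname(gf$freqs["A", 3]), 9 / 19)
  expect_equal(unname(gf$n_lines["A"]), 20L)
  # all-alt and half-half sanity
  allalt <- matrix(2L, 12, 1, dimnames = list(paste0("M", 1:12), "S1_1"))
  gfa <- group_freqs(allalt, mk_assign(rownames(allalt), rep("B", 12)), "B")
  expect_equal(unname(gfa$freqs["B", 1]), 1)
  # undersized groups are excluded with a warning
  expect_warning(
    expect_error(group_freqs(G, mk_assign(rownames(G), rep("tiny", 20)),
                             c("tiny"), min_lines = 30), "minimum"),
    "excluded")
})

test_that("locus classes follow the declared frequency bands", {
  t <- locus_class_thresholds()
  cl <- classify_loci(0.5, 0.02, t)
  expect_true(cl$neutral_a_fixed_b)   # 0.5 neutral, 0.02 near-fixed
  expect_true(cl$unique_a)            # segregates only in A
  expect_false(cl$differential)       # |0.48| < 0.5
  expect_equal(classify_loci(0.5, 0.5, t)$class, "none")
})

test_that("a constructed table cross-tabulates like a hand classification",
{
  fa <- c(0.50, 0.50, 0.02, 0.95, 0.10, 0.40, 0.30)
  fb <- c(0.50, 0.02, 0.50, 0.05, 0.92, 0.95, 0.72)
  cl <- classify_loci(fa, fb)
  # hand classification per locus:
  expect_equal(cl$class[1], "none")
  expect_equal(cl$unique_a[2], TRUE)   # A segregates, B near-fixed
  expect_equal(cl$neutral_a_fixed_b[2], TRUE)
  expect_equal(cl$unique_b[3], TRUE)
  expect_equal(cl$neutral_b_fixed_a[3], TRUE)
  expect_true(cl$differential[4])          # |0.95 - 0.05| = 0.90
  expect_false(cl$unique_a[4])             # both maf 0.05: both polymorphic
  expect_true(cl$differential[5])
  expect_false(cl$neutral_b_fixed_a[5])    # 0.92 outside the neutral band
  expect_true(cl$differential[6])          # 0.55 >= 0.5
  expect_true(cl$neutral_a_fixed_b[6])
  expect_equal(cl$class[7], "none")        # 0.42 diff, both inside bands
  # swapping the groups mirrors the labels
  cs <- classify_loci(fb, fa)
  expect_equal(cs$unique_a, cl$unique_b)
  expect_equal(cs$neutral_a_fixed_b, cl$neutral_b_fixed_a)
  expect_equal(cs$differential, cl$differential)
})

test_that("the frequency-difference table is exact on printed frequencies",
{
  tab <- read.delim(system.file("extdata", "mreid_tspt_freq_table.tsv",
                                package = "popstructr"))
  map <- data.frame(locus_id = tab$locus_id, chrom = as.character(tab$chrom),
                    pos = as.integer(sub(".*_", "", tab$locus_id)),
                    ref = "N", alt = tab$allele)
  dt <- diff_table(tab$p_mreid, tab$p_tspt, map)
  m <- merge(dt, tab, by = "locus_id")
  expect_equal(m$diff, m$p_a - m$p_b, tolerance = 1e-12)
  expect_lte(max(abs(m$diff - m$printed_diff)), 0.001 + 1e-9)
  # named spot checks
  expect_equal(dt$diff[dt$locus_id == "S1_45003478"], 0.732)
  expect_equal(dt$diff[dt$locus_id == "S8_16258836"], -0.881)
  # sorted by chromosome (numeric order) then position
  expect_equal(unique(dt$chrom), c("1", "2", "3", "4", "6", "8", "10"))
  expect_true(all(tapply(dt$pos, dt$chrom, function(p) all(diff(p) > 0))))
})

test_that("differential-locus counts grow with divergence", {
  counts <- vapply(c(0.1, 0.25, 0.4), function(F) {
    mean(vapply(1:3, function(s) {
      p <- simulate_panel(sim_config(n_lines = 100, n_loci = 500,
                                     n_chromosomes = 2, K_true = 2,
                                     divergence_F = F, pure_fraction = 1,
                                     residual_het_rate = 0,
                                     missing_rate = 0, seed = s))
      g1 <- p$truth$true_Q[, 1] == 1
      fa <- colMeans(p$genotypes[g1, ]) / 2
      fb <- colMeans(p$genotypes[!g1, ]) / 2
      sum(classify_loci(fa, fb)$differential, na.rm = TRUE)
    }, 0))
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("per-chromosome class counts add up", {
  fa <- c(0.5, 0.02, 0.95, 0.5)
  fb <- c(0.02, 0.5, 0.05, 0.5)
  map <- data.frame(locus_id = paste0("S", c(1, 1, 2, 2), "_", 1:4 * 10),
                    chrom = as.character(c(1, 1, 2, 2)), pos = 1:4 * 10L)
  ct <- class_count_table(classify_loci(fa, fb), map)
  expect_equal(ct$chrom, c("1", "2", "Total"))
  # only |0.95 - 0.05| reaches the 0.5 differential cut
  expect_equal(ct$differential, c(0, 1, 1))
  expect_equal(ct$unique_a, c(1, 0, 1))  # (0.5, 0.02) is unique to A
  expect_equal(ct$unique_a[3], sum(ct$unique_a[1:2]))
})
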