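write_toy_vcf <- function(path, extra_record = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "A1", "A2", sep = "\t"),
             paste("1", "100", "S1_100", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "0/1", sep = "\t"),
             paste("1", "200", "S1_200", "C", "T", ".", "PASS", ".", "GT",
                   "1/1", "./.", sep = "\t"))
  if (!is.null(extra_record)) lines <- c(lines, extra_record)
  writeLines(lines, path)
  path
}

test_that("VCF genotype codes map to dosages", {
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  x <- read_vcf(path)
  expect_equal(unname(x$genotypes),
               matrix(c(0L, 1L, 2L, NA), 2, 2), ignore_attr = TRUE)
  expect_equal(x$map$locus_id, c("S1_100", "S1_200"))
  expect_equal(rownames(x$genotypes), c("A1", "A2"))
})

test_that("non-biallelic records are skipped with a count", {
  tri <- paste("1", "300", "S1_300", "A", "G,T", ".", "PASS", ".", "GT",
               "0/1", "1/2", sep = "\t")
  path <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), tri)
  expect_message(x <- read_vcf(path), "skipped")
  expect_equal(ncol(x$genotypes), 2)
})

test_that("VCF and HapMap round-trip a simulated panel exactly", {
  p <- simulate_panel(sim_config(n_lines = 50, n_loci = 100,
                                 n_chromosomes = 2, K_true = 2, seed = 8))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  hmp <- withr::local_tempfile(fileext = ".hmp.txt")
  write_vcf(p$genotypes, p$map, vcf)
  write_hapmap(p$genotypes, p$map, hmp)
  rv <- read_vcf(vcf)
  rh <- read_hapmap(hmp)
  expect_identical(unname(rv$genotypes), unname(p$genotypes))
  expect_identical(unname(rh$genotypes), unname(p$genotypes))
  expect_equal(rh$map$pos, p$map$pos)
})

test_that("HapMap calls are decoded from IUPAC and two-letter forms", {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "L1", "L2", "L3"), collapse = "\t")
  rows <- c(paste(c("S1_10", "A/G", "1", "10", "+", rep("NA", 6),
                    "A", "R", "GG"), collapse = "\t"),
            paste(c("S1_20", "C/T", "1", "20", "+", rep("NA", 6),
                    "N", "CT", "G"), collapse = "\t"))  # G inconsistent
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  writeLines(c(hdr, rows), path)
  expect_message(x <- read_hapmap(path), "inconsistent")
  expect_equal(unname(x$genotypes),
               matrix(c(0L, 1L, 2L, NA, 1L, NA), 3, 2), ignore_attr = TRUE)
})

test_that("Q matrix IO renormalizes near-1 rows and rejects bad ones", {
  path <- withr::local_tempfile()
  writeLines(c("0.35 0.26 0.39", "0.5 0.2995 0.2"), path)
  Q <- read_q_matrix(path)
  expect_equal(Q[1, ], c(0.35, 0.26, 0.39))
  expect_equal(sum(Q[2, ]), 1)
  writeLines(c("0.5 0.2 0.2"), path)  # sums to 0.9
  expect_error(read_q_matrix(path), "sum to 1")
  # write-then-read identity at 6 decimals
  Qw <- matrix(c(0.123456, 0.876544, 0.4, 0.6), 2, 2, byrow = TRUE)
  write_q_matrix(Qw, path)
  expect_equal(read_q_matrix(path), Qw, tolerance = 1e-6)
  # ragged rows fail
  writeLines(c("0.5 0.5", "1.0"), path)
  expect_error(read_q_matrix(path))
})

test_that("P matrix files use the one-row-per-locus layout", {
  P <- matrix(runif(8), 2, 4)  # groups x loci in memory
  path <- withr::local_tempfile()
  write_p_matrix(P, path)
  expect_equal(length(readLines(path)), 4)  # loci rows
  expect_equal(read_p_matrix(path), P, tolerance = 1e-6)
})

test_that("QC filter reproduces a hand-enumerated 6-locus outcome", {
  n <- 20
  mk <- function(n2, n1 = 0, nmiss = 0) {
    c(rep(2L, n2), rep(1L, n1), rep(NA_integer_, nmiss),
      rep(0L, n - n2 - n1 - nmiss))
  }
  G <- cbind(maf_fail = mk(1),            # maf 0.05?? 2/40 = 0.05 passes; use 1 alt copy
             miss_fail = mk(8, 0, 5),     # missing 25% > 20%
             het_fail = mk(6, 2),         # het 10% > 5%
             pass1 = mk(10),              # maf 0.5
             pass2 = mk(5, 1),            # het 5% allowed, maf 11/40
             pass3 = mk(4, 0, 2))         # missing 10%, maf 8/36
  G[1:2, "maf_fail"] <- c(1L, 0L)         # exactly one alt copy: maf 1/40
  rownames(G) <- paste0("L", 1:20)
  res <- qc_filter(G)
  expect_equal(colnames(res$genotypes), c("pass1", "pass2", "pass3"))
  rep <- setNames(res$report$n, res$report$criterion)
  expect_equal(rep[["maf"]], 1)
  expect_equal(rep[["missing"]], 1)
  expect_equal(rep[["het"]], 1)
  expect_equal(rep[["retained"]], 3)
  # idempotence
  res2 <- qc_filter(res$genotypes)
  expect_identical(res2$genotypes, res$genotypes)
  # all-pass matrix unchanged
  allpass <- G[, c("pass1", "pass2", "pass3")]
  expect_identical(qc_filter(allpass)$genotypes, allpass)
})

test_that("the subgroup mask hides heterozygotes then drops gappy loci", {
  n <- 20
  G <- cbind(kept = c(1L, rep(2L, 10), rep(0L, 9)),       # 1 het -> 5%
             dropped = c(1L, 1L, 1L, rep(2L, 9), rep(0L, 8)),  # 15%
             clean = rep(c(0L, 2L), 10))
  rownames(G) <- paste0("L", 1:n)
  res <- subgroup_missing_mask(G)
  expect_equal(colnames(res$genotypes), c("kept", "clean"))
  expect_true(all(res$genotypes != 1L, na.rm = TRUE))
  expect_true(is.na(res$genotypes[1, "kept"]))
  # het-free matrix is unchanged
  hf <- G[, "clean", drop = FALSE]
  expect_identical(subgroup_missing_mask(hf)$genotypes, hf)
})
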