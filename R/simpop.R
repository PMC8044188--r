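#' Configuration for the structured inbred-panel simulator
#'
#' Describes a synthetic panel of near-homozygous inbred lines drawn from a
#' Balding-Nichols model: `K_true` ancestral groups whose allele frequencies
#' drift away from a shared ancestral frequency with per-group parameter
#' `divergence_F`, lines with admixture proportions drawn from a Dirichlet
#' (a stated fraction of lines forced to be "pure", i.e. one-hot), residual
#' heterozygosity from occasional independent two-allele draws, and
#' missing-completely-at-random genotype calls. SNP positions can be skewed
#' toward chromosome ends to emulate the telomere-enriched marker density of
#' reduced-representation genotyping.
#'
#' @param n_lines Number of inbred lines.
#' @param n_loci Total number of biallelic SNP loci across the genome.
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param chrom_length_bp Length of each chromosome in base pairs.
#' @param K_true Number of ancestral groups.
#' @param divergence_F Per-group drift parameter, strictly in (0, 1);
#'   recycled to length `K_true`.
#' @param dirichlet_alpha Dirichlet concentration for admixture rows;
#'   recycled to length `K_true`.
#' @param pure_fraction Fraction of lines with one-hot (single-group)
#'   ancestry; the rest are admixed Dirichlet draws.
#' @param residual_het_rate Probability that a line-by-locus call is formed
#'   from two independent allele draws (can be heterozygous) rather than one
#'   doubled draw.
#' @param missing_rate Probability a call is masked missing (MCAR).
#' @param telomere_enrichment Marker-density ratio of the outer 10% of a
#'   chromosome relative to its middle; must be >= 1 (1 = uniform).
#' @param seed Integer seed; a fixed seed gives byte-identical panels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 490, n_loci = 5000, n_chromosomes = 10,
                       chrom_length_bp = 2e8, K_true = 10,
                       divergence_F = 0.25, dirichlet_alpha = 0.3,
                       pure_fraction = 0.8, residual_het_rate = 0.02,
                       missing_rate = 0.05, telomere_enrichment = 3,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_loci = as.integer(n_loci),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, K_true = as.integer(K_true),
              divergence_F = rep_len(divergence_F, K_true),
              dirichlet_alpha = rep_len(dirichlet_alpha, K_true),
              pure_fraction = pure_fraction,
              residual_het_rate = residual_het_rate,
              missing_rate = missing_rate,
              telomere_enrichment = telomere_enrichment,
              seed = as.integer(seed))
  stopifnot(cfg$n_lines >= 1, cfg$n_loci >= 1, cfg$n_chromosomes >= 1,
            cfg$K_true >= 1, cfg$chrom_length_bp >= 1)
  if (any(cfg$divergence_F <= 0) || any(cfg$divergence_F >= 1))
    stop("divergence_F must lie strictly in (0, 1)")
  if (any(cfg$dirichlet_alpha <= 0))
    stop("dirichlet_alpha entries must be > 0")
  rates <- c(cfg$pure_fraction, cfg$residual_het_rate, cfg$missing_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("pure_fraction, residual_het_rate and missing_rate must be in [0, 1]")
  if (cfg$telomere_enrichment < 1)
    stop("telomere_enrichment must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# telomere-skewed density on [0,1]: relative density telomere_enrichment at
# the outer 10% of the chromosome, 1 in the middle 10%, linear in between
.telomere_density <- function(x, t) {
  d <- pmin(x, 1 - x)
  g <- ifelse(d <= 0.10, 1, ifelse(d >= 0.45, 0, (0.45 - d) / 0.35))
  1 + (t - 1) * g
}

.sample_positions <- function(n, length_bp, t) {
  if (n > length_bp) stop("more loci requested than integer positions available")
  pos <- integer(0)
  while (length(pos) < n) {
    m <- max(2L * (n - length(pos)), 100L)
    x <- runif(m)
    keep <- if (t > 1) runif(m) < .telomere_density(x, t) / t else rep(TRUE, m)
    cand <- pmin.int(pmax.int(as.integer(ceiling(x[keep] * length_bp)), 1L),
                     as.integer(length_bp))
    pos <- unique(c(pos, cand))
  }
  sort(pos[seq_len(n)])
}

#' Simulate a SNP map with telomere-enriched density
#'
#' Draws unique, sorted 1-based SNP positions per chromosome. With
#' `telomere_enrichment` t > 1, the expected marker density in the outer 10%
#' of each chromosome exceeds the middle 10% by a factor t.
#'
#' @param cfg A [sim_config()].
#' @return A variant table: `locus_id` (`S<chrom>_<pos>`), `chrom`, `pos`,
#'   `ref`, `alt`, sorted by (chromosome, position).
#' @export
plant_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    per <- rep(cfg$n_loci %/% cfg$n_chromosomes, cfg$n_chromosomes)
    extra <- cfg$n_loci %% cfg$n_chromosomes
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
      pos <- .sample_positions(per[ch], cfg$chrom_length_bp,
                               cfg$telomere_enrichment)
      data.frame(locus_id = sprintf("S%d_%d", ch, pos),
                 chrom = as.character(ch), pos = pos,
                 stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, maps)
    bases <- c("A", "C", "G", "T")
    map$ref <- sample(bases, nrow(map), replace = TRUE)
    map$alt <- vapply(map$ref, function(r) sample(setdiff(bases, r), 1L), "")
    rownames(map) <- NULL
    map
  })
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a structured inbred panel with known truth
#'
#' Balding-Nichols generative model: per locus an ancestral frequency
#' p ~ Uniform(0.05, 0.95); per group k a drifted frequency
#' P_kj ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k); per line an admixture row
#' Q_i (Dirichlet, or one-hot for pure lines). A call's alternate-allele
#' probability is sum_k Q_ik P_kj; with probability
#' `1 - residual_het_rate` one allele is drawn and doubled (dosage 0 or 2),
#' otherwise two independent alleles are drawn; calls are then masked missing
#' at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_panel`: `genotypes` (lines x loci dosage
#'   matrix, `NA` missing), `map` (variant table), `lines` (line registry
#'   with `known_group` set for pure lines), and `truth` (`true_Q`, `true_P`
#'   with groups as rows, `ancestral_p`, `divergence_F`, `seed`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  map <- plant_map(cfg)
  K <- cfg$K_true
  m <- nrow(map)
  n <- cfg$n_lines

  anc <- with_seed(cfg$seed + 1L, runif(m, 0.05, 0.95))
  P <- with_seed(cfg$seed + 2L, {
    t(vapply(seq_len(K), function(k) {
      f <- cfg$divergence_F[k]
      rbeta(m, anc * (1 - f) / f, (1 - anc) * (1 - f) / f)
    }, numeric(m)))
  })

  Q <- with_seed(cfg$seed + 3L, {
    Q <- .rdirichlet(n, cfg$dirichlet_alpha)
    n_pure <- round(cfg$pure_fraction * n)
    if (n_pure > 0) {
      grp <- sample(rep_len(seq_len(K), n_pure))
      Q[seq_len(n_pure), ] <- 0
      Q[cbind(seq_len(n_pure), grp)] <- 1
    }
    Q
  })

  G <- with_seed(cfg$seed + 4L, {
    pi <- Q %*% P
    a1 <- matrix(rbinom(n * m, 1L, pi), n, m)
    a2 <- matrix(rbinom(n * m, 1L, pi), n, m)
    het <- matrix(runif(n * m) < cfg$residual_het_rate, n, m)
    ifelse(het, a1 + a2, 2L * a1)
  })
  if (cfg$missing_rate > 0) {
    miss <- with_seed(cfg$seed + 5L,
                      matrix(runif(n * m) < cfg$missing_rate, n, m))
    G[miss] <- NA_integer_
  }
  storage.mode(G) <- "integer"

  line_names <- sprintf("L%04d", seq_len(n))
  rownames(G) <- line_names
  colnames(G) <- map$locus_id
  pure <- rowSums(Q == 1) == 1
  lines <- data.frame(line = line_names, origin = "synthetic",
                      known_group = ifelse(pure,
                                           sprintf("G%d", max.col(Q)),
                                           NA_character_),
                      stringsAsFactors = FALSE)
  rownames(Q) <- line_names
  dimnames(P) <- list(sprintf("G%d", seq_len(K)), map$locus_id)
  colnames(Q) <- rownames(P)

  structure(list(genotypes = G, map = map, lines = lines,
                 truth = list(true_Q = Q, true_P = P, ancestral_p = anc,
                              divergence_F = cfg$divergence_F,
                              seed = cfg$seed),
                 config = cfg),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("Synthetic inbred panel: %d lines x %d loci on %d chromosome(s), K_true = %d\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chrom)), ncol(x$truth$true_Q)))
  invisible(x)
}

#' Simulate a panel of perfectly linked haplotype blocks
#'
#' Linkage enters by block copying: each block has a small pool of founder
#' haplotypes and every (fully homozygous) line copies one founder per block,
#' independently across blocks. Within a block all loci are maximally
#' associated; across blocks loci are independent. Used to validate LD-decay
#' and block-detection behaviour against a known block structure.
#'
#' @param n_lines Number of inbred lines.
#' @param n_blocks Number of blocks on one chromosome.
#' @param loci_per_block SNPs per block.
#' @param block_len_bp Physical span of each block.
#' @param gap_bp Gap between consecutive blocks.
#' @param n_founders Founder haplotypes per block (default 2).
#' @param seed Integer seed.
#' @return A `sim_panel`-like list with `genotypes`, `map`, and
#'   `truth$block_bounds` (start/end locus index and bp of each true block).
#' @export
simulate_block_panel <- function(n_lines = 100, n_blocks = 10,
                                 loci_per_block = 6, block_len_bp = 1e5,
                                 gap_bp = 4e5, n_founders = 2, seed = 1L) {
  stopifnot(n_founders >= 2, loci_per_block >= 1)
  with_seed(seed, {
    m <- n_blocks * loci_per_block
    G <- matrix(NA_integer_, n_lines, m)
    pos <- integer(m)
    bounds <- data.frame(block = seq_len(n_blocks), start_idx = NA_integer_,
                         end_idx = NA_integer_, start_bp = NA_integer_,
                         end_bp = NA_integer_)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1L) * loci_per_block + 1L):(b * loci_per_block)
      start <- as.integer((b - 1L) * (block_len_bp + gap_bp) + 1L)
      pos[idx] <- as.integer(round(seq(start, start + block_len_bp - 1,
                                       length.out = loci_per_block)))
      repeat { # founder pool must leave every locus polymorphic
        H <- matrix(rbinom(n_founders * loci_per_block, 1L, 0.5),
                    n_founders, loci_per_block)
        if (all(colSums(H) > 0 & colSums(H) < n_founders)) break
      }
      pick <- sample.int(n_founders, n_lines, replace = TRUE)
      G[, idx] <- 2L * H[pick, , drop = FALSE]
      bounds$start_idx[b] <- idx[1]; bounds$end_idx[b] <- idx[length(idx)]
      bounds$start_bp[b] <- pos[idx[1]]; bounds$end_bp[b] <- pos[idx[length(idx)]]
    }
    map <- data.frame(locus_id = sprintf("S1_%d", pos), chrom = "1",
                      pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
    rownames(G) <- sprintf("L%04d", seq_len(n_lines))
    colnames(G) <- map$locus_id
    structure(list(genotypes = G, map = map,
                   lines = data.frame(line = rownames(G),
                                      origin = "synthetic",
                                      known_group = NA_character_),
                   truth = list(block_bounds = bounds, seed = seed)),
              class = "sim_panel")
  })
}

#' Write a simulated panel and its generating truth to disk
#'
#' Writes the genotypes as plain-text VCF 4.2 and TASSEL-style HapMap, the
#' true Q and P matrices in whitespace-delimited (ADMIXTURE-compatible)
#' layout, and the generator configuration as a two-column TSV.
#'
#' @param panel A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             hapmap = file.path(dir, "panel.hmp.txt"),
             q = file.path(dir, "truth.Q"), p = file.path(dir, "truth.P"),
             config = file.path(dir, "sim_config.tsv"))
  write_vcf(panel$genotypes, panel$map, paths["vcf"])
  write_hapmap(panel$genotypes, panel$map, paths["hapmap"])
  if (!is.null(panel$truth$true_Q)) {
    write_q_matrix(panel$truth$true_Q, paths["q"])
    write_p_matrix(panel$truth$true_P, paths["p"])
  }
  cfg <- panel$config
  if (!is.null(cfg)) {
    flat <- vapply(cfg, function(v) paste(format(v, digits = 10),
                                          collapse = ","), "")
    write.table(data.frame(key = names(flat), value = flat),
                paths["config"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
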