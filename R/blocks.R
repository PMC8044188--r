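#' D' point estimate with profile-likelihood confidence bounds
#'
#' Evaluates the two-locus haplotype likelihood on a grid of 101 |D'|
#' values (allele frequencies fixed at their estimates, D signed as the
#' point estimate) and reads 90% bounds from the normalized likelihood
#' treated as a posterior over the grid, in the manner of Gabriel-style
#' block callers. Lines resolvable without phase contribute their two
#' haplotypes directly; double heterozygotes contribute the coupling/
#' repulsion mixture term.
#'
#' @param gi,gj Dosage vectors.
#' @param n_grid Grid size (default 101).
#' @param conf Confidence level (default 0.90).
#' @param min_informative Minimum pairwise-complete lines; below this the
#'   pair is reported uninformative (default 10).
#' @return List: `dprime`, `ci_low`, `ci_high`, `n`, `informative`.
#' @export
dprime_ci <- function(gi, gj, n_grid = 101, conf = 0.90,
                      min_informative = 10) {
  ok <- !is.na(gi) & !is.na(gj)
  n <- sum(ok)
  bad <- list(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n = n, informative = FALSE)
  if (n < min_informative) return(bad)
  gi <- gi[ok]; gj <- gj[ok]
  if (var(gi) == 0 || var(gj) == 0) return(bad)
  f <- .hap_freq_em(gi, gj)
  est <- .dprime_from_hap(f)
  if (is.na(est[["dprime"]])) return(bad)
  pA <- unname(f["10"] + f["11"])
  pB <- unname(f["01"] + f["11"])
  s <- if (est[["D"]] >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(bad)

  # resolvable haplotype counts and double-het count reproduce the EM data
  dh <- gi == 1L & gj == 1L
  a <- gi[!dh]; b <- gj[!dh]
  cnt <- vapply(c("00", "01", "10", "11"), function(h) {
    ai <- as.integer(substr(h, 1, 1)); bj <- as.integer(substr(h, 2, 2))
    wi <- ifelse(a == 1L, 1L, ifelse(a == 2L * ai, 2L, 0L))
    wj <- ifelse(b == 1L, 1L, ifelse(b == 2L * bj, 2L, 0L))
    sum(pmin(wi, wj))
  }, 0)
  n_dh <- sum(dh)

  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, function(dp) {
    D <- s * dp * dmax
    h <- c(`00` = (1 - pA) * (1 - pB) + D, `01` = (1 - pA) * pB - D,
           `10` = pA * (1 - pB) - D, `11` = pA * pB + D)
    h <- pmax(h, 1e-12)
    sum(cnt * log(h)) +
      if (n_dh > 0) n_dh * log(2 * h["00"] * h["11"] +
                                 2 * h["01"] * h["10"]) else 0
  }, 0)
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  alpha <- (1 - conf) / 2
  list(dprime = est[["dprime"]],
       ci_low = grid[which(cum >= alpha)[1]],
       ci_high = grid[which(cum >= 1 - alpha)[1]],
       n = n, informative = TRUE)
}

#' Gabriel-style haplotype blocks from D' confidence intervals
#'
#' A pair is "strong LD" when `ci_low >= strong_low` and
#' `ci_high >= strong_high`, and "strong recombination" when
#' `ci_high < recomb_high`; other pairs carry no evidence. A candidate span
#' is a block when its outermost pair is strong and at least `strong_frac`
#' of its evidence-bearing pairs are strong. Maximal non-overlapping spans
#' are kept longest-first (physical length, ties by leftmost start).
#' Heterozygous calls should be masked upstream
#' (see [subgroup_missing_mask()]).
#'
#' @param G Dosage matrix.
#' @param map Variant table.
#' @param chromosome Optional single chromosome label; default all.
#' @param max_span_bp Maximum physical block span considered (default
#'   500 kb).
#' @param strong_low,strong_high,recomb_high,strong_frac Gabriel rule
#'   thresholds (Haploview defaults 0.70 / 0.98 / 0.90 / 0.95).
#' @param min_informative Passed to [dprime_ci()].
#' @return Data frame, one row per block: `chrom`, `start_bp`, `end_bp`,
#'   `n_members`, and a list-column `members` of locus ids in map order.
#' @export
find_blocks <- function(G, map, chromosome = NULL, max_span_bp = 5e5,
                        strong_low = 0.70, strong_high = 0.98,
                        recomb_high = 0.90, strong_frac = 0.95,
                        min_informative = 10) {
  check_map(map, G)
  chroms <- if (is.null(chromosome)) chrom_order(map$chrom)
  else as.character(chromosome)
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_members = integer(0))
  empty$members <- list()
  all_blocks <- list(empty)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < 2L) next
    pos <- map$pos[idx]
    # pair classification: 1 strong, -1 recombination, 0 no evidence, NA far
    cls <- matrix(NA_integer_, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (pos[j] - pos[i] > max_span_bp) break
        ci <- dprime_ci(G[, idx[i]], G[, idx[j]],
                        min_informative = min_informative)
        cls[i, j] <- if (!ci$informative) 0L
        else if (ci$ci_low >= strong_low && ci$ci_high >= strong_high) 1L
        else if (ci$ci_high < recomb_high) -1L
        else 0L
      }
    }
    cand <- list()
    for (i in seq_len(m - 1L)) {
      n_strong <- 0L; n_evid <- 0L
      for (j in (i + 1L):m) {
        if (pos[j] - pos[i] > max_span_bp) break
        new <- cls[i:(j - 1L), j]
        n_strong <- n_strong + sum(new == 1L, na.rm = TRUE)
        n_evid <- n_evid + sum(new != 0L, na.rm = TRUE)
        if (!is.na(cls[i, j]) && cls[i, j] == 1L && n_evid > 0L &&
            n_strong / n_evid >= strong_frac) {
          cand[[length(cand) + 1L]] <- c(i = i, j = j,
                                         len = pos[j] - pos[i])
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "len"], cand[, "i"]), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      blk <- data.frame(chrom = ch, start_bp = pos[i], end_bp = pos[j],
                        n_members = j - i + 1L)
      blk$members <- list(map$locus_id[idx[i:j]])
      all_blocks[[length(all_blocks) + 1L]] <- blk
    }
  }
  out <- do.call(rbind, all_blocks)
  out <- out[order(match(out$chrom, chrom_order(out$chrom)), out$start_bp), ]
  rownames(out) <- NULL
  out
}

#' Greedy tagSNP selection within a block
#'
#' Repeatedly picks the member locus that tags (r-squared >= `r2_min`) the
#' most still-untagged members, breaking ties by lower position, until
#' every member is tagged. Every locus tags itself, so the cover always
#' completes.
#'
#' @param members Character vector of member locus ids (or column indices).
#' @param G Dosage matrix.
#' @param map Variant table (for tie-breaking positions).
#' @param r2_min Tagging threshold (default 0.8).
#' @return Character vector of tag locus ids, in selection order.
#' @export
select_tags <- function(members, G, map, r2_min = 0.8) {
  cols <- if (is.character(members)) match(members, colnames(G)) else members
  if (anyNA(cols)) stop("unknown member locus id(s)")
  k <- length(cols)
  ids <- colnames(G)[cols] %||% as.character(cols)
  pos <- map$pos[match(ids, map$locus_id)]
  covers <- diag(TRUE, k)
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r2 <- pair_ld(G[, cols[i]], G[, cols[j]])$r2
    covers[i, j] <- covers[j, i] <- !is.na(r2) && r2 >= r2_min
  }
  untagged <- rep(TRUE, k)
  tags <- integer(0)
  while (any(untagged)) {
    gain <- colSums(covers & untagged)
    best <- which(gain == max(gain))
    best <- best[order(pos[best])][1]
    tags <- c(tags, best)
    untagged <- untagged & !covers[, best]
  }
  ids[tags]
}

#' Block and tagSNP inventory for a whole panel
#'
#' Runs [find_blocks()] per chromosome and [select_tags()] per block;
#' loci outside any block are their own tags, so the tag set preserves the
#' panel's information at the chosen r-squared level.
#'
#' @inheritParams find_blocks
#' @param r2_min Tagging threshold.
#' @param include_singletons Include non-block loci as their own tags in
#'   `tag_loci` (default TRUE).
#' @return List: `blocks` (block table with a `tags` list-column),
#'   `tag_loci` (character vector), and `per_chrom` summary
#'   (`chrom`, `n_blocks`, `n_tags`).
#' @export
haplotype_blocks <- function(G, map, max_span_bp = 5e5, r2_min = 0.8,
                             include_singletons = TRUE, ...) {
  blocks <- find_blocks(G, map, max_span_bp = max_span_bp, ...)
  tags <- lapply(blocks$members, select_tags, G = G, map = map,
                 r2_min = r2_min)
  blocks$tags <- tags
  blocks$n_tags <- lengths(tags)
  block_tags <- unlist(tags, use.names = FALSE)
  in_block <- unlist(blocks$members, use.names = FALSE)
  tag_loci <- if (include_singletons)
    map$locus_id[map$locus_id %in% c(block_tags,
                                     setdiff(map$locus_id, in_block))]
  else block_tags
  per_chrom <- do.call(rbind, lapply(chrom_order(map$chrom), function(ch) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, n_blocks = nrow(b), n_tags = sum(b$n_tags))
  }))
  list(blocks = blocks, tag_loci = tag_loci, per_chrom = per_chrom)
}
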