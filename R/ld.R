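# two-locus haplotype frequency estimation by EM over unphased dosages.
# homozygous(-or-single-het) lines contribute known haplotypes; double
# heterozygotes are split between the coupling/repulsion phases by EM.
# returns c(p00, p01, p10, p11) haplotype freqs (locus1 allele, locus2
# allele; 1 = alternate) or NULL when no informative lines.
.hap_freq_em <- function(gi, gj, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (n < 2L) return(NULL)
  # known haplotype counts from resolvable lines
  cnt <- c(`00` = 0, `01` = 0, `10` = 0, `11` = 0)
  dh <- gi == 1L & gj == 1L
  a <- gi[!dh]; b <- gj[!dh]
  # each non-double-het line contributes two resolvable haplotypes
  for (h in c("00", "01", "10", "11")) {
    ai <- as.integer(substr(h, 1, 1)); bj <- as.integer(substr(h, 2, 2))
    # copies of allele ai at locus 1 paired with bj at locus 2:
    wi <- ifelse(a == 1L, 1L, ifelse(a == 2L * ai, 2L, 0L))
    wj <- ifelse(b == 1L, 1L, ifelse(b == 2L * bj, 2L, 0L))
    # for single-het lines phase is known because the other locus is hom
    cnt[h] <- sum(pmin(wi, wj))
  }
  n_dh <- sum(dh)
  tot <- 2 * n
  if (n_dh == 0L) return(cnt / tot)
  f <- (cnt + n_dh * c(0.5, 0.5, 0.5, 0.5)) / tot
  for (it in seq_len(max_iter)) {
    coup <- f["00"] * f["11"]
    rep_ <- f["01"] * f["10"]
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    f_new <- (cnt + n_dh * c(w, 1 - w, 1 - w, w)) / tot
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  names(f) <- c("00", "01", "10", "11")
  f
}

.dprime_from_hap <- function(f) {
  pA <- f["10"] + f["11"]  # alt freq at locus 1
  pB <- f["01"] + f["11"]
  D <- f["11"] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(c(D = unname(D), dprime = NA_real_))
  c(D = unname(D), dprime = unname(abs(D) / dmax))
}

#' Pairwise linkage disequilibrium between two loci
#'
#' r-squared is the squared Pearson correlation of the dosage vectors over
#' pairwise-complete lines (composite LD). D' is computed from two-locus
#' haplotype frequencies: lines homozygous at one or both loci contribute
#' known haplotypes and double heterozygotes are resolved by EM.
#'
#' @param gi,gj Dosage vectors for the two loci (same lines).
#' @return List: `r2`, `dprime`, `n` (pairwise-complete lines), and
#'   `defined` (`FALSE` when either locus is monomorphic on the complete
#'   subset; such pairs are skipped by callers).
#' @export
pair_ld <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  n <- sum(ok)
  if (n < 2L || var(gi[ok]) == 0 || var(gj[ok]) == 0)
    return(list(r2 = NA_real_, dprime = NA_real_, n = n, defined = FALSE))
  r <- cor(gi[ok], gj[ok])
  f <- .hap_freq_em(gi, gj)
  dp <- .dprime_from_hap(f)[["dprime"]]
  list(r2 = r * r, dprime = dp, n = n, defined = TRUE)
}

# all within-window pair r2 for one chromosome; returns data.frame
# (i, j, dist, r2) over defined pairs, pairs capped at max_dist_bp apart
.chrom_pairs_r2 <- function(G, pos, max_dist_bp) {
  m <- length(pos)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    j <- i + 1L
    js <- integer(0)
    while (j <= m && pos[j] - pos[i] <= max_dist_bp) {
      js <- c(js, j); j <- j + 1L
    }
    if (!length(js)) next
    r2 <- vapply(js, function(jj) {
      gi <- G[, i]; gj <- G[, jj]
      ok <- !is.na(gi) & !is.na(gj)
      if (sum(ok) < 2L) return(NA_real_)
      si <- sd(gi[ok]); sj <- sd(gj[ok])
      if (si == 0 || sj == 0) return(NA_real_)
      cor(gi[ok], gj[ok])^2
    }, 0)
    out[[i]] <- data.frame(i = i, j = js, dist = pos[js] - pos[i], r2 = r2)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(i = integer(0), j = integer(0),
                                      dist = numeric(0), r2 = numeric(0))
  res[!is.na(res$r2), , drop = FALSE]
}

#' Mean r-squared per fixed physical segment
#'
#' Divides each chromosome into consecutive segments of `segment_bp` and
#' averages r-squared over all locus pairs falling inside the same segment.
#' Segments with fewer than two usable loci emit no record. The resulting
#' track supports the familiar high/low LD banding plots.
#'
#' @param G Dosage matrix.
#' @param map Variant table.
#' @param segment_bp Segment length (default 50 kb).
#' @return Data frame: `chrom`, `start`, `end`, `n_loci`, `n_pairs`,
#'   `mean_r2`.
#' @export
segment_ld_map <- function(G, map, segment_bp = 5e4) {
  check_map(map, G)
  out <- lapply(chrom_order(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    seg <- (map$pos[idx] - 1) %/% segment_bp
    recs <- lapply(split(idx, seg), function(loci) {
      if (length(loci) < 2L) return(NULL)
      pr <- .chrom_pairs_r2(G[, loci, drop = FALSE], map$pos[loci], Inf)
      if (!nrow(pr)) return(NULL)
      s <- (map$pos[loci[1]] - 1) %/% segment_bp
      data.frame(chrom = ch, start = s * segment_bp + 1,
                 end = (s + 1) * segment_bp, n_loci = length(loci),
                 n_pairs = nrow(pr), mean_r2 = mean(pr$r2))
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' LD decay curve and decay distance
#'
#' Pairs within `max_dist_bp` (computed within chromosomes) are binned by
#' physical distance into log-spaced bins; per-bin mean r-squared values
#' are made monotone non-increasing by an isotonic fit, and the decay
#' distance is the midpoint of the first bin where the fitted curve falls
#' to or below `threshold_r2`. When the fit never reaches the threshold the
#' distance is censored at `max_dist_bp` (`censored = TRUE`); a threshold
#' at or above the initial fitted value gives distance 0.
#'
#' @param G Dosage matrix.
#' @param map Variant table.
#' @param max_dist_bp Maximum pair distance considered (default 1 Mb).
#' @param threshold_r2 Crossing threshold (default 0.1).
#' @param n_bins Number of log-spaced distance bins.
#' @param by_chrom Also return per-chromosome decay distances.
#' @return List: `curve` (data frame `bin_mid`, `n_pairs`, `mean_r2`,
#'   `fit_r2` pooled over chromosomes), `decay_bp`, `censored`,
#'   `mean_r2` (mean over all pairs), and if `by_chrom` a data frame
#'   `per_chrom` with the same quantities per chromosome.
#' @export
ld_decay <- function(G, map, max_dist_bp = 1e6, threshold_r2 = 0.1,
                     n_bins = 25, by_chrom = FALSE) {
  check_map(map, G)
  pairs <- lapply(chrom_order(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2L) return(NULL)
    pr <- .chrom_pairs_r2(G[, idx, drop = FALSE], map$pos[idx], max_dist_bp)
    if (nrow(pr)) pr$chrom <- ch
    pr
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || !nrow(pairs)) stop("no usable locus pairs for LD decay")

  decay_from_pairs <- function(pr) {
    lo <- log10(max(min(pr$dist), 1))
    hi <- log10(max(pr$dist))
    edges <- if (hi > lo) 10^seq(lo, hi, length.out = n_bins + 1) else
      c(min(pr$dist) - 0.5, max(pr$dist) + 0.5)
    bin <- cut(pr$dist, breaks = edges, include.lowest = TRUE, labels = FALSE)
    mids <- sqrt(edges[-length(edges)] * pmax(edges[-1], 1))
    tab <- tapply(pr$r2, bin, mean)
    n_tab <- tapply(pr$r2, bin, length)
    used <- as.integer(names(tab))
    curve <- data.frame(bin_mid = mids[used], n_pairs = as.integer(n_tab),
                        mean_r2 = as.numeric(tab))
    curve <- curve[order(curve$bin_mid), ]
    # isotonic non-increasing fit
    ir <- isoreg(curve$bin_mid, -curve$mean_r2)
    curve$fit_r2 <- -ir$yf
    cross <- which(curve$fit_r2 <= threshold_r2)
    if (threshold_r2 >= curve$fit_r2[1]) {
      decay <- 0; cens <- FALSE
    } else if (length(cross)) {
      decay <- curve$bin_mid[cross[1]]; cens <- FALSE
    } else {
      decay <- max_dist_bp; cens <- TRUE
    }
    list(curve = curve, decay_bp = decay, censored = cens,
         mean_r2 = mean(pr$r2))
  }

  res <- decay_from_pairs(pairs)
  if (by_chrom) {
    per <- lapply(split(pairs, pairs$chrom), function(pr) {
      d <- decay_from_pairs(pr)
      data.frame(chrom = pr$chrom[1], n_pairs = nrow(pr),
                 mean_r2 = d$mean_r2, decay_bp = d$decay_bp,
                 censored = d$censored)
    })
    per <- do.call(rbind, per)
    per <- per[order(match(per$chrom, chrom_order(per$chrom))), ]
    rownames(per) <- NULL
    res$per_chrom <- per
  }
  res
}
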