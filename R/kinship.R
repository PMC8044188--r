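#' Genomic kinship matrix (centered relationship, zero-floored report)
#'
#' VanRaden-style centered genomic relationship:
#' K = Z Z' / (2 sum p_j (1 - p_j)), where Z is the dosage matrix with each
#' column centered at 2 p_j and missing calls imputed to the column mean.
#' Monomorphic loci are excluded. For the "relative kinship" report,
#' negative off-diagonal values are floored at zero (unrelated); the raw
#' centered matrix is retained alongside.
#'
#' @param G Dosage matrix (lines x loci).
#' @return Object of class `kinship_matrix`: list with `values` (floored),
#'   `raw`, `n_loci_used`.
#' @export
kinship_matrix <- function(G) {
  check_genotypes(G)
  p <- alt_freq(G)
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least two polymorphic loci for kinship")
  Gp <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(Gp, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  flo <- K
  off <- row(K) != col(K)
  flo[off] <- pmax(flo[off], 0)
  structure(list(values = flo, raw = K, n_loci_used = sum(poly)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Kinship matrix: %d lines, %d loci used\n",
              nrow(x$values), x$n_loci_used))
  ut <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal: mean %.4f, %.1f%% below 0.05\n",
              mean(ut), 100 * mean(ut < 0.05)))
  invisible(x)
}

#' Histogram of pairwise relative kinship
#'
#' Bins the off-diagonal upper triangle of the floored kinship matrix and
#' reports the fractions below / at-or-above 0.05, the conventional
#' near-zero relatedness cut.
#'
#' @param K A [kinship_matrix()] (or a plain symmetric matrix).
#' @param breaks Bin edges (default steps of 0.05 up to 0.5, then 1).
#' @return List: `histogram` (data frame `bin`, `n`, `fraction`, summing to
#'   1), `fraction_below_0.05`, `fraction_at_or_above_0.05`.
#' @export
kinship_histogram <- function(K, breaks = c(seq(0, 0.5, by = 0.05), 1)) {
  v <- if (inherits(K, "kinship_matrix")) K$values else K
  ut <- v[upper.tri(v)]
  breaks[length(breaks)] <- max(breaks[length(breaks)], max(ut) + 1e-9)
  cutv <- cut(ut, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tab <- table(cutv)
  list(histogram = data.frame(bin = names(tab), n = as.integer(tab),
                              fraction = as.integer(tab) / length(ut)),
       fraction_below_0.05 = mean(ut < 0.05),
       fraction_at_or_above_0.05 = mean(ut >= 0.05))
}
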