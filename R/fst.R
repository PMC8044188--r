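#' Pairwise Fst between two groups from allele frequencies
#'
#' Default is the Nei-style ratio of sums over loci:
#' Fst = sum_j (H_T,j - H_S,j) / sum_j H_T,j, with H_S the mean of the two
#' within-group gene diversities 2 p q and H_T the gene diversity of the
#' pooled mean frequency. `method = "wc"` gives the Weir-Cockerham (1984)
#' two-population estimator instead (requires per-group sample sizes; the
#' within-individual term is taken as zero, appropriate for inbred panels
#' with heterozygotes masked).
#'
#' @param p_a,p_b Per-locus alternate-allele frequencies of the two groups.
#' @param n_a,n_b Group sample sizes (lines), required for `method = "wc"`.
#' @param method `"nei"` (default) or `"wc"`.
#' @return Scalar Fst in `[0, 1]`.
#' @export
fst_pairwise <- function(p_a, p_b, n_a = NULL, n_b = NULL,
                         method = c("nei", "wc")) {
  method <- match.arg(method)
  ok <- !is.na(p_a) & !is.na(p_b)
  if (!any(ok)) stop("no loci with defined frequencies in both groups")
  p_a <- p_a[ok]; p_b <- p_b[ok]
  if (method == "nei") {
    hs <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
    pbar <- (p_a + p_b) / 2
    ht <- 2 * pbar * (1 - pbar)
    if (sum(ht) == 0) return(0)
    max(0, sum(ht - hs) / sum(ht))
  } else {
    if (is.null(n_a) || is.null(n_b))
      stop("method = 'wc' needs per-group sample sizes n_a, n_b")
    r <- 2
    nbar <- (n_a + n_b) / 2
    nc <- (r * nbar - (n_a^2 + n_b^2) / (r * nbar)) / (r - 1)
    pbar <- (n_a * p_a + n_b * p_b) / (r * nbar)
    s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    if (sum(a + b) == 0) return(0)
    min(1, max(0, sum(a) / sum(a + b)))
  }
}

#' Pairwise Fst matrix between all groups
#'
#' @param freqs Groups x loci allele-frequency matrix (e.g. a fitted P, or
#'   observed subgroup frequencies from [group_freqs()]).
#' @param ... Passed to [fst_pairwise()].
#' @return Symmetric K x K matrix with zero diagonal and group dimnames.
#' @export
fst_matrix <- function(freqs, ...) {
  K <- nrow(freqs)
  if (K < 2) stop("need at least two groups")
  labs <- rownames(freqs) %||% sprintf("G%d", seq_len(K))
  M <- matrix(0, K, K, dimnames = list(labs, labs))
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    M[i, j] <- M[j, i] <- fst_pairwise(freqs[i, ], freqs[j, ], ...)
  M
}

#' UPGMA tree of group differentiation
#'
#' Average-linkage agglomeration on the pairwise Fst distances; ties are
#' resolved deterministically by label order. The returned `phylo` tree is
#' ultrametric with leaf-to-root height half the largest merge distance.
#'
#' @param fst Symmetric Fst matrix with group dimnames.
#' @return An [ape::as.phylo()] tree; write with [ape::write.tree()].
#' @export
fst_tree <- function(fst) {
  if (nrow(fst) < 2) stop("need at least two groups for a tree")
  hc <- hclust(as.dist(fst), method = "average")
  ape::as.phylo(hc)
}

#' PCA coordinates of a genotype panel
#'
#' Eigendecomposition of the centered (optionally frequency-standardized)
#' dosage matrix: missing calls are imputed to the locus mean, columns are
#' centered at 2p and, with `standardize = TRUE`, scaled by
#' sqrt(2 p (1 - p)). Components are ordered by variance; each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param G Dosage matrix.
#' @param n_components Number of components returned.
#' @param standardize Scale loci by their expected standard deviation.
#' @return List: `scores` (lines x components), `var_explained`, `sdev`,
#'   `rotation`.
#' @export
pca_coordinates <- function(G, n_components = 10, standardize = TRUE) {
  check_genotypes(G)
  if (nrow(G) < 2) stop("need at least two lines")
  p <- alt_freq(G)
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least two polymorphic loci")
  X <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0
  if (standardize) X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  n_components <- min(n_components, nrow(G) - 1L, ncol(X))
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = n_components)
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  list(scores = pc$x, var_explained = pc$sdev^2 / sum(pc$sdev^2),
       sdev = pc$sdev, rotation = pc$rotation)
}
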