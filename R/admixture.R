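#' Admixture-model log-likelihood
#'
#' For line i and locus j with dosage g_ij and expected alternate-allele
#' frequency pi_ij = sum_k Q_ik P_kj, the contribution is
#' g_ij log(pi_ij) + (2 - g_ij) log(1 - pi_ij); missing calls are skipped.
#' P is clamped to `[eps, 1 - eps]` so the value is always finite.
#'
#' @param G Dosage matrix (lines x loci).
#' @param Q Lines x K admixture proportions.
#' @param P K x loci group allele frequencies.
#' @param eps Clamping bound (default 1e-6).
#' @return Scalar log-likelihood.
#' @export
admixture_loglik <- function(G, Q, P, eps = 1e-6) {
  if (nrow(G) != nrow(Q) || ncol(G) != ncol(P) || ncol(Q) != nrow(P))
    stop("shape mismatch between G, Q and P")
  pi <- Q %*% pmin(pmax(P, eps), 1 - eps)
  pi <- pmin(pmax(pi, eps), 1 - eps)
  sum(G * log(pi) + (2 - G) * log(1 - pi), na.rm = TRUE)
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of admixture proportions Q (lines x K) and
#' ancestral-group allele frequencies P (K x loci) for a fixed number of
#' groups K, by expectation-maximization on the binomial dosage likelihood.
#' The log-likelihood is non-decreasing along the trace; the fit is
#' deterministic given `seed`. Several random restarts are run and the best
#' likelihood kept. Group labels are arbitrary up to permutation; columns
#' are reported sorted by descending total Q mass.
#'
#' @param G Dosage matrix (lines x loci, codes 0/1/2, `NA` missing).
#' @param K Number of ancestral groups (>= 1, <= number of lines).
#' @param seed Integer seed for the restarts' initialization.
#' @param n_restarts Random restarts (default 5; best kept).
#' @param max_iter Maximum EM sweeps per restart (default 2000).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param eps Frequency clamping bound.
#' @return Object of class `admixture_fit` with elements `Q`, `P`, `K`,
#'   `loglik`, `trace`, `n_iter`, `converged`, `genotypes`.
#' @seealso [cv_error()] for choosing K, [fst_matrix()] for between-group
#'   differentiation from the fitted P.
#' @export
fit_admixture <- function(G, K, seed = 1L, n_restarts = 5, max_iter = 2000,
                          tol = 1e-6, eps = 1e-6) {
  check_genotypes(G)
  n <- nrow(G); m <- ncol(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K must not exceed the number of lines")
  p_obs <- alt_freq(G)
  if (all(is.na(p_obs) | p_obs == 0 | p_obs == 1))
    stop("panel is monomorphic; nothing to fit")
  p_obs[is.na(p_obs)] <- 0.5
  storage.mode(G) <- "integer"

  if (K == 1L) {
    Q <- matrix(1, n, 1)
    P <- matrix(pmin(pmax(p_obs, eps), 1 - eps), 1, m)
    ll <- admixture_loglik(G, Q, P, eps)
    fit <- list(Q = Q, P = P, trace = ll, iterations = 0L, converged = TRUE)
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- with_seed(seed + r - 1L, {
        Q0 <- .rdirichlet(n, rep(1, K))
        noise <- matrix(runif(K * m, -0.1, 0.1), K, m)
        P0 <- pmin(pmax(matrix(p_obs, K, m, byrow = TRUE) + noise, eps),
                   1 - eps)
        list(Q0 = Q0, P0 = P0)
      })
      res <- admixture_em_cpp(G, init$Q0, init$P0, max_iter, tol, eps)
      if (is.null(best) || max(res$trace) > max(best$trace)) best <- res
    }
    fit <- best
  }
  ord <- order(colSums(fit$Q), decreasing = TRUE)
  Q <- fit$Q[, ord, drop = FALSE]
  P <- fit$P[ord, , drop = FALSE]
  rownames(Q) <- rownames(G)
  colnames(Q) <- sprintf("G%d", seq_len(K))
  dimnames(P) <- list(colnames(Q), colnames(G))
  structure(list(Q = Q, P = P, K = K, loglik = max(fit$trace),
                 trace = fit$trace, n_iter = fit$iterations,
                 converged = fit$converged, n_restarts = n_restarts,
                 seed = seed, genotypes = G, call = match.call()),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit: %d lines x %d loci, K = %d\n",
              nrow(x$Q), ncol(x$P), x$K))
  cat(sprintf("  log-likelihood %.2f after %d EM iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) " (converged)" else " (iteration cap)"))
  tab <- table(factor(colnames(x$Q)[max.col(x$Q)], levels = colnames(x$Q)))
  cat("  lines per group (by max Q): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  grp <- colnames(object$Q)[max.col(object$Q)]
  out <- data.frame(group = colnames(object$Q),
                    total_q = colSums(object$Q),
                    n_max_q = as.integer(table(factor(grp,
                                                      colnames(object$Q)))),
                    mean_max_q = vapply(colnames(object$Q), function(g) {
                      v <- apply(object$Q[grp == g, , drop = FALSE], 1, max)
                      if (length(v)) mean(v) else NA_real_
                    }, 0),
                    row.names = NULL)
  structure(list(groups = out, loglik = object$loglik, K = object$K,
                 n_iter = object$n_iter, converged = object$converged),
            class = "summary.admixture_fit")
}

#' @export
print.summary.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture fit, K = %d, log-likelihood %.2f\n", x$K, x$loglik))
  print(x$groups, digits = 3)
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = nrow(object$Q) * (object$K - 1) + object$K * ncol(object$P),
            nobs = sum(!is.na(object$genotypes)), class = "logLik")
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' @export
fitted.admixture_fit <- function(object, ...) 2 * object$Q %*% object$P

#' @export
residuals.admixture_fit <- function(object, ...)
  object$genotypes - fitted(object)

#' @export
predict.admixture_fit <- function(object,
                                  type = c("dosage", "frequency"), ...) {
  type <- match.arg(type)
  pi <- object$Q %*% object$P
  if (type == "frequency") pi else 2 * pi
}

#' @export
simulate.admixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pi <- object$Q %*% object$P
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      g <- matrix(rbinom(length(pi), 2L, pi), nrow(pi), ncol(pi),
                  dimnames = dimnames(object$genotypes))
      g
    })
  })
}

#' @export
plot.admixture_fit <- function(x, ...) {
  barplot(t(x$Q), col = seq_len(x$K) + 1L, border = NA, space = 0,
          xlab = "line", ylab = "admixture proportion Q",
          legend.text = colnames(x$Q), ...)
  invisible(x)
}

#' Masking cross-validation error for choosing K
#'
#' Hides a fold of the observed (non-missing) genotype entries, refits the
#' admixture model on the remainder, and scores the held-out dosages
#' against their fitted expectation 2 * Q P by mean squared error; the
#' reported value is the average over folds. Deterministic given `seed`.
#'
#' @param G Dosage matrix.
#' @param K Number of groups.
#' @param n_folds Number of folds (default 5).
#' @param mask_rate Optional fraction of observed entries masked per fold;
#'   by default the observed entries are partitioned into `n_folds` equal
#'   disjoint folds. `mask_rate = 0` is an error (no held-out entries).
#' @param seed Integer seed.
#' @param n_restarts,max_iter,tol Fit settings for the per-fold refits
#'   (lighter defaults than [fit_admixture()]: K selection is robust to
#'   loose per-fold convergence).
#' @return Scalar cross-validation error.
#' @export
cv_error <- function(G, K, n_folds = 5, mask_rate = NULL, seed = 1L,
                     n_restarts = 1, max_iter = 200, tol = 1e-5) {
  check_genotypes(G)
  obs <- which(!is.na(G))
  if (!is.null(mask_rate) && mask_rate <= 0)
    stop("mask_rate must be positive: no held-out entries to score")
  folds <- with_seed(seed, {
    if (is.null(mask_rate)) {
      perm <- sample(obs)
      split(perm, rep_len(seq_len(n_folds), length(perm)))
    } else {
      lapply(seq_len(n_folds), function(f)
        sample(obs, max(1L, round(mask_rate * length(obs)))))
    }
  })
  errs <- vapply(seq_along(folds), function(f) {
    hold <- folds[[f]]
    Gm <- G
    Gm[hold] <- NA_integer_
    fit <- fit_admixture(Gm, K, seed = seed + 1000L * f,
                         n_restarts = n_restarts, max_iter = max_iter,
                         tol = tol)
    pred <- 2 * (fit$Q %*% fit$P)
    mean((G[hold] - pred[hold])^2)
  }, 0)
  mean(errs)
}

#' Cross-validation curve over a range of K
#'
#' @param G Dosage matrix.
#' @param K_values Integer vector of candidate K.
#' @param ... Passed to [cv_error()].
#' @return List: `table` (data frame `K`, `cv_error`) and `best_K`
#'   (the argmin).
#' @export
cv_select_k <- function(G, K_values = 1:6, ...) {
  errs <- vapply(K_values, function(k) cv_error(G, k, ...), 0)
  tab <- data.frame(K = K_values, cv_error = errs)
  list(table = tab, best_K = K_values[which.min(errs)])
}

#' Match estimated groups to reference groups
#'
#' Resolves label switching by the column permutation of `Q_est` minimizing
#' the mean absolute difference to `Q_ref` (exhaustive over permutations;
#' intended for small K).
#'
#' @param Q_est,Q_ref Lines x K matrices.
#' @return List: `perm` (columns of `Q_est` reordered to match `Q_ref`),
#'   `Q_matched`, `mean_abs_error`.
#' @export
match_groups <- function(Q_est, Q_ref) {
  K <- ncol(Q_ref)
  stopifnot(ncol(Q_est) == K, nrow(Q_est) == nrow(Q_ref))
  if (K > 7) stop("exhaustive matching supported for K <= 7")
  perms <- .permutations(K)
  err <- apply(perms, 1, function(pr)
    mean(abs(Q_est[, pr, drop = FALSE] - Q_ref)))
  best <- perms[which.min(err), ]
  list(perm = best, Q_matched = Q_est[, best, drop = FALSE],
       mean_abs_error = min(err))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}
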