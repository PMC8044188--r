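#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded helpers do not disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# dosage matrix sanity: integer-ish lines x loci in {0,1,2,NA}
check_genotypes <- function(G) {
  if (!is.matrix(G)) stop("genotypes must be a matrix (lines x loci)")
  v <- G[!is.na(G)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  invisible(G)
}

# alternate-allele frequency per locus from non-missing calls
# (hets contribute one copy of each allele)
alt_freq <- function(G) {
  n_called <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  p
}

# natural sort of chromosome labels: numeric labels numerically, rest after
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  ord <- order(is.na(num), num, u)
  u[ord]
}

sort_map <- function(map) {
  lev <- chrom_order(map$chrom)
  map[order(match(as.character(map$chrom), lev), map$pos), , drop = FALSE]
}

check_map <- function(map, G = NULL) {
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("variant table needs columns locus_id, chrom, pos")
  key <- paste(map$chrom, map$pos)
  if (anyDuplicated(key)) stop("duplicate (chromosome, position) in map")
  if (!is.null(G) && ncol(G) != nrow(map))
    stop("genotype matrix and variant table disagree on locus count")
  invisible(map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
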