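#' Per-group allele frequencies from assigned lines
#'
#' For each requested group, pools the lines whose assignment base group
#' matches (Para lines count with their base group; Mixed lines belong to
#' no group), masks residual heterozygotes, and computes the
#' alternate-allele frequency as alt copies / (2 x non-missing calls).
#' Groups below `min_lines` are excluded with a warning.
#'
#' @param G Dosage matrix.
#' @param assignments Output of [assign_groups()] (rows matched to `G` by
#'   line name).
#' @param groups Character vector of group labels to tabulate.
#' @param min_lines Minimum lines per group (default 10).
#' @return List: `freqs` (groups x loci matrix, `NA` where a group has no
#'   calls) and `n_lines` (named count of lines used per group).
#' @export
group_freqs <- function(G, assignments, groups, min_lines = 10) {
  check_genotypes(G)
  keep <- character(0)
  rows <- list()
  n_used <- integer(0)
  for (g in groups) {
    lines <- assignments$line[assignments$base_group == g]
    lines <- intersect(lines, rownames(G))
    if (length(lines) < min_lines) {
      warning("group ", g, " has ", length(lines), " line(s) < ", min_lines,
              "; excluded")
      next
    }
    Gg <- G[lines, , drop = FALSE]
    Gg[Gg == 1L] <- NA_integer_  # residual hets treated as missing
    n_called <- colSums(!is.na(Gg))
    f <- colSums(Gg, na.rm = TRUE) / (2 * n_called)
    f[n_called == 0] <- NA_real_
    rows[[g]] <- f
    keep <- c(keep, g)
    n_used[g] <- length(lines)
  }
  if (!length(rows)) stop("no group met the minimum line count")
  freqs <- do.call(rbind, rows)
  dimnames(freqs) <- list(keep, colnames(G))
  list(freqs = freqs, n_lines = n_used)
}

#' Thresholds for group-specific locus classification
#'
#' Numeric operationalization of "unique", "neutral" and "fixed":
#' a locus is polymorphic in a group when its within-group MAF is at least
#' `poly_min`; "neutral" means a frequency inside `neutral_band`; "fixed"
#' means a frequency outside `fixed_band` (near 0 or near 1, i.e. either
#' allele close to fixation); "differential" means an absolute
#' between-group frequency difference of at least `diff_min`.
#'
#' @param poly_min Polymorphism cut on within-group MAF (default 0.05).
#' @param neutral_band Two-vector frequency band (default `c(0.30, 0.70)`).
#' @param fixed_band Two-vector band whose outside counts as fixed
#'   (default `c(0.10, 0.90)`).
#' @param diff_min Minimum absolute frequency difference (default 0.50).
#' @return A `locus_class_thresholds` list.
#' @export
locus_class_thresholds <- function(poly_min = 0.05,
                                   neutral_band = c(0.30, 0.70),
                                   fixed_band = c(0.10, 0.90),
                                   diff_min = 0.50) {
  t <- list(poly_min = poly_min, neutral_band = neutral_band,
            fixed_band = fixed_band, diff_min = diff_min)
  v <- unlist(t)
  if (any(v < 0) || any(v > 1) || diff(neutral_band) <= 0 ||
      diff(fixed_band) <= 0)
    stop("classification thresholds must be ordered bands within [0, 1]")
  class(t) <- "locus_class_thresholds"
  t
}

#' Classify loci by group-specific allele-frequency patterns
#'
#' Flags, per locus and independently (a locus may carry several):
#' `unique_a` / `unique_b` — segregating (MAF >= `poly_min`) in exactly
#' that group; `neutral_a_fixed_b` / `neutral_b_fixed_a` — neutral
#' frequency in one group, near-fixed (either allele) in the other;
#' `differential` — absolute frequency difference >= `diff_min`.
#'
#' @param freq_a,freq_b Per-locus alternate-allele frequencies of groups A
#'   and B.
#' @param thresholds A [locus_class_thresholds()].
#' @return Data frame of logical flag columns plus `class`, a
#'   comma-separated label (`"none"` when no flag applies). Loci with an
#'   undefined frequency in either group get all-`NA` flags.
#' @export
classify_loci <- function(freq_a, freq_b,
                          thresholds = locus_class_thresholds()) {
  t <- thresholds
  maf_a <- pmin(freq_a, 1 - freq_a)
  maf_b <- pmin(freq_b, 1 - freq_b)
  poly_a <- maf_a >= t$poly_min
  poly_b <- maf_b >= t$poly_min
  neutral_a <- freq_a >= t$neutral_band[1] & freq_a <= t$neutral_band[2]
  neutral_b <- freq_b >= t$neutral_band[1] & freq_b <= t$neutral_band[2]
  fixed_a <- freq_a < t$fixed_band[1] | freq_a > t$fixed_band[2]
  fixed_b <- freq_b < t$fixed_band[1] | freq_b > t$fixed_band[2]
  out <- data.frame(unique_a = poly_a & !poly_b,
                    unique_b = poly_b & !poly_a,
                    neutral_a_fixed_b = neutral_a & fixed_b,
                    neutral_b_fixed_a = neutral_b & fixed_a,
                    differential = abs(freq_a - freq_b) >= t$diff_min)
  flags <- names(out)
  out$class <- apply(out, 1, function(r) {
    if (anyNA(r)) NA_character_
    else if (!any(r)) "none"
    else paste(flags[which(r)], collapse = ",")
  })
  out
}

#' Per-locus frequency-difference table between two groups
#'
#' Table of the allele frequencies in groups A and B and their exact
#' difference P_A - P_B, sorted by chromosome and position.
#'
#' @param freq_a,freq_b Per-locus frequencies (named by locus id, or
#'   aligned with `map`).
#' @param map Variant table supplying chromosome, position and allele.
#' @return Data frame: `locus_id`, `chrom`, `pos`, `allele`, `p_a`, `p_b`,
#'   `diff`.
#' @export
diff_table <- function(freq_a, freq_b, map) {
  check_map(map)
  stopifnot(length(freq_a) == nrow(map), length(freq_b) == nrow(map))
  out <- data.frame(locus_id = map$locus_id, chrom = map$chrom,
                    pos = map$pos,
                    allele = map$alt %||% rep(NA_character_, nrow(map)),
                    p_a = as.numeric(freq_a), p_b = as.numeric(freq_b),
                    diff = as.numeric(freq_a) - as.numeric(freq_b),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, chrom_order(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Per-chromosome counts of group-specific locus classes
#'
#' @param classes Output of [classify_loci()].
#' @param map Variant table aligned with `classes`.
#' @return Data frame with one row per chromosome plus a `Total` row, and
#'   one column per class flag.
#' @export
class_count_table <- function(classes, map) {
  flags <- c("unique_a", "unique_b", "neutral_a_fixed_b",
             "neutral_b_fixed_a", "differential")
  per <- lapply(chrom_order(map$chrom), function(ch) {
    idx <- map$chrom == ch
    cbind(data.frame(chrom = ch),
          as.data.frame(lapply(classes[idx, flags, drop = FALSE],
                               sum, na.rm = TRUE)))
  })
  per <- do.call(rbind, per)
  tot <- cbind(data.frame(chrom = "Total"),
               as.data.frame(lapply(classes[, flags, drop = FALSE],
                                    sum, na.rm = TRUE)))
  rbind(per, tot)
}
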