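#' Per-locus diversity statistics
#'
#' For each locus, computes from the non-missing calls: alternate-allele
#' frequency p (heterozygotes contribute one copy of each allele), minor
#' allele frequency MAF = min(p, 1-p), gene diversity GD = 1 - (p^2 + q^2),
#' polymorphic information content PIC = GD - 2 p^2 q^2 (biallelic form),
#' heterozygote fraction H, and missing rate. All-missing loci get `NA`
#' statistics and `defined = FALSE`; summaries exclude them.
#'
#' @param G Dosage matrix (lines x loci).
#' @return Data frame with one row per locus: `locus_id`, `p`, `maf`, `gd`,
#'   `pic`, `het`, `missing_rate`, `defined`.
#' @export
locus_stats <- function(G) {
  check_genotypes(G)
  n <- nrow(G)
  n_called <- colSums(!is.na(G))
  p <- alt_freq(G)
  q <- 1 - p
  gd <- 1 - (p^2 + q^2)
  data.frame(locus_id = colnames(G) %||% as.character(seq_len(ncol(G))),
             p = p, maf = pmin(p, q), gd = gd, pic = gd - 2 * p^2 * q^2,
             het = ifelse(n_called > 0,
                          colSums(G == 1L, na.rm = TRUE) / n_called, NA),
             missing_rate = 1 - n_called / n,
             defined = n_called > 0, row.names = NULL)
}

#' Panel-level diversity summary
#'
#' Per-chromosome and global means of the per-locus statistics, locus
#' counts, and marker density (loci per bp of spanned map).
#'
#' @param G Dosage matrix.
#' @param map Variant table matching `G`.
#' @return Data frame with one row per chromosome plus a final `all` row:
#'   `chrom`, `n_loci`, `span_bp`, `density_per_mb`, `mean_maf`, `mean_gd`,
#'   `mean_pic`, `mean_het`.
#' @export
panel_summary <- function(G, map) {
  check_map(map, G)
  st <- locus_stats(G)
  one <- function(idx, label) {
    s <- st[idx, , drop = FALSE]
    s <- s[s$defined, , drop = FALSE]
    span <- if (label == "all") {
      sum(vapply(split(map$pos[idx], map$chrom[idx]),
                 function(p) diff(range(p)) + 1, 0))
    } else diff(range(map$pos[idx])) + 1
    data.frame(chrom = label, n_loci = sum(idx), span_bp = span,
               density_per_mb = sum(idx) / span * 1e6,
               mean_maf = mean(s$maf), mean_gd = mean(s$gd),
               mean_pic = mean(s$pic), mean_het = mean(s$het))
  }
  chroms <- chrom_order(map$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) one(map$chrom == ch, ch)))
  rbind(out, one(rep(TRUE, nrow(map)), "all"))
}

#' Moving-window mean gene diversity along chromosomes
#'
#' Windows of `window_bp` advanced by `step_bp` (default one tenth of the
#' window); windows containing no locus emit no record.
#'
#' @param G Dosage matrix.
#' @param map Variant table.
#' @param window_bp Window size in bp (default 10 Mb).
#' @param step_bp Step between window starts (default `window_bp / 10`).
#' @return Data frame: `chrom`, `start`, `end`, `n_loci`, `mean_gd`.
#' @export
windowed_gd <- function(G, map, window_bp = 1e7, step_bp = window_bp / 10) {
  check_map(map, G)
  gd <- locus_stats(G)$gd
  out <- lapply(chrom_order(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    starts <- seq(1, max(pos), by = step_bp)
    recs <- lapply(starts, function(s) {
      inw <- idx[pos >= s & pos < s + window_bp]
      vals <- gd[inw]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(NULL)
      data.frame(chrom = ch, start = s, end = s + window_bp - 1,
                 n_loci = length(vals), mean_gd = mean(vals))
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' SNP density track
#'
#' Locus counts in fixed, non-overlapping bins along each chromosome.
#'
#' @param map Variant table.
#' @param bin_bp Bin width in bp.
#' @return Data frame: `chrom`, `start`, `end`, `n_loci` (empty bins
#'   included with zero counts, up to the last occupied bin).
#' @export
snp_density_track <- function(map, bin_bp = 1e6) {
  check_map(map)
  out <- lapply(chrom_order(map$chrom), function(ch) {
    pos <- map$pos[map$chrom == ch]
    bin <- (pos - 1) %/% bin_bp
    tab <- tabulate(bin + 1L, nbins = max(bin) + 1L)
    data.frame(chrom = ch, start = (seq_along(tab) - 1) * bin_bp + 1,
               end = seq_along(tab) * bin_bp, n_loci = tab)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Distances between adjacent loci
#'
#' Distances are taken within chromosomes only, giving
#' `n_loci - n_chromosomes` values, and summarized in the customary
#' banded histogram (0-0.1 kb, 0.1-1 kb, ..., > 75 kb).
#'
#' @param map Variant table (sorted).
#' @param bands Band edges in bp.
#' @return List: `distances` (integer vector) and `histogram` (data frame
#'   `band`, `n`, `fraction`).
#' @export
adjacent_distances <- function(map,
                               bands = c(0, 100, 1000, 5000, 10000, 25000,
                                         50000, 75000, Inf)) {
  check_map(map)
  map <- sort_map(map)
  d <- unlist(lapply(split(map$pos, map$chrom), diff), use.names = FALSE)
  cut_lab <- paste0(head(bands, -1) / 1000, "-",
                    ifelse(is.infinite(tail(bands, -1)), "Inf",
                           tail(bands, -1) / 1000), "kb")
  counts <- if (length(d)) {
    table(cut(d, breaks = bands, labels = cut_lab, include.lowest = TRUE))
  } else table(factor(character(0), levels = cut_lab))
  hist <- data.frame(band = names(counts), n = as.integer(counts),
                     fraction = if (length(d)) as.integer(counts) / length(d)
                                else 0)
  list(distances = as.integer(d), histogram = hist)
}
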