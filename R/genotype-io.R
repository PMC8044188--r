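#' Read a VCF file into a dosage panel
#'
#' Parses a VCF 4.x with [vcfR::read.vcfR()], keeps biallelic SNP records
#' only (others are skipped with a message), and converts unphased GT calls
#' to alternate-allele dosages: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2,
#' `./.` -> `NA`. Phased separators are accepted and treated as unphased.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A list: `genotypes` (lines x loci integer matrix), `map`
#'   (variant table with `locus_id`, `chrom`, `pos`, `ref`, `alt`),
#'   `lines` (line registry). Loci are sorted by (chromosome, position).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) {
    warning("no biallelic SNP records in ", path)
    return(list(genotypes = matrix(integer(0), 0, 0),
                map = data.frame(locus_id = character(0),
                                 chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0)),
                lines = data.frame(line = character(0))))
  }
  gt <- vcfR::extract.gt(v[snp, ], element = "GT")
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  codes[gt %in% "0/0"] <- 0L
  codes[gt %in% c("0/1", "1/0")] <- 1L
  codes[gt %in% "1/1"] <- 2L
  fix <- fix[snp, , drop = FALSE]
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               sprintf("S%s_%s", fix$CHROM, fix$POS), fix$ID)
  map <- data.frame(locus_id = id, chrom = as.character(fix$CHROM),
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  G <- t(codes)
  ord <- order(match(map$chrom, chrom_order(map$chrom)), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  G <- G[, ord, drop = FALSE]
  colnames(G) <- map$locus_id
  check_map(map, G)
  list(genotypes = G, map = map,
       lines = data.frame(line = rownames(G), origin = NA_character_,
                          known_group = NA_character_,
                          stringsAsFactors = FALSE))
}

#' Write a dosage panel as plain-text VCF 4.2
#'
#' @param G Lines x loci dosage matrix (`NA` missing).
#' @param map Variant table matching `G`'s columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, map, path) {
  check_genotypes(G); check_map(map, G)
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    calls <- ifelse(is.na(G[, j]), "./.", gt_code[G[, j] + 1L])
    paste(c(map$chrom[j], map$pos[j], map$locus_id[j], map$ref[j],
            map$alt[j], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popstructr",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

.iupac_het <- c(AC = "M", CA = "M", AG = "R", GA = "R", AT = "W", TA = "W",
                CG = "S", GC = "S", CT = "Y", TC = "Y", GT = "K", TG = "K")

#' Read a TASSEL-style HapMap genotype file
#'
#' Expects the TASSEL HapMap dialect: columns `rs#`, `alleles` (e.g. `A/G`),
#' `chrom`, `pos`, then metadata columns, then one call per line. Calls may
#' be single-letter (IUPAC: homozygote = the base, heterozygote = ambiguity
#' code) or two-letter (`AG`); `N`/`NN` is missing. A call inconsistent with
#' the declared alleles is set missing, counted, and reported by message.
#'
#' @param path Path to the HapMap text file.
#' @return Same structure as [read_vcf()].
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- 11L  # rs#..QCcode, TASSEL layout
  if (ncol(tab) <= meta_cols) stop("malformed HapMap file: no sample columns")
  alle <- strsplit(tab[["alleles"]], "/", fixed = TRUE)
  ref <- vapply(alle, `[`, "", 1L)
  alt <- vapply(alle, `[`, "", 2L)
  samp <- as.matrix(tab[, (meta_cols + 1L):ncol(tab), drop = FALSE])
  m <- nrow(tab)
  G <- matrix(NA_integer_, ncol(samp), m,
              dimnames = list(colnames(samp), tab[[1L]]))
  n_bad <- 0L
  for (j in seq_len(m)) {
    calls <- toupper(samp[j, ])
    het1 <- .iupac_het[[paste0(ref[j], alt[j])]]
    code <- rep(NA_integer_, length(calls))
    code[calls == ref[j] | calls == strrep(ref[j], 2L)] <- 0L
    code[calls == alt[j] | calls == strrep(alt[j], 2L)] <- 2L
    code[calls == het1 | calls == paste0(ref[j], alt[j]) |
           calls == paste0(alt[j], ref[j])] <- 1L
    missing_call <- calls %in% c("N", "NN", "", "-")
    n_bad <- n_bad + sum(is.na(code) & !missing_call)
    G[, j] <- code
  }
  if (n_bad > 0)
    message(n_bad, " call(s) inconsistent with declared alleles set missing")
  map <- data.frame(locus_id = tab[[1L]], chrom = as.character(tab[["chrom"]]),
                    pos = as.integer(tab[["pos"]]), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  ord <- order(match(map$chrom, chrom_order(map$chrom)), map$pos)
  map <- map[ord, , drop = FALSE]; rownames(map) <- NULL
  G <- G[, ord, drop = FALSE]
  colnames(G) <- map$locus_id
  check_map(map, G)
  list(genotypes = G, map = map,
       lines = data.frame(line = rownames(G), origin = NA_character_,
                          known_group = NA_character_,
                          stringsAsFactors = FALSE))
}

#' Write a dosage panel as TASSEL-style HapMap text
#'
#' Homozygotes are written as the doubled base is abbreviated to the single
#' IUPAC base, heterozygotes as the IUPAC ambiguity code, missing as `N`.
#'
#' @inheritParams write_vcf
#' @return Invisibly, `path`.
#' @export
write_hapmap <- function(G, map, path) {
  check_genotypes(G); check_map(map, G)
  hdr <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode", rownames(G))
  rows <- vapply(seq_len(ncol(G)), function(j) {
    het <- .iupac_het[[paste0(map$ref[j], map$alt[j])]]
    calls <- c(map$ref[j], het, map$alt[j])[G[, j] + 1L]
    calls[is.na(calls)] <- "N"
    paste(c(map$locus_id[j], paste0(map$ref[j], "/", map$alt[j]),
            map$chrom[j], map$pos[j], "+", "NA", "NA", "NA", "NA", "NA",
            "NA", calls), collapse = "\t")
  }, "")
  writeLines(c(paste(hdr, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read/write admixture Q and P matrices
#'
#' Whitespace-delimited numeric matrices in the layout ADMIXTURE uses:
#' a `.Q` file has one row per line (K columns); a `.P` file has one row per
#' locus (K columns) and is transposed on read so that in memory `P` is
#' groups x loci. Q rows are renormalized to sum to 1 when within 1e-3 of 1
#' and rejected otherwise.
#'
#' @param path File path.
#' @return `read_q_matrix`: lines x K matrix; `read_p_matrix`: K x loci
#'   matrix.
#' @export
read_q_matrix <- function(path) {
  Q <- as.matrix(read.table(path, header = FALSE))
  if (!is.numeric(Q)) stop("non-numeric Q matrix in ", path)
  s <- rowSums(Q)
  if (any(abs(s - 1) > 1e-3))
    stop("Q row(s) do not sum to 1 within 1e-3: rows ",
         paste(which(abs(s - 1) > 1e-3), collapse = ", "))
  Q <- Q / s
  dimnames(Q) <- NULL
  Q
}

#' @rdname read_q_matrix
#' @export
read_p_matrix <- function(path) {
  P <- as.matrix(read.table(path, header = FALSE))
  if (!is.numeric(P)) stop("non-numeric P matrix in ", path)
  if (any(P < 0 | P > 1)) stop("P entries outside [0, 1] in ", path)
  dimnames(P) <- NULL
  t(P)
}

#' @rdname read_q_matrix
#' @param Q,P Matrices to write (P given as groups x loci).
#' @export
write_q_matrix <- function(Q, path) {
  write.table(format(Q, digits = 6, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_q_matrix
#' @export
write_p_matrix <- function(P, path) {
  write.table(format(t(P), digits = 6, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locus quality-control thresholds
#'
#' Defaults follow the common GBS panel practice of dropping loci with minor
#' allele frequency below 5%, missing rate above 20%, or residual
#' heterozygosity above 5%.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param missing_max Maximum missing-call rate.
#' @param het_max Maximum heterozygous-call fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, missing_max = 0.20,
                          het_max = 0.05) {
  t <- list(maf_min = maf_min, missing_max = missing_max, het_max = het_max)
  if (any(unlist(t) < 0) || any(unlist(t) > 1))
    stop("QC thresholds must be in [0, 1]")
  class(t) <- "qc_thresholds"
  t
}

#' Filter loci by MAF, missing rate and residual heterozygosity
#'
#' Retains loci with MAF >= `maf_min`, missing rate <= `missing_max` and
#' heterozygote fraction (of non-missing calls) <= `het_max`. MAF counts a
#' heterozygous call as one copy of each allele and is computed on
#' non-missing calls. The criteria are independent conjunctions on the raw
#' calls, so the filter is idempotent and order-free. A locus failing
#' several criteria is counted once per criterion but removed once.
#'
#' @param G Dosage matrix.
#' @param map Optional variant table, subset alongside.
#' @param thresholds A [qc_thresholds()].
#' @return List: `genotypes`, `map` (if given), `keep` (logical per locus),
#'   and `report` (data.frame criterion / n_removed, plus totals).
#' @export
qc_filter <- function(G, map = NULL, thresholds = qc_thresholds()) {
  check_genotypes(G)
  n <- nrow(G)
  n_called <- colSums(!is.na(G))
  miss <- 1 - n_called / n
  p <- alt_freq(G)
  maf <- pmin(p, 1 - p)
  het <- colSums(G == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  fail_miss <- miss > thresholds$missing_max
  fail_het <- het > thresholds$het_max
  keep <- !(fail_maf | fail_miss | fail_het)
  report <- data.frame(
    criterion = c("maf", "missing", "het", "removed_total", "retained"),
    n = c(sum(fail_maf), sum(fail_miss), sum(fail_het), sum(!keep),
          sum(keep)))
  out <- list(genotypes = G[, keep, drop = FALSE], keep = keep,
              report = report)
  if (!is.null(map)) {
    out$map <- map[keep, , drop = FALSE]
    rownames(out$map) <- NULL
  }
  out
}

#' Mask residual heterozygotes and drop high-missing loci
#'
#' The subgroup-analysis convention: every heterozygous call is treated as
#' missing, then loci whose resulting missing rate exceeds
#' `loci_missing_max` are dropped.
#'
#' @param G Dosage matrix.
#' @param map Optional variant table, subset alongside.
#' @param loci_missing_max Maximum post-masking missing rate (default 0.10).
#' @return List: `genotypes`, `keep`, and `map` if given. The returned
#'   matrix contains no heterozygous calls.
#' @export
subgroup_missing_mask <- function(G, map = NULL, loci_missing_max = 0.10) {
  check_genotypes(G)
  G[G == 1L] <- NA_integer_
  keep <- colMeans(is.na(G)) <= loci_missing_max
  out <- list(genotypes = G[, keep, drop = FALSE], keep = keep)
  if (!is.null(map)) {
    out$map <- map[keep, , drop = FALSE]
    rownames(out$map) <- NULL
  }
  out
}
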