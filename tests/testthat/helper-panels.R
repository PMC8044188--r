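# small fixture builders shared across test files

# tiny deterministic panel: 4 lines x 3 loci with one het and one missing
toy_panel <- function() {
  G <- matrix(c(0L, 2L, 2L, 0L,
                1L, 2L, 0L, 0L,
                2L, NA, 2L, 2L), nrow = 4,
              dimnames = list(paste0("L", 1:4), c("S1_100", "S1_200",
                                                  "S2_50")))
  map <- data.frame(locus_id = colnames(G), chrom = c("1", "1", "2"),
                    pos = c(100L, 200L, 50L), ref = c("A", "C", "G"),
                    alt = c("G", "T", "A"), stringsAsFactors = FALSE)
  list(G = G, map = map)
}

# homozygous dosage columns realizing given two-locus haplotype counts
# (each inbred line = one haplotype doubled)
hap_columns <- function(n_ab = 0, n_aB = 0, n_Ab = 0, n_AB = 0) {
  gi <- c(rep(0L, n_ab), rep(0L, n_aB), rep(2L, n_Ab), rep(2L, n_AB))
  gj <- c(rep(0L, n_ab), rep(2L, n_aB), rep(0L, n_Ab), rep(2L, n_AB))
  list(gi = gi, gj = gj)
}

# genotype matrix from founder haplotypes and per-line founder picks
mat_from_haps <- function(H, picks) {
  G <- 2L * H[picks, , drop = FALSE]
  rownames(G) <- sprintf("L%03d", seq_along(picks))
  colnames(G) <- sprintf("S1_%d", seq_len(ncol(H)) * 1000L)
  G
}

simple_map <- function(G, chrom = "1", spacing = 1000L) {
  data.frame(locus_id = colnames(G), chrom = chrom,
             pos = seq_len(ncol(G)) * spacing, ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}
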