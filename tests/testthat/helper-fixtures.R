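# Shared fixtures: tiny gene models and alignments built in code.

# 60-bp toy gene: 10 bp 5'UTR, exon(9) - intron(21) - exon(12), 8 bp 3'UTR.
# CDS length 21 (7 codons).
toy_gene_model <- function() {
  gene_model(tibble::tibble(
    label = c("five_prime_utr", "exon_1", "intron_1", "exon_2", "three_prime_utr"),
    start = c(0, 10, 19, 40, 52),
    end   = c(10, 19, 40, 52, 60)
  ))
}

# An alignment of n copies of a base sequence with named substitutions:
# subs is a list of list(pos = 0-based, base = "X", rows = indices).
make_alignment <- function(base_seq, n, subs = list()) {
  chars <- strsplit(base_seq, "")[[1]]
  m <- matrix(rep(chars, each = n), nrow = n)
  for (s in subs) m[s$rows, s$pos + 1L] <- s$base
  rownames(m) <- paste0("seq_", seq_len(n))
  m
}

# A valid coding backbone for toy_gene_model: no stops in the 7 codons.
toy_base_seq <- function() {
  utr5 <- "ACGTACGTAC"            # 10
  exon1 <- "ATGGGGTAT"            # ATG GGG TAT
  intron1 <- "GTAAGTACGTACGTACGAG" # 21... needs to be 21
  exon2 <- "CATCCCAAATGG"         # CAT CCC AAA TGG
  utr3 <- "ACGTACGT"              # 8
  paste0(utr5, exon1, substr(paste0(intron1, "CCCCC"), 1, 21), exon2, utr3)
}

# Brute-force pi: average pairwise difference proportion over usable columns.
brute_force_pi <- function(m, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(m)) - 1L
  cols <- positions + 1L
  usable <- vapply(cols, function(j) {
    col <- m[, j]
    !any(col %in% c("-", ".", "N")) && length(unique(col)) <= 2L
  }, logical(1))
  cols <- cols[usable]
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(m[i, cols] != m[j, cols])
  }
  total / (n * (n - 1) / 2) / length(cols)
}

# Genotypes built from known phased haplotypes (2 rows per individual).
genotypes_from_haplotypes <- function(H) {
  n <- nrow(H) / 2
  G <- H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(G) <- sprintf("ind_%03d", seq_len(n))
  colnames(G) <- sprintf("SNP%d", seq_len(ncol(G)))
  G
}
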