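# Readers and writers for the standard formats the pipeline touches:
# FASTA alignments (Biostrings), VCF v4.2 genotypes (vcfR on read, a plain
# serializer on write), and TSV genotype / phenotype / matrix tables.
# Round-trips preserve values exactly.

#' Read a FASTA haplotype alignment
#' @param path FASTA file of equal-length aligned sequences.
#' @return Uppercase character alignment matrix.
#' @export
read_alignment_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  as_alignment_matrix(as.character(seqs))
}

#' Write an alignment as FASTA
#' @param alignment Alignment (see [as_alignment_matrix()]).
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  m <- as_alignment_matrix(alignment)
  seqs <- apply(m, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, rownames(m))), path)
  invisible(path)
}

#' Read a genotype TSV
#'
#' Dialect: an `individual_id` column plus one column per SNP with dosages
#' 0/1/2 and `NA` for missing.
#'
#' @param path TSV path.
#' @return Dosage matrix with individual row names.
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$individual_id
  G <- as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- ids
  G
}

#' Write a genotype TSV
#' @param genotypes Dosage matrix with row names.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(individual_id = rownames(genotypes)),
    tibble::as_tibble(as.data.frame(genotypes)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses GT fields of a VCF (v4.2) into a dosage matrix under
#' minor-allele orientation: the counted allele is the minor allele in the
#' file's samples, so `0/0`, `0/1`, `1/1` become 0/1/2 when ALT is minor
#' (and 2/1/0 otherwise). `./.` becomes `NA`.
#'
#' @param path VCF path.
#' @param orient `"minor"` (default) or `"alt"` (count ALT alleles as
#'   written).
#' @return A list: `genotypes` (individuals x SNPs), `positions` (0-based),
#'   `snp_ids`.
#' @export
read_genotypes_vcf <- function(path, orient = c("minor", "alt")) {
  orient <- match.arg(orient)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|.", "."), NA_integer_,
           stringr::str_count(x, "1"))
  }
  G <- apply(gt, 2, count_alt)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1, dimnames = list(NULL, names(G)))
  G <- t(G)  # individuals x SNPs
  colnames(G) <- rownames(gt)
  if (orient == "minor") {
    for (j in seq_len(ncol(G))) {
      f <- mean(G[, j], na.rm = TRUE) / 2
      if (!is.na(f) && f > 0.5) G[, j] <- 2L - G[, j]
    }
  }
  pos <- as.integer(v@fix[, "POS"]) - 1L
  list(genotypes = G, positions = pos, snp_ids = rownames(gt))
}

#' Write genotypes as VCF v4.2
#'
#' Serializes a dosage matrix as unphased GT calls (`0/0`, `0/1`, `1/1`,
#' `./.`), counting the ALT allele; REF/ALT bases are bookkeeping labels
#' unless supplied.
#'
#' @param genotypes Individuals x SNPs dosage matrix with row names.
#' @param path Output path.
#' @param positions 0-based bp positions (written 1-based).
#' @param chrom Chromosome/contig label.
#' @param ref,alt Optional allele base vectors.
#' @export
write_genotypes_vcf <- function(genotypes, path, positions = NULL,
                                chrom = "gene", ref = NULL, alt = NULL) {
  G <- as.matrix(genotypes)
  m <- ncol(G); n <- nrow(G)
  if (is.null(positions)) positions <- seq_len(m) - 1L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("SNP%d", seq_len(m))
  gt_of <- function(g) {
    ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cgassoc",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c(chrom, positions[j] + 1L, ids[j], ref[j], alt[j], ".", "PASS",
            ".", "GT", gt_of(G[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype TSV (`individual_id` + one column per trait)
#' @param path TSV path.
#' @return A tibble.
#' @export
read_phenotypes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a numeric matrix TSV with an `individual_id` first column
#' (Q or K matrices).
#' @param path TSV path.
#' @return Numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}

#' Write a numeric matrix as TSV with an `individual_id` first column
#' @param M Matrix with row names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(M)),
                         tibble::as_tibble(as.data.frame(M)))
  readr::write_tsv(df, path)
  invisible(path)
}
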