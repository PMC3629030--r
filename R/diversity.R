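# Nucleotide-polymorphism summaries of a haplotype alignment.
#
# All statistics operate on haplotype (phased, haploid) sequences; columns
# containing a gap and columns with more than two alleles are excluded from
# both the site counts and the per-site denominators.

region_positions <- function(model, region = NULL) {
  if (is.null(region)) return(seq_len(model$total_length) - 1L)
  reg <- model$regions[model$regions$label %in% region, , drop = FALSE]
  if (nrow(reg) == 0L) stop("unknown region: ", paste(region, collapse = ", "),
                            call. = FALSE)
  unlist(purrr::map2(reg$start, reg$end, function(s, e) seq.int(s, e - 1L)))
}

check_min_sequences <- function(aln) {
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 2L) stop("at least 2 sequences are required", call. = FALSE)
  m
}

#' Count segregating sites
#'
#' Number of biallelic columns (two distinct non-gap bases) among the
#' requested positions, excluding gap-containing and multiallelic columns.
#'
#' @param alignment Haplotype alignment (see [as_alignment_matrix()]).
#' @param positions Optional integer vector of 0-based column positions
#'   (default: all columns).
#' @return Integer count.
#' @export
segregating_sites <- function(alignment, positions = NULL) {
  m <- check_min_sequences(alignment)
  info <- alignment_column_info(m)
  if (!is.null(positions)) {
    if (length(positions) == 0L) {
      warning("empty region: 0 segregating sites", call. = FALSE)
      return(0L)
    }
    info <- info[info$position %in% positions, , drop = FALSE]
  }
  sum(info$segregating)
}

pairwise_diff_stats <- function(info) {
  seg <- info[info$segregating, , drop = FALSE]
  total_n <- seg$major_count + seg$minor_count
  diffs <- as.numeric(seg$major_count) * as.numeric(seg$minor_count)
  pairs <- as.numeric(total_n) * (total_n - 1) / 2
  sum(ifelse(pairs > 0, diffs / pairs, 0))
}

#' Nucleotide diversity (pi)
#'
#' Average over all unordered sequence pairs of the per-site difference
#' proportion, computed over usable (gap-free, at most biallelic) columns.
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity, or `NA` if no usable columns.
#' @export
nucleotide_diversity <- function(alignment, positions = NULL) {
  m <- check_min_sequences(alignment)
  info <- alignment_column_info(m)
  if (!is.null(positions)) info <- info[info$position %in% positions, , drop = FALSE]
  L <- sum(info$usable)
  if (L == 0L) {
    warning("all columns excluded; pi undefined", call. = FALSE)
    return(NA_real_)
  }
  pairwise_diff_stats(info) / L
}

#' Watterson's theta
#'
#' `theta_w = S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)` the harmonic
#' number of the sample size, `S` the segregating-site count and `L` the
#' usable column count.
#'
#' @inheritParams segregating_sites
#' @return Per-site Watterson estimate.
#' @export
watterson_theta <- function(alignment, positions = NULL) {
  m <- check_min_sequences(alignment)
  info <- alignment_column_info(m)
  if (!is.null(positions)) info <- info[info$position %in% positions, , drop = FALSE]
  L <- sum(info$usable)
  if (L == 0L) {
    warning("all columns excluded; theta_w undefined", call. = FALSE)
    return(NA_real_)
  }
  n <- nrow(m)
  a_n <- sum(1 / seq_len(n - 1L))
  sum(info$segregating) / (a_n * L)
}

#' SNP frequency as bp per SNP
#'
#' `round(length_bp / S)` with half rounded away from zero; `S = 0` yields
#' `NA` (no-SNP sentinel).
#'
#' @param length_bp Region length (possibly fractional).
#' @param S Segregating-site count.
#' @return Integer bp-per-SNP.
#' @examples
#' snp_frequency(4374, 243)  # 18
#' @export
snp_frequency <- function(length_bp, S) {
  stopifnot(all(S >= 0))
  out <- ifelse(S > 0, floor(length_bp / S + 0.5), NA_real_)
  as.integer(out)
}

#' Per-region nucleotide-polymorphism table
#'
#' One row per UTR/exon/intron region, per-exon synonymous and
#' nonsynonymous partitions (fractional site denominators from
#' Nei-Gojobori counting on the consensus coding sequence), gene-level
#' silent (noncoding + synonymous), synonymous and nonsynonymous
#' aggregates, and a gene total. The ratio of nonsynonymous to synonymous
#' diversity is attached as the `pi_ratio` attribute and reported by
#' [glance.cg_diversity()].
#'
#' @param alignment Haplotype alignment whose length equals the gene-model
#'   length.
#' @param model A `cg_gene_model`.
#' @param classifications Optional precomputed result of
#'   [classify_alignment_sites()].
#' @return A tibble of class `cg_diversity` with columns `region`,
#'   `partition`, `length_bp`, `n_sequences`, `S`, `percent_polymorphism`,
#'   `pi`, `theta_w`, `bp_per_snp`.
#' @export
diversity_table <- function(alignment, model, classifications = NULL) {
  m <- check_min_sequences(alignment)
  if (ncol(m) != model$total_length) {
    stop("alignment length must equal gene-model length", call. = FALSE)
  }
  if (is.null(classifications)) {
    classifications <- classify_alignment_sites(m, model)
  }
  info <- alignment_column_info(m)
  n <- nrow(m)
  a_n <- sum(1 / seq_len(n - 1L))
  cons <- consensus_sequence(m)
  cmap <- cds_map(model)

  # per-CDS-base synonymous fractions from the consensus coding sequence
  cds_cons <- cons[cmap$genomic_pos + 1L]
  if (model$strand == "-") cds_cons <- rev(chartr("ACGT", "TGCA", cds_cons))
  syn_frac_cds <- count_syn_nonsyn_sites(paste(cds_cons, collapse = ""),
                                         per_position = TRUE)
  # map back to genomic positions (syn fraction per coding genomic base)
  syn_frac <- rep(NA_real_, model$total_length)
  cds_order <- order(cmap$cds_pos)
  syn_frac[cmap$genomic_pos[cds_order] + 1L] <- syn_frac_cds

  seg_syn <- classifications$position[!classifications$excluded &
                                        classifications$coding_effect %in% "synonymous"]
  seg_nonsyn <- classifications$position[!classifications$excluded &
    classifications$coding_effect %in% c("missense", "nonsense")]

  col_pi <- rep(0, model$total_length)
  seg <- info[info$segregating, , drop = FALSE]
  tn <- seg$major_count + seg$minor_count
  col_pi[seg$position + 1L] <-
    as.numeric(seg$major_count) * seg$minor_count / (tn * (tn - 1) / 2)

  usable <- info$usable

  summarize_positions <- function(pos, length_override = NULL) {
    upos <- pos[usable[pos + 1L]]
    L <- if (is.null(length_override)) length(upos) else length_override
    S <- sum(info$segregating[upos + 1L])
    pi_sum <- sum(col_pi[upos + 1L])
    tibble::tibble(
      length_bp = L,
      n_sequences = n,
      S = as.integer(S),
      percent_polymorphism = if (L > 0) 100 * S / L else NA_real_,
      pi = if (L > 0) pi_sum / L else NA_real_,
      theta_w = if (L > 0) S / (a_n * L) else NA_real_,
      bp_per_snp = if (L > 0 && S > 0) snp_frequency(L, S) else NA_integer_
    )
  }

  # syn/nonsyn partitions restricted to a set of coding genomic positions
  summarize_partition <- function(pos, which = c("synonymous", "nonsynonymous")) {
    which <- match.arg(which)
    cpos <- pos[!is.na(syn_frac[pos + 1L])]
    upos <- cpos[usable[cpos + 1L]]
    frac <- syn_frac[upos + 1L]
    L <- if (which == "synonymous") sum(frac) else sum(1 - frac)
    seg_pos <- if (which == "synonymous") seg_syn else seg_nonsyn
    sel <- intersect(upos, seg_pos)
    S <- length(sel)
    pi_sum <- sum(col_pi[sel + 1L])
    tibble::tibble(
      length_bp = L,
      n_sequences = n,
      S = as.integer(S),
      percent_polymorphism = if (L > 0) 100 * S / L else NA_real_,
      pi = if (L > 0) pi_sum / L else NA_real_,
      theta_w = if (L > 0) S / (a_n * L) else NA_real_,
      bp_per_snp = NA_integer_
    )
  }

  rows <- list()
  for (i in seq_len(nrow(model$regions))) {
    lab <- model$regions$label[i]
    pos <- region_positions(model, lab)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(region = lab, partition = "all"), summarize_positions(pos))
    if (grepl("^exon_", lab)) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(region = lab, partition = "synonymous"),
        summarize_partition(pos, "synonymous"))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(region = lab, partition = "nonsynonymous"),
        summarize_partition(pos, "nonsynonymous"))
    }
  }

  all_pos <- region_positions(model)
  exon_pos <- region_positions(model, grep("^exon_", model$regions$label, value = TRUE))
  noncoding_pos <- setdiff(all_pos, cmap$genomic_pos)

  syn_row <- summarize_partition(exon_pos, "synonymous")
  nonsyn_row <- summarize_partition(exon_pos, "nonsynonymous")

  # total silent = noncoding + synonymous
  nc <- summarize_positions(noncoding_pos)
  silent <- tibble::tibble(
    length_bp = nc$length_bp + syn_row$length_bp,
    n_sequences = n,
    S = nc$S + syn_row$S,
    percent_polymorphism = NA_real_, pi = NA_real_, theta_w = NA_real_,
    bp_per_snp = NA_integer_
  )
  silent$percent_polymorphism <- 100 * silent$S / silent$length_bp
  silent$pi <- (nc$pi * nc$length_bp + syn_row$pi * syn_row$length_bp) / silent$length_bp
  silent$theta_w <- silent$S / (a_n * silent$length_bp)
  silent$bp_per_snp <- snp_frequency(silent$length_bp, silent$S)

  rows[[length(rows) + 1L]] <- dplyr::bind_cols(
    tibble::tibble(region = "total_silent", partition = "all"), silent)
  rows[[length(rows) + 1L]] <- dplyr::bind_cols(
    tibble::tibble(region = "total", partition = "synonymous"), syn_row)
  rows[[length(rows) + 1L]] <- dplyr::bind_cols(
    tibble::tibble(region = "total", partition = "nonsynonymous"), nonsyn_row)
  rows[[length(rows) + 1L]] <- dplyr::bind_cols(
    tibble::tibble(region = "total", partition = "all"), summarize_positions(all_pos))

  out <- dplyr::bind_rows(rows)
  pi_ratio <- if (!is.na(syn_row$pi) && isTRUE(syn_row$pi > 0)) {
    nonsyn_row$pi / syn_row$pi
  } else NA_real_
  attr(out, "pi_ratio") <- pi_ratio
  class(out) <- c("cg_diversity", class(out))
  out
}

#' @describeIn diversity_table one-line gene-total summary (total S, pi,
#'   theta_w, bp per SNP and the pi_nonsyn/pi_syn ratio).
#' @param x A `cg_diversity` table.
#' @param ... Unused.
#' @export
glance.cg_diversity <- function(x, ...) {
  tot <- x[x$region == "total" & x$partition == "all", ]
  tibble::tibble(
    length_bp = tot$length_bp,
    n_sequences = tot$n_sequences,
    S = tot$S,
    percent_polymorphism = tot$percent_polymorphism,
    pi = tot$pi,
    theta_w = tot$theta_w,
    bp_per_snp = tot$bp_per_snp,
    pi_nonsyn_over_pi_syn = attr(x, "pi_ratio")
  )
}
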