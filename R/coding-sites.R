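BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) {
    stop("cannot translate codon(s): ",
         paste(unique(codon[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  unname(aa)
}

#' Classify a single-base coding change
#'
#' Compares a reference codon to an alternate codon differing at exactly
#' one position under the standard nuclear genetic code: `synonymous` if
#' the amino acid is unchanged, `nonsense` if the alternate codon is a
#' stop, `missense` otherwise.
#'
#' @param ref_codon,alt_codon 3-mers over A/C/G/T. The reference codon may
#'   not be a stop codon.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`.
#' @examples
#' classify_coding_change("GGG", "GGA")  # Gly -> Gly
#' classify_coding_change("TAT", "CAT")  # Tyr -> His
#' classify_coding_change("TGG", "TGA")  # Trp -> stop
#' @export
classify_coding_change <- function(ref_codon, alt_codon) {
  check_codon <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || nchar(x) != 3L ||
        !all(strsplit(x, "")[[1]] %in% BASES)) {
      stop(what, " must be a 3-mer over A/C/G/T (ambiguous bases unclassifiable): ",
           x, call. = FALSE)
    }
  }
  check_codon(ref_codon, "ref_codon")
  check_codon(alt_codon, "alt_codon")
  ndiff <- sum(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
  if (ndiff != 1L) stop("codons must differ at exactly one position", call. = FALSE)
  ref_aa <- translate_codon(ref_codon)
  if (ref_aa == "*") stop("reference codon is a stop codon", call. = FALSE)
  alt_aa <- translate_codon(alt_codon)
  if (alt_aa == "*") return("nonsense")
  if (alt_aa == ref_aa) return("synonymous")
  "missense"
}

# Per-position synonymous fraction of one codon: for each of the 3 codon
# positions, the fraction of the 3 possible single-base changes that
# preserve the amino acid (stop-creating changes count as nonsynonymous,
# the standard Nei-Gojobori convention).
codon_syn_fractions <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  ref_aa <- translate_codon(codon)
  if (ref_aa == "*") stop("stop codon has no site counts", call. = FALSE)
  vapply(1:3, function(j) {
    alts <- setdiff(BASES, b[j])
    syn <- vapply(alts, function(a) {
      alt <- b; alt[j] <- a
      translate_codon(paste(alt, collapse = "")) == ref_aa
    }, logical(1))
    sum(syn) / 3
  }, numeric(1))
}

#' Nei-Gojobori synonymous/nonsynonymous site counting
#'
#' For every codon position of a coding sequence the synonymous fraction
#' is the number of single-base changes preserving the amino acid divided
#' by 3; synonymous and nonsynonymous sites partition the coding length
#' exactly.
#'
#' @param coding_sequence Nucleotide string, length divisible by 3, no
#'   internal stop codons.
#' @param per_position If `TRUE` return the per-base synonymous fractions
#'   (numeric vector of length `nchar(coding_sequence)`) instead of totals.
#' @return A tibble with `synonymous_sites` and `nonsynonymous_sites`
#'   (unless `per_position`).
#' @examples
#' count_syn_nonsyn_sites("GGG")  # 1 synonymous + 2 nonsynonymous sites
#' @export
count_syn_nonsyn_sites <- function(coding_sequence, per_position = FALSE) {
  n <- nchar(coding_sequence)
  if (n %% 3L != 0L) stop("coding sequence length must be divisible by 3", call. = FALSE)
  codons <- substring(coding_sequence, seq(1, n, 3), seq(3, n, 3))
  aas <- translate_codon(codons)
  internal_stop <- which(aas == "*")
  internal_stop <- setdiff(internal_stop, length(codons))  # terminal stop tolerated
  if (length(internal_stop) > 0L) {
    stop("internal stop codon at codon index ",
         paste(internal_stop, collapse = ", "), call. = FALSE)
  }
  fractions <- unlist(lapply(seq_along(codons), function(i) {
    if (aas[i] == "*") c(0, 0, 0) else codon_syn_fractions(codons[i])
  }))
  if (per_position) return(fractions)
  tibble::tibble(
    synonymous_sites = sum(fractions),
    nonsynonymous_sites = n - sum(fractions)
  )
}

# ---- alignment handling ----------------------------------------------------

#' Coerce sequences to an alignment matrix
#'
#' Accepts a character matrix (sequences x columns), a character vector of
#' equal-length sequences, or a `Biostrings::DNAStringSet`, and returns an
#' uppercase character matrix.
#'
#' @param x Sequences.
#' @return Character matrix with one row per sequence.
#' @export
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    x <- as.character(x)
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else if (is.character(x)) {
    if (length(unique(nchar(x))) != 1L) {
      stop("aligned sequences must all have the same length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else {
    stop("cannot interpret input as an alignment", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq_", seq_len(nrow(m)))
  m
}

# Per-column summary used by the diversity and classification code.
# A column is usable when it contains no gap and at most two distinct bases.
alignment_column_info <- function(aln) {
  m <- as_alignment_matrix(aln)
  n <- nrow(m)
  has_gap <- apply(m, 2, function(col) any(col %in% c("-", ".", "N")))
  info <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    tab <- sort(table(col[col %in% BASES]), decreasing = TRUE)
    n_alleles <- length(tab)
    list(
      n_alleles = n_alleles,
      major = if (n_alleles >= 1L) names(tab)[1] else NA_character_,
      minor = if (n_alleles >= 2L) names(tab)[2] else NA_character_,
      major_count = if (n_alleles >= 1L) unname(tab[1]) else 0L,
      minor_count = if (n_alleles >= 2L) unname(tab[2]) else 0L
    )
  })
  tibble::tibble(
    position = seq_len(ncol(m)) - 1L,
    has_gap = has_gap,
    n_alleles = vapply(info, function(x) as.integer(x$n_alleles), integer(1)),
    major = vapply(info, `[[`, character(1), "major"),
    minor = vapply(info, `[[`, character(1), "minor"),
    major_count = vapply(info, function(x) as.integer(x$major_count), integer(1)),
    minor_count = vapply(info, function(x) as.integer(x$minor_count), integer(1))
  ) |>
    dplyr::mutate(
      usable = !.data$has_gap & .data$n_alleles <= 2L,
      segregating = .data$usable & .data$n_alleles == 2L
    )
}

consensus_sequence <- function(aln) {
  m <- as_alignment_matrix(aln)
  apply(m, 2, function(col) {
    tab <- sort(table(col[col %in% BASES]), decreasing = TRUE)
    if (length(tab) == 0L) "N" else names(tab)[1]
  })
}

#' Classify segregating alignment sites by region and coding effect
#'
#' Every biallelic, gap-free segregating column is assigned its gene-model
#' region; columns inside exons are classified as synonymous, missense or
#' nonsense by substituting the minor allele into the consensus (majority)
#' codon. Gap-containing columns and columns with more than two alleles are
#' flagged excluded (multiallelic columns with a warning).
#'
#' @param alignment Alignment (see [as_alignment_matrix()]) whose length
#'   equals the gene-model length.
#' @param model A `cg_gene_model`.
#' @return A tibble with one row per segregating or excluded column:
#'   `position` (0-based), `region`, `ref`/`alt` alleles, `codon`,
#'   `alt_codon`, `coding_effect` (`noncoding`, `synonymous`, `missense`,
#'   `nonsense`), `excluded`, `exclusion_reason`.
#' @export
classify_alignment_sites <- function(alignment, model) {
  m <- as_alignment_matrix(alignment)
  if (ncol(m) != model$total_length) {
    stop("alignment length (", ncol(m), ") must equal gene-model length (",
         model$total_length, ")", call. = FALSE)
  }
  info <- alignment_column_info(m)
  cons <- consensus_sequence(m)
  cmap <- cds_map(model)
  cds_lookup <- match(seq_len(ncol(m)) - 1L, cmap$genomic_pos)

  rows <- dplyr::filter(info, .data$segregating | .data$has_gap | .data$n_alleles > 2L)
  if (nrow(rows) == 0L) {
    return(tibble::tibble(
      position = integer(), region = character(), ref = character(),
      alt = character(), codon = character(), alt_codon = character(),
      coding_effect = character(), excluded = logical(),
      exclusion_reason = character()
    ))
  }
  n_multi <- sum(rows$n_alleles > 2L & !rows$has_gap)
  if (n_multi > 0L) {
    warning(n_multi, " multiallelic column(s) excluded from classification",
            call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    pos <- r$position
    region <- assign_region(model, pos)
    excluded <- r$has_gap || r$n_alleles > 2L
    reason <- if (r$has_gap) "gap" else if (r$n_alleles > 2L) "multiallelic" else NA_character_
    codon <- NA_character_; alt_codon <- NA_character_
    effect <- "noncoding"
    ci <- cds_lookup[pos + 1L]
    if (!excluded && !is.na(ci) && grepl("^exon_", region)) {
      idx <- cmap$codon_index[ci]
      codon_rows <- cmap[cmap$codon_index == idx, ]
      codon_bases <- cons[codon_rows$genomic_pos + 1L]
      within <- cmap$codon_pos[ci]
      if (model$strand == "-") {
        codon_bases <- rev(chartr("ACGT", "TGCA", codon_bases))
      }
      codon <- paste(codon_bases, collapse = "")
      # the non-consensus allele defines the alternate codon
      alt_base <- if (identical(r$major, cons[pos + 1L])) r$minor else r$major
      if (model$strand == "-") alt_base <- chartr("ACGT", "TGCA", alt_base)
      ab <- strsplit(codon, "")[[1]]
      ab[within] <- alt_base
      alt_codon <- paste(ab, collapse = "")
      effect <- tryCatch(classify_coding_change(codon, alt_codon),
                         error = function(e) NA_character_)
    }
    tibble::tibble(
      position = pos, region = region,
      ref = r$major, alt = r$minor,
      codon = codon, alt_codon = alt_codon,
      coding_effect = if (excluded) NA_character_ else effect,
      excluded = excluded, exclusion_reason = reason
    )
  })
  dplyr::arrange(out, .data$position)
}
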