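#' Construct a gene model
#'
#' A gene model is an ordered, strand-aware partition of a gene into
#' 5'UTR, exon, intron and 3'UTR regions with a reading frame for the
#' coding sequence. Coordinates are 0-based half-open internally; the
#' regions must tile `[0, total_length)` without gaps or overlaps, and the
#' concatenated exon length (after trimming `coding_offset` bases) must be
#' divisible by 3.
#'
#' @param regions A data frame with columns `label`, `start`, `end`
#'   (0-based half-open). Labels are `five_prime_utr`, `exon_<k>`,
#'   `intron_<k>`, `three_prime_utr`; exon and intron indices must
#'   alternate.
#' @param coding_offset Frame of the first exon base (0, 1 or 2).
#' @param strand `"+"` or `"-"`. On the minus strand the coding sequence is
#'   the reverse complement of the concatenated exons.
#' @return An object of class `cg_gene_model`.
#' @examples
#' gm <- gene_model(tibble::tibble(
#'   label = c("five_prime_utr", "exon_1", "intron_1", "exon_2", "three_prime_utr"),
#'   start = c(0, 10, 19, 40, 52),
#'   end   = c(10, 19, 40, 52, 60)
#' ))
#' total_length(gm)
#' @export
gene_model <- function(regions, coding_offset = 0L, strand = "+") {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("label", "start", "end") %in% names(regions)))
  regions <- dplyr::arrange(regions, .data$start)
  if (nrow(regions) == 0L) stop("gene model has no regions", call. = FALSE)
  if (any(regions$end <= regions$start)) {
    stop("every region must have end > start", call. = FALSE)
  }
  if (regions$start[1] != 0L) stop("regions must start at 0", call. = FALSE)
  if (nrow(regions) > 1L &&
      any(regions$start[-1] != regions$end[-nrow(regions)])) {
    stop("regions must be contiguous and non-overlapping", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (!coding_offset %in% 0:2) stop("coding_offset must be 0, 1 or 2", call. = FALSE)

  ei <- regions$label[grepl("^(exon|intron)_\\d+$", regions$label)]
  if (length(ei) > 1L) {
    kinds <- sub("_\\d+$", "", ei)
    if (any(kinds[-1] == kinds[-length(kinds)])) {
      stop("exon and intron labels must alternate", call. = FALSE)
    }
  }
  exon_idx <- grepl("^exon_\\d+$", regions$label)
  cds_len <- sum(regions$end[exon_idx] - regions$start[exon_idx]) - coding_offset
  if (cds_len > 0 && cds_len %% 3L != 0L) {
    stop("concatenated exon length after coding_offset trim must be divisible by 3",
         call. = FALSE)
  }
  structure(
    list(
      regions = dplyr::mutate(regions, length = .data$end - .data$start),
      coding_offset = as.integer(coding_offset),
      strand = strand,
      total_length = max(regions$end)
    ),
    class = "cg_gene_model"
  )
}

#' @export
print.cg_gene_model <- function(x, ...) {
  cat("<cg_gene_model> ", x$total_length, " bp, strand ", x$strand,
      ", ", nrow(x$regions), " regions\n", sep = "")
  print(x$regions, n = nrow(x$regions))
  invisible(x)
}

#' Total length of a gene model in bp
#' @param model A `cg_gene_model`.
#' @export
total_length <- function(model) model$total_length

#' Gene model with the exon/intron layout of the poplar UXS1 gene
#'
#' Returns the 4374-bp gene model of the *Populus tomentosa* UDP-glucuronate
#' decarboxylase candidate gene used throughout the package examples:
#' 133 bp 5'UTR, seven exons totalling 1293 bp of coding sequence, six
#' introns totalling 2574 bp, and a 374 bp 3'UTR.
#'
#' @return A `cg_gene_model`.
#' @examples
#' uxs1_gene_model()
#' @export
uxs1_gene_model <- function() {
  lengths <- c(
    five_prime_utr = 133, exon_1 = 609, intron_1 = 135, exon_2 = 145,
    intron_2 = 88, exon_3 = 80, intron_3 = 1676, exon_4 = 84,
    intron_4 = 120, exon_5 = 75, intron_5 = 327, exon_6 = 93,
    intron_6 = 228, exon_7 = 207, three_prime_utr = 374
  )
  ends <- unname(cumsum(lengths))
  gene_model(tibble::tibble(
    label = names(lengths),
    start = ends - unname(lengths),
    end = ends
  ))
}

#' Assign gene-model regions to positions
#'
#' Total function over `[0, total_length)`: every position maps to exactly
#' one region label.
#'
#' @param model A `cg_gene_model`.
#' @param position Integer vector of 0-based positions.
#' @return Character vector of region labels.
#' @export
assign_region <- function(model, position) {
  stopifnot(inherits(model, "cg_gene_model"))
  if (any(position < 0 | position >= model$total_length)) {
    stop("position out of range [0, ", model$total_length, ")", call. = FALSE)
  }
  idx <- findInterval(position, model$regions$start)
  model$regions$label[idx]
}

#' Map genomic positions to coding-sequence positions
#'
#' @param model A `cg_gene_model`.
#' @return A tibble with one row per coding base: `genomic_pos` (0-based),
#'   `cds_pos` (0-based along the CDS, strand-aware), `codon_index`
#'   (1-based) and `codon_pos` (1, 2 or 3 within the codon).
#' @export
cds_map <- function(model) {
  ex <- dplyr::filter(model$regions, grepl("^exon_\\d+$", .data$label))
  gpos <- unlist(purrr::map2(ex$start, ex$end, function(s, e) seq.int(s, e - 1L)))
  if (model$coding_offset > 0L) gpos <- gpos[-seq_len(model$coding_offset)]
  cpos <- seq_along(gpos) - 1L
  if (model$strand == "-") cpos <- rev(cpos)
  tibble::tibble(
    genomic_pos = gpos,
    cds_pos = cpos,
    codon_index = cpos %/% 3L + 1L,
    codon_pos = cpos %% 3L + 1L
  )
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L) y else x

#' Read a gene model from TSV or GFF3
#'
#' The TSV dialect has columns `label`, `start`, `end` with 0-based
#' half-open coordinates. GFF3 input (1-based, closed) is converted on
#' read; `five_prime_UTR`, `exon` and `three_prime_UTR` features are used
#' and introns are implied by gaps between exons.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"` (default guessed from the extension).
#' @param coding_offset,strand Passed to [gene_model()] (for GFF3 the
#'   strand comes from the file).
#' @return A `cg_gene_model`.
#' @export
read_gene_model <- function(path, format = NULL, coding_offset = 0L, strand = "+") {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    reg <- readr::read_tsv(path, show_col_types = FALSE)
    return(gene_model(reg, coding_offset = coding_offset, strand = strand))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("five_prime_UTR", "exon", "three_prime_UTR")
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  strand <- if (any(df$strand == "-")) "-" else "+"
  n_ex <- 0L; n_in <- 0L
  rows <- list()
  prev_end <- NULL
  for (i in seq_len(nrow(df))) {
    s <- df$start[i] - 1L; e <- df$end[i]
    if (!is.null(prev_end) && s > prev_end) {
      n_in <- n_in + 1L
      rows[[length(rows) + 1L]] <-
        tibble::tibble(label = paste0("intron_", n_in), start = prev_end, end = s)
    }
    lab <- switch(as.character(df$type[i]),
      five_prime_UTR = "five_prime_utr",
      three_prime_UTR = "three_prime_utr",
      exon = { n_ex <- n_ex + 1L; paste0("exon_", n_ex) }
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(label = lab, start = s, end = e)
    prev_end <- e
  }
  reg <- dplyr::bind_rows(rows)
  origin <- min(reg$start)
  reg$start <- reg$start - origin
  reg$end <- reg$end - origin
  gene_model(reg, coding_offset = coding_offset, strand = strand)
}

#' Write a gene model as TSV
#' @param model A `cg_gene_model`.
#' @param path Output path.
#' @export
write_gene_model <- function(model, path) {
  readr::write_tsv(model$regions[, c("label", "start", "end")], path)
  invisible(path)
}
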