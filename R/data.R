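# Example tables shipped with the package. Both come from a published
# candidate-gene association study of the poplar UDP-glucuronate
# decarboxylase gene (UXS1) and are used as worked inputs for the
# arithmetic layers of the pipeline (gene-action classification and
# region-level polymorphism bookkeeping).

#' Reported marker effects for nine significant SNP-trait associations
#'
#' The published marker-effect table of a poplar UXS1 candidate-gene
#' study: for each significant SNP-trait pair the homozygote-class
#' difference `two_a` (2a), the dominance deviation `d`, the standardized
#' effect `two_a_over_sp` (2a/s_p), the minor-allele frequency with its
#' allele, and the reported additive effect. The `d_over_a` ratio and the
#' mode of gene action are recomputed by [gene_action()] /
#' [classify_gene_action()] rather than read from the table.
#'
#' @return A tibble with 9 rows.
#' @examples
#' eff <- uxs_marker_effects()
#' classify_gene_action(eff$d / (eff$two_a / 2))
#' @export
uxs_marker_effects <- function() {
  path <- system.file("extdata", "uxs_marker_effects.tsv",
                      package = "cgassoc", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Reported region-level nucleotide polymorphism of the poplar UXS1 gene
#'
#' Region lengths (fractional for the Nei-Gojobori synonymous /
#' nonsynonymous partitions), segregating-site counts, percent
#' polymorphism, pi and Watterson's theta as reported for the 4374-bp
#' UXS1 gene resequenced in 44 individuals. Used to exercise the
#' bookkeeping arithmetic (bp-per-SNP, additivity of counts, the
#' pi_nonsyn/pi_syn ratio) that [diversity_table()] reproduces on
#' alignments.
#'
#' @return A tibble with one row per region/partition.
#' @export
uxs_region_polymorphism <- function() {
  path <- system.file("extdata", "uxs_region_polymorphism.tsv",
                      package = "cgassoc", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
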