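#' Genome-of-one-gene association scan
#'
#' Runs the Q+K mixed-model single-marker test for every (SNP, trait)
#' pair: SNPs failing the common-variant filter (minor allele frequency
#' below `maf_min`) are skipped, Storey q-values are attached per
#' trait-family by default (or globally across all pairs), pairs with
#' `q < fdr_threshold` are flagged significant, and a gene-action record
#' is attached for each significant pair.
#'
#' @param genotypes Individuals x SNPs dosage matrix with individual row
#'   names.
#' @param phenotypes Tibble with `individual_id` and one column per trait.
#' @param Q Structure covariate matrix (individuals x subpopulations).
#' @param K Kinship matrix, or `"ritland"` to estimate it from the
#'   genotypes with [ritland_kinship()].
#' @param maf_min Common-SNP filter (default 0.10).
#' @param fdr_threshold Significance threshold on q (default 0.10).
#' @param fdr_family `"trait"` (default): q-values per trait across SNPs;
#'   `"global"`: one family over all pairs.
#' @param gene_action_formula Passed to [gene_action_from_data()].
#' @return A tibble of class `cg_scan` with one row per tested (SNP,
#'   trait): `snp_id`, `trait`, `beta_marker`, `p_value`, `q_value`,
#'   `r2_explained`, `maf`, `n_used`, `significant`, and gene-action
#'   columns (`two_a`, `d`, `d_over_a`, `std_effect`, `mode`) for the
#'   significant pairs.
#' @export
association_scan <- function(genotypes, phenotypes, Q = NULL, K = NULL,
                             maf_min = 0.10, fdr_threshold = 0.10,
                             fdr_family = c("trait", "global"),
                             gene_action_formula = "as_printed") {
  fdr_family <- match.arg(fdr_family)
  G <- as.matrix(genotypes)
  ph <- tibble::as_tibble(phenotypes)
  if (!"individual_id" %in% names(ph)) {
    stop("phenotypes must carry an individual_id column", call. = FALSE)
  }
  ids <- rownames(G)
  if (is.null(ids)) stop("genotypes must carry individual row names", call. = FALSE)
  missing_ids <- setdiff(ph$individual_id, ids)
  if (length(missing_ids) > 0L) {
    stop("individual IDs in phenotypes without genotypes: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  ph <- ph[match(ids, ph$individual_id), , drop = FALSE]
  if (any(is.na(ph$individual_id))) {
    stop("individual IDs in genotypes without phenotypes: ",
         paste(head(setdiff(ids, phenotypes$individual_id), 5), collapse = ", "),
         call. = FALSE)
  }

  if (identical(K, "ritland")) K <- ritland_kinship(G)
  eig <- if (!is.null(K)) mlm_eigen(as.matrix(K)) else NULL
  trait_cols <- setdiff(names(ph), "individual_id")
  snps <- colnames(G)
  if (is.null(snps)) snps <- sprintf("SNP%d", seq_len(ncol(G)))

  res <- purrr::map_dfr(trait_cols, function(tr) {
    y <- ph[[tr]]
    purrr::map_dfr(seq_len(ncol(G)), function(j) {
      fit <- mlm_single_marker(y, G[, j], Q = Q, K = K, eig = eig,
                               maf_min = maf_min)
      if (!is.na(fit$skipped %||% NA)) {
        return(tibble::tibble(snp_id = snps[j], trait = tr,
                              beta_marker = NA_real_, p_value = NA_real_,
                              r2_explained = NA_real_,
                              maf = fit$maf %||% NA_real_,
                              n_used = fit$n_used %||% NA_integer_,
                              skipped = fit$skipped))
      }
      tibble::tibble(snp_id = snps[j], trait = tr,
                     beta_marker = fit$beta_marker, p_value = fit$p_value,
                     r2_explained = fit$r2_explained, maf = fit$maf,
                     n_used = fit$n_used, skipped = NA_character_)
    })
  })

  if (fdr_family == "trait") {
    res <- res |>
      dplyr::group_by(.data$trait) |>
      dplyr::mutate(q_value = qvalues_allow_na(.data$p_value)) |>
      dplyr::ungroup()
  } else {
    res$q_value <- qvalues_allow_na(res$p_value)
  }
  res$significant <- !is.na(res$q_value) & res$q_value < fdr_threshold

  # gene action for the significant pairs
  ga_cols <- tibble::tibble(two_a = NA_real_, d = NA_real_,
                            d_over_a = NA_real_, std_effect = NA_real_,
                            additive_effect = NA_real_, mode = NA_character_)
  res <- dplyr::bind_cols(res, ga_cols[rep(1, nrow(res)), ])
  sig_idx <- which(res$significant)
  for (i in sig_idx) {
    j <- match(res$snp_id[i], snps)
    ga <- gene_action_from_data(ph[[res$trait[i]]], G[, j],
                                formula = gene_action_formula)
    res$two_a[i] <- ga$two_a; res$d[i] <- ga$d
    res$d_over_a[i] <- ga$d_over_a; res$std_effect[i] <- ga$std_effect
    res$additive_effect[i] <- ga$additive_effect; res$mode[i] <- ga$mode
  }
  class(res) <- c("cg_scan", class(res))
  attr(res, "fdr_threshold") <- fdr_threshold
  attr(res, "fdr_family") <- fdr_family
  res
}
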