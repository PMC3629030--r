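# Validation-population tests: Mendelian segregation chi-squared per locus
# and fixed-effects single-marker ANOVA in an F1 full-sib cross.

qvalues_allow_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- storey_qvalues(p[ok])
  q
}

mendelian_expectation <- function(p1, p2) {
  # expected genotype-class probabilities for dosages 0/1/2 given the two
  # parents' dosages at a biallelic locus
  gam <- function(g) switch(as.character(g),
    "0" = c(1, 0), "1" = c(0.5, 0.5), "2" = c(0, 1))
  a <- gam(p1); b <- gam(p2)
  probs <- c(0, 0, 0)
  for (i in 0:1) for (j in 0:1) {
    probs[i + j + 1L] <- probs[i + j + 1L] + a[i + 1L] * b[j + 1L]
  }
  probs
}

#' Mendelian segregation chi-squared test at one locus
#'
#' Pearson chi-squared of the observed progeny genotype counts against the
#' Mendelian expectation derived from the two parents' genotypes, with
#' degrees of freedom equal to the number of expected classes minus 1.
#' Loci where both parents are homozygous are skipped (monomorphic
#' progeny); progeny classes with zero Mendelian expectation but positive
#' observation fail the test outright. Missing progeny genotypes (e.g.
#' null-allele calls coded `NA`) are excluded.
#'
#' @param progeny Progeny dosage vector at the locus.
#' @param parent1,parent2 Parent dosages (0/1/2).
#' @param alpha Rejection level for the `keep` flag (default 0.01).
#' @return A tibble: `chi2`, `df`, `p_value`, `keep`
#'   (`p_value >= alpha`), `n_used`.
#' @examples
#' mendelian_test(rep(c(1, 2), c(40, 60)), 1, 2)  # chi2 = 4, p ~ 0.0455
#' @export
mendelian_test <- function(progeny, parent1, parent2, alpha = 0.01) {
  if (is.na(parent1) || is.na(parent2)) {
    stop("parent genotypes must be known", call. = FALSE)
  }
  progeny <- progeny[!is.na(progeny)]
  n <- length(progeny)
  probs <- mendelian_expectation(parent1, parent2)
  classes <- which(probs > 0) - 1L
  if (length(classes) == 1L) {
    return(tibble::tibble(chi2 = NA_real_, df = NA_integer_,
                          p_value = NA_real_, keep = NA, n_used = n,
                          skipped = "monomorphic"))
  }
  impossible <- setdiff(unique(progeny), classes)
  if (length(impossible) > 0L) {
    return(tibble::tibble(chi2 = Inf, df = length(classes) - 1L,
                          p_value = 0, keep = FALSE, n_used = n,
                          skipped = NA_character_))
  }
  obs <- vapply(classes, function(g) sum(progeny == g), numeric(1))
  expd <- probs[classes + 1L] * n
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(classes) - 1L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, df = df, p_value = p, keep = p >= alpha,
                 n_used = n, skipped = NA_character_)
}

#' Single-marker one-way ANOVA
#'
#' Fixed-effects model `y = mu + m_i + e_ij` over the genotype classes of
#' one marker: F-test over classes and the marker-explained variance
#' fraction `R2 = 100 * SS_marker / SS_total`.
#'
#' @param y Trait vector.
#' @param marker Dosage vector; treated as a categorical genotype class.
#' @return A tibble: `F`, `df1`, `df2`, `p_value`, `r2_explained`,
#'   `n_used`.
#' @export
single_marker_anova <- function(y, marker) {
  keep <- !is.na(y) & !is.na(marker)
  y <- y[keep]; marker <- factor(marker[keep])
  if (nlevels(marker) < 2L) {
    return(tibble::tibble(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                          p_value = NA_real_, r2_explained = NA_real_,
                          n_used = length(y), skipped = "single_class"))
  }
  fit <- lm(y ~ marker)
  an <- anova(fit)
  ss_marker <- an[["Sum Sq"]][1]
  ss_total <- sum(an[["Sum Sq"]])
  tibble::tibble(
    F = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1],
    r2_explained = 100 * ss_marker / ss_total,
    n_used = length(y), skipped = NA_character_
  )
}

#' Validate a marker panel in an F1 cross
#'
#' For every marker of the panel: Mendelian segregation test against the
#' parents' genotypes (markers failing at `mendelian_alpha` are dropped),
#' then single-marker ANOVA against every trait with a per-trait Storey
#' FDR correction.
#'
#' @param progeny_genotypes Progeny x markers dosage matrix.
#' @param parent1,parent2 Parent dosage vectors over the same markers.
#' @param phenotypes Tibble with `individual_id` and trait columns (or a
#'   plain data frame of traits in progeny order).
#' @param mendelian_alpha Mendelian rejection level (default 0.01).
#' @param fdr_threshold Significance threshold on q (default 0.10).
#' @return A tibble with one row per (marker, trait): Mendelian results,
#'   ANOVA p, q, R2 and a `significant` flag.
#' @export
validate_panel <- function(progeny_genotypes, parent1, parent2, phenotypes,
                           mendelian_alpha = 0.01, fdr_threshold = 0.10) {
  G <- as.matrix(progeny_genotypes)
  markers <- colnames(G)
  if (is.null(markers)) markers <- sprintf("SNP%d", seq_len(ncol(G)))
  ph <- tibble::as_tibble(phenotypes)
  trait_cols <- setdiff(names(ph), "individual_id")

  mend <- purrr::map_dfr(seq_len(ncol(G)), function(j) {
    dplyr::bind_cols(tibble::tibble(snp_id = markers[j]),
                     mendelian_test(G[, j], parent1[j], parent2[j],
                                    alpha = mendelian_alpha))
  })
  kept <- mend$snp_id[!is.na(mend$keep) & mend$keep]

  res <- purrr::map_dfr(trait_cols, function(tr) {
    y <- ph[[tr]]
    purrr::map_dfr(kept, function(sn) {
      j <- match(sn, markers)
      dplyr::bind_cols(tibble::tibble(trait = tr, snp_id = sn),
                       single_marker_anova(y, G[, j]))
    })
  })
  if (nrow(res) > 0L) {
    res <- res |>
      dplyr::group_by(.data$trait) |>
      dplyr::mutate(q_value = qvalues_allow_na(.data$p_value)) |>
      dplyr::ungroup() |>
      dplyr::mutate(significant = !is.na(.data$q_value) &
                      .data$q_value < fdr_threshold)
  }
  list(mendelian = mend, associations = res)
}
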