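# Gene-action decomposition of a marker-trait association from the three
# genotype-class means: 2a is the absolute homozygote-class difference,
# d the heterozygote deviation from the homozygote midpoint, and |d/a|
# classifies the mode of action.

#' Classify the mode of gene action from a d/a ratio
#'
#' `additive` (codominant) when `|d/a| <= 0.5`, `dominant` (partial to
#' full dominance) when `0.50 < |d/a| < 1.25`, `overdominant` when
#' `|d/a| > 1.25`. The boundary `|d/a| = 1.25` is not covered by the
#' published convention and is assigned `overdominant` with a warning.
#'
#' @param d_over_a Signed or absolute d/a ratio(s).
#' @return Character vector of modes.
#' @export
classify_gene_action <- function(d_over_a) {
  r <- abs(d_over_a)
  if (any(r == 1.25, na.rm = TRUE)) {
    warning("|d/a| exactly 1.25 is outside the published windows; ",
            "assigned 'overdominant'", call. = FALSE)
  }
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r <= 0.5 ~ "additive",
    r < 1.25 ~ "dominant",
    TRUE ~ "overdominant"
  )
}

#' Gene-action record from genotype-class means
#'
#' Computes `2a = |G_BB - G_bb|`, `d = G_Bb - 0.5 (G_BB + G_bb)`, the
#' signed `d/a` ratio (orientation chosen so `a > 0`, i.e. B is the
#' high-value homozygote), the standardized effect `2a / s_p`, the
#' additive effect by the published formula
#' `a_eff = p_B G_BB + p_b G_Bb - G` (taken as printed; the
#' `"substitution"` alternative is the average allele-substitution effect
#' `a + d (p_b - p_B)`), and the mode of gene action from `|d/a|`.
#'
#' @param g_BB,g_Bb,g_bb Trait means of the three genotype classes, where
#'   B is the allele whose dosage is counted.
#' @param freq_B Frequency of the counted (B) allele.
#' @param trait_sd Phenotypic standard deviation `s_p` (> 0).
#' @param overall_mean Overall trait mean `G` (for the additive-effect
#'   formula).
#' @param formula `"as_printed"` (default) or `"substitution"`.
#' @return A one-row tibble: `two_a`, `d`, `d_over_a`, `std_effect`,
#'   `freq_B`, `additive_effect`, `mode`.
#' @export
gene_action <- function(g_BB, g_Bb, g_bb, freq_B = NA_real_,
                        trait_sd = NA_real_, overall_mean = NA_real_,
                        formula = c("as_printed", "substitution")) {
  formula <- match.arg(formula)
  if (any(is.na(c(g_BB, g_Bb, g_bb)))) {
    return(tibble::tibble(two_a = NA_real_, d = NA_real_, d_over_a = NA_real_,
                          std_effect = NA_real_, freq_B = freq_B,
                          additive_effect = NA_real_, mode = NA_character_))
  }
  if (!is.na(trait_sd) && trait_sd <= 0) stop("trait_sd must be positive", call. = FALSE)
  two_a <- abs(g_BB - g_bb)
  d <- g_Bb - 0.5 * (g_BB + g_bb)
  # orient so that B labels the high-value homozygote: a = two_a/2 > 0
  a <- two_a / 2
  d_over_a <- if (a > 0) d / a else if (d == 0) 0 else sign(d) * Inf
  std_effect <- if (is.na(trait_sd)) NA_real_ else two_a / trait_sd
  p_B <- freq_B; p_b <- 1 - freq_B
  additive_effect <- if (formula == "as_printed") {
    p_B * g_BB + p_b * g_Bb - overall_mean
  } else {
    a + d * (p_b - p_B)
  }
  tibble::tibble(
    two_a = two_a, d = d, d_over_a = d_over_a, std_effect = std_effect,
    freq_B = freq_B, additive_effect = additive_effect,
    mode = classify_gene_action(d_over_a)
  )
}

#' Gene-action record for a marker from raw data
#'
#' Convenience wrapper: computes the genotype-class means of `y` over the
#' dosage classes of `marker` and calls [gene_action()]. All three classes
#' must be observed; otherwise the record is returned with `mode = NA`.
#'
#' @param y Trait vector.
#' @param marker Dosage vector (0/1/2).
#' @inheritParams gene_action
#' @return A one-row tibble as in [gene_action()].
#' @export
gene_action_from_data <- function(y, marker, formula = c("as_printed", "substitution")) {
  formula <- match.arg(formula)
  keep <- !is.na(y) & !is.na(marker)
  y <- y[keep]; marker <- marker[keep]
  means <- vapply(0:2, function(g) {
    if (any(marker == g)) mean(y[marker == g]) else NA_real_
  }, numeric(1))
  gene_action(g_BB = means[3], g_Bb = means[2], g_bb = means[1],
              freq_B = mean(marker) / 2, trait_sd = sd(y),
              overall_mean = mean(y), formula = formula)
}
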