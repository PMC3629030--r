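# Pairwise linkage disequilibrium from unphased diploid genotypes.
#
# Haplotype frequencies for a pair of biallelic loci are estimated by EM
# over the double-heterozygote phase ambiguity; the EM runs on the 3x3
# genotype count table (the sufficient statistic), so all-pairs scans over
# a candidate gene are fast.

two_locus_counts <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  tab <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) tab[a + 1, b + 1] <- sum(g1 == a & g2 == b)
  tab
}

# EM on a 3x3 dosage count table. Alleles: locus 1 has A (dosage-counted)
# and a; locus 2 has B and b. Haplotype order: AB, Ab, aB, ab.
em_from_counts <- function(tab, tol = 1e-8, max_iter = 200L) {
  n_ind <- sum(tab)
  if (n_ind < 2) stop("need >= 2 informative individuals", call. = FALSE)
  pA <- sum(tab * matrix(c(0:2), 3, 3)) / (2 * n_ind)
  pB <- sum(tab * matrix(c(0:2), 3, 3, byrow = TRUE)) / (2 * n_ind)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(freq = NULL, monomorphic = TRUE))
  }
  # linkage-equilibrium initialization
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  n_dh <- tab[2, 2]  # double heterozygotes: phase-ambiguous
  loglik <- -Inf
  loglik_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # E-step: split double heterozygotes between AB/ab and Ab/aB phases
    w_coupling <- f["AB"] * f["ab"]
    w_repulsion <- f["Ab"] * f["aB"]
    denom <- w_coupling + w_repulsion
    pc <- if (denom > 0) w_coupling / denom else 0.5
    # expected haplotype counts (2 haplotypes per individual)
    cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + n_dh * pc
    cAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + n_dh * (1 - pc)
    caB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + n_dh * (1 - pc)
    cab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + n_dh * pc
    f_new <- c(cAB, cAb, caB, cab) / (2 * n_ind)
    names(f_new) <- names(f)
    ll <- em_two_locus_loglik(tab, f_new)
    loglik_trace <- c(loglik_trace, ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  list(freq = f, monomorphic = FALSE, loglik = loglik_trace,
       n_individuals = n_ind)
}

em_two_locus_loglik <- function(tab, f) {
  # multinomial log-likelihood of the 9 genotype classes under HWE on
  # haplotypes
  P <- matrix(0, 3, 3)
  hap_a <- c(1, 1, 0, 0)  # A-allele count of haplotype AB, Ab, aB, ab
  hap_b <- c(1, 0, 1, 0)
  for (h1 in 1:4) for (h2 in 1:4) {
    i <- hap_a[h1] + hap_a[h2] + 1L
    j <- hap_b[h1] + hap_b[h2] + 1L
    P[i, j] <- P[i, j] + f[h1] * f[h2]
  }
  sum(tab[tab > 0] * log(P[tab > 0]))
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci from
#' unphased dosages, by EM over the double-heterozygote phase ambiguity
#' (linkage-equilibrium initialization, convergence when the largest
#' frequency change is below `tol`). When the coupling and repulsion
#' solutions are equally likely the reported solution has `D >= 0`
#' (r-squared is identical either way).
#'
#' @param g1,g2 Dosage vectors (0/1/2, `NA` allowed) at the two loci;
#'   pairwise-complete individuals are used.
#' @param tol,max_iter EM convergence controls.
#' @return A list: `freq` (named AB/Ab/aB/ab frequencies), `D`, `r2`,
#'   `loglik` (per-iteration trace, non-decreasing), `n_individuals`,
#'   `monomorphic`.
#' @export
em_two_locus_frequencies <- function(g1, g2, tol = 1e-8, max_iter = 200L) {
  tab <- two_locus_counts(g1, g2)
  fit <- em_from_counts(tab, tol = tol, max_iter = max_iter)
  if (fit$monomorphic) {
    return(list(freq = NULL, D = NA_real_, r2 = NA_real_,
                loglik = numeric(0), n_individuals = sum(tab),
                monomorphic = TRUE))
  }
  f <- fit$freq
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pA * pB)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) unname(D^2 / denom) else NA_real_
  list(freq = f, D = D, r2 = min(1, r2), loglik = fit$loglik,
       n_individuals = fit$n_individuals, monomorphic = FALSE)
}

#' All-pairs r-squared
#'
#' EM-based `r2` for every pair of polymorphic loci.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param positions Optional 0-based bp positions (for `distance_bp`).
#' @return A tibble of class `cg_ld_pairs`: `snp_i`, `snp_j` (column
#'   names), `i`, `j` (indices), `distance_bp`, `D`, `r2`.
#' @export
pairwise_r2 <- function(genotypes, positions = NULL) {
  m <- ncol(genotypes)
  if (m < 2L) stop("need >= 2 loci", call. = FALSE)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("SNP%d", seq_len(m))
  pairs <- utils::combn(m, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    fit <- em_two_locus_frequencies(genotypes[, i], genotypes[, j])
    tibble::tibble(
      snp_i = ids[i], snp_j = ids[j], i = i, j = j,
      distance_bp = if (is.null(positions)) NA_integer_ else
        abs(positions[j] - positions[i]),
      D = fit$D, r2 = fit$r2
    )
  })
  class(out) <- c("cg_ld_pairs", class(out))
  attr(out, "n_individuals") <- nrow(genotypes)
  attr(out, "n_snps") <- m
  out
}

#' Square r-squared matrix from an LD pair table
#' @param pairs Result of [pairwise_r2()].
#' @return Symmetric matrix with unit diagonal.
#' @export
r2_matrix <- function(pairs) {
  m <- attr(pairs, "n_snps")
  if (is.null(m)) m <- max(pairs$j)
  M <- diag(1, m)
  M[cbind(pairs$i, pairs$j)] <- pairs$r2
  M[cbind(pairs$j, pairs$i)] <- pairs$r2
  M
}

#' Permutation significance of r-squared
#'
#' Permutes one locus's genotypes across individuals and recomputes the EM
#' `r2`; `p = (1 + #(perm r2 >= observed)) / (1 + n_permutations)`.
#'
#' @param g1,g2 Dosage vectors.
#' @param n_permutations At least 100 (default 1000; published analyses of
#'   this kind often use 1e5).
#' @param seed Integer seed.
#' @return A list: `r2` observed, `p_perm`.
#' @export
r2_significance <- function(g1, g2, n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 100L) stop("n_permutations must be >= 100", call. = FALSE)
  obs <- em_two_locus_frequencies(g1, g2)
  if (is.na(obs$r2)) return(list(r2 = NA_real_, p_perm = NA_real_))
  set.seed(seed)
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    r2p <- em_two_locus_frequencies(g1, sample(g2))$r2
    if (!is.na(r2p) && r2p >= obs$r2 - 1e-12) hits <- hits + 1L
  }
  list(r2 = obs$r2, p_perm = (1 + hits) / (1 + n_permutations))
}

# Hill-Weir expectation of r2 as a function of C = rho * distance for
# sample size n (chromosomes).
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit LD decay with distance
#'
#' Fits (a) an ordinary least-squares line of `r2` on bp distance and
#' (b) the Hill-Weir drift expectation `E[r2 | C = rho * d]` by least
#' squares over the composite parameter `rho`, and reports the distance at
#' which each fitted curve crosses a threshold (default `r2 = 0.1`), or
#' `NA` ("beyond range") if it does not cross within the observed range.
#'
#' @param pairs A [pairwise_r2()] tibble (needs `distance_bp` and `r2`),
#'   or any data frame with those columns.
#' @param n_chromosomes Sample size in chromosomes (2 x individuals);
#'   taken from the pair table attribute when present.
#' @param threshold r2 level whose crossing distance is reported.
#' @return A list of class `cg_ld_decay`: `ols` (intercept, slope),
#'   `hill_weir` (rho), `crossing_ols`, `crossing_hill_weir`, `threshold`,
#'   `data`.
#' @export
fit_ld_decay <- function(pairs, n_chromosomes = NULL, threshold = 0.1) {
  df <- dplyr::filter(tibble::as_tibble(pairs),
                      !is.na(.data$distance_bp), !is.na(.data$r2))
  if (length(unique(df$distance_bp)) < 3L) {
    stop("need >= 3 pairs with distinct distances", call. = FALSE)
  }
  if (is.null(n_chromosomes)) {
    ni <- attr(pairs, "n_individuals")
    n_chromosomes <- if (is.null(ni)) 100L else 2L * ni
  }
  rng <- range(df$distance_bp)

  ols <- lm(r2 ~ distance_bp, data = df)
  co <- stats::coef(ols)
  crossing_ols <- if (co[2] < 0) {
    x <- (threshold - co[1]) / co[2]
    if (x >= rng[1] && x <= rng[2]) x else NA_real_
  } else NA_real_

  sse <- function(log_rho) {
    rho <- exp(log_rho)
    sum((df$r2 - hill_weir_expectation(rho * df$distance_bp, n_chromosomes))^2)
  }
  opt <- optimize(sse, interval = c(log(1e-8), log(10)))
  rho <- exp(opt$minimum)
  fhw <- function(d) hill_weir_expectation(rho * d, n_chromosomes)
  crossing_hw <- if ((fhw(rng[1]) - threshold) * (fhw(rng[2]) - threshold) < 0) {
    uniroot(function(d) fhw(d) - threshold, interval = rng)$root
  } else NA_real_

  structure(list(
    ols = c(intercept = unname(co[1]), slope = unname(co[2])),
    hill_weir = c(rho = rho),
    crossing_ols = unname(crossing_ols),
    crossing_hill_weir = unname(crossing_hw),
    threshold = threshold,
    n_chromosomes = n_chromosomes,
    data = df
  ), class = "cg_ld_decay")
}

#' @export
print.cg_ld_decay <- function(x, ...) {
  cat("<cg_ld_decay> OLS slope ", signif(x$ols["slope"], 4),
      "; Hill-Weir rho ", signif(x$hill_weir["rho"], 4), "\n", sep = "")
  cat("  r2 = ", x$threshold, " crossed at ",
      ifelse(is.na(x$crossing_ols), "beyond range", round(x$crossing_ols)),
      " bp (OLS), ",
      ifelse(is.na(x$crossing_hill_weir), "beyond range",
             round(x$crossing_hill_weir)),
      " bp (Hill-Weir)\n", sep = "")
  invisible(x)
}

#' @export
tidy.cg_ld_decay <- function(x, ...) {
  tibble::tibble(
    model = c("linear", "hill_weir"),
    parameter = c("slope", "rho"),
    estimate = c(unname(x$ols["slope"]), unname(x$hill_weir["rho"])),
    crossing_bp = c(x$crossing_ols, x$crossing_hill_weir),
    threshold = x$threshold
  )
}

#' Detect haplotype blocks from an r-squared matrix
#'
#' Maximal runs of two or more consecutive SNPs (in map order) in which
#' every within-run pair exceeds the r2 threshold (and, when permutation
#' p-values are supplied, falls below the p threshold). Runs are found
#' greedily left to right, so reported blocks never overlap.
#'
#' @param r2m Symmetric r2 matrix (SNPs in map order).
#' @param threshold r2 threshold (default 0.75).
#' @param p_matrix Optional matrix of permutation p-values.
#' @param p_threshold Applied when `p_matrix` is given (default 0.001).
#' @return A tibble with `start_snp_index`, `end_snp_index` (inclusive),
#'   `n_snps`.
#' @export
detect_blocks <- function(r2m, threshold = 0.75, p_matrix = NULL,
                          p_threshold = 0.001) {
  m <- ncol(r2m)
  ok_pair <- function(i, j) {
    val <- r2m[i, j]
    if (is.na(val) || val <= threshold) return(FALSE)
    if (!is.null(p_matrix) && !(p_matrix[i, j] < p_threshold)) return(FALSE)
    TRUE
  }
  blocks <- list()
  i <- 1L
  while (i < m) {
    j <- i
    repeat {
      if (j + 1L > m) break
      cand <- j + 1L
      if (all(vapply(i:j, function(k) ok_pair(k, cand), logical(1)))) {
        j <- cand
      } else break
    }
    if (j > i) {
      blocks[[length(blocks) + 1L]] <-
        tibble::tibble(start_snp_index = i, end_snp_index = j, n_snps = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(blocks) == 0L) {
    return(tibble::tibble(start_snp_index = integer(),
                          end_snp_index = integer(), n_snps = integer()))
  }
  dplyr::bind_rows(blocks)
}
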