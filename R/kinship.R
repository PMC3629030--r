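#' Ritland marker-based kinship
#'
#' Moment estimator of pairwise relatedness from allele sharing relative
#' to sample allele frequencies: with dosages scaled to allele fractions
#' `x = g/2` and sample frequency `p_l` per locus,
#' `r_ij = sum_l (x_il - p_l)(x_jl - p_l) / sum_l p_l (1 - p_l) / 2`,
#' which is 1 in expectation for an individual against itself and 0 for
#' unrelated pairs. Following common usage in Q+K association work,
#' negative pairwise estimates are truncated to 0 and the diagonal is set
#' to 1.
#'
#' @param genotypes Individuals x SNPs dosage matrix (0/1/2, `NA`
#'   tolerated and mean-imputed per locus for the moment sums).
#' @param truncate Truncate negative estimates to zero (default `TRUE`;
#'   set `FALSE` to inspect the raw estimator).
#' @return Symmetric kinship matrix with unit diagonal.
#' @export
ritland_kinship <- function(genotypes, truncate = TRUE) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2L) stop("need >= 2 individuals", call. = FALSE)
  X <- G / 2
  p <- colMeans(X, na.rm = TRUE)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic", call. = FALSE)
  if (any(!poly)) X <- X[, poly, drop = FALSE]
  p <- p[poly]
  # mean-impute missing dosages so they contribute 0 to the cross-products
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- p[j]
  }
  Xc <- sweep(X, 2, p)
  denom <- sum(p * (1 - p)) / 2
  K <- tcrossprod(Xc) / denom
  if (truncate) {
    K[K < 0] <- 0
    diag(K) <- 1
    K <- (K + t(K)) / 2
    # truncation can leave the matrix indefinite; project onto the PSD
    # cone and rescale to correlation form so the REML machinery is
    # well-defined and the diagonal stays exactly 1
    ev <- eigen(K, symmetric = TRUE)
    if (min(ev$values) < -1e-10) {
      K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
      s <- sqrt(pmax(diag(K), 1e-12))
      K <- K / tcrossprod(s)
      diag(K) <- 1
      K <- (K + t(K)) / 2
    }
  } else {
    diag(K) <- 1
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}
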