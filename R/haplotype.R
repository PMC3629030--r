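# Sliding-window haplotype analysis: EM haplotype-frequency estimation
# over small windows of biallelic SNPs and haplotype trend regression
# (regression of a trait on posterior expected haplotype dosages) with
# permutation significance.

# Enumerate the compatible ordered haplotype pairs for a multilocus
# genotype (dosage vector over w loci, no missing values). Haplotypes are
# indexed 1..2^w with allele bits in locus order.
hap_alleles <- function(w) {
  # matrix 2^w x w of 0/1 alleles
  H <- as.matrix(expand.grid(rep(list(0:1), w)))[, w:1, drop = FALSE]
  H <- H[, rev(seq_len(w)), drop = FALSE]  # restore locus order
  storage.mode(H) <- "integer"
  unname(H)
}

compatible_pairs <- function(geno, H) {
  het <- which(geno == 1L)
  fixed <- geno %/% 2L  # allele at homozygous loci (0 or 1)
  if (length(het) == 0L) {
    h <- which(apply(H, 1, function(x) all(x == fixed)))
    return(matrix(c(h, h), ncol = 2))
  }
  # one haplotype chooses alleles freely at het loci, the mate is forced
  n_conf <- 2L^(length(het) - 1L)
  confs <- as.matrix(expand.grid(rep(list(0:1), length(het))))
  keep_rows <- confs[, 1] == 0L  # fix first het locus to break symmetry
  confs <- confs[keep_rows, , drop = FALSE]
  out <- matrix(0L, nrow(confs), 2)
  for (r in seq_len(nrow(confs))) {
    h1 <- geno %/% 2L; h1[geno == 1L] <- as.integer(confs[r, ])
    h2 <- geno - h1
    idx1 <- sum(h1 * 2L^(seq_along(geno) - 1L)) + 1L
    idx2 <- sum(h2 * 2L^(seq_along(geno) - 1L)) + 1L
    out[r, ] <- c(idx1, idx2)
  }
  out
}

#' EM haplotype frequencies for a SNP window
#'
#' Estimates the frequencies of the up to `2^w` haplotypes spanned by a
#' window of `w` biallelic loci from unphased dosages, resolving phase
#' ambiguity probabilistically (equilibrium initialization, convergence
#' when the largest change is below `tol`). Individuals missing any locus
#' in the window are dropped. The returned dosage matrix holds every
#' analysed individual's posterior expected haplotype counts (each row
#' sums to 2).
#'
#' @param genotypes Individuals x w dosage matrix (w small, typically 3).
#' @param tol,max_iter EM controls.
#' @return A list of class `cg_window_haps`: `frequencies` (named by
#'   haplotype allele strings, summing to 1), `dosage` (individuals x
#'   haplotypes), `loglik` (non-decreasing trace), `n_used`, `kept` (row
#'   index of analysed individuals).
#' @export
em_window_haplotypes <- function(genotypes, tol = 1e-8, max_iter = 500L) {
  G <- as.matrix(genotypes)
  w <- ncol(G)
  if (w < 2L) stop("window must span >= 2 loci", call. = FALSE)
  keep <- which(rowSums(is.na(G)) == 0L)
  if (length(keep) < 2L) {
    stop("fewer than 2 individuals with complete genotypes in the window",
         call. = FALSE)
  }
  Gk <- G[keep, , drop = FALSE]
  nh <- 2L^w
  H <- hap_alleles(w)

  # collapse identical multilocus genotypes
  keys <- apply(Gk, 1, paste, collapse = ",")
  uk <- unique(keys)
  counts <- as.numeric(table(keys)[uk])
  genos <- do.call(rbind, strsplit(uk, ","))
  storage.mode(genos) <- "integer"
  pairs_by_geno <- lapply(seq_len(nrow(genos)), function(i)
    compatible_pairs(genos[i, ], H))

  # equilibrium initialization from single-locus frequencies
  p <- colMeans(Gk) / 2
  f <- apply(H, 1, function(h) prod(ifelse(h == 1L, p, 1 - p)))
  f <- pmax(f, 1e-12); f <- f / sum(f)

  n_ind <- length(keep)
  loglik <- numeric(0)
  post_by_geno <- vector("list", nrow(genos))
  for (iter in seq_len(max_iter)) {
    counts_h <- numeric(nh)
    ll <- 0
    for (i in seq_len(nrow(genos))) {
      prs <- pairs_by_geno[[i]]
      wgt <- f[prs[, 1]] * f[prs[, 2]] * ifelse(prs[, 1] == prs[, 2], 1, 2)
      tot <- sum(wgt)
      post <- wgt / tot
      post_by_geno[[i]] <- post
      ll <- ll + counts[i] * log(tot)
      for (r in seq_len(nrow(prs))) {
        counts_h[prs[r, 1]] <- counts_h[prs[r, 1]] + counts[i] * post[r]
        counts_h[prs[r, 2]] <- counts_h[prs[r, 2]] + counts[i] * post[r]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts_h / (2 * n_ind)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }

  # posterior expected haplotype dosages per individual
  D <- matrix(0, n_ind, nh)
  geno_of_ind <- match(keys, uk)
  for (i in seq_len(n_ind)) {
    prs <- pairs_by_geno[[geno_of_ind[i]]]
    post <- post_by_geno[[geno_of_ind[i]]]
    for (r in seq_len(nrow(prs))) {
      D[i, prs[r, 1]] <- D[i, prs[r, 1]] + post[r]
      D[i, prs[r, 2]] <- D[i, prs[r, 2]] + post[r]
    }
  }
  hap_names <- apply(H, 1, paste, collapse = "")
  names(f) <- hap_names
  colnames(D) <- hap_names
  structure(list(frequencies = f, dosage = D, loglik = loglik,
                 n_used = n_ind, kept = keep),
            class = "cg_window_haps")
}

# Observed and permuted F statistics for the regression of y on dosage
# columns, vectorized over permutations through one QR decomposition.
htr_f_stats <- function(y, X, n_perm, seed) {
  n <- length(y)
  X1 <- cbind(1, X)
  qrX <- qr(X1)
  rank_cols <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- ncol(X1) - qrX$rank
  if (dropped > 0L) {
    warning(dropped, " collinear dosage column(s) dropped", call. = FALSE)
    X1 <- X1[, sort(rank_cols), drop = FALSE]
    qrX <- qr(X1)
  }
  Qm <- qr.Q(qrX)
  df1 <- ncol(X1) - 1L
  df2 <- n - ncol(X1)
  f_of <- function(Y) {
    # Y: n x b matrix of responses
    tot <- colSums(Y^2) - colSums(Y)^2 / n
    fitted_ss <- colSums(crossprod(Qm, Y)^2) - colSums(Y)^2 / n
    resid_ss <- tot - fitted_ss
    (fitted_ss / df1) / (resid_ss / df2)
  }
  obs <- f_of(matrix(y, ncol = 1))
  set.seed(seed)
  perms <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perms[, b] <- y[sample.int(n)]
  list(obs = obs, perm = f_of(perms), df1 = df1, df2 = df2,
       model_r2 = NA)
}

#' Haplotype trend regression for one window
#'
#' Regresses the trait on the posterior expected dosages of the common
#' haplotypes (frequency >= `freq_min`; rarer haplotypes are pooled and
#' excluded from testing; the most frequent haplotype is the reference and
#' is dropped). Significance is the permutation p-value of the model
#' F-statistic with the trait permuted across individuals,
#' `p = (1 + #(perm F >= obs)) / (1 + n_permutations)`.
#'
#' @param y Trait vector over all individuals (subset to the window's
#'   analysed individuals internally).
#' @param window_haps A [em_window_haplotypes()] result.
#' @param freq_min Haplotype frequency filter (default 0.01).
#' @param n_permutations Number of trait permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble: `p_perm`, `f_statistic`, `r2_explained` (%),
#'   `n_haplotypes_tested`, `tested_haplotypes` (list column),
#'   `n_used`.
#' @export
htr_test <- function(y, window_haps, freq_min = 0.01, n_permutations = 1000L,
                     seed = 1L) {
  stopifnot(inherits(window_haps, "cg_window_haps"))
  f <- window_haps$frequencies
  common <- names(f)[f >= freq_min]
  if (length(common) < 2L) {
    stop("fewer than 2 haplotypes pass the frequency filter", call. = FALSE)
  }
  ref <- common[which.max(f[common])]
  tested <- setdiff(common, ref)
  yk <- y[window_haps$kept]
  ok <- !is.na(yk)
  X <- window_haps$dosage[ok, tested, drop = FALSE]
  yk <- yk[ok]

  st <- htr_f_stats(yk, X, n_permutations, seed)
  p_perm <- (1 + sum(st$perm >= st$obs - 1e-12)) / (1 + n_permutations)
  r2 <- 100 * (st$obs * st$df1) / (st$obs * st$df1 + st$df2)

  tibble::tibble(
    p_perm = p_perm, f_statistic = unname(st$obs), r2_explained = r2,
    n_haplotypes_tested = length(tested),
    tested_haplotypes = list(stats::setNames(as.numeric(f[tested]), tested)),
    reference_haplotype = ref,
    n_used = length(yk)
  )
}

#' Sliding-window haplotype trend regression scan
#'
#' Tests every window of `window` consecutive SNPs (in map order) against
#' every trait; `m - window + 1` windows per trait.
#'
#' @param genotypes Individuals x SNPs dosage matrix (map order).
#' @param phenotypes Tibble with `individual_id` and trait columns.
#' @param window Window width (default 3).
#' @param freq_min Haplotype frequency filter (default 0.01).
#' @param n_permutations Permutations per test (default 1000).
#' @param seed Master seed (per-window streams are derived from it).
#' @param alpha Significance level on the permutation p (default 0.05).
#' @return A tibble of class `cg_htr_scan`: one row per (window, trait)
#'   with `window_start`, `window_end`, `snp_ids`, the [htr_test()]
#'   columns and a `significant` flag.
#' @export
sliding_scan <- function(genotypes, phenotypes, window = 3L, freq_min = 0.01,
                         n_permutations = 1000L, seed = 1L, alpha = 0.05) {
  G <- as.matrix(genotypes)
  m <- ncol(G)
  if (m < window) stop("need at least `window` SNPs", call. = FALSE)
  ph <- tibble::as_tibble(phenotypes)
  trait_cols <- setdiff(names(ph), "individual_id")
  ids <- rownames(G)
  if (!is.null(ids) && "individual_id" %in% names(ph)) {
    ph <- ph[match(ids, ph$individual_id), , drop = FALSE]
  }
  snps <- colnames(G)
  if (is.null(snps)) snps <- sprintf("SNP%d", seq_len(m))

  starts <- seq_len(m - window + 1L)
  wh_list <- lapply(starts, function(s)
    em_window_haplotypes(G[, s:(s + window - 1L), drop = FALSE]))

  out <- purrr::map_dfr(trait_cols, function(tr) {
    y <- ph[[tr]]
    purrr::map_dfr(starts, function(s) {
      res <- htr_test(y, wh_list[[s]], freq_min = freq_min,
                      n_permutations = n_permutations,
                      seed = derive_seed(seed, paste0("htr_", tr, "_", s)))
      dplyr::bind_cols(
        tibble::tibble(trait = tr, window_start = s,
                       window_end = s + window - 1L,
                       snp_ids = paste(snps[s:(s + window - 1L)],
                                       collapse = "-")),
        res)
    })
  })
  out$significant <- out$p_perm <= alpha
  class(out) <- c("cg_htr_scan", class(out))
  out
}
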