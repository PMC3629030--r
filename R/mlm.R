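# Q+K mixed linear model, EMMA-style: y = X beta + u + e with
# Var(u) = sigma_a^2 K and Var(e) = sigma_e^2 I. A single symmetric
# eigendecomposition of K rotates the model to independent errors with
# weights (lambda_i + delta), and the REML log-likelihood is profiled over
# the single variance ratio delta = sigma_e^2 / sigma_a^2 on the log
# scale. The marker coefficient is tested by a Wald F with n - p
# denominator degrees of freedom; at K = I this reduces exactly to the
# ordinary-regression F-test.

#' Precompute the kinship eigendecomposition for repeated MLM fits
#'
#' @param K Symmetric positive semidefinite kinship matrix.
#' @return A list with `values` and `vectors`, reusable across traits and
#'   markers for the same panel.
#' @export
mlm_eigen <- function(K) {
  if (max(abs(K - t(K))) > 1e-10) stop("K must be symmetric", call. = FALSE)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1)) {
    stop("K is not positive semidefinite (min eigenvalue ",
         format(min(ev$values)), ")", call. = FALSE)
  }
  ev$values <- pmax(ev$values, 0)
  ev
}

reml_loglik <- function(log_delta, yr, Xr, lambda) {
  delta <- exp(log_delta)
  w <- lambda + delta
  n <- length(yr); p <- ncol(Xr)
  XtWX <- crossprod(Xr / w, Xr)
  XtWy <- crossprod(Xr / w, yr)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 / w)
  # REML: -0.5 [ (n-p) log(rss/(n-p)) + sum log w + log det(X'WX) + (n-p) ]
  -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) +
            2 * sum(log(diag(ch))) + (n - p))
}

#' Single-marker Q+K mixed-model association test
#'
#' Fits `y = mu + Q v + marker * beta + u + e` by REML with
#' `Var(u) = sigma_a^2 K`, using one eigendecomposition of `K` and a 1-D
#' profile of the variance ratio, and tests the marker coefficient by a
#' Wald F-test. Individuals with a missing trait or marker are dropped
#' (the kinship eigendecomposition is then recomputed on the subset).
#'
#' @param y Trait vector.
#' @param marker Dosage vector (0/1/2, `NA` allowed).
#' @param Q Optional structure covariate matrix (rows on the simplex); one
#'   column is dropped to avoid collinearity with the intercept.
#' @param K Kinship matrix, or `NULL` for independent errors.
#' @param eig Optional precomputed [mlm_eigen()] of `K` (only used when no
#'   individuals are dropped).
#' @param maf_min Minimum minor-allele frequency among the analysed
#'   individuals (default 0.10).
#' @param min_n Minimum number of analysed individuals (default 30).
#' @return An object of class `cg_mlm`: marker effect, standard error,
#'   F statistic, p-value, explained variance (% of phenotypic variance),
#'   variance components and sample size. `NULL` fields with a `skipped`
#'   reason when the marker fails the MAF filter or is collinear.
#' @export
mlm_single_marker <- function(y, marker, Q = NULL, K = NULL, eig = NULL,
                              maf_min = 0.10, min_n = 30L) {
  keep <- !is.na(y) & !is.na(marker)
  n_all <- length(y)
  y <- y[keep]; marker <- marker[keep]
  n <- length(y)
  if (n < min_n) {
    return(structure(list(skipped = "too_few_individuals", n_used = n),
                     class = "cg_mlm"))
  }
  f <- mean(marker) / 2
  maf <- min(f, 1 - f)
  if (maf < maf_min) {
    return(structure(list(skipped = "maf_filter", maf = maf, n_used = n),
                     class = "cg_mlm"))
  }
  X <- cbind(`(Intercept)` = 1, marker = marker)
  if (!is.null(Q)) {
    Qk <- as.matrix(Q)[keep, , drop = FALSE]
    if (ncol(Qk) > 1L) Qk <- Qk[, -1L, drop = FALSE]  # drop one column
    X <- cbind(X[, 1, drop = FALSE], Qk, marker = marker)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    return(structure(list(skipped = "collinear", n_used = n), class = "cg_mlm"))
  }

  if (is.null(K)) {
    lambda <- rep(1, n)
    U <- NULL
    yr <- y; Xr <- X
  } else {
    if (is.null(eig) || !all(keep)) {
      eig <- mlm_eigen(as.matrix(K)[keep, keep, drop = FALSE])
    }
    lambda <- eig$values
    U <- eig$vectors
    yr <- crossprod(U, y)
    Xr <- crossprod(U, X)
  }

  opt <- optimize(reml_loglik, interval = c(-12, 12), yr = yr, Xr = Xr,
                  lambda = lambda, maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- lambda + delta
  p <- ncol(X)
  XtWX <- crossprod(Xr / w, Xr)
  XtWy <- crossprod(Xr / w, yr)
  beta <- solve(XtWX, XtWy)
  r <- yr - Xr %*% beta
  sigma2 <- sum(r^2 / w) / (n - p)   # sigma_a^2 scale (V = sigma2*(K + delta I))
  covb <- sigma2 * solve(XtWX)
  bm <- beta[p]
  se <- sqrt(covb[p, p])
  Fstat <- (bm / se)^2
  pval <- pf(Fstat, 1, n - p, lower.tail = FALSE)
  r2_explained <- 100 * var(marker * bm) / var(y)

  structure(list(
    beta_marker = unname(bm), se = unname(se), F = unname(Fstat),
    p_value = unname(pval), r2_explained = unname(r2_explained),
    n_used = n, maf = maf,
    sigma_a2 = sigma2, sigma_e2 = sigma2 * delta, delta = delta,
    reml = opt$objective, df_residual = n - p,
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    skipped = NA_character_
  ), class = "cg_mlm")
}

#' @export
print.cg_mlm <- function(x, ...) {
  if (!is.na(x$skipped %||% NA)) {
    cat("<cg_mlm> skipped:", x$skipped, "\n")
    return(invisible(x))
  }
  cat("<cg_mlm> beta =", signif(x$beta_marker, 4),
      " p =", format.pval(x$p_value, digits = 3),
      " R2 =", sprintf("%.2f%%", x$r2_explained),
      " n =", x$n_used, "\n")
  invisible(x)
}

#' @export
tidy.cg_mlm <- function(x, ...) {
  if (!is.na(x$skipped %||% NA)) {
    return(tibble::tibble(term = "marker", estimate = NA_real_,
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, skipped = x$skipped))
  }
  tibble::tibble(term = "marker", estimate = x$beta_marker,
                 std.error = x$se, statistic = x$F, p.value = x$p_value,
                 skipped = NA_character_)
}

#' @export
glance.cg_mlm <- function(x, ...) {
  if (!is.na(x$skipped %||% NA)) {
    return(tibble::tibble(n_used = x$n_used %||% NA_integer_,
                          skipped = x$skipped))
  }
  tibble::tibble(
    sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, delta = x$delta,
    r2_explained = x$r2_explained, df_residual = x$df_residual,
    n_used = x$n_used, skipped = NA_character_
  )
}
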