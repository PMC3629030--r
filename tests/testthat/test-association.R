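test_that("MLM at K = identity reproduces ordinary regression exactly", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 80
    g <- rbinom(n, 2, 0.4)
    Q <- cbind(a = rbinom(n, 1, 0.5))
    Q <- cbind(Q, b = 1 - Q[, 1])
    y <- 0.3 * g + 0.5 * Q[, 1] + rnorm(n)
    fit <- mlm_single_marker(y, g, Q = Q, K = diag(n))
    ols <- lm(y ~ Q[, 2] + g)
    expect_equal(fit$p_value, summary(ols)$coefficients["g", 4],
                 tolerance = 1e-6)
    expect_equal(fit$beta_marker, unname(coef(ols)["g"]), tolerance = 1e-6)
  }
})

test_that("MLM filters rare markers, small samples and collinear markers", {
  set.seed(3)
  n <- 200
  y <- rnorm(n)
  rare <- c(rep(1L, 10), rep(0L, n - 10))      # MAF 0.025
  expect_equal(mlm_single_marker(y, rare)$skipped, "maf_filter")
  expect_equal(mlm_single_marker(y[1:10], rbinom(10, 2, .5))$skipped,
               "too_few_individuals")
  g <- rbinom(n, 2, 0.5)
  # marker collinear with a covariate: flagged, no test
  fit_col <- mlm_single_marker(y, g, Q = cbind(1 - g / 2, g / 2))
  expect_equal(fit_col$skipped, "collinear")

  # missing data: complete-case
  y2 <- y; y2[1:5] <- NA
  g2 <- g; g2[6:8] <- NA
  fit2 <- mlm_single_marker(y2, g2)
  expect_equal(fit2$n_used, n - 8)
})

test_that("MLM p-values are invariant to affine trait rescaling", {
  set.seed(4)
  cfg <- sim_config(seed = 4, n_individuals = 150, n_snps = 8)
  pop <- simulate_structured_population(cfg)
  K <- ritland_kinship(pop$genotypes)
  y <- rnorm(150) + 0.3 * pop$genotypes[, 2]
  f1 <- mlm_single_marker(y, pop$genotypes[, 2], Q = pop$Q, K = K)
  f2 <- mlm_single_marker(5 + 3 * y, pop$genotypes[, 2], Q = pop$Q, K = K)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-8)
  expect_equal(f1$r2_explained, f2$r2_explained, tolerance = 1e-6)
})

test_that("null MLM p-values are uniform (type-I error calibrated)", {
  set.seed(5)
  n <- 200
  n_rep <- 400
  K <- diag(n)
  pvals <- vapply(seq_len(n_rep), function(r) {
    g <- rbinom(n, 2, runif(1, 0.15, 0.5))
    y <- rnorm(n)
    mlm_single_marker(y, g, K = K)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Storey q-values match BH at pi0 = 1 and stay monotone", {
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  set.seed(6)
  for (rep in 1:5) {
    p <- runif(50)^1.5
    expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"),
                 tolerance = 1e-12)
    q <- storey_qvalues(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    expect_true(all(q <= 1 + 1e-12) && all(q >= 0))
  }
  # identical p-values get identical q-values
  expect_equal(length(unique(storey_qvalues(rep(0.2, 10)))), 1)
  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
})

test_that("gene action arithmetic follows the class-mean definitions", {
  ga <- gene_action(g_BB = 10, g_Bb = 9, g_bb = 8, freq_B = 0.5,
                    trait_sd = 2, overall_mean = 9)
  expect_equal(ga$two_a, 2)
  expect_equal(ga$d, 0)
  expect_equal(ga$d_over_a, 0)
  expect_equal(ga$std_effect, 1)
  expect_equal(ga$mode, "additive")

  # published row arithmetic: 2a = 1.3871, d = 0.3247 -> d/a = 0.4682
  expect_equal(round(0.3247 / (1.3871 / 2), 4), 0.4682)
  expect_equal(classify_gene_action(0.3247 / (1.3871 / 2)), "additive")
  # 2a = 1.7470, d = 3.2853 -> overdominant
  expect_equal(classify_gene_action(3.2853 / (1.7470 / 2)), "overdominant")

  # thresholds: 0.5 is additive, just above is dominant, 1.25 flagged
  expect_equal(classify_gene_action(c(0.5, 0.500001, -1.2, 1.3)),
               c("additive", "dominant", "dominant", "overdominant"))
  expect_warning(classify_gene_action(1.25), "1.25")

  # additive-effect formula: as printed vs substitution alternative
  ga_p <- gene_action(12, 10, 9, freq_B = 0.3, trait_sd = 1, overall_mean = 10)
  expect_equal(ga_p$additive_effect, 0.3 * 12 + 0.7 * 10 - 10)
  ga_s <- gene_action(12, 10, 9, freq_B = 0.3, trait_sd = 1,
                      overall_mean = 10, formula = "substitution")
  a <- (12 - 9) / 2; d <- 10 - 0.5 * (12 + 9)
  expect_equal(ga_s$additive_effect, a + d * (0.7 - 0.3))

  # missing class: mode undefined
  ga_na <- gene_action(NA, 10, 9)
  expect_true(is.na(ga_na$mode))
})

test_that("Mendelian chi-squared test matches hand arithmetic and its size", {
  res <- mendelian_test(rep(c(1L, 2L), c(40, 60)), 1, 2)
  expect_equal(res$chi2, 4.0)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_true(res$keep)  # 0.0455 >= 0.01

  perfect <- mendelian_test(rep(c(0L, 1L, 2L), c(25, 50, 25)), 1, 1)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)

  expect_equal(mendelian_test(rep(1L, 10), 0, 0)$skipped, "monomorphic")
  # impossible class fails outright
  expect_false(mendelian_test(c(rep(1L, 50), 0L), 1, 2)$keep)

  # size: ~1% rejections under true Mendelian segregation
  rejections <- vapply(1:20, function(s) {
    g <- simulate_f1_cross(rep(1L, 25), rep(1L, 25), 400, seed = 700 + s)
    keep <- vapply(seq_len(25), function(j)
      mendelian_test(g[, j], 1, 1)$keep, logical(1))
    mean(!keep)
  }, numeric(1))
  expect_lt(mean(rejections), 0.03)
})

test_that("single-marker ANOVA matches textbook F arithmetic", {
  y <- c(1, 2, 3, 7, 8, 9)
  m <- c(0, 0, 0, 2, 2, 2)
  res <- single_marker_anova(y, m)
  # two classes: F = t^2 of the two-sample equal-variance t-test
  tt <- t.test(y ~ m, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  ss_tot <- sum((y - mean(y))^2)
  ss_m <- ss_tot - sum((y - ave(y, m))^2)
  expect_equal(res$r2_explained, 100 * ss_m / ss_tot, tolerance = 1e-9)

  # identical class means at large n: p near 1, r2 near 0
  set.seed(9)
  y_eq <- rep(5, 2000) + rnorm(2000)
  m_eq <- rep(c(0, 1, 2), length.out = 2000)
  same <- single_marker_anova(y_eq, m_eq)
  expect_gt(same$p_value, 0.05)
  expect_lt(same$r2_explained, 1)
  expect_equal(single_marker_anova(rnorm(10), rep(1, 10))$skipped,
               "single_class")
})

test_that("association scan flags planted QTL and handles LD duplicates", {
  cfg <- sim_config(seed = 17, n_individuals = 426, n_snps = 20,
                    qtl_effects = list(qtl_spec(5, 1, additive_effect = 0.45)))
  pop <- simulate_structured_population(cfg)
  ph <- simulate_phenotypes(pop$genotypes, pop$K, qtl = cfg$qtl_effects,
                            h2_polygenic = 0.2, noise_sd = 1,
                            seed = 18, n_traits = 2)
  G <- cbind(pop$genotypes, SNPdup = pop$genotypes[, 5])
  scan <- association_scan(G, ph, Q = pop$Q, K = pop$K)
  expect_s3_class(scan, "cg_scan")
  expect_equal(nrow(scan), 21 * 2)

  hit <- scan[scan$snp_id == "SNP5" & scan$trait == "trait_1", ]
  expect_true(hit$significant)
  expect_false(is.na(hit$mode))

  dup <- scan[scan$snp_id == "SNPdup" & scan$trait == "trait_1", ]
  expect_equal(dup$p_value, hit$p_value, tolerance = 1e-9)

  # ID mismatch errors
  ph_bad <- ph; ph_bad$individual_id[1] <- "nobody"
  expect_error(association_scan(pop$genotypes, ph_bad, Q = pop$Q, K = pop$K),
               "without genotypes")
})

test_that("validation panel pipeline keeps Mendelian loci and finds effects", {
  set.seed(19)
  p1 <- rep(1L, 6); p2 <- c(1L, 1L, 2L, 0L, 1L, 1L)
  prog <- simulate_f1_cross(p1, p2, 600, seed = 20)
  ph <- simulate_phenotypes(prog, diag(600),
                            qtl = list(qtl_spec(2, 1, additive_effect = 0.4)),
                            h2_polygenic = 0, noise_sd = 1, seed = 21,
                            n_traits = 2)
  out <- validate_panel(prog, p1, p2, ph)
  expect_equal(nrow(out$mendelian), 6)
  expect_true(all(out$mendelian$keep, na.rm = TRUE))
  hit <- out$associations[out$associations$snp_id == "SNP2" &
                            out$associations$trait == "trait_1", ]
  expect_lt(hit$p_value, 0.01)
  expect_true(hit$significant)
})
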