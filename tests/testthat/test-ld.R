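test_that("two-locus EM recovers haplotype frequencies", {
  # 50 AABB + 50 aabb: no phase ambiguity
  g1 <- rep(c(2L, 0L), each = 50)
  g2 <- rep(c(2L, 0L), each = 50)
  fit <- em_two_locus_frequencies(g1, g2)
  expect_equal(unname(fit$freq[c("AB", "ab")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(fit$freq[c("Ab", "aB")]), c(0, 0), tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # all double heterozygotes: symmetric optimum, resolved to D = 0
  fit_dh <- em_two_locus_frequencies(rep(1L, 40), rep(1L, 40))
  expect_equal(fit_dh$D, 0, tolerance = 1e-9)

  # genotypes from known phased haplotypes match the counting oracle
  set.seed(31)
  for (rep in 1:5) {
    p_hap <- c(0.4, 0.25, 0.2, 0.15)
    hap_idx <- sample(1:4, 1000, replace = TRUE, prob = p_hap)
    alle <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
    H <- alle[hap_idx, ]
    G <- H[seq(1, 999, 2), ] + H[seq(2, 1000, 2), ]
    fit2 <- em_two_locus_frequencies(G[, 1], G[, 2])
    truth <- tabulate(hap_idx, 4) / 1000
    expect_equal(unname(fit2$freq), truth, tolerance = 0.06)
  }

  # fully homozygous data (no ambiguity): exact equality with counting
  H <- rbind(c(1, 1), c(1, 1), c(0, 1), c(0, 1), c(0, 0), c(0, 0))
  H <- H[rep(1:6, each = 10), ]
  G <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
  fit3 <- em_two_locus_frequencies(G[, 1], G[, 2])
  expect_equal(unname(fit3$freq),
               c(mean(H[, 1] & H[, 2]), mean(H[, 1] & !H[, 2]),
                 mean(!H[, 1] & H[, 2]), mean(!H[, 1] & !H[, 2])),
               tolerance = 1e-6)

  # EM log-likelihood is non-decreasing
  set.seed(8)
  g1r <- rbinom(200, 2, 0.4); g2r <- rbinom(200, 2, 0.3)
  trace <- em_two_locus_frequencies(g1r, g2r)$loglik
  expect_true(all(diff(trace) > -1e-9))
})

test_that("pairwise r2 is symmetric, bounded and matches per-pair brute force", {
  set.seed(12)
  cfg <- sim_config(seed = 12, n_individuals = 120, n_snps = 6,
                    fst = 0, subpop_proportions = 1)
  pop <- simulate_structured_population(cfg)
  pr <- pairwise_r2(pop$genotypes, pop$positions)
  expect_equal(nrow(pr), choose(6, 2))
  expect_true(all(pr$r2 >= 0 & pr$r2 <= 1))
  for (k in seq_len(nrow(pr))) {
    direct <- em_two_locus_frequencies(pop$genotypes[, pr$i[k]],
                                       pop$genotypes[, pr$j[k]])$r2
    expect_equal(pr$r2[k], direct, tolerance = 1e-12)
  }
  M <- r2_matrix(pr)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 6))

  # duplicated locus: r2 = 1
  G <- cbind(pop$genotypes[, 1], pop$genotypes[, 1])
  expect_equal(em_two_locus_frequencies(G[, 1], G[, 2])$r2, 1, tolerance = 1e-9)

  # independent loci at large n: mean r2 ~ 1/n
  set.seed(99)
  G1 <- rbinom(10000, 2, 0.3); G2 <- rbinom(10000, 2, 0.4)
  expect_lt(em_two_locus_frequencies(G1, G2)$r2, 0.01)
})

test_that("permutation p-values behave at the extremes", {
  set.seed(14)
  g <- rbinom(100, 2, 0.5)
  # duplicated locus: p at its minimum scale
  res <- r2_significance(g, g, n_permutations = 499, seed = 3)
  expect_lt(res$p_perm, 0.02)
  # independent loci: p not extreme
  g2 <- rbinom(100, 2, 0.5)
  res2 <- r2_significance(g, g2, n_permutations = 199, seed = 3)
  expect_gt(res2$p_perm, 0.005)
  expect_error(r2_significance(g, g2, n_permutations = 10), ">= 100")
})

test_that("LD decay fit recovers a known decaying curve", {
  set.seed(41)
  # pairs from a known Hill-Weir curve + noise; recover the crossing
  n_chrom <- 800
  rho_true <- 0.02
  truth_cross <- uniroot(function(d)
    cgassoc:::hill_weir_expectation(rho_true * d, n_chrom) - 0.1,
    c(1, 5000))$root
  rel_err <- vapply(1:20, function(s) {
    set.seed(s)
    d <- runif(300, 10, 4000)
    r2 <- pmin(pmax(cgassoc:::hill_weir_expectation(rho_true * d, n_chrom) +
                      rnorm(300, 0, 0.05), 0), 1)
    fit <- fit_ld_decay(tibble::tibble(distance_bp = d, r2 = r2),
                        n_chromosomes = n_chrom)
    abs(fit$crossing_hill_weir - truth_cross) / truth_cross
  }, numeric(1))
  expect_lt(mean(rel_err), 0.15)

  # constant r2 = 1: no crossing reported
  const <- tibble::tibble(distance_bp = c(10, 500, 1000, 2000), r2 = 1)
  fit_c <- fit_ld_decay(const, n_chromosomes = 100)
  expect_true(is.na(fit_c$crossing_hill_weir))

  # OLS slope negative for data simulated with decaying LD
  cfg <- sim_config(seed = 61, n_individuals = 200, n_snps = 30,
                    fst = 0, subpop_proportions = 1, ld_decay_scale = 500)
  pop <- simulate_structured_population(
    cfg, positions = as.integer(seq(0, 4300, length.out = 30)))
  fit_s <- fit_ld_decay(pairwise_r2(pop$genotypes, pop$positions))
  expect_lt(fit_s$ols["slope"], 0)
})

test_that("block detection finds exactly the planted runs", {
  # hand-built r2 matrix: SNPs 2-5 in perfect LD, others independent
  m <- 8
  M <- diag(1, m)
  M[2:5, 2:5] <- 1
  M[M < 1] <- 0.05
  diag(M) <- 1
  blocks <- detect_blocks(M, threshold = 0.75)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$start_snp_index, 2)
  expect_equal(blocks$end_snp_index, 5)

  # no blocks when everything is independent
  expect_equal(nrow(detect_blocks(diag(1, 5) + 0.02, threshold = 0.75)), 0)

  # invariance to r2 values strictly above the threshold
  M2 <- M; M2[2:5, 2:5] <- 0.76; diag(M2) <- 1
  expect_equal(detect_blocks(M2, threshold = 0.75), blocks)

  # permutation p filter can veto a block
  P <- matrix(1, m, m)
  expect_equal(nrow(detect_blocks(M, threshold = 0.75, p_matrix = P)), 0)

  # planted blocks in simulated genotypes are recovered
  cfg <- sim_config(seed = 33, n_individuals = 250, n_snps = 20,
                    fst = 0, subpop_proportions = 1, ld_decay_scale = 30)
  pop <- simulate_structured_population(
    cfg, positions = as.integer(seq(0, 4300, length.out = 20)),
    blocks = list(4:7, 12:14))
  pr <- pairwise_r2(pop$genotypes)
  blocks_sim <- detect_blocks(r2_matrix(pr), threshold = 0.75)
  expect_equal(blocks_sim$start_snp_index, c(4L, 12L))
  expect_equal(blocks_sim$end_snp_index, c(7L, 14L))
})
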