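test_that("haplotype alignment generator honours its contract", {
  # no mutation at theta = 0
  cfg0 <- sim_config(seed = 1, n_haplotypes = 10, theta_per_site = 0)
  aln0 <- simulate_haplotype_alignment(cfg0)
  expect_equal(segregating_sites(aln0), 0)
  expect_equal(dim(aln0), c(10, 4374))

  # bit-reproducible given the seed
  cfg <- sim_config(seed = 5, n_haplotypes = 16, theta_per_site = 0.004)
  expect_identical(simulate_haplotype_alignment(cfg),
                   simulate_haplotype_alignment(cfg))

  # every variant column maps to exactly one region of the gene model
  aln <- simulate_haplotype_alignment(cfg)
  truth <- attr(aln, "truth")
  expect_true(all(truth$region %in% cfg$gene_model$regions$label))
  expect_equal(anyDuplicated(truth$position), 0)

  # observed S lies in the central 99% of the simulator's own S distribution
  small <- function(s) sim_config(seed = s, n_haplotypes = 2,
                                  gene_model = toy_gene_model(),
                                  theta_per_site = 0.01)
  s_dist <- vapply(1:1000, function(s)
    nrow(attr(simulate_haplotype_alignment(small(s)), "truth")), numeric(1))
  s_obs <- nrow(attr(simulate_haplotype_alignment(small(424242)), "truth"))
  expect_gte(s_obs, quantile(s_dist, 0.005))
  expect_lte(s_obs, quantile(s_dist, 0.995))

  # gap columns are injected on request and excluded from S
  aln_g <- simulate_haplotype_alignment(cfg, gap_columns = 3)
  expect_equal(length(attr(aln_g, "gap_columns")), 3)
  expect_true(all(colSums(aln_g == "-")[attr(aln_g, "gap_columns") + 1L] > 0))
})

test_that("mutation counts per region are proportional to region length", {
  cfg <- sim_config(seed = 77, n_haplotypes = 20, theta_per_site = 0.02)
  counts <- integer(nrow(cfg$gene_model$regions))
  names(counts) <- cfg$gene_model$regions$label
  for (r in 1:30) {
    cfg_r <- sim_config(seed = 77 + r, n_haplotypes = 20, theta_per_site = 0.02)
    truth <- attr(simulate_haplotype_alignment(cfg_r), "truth")
    tab <- table(truth$region)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  frac <- counts / sum(counts)
  expected <- cfg$gene_model$regions$length / total_length(cfg$gene_model)
  # multinomial SEs on the pooled counts
  se <- sqrt(expected * (1 - expected) / sum(counts))
  expect_true(all(abs(frac - expected) < 4 * se + 1e-3))
})

test_that("structured population generator enforces MAF and bookkeeping", {
  cfg <- sim_config(seed = 9, n_individuals = 426, n_snps = 40,
                    subpop_proportions = c(180, 86, 160) / 426)
  pop <- simulate_structured_population(cfg)
  expect_equal(dim(pop$genotypes), c(426, 40))
  expect_true(all(pop$genotypes %in% 0:2))

  f <- colMeans(pop$genotypes) / 2
  expect_true(all(pmin(f, 1 - f) >= cfg$maf_min))

  # Q matrix column sums equal the subpopulation sizes
  expect_equal(unname(colSums(pop$Q)), c(180, 86, 160))
  expect_true(all(rowSums(pop$Q) == 1))

  # identity kinship when no families are simulated
  expect_equal(pop$K, diag(426), ignore_attr = TRUE)

  # determinism
  pop2 <- simulate_structured_population(cfg)
  expect_identical(pop$genotypes, pop2$genotypes)
})

test_that("LD in the generated panel decays with distance and blocks plant r2 = 1", {
  cfg <- sim_config(seed = 21, n_individuals = 300, n_snps = 24,
                    fst = 0, subpop_proportions = 1, ld_decay_scale = 300)
  pop <- simulate_structured_population(
    cfg, positions = as.integer(seq(0, 4300, length.out = 24)),
    blocks = list(5:8))
  pr <- pairwise_r2(pop$genotypes, pop$positions)
  # planted block is in perfect LD
  blk <- pr[pr$i >= 5 & pr$j <= 8 & pr$j > pr$i, ]
  expect_true(all(blk$r2 > 0.999))
  # r2 decreases with distance on average: OLS slope negative
  free <- pr[!(pr$i %in% 5:8 & pr$j %in% 5:8), ]
  expect_lt(coef(lm(r2 ~ distance_bp, data = free))[2], 0)
})

test_that("kinship is near zero for unstructured panels and ranks families", {
  # fst = 0, one subpopulation, no families: raw Ritland estimates ~ 0
  means <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 100 + s, n_individuals = 100, n_snps = 60,
                      fst = 0, subpop_proportions = 1)
    pop <- simulate_structured_population(cfg)
    K <- ritland_kinship(pop$genotypes, truncate = FALSE)
    mean(K[upper.tri(K)])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 0.01)

  # families: sib pairs score higher than non-sib pairs
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 300 + s, n_individuals = 80, n_snps = 80,
                      fst = 0, subpop_proportions = 1)
    pop <- simulate_structured_population(cfg, n_families = 4, family_size = 5)
    K <- ritland_kinship(pop$genotypes, truncate = FALSE)
    fam <- attr(pop$K, "family_rows")
    sib_mask <- (pop$K > 0 & upper.tri(pop$K))
    nonsib_mask <- upper.tri(pop$K) & !sib_mask
    mean(K[sib_mask]) > mean(K[nonsib_mask])
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  # duplicated individual scores ~ 1
  cfg <- sim_config(seed = 500, n_individuals = 50, n_snps = 100,
                    fst = 0, subpop_proportions = 1)
  pop <- simulate_structured_population(cfg)
  G <- rbind(pop$genotypes, dup = pop$genotypes[1, ])
  K <- ritland_kinship(G, truncate = FALSE)
  expect_gte(K[1, nrow(G)], 0.9)
})

test_that("phenotype simulation plants the requested genetic architecture", {
  cfg <- sim_config(seed = 13, n_individuals = 426, n_snps = 10)
  pop <- simulate_structured_population(cfg)

  # no QTL, no polygenic term, unit noise: trait variance ~ 1
  ph <- simulate_phenotypes(pop$genotypes, pop$K, h2_polygenic = 0,
                            noise_sd = 1, seed = 4, n_traits = 4)
  v <- vapply(paste0("trait_", 1:4), function(tr) var(ph[[tr]]), numeric(1))
  expect_true(all(abs(v - 1) < 0.25))

  # planted pure-additive QTL with no noise: d = 0 exactly
  ph2 <- simulate_phenotypes(pop$genotypes, pop$K,
                             qtl = list(qtl_spec(3, 1, additive_effect = 0.8)),
                             h2_polygenic = 0, noise_sd = 0, seed = 1,
                             n_traits = 1)
  ga <- gene_action_from_data(ph2$trait_1, pop$genotypes[, 3])
  expect_equal(ga$d, 0)
  expect_equal(ga$two_a, 1.6)

  # boundary case d/a = 0.5 classifies additive (<= 0.5 rule)
  ph3 <- simulate_phenotypes(pop$genotypes, pop$K,
                             qtl = list(qtl_spec(3, 1, 0.7, 0.35)),
                             h2_polygenic = 0, noise_sd = 0, seed = 1,
                             n_traits = 1)
  ga3 <- gene_action_from_data(ph3$trait_1, pop$genotypes[, 3])
  expect_equal(ga3$d_over_a, 0.5)
  expect_equal(ga3$mode, "additive")

  # determinism
  expect_identical(ph, simulate_phenotypes(pop$genotypes, pop$K,
                                           h2_polygenic = 0, noise_sd = 1,
                                           seed = 4, n_traits = 4))
  expect_error(simulate_phenotypes(pop$genotypes, matrix(-1, 426, 426),
                                   seed = 1, h2_polygenic = 0.5),
               "symmetric|semidefinite")
})

test_that("F1 cross segregates Mendelian ratios", {
  # AA x AA: all progeny AA
  g <- simulate_f1_cross(rep(2L, 3), rep(2L, 3), 50, seed = 1)
  expect_true(all(g == 2L))

  # Aa x AA: only AA and Aa
  g2 <- simulate_f1_cross(c(1L), c(2L), 500, seed = 2)
  expect_true(all(g2 %in% 1:2))

  # Aa x Aa at n = 4000: 1:2:1 within 3 binomial SEs
  g3 <- simulate_f1_cross(c(1L), c(1L), 4000, seed = 3)
  counts <- table(factor(g3, levels = 0:2))
  expected <- c(0.25, 0.5, 0.25) * 4000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) * 4000)
  expect_true(all(abs(counts - expected) < 3 * se))

  # missing parent genotype: locus skipped with warning
  expect_warning(g4 <- simulate_f1_cross(c(1L, NA), c(1L, 1L), 10, seed = 4),
                 "skipped")
  expect_true(all(is.na(g4[, 2])))
  expect_true(all(!is.na(g4[, 1])))
})
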