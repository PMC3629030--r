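test_that("segregating sites counts biallelic columns and honours exclusions", {
  m <- make_alignment("ACGTACGTAC", 4)
  expect_equal(segregating_sites(m), 0)

  m2 <- make_alignment("ACGTACGTAC", 4, subs = list(
    list(pos = 2, base = "T", rows = 1),
    list(pos = 5, base = "-", rows = 2),     # gap column excluded
    list(pos = 7, base = "A", rows = 1),
    list(pos = 7, base = "C", rows = 2)      # multiallelic excluded
  ))
  expect_equal(segregating_sites(m2), 1)
  # excluding gap columns never increases S
  expect_lte(segregating_sites(m2), segregating_sites(
    make_alignment("ACGTACGTAC", 4, subs = list(
      list(pos = 2, base = "T", rows = 1),
      list(pos = 5, base = "T", rows = 2)))))
})

test_that("pi matches its definition on simple cases and brute force", {
  # 2 sequences differing at 1 of 10 sites
  m <- make_alignment("ACGTACGTAC", 2, subs = list(
    list(pos = 3, base = "A", rows = 1)))
  expect_equal(nucleotide_diversity(m), 0.1)
  expect_equal(nucleotide_diversity(make_alignment("ACGTACGTAC", 5)), 0)

  # random 6 x 50 alignment vs O(n^2 L) enumeration oracle
  set.seed(19)
  for (rep in 1:3) {
    base <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                  collapse = "")
    subs <- lapply(sample(50, 12), function(p) {
      list(pos = p - 1, base = sample(c("A", "C", "G", "T"), 1),
           rows = sample(6, sample(3, 1)))
    })
    m <- make_alignment(base, 6, subs = subs)
    expect_equal(nucleotide_diversity(m), brute_force_pi(m), tolerance = 1e-12)
  }
})

test_that("Watterson's theta uses the harmonic number of the sample size", {
  m <- make_alignment("ACGTACGTAC", 2, subs = list(
    list(pos = 3, base = "A", rows = 1)))
  expect_equal(watterson_theta(m), 0.1)  # a_1 = 1

  expect_equal(watterson_theta(make_alignment("ACGTACGTAC", 5)), 0)

  # n=5, S=7, L=100 -> 7 / (a_4 * 100)
  set.seed(7)
  base <- paste(rep("A", 100), collapse = "")
  subs <- lapply(1:7, function(k) list(pos = k * 9, base = "G", rows = k %% 4 + 1))
  m5 <- make_alignment(base, 5, subs = subs)
  a4 <- 1 + 1/2 + 1/3 + 1/4
  expect_equal(watterson_theta(m5), 7 / (a4 * 100), tolerance = 1e-12)
  expect_equal(round(watterson_theta(m5), 4), 0.0336)
})

test_that("bp-per-SNP rounds half away from zero", {
  expect_equal(snp_frequency(4374, 243), 18L)
  expect_equal(snp_frequency(133, 7), 19L)
  expect_equal(snp_frequency(374, 25), 15L)
  expect_equal(snp_frequency(15, 2), 8L)    # 7.5 rounds up
  expect_true(is.na(snp_frequency(100, 0)))
})

test_that("diversity table partitions counts additively", {
  cfg <- sim_config(seed = 23, n_haplotypes = 30, theta_per_site = 0.005)
  aln <- simulate_haplotype_alignment(cfg)
  gm <- cfg$gene_model
  div <- diversity_table(aln, gm)

  per_region <- div[div$partition == "all" &
                      !div$region %in% c("total", "total_silent"), ]
  tot <- div[div$region == "total" & div$partition == "all", ]
  expect_equal(sum(per_region$S), tot$S)
  expect_equal(sum(per_region$length_bp), tot$length_bp)

  # silent + nonsynonymous = total
  silent <- div[div$region == "total_silent", ]
  nonsyn <- div[div$region == "total" & div$partition == "nonsynonymous", ]
  syn <- div[div$region == "total" & div$partition == "synonymous", ]
  expect_equal(silent$S + nonsyn$S, tot$S)
  expect_equal(silent$length_bp + nonsyn$length_bp, tot$length_bp,
               tolerance = 1e-9)

  # per-exon syn/nonsyn partitions sum to the gene-level partition rows
  exon_syn <- div[grepl("^exon_", div$region) & div$partition == "synonymous", ]
  exon_nonsyn <- div[grepl("^exon_", div$region) & div$partition == "nonsynonymous", ]
  expect_equal(sum(exon_syn$S), syn$S)
  expect_equal(sum(exon_nonsyn$S), nonsyn$S)
  expect_equal(sum(exon_syn$length_bp), syn$length_bp, tolerance = 1e-9)

  # table statistics agree with direct recomputation per region
  for (lab in c("five_prime_utr", "intron_3", "exon_1")) {
    pos <- which(assign_region(gm, 0:(total_length(gm) - 1)) == lab) - 1L
    row <- div[div$region == lab & div$partition == "all", ]
    expect_equal(row$S, segregating_sites(aln, pos))
    expect_equal(row$pi, nucleotide_diversity(aln, pos), tolerance = 1e-12)
    expect_equal(row$theta_w, watterson_theta(aln, pos), tolerance = 1e-12)
  }
  expect_equal(glance(div)$pi, nucleotide_diversity(aln), tolerance = 1e-12)
})

test_that("theta recovery: simulated alignments estimate the planted theta", {
  # parameter-recovery at theta = 0.01/bp, n = 44 haplotypes
  n_rep <- 60
  ests <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(seed = 1000 + r, n_haplotypes = 44, theta_per_site = 0.01)
    watterson_theta(simulate_haplotype_alignment(cfg))
  }, numeric(1))
  se <- sd(ests) / sqrt(n_rep)
  expect_lt(abs(mean(ests) - 0.01), 3 * se)
})
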