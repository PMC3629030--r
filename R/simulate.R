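# Synthetic-data generators for the whole pipeline: coalescent haplotype
# alignments, Balding-Nichols structured genotype panels with tunable LD
# decay, quantitative traits with planted QTL plus a polygenic background,
# and Mendelian F1 crosses.

#' Derive a reproducible sub-seed from a master seed
#'
#' Each generator draws from its own stream obtained by stable hashing of
#' (master seed, generator name), so adding a generator never perturbs the
#' draws of another.
#'
#' @param master Integer master seed.
#' @param name Generator name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 48271 + h * 10007) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles the study-design parameters used by the generators: a discovery
#' panel of 44 sequenced diploid individuals (88 haplotypes) over a ~4.4 kb
#' candidate gene, 82 common SNPs (minor allele frequency >= 0.10)
#' genotyped in 426 individuals drawn from three geographic subpopulations
#' (proportions 180/86/160), ten quantitative traits, and a 1200-progeny
#' F1 validation cross.
#'
#' @param seed Master seed; generator streams are derived from it.
#' @param n_haplotypes Number of haplotype sequences in the alignment.
#' @param theta_per_site Population mutation rate per bp (4*N*mu).
#' @param gene_model A `cg_gene_model` (default [uxs1_gene_model()]).
#' @param n_individuals Association-panel size.
#' @param subpop_proportions Proportions of the subpopulations (sum to 1).
#' @param fst Balding-Nichols divergence of subpopulation allele
#'   frequencies, in `[0, 1)`.
#' @param ld_decay_scale Distance in bp at which the latent haplotype
#'   correlation halves.
#' @param n_snps Number of genotyped common SNPs.
#' @param maf_min Minimum minor-allele frequency of an emitted SNP.
#' @param qtl_effects List of [qtl_spec()] planted marker effects.
#' @param h2_polygenic Proportion of non-QTL variance that is polygenic.
#' @param n_traits Number of quantitative traits.
#' @param n_progeny F1 validation-cross size.
#' @param noise_sd Residual standard deviation of the traits.
#' @return A list of class `cg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = 88L,
                       theta_per_site = 0.0128,
                       gene_model = uxs1_gene_model(),
                       n_individuals = 426L,
                       subpop_proportions = c(180, 86, 160) / 426,
                       fst = 0.05,
                       ld_decay_scale = 350,
                       n_snps = 82L,
                       maf_min = 0.10,
                       qtl_effects = list(),
                       h2_polygenic = 0.3,
                       n_traits = 10L,
                       n_progeny = 1200L,
                       noise_sd = 1) {
  if (abs(sum(subpop_proportions) - 1) > 1e-12) {
    stop("subpop_proportions must sum to 1", call. = FALSE)
  }
  if (theta_per_site < 0) stop("theta_per_site must be non-negative", call. = FALSE)
  if (n_haplotypes < 2L || n_individuals < 2L || n_snps < 2L || n_progeny < 1L) {
    stop("sizes must be positive (>= 2 for samples)", call. = FALSE)
  }
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
  if (h2_polygenic < 0 || h2_polygenic >= 1) {
    stop("h2_polygenic must be in [0, 1)", call. = FALSE)
  }
  if (ld_decay_scale <= 0) stop("ld_decay_scale must be positive", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_haplotypes = as.integer(n_haplotypes),
    theta_per_site = theta_per_site, gene_model = gene_model,
    n_individuals = as.integer(n_individuals),
    subpop_proportions = subpop_proportions, fst = fst,
    ld_decay_scale = ld_decay_scale, n_snps = as.integer(n_snps),
    maf_min = maf_min, qtl_effects = qtl_effects,
    h2_polygenic = h2_polygenic, n_traits = as.integer(n_traits),
    n_progeny = as.integer(n_progeny), noise_sd = noise_sd
  ), class = "cg_sim_config")
}

#' Planted QTL specification
#'
#' @param snp_index Index of the causal SNP (1-based, in map order).
#' @param trait_index Index of the affected trait.
#' @param additive_effect Additive effect `a` (half the homozygote-class
#'   difference), in trait units.
#' @param dominance_effect Dominance deviation `d` of the heterozygote from
#'   the homozygote midpoint, in trait units.
#' @return A list of class `cg_qtl_spec`.
#' @export
qtl_spec <- function(snp_index, trait_index, additive_effect, dominance_effect = 0) {
  stopifnot(snp_index >= 1L, trait_index >= 1L)
  structure(list(snp_index = as.integer(snp_index),
                 trait_index = as.integer(trait_index),
                 additive_effect = additive_effect,
                 dominance_effect = dominance_effect),
            class = "cg_qtl_spec")
}

# Kingman coalescent of n lineages; returns segments (leaf sets + branch
# lengths in units of 2N generations) on which mutations fall.
coalescent_segments <- function(n) {
  leafsets <- as.list(seq_len(n))
  lens <- numeric(n)
  seg_sets <- list(); seg_lens <- numeric(0)
  k <- n
  while (k > 1L) {
    dt <- rexp(1, rate = k * (k - 1) / 2)
    lens <- lens + dt
    pick <- sample.int(k, 2L)
    for (p in pick) {
      seg_sets[[length(seg_sets) + 1L]] <- leafsets[[p]]
      seg_lens <- c(seg_lens, lens[p])
    }
    merged <- c(leafsets[[pick[1]]], leafsets[[pick[2]]])
    leafsets <- c(leafsets[-pick], list(merged))
    lens <- c(lens[-pick], 0)
    k <- k - 1L
  }
  list(sets = seg_sets, lens = seg_lens)
}

#' Simulate a haplotype alignment under the infinite-sites model
#'
#' Generates `n_haplotypes` sequences of the gene-model length from a
#' neutral Kingman coalescent (no recombination): mutations fall on
#' branches as a Poisson process with per-site rate `theta_per_site / 2`
#' per unit of 2N generations, each at a distinct uniformly chosen column
#' (so every polymorphic column is biallelic, and the expected mutation
#' count per region is proportional to region length). The ancestral
#' coding sequence is drawn from sense codons so that the consensus
#' translates cleanly. Optionally a few gap columns are injected to
#' exercise the indel-exclusion rules downstream.
#'
#' @param config A `cg_sim_config`.
#' @param gap_columns Number of columns in which a random subset of
#'   sequences carries a gap character (default 0).
#' @return A character alignment matrix with a `truth` attribute (tibble
#'   of planted mutation positions, region labels and derived alleles).
#' @export
simulate_haplotype_alignment <- function(config, gap_columns = 0L) {
  stopifnot(inherits(config, "cg_sim_config"))
  model <- config$gene_model
  L <- model$total_length
  if (L <= 0) stop("gene model must have positive length", call. = FALSE)
  set.seed(derive_seed(config$seed, "haplotype_alignment"))
  n <- config$n_haplotypes

  # ancestral sequence: sense codons in the CDS, uniform bases elsewhere
  anc <- sample(BASES, L, replace = TRUE)
  cmap <- cds_map(model)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  n_codons <- nrow(cmap) / 3L
  cds <- unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""))
  ord <- order(cmap$cds_pos)
  anc[cmap$genomic_pos[ord] + 1L] <-
    if (model$strand == "-") chartr("ACGT", "TGCA", cds) else cds

  m <- matrix(rep(anc, each = n), nrow = n)
  rownames(m) <- sprintf("hap_%02d", seq_len(n))

  truth <- tibble::tibble(position = integer(), region = character(),
                          ancestral = character(), derived = character(),
                          n_derived = integer())
  if (config$theta_per_site > 0) {
    segs <- coalescent_segments(n)
    total_len <- sum(segs$lens)
    n_mut <- rpois(1, config$theta_per_site / 2 * L * total_len)
    n_mut <- min(n_mut, L)  # infinite sites: distinct columns
    if (n_mut > 0) {
      pos <- sample.int(L, n_mut) - 1L
      branch <- sample.int(length(segs$lens), n_mut, replace = TRUE,
                           prob = segs$lens)
      derived <- character(n_mut)
      for (i in seq_len(n_mut)) {
        carriers <- segs$sets[[branch[i]]]
        derived[i] <- sample(setdiff(BASES, anc[pos[i] + 1L]), 1L)
        m[carriers, pos[i] + 1L] <- derived[i]
      }
      truth <- tibble::tibble(
        position = pos,
        region = assign_region(model, pos),
        ancestral = anc[pos + 1L],
        derived = derived,
        n_derived = vapply(branch, function(b) length(segs$sets[[b]]), integer(1))
      ) |> dplyr::arrange(.data$position)
    }
  }
  if (gap_columns > 0L) {
    gpos <- sample(setdiff(seq_len(L), truth$position + 1L), gap_columns)
    for (g in gpos) m[sample.int(n, max(1L, n %/% 4L)), g] <- "-"
    attr(m, "gap_columns") <- sort(gpos) - 1L
  }
  attr(m, "truth") <- truth
  m
}

largest_remainder_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a structured association panel
#'
#' Diploid dosages (0/1/2) for `n_individuals` x `n_snps` common SNPs with
#' three layers of structure: (i) subpopulation allele frequencies drawn
#' from the Balding-Nichols model
#' `Beta((1-Fst)/Fst * p, (1-Fst)/Fst * (1-p))` around an ancestral
#' frequency `p`; (ii) linkage disequilibrium within the gene produced by
#' thresholding a stationary latent Gaussian process over SNP positions
#' with correlation `0.5^(distance / ld_decay_scale)` at the per-SNP
#' frequency quantile, so r2 decays smoothly with bp distance; and
#' (iii) optional full-sib families for kinship. Every emitted SNP
#' satisfies the `maf_min` constraint after bounded rejection sampling of
#' its frequencies (the latent field is kept fixed so LD is preserved).
#'
#' @param config A `cg_sim_config`.
#' @param positions Optional 0-based SNP positions (default: uniform draw
#'   within the gene, sorted).
#' @param blocks Optional list of integer ranges (e.g. `list(4:7, 9:16)`):
#'   SNPs within a range share a single latent variable (perfect LD), which
#'   plants detectable haplotype blocks.
#' @param n_families,family_size If positive, the last
#'   `n_families * family_size` individuals are replaced by full-sib
#'   families whose parents are drawn from the panel haplotype pool; the
#'   kinship matrix records the realized within-family allele sharing.
#' @return A list with `genotypes` (individuals x SNPs dosage matrix),
#'   `positions`, `Q` (individuals x subpopulations membership matrix),
#'   `K` (realized kinship; identity when no families), and `truth`
#'   (per-SNP subpopulation allele frequencies).
#' @export
simulate_structured_population <- function(config, positions = NULL,
                                           blocks = NULL,
                                           n_families = 0L, family_size = 0L) {
  stopifnot(inherits(config, "cg_sim_config"))
  set.seed(derive_seed(config$seed, "structured_population"))
  n <- config$n_individuals
  m_snps <- config$n_snps
  L <- config$gene_model$total_length
  n_sub <- length(config$subpop_proportions)

  if (is.null(positions)) {
    positions <- sort(sample.int(L, m_snps)) - 1L
  }
  stopifnot(length(positions) == m_snps)

  # SNPs inside a planted block share their block's first SNP outright, so
  # the latent Gaussian field is built over the block representatives only
  block_master <- seq_len(m_snps)
  if (!is.null(blocks)) {
    for (b in blocks) block_master[b] <- min(b)
  }
  masters <- which(block_master == seq_len(m_snps))

  # latent correlation: exponential decay halving at ld_decay_scale
  d <- abs(outer(positions[masters], positions[masters], "-"))
  R <- 0.5^(d / config$ld_decay_scale)
  ch <- tryCatch(chol(R), error = function(e)
    chol(R + diag(1e-8, length(masters))))

  n_hap <- 2L * n
  Z <- matrix(0, n_hap, m_snps)
  Z[, masters] <- matrix(rnorm(n_hap * length(masters)), n_hap) %*% ch

  sub_sizes <- largest_remainder_counts(n, config$subpop_proportions)
  subpop <- rep(seq_len(n_sub), sub_sizes)
  hap_sub <- rep(subpop, each = 2L)

  draw_freqs <- function() {
    p_anc <- runif(1, config$maf_min + 0.05, 1 - config$maf_min - 0.05)
    if (config$fst == 0) return(rep(p_anc, n_sub))
    shape <- (1 - config$fst) / config$fst
    rbeta_clamped <- pmin(pmax(
      stats::rbeta(n_sub, shape * p_anc, shape * (1 - p_anc)), 1e-4), 1 - 1e-4)
    rbeta_clamped
  }

  H <- matrix(0L, n_hap, m_snps)
  freqs <- matrix(NA_real_, n_sub, m_snps)
  for (j in seq_len(m_snps)) {
    if (block_master[j] != j) {
      # perfect-LD copy of the block's first SNP
      H[, j] <- H[, block_master[j]]
      freqs[, j] <- freqs[, block_master[j]]
      next
    }
    ok <- FALSE
    for (try in seq_len(50L)) {
      pj <- draw_freqs()
      thr <- qnorm(pj)[hap_sub]
      allele <- as.integer(Z[, j] < thr)
      geno_j <- allele[seq(1, n_hap, 2)] + allele[seq(2, n_hap, 2)]
      f <- mean(geno_j) / 2
      if (min(f, 1 - f) >= config$maf_min) {
        H[, j] <- allele
        freqs[, j] <- pj
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not satisfy MAF constraint for SNP ", j,
           " after 50 retries", call. = FALSE)
    }
  }

  G <- H[seq(1, n_hap, 2), , drop = FALSE] + H[seq(2, n_hap, 2), , drop = FALSE]
  K <- diag(n)

  if (n_families > 0L && family_size > 1L) {
    n_fam_ind <- n_families * family_size
    if (n_fam_ind > n) stop("too many family individuals", call. = FALSE)
    fam_rows <- (n - n_fam_ind + 1L):n
    idx <- 0L
    for (f in seq_len(n_families)) {
      # two parents = four haplotypes drawn from the haplotype pool
      par_h <- H[sample.int(n_hap, 4L), , drop = FALSE]
      trans <- matrix(0L, family_size, 2L)
      kids <- matrix(0L, family_size, m_snps)
      for (k in seq_len(family_size)) {
        a <- sample(1:2, 1L); b <- sample(3:4, 1L)
        trans[k, ] <- c(a, b)
        kids[k, ] <- par_h[a, ] + par_h[b, ]
      }
      rows <- fam_rows[idx + seq_len(family_size)]
      G[rows, ] <- kids
      for (k1 in seq_len(family_size - 1L)) {
        for (k2 in (k1 + 1L):family_size) {
          share <- (trans[k1, 1] == trans[k2, 1]) + (trans[k1, 2] == trans[k2, 2])
          K[rows[k1], rows[k2]] <- K[rows[k2], rows[k1]] <- share / 2
        }
      }
      idx <- idx + family_size
    }
    attr(K, "family_rows") <- fam_rows
  }

  ids <- sprintf("ind_%03d", seq_len(n))
  rownames(G) <- ids
  colnames(G) <- sprintf("SNP%d", seq_len(m_snps))
  Q <- matrix(0, n, n_sub, dimnames = list(ids, paste0("subpop_", seq_len(n_sub))))
  Q[cbind(seq_len(n), subpop)] <- 1
  dimnames(K) <- list(ids, ids)

  list(genotypes = G, positions = positions, Q = Q, K = K,
       truth = list(subpop = subpop, freqs = freqs))
}

#' Simulate quantitative traits with planted QTL
#'
#' Inverse model of the Q+K mixed model: for each trait,
#' `y = mu + sum_qtl [a * (dosage - 1) + d * 1(dosage == 1)] + g + e`
#' where the polygenic term `g` has covariance `sigma_a^2 * K` with
#' `sigma_a^2 = noise_sd^2 * h2 / (1 - h2)`, and `e` is iid Gaussian noise
#' with standard deviation `noise_sd`.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param kinship Symmetric positive semidefinite kinship matrix.
#' @param qtl List of [qtl_spec()] planted effects.
#' @param h2_polygenic Polygenic proportion of the non-QTL variance.
#' @param noise_sd Residual standard deviation (> 0 unless `h2 = 0` and a
#'   noise-free check is wanted; 0 is allowed).
#' @param seed Integer seed.
#' @param n_traits Number of traits.
#' @param mu Intercept.
#' @return A tibble: `individual_id` plus `trait_1 ... trait_k` columns.
#' @export
simulate_phenotypes <- function(genotypes, kinship, qtl = list(),
                                h2_polygenic = 0, noise_sd = 1, seed = 1L,
                                n_traits = 10L, mu = 0) {
  n <- nrow(genotypes)
  stopifnot(nrow(kinship) == n, ncol(kinship) == n)
  if (max(abs(kinship - t(kinship))) > 1e-8) {
    stop("kinship matrix must be symmetric", call. = FALSE)
  }
  set.seed(seed)
  sigma_a2 <- noise_sd^2 * h2_polygenic / (1 - h2_polygenic)
  Ksq <- NULL
  if (sigma_a2 > 0) {
    ev <- eigen(kinship, symmetric = TRUE)
    if (min(ev$values) < -1e-6 * max(abs(ev$values))) {
      stop("kinship matrix is not positive semidefinite (min eigenvalue ",
           format(min(ev$values)), ")", call. = FALSE)
    }
    Ksq <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  }
  Y <- matrix(mu, n, n_traits)
  for (q in qtl) {
    stopifnot(inherits(q, "cg_qtl_spec"))
    if (q$snp_index > ncol(genotypes) || q$trait_index > n_traits) {
      stop("QTL index out of bounds", call. = FALSE)
    }
    g <- genotypes[, q$snp_index]
    Y[, q$trait_index] <- Y[, q$trait_index] +
      q$additive_effect * (g - 1) + q$dominance_effect * (g == 1)
  }
  if (!is.null(Ksq)) {
    Y <- Y + sqrt(sigma_a2) * (Ksq %*% matrix(rnorm(n * n_traits), n, n_traits))
  }
  if (noise_sd > 0) {
    Y <- Y + noise_sd * matrix(rnorm(n * n_traits), n, n_traits)
  }
  colnames(Y) <- paste0("trait_", seq_len(n_traits))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(n))
  dplyr::bind_cols(tibble::tibble(individual_id = ids), tibble::as_tibble(Y))
}

#' Simulate an F1 full-sib cross
#'
#' Each progeny genotype at each biallelic locus is the sum of one
#' Mendelian gamete per parent, independently per locus (no linkage within
#' the cross). Loci where a parent genotype is missing are skipped with a
#' warning; loci where both parents are homozygous yield monomorphic
#' progeny.
#'
#' @param parent1,parent2 Dosage vectors (0/1/2, `NA` missing) at the same
#'   loci.
#' @param n_progeny Number of progeny.
#' @param seed Integer seed.
#' @return Progeny x loci dosage matrix (skipped loci are all-`NA`).
#' @export
simulate_f1_cross <- function(parent1, parent2, n_progeny, seed = 1L) {
  stopifnot(length(parent1) == length(parent2))
  bad <- !(parent1 %in% c(0L, 1L, 2L, NA)) | !(parent2 %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("parent genotypes must be 0/1/2 or NA", call. = FALSE)
  set.seed(seed)
  m <- length(parent1)
  G <- matrix(NA_integer_, n_progeny, m)
  gamete <- function(g) {
    if (g == 0L) rep(0L, n_progeny)
    else if (g == 2L) rep(1L, n_progeny)
    else rbinom(n_progeny, 1L, 0.5)
  }
  skipped <- integer(0)
  for (j in seq_len(m)) {
    if (is.na(parent1[j]) || is.na(parent2[j])) {
      skipped <- c(skipped, j)
      next
    }
    G[, j] <- gamete(parent1[j]) + gamete(parent2[j])
  }
  if (length(skipped) > 0L) {
    warning("skipped ", length(skipped), " locus/loci with missing parent genotype: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  rownames(G) <- sprintf("f1_%04d", seq_len(n_progeny))
  colnames(G) <- if (!is.null(names(parent1))) names(parent1) else
    sprintf("SNP%d", seq_len(m))
  G
}
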