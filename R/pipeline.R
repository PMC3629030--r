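#' Pipeline configuration
#'
#' Bundles the thresholds and seeds of the full analysis. Defaults follow
#' the study design the generators emulate: common-SNP filter MAF > 0.10,
#' FDR threshold 0.10, block threshold r2 > 0.75, haplotype frequency
#' filter 1%, Mendelian rejection level 0.01, significance level 0.05.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] used when the pipeline generates its own
#'   inputs.
#' @param maf_min,fdr,block_r2,hap_freq_min,mendelian_alpha,
#'   significance_alpha Thresholds.
#' @param n_permutations Permutations for the haplotype tests.
#' @return A list of class `cg_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            maf_min = 0.10, fdr = 0.10, block_r2 = 0.75,
                            hap_freq_min = 0.01, mendelian_alpha = 0.01,
                            significance_alpha = 0.05,
                            n_permutations = 200L) {
  stopifnot(maf_min > 0, maf_min < 0.5, fdr > 0, fdr < 1,
            block_r2 > 0, block_r2 < 1, hap_freq_min >= 0,
            mendelian_alpha > 0, significance_alpha > 0)
  structure(list(seed = as.integer(seed), sim = sim, maf_min = maf_min,
                 fdr = fdr, block_r2 = block_r2,
                 hap_freq_min = hap_freq_min,
                 mendelian_alpha = mendelian_alpha,
                 significance_alpha = significance_alpha,
                 n_permutations = as.integer(n_permutations)),
            class = "cg_pipeline_config")
}

#' Run the full candidate-gene analysis on synthetic inputs
#'
#' Orchestrates simulate -> diversity -> LD -> association -> haplotype ->
#' validation and writes one TSV per result table to `out_dir`:
#' the region diversity table, LD pairs / blocks / decay parameters, the
#' discovery association scan with gene-action records, the
#' haplotype-window scan, and the validation results (Mendelian-kept
#' panel forwarded from the discovery-significant SNPs at
#' `significance_alpha`). Outputs are deterministic given the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list of result tables plus a `report` tibble of per-stage row
#'   counts and filter bookkeeping.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cg_pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  note <- function(stage, rows, before = NA_integer_, removed = NA_integer_) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, rows = rows, before = before, removed = removed,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }
  sim <- config$sim
  model <- sim$gene_model

  aln <- simulate_haplotype_alignment(sim)
  note("alignment", nrow(aln))

  div <- diversity_table(aln, model)
  note("diversity", nrow(div))

  pop <- simulate_structured_population(sim)
  note("genotypes", nrow(pop$genotypes))

  phen <- simulate_phenotypes(pop$genotypes, pop$K, qtl = sim$qtl_effects,
                              h2_polygenic = sim$h2_polygenic,
                              noise_sd = sim$noise_sd,
                              seed = derive_seed(sim$seed, "phenotypes"),
                              n_traits = sim$n_traits)
  note("phenotypes", nrow(phen))

  ld_pairs <- pairwise_r2(pop$genotypes, pop$positions)
  decay <- fit_ld_decay(ld_pairs)
  blocks <- detect_blocks(r2_matrix(ld_pairs), threshold = config$block_r2)
  note("ld_pairs", nrow(ld_pairs))
  note("ld_blocks", nrow(blocks))

  scan <- association_scan(pop$genotypes, phen, Q = pop$Q, K = pop$K,
                           maf_min = config$maf_min,
                           fdr_threshold = config$fdr)
  tested <- sum(is.na(scan$skipped))
  note("association", nrow(scan), before = nrow(scan),
       removed = nrow(scan) - tested)

  htr <- sliding_scan(pop$genotypes, phen, window = 3L,
                      freq_min = config$hap_freq_min,
                      n_permutations = config$n_permutations,
                      seed = derive_seed(sim$seed, "htr"),
                      alpha = config$significance_alpha)
  note("haplotype_scan", nrow(htr))

  # panel of discovery-significant SNPs (p < significance_alpha) forwarded
  # to the validation population
  panel <- unique(scan$snp_id[!is.na(scan$p_value) &
                                scan$p_value < config$significance_alpha])
  validation <- NULL
  if (length(panel) > 0L) {
    jdx <- match(panel, colnames(pop$genotypes))
    set.seed(derive_seed(sim$seed, "validation_parents"))
    parents_pool <- pop$genotypes[sample.int(nrow(pop$genotypes), 2L), jdx,
                                  drop = FALSE]
    progeny <- simulate_f1_cross(parents_pool[1, ], parents_pool[2, ],
                                 n_progeny = sim$n_progeny,
                                 seed = derive_seed(sim$seed, "f1_cross"))
    qtl_val <- purrr::keep(sim$qtl_effects, function(q)
      colnames(pop$genotypes)[q$snp_index] %in% panel)
    qtl_val <- purrr::map(qtl_val, function(q) {
      q$snp_index <- match(colnames(pop$genotypes)[q$snp_index], panel)
      q
    })
    vph <- simulate_phenotypes(progeny, diag(nrow(progeny)), qtl = qtl_val,
                               h2_polygenic = 0, noise_sd = sim$noise_sd,
                               seed = derive_seed(sim$seed, "validation_phen"),
                               n_traits = sim$n_traits)
    validation <- validate_panel(progeny, parents_pool[1, ], parents_pool[2, ],
                                 vph, mendelian_alpha = config$mendelian_alpha,
                                 fdr_threshold = config$fdr)
    note("validation_panel", length(panel))
    note("validation_kept", sum(validation$mendelian$keep, na.rm = TRUE),
         before = length(panel))
  }

  report <- dplyr::bind_rows(stages)
  out <- list(diversity = div, ld_pairs = ld_pairs, ld_decay = decay,
              ld_blocks = blocks, association = scan, haplotype = htr,
              validation = validation, report = report,
              config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) readr::write_tsv(tibble::as_tibble(x),
                                            file.path(out_dir, name))
    w(div, "diversity.tsv")
    w(ld_pairs, "ld_pairs.tsv")
    w(tidy(decay), "ld_decay.tsv")
    w(blocks, "ld_blocks.tsv")
    w(scan, "association.tsv")
    w(dplyr::select(htr, -"tested_haplotypes"), "haplotype.tsv")
    if (!is.null(validation)) {
      w(validation$mendelian, "validation_mendelian.tsv")
      w(validation$associations, "validation_association.tsv")
    }
    w(report, "run_report.tsv")
  }
  out
}
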