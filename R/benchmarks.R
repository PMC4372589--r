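#' Null-simulation type-I error study
#'
#' Simulates pairs of libraries from identical ground truth (no DE genes)
#' and counts how often the full pipeline (clean tags -> mapping -> TPM ->
#' Audic-Claverie + FDR + fold threshold) calls a gene differentially
#' expressed. Under the null every call is a false rejection.
#'
#' @param n_seeds Number of independent library pairs.
#' @param n_genes Genes in the simulated transcriptome.
#' @param depth Reads per library.
#' @param alpha FDR threshold for the calls.
#' @param error_rate Per-base substitution error rate.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return List: \code{rate} (pooled rejection proportion), \code{rejected},
#'   \code{tested}, \code{sigma} (binomial SD of the proportion at
#'   \code{alpha}), and per-seed counts.
#' @export
null_rejection_rate <- function(n_seeds = 10, n_genes = 500, depth = 1e5,
                                alpha = 0.01, error_rate = 0.005, seed = 1) {
  rejected <- 0L
  tested <- 0L
  per_seed <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- seed * 1000L + s * 17L
    ref <- simulate_transcriptome(n_genes, seed = base)
    truth <- assign_ground_truth(ref, de_fraction = 0, fold_values = 2,
                                 conditions = c("CON", "CS"), seed = base + 1L)
    idx <- build_index(ref)
    exprs <- lapply(1:2, function(i) {
      rr <- simulate_tag_reads(ref, truth, "CON", depth,
                               error_rate = error_rate, seed = base + 1L + i)
      lib <- extract_clean_tags(rr)
      lib$condition <- c("CON", "CS")[i]
      tpm_normalize(gene_counts(map_tags(lib, idx), lib))
    })
    d <- call_degs(exprs[[1]], exprs[[2]], alpha = alpha)
    per_seed[s] <- sum(d$records$call != "ns")
    rejected <- rejected + per_seed[s]
    tested <- tested + nrow(d$records)
  }
  list(rate = rejected / tested, rejected = rejected, tested = tested,
       sigma = sqrt(alpha * (1 - alpha) / tested), per_seed = per_seed)
}

#' Parameter-recovery study for DEG calling
#'
#' Simulates treatment-vs-control pairs with a known fraction of genes
#' differentially expressed at a fixed fold change, runs the full pipeline,
#' and reports the pooled sensitivity on well-expressed DE genes (baseline
#' expression at least \code{min_base_tpm} tags per million) together with
#' the empirical false-discovery proportion over all calls.
#'
#' @inheritParams null_rejection_rate
#' @param de_fraction Fraction of genes DE in the treatment condition.
#' @param fold Simulated fold change of DE genes (up or down with equal
#'   probability unless \code{prob_up} says otherwise).
#' @param prob_up Probability a DE gene is up-regulated.
#' @param min_base_tpm Baseline expression floor (TPM) defining the
#'   eligible truth set for sensitivity.
#' @return List: \code{sensitivity}, \code{fdp}, plus the pooled counts
#'   (\code{eligible}, \code{recovered}, \code{discoveries},
#'   \code{false_discoveries}).
#' @export
deg_recovery <- function(n_seeds = 10, n_genes = 500, depth = 2e5,
                         de_fraction = 0.1, fold = 8, prob_up = 0.5,
                         error_rate = 0.005, alpha = 0.01,
                         min_base_tpm = 50, seed = 1) {
  eligible <- recovered <- discoveries <- false_disc <- 0L
  for (s in seq_len(n_seeds)) {
    base <- seed * 1000L + s * 29L
    ref <- simulate_transcriptome(n_genes, seed = base)
    truth <- assign_ground_truth(ref, de_fraction = de_fraction,
                                 fold_values = fold,
                                 conditions = c("CON", "CS"),
                                 prob_up = prob_up, seed = base + 1L)
    idx <- build_index(ref)
    exprs <- lapply(c("CON", "CS"), function(cond) {
      rr <- simulate_tag_reads(ref, truth, cond, depth,
                               error_rate = error_rate,
                               seed = base + 1L + match(cond, c("CON", "CS")))
      lib <- extract_clean_tags(rr)
      tpm_normalize(gene_counts(map_tags(lib, idx), lib))
    })
    d <- call_degs(exprs[[1]], exprs[[2]], alpha = alpha)
    called <- d$records$gene_id[d$records$call != "ns"]
    de <- truth$gene_id[truth$de_CS]
    elig <- truth$gene_id[truth$de_CS & truth$base_abundance * 1e6 >= min_base_tpm]
    eligible <- eligible + length(elig)
    recovered <- recovered + sum(elig %in% called)
    discoveries <- discoveries + length(called)
    false_disc <- false_disc + sum(!(called %in% de))
  }
  list(sensitivity = recovered / eligible,
       fdp = if (discoveries > 0) false_disc / discoveries else 0,
       eligible = eligible, recovered = recovered,
       discoveries = discoveries, false_discoveries = false_disc)
}
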