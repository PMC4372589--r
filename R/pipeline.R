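#' Build a pipeline run configuration
#'
#' A flat configuration for \code{\link{run_pipeline}}. Either simulation
#' parameters (\code{simulate = list(...)}) or paths to existing inputs
#' (\code{reference}, \code{tag_tables}) must be given. Round-trips
#' losslessly through YAML via \code{\link{write_run_config}} /
#' \code{\link{read_run_config}}.
#'
#' @param out_dir Output directory (created if absent).
#' @param conditions Condition labels; first is the control.
#' @param pairs List of 2-vectors of condition labels to compare; default
#'   all control-vs-treatment plus treatment-vs-treatment pairs.
#' @param simulate NULL, or a list of overrides for the simulation stage:
#'   \code{n_genes}, \code{depth}, \code{de_fraction}, \code{fold},
#'   \code{error_rate}, \code{empty_read_rate}, \code{catg_fraction},
#'   \code{prob_up}.
#' @param reference Path to a reference FASTA (ignored when simulating).
#' @param tag_tables Named character vector of tag-table TSVs per
#'   condition (ignored when simulating).
#' @param min_copy,max_mismatch,alpha,min_abs_log2,tpm_floor Stage
#'   thresholds.
#' @param adapter 3' adapter sequence.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, conditions = c("CON", "CS", "FS"),
                       pairs = NULL, simulate = list(), reference = NULL,
                       tag_tables = NULL, min_copy = 2L, max_mismatch = 1L,
                       alpha = 0.01, min_abs_log2 = 1, tpm_floor = 0.01,
                       adapter = DEFAULT_ADAPTER, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop_param("alpha must be in (0, 1]")
  if (min_copy < 1) stop_param("min_copy must be >= 1")
  if (!max_mismatch %in% 0:1) stop_param("max_mismatch must be 0 or 1")
  if (tpm_floor <= 0) stop_param("tpm_floor must be positive")
  if (is.null(pairs)) {
    cmb <- utils::combn(conditions, 2, simplify = FALSE)
    pairs <- cmb
  }
  sim_defaults <- list(n_genes = 500L, depth = 50000L, de_fraction = 0.1,
                       fold = 8, error_rate = 0.005, empty_read_rate = 0.05,
                       catg_fraction = 0.9, prob_up = 0.5)
  if (!is.null(simulate)) {
    unknown <- setdiff(names(simulate), names(sim_defaults))
    if (length(unknown)) stop_param("unknown simulate option: ",
                                    paste(unknown, collapse = ", "))
    simulate <- utils::modifyList(sim_defaults, simulate)
  }
  structure(list(out_dir = out_dir, conditions = conditions, pairs = pairs,
                 simulate = simulate, reference = reference,
                 tag_tables = tag_tables, min_copy = min_copy,
                 max_mismatch = max_mismatch, alpha = alpha,
                 min_abs_log2 = min_abs_log2, tpm_floor = tpm_floor,
                 adapter = adapter, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A \code{run_config}.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$pairs <- lapply(x$pairs, unlist)
  do.call(run_config, x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full DeepSAGE pipeline
#'
#' Executes simulate (optional) -> clean-tag extraction -> virtual-tag
#' mapping -> TPM -> DEG calling per comparison pair -> QC, writing every
#' intermediate artifact (TSV), a library summary, per-comparison up/down
#' counts, and a machine-readable \code{run.log} (package version, seeds,
#' thresholds) under \code{config$out_dir}. Re-running with an identical
#' config reproduces byte-identical TSV outputs.
#'
#' @param config A \code{run_config}.
#' @param quiet Suppress progress messages.
#' @return Invisible list of class \code{pipeline_run} with elements
#'   \code{libraries}, \code{index}, \code{expressions}, \code{dge},
#'   \code{summary}, \code{deg_summary}, \code{correlations},
#'   \code{artifacts}.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (!inherits(config, "run_config")) stop_param("config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  art <- character(0)
  keep <- function(p) { art <<- c(art, p); p }

  conds <- config$conditions
  truth <- NULL
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    say("simulating reference and reads")
    ref <- stage("simulate", simulate_transcriptome(
      sm$n_genes, catg_fraction = sm$catg_fraction, seed = config$seed))
    truth <- assign_ground_truth(ref, de_fraction = sm$de_fraction,
                                 fold_values = sm$fold, conditions = conds,
                                 prob_up = sm$prob_up,
                                 seed = config$seed + 1L)
    keep(write_transcriptome_fasta(ref, file.path(config$out_dir, "reference.fasta")))
    keep(write_ground_truth(truth, file.path(config$out_dir, "ground_truth.tsv")))
    libs <- lapply(seq_along(conds), function(i) {
      rr <- simulate_tag_reads(ref, truth, conds[i], sm$depth,
                               error_rate = sm$error_rate,
                               empty_read_rate = sm$empty_read_rate,
                               adapter = config$adapter,
                               seed = config$seed + 10L + i)
      stage("tags", extract_clean_tags(rr, adapter = config$adapter,
                                       min_copy = config$min_copy))
    })
  } else {
    if (is.null(config$reference) || is.null(config$tag_tables))
      stop_param("config needs either simulate parameters or reference + tag_tables")
    ref <- stage("read_reference", read_transcriptome_fasta(config$reference))
    libs <- lapply(conds, function(cond) {
      p <- config$tag_tables[[cond]]
      if (is.null(p)) stop_param("no tag table for condition ", cond)
      stage("read_tags", read_tag_table(p, condition = cond))
    })
  }
  names(libs) <- conds
  for (cond in conds)
    keep(write_tag_table(libs[[cond]],
                         file.path(config$out_dir, paste0("tags_", cond, ".tsv"))))

  say("building index and mapping")
  idx <- stage("index", build_index(ref))
  maps <- lapply(libs, function(l)
    stage("map", map_tags(l, idx, max_mismatch = config$max_mismatch)))
  exprs <- lapply(conds, function(cond)
    stage("counts", tpm_normalize(gene_counts(maps[[cond]], libs[[cond]]))))
  names(exprs) <- conds
  for (cond in conds)
    keep(write_expression_table(exprs[[cond]],
                                file.path(config$out_dir,
                                          paste0("expression_", cond, ".tsv"))))

  say("calling DEGs")
  dges <- lapply(config$pairs, function(pr)
    stage("dge", call_degs(exprs[[pr[1]]], exprs[[pr[2]]],
                           alpha = config$alpha,
                           min_abs_log2 = config$min_abs_log2,
                           tpm_floor = config$tpm_floor)))
  names(dges) <- vapply(config$pairs, paste, "", collapse = "_vs_")
  for (nm in names(dges))
    keep(write_dge_table(dges[[nm]],
                         file.path(config$out_dir, paste0("dge_", nm, ".tsv"))))
  deg_summary <- do.call(rbind, lapply(dges, summary))
  keep(write_tsv(deg_summary, file.path(config$out_dir, "deg_summary.tsv")))

  lib_summary <- library_summary(libs)
  keep(write_tsv(lib_summary, file.path(config$out_dir, "library_summary.tsv")))
  keep(write_tsv(tag_class_report(libs),
                 file.path(config$out_dir, "tag_classes.tsv")))

  say("QC")
  cors <- do.call(rbind, lapply(config$pairs, function(pr)
    data.frame(pair = paste(pr, collapse = "_vs_"),
               pearson_r = library_correlation(exprs[[pr[1]]], exprs[[pr[2]]]))))
  keep(write_tsv(cors, file.path(config$out_dir, "correlations.tsv")))

  log <- c(
    paste0("package_version: ", as.character(utils::packageVersion("deepsage"))),
    paste0("seed: ", config$seed),
    paste0("min_copy: ", config$min_copy),
    paste0("max_mismatch: ", config$max_mismatch),
    paste0("alpha: ", config$alpha),
    paste0("min_abs_log2: ", config$min_abs_log2),
    paste0("tpm_floor: ", config$tpm_floor),
    paste0("conditions: ", paste(conds, collapse = ",")),
    paste0("pairs: ", paste(vapply(config$pairs, paste, "", collapse = "-"),
                            collapse = ","))
  )
  writeLines(log, file.path(config$out_dir, "run.log"))
  keep(file.path(config$out_dir, "run.log"))

  invisible(structure(list(libraries = libs, index = idx,
                           expressions = exprs, dge = dges,
                           truth = truth, summary = lib_summary,
                           deg_summary = deg_summary, correlations = cors,
                           artifacts = art),
                      class = "pipeline_run"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("DeepSAGE pipeline run\n")
  print(x$summary)
  cat("\nDEG summary:\n")
  print(x$deg_summary)
  invisible(x)
}
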