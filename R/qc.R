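#' Sequencing saturation curve
#'
#' Subsamples tag copies without replacement at increasing depths and
#' counts the distinct genes hit by unambiguously mapped tags at each
#' depth. A plateau indicates that further sequencing detects no new
#' genes. One random permutation of the copy-level library is drawn, so
#' the grid points are nested and the curve is non-decreasing by
#' construction; fixed seed gives a fixed curve.
#'
#' @param lib A \code{tag_library}.
#' @param index A \code{virtual_tag_index}.
#' @param grid Increasing tag depths; all must be <= the library clean
#'   total.
#' @param seed Random seed for the subsampling permutation.
#' @param max_mismatch Passed to \code{\link{map_tags}}.
#' @return Object of class \code{saturation_curve}: data.frame with
#'   \code{tags_sampled}, \code{genes_detected}.
#' @export
saturation_curve <- function(lib, index, grid, seed, max_mismatch = 1L) {
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1) || any(grid > lib$clean_total))
    stop_param("grid depths must lie in [1, clean_total = ",
               lib$clean_total, "]")
  # map each distinct tag once, then work at the copy level
  mp <- map_tags(lib, index, max_mismatch = max_mismatch)
  a <- mp$assignments
  gene_of <- ifelse(a$status == "unambiguous", a$gene_id, NA_character_)
  copies <- rep(seq_len(nrow(a)), a$count)
  pts <- with_seed(seed, {
    perm <- sample(copies)
    vapply(grid, function(d) {
      length(unique(gene_of[perm[seq_len(d)]])) -
        anyNA(gene_of[perm[seq_len(d)]])
    }, integer(1))
  })
  structure(data.frame(tags_sampled = grid, genes_detected = pts),
            class = c("saturation_curve", "data.frame"),
            condition = lib$condition, seed = seed)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  plot(x$tags_sampled, x$genes_detected, type = "b", pch = 16,
       xlab = "tags sampled", ylab = "genes detected",
       main = paste("Saturation:", attr(x, "condition")), ...)
  invisible(x)
}

#' Pearson correlation between two expression tables
#'
#' Correlates per-gene TPM over the union of genes (absent genes at 0), the
#' standard reproducibility check between parallel libraries. Optionally on
#' log2(TPM + 1).
#'
#' @param exprA,exprB \code{gene_expression} objects with TPM computed.
#' @param log2 Correlate log2(TPM + 1) instead of raw TPM.
#' @return Pearson r in [-1, 1].
#' @export
library_correlation <- function(exprA, exprB, log2 = FALSE) {
  genes <- sort(union(exprA$genes$gene_id, exprB$genes$gene_id))
  if (length(genes) < 3) stop_param("need at least 3 genes")
  a <- setNames(numeric(length(genes)), genes)
  b <- a
  a[exprA$genes$gene_id] <- exprA$genes$tpm
  b[exprB$genes$gene_id] <- exprB$genes$tpm
  if (anyNA(a) || anyNA(b))
    stop_param("TPM missing; run tpm_normalize() first")
  if (log2) { a <- log2(a + 1); b <- log2(b + 1) }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_data("undefined correlation: zero variance in TPM vector")
  cor(a, b, method = "pearson")
}

#' Abundance-class report across libraries
#'
#' Stacks \code{\link{abundance_histogram}} over libraries into one table
#' (the classical six-class tag-distribution figure as data).
#'
#' @param libs List of \code{tag_library} objects.
#' @return data.frame: library, class, distinct_prop, total_prop.
#' @export
tag_class_report <- function(libs) {
  if (inherits(libs, "tag_library")) libs <- list(libs)
  do.call(rbind, lapply(libs, function(l) {
    h <- abundance_histogram(l)
    cbind(library = l$condition, h)
  }))
}
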