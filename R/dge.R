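#' Audic-Claverie exact test for two tag counts
#'
#' Exact significance test for a difference between a count \code{x} in a
#' library of \code{N1} total tags and a count \code{y} in a library of
#' \code{N2} total tags. Conditional on \code{x}, the second count follows
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}{
#'   p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))}
#' and the two-sided p-value doubles the smaller of the two tail sums,
#' capped at 1. Terms are accumulated in log space via \code{lgamma}; the
#' minor tail is summed directly (with a convergence cutoff) whenever the
#' complement would cancel, so the result keeps relative accuracy even for
#' p-values near the double-precision floor.
#'
#' @param x,y Non-negative integer counts (vectorized).
#' @param N1,N2 Library clean-tag totals (>= 1).
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' audic_claverie_p(10, 0, 1e6, 1e6)   # 2^-10
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stop_param("x and y must be non-negative integers")
  if (any(N1 < 1) || any(N2 < 1)) stop_param("N1 and N2 must be >= 1")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) ac_p_scalar(x[i], y[i], N1[i], N2[i]),
         numeric(1))
}

# log p(k|x) for k = 0..kmax; r = N2/N1
ac_log_pmf <- function(x, kmax, logr, log1pr) {
  k <- 0:kmax
  k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1pr
}

ac_p_scalar <- function(x, y, N1, N2) {
  logr <- log(N2) - log(N1)
  log1pr <- log1p(N2 / N1)
  lp <- ac_log_pmf(x, y, logr, log1pr)
  terms <- exp(lp)
  lower <- sum(terms)                       # sum_{k <= y}
  lower_m1 <- lower - terms[y + 1]          # sum_{k <= y-1}
  upper <- 1 - lower_m1                     # sum_{k >= y}
  if (upper < 0.1) {
    # complement cancels; sum the upper tail directly until it converges
    upper <- ac_upper_direct(x, y, logr, log1pr)
  }
  # keep p in (0, 1]: guard against total underflow at extreme counts
  max(min(1, 2 * min(lower, upper)), .Machine$double.xmin)
}

# Direct summation of sum_{k >= y} p(k|x) in chunks, stopping when the
# remaining geometric bound is negligible relative to the accumulated sum.
ac_upper_direct <- function(x, y, logr, log1pr, chunk = 256L) {
  total <- 0
  k0 <- y
  repeat {
    k <- k0:(k0 + chunk - 1L)
    lt <- k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1pr
    t <- exp(lt)
    total <- total + sum(t)
    klast <- k0 + chunk - 1L
    ratio <- exp(logr - log1pr) * (x + klast + 1) / (klast + 1)
    if (ratio < 1) {
      bound <- t[chunk] * ratio / (1 - ratio)
      if (bound <= total * 1e-14 || t[chunk] == 0) return(total)
    }
    k0 <- k0 + chunk
  }
}

#' False-discovery-rate adjustment
#'
#' Step-up adjustment of a p-value vector (Benjamini-Hochberg by default,
#' Benjamini-Yekutieli available); output order matches input order and no
#' p-value decreases.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param method \code{"BH"} or \code{"BY"}.
#' @return Adjusted p-values, same order.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) && (any(is.na(p_values)) ||
                           any(p_values < 0 | p_values > 1)))
    stop_param("p-values must lie in [0, 1]")
  p.adjust(p_values, method = method)
}

#' Floored log2 expression ratio
#'
#' \code{log2(max(tpm2, floor) / max(tpm1, floor))}. The floor (default
#' 0.01 TPM) substitutes for undetected genes so that ratios against a zero
#' remain finite; with the default, a gene absent in one library and at
#' 1.42 TPM in the other reports log2(142) = 7.15.
#'
#' @param tpm1,tpm2 Non-negative TPM values (vectorized).
#' @param floor Positive detection floor in TPM.
#' @return log2 ratio(s) of library 2 over library 1.
#' @export
log2_ratio <- function(tpm1, tpm2, floor = 0.01) {
  if (floor <= 0) stop_param("floor must be positive")
  if (any(tpm1 < 0) || any(tpm2 < 0)) stop_param("TPM must be non-negative")
  log2(pmax(tpm2, floor) / pmax(tpm1, floor))
}

#' Call differentially expressed genes between two libraries
#'
#' One record per gene with a nonzero unambiguous count in either library.
#' Significance is the Audic-Claverie exact test on the raw counts with the
#' library clean totals as denominators, FDR-adjusted across genes; effect
#' size is the floored log2 TPM ratio. A gene is called up (down) when
#' \code{fdr <= alpha} and the log2 ratio is at least (at most minus)
#' \code{min_abs_log2}.
#'
#' @param expr1,expr2 \code{gene_expression} objects (TPM-normalized or
#'   not; TPM is recomputed from counts and clean totals).
#' @param alpha FDR threshold (default 0.01).
#' @param min_abs_log2 Minimum absolute log2 ratio (default 1, i.e.
#'   two-fold).
#' @param tpm_floor Detection floor passed to \code{\link{log2_ratio}}.
#' @param fdr_method \code{"BH"} or \code{"BY"}.
#' @return Object of class \code{dge_result}: data.frame \code{records}
#'   (gene_id, x, y, N1, N2, tpm1, tpm2, log2_ratio, p_value, fdr, call)
#'   plus the comparison labels and thresholds.
#' @examples
#' ref <- simulate_transcriptome(30, c(100, 300), seed = 1)
#' tr <- assign_ground_truth(ref, de_fraction = 0.2, fold_values = 8, seed = 2)
#' r1 <- simulate_tag_reads(ref, tr, "CON", 5000, seed = 3)
#' r2 <- simulate_tag_reads(ref, tr, "CS", 5000, seed = 4)
#' idx <- build_index(ref)
#' e1 <- tpm_normalize(gene_counts(map_tags(extract_clean_tags(r1), idx)))
#' e2 <- tpm_normalize(gene_counts(map_tags(extract_clean_tags(r2), idx)))
#' dge <- call_degs(e1, e2)
#' summary(dge)
#' @export
call_degs <- function(expr1, expr2, alpha = 0.01, min_abs_log2 = 1,
                      tpm_floor = 0.01, fdr_method = "BH") {
  if (identical(expr1$condition, expr2$condition) &&
      !is.na(expr1$condition))
    stop_param("the two libraries must differ: ", expr1$condition)
  if (alpha <= 0 || alpha > 1) stop_param("alpha must be in (0, 1]")
  g1 <- expr1$genes; g2 <- expr2$genes
  genes <- sort(union(g1$gene_id, g2$gene_id))
  x <- setNames(integer(length(genes)), genes)
  y <- x
  x[g1$gene_id] <- g1$count
  y[g2$gene_id] <- g2$count
  keep <- x + y > 0
  genes <- genes[keep]; x <- x[keep]; y <- y[keep]
  N1 <- expr1$clean_total; N2 <- expr2$clean_total
  tpm1 <- x / N1 * 1e6
  tpm2 <- y / N2 * 1e6
  lr <- log2_ratio(tpm1, tpm2, floor = tpm_floor)
  p <- audic_claverie_p(x, y, N1, N2)
  fdr <- fdr_adjust(p, method = fdr_method)
  call <- rep("ns", length(genes))
  call[fdr <= alpha & lr >= min_abs_log2] <- "up"
  call[fdr <= alpha & lr <= -min_abs_log2] <- "down"
  structure(list(
    records = data.frame(gene_id = genes, x = as.integer(x),
                         y = as.integer(y), N1 = N1, N2 = N2,
                         tpm1 = tpm1, tpm2 = tpm2, log2_ratio = lr,
                         p_value = p, fdr = fdr, call = call,
                         stringsAsFactors = FALSE, row.names = NULL),
    lib1 = expr1$condition, lib2 = expr2$condition,
    alpha = alpha, min_abs_log2 = min_abs_log2, tpm_floor = tpm_floor
  ), class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  s <- table(factor(x$records$call, levels = c("up", "down", "ns")))
  cat(sprintf("DGE %s vs %s: %d genes tested, %d up, %d down (FDR <= %g, |log2| >= %g)\n",
              x$lib1, x$lib2, nrow(x$records), s[["up"]], s[["down"]],
              x$alpha, x$min_abs_log2))
  invisible(x)
}

#' @export
summary.dge_result <- function(object, ...) {
  r <- object$records
  data.frame(comparison = paste(object$lib1, "vs", object$lib2),
             tested = nrow(r),
             up = sum(r$call == "up"),
             down = sum(r$call == "down"),
             ns = sum(r$call == "ns"))
}

#' Extract called DEGs
#' @param dge A \code{dge_result}.
#' @return The subset of records with call != "ns".
#' @export
deg_table <- function(dge) {
  dge$records[dge$records$call != "ns", , drop = FALSE]
}

#' Write a DGE table as TSV
#' @param dge A \code{dge_result}.
#' @param path TSV path.
#' @export
write_dge_table <- function(dge, path) {
  write.table(dge$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Hypergeometric term enrichment of a DEG set
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the overlap between the DEG set and the term's members, with the
#' whole gene universe as background; BH-adjusted and sorted by p.
#'
#' @param deg_genes Character vector of DEG identifiers (subset of
#'   \code{background}).
#' @param background Character vector: the gene universe.
#' @param term_map data.frame with columns \code{gene_id}, \code{term_id}
#'   (genes outside the background are dropped).
#' @param alpha FDR threshold used to flag significant terms.
#' @return data.frame: term_id, k (DEGs in term), K (background genes in
#'   term), n (DEGs), N (background size), p_value, fdr, significant.
#' @export
enrich_terms <- function(deg_genes, background, term_map, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0) stop_param("background must be non-empty")
  deg_genes <- unique(deg_genes)
  if (!all(deg_genes %in% background))
    stop_param("deg_genes must be a subset of background")
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(deg_genes)
  pairs <- unique(tm[c("gene_id", "term_id")])
  terms <- split(pairs$gene_id, pairs$term_id)
  terms <- terms[lengths(terms) > 0]
  if (length(terms) == 0)
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(g %in% deg_genes), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fdr <- fdr_adjust(p)
  out <- data.frame(term_id = names(terms), k = as.integer(k),
                    K = as.integer(K), n = n, N = N,
                    p_value = as.numeric(p), fdr = as.numeric(fdr),
                    significant = fdr <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
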