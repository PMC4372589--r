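# Independent oracles and tiny fixture builders shared across tests.

# Audic-Claverie two-sided p via the negative-binomial identity:
# conditional on x, the second count is NB(size = x + 1, prob = N1/(N1+N2)).
# This goes through pnbinom/pbeta, a code path disjoint from the package's
# log-space summation.
ac_oracle <- function(x, y, N1, N2) {
  q <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = q)
  upper <- pnbinom(y - 1, size = x + 1, prob = q, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Exact-rational reference values (computed once with arbitrary-precision
# rational arithmetic from the per-count term
# p(k|x) = C(x+k, k) r^k / (1+r)^(x+k+1), r = N2/N1).
ac_exact_cases <- data.frame(
  x  = c(0, 10, 5, 100, 3, 50, 0, 100, 7, 42),
  y  = c(0, 0, 5, 37, 97, 60, 100, 0, 120, 17),
  N1 = c(1e4, 1e4, 1e4, 1e6, 1e4, 1e7, 1e7, 1e4, 1e4, 1e6),
  N2 = c(1e4, 1e4, 1e6, 1e4, 1e4, 1e7, 1e4, 1e7, 1e6, 1e6),
  p  = c(1.0, 0.0009765625, 8.341485289977271e-10, 2.050784422011672e-41,
         2.630866896130179e-25, 0.39092745669950485, 1.8097652617955523e-300,
         1.8079573044910612e-303, 9.20973094233899e-05,
         0.0010657657791434353)
)

# Brute-force virtual-tag enumeration: every CATG-prefixed 21-mer on either
# strand, found by scanning all substrings (no pattern matching library).
brute_index_tags <- function(transcriptome) {
  out <- list()
  for (i in seq_len(nrow(transcriptome))) {
    for (s in c("sense", "antisense")) {
      sq <- transcriptome$sequence[i]
      if (s == "antisense")
        sq <- chartr("ACGT", "TGCA", paste(rev(strsplit(sq, "")[[1]]),
                                           collapse = ""))
      n <- nchar(sq)
      if (n < 21) next
      for (p in seq_len(n - 20)) {
        k <- substr(sq, p, p + 20)
        if (startsWith(k, "CATG"))
          out[[length(out) + 1L]] <- data.frame(
            tag = k, gene_id = transcriptome$gene_id[i], pos = p - 1L,
            strand = s)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(tag = character(0), gene_id = character(0),
                      pos = integer(0), strand = character(0)))
  do.call(rbind, out)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force all-pairs mapping oracle mirroring the published rules:
# exact hits first, otherwise distance-1 hits (suffix only when anchored);
# one gene -> unambiguous (sense-first), >= 2 genes -> ambiguous.
brute_map <- function(tags, entries, max_mismatch = 1, anchor_exact = TRUE) {
  res <- data.frame(tag = tags, status = "unknown", gene_id = NA_character_,
                    strand = NA_character_, mismatch = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(tags)) {
    d <- vapply(entries$tag, hamming, integer(1), a = tags[i])
    if (anchor_exact) {
      anchor_ok <- vapply(entries$tag, function(k)
        substr(k, 1, 4) == substr(tags[i], 1, 4), logical(1))
      d[!anchor_ok & d == 1] <- 2L
    }
    best <- if (any(d == 0)) 0L else if (any(d == 1) && max_mismatch >= 1) 1L
            else next
    hit <- entries[d == best, , drop = FALSE]
    genes <- unique(hit$gene_id)
    if (length(genes) == 1) {
      res$status[i] <- "unambiguous"
      res$gene_id[i] <- genes
      res$strand[i] <- if ("sense" %in% hit$strand) "sense" else "antisense"
      res$mismatch[i] <- best
    } else {
      res$status[i] <- "ambiguous"
      res$mismatch[i] <- best
    }
  }
  res
}

# Tiny deterministic transcriptome: hand-built sequences with known sites.
toy_transcriptome <- function() {
  structure(data.frame(
    gene_id = c("g1", "g2", "g3"),
    sequence = c(
      paste0("AAACATG", "ACGTACGTACGTACGTA", "TTTT"),      # one sense site
      paste0("CATG", "AAAAAAAAAAAAAAAAA", "GGGGCCCC"),     # site at 5' end
      strrep("AC", 30)                                     # no CATG anywhere
    ),
    stringsAsFactors = FALSE), class = c("reference_transcriptome", "data.frame"))
}

# A library straight from named counts (bypasses read filtering).
lib_from_counts <- function(counts, condition = "X") {
  tag_library(counts, condition = condition)
}

rand_tag <- function(n) {
  paste0("CATG", vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""),
    ""))
}
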