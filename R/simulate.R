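#' Simulate a reference transcriptome with CATG tag sites
#'
#' Generates random transcript sequences for use as a mapping reference. A
#' configurable fraction of transcripts is guaranteed to carry at least one
#' NlaIII recognition site (\code{CATG}) with at least 17 nt downstream, so
#' that an MmeI-released 21-nt tag (\code{CATG} + 17 nt) can be extracted;
#' the remainder model the unmappable fraction of a real transcriptome.
#'
#' @param n_genes Number of transcripts to generate (>= 1).
#' @param length_range Integer vector \code{c(min, max)} of transcript
#'   lengths in nt; \code{min} must be >= 25 (room for CATG + 17 nt + margin).
#' @param catg_fraction Fraction of transcripts forced to contain a usable
#'   CATG site (each remaining transcript is scrubbed of usable sites).
#' @param seed Random seed; output is byte-identical for a fixed seed.
#' @return An object of class \code{reference_transcriptome}: a data.frame
#'   with columns \code{gene_id}, \code{sequence}, plus attribute
#'   \code{n_catg_genes}, the realized number of tag-bearing transcripts.
#' @examples
#' ref <- simulate_transcriptome(10, c(100, 300), seed = 1)
#' attr(ref, "n_catg_genes")
#' @export
simulate_transcriptome <- function(n_genes, length_range = c(200L, 2000L),
                                   catg_fraction = 0.9, seed) {
  if (!is_count(n_genes) || n_genes < 1) stop_param("n_genes must be >= 1")
  if (length(length_range) != 2 || length_range[1] < 25 ||
      length_range[2] < length_range[1])
    stop_param("length_range must be c(min, max) with 25 <= min <= max")
  if (!is.numeric(catg_fraction) || catg_fraction < 0 || catg_fraction > 1)
    stop_param("catg_fraction must be in [0, 1]")

  with_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_genes,
                 replace = TRUE)
    seqs <- random_dna(n_genes, lens)
    has_site <- runif(n_genes) < catg_fraction
    seqs[has_site] <- vapply(seqs[has_site], force_catg_site, "")
    seqs[!has_site] <- vapply(seqs[!has_site], scrub_catg_sites, "")
    out <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      sequence = unname(seqs),
      stringsAsFactors = FALSE
    )
    realized <- sum(vapply(out$sequence, has_usable_catg, logical(1)))
    structure(out,
              class = c("reference_transcriptome", "data.frame"),
              n_catg_genes = realized)
  })
}

# A usable site is a CATG whose 17-nt downstream extension fits on the
# transcript (sense strand; simulation emits sense tags only).
usable_site_starts <- function(seq) {
  m <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  m[m + TAG_LEN - 1L <= nchar(seq)]
}

has_usable_catg <- function(seq) length(usable_site_starts(seq)) > 0

# Plant a CATG with full 17-nt runway at a random admissible position.
force_catg_site <- function(seq) {
  if (has_usable_catg(seq)) return(seq)
  pos <- sample.int(nchar(seq) - TAG_LEN + 1L, 1L)
  paste0(substr(seq, 1, pos - 1L), ANCHOR,
         substr(seq, pos + 4L, nchar(seq)))
}

# Remove usable sense CATG sites by mutating the anchor's first base.
scrub_catg_sites <- function(seq) {
  repeat {
    s <- usable_site_starts(seq)
    if (length(s) == 0) return(seq)
    substr(seq, s[1], s[1]) <- "T"
  }
}

#' Assign ground-truth expression and differential-expression status
#'
#' Draws per-gene baseline abundances from a log-normal distribution and
#' flags a fixed fraction of genes as differentially expressed in each
#' non-control condition, with fold changes drawn from \code{fold_values}
#' (direction up with probability \code{prob_up}, else the reciprocal).
#' Condition-specific abundances are baseline x fold, renormalized to sum
#' to one.
#'
#' @param transcriptome A \code{reference_transcriptome}.
#' @param de_fraction Fraction of genes DE per non-control condition;
#'   exactly \code{round(de_fraction * n_genes)} genes are flagged.
#' @param fold_values Positive fold changes sampled (with replacement) for
#'   DE genes.
#' @param conditions Condition labels; the first is the control and gets no
#'   DE genes.
#' @param prob_up Probability that a DE gene is up- rather than
#'   down-regulated.
#' @param meanlog,sdlog Log-normal parameters of the baseline abundance
#'   distribution.
#' @param seed Random seed.
#' @return An object of class \code{ground_truth}: a data.frame with
#'   \code{gene_id}, \code{base_abundance} (sums to 1), and per non-control
#'   condition \code{fold_<cond>} and \code{de_<cond>} columns, plus
#'   \code{abundance_<cond>} columns for every condition (renormalized).
#' @export
assign_ground_truth <- function(transcriptome, de_fraction = 0.1,
                                fold_values = 8, conditions = c("CON", "CS", "FS"),
                                prob_up = 0.5, meanlog = 0, sdlog = 1.5, seed) {
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stop_param("de_fraction must be in [0, 1]")
  if (length(fold_values) == 0 || any(fold_values <= 0))
    stop_param("fold_values must be positive and non-empty")
  if (length(conditions) < 1 || anyDuplicated(conditions))
    stop_param("conditions must be distinct labels")

  n <- nrow(transcriptome)
  with_seed(seed, {
    base <- rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    base <- base / sum(base)
    truth <- data.frame(gene_id = transcriptome$gene_id,
                        base_abundance = base, stringsAsFactors = FALSE)
    n_de <- round(de_fraction * n)
    for (cond in conditions) {
      if (cond == conditions[1]) {
        truth[[paste0("abundance_", cond)]] <- base
        next
      }
      fold <- rep(1, n)
      if (n_de > 0) {
        idx <- sample.int(n, n_de)
        f <- fold_values[sample.int(length(fold_values), n_de, replace = TRUE)]
        up <- runif(n_de) < prob_up
        fold[idx] <- ifelse(up, f, 1 / f)
      }
      truth[[paste0("fold_", cond)]] <- fold
      truth[[paste0("de_", cond)]] <- fold != 1
      ab <- base * fold
      truth[[paste0("abundance_", cond)]] <- ab / sum(ab)
    }
    structure(truth, class = c("ground_truth", "data.frame"),
              conditions = conditions, control = conditions[1])
  })
}

#' Simulate raw 49-bp DeepSAGE reads for one condition
#'
#' Emulates the library chemistry: each sequenced fragment is the canonical
#' tag of its transcript (the \code{CATG} anchor at the 3'-most usable site
#' plus the 17 nt released downstream by MmeI) followed by the 3' adapter,
#' filled or truncated to exactly 49 nt. Transcripts are sampled in
#' proportion to their condition abundance; transcripts without a usable
#' CATG site emit no reads. A fraction of reads are empty (pure adapter)
#' and each base suffers an independent substitution error.
#'
#' @param transcriptome A \code{reference_transcriptome}.
#' @param truth A \code{ground_truth} from \code{\link{assign_ground_truth}}.
#' @param condition Condition label present in \code{truth}.
#' @param depth Total number of reads to emit (exactly).
#' @param error_rate Per-base substitution probability.
#' @param empty_read_rate Fraction of reads that are pure adapter.
#' @param adapter 3' adapter sequence, >= 28 nt (to fill a 49-nt read
#'   after the 21-nt tag).
#' @param seed Random seed.
#' @return Object of class \code{raw_read_set}: list with \code{reads}
#'   (character, each 49 nt), \code{condition}, \code{seed}, and
#'   ground-truth bookkeeping \code{n_empty} (empty reads emitted) and
#'   \code{gene_reads} (named vector of non-empty reads emitted per gene).
#' @export
simulate_tag_reads <- function(transcriptome, truth, condition, depth,
                               error_rate = 0.005, empty_read_rate = 0.05,
                               adapter = DEFAULT_ADAPTER, seed) {
  if (!is_count(depth) || depth < 1) stop_param("depth must be >= 1")
  if (nchar(adapter) < READ_LEN - TAG_LEN)
    stop_param("adapter must be at least ", READ_LEN - TAG_LEN,
               " nt to fill a ", READ_LEN, "-nt read")
  ab_col <- paste0("abundance_", condition)
  if (!ab_col %in% names(truth)) stop_param("unknown condition: ", condition)

  tags <- canonical_tags(transcriptome)
  emitters <- !is.na(tags)
  if (!any(emitters)) stop_data("no transcript carries a usable CATG site")
  ab <- truth[[ab_col]][emitters]
  ab <- ab / sum(ab)
  genes <- transcriptome$gene_id[emitters]
  adapter_fill <- substr(adapter, 1, READ_LEN - TAG_LEN)
  empty_read <- substr(strrep(adapter, ceiling(READ_LEN / nchar(adapter))),
                       1, READ_LEN)

  with_seed(seed, {
    is_empty <- runif(depth) < empty_read_rate
    n_tag <- sum(!is_empty)
    gi <- sample.int(length(genes), n_tag, replace = TRUE, prob = ab)
    reads <- character(depth)
    reads[is_empty] <- empty_read
    reads[!is_empty] <- paste0(tags[emitters][gi], adapter_fill)
    reads <- inject_errors(reads, error_rate)
    gene_reads <- tabulate(gi, nbins = length(genes))
    names(gene_reads) <- genes
    structure(list(reads = reads, condition = condition, seed = seed,
                   n_empty = sum(is_empty), gene_reads = gene_reads,
                   adapter = adapter),
              class = "raw_read_set")
  })
}

#' Canonical tag of each transcript
#'
#' The canonical DeepSAGE tag is anchored at the 3'-most CATG with at least
#' 17 nt downstream, matching the Oligo(dT)-bead protocol in which only the
#' 3'-terminal NlaIII fragment stays bead-bound. \code{NA} for transcripts
#' without a usable site.
#'
#' @param transcriptome A \code{reference_transcriptome}.
#' @return Named character vector of 21-nt tags (or \code{NA}).
#' @export
canonical_tags <- function(transcriptome) {
  out <- vapply(transcriptome$sequence, function(s) {
    st <- usable_site_starts(s)
    if (length(st) == 0) return(NA_character_)
    substr(s, max(st), max(st) + TAG_LEN - 1L)
  }, "")
  names(out) <- transcriptome$gene_id
  out
}

# Sprinkle substitution errors over fixed-length reads. Expected number of
# errors is length(reads) * 49 * rate; positions drawn uniformly.
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  n_bases <- length(reads) * READ_LEN
  n_err <- rbinom(1, n_bases, rate)
  if (n_err == 0) return(reads)
  pos <- sample.int(n_bases, n_err)
  ri <- (pos - 1L) %/% READ_LEN + 1L
  pj <- (pos - 1L) %% READ_LEN + 1L
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
  orig <- substr(reads[ri], pj, pj)
  col <- match(orig, colnames(alt))
  new <- ifelse(is.na(col), "A",
                alt[cbind(sample.int(3, n_err, replace = TRUE),
                          ifelse(is.na(col), 1L, col))])
  for (i in seq_along(ri)) substr(reads[ri[i]], pj[i], pj[i]) <- new[i]
  reads
}

#' Write simulation artifacts to disk
#'
#' FASTA for the reference, FASTQ (fixed quality "I") for reads, TSV for
#' the ground truth.
#' @param transcriptome A \code{reference_transcriptome}.
#' @param path Output file path.
#' @name simulation-io
NULL

#' @rdname simulation-io
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(x) <- transcriptome$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname simulation-io
#' @export
read_transcriptome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(data.frame(gene_id = sub("\\s.*$", "", names(x)),
                       sequence = as.character(x),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("reference_transcriptome", "data.frame"))
}

#' @rdname simulation-io
#' @param reads A \code{raw_read_set}.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$reads)
  names(x) <- sprintf("read%07d", seq_along(reads$reads))
  q <- Biostrings::BStringSet(rep(strrep("I", READ_LEN), length(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname simulation-io
#' @param condition Condition label to attach to the read set.
#' @export
read_reads_fastq <- function(path, condition = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(list(reads = as.character(x), condition = condition,
                 seed = NA_integer_, n_empty = NA_integer_,
                 gene_reads = NULL, adapter = NA_character_),
            class = "raw_read_set")
}

#' @rdname simulation-io
#' @param truth A \code{ground_truth}.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.reference_transcriptome <- function(x, ...) {
  cat(sprintf("Reference transcriptome: %d transcripts (%d with usable CATG site)\n",
              nrow(x), sum(vapply(x$sequence, has_usable_catg, logical(1)))))
  invisible(x)
}

#' @export
print.raw_read_set <- function(x, ...) {
  cat(sprintf("Raw read set [%s]: %d reads of %d nt (%s empty)\n",
              x$condition, length(x$reads), READ_LEN,
              ifelse(is.na(x$n_empty), "?", x$n_empty)))
  invisible(x)
}
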