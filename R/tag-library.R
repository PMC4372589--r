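#' Construct a clean-tag library
#'
#' Low-level constructor; most users build libraries with
#' \code{\link{extract_clean_tags}} or \code{\link{read_tag_table}}.
#'
#' @param counts Named integer vector: 21-nt tag (CATG-prefixed) -> copy
#'   number.
#' @param condition Library label.
#' @param raw_total Total raw reads the library was derived from (defaults
#'   to the clean total when unknown).
#' @param distinct_raw Distinct raw tags before filtering.
#' @param filter_log Named numeric vector of read copies removed per filter
#'   stage.
#' @return Object of class \code{tag_library}.
#' @export
tag_library <- function(counts, condition = NA_character_,
                        raw_total = NULL, distinct_raw = NULL,
                        filter_log = c(empty = 0, low_quality = 0,
                                       length_mismatch = 0, low_copy = 0)) {
  if (length(counts) == 0) counts <- setNames(integer(0), character(0))
  counts <- counts[order(names(counts))]
  bad <- names(counts)[nchar(names(counts)) != TAG_LEN |
                         !startsWith(names(counts), ANCHOR)]
  if (length(bad))
    stop_data("malformed tag(s): ", paste(head(bad, 3), collapse = ", "))
  clean_total <- sum(counts)
  structure(list(
    condition = condition,
    counts = counts,
    raw_total = if (is.null(raw_total)) clean_total else raw_total,
    clean_total = clean_total,
    distinct_raw = if (is.null(distinct_raw)) length(counts) else distinct_raw,
    distinct_clean = length(counts),
    filter_log = filter_log
  ), class = "tag_library")
}

#' Filter raw reads into a clean-tag library
#'
#' Applies the DeepSAGE clean-up cascade to raw 49-bp reads:
#' \enumerate{
#'   \item drop empty reads (reads that are pure 3' adapter);
#'   \item drop low-quality reads: no \code{CATG} prefix or an \code{N}
#'     within the 21-nt tag region;
#'   \item verify the adapter follows the tag at position 22 (guards
#'     against too-long/too-short tag inserts) when \code{adapter} given;
#'   \item count identical tags and drop tags with library copy number
#'     below \code{min_copy} (default 2).
#' }
#' Copies removed at each stage are recorded in \code{filter_log}, so that
#' \code{raw_total = clean_total + sum(filter_log)} always holds.
#'
#' @param reads A \code{raw_read_set} (or character vector of 49-nt reads).
#' @param adapter 3' adapter sequence; \code{NULL} skips the adapter check.
#' @param min_copy Minimum copy number for a clean tag.
#' @param condition Library label; defaults to the read set's.
#' @return A \code{tag_library}. All reads filtered yields a valid empty
#'   library with a warning.
#' @examples
#' lib <- tag_library(c(CATGAAAAAAAAAAAAAAAAA = 5L), "CON")
#' lib$clean_total
#' @export
extract_clean_tags <- function(reads, adapter = DEFAULT_ADAPTER,
                               min_copy = 2L, condition = NULL) {
  if (inherits(reads, "raw_read_set")) {
    if (is.null(condition)) condition <- reads$condition
    reads <- reads$reads
  }
  if (length(reads) == 0) stop_param("reads must be non-empty")
  if (is.null(condition)) condition <- NA_character_
  raw_total <- length(reads)
  distinct_raw <- length(unique(substr(reads, 1L, TAG_LEN)))

  flog <- c(empty = 0, low_quality = 0, length_mismatch = 0, low_copy = 0)

  # (1) empty reads: pure adapter from position 1
  if (!is.null(adapter)) {
    is_empty <- startsWith(reads, substr(adapter, 1, min(nchar(adapter), READ_LEN)))
    flog["empty"] <- sum(is_empty)
    reads <- reads[!is_empty]
  }

  # (2) low quality: no CATG anchor, or N in the tag region
  tagr <- substr(reads, 1L, TAG_LEN)
  ok <- startsWith(tagr, ANCHOR) & !grepl("N", tagr, fixed = TRUE) &
    nchar(tagr) == TAG_LEN
  flog["low_quality"] <- sum(!ok)
  reads <- reads[ok]
  tagr <- tagr[ok]

  # (3) adapter must follow the 21-nt tag (too long / too short guard)
  if (!is.null(adapter) && length(reads)) {
    fill <- substr(adapter, 1, READ_LEN - TAG_LEN)
    good <- substr(reads, TAG_LEN + 1L, READ_LEN) == fill
    flog["length_mismatch"] <- sum(!good)
    tagr <- tagr[good]
  }

  # (4) copy-number filter within the library
  counts <- table(tagr)
  counts <- setNames(as.integer(counts), names(counts))
  low <- counts < min_copy
  flog["low_copy"] <- sum(counts[low])
  counts <- counts[!low]

  if (length(counts) == 0)
    warning("all reads removed by filtering; returning an empty library")
  tag_library(counts, condition = condition, raw_total = raw_total,
              distinct_raw = distinct_raw, filter_log = flog)
}

ABUNDANCE_CLASSES <- c("2-5", "6-10", "11-20", "21-50", "51-100", ">100")
ABUNDANCE_BREAKS <- c(2, 6, 11, 21, 51, 101, Inf)

#' Tag abundance-class histogram
#'
#' Bins clean tags into the six classical copy-number classes 2-5, 6-10,
#' 11-20, 21-50, 51-100 and >100 (boundaries inclusive), reporting the
#' proportion of distinct tags and of total tag copies per class.
#'
#' @param lib A non-empty \code{tag_library}.
#' @return data.frame with columns \code{class}, \code{distinct_prop},
#'   \code{total_prop}; each proportion column sums to 1.
#' @export
abundance_histogram <- function(lib) {
  if (lib$distinct_clean == 0) stop_param("library is empty")
  cls <- cut(lib$counts, breaks = ABUNDANCE_BREAKS, labels = ABUNDANCE_CLASSES,
             right = FALSE)
  distinct <- tapply(rep(1L, length(cls)), cls, sum, default = 0L)
  total <- tapply(lib$counts, cls, sum, default = 0L)
  data.frame(class = ABUNDANCE_CLASSES,
             distinct_prop = as.numeric(distinct / sum(distinct)),
             total_prop = as.numeric(total / sum(total)),
             row.names = NULL)
}

#' Percent arithmetic for a library-summary table
#'
#' Given per-library raw/clean totals, recomputes the derived report
#' percentages (half-away-from-zero, two decimals): clean totals as a
#' percent of raw totals, distinct clean tags as a percent of distinct raw
#' tags, and grand totals across libraries.
#'
#' @param totals data.frame with columns \code{library}, \code{raw_total},
#'   \code{distinct_raw}, \code{clean_total}, \code{distinct_clean}.
#' @return data.frame adding \code{clean_pct} and \code{distinct_clean_pct}
#'   plus a final \code{TOTAL} row.
#' @export
tag_summary_table <- function(totals) {
  need <- c("library", "raw_total", "distinct_raw", "clean_total",
            "distinct_clean")
  if (!all(need %in% names(totals)))
    stop_param("totals must have columns: ", paste(need, collapse = ", "))
  out <- totals[need]
  tot <- data.frame(library = "TOTAL",
                    raw_total = sum(out$raw_total),
                    distinct_raw = sum(out$distinct_raw),
                    clean_total = sum(out$clean_total),
                    distinct_clean = sum(out$distinct_clean))
  out <- rbind(out, tot)
  out$clean_pct <- pct(out$clean_total, out$raw_total)
  out$distinct_clean_pct <- pct(out$distinct_clean, out$distinct_raw)
  out
}

#' Summarize one or more tag libraries
#'
#' Table-1-style per-library summary: raw totals, distinct raw tags, clean
#' totals with percent of raw, distinct clean tags with percent of distinct
#' raw, and grand totals.
#'
#' @param libs A \code{tag_library} or list of them.
#' @return data.frame as from \code{\link{tag_summary_table}}.
#' @export
library_summary <- function(libs) {
  if (inherits(libs, "tag_library")) libs <- list(libs)
  if (length(libs) < 1) stop_param("need at least one library")
  totals <- do.call(rbind, lapply(libs, function(l)
    data.frame(library = l$condition, raw_total = l$raw_total,
               distinct_raw = l$distinct_raw, clean_total = l$clean_total,
               distinct_clean = l$distinct_clean)))
  tag_summary_table(totals)
}

#' Read / write tag tables
#'
#' Tag tables are two-column TSVs (\code{tag}, \code{count}); writing then
#' reading reproduces the library counts exactly.
#'
#' @param path TSV path.
#' @param condition Library label to attach on read (defaults to the file
#'   base name).
#' @return \code{read_tag_table} returns a \code{tag_library}.
#' @export
read_tag_table <- function(path, condition = NULL) {
  df <- read.delim(path, header = TRUE, colClasses = c("character", "integer"))
  if (!all(c("tag", "count") %in% names(df)))
    stop_data("tag table must have columns 'tag' and 'count': ", path)
  bad <- which(nchar(df$tag) != TAG_LEN | !grepl("^CATG[ACGT]{17}$", df$tag))
  if (length(bad))
    stop_data("malformed tag at data line ", bad[1], " of ", path, ": ",
              df$tag[bad[1]])
  if (is.null(condition))
    condition <- tools::file_path_sans_ext(basename(path))
  tag_library(setNames(df$count, df$tag), condition = condition)
}

#' @rdname read_tag_table
#' @param lib A \code{tag_library}.
#' @export
write_tag_table <- function(lib, path) {
  write.table(data.frame(tag = names(lib$counts),
                         count = as.integer(lib$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("Clean-tag library [%s]\n", x$condition))
  cat(sprintf("  raw reads:      %d\n", x$raw_total))
  cat(sprintf("  clean tags:     %d total, %d distinct\n",
              x$clean_total, x$distinct_clean))
  if (sum(x$filter_log) > 0) {
    fl <- x$filter_log[x$filter_log > 0]
    cat("  filtered:       ",
        paste(sprintf("%s=%d", names(fl), fl), collapse = ", "), "\n")
  }
  invisible(x)
}
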