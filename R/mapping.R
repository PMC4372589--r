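#' Build a virtual CATG+17 tag index over a reference transcriptome
#'
#' Every occurrence of \code{CATG} with at least 17 nt downstream, on the
#' transcript and on its reverse complement, yields one virtual 21-nt tag
#' (sense and antisense respectively). All sites are indexed, not only the
#' 3'-most: against cross-species references the 3' annotation is not
#' trustworthy, so mapping must tolerate any site even though the library
#' chemistry emits 3'-most tags.
#'
#' @param transcriptome A \code{reference_transcriptome}.
#' @return Object of class \code{virtual_tag_index}: a list with
#'   \code{entries} (data.frame: \code{tag}, \code{gene_id}, \code{pos}
#'   0-based offset of the CATG on the indexed strand, \code{strand}
#'   \code{"sense"}/\code{"antisense"}), \code{n_reference_tags} (distinct
#'   virtual tags) and \code{n_genes_with_catg}.
#' @examples
#' ref <- simulate_transcriptome(5, c(100, 200), seed = 1)
#' idx <- build_index(ref)
#' idx$n_reference_tags
#' @export
build_index <- function(transcriptome) {
  if (nrow(transcriptome) == 0) stop_param("transcriptome is empty")
  sense <- site_entries(transcriptome$gene_id, transcriptome$sequence, "sense")
  anti <- site_entries(transcriptome$gene_id, revcomp(transcriptome$sequence),
                       "antisense")
  entries <- rbind(sense, anti)
  structure(list(
    entries = entries,
    n_reference_tags = length(unique(entries$tag)),
    n_genes_with_catg = length(unique(entries$gene_id))
  ), class = "virtual_tag_index")
}

site_entries <- function(gene_ids, seqs, strand) {
  hits <- Biostrings::vmatchPattern(ANCHOR, Biostrings::DNAStringSet(seqs))
  starts <- lapply(hits, Biostrings::start)
  n <- lengths(starts)
  gi <- rep(seq_along(seqs), n)
  st <- unlist(starts, use.names = FALSE)
  if (length(st) == 0)
    return(data.frame(tag = character(0), gene_id = character(0),
                      pos = integer(0), strand = character(0)))
  keep <- st + TAG_LEN - 1L <= nchar(seqs)[gi]
  gi <- gi[keep]; st <- st[keep]
  data.frame(tag = substr(seqs[gi], st, st + TAG_LEN - 1L),
             gene_id = gene_ids[gi],
             pos = st - 1L,
             strand = rep(strand, length(gi)),
             stringsAsFactors = FALSE)
}

#' Map clean tags onto a virtual tag index
#'
#' Tags are looked up exactly first; only tags without an exact hit are
#' searched at Hamming distance 1. By default the mismatch may fall only in
#' the 17-nt suffix (the CATG anchor is the enzymatic recognition site and
#' was verified upstream); \code{anchor_exact = FALSE} also allows it
#' inside the anchor. At its best mismatch level a tag hitting exactly one
#' gene is \emph{unambiguous} (multi-position hits within one gene stay
#' unambiguous; a gene hit on both strands resolves sense-first), a tag
#' hitting two or more genes is \emph{ambiguous}, and a tag with no hit is
#' \emph{unknown}.
#'
#' @param lib A \code{tag_library}.
#' @param index A \code{virtual_tag_index}.
#' @param max_mismatch 0 or 1.
#' @param anchor_exact If \code{TRUE} (default) the CATG anchor must match
#'   exactly and the single mismatch is confined to the 17-nt suffix.
#' @return Object of class \code{tag_mapping}: data.frame \code{assignments}
#'   (per distinct tag: \code{tag}, \code{count}, \code{status},
#'   \code{gene_id}, \code{strand}, \code{mismatch}) plus the source
#'   library's totals.
#' @export
map_tags <- function(lib, index, max_mismatch = 1L, anchor_exact = TRUE) {
  if (!max_mismatch %in% c(0L, 1L)) stop_param("max_mismatch must be 0 or 1")
  tags <- names(lib$counts)
  n <- length(tags)
  status <- rep("unknown", n)
  gene <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)

  if (n > 0) {
    ent <- index$entries
    keys <- unique(ent$tag)
    key_of <- match(ent$tag, keys)
    rows_by_key <- split(seq_len(nrow(ent)),
                         factor(key_of, levels = seq_along(keys)))

    resolve <- function(i, hit_keys, mm) {
      sel <- unlist(rows_by_key[hit_keys], use.names = FALSE)
      g <- ent$gene_id[sel]; s <- ent$strand[sel]
      ug <- unique(g)
      if (length(ug) == 1L) {
        status[i] <<- "unambiguous"
        gene[i] <<- ug
        strand[i] <<- if ("sense" %in% s) "sense" else "antisense"
        mism[i] <<- mm
      } else {
        status[i] <<- "ambiguous"
        mism[i] <<- mm
      }
    }

    exact <- match(tags, keys)
    for (i in which(!is.na(exact))) resolve(i, exact[i], 0L)

    if (max_mismatch >= 1L) {
      todo <- which(is.na(exact))
      if (length(todo)) {
        vars <- mismatch_neighbors(tags[todo], anchor_exact)
        vm <- match(vars$variant, keys)
        hit <- !is.na(vm)
        if (any(hit)) {
          by_tag <- split(vm[hit], vars$origin[hit])
          for (nm in names(by_tag))
            resolve(todo[as.integer(nm)], unique(by_tag[[nm]]), 1L)
        }
      }
    }
  }

  structure(list(
    assignments = data.frame(tag = tags,
                             count = as.integer(lib$counts),
                             status = status, gene_id = gene,
                             strand = strand, mismatch = mism,
                             stringsAsFactors = FALSE, row.names = NULL),
    condition = lib$condition,
    clean_total = lib$clean_total,
    distinct_clean = lib$distinct_clean
  ), class = "tag_mapping")
}

# All Hamming-distance-1 neighbors of each tag; mismatch restricted to the
# 17-nt suffix when anchor_exact. Returns origin (index into tags) and
# variant strings.
mismatch_neighbors <- function(tags, anchor_exact = TRUE) {
  from <- if (anchor_exact) 5L else 1L
  positions <- from:TAG_LEN
  bases <- c("A", "C", "G", "T")
  origin <- list(); variant <- list()
  for (p in positions) {
    cur <- substr(tags, p, p)
    for (b in bases) {
      sel <- cur != b
      if (!any(sel)) next
      v <- tags[sel]
      substr(v, p, p) <- b
      origin[[length(origin) + 1L]] <- which(sel)
      variant[[length(variant) + 1L]] <- v
    }
  }
  list(origin = unlist(origin, use.names = FALSE),
       variant = unlist(variant, use.names = FALSE))
}

#' Per-gene unambiguous tag counts
#'
#' Sums copies of unambiguous sense tags per gene; antisense copies are
#' tallied in a separate ledger. Copy conservation holds:
#' sense + antisense unambiguous + ambiguous + unknown copies equal the
#' library's clean total.
#'
#' @param mapping A \code{tag_mapping} produced from \code{lib}.
#' @param lib The \code{tag_library} the mapping came from (for the TPM
#'   denominator).
#' @return Object of class \code{gene_expression}: data.frame
#'   \code{genes} (\code{gene_id}, \code{count}, \code{antisense_count},
#'   \code{tpm} initialized NA until \code{\link{tpm_normalize}}), plus
#'   \code{condition} and \code{clean_total}.
#' @export
gene_counts <- function(mapping, lib) {
  if (!missing(lib)) {
    if (!identical(mapping$clean_total, lib$clean_total))
      stop_param("mapping was not produced from this library")
  }
  a <- mapping$assignments
  un <- a[a$status == "unambiguous", , drop = FALSE]
  sense <- un[un$strand == "sense", , drop = FALSE]
  anti <- un[un$strand == "antisense", , drop = FALSE]
  genes <- sort(unique(un$gene_id))
  cnt <- setNames(numeric(length(genes)), genes)
  s <- tapply(sense$count, sense$gene_id, sum)
  ac <- setNames(numeric(length(genes)), genes)
  at <- tapply(anti$count, anti$gene_id, sum)
  cnt[names(s)] <- s
  ac[names(at)] <- at
  structure(list(
    genes = data.frame(gene_id = genes, count = as.integer(cnt),
                       antisense_count = as.integer(ac),
                       tpm = NA_real_, stringsAsFactors = FALSE,
                       row.names = NULL),
    condition = mapping$condition,
    clean_total = mapping$clean_total
  ), class = "gene_expression")
}

#' Tags-per-million normalization
#'
#' TPM here is the classical DGE normalization: unambiguous tag copies per
#' million \emph{clean} tags in the library (the denominator is the clean
#' total, not the mapped total). Not the modern length-normalized
#' transcripts-per-million.
#'
#' @param expr A \code{gene_expression}.
#' @return The same object with \code{tpm = count / clean_total * 1e6}.
#' @export
tpm_normalize <- function(expr) {
  if (expr$clean_total <= 0) stop_param("clean_total must be positive")
  expr$genes$tpm <- expr$genes$count / expr$clean_total * 1e6
  expr
}

#' Mapping summary in report-table layout
#'
#' Per-strand and combined tallies of mapped and unambiguously mapped tags
#' (total copies, distinct tags, genes hit), unknown tags, and percentages
#' of the library's clean totals.
#'
#' @param object A \code{tag_mapping}.
#' @param ... Unused.
#' @return data.frame with columns \code{row}, \code{total}, \code{total_pct},
#'   \code{distinct}, \code{distinct_pct}, \code{genes}.
#' @export
summary.tag_mapping <- function(object, ...) {
  a <- object$assignments
  ct <- object$clean_total
  dc <- object$distinct_clean
  line <- function(row, sel, genes = NA_integer_) {
    data.frame(row = row, total = sum(a$count[sel]),
               total_pct = pct(sum(a$count[sel]), ct),
               distinct = sum(sel), distinct_pct = pct(sum(sel), dc),
               genes = genes)
  }
  un <- a$status == "unambiguous"
  sense <- un & a$strand == "sense"
  anti <- un & a$strand == "antisense"
  mapped <- a$status %in% c("unambiguous", "ambiguous")
  rbind(
    line("unambiguous_sense", sense, length(unique(a$gene_id[sense]))),
    line("unambiguous_antisense", anti, length(unique(a$gene_id[anti]))),
    line("unambiguous_all", un, length(unique(a$gene_id[un]))),
    line("ambiguous", a$status == "ambiguous"),
    line("mapped_all", mapped),
    line("unknown", a$status == "unknown")
  )
}

#' @export
print.tag_mapping <- function(x, ...) {
  s <- table(x$assignments$status)
  cat(sprintf("Tag mapping [%s]: %d distinct tags (%s)\n", x$condition,
              nrow(x$assignments),
              paste(sprintf("%s=%d", names(s), s), collapse = ", ")))
  invisible(x)
}

#' @export
print.gene_expression <- function(x, ...) {
  cat(sprintf("Gene expression [%s]: %d genes, %d unambiguous sense copies\n",
              x$condition, nrow(x$genes), sum(x$genes$count)))
  invisible(x)
}

#' Write / read a gene-expression table
#' @param expr A \code{gene_expression}.
#' @param path TSV path.
#' @export
write_expression_table <- function(expr, path) {
  df <- expr$genes
  df$library <- expr$condition
  write.table(df[c("gene_id", "library", "count", "antisense_count", "tpm")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
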