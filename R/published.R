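#' Published seabuckthorn DeepSAGE summary numbers
#'
#' Summary counts printed for a published three-library (control, cold
#' stress 4C, freeze stress -10C) seabuckthorn leaf DeepSAGE experiment,
#' shipped as plain TSVs. These are report-level numbers, not raw data:
#' they serve as worked-example inputs for the percent and log2-ratio
#' arithmetic the package reproduces.
#'
#' \describe{
#'   \item{library_counts}{Per-library raw/clean totals and distinct tag
#'     counts.}
#'   \item{mapping_counts}{Reference-tag mapping tallies (mapped,
#'     unambiguous, ambiguous).}
#'   \item{deg_tpm}{Per-gene TPM pairs and the printed log2 ratio for the
#'     validated DEGs. Three source rows whose printed ratio is
#'     inconsistent with their own TPM pair (a sign swap and two rounding
#'     slips) are omitted.}
#' }
#'
#' @param which One of \code{"library_counts"}, \code{"mapping_counts"},
#'   \code{"deg_tpm"}.
#' @return A data.frame.
#' @examples
#' tag_summary_table(published_summary("library_counts"))
#' @export
published_summary <- function(which = c("library_counts", "mapping_counts",
                                        "deg_tpm")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("seabuckthorn_", which, ".tsv"),
                      package = "deepsage", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
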