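#' Read a qRT-PCR Ct table
#'
#' CSV with columns \code{gene}, \code{sample}, \code{condition},
#' \code{timepoint}, \code{ct}, \code{is_reference}. Exactly one reference
#' gene (the endogenous control, e.g. actin) must be present per sample;
#' technical replicates (repeated rows) are allowed and averaged at
#' quantification time.
#'
#' @param path CSV path.
#' @return data.frame of class \code{ct_table}.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_ct_table(df)
}

#' @rdname read_ct_table
#' @param df data.frame with the Ct-table columns.
#' @export
as_ct_table <- function(df) {
  need <- c("gene", "sample", "condition", "timepoint", "ct", "is_reference")
  if (!all(need %in% names(df)))
    stop_data("Ct table must have columns: ", paste(need, collapse = ", "))
  df$is_reference <- as.logical(df$is_reference)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop_data("Ct values must be positive")
  for (s in unique(df$sample)) {
    refs <- unique(df$gene[df$sample == s & df$is_reference])
    if (length(refs) == 0)
      stop_data("sample '", s, "' has no reference gene")
    if (length(refs) > 1)
      stop_data("sample '", s, "' has multiple reference genes: ",
                paste(refs, collapse = ", "))
  }
  structure(df, class = c("ct_table", "data.frame"))
}

# Mean (or median) Ct of a gene under one condition/timepoint.
ct_of <- function(table, gene, condition, timepoint, aggregate) {
  sel <- table$gene == gene & table$condition == condition
  if (!is.null(timepoint)) sel <- sel & table$timepoint == timepoint
  v <- table$ct[sel]
  if (length(v) == 0) return(NA_real_)
  if (aggregate == "median") stats::median(v) else mean(v)
}

#' Relative quantification by the 2^-ddCt method
#'
#' For a target gene, computes dCt = Ct(target) - Ct(reference) in the
#' treated and calibrator conditions (technical replicates averaged
#' first), then ddCt = dCt(treated) - dCt(calibrator), and returns
#' 2^-ddCt: the expression of the target in the treated condition relative
#' to the calibrator, normalized to the endogenous control. No
#' amplification-efficiency correction is applied.
#'
#' @param table A \code{ct_table}.
#' @param target Target gene label.
#' @param treated,calibrator Condition labels.
#' @param timepoint Optional timepoint label to restrict to.
#' @param aggregate \code{"mean"} (default) or \code{"median"} replicate
#'   aggregation.
#' @return Fold change (positive real).
#' @examples
#' ct <- as_ct_table(data.frame(
#'   gene = c("MAP2K", "actin", "MAP2K", "actin"),
#'   sample = c("s1", "s1", "s2", "s2"),
#'   condition = c("CS", "CS", "CON", "CON"),
#'   timepoint = "6h", ct = c(20, 15, 24, 15),
#'   is_reference = c(FALSE, TRUE, FALSE, TRUE)))
#' ddct_fold_change(ct, "MAP2K", treated = "CS", calibrator = "CON")  # 16
#' @export
ddct_fold_change <- function(table, target, treated, calibrator,
                             timepoint = NULL, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  table <- as_ct_table(as.data.frame(table))
  ref <- unique(table$gene[table$is_reference])
  if (length(ref) != 1)
    stop_data("expected a single endogenous-control gene, found: ",
              paste(ref, collapse = ", "))
  dct <- vapply(c(treated, calibrator), function(cond) {
    t_ct <- ct_of(table, target, cond, timepoint, aggregate)
    r_ct <- ct_of(table, ref, cond, timepoint, aggregate)
    if (is.na(t_ct))
      stop_data("no Ct for target '", target, "' in condition '", cond, "'")
    if (is.na(r_ct))
      stop_data("no reference Ct in condition '", cond, "'")
    t_ct - r_ct
  }, numeric(1))
  2^-(dct[[1]] - dct[[2]])
}

#' Fold changes for every target gene and condition
#'
#' Applies \code{\link{ddct_fold_change}} over all non-reference genes and
#' all non-calibrator condition/timepoint combinations present.
#'
#' @inheritParams ddct_fold_change
#' @return data.frame: gene, condition, timepoint, fold_change, direction.
#' @export
ddct_table <- function(table, calibrator, aggregate = "mean") {
  table <- as_ct_table(as.data.frame(table))
  targets <- unique(table$gene[!table$is_reference])
  conds <- setdiff(unique(table$condition), calibrator)
  out <- list()
  for (g in targets) for (cond in conds) {
    tps <- unique(table$timepoint[table$gene == g & table$condition == cond])
    for (tp in tps) {
      fc <- tryCatch(
        ddct_fold_change(table, g, cond, calibrator, timepoint = tp,
                         aggregate = aggregate),
        deepsage_data_error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, timepoint = tp, fold_change = fc,
        direction = ifelse(is.na(fc), NA_character_,
                           ifelse(fc >= 1, "up", "down")))
    }
  }
  do.call(rbind, out)
}
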