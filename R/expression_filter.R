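# Differential-expression significance rule. Model fitting (e.g. DESeq2)
# is out of scope: this consumes its standard output columns plus per-group
# median FPKM and applies the compound significance filter.

#' Filter a differential-expression table
#'
#' A gene is called differentially expressed iff the adjusted p-value is
#' below 0.05 (strict) and either the log2 fold change is at most -1 with a
#' reference-group median FPKM of at least 10 (direction `down`), or the
#' log2 fold change is at least 1 with a target-group median FPKM of at
#' least 10 (direction `up`). Fold-change and expression bounds are
#' non-strict, as the rule is stated. Records with missing required fields
#' are rejected with a warning tally.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `padj`,
#'   `median_fpkm_ref`, `median_fpkm_target`.
#' @param padj_max adjusted p-value bound (strict; default 0.05).
#' @param lfc_min absolute log2 fold-change bound (non-strict; default 1).
#' @param fpkm_min median FPKM guard on the relevant group (non-strict;
#'   default 10).
#' @return the significant subset with an added `direction` column
#'   (`up`/`down`); attribute `rejected` counts malformed records.
#' @export
filter_deg <- function(records, padj_max = 0.05, lfc_min = 1, fpkm_min = 10) {
  req <- c("gene", "log2fc", "padj", "median_fpkm_ref", "median_fpkm_target")
  miss <- setdiff(req, names(records))
  if (length(miss)) stopf("DE table lacks columns: %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(records)[, req]
  ok <- stats::complete.cases(df[, c("log2fc", "padj", "median_fpkm_ref",
                                     "median_fpkm_target")])
  rejected <- sum(!ok)
  if (rejected > 0)
    warnf("%d record(s) rejected for missing fields", rejected)
  df <- df[ok, , drop = FALSE]
  if (any(df$padj < 0 | df$padj > 1)) stopf("padj must lie in [0, 1]")
  if (any(df$median_fpkm_ref < 0 | df$median_fpkm_target < 0))
    stopf("median FPKM values must be >= 0")
  down <- df$padj < padj_max & df$log2fc <= -lfc_min &
    df$median_fpkm_ref >= fpkm_min
  up <- df$padj < padj_max & df$log2fc >= lfc_min &
    df$median_fpkm_target >= fpkm_min
  out <- df[down | up, , drop = FALSE]
  out$direction <- ifelse(out$log2fc <= -lfc_min, "down", "up")
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}
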