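#' Residue-level confusion counts
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  stopifnot(length(y_true) >= 1L, all(y_true %in% c(0, 1)),
            all(y_pred %in% c(0, 1)))
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FN = sum(y_true == 1 & y_pred == 0)
  ), class = "confusion_counts")
}

#' Sum confusion counts across chains (for pooled metrics)
#' @param counts_list List of `confusion_counts`.
#' @export
pool_counts <- function(counts_list) {
  structure(list(
    TP = sum(vapply(counts_list, `[[`, numeric(1), "TP")),
    FP = sum(vapply(counts_list, `[[`, numeric(1), "FP")),
    TN = sum(vapply(counts_list, `[[`, numeric(1), "TN")),
    FN = sum(vapply(counts_list, `[[`, numeric(1), "FN"))
  ), class = "confusion_counts")
}

#' The six residue-level evaluation metrics
#'
#' Sensitivity, specificity, accuracy and precision as percentages, F1 as a
#' percentage (harmonic mean of Sen and Pre), and the Matthews correlation
#' coefficient in `[-1, 1]`. A zero factor in MCC's denominator yields `NA`
#' (reported as N/A). Values are kept at full precision; rounding to two
#' decimals happens only when formatting reports.
#'
#' @param counts A `confusion_counts`.
#' @return A `metrics_report` list with `Sen`, `Spe`, `Acc`, `Pre`, `F1`,
#'   `MCC`.
#' @export
metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  stopifnot(total > 0)
  frac <- function(num, den) if (den == 0) 0 else num / den
  sen <- frac(TP, TP + FN) * 100
  spe <- frac(TN, TN + FP) * 100
  acc <- (TP + TN) / total * 100
  pre <- frac(TP, TP + FP) * 100
  f1 <- if (sen + pre == 0) 0 else 2 * sen * pre / (sen + pre)
  den <- as.numeric(TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  mcc <- if (den == 0) NA_real_ else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  structure(list(Sen = sen, Spe = spe, Acc = acc, Pre = pre, F1 = f1,
                 MCC = mcc), class = "metrics_report")
}

#' Aggregate per-chain metric reports
#'
#' Macro mode takes the unweighted mean of each metric over chains (chains
#' with undefined MCC are excluded from the MCC mean, and their number is
#' reported); pooled mode computes the metrics of the summed confusion
#' counts and therefore needs the raw counts.
#'
#' @param reports List of `metrics_report`s (macro mode).
#' @param mode `"macro"` or `"pooled"`.
#' @param counts_list List of `confusion_counts` (required for pooled mode).
#' @return A `metrics_report`; macro mode adds `n_undefined_mcc`.
#' @export
aggregate_metrics <- function(reports = NULL, mode = c("macro", "pooled"),
                              counts_list = NULL) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    if (is.null(counts_list)) stop("pooled mode requires raw counts")
    return(metrics(pool_counts(counts_list)))
  }
  if (is.null(reports) || length(reports) == 0L) stop("no reports to aggregate")
  gather <- function(f) vapply(reports, `[[`, numeric(1), f)
  mccs <- gather("MCC")
  out <- structure(list(
    Sen = mean(gather("Sen")), Spe = mean(gather("Spe")),
    Acc = mean(gather("Acc")), Pre = mean(gather("Pre")),
    F1 = mean(gather("F1")),
    MCC = if (all(is.na(mccs))) NA_real_ else mean(mccs, na.rm = TRUE)
  ), class = "metrics_report")
  out$n_undefined_mcc <- sum(is.na(mccs))
  out
}

#' Per-residue TN/TP/FP/FN category manifest
#'
#' One row per residue with the author residue id, one-letter code,
#' predicted probability and confusion category — the table downstream
#' structure viewers color by.
#'
#' @param y_true,y_pred Aligned 0/1 vectors.
#' @param chain Optional `chain_structure` supplying author ids and codes.
#' @param probabilities Optional predicted probabilities.
#' @return Data frame with columns `author_id`, `residue`, `probability`,
#'   `category`.
#' @export
category_manifest <- function(y_true, y_pred, chain = NULL,
                              probabilities = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  cat_ <- ifelse(y_true == 1,
                 ifelse(y_pred == 1, "TP", "FN"),
                 ifelse(y_pred == 1, "FP", "TN"))
  n <- length(y_true)
  data.frame(
    author_id = if (is.null(chain)) as.character(seq_len(n) - 1L)
    else vapply(chain$residues, function(r) r$author_seq_id, character(1)),
    residue = if (is.null(chain)) rep("X", n)
    else strsplit(chain$sequence, "")[[1]],
    probability = if (is.null(probabilities)) rep(NA_real_, n)
    else probabilities,
    category = cat_,
    stringsAsFactors = FALSE
  )
}

#' Format a metric value the way reports print it
#'
#' Two-decimal rounding with trailing zeros trimmed (`50` not `50.00`,
#' `93.33` stays `93.33`); MCC uses three decimals trimmed the same way;
#' undefined values print `"N/A"`.
#'
#' @param x Numeric value.
#' @param digits Decimal places before trimming.
#' @export
format_metric <- function(x, digits = 2) {
  if (is.na(x)) return("N/A")
  format(round(x, digits), drop0trailing = TRUE, scientific = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sen %s  Spe %s  Acc %s  Pre %s  F1 %s  MCC %s\n",
              format_metric(x$Sen), format_metric(x$Spe),
              format_metric(x$Acc), format_metric(x$Pre),
              format_metric(x$F1), format_metric(x$MCC, 3)))
  invisible(x)
}

#' Write a metrics report to JSON and TSV
#' @param report A `metrics_report`.
#' @param path Output path without extension; writes `path.json` and
#'   `path.tsv`.
#' @export
write_metrics_report <- function(report, path) {
  vals <- list(Sen = report$Sen, Spe = report$Spe, Acc = report$Acc,
               Pre = report$Pre, F1 = report$F1, MCC = report$MCC)
  jsonlite::write_json(vals, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  df <- data.frame(metric = names(vals),
                   value = vapply(vals, function(v)
                     format_metric(v, if (identical(v, report$MCC)) 3 else 2),
                     character(1)))
  write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
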