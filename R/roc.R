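#' Label QA comparison records against the clinical model
#'
#' A record is *negative* (acceptable) when its candidate model matches
#' the clinical leaf-tip offset and width exactly, and *positive*
#' (a model failure that QA should detect) otherwise.
#'
#' @param records data frame with at least `offset_mm` and `width_mm`
#'   columns (one row per QA comparison, e.g. from
#'   [run_detectability()]).
#' @param clinical the clinical [beam_model()].
#' @return `records` with a `label` column (`"negative"`/`"positive"`).
#'   Errors when no record matches the clinical model.
#' @export
label_records <- function(records, clinical) {
  stopifnot(is.data.frame(records),
            all(c("offset_mm", "width_mm") %in% names(records)),
            inherits(clinical, "beam_model"))
  neg <- records$offset_mm == clinical$leaf_tip_offset_mm &
    records$width_mm == clinical$leaf_tip_width_mm
  if (!any(neg))
    stop("no record matches the clinical model: cannot define negatives")
  records$label <- ifelse(neg, "negative", "positive")
  records
}

#' ROC curve over the gamma pass rate
#'
#' Sweeps every distinct pass rate as a decision threshold, flagging a
#' record positive when its pass rate is less than or equal to the
#' threshold (low pass rate indicates a failing model).  Records with
#' equal pass rates move together (tie-aware), and the curve always
#' includes the endpoints (0, 0) and (1, 1).  The AUC is the trapezoidal
#' area, which for this construction equals the tie-corrected
#' Mann-Whitney concordance probability.
#'
#' @param records labeled data frame (see [label_records()]) with columns
#'   `pass_rate` and `label`.
#' @return An object of class `roc_curve`: data frame `curve`
#'   (`threshold`, `tpr`, `fpr`), and scalars `auc`, `n_pos`, `n_neg`.
#'   Errors on one-class input.
#' @examples
#' rec <- data.frame(pass_rate = c(60, 80, 90, 70),
#'                   label = c("positive", "positive", "negative", "negative"))
#' roc_curve(rec)$auc   # 0.75
#' @export
roc_curve <- function(records) {
  stopifnot(all(c("pass_rate", "label") %in% names(records)))
  pos <- records$pass_rate[records$label == "positive"]
  neg <- records$pass_rate[records$label == "negative"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("ROC needs at least one positive and one negative record")
  th <- sort(unique(records$pass_rate))
  tpr <- vapply(th, function(t) mean(pos <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg <= t), numeric(1))
  curve <- data.frame(threshold = c(-Inf, th), tpr = c(0, tpr),
                      fpr = c(0, fpr))
  if (curve$tpr[nrow(curve)] != 1 || curve$fpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = Inf, tpr = 1, fpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}
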