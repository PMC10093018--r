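#' Macro-averaged classification metrics from a confusion matrix
#'
#' Per class, sensitivity is TP/(TP+FN) and precision TP/(TP+FP); both are
#' macro-averaged with equal class weight and expressed in percent. F1 is
#' the harmonic mean of the macro sensitivity and macro precision; the
#' false-negative rate is 100 minus macro sensitivity; accuracy is the
#' confusion-matrix trace over its total. AUC is a midrank Wilcoxon
#' statistic over the continuous scores: a single AUC for binary problems,
#' a macro one-vs-rest average otherwise. Classes absent from the test set
#' are excluded from the macro averages with a warning.
#'
#' @param cm K x K confusion table/matrix, rows = true class, columns =
#'   predicted class, total > 0.
#' @param scores optional numeric matrix of per-class scores (test rows x
#'   classes, columns named by class) used for AUC.
#' @param truth optional factor of true test labels (required for AUC).
#' @return a list of class `metrics_report` with elements
#'   `sensitivity_pct`, `precision_pct`, `f1_pct`, `auc`, `accuracy_pct`,
#'   `fnr_pct`.
#' @export
metrics_from_confusion <- function(cm, scores = NULL, truth = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  present <- rowSums(cm) > 0
  if (!all(present))
    warning("classes absent from the test set excluded from macro averages: ",
            paste(rownames(cm)[!present], collapse = ", "))
  tp <- diag(cm)
  sens_c <- (tp / rowSums(cm))[present]
  prec_den <- colSums(cm)
  prec_c <- ifelse(prec_den > 0, tp / prec_den, 0)[present]
  S <- mean(sens_c) * 100
  P <- mean(prec_c) * 100
  f1 <- if (S + P > 0) 2 * S * P / (S + P) else 0
  auc <- NA_real_
  if (!is.null(scores) && !is.null(truth)) {
    truth <- factor(truth)
    lev <- intersect(levels(truth)[table(truth) > 0], colnames(scores))
    if (length(lev) == 2) {
      auc <- rank_auc(scores[, lev[2]], truth == lev[2])
    } else if (length(lev) > 2) {
      auc <- mean(vapply(lev, function(l)
        rank_auc(scores[, l], truth == l), numeric(1)))
    }
  }
  structure(list(sensitivity_pct = S, precision_pct = P, f1_pct = f1,
                 auc = auc, accuracy_pct = sum(tp) / total * 100,
                 fnr_pct = 100 - S),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.2f%%  precision %.2f%%  F1 %.2f  ",
                     "AUC %s  accuracy %.2f%%  FNR %.2f%%\n"),
              x$sensitivity_pct, x$precision_pct, x$f1_pct,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$accuracy_pct, x$fnr_pct))
  invisible(x)
}

# Midrank (tie-aware) Wilcoxon AUC of scores for the positive class.
rank_auc <- function(score, positive) {
  npos <- sum(positive)
  nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' F1 score from sensitivity and precision (percent)
#'
#' Harmonic mean `2 S P / (S + P)` of two rates given in percent; the
#' worked-example arithmetic used by the internal-consistency checks
#' (e.g. sensitivity 95.4 and precision 95.35 give F1 95.37 at 2 d.p.).
#'
#' @param sensitivity_pct,precision_pct rates in percent.
#' @return F1 in percent.
#' @export
f1_from_rates <- function(sensitivity_pct, precision_pct) {
  ifelse(sensitivity_pct + precision_pct > 0,
         2 * sensitivity_pct * precision_pct /
           (sensitivity_pct + precision_pct), 0)
}

#' False-negative rate from sensitivity (percent)
#'
#' @param sensitivity_pct macro sensitivity in percent.
#' @return FNR in percent (`100 - sensitivity`).
#' @export
fnr_from_sensitivity <- function(sensitivity_pct) 100 - sensitivity_pct

#' Bundled reference table of reported classifier metrics
#'
#' Loads the package's bundled table of classifier metric rows (sensitivity,
#' precision, F1, AUC, accuracy, FNR, all in percent except AUC) reported
#' for this pipeline family on the CBIS-DDSM and INbreast mammography
#' benchmarks. Used by the internal-consistency checks, which recompute F1
#' from sensitivity/precision and FNR from sensitivity for every row.
#'
#' @return a data.frame with columns `experiment` (dataset and pipeline
#'   stage, e.g. `cbis_selected`), `classifier`, `sensitivity`,
#'   `precision`, `f1`, `auc`, `accuracy`, `fnr`.
#' @export
reported_metrics <- function() {
  path <- system.file("extdata", "reported_metrics.csv",
                      package = "mammofuse", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
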