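# Evaluation statistics: confusion-matrix metrics, one-vs-rest ROC/AUC,
# Wilson score intervals, and continuity-corrected two-sided McNemar tests.

#' Build a confusion matrix
#'
#' @param truth,pred 0-based integer class labels of equal length.
#' @param n_classes number of classes (rows/cols).
#' @param class_names optional dimnames.
#' @return `K x K` integer matrix, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred) + 1L,
                             class_names = NULL) {
  stopifnot(length(truth) == length(pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  pred = class_names)
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Conventions: `Rec` is the macro average of per-class recall and `Pre` the
#' macro average of per-class precision, where a class never predicted
#' contributes precision 0; classes absent from the truth are excluded from
#' the macro averages.  `Top1Acc` is trace/total (integer arithmetic before
#' the final division).  `MAcc` is the mean of per-class one-vs-rest
#' accuracies `(TP + TN) / total`.  `F1` is the macro F1 (harmonic mean per
#' class, 0 where precision + recall is 0).
#'
#' @param cm confusion matrix (rows = true, cols = predicted).
#' @return named list `Rec`, `Top1Acc`, `MAcc`, `Pre`, `F1`, all in `[0, 1]`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("confusion matrix is empty")
  K <- nrow(cm)
  tp <- diag(cm)
  rs <- rowSums(cm)   # per-class truth counts
  cs <- colSums(cm)   # per-class prediction counts
  present <- rs > 0L
  rec_c <- ifelse(rs > 0L, tp / rs, NA_real_)
  pre_c <- ifelse(cs > 0L, tp / cs, 0)
  f1_c <- ifelse(pre_c + rec_c > 0, 2 * pre_c * rec_c / (pre_c + rec_c), 0)
  macc_c <- vapply(seq_len(K), function(k) {
    tn <- total - rs[k] - cs[k] + tp[k]
    (tp[k] + tn) / total
  }, numeric(1L))
  list(Rec = mean(rec_c[present]),
       Top1Acc = sum(tp) / total,
       MAcc = mean(macc_c[present]),
       Pre = mean(pre_c[present]),
       F1 = mean(f1_c[present]))
}

#' One-vs-rest ROC curves and AUC
#'
#' Per-class AUC is computed with midranks (tie-aware, equivalent to the
#' Mann-Whitney statistic and to the trapezoid area under the threshold-swept
#' ROC).  A class with no positives or no negatives in the truth has
#' undefined AUC and is returned as `NA`.
#'
#' @param scores `n x K` matrix of class probabilities (rows sum to 1).
#' @param truths 0-based true labels of length `n`.
#' @return list with `per_class` (length-K numeric), `macro` (mean over
#'   defined classes).
#' @export
roc_auc <- function(scores, truths) {
  stopifnot(nrow(scores) == length(truths))
  if (any(abs(rowSums(scores) - 1) > 1e-4))
    warning("score rows do not sum to 1")
  K <- ncol(scores)
  per <- vapply(seq_len(K), function(k) {
    pos <- truths == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, k])      # midranks
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1L))
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' ROC curve points for one class (threshold sweep)
#'
#' @param score numeric scores for the positive class.
#' @param positive logical vector, TRUE for positives.
#' @return data frame with `threshold`, `tpr`, `fpr`, ordered from the
#'   all-positive corner to the origin.
#' @export
roc_points <- function(score, positive) {
  th <- c(-Inf, sort(unique(score)), Inf)
  n1 <- sum(positive); n0 <- sum(!positive)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) sum(score >= t & positive) / n1,
                          numeric(1L)),
             fpr = vapply(th, function(t) sum(score >= t & !positive) / n0,
                          numeric(1L)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return named vector `c(lo, hi)`; always brackets `successes / n`.
#' @export
binom_ci <- function(successes, n, level = 0.95) {
  if (n < 1L) stop("n must be >= 1")
  if (successes < 0L || successes > n) stop("successes must be in 0..n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Upper-tail p-value of a chi-square statistic with 1 df
#'
#' `p = 2 * (1 - Phi(sqrt(stat)))`, the asymptotic two-sided significance of
#' a continuity-corrected McNemar statistic.  Monotonically decreasing in the
#' statistic; `p(0) = 1`.
#'
#' @param stat non-negative statistic.
#' @return p-value in `(0, 1]`.
#' @export
chisq1_pvalue <- function(stat) {
  if (any(stat < 0)) stop("statistic must be non-negative")
  2 * (1 - stats::pnorm(sqrt(stat)))
}

#' Two-sided McNemar test with continuity correction
#'
#' For discordant counts `b` (method 1 correct, method 2 wrong) and `c`
#' (the reverse): `statistic = max(|b - c| - 1, 0)^2 / (b + c)` — the
#' continuity correction is clamped so that `b == c` gives statistic 0 and
#' p 1 — with the asymptotic chi-square (1 df) two-sided p-value.  With
#' `b + c == 0` the test is undefined and flagged.
#'
#' @param b,c non-negative discordant counts.
#' @return list of class `"mcnemar_result"` with `b`, `c`, `statistic`, `p`,
#'   `defined`.
#' @export
mcnemar_test <- function(b, c) {
  if (b < 0L || c < 0L) stop("b and c must be non-negative")
  if (b + c == 0L) {
    return(structure(list(b = b, c = c, statistic = NA_real_, p = NA_real_,
                          defined = FALSE), class = "mcnemar_result"))
  }
  stat <- max(abs(b - c) - 1, 0)^2 / (b + c)
  structure(list(b = b, c = c, statistic = stat, p = chisq1_pvalue(stat),
                 defined = TRUE), class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  if (!x$defined) cat("McNemar: undefined (no discordant pairs)\n")
  else cat(sprintf("McNemar: b=%d c=%d statistic=%.3f p=%.5f\n", x$b, x$c,
                   x$statistic, x$p))
  invisible(x)
}

# discordant counts between two classifiers against the same truth,
# optionally restricted to one true class (one-vs-rest correctness)
discordant_counts <- function(truth, pred1, pred2, class = NULL) {
  keep <- if (is.null(class)) rep(TRUE, length(truth)) else truth == class
  ok1 <- pred1[keep] == truth[keep]
  ok2 <- pred2[keep] == truth[keep]
  c(b = sum(ok1 & !ok2), c = sum(!ok1 & ok2))
}

#' Full evaluation report
#'
#' Confusion matrix, macro metrics, per-class one-vs-rest AUC,
#' sensitivity/specificity with Wilson 95% intervals, and (when a reference
#' classifier's predictions are given) per-class McNemar tests on
#' one-vs-rest correctness.
#'
#' @param truth,pred 0-based labels.
#' @param scores optional `n x K` probability matrix (enables ROC/AUC).
#' @param class_names optional class labels.
#' @param reference_pred optional predictions of a comparison method.
#' @return list of class `"eval_report"`.
#' @export
eval_report <- function(truth, pred, scores = NULL, class_names = NULL,
                        reference_pred = NULL) {
  K <- if (!is.null(scores)) ncol(scores) else max(truth, pred) + 1L
  if (is.null(class_names)) class_names <- as.character(seq_len(K) - 1L)
  cm <- confusion_matrix(truth, pred, K, class_names)
  per_class <- lapply(seq_len(K) - 1L, function(k) {
    pos <- truth == k
    tp <- sum(pred == k & pos); fn <- sum(pred != k & pos)
    tn <- sum(pred != k & !pos); fp <- sum(pred == k & !pos)
    sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
    out <- list(class = class_names[k + 1L],
                sensitivity = sens,
                sensitivity_ci = if (tp + fn > 0L) binom_ci(tp, tp + fn),
                specificity = spec,
                specificity_ci = if (tn + fp > 0L) binom_ci(tn, tn + fp))
    if (!is.null(reference_pred)) {
      dc <- discordant_counts(truth, pred, reference_pred, class = k)
      out$mcnemar <- mcnemar_test(dc[["b"]], dc[["c"]])
    }
    out
  })
  structure(list(confusion = cm,
                 metrics = classification_metrics(cm),
                 auc = if (!is.null(scores)) roc_auc(scores, truth),
                 per_class = per_class,
                 n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("n=%d  Top-1 %.3f  Rec %.3f  MAcc %.3f  Pre %.3f  F1 %.3f\n",
              x$n, m$Top1Acc, m$Rec, m$MAcc, m$Pre, m$F1))
  if (!is.null(x$auc)) cat(sprintf("macro AUC %.3f\n", x$auc$macro))
  invisible(x)
}

#' Write an evaluation report and its tables to disk
#'
#' JSON for the report, CSV for the confusion matrix, and (when scores were
#' supplied) per-class ROC points as CSV.
#'
#' @param report an [eval_report()].
#' @param dir output directory (created if needed).
#' @param scores,truth optional; when given, ROC point CSVs are written.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir, scores = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_class <- lapply(report$per_class, function(pc) {
    if (!is.null(pc$mcnemar)) pc$mcnemar <- unclass(pc$mcnemar)
    pc
  })
  rep_json <- list(n = report$n, metrics = report$metrics,
                   auc = report$auc, per_class = per_class)
  jsonlite::write_json(rep_json, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$confusion, file.path(dir, "confusion_matrix.csv"))
  if (!is.null(scores) && !is.null(truth)) {
    for (k in seq_len(ncol(scores))) {
      pts <- roc_points(scores[, k], truth == (k - 1L))
      utils::write.csv(pts, file.path(dir, sprintf("roc_class%d.csv", k - 1L)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
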