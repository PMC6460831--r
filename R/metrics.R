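#' Sensitivity, specificity and Matthews correlation
#'
#' SN = TP / (TP + FN), SP = TN / (TN + FP), and the Matthews correlation
#' coefficient. A metric whose denominator is zero is reported as `NA`;
#' MCC with any zero marginal is reported as 0 and flagged (`mcc_defined
#' = FALSE`), the usual convention for degenerate confusion tables.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return One-row tibble `sn`, `sp`, `mcc`, `mcc_defined`.
#' @examples
#' confusion_metrics(8, 1, 9, 2)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  marg <- c(tp + fn, tp + fp, tn + fp, tn + fn)
  if (all(marg > 0)) {
    mcc <- (tp * tn - fn * fp) / sqrt(prod(marg))
    defined <- TRUE
  } else {
    mcc <- 0
    defined <- FALSE
  }
  tibble::tibble(sn = sn, sp = sp, mcc = mcc, mcc_defined = defined)
}

#' Q9 global accuracy index
#'
#' A class-skew-invariant accuracy measure: with per-class error rates
#' e+ = FN/(TP+FN) and e- = FP/(TN+FP),
#' q9 = 1 - sqrt(2) * sqrt(e+^2 + e-^2) when both classes are present;
#' when one class is absent q9 falls back to the other class's signed
#' accuracy, (TN - FP)/(TN + FP) or (TP - FN)/(TP + FN). Q9 = (1 + q9)/2,
#' so perfect prediction gives 1 and a coin flip on both classes 0.5.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts with positive total.
#' @return Q9, a scalar in \[0, 1\] for error rates at most 1/sqrt(2) each.
#' @export
q9 <- function(tp, fp, tn, fn) {
  stopifnot(tp + fp + tn + fn > 0)
  q <- if (tp + fn == 0) {
    (tn - fp) / (tn + fp)
  } else if (tn + fp == 0) {
    (tp - fn) / (tp + fn)
  } else {
    1 - sqrt(2) * sqrt((fn / (tp + fn))^2 + (fp / (tn + fp))^2)
  }
  (1 + q) / 2
}

#' ROC and precision-recall curves with their areas
#'
#' Thresholds sweep the distinct score values from high to low, so tied
#' scores move as one block. AUC-ROC is the trapezoidal area under
#' sensitivity against 1 - specificity. AUC-PR uses Davis-Goadrich
#' interpolation: between consecutive achievable points, intermediate
#' points are created for every unit step in TP with FP increasing along
#' the local slope — precision is interpolated nonlinearly in the counts,
#' never linearly — and the trapezoid is taken on the densified curve.
#' The segment from recall 0 to the first achievable point contributes
#' its area at that point's precision.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Labels (`"positive"`/`"negative"` or logical); both
#'   classes must be present.
#' @return A `chidt_curves` list: `roc` tibble (`threshold`, `fpr`,
#'   `tpr`), `pr` tibble (`recall`, `precision`), `auc_roc`, `auc_pr`.
#' @export
roc_pr <- function(scores, labels) {
  lab <- as_label_vector(labels)
  stopifnot(length(scores) == length(lab))
  npos <- sum(lab == "positive")
  nneg <- sum(lab == "negative")
  if (npos == 0 || nneg == 0) {
    stop("curve construction needs both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- lab[ord] == "positive"
  keep <- !duplicated(s, fromLast = TRUE)  # block ends of tied scores
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  thr <- s[keep]
  roc <- tibble::tibble(threshold = c(Inf, thr),
                        fpr = c(0, fp) / nneg, tpr = c(0, tp) / npos)
  auc_roc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                    utils::tail(roc$tpr, -1)) / 2)

  # densify achievable PR points in TP/FP count space (Davis-Goadrich)
  ach <- cbind(tp = c(0, tp), fp = c(0, fp))
  dtp <- numeric(0); dfp <- numeric(0)
  for (i in seq_len(nrow(ach) - 1)) {
    a <- ach[i, ]; b <- ach[i + 1, ]
    step_tp <- b["tp"] - a["tp"]
    if (step_tp > 1) {
      x <- seq_len(step_tp - 1)
      slope <- (b["fp"] - a["fp"]) / step_tp
      dtp <- c(dtp, a["tp"] + x, b["tp"])
      dfp <- c(dfp, a["fp"] + slope * x, b["fp"])
    } else {
      dtp <- c(dtp, b["tp"]); dfp <- c(dfp, b["fp"])
    }
  }
  pr_pts <- tibble::tibble(tp = dtp, fp = dfp)
  pr_pts <- pr_pts[pr_pts$tp > 0, , drop = FALSE]
  pr <- tibble::tibble(recall = pr_pts$tp / npos,
                       precision = pr_pts$tp / (pr_pts$tp + pr_pts$fp))
  # leading segment: flat at the first achievable precision
  rec <- c(0, pr$recall)
  prec <- c(pr$precision[1], pr$precision)
  auc_pr <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr),
            class = "chidt_curves")
}

#' @export
print.chidt_curves <- function(x, ...) {
  cat(sprintf("<chidt_curves: AUC-ROC %.4f, AUC-PR %.4f>\n",
              x$auc_roc, x$auc_pr))
  invisible(x)
}

#' Seeded k-fold split
#'
#' Partitions indices 1..n into k folds whose sizes differ by at most one.
#' The stratified variant (default when labels are supplied) shuffles and
#' deals each class separately so every fold preserves the class ratio —
#' important when negatives outnumber positives a hundredfold.
#'
#' @param n Number of samples, or ignored when `labels` given.
#' @param k Number of folds.
#' @param seed Integer seed; same seed, same folds.
#' @param labels Optional labels for stratification.
#' @return List of k integer vectors of fold indices.
#' @export
kfold_split <- function(n, k, seed = 1, labels = NULL) {
  if (!is.null(labels)) n <- length(labels)
  stopifnot(k >= 1, k <= n)
  withr::local_seed(seed)
  assign_folds <- function(idx) {
    idx <- sample(idx)
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  if (is.null(labels)) {
    folds <- assign_folds(seq_len(n))
  } else {
    lab <- as_label_vector(labels)
    per_class <- lapply(split(seq_len(n), lab), assign_folds)
    folds <- lapply(seq_len(k), function(i) {
      sort(unlist(lapply(per_class, `[[`, i), use.names = FALSE))
    })
  }
  unname(lapply(folds, function(f) sort(unname(f))))
}

#' Evaluate a prediction table
#'
#' @param data Data frame with a truth column `label`, a predicted label
#'   column `.pred_label` (as produced by [predict.chidt_model()]) and a
#'   `score` column.
#' @param curves Also compute ROC/PR AUCs (needs both classes).
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `sn`, `sp`, `mcc`,
#'   `q9`, and when `curves` is `TRUE`, `auc_roc`, `auc_pr`.
#' @export
evaluate_predictions <- function(data, curves = TRUE) {
  stopifnot(all(c("label", ".pred_label") %in% names(data)))
  truth <- as_label_vector(data$label)
  pred <- as_label_vector(data$.pred_label)
  tp <- sum(truth == "positive" & pred == "positive")
  fp <- sum(truth == "negative" & pred == "positive")
  tn <- sum(truth == "negative" & pred == "negative")
  fn <- sum(truth == "positive" & pred == "negative")
  out <- dplyr::bind_cols(tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn),
                          confusion_metrics(tp, fp, tn, fn),
                          tibble::tibble(q9 = q9(tp, fp, tn, fn)))
  if (curves && "score" %in% names(data) &&
      length(unique(truth)) == 2) {
    cv <- roc_pr(data$score, truth)
    out$auc_roc <- cv$auc_roc
    out$auc_pr <- cv$auc_pr
  }
  out
}
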