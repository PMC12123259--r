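#' Classification metrics for interaction scores
#'
#' Scores a binary label vector against predicted probabilities:
#' threshold-free AUC (Mann-Whitney rank statistic, ties counted half) and
#' PR-AUC (step interpolation from the highest score down, the
#' average-precision construction), plus the confusion table at threshold
#' `tau` (classification rule: `score > tau` predicts an interaction) with
#' accuracy, Cohen's Kappa and the Matthews correlation coefficient.
#'
#' @param labels 0/1 vector of true classes.
#' @param scores Numeric score vector, same length.
#' @param tau Classification threshold (default 0.4).
#' @return One-row tibble: `auc`, `pr_auc`, `accuracy`, `kappa`, `mcc`,
#'   `tp`, `fp`, `fn`, `tn`, `threshold`. With a one-class label vector the
#'   rank-based metrics are undefined and returned as `NA` with a warning;
#'   the confusion-based metrics are still computed.
#' @export
#' @examples
#' evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
evaluate_scores <- function(labels, scores, tau = 0.4) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_data("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)

  if (n1 == 0L || n0 == 0L) {
    warn("only one class present: AUC and PR-AUC are undefined")
    auc <- pr_auc <- NA_real_
  } else {
    r <- rank(scores)
    auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord]
    s <- scores[ord]
    cum_tp <- cumsum(y)
    cum_fp <- cumsum(1L - y)
    last_of_block <- c(diff(s) != 0, TRUE) # tied scores enter as one block
    tp_k <- cum_tp[last_of_block]
    fp_k <- cum_fp[last_of_block]
    prec <- tp_k / (tp_k + fp_k)
    rec <- tp_k / n1
    pr_auc <- sum(diff(c(0, rec)) * prec)
  }

  pred <- as.integer(scores > tau)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  n <- tp + fp + fn + tn
  accuracy <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (accuracy - p_e) / (1 - p_e)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }

  tibble::tibble(auc = auc, pr_auc = pr_auc, accuracy = accuracy,
                 kappa = kappa, mcc = mcc, tp = tp, fp = fp, fn = fn,
                 tn = tn, threshold = tau)
}

#' Select a pruning threshold for predicted probabilities
#'
#' `"fixed"` returns the configured threshold unchanged (default 0.4, the
#' value used to prune the case-study metanetwork). `"max_kappa"` and
#' `"max_youden"` search the grid 0.01, 0.02, ..., 0.99 for the threshold
#' maximising Cohen's Kappa or Youden's J (sensitivity + specificity - 1),
#' breaking ties in favour of the smallest threshold.
#'
#' @inheritParams evaluate_scores
#' @param method One of `"fixed"`, `"max_kappa"`, `"max_youden"`.
#' @param tau Threshold returned by `method = "fixed"`.
#' @return A single threshold in `(0, 1)`.
#' @export
choose_threshold <- function(labels, scores,
                             method = c("fixed", "max_kappa", "max_youden"),
                             tau = 0.4) {
  method <- match.arg(method)
  if (method == "fixed") return(tau)
  labels <- as.integer(labels)
  grid <- seq(0.01, 0.99, by = 0.01)
  score_at <- function(t) {
    pred <- as.integer(scores > t)
    tp <- sum(pred & labels)
    fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    tn <- sum(!pred & !labels)
    if (method == "max_kappa") {
      n <- length(labels)
      acc <- (tp + tn) / n
      p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
      if (p_e == 1) 0 else (acc - p_e) / (1 - p_e)
    } else {
      sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
      spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
      sens + spec - 1
    }
  }
  vals <- vapply(grid, score_at, numeric(1))
  grid[which.max(vals)] # which.max returns the first (smallest) maximiser
}
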