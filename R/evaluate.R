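#' Evaluate a classifier on a labeled test set
#'
#' Computes the ROC curve and AUC over neutral truth, the confusion matrix
#' at a decision threshold, and FPR/TPR at the standard reporting thresholds.
#' Two false-positive rates are emitted, clearly labeled, because both senses
#' appear in sweep-scan practice: `fpr_neutral` = FP / all true neutrals (the
#' ROC sense) and `fpr_positive` = FP / all positive classifications (the
#' precision-complement sense used in FDR-style reporting).
#'
#' @param model a `sweep_cnn`, or `NULL` if `scores` are supplied directly.
#' @param tensors test tensors (list or stacked array); ignored when
#'   `scores` given.
#' @param labels `"neutral"`/`"sweep"` (or 0/1) truth labels.
#' @param scores optional precomputed probabilities.
#' @param threshold confusion-matrix decision threshold (default 0.5).
#' @param report_thresholds thresholds at which FPR/TPR are tabulated.
#' @param strata optional data frame of per-replicate sweep parameters
#'   (e.g. columns tau, s, saf, eaf); when given, per-stratum detection
#'   power at `threshold` is reported over quartile bins of each column.
#' @return an `eval_report` list: `roc` (tibble fpr/tpr/threshold), `auc`,
#'   `confusion` (2x2 matrix), `rates` (tibble threshold/fpr_neutral/
#'   `fpr_positive`/tpr), `threshold`, `n`, and optionally `power_by_stratum`.
#' @export
evaluate <- function(model, tensors = NULL, labels, scores = NULL,
                     threshold = 0.5,
                     report_thresholds = c(0.001, 0.01, 0.02, 0.5, 0.8,
                                           0.99),
                     strata = NULL) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "sweep") else as.integer(labels)
  if (!length(y)) stop("empty test set", call. = FALSE)
  if (is.null(scores)) {
    stopifnot(inherits(model, "sweep_cnn"))
    scores <- stats::predict(model, tensors)
  }
  if (length(scores) != length(y))
    stop("scores/labels length mismatch", call. = FALSE)

  auc <- .auc(scores, y)
  roc <- .roc_points(scores, y)

  pred <- as.integer(scores >= threshold)
  confusion <- matrix(c(sum(pred == 0 & y == 0), sum(pred == 0 & y == 1),
                        sum(pred == 1 & y == 0), sum(pred == 1 & y == 1)),
                      2L, 2L, byrow = TRUE,
                      dimnames = list(predicted = c("neutral", "sweep"),
                                      truth = c("neutral", "sweep")))

  rates <- do.call(rbind, lapply(report_thresholds, function(th) {
    pos <- scores >= th
    fp <- sum(pos & y == 0); tp <- sum(pos & y == 1)
    tibble::tibble(threshold = th,
                   fpr_neutral = if (sum(y == 0)) fp / sum(y == 0) else NA,
                   fpr_positive = if (fp + tp > 0) fp / (fp + tp) else NA,
                   tpr = if (sum(y == 1)) tp / sum(y == 1) else NA)
  }))

  out <- list(roc = roc, auc = auc, confusion = confusion, rates = rates,
              threshold = threshold, n = length(y))
  if (!is.null(strata)) {
    out$power_by_stratum <- .power_by_stratum(scores, y, strata, threshold)
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, " AUC =", signif(x$auc, 4), "\n")
  print(x$confusion)
  invisible(x)
}

# rank (Mann-Whitney) AUC; ties handled by midranks
.auc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.roc_points <- function(scores, y) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  fpr <- vapply(ths, function(t) sum(scores >= t & y == 0) / max(n0, 1), 0)
  tpr <- vapply(ths, function(t) sum(scores >= t & y == 1) / max(n1, 1), 0)
  tibble::tibble(threshold = ths, fpr = fpr, tpr = tpr)
}

.power_by_stratum <- function(scores, y, strata, threshold) {
  sweep_sel <- y == 1
  out <- list()
  for (col in names(strata)) {
    v <- strata[[col]][sweep_sel]
    sc <- scores[sweep_sel]
    br <- unique(stats::quantile(v, probs = seq(0, 1, 0.25), na.rm = TRUE))
    if (length(br) < 2L) next
    bin <- cut(v, br, include.lowest = TRUE)
    pw <- as.numeric(tapply(sc >= threshold, bin, mean))
    nn <- as.integer(table(bin))
    out[[col]] <- tibble::tibble(parameter = col, bin = levels(bin),
                                 power = pw, n = nn)
  }
  do.call(rbind, out)
}
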