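#' Precision, recall and F1 from gold and predicted labels
#'
#' Standard definitions from the confusion matrix. Per-class metrics are
#' always computed; the aggregate is micro-averaged by default (for
#' single-label classification micro-P = micro-R = micro-F1 = accuracy),
#' with macro averaging available. Zero-denominator cells are reported as 0
#' and flagged.
#'
#' @param gold Character vector of gold labels.
#' @param pred Character vector of predicted labels (same length).
#' @param labels Optional ordered label set; defaults to the union of
#'   observed labels.
#' @param average Aggregate averaging mode, `"micro"` or `"macro"`.
#' @return An object of class `weaktext_eval`: per-class tibble, aggregate
#'   precision/recall/F1, confusion matrix, `n`. Use [tidy()] / [glance()]
#'   for tibble views.
#' @export
prf <- function(gold, pred, labels = NULL, average = c("micro", "macro")) {
  average <- match.arg(average)
  if (length(gold) != length(pred))
    stop("`gold` and `pred` must have the same length", call. = FALSE)
  gold <- as.character(gold); pred <- as.character(pred)
  if (is.null(labels)) labels <- sort(unique(c(gold, pred)))
  if (!all(c(gold, pred) %in% labels))
    stop("labels outside the declared label set", call. = FALSE)
  cm <- table(factor(gold, levels = labels), factor(pred, levels = labels))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  per_class <- tibble::tibble(
    label = labels,
    support = as.integer(rowSums(cm)),
    precision = as.numeric(p), recall = as.numeric(r), f1 = as.numeric(f1),
    zero_denominator = as.logical((tp + fp == 0) | (tp + fn == 0) | (p + r == 0)))
  if (average == "micro") {
    P <- safe_div(sum(tp), sum(tp + fp))
    R <- safe_div(sum(tp), sum(tp + fn))
  } else {
    P <- mean(p); R <- mean(r)
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(per_class = per_class,
                 precision = as.numeric(P), recall = as.numeric(R),
                 f1 = as.numeric(F1),
                 average = average, confusion = cm, n = length(gold)),
            class = "weaktext_eval")
}

#' @export
print.weaktext_eval <- function(x, digits = 4, ...) {
  cat("<evaluation on n = ", x$n, " documents (", x$average, "-averaged)>\n",
      sep = "")
  print(as.data.frame(x$per_class), digits = digits)
  cat(sprintf("aggregate: precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Paired bootstrap t-test on the F1 difference of two systems
#'
#' Operationalizes the significance test as a paired bootstrap: the test set
#' is resampled with replacement `n_boot` times, the F1 difference
#' (system A minus system B) is computed on each resample, and the
#' t-statistic is the mean resampled difference divided by the bootstrap
#' standard deviation (the bootstrap estimate of the difference's standard
#' error), referred to a t distribution with n - 1 degrees of freedom (null:
#' no difference, significance level 5%). Dividing by the plain bootstrap
#' standard deviation — not by `sd / sqrt(n_boot)` — is what keeps the test
#' calibrated: the resamples estimate the sampling variability of one
#' observed test set, they are not independent observations. Seeded and
#' reproducible.
#'
#' @param gold Gold labels.
#' @param preds_a,preds_b Predictions of the two systems (same length as
#'   `gold`).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param average F1 averaging mode for each resample.
#' @return A tibble with one row: `mean_diff` (mean resampled F1 A - B),
#'   `statistic`, `p_value`, `significant` (at 0.05), `n`, `n_boot`,
#'   `degenerate` (`TRUE` when every resampled difference is identical, in
#'   which case the t-statistic is undefined and `p_value` is `NA`).
#' @export
significance_test <- function(gold, preds_a, preds_b, n_boot = 1000, seed = 1,
                              average = c("micro", "macro")) {
  average <- match.arg(average)
  if (length(gold) != length(preds_a) || length(gold) != length(preds_b))
    stop("`gold`, `preds_a`, `preds_b` must have the same length", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  n <- length(gold)
  labels <- sort(unique(c(gold, preds_a, preds_b)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  f1_of <- function(g, p) prf(g, p, labels = labels, average = average)$f1
  diffs <- numeric(n_boot)
  if (average == "micro") {
    # micro-F1 = accuracy for single-label tasks; resampling reduces to
    # resampled means of the per-document correctness indicators
    ca <- as.numeric(preds_a == gold)
    cb <- as.numeric(preds_b == gold)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      diffs[b] <- mean(ca[idx]) - mean(cb[idx])
    }
  } else {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      diffs[b] <- f1_of(gold[idx], preds_a[idx]) - f1_of(gold[idx], preds_b[idx])
    }
  }
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    stat <- NA_real_; pval <- NA_real_
  } else {
    stat <- mean(diffs) / stats::sd(diffs)
    pval <- 2 * stats::pt(-abs(stat), df = n - 1)
  }
  tibble::tibble(mean_diff = mean(diffs), statistic = stat, p_value = pval,
                 significant = !degenerate && pval < 0.05,
                 n = n, n_boot = n_boot, degenerate = degenerate)
}

#' Report the documents where rules and model disagree
#'
#' Lists exactly the documents on which the rule labeler and the trained
#' model disagree, marks which system got each one right against gold, and
#' tallies the wins (the "model correct on 5 of 7 disagreements" style of
#' error analysis). On every listed case the two systems differ, and
#' `model_right + rules_right + both_wrong` equals the number of
#' disagreements.
#'
#' @param corpus Corpus tibble carrying gold labels in `label`.
#' @param rule_labels Character vector of rule-assigned labels, aligned with
#'   the corpus rows (or a labeled corpus from [label_corpus()], in which
#'   case its `weak_label` column is used after id alignment).
#' @param model_labels Character vector of model predictions, aligned with
#'   the corpus rows.
#' @return A list of class `weaktext_disagreement`: `cases` (tibble with id,
#'   text, gold, rule, model, winner) and `tally` (named counts).
#' @export
disagreement_report <- function(corpus, rule_labels, model_labels) {
  corpus <- as_corpus(corpus)
  if (is.data.frame(rule_labels)) {
    if (!"weak_label" %in% names(rule_labels) ||
        !identical(rule_labels$id, corpus$id))
      stop("rule labels misaligned with the corpus ids", call. = FALSE)
    rule_labels <- rule_labels$weak_label
  }
  if (length(rule_labels) != nrow(corpus) || length(model_labels) != nrow(corpus))
    stop("label vectors must align with the corpus", call. = FALSE)
  if (anyNA(corpus$label))
    stop("the corpus must carry gold labels", call. = FALSE)
  dis <- which(rule_labels != model_labels)
  winner <- dplyr::case_when(
    model_labels[dis] == corpus$label[dis] ~ "model",
    rule_labels[dis] == corpus$label[dis] ~ "rules",
    TRUE ~ "neither")
  cases <- tibble::tibble(id = corpus$id[dis], text = corpus$text[dis],
                          gold = corpus$label[dis], rule = rule_labels[dis],
                          model = model_labels[dis], winner = winner)
  tally <- c(model_right = sum(winner == "model"),
             rules_right = sum(winner == "rules"),
             both_wrong = sum(winner == "neither"),
             disagreements = length(dis))
  structure(list(cases = cases, tally = tally),
            class = "weaktext_disagreement")
}

#' @export
print.weaktext_disagreement <- function(x, ...) {
  t <- x$tally
  cat("<disagreement report: ", t[["disagreements"]], " cases; model right on ",
      t[["model_right"]], ", rules right on ", t[["rules_right"]],
      ", both wrong on ", t[["both_wrong"]], ">\n", sep = "")
  invisible(x)
}

#' Write a disagreement report as TSV
#'
#' @param report A `weaktext_disagreement`.
#' @param path Output path.
#' @export
write_disagreements <- function(report, path) {
  utils::write.table(report$cases, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
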