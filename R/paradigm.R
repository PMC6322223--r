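#' Run the full weak-supervision paradigm end to end
#'
#' The single entry point for the pipeline: (1) the rule set weak-labels the
#' training corpus; (2) the featurizer is fitted on training text only;
#' (3) a classifier is trained on (features, weak labels); (4) the test
#' corpus is predicted; (5) both the model and the rule labeler are evaluated
#' against the test corpus' gold labels, and their disagreements are
#' tabulated. Training documents need no gold labels; the test corpus must
#' carry them.
#'
#' When the weak labels coincide with gold labels (perfect rules), the run is
#' exactly supervised learning: weak supervision reduces to supervision.
#'
#' @param train_corpus Corpus tibble (gold labels not required).
#' @param test_corpus Corpus tibble with gold labels in `label`.
#' @param rs A `weaktext_ruleset`.
#' @param spec A [classifier_spec()].
#' @param features Feature mode for non-CNN classifiers (`"embedding_mean"`,
#'   `"tfidf"`, `"topic"`); the CNN consumes token sequences directly through
#'   its embedding layer.
#' @param table Embedding table (required for `"embedding_mean"`; the CNN
#'   takes its table from `spec`).
#' @param seed Integer seed for the featurizer (topic mode).
#' @param ... Passed to [fit_featurizer()].
#' @return An object of class `weaktext_paradigm`: `model`, `predictions`
#'   (tibble id/gold/rule/model), `model_eval` and `rule_eval`
#'   (`weaktext_eval`), `disagreements`, `weak_train` (the weak-labeled
#'   training corpus), `featurizer`.
#' @export
run_paradigm <- function(train_corpus, test_corpus, rs, spec,
                         features = c("embedding_mean", "tfidf", "topic"),
                         table = NULL, seed = NULL, ...) {
  features <- match.arg(features)
  train_corpus <- as_corpus(train_corpus)
  test_corpus <- as_corpus(test_corpus)
  if (anyNA(test_corpus$label))
    stop("the test corpus must carry gold labels", call. = FALSE)
  weak_train <- label_corpus(train_corpus, rs)
  rule_test <- label_corpus(test_corpus, rs)
  if (spec$kind == "cnn") {
    featurizer <- NULL
    model <- train_classifier(weak_train, weak_train$weak_label, spec)
    preds <- predict(model, test_corpus)
  } else {
    featurizer <- fit_featurizer(train_corpus, mode = features, table = table,
                                 seed = seed, ...)
    x_train <- featurize(train_corpus, featurizer)
    model <- train_classifier(x_train, weak_train$weak_label, spec)
    preds <- predict(model, featurize(test_corpus, featurizer))
  }
  labels <- rs$labels
  model_eval <- prf(test_corpus$label, preds,
                    labels = union(labels, unique(c(test_corpus$label, preds))))
  rule_eval <- prf(test_corpus$label, rule_test$weak_label,
                   labels = union(labels, unique(test_corpus$label)))
  dis <- disagreement_report(test_corpus, rule_test$weak_label, preds)
  structure(list(model = model,
                 predictions = tibble::tibble(id = test_corpus$id,
                                              gold = test_corpus$label,
                                              rule = rule_test$weak_label,
                                              model = preds),
                 model_eval = model_eval, rule_eval = rule_eval,
                 disagreements = dis, weak_train = weak_train,
                 featurizer = featurizer),
            class = "weaktext_paradigm")
}

#' @export
print.weaktext_paradigm <- function(x, ...) {
  cat("<weak-supervision paradigm run: ", x$model$spec$kind, " on ",
      x$model$n_train, " weakly labeled documents>\n", sep = "")
  cat(sprintf("  model vs gold: P %.3f R %.3f F1 %.3f\n",
              x$model_eval$precision, x$model_eval$recall, x$model_eval$f1))
  cat(sprintf("  rules vs gold: P %.3f R %.3f F1 %.3f\n",
              x$rule_eval$precision, x$rule_eval$recall, x$rule_eval$f1))
  print(x$disagreements)
  invisible(x)
}

#' Training-size study of the paradigm
#'
#' Re-runs [run_paradigm()] on nested random subsamples of the training
#' corpus and reports model and rule F1 at each size — the data-size
#' sensitivity study, replicated on synthetic corpora.
#'
#' @inheritParams run_paradigm
#' @param sizes Integer vector of training sizes.
#' @param seed Seed for the subsampling.
#' @return A tibble of class `weaktext_curve` with columns `size`,
#'   `model_f1`, `rule_f1`.
#' @export
learning_curve <- function(train_corpus, test_corpus, rs, spec,
                           sizes, features = "embedding_mean",
                           table = NULL, seed = 1, ...) {
  train_corpus <- as_corpus(train_corpus)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ord <- sample.int(nrow(train_corpus))
  rows <- lapply(sizes, function(n) {
    sub <- train_corpus[ord[seq_len(min(n, nrow(train_corpus)))], , drop = FALSE]
    run <- run_paradigm(sub, test_corpus, rs, spec, features = features,
                        table = table, seed = seed, ...)
    tibble::tibble(size = n, model_f1 = run$model_eval$f1,
                   rule_f1 = run$rule_eval$f1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weaktext_curve", class(out))
  out
}

#' Split a corpus into train and test partitions
#'
#' @param corpus A corpus tibble.
#' @param n_test Number of held-out test documents.
#' @param seed Integer seed.
#' @return A list with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus, n_test, seed = 1) {
  corpus <- as_corpus(corpus)
  if (n_test >= nrow(corpus)) stop("`n_test` must be smaller than the corpus", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  idx <- sample.int(nrow(corpus), n_test)
  list(train = corpus[-idx, , drop = FALSE], test = corpus[idx, , drop = FALSE])
}
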