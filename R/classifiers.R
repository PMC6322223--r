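#' Classifier specification
#'
#' Hyperparameters default to the paradigm's fixed settings: linear SVM with
#' cost C = 10; random forest with 5 trees; a single-hidden-layer perceptron
#' with 15 rectified-linear units trained with RMSprop on the cross-entropy;
#' and a text CNN (embedding layer initialized from a pre-trained table, one
#' width-3 convolution layer with 128 rectified-linear filters, global max
#' pooling, fully-connected softmax output, categorical cross-entropy,
#' RMSprop). No hyperparameter search is performed.
#'
#' @param kind One of `"svm_linear"`, `"random_forest"`, `"mlp"`, `"cnn"`.
#' @param cost SVM cost parameter C.
#' @param trees Number of random-forest trees.
#' @param hidden MLP hidden-layer width.
#' @param filters CNN convolution filters.
#' @param window CNN convolution window (tokens).
#' @param max_len CNN sequence length; token-index sequences are padded or
#'   truncated to this many tokens.
#' @param table Embedding table for the CNN embedding layer.
#' @param freeze_embeddings Keep the CNN embedding layer fixed at the
#'   pre-trained vectors (default `FALSE`: trainable).
#' @param epochs,batch_size,learning_rate,decay Optimizer settings for the
#'   neural models (documented defaults, not tuned).
#' @param seed Integer seed; mandatory for `"random_forest"`, `"mlp"` and
#'   `"cnn"`.
#' @return A `weaktext_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_linear", "random_forest", "mlp", "cnn"),
                            cost = 10, trees = 5, hidden = 15,
                            filters = 128, window = 3, max_len = 100,
                            table = NULL, freeze_embeddings = FALSE,
                            epochs = 30, batch_size = 32,
                            learning_rate = 0.01, decay = 0.9, seed = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("random_forest", "mlp", "cnn") && is.null(seed))
    stop("`seed` is mandatory for ", kind, call. = FALSE)
  if (kind == "cnn" && is.null(table))
    stop("the cnn requires an embedding table bound via `table`", call. = FALSE)
  structure(list(kind = kind, cost = cost, trees = trees, hidden = hidden,
                 filters = filters, window = window, max_len = max_len,
                 table = table, freeze_embeddings = freeze_embeddings,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, decay = decay, seed = seed),
            class = "weaktext_classifier_spec")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "weaktext_features")) x$x
  else if (is.matrix(x)) x
  else stop("expected a feature matrix or weaktext_features object", call. = FALSE)
}

#' Train a classifier on (features, labels)
#'
#' For `"svm_linear"`, `"random_forest"` and `"mlp"` the input is a feature
#' matrix (or [featurize()] output); for `"cnn"` it is a list of token
#' vectors (or a corpus tibble, tokenized internally), which are mapped to
#' index sequences over the bound embedding table's vocabulary and padded or
#' truncated to the spec's `max_len`. Training is reproducible given
#' (data, spec, seed).
#'
#' @param x Features or token sequences (see above).
#' @param labels Character vector of (weak or gold) labels; at least 2
#'   distinct classes are required.
#' @param spec A [classifier_spec()].
#' @return A `weaktext_model`; use [predict()] on new inputs of the same
#'   feature mode, and [tidy()]/[glance()] for summaries.
#' @export
train_classifier <- function(x, labels, spec) {
  if (!inherits(spec, "weaktext_classifier_spec"))
    stop("`spec` must come from classifier_spec()", call. = FALSE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("training labels contain a single class; at least 2 are required",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$kind == "cnn") {
    seqs <- cnn_sequences(x, spec)
    fit <- cnn_train(seqs, factor(labels, levels = classes), spec)
    mode <- "tokens"; dim <- NA_integer_
  } else {
    xm <- as_feature_matrix(x)
    if (nrow(xm) != length(labels))
      stop("feature/label length mismatch", call. = FALSE)
    y <- factor(labels, levels = classes)
    fit <- switch(spec$kind,
      svm_linear = e1071::svm(xm, y, kernel = "linear", cost = spec$cost,
                              scale = FALSE),
      random_forest = randomForest::randomForest(xm, y, ntree = spec$trees),
      mlp = mlp_train(xm, y, spec))
    mode <- "matrix"; dim <- ncol(xm)
  }
  structure(list(spec = spec, fit = fit, classes = classes,
                 input_mode = mode, dim = dim,
                 n_train = if (spec$kind == "cnn") length(labels) else nrow(as_feature_matrix(x)),
                 seed = spec$seed),
            class = "weaktext_model")
}

#' @export
print.weaktext_model <- function(x, ...) {
  cat("<weaktext model: ", x$spec$kind, ", classes {",
      paste(x$classes, collapse = ", "), "}, trained on n = ", x$n_train,
      ">\n", sep = "")
  invisible(x)
}

#' Predict labels with a trained model
#'
#' @param object A `weaktext_model`.
#' @param newdata Features (matrix / [featurize()] output) or, for the CNN,
#'   token sequences or a corpus tibble. An empty input gives an empty
#'   output.
#' @param ... Unused.
#' @return Character vector of predicted labels, each in the bound label
#'   set; deterministic for a fixed model.
#' @export
predict.weaktext_model <- function(object, newdata, ...) {
  if (object$input_mode == "tokens") {
    seqs <- cnn_sequences(newdata, object$spec)
    if (length(seqs) == 0) return(character(0))
    return(object$classes[cnn_predict(object$fit, seqs)])
  }
  xm <- as_feature_matrix(newdata)
  if (nrow(xm) == 0) return(character(0))
  if (ncol(xm) != object$dim)
    stop("feature dimension ", ncol(xm), " does not match the model's bound ",
         "dimension ", object$dim, call. = FALSE)
  out <- switch(object$spec$kind,
    svm_linear = as.character(stats::predict(object$fit, xm)),
    random_forest = as.character(stats::predict(object$fit, xm)),
    mlp = object$classes[mlp_predict(object$fit, xm)])
  out
}

# ---- native multilayer perceptron ----------------------------------------
# One hidden layer of rectified-linear units, softmax output, categorical
# cross-entropy, RMSprop. Implemented natively: no installed R package
# provides a ReLU single-hidden-layer network.

mlp_train <- function(x, y, spec) {
  n <- nrow(x); d <- ncol(x); h <- spec$hidden; L <- nlevels(y)
  yi <- as.integer(y)
  sc <- pmax(apply(x, 2, stats::sd), 1e-8)
  ct <- colMeans(x)
  xs <- sweep(sweep(x, 2, ct), 2, sc, "/")
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h); b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * L, sd = sqrt(2 / h)), h, L); b2 <- numeric(L)
  cache <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  lr <- spec$learning_rate; dc <- spec$decay; epsv <- 1e-8
  onehot <- matrix(0, n, L); onehot[cbind(seq_len(n), yi)] <- 1
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      xb <- xs[idx, , drop = FALSE]; tb <- onehot[idx, , drop = FALSE]
      m <- length(idx)
      z1 <- sweep(xb %*% W1, 2, b1, "+")
      a1 <- pmax(z1, 0)
      z2 <- sweep(a1 %*% W2, 2, b2, "+")
      z2 <- z2 - apply(z2, 1, max)
      pr <- exp(z2); pr <- pr / rowSums(pr)
      dz2 <- (pr - tb) / m
      gW2 <- crossprod(a1, dz2); gb2 <- colSums(dz2)
      da1 <- dz2 %*% t(W2); dz1 <- da1 * (z1 > 0)
      gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
      upd <- function(p, g, key) {
        cache[[key]] <<- dc * cache[[key]] + (1 - dc) * g^2
        p - lr * g / (sqrt(cache[[key]]) + epsv)
      }
      W1 <- upd(W1, gW1, "W1"); b1 <- upd(b1, gb1, "b1")
      W2 <- upd(W2, gW2, "W2"); b2 <- upd(b2, gb2, "b2")
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = ct, scale = sc)
}

mlp_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  a1 <- pmax(sweep(xs %*% fit$W1, 2, fit$b1, "+"), 0)
  z2 <- sweep(a1 %*% fit$W2, 2, fit$b2, "+")
  max.col(z2, ties.method = "first")
}
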