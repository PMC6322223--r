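test_that("the linear SVM separates separable blobs and is reproducible", {
  d <- gaussian_blobs(200, seed = 101)
  m <- train_classifier(d$x, d$y, classifier_spec("svm_linear"))
  expect_equal(mean(predict(m, d$x) == d$y), 1)        # training accuracy 1.0

  m2 <- train_classifier(d$x, d$y, classifier_spec("svm_linear"))
  probe <- gaussian_blobs(50, seed = 102)$x
  expect_identical(predict(m, probe), predict(m2, probe))
})

test_that("permuted labels give chance-level holdout accuracy", {
  d <- gaussian_blobs(400, seed = 103)
  set.seed(104)
  yperm <- sample(d$y)
  tr <- 1:300; te <- 301:400
  m <- train_classifier(d$x[tr, ], yperm[tr], classifier_spec("svm_linear"))
  acc <- mean(predict(m, d$x[te, ]) == yperm[te])
  se <- sqrt(0.25 / length(te))
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("random forest and MLP train reproducibly with mandatory seeds", {
  d <- gaussian_blobs(200, seed = 105)
  expect_error(classifier_spec("random_forest"), "seed")
  expect_error(classifier_spec("mlp"), "seed")

  for (kind in c("random_forest", "mlp")) {
    m1 <- train_classifier(d$x, d$y, classifier_spec(kind, seed = 7))
    m2 <- train_classifier(d$x, d$y, classifier_spec(kind, seed = 7))
    expect_identical(predict(m1, d$x), predict(m2, d$x))
    expect_gt(mean(predict(m1, d$x) == d$y), 0.95)
  }
})

test_that("training and prediction validate their inputs", {
  d <- gaussian_blobs(60, seed = 106)
  expect_error(train_classifier(d$x, rep("one", 60),
                                classifier_spec("svm_linear")),
               "single class")
  m <- train_classifier(d$x, d$y, classifier_spec("svm_linear"))
  expect_error(predict(m, d$x[, 1:2]), "dimension")
  expect_identical(predict(m, d$x[0, , drop = FALSE]), character(0))
})

test_that("models survive serialization with identical predictions", {
  d <- gaussian_blobs(120, seed = 107)
  m <- train_classifier(d$x, d$y, classifier_spec("random_forest", seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  back <- readRDS(f)
  expect_identical(predict(back, d$x), predict(m, d$x))
})

test_that("relabeling categories permutes predictions consistently", {
  d <- gaussian_blobs(150, seed = 108)
  ren <- c(pos = "case", neg = "control")
  m1 <- train_classifier(d$x, d$y, classifier_spec("svm_linear"))
  m2 <- train_classifier(d$x, unname(ren[d$y]), classifier_spec("svm_linear"))
  expect_identical(unname(ren[predict(m1, d$x)]), predict(m2, d$x))
})

test_that("the CNN gradients match numerical differentiation", {
  toks <- paste0("t", 1:12)
  tab <- random_embeddings(toks, k = 4, seed = 200)
  spec <- classifier_spec("cnn", table = tab, filters = 3, max_len = 6,
                          seed = 1)
  set.seed(201)
  par <- weaktext:::cnn_init(spec, n_classes = 3)
  seq_idx <- c(3L, 5L, 2L, 9L, 1L, 7L)
  y <- 2L
  g <- weaktext:::cnn_loss_grad(par, seq_idx, y)
  eps <- 1e-6
  num_grad <- function(get, set) {
    p0 <- get(par)
    up <- par; up <- set(up, p0 + eps)
    dn <- par; dn <- set(dn, p0 - eps)
    (weaktext:::cnn_loss_grad(up, seq_idx, y)$loss -
       weaktext:::cnn_loss_grad(dn, seq_idx, y)$loss) / (2 * eps)
  }
  # spot-check entries of every parameter block
  for (idx in list(c(1, 2), c(2, 7), c(3, 11))) {
    num <- num_grad(function(p) p$W[idx[1], idx[2]],
                    function(p, v) { p$W[idx[1], idx[2]] <- v; p })
    expect_equal(g$gW[idx[1], idx[2]], num, tolerance = 1e-4)
  }
  num <- num_grad(function(p) p$b[2], function(p, v) { p$b[2] <- v; p })
  expect_equal(g$gb[2], num, tolerance = 1e-4)
  num <- num_grad(function(p) p$W2[1, 3], function(p, v) { p$W2[1, 3] <- v; p })
  expect_equal(g$gW2[1, 3], num, tolerance = 1e-4)
  num <- num_grad(function(p) p$b2[2], function(p, v) { p$b2[2] <- v; p })
  expect_equal(g$gb2[2], num, tolerance = 1e-4)
  # embedding gradient for a token used in the sequence (row 5 = token t4+1)
  row <- 5L; col <- 2L
  key <- as.character(row)
  if (!is.null(g$gE[[key]])) {
    num <- num_grad(function(p) p$E[row, col],
                    function(p, v) { p$E[row, col] <- v; p })
    expect_equal(g$gE[[key]][col], num, tolerance = 1e-4)
  }
})

test_that("the CNN learns a tiny cue-word task end to end", {
  cue_pos <- paste0("p", 1:4); cue_neg <- paste0("n", 1:4)
  fill <- paste0("f", 1:12)
  tab <- random_embeddings(c(cue_pos, cue_neg, fill), k = 8, seed = 300)
  set.seed(301)
  make_doc <- function(cue) paste(sample(c(cue, sample(fill, 4))), collapse = " ")
  n <- 60
  y <- rep(c("yes", "no"), length.out = n)
  txt <- vapply(y, function(l)
    make_doc(if (l == "yes") sample(cue_pos, 1) else sample(cue_neg, 1)),
    character(1))
  cp <- corpus(id = paste0("d", 1:n), text = txt, label = y)
  spec <- classifier_spec("cnn", table = tab, filters = 16, max_len = 8,
                          epochs = 40, seed = 5)
  m <- train_classifier(cp, cp$label, spec)
  expect_gt(mean(predict(m, cp) == cp$label), 0.9)
  m2 <- train_classifier(cp, cp$label, spec)
  expect_identical(predict(m2, cp), predict(m, cp))
  expect_error(classifier_spec("cnn", seed = 1), "table")
})

test_that("run_paradigm wires rules, features, training and evaluation", {
  b <- generate_corpus(generator_config("smoking_binary", n = 500, seed = 400))
  emb <- generate_embeddings(b, k = 25, seed = 401)
  sp <- split_corpus(b$corpus, n_test = 100, seed = 402)
  run <- run_paradigm(sp$train, sp$test, load_builtin("mayo_smoking"),
                      classifier_spec("svm_linear"), table = emb)
  expect_s3_class(run$model_eval, "weaktext_eval")
  expect_s3_class(run$rule_eval, "weaktext_eval")
  expect_equal(nrow(run$predictions), 100)
  expect_true(all(c("precision", "recall", "f1") %in%
                    names(glance(run$model_eval))))

  # on a clean corpus the rules are perfect, so weak supervision is exactly
  # supervised learning: the weak labels equal gold
  expect_identical(run$weak_train$weak_label, run$weak_train$label)
  gold_model <- train_classifier(
    featurize(sp$train, run$featurizer), sp$train$label,
    classifier_spec("svm_linear"))
  expect_identical(predict(gold_model, featurize(sp$test, run$featurizer)),
                   run$predictions$model)

  unlabeled <- sp$test
  unlabeled$label <- NA_character_
  expect_error(run_paradigm(sp$train, unlabeled, load_builtin("mayo_smoking"),
                            classifier_spec("svm_linear"), table = emb),
               "gold")
})

test_that("learning curves track training size for model and rules", {
  b <- generate_corpus(generator_config("smoking_binary", n = 700,
                                        p_miss = 0.1, seed = 500))
  emb <- generate_embeddings(b, k = 25, seed = 501)
  sp <- split_corpus(b$corpus, n_test = 150, seed = 502)
  cv <- learning_curve(sp$train, sp$test, load_builtin("mayo_smoking"),
                       classifier_spec("svm_linear"),
                       sizes = c(100, 400), table = emb, seed = 503)
  expect_equal(cv$size, c(100, 400))
  expect_true(all(cv$model_f1 >= 0 & cv$model_f1 <= 1))
  expect_equal(length(unique(cv$rule_f1)), 1)   # rules don't depend on n_train
})
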