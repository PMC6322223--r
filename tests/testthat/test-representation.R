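test_that("tokenization lowercases and strips punctuation", {
  expect_equal(tokenize("No smoking after age 40")[[1]],
               c("no", "smoking", "after", "age", "40"))
  expect_equal(tokenize("tobacco use: yes")[[1]], c("tobacco", "use", "yes"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_identical(tokenize("a-b c"), tokenize("a-b c"))
})

test_that("mean-pooled embeddings follow the averaging contract", {
  tab <- tiny_embeddings()
  expect_equal(as.numeric(embed_mean("a", tab)), c(1, 2))
  expect_equal(as.numeric(embed_mean(c("a", "b"), tab)), c(2, 3))

  v <- embed_mean(c("a", "zzz", "b"), tab)
  expect_equal(as.numeric(v), c(2, 3))      # OOV skipped, not zero-imputed
  expect_equal(attr(v, "oov_count"), 1)
  expect_equal(attr(v, "matched_count"), 2)

  allv <- embed_mean(c("xx", "yy"), tab)
  expect_equal(as.numeric(allv), c(0, 0))
  expect_true(attr(allv, "degenerate"))
})

test_that("mean pooling matches a direct-summation oracle and its algebra", {
  toks <- paste0("w", 1:40)
  tab <- random_embeddings(toks, k = 7, seed = 42)
  set.seed(43)
  doc <- sample(c(toks, paste0("oov", 1:10)), 50, replace = TRUE)
  got <- embed_mean(doc, tab)
  # independent brute-force summation
  acc <- numeric(7); m <- 0
  for (t in doc) if (t %in% rownames(tab)) {
    acc <- acc + unclass(tab)[t, ]; m <- m + 1
  }
  expect_equal(as.numeric(got), acc / m, tolerance = 1e-12)
  expect_equal(attr(got, "matched_count"), m)

  # permutation invariance
  expect_equal(as.numeric(embed_mean(rev(doc), tab)), as.numeric(got))
  # linear scaling: doubling every vector doubles the feature
  tab2 <- embedding_table(unclass(tab) * 2)
  expect_equal(as.numeric(embed_mean(doc, tab2)), 2 * as.numeric(got))
})

test_that("tf-idf follows the smoothed, L2-normalized definition", {
  cp <- corpus(id = paste0("d", 1:2), text = c("smoking", "smoking"))
  fz <- fit_featurizer(cp, "tfidf")
  ft <- featurize(cp, fz)
  expect_equal(as.numeric(ft$x[1, ]), 1)    # single-word docs -> unit vector

  cp5 <- corpus(id = paste0("d", 1:5),
                text = c("smoking cessation advised", "no smoking",
                         "patient smokes", "smoking smoking heavy",
                         "exercise advised"))
  fz5 <- fit_featurizer(cp5, "tfidf")
  ft5 <- featurize(cp5, fz5)
  vocab <- fz5$vocab
  expect_equal(vocab, sort(c("advised", "cessation", "exercise", "heavy",
                             "no", "patient", "smokes", "smoking")))
  # frozen oracle values (independent hand computation of tf * idf, L2-norm)
  expect_equal(as.numeric(ft5$x[1, match(c("advised", "cessation", "smoking"),
                                         vocab)]),
               c(0.5568161504, 0.6901592663, 0.4622077041), tolerance = 1e-9)
  expect_equal(as.numeric(ft5$x[4, match(c("heavy", "smoking"), vocab)]),
               c(0.5982497697, 0.8013096861), tolerance = 1e-9)
  # idf monotonicity: ubiquitous words weigh less than rare ones
  expect_lt(fz5$idf[match("smoking", vocab)], fz5$idf[match("heavy", vocab)])
  # rows have unit norm when non-zero; unseen words contribute nothing
  expect_equal(sqrt(rowSums(ft5$x^2)), rep(1, 5), ignore_attr = TRUE)
  new <- featurize(corpus(id = "t", text = "smoking unseen words"), fz5)
  expect_equal(sum(new$x != 0), 1)
  expect_error(featurize(cp5, "tfidf"), "fit_featurizer")
})

test_that("topic features live on the simplex and separate disjoint vocabularies", {
  half1 <- paste("alpha beta gamma delta", c("alpha beta", "gamma alpha"))
  half2 <- paste("omega sigma theta kappa", c("omega sigma", "theta omega"))
  cp <- corpus(id = paste0("d", 1:8),
               text = rep(c(half1, half2), 2))
  fz <- fit_featurizer(cp, "topic", k = 2, seed = 5, iterations = 80)
  ft <- featurize(cp, fz)
  expect_equal(rowSums(ft$x), rep(1, 8), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(ft$x >= 0))
  # documents from the two disjoint halves land nearer different topic axes
  t1 <- max.col(ft$x[cp$text %in% half1, , drop = FALSE])
  t2 <- max.col(ft$x[cp$text %in% half2, , drop = FALSE])
  expect_equal(length(unique(t1)), 1)
  expect_equal(length(unique(t2)), 1)
  expect_false(unique(t1) == unique(t2))

  refit <- featurize(cp, fit_featurizer(cp, "topic", k = 2, seed = 5,
                                        iterations = 80))
  expect_identical(ft$x, refit$x)          # seeded determinism
  expect_error(fit_featurizer(cp, "topic", k = 1, seed = 1), "at least 2")
})

test_that("nearest neighbors rank by cosine with lexicographic ties", {
  m <- rbind(a = c(1, 1), b = c(2, 2), c = c(1, 0), d = c(0, 1))
  tab <- embedding_table(m)
  nn <- nearest_neighbors("a", tab, 3)
  expect_equal(nn$token[1], "b")            # colinear vector ranks first
  expect_equal(nn$similarity[1], 1, tolerance = 1e-12)
  expect_equal(nn$token[2:3], c("c", "d"))  # equal similarity -> alphabetical
  expect_equal(nn$similarity[2], nn$similarity[3])

  ortho <- embedding_table(rbind(x = c(1, 0), y = c(0, 1)))
  expect_equal(nearest_neighbors("x", ortho, 1)$similarity, 0)

  expect_error(nearest_neighbors("ghost", tab, 1), "ghost")
})

test_that("featurize reports per-document diagnostics", {
  cp <- corpus(id = c("a", "b"), text = c("a b", "zz qq"))
  ft <- featurize(cp, fit_featurizer(cp, "embedding_mean",
                                     table = tiny_embeddings()))
  expect_equal(ft$info$oov_count, c(0L, 2L))
  expect_equal(ft$info$degenerate, c(FALSE, TRUE))
  expect_equal(rownames(ft$x), c("a", "b"))
})

test_that("feature matrices export to TSV/MTX and featurizers persist", {
  cp <- corpus(id = c("a", "b", "c"),
               text = c("no smoking", "smokes daily", "no news"))
  fz <- fit_featurizer(cp, "tfidf")
  ft <- featurize(cp, fz)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features(ft, tsv, "tsv")
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(back$id, cp$id)
  expect_equal(as.matrix(back[, -1]), ft$x, ignore_attr = TRUE,
               tolerance = 1e-12)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_features(ft, mtx, "mtx")
  m <- as.matrix(Matrix::readMM(mtx))
  expect_equal(m, ft$x, ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(readLines(paste0(mtx, ".cols")), fz$vocab)

  arc <- withr::local_tempfile(fileext = ".rds")
  save_featurizer(fz, arc)
  fz2 <- load_featurizer(arc)
  expect_identical(featurize(cp, fz2)$x, ft$x)
  saveRDS(list(other = 1), arc)
  expect_error(load_featurizer(arc), "archive")
})
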