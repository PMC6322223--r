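#' Tokenize text
#'
#' Lowercases and splits on runs of non-alphanumeric characters. Punctuation
#' carries no weight at the bag-of-words level here — the rule engine, not the
#' featurizer, is where punctuation-sensitive patterns live.
#'
#' @param text Character vector.
#' @return A list of character token vectors, one per input element; empty
#'   text gives an empty vector.
#' @export
tokenize <- function(text) {
  out <- stringr::str_split(tolower(text), "[^a-z0-9]+")
  lapply(out, function(t) t[t != ""])
}

#' Mean-pooled word-embedding document feature
#'
#' The document representation is the arithmetic mean of the embedding
#' vectors of its in-vocabulary tokens: x = (1/M') * sum_i x_i, where M' is
#' the number of tokens found in the table. Out-of-vocabulary tokens are
#' skipped (they are counted in `oov_count` but contribute nothing); a
#' document whose tokens are all out of vocabulary gets the zero vector with
#' `degenerate = TRUE`.
#'
#' @param tokens Character vector of tokens (e.g. one element of
#'   [tokenize()]'s output).
#' @param table A `weaktext_embeddings` table.
#' @return A numeric vector of length `embedding_dim(table)` with attributes
#'   `token_count` (M, all tokens), `matched_count` (M'), `oov_count`, and
#'   `degenerate`.
#' @export
embed_mean <- function(tokens, table) {
  if (nrow(table) == 0) stop("empty embedding table", call. = FALSE)
  vecs <- embedding_lookup(table, tokens)
  m2 <- nrow(vecs)
  x <- if (m2 == 0) numeric(ncol(table)) else colMeans(vecs)
  x <- as.numeric(x)
  attr(x, "token_count") <- length(tokens)
  attr(x, "matched_count") <- m2
  attr(x, "oov_count") <- length(attr(vecs, "oov"))
  attr(x, "degenerate") <- m2 == 0
  x
}

new_features <- function(x, mode, info) {
  structure(list(x = x, mode = mode, info = info), class = "weaktext_features")
}

#' @export
print.weaktext_features <- function(x, ...) {
  cat("<", x$mode, " features: ", nrow(x$x), " documents x ", ncol(x$x),
      " dimensions>\n", sep = "")
  invisible(x)
}

#' Fit a document featurizer on a training corpus
#'
#' Three feature modes cover the paradigm's representations:
#'
#' * `"embedding_mean"` — mean-pooled word embeddings (requires `table`);
#'   dimension k is the embedding dimension (the paradigm default is 100).
#' * `"tfidf"` — term frequency x smoothed inverse document frequency,
#'   `tf(w, d) * (ln((1 + N) / (1 + df(w))) + 1)`, L2-normalized per
#'   document; dimension is the training vocabulary size and unseen words
#'   contribute 0 at transform time.
#' * `"topic"` — latent Dirichlet allocation with `k` topics (default 100,
#'   matching the embedding dimension) fitted by a seeded collapsed Gibbs
#'   sampler with symmetric priors alpha = 50/k and eta = 0.01; the document
#'   feature is the mean over in-vocabulary tokens of each word's topic
#'   mixture, so it lies on the probability simplex.
#'
#' @param corpus A corpus tibble (at least 1 document).
#' @param mode One of `"embedding_mean"`, `"tfidf"`, `"topic"`.
#' @param table Embedding table (required for `"embedding_mean"`).
#' @param k Number of topics for `"topic"` (>= 2).
#' @param seed Integer seed (mandatory for `"topic"`).
#' @param iterations Gibbs sweeps for `"topic"`.
#' @param alpha,eta Symmetric Dirichlet priors for `"topic"`; `alpha`
#'   defaults to 50/k.
#' @return A `weaktext_featurizer` to pass to [featurize()].
#' @export
fit_featurizer <- function(corpus, mode = c("embedding_mean", "tfidf", "topic"),
                           table = NULL, k = 100, seed = NULL,
                           iterations = 150, alpha = NULL, eta = 0.01) {
  mode <- match.arg(mode)
  fz <- switch(mode,
    embedding_mean = {
      if (is.null(table)) stop("embedding_mean requires an embedding table", call. = FALSE)
      list(mode = mode, table = table, dim = embedding_dim(table))
    },
    tfidf = fit_tfidf_state(corpus),
    topic = fit_topics_state(corpus, k = k, seed = seed,
                             iterations = iterations, alpha = alpha, eta = eta)
  )
  structure(fz, class = "weaktext_featurizer")
}

#' @export
print.weaktext_featurizer <- function(x, ...) {
  cat("<featurizer: ", x$mode, ", dimension ", x$dim, ">\n", sep = "")
  invisible(x)
}

#' Transform a corpus into a feature matrix
#'
#' @param corpus A corpus tibble.
#' @param featurizer A fitted `weaktext_featurizer`.
#' @return A `weaktext_features` object: `x` is the n x dim numeric matrix
#'   (rows named by document id), `info` a per-document diagnostics tibble
#'   (`token_count`, `oov_count`, `degenerate`).
#' @export
featurize <- function(corpus, featurizer) {
  if (!inherits(featurizer, "weaktext_featurizer"))
    stop("`featurizer` must come from fit_featurizer()", call. = FALSE)
  corpus <- as_corpus(corpus)
  toks <- tokenize(corpus$text)
  n <- nrow(corpus)
  x <- matrix(0, nrow = n, ncol = featurizer$dim)
  info <- tibble::tibble(id = corpus$id, token_count = lengths(toks),
                         oov_count = 0L, degenerate = FALSE)
  for (i in seq_len(n)) {
    v <- switch(featurizer$mode,
                embedding_mean = embed_mean(toks[[i]], featurizer$table),
                tfidf = transform_tfidf_one(toks[[i]], featurizer),
                topic = transform_topics_one(toks[[i]], featurizer))
    x[i, ] <- v
    info$oov_count[i] <- attr(v, "oov_count")
    info$degenerate[i] <- attr(v, "degenerate")
  }
  rownames(x) <- corpus$id
  if (featurizer$mode == "tfidf") colnames(x) <- featurizer$vocab
  new_features(x, featurizer$mode, info)
}

# ---- tf-idf ---------------------------------------------------------------

fit_tfidf_state <- function(corpus) {
  corpus <- as_corpus(corpus)
  if (nrow(corpus) < 1) stop("tf-idf must be fitted on at least 1 document", call. = FALSE)
  toks <- tokenize(corpus$text)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) stop("tf-idf training corpus has no tokens", call. = FALSE)
  df <- table(factor(unlist(lapply(toks, unique)), levels = vocab))
  n <- nrow(corpus)
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  list(mode = "tfidf", vocab = vocab, idf = idf, n_docs = n,
       dim = length(vocab))
}

transform_tfidf_one <- function(tokens, fz) {
  known <- tokens[tokens %in% fz$vocab]
  v <- numeric(fz$dim)
  if (length(known) > 0) {
    tf <- table(factor(known, levels = fz$vocab))
    v <- as.numeric(tf) * fz$idf
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
  }
  attr(v, "token_count") <- length(tokens)
  attr(v, "oov_count") <- length(tokens) - length(known)
  attr(v, "degenerate") <- length(known) == 0
  v
}

# ---- LDA topic features ---------------------------------------------------

# Collapsed Gibbs sampler for latent Dirichlet allocation with symmetric
# priors. Small and seeded: reports are reproducible and the corpora this
# package targets (short snippets) keep the token count desk-scale.
fit_topics_state <- function(corpus, k, seed, iterations, alpha, eta) {
  if (k < 2) stop("the number of topics must be at least 2", call. = FALSE)
  if (is.null(seed)) stop("topic fitting requires a seed", call. = FALSE)
  if (is.null(alpha)) alpha <- 50 / k
  corpus <- as_corpus(corpus)
  toks <- tokenize(corpus$text)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) stop("topic training corpus has no tokens", call. = FALSE)
  wid <- lapply(toks, function(t) match(t, vocab))
  doc <- rep(seq_along(wid), lengths(wid))
  w <- unlist(wid)
  n_tok <- length(w)
  V <- length(vocab); D <- length(wid)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  z <- sample.int(k, n_tok, replace = TRUE)
  nwk <- matrix(0L, nrow = V, ncol = k)   # word-topic counts
  ndk <- matrix(0L, nrow = D, ncol = k)   # doc-topic counts
  nk <- integer(k)
  for (i in seq_len(n_tok)) {
    nwk[w[i], z[i]] <- nwk[w[i], z[i]] + 1L
    ndk[doc[i], z[i]] <- ndk[doc[i], z[i]] + 1L
    nk[z[i]] <- nk[z[i]] + 1L
  }
  for (it in seq_len(iterations)) {
    u <- stats::runif(n_tok)
    for (i in seq_len(n_tok)) {
      zi <- z[i]; wi <- w[i]; di <- doc[i]
      nwk[wi, zi] <- nwk[wi, zi] - 1L
      ndk[di, zi] <- ndk[di, zi] - 1L
      nk[zi] <- nk[zi] - 1L
      p <- (nwk[wi, ] + eta) / (nk + V * eta) * (ndk[di, ] + alpha)
      cp <- cumsum(p)
      zi <- findInterval(u[i] * cp[k], cp) + 1L
      if (zi > k) zi <- k
      z[i] <- zi
      nwk[wi, zi] <- nwk[wi, zi] + 1L
      ndk[di, zi] <- ndk[di, zi] + 1L
      nk[zi] <- nk[zi] + 1L
    }
  }
  # per-word topic mixture: p(topic | word), smoothed and normalized over topics
  wt <- (nwk + eta)
  wt <- wt / rowSums(wt)
  rownames(wt) <- vocab
  list(mode = "topic", vocab = vocab, word_topic = wt, k = k, dim = k,
       alpha = alpha, eta = eta, seed = seed, iterations = iterations)
}

transform_topics_one <- function(tokens, fz) {
  known <- tokens[tokens %in% fz$vocab]
  v <- if (length(known) == 0) numeric(fz$dim)
       else colMeans(fz$word_topic[known, , drop = FALSE])
  v <- as.numeric(v)
  attr(v, "token_count") <- length(tokens)
  attr(v, "oov_count") <- length(tokens) - length(known)
  attr(v, "degenerate") <- length(known) == 0
  v
}

# ---- nearest neighbors ----------------------------------------------------

#' Nearest neighbors of a token in embedding space
#'
#' Ranks the vocabulary by cosine similarity to the query token (query
#' excluded), with ties broken lexicographically. This is the report used to
#' inspect what the embedding space considers "semantically similar" — e.g.
#' misspellings such as "tobaco" landing next to "tobacco".
#'
#' @param token Query token (must be in the table's vocabulary).
#' @param table A `weaktext_embeddings` table.
#' @param n Number of neighbors (>= 1).
#' @return A tibble with columns `token` and `similarity`, most similar first.
#' @export
nearest_neighbors <- function(token, table, n = 5) {
  token <- tolower(token)
  if (!token %in% rownames(table))
    stop("token \"", token, "\" is out of vocabulary", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  m <- unclass(table)
  q <- m[token, ]
  qn <- sqrt(sum(q^2))
  norms <- sqrt(rowSums(m^2))
  sims <- as.numeric(m %*% q) / (norms * qn)
  sims[!is.finite(sims)] <- 0
  cand <- setdiff(rownames(m), token)
  sims <- unname(sims[match(cand, rownames(m))])
  ord <- order(-sims, cand)
  take <- utils::head(ord, n)
  tibble::tibble(token = cand[take], similarity = sims[take])
}

# Save/restore the global RNG so seeded internals do not perturb the caller's
# random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# ---- export / persistence -------------------------------------------------

#' Export a feature matrix
#'
#' Dense TSV (an `id` column followed by one named column per feature
#' dimension) or MatrixMarket MTX for sparse tf-idf matrices (row/column
#' names written to sidecar `.rows`/`.cols` files).
#'
#' @param features A `weaktext_features` object from [featurize()].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(features, "weaktext_features"))
  x <- features$x
  if (format == "tsv") {
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     row.names = NULL)
    if (is.null(colnames(x)))
      names(df)[-1] <- paste0(substr(features$mode, 1, 1), seq_len(ncol(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".rows"))
    if (!is.null(colnames(x))) writeLines(colnames(x), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Persist and restore a fitted featurizer
#'
#' The archive is an RDS carrying the fitted state plus a format version, so
#' a transform can be reproduced later against the identical vocabulary and
#' statistics.
#'
#' @param featurizer A `weaktext_featurizer`.
#' @param path Archive path.
#' @return `save_featurizer` returns `path` invisibly; `load_featurizer`
#'   returns the featurizer.
#' @export
save_featurizer <- function(featurizer, path) {
  stopifnot(inherits(featurizer, "weaktext_featurizer"))
  saveRDS(list(format = "weaktext_featurizer", version = 1L,
               state = unclass(featurizer)), path)
  invisible(path)
}

#' @rdname save_featurizer
#' @export
load_featurizer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "weaktext_featurizer"))
    stop("not a featurizer archive: ", path, call. = FALSE)
  structure(obj$state, class = "weaktext_featurizer")
}
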