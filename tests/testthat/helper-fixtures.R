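# shared fixtures built in code

tiny_corpus <- function() {
  corpus(id = c("a", "b", "c"),
         text = c("No smoking after age 40",
                  "He smokes two packs daily.",
                  "Patient enjoys gardening."),
         label = c("non-smoker", "smoker", "non-smoker"),
         meta = list(list(section = "social history"), NULL, NULL))
}

tiny_embeddings <- function() {
  m <- rbind(a = c(1, 2), b = c(3, 4), c = c(0, 1))
  embedding_table(m)
}

random_embeddings <- function(tokens, k, seed) {
  set.seed(seed)
  m <- matrix(rnorm(length(tokens) * k), nrow = length(tokens),
              dimnames = list(tokens, NULL))
  embedding_table(m)
}

# brute-force reference labeler: enumerates every (pattern, sentence) pair
# with plain grepl, independent of the engine's vectorized matching and
# short-circuiting, then applies the same precedence/co-occurrence semantics
brute_label <- function(text, rs) {
  sents <- split_sentences(text)$text
  fired <- expand.grid(rule = seq_len(nrow(rs$rules)),
                       sentence = seq_along(sents))
  if (nrow(fired) > 0) {
    hit <- mapply(function(r, s)
      grepl(rs$rules$compiled[r], sents[s], perl = TRUE, ignore.case = TRUE),
      fired$rule, fired$sentence)
    fired <- fired[hit, , drop = FALSE]
  }
  fired$category <- rs$rules$category[fired$rule]
  fired$role <- rs$rules$role[fired$rule]
  if (rs$cooccurrence) {
    for (cat in rs$precedence) {
      f <- fired[fired$category == cat, , drop = FALSE]
      ok <- intersect(f$sentence[f$role == "keyword"],
                      f$sentence[f$role == "modifier"])
      if (length(ok) > 0) return(cat)
    }
  } else {
    for (cat in rs$precedence) {
      if (any(fired$category == cat)) return(cat)
    }
  }
  rs$default
}

# two linearly separable gaussian blobs in d dimensions (sep = 8 puts the
# class means 8 sd apart, so overlap is negligible at these sample sizes)
gaussian_blobs <- function(n, d = 4, sep = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("pos", "neg"), length.out = n)
  x <- matrix(rnorm(n * d), nrow = n)
  x[y == "pos", 1] <- x[y == "pos", 1] + sep
  list(x = x, y = y)
}
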