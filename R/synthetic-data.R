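#' Configuration for the synthetic clinical-note generator
#'
#' The generator emulates the statistical structure the weak-supervision
#' paradigm assumes in short clinical snippets: affirmative and negated
#' smoking cue phrases ("smokes two packs", "no smoking", "denies smoking"),
#' semi-structured lines ("tobacco: no"), misspelled cue words
#' ("tobacco" -> "tobaco"), and — for the fracture task — anatomical
#' keyword / fracture modifier pairs that may be split across sentences so
#' that sentence-scoped co-occurrence rules miss them.
#'
#' @param task `"smoking_binary"`, `"fracture_binary"` or
#'   `"smoking_multiclass"`.
#' @param n Number of documents.
#' @param proportions Named class proportions summing to 1. Defaults:
#'   balanced for the binary tasks; the printed four-way mix
#'   (35/66/36/252, normalized) for the multiclass task, so its class
#'   imbalance failure mode is reproducible.
#' @param p_miss Per-cue-token misspelling rate in \[0, 1\]. A misspelling is
#'   a single-character deletion or adjacent swap that never touches the
#'   first character and is guaranteed not to match any rule pattern of the
#'   task's built-in rule set (so misspelled cues always fall through the
#'   rules).
#' @param p_cross Probability that a positive fracture document splits its
#'   keyword and modifier across two sentences (fracture task only).
#' @param p_semi Rate of semi-structured negation lines in non-smoker
#'   documents (smoking tasks).
#' @param filler_vocab Size of the neutral filler vocabulary.
#' @param seed Integer seed (mandatory; all generator randomness flows from
#'   it).
#' @return A `weaktext_generator_config`.
#' @export
generator_config <- function(task = c("smoking_binary", "fracture_binary",
                                      "smoking_multiclass"),
                             n = 1000, proportions = NULL,
                             p_miss = 0, p_cross = 0, p_semi = 0.1,
                             filler_vocab = 200, seed = NULL) {
  task <- match.arg(task)
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(proportions)) {
    proportions <- switch(task,
      smoking_binary = c("smoker" = 0.5, "non-smoker" = 0.5),
      fracture_binary = c("fracture" = 0.5, "no-fracture" = 0.5),
      smoking_multiclass = c("current smoker" = 35, "non-smoker" = 66,
                             "past smoker" = 36, "unknown" = 252) / 389)
  }
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  for (r in c(p_miss, p_cross, p_semi))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(task = task, n = n, proportions = proportions,
                 p_miss = p_miss, p_cross = p_cross, p_semi = p_semi,
                 filler_vocab = filler_vocab, seed = seed),
            class = "weaktext_generator_config")
}

# deterministic pseudo-word filler vocabulary (independent of the seed so
# that independently generated corpora share filler tokens)
filler_words <- function(size) {
  syl <- c("bal", "dem", "fin", "gor", "lun", "mer", "nal", "por", "ris",
           "tam", "ven", "zor", "cam", "hel", "ong", "pri", "sul", "tor",
           "wex", "yam")
  out <- character(size)
  for (i in seq_len(size)) {
    a <- ((i - 1) %% 20) + 1
    b <- (((i - 1) %/% 20) %% 20) + 1
    c3 <- (((i - 1) %/% 400) %% 20) + 1
    out[i] <- if (i <= 400) paste0(syl[a], syl[b]) else paste0(syl[a], syl[b], syl[c3])
  }
  unique(out)
}

smoking_templates <- list(
  smoker = list(
    list(text = "patient {smokes} one pack per day", cues = "smokes"),
    list(text = "he {smoked} for twenty years", cues = "smoked"),
    list(text = "she is a {smoker} with copd", cues = "smoker"),
    list(text = "admits {smoking} daily", cues = "smoking"),
    list(text = "{tobacco} use daily for many years", cues = "tobacco"),
    list(text = "uses {cigarettes} regularly", cues = "cigarettes"),
    list(text = "heavy {nicotine} dependence noted", cues = "nicotine"),
    list(text = "enjoys {cigars} on weekends", cues = "cigars")),
  `non-smoker` = list(
    list(text = "no {smoking} after age forty", cues = "smoking"),
    list(text = "denies {smoking} currently", cues = "smoking"),
    list(text = "never {smoked} per report", cues = "smoked"),
    list(text = "{nonsmoker} per chart review", cues = "nonsmoker"),
    list(text = "patient does not use any such products", cues = character(0)),
    list(text = "reviewed habits with patient today", cues = character(0))),
  semi = list(
    list(text = "{tobacco}: no", cues = "tobacco"),
    list(text = "{smoking}: never", cues = "smoking"))
)

multiclass_templates <- list(
  `current smoker` = list(
    list(text = "he is a current {smoker}", cues = "smoker"),
    list(text = "active {smoker} for many years", cues = "smoker"),
    list(text = "patient uses {tobacco} daily", cues = "tobacco"),
    list(text = "currently {smoking} one pack per day", cues = "smoking")),
  `past smoker` = list(
    list(text = "she quit {smoking} last year", cues = "smoking"),
    list(text = "former {smoker} quit years ago", cues = "smoker"),
    list(text = "stopped {smoking} two years ago", cues = "smoking"),
    list(text = "remote {smoker} history noted", cues = "smoker")),
  `non-smoker` = list(
    list(text = "denies {smoking} at this time", cues = "smoking"),
    list(text = "never {smoked} per report", cues = "smoked"),
    list(text = "{nonsmoker} per chart review", cues = "nonsmoker")),
  unknown = list(
    list(text = "vitals stable on exam", cues = character(0)),
    list(text = "follow up in six months", cues = character(0)),
    list(text = "reviewed medication list today", cues = character(0)))
)

# positive fracture templates: exactly one anatomical keyword cue and one
# fracture modifier cue; `split` gives the cross-sentence variant in which
# the modifier's sentence has no keyword and vice versa
fracture_pairs <- list(
  list(co = "{fx} of the femoral {neck} noted",
       split = "indications femur {fx}. fixation of the femoral {neck} performed",
       cues = c("fx", "neck")),
  list(co = "acute {subcapital} {fracture} of the left hip",
       split = "{fracture} suspected clinically. alignment of the {subcapital} region assessed",
       cues = c("fracture", "subcapital")),
  list(co = "{intertrochanteric} {fracture} with displacement",
       split = "{fracture} suspected on exam. views of the {intertrochanteric} region obtained",
       cues = c("fracture", "intertrochanteric")),
  list(co = "{cervical} hip {fx} seen on imaging",
       split = "plain film shows {fx}. the {cervical} region of the hip was imaged",
       cues = c("fx", "cervical")),
  list(co = "{broken} bone at the greater {trochanter}",
       split = "{broken} bone suspected. the greater {trochanter} appears abnormal",
       cues = c("broken", "trochanter")))

fracture_negatives <- list(
  list(text = "mri of the femoral {neck} unremarkable", cues = "neck"),
  list(text = "degenerative changes of the hip joint noted", cues = character(0)),
  list(text = "views of the {intertrochanteric} region normal", cues = "intertrochanteric"),
  list(text = "wrist {fracture} noted on prior imaging", cues = "fracture"),
  list(text = "no acute abnormality seen", cues = character(0)))

# single-character deletion or adjacent swap, never touching the first
# character; retried until the result matches no rule pattern of `rs`
misspell_token <- function(token, rs) {
  nc <- nchar(token)
  if (nc < 3) return(list(token = token, applied = FALSE))
  for (try in 1:20) {
    ch <- strsplit(token, "")[[1]]
    if (stats::runif(1) < 0.5 && nc >= 4) {          # deletion
      p <- sample(2:nc, 1)
      cand <- paste(ch[-p], collapse = "")
    } else {                                          # adjacent swap
      p <- sample(2:(nc - 1), 1)
      tmp <- ch[p]; ch[p] <- ch[p + 1]; ch[p + 1] <- tmp
      cand <- paste(ch, collapse = "")
    }
    if (cand == token) next
    hit <- any(vapply(rs$rules$compiled,
                      function(p) grepl(p, cand, perl = TRUE, ignore.case = TRUE),
                      logical(1)))
    if (!hit) return(list(token = cand, applied = TRUE))
  }
  list(token = token, applied = FALSE)
}

fill_template <- function(text, cues, rs, p_miss, lexicon_env) {
  n_miss <- 0L
  for (cue in cues) {
    surface <- cue
    if (p_miss > 0 && stats::runif(1) < p_miss) {
      ms <- misspell_token(cue, rs)
      if (ms$applied) {
        surface <- ms$token
        n_miss <- n_miss + 1L
        lexicon_env$rows[[length(lexicon_env$rows) + 1L]] <-
          tibble::tibble(token = surface, concept = cue, misspelling = TRUE)
      }
    }
    text <- sub(paste0("{", cue, "}"), surface, text, fixed = TRUE)
  }
  list(text = text, n_miss = n_miss)
}

#' Generate a seeded synthetic corpus bundle
#'
#' Gold labels are assigned by construction (by template class), before and
#' independently of any corruption, and are recoverable from the provenance
#' log alone. With `p_miss = 0` and `p_cross = 0` the matching built-in rule
#' set reproduces the gold labels exactly; misspellings and cross-sentence
#' splits then degrade rule accuracy in a controlled, monotone way while a
#' classifier over clustered embeddings is unaffected — the mechanism the
#' paradigm exists to exploit.
#'
#' @param config A [generator_config()].
#' @return A list of class `weaktext_bundle`: `corpus` (with gold labels),
#'   `lexicon` (tibble token/concept/misspelling covering every token in the
#'   corpus), `provenance` (per-document log: gold, template, cue tokens,
#'   misspellings applied, cross-sentence split, semi-structured), and
#'   `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "weaktext_generator_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  rs <- load_builtin(switch(config$task,
                            smoking_binary = "mayo_smoking",
                            fracture_binary = "hip_fracture",
                            smoking_multiclass = "i2b2_smoking"))
  fillers <- filler_words(config$filler_vocab)
  lexicon_env <- new.env(parent = emptyenv())
  lexicon_env$rows <- list()
  n <- config$n
  classes <- names(config$proportions)
  gold <- if (n > 0) sample(classes, n, replace = TRUE, prob = config$proportions)
          else character(0)
  texts <- character(n)
  p_template <- character(n); p_cues <- character(n)
  p_nmiss <- integer(n); p_cross_v <- logical(n); p_semi_v <- logical(n)
  for (i in seq_len(n)) {
    g <- gold[i]
    cross <- FALSE; semi <- FALSE
    if (config$task == "fracture_binary") {
      if (g == "fracture") {
        tpl <- fracture_pairs[[sample(length(fracture_pairs), 1)]]
        cross <- stats::runif(1) < config$p_cross
        raw <- if (cross) tpl$split else tpl$co
        cues <- tpl$cues
      } else {
        tpl <- fracture_negatives[[sample(length(fracture_negatives), 1)]]
        raw <- tpl$text; cues <- tpl$cues
      }
    } else {
      tset <- if (config$task == "smoking_binary") smoking_templates
              else multiclass_templates
      if (g %in% c("non-smoker") && stats::runif(1) < config$p_semi &&
          config$task == "smoking_binary") {
        tpl <- smoking_templates$semi[[sample(length(smoking_templates$semi), 1)]]
        semi <- TRUE
      } else {
        tpl <- tset[[g]][[sample(length(tset[[g]]), 1)]]
      }
      raw <- tpl$text; cues <- tpl$cues
    }
    filled <- fill_template(raw, cues, rs, config$p_miss, lexicon_env)
    text <- filled$text
    if (stats::runif(1) < 0.5) {
      pad <- paste(sample(fillers, sample(3:7, 1), replace = TRUE),
                   collapse = " ")
      text <- paste0(text, ". ", pad)
    }
    texts[i] <- text
    p_template[i] <- raw
    p_cues[i] <- paste(cues, collapse = " ")
    p_nmiss[i] <- filled$n_miss
    p_cross_v[i] <- cross
    p_semi_v[i] <- semi
  }
  prov <- tibble::tibble(id = sprintf("doc%05d", seq_len(n)), gold = gold,
                         template = p_template, cues = p_cues,
                         n_misspelled = p_nmiss, cross_split = p_cross_v,
                         semi_structured = p_semi_v)
  corp <- corpus(id = sprintf("doc%05d", seq_len(n)), text = texts,
                 label = gold)
  all_tokens <- unique(unlist(tokenize(corp$text)))
  mis <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(token = character(), concept = character(),
                   misspelling = logical()), lexicon_env$rows))
  plain <- setdiff(all_tokens, mis$token)
  lexicon <- dplyr::bind_rows(
    tibble::tibble(token = plain, concept = plain, misspelling = FALSE), mis)
  structure(list(corpus = corp, lexicon = lexicon,
                 provenance = prov, config = config),
            class = "weaktext_bundle")
}

#' @export
print.weaktext_bundle <- function(x, ...) {
  cat("<synthetic corpus bundle: task ", x$config$task, ", n = ",
      nrow(x$corpus), ", lexicon ", nrow(x$lexicon), " tokens>\n", sep = "")
  invisible(x)
}

#' Generate a clustered synthetic embedding table for a bundle
#'
#' Every concept in the bundle's lexicon receives a random cluster center;
#' each surface form of the concept — including misspelled variants — gets
#' the center plus isotropic Gaussian noise of standard deviation
#' `cluster_sd` (relative to unit-norm centers). Misspellings therefore land
#' near their correct forms in cosine space, which is exactly the property
#' pre-trained clinical embeddings show for frequent misspellings, and filler
#' words get independent vectors.
#'
#' @param bundle A `weaktext_bundle`.
#' @param k Embedding dimension (default 100).
#' @param cluster_sd Within-concept noise scale.
#' @param seed Integer seed.
#' @return A `weaktext_embeddings` table covering the bundle's whole lexicon.
#' @export
generate_embeddings <- function(bundle, k = 100, cluster_sd = 0.15, seed = 1) {
  stopifnot(inherits(bundle, "weaktext_bundle"))
  if (k < 2) stop("embedding dimension must be at least 2", call. = FALSE)
  lex <- bundle$lexicon
  if (nrow(lex) == 0) stop("bundle lexicon is empty", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  concepts <- sort(unique(lex$concept))
  centers <- matrix(stats::rnorm(length(concepts) * k, sd = 1 / sqrt(k)),
                    nrow = length(concepts),
                    dimnames = list(concepts, NULL))
  lex <- lex[order(lex$token), , drop = FALSE]
  noise <- matrix(stats::rnorm(nrow(lex) * k, sd = cluster_sd / sqrt(k)),
                  nrow = nrow(lex))
  vecs <- centers[lex$concept, , drop = FALSE] + noise
  rownames(vecs) <- lex$token
  embedding_table(vecs)
}

#' Corrupt gold labels through the weak-label distribution
#'
#' Convenience wrapper exposing the theory module's sampler
#' ([sample_weak_labels()]) to pipeline tests: category labels of a binary
#' task are mapped to +1/-1, flipped with probability
#' 1 - [agreement_probability()]`(phi)`, and mapped back.
#'
#' @param labels Character vector with exactly two distinct values.
#' @param phi Per-rule correctness probabilities.
#' @param seed Integer seed.
#' @return Character vector of weak labels.
#' @export
corrupt_labels <- function(labels, phi, seed) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("corrupt_labels is defined for binary tasks", call. = FALSE)
  y <- ifelse(labels == lv[2], 1, -1)
  wk <- sample_weak_labels(y, phi, seed)
  ifelse(wk == 1, lv[2], lv[1])
}
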