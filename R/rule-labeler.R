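#' Split text into sentence spans
#'
#' Sentences are maximal runs of non-delimiter characters; the delimiter set
#' is `.`, `!`, `?`, `;` and newline. The semicolon matters for radiology
#' report lines such as `"R hip inj; fx femur neck nos closed"`, where the
#' keyword/modifier co-occurrence has to be assessed within the post-`;`
#' segment. Spans are non-overlapping, ordered, cover all non-delimiter text,
#' and concatenating spans and delimiters reconstructs the input.
#'
#' @param text A single character string.
#' @return A tibble with columns `sentence` (1-based index), `start`, `end`
#'   (character positions, inclusive) and `text` (the span). Empty input
#'   gives zero rows.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || nchar(text) == 0)
    return(tibble::tibble(sentence = integer(), start = integer(),
                          end = integer(), text = character()))
  m <- gregexpr("[^.!?;\n]+", text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(tibble::tibble(sentence = integer(), start = integer(),
                          end = integer(), text = character()))
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  tibble::tibble(sentence = seq_along(start), start = start, end = end,
                 text = substring(text, start, end))
}

# Split a regex on top-level alternation bars (ignoring bars inside groups,
# character classes, or escapes).
split_top_alternatives <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  depth <- 0L; in_class <- FALSE; esc <- FALSE
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (in_class) { if (ch == "]") in_class <- FALSE; next }
    if (ch == "[") { in_class <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "|" && depth == 0L) cuts <- c(cuts, i)
  }
  if (length(cuts) == 0) return(pattern)
  bounds <- c(0L, cuts, length(chars) + 1L)
  vapply(seq_len(length(bounds) - 1L), function(j)
    paste(chars[seq.int(bounds[j] + 1L, bounds[j + 1L] - 1L)], collapse = ""),
    character(1))
}

# Wrap every top-level alternative of a printed pattern in word-boundary
# anchors, so e.g. "smokers?" cannot fire inside "nonsmoker" while composite
# rules like "(no|non|...)\W*(smoker|...)" keep their printed structure.
compile_rule_pattern <- function(pattern) {
  alts <- split_top_alternatives(pattern)
  paste0("\\b(?:", alts, ")\\b", collapse = "|")
}

#' Construct a rule set (a labeling function)
#'
#' A rule set is the paradigm's labeling function: an ordered list of
#' regular-expression rules, each tied to a category (or, for co-occurrence
#' rule sets, to a `keyword`/`modifier` role), a precedence order over
#' categories, and a default category assigned when nothing fires. Matching is
#' case-insensitive and every top-level pattern alternative is anchored by
#' word boundaries at both ends.
#'
#' @param name Rule-set name.
#' @param labels Ordered character vector of category names (at least 2).
#' @param default The category assigned when no rule fires; must be one of
#'   `labels`.
#' @param rules A data frame with columns `pattern` (regex as printed in the
#'   rule table), `category`, and optionally `role` (one of `"pattern"`,
#'   `"keyword"`, `"modifier"`; default `"pattern"`) and `accuracy` (the
#'   assumed per-rule correctness probability in (0.5, 1], used only by the
#'   theory simulator).
#' @param precedence Ordered character vector of categories tested
#'   first-match-wins; must cover every category that carries rules (it may
#'   include the default when the default also has patterns, as in the Mayo
#'   smoking rule set).
#' @param scope `"document"` or `"sentence"`.
#' @param cooccurrence If `TRUE`, a non-default label requires at least one
#'   keyword-role and one modifier-role match within a single sentence
#'   (implies `scope = "sentence"`).
#' @return An object of class `weaktext_ruleset`.
#' @export
ruleset <- function(name, labels, default, rules,
                    precedence = setdiff(labels, default),
                    scope = c("document", "sentence"),
                    cooccurrence = FALSE) {
  scope <- match.arg(scope)
  labels <- as.character(labels)
  if (length(labels) < 2) stop("a rule set needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(labels)) stop("categories must be unique", call. = FALSE)
  if (!default %in% labels) stop("default category must be one of the labels", call. = FALSE)
  rules <- tibble::as_tibble(rules)
  if (nrow(rules) < 1) stop("a rule set needs at least one rule (m >= 1)", call. = FALSE)
  if (!"role" %in% names(rules)) rules$role <- "pattern"
  rules$role[is.na(rules$role)] <- "pattern"
  if (!all(rules$role %in% c("pattern", "keyword", "modifier")))
    stop("rule role must be pattern, keyword or modifier", call. = FALSE)
  if (!"accuracy" %in% names(rules)) rules$accuracy <- NA_real_
  ok_acc <- is.na(rules$accuracy) | (rules$accuracy > 0.5 & rules$accuracy <= 1)
  if (!all(ok_acc)) stop("assumed rule accuracy must lie in (0.5, 1]", call. = FALSE)
  if (!all(rules$category %in% labels))
    stop("every rule category must belong to the label set", call. = FALSE)
  if (cooccurrence) {
    scope <- "sentence"
    if (!any(rules$role == "keyword") || !any(rules$role == "modifier"))
      stop("a co-occurrence rule set needs keyword and modifier rules", call. = FALSE)
  }
  ruled <- unique(rules$category)
  if (!all(ruled %in% precedence))
    stop("precedence must cover every category that carries rules", call. = FALSE)
  if (!all(precedence %in% labels) || anyDuplicated(precedence))
    stop("precedence must be a subset permutation of the categories", call. = FALSE)
  rules$rule <- seq_len(nrow(rules))
  rules$compiled <- vapply(rules$pattern, compile_rule_pattern, character(1),
                           USE.NAMES = FALSE)
  for (p in rules$compiled) {
    ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("pattern does not compile: ", p, call. = FALSE)
  }
  structure(list(name = name, labels = labels, default = default,
                 precedence = precedence, scope = scope,
                 cooccurrence = cooccurrence,
                 rules = rules[, c("rule", "category", "role", "pattern",
                                   "accuracy", "compiled")]),
            class = "weaktext_ruleset")
}

#' @export
print.weaktext_ruleset <- function(x, ...) {
  cat("<rule set \"", x$name, "\": m = ", nrow(x$rules), " rules, categories {",
      paste(x$labels, collapse = ", "), "}, default \"", x$default, "\"",
      if (x$cooccurrence) ", sentence-scoped keyword x modifier co-occurrence",
      ">\n", sep = "")
  invisible(x)
}

# -- built-in rule sets: patterns transcribed verbatim from the published
#    smoking-status and hip-fracture rule tables --------------------------

mayo_smoker_patterns <- c(
  "smokes?", "smoked", "smoking", "smokers?", "tobaccos?", "cigarettes?",
  "cigs?", "pipes?", "nicotine", "cigars?", "tob"
)

mayo_nonsmoker_patterns <- c(
  "(no|non|not|never|negative)\\W*(smoker|smoking|smoked|tobacco)",
  "nonsmoker",
  "denies\\W*smoking",
  "(tobacco|smoke|smoking|nicotine)\\W*(never|no)",
  "doesn\\'t smoke",
  "0|zero smokers?"
)

hip_keyword_patterns <- function(strict_trochanteric = FALSE) c(
  "cervical|femoral head|neck",
  "(trans)?cervical",
  "(sub)?capital",
  "intracapsular",
  "trans(|-)?epiphyseal",
  "base of neck",
  "basilar femoral neck",
  "cervicotrochanteric",
  "(greater|lesser) trochanter",
  # the printed entry reads "(inter|per|intra) trochanteric"; by default an
  # optional space or hyphen is allowed so "intertrochanteric" (a task keyword
  # in its own right) is covered; the strict-space reading is available
  if (strict_trochanteric) "(inter|per|intra) trochanteric"
  else "(inter|per|intra)[ -]?trochanteric"
)

hip_modifier_patterns <- c(
  "(micro-?)?fracture(s|d)?", "(epi|meta)physis", "separation", "fxs?",
  "broken", "cracked", "displace(d)?", "fragment"
)

i2b2_current_patterns <- c(
  "(does|has|continues to) smoked?",
  "uses tobacco",
  "active smoker",
  "(current|currently) (smoker|smoking)",
  "current smoker",
  "tobacco use\\W*(yes|still using|still smoking|smokes)"
)

i2b2_past_patterns <- c(
  "(stop|stopped|quit|quitted|discontinued) (tobacco|smoking)",
  "(previous|prior|remote|distant|former|ex-|ex) (tobacco|smoker)",
  "stop(ped)? smoking",
  "tobacco use\\W*(smoked|quit)",
  "smoking\\W*(used|former)"
)

#' Load one of the built-in rule sets
#'
#' Three labeling functions ship with the package, with patterns transcribed
#' verbatim from the published rule tables:
#'
#' * `"mayo_smoking"` — binary smoking status. Categories `smoker` /
#'   `non-smoker`; non-smoker patterns are checked first (negations such as
#'   "no smoking" subsume the bare smoker keywords) and the default when
#'   nothing fires is `non-smoker`.
#' * `"hip_fracture"` — proximal femur (hip) fracture detection from
#'   radiology report text. A `fracture` label requires an anatomical keyword
#'   (e.g. "femoral neck", "intertrochanteric") and a fracture modifier
#'   (e.g. "fx", "fracture", "displaced") within one sentence; default
#'   `no-fracture`.
#' * `"i2b2_smoking"` — the four-way discharge-record task. Categories
#'   `past smoker`, `current smoker`, `non-smoker`, `unknown` with precedence
#'   past > current > non-smoker and default `unknown`; the non-smoker
#'   patterns are those of the Mayo rule set.
#'
#' @param name One of `"mayo_smoking"`, `"hip_fracture"`, `"i2b2_smoking"`.
#' @param strict_trochanteric Compile the trochanteric keyword entry with a
#'   mandatory space (the literal printed form) instead of the default
#'   optional space/hyphen.
#' @return A `weaktext_ruleset`.
#' @export
load_builtin <- function(name, strict_trochanteric = FALSE) {
  valid <- c("mayo_smoking", "hip_fracture", "i2b2_smoking")
  if (length(name) != 1 || !name %in% valid)
    stop("unknown rule set \"", paste(name, collapse = ","),
         "\"; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  switch(name,
    mayo_smoking = ruleset(
      name = "mayo_smoking",
      labels = c("smoker", "non-smoker"),
      default = "non-smoker",
      precedence = c("non-smoker", "smoker"),
      rules = tibble::tibble(
        category = c(rep("smoker", length(mayo_smoker_patterns)),
                     rep("non-smoker", length(mayo_nonsmoker_patterns))),
        pattern = c(mayo_smoker_patterns, mayo_nonsmoker_patterns)
      ),
      scope = "document"
    ),
    hip_fracture = {
      kw <- hip_keyword_patterns(strict_trochanteric)
      ruleset(
        name = "hip_fracture",
        labels = c("fracture", "no-fracture"),
        default = "no-fracture",
        precedence = "fracture",
        rules = tibble::tibble(
          category = "fracture",
          role = c(rep("keyword", length(kw)),
                   rep("modifier", length(hip_modifier_patterns))),
          pattern = c(kw, hip_modifier_patterns)
        ),
        cooccurrence = TRUE
      )
    },
    i2b2_smoking = ruleset(
      name = "i2b2_smoking",
      labels = c("past smoker", "current smoker", "non-smoker", "unknown"),
      default = "unknown",
      precedence = c("past smoker", "current smoker", "non-smoker"),
      rules = tibble::tibble(
        category = c(rep("current smoker", length(i2b2_current_patterns)),
                     rep("past smoker", length(i2b2_past_patterns)),
                     rep("non-smoker", length(mayo_nonsmoker_patterns))),
        pattern = c(i2b2_current_patterns, i2b2_past_patterns,
                    mayo_nonsmoker_patterns)
      ),
      scope = "document"
    )
  )
}

#' Enumerate all rule matches in a text
#'
#' Applies every compiled rule to every sentence and reports each hit with
#' its character span. This is the evidence layer under [apply_ruleset()] and
#' is also useful for rule debugging ("why did this note fire?").
#'
#' @param text A single string.
#' @param rs A `weaktext_ruleset`.
#' @return A tibble with columns `rule`, `category`, `role`, `sentence`,
#'   `start`, `end`, `match`.
#' @export
rule_matches <- function(text, rs) {
  empty <- tibble::tibble(rule = integer(), category = character(),
                          role = character(), sentence = integer(),
                          start = integer(), end = integer(),
                          match = character())
  sents <- split_sentences(text)
  if (nrow(sents) == 0) return(empty)
  out <- vector("list", nrow(rs$rules))
  for (i in seq_len(nrow(rs$rules))) {
    p <- rs$rules$compiled[i]
    hits <- vector("list", nrow(sents))
    for (s in seq_len(nrow(sents))) {
      m <- gregexpr(p, sents$text[s], perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1) next
      st <- sents$start[s] + as.integer(m) - 1L
      en <- st + attr(m, "match.length") - 1L
      hits[[s]] <- tibble::tibble(rule = rs$rules$rule[i],
                                  category = rs$rules$category[i],
                                  role = rs$rules$role[i],
                                  sentence = sents$sentence[s],
                                  start = st, end = en,
                                  match = substring(text, st, en))
    }
    out[[i]] <- dplyr::bind_rows(hits)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else dplyr::arrange(res, .data$sentence, .data$start, .data$rule)
}

#' Apply a rule set to one document
#'
#' Matching is case-insensitive with word-boundary anchoring at both ends of
#' every pattern alternative. Categories are tested in precedence order and
#' the first category with any match wins. For co-occurrence rule sets
#' (hip fracture), a non-default label additionally requires at least one
#' keyword-role match and one modifier-role match within the same sentence.
#' If nothing fires, the default category is returned with empty evidence.
#'
#' @param text A single document text.
#' @param rs A `weaktext_ruleset`.
#' @return A list of class `weaktext_weaklabel` with elements `category` and
#'   `evidence` (a [rule_matches()] tibble restricted to the winning
#'   category; empty if and only if the default was assigned with no match).
#' @export
apply_ruleset <- function(text, rs) {
  hits <- rule_matches(text, rs)
  if (rs$cooccurrence) {
    pos <- setdiff(rs$precedence, character(0))
    for (cat in pos) {
      h <- hits[hits$category == cat, , drop = FALSE]
      ok_sent <- intersect(unique(h$sentence[h$role == "keyword"]),
                           unique(h$sentence[h$role == "modifier"]))
      if (length(ok_sent) > 0) {
        ev <- h[h$sentence %in% ok_sent, , drop = FALSE]
        return(structure(list(category = cat, evidence = ev),
                         class = "weaktext_weaklabel"))
      }
    }
  } else {
    for (cat in rs$precedence) {
      ev <- hits[hits$category == cat, , drop = FALSE]
      if (nrow(ev) > 0)
        return(structure(list(category = cat, evidence = ev),
                         class = "weaktext_weaklabel"))
    }
  }
  structure(list(category = rs$default, evidence = hits[0, , drop = FALSE]),
            class = "weaktext_weaklabel")
}

#' @export
print.weaktext_weaklabel <- function(x, ...) {
  cat("<weak label \"", x$category, "\" (", nrow(x$evidence),
      " evidence span", if (nrow(x$evidence) != 1) "s", ")>\n", sep = "")
  invisible(x)
}

#' Weak-label a corpus with a rule set
#'
#' Semantically identical to applying [apply_ruleset()] to every document
#' (rule matching is vectorized across the corpus for speed). The output is
#' deterministic: the same corpus and rule set always give the same labels.
#'
#' @param corpus A corpus tibble.
#' @param rs A `weaktext_ruleset`.
#' @return The corpus with two added columns: `weak_label` (character) and
#'   `evidence` (list of evidence tibbles). Row order is preserved.
#' @export
label_corpus <- function(corpus, rs) {
  corpus <- as_corpus(corpus)
  n <- nrow(corpus)
  if (n == 0) {
    corpus$weak_label <- character(0)
    corpus$evidence <- list()
    return(corpus)
  }
  # flatten all sentences of all documents, then run each compiled rule once
  # over the whole sentence vector
  sents <- lapply(corpus$text, split_sentences)
  ns <- vapply(sents, nrow, integer(1))
  doc_of <- rep(seq_len(n), ns)
  flat <- dplyr::bind_rows(sents)
  hits_by_rule <- vector("list", nrow(rs$rules))
  if (nrow(flat) > 0) {
    for (i in seq_len(nrow(rs$rules))) {
      m <- gregexpr(rs$rules$compiled[i], flat$text, perl = TRUE,
                    ignore.case = TRUE)
      hit_rows <- which(vapply(m, function(x) x[1] != -1L, logical(1)))
      if (length(hit_rows) == 0) next
      st <- unlist(lapply(hit_rows, function(r)
        flat$start[r] + as.integer(m[[r]]) - 1L))
      en <- unlist(lapply(hit_rows, function(r)
        flat$start[r] + as.integer(m[[r]]) +
          attr(m[[r]], "match.length") - 2L))
      reps <- vapply(m[hit_rows], length, integer(1))
      hits_by_rule[[i]] <- tibble::tibble(
        doc = rep(doc_of[hit_rows], reps),
        rule = rs$rules$rule[i], category = rs$rules$category[i],
        role = rs$rules$role[i],
        sentence = rep(flat$sentence[hit_rows], reps),
        start = st, end = en)
    }
  }
  hits <- dplyr::bind_rows(hits_by_rule)
  empty_ev <- tibble::tibble(rule = integer(), category = character(),
                             role = character(), sentence = integer(),
                             start = integer(), end = integer(),
                             match = character())
  weak <- rep(rs$default, n)
  evid <- rep(list(empty_ev), n)
  if (nrow(hits) > 0) {
    hits$match <- substring(corpus$text[hits$doc], hits$start, hits$end)
    hits <- dplyr::arrange(hits, .data$doc, .data$sentence, .data$start,
                           .data$rule)
    for (d in unique(hits$doc)) {
      h <- hits[hits$doc == d, , drop = FALSE]
      if (rs$cooccurrence) {
        for (cat in rs$precedence) {
          hc <- h[h$category == cat, , drop = FALSE]
          ok <- intersect(unique(hc$sentence[hc$role == "keyword"]),
                          unique(hc$sentence[hc$role == "modifier"]))
          if (length(ok) > 0) {
            weak[d] <- cat
            evid[[d]] <- hc[hc$sentence %in% ok, names(empty_ev), drop = FALSE]
            break
          }
        }
      } else {
        for (cat in rs$precedence) {
          hc <- h[h$category == cat, , drop = FALSE]
          if (nrow(hc) > 0) {
            weak[d] <- cat
            evid[[d]] <- hc[, names(empty_ev), drop = FALSE]
            break
          }
        }
      }
    }
  }
  corpus$weak_label <- weak
  corpus$evidence <- evid
  corpus
}

#' Read / write a rule-set configuration (JSON)
#'
#' The config schema is `{"name", "labels": [..], "default",
#' "precedence": [..], "scope", "cooccurrence": bool,
#' "rules": [{"category", "role", "pattern", "accuracy"}]}`.
#'
#' @param path Path to a JSON rule-set config.
#' @return For `read_ruleset`, a compiled `weaktext_ruleset`.
#' @export
read_ruleset <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rules <- tibble::as_tibble(cfg$rules)
  ruleset(name = cfg$name, labels = cfg$labels, default = cfg$default,
          rules = rules,
          precedence = if (!is.null(cfg$precedence)) cfg$precedence
                       else setdiff(cfg$labels, cfg$default),
          scope = if (!is.null(cfg$scope)) cfg$scope else "document",
          cooccurrence = isTRUE(cfg$cooccurrence))
}

#' @rdname read_ruleset
#' @param rs A `weaktext_ruleset`.
#' @export
write_ruleset <- function(rs, path) {
  cfg <- list(name = rs$name, labels = rs$labels, default = rs$default,
              precedence = rs$precedence, scope = rs$scope,
              cooccurrence = rs$cooccurrence,
              rules = rs$rules[, c("category", "role", "pattern", "accuracy")])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
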