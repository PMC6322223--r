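#' Construct a corpus of clinical text snippets
#'
#' A corpus is an ordered tibble of documents, one row per snippet, with a
#' unique `id`, the raw `text`, an optional gold `label`, and a free-form
#' `meta` list-column (e.g. the source note section). Iteration order is the
#' row order and is preserved by all weaktext functions.
#'
#' @param id Character vector of unique, non-empty document ids.
#' @param text Character vector of raw snippet text (may contain empty
#'   strings; a zero-length corpus is legal).
#' @param label Optional character vector of gold category names; `NA` marks
#'   an unlabeled document.
#' @param meta Optional list of per-document key/value tag lists.
#' @return A tibble with columns `id`, `text`, `label`, `meta`.
#' @examples
#' corpus(id = c("a", "b"),
#'        text = c("No smoking after age 40", "He smokes daily"),
#'        label = c("non-smoker", "smoker"))
#' @export
corpus <- function(id, text, label = NULL, meta = NULL) {
  id <- as.character(id)
  text <- as.character(text)
  n <- length(id)
  if (length(text) != n) stop("`id` and `text` must have the same length", call. = FALSE)
  if (is.null(label)) label <- rep(NA_character_, n)
  if (is.null(meta)) meta <- rep(list(NULL), n)
  out <- tibble::tibble(id = id, text = text,
                        label = as.character(label), meta = meta)
  validate_corpus(out)
}

#' Coerce a data frame to a valid corpus
#'
#' @param x A data frame with at least `id` and `text` columns.
#' @return A validated corpus tibble (missing `label`/`meta` columns added).
#' @export
as_corpus <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  if (!all(c("id", "text") %in% names(x)))
    stop("a corpus needs `id` and `text` columns", call. = FALSE)
  x <- tibble::as_tibble(x)
  if (!"label" %in% names(x)) x$label <- NA_character_
  if (!"meta" %in% names(x)) x$meta <- rep(list(NULL), nrow(x))
  validate_corpus(x[, c("id", "text", "label", "meta"),
                    drop = FALSE])
}

validate_corpus <- function(x) {
  if (any(is.na(x$id) | x$id == ""))
    stop("document ids must be non-empty", call. = FALSE)
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0)
    stop("duplicate document id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  x$text[is.na(x$text)] <- ""
  x
}

#' Read a corpus from disk
#'
#' Two formats are supported: `"jsonl"` (one JSON object per line with fields
#' `id`, `text`, and optional `label` and `meta`) and `"text-dir"` (a
#' directory of `*.txt` files, one document each, id taken from the file name;
#' files are read in sorted-name order for stability).
#'
#' @param path Path to a `.jsonl` file or a directory.
#' @param format `"jsonl"` or `"text-dir"`.
#' @return A corpus tibble preserving input order. Missing gold labels become
#'   `NA`, never empty strings.
#' @examples
#' read_corpus(system.file("extdata", "synthetic_smoking_corpus.jsonl",
#'                         package = "weaktext"))
#' @export
read_corpus <- function(path, format = c("jsonl", "text-dir")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- which(trimws(lines) != "")
    recs <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) {
                        stop("malformed jsonl at line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      if (is.null(rec$id) || is.null(rec$text))
        stop("malformed jsonl at line ", i,
             ": each record needs \"id\" and \"text\"", call. = FALSE)
      recs[[j]] <- rec
    }
    corpus(
      id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      label = vapply(recs, function(r)
        if (is.null(r$label)) NA_character_ else as.character(r$label),
        character(1)),
      meta = lapply(recs, function(r) r$meta)
    )
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    corpus(
      id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
        character(1), USE.NAMES = FALSE)
    )
  }
}

#' Write a corpus to JSONL
#'
#' Round-trips through [read_corpus()] field for field; text is written as
#' UTF-8 and no character normalization is applied (misspellings are
#' semantically load-bearing for this paradigm and must survive I/O).
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (!is.na(corpus$label[i])) rec$label <- corpus$label[i]
    m <- corpus$meta[[i]]
    if (!is.null(m) && length(m) > 0) rec$meta <- m
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0)
    writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Embedding tables (token -> k-dimensional word vector)
#'
#' An embedding table maps case-folded tokens to dense vectors of a common
#' dimension `k` (the paradigm's default is k = 100). Stored as a numeric
#' matrix with tokens as row names.
#'
#' @param x A numeric matrix with one row per token; row names are tokens.
#' @return An object of class `weaktext_embeddings`.
#' @export
embedding_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || any(rownames(x) == ""))
    stop("`x` must have token row names", call. = FALSE)
  rownames(x) <- tolower(rownames(x))
  if (anyDuplicated(rownames(x)))
    x <- x[!duplicated(rownames(x)), , drop = FALSE]
  structure(x, class = c("weaktext_embeddings", "matrix", "array"))
}

#' @export
print.weaktext_embeddings <- function(x, ...) {
  cat("<embedding table: ", nrow(x), " tokens, dimension ", ncol(x), ">\n", sep = "")
  invisible(x)
}

#' @rdname embedding_table
#' @param table An embedding table.
#' @export
embedding_dim <- function(table) ncol(table)

#' @rdname embedding_table
#' @export
embedding_vocab <- function(table) rownames(table)

#' Look up token vectors, failing closed on out-of-vocabulary tokens
#'
#' @param table An embedding table.
#' @param tokens Character vector of tokens (case-folded before lookup).
#' @return A matrix of vectors for the in-vocabulary tokens; attribute `oov`
#'   holds the tokens that were not found.
#' @export
embedding_lookup <- function(table, tokens) {
  tokens <- tolower(tokens)
  hit <- tokens %in% rownames(table)
  out <- unclass(table)[tokens[hit], , drop = FALSE]
  attr(out, "oov") <- tokens[!hit]
  out
}

#' Read word vectors from the whitespace-delimited text format
#'
#' Accepts both dialects in the wild: an optional first header line
#' `"<vocab> <dim>"` (two integers) followed by one `token v1 ... vk` line per
#' word, or the same without the header. Tokens are case-folded; later
#' duplicates of a case-folded token are dropped.
#'
#' @param path Path to the vector file.
#' @return A `weaktext_embeddings` table.
#' @examples
#' read_word_vectors(system.file("extdata", "synthetic_smoking_vectors.txt",
#'                               package = "weaktext"))
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) stop("empty word-vector file: ", path, call. = FALSE)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first)))) {
    lines <- lines[-1]  # header "vocab dim"
    if (length(lines) == 0) stop("word-vector file has a header but no rows", call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  dim0 <- length(parts[[1]]) - 1L
  if (dim0 < 1) stop("malformed word-vector row: ", lines[1], call. = FALSE)
  vecs <- matrix(NA_real_, nrow = length(parts), ncol = dim0)
  toks <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != dim0)
      stop("inconsistent vector length for token \"", p[1], "\" (expected ",
           dim0, ", got ", length(p) - 1L, ")", call. = FALSE)
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v))
      stop("non-numeric vector entries for token \"", p[1], "\"", call. = FALSE)
    toks[i] <- p[1]
    vecs[i, ] <- v
  }
  rownames(vecs) <- toks
  embedding_table(vecs)
}

#' Write word vectors in the whitespace-delimited text format
#'
#' @param table A `weaktext_embeddings` table.
#' @param path Output path.
#' @param header Write the `"<vocab> <dim>"` header line (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_word_vectors <- function(table, path, header = TRUE) {
  m <- unclass(table)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(rownames(m)[i], paste(format(m[i, ], scientific = FALSE, trim = TRUE),
                                collapse = " ")),
    character(1))
  if (header) rows <- c(paste(nrow(m), ncol(m)), rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
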