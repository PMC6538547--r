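# Reserved symbols. PAD occupies index 1 so the C++ kernels can assume the
# padding embedding is the first column; UNK is index 2.
PAD_TOKEN <- "<PAD>"
UNK_TOKEN <- "<UNK>"

#' Build token and character vocabularies
#'
#' Collects every token of the training splits of the given corpora (plus,
#' optionally, the tokens of a pretrained embedding) and every character
#' observed in them, and assigns contiguous integer ids. Ordering is sorted,
#' so the result is independent of corpus order (reproducibility). Reserved
#' symbols `<PAD>` (id 1) and `<UNK>` (id 2) are always present, for both
#' tokens and characters; the character inventory is built from training
#' data only and unseen characters map to the UNK character at lookup time.
#'
#' @param corpora List of [labeled_corpus()] objects (train splits are
#'   scanned).
#' @param embedding_tokens Optional character vector of additional tokens to
#'   include (e.g. the vocabulary of a pretrained embedding table).
#' @return An object of class `vocab`: list with named integer vectors
#'   `token_to_id` and `char_to_id`.
#' @export
build_vocab <- function(corpora, embedding_tokens = NULL) {
  if (length(corpora) == 0L) {
    abort_validation("build_vocab() needs at least one corpus")
  }
  toks <- unlist(lapply(corpora, function(co) {
    unlist(lapply(co$train, `[[`, "tokens"), use.names = FALSE)
  }), use.names = FALSE)
  toks <- sort(unique(c(toks, as.character(embedding_tokens %||% character()))))
  toks <- setdiff(toks, c(PAD_TOKEN, UNK_TOKEN))
  chars <- sort(unique(unlist(strsplit(toks, "", fixed = TRUE), use.names = FALSE)))
  token_names <- c(PAD_TOKEN, UNK_TOKEN, toks)
  char_names <- c(PAD_TOKEN, UNK_TOKEN, chars)
  structure(list(
    token_to_id = stats::setNames(seq_along(token_names), token_names),
    char_to_id = stats::setNames(seq_along(char_names), char_names)
  ), class = "vocab")
}

#' @export
print.vocab <- function(x, ...) {
  cat(sprintf("<vocab> %d tokens, %d characters (incl. PAD/UNK)\n",
              length(x$token_to_id), length(x$char_to_id)))
  invisible(x)
}

#' Look up token ids
#'
#' Tokens are matched verbatim first, then lowercased (biomedical casing is
#' informative but pretrained vocabularies are often lowercased), then
#' mapped to UNK.
#'
#' @param vocab A [build_vocab()] result.
#' @param tokens Character vector of surface tokens.
#' @return Integer vector of 1-based token ids.
#' @export
token_ids <- function(vocab, tokens) {
  ids <- unname(vocab$token_to_id[tokens])
  miss <- is.na(ids)
  if (any(miss)) {
    ids[miss] <- unname(vocab$token_to_id[tolower(tokens[miss])])
    ids[is.na(ids)] <- vocab$token_to_id[[UNK_TOKEN]]
  }
  as.integer(ids)
}

#' Look up character ids of one token
#'
#' @param vocab A [build_vocab()] result.
#' @param token A single surface token.
#' @return Integer vector of 1-based character ids (unseen characters map to
#'   the UNK character).
#' @export
char_ids <- function(vocab, token) {
  cs <- strsplit(token, "", fixed = TRUE)[[1L]]
  ids <- unname(vocab$char_to_id[cs])
  ids[is.na(ids)] <- vocab$char_to_id[[UNK_TOKEN]]
  as.integer(ids)
}

#' Load a word2vec text-format embedding table
#'
#' The interchange format: a header line `count dim`, then one line per
#' token, `token v1 ... vdim`, whitespace-separated.
#'
#' @param path Path to the text file (UTF-8).
#' @return An object of class `word2vec_table`: list with `vectors` (a
#'   `count x dim` numeric matrix with tokens as row names) and `dim`.
#' @export
load_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) abort_parse("'%s': empty word2vec file", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    abort_parse("'%s': header must be 'count dim'", path)
  }
  count <- as.integer(header[[1L]])
  dim <- as.integer(header[[2L]])
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != count) {
    abort_parse("'%s': header promises %d rows, file has %d", path, count, length(body))
  }
  vectors <- matrix(0, nrow = count, ncol = dim)
  tokens <- character(count)
  for (i in seq_len(count)) {
    fields <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(fields) != dim + 1L) {
      abort_parse("'%s': row %d has %d values, expected %d", path, i,
                  length(fields) - 1L, dim)
    }
    tokens[i] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) abort_parse("'%s': row %d contains a non-numeric value", path, i)
    vectors[i, ] <- vals
  }
  rownames(vectors) <- tokens
  structure(list(vectors = vectors, dim = dim), class = "word2vec_table")
}

#' Look up a pretrained embedding vector
#'
#' Tokens absent from the table fall back to the supplied vector (the
#' trainable UNK row of the model), matching the package's OOV policy:
#' verbatim, then lowercased, then fallback.
#'
#' @param table A [load_word2vec_text()] result.
#' @param token Single token to look up.
#' @param fallback Numeric vector of length `table$dim` returned for
#'   unlisted tokens.
#' @return Numeric vector of length `table$dim`.
#' @export
embedding_lookup <- function(table, token, fallback = rep(0, table$dim)) {
  if (token %in% rownames(table$vectors)) return(table$vectors[token, ])
  lo <- tolower(token)
  if (lo %in% rownames(table$vectors)) return(table$vectors[lo, ])
  if (length(fallback) != table$dim) {
    abort_validation("fallback vector has length %d, expected %d",
                     length(fallback), table$dim)
  }
  fallback
}
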