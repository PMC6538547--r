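#' Labeled sentences and corpora
#'
#' A `labeled_sentence` holds one tokenized sentence together with its aligned
#' per-token tags ("O", or `PREFIX-TYPE` with prefix `B`, `I`, `E` or `S`).
#' A `labeled_corpus` bundles train/dev/test splits of labeled sentences for
#' one dataset, typically annotated with a single entity type (as biomedical
#' NER gold standards usually are).
#'
#' Token indices are 0-based throughout the package and entity spans are
#' closed intervals `[start, end]`.
#'
#' @param tokens Character vector of surface tokens.
#' @param tags Character vector of tags, same length as `tokens`.
#' @param validate If `TRUE`, additionally require the tag sequence to parse
#'   under the BIOES grammar (see [is_valid_bioes()]).
#' @return An object of class `labeled_sentence` (a list with elements
#'   `tokens` and `tags`).
#' @examples
#' s <- labeled_sentence(c("IL-2", "binds"), c("S-gene", "O"))
#' s$tokens
#' @export
labeled_sentence <- function(tokens, tags, validate = FALSE) {
  tokens <- as.character(tokens)
  tags <- as.character(tags)
  if (length(tokens) == 0L) {
    abort_validation("a labeled sentence must contain at least one token")
  }
  if (length(tokens) != length(tags)) {
    abort_validation("tokens (%d) and tags (%d) differ in length",
                     length(tokens), length(tags))
  }
  bad <- !grepl("^(O|[BIES]-.+)$", tags)
  if (any(bad)) {
    abort_validation("malformed tag '%s' (expected 'O' or 'PREFIX-TYPE')",
                     tags[which(bad)[1L]])
  }
  if (validate && !is_valid_bioes(tags)) {
    abort_validation("tag sequence does not parse under the BIOES grammar")
  }
  structure(list(tokens = tokens, tags = tags), class = "labeled_sentence")
}

#' @param name Dataset identifier.
#' @param entity_types Character vector of entity-type labels annotated in
#'   this corpus.
#' @param train,dev,test Lists of [labeled_sentence()] objects.
#' @rdname labeled_sentence
#' @export
labeled_corpus <- function(name, entity_types, train = list(), dev = list(),
                           test = list()) {
  corpus <- structure(
    list(name = as.character(name),
         entity_types = sort(unique(as.character(entity_types))),
         train = train, dev = dev, test = test),
    class = "labeled_corpus")
  for (split in c("train", "dev", "test")) {
    for (s in corpus[[split]]) {
      types <- tag_types(s$tags)
      unknown <- setdiff(types, corpus$entity_types)
      if (length(unknown)) {
        abort_validation("corpus '%s' (%s split) contains tag type '%s' not in entity_types",
                         corpus$name, split, unknown[1L])
      }
    }
  }
  corpus
}

# Entity types mentioned by a tag vector.
#' @keywords internal
#' @noRd
tag_types <- function(tags) {
  ent <- tags[tags != "O"]
  unique(sub("^[BIES]-", "", ent))
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus> %s  [types: %s]\n", x$name,
              paste(x$entity_types, collapse = ", ")))
  cat(sprintf("  train: %d  dev: %d  test: %d sentences\n",
              length(x$train), length(x$dev), length(x$test)))
  invisible(x)
}

#' Read a two-column CoNLL-style corpus file
#'
#' Each non-blank line is `token<TAB>tag`; a blank line ends a sentence.
#' Tags may be in the BIO or BIOES dialect, declared by the caller; the file
#' content is not converted (use [bio_to_bioes()] for that).
#'
#' @param path Path to a UTF-8 text file.
#' @param scheme Tag dialect the file is written in, `"bioes"` or `"bio"`.
#'   Recorded on the result as an attribute; malformed tag strings are
#'   rejected either way.
#' @return A list of [labeled_sentence()] objects, in file order. An empty
#'   file yields an empty list.
#' @export
read_conll <- function(path, scheme = c("bioes", "bio")) {
  scheme <- match.arg(scheme)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  tok <- character()
  tag <- character()
  flush <- function() {
    if (length(tok)) {
      sentences[[length(sentences) + 1L]] <<- labeled_sentence(tok, tag)
      tok <<- character(); tag <<- character()
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") { flush(); next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L) {
      abort_parse("line %d of '%s': expected 'token<TAB>tag', got %d field(s)",
                  i, path, length(fields))
    }
    tok <- c(tok, fields[[1L]])
    tag <- c(tag, fields[[2L]])
  }
  flush()
  attr(sentences, "scheme") <- scheme
  sentences
}

#' Write sentences to a two-column CoNLL-style file
#'
#' Inverse of [read_conll()]: `read_conll(write_conll(x))` reproduces `x`.
#'
#' @param sentences List of [labeled_sentence()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    if (any(grepl("\t", s$tokens, fixed = TRUE))) {
      abort_validation("token contains a TAB character; not representable in CoNLL format")
    }
    paste(paste(s$tokens, s$tags, sep = "\t"), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(blocks)) {
    writeLines(c(paste(blocks, collapse = "\n\n"), ""), con, useBytes = TRUE)
  }
  invisible(path)
}
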