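# Parameter initialization and the reference (pure-R) embedding path.
# The training loop evaluates the same operations in compiled code; these
# functions define the semantics and serve the user-facing API.

# Uniform Glorot-style initialization for an affine map fan_out x fan_in.
#' @keywords internal
#' @noRd
glorot <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -limit, limit), nrow, ncol)
}

# Character embeddings: uniform in [-0.5/d_char, +0.5/d_char].
#' @keywords internal
#' @noRd
init_char_embedding <- function(n_chars, d_char) {
  E <- matrix(runif(n_chars * d_char, -0.5 / d_char, 0.5 / d_char), d_char, n_chars)
  E[, 1L] <- 0   # PAD column
  E
}

# Word embedding table d_word x |vocab|; pretrained rows (verbatim, then
# lowercased match) override the random initialization; PAD is zero; UNK and
# unlisted tokens keep the trained random initialization.
#' @keywords internal
#' @noRd
init_word_embedding <- function(vocab, d_word, pretrained = NULL) {
  tokens <- names(vocab$token_to_id)
  E <- matrix(runif(d_word * length(tokens), -0.5 / d_word, 0.5 / d_word),
              d_word, length(tokens))
  E[, vocab$token_to_id[[PAD_TOKEN]]] <- 0
  if (!is.null(pretrained)) {
    if (pretrained$dim != d_word) {
      abort_validation("pretrained embedding dimension %d != d_word %d",
                       pretrained$dim, d_word)
    }
    known <- rownames(pretrained$vectors)
    for (tok in tokens) {
      if (tok %in% c(PAD_TOKEN, UNK_TOKEN)) next
      hit <- if (tok %in% known) tok else if (tolower(tok) %in% known) tolower(tok) else NA
      if (!is.na(hit)) E[, vocab$token_to_id[[tok]]] <- pretrained$vectors[hit, ]
    }
  }
  E
}

#' Character windows of a word
#'
#' For a word of `M` characters and odd window size `k`, returns the `M`
#' window vectors: each column is the concatenation of the `k` character
#' embeddings centred on one character, with `(k-1)/2` padding positions on
#' each side drawn from the dedicated PAD character embedding.
#'
#' @param word A single surface token (at least one character).
#' @param k Odd window size.
#' @param model A single-task model (see [stm_init()]) supplying the
#'   character embedding matrix and vocabulary.
#' @return A numeric matrix of shape `(k * d_char) x M`.
#' @export
char_windows <- function(word, k, model) {
  if (nchar(word) < 1L) abort_validation("char_windows() requires a non-empty word")
  if (k %% 2L == 0L) abort_validation("window size must be odd")
  ids <- char_ids(model$vocab, word)
  M <- length(ids)
  d_char <- nrow(model$params$Echar)
  pad <- (k - 1L) / 2L
  pad_id <- model$vocab$char_to_id[[PAD_TOKEN]]
  padded <- c(rep(pad_id, pad), ids, rep(pad_id, pad))
  out <- matrix(0, k * d_char, M)
  for (i in seq_len(M)) {
    cols <- padded[i:(i + k - 1L)]
    out[, i] <- as.vector(model$params$Echar[, cols])
  }
  out
}

#' Character-level word embedding of a word
#'
#' For each window size `k`, applies the filter bank (affine map) to every
#' character window and takes the coordinate-wise maximum over the word's
#' positions; the per-window-size results are concatenated into a vector of
#' dimension `d_clwe`.
#'
#' @inheritParams char_windows
#' @return Numeric vector of length `d_clwe`.
#' @export
char_embed <- function(word, model) {
  parts <- lapply(model$windows, function(k) {
    W <- model$params[[paste0("convW_", k)]]
    b <- model$params[[paste0("convb_", k)]]
    scores <- W %*% char_windows(word, k, model) + b
    apply(scores, 1L, max)
  })
  unlist(parts, use.names = FALSE)
}

#' Embed a sentence
#'
#' Maps each token to the concatenation of its word embedding and its
#' CNN character-level word embedding, `x̂_t = [x_t, x^c_t]`.
#'
#' @param tokens Character vector of surface tokens.
#' @param model A single-task model (see [stm_init()]).
#' @return Numeric matrix of shape `(d_word + d_clwe) x N`, one column per
#'   token in order.
#' @export
embed_sentence <- function(tokens, model) {
  wid <- token_ids(model$vocab, tokens)
  word_part <- model$params$Eword[, wid, drop = FALSE]
  char_part <- vapply(tokens, function(w) char_embed(w, model),
                      numeric(model$config$d_clwe))
  out <- rbind(word_part, matrix(char_part, ncol = length(tokens)))
  dimnames(out) <- NULL
  out
}
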