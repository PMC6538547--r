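# Shared fixtures and independent oracles. Everything here is written
# directly from the definitions (enumeration, brute force) so that it never
# shares code with the implementation it checks.

tiny_corpus <- function(n_train = 30L, n_dev = 10L, n_test = 10L, seed = 3L,
                        types = "gene", n_poly = 0L) {
  spec <- synth_spec(entity_types = types, n_polysemous = n_poly,
                     n_sentences = c(n_train, n_dev, n_test), seed = seed)
  generate_corpora(spec)
}

desk_model <- function(types = "gene", seed = 2L, ...) {
  corp <- tiny_corpus(types = types)
  vocab <- build_vocab(corp)
  stm_init(vocab, types, stm_config("desk", ...), seed = seed)
}

# Random CRF instance: emissions n_tags x T and transition (n_tags+1) x n_tags.
random_crf_instance <- function(T, n_tags = 5L, scale = 1) {
  list(z = matrix(rnorm(n_tags * T, sd = scale), n_tags, T),
       A = matrix(rnorm((n_tags + 1L) * n_tags, sd = scale), n_tags + 1L, n_tags))
}

# Brute-force path score, written independently from the package.
oracle_path_score <- function(z, A, y) {
  n <- nrow(z)
  s <- A[n + 1L, y[1L]] + z[y[1L], 1L]
  for (t in seq_along(y)[-1L]) s <- s + A[y[t - 1L], y[t]] + z[y[t], t]
  s
}

# All tag-index paths of length T over n tags.
all_paths <- function(T, n_tags) {
  as.matrix(expand.grid(rep(list(seq_len(n_tags)), T)))
}

# Brute-force log partition function by full enumeration.
oracle_logZ <- function(z, A) {
  paths <- all_paths(ncol(z), nrow(z))
  scores <- apply(paths, 1L, function(y) oracle_path_score(z, A, y))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# Independent BIO validity: I must continue a same-type B/I.
oracle_valid_bio <- function(tags) {
  prev <- "O"
  for (tg in tags) {
    p <- substr(tg, 1L, 1L)
    ty <- sub("^[BI]-", "", tg)
    if (p == "I") {
      pp <- substr(prev, 1L, 1L)
      if (!(pp %in% c("B", "I")) || sub("^[BI]-", "", prev) != ty) return(FALSE)
    }
    prev <- tg
  }
  TRUE
}

# Independent BIOES validity via explicit state machine.
oracle_valid_bioes <- function(tags) {
  open <- NULL
  for (tg in tags) {
    p <- substr(tg, 1L, 1L)
    ty <- sub("^[BIES]-", "", tg)
    if (is.null(open)) {
      if (p %in% c("I", "E")) return(FALSE)
      if (p == "B") open <- ty
    } else {
      if (p == "I" && ty == open) next
      if (p == "E" && ty == open) { open <- NULL; next }
      return(FALSE)
    }
  }
  is.null(open)
}

# Enumerate all VALID BIO sequences of a given length by recursive
# construction from the grammar (O and B-t always allowed; I-t only after
# B-t/I-t).
enumerate_valid_bio <- function(len, types) {
  recur <- function(prefix, remaining) {
    if (remaining == 0L) return(list(prefix))
    out <- list()
    last <- if (length(prefix)) prefix[length(prefix)] else "O"
    for (tg in bio_alphabet(types)) {
      p <- substr(tg, 1L, 1L)
      if (p == "I") {
        lp <- substr(last, 1L, 1L)
        if (!(lp %in% c("B", "I")) ||
            sub("^[BI]-", "", last) != sub("^I-", "", tg)) next
      }
      out <- c(out, recur(c(prefix, tg), remaining - 1L))
    }
    out
  }
  recur(character(0), len)
}

# Enumerate all VALID BIOES sequences: state is the open run type (or none).
enumerate_valid_bioes <- function(len, types) {
  recur <- function(prefix, open, remaining) {
    if (remaining == 0L) {
      return(if (is.null(open)) list(prefix) else list())
    }
    out <- list()
    if (is.null(open)) {
      for (tg in c("O", paste0("S-", types))) {
        out <- c(out, recur(c(prefix, tg), NULL, remaining - 1L))
      }
      for (ty in types) {
        out <- c(out, recur(c(prefix, paste0("B-", ty)), ty, remaining - 1L))
      }
    } else {
      out <- c(out, recur(c(prefix, paste0("I-", open)), open, remaining - 1L))
      out <- c(out, recur(c(prefix, paste0("E-", open)), NULL, remaining - 1L))
    }
    out
  }
  recur(character(0), NULL, len)
}

# All tag sequences of a given length over an alphabet.
all_tag_seqs <- function(length, alphabet) {
  grid <- expand.grid(rep(list(alphabet), length), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

bio_alphabet <- function(types) c("O", paste0(rep(c("B-", "I-"), length(types)),
                                              rep(types, each = 2L)))
bioes_alphabet <- function(types) c("O", paste0(rep(c("B-", "I-", "E-", "S-"),
                                                    length(types)),
                                                rep(types, each = 4L)))

# Entity spans of a valid BIOES sequence, recomputed independently.
oracle_spans <- function(tags) {
  out <- list()
  start <- NA
  for (t in seq_along(tags)) {
    p <- substr(tags[t], 1L, 1L)
    ty <- sub("^[BIES]-", "", tags[t])
    if (p == "S") out[[length(out) + 1L]] <- c(t - 1L, t - 1L, ty)
    if (p == "B") start <- t - 1L
    if (p == "E") { out[[length(out) + 1L]] <- c(start, t - 1L, ty); start <- NA }
  }
  out
}
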