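#' Specification of a synthetic multi-corpus NER benchmark
#'
#' Describes a family of single-entity-type corpora over a shared vocabulary,
#' emulating the setting of real biomedical NER gold standards: each corpus
#' annotates only its own entity type (mentions of the other types occur but
#' are tagged `O`), and a configurable number of *polysemous* tokens are
#' valid entities of more than one type, their true type in a sentence being
#' determined by the nearest preceding context-cue token — the planted
#' analogue of names like *VHL* that are a disease in one context and a gene
#' in another.
#'
#' Surface rule: unambiguous entity tokens of type `t` carry the suffix
#' `_t` (learnable by a character CNN); polysemous tokens and cue tokens
#' carry no suffix, so only context disambiguates them.
#'
#' @param entity_types Character vector of type names (one corpus each).
#' @param vocab_size_per_type Number of unambiguous entity tokens per type.
#' @param n_polysemous Number of tokens valid as entities of any type.
#' @param n_context_cues Number of cue tokens per type.
#' @param sentence_length Length-2 integer vector `(min, max)`: target
#'   sentence length in tokens.
#' @param entity_rate Expected number of entity mentions per sentence
#'   (Poisson, capped at 3).
#' @param own_type_rate Probability that a mention in a corpus is of that
#'   corpus's own entity type (remaining mass uniform over the other
#'   types). Real single-type gold standards are collected to be rich in
#'   their own type, which is precisely what starves a single-task model of
#'   other-type context; ignored when only one type exists.
#' @param n_sentences Sentences per split, a length-3 vector
#'   `(train, dev, test)` (a single value is used for all three splits).
#'   The default approximates a 70/15/15 division.
#' @param seed Integer seed; identical specs generate byte-identical
#'   corpora.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(entity_types = c("disease", "gene"),
                       vocab_size_per_type = 30L,
                       n_polysemous = 5L,
                       n_context_cues = 3L,
                       sentence_length = c(6L, 12L),
                       entity_rate = 1.5,
                       own_type_rate = 0.8,
                       n_sentences = c(2000L, 430L, 430L),
                       seed = 42L) {
  spec <- list(entity_types = as.character(entity_types),
               vocab_size_per_type = as.integer(vocab_size_per_type),
               n_polysemous = as.integer(n_polysemous),
               n_context_cues = as.integer(n_context_cues),
               sentence_length = as.integer(sentence_length),
               entity_rate = as.numeric(entity_rate),
               own_type_rate = as.numeric(own_type_rate),
               n_sentences = as.integer(n_sentences),
               seed = as.integer(seed))
  if (length(spec$n_sentences) == 1L) spec$n_sentences <- rep(spec$n_sentences, 3L)
  if (length(spec$entity_types) < 1L || anyDuplicated(spec$entity_types)) {
    abort_validation("entity_types must be a non-empty set of distinct names")
  }
  if (spec$vocab_size_per_type < 1L || spec$n_context_cues < 1L ||
      any(spec$n_sentences < 1L) || spec$n_polysemous < 0L) {
    abort_validation("all synthetic-spec counts must be positive")
  }
  if (length(spec$sentence_length) != 2L ||
      spec$sentence_length[1L] > spec$sentence_length[2L] ||
      spec$sentence_length[1L] < 1L) {
    abort_validation("sentence_length must be (min, max) with 1 <= min <= max")
  }
  if (spec$entity_rate < 0 || spec$entity_rate > spec$sentence_length[2L]) {
    abort_validation("entity_rate must lie in [0, max sentence length]")
  }
  if (spec$own_type_rate < 0 || spec$own_type_rate > 1) {
    abort_validation("own_type_rate must lie in [0, 1]")
  }
  structure(spec, class = "synth_spec")
}

#' The two-type polysemy benchmark
#'
#' A fixed desk-scale configuration used to measure the collaboration
#' effect: two entity types, five planted polysemous tokens, 800/200/200
#' sentences per corpus.
#'
#' @param seed Integer seed.
#' @return A [synth_spec()].
#' @export
polysemy_benchmark_spec <- function(seed = 42L) {
  synth_spec(entity_types = c("disease", "gene"), n_polysemous = 5L,
             n_sentences = c(800L, 200L, 200L), seed = seed)
}

# Number of filler (always-O) tokens in the shared vocabulary.
N_FILLER <- 40L
# Probability that a mention uses a polysemous surface (when any exist).
P_POLYSEMOUS <- 0.3
# Probability that an unambiguous mention spans 2-3 tokens (B/I/E), else S.
P_MULTI_TOKEN <- 0.3
MAX_MENTIONS <- 3L

#' Generate synthetic single-entity-type corpora
#'
#' Produces one [labeled_corpus()] per entity type of the spec. Each
#' sentence is generated once with a full gold annotation over all types
#' (kept in the per-sentence element `full_tags`) and then projected so the
#' corpus tags only its own type — replicating the single-type annotation of
#' real biomedical datasets. Polysemous mentions are always preceded (within
#' 1-2 tokens) by a cue token of their true type, and cue tokens occur
#' nowhere else, so the nearest preceding cue determines the gold type.
#'
#' @param spec A [synth_spec()].
#' @return Named list of [labeled_corpus()] objects, one per entity type
#'   (sorted), with the token inventories attached as attribute
#'   `"inventory"`.
#' @export
generate_corpora <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  types <- sort(spec$entity_types)
  inv <- make_inventories(spec, types)
  corpora <- stats::setNames(vector("list", length(types)), types)
  splits <- c(train = spec$n_sentences[1L], dev = spec$n_sentences[2L],
              test = spec$n_sentences[3L])
  for (ty in types) {
    parts <- lapply(splits, function(n) {
      lapply(seq_len(n), function(i) make_sentence(spec, inv, types, ty))
    })
    corpora[[ty]] <- labeled_corpus(name = ty, entity_types = ty,
                                    train = parts$train, dev = parts$dev,
                                    test = parts$test)
  }
  attr(corpora, "inventory") <- inv
  corpora
}

#' @keywords internal
#' @noRd
make_inventories <- function(spec, types) {
  n_types <- length(types)
  need <- N_FILLER + spec$n_polysemous + n_types * spec$n_context_cues +
    n_types * spec$vocab_size_per_type
  stems <- character(0)
  while (length(stems) < need) {
    cand <- replicate(need, paste(sample(letters, 4L, replace = TRUE), collapse = ""))
    stems <- unique(c(stems, cand))
  }
  stems <- stems[seq_len(need)]
  take <- function(n) { out <- stems[seq_len(n)]; stems <<- stems[-seq_len(n)]; out }
  filler <- take(N_FILLER)
  poly <- if (spec$n_polysemous > 0L) take(spec$n_polysemous) else character(0)
  cues <- stats::setNames(lapply(types, function(ty) take(spec$n_context_cues)), types)
  entities <- stats::setNames(lapply(types, function(ty) {
    paste0(take(spec$vocab_size_per_type), "_", ty)
  }), types)
  list(filler = filler, poly = poly, cues = cues, entities = entities)
}

# One sentence with full annotation over all types, projected to `own_type`.
#' @keywords internal
#' @noRd
make_sentence <- function(spec, inv, types, own_type) {
  target_len <- sample(seq(spec$sentence_length[1L], spec$sentence_length[2L]), 1L)
  n_ent <- min(stats::rpois(1L, spec$entity_rate), MAX_MENTIONS)
  groups <- vector("list", n_ent)
  for (i in seq_len(n_ent)) {
    ty <- if (length(types) == 1L || stats::runif(1L) < spec$own_type_rate) {
      own_type
    } else {
      others <- setdiff(types, own_type)
      others[sample.int(length(others), 1L)]
    }
    if (length(inv$poly) && stats::runif(1L) < P_POLYSEMOUS) {
      gap <- if (stats::runif(1L) < 0.5) inv$filler[sample.int(N_FILLER, 1L)] else character(0)
      toks <- c(inv$cues[[ty]][sample.int(length(inv$cues[[ty]]), 1L)], gap,
                inv$poly[sample.int(length(inv$poly), 1L)])
      tags <- c(rep("O", length(toks) - 1L), paste0("S-", ty))
    } else if (stats::runif(1L) < P_MULTI_TOKEN) {
      len <- sample(2:3, 1L)
      toks <- inv$entities[[ty]][sample.int(length(inv$entities[[ty]]), len, replace = TRUE)]
      tags <- c(paste0("B-", ty), rep(paste0("I-", ty), len - 2L), paste0("E-", ty))
    } else {
      toks <- inv$entities[[ty]][sample.int(length(inv$entities[[ty]]), 1L)]
      tags <- paste0("S-", ty)
    }
    groups[[i]] <- list(toks = toks, tags = tags)
  }
  n_group_tokens <- sum(vapply(groups, function(g) length(g$toks), integer(1)))
  # At least one filler token between consecutive mentions: keeps the gold
  # segmentation a deterministic function of the token string (adjacent
  # entities would be irreducibly ambiguous under exact-match scoring).
  n_fill <- max(1L, n_ent, target_len - n_group_tokens)
  fill <- inv$filler[sample.int(N_FILLER, n_fill, replace = TRUE)]
  cuts <- sort(sample(0:n_fill, n_ent, replace = FALSE))
  tokens <- character(0); full <- character(0)
  prev <- 0L
  for (i in seq_len(n_ent)) {
    if (cuts[i] > prev) {
      tokens <- c(tokens, fill[(prev + 1L):cuts[i]])
      full <- c(full, rep("O", cuts[i] - prev))
    }
    tokens <- c(tokens, groups[[i]]$toks)
    full <- c(full, groups[[i]]$tags)
    prev <- cuts[i]
  }
  if (prev < n_fill) {
    tokens <- c(tokens, fill[(prev + 1L):n_fill])
    full <- c(full, rep("O", n_fill - prev))
  }
  own <- ifelse(full == "O" | sub("^[BIES]-", "", full) != own_type, "O", full)
  s <- labeled_sentence(tokens, own)
  s$full_tags <- full
  s
}

#' Summarize generated corpora
#'
#' @param corpora Result of [generate_corpora()] (or any list of
#'   [labeled_corpus()] objects whose sentences may carry `full_tags`).
#' @return Data frame with one row per corpus and split: sentence count,
#'   own-type entity count, and the number of entity mentions whose surface
#'   is polysemous (no type suffix).
#' @export
describe_corpora <- function(corpora) {
  rows <- list()
  for (co in corpora) {
    for (split in c("train", "dev", "test")) {
      sents <- co[[split]]
      n_ent <- 0L; n_poly <- 0L
      for (s in sents) {
        sp <- extract_spans(s$tags)
        n_ent <- n_ent + nrow(sp)
        if (nrow(sp)) {
          surf <- s$tokens[sp$start + 1L]
          n_poly <- n_poly + sum(!grepl("_", surf, fixed = TRUE))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        corpus = co$name, split = split, sentences = length(sents),
        entities = n_ent, polysemous_mentions = n_poly,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(corpus = character(0), split = character(0),
                      sentences = integer(0), entities = integer(0),
                      polysemous_mentions = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
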