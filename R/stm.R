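#' Initialize a single-task BiLSTM-CRF tagger
#'
#' A single-task model (STM) couples the embedding layers (word table and
#' character CNN), a bidirectional LSTM encoder whose input additionally
#' carries a fixed-size *collaborator-feature slot* (zero when the model
#' runs alone), a per-tag emission layer and a learned tag-transition
#' matrix. All affine maps use uniform Glorot-style initialization; the
#' transition matrix starts at zero and is learned freely — structurally
#' invalid BIOES transitions are handled after decoding by
#' [fix_invalid_bioes()], not by masking.
#'
#' @param vocab A [build_vocab()] result.
#' @param entity_types Entity types this model tags (usually one).
#' @param config An [stm_config()].
#' @param pretrained Optional [load_word2vec_text()] table for the word
#'   embeddings.
#' @param seed Integer seed controlling initialization.
#' @return An object of class `collabotag_stm`.
#' @export
stm_init <- function(vocab, entity_types, config = stm_config("desk"),
                     pretrained = NULL, seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed))
  tags <- bioes_tag_set(entity_types)
  n_tags <- length(tags)
  slot_dim <- as.integer(config$slot_dim %||% (2L * config$d_lstm))
  d_in <- config$d_word + config$d_clwe + slot_dim
  H <- config$d_lstm
  dk <- config$d_clwe %/% length(config$windows)
  params <- list(
    Eword = init_word_embedding(vocab, config$d_word, pretrained),
    Echar = init_char_embedding(length(vocab$char_to_id), config$d_char))
  for (k in config$windows) {
    params[[paste0("convW_", k)]] <- glorot(dk, k * config$d_char)
    params[[paste0("convb_", k)]] <- rep(0, dk)
  }
  params$fWx <- glorot(4L * H, d_in); params$fWh <- glorot(4L * H, H)
  params$fb <- rep(0, 4L * H)
  params$bWx <- glorot(4L * H, d_in); params$bWh <- glorot(4L * H, H)
  params$bb <- rep(0, 4L * H)
  params$Wy <- glorot(n_tags, 2L * H); params$by <- rep(0, n_tags)
  params$A <- matrix(0, n_tags + 1L, n_tags)
  structure(list(params = params, windows = as.integer(config$windows),
                 tag_set = tags, entity_types = sort(unique(entity_types)),
                 vocab = vocab, config = config,
                 epochs_trained = 0L, version = 0L),
            class = "collabotag_stm")
}

#' @export
print.collabotag_stm <- function(x, ...) {
  cat(sprintf(
    "<collabotag_stm> types: %s | d_word=%d d_clwe=%d d_lstm=%d | %d tags | %d epochs trained\n",
    paste(x$entity_types, collapse = ","), x$config$d_word, x$config$d_clwe,
    x$config$d_lstm, length(x$tag_set), x$epochs_trained))
  invisible(x)
}

# Convert one labeled_sentence into the id form the kernels consume.
#' @keywords internal
#' @noRd
prepare_sentence <- function(model, sentence, with_gold = TRUE) {
  tag_ids <- NULL
  if (with_gold) {
    tag_ids <- match(sentence$tags, model$tag_set)
    if (anyNA(tag_ids)) {
      abort_validation("tag '%s' not in this model's tag set",
                       sentence$tags[which(is.na(tag_ids))[1L]])
    }
  }
  list(wid = token_ids(model$vocab, sentence$tokens),
       chars = lapply(sentence$tokens, function(w) char_ids(model$vocab, w)),
       gold = tag_ids)
}

#' @keywords internal
#' @noRd
prepare_split <- function(model, sentences, with_gold = TRUE) {
  lapply(sentences, prepare_sentence, model = model, with_gold = with_gold)
}

#' Encode a sentence with the BiLSTM
#'
#' Runs the embedding layers and the bidirectional LSTM in inference mode
#' (no dropout) and returns the concatenated hidden states
#' `h^bi_t = [h^f_t, h^b_t]`. Forward states depend only on tokens at
#' positions `<= t`, backward states only on positions `>= t`.
#'
#' @param model A [stm_init()] model.
#' @param tokens Character vector of surface tokens.
#' @param slot Optional `2*d_lstm x N` matrix of collaborator features
#'   concatenated to each token's embedding; zeros when omitted.
#' @return Numeric matrix `2*d_lstm x N`.
#' @export
encode_sentence <- function(model, tokens, slot = NULL) {
  prep <- prepare_sentence(model, labeled_sentence(tokens, rep("O", length(tokens))),
                           with_gold = FALSE)
  if (!is.null(slot)) {
    if (nrow(slot) != 2L * model$config$d_lstm || ncol(slot) != length(tokens)) {
      abort_validation("slot must be a %d x %d matrix",
                       2L * model$config$d_lstm, length(tokens))
    }
    prep$slot <- slot
  }
  cpp_stm_encode(model$params, model$windows, prep)
}

#' Emission scores and tag probabilities
#'
#' `emissions()` applies the fully connected layer `z_t = W_y h_t + b_y` to
#' encoder states; `tag_probabilities()` turns emission scores into
#' per-position softmax distributions over tags (columns sum to 1).
#'
#' @param model A [stm_init()] model.
#' @param h Matrix of encoder states (`2*d_lstm x N`).
#' @return `emissions()`: an `n_tags x N` score matrix. `tag_probabilities()`:
#'   a matrix of the same shape with non-negative columns summing to 1.
#' @export
emissions <- function(model, h) {
  model$params$Wy %*% h + model$params$by
}

#' @param z Emission score matrix (`n_tags x N`).
#' @rdname emissions
#' @export
tag_probabilities <- function(z) {
  apply(z, 2L, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
}

#' CRF path score, losses and decoding
#'
#' For emission scores `z` (`n_tags x T`), transition matrix `A`
#' (`(n_tags+1) x n_tags`, last row = start scores) and a tag-index path
#' `y` (1-based):
#' \describe{
#'   \item{`path_score()`}{`A[start, y_1] + z[y_1, 1] + sum_t (A[y_{t-1}, y_t] + z[y_t, t])`.}
#'   \item{`crf_nll()`}{with `mode = "nll"` (default), the negative
#'     sentence-level log likelihood `log Z - path_score(y)`, with the
#'     partition function computed by the forward algorithm; with
#'     `mode = "neg_score"`, the literal negated path score (no partition
#'     term).}
#'   \item{`lstm_loss()`}{the per-position softmax cross entropy
#'     `-sum_t log softmax(z_t)[y_t]`.}
#'   \item{`total_loss()`}{`lstm_loss + crf_nll`.}
#'   \item{`viterbi_decode()`}{the highest-scoring tag path; ties broken
#'     toward the lowest tag index at every backtrack step, so the result
#'     is deterministic.}
#' }
#'
#' @param z Emission matrix, `n_tags x T`.
#' @param A Transition matrix, `(n_tags+1) x n_tags`.
#' @param y Integer vector of 1-based gold tag indices, length `T`.
#' @param mode `"nll"` or `"neg_score"`.
#' @return `path_score`, `crf_nll`, `lstm_loss`, `total_loss`: a scalar.
#'   `viterbi_decode`: list with `path` (1-based integer vector) and
#'   `score`.
#' @export
path_score <- function(z, A, y) {
  check_crf_args(z, A, y)
  cpp_path_score(z, A, as.integer(y))
}

#' @rdname path_score
#' @export
crf_nll <- function(z, A, y, mode = c("nll", "neg_score")) {
  mode <- match.arg(mode)
  check_crf_args(z, A, y)
  cpp_crf_loss(z, A, as.integer(y), mode)
}

#' @rdname path_score
#' @export
lstm_loss <- function(z, y) {
  stopifnot(ncol(z) == length(y))
  sum(vapply(seq_along(y), function(t) {
    log_sum_exp(z[, t]) - z[y[t], t]
  }, numeric(1)))
}

#' @rdname path_score
#' @export
total_loss <- function(z, A, y, mode = c("nll", "neg_score")) {
  mode <- match.arg(mode)
  lstm_loss(z, y) + crf_nll(z, A, y, mode)
}

#' @rdname path_score
#' @export
viterbi_decode <- function(z, A) {
  check_crf_args(z, A, NULL)
  cpp_viterbi(z, A)
}

#' @keywords internal
#' @noRd
check_crf_args <- function(z, A, y) {
  n <- nrow(z)
  if (nrow(A) != n + 1L || ncol(A) != n) {
    abort_validation("A must be (n_tags+1) x n_tags for n_tags = %d", n)
  }
  if (!is.null(y)) {
    if (length(y) != ncol(z)) abort_validation("y and z disagree in length")
    if (any(y < 1L | y > n)) abort_validation("tag index out of range")
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Optimization

#' @keywords internal
#' @noRd
init_adagrad <- function(params) {
  lapply(params, function(p) p * 0)
}

# One AdaGrad step on a named list of parameters. Returns list(params, state).
#' @keywords internal
#' @noRd
adagrad_step <- function(params, grads, state, lr, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- state[[nm]] + g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

#' @keywords internal
#' @noRd
global_norm <- function(grad_list) {
  sqrt(sum(vapply(grad_list, function(g) sum(g * g), numeric(1))))
}

#' Train a single-task model for one epoch
#'
#' One full pass over the training split in mini-batches of the configured
#' size, with AdaGrad updates at learning rate `lr * decay^epoch` (the
#' epoch counter lives on the model), dropout active (CLWE and BiLSTM
#' output rates from the config), and global-norm gradient clipping.
#' Gradients are averaged within each mini-batch. When `collab` is given,
#' each sentence's collaborator-feature slot is concatenated to the encoder
#' input and the aggregation weights alpha receive gradients through the
#' weighted max-pooling (collaborator parameters are never touched).
#'
#' @param model A [stm_init()] model.
#' @param data Prepared training sentences (internal id form); use
#'   [train_stm()] for the corpus-level interface.
#' @param opt AdaGrad state from a previous call, or `NULL` to start fresh.
#' @param collab Optional collaborator-feature bundle built by
#'   [collaborator_features()] applied to each sentence: list with `slots`
#'   (per-sentence feature lists), `alpha` (named numeric), `opt_alpha`.
#' @param shuffle Shuffle sentence order (uses the R RNG, so seeded runs
#'   are reproducible).
#' @return List with the updated `model`, `opt`, `alpha`, `opt_alpha`, and
#'   `mean_loss`.
#' @export
train_epoch <- function(model, data, opt = NULL, collab = NULL, shuffle = TRUE) {
  cfg <- model$config
  if (is.null(opt)) opt <- init_adagrad(model$params)
  alpha <- collab$alpha
  opt_alpha <- collab$opt_alpha
  if (!is.null(collab) && is.null(opt_alpha)) {
    opt_alpha <- setNames(rep(0, length(alpha)), names(alpha))
  }
  n <- length(data)
  if (n == 0L) {
    return(list(model = model, opt = opt, alpha = alpha,
                opt_alpha = opt_alpha, mean_loss = NA_real_))
  }
  lr <- cfg$lr * cfg$lr_decay^model$epochs_trained
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  trainable <- names(model$params)
  if (isTRUE(cfg$freeze_word_embeddings)) trainable <- setdiff(trainable, "Eword")
  if (isTRUE(cfg$freeze_target_embeddings) && !is.null(collab)) {
    trainable <- setdiff(trainable, grep("^(Eword|Echar|conv)", names(model$params), value = TRUE))
  }
  total_loss <- 0
  starts <- seq(1L, n, by = cfg$batch_size)
  for (s in starts) {
    idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
    sents <- data[idx]
    if (!is.null(collab)) {
      for (j in seq_along(idx)) sents[[j]]$slot <- collab$slots[[idx[j]]]$slot
    }
    res <- cpp_stm_batch(model$params, model$windows, sents,
                         cfg$dropout_clwe, cfg$dropout_lstm, cfg$crf_loss)
    if (any(!is.finite(res$loss_total))) {
      stop(errorCondition(
        sprintf("non-finite training loss in batch starting at sentence %d (losses: %s)",
                s, paste(signif(res$loss_total, 4), collapse = ", ")),
        class = c("collabotag_numeric_error", "error")))
    }
    total_loss <- total_loss + sum(res$loss_total)
    grads <- lapply(setNames(trainable, trainable), function(nm) {
      g <- res$grads[[nm]] / length(idx)
      if (is.null(dim(model$params[[nm]]))) as.vector(g) else g
    })
    dalpha <- NULL
    if (!is.null(collab)) {
      dalpha <- setNames(rep(0, length(alpha)), names(alpha))
      for (j in seq_along(idx)) {
        sl <- collab$slots[[idx[j]]]
        ds <- res$dslot[[j]]
        if (is.null(ds) || length(ds) == 0L) next
        for (ki in seq_along(names(alpha))) {
          k <- names(alpha)[ki]
          sel <- sl$amax == ki
          if (any(sel)) dalpha[[k]] <- dalpha[[k]] + sum(ds[sel] * sl$h[[k]][sel])
        }
      }
      dalpha <- dalpha / length(idx)
    }
    gn <- global_norm(c(grads, if (!is.null(dalpha)) list(dalpha)))
    if (is.finite(gn) && gn > cfg$clip_norm) {
      scale <- cfg$clip_norm / gn
      grads <- lapply(grads, `*`, scale)
      if (!is.null(dalpha)) dalpha <- dalpha * scale
    }
    step <- adagrad_step(model$params, grads, opt, lr)
    model$params[names(grads)] <- step$params[names(grads)]
    opt <- step$state
    if (!is.null(dalpha)) {
      opt_alpha <- opt_alpha + dalpha * dalpha
      alpha <- alpha - lr * dalpha / (sqrt(opt_alpha) + 1e-8)
    }
  }
  model$epochs_trained <- model$epochs_trained + 1L
  list(model = model, opt = opt, alpha = alpha, opt_alpha = opt_alpha,
       mean_loss = total_loss / n)
}

#' Train a single-task model on a corpus
#'
#' Convenience driver around [train_epoch()]: trains with a zeroed
#' collaborator slot until dev entity F1 fails to improve for
#' `config$patience` consecutive epochs (or `config$max_epochs` is
#' reached), and restores the best-epoch parameters.
#'
#' @param corpus A [labeled_corpus()] with train and dev splits.
#' @param config An [stm_config()].
#' @param vocab Optional shared [build_vocab()]; built from the corpus when
#'   omitted.
#' @param pretrained Optional pretrained word embeddings.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param quiet Suppress per-epoch progress lines (written with
#'   [message()]).
#' @return List with `model` (best epoch), `opt`, `log` (per-epoch data
#'   frame: epoch, loss, dev precision/recall/F1) and `best_epoch`.
#' @export
train_stm <- function(corpus, config = stm_config("desk"), vocab = NULL,
                      pretrained = NULL, seed = 1L, quiet = TRUE) {
  if (length(corpus$train) == 0L) abort_validation("empty training split")
  vocab <- vocab %||% build_vocab(list(corpus))
  model <- stm_init(vocab, corpus$entity_types, config, pretrained, seed)
  data <- prepare_split(model, corpus$train)
  dev <- prepare_split(model, corpus$dev, with_gold = FALSE)
  dev_gold <- lapply(corpus$dev, `[[`, "tags")
  opt <- NULL
  best <- list(f1 = -Inf, params = NULL, epoch = NA_integer_, epochs_trained = 0L)
  bad <- 0L
  log <- list()
  for (epoch in seq_len(config$max_epochs) - 1L) {
    res <- train_epoch(model, data, opt)
    model <- res$model; opt <- res$opt
    rep <- evaluate_tags(dev_gold, predict_prepared(model, dev))
    log[[length(log) + 1L]] <- data.frame(
      epoch = epoch, loss = res$mean_loss, dev_precision = rep$precision,
      dev_recall = rep$recall, dev_f1 = rep$f1)
    if (!quiet) {
      message(sprintf("epoch %d: loss %.4f dev F1 %.4f", epoch,
                      res$mean_loss, rep$f1))
    }
    if (rep$f1 > best$f1) {
      best <- list(f1 = rep$f1, params = model$params, epoch = epoch,
                   epochs_trained = model$epochs_trained)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model$params <- best$params
  model$epochs_trained <- best$epochs_trained
  list(model = model, opt = opt,
       log = do.call(rbind, c(log, list(make.row.names = FALSE))),
       best_epoch = best$epoch)
}

# Viterbi-decode prepared sentences; returns tag-index paths mapped to tags.
#' @keywords internal
#' @noRd
predict_prepared <- function(model, prepared, slots = NULL, repair = TRUE) {
  lapply(seq_along(prepared), function(i) {
    p <- prepared[[i]]
    if (!is.null(slots)) p$slot <- slots[[i]]$slot
    z <- cpp_stm_emissions(model$params, model$windows, p)
    tags <- model$tag_set[cpp_viterbi(z, model$params$A)$path]
    if (repair) fix_invalid_bioes(tags) else tags
  })
}

#' Predict tags for sentences with a single-task model
#'
#' Deterministic: dropout is disabled and Viterbi ties are broken toward
#' the lowest tag index. Structurally invalid BIOES output is repaired with
#' [fix_invalid_bioes()] unless `repair = FALSE`.
#'
#' @param model A trained [stm_init()] model.
#' @param sentences List of [labeled_sentence()] objects (tags ignored) or
#'   character vectors of tokens.
#' @param repair Apply [fix_invalid_bioes()] to the decoded tags.
#' @return List of character tag vectors, one per sentence.
#' @export
stm_predict <- function(model, sentences, repair = TRUE) {
  sentences <- lapply(sentences, function(s) {
    if (is.character(s)) labeled_sentence(s, rep("O", length(s))) else s
  })
  prepared <- prepare_split(model, sentences, with_gold = FALSE)
  predict_prepared(model, prepared, repair = repair)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing archive holding every
#' parameter array plus the configuration, vocabulary and counters;
#' `load_checkpoint(save_checkpoint(m, p))` reproduces `m` exactly.
#'
#' @param model A [stm_init()] model.
#' @param path File path (conventionally `.rds`).
#' @return `save_checkpoint()`: `path`, invisibly. `load_checkpoint()`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "collabotag_stm")) {
    abort_validation("'%s' is not a collabotag checkpoint", path)
  }
  model
}
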