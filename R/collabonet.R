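#' Initialize a collaboration state over several single-task models
#'
#' Builds one single-task BiLSTM-CRF expert per corpus over a shared
#' vocabulary, plus the per-(target, collaborator) aggregation weights
#' alpha, all initialized to 1, and a phase counter starting at 0. During
#' later phases each expert in turn becomes the *target* (the one model
#' trained for one epoch) while the others act as frozen *collaborators*
#' whose encoder outputs, scaled by alpha and combined by coordinate-wise
#' max pooling (or concatenation), fill the target's input slot.
#'
#' @param corpora List of [labeled_corpus()] objects, one per dataset
#'   (each typically annotating a single entity type).
#' @param config An [stm_config()] shared by all experts.
#' @param pretrained Optional [load_word2vec_text()] table.
#' @param seed Integer seed; model `i` is initialized with `seed + i`.
#' @return An object of class `collabo_state`.
#' @export
collabo_init <- function(corpora, config = stm_config("desk"),
                         pretrained = NULL, seed = 1L) {
  names(corpora) <- vapply(corpora, `[[`, character(1), "name")
  if (anyDuplicated(names(corpora))) {
    abort_validation("corpus names must be distinct")
  }
  schedule <- sort(names(corpora))
  corpora <- corpora[schedule]
  if (identical(config$aggregation, "concat") && length(corpora) > 1L) {
    config$slot_dim <- 2L * config$d_lstm * (length(corpora) - 1L)
  }
  vocab <- build_vocab(corpora)
  models <- list()
  data <- list()
  for (i in seq_along(schedule)) {
    d <- schedule[[i]]
    models[[d]] <- stm_init(vocab, corpora[[d]]$entity_types, config,
                            pretrained, seed = as.integer(seed) + i)
    if (length(corpora[[d]]$train) == 0L) {
      abort_validation("corpus '%s' has an empty training split", d)
    }
    data[[d]] <- list(
      train = prepare_split(models[[d]], corpora[[d]]$train),
      dev = prepare_split(models[[d]], corpora[[d]]$dev, with_gold = FALSE),
      dev_gold = lapply(corpora[[d]]$dev, `[[`, "tags"))
  }
  alphas <- lapply(schedule, function(d) {
    others <- setdiff(schedule, d)
    setNames(rep(1, length(others)), others)
  })
  names(alphas) <- schedule
  structure(list(models = models, alphas = alphas,
                 opt = setNames(vector("list", length(schedule)), schedule),
                 opt_alpha = setNames(vector("list", length(schedule)), schedule),
                 phase = 0L, schedule = schedule, config = config,
                 vocab = vocab, data = data, prepared_done = FALSE,
                 log = NULL),
            class = "collabo_state")
}

#' @export
print.collabo_state <- function(x, ...) {
  cat(sprintf("<collabo_state> %d experts (%s), phase %d\n",
              length(x$models), paste(x$schedule, collapse = ", "), x$phase))
  invisible(x)
}

# Slot features for one prepared sentence from a set of frozen collaborator
# models. Returns slot matrix, per-collaborator h matrices, and (max mode)
# the argmax collaborator index per coordinate.
#' @keywords internal
#' @noRd
collab_slot_for <- function(models, alpha, d, prep, aggregation = "max") {
  others <- names(alpha)
  p <- prep
  p$gold <- NULL
  p$slot <- NULL
  h <- lapply(models[others], function(m) cpp_stm_encode(m$params, m$windows, p))
  names(h) <- others
  if (aggregation == "concat") {
    slot <- do.call(rbind, lapply(others, function(k) alpha[[k]] * h[[k]]))
    # Block-diagonal layout so the generic alpha-gradient rule (match the
    # coordinate's source collaborator, multiply by its h) applies unchanged.
    two_h <- nrow(h[[1L]])
    amax <- matrix(rep(seq_along(others), each = two_h), nrow(slot), ncol(slot))
    h_blocks <- lapply(seq_along(others), function(ki) {
      hb <- matrix(0, nrow(slot), ncol(slot))
      hb[((ki - 1L) * two_h + 1L):(ki * two_h), ] <- h[[others[ki]]]
      hb
    })
    names(h_blocks) <- others
    return(list(slot = slot, h = h_blocks, amax = amax))
  }
  scaled <- lapply(others, function(k) alpha[[k]] * h[[k]])
  slot <- scaled[[1L]]
  amax <- matrix(1L, nrow(slot), ncol(slot))
  if (length(scaled) > 1L) {
    for (ki in 2L:length(scaled)) {
      better <- scaled[[ki]] > slot
      slot[better] <- scaled[[ki]][better]
      amax[better] <- ki
    }
  }
  list(slot = slot, h = h, amax = amax)
}

#' Collaborator features for one sentence
#'
#' Runs every collaborator expert (all models except the target `d`) over
#' the sentence in inference mode with a zeroed slot, scales each
#' collaborator's BiLSTM output by its aggregation weight alpha, and
#' combines them coordinate-wise (weighted max pooling by default). No
#' gradient ever reaches collaborator parameters; the alpha weights are
#' trained through this pooling during [run_phase()].
#'
#' @param state A [collabo_init()] state whose preparation phase has run.
#' @param d Name of the target dataset.
#' @param sentence A [labeled_sentence()] or character vector of tokens.
#' @return List with `slot` (matrix `slot_dim x N`), `h` (per-collaborator
#'   encoder outputs) and `amax` (argmax collaborator per coordinate, max
#'   mode only).
#' @export
collaborator_features <- function(state, d, sentence) {
  if (length(state$models) < 2L) {
    abort_validation("collaborator features require at least two datasets")
  }
  if (!d %in% state$schedule) abort_validation("unknown dataset '%s'", d)
  if (is.character(sentence)) {
    sentence <- labeled_sentence(sentence, rep("O", length(sentence)))
  }
  prep <- prepare_sentence(state$models[[d]], sentence, with_gold = FALSE)
  collab_slot_for(state$models, state$alphas[[d]], d, prep,
                  state$config$aggregation)
}

# Patience-based fitting of one model (used by the preparation phase and by
# train_stm); returns best-epoch model plus the per-epoch log.
#' @keywords internal
#' @noRd
fit_stm <- function(model, train_data, dev_data, dev_gold, opt = NULL,
                    quiet = TRUE, label = "stm", phase = 0L, eval_fn = NULL) {
  cfg <- model$config
  if (is.null(eval_fn)) {
    eval_fn <- function(m) evaluate_tags(dev_gold, predict_prepared(m, dev_data))
  }
  best <- list(f1 = -Inf, params = model$params, epoch = NA_integer_,
               epochs_trained = model$epochs_trained, opt = opt)
  bad <- 0L
  log <- list()
  for (e in seq_len(cfg$max_epochs)) {
    res <- train_epoch(model, train_data, opt)
    model <- res$model; opt <- res$opt
    rep <- eval_fn(model)
    epoch <- model$epochs_trained - 1L
    log[[length(log) + 1L]] <- data.frame(
      phase = phase, dataset = label, epoch = epoch, loss = res$mean_loss,
      dev_precision = rep$precision, dev_recall = rep$recall, dev_f1 = rep$f1)
    if (!quiet) {
      message(sprintf("[%s] epoch %d: loss %.4f dev F1 %.4f", label, epoch,
                      res$mean_loss, rep$f1))
    }
    if (rep$f1 > best$f1) {
      best <- list(f1 = rep$f1, params = model$params, epoch = epoch,
                   epochs_trained = model$epochs_trained, opt = opt)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$epochs_trained <- best$epochs_trained
  list(model = model, opt = best$opt, best_epoch = best$epoch,
       best_f1 = best$f1,
       log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}

#' Run the preparation phase
#'
#' Trains every expert independently (zeroed collaborator slot) on its own
#' corpus until its dev entity F1 stops improving for `config$patience`
#' consecutive epochs, keeping the best-epoch checkpoint. Models are fully
#' independent: training one never touches another.
#'
#' @param state A [collabo_init()] state.
#' @param quiet Suppress progress messages.
#' @return The updated state, at phase 0, with a per-epoch metrics log.
#' @export
run_preparation_phase <- function(state, quiet = TRUE) {
  logs <- list(state$log)
  for (d in state$schedule) {
    fit <- fit_stm(state$models[[d]], state$data[[d]]$train,
                   state$data[[d]]$dev, state$data[[d]]$dev_gold,
                   opt = state$opt[[d]], quiet = quiet, label = d, phase = 0L)
    state$models[[d]] <- fit$model
    state$opt[[d]] <- fit$opt
    logs[[length(logs) + 1L]] <- fit$log
  }
  state$phase <- 0L
  state$prepared_done <- TRUE
  state$log <- do.call(rbind, c(logs, list(make.row.names = FALSE)))
  state
}

#' Run one collaboration phase
#'
#' For each dataset `d` in schedule order: collaborator features for every
#' training sentence of `d` are computed from the models *as frozen at the
#' phase boundary* (so within-phase dataset order leaks no updates), the
#' target model is trained for exactly one epoch on the concatenated
#' inputs, and its alpha weights are updated through the weighted
#' max-pooling. Collaborator parameters are bit-identical before and after.
#' The phase counter increments once all datasets have taken the target
#' role.
#'
#' @param state A [collabo_init()] state (preparation phase recommended
#'   first).
#' @param quiet Suppress progress messages.
#' @return The updated state at phase `n + 1`.
#' @export
run_phase <- function(state, quiet = TRUE) {
  if (length(state$models) < 2L) {
    abort_validation("a collaboration phase requires at least two datasets")
  }
  snapshot <- state$models           # frozen M^{n-1} for the whole phase
  new_phase <- state$phase + 1L
  logs <- list(state$log)
  for (d in state$schedule) {
    slots <- lapply(state$data[[d]]$train, function(p) {
      collab_slot_for(snapshot, state$alphas[[d]], d, p, state$config$aggregation)
    })
    collab <- list(slots = slots, alpha = state$alphas[[d]],
                   opt_alpha = state$opt_alpha[[d]])
    res <- train_epoch(state$models[[d]], state$data[[d]]$train,
                       state$opt[[d]], collab)
    state$models[[d]] <- res$model
    state$opt[[d]] <- res$opt
    state$alphas[[d]] <- res$alpha
    state$opt_alpha[[d]] <- res$opt_alpha
    dev_slots <- lapply(state$data[[d]]$dev, function(p) {
      collab_slot_for(snapshot, state$alphas[[d]], d, p, state$config$aggregation)
    })
    rep <- evaluate_tags(state$data[[d]]$dev_gold,
                         predict_prepared(state$models[[d]], state$data[[d]]$dev,
                                          dev_slots))
    logs[[length(logs) + 1L]] <- data.frame(
      phase = new_phase, dataset = d, epoch = state$models[[d]]$epochs_trained - 1L,
      loss = res$mean_loss, dev_precision = rep$precision,
      dev_recall = rep$recall, dev_f1 = rep$f1)
    if (!quiet) {
      message(sprintf("[phase %d, %s] loss %.4f dev F1 %.4f", new_phase, d,
                      res$mean_loss, rep$f1))
    }
  }
  state$phase <- new_phase
  for (d in state$schedule) state$models[[d]]$version <- new_phase
  state$log <- do.call(rbind, c(logs, list(make.row.names = FALSE)))
  state
}

#' Train a full collaboration schedule
#'
#' Preparation phase, then collaboration phases: a fixed number when
#' `n_phases` is given, otherwise until the macro-average dev F1 over all
#' datasets stops improving for `phase_patience` phases (the best-phase
#' state is returned).
#'
#' @param corpora List of [labeled_corpus()] objects.
#' @param config An [stm_config()].
#' @param n_phases Fixed number of collaboration phases, or `NULL` for the
#'   patience rule.
#' @param phase_patience Phases without macro dev F1 improvement before
#'   stopping (patience mode).
#' @param max_phases Upper bound on phases in patience mode.
#' @param pretrained,seed,quiet See [collabo_init()].
#' @return The trained `collabo_state`; its `log` element holds one row per
#'   (phase, dataset, epoch).
#' @export
collabo_train <- function(corpora, config = stm_config("desk"),
                          n_phases = NULL, phase_patience = 3L,
                          max_phases = 10L, pretrained = NULL, seed = 1L,
                          quiet = TRUE) {
  state <- collabo_init(corpora, config, pretrained, seed)
  if (length(state$models) == 1L) {
    warning("single dataset: collaboration skipped, training a plain single-task model")
    return(run_preparation_phase(state, quiet = quiet))
  }
  state <- run_preparation_phase(state, quiet = quiet)
  if (!is.null(n_phases)) {
    for (i in seq_len(n_phases)) state <- run_phase(state, quiet = quiet)
    return(state)
  }
  best <- list(f1 = macro_dev_f1(state), state = state)
  bad <- 0L
  for (i in seq_len(max_phases)) {
    state <- run_phase(state, quiet = quiet)
    f1 <- macro_dev_f1(state)
    if (f1 > best$f1) {
      best <- list(f1 = f1, state = state)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= phase_patience) break
    }
  }
  best$state
}

# Macro-average dev F1 of the current state (collaborative prediction when
# phase >= 1).
#' @keywords internal
#' @noRd
macro_dev_f1 <- function(state) {
  reports <- lapply(state$schedule, function(d) {
    evaluate_tags(state$data[[d]]$dev_gold, predict_state(state, d, state$data[[d]]$dev))
  })
  macro_average(reports)$f1
}

# Predict prepared sentences with the state's expert for dataset d.
#' @keywords internal
#' @noRd
predict_state <- function(state, d, prepared) {
  slots <- NULL
  if (state$phase >= 1L && length(state$models) > 1L) {
    slots <- lapply(prepared, function(p) {
      collab_slot_for(state$models, state$alphas[[d]], d, p, state$config$aggregation)
    })
  }
  predict_prepared(state$models[[d]], prepared, slots)
}

#' Predict tags with a collaboration state
#'
#' At phase 0 this equals plain single-task prediction (zero slot); from
#' phase 1 on, collaborator features from the current experts fill the
#' target's slot. Deterministic: dropout is disabled; invalid BIOES output
#' is repaired.
#'
#' @param state A trained [collabo_train()] state.
#' @param d Name of the target dataset.
#' @param sentences List of [labeled_sentence()] objects or character token
#'   vectors.
#' @return List of BIOES tag vectors.
#' @export
collabo_predict <- function(state, d, sentences) {
  if (!d %in% state$schedule) abort_validation("unknown dataset '%s'", d)
  sentences <- lapply(sentences, function(s) {
    if (is.character(s)) labeled_sentence(s, rep("O", length(s))) else s
  })
  prepared <- prepare_split(state$models[[d]], sentences, with_gold = FALSE)
  predict_state(state, d, prepared)
}

#' Save / load a collaboration state archive
#'
#' The archive is a directory holding one checkpoint per expert model, plus
#' the alpha table, phase counter, optimizer state, metrics log and the
#' resolved configuration; loading resumes exactly where saving left off.
#'
#' @param state A `collabo_state`.
#' @param dir Directory path (created if missing).
#' @return `save_collabo_state()`: `dir`, invisibly; `load_collabo_state()`:
#'   the state.
#' @export
save_collabo_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in state$schedule) {
    save_checkpoint(state$models[[d]], file.path(dir, paste0("model_", d, ".rds")))
  }
  rest <- state
  rest$models <- NULL
  saveRDS(rest, file.path(dir, "state.rds"))
  invisible(dir)
}

#' @rdname save_collabo_state
#' @export
load_collabo_state <- function(dir) {
  state_path <- file.path(dir, "state.rds")
  if (!file.exists(state_path)) {
    abort_validation("'%s' is not a collabotag state archive", dir)
  }
  state <- readRDS(state_path)
  state$models <- setNames(lapply(state$schedule, function(d) {
    load_checkpoint(file.path(dir, paste0("model_", d, ".rds")))
  }), state$schedule)
  class(state) <- "collabo_state"
  state
}
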