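#' Model and training configuration
#'
#' Returns the full hyperparameter set of one single-task tagger. The
#' default profile (`"full"`) is the full-scale configuration: 200-dim word
#' embeddings, 30-dim character embeddings, character-CNN window sizes
#' 3/5/7 with 200 output channels each (600-dim CLWE), 300 LSTM hidden
#' units per direction, dropout 0.5 on the CLWE output and 0.3 on the
#' BiLSTM output, AdaGrad with initial learning rate 0.01 decayed by 0.95
#' per epoch, mini-batches of 10. The `"desk"` profile is a small
#' configuration (16/8/24 via a single window of 3, 32 hidden units) suited
#' to CPU-scale experiments and the synthetic benchmarks.
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... Named overrides of individual fields.
#' @return An object of class `stm_config` (a named list).
#' @export
stm_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    d_word = 200L, d_char = 30L, d_clwe = 600L, windows = c(3L, 5L, 7L),
    d_lstm = 300L,
    dropout_clwe = 0.5, dropout_lstm = 0.3,
    lr = 0.01, lr_decay = 0.95, batch_size = 10L,
    crf_loss = "nll",              # "nll" or "neg_score"
    aggregation = "max",           # "max" or "concat" (collaborator features)
    slot_dim = NULL,               # collaborator-slot width; default 2*d_lstm
    patience = 3L, max_epochs = 50L,
    clip_norm = 5.0,
    freeze_word_embeddings = FALSE,
    freeze_target_embeddings = FALSE,
    profile = profile)
  if (profile == "desk") {
    cfg[c("d_word", "d_char", "d_clwe", "d_lstm")] <-
      list(16L, 8L, 24L, 32L)
    cfg$windows <- 3L
    cfg$max_epochs <- 30L
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort_validation("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  structure(cfg, class = "stm_config")
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  dims <- c(cfg$d_word, cfg$d_char, cfg$d_clwe, cfg$d_lstm, cfg$batch_size)
  if (any(dims < 1L)) abort_validation("all dimensions must be positive")
  if (any(cfg$windows %% 2L == 0L)) abort_validation("window sizes must be odd")
  if (cfg$d_clwe %% length(cfg$windows) != 0L) {
    abort_validation("d_clwe (%d) must be divisible by the number of window sizes (%d)",
                     cfg$d_clwe, length(cfg$windows))
  }
  if (cfg$dropout_clwe < 0 || cfg$dropout_clwe >= 1 ||
      cfg$dropout_lstm < 0 || cfg$dropout_lstm >= 1) {
    abort_validation("dropout rates must lie in [0, 1)")
  }
  if (!cfg$crf_loss %in% c("nll", "neg_score")) {
    abort_validation("crf_loss must be 'nll' or 'neg_score'")
  }
  if (!cfg$aggregation %in% c("max", "concat")) {
    abort_validation("aggregation must be 'max' or 'concat'")
  }
  invisible(cfg)
}

#' The BIOES tag set for a collection of entity types
#'
#' Tag 1 is always `"O"`; each entity type (sorted) contributes its
#' `B-`/`I-`/`E-`/`S-` tags, so `n_tags = 4 * n_types + 1`.
#'
#' @param entity_types Character vector of entity-type labels.
#' @return Character vector of tags.
#' @export
bioes_tag_set <- function(entity_types) {
  types <- sort(unique(as.character(entity_types)))
  c("O", unlist(lapply(types, function(ty) paste0(c("B-", "I-", "E-", "S-"), ty))))
}
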