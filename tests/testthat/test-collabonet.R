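# Small two-corpus family shared by the tests in this file.
small_family <- function(seed = 31L, n_train = 60L) {
  spec <- synth_spec(entity_types = c("disease", "gene"), n_polysemous = 3L,
                     n_sentences = c(n_train, 20L, 20L), seed = seed)
  generate_corpora(spec)
}

test_that("collabo_init builds independent experts with unit alphas at phase 0", {
  corpora <- small_family()
  state <- collabo_init(corpora, stm_config("desk"), seed = 3L)
  expect_equal(state$phase, 0L)
  expect_equal(state$schedule, c("disease", "gene"))
  expect_equal(state$alphas$disease, c(gene = 1))
  expect_equal(state$alphas$gene, c(disease = 1))
  # disjoint parameter identities
  expect_false(identical(state$models$disease$params$fWx,
                         state$models$gene$params$fWx))
})

test_that("collaborator features are the alpha-weighted coordinate-wise max of frozen encoders", {
  corpora <- small_family()
  state <- collabo_init(corpora, stm_config("desk"), seed = 3L)
  state$prepared_done <- TRUE
  toks <- corpora$disease$dev[[1L]]$tokens
  # single collaborator with alpha = 1: slot equals its encoder output
  feats <- collaborator_features(state, "disease", toks)
  h_gene <- encode_sentence(state$models$gene, toks)
  expect_equal(feats$slot, h_gene)
  expect_true(all(feats$amax == 1L))
  # alpha = 0 zeroes the slot
  state0 <- state
  state0$alphas$disease["gene"] <- 0
  expect_equal(collaborator_features(state0, "disease", toks)$slot,
               matrix(0, nrow(h_gene), ncol(h_gene)))
  # scaling by alpha
  state2 <- state
  state2$alphas$disease["gene"] <- -2
  expect_equal(collaborator_features(state2, "disease", toks)$slot, -2 * h_gene)
})

test_that("coordinate-wise max pooling over two collaborators picks the larger coordinate", {
  spec <- synth_spec(entity_types = c("a", "b", "c"), n_polysemous = 0L,
                     n_sentences = c(25L, 8L, 8L), seed = 5L)
  corpora <- generate_corpora(spec)
  state <- collabo_init(corpora, stm_config("desk"), seed = 4L)
  state$prepared_done <- TRUE
  toks <- corpora$a$dev[[1L]]$tokens
  feats <- collaborator_features(state, "a", toks)
  hb <- encode_sentence(state$models$b, toks)
  hc <- encode_sentence(state$models$c, toks)
  expect_equal(feats$slot, pmax(hb, hc))
  # the worked example: coordinates (1,-2) vs (3,-4) pool to (3,-2)
  expect_equal(pmax(c(1, -2), c(3, -4)), c(3, -2))
})

test_that("a single dataset has no collaborators", {
  corpora <- tiny_corpus()
  state <- collabo_init(corpora, stm_config("desk"), seed = 2L)
  expect_error(collaborator_features(state, "gene", c("a", "b")),
               class = "collabotag_validation_error")
  expect_error(run_phase(state), class = "collabotag_validation_error")
})

test_that("the preparation patience policy stops after `patience` flat epochs and keeps the best", {
  corpora <- tiny_corpus(n_train = 8L, n_dev = 4L)
  vocab <- build_vocab(corpora)
  cfg <- stm_config("desk", patience = 3L, max_epochs = 20L)
  model <- stm_init(vocab, "gene", cfg, seed = 5L)
  data <- collabotag:::prepare_split(model, corpora$gene$train)
  history <- c(0.2, 0.5, 0.5, 0.5, 0.5, 0.9)     # 0.9 must never be reached
  calls <- 0L
  scripted <- function(m) {
    calls <<- calls + 1L
    list(precision = 0, recall = 0, f1 = history[calls])
  }
  set.seed(1)
  fit <- collabotag:::fit_stm(model, data, NULL, NULL, eval_fn = scripted)
  expect_equal(calls, 5L)              # stops after the 5th epoch (index 4)
  expect_equal(fit$best_epoch, 1L)     # the first 0.5 wins
  expect_equal(fit$best_f1, 0.5)
})

test_that("preparation training is reproducible and its stored dev F1 can be recomputed", {
  corpora <- small_family(n_train = 40L)
  cfg <- stm_config("desk", max_epochs = 4L, patience = 2L)
  set.seed(8); s1 <- run_preparation_phase(collabo_init(corpora, cfg, seed = 8L))
  set.seed(8); s2 <- run_preparation_phase(collabo_init(corpora, cfg, seed = 8L))
  expect_identical(s1$log, s2$log)
  expect_identical(lapply(s1$models, `[[`, "params"),
                   lapply(s2$models, `[[`, "params"))
  # prediction with the checkpointed model reproduces the logged best dev F1
  for (d in s1$schedule) {
    best <- max(s1$log$dev_f1[s1$log$dataset == d])
    pred <- collabo_predict(s1, d, corpora[[d]]$dev)
    rep <- evaluate_tags(lapply(corpora[[d]]$dev, `[[`, "tags"), pred)
    expect_equal(rep$f1, best, tolerance = 1e-12)
  }
})

test_that("a phase trains only the target: collaborators stay byte-identical, counters advance", {
  corpora <- small_family(n_train = 30L)
  cfg <- stm_config("desk", max_epochs = 2L, patience = 1L)
  set.seed(21)
  state <- run_preparation_phase(collabo_init(corpora, cfg, seed = 21L))
  before <- lapply(state$models, function(m) serialize(m$params, NULL))
  # manually run one target epoch the way run_phase does, gene as target
  snapshot <- state$models
  slots <- lapply(state$data$gene$train, function(p) {
    collabotag:::collab_slot_for(snapshot, state$alphas$gene, "gene", p, "max")
  })
  collab <- list(slots = slots, alpha = state$alphas$gene, opt_alpha = NULL)
  res <- train_epoch(state$models$gene, state$data$gene$train,
                     state$opt$gene, collab)
  expect_identical(serialize(snapshot$disease$params, NULL), before$disease)
  expect_false(identical(serialize(res$model$params, NULL), before$gene))
  # the full phase: counter and version tags advance together
  set.seed(22)
  state2 <- run_phase(state)
  expect_equal(state2$phase, 1L)
  expect_true(all(vapply(state2$models, `[[`, integer(1), "version") == 1L))
})

test_that("with the slot forced to zero a phase epoch equals plain training exactly", {
  corpora <- small_family(n_train = 30L)
  cfg <- stm_config("desk", max_epochs = 1L, patience = 1L, clip_norm = 1e9)
  set.seed(33)
  state <- run_preparation_phase(collabo_init(corpora, cfg, seed = 33L))
  for (d in state$schedule) state$alphas[[d]][] <- 0   # slot = max_k 0*h_k = 0
  arm_a <- state
  set.seed(101)
  arm_a <- run_phase(arm_a)
  arm_b <- state
  set.seed(101)
  for (d in arm_b$schedule) {
    res <- train_epoch(arm_b$models[[d]], arm_b$data[[d]]$train, arm_b$opt[[d]])
    arm_b$models[[d]] <- res$model
    arm_b$opt[[d]] <- res$opt
  }
  for (d in state$schedule) {
    expect_equal(arm_a$models[[d]]$params, arm_b$models[[d]]$params,
                 tolerance = 1e-12)
  }
})

test_that("phase-0 collaborative prediction equals plain single-task prediction", {
  corpora <- small_family(n_train = 30L)
  cfg <- stm_config("desk", max_epochs = 2L, patience = 1L)
  set.seed(13)
  state <- run_preparation_phase(collabo_init(corpora, cfg, seed = 13L))
  p1 <- collabo_predict(state, "gene", corpora$gene$test[1:5])
  p2 <- stm_predict(state$models$gene, corpora$gene$test[1:5])
  expect_identical(p1, p2)
  expect_identical(p1, collabo_predict(state, "gene", corpora$gene$test[1:5]))
  expect_error(collabo_predict(state, "chem", corpora$gene$test[1:5]),
               class = "collabotag_validation_error")
})

test_that("state archives round-trip and predictions survive reload", {
  corpora <- small_family(n_train = 30L)
  cfg <- stm_config("desk", max_epochs = 2L, patience = 1L)
  set.seed(17)
  state <- run_preparation_phase(collabo_init(corpora, cfg, seed = 17L))
  set.seed(18)
  state <- run_phase(state)
  dir <- withr::local_tempdir()
  save_collabo_state(state, dir)
  back <- load_collabo_state(dir)
  expect_equal(back$phase, state$phase)
  expect_identical(back$alphas, state$alphas)
  expect_identical(collabo_predict(back, "disease", corpora$disease$test[1:5]),
                   collabo_predict(state, "disease", corpora$disease$test[1:5]))
  # training resumes at the stored phase
  set.seed(19)
  resumed <- run_phase(back)
  expect_equal(resumed$phase, state$phase + 1L)
  expect_error(load_collabo_state(withr::local_tempdir()),
               class = "collabotag_validation_error")
})

test_that("concatenation aggregation widens the slot and still trains", {
  corpora <- small_family(n_train = 20L)
  cfg <- stm_config("desk", aggregation = "concat", max_epochs = 1L, patience = 1L)
  set.seed(41)
  state <- collabo_init(corpora, cfg, seed = 41L)
  expect_equal(state$models$gene$config$slot_dim, 2L * cfg$d_lstm)
  state <- run_preparation_phase(state)
  state <- run_phase(state)
  expect_equal(state$phase, 1L)
  feats <- collaborator_features(state, "gene", corpora$gene$dev[[1L]]$tokens)
  expect_equal(nrow(feats$slot), 2L * cfg$d_lstm)
})
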