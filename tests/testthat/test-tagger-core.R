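test_that("zero parameters give all-zero encoder states", {
  m <- desk_model()
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  h <- encode_sentence(m, c("abc", "def"))
  expect_equal(h, matrix(0, 2L * m$config$d_lstm, 2L))
})

test_that("encoder output has dimension 2*d_lstm and respects causality", {
  m <- desk_model()
  H <- m$config$d_lstm
  h1 <- encode_sentence(m, "abc")
  expect_equal(dim(h1), c(2L * H, 1L))
  toks_a <- c("abc", "def", "ghi", "jkl")
  toks_b <- c("abc", "def", "zzz", "jkl")   # perturb position 3
  ha <- encode_sentence(m, toks_a)
  hb <- encode_sentence(m, toks_b)
  # forward states before the perturbation are unchanged
  expect_equal(ha[1:H, 1:2], hb[1:H, 1:2])
  # backward states after it are unchanged
  expect_equal(ha[(H + 1L):(2L * H), 4L], hb[(H + 1L):(2L * H), 4L])
  # states at the perturbed position change
  expect_false(isTRUE(all.equal(ha[, 3L], hb[, 3L])))
  expect_error(encode_sentence(m, c("a", "b"), slot = matrix(0, 3, 2)),
               class = "collabotag_validation_error")
})

test_that("tag probabilities are a shift-invariant softmax", {
  z <- matrix(0, 5L, 3L)
  p <- tag_probabilities(z)
  expect_equal(p, matrix(0.2, 5L, 3L))
  z1 <- matrix(c(1, 0, 0, 0, 0), 5L, 1L)
  expect_equal(tag_probabilities(z1)[1L], exp(1) / (exp(1) + 4), tolerance = 1e-10)
  expect_equal(tag_probabilities(z1 + 7), tag_probabilities(z1))
  expect_equal(colSums(tag_probabilities(matrix(rnorm(15), 5L))), rep(1, 3L))
})

test_that("path_score matches its definition", {
  set.seed(1)
  inst <- random_crf_instance(1L)
  expect_equal(path_score(inst$z, inst$A, 3L), inst$A[6L, 3L] + inst$z[3L, 1L])
  # all-zero transitions: sum of emissions along the path
  z <- matrix(rnorm(20), 5L, 4L)
  A0 <- matrix(0, 6L, 5L)
  y <- c(2L, 5L, 1L, 4L)
  expect_equal(path_score(z, A0, y), sum(z[cbind(y, 1:4)]))
  for (i in 1:20) {
    inst <- random_crf_instance(sample(1:5, 1L))
    y <- sample(5L, ncol(inst$z), replace = TRUE)
    expect_equal(path_score(inst$z, inst$A, y), oracle_path_score(inst$z, inst$A, y))
  }
})

test_that("crf_nll equals the enumerated negative log likelihood", {
  # uniform single position: log 5
  expect_equal(crf_nll(matrix(0, 5L, 1L), matrix(0, 6L, 5L), 1L), log(5))
  # large-margin gold path drives the nll to zero
  z <- matrix(-100, 5L, 3L); z[2L, ] <- 100
  expect_lt(crf_nll(z, matrix(0, 6L, 5L), c(2L, 2L, 2L)), 1e-12)
  set.seed(2)
  for (i in 1:20) {
    T <- sample(1:6, 1L)
    inst <- random_crf_instance(T)
    y <- sample(5L, T, replace = TRUE)
    expected <- oracle_logZ(inst$z, inst$A) - oracle_path_score(inst$z, inst$A, y)
    expect_equal(crf_nll(inst$z, inst$A, y), expected, tolerance = 1e-6)
    expect_gte(crf_nll(inst$z, inst$A, y), 0)
    # the literal variant is just the negated path score
    expect_equal(crf_nll(inst$z, inst$A, y, mode = "neg_score"),
                 -oracle_path_score(inst$z, inst$A, y))
  }
})

test_that("lstm_loss is the summed softmax cross entropy", {
  expect_equal(lstm_loss(matrix(0, 5L, 4L), c(1L, 2L, 3L, 4L)), 4 * log(5))
  z <- matrix(-100, 5L, 2L); z[cbind(c(3L, 1L), 1:2)] <- 100
  expect_lt(lstm_loss(z, c(3L, 1L)), 1e-12)
  set.seed(3)
  z <- matrix(rnorm(20), 5L, 4L)
  y <- c(2L, 2L, 5L, 1L)
  direct <- -sum(log(tag_probabilities(z)[cbind(y, 1:4)]))
  expect_equal(lstm_loss(z, y), direct, tolerance = 1e-10)
})

test_that("total_loss decomposes exactly", {
  set.seed(4)
  for (i in 1:10) {
    inst <- random_crf_instance(4L)
    y <- sample(5L, 4L, replace = TRUE)
    expect_identical(total_loss(inst$z, inst$A, y),
                     lstm_loss(inst$z, y) + crf_nll(inst$z, inst$A, y))
  }
  expect_equal(total_loss(matrix(0, 5L, 1L), matrix(0, 6L, 5L), 1L), 2 * log(5))
})

test_that("viterbi decoding is optimal and breaks ties toward the lowest index", {
  # A = 0: per-position argmax
  z <- matrix(rnorm(15), 5L, 3L)
  v <- viterbi_decode(z, matrix(0, 6L, 5L))
  expect_equal(v$path, apply(z, 2L, which.max))
  # all scores equal: lowest tag index everywhere
  v0 <- viterbi_decode(matrix(0, 5L, 4L), matrix(0, 6L, 5L))
  expect_equal(v0$path, rep(1L, 4L))
  # constructed two-way tie through transitions resolves to the lower index
  zt <- matrix(0, 2L, 2L)
  At <- matrix(0, 3L, 2L)
  vt <- viterbi_decode(zt, At)
  expect_equal(vt$path, c(1L, 1L))
  set.seed(5)
  for (i in 1:50) {
    T <- sample(1:8, 1L)
    inst <- random_crf_instance(T)
    v <- viterbi_decode(inst$z, inst$A)
    scores <- apply(all_paths(T, 5L), 1L, function(y) oracle_path_score(inst$z, inst$A, y))
    expect_equal(v$score, max(scores), tolerance = 1e-9)
    expect_equal(oracle_path_score(inst$z, inst$A, v$path), v$score, tolerance = 1e-9)
  }
})

test_that("the CRF distribution normalizes: enumerated path probabilities sum to 1", {
  set.seed(6)
  for (i in 1:10) {
    T <- sample(1:6, 1L)
    inst <- random_crf_instance(T)
    logZ <- collabotag:::cpp_crf_logZ(inst$z, inst$A)
    scores <- apply(all_paths(T, 5L), 1L, function(y) oracle_path_score(inst$z, inst$A, y))
    expect_equal(sum(exp(scores - logZ)), 1, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences", {
  m <- desk_model(seed = 9L)
  corp <- tiny_corpus()
  prep <- collabotag:::prepare_sentence(m, corp$gene$train[[2L]])
  for (mode in c("nll", "neg_score")) {
    run <- collabotag:::cpp_stm_run(m$params, m$windows, prep, 0, 0, TRUE, mode, TRUE)
    loss_at <- function(params) {
      collabotag:::cpp_stm_run(params, m$windows, prep, 0, 0, TRUE, mode, FALSE)$loss_total
    }
    eps <- 1e-6
    set.seed(10)
    for (nm in names(m$params)) {
      for (r in 1:2) {
        i <- sample(length(m$params[[nm]]), 1L)
        up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(unname(run$grads[[nm]][i]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training lowers the loss, is deterministic under a seed, and leaves empty splits untouched", {
  corp <- tiny_corpus(n_train = 60L, seed = 19L)$gene
  vocab <- build_vocab(list(corp))
  cfg <- stm_config("desk", max_epochs = 4L)
  run_losses <- function() {
    model <- stm_init(vocab, "gene", cfg, seed = 6L)
    data <- collabotag:::prepare_split(model, corp$train)
    opt <- NULL
    losses <- numeric(4L)
    for (e in 1:4) {
      res <- train_epoch(model, data, opt)
      model <- res$model; opt <- res$opt
      losses[e] <- res$mean_loss
    }
    losses
  }
  set.seed(99); l1 <- run_losses()
  set.seed(99); l2 <- run_losses()
  expect_identical(l1, l2)
  expect_lt(l1[4L], l1[1L])
  m <- stm_init(vocab, "gene", cfg, seed = 6L)
  res <- train_epoch(m, list())
  expect_identical(res$model$params, m$params)
})

test_that("the learning-rate schedule decays exponentially per epoch", {
  # fresh AdaGrad makes the first update of each coordinate lr * g/|g|, so
  # the largest parameter move directly reveals the epoch's learning rate
  corp <- tiny_corpus()$gene
  vocab <- build_vocab(list(corp))
  cfg <- stm_config("desk", dropout_clwe = 0, dropout_lstm = 0, batch_size = 1L)
  step_size <- function(epochs_done) {
    m <- stm_init(vocab, "gene", cfg, seed = 8L)
    m$epochs_trained <- epochs_done
    data <- collabotag:::prepare_split(m, corp$train[1L])
    set.seed(1)
    res <- train_epoch(m, data, shuffle = FALSE)
    max(abs(res$model$params$Wy - m$params$Wy))
  }
  expect_equal(step_size(0L), 0.01, tolerance = 1e-4)
  expect_equal(step_size(2L), 0.01 * 0.95^2, tolerance = 1e-4)
})

test_that("checkpoints round-trip bit-wise", {
  m <- desk_model(seed = 12L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_identical(load_checkpoint(path), m)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(load_checkpoint(bad), class = "collabotag_validation_error")
})

test_that("non-finite losses abort with a diagnostic", {
  m <- desk_model()
  m$params$by[] <- Inf    # emission scores all Inf: loss Inf - Inf = NaN
  corp <- tiny_corpus()
  data <- collabotag:::prepare_split(m, corp$gene$train[1:3])
  err <- expect_error(train_epoch(m, data), class = "collabotag_numeric_error")
  expect_match(conditionMessage(err), "non-finite")
})
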