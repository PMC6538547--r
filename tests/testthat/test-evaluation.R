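test_that("is_valid_bioes implements the grammar", {
  expect_true(is_valid_bioes(c("O", "S-g", "O")))
  expect_true(is_valid_bioes(c("B-g", "E-g")))
  expect_true(is_valid_bioes(c("B-g", "I-g", "I-g", "E-g")))
  expect_false(is_valid_bioes(c("B-g", "O")))
  expect_false(is_valid_bioes("I-g"))
  expect_false(is_valid_bioes(c("B-g", "I-d", "E-g")))
  expect_false(is_valid_bioes(c("B-g", "E-d")))
  expect_false(is_valid_bioes("E-g"))
  expect_true(is_valid_bioes(character(0)))
})

test_that("fix_invalid_bioes applies the documented local repair rules", {
  expect_equal(fix_invalid_bioes(c("I-g", "E-g")), c("B-g", "E-g"))
  expect_equal(fix_invalid_bioes(c("B-g", "I-g", "O")), c("B-g", "E-g", "O"))
  expect_equal(fix_invalid_bioes(c("B-g", "O")), c("S-g", "O"))
  expect_equal(fix_invalid_bioes("E-g"), "S-g")
  expect_equal(fix_invalid_bioes("I-g"), "S-g")
  # type switch inside a run closes the run and opens a new one
  expect_equal(fix_invalid_bioes(c("B-g", "I-d", "E-d")), c("S-g", "B-d", "E-d"))
  expect_equal(fix_invalid_bioes(c("B-g", "I-g", "I-d", "E-d")),
               c("B-g", "E-g", "B-d", "E-d"))
})

test_that("fix_invalid_bioes is total, idempotent and the identity on valid input (all 5^4)", {
  seqs <- all_tag_seqs(4L, bioes_alphabet("g"))
  for (tags in seqs) {
    fixed <- fix_invalid_bioes(tags)
    expect_true(oracle_valid_bioes(fixed))
    expect_identical(fix_invalid_bioes(fixed), fixed)
    expect_length(fixed, length(tags))
    if (oracle_valid_bioes(tags)) expect_identical(fixed, tags)
  }
})

test_that("extract_spans produces sorted non-overlapping spans and demands valid input", {
  expect_equal(extract_spans("S-d"),
               data.frame(start = 0L, end = 0L, type = "d", stringsAsFactors = FALSE))
  sp <- extract_spans(c("B-c", "I-c", "E-c", "O", "S-c"))
  expect_equal(sp$start, c(0L, 4L))
  expect_equal(sp$end, c(2L, 4L))
  expect_equal(nrow(extract_spans(c("O", "O"))), 0L)
  expect_error(extract_spans(c("B-c", "O")), class = "collabotag_validation_error")
})

test_that("exact match PRF follows C/M, C/N and the harmonic mean with zero conventions", {
  g <- data.frame(start = 0, end = 2, type = "g")
  expect_equal(exact_match_prf(g, g)$f1, 1)
  shifted <- data.frame(start = 0, end = 1, type = "g")
  r <- exact_match_prf(g, shifted)
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
  # N=2, M=4, C=1
  gold <- data.frame(start = c(0, 5), end = c(0, 6), type = "g")
  pred <- data.frame(start = c(0, 2, 3, 8), end = c(0, 2, 4, 9), type = "g")
  r <- exact_match_prf(gold, pred)
  expect_equal(r$M, 4L); expect_equal(r$N, 2L); expect_equal(r$C, 1L)
  expect_equal(r$precision, 0.25)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 1 / 3)
  # empty sides
  none <- data.frame(start = integer(0), end = integer(0), type = character(0))
  r0 <- exact_match_prf(none, none)
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
})

test_that("type must match for a span to count and per-type breakdown pools correctly", {
  gold <- data.frame(start = 0, end = 0, type = "gene")
  pred <- data.frame(start = 0, end = 0, type = "disease")
  r <- exact_match_prf(gold, pred)
  expect_equal(r$C, 0L)
  expect_equal(sort(r$by_type$type), c("disease", "gene"))
})

test_that("F1 lies between min and max of P and R when both are positive", {
  set.seed(42)
  for (i in 1:50) {
    C <- sample(1:20, 1)
    M <- C + sample(0:20, 1)
    N <- C + sample(0:20, 1)
    P <- C / M; R <- C / N; F1 <- 2 * P * R / (P + R)
    expect_gte(F1, min(P, R) - 1e-12)
    expect_lte(F1, max(P, R) + 1e-12)
  }
})

test_that("evaluate_tags pools counts over sentences and repairs predictions", {
  gold <- list(c("S-g", "O"), c("B-g", "E-g"))
  pred <- list(c("S-g", "O"), c("B-g", "I-g"))   # second is invalid, repaired to B,E
  r <- evaluate_tags(gold, pred)
  expect_equal(r$C, 2L)
  expect_equal(r$f1, 1)
  expect_error(evaluate_tags(gold, pred[1]), class = "collabotag_validation_error")
})

test_that("macro_average is the arithmetic mean of per-dataset scores", {
  r1 <- exact_match_prf(data.frame(start = 0, end = 0, type = "g"),
                        data.frame(start = 0, end = 0, type = "g"))
  r2 <- exact_match_prf(data.frame(start = 0, end = 0, type = "g"),
                        data.frame(start = 1, end = 1, type = "g"))
  expect_equal(macro_average(list(r1, r2))$f1, 0.5)
})

test_that("classify_errors reproduces the polysemy, modifier and spurious patterns", {
  gold_t <- data.frame(start = 1, end = 3, type = "disease")
  gold_o <- data.frame(start = 6, end = 6, type = "gene")
  pred <- data.frame(start = c(6, 0, 9), end = c(6, 3, 9),
                     type = c("disease", "disease", "disease"))
  rec <- classify_errors(pred, gold_t, gold_o)
  # (6,6) exactly matches an other-type gold span -> bio-entity error
  expect_equal(rec$category[rec$start == 6], "bio_entity")
  # (0,3) overlaps same-type gold (1,3) with different boundaries -> span error
  expect_equal(rec$category[rec$start == 0], "span")
  expect_equal(rec$category[rec$start == 9], "spurious")
  # unmatched gold span is reported missed
  expect_equal(sum(rec$category == "missed"), 1L)
})

test_that("bio-entity precedence and exact-only mode", {
  # prediction overlaps both an other-type span and a same-type span:
  # bio_entity wins
  gold_t <- data.frame(start = 0, end = 2, type = "d")
  gold_o <- data.frame(start = 2, end = 3, type = "g")
  pred <- data.frame(start = 1, end = 3, type = "d")
  expect_equal(classify_errors(pred, gold_t, gold_o)$category[1], "bio_entity")
  # with exact matching only, the same prediction becomes a span error
  expect_equal(classify_errors(pred, gold_t, gold_o, overlap = FALSE)$category[1], "span")
  expect_error(classify_errors(pred, rbind(gold_t, data.frame(start = 1, end = 4, type = "d")),
                               gold_o),
               class = "collabotag_validation_error")
})

test_that("error categories partition the incorrect predictions", {
  set.seed(7)
  corp <- tiny_corpus(types = c("disease", "gene"), n_poly = 3L, seed = 5L)$gene
  gold <- lapply(corp$train[1:40], `[[`, "tags")
  full <- lapply(corp$train[1:40], `[[`, "full_tags")
  # perturb gold into an imperfect "prediction"
  pred <- lapply(gold, function(tg) {
    if (runif(1) < 0.4 && length(tg) > 2) tg[sample(length(tg), 1)] <- "S-gene"
    fix_invalid_bioes(tg)
  })
  ps <- collabotag:::spans_of_sentences(pred)
  gs <- collabotag:::spans_of_sentences(gold)
  fs <- collabotag:::spans_of_sentences(full)
  os <- fs[fs$type != "gene", , drop = FALSE]
  rec <- classify_errors(ps, gs, os)
  r <- exact_match_prf(gs, ps)
  pred_cats <- rec$category[rec$category != "missed"]
  expect_equal(length(pred_cats), r$M - r$C)
  expect_equal(sum(rec$category == "missed"), r$N - r$C)
})

test_that("error_summary counts and ratio", {
  rec <- data.frame(category = c("bio_entity", "bio_entity", "span", "spurious", "missed"))
  s <- error_summary(rec)
  expect_equal(s$total, 5L)
  expect_equal(s$bio_entity_ratio, 0.4)
  expect_false(s$empty)
  s0 <- error_summary(data.frame(category = character(0)))
  expect_equal(s0$bio_entity_ratio, 0)
  expect_true(s0$empty)
})
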