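#' Validate a BIOES tag sequence
#'
#' The BIOES grammar accepted here: `O` and `S-TYPE` stand alone; `B-TYPE`
#' must open a run continued by zero or more `I-TYPE` of the same type and
#' closed by `E-TYPE` of that type.
#'
#' @param tags Character vector of tag strings.
#' @return `TRUE` iff the sequence parses under the grammar.
#' @examples
#' is_valid_bioes(c("O", "S-gene", "O"))     # TRUE
#' is_valid_bioes(c("B-gene", "O"))          # FALSE: unclosed run
#' @export
is_valid_bioes <- function(tags) {
  if (length(tags) == 0L) return(TRUE)
  if (any(!grepl("^(O|[BIES]-.+)$", tags))) return(FALSE)
  pfx <- substr(tags, 1L, 1L)
  typ <- ifelse(pfx == "O", "", sub("^[BIES]-", "", tags))
  open <- FALSE
  open_type <- ""
  for (t in seq_along(tags)) {
    p <- pfx[t]
    if (open) {
      if (p == "I" && typ[t] == open_type) next
      if (p == "E" && typ[t] == open_type) { open <- FALSE; next }
      return(FALSE)
    }
    if (p == "O" || p == "S") next
    if (p == "B") { open <- TRUE; open_type <- typ[t]; next }
    return(FALSE)               # orphan I or E
  }
  !open
}

#' Repair an invalid BIOES tag sequence
#'
#' Decoders with freely learned transition scores can emit structurally
#' invalid BIOES sequences; a deterministic local post-processing step makes
#' them valid before span extraction. Repair rules: an `I` that starts a run
#' becomes `B`; a run left unclosed has its last tag turned into `E` (or `S`
#' if the run has length 1); an orphan `E` becomes `S`; a type switch inside
#' a run closes the previous run and opens a new one.
#'
#' The function is total (defined for every well-formed tag string sequence),
#' idempotent, length-preserving, and the identity on already-valid input.
#'
#' @param tags Character vector of tag strings (each `O` or `PREFIX-TYPE`).
#' @return A valid BIOES tag sequence of the same length.
#' @examples
#' fix_invalid_bioes(c("I-gene", "E-gene"))       # B-gene E-gene
#' fix_invalid_bioes(c("B-gene", "I-gene", "O"))  # B-gene E-gene O
#' @export
fix_invalid_bioes <- function(tags) {
  if (length(tags) == 0L) return(tags)
  if (any(!grepl("^(O|[BIES]-.+)$", tags))) {
    abort_validation("malformed tag string (expected 'O' or 'PREFIX-TYPE')")
  }
  pfx <- substr(tags, 1L, 1L)
  typ <- ifelse(pfx == "O", "", sub("^[BIES]-", "", tags))
  out <- character(length(tags))
  run_start <- NA_integer_   # index in out where the open run began
  run_type <- ""
  run_len <- 0L
  close_open <- function(upto) {
    # Close a dangling B(I*) run ending at position `upto`.
    if (is.na(run_start)) return()
    if (run_len == 1L) {
      out[run_start] <<- paste0("S-", run_type)
    } else {
      out[upto] <<- paste0("E-", run_type)
    }
    run_start <<- NA_integer_; run_len <<- 0L
  }
  for (t in seq_along(tags)) {
    p <- pfx[t]; ty <- typ[t]
    if (!is.na(run_start) && p %in% c("I", "E") && ty == run_type) {
      if (p == "I") {
        out[t] <- paste0("I-", ty); run_len <- run_len + 1L
      } else {
        out[t] <- paste0("E-", ty)
        run_start <- NA_integer_; run_len <- 0L
      }
      next
    }
    close_open(t - 1L)
    if (p == "O") {
      out[t] <- "O"
    } else if (p == "S") {
      out[t] <- paste0("S-", ty)
    } else if (p == "E") {
      out[t] <- paste0("S-", ty)            # orphan E
    } else {                                 # B, or orphan I opening a run
      out[t] <- paste0("B-", ty)
      run_start <- t; run_type <- ty; run_len <- 1L
    }
  }
  close_open(length(tags))
  out
}

#' Extract entity spans from a valid BIOES sequence
#'
#' One span per `S` tag and per `B...E` run. Spans use 0-based token indices
#' and closed intervals `[start, end]`.
#'
#' @param tags A valid BIOES tag sequence (see [is_valid_bioes()]); invalid
#'   input raises a validation error — repair with [fix_invalid_bioes()]
#'   first.
#' @return A data frame with columns `start`, `end` (0-based, inclusive) and
#'   `type`, sorted by `start`.
#' @examples
#' extract_spans(c("B-chem", "I-chem", "E-chem", "O", "S-disease"))
#' @export
extract_spans <- function(tags) {
  if (!is_valid_bioes(tags)) {
    abort_validation("tags are not a valid BIOES sequence; apply fix_invalid_bioes() first")
  }
  pfx <- substr(tags, 1L, 1L)
  typ <- ifelse(pfx == "O", "", sub("^[BIES]-", "", tags))
  start <- integer(); end <- integer(); type <- character()
  open <- NA_integer_
  for (t in seq_along(tags)) {
    if (pfx[t] == "S") {
      start <- c(start, t - 1L); end <- c(end, t - 1L); type <- c(type, typ[t])
    } else if (pfx[t] == "B") {
      open <- t
    } else if (pfx[t] == "E") {
      start <- c(start, open - 1L); end <- c(end, t - 1L); type <- c(type, typ[open])
      open <- NA_integer_
    }
  }
  data.frame(start = start, end = end, type = type, stringsAsFactors = FALSE)
}

# Spans for a list of sentences, with a sentence id column.
#' @keywords internal
#' @noRd
spans_of_sentences <- function(tag_lists) {
  out <- lapply(seq_along(tag_lists), function(i) {
    sp <- extract_spans(tag_lists[[i]])
    if (nrow(sp)) sp$sentence <- i else sp$sentence <- integer(0)
    sp
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Exact-match entity-level precision, recall and F1
#'
#' A predicted entity counts as correct only if its start, end and type all
#' equal a gold span's. With `M` predicted entities, `N` gold entities and
#' `C` correct ones: precision `P = C/M`, recall `R = C/N`,
#' `F1 = 2PR/(P+R)`. Conventions for empty denominators: `P = 0` when
#' `M = 0`, `R = 0` when `N = 0`, `F1 = 0` when `P + R = 0`. Counts are
#' pooled (micro-averaged) over sentences; use [macro_average()] to average
#' reports across datasets.
#'
#' @param gold,pred Span data frames as returned by [extract_spans()], with
#'   an optional `sentence` column when spans come from several sentences.
#' @return A `metrics_report`: list with `M`, `N`, `C`, `precision`,
#'   `recall`, `f1`, and a per-type breakdown data frame `by_type`.
#' @examples
#' g <- data.frame(start = 0, end = 2, type = "gene")
#' exact_match_prf(g, g)$f1   # 1
#' @export
exact_match_prf <- function(gold, pred) {
  gold <- normalize_spans(gold)
  pred <- normalize_spans(pred)
  key <- function(df) paste(df$sentence, df$start, df$end, df$type)
  C <- sum(key(pred) %in% key(gold))
  types <- sort(unique(c(gold$type, pred$type)))
  by_type <- do.call(rbind, lapply(types, function(ty) {
    g <- gold[gold$type == ty, , drop = FALSE]
    p <- pred[pred$type == ty, , drop = FALSE]
    c_ty <- sum(key(p) %in% key(g))
    data.frame(type = ty, M = nrow(p), N = nrow(g), C = c_ty,
               precision = prf_ratio(c_ty, nrow(p)),
               recall = prf_ratio(c_ty, nrow(g)),
               f1 = f1_of(prf_ratio(c_ty, nrow(p)), prf_ratio(c_ty, nrow(g))),
               stringsAsFactors = FALSE)
  }))
  P <- prf_ratio(C, nrow(pred))
  R <- prf_ratio(C, nrow(gold))
  structure(list(M = nrow(pred), N = nrow(gold), C = C,
                 precision = P, recall = R, f1 = f1_of(P, R),
                 by_type = by_type %||% data.frame()),
            class = "metrics_report")
}

#' @keywords internal
#' @noRd
prf_ratio <- function(num, den) if (den == 0L) 0 else num / den

#' @keywords internal
#' @noRd
f1_of <- function(P, R) if (P + R == 0) 0 else 2 * P * R / (P + R)

#' @keywords internal
#' @noRd
normalize_spans <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0L) {
    return(data.frame(sentence = integer(0), start = integer(0),
                      end = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(spans$sentence)) spans$sentence <- 1L
  spans[, c("sentence", "start", "end", "type")]
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> M=%d N=%d C=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$M, x$N, x$C, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate predicted against gold tag sequences
#'
#' Convenience wrapper: repairs predicted tags with [fix_invalid_bioes()],
#' extracts spans from both sides and pools exact-match counts over all
#' sentences.
#'
#' @param gold_tags,pred_tags Lists of BIOES tag vectors (one per sentence,
#'   aligned).
#' @return A `metrics_report` (see [exact_match_prf()]).
#' @export
evaluate_tags <- function(gold_tags, pred_tags) {
  if (length(gold_tags) != length(pred_tags)) {
    abort_validation("gold (%d) and predicted (%d) sentence counts differ",
                     length(gold_tags), length(pred_tags))
  }
  pred_tags <- lapply(pred_tags, fix_invalid_bioes)
  exact_match_prf(spans_of_sentences(gold_tags), spans_of_sentences(pred_tags))
}

#' Macro-average metric reports across datasets
#'
#' Arithmetic mean of per-dataset precision, recall and F1 — the
#' cross-dataset summary used when comparing tagger families over several
#' single-entity-type corpora.
#'
#' @param reports List of `metrics_report` objects.
#' @return A list with `precision`, `recall` and `f1`.
#' @export
macro_average <- function(reports) {
  list(precision = mean(vapply(reports, `[[`, numeric(1), "precision")),
       recall = mean(vapply(reports, `[[`, numeric(1), "recall")),
       f1 = mean(vapply(reports, `[[`, numeric(1), "f1")))
}

#' Classify incorrect predictions into an error taxonomy
#'
#' Each predicted span that is not an exact match of a target-type gold span
#' is assigned one category, with precedence bio-entity > span > spurious:
#' \describe{
#'   \item{bio_entity}{the prediction exactly matches — or, by default,
#'     overlaps — a gold entity of a *different* type: the polysemy failure
#'     mode (e.g. a gene name tagged as a disease).}
#'   \item{span}{the prediction overlaps a same-type gold entity but with
#'     different boundaries (typically modifier inclusion/exclusion).}
#'   \item{spurious}{no gold overlap of any type.}
#' }
#' Gold target-type spans with no exactly matching prediction are emitted as
#' `missed` records.
#'
#' @param pred Predicted spans (data frame, see [extract_spans()]).
#' @param gold_target Gold spans of the dataset's own entity type(s).
#' @param gold_other Gold spans of other entity types at the same token
#'   positions (from companion corpora or a fully annotated synthetic
#'   corpus).
#' @param overlap If `TRUE` (default) a bio-entity error requires only token
#'   overlap with an other-type gold span; if `FALSE`, an exact span match.
#' @return Data frame of error records: `sentence`, `start`, `end`, `type`,
#'   `category`, and the matched gold span (`matched_start`, `matched_end`,
#'   `matched_type`, `NA` when none).
#' @export
classify_errors <- function(pred, gold_target, gold_other, overlap = TRUE) {
  pred <- normalize_spans(pred)
  gold_target <- normalize_spans(gold_target)
  gold_other <- normalize_spans(gold_other)
  for (g in list(gold_target, gold_other)) {
    if (has_same_type_overlap(g)) {
      abort_validation("gold spans of one type overlap within a sentence")
    }
  }
  key <- function(df) paste(df$sentence, df$start, df$end, df$type)
  rec <- list()
  correct <- key(pred) %in% key(gold_target)
  for (i in seq_len(nrow(pred))) {
    if (correct[i]) next
    p <- pred[i, ]
    m <- find_overlap(p, gold_other, exact = !overlap)
    if (!is.null(m)) {
      rec[[length(rec) + 1L]] <- error_record(p, "bio_entity", m)
      next
    }
    m <- find_overlap(p, gold_target[gold_target$type == p$type, , drop = FALSE],
                      exact = FALSE)
    if (!is.null(m)) {
      rec[[length(rec) + 1L]] <- error_record(p, "span", m)
    } else {
      rec[[length(rec) + 1L]] <- error_record(p, "spurious", NULL)
    }
  }
  matched_gold <- key(gold_target) %in% key(pred)
  for (i in seq_len(nrow(gold_target))) {
    if (!matched_gold[i]) {
      rec[[length(rec) + 1L]] <- error_record(gold_target[i, ], "missed", NULL)
    }
  }
  if (!length(rec)) {
    return(data.frame(sentence = integer(0), start = integer(0),
                      end = integer(0), type = character(0),
                      category = character(0), matched_start = integer(0),
                      matched_end = integer(0), matched_type = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rec, list(make.row.names = FALSE)))
}

#' @keywords internal
#' @noRd
error_record <- function(span, category, matched) {
  data.frame(sentence = span$sentence, start = span$start, end = span$end,
             type = span$type, category = category,
             matched_start = if (is.null(matched)) NA_integer_ else matched$start,
             matched_end = if (is.null(matched)) NA_integer_ else matched$end,
             matched_type = if (is.null(matched)) NA_character_ else matched$type,
             stringsAsFactors = FALSE)
}

# First gold span in `gold` that (exactly matches | token-overlaps) `p`,
# within the same sentence; exact matches take priority in overlap mode.
#' @keywords internal
#' @noRd
find_overlap <- function(p, gold, exact) {
  g <- gold[gold$sentence == p$sentence, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  is_exact <- g$start == p$start & g$end == p$end
  if (any(is_exact)) return(g[which(is_exact)[1L], ])
  if (exact) return(NULL)
  hits <- g$start <= p$end & g$end >= p$start
  if (any(hits)) g[which(hits)[1L], ] else NULL
}

#' @keywords internal
#' @noRd
has_same_type_overlap <- function(spans) {
  if (nrow(spans) < 2L) return(FALSE)
  by_grp <- split(spans, paste(spans$sentence, spans$type))
  any(vapply(by_grp, function(g) {
    g <- g[order(g$start), ]
    nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)])
  }, logical(1)))
}

#' Summarize error records
#'
#' Per-category counts from [classify_errors()] plus the ratio of bio-entity
#' errors to all errors — the quantity that drops when collaborating expert
#' models suppress each other's entity types.
#'
#' @param records Data frame from [classify_errors()].
#' @return List with `counts` (named integer vector over the four
#'   categories), `total`, `bio_entity_ratio`, and `empty` (`TRUE` when
#'   there were no errors at all, in which case the ratio is reported as 0).
#' @export
error_summary <- function(records) {
  cats <- c("bio_entity", "span", "spurious", "missed")
  counts <- vapply(cats, function(ct) sum(records$category == ct), integer(1))
  total <- sum(counts)
  list(counts = counts, total = total,
       bio_entity_ratio = if (total == 0L) 0 else unname(counts["bio_entity"]) / total,
       empty = total == 0L)
}
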