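#' Convert between BIO and BIOES tag schemes
#'
#' The BIOES scheme refines BIO by marking single-token entities `S` and the
#' last token of a multi-token entity `E`, which gives a sequence tagger an
#' explicit signal for entity boundaries. `bio_to_bioes()` rewrites a valid
#' BIO sequence (singleton `B` becomes `S`; the final `I` of a run becomes
#' `E`); `bioes_to_bio()` is its inverse (`S` to `B`, `E` to `I`). The two
#' functions are mutually inverse bijections between the valid sublanguages.
#'
#' Invalid input raises a validation error; repairing broken BIOES output is
#' the job of [fix_invalid_bioes()], not of these converters.
#'
#' @param tags Character vector of tags.
#' @return Character vector of converted tags, same length.
#' @examples
#' bio_to_bioes(c("B-gene", "I-gene", "O", "B-gene"))
#' bioes_to_bio(c("B-gene", "E-gene", "O", "S-gene"))
#' @export
bio_to_bioes <- function(tags) {
  if (!is_valid_bio(tags)) {
    abort_validation("input is not a valid BIO tag sequence")
  }
  n <- length(tags)
  out <- tags
  pfx <- substr(tags, 1L, 1L)
  typ <- ifelse(pfx == "O", "", sub("^[BI]-", "", tags))
  for (t in seq_len(n)) {
    if (pfx[t] == "O") next
    run_continues <- t < n && pfx[t + 1L] == "I" && typ[t + 1L] == typ[t]
    if (pfx[t] == "B") {
      out[t] <- paste0(if (run_continues) "B" else "S", "-", typ[t])
    } else {                      # "I"
      out[t] <- paste0(if (run_continues) "I" else "E", "-", typ[t])
    }
  }
  out
}

#' @rdname bio_to_bioes
#' @export
bioes_to_bio <- function(tags) {
  if (!is_valid_bioes(tags)) {
    abort_validation("input is not a valid BIOES tag sequence")
  }
  out <- sub("^S-", "B-", tags)
  sub("^E-", "I-", out)
}

# Valid BIO: tags are O or B-/I-TYPE, and I only continues a same-type B/I.
#' @keywords internal
#' @noRd
is_valid_bio <- function(tags) {
  if (length(tags) == 0L) return(TRUE)
  if (any(!grepl("^(O|[BI]-.+)$", tags))) return(FALSE)
  pfx <- substr(tags, 1L, 1L)
  typ <- ifelse(pfx == "O", "", sub("^[BI]-", "", tags))
  for (t in seq_along(tags)) {
    if (pfx[t] == "I") {
      if (t == 1L || pfx[t - 1L] == "O" || typ[t - 1L] != typ[t]) return(FALSE)
    }
  }
  TRUE
}
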