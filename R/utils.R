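# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("collabotag_validation_error", "error")))
}

#' @keywords internal
#' @noRd
abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("collabotag_parse_error",
                                "collabotag_validation_error", "error")))
}

# Numerically stable log(sum(exp(x))).
#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
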