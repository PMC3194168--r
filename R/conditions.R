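# Classed error conditions. Every domain error carries a stable `code` so
# callers (and the CLI) can dispatch on it; testthat matches on the class
# "mdr_error_<code>".

mdr_abort <- function(code, message, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    code = code,
    class = c(paste0("mdr_error_", code), "mdr_error")
  ))
}

#' Construct a validation report
#'
#' A validation report is a data frame with one row per finding and columns
#' `code`, `entity` and `message`. An empty report means the graph or
#' registry satisfies every enforced invariant.
#'
#' @param findings A list of lists, each with elements `code`, `entity`,
#'   `message`.
#' @return A data frame of class `mdr_validation_report`.
#' @keywords internal
new_validation_report <- function(findings = list()) {
  if (length(findings) == 0L) {
    out <- data.frame(code = character(), entity = character(),
                      message = character(), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      code = vapply(findings, `[[`, character(1), "code"),
      entity = vapply(findings, `[[`, character(1), "entity"),
      message = vapply(findings, `[[`, character(1), "message"),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("mdr_validation_report", class(out))
  out
}

#' @export
print.mdr_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation report: 0 findings>\n")
  } else {
    cat(sprintf("<validation report: %d finding(s)>\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
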