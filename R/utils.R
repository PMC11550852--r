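#' @importFrom rlang abort warn inform .data :=
#' @importFrom stats quantile sd qt pt rnorm runif var setNames complete.cases
#' @importFrom utils head
NULL

# Package-level verbosity switch; all drop/exclusion logging funnels through here
# so tests can silence or capture it.
fc_log <- function(...) {
  if (isTRUE(getOption("fertconv.quiet", FALSE))) return(invisible(NULL))
  rlang::inform(paste0(...), class = "fertconv_log")
}

fc_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "fertconv_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a few offending keys for an error message without flooding it.
fc_key_preview <- function(df, cols, n = 5L) {
  keys <- do.call(paste, c(unname(as.list(df[cols])), sep = "/"))
  keys <- unique(keys)
  out <- paste(utils::head(keys, n), collapse = ", ")
  if (length(keys) > n) out <- paste0(out, ", ... (", length(keys), " total)")
  out
}
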