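## Shared condition constructors and small helpers.

crmlit_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "crmlit_error")))
}

err_io <- function(msg, ...) crmlit_error(msg, "crmlit_io_error", ...)
err_format <- function(msg, ...) crmlit_error(msg, "crmlit_format_error", ...)
err_config <- function(msg, ...) crmlit_error(msg, "crmlit_config_error", ...)
err_contract <- function(msg, ...) crmlit_error(msg, "crmlit_contract_error", ...)
err_state <- function(msg, ...) crmlit_error(msg, "crmlit_state_error", ...)
err_data <- function(msg, ...) crmlit_error(msg, "crmlit_data_error", ...)
err_retrieval <- function(msg, ...) crmlit_error(msg, "crmlit_retrieval_error", ...)
err_parse <- function(msg, ...) crmlit_error(msg, "crmlit_parse_error", ...)
err_eval <- function(msg, ...) crmlit_error(msg, "crmlit_evaluation_error", ...)

## Structured per-article log records surface as messages so batch runs are
## auditable without aborting.
crmlit_log <- function(..., pmid = NULL, stage = NULL) {
  prefix <- paste0(
    if (!is.null(stage)) paste0("[", stage, "] ") else "",
    if (!is.null(pmid)) paste0("pmid=", pmid, " ") else ""
  )
  message("crmlit: ", prefix, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    err_contract(sprintf("%s must be a single string", what))
  }
}

## Lowercase, strip punctuation, squeeze whitespace: the normal form used for
## section-title matching and stoplist lookup.
normalize_title <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
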