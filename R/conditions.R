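# Classed conditions used across the pipeline. Every stage signals a subclass
# of "cypscreen_error" so callers can distinguish chemistry failures from
# statistical ones.

cyp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cypscreen_error"), ...)
}

#' @noRd
parse_error <- function(id, msg) {
  cyp_abort(
    sprintf("structure for '%s' could not be parsed: %s", id, msg),
    class = "cyp_parse_error", id = id
  )
}

inorganic_error <- function(id) {
  cyp_abort(
    sprintf("'%s' has no carbon-containing fragment", id),
    class = "cyp_inorganic_error", id = id
  )
}

split_error <- function(msg) cyp_abort(msg, class = "cyp_split_error")
train_error <- function(msg) cyp_abort(msg, class = "cyp_train_error")
eval_error  <- function(msg) cyp_abort(msg, class = "cyp_eval_error")
apd_error   <- function(msg) cyp_abort(msg, class = "cyp_apd_error")
screen_error <- function(msg) cyp_abort(msg, class = "cyp_screen_error")
filter_error <- function(field) {
  cyp_abort(sprintf("descriptor '%s' is missing", field),
            class = "cyp_filter_error", field = field)
}
assay_error <- function(msg) cyp_abort(msg, class = "cyp_assay_error")
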