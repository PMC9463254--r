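#' @importFrom rlang %||% abort .data enquo eval_tidy
#' @importFrom stats median sd optimize rnorm setNames
#' @keywords internal
"_PACKAGE"

# internal: stop with a classed condition so callers can distinguish
# validation problems (bad values) from format problems (bad files)
t2_abort <- function(msg, class = "t2star_validation_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg, class = "t2star_validation_error") {
  if (!isTRUE(ok)) t2_abort(msg, class)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
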