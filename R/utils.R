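# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_domfun <- function(..., call. = FALSE) stop(..., call. = call.)

#' @keywords internal
msg <- function(..., verbose = getOption("domfun.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}

# validate a protein -> character-vector mapping (annotation sets and
# domain compositions share this shape)
check_named_sets <- function(x, what) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop_domfun(what, " must be a named list of character vectors")
  if (any(lengths(x) == 0L))
    stop_domfun(what, " contains empty sets: ",
                paste(utils::head(names(x)[lengths(x) == 0L], 3L), collapse = ", "))
  invisible(x)
}

is_go_id <- function(x) grepl("^GO:\\d{7}$", x)
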