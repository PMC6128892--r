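# internal helpers: error signalling and small shared checks

cx_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "chromexpress_error"), ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    cx_abort(sprintf("`%s` must be a single finite number.", name),
             "cx_validation_error")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    cx_abort(sprintf(
      "`%s` = %s is outside the allowed range %s%s, %s%s.",
      name, format(x), if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]"
    ), "cx_validation_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    cx_abort(sprintf("%s is missing required column(s): %s.",
                     what, paste(missing, collapse = ", ")),
             "cx_validation_error")
  }
  invisible(df)
}

`%||%` <- rlang::`%||%`
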