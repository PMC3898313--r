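# Shared low-level helpers: identifier lexicon, error classes, sorting.

# Shell variable lexicon: first char letter/underscore, then letters, digits,
# underscores. Used for script names, variable names and addressable
# environment-variable names alike.
is_identifier <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

assert_identifier <- function(x, what = "identifier") {
  if (!is_identifier(x)) {
    stop(sw_error("invalid_identifier",
                  sprintf("invalid %s: %s", what, deparse1(x))))
  }
  invisible(x)
}

# Classed conditions so callers (and the CLI) can distinguish parse errors,
# evaluation errors and contract violations without string matching.
sw_error <- function(class, message, ...) {
  structure(
    class = c(paste0("scriptwright_", class), "scriptwright_error",
              "error", "condition"),
    list(message = message, call = NULL, ...)
  )
}

sw_stop <- function(class, fmt, ...) {
  stop(sw_error(class, sprintf(fmt, ...)))
}

# Byte-wise (C locale) lexicographic sort, so ordering does not depend on the
# session locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
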