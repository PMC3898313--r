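#' Match filenames in a directory against a pattern
#'
#' Produces the sorted list of directory entries whose names match a
#' wildcard or regular-expression pattern, for building command arguments
#' from file sets.
#'
#' Wildcard mode supports `*` (any run of characters) and `?` (any single
#' character) within one path segment; patterns never cross directories and
#' matching is not recursive. Regex mode applies the pattern as a full match
#' against each entry name. Hidden entries (dot-prefixed) match only when
#' the pattern itself starts with a literal `.`. Zero matches is an empty
#' result, not an error.
#'
#' @param directory directory whose entries are matched, or a `path_pattern`
#'   object carrying all three fields.
#' @param pattern wildcard or regular-expression pattern (non-empty).
#' @param mode `"wildcard"` or `"regex"`.
#' @return Character vector of matching entry names, sorted byte-wise
#'   lexicographically.
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' file.create(file.path(d, c("a.sam", "b.sam", "c.txt")))
#' match_paths(d, "*.sam")                      # "a.sam" "b.sam"
#' match_paths(d, "^[ab]\\.sam$", mode = "regex")
#' match_paths(path_pattern(d, "?.txt"))
match_paths <- function(directory, pattern, mode = c("wildcard", "regex")) {
  if (inherits(directory, "path_pattern")) {
    p <- directory
    return(match_paths(p$directory, p$pattern, p$mode))
  }
  mode <- match.arg(mode)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) == 0L) sw_stop("bad_pattern", "empty pattern")
  if (!dir.exists(directory)) {
    sw_stop("io_error", "not a readable directory: %s", directory)
  }
  entries <- list.files(directory, all.files = TRUE, no.. = TRUE,
                        full.names = FALSE)
  hidden_ok <- substr(pattern, 1L, 1L) == "."
  entries <- entries[hidden_ok | substr(entries, 1L, 1L) != "."]

  rx <- if (mode == "wildcard") {
    if (grepl("/", pattern, fixed = TRUE)) {
      sw_stop("bad_pattern", "wildcard pattern may not cross directories: %s",
              pattern)
    }
    utils::glob2rx(pattern)
  } else {
    paste0("^(?:", pattern, ")$")
  }
  hits <- tryCatch(
    suppressWarnings(grepl(rx, entries, perl = (mode == "regex"))),
    error = function(e) {
      sw_stop("bad_pattern", "invalid pattern %s: %s", pattern,
              conditionMessage(e))
    }
  )
  sort_c(entries[hits])
}

#' @rdname match_paths
#' @export
path_pattern <- function(directory, pattern, mode = c("wildcard", "regex")) {
  mode <- match.arg(mode)
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) > 0L)
  structure(list(directory = directory, pattern = pattern, mode = mode),
            class = "path_pattern")
}
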