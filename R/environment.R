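#' Environment sources
#'
#' An environment source is a named origin of environment variables that a
#' script can load, reload and enumerate: a snapshot of the ambient process
#' environment, a `KEY=VALUE` definitions file, or a plugin configuration
#' (see [plugin_environment_source()]). Sources make the execution
#' environment explicit: scripts declare which sources they load, the checker
#' flags reads of variables no loaded source declares, and completion-style
#' queries ([available_names()]) enumerate what may be read.
#'
#' A source id is stable across reloads, so statements referencing a source
#' survive a refresh of its variables.
#'
#' @name environment-sources
NULL

new_env_source <- function(id, kind, params, variables) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(kind %in% c("process", "file", "plugin-config"))
  vars <- as.character(variables)
  names(vars) <- names(variables)
  structure(list(id = id, kind = kind, params = params, variables = vars),
            class = "env_source")
}

#' @export
print.env_source <- function(x, ...) {
  cat(sprintf("<env_source %s> kind=%s, %d variable(s)\n",
              x$id, x$kind, length(x$variables)))
  invisible(x)
}

#' Snapshot the ambient process environment
#'
#' @return An `env_source` of kind `"process"` holding the environment of the
#'   calling process at call time. [reload_source()] takes a fresh snapshot.
#' @export
load_process_source <- function() {
  e <- Sys.getenv()
  vars <- as.character(e)
  names(vars) <- names(e)
  new_env_source("process", "process", params = list(), variables = vars)
}

#' Load environment definitions from a file
#'
#' Parses a dotenv-style file: one `KEY=VALUE` per line, `#`-prefixed comment
#' lines and blank lines ignored, values taken verbatim after the first `=`
#' (no quote expansion), later duplicate keys win.
#'
#' @param path path to the definitions file.
#' @return An `env_source` of kind `"file"`.
#' @export
load_file_source <- function(path) {
  if (!file.exists(path)) {
    sw_stop("io_error", "environment file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  vars <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*(#|$)", line)) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 1L) {
      sw_stop("parse_error", "%s:%d: malformed line (no '=')", path, i)
    }
    key <- substr(line, 1L, eq - 1L)
    if (nchar(key) == 0L) {
      sw_stop("parse_error", "%s:%d: malformed line (empty key)", path, i)
    }
    vars[[key]] <- substr(line, eq + 1L, nchar(line))  # last one wins
  }
  new_env_source(paste0("file:", path), "file",
                 params = list(path = path), variables = vars)
}

#' Re-read a source from its origin
#'
#' Returns a source with the same id and freshly read variables. If the
#' origin has vanished (e.g. the file was deleted) an error is signalled and
#' the caller's source is left usable as-is.
#'
#' @param source an `env_source`.
#' @return An `env_source` with identical id and refreshed variables.
#' @export
reload_source <- function(source) {
  stopifnot(inherits(source, "env_source"))
  switch(source$kind,
    process = load_process_source(),
    file    = load_file_source(source$params$path),
    # plugin-config sources are pure functions of the descriptor, which is
    # kept in params; re-deriving gives the same variables.
    `plugin-config` = plugin_environment_source(source$params$descriptor)
  )
}

addressable_names <- function(source) {
  nm <- names(source$variables)
  nm[vapply(nm, is_identifier, logical(1))]
}

#' Resolve a variable across an ordered list of sources
#'
#' Later sources shadow earlier ones: resolution scans the list last-to-first
#' and returns the first hit. Only identifier-shaped names are addressable;
#' ambient names containing other characters are stored but never resolved.
#'
#' @param name variable name.
#' @param sources list of `env_source` objects, in load order.
#' @return character scalar value.
#' @export
resolve_variable <- function(name, sources) {
  for (s in rev(sources)) {
    if (is_identifier(name) && name %in% names(s$variables)) {
      return(unname(s$variables[[name]]))
    }
  }
  sw_stop("resolve_error", "variable %s is declared by no loaded source", name)
}

#' Enumerate addressable variable names
#'
#' @param sources list of `env_source` objects.
#' @return Sorted character vector: the union of addressable names over all
#'   sources (the design-time completion set).
#' @export
available_names <- function(sources) {
  sort_c(unique(unlist(lapply(sources, addressable_names), use.names = FALSE)))
}
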