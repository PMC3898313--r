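#' Interpolated strings with lazily evaluated references
#'
#' A `gstring` is an ordered list of components, each one of:
#' \describe{
#'   \item{literal}{a plain text run;}
#'   \item{varref}{a reference to a program variable, written `${name}`;}
#'   \item{envread}{a read of an environment variable, also written `${name}`.}
#' }
#' Nothing is substituted at construction time: [evaluate_gstring()] resolves
#' the references against the bindings current at the moment of evaluation, so
#' rebinding a variable and re-evaluating yields the new value (lazy
#' evaluation). The normal form keeps no empty literals and never two adjacent
#' literals.
#'
#' @param components list of components built with [gs_literal()],
#'   [gs_varref()] or [gs_envread()].
#' @return An object of class `gstring`.
#' @seealso [parse_gstring()], [evaluate_gstring()], [normalize_gstring()]
#' @export
#' @examples
#' g <- gstring(list(gs_literal("x="), gs_varref("a")))
#' evaluate_gstring(g, bindings = c(a = "1"))
gstring <- function(components = list()) {
  stopifnot(is.list(components))
  structure(list(components = components), class = "gstring")
}

#' @rdname gstring
#' @param text literal text.
#' @export
gs_literal <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  list(kind = "literal", text = text)
}

#' @rdname gstring
#' @param name variable name (shell identifier).
#' @param declaration_id id of the targeted declaration node, or `NA` when the
#'   reference has not (yet) been linked to a declaration.
#' @export
gs_varref <- function(name, declaration_id = NA_character_) {
  assert_identifier(name, "variable name")
  list(kind = "varref", name = name,
       declaration_id = as.character(declaration_id))
}

#' @rdname gstring
#' @export
gs_envread <- function(name) {
  assert_identifier(name, "environment variable name")
  list(kind = "envread", name = name)
}

is_gstring <- function(x) inherits(x, "gstring")

#' @export
print.gstring <- function(x, ...) {
  kinds <- vapply(x$components, `[[`, "", "kind")
  cat("<gstring> ", render_gstring(x), "\n  components: ",
      paste(kinds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.gstring <- function(x) length(x$components)

gs_kinds <- function(g) vapply(g$components, `[[`, "", "kind")

#' Parse marker syntax into a gstring
#'
#' Scans `text` for `${name}` markers. A marker becomes a `varref` when its
#' name is in `scope`, an `envread` when it is in `env_names`; a name known to
#' neither becomes an unlinked `varref` (the checker later reports it as a
#' reference to an undeclared variable). On a collision, `scope` wins: a
#' program variable shadows an environment variable of the same name.
#' Interior whitespace in a marker (`${ b}`) is trimmed. `\${` escapes the
#' marker and yields a literal `${`; a `$` not followed by `{` is an ordinary
#' character.
#'
#' @param text character scalar to parse.
#' @param scope character vector of in-scope program variable names.
#' @param env_names character vector of known environment variable names.
#' @return A `gstring` in normal form.
#' @export
#' @examples
#' g <- parse_gstring("hello ${who}", scope = "who")
#' evaluate_gstring(g, bindings = c(who = "world"))
parse_gstring <- function(text, scope = character(), env_names = character()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  comps <- list()
  lit <- character(0)        # accumulating literal chunks
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  flush_lit <- function() {
    if (length(lit) > 0L) {
      comps[[length(comps) + 1L]] <<- gs_literal(paste(lit, collapse = ""))
      lit <<- character(0)
    }
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i + 1L <= n && chars[i + 1L] == "$" &&
        i + 2L <= n && chars[i + 2L] == "{") {
      lit <- c(lit, "${")
      # consume up to the matching brace? No: escape covers only the marker
      # opener; the rest of the would-be marker is plain text.
      i <- i + 3L
      next
    }
    if (ch == "$" && i + 1L <= n && chars[i + 1L] == "{") {
      close <- i + 2L
      while (close <= n && chars[close] != "}") close <- close + 1L
      if (close > n) {
        sw_stop("parse_error",
                "unterminated ${ marker at offset %d", i - 1L)
      }
      name <- trimws(paste(chars[seq.int(i + 2L, length.out = close - i - 2L)],
                           collapse = ""))
      if (!is_identifier(name)) {
        sw_stop("parse_error",
                "invalid variable name in ${ } marker at offset %d", i - 1L)
      }
      flush_lit()
      comps[[length(comps) + 1L]] <-
        if (name %in% scope) gs_varref(name)
        else if (name %in% env_names) gs_envread(name)
        else gs_varref(name)   # undeclared; flagged later by the checker
      i <- close + 1L
      next
    }
    lit <- c(lit, ch)
    i <- i + 1L
  }
  flush_lit()
  normalize_gstring(gstring(comps))
}

#' Evaluate a gstring against current bindings
#'
#' Concatenates literal components with the *current* values of the referenced
#' variables. Evaluation is a pure function of `(bindings, env)`: evaluating
#' the same gstring again after a rebinding reflects the new values.
#'
#' @param g a `gstring`.
#' @param bindings named character vector of program-variable values.
#' @param env named character vector of environment-variable values, or a
#'   function `name -> value` (used by the executor to resolve reads against
#'   loaded environment sources).
#' @return character scalar.
#' @export
evaluate_gstring <- function(g, bindings = character(), env = character()) {
  stopifnot(is_gstring(g))
  env_get <- if (is.function(env)) env else function(name) {
    if (name %in% names(env)) env[[name]] else
      sw_stop("eval_error", "unbound environment variable %s", name)
  }
  parts <- vapply(g$components, function(co) {
    switch(co$kind,
      literal = co$text,
      varref  = {
        if (!co$name %in% names(bindings)) {
          sw_stop("eval_error", "unbound variable %s", co$name)
        }
        as.character(bindings[[co$name]])
      },
      envread = as.character(env_get(co$name)),
      sw_stop("internal", "unknown gstring component kind %s", co$kind)
    )
  }, character(1))
  paste(parts, collapse = "")
}

#' Normalize a gstring
#'
#' Merges adjacent literal components and drops empty literals. Idempotent and
#' evaluation-equivalent to its input.
#'
#' @param g a `gstring`.
#' @return A `gstring` in normal form.
#' @export
normalize_gstring <- function(g) {
  stopifnot(is_gstring(g))
  out <- list()
  for (co in g$components) {
    if (co$kind == "literal") {
      if (nchar(co$text) == 0L) next
      last <- if (length(out) > 0L) out[[length(out)]] else NULL
      if (!is.null(last) && last$kind == "literal") {
        out[[length(out)]] <- gs_literal(paste0(last$text, co$text))
        next
      }
    }
    out[[length(out) + 1L]] <- co
  }
  gstring(out)
}

#' Render a gstring back to marker syntax
#'
#' Inverse of [parse_gstring()] for escape-free inputs: literals are emitted
#' verbatim (any literal `${` is re-escaped as `\${`), references as
#' `${name}`.
#'
#' @param g a `gstring`.
#' @return character scalar.
#' @export
render_gstring <- function(g) {
  stopifnot(is_gstring(g))
  parts <- vapply(g$components, function(co) {
    switch(co$kind,
      literal = gsub("${", "\\${", co$text, fixed = TRUE),
      varref  = paste0("${", co$name, "}"),
      envread = paste0("${", co$name, "}")
    )
  }, character(1))
  paste(parts, collapse = "")
}

# TRUE when the gstring is raw pasted text: a single literal (or empty).
gs_is_literal_only <- function(g) {
  all(gs_kinds(g) == "literal")
}
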