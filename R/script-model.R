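#' Script models: a typed AST for shell scripts
#'
#' A script model is the whole-script abstract syntax tree: a name, a script
#' type, optional plugin binding, an ordered list of environment sources, an
#' ordered list of statements, and a map of named entry points (each an
#' ordered statement list). Every statement and pipeline node carries a
#' model-unique id, so diagnostics and references survive persistence.
#'
#' Statement variants:
#' \describe{
#'   \item{var_decl}{declare a program variable with a gstring initializer;}
#'   \item{execute}{run a command pipeline ([execute_command]);}
#'   \item{load_env}{make the referenced environment sources resolvable for
#'     subsequent statements in the same scope;}
#'   \item{env_assign}{set an environment variable for later commands; both
#'     the name and the value are gstrings, so computed names are allowed.}
#' }
#'
#' The main statement list and each entry point are independent scopes: a
#' variable reference must target a declaration earlier in the *same* list,
#' and environment loads only cover later statements of their own list.
#'
#' @param name script name (shell identifier).
#' @param script_type one of `"plain"`, `"aligner"`, `"alignment-analysis"`,
#'   `"resource"`, `"artifact-install"`, `"task"`. Non-plain types are plugin
#'   scripts and are expected to carry a plugin binding and the entry points
#'   their type requires (see [scaffold_script()]).
#' @return A `script_model`.
#' @seealso [check_script()], [save_script()], [run_script()]
#' @export
#' @examples
#' m <- new_script("demo")
#' m <- add_declaration(m, "who", "world")
#' m <- add_execute(m, "echo hello ${who}")
#' check_script(m)   # no findings
new_script <- function(name, script_type = "plain") {
  assert_identifier(name, "script name")
  if (!script_type %in% SCRIPT_TYPES) {
    sw_stop("bad_type", "unknown script type: %s", script_type)
  }
  structure(list(
    name = name,
    script_type = script_type,
    format_version = 1L,
    plugin_header = NULL,
    sources = list(),
    statements = list(),
    entry_points = empty_named_list(),
    next_id = 1L
  ), class = "script_model")
}

SCRIPT_TYPES <- c("plain", "aligner", "alignment-analysis", "resource",
                  "artifact-install", "task")
PLUGIN_TYPES <- setdiff(SCRIPT_TYPES, "plain")

empty_named_list <- function() structure(list(), names = character(0))

#' @export
print.script_model <- function(x, ...) {
  cat(sprintf("<script_model %s> type=%s, %d source(s), %d statement(s)",
              x$name, x$script_type, length(x$sources), length(x$statements)))
  if (length(x$entry_points) > 0L) {
    cat(", entry points: ", paste(names(x$entry_points), collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- node ids ---------------------------------------------------------------

alloc_id <- function(model) {
  id <- sprintf("n%d", model$next_id)
  model$next_id <- model$next_id + 1L
  list(model = model, id = id)
}

# Assign fresh ids to a statement and (recursively) its pipeline nodes.
assign_ids <- function(model, stmt) {
  a <- alloc_id(model); model <- a$model
  stmt$id <- a$id
  if (stmt$kind == "execute") {
    for (k in seq_along(stmt$pipeline$nodes)) {
      a <- alloc_id(model); model <- a$model
      stmt$pipeline$nodes[[k]]$id <- a$id
    }
  }
  list(model = model, stmt = stmt)
}

# ---- statement constructors (ids filled in when attached) -------------------

stmt_var_decl <- function(name, initializer) {
  assert_identifier(name, "variable name")
  if (is.character(initializer)) initializer <- gstring(list(gs_literal(initializer)))
  stopifnot(is_gstring(initializer))
  list(id = NA_character_, kind = "var_decl", name = name,
       initializer = initializer)
}

stmt_execute <- function(pipeline) {
  stopifnot(inherits(pipeline, "execute_command"))
  list(id = NA_character_, kind = "execute", pipeline = pipeline)
}

stmt_load_env <- function(source_refs) {
  list(id = NA_character_, kind = "load_env",
       source_refs = as.character(source_refs))
}

stmt_env_assign <- function(var_name, value) {
  if (is.character(var_name)) var_name <- gstring(list(gs_literal(var_name)))
  if (is.character(value)) value <- gstring(list(gs_literal(value)))
  stopifnot(is_gstring(var_name), is_gstring(value))
  list(id = NA_character_, kind = "env_assign", var_name = var_name,
       value = value)
}

# ---- builders ---------------------------------------------------------------

# Scope of declared variable names in a statement list.
decl_names <- function(stmts) {
  nm <- vapply(stmts, function(s) if (s$kind == "var_decl") s$name else NA_character_,
               character(1))
  nm[!is.na(nm)]
}

stmt_list_of <- function(model, entry) {
  if (is.null(entry)) model$statements else model$entry_points[[entry]]
}

append_stmt <- function(model, stmt, entry = NULL) {
  if (!is.null(entry) && !entry %in% names(model$entry_points)) {
    sw_stop("no_entry_point", "entry point not defined: %s", entry)
  }
  r <- assign_ids(model, stmt)
  model <- r$model
  if (is.null(entry)) {
    model$statements[[length(model$statements) + 1L]] <- r$stmt
  } else {
    model$entry_points[[entry]][[length(model$entry_points[[entry]]) + 1L]] <- r$stmt
  }
  model
}

#' Add statements to a script model
#'
#' Builder functions append one statement to the main statement list, or to a
#' named entry point when `entry` is given. `add_execute()` accepts either an
#' [execute_command] or raw pipeline text, which is micro-parsed with
#' [parse_pipeline()] against the names currently in scope (declared
#' variables, and the union of variable names of the model's sources).
#'
#' @param model a `script_model`.
#' @param name variable name to declare.
#' @param initializer gstring or character initializer.
#' @param entry entry-point name, or `NULL` for the main list.
#' @return The extended model.
#' @export
add_declaration <- function(model, name, initializer, entry = NULL) {
  assert_identifier(name, "variable name")
  if (name %in% decl_names(stmt_list_of(model, entry))) {
    sw_stop("duplicate_declaration",
            "variable %s already declared in this scope", name)
  }
  if (is.character(initializer)) {
    initializer <- parse_gstring(initializer,
                                 scope = decl_names(stmt_list_of(model, entry)),
                                 env_names = model_env_names(model))
  }
  append_stmt(model, stmt_var_decl(name, initializer), entry)
}

model_env_names <- function(model) {
  unique(unlist(lapply(model$sources, addressable_names), use.names = FALSE))
}

#' @rdname add_declaration
#' @param pipeline an [execute_command] or raw BASH pipeline text.
#' @export
add_execute <- function(model, pipeline, entry = NULL) {
  if (is.character(pipeline)) {
    pipeline <- parse_pipeline(pipeline,
                               scope = decl_names(stmt_list_of(model, entry)),
                               env_names = model_env_names(model))
  }
  append_stmt(model, stmt_execute(pipeline), entry)
}

#' @rdname add_declaration
#' @param source an `env_source` to attach to the model.
#' @export
add_source <- function(model, source) {
  stopifnot(inherits(source, "env_source"))
  if (source$id %in% vapply(model$sources, `[[`, "", "id")) {
    sw_stop("duplicate_source", "source already attached: %s", source$id)
  }
  model$sources[[length(model$sources) + 1L]] <- source
  model
}

#' @rdname add_declaration
#' @param source_refs character vector of source ids to load (defaults to all
#'   attached sources).
#' @export
add_load_env <- function(model, source_refs = NULL, entry = NULL) {
  if (is.null(source_refs)) {
    source_refs <- vapply(model$sources, `[[`, "", "id")
  }
  known <- vapply(model$sources, `[[`, "", "id")
  bad <- setdiff(source_refs, known)
  if (length(bad) > 0L) {
    sw_stop("unknown_source", "load_env references unattached source(s): %s",
            paste(bad, collapse = ", "))
  }
  append_stmt(model, stmt_load_env(source_refs), entry)
}

#' @rdname add_declaration
#' @param var_name,value gstrings (or character, parsed against the current
#'   scope) for the environment variable name and value.
#' @export
add_env_assign <- function(model, var_name, value, entry = NULL) {
  sc <- decl_names(stmt_list_of(model, entry))
  en <- model_env_names(model)
  if (is.character(var_name)) var_name <- parse_gstring(var_name, sc, en)
  if (is.character(value))    value    <- parse_gstring(value, sc, en)
  append_stmt(model, stmt_env_assign(var_name, value), entry)
}

#' @rdname add_declaration
#' @param entry_point name of the entry point to create (empty).
#' @export
add_entry_point <- function(model, entry_point) {
  assert_identifier(entry_point, "entry point name")
  if (entry_point %in% names(model$entry_points)) {
    sw_stop("duplicate_entry_point", "entry point already defined: %s",
            entry_point)
  }
  model$entry_points[[entry_point]] <- list()
  model
}

# ---- structural equality ----------------------------------------------------

#' Structural equality of script models
#'
#' Two models are structurally equal when their canonical serialized forms
#' (see [save_script()]) are byte-identical: same nodes, same ids, same
#' order.
#'
#' @param a,b script models.
#' @return logical scalar.
#' @export
models_equal <- function(a, b) {
  identical(model_to_json(a), model_to_json(b))
}
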