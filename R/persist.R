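# Persisted script-model format: a versioned JSON document, one file per
# script, with explicit node ids so references round-trip exactly.
# load_script(save_script(m)) is structurally identical to m.

FORMAT_VERSION <- 1L

gstring_to_list <- function(g) {
  lapply(g$components, function(co) {
    switch(co$kind,
      literal = list(kind = "literal", text = co$text),
      varref  = list(kind = "varref", name = co$name,
                     declaration_id = co$declaration_id),
      envread = list(kind = "envread", name = co$name)
    )
  })
}

gstring_from_list <- function(x) {
  gstring(lapply(x, function(co) {
    switch(co$kind,
      literal = gs_literal(co$text),
      varref  = gs_varref(co$name, co$declaration_id %||% NA_character_),
      envread = gs_envread(co$name),
      sw_stop("parse_error", "unknown gstring component kind: %s",
              co$kind %||% "<missing>")
    )
  }))
}

node_to_list <- function(nd) {
  base <- list(id = nd$id, kind = nd$kind)
  switch(nd$kind,
    command   = c(base, list(line = gstring_to_list(nd$line),
                             background = nd$background)),
    operator  = c(base, list(op = nd$op)),
    redirect  = c(base, list(target = gstring_to_list(nd$target))),
    slot_command = c(base, list(direction = nd$direction, slot = nd$slot)),
    sw_stop("parse_error", "unknown pipeline node kind: %s", nd$kind)
  )
}

node_from_list <- function(x) {
  nd <- switch(x$kind %||% "<missing>",
    command   = cmd_node(gstring_from_list(x$line), isTRUE(x$background)),
    operator  = op_node(x$op),
    redirect  = redirect_node(gstring_from_list(x$target)),
    slot_command = slot_command_node(x$direction, x$slot),
    sw_stop("parse_error", "unknown pipeline node kind: %s",
            x$kind %||% "<missing>")
  )
  nd$id <- as.character(x$id)
  nd
}

stmt_to_list <- function(st) {
  base <- list(id = st$id, kind = st$kind)
  switch(st$kind,
    var_decl  = c(base, list(name = st$name,
                             initializer = gstring_to_list(st$initializer))),
    execute   = c(base, list(nodes = lapply(st$pipeline$nodes, node_to_list))),
    load_env  = c(base, list(source_refs = as.list(st$source_refs))),
    env_assign = c(base, list(var_name = gstring_to_list(st$var_name),
                              value = gstring_to_list(st$value))),
    sw_stop("parse_error", "unknown statement kind: %s", st$kind)
  )
}

stmt_from_list <- function(x) {
  st <- switch(x$kind %||% "<missing>",
    var_decl  = stmt_var_decl(x$name, gstring_from_list(x$initializer)),
    execute   = stmt_execute(execute_command(lapply(x$nodes, node_from_list))),
    load_env  = stmt_load_env(unlist(x$source_refs) %||% character(0)),
    env_assign = stmt_env_assign(gstring_from_list(x$var_name),
                                 gstring_from_list(x$value)),
    sw_stop("parse_error", "unknown statement kind: %s",
            x$kind %||% "<missing>")
  )
  st$id <- as.character(x$id)
  st
}

source_to_list <- function(s) {
  list(id = s$id, kind = s$kind,
       params = if (s$kind == "plugin-config")
         list(descriptor = descriptor_to_list(s$params$descriptor))
       else s$params,
       variables = as.list(s$variables))
}

source_from_list <- function(x) {
  vars <- unlist(lapply(x$variables, as.character)) %||% character(0)
  if (length(x$variables) > 0L) names(vars) <- names(x$variables)
  params <- if (identical(x$kind, "plugin-config")) {
    list(descriptor = descriptor_from_list(x$params$descriptor))
  } else {
    lapply(x$params, function(p) p)
  }
  new_env_source(as.character(x$id), x$kind, params, vars)
}

model_to_list <- function(model) {
  stopifnot(inherits(model, "script_model"))
  list(
    format_version = model$format_version,
    name = model$name,
    script_type = model$script_type,
    plugin_header = model$plugin_header,
    sources = lapply(model$sources, source_to_list),
    statements = lapply(model$statements, stmt_to_list),
    entry_points = lapply(model$entry_points,
                          function(stmts) lapply(stmts, stmt_to_list)),
    next_id = model$next_id
  )
}

model_to_json <- function(model) {
  jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE, null = "null",
                   digits = NA, pretty = TRUE)
}

model_from_list <- function(x, where = "<model>") {
  fv <- x$format_version
  if (is.null(fv) || !is.numeric(fv)) {
    sw_stop("parse_error", "%s: missing or non-numeric format_version", where)
  }
  if (fv > FORMAT_VERSION) {
    sw_stop("version_error",
            "%s: format version %d is newer than supported version %d",
            where, as.integer(fv), FORMAT_VERSION)
  }
  if (fv < 1L) sw_stop("parse_error", "%s: format_version must be >= 1", where)
  model <- new_script(x$name, x$script_type)
  model$format_version <- as.integer(fv)
  if (!is.null(x$plugin_header)) {
    model$plugin_header <- list(plugin_id = x$plugin_header$plugin_id,
                                plugin_type = x$plugin_header$plugin_type,
                                config_path = x$plugin_header$config_path)
  }
  model$sources <- lapply(x$sources, source_from_list)
  model$statements <- lapply(x$statements, stmt_from_list)
  eps <- lapply(x$entry_points, function(stmts) lapply(stmts, stmt_from_list))
  names(eps) <- names(x$entry_points) %||% character(0)
  if (length(eps) == 0L) eps <- empty_named_list()
  model$entry_points <- eps
  model$next_id <- as.integer(x$next_id)
  if (anyDuplicated(names(model$entry_points))) {
    sw_stop("parse_error", "%s: duplicate entry-point names", where)
  }
  model
}

#' Persist and restore script models
#'
#' `save_script()` writes the model as a versioned JSON document with
#' explicit node ids; `load_script()` restores it. The round trip is the
#' identity on structurally valid models, including node ids. Files written
#' by a newer, unknown format version are rejected with a version error; a
#' malformed or truncated file raises a parse error and never yields a
#' partial model.
#'
#' @param model a `script_model`.
#' @param path file path.
#' @return `save_script()` returns `path` invisibly; `load_script()` returns
#'   a `script_model`.
#' @export
save_script <- function(model, path) {
  stopifnot(inherits(model, "script_model"))
  writeLines(model_to_json(model), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_script
#' @export
load_script <- function(path) {
  if (!file.exists(path)) sw_stop("io_error", "no such model file: %s", path)
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      sw_stop("parse_error", "%s: not a valid model file (%s)",
              path, conditionMessage(e))
    }
  )
  model_from_list(x, where = path)
}
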