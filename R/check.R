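#' Semantic checking of script models
#'
#' Runs every checking rule over the model and returns all findings as a
#' data frame of diagnostics, ordered by node position (main statements
#' first, then entry points in definition order). The checker is pure: the
#' same model always yields the same diagnostics. An empty result means the
#' script is clean; the executor refuses models with error-severity
#' findings.
#'
#' Rules (codes are stable across releases):
#' \describe{
#'   \item{NYS001}{malformed operator sequence in a pipeline: consecutive
#'     binary operators, or a pipeline that begins or ends with one;}
#'   \item{NYS002}{redirect-to-file node not in final position, or more than
#'     one redirect;}
#'   \item{NYS003}{reference to a variable with no preceding declaration in
#'     the same scope;}
#'   \item{NYS010}{environment read of a name no previously loaded source
#'     declares (the design-time twin of a runtime resolution error);}
#'   \item{NYS020}{plugin-typed script missing its plugin binding or one of
#'     the entry points its type requires.}
#' }
#'
#' @param model a `script_model`.
#' @param contract entry-point contract (see [entry_point_contract()]); used
#'   by rule NYS020 for plugin-typed scripts.
#' @return A data frame with columns `severity`, `code`, `node_id`,
#'   `message`; zero rows when the script is clean.
#' @export
#' @examples
#' m <- new_script("demo")
#' m <- add_execute(m, "echo hi | sort")
#' nrow(check_script(m))   # 0
check_script <- function(model, contract = entry_point_contract()) {
  stopifnot(inherits(model, "script_model"))
  diags <- list()
  emit <- function(severity, code, node_id, message) {
    diags[[length(diags) + 1L]] <<- list(severity = severity, code = code,
                                         node_id = node_id, message = message)
  }

  check_scope <- function(stmts) {
    declared <- character(0)
    loaded_env <- character(0)       # addressable names of loaded sources
    src_by_id <- model$sources
    names(src_by_id) <- vapply(model$sources, `[[`, "", "id")

    check_gstring <- function(g, node_id) {
      for (co in g$components) {
        if (co$kind == "varref" && !co$name %in% declared) {
          emit("error", "NYS003", node_id,
               sprintf("reference to undeclared variable %s", co$name))
        }
        if (co$kind == "envread" && !co$name %in% loaded_env) {
          emit("error", "NYS010", node_id,
               sprintf("environment read of %s, but no loaded source declares it",
                       co$name))
        }
      }
    }

    for (st in stmts) {
      switch(st$kind,
        var_decl = {
          check_gstring(st$initializer, st$id)
          declared <- c(declared, st$name)
        },
        execute = {
          check_pipeline(st$pipeline, st$id, check_gstring, emit)
        },
        load_env = {
          for (ref in st$source_refs) {
            if (ref %in% names(src_by_id)) {
              loaded_env <- union(loaded_env,
                                  addressable_names(src_by_id[[ref]]))
            } else {
              emit("error", "NYS010", st$id,
                   sprintf("load of unattached source %s", ref))
            }
          }
        },
        env_assign = {
          check_gstring(st$var_name, st$id)
          check_gstring(st$value, st$id)
        }
      )
    }
  }

  check_scope(model$statements)
  for (ep in names(model$entry_points)) check_scope(model$entry_points[[ep]])

  if (model$script_type != "plain") {
    if (is.null(model$plugin_header)) {
      emit("error", "NYS020", "model",
           sprintf("%s script has no plugin binding", model$script_type))
    }
    required <- contract[[model$script_type]] %||% character(0)
    missing <- setdiff(required, names(model$entry_points))
    for (ep in missing) {
      emit("error", "NYS020", "model",
           sprintf("%s script is missing required entry point %s",
                   model$script_type, ep))
    }
  }

  if (length(diags) == 0L) {
    return(data.frame(severity = character(0), code = character(0),
                      node_id = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    severity = vapply(diags, `[[`, "", "severity"),
    code     = vapply(diags, `[[`, "", "code"),
    node_id  = vapply(diags, `[[`, "", "node_id"),
    message  = vapply(diags, `[[`, "", "message"),
    stringsAsFactors = FALSE
  )
}

# Pipeline structure rules: NYS001 (operator placement), NYS002 (redirect
# position); gstrings inside command nodes are checked by the caller's
# closure so scope state is shared.
check_pipeline <- function(exec, stmt_id, check_gstring, emit) {
  nodes <- exec$nodes
  n <- length(nodes)
  if (n == 0L) {
    emit("error", "NYS001", stmt_id, "empty pipeline")
    return(invisible())
  }
  kinds <- vapply(nodes, `[[`, "", "kind")
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    if (nd$kind == "operator") {
      if (i == 1L) {
        emit("error", "NYS001", nd$id, "pipeline begins with a binary operator")
      } else if (nodes[[i - 1L]]$kind == "operator") {
        emit("error", "NYS001", nd$id, "two consecutive binary operators")
      }
      if (i == n) {
        emit("error", "NYS001", nd$id, "pipeline ends with a binary operator")
      }
    }
    if (nd$kind == "redirect" && i < n) {
      emit("error", "NYS002", nd$id, "redirect must be the final node")
    }
    if (nd$kind == "redirect" && i > 1L && nodes[[i - 1L]]$kind == "operator") {
      emit("error", "NYS001", nd$id, "redirect follows a binary operator")
    }
  }
  if (sum(kinds == "redirect") > 1L) {
    first_extra <- nodes[[which(kinds == "redirect")[2L]]]
    emit("error", "NYS002", first_extra$id, "more than one redirect")
  }
  # two adjacent command nodes (missing operator) are also malformed
  for (i in seq_len(n - 1L)) {
    if (is_commandish(nodes[[i]]) && is_commandish(nodes[[i + 1L]])) {
      emit("error", "NYS001", nodes[[i + 1L]]$id,
           "two commands with no separating operator")
    }
  }
  for (nd in nodes) {
    if (nd$kind == "command") check_gstring(nd$line, nd$id)
    if (nd$kind == "redirect") check_gstring(nd$target, nd$id)
  }
  invisible()
}

#' Render diagnostics for command-line output
#'
#' Formats each finding as `FILE:nodeId: CODE message`.
#'
#' @param diags diagnostics data frame from [check_script()].
#' @param file label for the model file (used as the line prefix).
#' @return character vector, one line per diagnostic.
#' @export
format_diagnostics <- function(diags, file = "<model>") {
  if (nrow(diags) == 0L) return(character(0))
  sprintf("%s:%s: %s %s", file, diags$node_id, diags$code, diags$message)
}
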