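#' Command pipelines
#'
#' An `execute_command` holds the ordered node list of one pipeline: command
#' nodes strictly alternating with binary operator nodes, optionally ending
#' in a single redirect-to-file node. Operator kinds map one-to-one to the
#' BASH surface tokens: `pipe` (`|`), `and` (`&&`), `or` (`||`), `seq` (`;`),
#' `background` (`&`). A trailing `&` does not create an operator node; it
#' marks the final command as background.
#'
#' Plugin-domain pipelines may additionally contain `slot_command` nodes
#' (fetch/push on a named plugin slot); these are lowered to ordinary
#' commands by [reduce_model()] before execution.
#'
#' @param nodes list of nodes built with [cmd_node()], [op_node()],
#'   [redirect_node()] or [slot_command_node()].
#' @return An object of class `execute_command`.
#' @export
execute_command <- function(nodes = list()) {
  stopifnot(is.list(nodes))
  structure(list(nodes = nodes), class = "execute_command")
}

OPERATOR_KINDS <- c(pipe = "|", and = "&&", or = "||", seq = ";",
                    background = "&")

#' @rdname execute_command
#' @param line a `gstring` (or character scalar) command line.
#' @param background logical; `TRUE` when the command ends in a trailing `&`.
#' @export
cmd_node <- function(line, background = FALSE) {
  if (is.character(line)) line <- gstring(list(gs_literal(line)))
  stopifnot(is_gstring(line))
  list(id = NA_character_, kind = "command", line = line,
       background = isTRUE(background))
}

#' @rdname execute_command
#' @param op operator kind: `"pipe"`, `"and"`, `"or"`, `"seq"` or
#'   `"background"`.
#' @export
op_node <- function(op) {
  if (!op %in% names(OPERATOR_KINDS)) {
    sw_stop("bad_operator", "unknown operator kind: %s", op)
  }
  list(id = NA_character_, kind = "operator", op = op)
}

#' @rdname execute_command
#' @param target a `gstring` (or character scalar) evaluating to the file the
#'   final stdout is written to.
#' @export
redirect_node <- function(target) {
  if (is.character(target)) target <- gstring(list(gs_literal(target)))
  stopifnot(is_gstring(target))
  list(id = NA_character_, kind = "redirect", target = target)
}

#' @rdname execute_command
#' @param direction `"fetch"` (obtain input files for a slot) or `"push"`
#'   (publish output files of a slot).
#' @param slot plugin slot name.
#' @export
slot_command_node <- function(direction, slot) {
  stopifnot(direction %in% c("fetch", "push"))
  assert_identifier(slot, "slot name")
  list(id = NA_character_, kind = "slot_command", direction = direction,
       slot = slot)
}

#' @export
print.execute_command <- function(x, ...) {
  cat("<execute_command> ", render_pipeline(x), "\n", sep = "")
  invisible(x)
}

node_kinds <- function(exec) vapply(exec$nodes, `[[`, "", "kind")

# Command-like nodes (things an operator may separate).
is_commandish <- function(node) node$kind %in% c("command", "slot_command")

#' Render a pipeline back to BASH surface syntax
#'
#' @param exec an `execute_command`.
#' @return character scalar; re-parsing it with [parse_pipeline()] yields a
#'   structurally equal pipeline (modulo node ids).
#' @export
render_pipeline <- function(exec) {
  stopifnot(inherits(exec, "execute_command"))
  parts <- vapply(exec$nodes, function(nd) {
    switch(nd$kind,
      command   = paste0(render_gstring(nd$line),
                         if (isTRUE(nd$background)) " &" else ""),
      operator  = unname(OPERATOR_KINDS[[nd$op]]),
      redirect  = paste0("> ", render_gstring(nd$target)),
      slot_command = sprintf("%%%s %s", nd$direction, nd$slot)
    )
  }, character(1))
  paste(parts, collapse = " ")
}
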