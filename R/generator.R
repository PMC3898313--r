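#' Lower plugin-domain commands to core execute commands
#'
#' Model-to-model reduction: every fetch/push slot command in the model is
#' replaced by an ordinary command node whose line instantiates the
#' descriptor's SDK command-line template for that direction, with `{slot}`
#' substituted by the slot name. Fetch commands must name a declared input
#' slot, push commands a declared output slot. A model with no slot
#' commands passes through structurally unchanged, and reduction is
#' idempotent.
#'
#' @param model a `script_model`.
#' @param descriptor a `plugin_descriptor`; required if (and only if) the
#'   model contains slot commands.
#' @return The reduced `script_model`, containing no slot commands.
#' @export
reduce_model <- function(model, descriptor = NULL) {
  stopifnot(inherits(model, "script_model"))
  reduce_node <- function(nd) {
    if (nd$kind != "slot_command") return(nd)
    if (is.null(descriptor)) {
      sw_stop("must_reduce",
              "model contains %s commands but no descriptor was given",
              nd$direction)
    }
    tmpl <- descriptor$sdk_templates[[nd$direction]]
    if (is.null(tmpl)) {
      sw_stop("missing_template", "descriptor %s has no %s SDK template",
              descriptor$plugin_id, nd$direction)
    }
    declared <- if (nd$direction == "fetch") descriptor$input_slots$name
                else descriptor$output_slots$name
    if (!nd$slot %in% declared) {
      sw_stop("unknown_slot", "%s names slot %s, which descriptor %s does not declare",
              nd$direction, nd$slot, descriptor$plugin_id)
    }
    line <- gsub("{slot}", nd$slot, tmpl, fixed = TRUE)
    new <- cmd_node(gstring(list(gs_literal(line))))
    new$id <- nd$id              # reduction preserves node identity
    new
  }
  reduce_stmts <- function(stmts) {
    lapply(stmts, function(st) {
      if (st$kind != "execute") return(st)
      st$pipeline$nodes <- lapply(st$pipeline$nodes, reduce_node)
      st
    })
  }
  model$statements <- reduce_stmts(model$statements)
  model$entry_points <- lapply(model$entry_points, reduce_stmts)
  model
}

model_has_slot_commands <- function(model) {
  any_in <- function(stmts) any(vapply(stmts, function(st) {
    st$kind == "execute" && "slot_command" %in% node_kinds(st$pipeline)
  }, logical(1)))
  any_in(model$statements) ||
    any(vapply(model$entry_points, any_in, logical(1)))
}

#' Render a script model to a standalone runnable artifact
#'
#' Renders a reduced, check-clean model as a self-contained POSIX shell
#' program plus a thin launcher that invokes it by relative path. Executing
#' the rendered pair reproduces [run_script()]'s observable behavior
#' (stdout and exit code). Rendering is byte-deterministic: the same model
#' always produces byte-identical artifacts (stable node ordering, no
#' timestamps).
#'
#' Layout: `<out_dir>/<script-name>/program.sh` and
#' `<out_dir>/<script-name>/launcher` (executable). The launcher runs the
#' main statement list; `launcher <entry-point>` runs a named entry point.
#' Environment-source loads are rendered as export lines snapshotting the
#' source's variables at render time, keeping the artifact self-contained.
#'
#' @param model a reduced, check-clean `script_model`.
#' @param out_dir output directory (created if needed).
#' @param contract entry-point contract used for checking.
#' @return Invisibly, a list with `program` and `launcher` paths.
#' @export
render_program <- function(model, out_dir, contract = entry_point_contract()) {
  stopifnot(inherits(model, "script_model"))
  if (model_has_slot_commands(model)) {
    sw_stop("must_reduce",
            "model contains unreduced plugin commands; run reduce_model() first")
  }
  diags <- check_script(model, contract = contract)
  if (any(diags$severity == "error")) {
    sw_stop("check_failed", "model has checker errors; first: %s",
            format_diagnostics(diags[diags$severity == "error", ])[1])
  }
  dir <- file.path(out_dir, model$name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) sw_stop("io_error", "cannot create %s", dir)

  program <- file.path(dir, "program.sh")
  launcher <- file.path(dir, "launcher")
  writeLines(render_sh(model), program, useBytes = TRUE)
  writeLines(c(
    "#!/bin/sh",
    "dir=$(CDPATH='' cd -- \"$(dirname -- \"$0\")\" && pwd)",
    "exec /bin/sh \"$dir/program.sh\" \"$@\""
  ), launcher, useBytes = TRUE)
  Sys.chmod(launcher, "0755")
  Sys.chmod(program, "0755")
  invisible(list(program = program, launcher = launcher))
}

# ---- sh rendering -----------------------------------------------------------

# Escape literal text for the inside of a double-quoted sh string.
sh_dq_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("`", "\\`", x, fixed = TRUE)
  gsub("$", "\\$", x, fixed = TRUE)
}

# Inner text of a double-quoted sh string for a gstring: escaped literals,
# references as ${name}.
sh_inner_gstring <- function(g) {
  inner <- vapply(g$components, function(co) {
    switch(co$kind,
      literal = sh_dq_escape(co$text),
      varref  = paste0("${", co$name, "}"),
      envread = paste0("${", co$name, "}")
    )
  }, character(1))
  paste(inner, collapse = "")
}

# Render a gstring as one double-quoted sh word (declaration initializers,
# assignment names/values, redirect targets).
sh_quoted_gstring <- function(g) {
  paste0('"', sh_inner_gstring(g), '"')
}

# Render a command-line gstring. Literal text passes through verbatim (it
# carries its own quoting); interpolations are emitted quoted ("${x}") when
# they fall outside double quotes, bare (${x}) inside them, so the value is
# never field-split — matching the executor's no-resplit rule.
sh_command_gstring <- function(g) {
  out <- character(0)
  in_double <- FALSE
  in_single <- FALSE
  for (co in g$components) {
    if (co$kind == "literal") {
      chars <- strsplit(co$text, "", fixed = TRUE)[[1]]
      for (ch in chars) {
        if (ch == "'" && !in_double) in_single <- !in_single
        if (ch == '"' && !in_single) in_double <- !in_double
      }
      out <- c(out, co$text)
    } else {
      ref <- paste0("${", co$name, "}")
      out <- c(out, if (in_double) ref else paste0('"', ref, '"'))
    }
  }
  paste(out, collapse = "")
}

render_stmt_sh <- function(st) {
  switch(st$kind,
    var_decl = paste0(st$name, "=", sh_quoted_gstring(st$initializer)),
    env_assign = paste0('export "', sh_inner_gstring(st$var_name), "=",
                        sh_inner_gstring(st$value), '"'),
    load_env = NA_character_,      # handled by the caller (needs sources)
    execute = {
      parts <- vapply(st$pipeline$nodes, function(nd) {
        switch(nd$kind,
          command  = paste0(sh_command_gstring(nd$line),
                            if (isTRUE(nd$background)) " &" else ""),
          operator = unname(OPERATOR_KINDS[[nd$op]]),
          redirect = paste0("> ", sh_quoted_gstring(nd$target))
        )
      }, character(1))
      paste(parts, collapse = " ")
    }
  )
}

render_block_sh <- function(stmts, sources, indent = "") {
  src_by_id <- sources
  names(src_by_id) <- vapply(sources, `[[`, "", "id")
  lines <- character(0)
  for (st in stmts) {
    if (st$kind == "load_env") {
      for (ref in st$source_refs) {
        s <- src_by_id[[ref]]
        for (nm in sort_c(addressable_names(s))) {
          lines <- c(lines, paste0(indent, "export ", nm, "=\"",
                                   sh_dq_escape(unname(s$variables[[nm]])),
                                   "\""))
        }
      }
    } else {
      lines <- c(lines, paste0(indent, render_stmt_sh(st)))
    }
  }
  if (length(lines) == 0L) lines <- paste0(indent, ":")
  lines
}

render_sh <- function(model) {
  lines <- c("#!/bin/sh",
             paste0("# ", model$name, " (rendered script model, format v",
                    model$format_version, ")"))
  eps <- names(model$entry_points)
  for (ep in eps) {
    lines <- c(lines,
               paste0("ep_", ep, "() {"),
               render_block_sh(model$entry_points[[ep]], model$sources,
                               indent = "  "),
               "}")
  }
  if (length(eps) > 0L) {
    lines <- c(lines,
               "if [ $# -ge 1 ]; then",
               "  entry=\"$1\"; shift",
               "  case \"$entry\" in",
               vapply(eps, function(ep)
                 paste0("    ", ep, ") ep_", ep, " \"$@\" ;;"), character(1)),
               "    *) echo \"unknown entry point: $entry\" >&2; exit 1 ;;",
               "  esac",
               "  exit $?",
               "fi")
  }
  c(lines, render_block_sh(model$statements, model$sources))
}

# ---- phrase templates -------------------------------------------------------

#' Phrase templates: structured slots inside mostly unstructured text
#'
#' Captures a block of text line-by-line, parses only selected lines at a
#' single-character delimiter, and turns designated segments of those lines
#' into named slots. Rendering substitutes slot bindings and rejoins
#' segments with the original delimiter — the mechanism used to generate
#' configuration files whose bulk is fixed text with a few varying fields.
#' A template with no phrase lines renders back to its input verbatim.
#'
#' @param text the template text (lines separated by `\n`).
#' @param delimiter single character used to split phrase lines.
#' @param slots data frame with columns `line` (1-based line number),
#'   `segment` (1-based segment index within that line) and `name` (slot
#'   name, unique per template). Lines not mentioned stay raw text.
#' @return A `phrase_template`.
#' @export
#' @examples
#' t <- build_template("k,v", ",", data.frame(line = 1, segment = 2,
#'                                            name = "value"))
#' render_template(t, c(value = "42"))   # "k,42"
build_template <- function(text, delimiter,
                           slots = data.frame(line = integer(0),
                                              segment = integer(0),
                                              name = character(0))) {
  stopifnot(is.character(text), length(text) == 1L,
            is.character(delimiter), nchar(delimiter) == 1L)
  if (anyDuplicated(slots$name)) {
    sw_stop("duplicate_slot", "duplicate slot name %s",
            slots$name[duplicated(slots$name)][1])
  }
  text_lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text_lines) == 0L) text_lines <- ""
  bad <- setdiff(unique(slots$line), seq_along(text_lines))
  if (length(bad) > 0L) {
    sw_stop("bad_line", "phrase line %d is outside the template (%d line(s))",
            bad[1], length(text_lines))
  }
  parsed <- lapply(seq_along(text_lines), function(i) {
    here <- slots[slots$line == i, , drop = FALSE]
    if (nrow(here) == 0L) {
      return(list(kind = "raw", text = text_lines[[i]]))
    }
    segs <- strsplit(text_lines[[i]], delimiter, fixed = TRUE)[[1]]
    if (length(segs) == 0L) segs <- ""
    if (any(here$segment > length(segs))) {
      sw_stop("bad_segment",
              "line %d has %d segment(s); slot asks for segment %d",
              i, length(segs), max(here$segment))
    }
    segments <- lapply(seq_along(segs), function(j) {
      hit <- here$name[here$segment == j]
      if (length(hit) == 1L) list(kind = "slot", name = hit)
      else list(kind = "fixed", text = segs[[j]])
    })
    list(kind = "phrase", segments = segments)
  })
  structure(list(lines = parsed, delimiter = delimiter,
                 slot_names = as.character(slots$name)),
            class = "phrase_template")
}

#' @rdname build_template
#' @param template a `phrase_template`.
#' @param bindings named character vector supplying a value for every slot.
#' @return `render_template()`: character scalar.
#' @export
render_template <- function(template, bindings = character()) {
  stopifnot(inherits(template, "phrase_template"))
  lines <- vapply(template$lines, function(ln) {
    if (ln$kind == "raw") return(ln$text)
    segs <- vapply(ln$segments, function(sg) {
      if (sg$kind == "fixed") return(sg$text)
      if (!sg$name %in% names(bindings)) {
        sw_stop("unbound_slot", "no binding for slot %s", sg$name)
      }
      as.character(bindings[[sg$name]])
    }, character(1))
    paste(segs, collapse = template$delimiter)
  }, character(1))
  paste(lines, collapse = "\n")
}
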