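#' Micro-parse a raw BASH pipeline into a typed command tree
#'
#' Converts one raw shell command line into a well-formed [execute_command]:
#' operators are tokenized with maximal munch (`||` before `|`, `&&` before
#' `&`) outside single and double quotes, each command segment becomes a
#' command node whose text is parsed for `${name}` markers, and a trailing
#' `> target` becomes a redirect node. A final `&` marks the last command as
#' background rather than adding an operator.
#'
#' Quote handling mirrors BASH: single quotes suppress both operators and
#' `${}` interpolation; double quotes suppress operators but keep `${}`
#' live. Only the overwrite redirect `>` is modeled; `>>`, `2>` and `<` are
#' rejected as unsupported rather than mis-parsed.
#'
#' Parsing is atomic: on any error (consecutive operators, leading or
#' trailing operator, empty command segment, unbalanced quote) a parse error
#' carrying the byte offset is signalled and nothing is produced, so the raw
#' text a caller holds is never half-consumed.
#'
#' @param text raw pipeline text (non-empty).
#' @param scope character vector of in-scope program variable names.
#' @param env_names character vector of known environment variable names.
#' @return An [execute_command]; node ids are assigned when the pipeline is
#'   attached to a model with [add_execute()].
#' @export
#' @examples
#' p <- parse_pipeline("sort reads.sam | head > top.sam")
#' render_pipeline(p)
parse_pipeline <- function(text, scope = character(), env_names = character()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(trimws(text))) sw_stop("parse_error", "empty pipeline text")
  toks <- tokenize_pipeline(text)

  nodes <- list()
  i <- 1L
  n <- length(toks)
  last_was_cmd <- FALSE
  while (i <= n) {
    tk <- toks[[i]]
    if (tk$type == "seg") {
      if (!nzchar(trimws(tk$text))) {
        # empty segments surface as operator-placement errors below
        i <- i + 1L
        next
      }
      nodes[[length(nodes) + 1L]] <-
        cmd_node(parse_command_gstring(trimws(tk$text), scope, env_names))
      last_was_cmd <- TRUE
      i <- i + 1L
      next
    }
    if (tk$type == "op") {
      if (!last_was_cmd) {
        prev_op <- i > 1L && any(vapply(toks[seq_len(i - 1L)], function(t)
          t$type %in% c("op", "redir"), logical(1)))
        sw_stop("parse_error", "%s at offset %d",
                if (prev_op) "consecutive operators" else "leading operator",
                tk$pos)
      }
      rest <- if (i < n) toks[(i + 1L):n] else list()
      rest_text <- paste(vapply(rest, function(t)
        if (t$type == "seg") t$text else "X", character(1)), collapse = "")
      if (!nzchar(trimws(rest_text))) {
        if (tk$op == "background") {
          nodes[[length(nodes)]]$background <- TRUE
          i <- i + 1L
          last_was_cmd <- TRUE
          next
        }
        sw_stop("parse_error", "trailing operator at offset %d", tk$pos)
      }
      nodes[[length(nodes) + 1L]] <- op_node(tk$op)
      last_was_cmd <- FALSE
      i <- i + 1L
      next
    }
    if (tk$type == "redir") {
      if (!last_was_cmd) {
        sw_stop("parse_error", "redirect with no preceding command at offset %d",
                tk$pos)
      }
      target <- ""
      j <- i + 1L
      while (j <= n && toks[[j]]$type == "seg") {
        target <- paste0(target, toks[[j]]$text)
        j <- j + 1L
      }
      if (j <= n) {
        sw_stop("parse_error", "operator after redirect at offset %d",
                toks[[j]]$pos)
      }
      target <- trimws(target)
      if (!nzchar(target)) {
        sw_stop("parse_error", "missing redirect target at offset %d", tk$pos)
      }
      nodes[[length(nodes) + 1L]] <-
        redirect_node(parse_command_gstring(target, scope, env_names))
      i <- n + 1L
      next
    }
  }
  if (length(nodes) == 0L) sw_stop("parse_error", "empty pipeline text")
  execute_command(nodes)
}

# Tokenize one pipeline into segment / operator / redirect tokens, tracking
# 0-based byte offsets. Quotes suppress operator recognition; backslash
# escapes the next character outside quotes.
tokenize_pipeline <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  seg_start <- 1L
  push_seg <- function(upto) {
    toks[[length(toks) + 1L]] <<- list(
      type = "seg",
      text = if (upto >= seg_start)
        paste(chars[seg_start:upto], collapse = "") else "",
      pos = seg_start - 1L)
  }
  push_op <- function(op, at, width) {
    toks[[length(toks) + 1L]] <<- list(type = "op", op = op, pos = at - 1L)
    seg_start <<- at + width
  }
  quote <- NA_character_
  quote_pos <- NA_integer_
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (!is.na(quote)) {
      if (ch == quote) quote <- NA_character_
      i <- i + 1L
      next
    }
    if (ch == "\\") { i <- i + 2L; next }
    if (ch == "'" || ch == '"') {
      quote <- ch
      quote_pos <- i - 1L
      i <- i + 1L
      next
    }
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two == "||" || two == "&&") {
      push_seg(i - 1L)
      push_op(if (two == "||") "or" else "and", i, 2L)
      i <- i + 2L
      next
    }
    if (ch == "|" || ch == "&" || ch == ";") {
      push_seg(i - 1L)
      push_op(switch(ch, "|" = "pipe", "&" = "background", ";" = "seq"), i, 1L)
      i <- i + 1L
      next
    }
    if (ch == "<") {
      sw_stop("parse_error", "unsupported redirect '<' at offset %d", i - 1L)
    }
    if (ch == ">") {
      if (i < n && chars[i + 1L] == ">") {
        sw_stop("parse_error", "unsupported redirect '>>' at offset %d", i - 1L)
      }
      # "2> err" style descriptor redirects: digit glued to '>' at word start
      if (i > 1L && grepl("[0-9]", chars[i - 1L]) &&
          (i == 2L || grepl("[ \t]", chars[i - 2L]))) {
        sw_stop("parse_error",
                "unsupported descriptor redirect at offset %d", i - 2L)
      }
      push_seg(i - 1L)
      toks[[length(toks) + 1L]] <- list(type = "redir", pos = i - 1L)
      seg_start <- i + 1L
      i <- i + 1L
      next
    }
    i <- i + 1L
  }
  if (!is.na(quote)) {
    sw_stop("parse_error", "unbalanced quote opened at offset %d", quote_pos)
  }
  push_seg(n)
  toks
}

# gstring parse with shell-quote awareness: ${ } markers are inert inside
# single quotes, live inside double quotes and bare text. Quote characters
# stay in the literal text; word splitting strips them at execution time.
parse_command_gstring <- function(text, scope = character(),
                                  env_names = character()) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  comps <- list()
  lit <- character(0)
  flush_lit <- function() {
    if (length(lit) > 0L) {
      comps[[length(comps) + 1L]] <<- gs_literal(paste(lit, collapse = ""))
      lit <<- character(0)
    }
  }
  in_single <- FALSE
  in_double <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (in_single) {
      if (ch == "'") in_single <- FALSE
      lit <- c(lit, ch)
      i <- i + 1L
      next
    }
    if (ch == "'" && !in_double) {
      in_single <- TRUE
      lit <- c(lit, ch)
      i <- i + 1L
      next
    }
    if (ch == '"') {
      in_double <- !in_double
      lit <- c(lit, ch)
      i <- i + 1L
      next
    }
    if (ch == "\\" && i + 1L <= n && chars[i + 1L] == "$" &&
        i + 2L <= n && chars[i + 2L] == "{") {
      lit <- c(lit, "${")
      i <- i + 3L
      next
    }
    if (ch == "$" && i + 1L <= n && chars[i + 1L] == "{") {
      close <- i + 2L
      while (close <= n && chars[close] != "}") close <- close + 1L
      if (close > n) {
        sw_stop("parse_error", "unterminated ${ marker at offset %d", i - 1L)
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
        else gs_varref(name)
      i <- close + 1L
      next
    }
    lit <- c(lit, ch)
    i <- i + 1L
  }
  flush_lit()
  normalize_gstring(gstring(comps))
}

#' Extract `${name}` markers of a pasted statement into program variables
#'
#' The second micro-parsing intention: given a statement whose gstrings are
#' still raw pasted text (literal-only), re-parse each literal for `${name}`
#' markers, turn the markers into variable references, and insert a
#' declaration immediately before the statement for every distinct name that
#' has no preceding declaration in scope — one declaration per name, in
#' first-occurrence order. Names already declared are referenced, not
#' redeclared. On a parse error the model is returned unchanged (the error
#' propagates; no partial mutation is possible).
#'
#' @param model a `script_model`.
#' @param stmt_id id of the statement to convert.
#' @param entry entry-point name the statement lives in, or `NULL` for the
#'   main list.
#' @return A list with elements `model` (the updated model), `new_names`
#'   (character vector of newly declared variables) and `gstrings` (the
#'   converted gstrings, in statement-field order).
#' @export
extract_variables <- function(model, stmt_id, entry = NULL) {
  stopifnot(inherits(model, "script_model"))
  stmts <- stmt_list_of(model, entry)
  k <- which(vapply(stmts, `[[`, "", "id") == stmt_id)
  if (length(k) != 1L) {
    sw_stop("no_such_node", "no statement with id %s in this scope", stmt_id)
  }
  stmt <- stmts[[k]]
  scope_before <- decl_names(stmts[seq_len(k - 1L)])
  env_names <- model_env_names(model)

  decl_ids <- character(0)
  for (s in stmts[seq_len(k - 1L)]) {
    if (s$kind == "var_decl") decl_ids[[s$name]] <- s$id
  }

  new_names <- character(0)
  convert <- function(g, quote_aware = FALSE) {
    if (!gs_is_literal_only(g)) return(g)   # already structured; leave alone
    raw <- paste(vapply(g$components, `[[`, "", "text"), collapse = "")
    parser <- if (quote_aware) parse_command_gstring else parse_gstring
    parsed <- parser(raw, scope = c(scope_before, new_names),
                     env_names = env_names)
    for (co in parsed$components) {
      if (co$kind == "varref" &&
          !co$name %in% c(scope_before, new_names)) {
        new_names <<- c(new_names, co$name)
      }
    }
    parsed
  }

  gstrings <- list()
  keep <- function(g) { gstrings[[length(gstrings) + 1L]] <<- g; g }
  stmt <- switch(stmt$kind,
    var_decl = { stmt$initializer <- keep(convert(stmt$initializer)); stmt },
    execute = {
      for (j in seq_along(stmt$pipeline$nodes)) {
        nd <- stmt$pipeline$nodes[[j]]
        if (nd$kind == "command") {
          stmt$pipeline$nodes[[j]]$line <- keep(convert(nd$line, TRUE))
        } else if (nd$kind == "redirect") {
          stmt$pipeline$nodes[[j]]$target <- keep(convert(nd$target, TRUE))
        }
      }
      stmt
    },
    env_assign = {
      stmt$var_name <- keep(convert(stmt$var_name))
      stmt$value <- keep(convert(stmt$value))
      stmt
    },
    stmt
  )

  decls <- list()
  for (nm in new_names) {
    d <- stmt_var_decl(nm, gstring(list()))   # declared, initially empty
    r <- assign_ids(model, d)
    model <- r$model
    decls[[length(decls) + 1L]] <- r$stmt
    decl_ids[[nm]] <- r$stmt$id
  }

  # link every reference to its declaration node
  link <- function(g) {
    g$components <- lapply(g$components, function(co) {
      if (co$kind == "varref" && co$name %in% names(decl_ids)) {
        co$declaration_id <- unname(decl_ids[[co$name]])
      }
      co
    })
    g
  }
  stmt <- switch(stmt$kind,
    var_decl = { stmt$initializer <- link(stmt$initializer); stmt },
    execute = {
      for (j in seq_along(stmt$pipeline$nodes)) {
        nd <- stmt$pipeline$nodes[[j]]
        if (nd$kind == "command") stmt$pipeline$nodes[[j]]$line <- link(nd$line)
        if (nd$kind == "redirect") stmt$pipeline$nodes[[j]]$target <- link(nd$target)
      }
      stmt
    },
    env_assign = {
      stmt$var_name <- link(stmt$var_name)
      stmt$value <- link(stmt$value)
      stmt
    },
    stmt
  )

  updated <- append(stmts[seq_len(k - 1L)], decls)
  updated <- append(updated, list(stmt))
  if (k < length(stmts)) updated <- append(updated, stmts[(k + 1L):length(stmts)])
  if (is.null(entry)) model$statements <- updated
  else model$entry_points[[entry]] <- updated

  list(model = model, new_names = new_names, gstrings = gstrings)
}
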