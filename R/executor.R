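#' Run a command pipeline with BASH-equivalent operator semantics
#'
#' Executes an [execute_command]: `|` connects stdout to stdin along a chain
#' of commands, `&&` runs its right side only when the left side exited 0,
#' `||` only when it exited non-zero, `;` runs unconditionally, and a
#' background `&` launches its command and contributes exit status 0 to the
#' control flow. The pipeline exit code is the exit code of the last
#' executed command (no pipefail unless requested); a trailing redirect
#' writes the final pipe chain's stdout to its target file, overwriting.
#'
#' Every command line is logged after gstring evaluation, and one
#' `CommandRecord` is kept per launched command, in launch order: evaluated
#' text, exit code, captured stderr. A command that cannot be found yields
#' the conventional exit code 127. An evaluation error (unbound variable)
#' aborts before anything is launched.
#'
#' Word splitting happens after gstring evaluation on unquoted whitespace of
#' the literal text; values substituted for variable or environment
#' references are never re-split (a deliberate, safer deviation from BASH).
#'
#' @param exec an [execute_command] with no checker errors.
#' @param bindings named character vector of program-variable values.
#' @param sources list of loaded `env_source` objects used to resolve
#'   environment reads (later sources win).
#' @param workdir working directory for the commands.
#' @param env_overrides named character vector of environment variables to
#'   set for the launched commands.
#' @param pipefail if `TRUE`, a pipe chain's exit code is the last non-zero
#'   stage exit code (off by default, as in BASH).
#' @return An `execution_result`: list with `exit_code`, `records` (one per
#'   launched command: `evaluated_text`, `exit_code`, `stderr`,
#'   `background`), `stdout`, and `log_lines`.
#' @export
#' @examples
#' r <- run_pipeline(parse_pipeline("printf 'b\\na\\n' | sort"))
#' r$stdout      # "a\nb\n"
#' r$exit_code   # 0
run_pipeline <- function(exec, bindings = character(), sources = list(),
                         workdir = getwd(), env_overrides = character(),
                         pipefail = FALSE) {
  stopifnot(inherits(exec, "execute_command"))
  bad <- node_kinds(exec)
  if ("slot_command" %in% bad) {
    sw_stop("must_reduce", "pipeline contains unreduced plugin commands")
  }
  env_fun <- make_env_resolver(sources, env_overrides)

  # Split nodes into pipe chains ("groups") separated by control operators.
  groups <- split_pipe_groups(exec)

  # Evaluate every command line up-front: an unbound variable aborts before
  # anything is launched.
  for (g in groups) {
    for (nd in g$commands) {
      split_words(nd$line, bindings, env_fun)
    }
    if (!is.null(g$redirect)) {
      evaluate_gstring(g$redirect$target, bindings, env_fun)
    }
  }

  records <- list()
  log_lines <- character(0)
  out_text <- character(0)
  last_status <- 0L

  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    run_it <- switch(g$joiner,
      first = TRUE,
      and   = last_status == 0L,
      or    = last_status != 0L,
      seq   = TRUE,
      background = TRUE
    )
    if (!run_it) next
    res <- run_pipe_group(g, bindings, env_fun, workdir, env_overrides,
                          pipefail)
    records <- c(records, res$records)
    log_lines <- c(log_lines, res$log_lines)
    if (!res$redirected) out_text <- c(out_text, res$stdout)
    last_status <- if (g$background) 0L else res$exit_code
  }

  structure(list(
    exit_code = last_status,
    records = records,
    stdout = paste(out_text, collapse = ""),
    log_lines = log_lines
  ), class = "execution_result")
}

#' @export
print.execution_result <- function(x, ...) {
  cat(sprintf("<execution_result> exit=%d, %d command(s) launched\n",
              x$exit_code, length(x$records)))
  invisible(x)
}

make_env_resolver <- function(sources, env_overrides = character()) {
  function(name) {
    if (name %in% names(env_overrides)) return(env_overrides[[name]])
    resolve_variable(name, sources)
  }
}

# Partition pipeline nodes into pipe chains. Each group: commands (pipe
# stages), joiner operator linking it to the previous group, optional
# redirect (only meaningful on the final group), background flag.
split_pipe_groups <- function(exec) {
  groups <- list()
  cur <- list()
  joiner <- "first"
  redirect <- NULL
  background <- FALSE
  flush <- function() {
    if (length(cur) > 0L) {
      groups[[length(groups) + 1L]] <<- list(commands = cur, joiner = joiner,
                                             redirect = NULL,
                                             background = background)
      cur <<- list()
      background <<- FALSE
    }
  }
  for (nd in exec$nodes) {
    if (nd$kind == "command") {
      cur[[length(cur) + 1L]] <- nd
      if (isTRUE(nd$background)) background <- TRUE
    } else if (nd$kind == "operator") {
      if (nd$op == "pipe") next                 # same group continues
      if (nd$op == "background") background <- TRUE
      flush()
      joiner <- if (nd$op == "background") "background" else nd$op
    } else if (nd$kind == "redirect") {
      redirect <- nd
    }
  }
  flush()
  if (!is.null(redirect) && length(groups) > 0L) {
    groups[[length(groups)]]$redirect <- redirect
  }
  groups
}

# Execute one pipe chain: stages plumbed stdout -> stdin through buffered
# temporary files, in stage order.
run_pipe_group <- function(g, bindings, env_fun, workdir, env_overrides,
                           pipefail) {
  records <- list()
  log_lines <- character(0)
  stdin_file <- ""
  statuses <- integer(0)
  out_file <- NULL
  for (ci in seq_along(g$commands)) {
    nd <- g$commands[[ci]]
    words <- split_words(nd$line, bindings, env_fun)
    evaluated <- paste(words, collapse = " ")
    log_lines <- c(log_lines, paste0("+ ", evaluated))
    out_file <- tempfile("sw-out-")
    err_file <- tempfile("sw-err-")
    status <- launch_command(words, stdin_file, out_file, err_file, workdir,
                             env_overrides)
    statuses <- c(statuses, status)
    records[[length(records) + 1L]] <- list(
      evaluated_text = evaluated,
      exit_code = status,
      stderr = read_text(err_file),
      background = isTRUE(g$background) && ci == length(g$commands)
    )
    unlink(err_file)
    if (nzchar(stdin_file)) unlink(stdin_file)
    stdin_file <- out_file
  }
  exit_code <- if (pipefail && any(statuses != 0L)) {
    statuses[max(which(statuses != 0L))]
  } else {
    statuses[length(statuses)]
  }
  stdout_text <- read_text(out_file)
  redirected <- FALSE
  if (!is.null(g$redirect)) {
    target <- evaluate_gstring(g$redirect$target, bindings, env_fun)
    if (!nzchar(target)) {
      sw_stop("eval_error", "redirect target evaluated to an empty path")
    }
    if (!grepl("^/", target)) target <- file.path(workdir, target)
    if (!file.copy(out_file, target, overwrite = TRUE)) {
      sw_stop("io_error", "cannot write redirect target: %s", target)
    }
    redirected <- TRUE
  }
  unlink(out_file)
  list(records = records, log_lines = log_lines, stdout = stdout_text,
       exit_code = exit_code, redirected = redirected)
}

read_text <- function(path) {
  if (is.null(path) || !file.exists(path)) return("")
  readChar(path, file.size(path), useBytes = TRUE)
}

launch_command <- function(words, stdin_file, out_file, err_file, workdir,
                           env_overrides) {
  if (length(words) == 0L || !nzchar(words[[1]])) {
    writeLines("empty command", err_file)
    return(127L)
  }
  env_arg <- if (length(env_overrides) > 0L) {
    paste0(names(env_overrides), "=", shQuote(as.character(env_overrides)))
  } else {
    character(0)
  }
  owd <- setwd(workdir)
  on.exit(setwd(owd), add = TRUE)
  args <- if (length(words) > 1L) shQuote(words[-1]) else character(0)
  status <- suppressWarnings(system2(
    words[[1]], args = args,
    stdout = out_file, stderr = err_file,
    stdin = if (nzchar(stdin_file)) stdin_file else "",
    env = env_arg
  ))
  if (is.na(status)) 127L else as.integer(status)
}

# Word splitting with shell quote rules over gstring components: unquoted
# whitespace in literal text separates words, quotes group and are stripped,
# backslash escapes the next literal character; substituted values join the
# current word verbatim and are never re-split.
split_words <- function(g, bindings, env_fun) {
  words <- character(0)
  cur <- character(0)       # chunks of the word being assembled
  has_cur <- FALSE
  push_word <- function() {
    if (has_cur) {
      words[[length(words) + 1L]] <<- paste(cur, collapse = "")
      cur <<- character(0)
      has_cur <<- FALSE
    }
  }
  add <- function(txt) { cur <<- c(cur, txt); has_cur <<- TRUE }
  in_single <- FALSE
  in_double <- FALSE
  for (co in g$components) {
    if (co$kind != "literal") {
      val <- switch(co$kind,
        varref = {
          if (!co$name %in% names(bindings)) {
            sw_stop("eval_error", "unbound variable %s", co$name)
          }
          as.character(bindings[[co$name]])
        },
        envread = as.character(env_fun(co$name))
      )
      add(val)
      next
    }
    chars <- strsplit(co$text, "", fixed = TRUE)[[1]]
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (in_single) {
        if (ch == "'") in_single <- FALSE else add(ch)
        i <- i + 1L
        next
      }
      if (in_double) {
        if (ch == '"') {
          in_double <- FALSE
        } else if (ch == "\\" && i < n && chars[i + 1L] %in% c('"', "\\", "$")) {
          add(chars[i + 1L])
          i <- i + 1L
        } else {
          add(ch)
        }
        i <- i + 1L
        next
      }
      if (ch == "'") { in_single <- TRUE; has_cur <- TRUE }
      else if (ch == '"') { in_double <- TRUE; has_cur <- TRUE }
      else if (ch == "\\" && i < n) { add(chars[i + 1L]); i <- i + 1L }
      else if (ch %in% c(" ", "\t")) push_word()
      else add(ch)
      i <- i + 1L
    }
  }
  if (in_single || in_double) {
    sw_stop("eval_error", "unbalanced quote in command line")
  }
  push_word()
  words
}

#' Run a whole script model
#'
#' Executes the statements of a script (or of one named entry point) in
#' order: variable declarations evaluate their initializer into the binding
#' environment, `load_env` statements make their sources resolvable for the
#' following statements, `env_assign` statements set environment variables
#' for later commands, and execute statements run their pipeline with
#' [run_pipeline()]. The aggregate exit code is the last statement's (0 when
#' nothing ran).
#'
#' The model must have zero error-severity diagnostics; the executor checks
#' first and refuses otherwise (checker soundness on the executable subset).
#'
#' @param model a `script_model`.
#' @param entry_point entry-point name, or `NULL` to run the main statement
#'   list (plain scripts).
#' @param sources optional list of already-loaded `env_source` objects to
#'   use in place of the model's attached sources (e.g. after an external
#'   reload); defaults to the model's own.
#' @param workdir working directory for commands.
#' @param contract entry-point contract used for checking plugin scripts.
#' @return An `execution_result` aggregating all launched commands.
#' @export
run_script <- function(model, entry_point = NULL, sources = NULL,
                       workdir = getwd(),
                       contract = entry_point_contract()) {
  stopifnot(inherits(model, "script_model"))
  if (!is.null(entry_point) && !entry_point %in% names(model$entry_points)) {
    sw_stop("no_entry_point", "unknown entry point: %s", entry_point)
  }
  diags <- check_script(model, contract = contract)
  if (any(diags$severity == "error")) {
    sw_stop("check_failed", "model has %d checker error(s); first: %s",
            sum(diags$severity == "error"),
            format_diagnostics(diags[diags$severity == "error", ])[1])
  }
  stmts <- if (is.null(entry_point)) model$statements
           else model$entry_points[[entry_point]]

  model_sources <- sources %||% model$sources
  src_by_id <- model_sources
  names(src_by_id) <- vapply(model_sources, `[[`, "", "id")

  bindings <- character(0)
  loaded <- list()
  env_overrides <- character(0)
  records <- list()
  log_lines <- character(0)
  out_text <- character(0)
  last_status <- 0L

  for (st in stmts) {
    switch(st$kind,
      var_decl = {
        bindings[[st$name]] <- evaluate_gstring(
          st$initializer, bindings, make_env_resolver(loaded, env_overrides))
        last_status <- 0L
      },
      load_env = {
        for (ref in st$source_refs) loaded[[length(loaded) + 1L]] <- src_by_id[[ref]]
        last_status <- 0L
      },
      env_assign = {
        resolver <- make_env_resolver(loaded, env_overrides)
        nm <- evaluate_gstring(st$var_name, bindings, resolver)
        env_overrides[[nm]] <- evaluate_gstring(st$value, bindings, resolver)
        last_status <- 0L
      },
      execute = {
        r <- run_pipeline(st$pipeline, bindings = bindings, sources = loaded,
                          workdir = workdir, env_overrides = env_overrides)
        records <- c(records, r$records)
        log_lines <- c(log_lines, r$log_lines)
        out_text <- c(out_text, r$stdout)
        last_status <- r$exit_code
      }
    )
  }

  structure(list(
    exit_code = last_status,
    records = records,
    stdout = paste(out_text, collapse = ""),
    log_lines = log_lines
  ), class = "execution_result")
}
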