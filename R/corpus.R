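# Seeded fuzzing corpora. These generators draw from the session RNG (set a
# seed before calling them) and are used by the test suite and the
# acceptance script to exercise the parser, executor and persistence layer
# against independent oracles (the system shell, brute-force filtering,
# before/after hashing).

SAFE_WORDS <- c("alpha", "beta", "gamma", "delta", "omega", "zz9")

# A command over the safe alphabet. Pipe-interior positions may consume
# stdin (cat/sort/grep); group-leading positions must produce output or a
# status on their own so nothing ever reads the calling process's stdin.
random_safe_command <- function(leading) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  producers <- c("true", "false", "echo", "printf")
  consumers <- c("cat", "sort", "grep")
  kind <- if (leading) pick(producers) else pick(c(producers, consumers))
  switch(kind,
    true = "true",
    false = "false",
    echo = paste(c("echo", sample(SAFE_WORDS, sample.int(2L, 1L))),
                 collapse = " "),
    printf = sprintf("printf '%%s\\n' %s",
                     paste(sample(SAFE_WORDS, sample.int(3L, 1L)),
                           collapse = " ")),
    cat = "cat",
    sort = "sort",
    grep = paste("grep", pick(SAFE_WORDS))
  )
}

#' Random well-formed pipeline text over a safe command alphabet
#'
#' Draws a pipeline of 1-4 commands over `true`, `false`, `echo`, `printf`,
#' `cat`, `sort` and `grep`, joined by the operators `|`, `&&`, `||` and
#' `;`. Every generated line is valid BASH and valid input for
#' [parse_pipeline()], reads nothing from the ambient stdin, and terminates
#' immediately — the corpus used to compare the execution engine against
#' the system shell, command for command.
#'
#' @param max_commands maximum number of commands per pipeline.
#' @return character scalar: one pipeline.
#' @export
#' @examples
#' set.seed(1)
#' random_pipeline_text()
random_pipeline_text <- function(max_commands = 4L) {
  n <- sample.int(max_commands, 1L)
  ops <- c("|", "&&", "||", ";")
  parts <- character(0)
  leading <- TRUE
  for (i in seq_len(n)) {
    parts <- c(parts, random_safe_command(leading))
    if (i < n) {
      op <- ops[[sample.int(length(ops), 1L)]]
      parts <- c(parts, op)
      leading <- op != "|"
    }
  }
  paste(parts, collapse = " ")
}

#' Random malformed pipeline text
#'
#' Draws a pipeline with one deliberate defect — consecutive operators, a
#' leading or trailing operator, an unbalanced quote, an empty segment, or
#' an unsupported redirect form — for exercising parse-failure atomicity:
#' a failed import must leave the model untouched.
#'
#' @return character scalar: one malformed pipeline.
#' @export
random_malformed_pipeline_text <- function() {
  base <- random_pipeline_text(2L)
  defect <- sample.int(6L, 1L)
  switch(defect,
    paste(base, "&& ||", random_safe_command(TRUE)),   # consecutive operators
    paste("&&", base),                                  # leading operator
    paste(base, "&&"),                                  # trailing operator
    paste0(base, " | echo 'unterminated"),              # unbalanced quote
    paste(base, "; ;", random_safe_command(TRUE)),      # empty segment
    paste(base, ">> appended.txt")                      # unsupported redirect
  )
}

#' Random gstring
#'
#' Draws a gstring of 1-6 components mixing literals, variable references
#' over `scope` and environment reads over `env_names`. Used for the
#' lazy-evaluation and normalization property checks.
#'
#' @param scope variable names references may target.
#' @param env_names environment names reads may target.
#' @return A `gstring` (not necessarily in normal form).
#' @export
random_gstring <- function(scope = c("a", "b"), env_names = c("E1", "E2")) {
  n <- sample.int(6L, 1L)
  comps <- lapply(seq_len(n), function(i) {
    switch(sample.int(3L, 1L),
      gs_literal(paste(sample(c(SAFE_WORDS, "", " ", "x=.y"), 1L), collapse = "")),
      gs_varref(scope[[sample.int(length(scope), 1L)]]),
      gs_envread(env_names[[sample.int(length(env_names), 1L)]])
    )
  })
  gstring(comps)
}

#' Random script model
#'
#' Draws a structurally valid script model: a dotenv file source written
#' under `dir`, variable declarations, execute statements over the safe
#' command alphabet, environment loads and assignments, and (sometimes) an
#' entry point. With `executable = TRUE` the model is also check-clean and
#' runnable, for comparing [run_script()] with the rendered program.
#'
#' @param dir directory for generated environment files.
#' @param executable if `TRUE`, keep the model check-clean and runnable.
#' @return A `script_model`.
#' @export
random_script_model <- function(dir = tempdir(), executable = FALSE) {
  nm <- sprintf("fuzz_%d", sample.int(1e6L, 1L))
  model <- new_script(nm)

  with_source <- runif(1) < 0.7
  if (with_source) {
    env_file <- file.path(dir, paste0(nm, ".env"))
    writeLines(c("GREETING=hello", "TARGET=world", "# comment",
                 sprintf("COUNT=%d", sample.int(99L, 1L))), env_file)
    model <- add_source(model, load_file_source(env_file))
    model <- add_load_env(model)
  }

  n_decl <- sample.int(3L, 1L)
  decl_names_pool <- c("a", "b", "c")
  for (i in seq_len(n_decl)) {
    model <- add_declaration(model, decl_names_pool[[i]],
                             sample(SAFE_WORDS, 1L))
  }

  n_exec <- sample.int(3L, 1L)
  for (i in seq_len(n_exec)) {
    text <- random_pipeline_text()
    if (runif(1) < 0.3) {
      text <- paste0("echo ${", sample(decl_names_pool[seq_len(n_decl)], 1L),
                     "}")
    } else if (with_source && runif(1) < 0.3) {
      text <- "echo ${GREETING} ${TARGET}"
    }
    model <- add_execute(model, text)
  }

  if (runif(1) < 0.3) {
    model <- add_env_assign(model, "SW_FUZZ", sample(SAFE_WORDS, 1L))
  }

  if (!executable && runif(1) < 0.4) {
    model <- add_entry_point(model, "extra")
    model <- add_declaration(model, "z", sample(SAFE_WORDS, 1L),
                             entry = "extra")
    model <- add_execute(model, "echo ${z}", entry = "extra")
  }
  model
}

#' Evaluate a pipeline with the system shell (oracle)
#'
#' Runs `text` verbatim with `/bin/sh -c` and returns its stdout and exit
#' code — the independent reference the execution engine is compared
#' against. Never used by the engine itself.
#'
#' @param text pipeline text.
#' @param workdir working directory.
#' @return List with `stdout` and `exit_code`.
#' @export
shell_oracle <- function(text, workdir = getwd()) {
  out_file <- tempfile("sw-oracle-")
  on.exit(unlink(out_file), add = TRUE)
  owd <- setwd(workdir)
  on.exit(setwd(owd), add = TRUE)
  status <- suppressWarnings(
    system2("/bin/sh", c("-c", shQuote(text)),
            stdout = out_file, stderr = FALSE, stdin = "")
  )
  list(stdout = read_text(out_file),
       exit_code = if (is.na(status)) 127L else as.integer(status))
}
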