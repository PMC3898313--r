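# scriptwright

Typed modeling, checking, execution and generation of shell pipelines.

## The problem

Bioinformatics analyses are still largely automated with BASH scripts, and
shell interpreters only discover an error if and when execution reaches the
offending line: a typo in the branch that handles an unusual input can sit
undetected until that input arrives. Shell scripts also offer no way to
enforce a structural contract — for example, that a plugin script for an
analysis platform provides the `setup`/`align`/`teardown` hooks the platform
will call.

`scriptwright` addresses both problems by representing a script as a typed
abstract syntax tree instead of raw text:

- **GStrings** — interpolated strings made of literal, program-variable
  reference (`${name}`) and environment-read (`${USER}`) components,
  evaluated *lazily*: references are resolved against the bindings current
  at evaluation time, so rebinding a variable changes what the string
  produces.
- **Execute commands** — pipelines of commands joined by the familiar BASH
  binary operators `|`, `&&`, `||`, `;`, `&`, with an optional trailing
  `> file` redirect, executed with BASH-equivalent operator semantics.
- **Environment sources** — explicit, reloadable origins of environment
  variables (process snapshot, dotenv file, plugin configuration) that
  scripts declare and load; reads of undeclared variables are caught before
  anything runs.
- **Micro-parsing** — raw BASH command lines developed interactively in a
  terminal are imported into well-formed trees (`parse_pipeline()`), and
  `${var}` markers in pasted text are extracted into declared program
  variables (`extract_variables()`). A failed parse never leaves a
  half-modified model.
- **A semantic checker** (`check_script()`) with stable diagnostic codes:
  malformed operator sequences (NYS001), misplaced redirects (NYS002),
  references to undeclared variables (NYS003), environment reads no loaded
  source declares (NYS010), and plugin scripts missing their binding or
  required entry points (NYS020).
- **A generator** that lowers plugin fetch/push slot commands to SDK command
  lines (`reduce_model()`) and renders any check-clean model as a standalone
  POSIX program plus launcher (`render_program()`), byte-deterministically.

## A worked example

```r
library(scriptwright)

env_file <- tempfile()
writeLines("USER=alice", env_file)

m <- new_script("demo")
m <- add_source(m, load_file_source(env_file))
m <- add_load_env(m)
m <- add_declaration(m, "greeting", "hello")
m <- add_execute(m, "echo ${greeting} ${USER} | tr a-z A-Z")

check_script(m)
#> [1] severity code     node_id  message      <0 rows> (or 0-length row.names)

res <- run_script(m)
res$stdout
#> [1] "HELLO ALICE\n"
res$exit_code
#> [1] 0
res$log_lines
#> [1] "+ echo hello alice" "+ tr a-z A-Z"
```

The checker returned zero findings, so the script ran: the pipeline
evaluated `${greeting}` from the program scope, `${USER}` from the loaded
file source, piped `echo`'s stdout into `tr`, and recorded one log line per
launched command. Had we executed `echo ${ghost}` instead, `check_script()`
would have reported `NYS003 reference to undeclared variable ghost` and
`run_script()` would have refused to start.

The same model renders to a runnable artifact:

```r
paths <- render_program(m, tempdir())
system2(paths$launcher, stdout = TRUE)
#> [1] "HELLO ALICE"
```

A command-line front end wrapping these functions is installed at
`system.file("cli", "scriptwright", package = "scriptwright")` with
subcommands `new`, `check`, `import`, `run`, `generate`, `env list` and
`scaffold` (exit codes: 0 success, 1 diagnostics/runtime failure, 2 usage).

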