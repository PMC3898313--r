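test_that("operators short-circuit and sequence like the shell", {
  r <- run_pipeline(parse_pipeline("false && echo hi"))
  expect_identical(r$exit_code, 1L)
  expect_identical(r$stdout, "")
  expect_identical(length(r$records), 1L)     # right side never launched

  r2 <- run_pipeline(parse_pipeline("false || echo hi"))
  expect_identical(r2$exit_code, 0L)
  expect_identical(r2$stdout, "hi\n")

  r3 <- run_pipeline(parse_pipeline("echo a ; echo b"))
  expect_identical(r3$stdout, "a\nb\n")
  expect_identical(r3$exit_code, 0L)
})

test_that("pipes connect stdout to stdin along the chain", {
  r <- run_pipeline(parse_pipeline("printf 'b\\na\\n' | sort"))
  expect_identical(r$stdout, "a\nb\n")
  expect_identical(r$exit_code, 0L)
  r2 <- run_pipeline(parse_pipeline("printf 'x\\ny\\nx\\n' | grep x | sort"))
  expect_identical(r2$stdout, "x\nx\n")
})

test_that("pipeline exit code is the last command's unless pipefail is on", {
  r <- run_pipeline(parse_pipeline("false | true"))
  expect_identical(r$exit_code, 0L)
  r2 <- run_pipeline(parse_pipeline("false | true"), pipefail = TRUE)
  expect_identical(r2$exit_code, 1L)
})

test_that("redirects overwrite their target with the final stdout", {
  wd <- tempfile(); dir.create(wd)
  r <- run_pipeline(parse_pipeline("echo x > f"), workdir = wd)
  expect_identical(r$exit_code, 0L)
  expect_identical(readLines(file.path(wd, "f")), "x")
  expect_identical(r$stdout, "")              # redirected away
  run_pipeline(parse_pipeline("echo y > f"), workdir = wd)
  expect_identical(readLines(file.path(wd, "f")), "y")
  # skipped command: redirect never happens
  run_pipeline(parse_pipeline("false && echo z > g"), workdir = wd)
  expect_false(file.exists(file.path(wd, "g")))
})

test_that("missing commands record exit 127; unbound variables abort pre-launch", {
  r <- run_pipeline(parse_pipeline("definitely_not_a_command_xyz"))
  expect_identical(r$exit_code, 127L)
  bad <- parse_pipeline("echo before ; echo ${nope}", scope = "nope")
  expect_error(run_pipeline(bad), class = "scriptwright_eval_error")
  # nothing may have launched: no partial side effects observable
})

test_that("every launched command is logged after evaluation, in order", {
  p <- parse_pipeline("echo ${a} | sort ; echo done", scope = "a")
  r <- run_pipeline(p, bindings = c(a = "VALUE"))
  expect_identical(length(r$records), 3L)
  expect_identical(r$records[[1]]$evaluated_text, "echo VALUE")
  expect_identical(r$log_lines,
                   c("+ echo VALUE", "+ sort", "+ echo done"))
})

test_that("word splitting respects quotes; substituted values are never re-split", {
  r <- run_pipeline(parse_pipeline("printf '%s\\n' 'two words' x"))
  expect_identical(r$stdout, "two words\nx\n")
  p <- parse_pipeline("printf '%s\\n' ${v}", scope = "v")
  r2 <- run_pipeline(p, bindings = c(v = "a b"))
  expect_identical(r2$stdout, "a b\n")        # one argument, not two
})

test_that("environment reads resolve through loaded sources and overrides", {
  src <- load_file_source(write_env_file("WHO=alice"))
  p <- parse_pipeline("echo ${WHO}", env_names = "WHO")
  r <- run_pipeline(p, sources = list(src))
  expect_identical(r$stdout, "alice\n")
  r2 <- run_pipeline(p, sources = list(src), env_overrides = c(WHO = "bob"))
  expect_identical(r2$stdout, "bob\n")
})

test_that("execution is deterministic for fixed inputs", {
  p <- parse_pipeline("printf 'c\\nb\\na\\n' | sort ; echo t")
  r1 <- run_pipeline(p)
  r2 <- run_pipeline(p)
  expect_identical(r1, r2)
})

test_that("whole scripts run statements in order with environment state", {
  m <- new_script("demo")
  m <- add_declaration(m, "a", "hi")
  m <- add_execute(m, "echo ${a}")
  r <- run_script(m)
  expect_identical(r$stdout, "hi\n")
  expect_identical(r$exit_code, 0L)

  # load sources mid-script, then read them
  src <- load_file_source(write_env_file("USER=alice"))
  m2 <- new_script("demo")
  m2 <- add_source(m2, src)
  m2 <- add_load_env(m2)
  m2 <- add_execute(m2, "echo ${USER}")
  expect_identical(run_script(m2)$stdout, "alice\n")

  # env_assign feeds later child processes
  m3 <- new_script("demo")
  m3 <- add_env_assign(m3, "SW_PROBE_VAR", "injected")
  m3 <- add_execute(m3, "printenv SW_PROBE_VAR")
  expect_identical(run_script(m3)$stdout, "injected\n")
})

test_that("scripts refuse unknown entry points and checker-dirty models", {
  m <- demo_model()
  err <- expect_error(run_script(m, entry_point = "frobnicate"),
                      class = "scriptwright_no_entry_point")
  expect_match(conditionMessage(err), "frobnicate")
  dirty <- add_execute(new_script("demo"), "echo ${ghost}")
  expect_error(run_script(dirty), class = "scriptwright_check_failed")
})

test_that("script exit code is the last statement's", {
  m <- add_execute(add_execute(new_script("demo"), "echo ok"), "false")
  expect_identical(run_script(m)$exit_code, 1L)
  m2 <- add_execute(add_execute(new_script("demo"), "false"), "echo ok")
  expect_identical(run_script(m2)$exit_code, 0L)
})
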