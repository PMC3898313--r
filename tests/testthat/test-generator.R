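aligner_descriptor <- function(...) {
  load_plugin_config(write_plugin_xml(...))
}

test_that("fetch/push commands lower to SDK command lines", {
  d <- aligner_descriptor(sdk_fetch = "sdk fetch --slot {slot}",
                          sdk_push = "sdk push --slot {slot}")
  m <- scaffold_script("aligner", d)
  m <- add_execute(m, execute_command(list(slot_command_node("fetch", "READS"))),
                   entry = "align")
  m <- add_execute(m, execute_command(list(slot_command_node("push", "ALIGN"))),
                   entry = "align")
  red <- reduce_model(m, d)
  lines <- vapply(red$entry_points$align[2:3], function(st)
    evaluate_gstring(st$pipeline$nodes[[1]]$line), character(1))
  expect_identical(lines, c("sdk fetch --slot READS", "sdk push --slot ALIGN"))
  # no slot commands remain; node ids are preserved
  expect_identical(red$entry_points$align[[2]]$pipeline$nodes[[1]]$id,
                   m$entry_points$align[[2]]$pipeline$nodes[[1]]$id)
})

test_that("reduction is the identity on core models and idempotent", {
  core <- demo_model()
  expect_true(models_equal(reduce_model(core), core))
  d <- aligner_descriptor()
  m <- add_execute(scaffold_script("aligner", d),
                   execute_command(list(slot_command_node("fetch", "READS"))),
                   entry = "align")
  r1 <- reduce_model(m, d)
  expect_true(models_equal(reduce_model(r1, d), r1))
})

test_that("reduction rejects undeclared slots and missing descriptors", {
  d <- aligner_descriptor()
  m <- add_execute(scaffold_script("aligner", d),
                   execute_command(list(slot_command_node("push", "NOPE"))),
                   entry = "align")
  err <- expect_error(reduce_model(m, d), class = "scriptwright_unknown_slot")
  expect_match(conditionMessage(err), "NOPE")
  expect_error(reduce_model(m), class = "scriptwright_must_reduce")
  # fetch checks input slots, not output slots
  m2 <- add_execute(scaffold_script("aligner", d),
                    execute_command(list(slot_command_node("fetch", "ALIGN"))),
                    entry = "align")
  expect_error(reduce_model(m2, d), class = "scriptwright_unknown_slot")
})

test_that("rendering is byte-deterministic and refuses unreduced models", {
  m <- demo_model()
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- render_program(m, d1)
  p2 <- render_program(m, d2)
  expect_identical(readLines(p1$program), readLines(p2$program))
  expect_identical(readLines(p1$launcher), readLines(p2$launcher))

  d <- aligner_descriptor()
  unreduced <- add_execute(scaffold_script("aligner", d),
                           execute_command(list(slot_command_node("fetch", "READS"))),
                           entry = "align")
  expect_error(render_program(unreduced, tempfile()),
               class = "scriptwright_must_reduce")
})

test_that("the rendered launcher reproduces run_script's stdout and exit code", {
  src <- load_file_source(write_env_file(c("GREETING=hello", "WHO=world")))
  m <- new_script("hello")
  m <- add_source(m, src)
  m <- add_load_env(m)
  m <- add_declaration(m, "n", "3")
  m <- add_execute(m, "echo ${GREETING} ${WHO} run ${n}")
  m <- add_execute(m, "printf '%s\\n' b a | sort")
  ref <- run_script(m)
  paths <- render_program(m, tempfile())
  out_file <- tempfile()
  status <- suppressWarnings(system2(paths$launcher, stdout = out_file))
  expect_identical(read_file_text(out_file), ref$stdout)
  expect_identical(as.integer(status), ref$exit_code)

  # entry points are reachable as launcher arguments
  d <- aligner_descriptor()
  sc <- scaffold_script("aligner", d)
  sc <- add_execute(sc, "echo aligning ${REF}", entry = "align")
  ref2 <- run_script(sc, entry_point = "align")
  paths2 <- render_program(sc, tempfile())
  out2 <- tempfile()
  status2 <- suppressWarnings(system2(paths2$launcher, "align", stdout = out2))
  expect_identical(read_file_text(out2), ref2$stdout)
  expect_identical(as.integer(status2), ref2$exit_code)
  # unknown entry point fails from the artifact too
  expect_identical(
    suppressWarnings(system2(paths2$launcher, "bogus",
                             stdout = FALSE, stderr = FALSE)), 1L)
})

test_that("phrase templates substitute only designated segments", {
  t <- build_template("k,v", ",", data.frame(line = 1L, segment = 2L,
                                             name = "value"))
  expect_identical(render_template(t, c(value = "42")), "k,42")

  txt <- "header\nname=fixme\nfooter"
  t2 <- build_template(txt, "=", data.frame(line = 2L, segment = 2L,
                                            name = "v"))
  expect_identical(render_template(t2, c(v = "real")),
                   "header\nname=real\nfooter")

  # no phrase lines: identity on text
  t3 <- build_template(txt, "=")
  expect_identical(render_template(t3), txt)

  err <- expect_error(render_template(t, character()),
                      class = "scriptwright_unbound_slot")
  expect_match(conditionMessage(err), "value")
  expect_error(build_template("a,b", ",", data.frame(line = 1L, segment = 5L,
                                                     name = "x")),
               class = "scriptwright_bad_segment")
  expect_error(build_template("a,b", ",", data.frame(line = 9L, segment = 1L,
                                                     name = "x")),
               class = "scriptwright_bad_line")
  expect_error(build_template("a,b\nc,d", ",",
                              data.frame(line = c(1L, 2L), segment = c(1L, 1L),
                                         name = c("x", "x"))),
               class = "scriptwright_duplicate_slot")
})
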