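test_that("new scripts are empty, check-clean, and validate their names", {
  m <- new_script("demo")
  expect_identical(length(m$statements), 0L)
  expect_identical(nrow(check_script(m)), 0L)
  expect_identical(m$format_version, 1L)
  expect_error(new_script("1bad"), class = "scriptwright_invalid_identifier")
  expect_error(new_script("demo", "mapper"), class = "scriptwright_bad_type")
})

test_that("builders enforce scope rules and assign unique node ids", {
  m <- new_script("demo")
  m <- add_declaration(m, "a", "1")
  expect_error(add_declaration(m, "a", "2"),
               class = "scriptwright_duplicate_declaration")
  m <- add_execute(m, "echo ${a} | sort")
  ids <- c(vapply(m$statements, `[[`, "", "id"),
           vapply(m$statements[[2]]$pipeline$nodes, `[[`, "", "id"))
  expect_false(anyDuplicated(ids) > 0)
  expect_false(any(is.na(ids)))
  # same name is allowed in a different scope (entry point)
  m <- add_entry_point(m, "extra")
  expect_no_error(add_declaration(m, "a", "2", entry = "extra"))
  expect_error(add_entry_point(m, "extra"),
               class = "scriptwright_duplicate_entry_point")
})

test_that("persistence round-trips models byte-for-byte, ids included", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_script_model()
    f <- tempfile(fileext = ".json")
    save_script(m, f)
    m2 <- load_script(f)
    expect_true(models_equal(m, m2))
    expect_identical(vapply(m2$statements, `[[`, "", "id"),
                     vapply(m$statements, `[[`, "", "id"))
  }
})

test_that("unknown future format versions and malformed files are rejected", {
  m <- demo_model()
  f <- tempfile(fileext = ".json")
  save_script(m, f)
  x <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  x$format_version <- 999L
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE), f)
  expect_error(load_script(f), class = "scriptwright_version_error")

  # truncated file: parse error, no partial model
  save_script(m, f)
  txt <- readLines(f)
  writeLines(txt[seq_len(length(txt) %/% 2)], f)
  expect_error(load_script(f), class = "scriptwright_parse_error")
  expect_error(load_script(tempfile()), class = "scriptwright_io_error")
})

test_that("checker reports operator, reference, environment and plugin rules", {
  # NYS001: consecutive operators
  m <- new_script("demo")
  bad <- execute_command(list(cmd_node("a"), op_node("pipe"), op_node("pipe"),
                              cmd_node("b")))
  m <- add_execute(m, bad)
  d <- check_script(m)
  expect_identical(d$code, "NYS001")

  # NYS002: redirect not last
  m2 <- add_execute(new_script("demo"), execute_command(list(
    cmd_node("a"), redirect_node("f"), op_node("pipe"), cmd_node("b"))))
  expect_true("NYS002" %in% check_script(m2)$code)

  # NYS003: reference before/without declaration
  m3 <- add_execute(new_script("demo"), "echo ${ghost}")
  expect_identical(check_script(m3)$code, "NYS003")
  m3b <- add_declaration(m3, "ghost", "now")   # declared *after* the use
  expect_identical(check_script(m3b)$code, "NYS003")

  # NYS010: environment read with no declaring source loaded
  m4 <- new_script("demo")
  m4 <- add_execute(m4, execute_command(list(
    cmd_node(gstring(list(gs_literal("echo "), gs_envread("FOO")))))))
  expect_identical(check_script(m4)$code, "NYS010")
  # loading a source that declares FOO clears it
  src <- load_file_source(write_env_file("FOO=1"))
  m5 <- new_script("demo")
  m5 <- add_source(m5, src)
  m5 <- add_load_env(m5)
  m5 <- add_execute(m5, "echo ${FOO}")
  expect_identical(nrow(check_script(m5)), 0L)

  # NYS020: plugin script without binding / entry points
  m6 <- new_script("demo", "aligner")
  codes <- check_script(m6)$code
  expect_true(all(codes == "NYS020"))
  expect_identical(length(codes), 1L + length(entry_point_contract()$aligner))
})

test_that("checking is pure and ordered by node position", {
  m <- new_script("demo")
  m <- add_execute(m, "echo ${ghost}")
  m <- add_execute(m, execute_command(list(
    cmd_node(gstring(list(gs_envread("FOO")))))))
  d1 <- check_script(m)
  d2 <- check_script(m)
  expect_identical(d1, d2)
  expect_identical(d1$code, c("NYS003", "NYS010"))
})

test_that("empty plain scripts and clean pipelines yield no findings", {
  expect_identical(nrow(check_script(new_script("empty"))), 0L)
  m <- demo_model()
  expect_identical(nrow(check_script(m)), 0L)
})
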