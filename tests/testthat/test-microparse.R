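test_that("pipeline parsing produces the expected node structure", {
  cases <- list(
    list("a | b | c > md-alignment.sam",
         c("command", "operator", "command", "operator", "command", "redirect")),
    list("true && echo ok", c("command", "operator", "command")),
    list("echo 'a | b'", "command"),                 # quoted pipe is not an operator
    list("echo \"x && y\"", "command"),
    list("a ; b || c", c("command", "operator", "command", "operator", "command"))
  )
  for (cs in cases) {
    p <- parse_pipeline(cs[[1]])
    expect_identical(vapply(p$nodes, `[[`, "", "kind"), cs[[2]], info = cs[[1]])
  }
  p <- parse_pipeline("a | b | c > md-alignment.sam")
  expect_identical(evaluate_gstring(p$nodes[[6]]$target), "md-alignment.sam")
  ops <- vapply(Filter(function(n) n$kind == "operator", p$nodes), `[[`, "", "op")
  expect_identical(ops, c("pipe", "pipe"))
})

test_that("operator tokenization is maximal-munch and quote-aware", {
  p <- parse_pipeline("a && b")
  expect_identical(p$nodes[[2]]$op, "and")
  p2 <- parse_pipeline("a || b")
  expect_identical(p2$nodes[[2]]$op, "or")
  p3 <- parse_pipeline("a & b")
  expect_identical(p3$nodes[[2]]$op, "background")
  # trailing & marks the final command background instead of dangling
  p4 <- parse_pipeline("sleep 0 &")
  expect_identical(vapply(p4$nodes, `[[`, "", "kind"), "command")
  expect_true(p4$nodes[[1]]$background)
})

test_that("malformed pipelines fail with positions and leave inputs untouched", {
  expect_error(parse_pipeline("a && && b"), class = "scriptwright_parse_error")
  err <- expect_error(parse_pipeline("a && && b"),
                      class = "scriptwright_parse_error")
  expect_match(conditionMessage(err), "consecutive operators at offset 5")
  expect_error(parse_pipeline("&& b"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a &&"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("echo 'oops"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a >> f"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a 2> f"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a < f"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a > f | b"), class = "scriptwright_parse_error")
  expect_error(parse_pipeline("a >"), class = "scriptwright_parse_error")
})

test_that("command text resolves ${} against scope and environment names", {
  p <- parse_pipeline("echo ${a} ${USER}", scope = "a", env_names = "USER")
  comps <- p$nodes[[1]]$line$components
  expect_identical(vapply(comps, `[[`, "", "kind"),
                   c("literal", "varref", "literal", "envread"))
  # single quotes suppress interpolation; double quotes keep it live
  p2 <- parse_pipeline("echo '${a}' \"${a}\"", scope = "a")
  kinds2 <- vapply(p2$nodes[[1]]$line$components, `[[`, "", "kind")
  expect_identical(sum(kinds2 == "varref"), 1L)
})

test_that("parse-render loops are stable", {
  set.seed(5)
  for (i in 1:60) {
    t <- random_pipeline_text()
    p1 <- parse_pipeline(t)
    p2 <- parse_pipeline(render_pipeline(p1))
    expect_identical(p2, p1, info = t)
  }
})

test_that("variable extraction declares each new name once, before the statement", {
  m <- new_script("demo")
  m <- add_declaration(m, "cmd", gstring(list(gs_literal("run ${N} of ${M}"))))
  stmt_id <- m$statements[[1]]$id
  r <- extract_variables(m, stmt_id)
  expect_identical(r$new_names, c("N", "M"))
  kinds <- vapply(r$model$statements, `[[`, "", "kind")
  expect_identical(kinds, c("var_decl", "var_decl", "var_decl"))
  expect_identical(vapply(r$model$statements[1:2], `[[`, "", "name"),
                   c("N", "M"))
  conv <- r$model$statements[[3]]$initializer
  expect_identical(vapply(conv$components, `[[`, "", "kind"),
                   c("literal", "varref", "literal", "varref"))
  # references are linked to the inserted declarations
  expect_identical(conv$components[[2]]$declaration_id,
                   r$model$statements[[1]]$id)
})

test_that("extraction reuses existing declarations and handles repeats", {
  m <- new_script("demo")
  m <- add_declaration(m, "N", "5")
  m <- add_declaration(m, "cmd", gstring(list(gs_literal("${N} ${N} ${X}"))))
  r <- extract_variables(m, m$statements[[2]]$id)
  expect_identical(r$new_names, "X")      # N was already in scope
  expect_identical(sum(vapply(r$model$statements, `[[`, "", "kind") == "var_decl"),
                   3L)
  # literal text with no markers: nothing declared, gstring unchanged
  m2 <- add_declaration(new_script("demo"), "p", "plain text")
  r2 <- extract_variables(m2, m2$statements[[1]]$id)
  expect_identical(r2$new_names, character(0))
})

test_that("failed extraction leaves the model byte-identical", {
  m <- new_script("demo")
  m <- add_declaration(m, "cmd", gstring(list(gs_literal("broken ${unterminated"))))
  before <- model_digest(m)
  expect_error(extract_variables(m, m$statements[[1]]$id),
               class = "scriptwright_parse_error")
  expect_identical(model_digest(m), before)
})
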