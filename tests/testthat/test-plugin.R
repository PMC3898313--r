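test_that("plugin configurations parse, with element-level validation", {
  d <- load_plugin_config(write_plugin_xml(
    output_slots = c(COUNTS = "tsv", ALIGN = "bam")))
  expect_s3_class(d, "plugin_descriptor")
  expect_identical(nrow(d$output_slots), 2L)
  expect_identical(d$plugin_type, "aligner")
  expect_identical(unname(d$env_entries[["REF"]]), "hg19")

  expect_error(load_plugin_config(write_plugin_xml(type = "mapper")),
               class = "scriptwright_parse_error")
  err <- expect_error(
    load_plugin_config(write_plugin_xml(
      input_slots = c(READS = "fastq"), output_slots = c(READS = "bam"))),
    class = "scriptwright_parse_error")
  expect_match(conditionMessage(err), "READS")
  expect_error(load_plugin_config(tempfile()), class = "scriptwright_io_error")
  no_id <- tempfile(fileext = ".xml")
  writeLines('<plugin type="task"></plugin>', no_id)
  expect_error(load_plugin_config(no_id), class = "scriptwright_parse_error")
})

test_that("every plugin type scaffolds check-clean with its entry points", {
  contract <- entry_point_contract()
  for (type in names(contract)) {
    d <- load_plugin_config(write_plugin_xml(id = paste0("p-", type),
                                             type = type))
    m <- scaffold_script(type, d)
    expect_identical(sort(names(m$entry_points)), sort(contract[[type]]),
                     info = type)
    expect_identical(nrow(check_script(m)), 0L, info = type)
    expect_identical(m$plugin_header$plugin_type, type)
    # each entry point starts by loading the plugin environment
    for (ep in names(m$entry_points)) {
      expect_identical(m$entry_points[[ep]][[1]]$kind, "load_env")
    }
  }
})

test_that("scaffolding rejects type/descriptor mismatches", {
  d <- load_plugin_config(write_plugin_xml(type = "aligner"))
  expect_error(scaffold_script("task", d),
               class = "scriptwright_type_mismatch")
  expect_error(scaffold_script("mapper", d), class = "scriptwright_bad_type")
})

test_that("descriptors expose environment entries and sorted slot names", {
  d <- load_plugin_config(write_plugin_xml(
    output_slots = c(COUNTS = "tsv", ALIGN = "bam"), env = c(REF = "hg19")))
  src <- plugin_environment_source(d)
  expect_identical(resolve_variable("REF", list(src)), "hg19")
  expect_identical(slot_names(d, "output"), c("ALIGN", "COUNTS"))
  expect_identical(slot_names(d, "input"), "READS")

  d0 <- load_plugin_config(write_plugin_xml(id = "bare", input_slots = character(0),
                                            output_slots = character(0),
                                            env = character(0)))
  expect_identical(slot_names(d0, "input"), character(0))
  expect_identical(available_names(list(plugin_environment_source(d0))),
                   character(0))
})

test_that("entry-point reads of the plugin environment execute end to end", {
  d <- load_plugin_config(write_plugin_xml(env = c(REF = "hg19")))
  m <- scaffold_script("aligner", d)
  m <- add_execute(m, "echo ref is ${REF}", entry = "align")
  expect_identical(run_script(m, entry_point = "align")$stdout,
                   "ref is hg19\n")
})

test_that("scaffolded plugin models survive persistence", {
  d <- load_plugin_config(write_plugin_xml())
  m <- scaffold_script("aligner", d)
  f <- tempfile(fileext = ".json")
  save_script(m, f)
  m2 <- load_script(f)
  expect_true(models_equal(m, m2))
  expect_identical(nrow(check_script(m2)), 0L)
})
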