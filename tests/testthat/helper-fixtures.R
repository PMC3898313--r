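# Fixtures are built in code at test time.

write_plugin_xml <- function(path = tempfile(fileext = ".xml"),
                             id = "demo-aln", type = "aligner",
                             input_slots = c(READS = "fastq"),
                             output_slots = c(ALIGN = "bam"),
                             env = c(REF = "hg19"),
                             sdk_fetch = "echo sdk fetch --slot {slot}",
                             sdk_push = "echo sdk push --slot {slot}") {
  slot_xml <- function(slots) {
    if (length(slots) == 0L) return(character(0))
    sprintf('  <slot name="%s" fileType="%s"/>', names(slots), slots)
  }
  env_xml <- if (length(env) > 0L) {
    sprintf('  <entry name="%s" value="%s"/>', names(env), env)
  } else character(0)
  writeLines(c(
    sprintf('<plugin id="%s" type="%s">', id, type),
    "<input-slots>", slot_xml(input_slots), "</input-slots>",
    "<output-slots>", slot_xml(output_slots), "</output-slots>",
    "<environment>", env_xml, "</environment>",
    "<sdk>",
    sprintf("  <fetch>%s</fetch>", sdk_fetch),
    sprintf("  <push>%s</push>", sdk_push),
    "</sdk>",
    "</plugin>"
  ), path)
  path
}

write_env_file <- function(lines, path = tempfile(fileext = ".env")) {
  writeLines(lines, path)
  path
}

# a small runnable model: declaration + pipeline echoing it
demo_model <- function() {
  m <- new_script("demo")
  m <- add_declaration(m, "a", "hi")
  add_execute(m, "echo ${a}")
}

read_file_text <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return("")
  readChar(path, file.size(path), useBytes = TRUE)
}

model_digest <- function(model) {
  # stable content hash for failure-atomicity checks
  paste(as.integer(serialize(model_to_json_chr(model), NULL)), collapse = "")
}

model_to_json_chr <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  save_script(model, f)
  paste(readLines(f), collapse = "\n")
}
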