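#' Plugin descriptors and script scaffolding
#'
#' A plugin descriptor binds a script to an analysis-plugin system: an id,
#' one of five plugin types (`aligner`, `alignment-analysis`, `resource`,
#' `artifact-install`, `task`), named input and output slots (the plugin's
#' file channels), environment entries injected into the script's
#' environment, and SDK command-line templates used to lower fetch/push slot
#' commands. Descriptors are read from an XML configuration file; the
#' schema this package reads is its own documented dialect (shipped as
#' `schema/plugin.xsd`), a stand-in rather than any external system's real
#' schema.
#'
#' @param path path to the plugin XML configuration.
#' @return A `plugin_descriptor`: list with `plugin_id`, `plugin_type`,
#'   `input_slots`, `output_slots` (data frames with `name`, `file_type`),
#'   `env_entries` (named character), `sdk_templates` (named list with
#'   `fetch`/`push`), `error_management` (stored, not acted on), and
#'   `config_path`.
#' @export
load_plugin_config <- function(path) {
  if (!file.exists(path)) sw_stop("io_error", "no such plugin config: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    sw_stop("parse_error", "%s: not valid XML (%s)", path, conditionMessage(e))
  })
  if (xml2::xml_name(doc) != "plugin") {
    sw_stop("parse_error", "%s: root element must be <plugin>", path)
  }
  id <- xml2::xml_attr(doc, "id")
  if (is.na(id) || !nzchar(id)) {
    sw_stop("parse_error", "%s: <plugin> element is missing its id", path)
  }
  type <- xml2::xml_attr(doc, "type")
  if (is.na(type) || !type %in% PLUGIN_TYPES) {
    sw_stop("parse_error",
            "%s: unknown plugin type %s (must be one of: %s)", path,
            type %||% "<missing>", paste(PLUGIN_TYPES, collapse = ", "))
  }
  read_slots <- function(elem) {
    nodes <- xml2::xml_find_all(doc, sprintf("./%s/slot", elem))
    nm <- xml2::xml_attr(nodes, "name")
    if (any(is.na(nm) | !nzchar(nm))) {
      sw_stop("parse_error", "%s: <%s> has a slot without a name", path, elem)
    }
    data.frame(name = nm,
               file_type = xml2::xml_attr(nodes, "fileType"),
               stringsAsFactors = FALSE)
  }
  input_slots <- read_slots("input-slots")
  output_slots <- read_slots("output-slots")
  all_slots <- c(input_slots$name, output_slots$name)
  if (anyDuplicated(all_slots)) {
    sw_stop("parse_error", "%s: duplicate slot name %s", path,
            all_slots[duplicated(all_slots)][1])
  }
  env_nodes <- xml2::xml_find_all(doc, "./environment/entry")
  env_entries <- xml2::xml_attr(env_nodes, "value")
  names(env_entries) <- xml2::xml_attr(env_nodes, "name")
  sdk <- list()
  for (d in c("fetch", "push")) {
    nd <- xml2::xml_find_first(doc, sprintf("./sdk/%s", d))
    if (!inherits(nd, "xml_missing")) sdk[[d]] <- xml2::xml_text(nd)
  }
  em <- xml2::xml_find_first(doc, "./error-management")
  structure(list(
    plugin_id = id,
    plugin_type = type,
    input_slots = input_slots,
    output_slots = output_slots,
    env_entries = env_entries,
    sdk_templates = sdk,
    error_management = if (inherits(em, "xml_missing")) NA_character_
                       else xml2::xml_text(em),
    config_path = path
  ), class = "plugin_descriptor")
}

#' @export
print.plugin_descriptor <- function(x, ...) {
  cat(sprintf("<plugin_descriptor %s> type=%s, %d in / %d out slot(s)\n",
              x$plugin_id, x$plugin_type,
              nrow(x$input_slots), nrow(x$output_slots)))
  invisible(x)
}

# list form for persisting plugin-config environment sources
descriptor_to_list <- function(d) {
  list(plugin_id = d$plugin_id, plugin_type = d$plugin_type,
       input_slots = list(name = as.list(d$input_slots$name),
                          file_type = as.list(d$input_slots$file_type)),
       output_slots = list(name = as.list(d$output_slots$name),
                           file_type = as.list(d$output_slots$file_type)),
       env_entries = as.list(d$env_entries),
       sdk_templates = d$sdk_templates,
       error_management = d$error_management,
       config_path = d$config_path)
}

descriptor_from_list <- function(x) {
  slots_df <- function(s) {
    data.frame(name = as.character(unlist(s$name) %||% character(0)),
               file_type = as.character(unlist(s$file_type) %||% character(0)),
               stringsAsFactors = FALSE)
  }
  env <- as.character(unlist(x$env_entries) %||% character(0))
  if (length(x$env_entries) > 0L) names(env) <- names(x$env_entries)
  structure(list(
    plugin_id = x$plugin_id, plugin_type = x$plugin_type,
    input_slots = slots_df(x$input_slots),
    output_slots = slots_df(x$output_slots),
    env_entries = env,
    sdk_templates = lapply(x$sdk_templates, as.character),
    error_management = x$error_management %||% NA_character_,
    config_path = x$config_path
  ), class = "plugin_descriptor")
}

#' Entry-point contract for plugin script types
#'
#' Returns the mapping from plugin type to the entry points a script of that
#' type must provide. The default contract ships with the package
#' (`contracts/entry-points.yaml`) and can be replaced by a user file of the
#' same form.
#'
#' @param path YAML contract file; defaults to the shipped contract.
#' @return Named list: plugin type -> character vector of entry-point names.
#' @export
entry_point_contract <- function(path = NULL) {
  path <- path %||% system.file("contracts", "entry-points.yaml",
                                package = "scriptwright", mustWork = TRUE)
  contract <- yaml::read_yaml(path)
  lapply(contract, as.character)
}

#' Scaffold a plugin script from a descriptor
#'
#' Creates a script model of the descriptor's plugin type with its plugin
#' binding filled in, the type's required entry points created, the plugin
#' environment source attached, and a load-environment statement pre-
#' inserted at the top of every entry point — so each entry point can read
#' the plugin's environment entries with `${name}` from the first statement.
#' The scaffold passes [check_script()] with zero findings.
#'
#' @param plugin_type one of the five plugin types; must equal the
#'   descriptor's type.
#' @param descriptor a `plugin_descriptor`.
#' @param name script name; defaults to a name derived from the plugin id.
#' @param contract entry-point contract (see [entry_point_contract()]).
#' @return A check-clean `script_model`.
#' @export
scaffold_script <- function(plugin_type, descriptor, name = NULL,
                            contract = entry_point_contract()) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  if (!plugin_type %in% PLUGIN_TYPES) {
    sw_stop("bad_type", "unknown plugin type: %s", plugin_type)
  }
  if (!identical(plugin_type, descriptor$plugin_type)) {
    sw_stop("type_mismatch",
            "requested type %s but descriptor %s is of type %s",
            plugin_type, descriptor$plugin_id, descriptor$plugin_type)
  }
  name <- name %||% gsub("[^A-Za-z0-9_]", "_",
                         paste0("plugin_", descriptor$plugin_id))
  model <- new_script(name, plugin_type)
  model$plugin_header <- list(plugin_id = descriptor$plugin_id,
                              plugin_type = plugin_type,
                              config_path = descriptor$config_path)
  src <- plugin_environment_source(descriptor)
  model <- add_source(model, src)
  for (ep in contract[[plugin_type]] %||% character(0)) {
    model <- add_entry_point(model, ep)
    model <- add_load_env(model, src$id, entry = ep)
  }
  model
}

#' Plugin environment source and slot discovery
#'
#' `plugin_environment_source()` exposes a descriptor's environment entries
#' as an `env_source` (kind `"plugin-config"`), so scripts can load and read
#' them like any other source. `slot_names()` returns the declared slot
#' names for one direction, sorted — the completion set for fetch/push
#' commands.
#'
#' @param descriptor a `plugin_descriptor`.
#' @return An `env_source`.
#' @export
plugin_environment_source <- function(descriptor) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  new_env_source(paste0("plugin:", descriptor$plugin_id), "plugin-config",
                 params = list(descriptor = descriptor),
                 variables = descriptor$env_entries)
}

#' @rdname plugin_environment_source
#' @param direction `"input"` or `"output"`.
#' @return `slot_names()`: sorted character vector of slot names.
#' @export
slot_names <- function(descriptor, direction = c("input", "output")) {
  stopifnot(inherits(descriptor, "plugin_descriptor"))
  direction <- match.arg(direction)
  sort_c(if (direction == "input") descriptor$input_slots$name
         else descriptor$output_slots$name)
}
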