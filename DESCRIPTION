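Package: scriptwright
Title: Typed Modeling, Checking, Execution and Generation of Shell Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models shell scripts as typed abstract syntax trees instead of
    raw text: interpolated strings with lazily evaluated variable and
    environment references, command pipelines with the familiar BASH binary
    operators, loadable environment sources, and filename pattern matching.
    A micro-parser imports raw BASH command lines into well-formed trees,
    a semantic checker reports stable diagnostic codes before anything runs,
    an execution engine runs pipelines with BASH-equivalent operator
    semantics while recording per-command logs, and a generator lowers
    plugin-domain commands and renders standalone runnable POSIX artifacts.
    Includes a plugin-descriptor contract (XML) for scaffolding typed
    analysis scripts with required entry points, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
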