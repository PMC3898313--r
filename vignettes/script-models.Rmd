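---
title: "Script models: design and semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Script models: design and semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scriptwright)
```

## The model

`scriptwright` treats a shell script not as text but as a typed tree. The
motivation is the usual weakness of interpreted shell scripting: errors in
rarely exercised branches are found only when an execution reaches them,
and nothing enforces structural contracts such as "an aligner plugin must
provide `setup`, `align` and `teardown` hooks". Working on a tree lets a
checker inspect the whole program before anything runs, lets tooling
enumerate what a script may legally reference, and lets a generator emit a
runnable artifact whose behavior provably matches the in-package executor.

A script model contains, in order: attached environment sources, a main
statement list, and named entry points (each an independent statement
list). Four statement forms are modeled — variable declaration, execute
(pipeline), load-environment, and environment assignment. Control
structures (loops, conditionals) are deliberately not modeled: the package
models the pipeline-and-environment layer where shell scripting is
genuinely hard to check, and expects host-language control flow to live
outside the model (e.g. in the R code that assembles and runs models).

### Scoping

The main list and each entry point are independent scopes: a variable
reference must target a declaration *earlier in the same list*, and a
load-environment statement covers only the later statements of its own
list. This mirrors how plugin scripts are actually written — each hook is
invoked on its own and therefore loads the plugin environment itself — and
keeps checking compositional: a scope can be validated without knowing
which other entry point might run first.

## Interpolated strings and laziness

A GString is an ordered list of literal, variable-reference and
environment-read components. Construction never substitutes anything;
`evaluate_gstring()` resolves references against the bindings current at
that moment. Evaluation is thus a pure function of `(bindings, env)` — the
property the test suite checks by evaluating random gstrings under
interleaved binding sets.

Marker syntax is exactly `${name}`. Interior whitespace (`${ b}`) is
accepted and trimmed, because that spacing variant occurs in practice.
`\${` escapes a marker; a `$` not followed by `{` is an ordinary
character. Only names are allowed inside markers — no expressions — since
anything richer would smuggle an expression language into strings and make
checking undecidable without an evaluator. At parse time, a name found in
the program scope wins over an identically named environment variable
(inner scope shadows environment); a name known to neither becomes an
unlinked variable reference that the checker reports as NYS003 rather than
a parse failure, so imports of not-yet-complete scripts stay possible.

## Micro-parsing

Raw BASH lines are imported in two steps that deliberately never destroy
input on failure: parse the text, build the replacement tree fragment, and
only then discard the raw text — if parsing fails, the caller's model is
untouched (R's copy semantics make this structural; the tests verify it by
hashing the serialized model before and after failed imports).

The pipeline tokenizer recognizes operators with maximal munch (`||`
before `|`, `&&` before `&`) outside quotes. Single quotes suppress both
operators and `${}`; double quotes suppress operators but keep `${}` live —
the same rule BASH applies to its own expansion. Only the overwrite
redirect `>` is modeled; `>>`, `2>` and `<` are rejected with explicit
"unsupported redirect" errors rather than silently mis-parsed, because a
wrong parse of a redirect changes where data lands. A trailing `&` marks
the final command as background instead of dangling as a terminal
operator, which keeps the command/operator alternation invariant intact.

## Checking

`check_script()` runs five rules in statement order and returns every
finding (never auto-fixing): NYS001 operator placement, NYS002 redirect
position, NYS003 undeclared variable references, NYS010 environment reads
with no declaring source loaded, NYS020 plugin contract violations.
Diagnostics are ordered by node position, making output deterministic and
diffable. The executor refuses any model with error-severity findings, so
the checker is sound on the executable subset by construction.

## Execution semantics

The executor implements the BASH operator semantics directly: the node
list is partitioned into pipe chains; chains are then run left to right
with `&&` (run iff previous exit 0), `||` (iff non-zero), `;`
(unconditional) and `&`. As in BASH, flat left-to-right evaluation of
equal-precedence `&&`/`||` reproduces the interpreter's behavior, and a
skipped chain leaves the previous exit status in place. The pipeline exit
code is the last command's; a `pipefail` toggle (rightmost non-zero
status) exists but is off, matching the shell default.

Three deliberate deviations, chosen for determinism and testability:

- **Pipes are staged through buffered temporary files**, not concurrent
  processes. For finite streams the observable stdout and exit codes are
  identical; what is lost is concurrency (and deadlock) behavior for
  infinite streams, which the modeled scripts do not produce.
- **Substituted values are never field-split.** After evaluation, literal
  text is split on unquoted whitespace with quote stripping, but a value
  substituted for `${x}` stays one word. This is safer than BASH's
  re-splitting and is matched by the generator, which renders
  interpolations quoted.
- **Background commands are run synchronously and waited immediately**;
  launching one contributes exit status 0 to control flow, as in BASH.
  This keeps results reproducible and leaves no orphan processes.

Commands are launched directly (argument-quoted, not via shell parsing of
the whole line), with explicit working directory and environment — the
executor shares no parsing machinery with `/bin/sh`, which is what makes
the shell a meaningful independent oracle: the test suite and acceptance
script compare exit code and stdout against `/bin/sh -c` on hundreds of
seeded random pipelines and require exact agreement.

Environment reads at run time resolve only through explicitly loaded
sources (later sources win) plus script-level assignments — never the
ambient process environment — so a script's inputs are fully enumerable,
and the NYS010 rule is the exact design-time twin of the runtime
resolution error.

## Generation

`reduce_model()` lowers plugin fetch/push slot commands into ordinary
execute commands by instantiating the descriptor's SDK template
(`{slot}` is the only substitution token, since the SDK invocation is
configuration, not language). Reduction validates slots against the
declared input/output sets, preserves node ids, and is idempotent.

`render_program()` emits a POSIX `sh` program plus a launcher that invokes
it by relative path. Rendering to `sh` (rather than to an R source file)
was chosen because the model's semantics are the shell's to begin with, a
`sh` artifact is self-contained on any POSIX system with no runtime
library, and it yields a strong cross-check: the rendered artifact is
executed by a *different* engine (`/bin/sh`) and must reproduce
`run_script()`'s stdout and exit code, which the test suite verifies over
a random executable corpus. Rendering is byte-deterministic — stable
ordering, no timestamps — so artifacts can be diffed and cached.
Environment-source loads are rendered as export lines snapshotting the
source at render time: the artifact is a frozen, standalone counterpart of
the live model, not a client of it.

Phrase templates (`build_template()`) cover the configuration-file corner
of generation: text is split at newlines, only explicitly selected lines
are parsed at a single-character delimiter, and designated segments become
named slots. Which lines are phrases is an explicit argument rather than a
heuristic; a template with no phrase lines renders back to its input
verbatim.

## Plugin contract

Plugin descriptors are XML (`schema/plugin.xsd` ships in the package):
id, one of five plugin types, input/output slots, environment entries, SDK
templates. This schema is the package's own documented dialect — a
stand-in contract, not a claim about any external platform's real
configuration format. Likewise the per-type entry-point sets are not fixed
by any published specification, so they live in a user-overridable YAML
contract file (`contracts/entry-points.yaml`): aligner =
setup/align/teardown, alignment-analysis = setup/analyze/combine, resource
and artifact-install = install, task = setup/run/teardown. The
`error-management` descriptor field is stored and round-tripped but not
acted on, as no runtime policy is defined for it.

## The fuzz corpora

The generators in `R/corpus.R` define the study conditions for the
property checks:

- `random_pipeline_text()` draws 1–4 commands over `true`, `false`,
  `echo`, `printf`, `cat`, `sort`, `grep` joined by `|`, `&&`, `||`, `;`.
  Consumers appear only after pipes so nothing reads the ambient stdin;
  every line is valid BASH, deterministic, and terminates immediately.
  This emulates the operator/exit-status structure of real pipelines while
  deliberately excluding what real analysis commands add: large streams,
  nondeterministic output, long runtimes, and exotic quoting. Passing the
  oracle comparison therefore demonstrates operator semantics, not
  performance or full BASH grammar coverage.
- `random_malformed_pipeline_text()` injects one defect per line
  (consecutive/leading/trailing operators, unbalanced quote, empty
  segment, unsupported redirect) for the atomicity property.
- `random_script_model()` draws structurally valid models (sources,
  declarations, pipelines, assignments, entry points) for round-trip and
  generator-equivalence checks.

Corpus sizes used by the tests and the acceptance script — 200 pipelines
for the shell-oracle comparison, 100 models for round-trips, 100 malformed
lines, 25 rendered programs — were chosen so each property is exercised
across all generator branches many times over while the whole suite runs
in seconds.

## Numerical and formatting choices

- Node ids are model-scoped strings (`n1`, `n2`, …) allocated from a
  persisted counter, so persistence round-trips references exactly.
- Persisted models are versioned JSON; files claiming a newer format
  version are rejected outright rather than partially read.
- All name orderings (available environment names, slot names, path
  matches) are byte-wise (C-locale) sorts, so output does not depend on
  the session locale.
- Path patterns: `*`/`?` within one segment, no recursion, hidden entries
  only via dot-leading patterns — the smallest dialect with predictable
  semantics; regex mode anchors the pattern as a full match.
- Dotenv parsing: split at the first `=`, values verbatim (no quote
  expansion), later duplicates win, `#` lines ignored.

## Known limitations

- No control flow, subshells, functions, here-docs or arithmetic
  expansion in the modeled language.
- Pipe stages are sequential; a stage producing unbounded output before
  its consumer runs would buffer it all to disk.
- Only `>` redirects; stderr plumbing between modeled commands is limited
  to capture into execution records.
- The plugin XML dialect and entry-point sets are this package's own
  contract; integrating with a real plugin platform means mapping its
  configuration onto them.
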