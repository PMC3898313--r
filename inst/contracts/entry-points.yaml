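# Required entry-point sets per plugin script type.
# These names are this package's own contract (override with the `contract`
# argument of scaffold_script()/check_script()); a plugin execution system
# may define different hook names.
aligner:
  - setup
  - align
  - teardown
alignment-analysis:
  - setup
  - analyze
  - combine
resource:
  - install
artifact-install:
  - install
task:
  - setup
  - run
  - teardown
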