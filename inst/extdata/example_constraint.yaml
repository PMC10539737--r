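# Example structure-prior support: prior knowledge removes unrealistic
# edges. Here nothing may point into the demographic factor (age is not
# caused by symptoms), and parent sets are capped at 4.
forbidden:
  - [ideation, older]
  - [depression, older]
  - [sofas_good, older]
max_parents: 4
ess: 1
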