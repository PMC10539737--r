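# Example factor specification: a small slice of a youth mental-health
# factor inventory. Continuous source columns (a functioning scale, age)
# are thresholded by the reader; diagnoses are three-level.
sofas_good:
  levels: [poor, good]
  truthy_levels: [good]
  domain_group: function
  binarize:
    source_column: sofas
    threshold: 70
    direction: gt
older:
  levels: ["false", "true"]
  truthy_levels: ["true"]
  domain_group: demographic
  binarize:
    source_column: age
    threshold: 18
    direction: gt
ideation:
  levels: ["false", "true"]
  truthy_levels: ["true"]
  domain_group: suicidality
depression:
  levels: [none, subthreshold, full-threshold]
  truthy_levels: [subthreshold, full-threshold]
  domain_group: syndrome
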