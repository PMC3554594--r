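# Code-count surrogate phenotyping rule for type 2 diabetes mellitus:
# >= 2 events with an ICD-9-CM 250.* code, no exclusions.
disease_label: type 2 diabetes mellitus
case_codes:
- '250'
min_case_events: 2
exclusion_codes: []
control_requires_zero: yes
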