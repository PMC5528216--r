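Drop-in location for external data.

study_supplementary_samples.csv — the third-party per-sample supplementary
table (schema: sample_id, cohort, adipocyte_area_um2, ai, lipid_percent).
It is not redistributed with the package; when present, the test suite
runs the published-summary reproduction against it.
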