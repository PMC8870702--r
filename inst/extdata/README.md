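# Bundled example data

Both files are SYNTHETIC: they were produced by the package's own Ct-table
generator (`default_synthetic_spec()` / `generate_cohort()`, seeds 60923 and
60924) followed by `normalize_ct_table()`, and are shipped only so the
validation pathway can be exercised on a file-shaped input. They are not
measurements from any patient cohort.

- `synthetic_discovery_expression.csv` — 30 labeled discovery samples
  (10 ACA / 10 ACC / 10 NAC), normalized log2 relative expression
  (-deltaCt) for the refined 9-miRNA validation panel.
- `synthetic_validation_expression.csv` — 43 validation samples
  (22 ACA / 21 ACC) in the same layout; the `group` column carries the
  revealed diagnosis used only for scoring, never for classification.

Real per-sample expression tables in the same layout (CSV with
`sample_id`, `group`, then one column per assay) can be substituted via
`read_expr_matrix()`.
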