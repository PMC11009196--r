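# Dictionary file schema

A dictionary file is a YAML sequence of rule records. Each record maps one
raw biomarker column to the 0-1 deficit scale and carries the panel and
health-domain tags the pipeline groups by. The file round-trips losslessly
through `read_dictionary()` / `write_dictionary()`.

Common fields (all records):

| field    | type   | values                                                    |
|----------|--------|-----------------------------------------------------------|
| `item`   | string | column name in the cohort table; unique within the file   |
| `panel`  | string | `blood` or `examination`                                  |
| `domain` | string | e.g. `blood chemistry`, `physical performance`, `cognitive`, `anthropometric`, `spirometry`, `hearing/vision`, `cardiac` |
| `kind`   | string | `binary_range`, `ordinal`, or `normalized`                |

Exactly one kind-specific block must be present:

* `kind: binary_range` — `normal_range: [low, high]` in item units; values
  inside the range (inclusive) code to 0, outside to 1.
* `kind: ordinal` — `cut_points`: strictly ascending thresholds;
  `levels`: deficit levels of length `len(cut_points) + 1`, strictly
  increasing within [0, 1] and containing 0 and 1. A value equal to a
  cut-point belongs to the higher deficit level.
* `kind: normalized` — `reference_min`, `reference_max` (item units,
  `min < max`) and `direction`: `higher_is_deficit` or
  `lower_is_deficit`. Values are min-max rescaled and clamped to [0, 1].

Example:

```yaml
- item: Albumin
  panel: blood
  domain: blood chemistry
  kind: binary_range
  normal_range: [35.0, 50.0]
- item: Timed 4-m walk
  panel: examination
  domain: physical performance
  kind: normalized
  reference_min: 2.0
  reference_max: 15.0
  direction: higher_is_deficit
```

`default_dictionary.yaml` in this directory is the serialized form of
`default_dictionary()`: the 70-item catalogue (23 blood, 47 examination)
with *synthetic placeholder* numeric rules on plausible clinical scales.
The placeholder cut-points are suitable for simulation and method
exercise, not for coding real cohort data.
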