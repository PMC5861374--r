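# analogseries

Mining **analog series with high assay hit rates** from compound screening
data, in R.

Screening archives test some compounds in hundreds of assays. Compounds that
are active far more often than the background are either genuinely
multi-target or artifacts of assay interference — and single compounds rarely
tell you which. Analog series (compounds sharing one core structure,
differing by a substituent at a single site) provide built-in controls:
consistent activity of close analogs across unrelated assays points to
interference, consistent activity against shared targets points to
promiscuity worth exploring, and inconsistent activity among near-twins
points at the data itself.

`analogseries` implements the full workflow:

1. **Compound selection** — per-compound hit rate
   `HR = 100 · n_active / n_tested` over primary assays with a definite
   outcome, followed by a strict three-stage cascade: tested in more than
   `min_primary_assays` (default 257) primary assays, then HR above the
   third quartile of the surviving distribution (or a fixed threshold), then
   HR above the median of the remainder (or a fixed threshold).
2. **Series extraction** — matching molecular series via single-cut
   fragmentation of acyclic bonds (exhaustive, or restricted to
   RECAP-style retrosynthetic bond rules given as two-atom SMARTS), with a
   13-heavy-atom substituent cap, substituent-smaller-than-core rule, and
   optional hydrogen-analog membership. Cores and substituents are canonical
   aromatic non-stereo SMILES with a `[*]` attachment token. Chemistry is
   delegated to Open Babel via ChemmineOB.
3. **Series parameters** — for member tested sets `T_i` and active sets
   `A_i`, with `U = ∪T_i` and `S = ∩T_i`: cumulative hit rate
   `100·|∪A_i|/|U|`, assay overlap `100·|S|/|U|`, and inconsistent activity
   (the share of `S` where some members are active and others inactive).
4. **Rank fusion** — series ranked separately by the three parameters
   (average ranks on ties), prioritized by the smallest rank sum; ties broken
   by series id, giving a deterministic consensus permutation.
5. **Interference flagging** — SMARTS substructure filters (file-driven, with
   PAINS-style exemplars included for testing) and interference-free series
   classification.
6. **Deposition I/O** — writer, reader, and validator for the two-file
   tab-separated exchange format (`AS.txt`,
   `AS_SupportingInformation.txt`).
7. **Synthetic data** — a seeded generator for analog libraries and assay
   panels with known ground truth, so the entire pipeline is testable
   offline.

## Worked example

```r
library(analogseries)

cfg <- synthetic_config(n_series = 12, decoy_compounds = 6, seed = 7)
lib <- generate_library(cfg)
sim <- simulate_assays(lib, cfg)
dir <- tempfile()
write_synthetic_dataset(lib, sim, dir)

res <- run_analog_pipeline(
  file.path(dir, "compounds.smi"), file.path(dir, "activity.tsv"),
  file.path(dir, "out"),
  selection = selection_config(257, 1.0, 1.8),
  policy = fragmentation_policy(bond_rule = "all_acyclic"))
res$report
```

```
Deposition validation report
  n_series                     12
  n_memberships                50
  n_unique_compounds           25
  n_multi_series_compounds     18
  members_min                  2
  members_max                  8
  as_hr_min                    6.17
  as_hr_max                    12.32
  as_hr_median                 8.085
  n_interference_free_series   12
  n_violations                 0
  no violations
```

Twelve analog series were extracted from the 25 selected high-hit-rate
compounds (of 40 in the library); the median cumulative series hit rate is
8.09%, 18 compounds belong to more than one series, no member matches an
interference filter, and the written deposition parses back with zero
consistency violations. `file.path(dir,
"out")` now contains `AS.txt`, `AS_SupportingInformation.txt`, the series /
metrics / flag tables, and `manifest.json` recording thresholds, policy,
and filter checksums for reproduction.

Individual stages are exported too — `read_compound_table()`,
`read_activity_table()`, `compute_hit_rates()`, `cascade_select()`,
`build_series()`, `series_metrics()`, `rank_series()`, `flag_compounds()`,
`write_deposition()`, `read_deposition()`, `validate_deposition()` — and a
thin command-line front end lives at `inst/scripts/analogseries-cli.R`
(subcommands `simulate`, `select`, `extract`, `metrics`, `flag`, `validate`,
`run-all`).

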