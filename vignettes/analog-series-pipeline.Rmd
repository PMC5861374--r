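---
title: "Mining analog series with high assay hit rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining analog series with high assay hit rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(analogseries)
```

## The problem

High-throughput screening archives such as PubChem BioAssay contain compounds
that were tested in hundreds of assays. Some of these compounds are active far
more often than the global background, and that promiscuity has two very
different explanations: genuine multi-target pharmacology, or assay
interference (reactive, aggregating, or autofluorescent chemotypes producing
false positives). Individual promiscuous compounds are hard to interpret;
*analog series* — groups of compounds sharing a core structure and differing
by one substituent at a single site — provide built-in controls. If closely
related analogs are active across many unrelated assays, interference is
likely; if they hit the same targets consistently, promiscuity deserves
follow-up; if some analogs are frequently active while their near-twins are
not, the underlying data merit scrutiny.

`analogseries` implements this analysis as a reusable pipeline: select
extensively tested, frequently active compounds; extract single-site analog
series from them; score each series; prioritize by rank fusion; flag
interference candidates; and exchange results in a fixed two-file deposition
format. A synthetic-data generator with known ground truth makes every stage
testable without any external download.

## Compound selection

The per-compound **hit rate** is
$\mathrm{HR} = 100 \cdot n_\text{active} / n_\text{tested}$
over primary assays with a definite outcome. Outcomes that are neither
`active` nor `inactive` (e.g. `inconclusive`) are excluded from both counts —
a hit rate is only meaningful over assays that produced a decision — and the
reader logs how many rows it dropped. Identical duplicate outcome rows are
tolerated (public extracts contain them); contradictory ones are a fatal
error, since the hit rate is ill-defined under contradiction.

Selection proceeds as a three-stage cascade with strict (`>`) comparisons:

1. keep compounds tested in more than `min_primary_assays` primary assays
   (default 257);
2. keep compounds with HR above a threshold derived as the **third quartile**
   of the survivors' HR distribution, or supplied as a fixed percentage;
3. keep compounds with HR above the **median** of the remaining distribution,
   or a fixed percentage.

Both modes exist because the procedure and its realized values are distinct
reproduction targets: on the public screening corpus this cascade realizes
thresholds of 1.0% and 1.8%. The quantile convention is linear interpolation
between order statistics (`stats::quantile` type 7); the convention is not
dictated by the method, but it must be fixed and reported for thresholds to
be reproducible, and the run report records which mode produced each
threshold. Compounds never tested in a confirmatory assay count in the
denominator of the confirmatory-consistency fraction, making that statistic
conservative.

## Series extraction

A **matching molecular series** (MMS) is two or more compounds distinguished
only by a substitution at a single site. Extraction works by single-cut
fragmentation:

* every single-order, acyclic bond between two heavy atoms is a candidate
  cut; cutting yields a **core** and a **substituent**, each written as
  canonical aromatic non-stereo SMILES with one `[*]` attachment token;
* under the default *retrosynthetic* rule, only bonds matching a configurable
  SMARTS rule set are cut. Each rule maps exactly two atoms — the cleavable
  bond — with environment conditions expressed as recursive SMARTS. The
  shipped set covers RECAP-style lability points (amide C–N, ester C–O,
  sulfonamide S–N, amine C–N, ether C–O), restricted to sp3 carbon partners
  so bonds adjacent to olefinic carbons are not cut. The exhaustive
  `all_acyclic` rule exists for oracle-style testing and for synthetic
  libraries whose attachment bonds are not retrosynthetically labile;
* the substituent must be strictly smaller than the core (equal halves yield
  no fragmentation) and at most 13 heavy atoms — the common
  matched-molecular-pair convention. Both restrictions are configurable, and
  the exact policy (including an md5 of the rule set) lands in the run
  manifest;
* every core shared by at least two compounds becomes a series. A library
  compound identical to a core's unsubstituted parent joins that series with
  the substituent token `[*][H]`: single-site series conventionally admit the
  hydrogen analog. This is switchable (`allow_hydrogen_substituent`).

Series identifiers are sequential integers assigned after sorting cores
lexicographically in the C locale, so ids are deterministic across runs,
platforms, and input orderings. All chemistry — parsing, aromatic perception,
canonicalization, stereo stripping, fragment surgery, SMARTS matching — is
delegated to Open Babel through ChemmineOB; the package adds only the
series-level logic.

## Series parameters and rank fusion

For a series with member tested-assay sets $T_1,\dots,T_k$ and active sets
$A_1,\dots,A_k$, with $U=\bigcup T_i$ and $S=\bigcap T_i$ (the *shared*
assays):

* **cumulative hit rate** $= 100\,|\bigcup A_i| / |U|$,
* **assay overlap** $= 100\,|S| / |U|$,
* **inconsistent activity** $= 100\,|\{a \in S : \exists\, i,j,\;
  a \in A_i,\; a \in T_j \setminus A_j\}| / |S|$.

The cumulative-rate denominator is the union of tested assays: the
intersection already has its own name (shared assays) and its own parameter,
so reading "assays in which all analogs were tested" as the intersection
would make the first two parameters redundant. A series without shared assays
gets inconsistency 0 rather than an error, keeping the ranking total; the
condition is noted in the metrics.

Series are ranked separately by each parameter — cumulative rate and overlap
descending, inconsistency ascending, ties receiving the average rank within
the tied block — and fused by summing the three ranks. The consensus order
sorts by rank sum, with ties broken by series id. Average ranks plus an
id tie-break make the consensus a deterministic permutation of $1..N$
regardless of input order. A high-priority series is thus one whose members
were tested together in many assays, were frequently active, and agreed with
each other. Percentages are carried at full precision internally and rounded
to two decimals only at serialization.

By default the parameters are computed over primary assays, the same scope in
which compound hit rates are defined; `assay_type = "all"` widens the scope.

## Interference flagging

Compounds are flagged by SMARTS substructure match against a filter set
loaded from a file (one SMARTS per line, optional id, `#` comments). A series
is *interference-free* when no member is flagged. The shipped default set is
a half-dozen PAINS-style exemplars (quinone, catechol, rhodanine-like,
enone, aromatic azo, hydrazone) intended for exercising the mechanism;
production triage should load a curated collection, and the run manifest
records the filter file's checksum so any run can be reproduced with the
exact list it used.

## Deposition format

`AS.txt` holds one row per series (id, consensus rank, core, the three
percentages, comma-separated member ids and SMILES, ordered by rank);
`AS_SupportingInformation.txt` holds one row per compound–series membership
with the compound's primary-assay counts, hit rate, active-target ids, and
interference flag. Columns are tab-separated; lists are comma-separated
without spaces; percentages carry two decimals; the writer emits LF endings
and the reader also accepts CRLF, spaces after commas, case-insensitive
yes/no/true/false/1/0 flags, and the earlier nine-column file version
(interference then reads as unknown). The validator recomputes each
compound's hit rate from its counts and compares at 0.05 absolute tolerance,
absorbing two-decimal rounding, and cross-checks referential integrity
between the two files.

## The synthetic generator

`generate_library()` plants analog series by attaching distinct R-groups to
scaffold templates (phenyl, biphenyl, benzamide, indolyl,
piperidinyl-phenyl), plus singleton decoys from separate scaffolds checked at
generation time not to share any cut core with the series templates. Member
counts are drawn as $2 + \mathrm{Poisson}(0.5)$ truncated to 2–17, matching
the small right-skewed series sizes (mean ≈ 2.5) seen when series are mined
from real screening collections. R-groups are always strictly smaller than
their core, so every planted member is recoverable by fragmentation.

`simulate_assays()` draws, per series, a union assay set of 261–592 primary
assays from a 650-assay panel — reproducing per-series testing ranges and
per-compound testing frequencies in the hundreds — then realizes the three
target parameters by construction: a shared subset of size
$\lceil \mathrm{OV} \cdot U \rceil$ tested by all members, non-shared assays
dealt to proper member subsets, $\lceil \mathrm{HR} \cdot U \rceil$ union
assays active-in-series, and $\mathrm{round}(\mathrm{INC} \cdot |S|)$ shared
assays given mixed outcomes. Default targets are 6% cumulative hit rate (the
middle of the high-hit-rate regime the pipeline isolates), 70% overlap, and
5% inconsistency; decoys are active at a 0.5% background rate, and compounds
with primary activity are confirmatory-active with probability 0.9. Because
integer assay counts cannot hit arbitrary fractions, the ground truth stores
the *realized* values, and recovery tests compare measurements against those
exactly — no tuned tolerances — while realized-versus-target deviations are
bounded by one assay's granularity, $100/U$ percentage points.

Requesting mixed activity without shared assays, or more mixed assays than
the active budget allows, is rejected as infeasible at configuration or
simulation time. Both generator stages draw every random number from the
single configured seed, so a fixed config reproduces byte-identical files.

What the generator does **not** emulate: correlated assay panels (real series
are tested in overlapping campaign-driven assay sets, not uniform draws),
target-family structure, realistic medicinal chemistry beyond valence-correct
analogs, PubChem identifier conventions, or interference chemotypes among the
planted compounds. Passing recovery tests therefore demonstrates correctness
of the bookkeeping and the algorithms, not robustness to the messiness of
real screening data.

## Worked example

```{r example, eval = FALSE}
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

On this configuration the pipeline selects 25 of 40 compounds, extracts 12
series (50 memberships, 18 compounds in more than one series), writes a
deposition whose validation reports zero violations, and reproduces the same
bytes on a second run.

## Numerical and design notes

* Problem sizes in the test-suite properties (libraries of up to ~50
  compounds, 20 oracle replicates, 50 simulation replicates at 20 series, a
  100-series deposition round trip) were chosen so the whole suite exercises
  every stage at series counts where exhaustive brute-force oracles are
  still exact.
* Equal-sized fragments produce no core/substituent assignment under the
  strictly-smaller rule; with the rule disabled, both assignments are
  emitted as alternative fragmentations.
* Two compound ids mapping to the same structure would create a duplicate
  (core, substituent) membership; the extractor keeps the smallest id and
  warns, since series membership is defined on structures.
* Compounds never tested in a primary assay carry an undefined (`NA`) hit
  rate and are excluded from quantile computations.
* The deposition reader treats a support row whose trailing target field was
  dropped by a tab-stripping editor as having an empty target list; all other
  field-count deviations are fatal with a line number.

## Limitations

* Retro rules are structural SMARTS only; no reaction-aware or
  machine-learned bond lability.
* Only single-site series are built; multi-site cores and scaffold trees are
  out of scope.
* Interference flagging is substructure matching only — no aggregation,
  autofluorescence, or reactivity prediction.
* The validator can check a deposition's internal consistency and summarize
  it, but the original corpus-level compound counts depend on a specific
  screening-archive snapshot and are not reproducible from the deposition
  alone.
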