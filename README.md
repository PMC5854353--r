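# myzaphid

An interval knowledge base and identification engine for the rose aphids of
the genus *Myzaphis* (Hemiptera: Aphididae: Macrosiphini) and the related
*Ericaphis avariolosa* and *Richardsaphis canadensis*.

For these aphids no specimen-level measurement data are deposited anywhere:
everything known about telling the species apart lives in printed
per-species, per-morph measurement ranges (mm), morphometric ratio ranges
(SIPH/cauda, PT/BASE, URS/ANT III, ...), setal and sensorial counts,
categorical states, six dichotomous keys, and comparative diagnosis
paragraphs. This package transcribes that decision content into a
machine-checkable reference dataset and makes it executable, for
aphidologists and for anyone studying how much identification signal a
published taxonomic treatment actually carries.

## What is inside

* **Reference dataset** — 34 taxon-by-morph interval profiles (over 1,600
  entries) bundled as plain CSV/JSON, in two layers: a verbatim
  *as-printed* transcription (anomalies included, original strings
  preserved) and a *curated* layer whose few corrections each carry a
  justification. `validate_dataset()` audits either layer; `query_range()`
  looks any value up.
* **Key engine** — the five species-level keys (fundatrices, apterae,
  alatae, oviparae, males) and the tribe-level key to Macrosiphini genera
  with 2-2-2 first-tarsal chaetotaxy, as couplet graphs in JSON.
  `traverse()` walks them with three-valued lead evaluation: missing data
  branch both ways and the terminal sets are unioned, so partial specimens
  degrade to candidate sets instead of wrong answers.
* **Multi-access identifier** — `identify_specimen()` scores a partial
  specimen against every profile of its morph by closed-interval
  containment (score = fraction of evaluable characters inside their
  ranges) and ranks the candidates.
* **Diagnosability analyzer** — `diagnose_pair()` and `pairwise_count()`
  recover which characters separate which species pairs and by how much
  (disjoint printed intervals; shared endpoints count as overlap).
* **Synthetic-specimen generator** — `generate_specimens()` draws seeded
  specimens honoring the printed absolute ranges, the printed ratio ranges
  (by interval propagation with rejection), or the predicates along one key
  path; `corrupt_specimens()` masks and perturbs them for degradation
  experiments. The generator doubles as a dataset health check: it reports,
  per profile, whether the printed tables and ratio ranges are jointly
  satisfiable as printed.

## A worked example

```r
library(myzaphid)
ds   <- load_reference()        # curated layer
keys <- load_keys(ds)

# an oviparous female with swollen hind tibiae bearing 70 pseudosensoria
ov <- myz_specimen("field-01", "ovipara",
                   linear = c(BL = 1.20, ANT_III = 0.14, ANT_IV = 0.068,
                              ANT_V = 0.069, HT_II = 0.085, SIPH = 0.25,
                              CAUDA = 0.13),
                   counts = c(PSEUDO_TIBIA_III = 70),
                   states = c(ANT_SEGMENTS = "6", TIBIA_III_FORM = "swollen"))
identify_specimen(ov, ds)$ranking
#>        taxon     score n_evaluated n_in
#> 1 oezdemirae 0.9285714          14   13
#> 2    rosarum 0.6428571          14    9
#> 3   turanica 0.3333333          15    5
#> 4   bucktoni 0.2857143          14    4
#> 5 canadensis 0.2142857          14    3
#> 6   rezwanii 0.2000000          15    3

traverse(ov, keys$myzaphis_oviparae, ds$registry)$terminals
#> [1] "oezdemirae"
```

Seventy pseudosensoria fall inside the printed 61–80 range of *M.
oezdemirae* and outside every other oviparous range (32–46, 4–10, 20–52,
7–20, 11–19); the antennal ratios derived from the raw segment lengths
(ANT V/ANT III = 0.49) agree, so both the matrix identifier and the
dichotomous key settle on *M. oezdemirae*.  The score column is the
fraction of the specimen's evaluable characters (raw and derived) lying
inside each candidate's printed ranges — 13 of this specimen's 14
characters fit the *M. oezdemirae* profile.

```r
d <- diagnose_pair(ds, "oezdemirae", "turanica", "ovipara")
subset(d$discriminating, kind != "categorical")[1:3, c(1, 3:6, 9)]
#>      character_id a_lo a_hi b_lo b_hi  gap
#> 4   ANT_V_ANT_III 0.48 0.50 0.90 1.03 0.40
#> 5           ANT_V 0.07 0.08 0.16 0.19 0.08
#> 6     URS_ANT_III 0.50 0.55 0.33 0.37 0.13
```

## The analysis workflow

Numbered scripts under `analysis/` run the package end to end and write
tables under `results/`:

1. `01_audit_dataset.R` — consistency audit of both data layers and of the
   keys against the profiles.
2. `02_key_roundtrips.R` — a path-constrained synthetic specimen for every
   terminal lead of every key, checked to land exactly on its terminal.
3. `03_diagnosability.R` — the full pairwise diagnosability matrix per
   morph.
4. `04_identification_roundtrips.R` — midpoint and ratio-constrained
   identification round trips, degradation under 50% missing data, and the
   per-profile satisfiability health check.

## Data provenance

`inst/extdata/` holds the reference bundle: `registry.json` (71 character
definitions), `taxa.json`, `measurements.csv` (the six measurement tables),
`description_ranges.csv` (ratio/count/seta ranges from the morph
descriptions), `states.csv`, `curation.csv` and `key_curation.json` (the
documented corrections), and `keys/*.json`. Every quantitative entry keeps
the verbatim printed string alongside its parsed bounds, so the
transcription itself is auditable.
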