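---
title: "An interval knowledge base and identification engine for Myzaphis and relatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An interval knowledge base and identification engine for Myzaphis and relatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myzaphid)
```

## The problem

The rose-feeding aphid genus *Myzaphis* comprises eight valid species known
from up to five morphs each (fundatrix, apterous and alate viviparous
females, oviparous females, males), plus two close relatives treated here:
*Ericaphis avariolosa* and *Richardsaphis canadensis*.  All published
knowledge about how to tell these taxa apart is carried by printed
measurement tables (ranges in mm per taxon and morph), morphometric ratio
ranges embedded in prose descriptions (SIPH/cauda, PT/BASE, URS/ANT III,
...), setal and sensorial counts, categorical states (frontal-tubercle
shape, siphuncular form, pleural stripes, tarsal chaetotaxy), six
dichotomous keys, and comparative Diagnosis paragraphs.  No specimen-level
data are deposited anywhere: the printed intervals *are* the data.

This package turns that decision content into an executable, testable
artifact:

* a **reference dataset** of 34 taxon-by-morph interval profiles
  (1,600+ entries), bundled as plain CSV/JSON and schema-checked at load;
* the six **dichotomous keys** as data (couplet graphs in JSON) with a
  traversal engine whose ambiguity semantics are explicit;
* a **multi-access identifier** that scores a partial specimen against
  every profile of its morph by closed-interval containment;
* a **diagnosability analyzer** that recovers, pair by pair, which
  characters separate which taxa and by how much;
* a seedable **synthetic-specimen generator** that makes all of the above
  testable without any field material.

## The two data layers

Printed tables contain misprints.  The dataset therefore ships in two
layers.  The *as-printed* layer is a verbatim transcription, anomalies
included, and every entry keeps the exact printed string.  The *curated*
layer (default for all analysis) applies a small correction table in which
every entry carries a justification — e.g. the apterous *M. tuatayae*
ANT IV range "0.08–1.10", whose upper endpoint exceeds the whole antenna,
is read as 0.08–0.10.  Two further corrections live at the key level: the
alate key's last couplet prints ANT IV/ANT III "1.00–1.45" for
*M. bucktoni*, which contradicts the preceding couplet (0.33–0.46) and
makes the terminal unreachable as printed — the curated key substitutes the
species' own printed alate ratio 0.40–0.46; and the oviparae key's lead for
the 5-segmented *M. turanica* prints a ratio against "ANT VI", a segment
those females do not have, which the curated key recodes against ANT V.

The consistency audit (`validate_dataset()`) never throws: it returns
findings.  Run on the as-printed layer it reports the anomalies (inverted
intervals, segments longer than the whole antenna); run on the curated
layer it returns nothing.  `audit_key()` plays each taxon's own profile
down its key path and classifies every lead as holds / partial / fails.
Two of its findings are worth knowing about, because they are properties of
the published treatment, not of this implementation: the apterae key sends
*M. oezdemirae* through a couplet requiring frontal setae 0.80–1.10 × BD III
although the species' own description prints 1.35–1.66; and the alatae of
*M. bucktoni* and *M. turanica* have no disjoint printed character at all
(`analysis/03_diagnosability.R`), so that pair rests entirely on the key's
(corrected) overlapping ratio.

```{r audit}
ds <- load_reference()                       # curated layer
printed <- load_reference(layer = "as_printed")
validate_dataset(printed)[, c("severity", "taxon", "morph", "character_id")]
nrow(validate_dataset(ds))
```

Values printed as "about *x*" become closed intervals
`[0.95x, 1.05x]`; the 5% half-width is the `about_tolerance` argument of
`load_reference()`.  It was chosen once: it spans the neighbouring printed
ranges of the keys that use "about" leads without merging any two leads of
one couplet.

## Key semantics

Keys are couplet graphs: each couplet has exactly two leads, each lead a
conjunction of predicates over registered characters, ending either at
another couplet or at a taxon.  Predicate intervals are closed — a specimen
exactly at a printed bound satisfies the lead — and "x or less / x or
more" phrasings become `[0, x]` and `[x, Inf)`.  Lead evaluation is
three-valued: *false* if any conjunct fails, *unknown* if none fails but
some character is missing, *true* otherwise.  Traversal follows a single
lead when exactly one is true and the other false; with both true, or any
verdict unknown, it follows **both** branches and unions the terminals; with
both false it records a dead end.  A specimen with no data therefore
returns every terminal — total ignorance is answered honestly — and a
specimen contradicting both leads returns none.

```{r keys}
keys <- load_keys(ds)
sp <- midpoint_specimen(ds, "tianshanica", "aptera")
traverse(sp, keys$myzaphis_apterae, ds$registry)
```

## Identification by interval containment

`identify_specimen()` scores a specimen against every profile of its morph:
a character is evaluable if present on both sides, a verdict is "in" iff
the value lies in the closed profile interval (states: token equality), and
the score is the fraction "in".  Candidates sharing fewer than
`min_characters = 3` evaluable characters are reported but not ranked — a
one-character match is taxonomically meaningless.  Ratio characters are
scored only against description-derived ratio ranges; quotients of table
endpoints are deliberately never used as bounds, because the ratio of two
column extremes is not a specimen-wise extreme.  No weighting is applied;
categorical mismatches count like quantitative ones.

```{r identify}
id <- identify_specimen(midpoint_specimen(ds, "rosarum", "aptera"), ds)
id$ranking
```

## Diagnosability

`diagnose_pair()` enumerates the characters recorded for both taxa of a
pair and lists those with disjoint intervals (categorical: differing
states), with the absolute gap and the gap relative to the pooled span.  A
shared endpoint counts as overlap: a specimen at the boundary is genuinely
ambiguous, so this is the conservative reading.  Genus-level traits — the
5-5-5 versus 2-2-2 first-tarsal chaetotaxy, the 6–7 versus 4 caudal
setae — are materialized into every profile at load, so genus-level
contrasts appear in species pairs.

```{r diagnose}
d <- diagnose_pair(ds, "oezdemirae", "turanica", "ovipara")
head(d$discriminating[, c("character_id", "a_lo", "a_hi", "b_lo", "b_hi", "gap")])
```

## The synthetic-specimen generator

The generator is the package's test substrate and is first-class code.
Three modes:

* `table_only` draws every raw value independently and uniformly (or
  truncated-normally, centred at the midpoint with
  `sd = sd_fraction × half-width`, clipped by resampling) from its printed
  interval; counts are integers; states are copied.
* `ratio_constrained` (default) additionally enforces every
  description-derived ratio range.  Characters are fixed one at a time —
  shared denominators such as ANT III, BASE and CAUDA first — each sampled
  from the intersection of its absolute interval with the intervals implied
  by already-fixed ratio partners; the rare draws violating a
  not-yet-propagated constraint are rejected (cap: `max_rejections = 1000`
  per specimen).
* `path_constrained` builds specimens from the predicates along one key
  path, decides each sibling lead against them, and verifies by traversal
  that exactly the requested terminal is returned.  No profile is needed,
  so the non-aphid genera of the tribe-level key are exercised too.

Characters that the treatment defines only through ratios (BD III, LS III, HLS)
have no printed absolute range; they are sampled from a fallback domain
(BD III: 0.010–0.035 mm, a realistic basal diameter of ANT III for aphids
of this size) and then propagate through their ratio constraints, which
makes their cluster scale-consistent by construction.

**What the generator emulates and what it does not.**  Specimens honor the
printed ranges but characters are otherwise sampled independently: there is
no allometric covariance (none is published), no measurement error model,
and no within-population structure.  Tests passing on these specimens
demonstrate that the engine is faithful to the printed intervals — not that
it would resolve real populations whose character correlations the
treatment does not report.

**Joint satisfiability as a health check.**  The printed tables and the
printed ratio ranges describe the same specimens but were rounded
independently (lengths to 0.01 mm, ratios to two decimals).  Read strictly,
they are jointly unsatisfiable for 10 of the 34 profiles — the apterous
*M. oezdemirae* print URS 0.07 and HT II 0.08 but URS/HT II 0.82–0.87,
while 0.07/0.08 = 0.875; the apterous *M. tianshanica* print
URS/ANT VI 0.65–0.80 although their table values imply 0.36–0.42.  The
generator therefore reconciles before sampling: a ratio constraint that
misses its table-implied achievable range by no more than half the printed
resolution is widened by that amount; one the tables flatly contradict is
dropped; and chain conflicts discovered during sampling trigger up to four
global half-resolution relaxations.  Every emitted specimen still lies
strictly inside the printed table intervals, and the batch report names the
profile's offending ratios (`report$strictly_satisfiable`,
`report$ratio_constraints_dropped`) — this per-profile satisfiability
report is itself one of the package's findings about the published data
(`analysis/04_identification_roundtrips.R`).

```{r health}
g <- generate_specimens(ds, 5, "oezdemirae", "aptera", seed = 1)
g$report[c("strictly_satisfiable", "ratio_constraints_dropped")]
```

`corrupt_specimens()` masks characters and multiplicatively perturbs values
under a seed, for degradation experiments.

## Numerical and design choices

* All lengths are mm as printed, to the printed precision; no unit
  conversion anywhere.
* Ratios are compared at full floating precision; display rounding never
  feeds back into comparisons, so printed-bound equality does not create
  boundary artifacts.
* Both ratio directions around HW and ANT are registered (`HW_ANT`,
  `ANT_HW`); keys and descriptions each use the direction they print, which
  avoids silent reciprocal bugs.
* Ties in identification rankings break alphabetically; traversal output is
  sorted; audit findings are ordered by taxon, morph, character — all
  output is deterministic given the seed (ordering is byte-wise, so it does
  not depend on the session locale).
* Midpoint specimens round count midpoints down, keeping them integers
  inside their intervals.
* Single printed values become degenerate intervals `[x, x]`; the
  generator's resolution-aware reconciliation (above) is what keeps those
  workable jointly with ratio ranges.
* Reproducibility: `generate_specimens()` and `corrupt_specimens()` are
  pure functions of (arguments, seed, dataset layer); the test suite runs
  with fixed seeds, 100 ratio-constrained specimens per profile in the
  acceptance checks and 3–5 per terminal in the key round trips — sizes at
  which every check is exact, not sampled opinion.

## Known limitations

* The knowledge base encodes what the treatment prints; characters mentioned
  only qualitatively (sculpture detail beyond the registered states, colour
  in life) are out of scope, and the tribe-level key's non-aphid genera
  exist only as key terminals, without profiles.
* Identification scores are unweighted fractions; no information-content
  ordering or probabilistic matching is attempted.
* Where the printed treatment contradicts itself beyond rounding (the flagged key
  couplets, the dropped ratio constraints, the bucktoni–turanica alate
  pair), the package surfaces the contradiction rather than resolving it:
  the audit trail is the product, not a by-product.
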