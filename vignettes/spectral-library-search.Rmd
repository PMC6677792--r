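---
title: "Searching in silico MS/MS spectral libraries: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching in silico MS/MS spectral libraries: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmatch)
```

## The problem

Non-targeted analysis (NTA) by high-resolution mass spectrometry observes
thousands of features — a parent m/z plus a fragmentation spectrum — without
knowing in advance which chemicals are present. Empirical MS/MS libraries
cover only a small slice of the chemical space of interest, so screening
workflows increasingly rely on libraries of *predicted* spectra computed in
bulk for entire chemical inventories, with each structure fragmented in
silico at several collision energies. Identification then becomes a
retrieval-and-scoring problem: find library chemicals whose parent mass (or
formula) is compatible with the observed precursor, compare the observed
fragments with each candidate's predicted fragments, and rank candidates —
ideally blending the spectral evidence with prior knowledge of how commonly
each chemical occurs.

This package implements that workflow end to end at desk scale: a formula
and mass engine, readers/writers for a multi-energy predicted-spectrum flat
format and a companion chemical-metadata table, an embedded relational store
with indexed retrieval, cosine dot-product scoring per collision energy,
metadata-fused ranking, and a seeded synthetic-data generator that stands in
for the (hundreds-of-gigabytes) production libraries in all tests.

## Masses and search windows

Candidate retrieval and fragment matching both operate on monoisotopic
masses. `monoisotopic_mass()` sums most-abundant-isotope masses per element
(`isotope_masses()`, shipped as a plain-text table with carbon fixed at
exactly 12 Da); this is the convention under which published metadata tables
print their "MS-Ready monoisotopic mass" columns, and the package reproduces
those printed values at 5–6 decimal places:

```{r}
monoisotopic_mass("C8H10N4O2")    # caffeine
monoisotopic_mass("C12 H12N4O3S") # whitespace in printed formulas is tolerated
```

Mass windows are expressed in parts per million. Two conventions are fixed
once and documented rather than left ambiguous:

* the ppm denominator is the **query** mass, not the candidate mass;
* the window is a **closed** interval — a candidate exactly on the boundary
  is retained.

The parent-mass window defaults to 10 ppm, a typical accuracy level for
modern HRMS instruments. The fragment-match window also defaults to 10 ppm
but with an absolute floor of 0.001 Da, because a purely relative window
becomes unrealistically narrow below ~100 m/z.

Charged or isotope-labelled formulas are rejected loudly by
`parse_formula()`: permanently charged species are exactly the structures
for which fragmentation prediction tends to fail, and silently accepting
them would corrupt downstream mass arithmetic.

## The flat format and the store

Each library record carries a seven-field header (timestamp, predictor
version, chemical identifier, SMILES, neutral mass, formula, InChIKey),
up to three collision-energy blocks for electrospray records (10/20/40 eV;
electron-impact records carry a single block), and a trailing table of
fragment-annotation SMILES. Because the reference layout for peak rows is
only available as prose, this package fixes a concrete dialect — documented
at the top of `R/spectra_io.R` — in which a peak row is
`mz intensity id1 [id2 ...] (a1 [a2 ...])`, the parenthesized per-annotation
intensities appearing only for multi-annotation peaks. Numeric fields are
written at six decimal places, which makes `parse_dat(write_dat(x))` an
exact identity for any data the generator produces. A strict mode turns
malformed records into errors; the default is skip-and-report, which is the
only sane policy when streaming hundreds of thousands of records.

`load_library()` normalizes records into four relational tables — chemical,
job (one chemical × mode × energy), peak, and fragment-annotation
intensities — keyed so that re-loading a (chemical, mode, energy) replaces
the previous job rather than duplicating it; rebuilds are therefore
idempotent. The same schema is exportable as engine-neutral DDL
(`write_schema_sql()`) for loading onto a server RDBMS. In-memory the tables
are data.tables with a sorted key on chemical mass, so the ppm-window
retrieval is a binary-search range scan rather than a linear pass.

## Matching and scoring

Fragment matching (`match_fragments()`) is a greedy nearest-mass one-to-one
assignment: all within-tolerance pairs are ordered by absolute mass
difference (ties broken by lower query index, then lower library index) and
accepted in order, skipping already-used peaks. At MS mass accuracies the
greedy solution is almost always the optimal assignment; greedy was chosen
because it is deterministic, linear to reason about, and easy to verify
against an exhaustive oracle on small inputs.

The spectral similarity is the cosine dot product

$$
S = \frac{\sum_{(i,j)\,\in\,\text{matched}} I^{q}_{i}\, I^{\ell}_{j}}
  {\sqrt{\sum_{i\in q} (I^{q}_{i})^{2}}\;\sqrt{\sum_{j\in \ell} (I^{\ell}_{j})^{2}}}
  \in [0, 1],
$$

with the denominators running over **all** peaks of each spectrum, so
unmatched peaks — spurious signal in the query, or predicted fragments the
instrument never saw — pull the score down. This is the standard behaviour
in the spectral-matching literature; a variant restricted to matched peaks
would assign perfect scores to spectra sharing a single peak. An optional
Stein–Scott style weighting $I \leftarrow m/z^{a} I^{b}$ is exposed
(`mz_power`, `intensity_power`) but defaults to unweighted ($a=0, b=1$),
since nothing in the reference workflow prescribes a weighting. Scores are
computed per collision energy; `sum_score` adds the present energies, so a
three-energy candidate can score up to 3.

Ranking (`rank_candidates()`) sorts descending by the chosen key, compares
scores with a 1e-12 tolerance before tie-breaking (avoiding float-order
nondeterminism), and assigns competition ranks (1, 2, 2, 4): tied scores
share a rank, and the order *within* a tie class is resolved by higher
matched-peak count, then identifier. Competition ranks rather than dense
ranks were chosen so that a rank of *r* always means "*r − 1* candidates
scored strictly better", which is the quantity an analyst acts on.

## Metadata fusion

The prevalence of a chemical across curated data sources is a strong prior
for which candidate actually occurs in a sample. Since the optimal way of
merging that prior with spectral scores is an open question, the package
ships three documented strategies behind one interface (`combined_rank()`):

* **Reciprocal-rank fusion** (default): $c = 1/(k + r_{\text{spec}}) +
  w/(k + r_{\text{meta}})$ with $k = 60$. RRF is robust to the wildly
  different scales of cosine scores and source counts, needs no tuning
  beyond $k$, and degrades gracefully: with $w = 0$, or when all counts are
  equal, it reduces *exactly* to the spectral ranking (a property the tests
  enforce).
* **z-score sum**: standardized cosine score plus weighted standardized
  $\log(1 + \text{count})$, for users who want score magnitudes, not just
  ranks, to matter.
* **tie-break only**: metadata never overrides spectral evidence, only
  orders candidates the spectra cannot separate.

## What the synthetic generator emulates — and what it does not

`generate_library()` draws parent masses uniformly over 80–600 Da (the
typical small-molecule screening range), gives each ESI chemical three
energy blocks of 5–20 fragments with log-normal relative intensities
(long-tailed, like real MS/MS), plants a configurable fraction (default
10%) of near-isobaric pairs within 5 ppm to stress ranking, and draws
long-tailed metadata counts. `make_query()` corrupts a chosen energy block
with Gaussian ppm jitter on m/z (applied to the parent mass too),
multiplicative log-normal intensity noise of a given CV, Bernoulli peak
dropout (resampled until at least one peak survives), and Poisson-count
spurious peaks.

Synthetic fragments are *mass values, not chemistry*: no valence rules, no
plausible neutral losses, no correlation between collision energy and
fragmentation depth, and placeholder alkane tokens for annotation SMILES.
Passing recovery tests therefore demonstrates that the retrieval, matching,
scoring, and ranking machinery is correct under a realistic noise model —
not that predicted spectra resemble instrument spectra for real compounds,
which is a property of the upstream prediction model, not of this package.

## Numerical and degenerate-input choices

* Flat-format numerics are fixed-point at six decimals; the generator snaps
  to the same grid, making round-trips bit-exact.
* `normalize_relative()` errors on empty or all-zero peak lists rather than
  guessing; an energy block that is present but empty scores 0.
* A query whose parent window catches nothing returns an empty table, not
  an error — an empty result is a legitimate screening outcome.
* Recovery experiments with all peaks dropped cannot occur by construction
  (dropout < 1 enforced, resampling on total dropout).
* Random-number use is scoped: generators take explicit seeds and restore
  the caller's RNG state, so library generation, query noise, and
  experiment sampling are independently reproducible.

## Problem sizes

The shipped checks run at sizes chosen to exercise every code path while
staying comfortable on a laptop: round-trip fidelity on 500 records,
retrieval-vs-linear-scan agreement on a 1,000-chemical library × 200
queries, and recovery on a 500-chemical library with 200 noisy queries
(5 ppm jitter, 20% intensity CV, 10% dropout), where the true chemical
ranks in the top 5 in well over 90% of queries and at rank 1 in ~96%.

## Known limitations

* Only [M+H]+ / [M−H]− / neutral adducts; no multimer or multi-charge
  handling.
* Greedy (not optimal bipartite) fragment assignment; differences are
  confined to pathological near-tie layouts.
* The store lives in memory and serializes via RDS; the DDL export exists
  precisely so production-scale deployments can use a server engine.
* The flat-format dialect was fixed from prose; field markers are isolated
  in one reader/writer pair so a one-line remap adapts it to deposited
  files whose byte layout differs.
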