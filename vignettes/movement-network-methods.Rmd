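---
title: "Methods: swine movement networks from permit records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swine movement networks from permit records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinenet)
```

## The data model

A movement permit records one shipment of pigs: origin state and
municipality, destination state and municipality, the declared purpose
(slaughter, fattening, breeding, or fairs/exhibitions), a date, and a head
count. Municipality identity is always the qualified pair
`state:municipality`, because Mexican municipality names repeat across
states. Aggregating permits under optional category and year filters gives
a weighted origin–destination matrix whose diagonal holds intra-unit
movements — pigs moved within a state (or municipality) are loops, not
discarded.

Two conventions in the possible-link bookkeeping deserve emphasis because
they are deliberately different:

* **Density** counts possible links over *all ordered pairs including
  self-pairs*: a 32-state roster has $32^2 = 1{,}024$ possible adjacencies
  and the 2,446-municipality roster $2{,}446^2 = 5{,}982{,}916$. The
  diagonal is part of the market.
* **Degree centrality** excludes self-links: the maximum degree on a
  32-state network is 31.

Both conventions are anchored to how these quantities are conventionally
reported for this market, and both are exercised by tests.

### Relative centrality denominators

Published analyses of this market use at least three denominators for
"percent centrality": the full roster size $N$ (a state linked to all
31 others plus itself reports $31/32 = 96.9\%$), $N-1$ (classical
normalized degree), and the number of *active* partners on the opposite
side (a destination receiving from 24 of 25 active source states reports
$96.0\%$). `degree_centrality()` therefore takes an explicit
`denominator` argument (`"n_total"`, the reporting default; `"n_minus_1"`;
`"active_partners"`), and every pipeline summary logs which convention was
used. Under `"active_partners"`, an *active source* is a node with at
least one outgoing off-diagonal link, and symmetrically for destinations.

### Eigenvector prestige

Prestige captures that a node can have high degree yet unimportant
partners. On a directed matrix, raw eigenvector centrality is ill-posed
(the adjacency matrix is asymmetric, its principal eigenvector need not be
real or nonnegative), so the package uses the hub/authority construction:
supply prestige is the principal eigenvector of $MM^\top$ and demand
prestige that of $M^\top M$, where $M$ is by default the dichotomized
matrix (the analysis tradition here dichotomizes before network
statistics; a weighted option is exposed since the software historically
used for these analyses does not document which it uses). Both matrices
are symmetric positive semi-definite, so power iteration from the uniform
vector with Euclidean normalization converges monotonically in the
principal eigenspace; iteration stops when successive iterates differ by
less than `tol` (default $10^{-10}$, `max_iter` 10,000). Scores are
nonnegative with unit norm. A zero matrix is a degenerate-spectrum error,
and non-convergence is an error reporting the last residual rather than a
silent partial answer. Ties in any ranking are broken lexicographically by
node label so reports are deterministic.

## Market-structure statistics

**Location quotient.** With $V_{ir}$ the heads of category $i$ in region
$r$, $Q_{ir} = (V_{ir}/V_{\cdot r}) / (V_{i\cdot}/V_{\cdot\cdot})$.
Following the temporal reading of "region" in this market's literature,
regions are *years* by default: $Q$ then asks whether a category was over-
or under-represented in a given year relative to its five-year share. The
functions are agnostic — any category-by-region table works, so a spatial
(state) analysis is the same call. The algebraic identity
$\sum_i s_{i\cdot} Q_{ir} = 1$ (national-share-weighted quotients sum to
one in every region) is tested on random tables.

**Specialization coefficient.** $CS_r$ is half the L1 distance between the
region's category shares and the national ones; it is 0 exactly when the
region mirrors the national structure and at most 1. Both $Q$ and $CS$ are
invariant to uniform rescaling of volumes, so tables may be in heads,
thousands of heads, or shares.

**Growth and trend.** `annual_growth()` defaults to the compound annual
growth rate $100((x_n/x_1)^{1/(n-1)} - 1)$; the arithmetic mean of
year-over-year changes is available (`method = "mean"`) because "average
annual growth" is ambiguous in market reports and the two differ on
volatile series. `trend_correlation()` is the Pearson correlation of
volume against year index with the usual $t$-transform p-value on $n-2$
degrees of freedom.

**Transport compliance.** Mexican regulation caps continuous livestock
transport at 20 driving hours and requires one hour of rest after every
8 hours of uninterrupted travel. The 20-hour ceiling is read as inclusive
(exactly 20 h is compliant). A rest that would fall exactly at journey end
(e.g. at hour 8 of an 8-hour trip) is not counted by default — the
regulation's intent there is ambiguous — and `rest_at_end = TRUE` flips
the reading. A 20-hour journey therefore has 2 rest stops and 22 elapsed
hours.

## The synthetic permit generator

`senasica_preset()` encodes the national market's published structure as
generator defaults:

| parameter | default | meaning |
|---|---|---|
| `n_states` | 32 | full state roster |
| `n_active_source_states` | 25 | states that ever ship pigs |
| `municipalities_per_state` | 77/76 (total 2,446) | full municipal roster |
| `years` | 2017–2021 | analysis window |
| `annual_head_total` | 33.3 × 10⁶ | heads moved per year |
| `category_probs` | 0.8729 / 0.1220 / 0.0050 / 0.0001 | head share of slaughter/fattening/breeding/fairs |
| `intra_state_prob` | 0.38 | probability a movement stays in its origin state |
| `source_concentration` | 1.4441 | Zipf exponent over active source states |
| `dest_concentration` | 1.2 | Zipf exponent over destination states |
| `mean_heads_per_permit` | ≈143.2 | 33.3 M × 5 yr over ≈1.16 M permits |
| `supply_municipality_frac` | 0.088 | active suppliers per state's municipalities |
| `demand_municipality_frac` | 0.153 | active receivers per state's municipalities |

Design choices where the published record is silent:

* **Permit sizes** are log-normal (σ = 1 on the log scale) around the
  configured mean — a heavy right tail matching a market that mixes small
  local trucks with large commercial shipments. The per-year permit count
  is the annual head total divided by the mean permit size, so yearly head
  totals concentrate around the target (tested within 3 standard errors).
* **Volume concentration** across nodes is a Dirichlet draw whose mean
  follows a Zipf decay $k^{-s}$ over ranked nodes. The exponent
  $s = 1.4441$ was solved once so the expected top-4 source-state share is
  73.4%; the Dirichlet precision (sum of concentration parameters) is
  fixed at 1,000, which keeps the realized top-4 share within roughly
  ±3 points of its mean while still making each seed's market a distinct
  random draw. Within-state municipal weights reuse the same law.
* **Destination choice** for an inter-state movement is the demand-weight
  distribution over the other 31 states — no gravity or distance model, a
  stated simplification. This is the one place the synthetic network is
  visibly more connected than a real one: with ~1.16 M permits, nearly
  every active source eventually ships to nearly every state, so the
  synthetic state network's density (~78%) sits well above a real permit
  network's (~26%). Calibration checks therefore target the quantities the
  generator controls (category shares, intra-state fraction, top-4
  concentration, active-state counts) and treat density only qualitatively
  (strictly inside (0, 100), reproducible under a fixed seed).
* **Dates** are uniform within each year at daily resolution — enough for
  daily-frequency statistics, with no seasonal signal.
* The published intra-state (38.4%) and inter-state (62.3%) shares sum to
  slightly over 100; the preset uses 0.38 and reports whatever the draw
  realizes.
* The 6.8% supplying / 15.3% demanding municipality fractions are
  reproduced by activating 8.8% of municipalities in each of the 25 active
  source states (≈169 of 2,446 nationally ≈ 6.9%) and 15.3% on the demand
  side in all 32 states.

What passing the calibration tests shows — and does not. Recovery of the
configured shares at ~10⁶ permits demonstrates the generator and the
ingest/aggregation path are mutually consistent and that the estimators
converge at the documented rates. It does not validate the generator
against the real permit database: statistics that depend on the database's
fine structure (real network density and centrality, prestige scores of
named states, daily frequency dispersion) are not reproducible from
published summaries and are left as qualitative checks only.

## Determinism and numerical notes

Every random draw is governed by the config's `seed` through an isolated
RNG scope (`withr::with_seed`), so a config is a complete recipe: same
config, byte-identical permits, and the caller's RNG state is untouched.
Matrix row/column labels are always sorted lexicographically, making
aggregation permutation-invariant in record order and all outputs stable
across runs. Degenerate inputs fail loudly: zero-total matrices for
intra/inter splits or market shares, empty indices for density, zero
matrices for prestige, constant series for trend correlation.

Problem sizes in the test suite are chosen to keep the full suite fast
while leaving the convergence claims meaningful: calibration checks run at
the full ~1.16 million-permit national scale (a few seconds, vectorized),
property suites run on 6–10-node networks and 4×5 tables across several
seeds.

## Known limitations

* No gravity/distance structure in destination choice (see above); no
  seasonality; no farm-level attributes (breed, weight, age) — the
  underlying permits do not carry them.
* The ingest validator handles the documented schema (category synonyms,
  case/whitespace noise, bad head counts and dates); it does not attempt
  fuzzy matching of misspelled state or municipality names.
* Geographic analyses (routes, distances, travel-time estimation from
  coordinates) are out of scope; `transport_compliance()` takes driving
  hours as given.
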