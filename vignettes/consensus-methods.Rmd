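---
title: "Consensus statistics for multi-round appropriateness panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus statistics for multi-round appropriateness panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randelphi)
```

## The problem and the model

In a RAND/UCLA appropriateness study an expert panel scores each clinical
scenario on a 9-point scale (1 = highly inappropriate, 9 = highly
appropriate). The panel's verdict on a scenario is read off the rating
distribution, not off individual votes, using three ingredients:

1. **Location** — the median rating, placing the scenario in one of three
   bands: *inappropriate* (1–3), *equivocal* (4–6), *appropriate* (7–9).
2. **Spread** — the interpercentile range `IPR = P70 − P30` between the
   30th and 70th percentiles.
3. **Asymmetry correction** — because a panel piling up near one end of
   the scale has less room to spread out, the IPR is compared against the
   *interpercentile range adjusted for symmetry*,

   `IPRAS = 2.35 + 1.5 · AI`, with `AI = |5 − IPRCP|` and
   `IPRCP = (P30 + P70)/2`.

The **disagreement index** is `DI = IPR / IPRAS`. `DI < 1` means the
panel agrees (and the median band then names what it agrees on);
`DI ≥ 1` means disagreement. A panel split evenly between the scale ends
has `P30 = 1`, `P70 = 9` and therefore `DI = 8/2.35 ≈ 3.40`, the
analytic extreme for a symmetric split; a degenerate panel has `DI = 0`.

In a multi-round (Delphi) design the panel re-rates every scenario after
seeing anonymised feedback, some scenarios are reworded or split in two,
and panellists drop out between rounds. The package adds the bookkeeping
this requires: item lineage (identical / modified / split), band
transitions between rounds, and cross-tabulation of verdicts by problem
category.

## Tunable parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `q_low`, `q_high` | 0.30, 0.70 | percentile pair summarising spread |
| `method` | `"linear"` | percentile interpolation (see below) |
| `di_threshold` | 1 | DI at or above this is disagreement |
| `band_edges` | 3.5, 6.5 | median cut points between the three bands |
| `ipras_intercept`, `ipras_slope` | 2.35, 1.5 | IPRAS constants |

**Percentile interpolation.** Published panel reports rarely say which
quantile convention their software used, and the conventions genuinely
differ at panel sizes of 19–24. The default here is linear interpolation
at plotting position `(n − 1)q + 1` (`stats::quantile` type 7, the most
widely used convention); nearest-rank (type 1) and the `(n + 1)q`
position (type 6) are available via `consensus_config(method = ...)` so
users can match other software. On the ratings `1..9`,
`percentile_score(1:9, 0.30)` is 3.4 under the default rule.

**Ties at the boundary.** A DI exactly equal to the threshold is
classified as disagreement: the agreement rule is deliberately the
conservative complement of `DI < 1`.

**Half-integer medians.** Even-sized panels produce medians such as 2.5
or 4.5. The band edges 3.5/6.5 send each half-integer median to the band
of its nearest integers (2.5 → inappropriate, 4.5 → equivocal), which is
how published tables place them; a median exactly on an edge falls to
equivocal, again the conservative choice.

## Working from published summary tables

The bundled dataset (`opioid_delphi_summaries()`) carries the *printed*
per-item statistics of a two-round opioid prescribing-safety e-Delphi
study: medians, 30th/70th percentiles, rating-bin counts, DI and verdict
label for 20 scenarios in two rounds plus 13 reworded/split items rated
in round 2. Two caveats a user of such tables should know:

* Printed percentiles are rounded. Recomputing a DI from them does not
  reproduce the printed DI (rows printing percentiles "(2, 2)" carry
  DI 0.203, not 0; two rows printing "4 (3, 6)" carry different DIs),
  which shows the original analysis used unrounded percentiles. The
  package therefore never asserts printed DI values from printed
  percentiles; it classifies from the printed `(median, DI)` pair.
* Published tables can be internally inconsistent. In the bundled data
  one round-1 row prints median 4 with an agreed-inappropriate label and
  another prints a median below its 30th percentile. `label_classification()`
  exists precisely so analyses can work from the printed labels where
  reproducing the published bookkeeping is the goal, and from recomputed
  classifications where consistency is the goal.

```{r published}
cl <- classify_summaries(opioid_delphi_summaries())
table(round = cl$round, label = cl$label)
```

## Round linkage and convergence

`transition_table()` compares every later-round item against its
comparison state. Items rated unchanged in both rounds are compared
across rounds — the effect of feedback. Reworded (`modified`) and
`split` items exist only in the later round, so they are compared
against their parent *within that round* — the effect of the rewording
itself. This separation is what lets a single run reproduce both the
"converged between rounds" count and the "converged after rewording"
count of a published study. An item is *converged* when an
agreed-equivocal state becomes agreed-inappropriate.

## The synthetic panel generator

Raw panellist-level ratings are rarely released, so the package ships a
seeded generator whose defaults emulate the motivating study's design:
24 panellists over 20 items in round 1; independent per-panellist
dropout with probability 5/24 (expected round-2 panel of 19); 13
reworded child items added in round 2; and a feedback shift that moves a
retained panellist's fresh round-2 rating one scale step toward the
round-1 item median with probability 0.5, never crossing it. The default
item mix is 15 consensus items at location 2 and 5 at location 5, both
with dispersion 1 — the 15 agreed-inappropriate / 5 agreed-equivocal
split the study reached. The feedback-shift probability is not reported
in any study; 0.5 is chosen as a moderate value that produces visible
but not overwhelming convergence, and it is a config field.

Item archetypes:

* **consensus** — a latent normal at `location` with sd `dispersion`,
  rounded to the nearest integer and clamped to `[1, 9]`. `dispersion = 0`
  gives the degenerate all-identical panel.
* **polarized** — two camps at `poles`, a fraction `mix` at the first.
  By default exactly `round(mix · n)` panellists sit at the first pole
  (`pole_assignment = "fixed"`). This is a deliberate design choice: the
  archetype exists to represent a *genuinely* split panel whose true
  state is "disagreement", and under per-panellist Bernoulli camp
  assignment a nominal 50/50 split of 24 raters fails to straddle the
  scale in about 6% of realizations (the camp sizes drift below 8), so
  the archetype's own truth would wobble. Bernoulli assignment remains
  available (`pole_assignment = "random"`) for studying exactly that
  sampling variability.
* **uniform** — structureless ratings, equiprobable over 1–9.

Seeding is hierarchical (study stream for attrition, one stream per
item × round), so adding items to a config never perturbs the draws of
existing items.

**What the generator does not emulate:** intra-panellist correlation
across items (hawks/doves), item skipping by default (`skip_prob = 0`
since the motivating study shows near-complete response), rating drift
from genuine opinion change as opposed to feedback, and any free-text
feedback content. Passing recovery tests therefore demonstrates that the
pipeline recovers the structure this generator encodes — not that any
particular real panel behaved this way.

## Operating characteristics

`recovery_experiment()` measures, per archetype and panel size, the
probability of reaching agreement, the probability of recovering the
archetype's true band (truth is the location's band for consensus items
and "disagreement" for polarized/uniform ones), and the mean DI, with
Monte-Carlo standard errors. Cell seeds depend on the archetype and
replicate but not the panel size, so comparisons across `n` use common
random numbers. The package's own checks run a 10,000-replicate grid at
`n = 24` for the degenerate-consensus and split-panel archetypes and a
150-replicate grid over `n ∈ {6, 12, 24, 48}` for the monotonicity
check; these sizes keep each check well under a minute per cell while
leaving Monte-Carlo error far below the margins being asserted.

```{r recovery}
recovery_experiment(
  list(item_archetype("consensus", 2, 1), item_archetype("uniform")),
  n_panellists = c(12, 24), replicates = 200, seed = 1)
```

## Numerical and degenerate-input choices

* All computation is at full double precision; rounding (medians and
  percentiles to the table's display precision, DI to 3 decimals with
  round-half-even) happens only in the report renderer.
* An empty rating vector, an empty classification set and an empty
  archetype grid raise dedicated condition classes rather than returning
  `NA`, because silent empties in panel data almost always indicate a
  join gone wrong.
* Ratings are validated as integers in `[1, 9]` at the boundary
  (`rating_study()`), so the statistics layer can assume clean input.
* Missing ratings are represented by absent rows, never imputed; each
  item's `n` is the count of present ratings.
* Attrition can in principle remove every panellist; the generator keeps
  at least one to avoid an empty round-2 panel.

## Known limitations

* Exact reproduction of published DIs requires the raw ratings, which
  the motivating study did not deposit; the package reproduces published
  *verdict counts, cross-tabs and convergence counts*, and validates its
  statistics against exhaustive enumeration and analytic values instead.
* Only the DI-based agreement rule is implemented; the older
  extreme-thirds frequency rules for disagreement are out of scope.
* The report renderer targets delimited text and Markdown grids, not
  typeset output.
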