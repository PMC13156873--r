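---
title: "Stopping rules for active-learning screening: model, simulation design and evaluation"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Title-and-abstract screening for a systematic review asks a reviewer to label
every retrieved citation as relevant or irrelevant. Technology-assisted
review replaces the arbitrary screening order with a learned one: a
relevance classifier is trained on the labels so far, the unscreened records
are re-ranked by predicted relevance after every decision, and the reviewer
always sees the most promising record next. Because most relevant records
then surface early, it is tempting to stop before the end — but any early
stop risks missing relevant records that the ranker happened to place late.

`screenstop` simulates this process to exhaustion on corpora whose true
labels are known, and evaluates three early-stopping rules retrospectively
on each recorded screening order:

1. **Count-based** — stop when the number of relevant records found reaches
   an estimate extrapolated from an initial random sample
   (`estimate_relevant_total()`: if `r_s` of `n_s` sampled records are
   relevant, `R_hat = round(r_s / n_s * N)`).
2. **Streak-based** — stop after `c` consecutively screened irrelevant
   records.
3. **Fraction-based** — stop once `ceiling(p * N)` records have been
   screened.

Because every simulated run screens all `N` records, each rule's stopping
point, recall at stop, missed count and work saved can be computed exactly
after the fact, and the per-run break-even values of rules 2 and 3 — the
largest interior irrelevant gap (`minimal_safe_streak()`) and the position
of the last relevant record (`pct_to_last_relevant()`) — quantify the best
each rule could possibly have done on that run.

# The screening model

The ranker is the classic default pipeline of active-learning screening
tools: smoothed TF-IDF features with a two-class multinomial naive Bayes,
and certainty-based selection (always reveal the record with the highest
predicted relevance).

* **Tokenization** (frozen deliberately, since TF-IDF dialects differ across
  implementations and would make trajectories irreproducible): text is
  `title + " " + abstract`, lowercased, split on runs of non-alphanumeric
  characters; tokens shorter than 2 characters are dropped.
* **Weights**: `tf(t, d) * (ln((1 + N) / (1 + df(t))) + 1)` with per-record
  L2 normalization. The vocabulary is fit once on the whole corpus; labels
  never enter featurization, so the ranking cannot leak oracle information.
* **Classifier**: multinomial naive Bayes over the (fractional) TF-IDF
  weights with additive smoothing `alpha` (default 1). `alpha` is exposed
  because no canonical value is fixed by the screening-tool default; note
  that with additive smoothing the model is *not* invariant to duplicating
  the training data (duplication halves the influence of the smoothing
  pseudo-counts) — the exact invariance is duplication with proportionally
  scaled `alpha`.
* **Tie-breaking**: equal predicted relevance is resolved by ascending
  corpus row order; records with no text are retained (dropping them would
  change `N` and every percentage) but flagged and always ranked last.
* **Retraining**: after every reveal by default (`retrain_every = 1`);
  small batches consume the current ranking between refits and do not
  change results on separable corpora.

The simulation loop (`simulate_screening()`) seeds the model with a uniform
random **prior sample** of `max(2, round(f * N))` records, `f` from 1% to
30%. The prior phase counts as screened in all percentage statistics — those
records were reviewed, just not by the ranker. A classifier needs both
classes, so a one-class prior draw is redrawn under an incremented sub-seed
(`prior_policy = "resample"`, budgeted and logged). This conditioning biases
the sample's relevant count upward precisely at small `f` and low
prevalence, which is a real feature of the count-based rule's operating
conditions, not an artifact; `"accept-degenerate"` is provided for unbiased
estimator studies, and the grid records the resample count of every run.

# What the synthetic generator emulates — and what it does not

`generate_corpus()` draws each record's tokens from a two-component
multinomial mixture: a Zipf-weighted background distribution over 90% of the
vocabulary, and a topic distribution over the remaining 10%. Relevant
records draw from `delta * topic + (1 - delta) * background`; a
`hard_fraction` subset of relevant records draws from the pure background
and is therefore textually indistinguishable from irrelevant records —
these are the records that surface late under any text-based ranker and
make early stopping dangerous.

Defaults (chosen once, as plausible for screening corpora, and then left
alone): `vocab_size = 300` and `doc_length = 40` give title+abstract-scale
token counts with substantial term overlap; `delta = 0.8` produces the
strong-but-imperfect separability that published screening simulations
show; `hard_fraction = 0.1` reproduces the qualitative pattern that a small
minority of relevant records rank very late. Prevalences in the package's
demonstration grid (1.0% and 7.6% over `N = 500`) bracket the range of the
real screening corpora the study design targets (0.2%–7.6%).

Limits worth stating plainly. The generator produces bags of synthetic
tokens, not language: no word order, no bigrams, no citation metadata, and
a single coherent topic for the relevant class. A ranked position of a
"hard" relevant record is fixed at corpus-generation time (it is a property
of the document draw), so across-replicate variation reflects only the
prior sample, exactly as across-simulation variation on a fixed real corpus
does — but a single synthetic corpus draw can be luckier or unluckier than
a real dataset. Passing tests on these corpora validate the machinery and
the qualitative behaviour of the stopping rules, not their quantitative
thresholds on any real review.

# Numerical and design choices

* **Rounding**: printed percentages and the count estimator round half away
  from zero (`round_half_up()`), matching the worked arithmetic of the
  estimator's definition; base R's round-half-even would disagree on exact
  halves.
* **Fraction stop** uses a plain `ceiling(p * N)` with no epsilon guard;
  thresholds are user-chosen round numbers for which the expression is
  exact.
* **Streak scope**: both the streak rule and the interior-gap statistic
  default to the active phase only. Gaps inside the randomly ordered prior
  sample say nothing about the ranker, and a low-prevalence corpus with a
  30% prior would otherwise register large prior-phase gaps that no ranked
  screen exhibits; `scope = "full"` is available for sensitivity analysis.
* **Gap off-by-one**: the reported statistic is the gap `g` itself (as the
  study tables print it); the provably safe streak threshold is `g + 1`,
  and the two are labelled distinctly. A threshold of `g + 1` can still
  fire before the first relevant record if the leading irrelevant run is at
  least that long — the exact per-run safe threshold is
  `max(leading run, g) + 1`, which the test suite checks against a
  brute-force scanner.
* **Count rule with `R_hat = 0`** fires immediately (stop index 0, recall
  0): a sample with no relevant records extrapolates to "nothing to find".
  The outcome is recorded, not repaired.
* **SD** is the sample standard deviation (n − 1). At 1,000 replicates the
  distinction from n is negligible; the choice is frozen for
  reproducibility.
* **Pooled rows**: the `Total` row of the relative-error table pools all
  runs rather than averaging per-dataset means, so datasets with equal
  replicate counts contribute equally and the row is a genuine grid-level
  statistic.
* **Seeding**: replicate `k` of fraction `j` of dataset `i` runs under
  `mix_seed(base_seed, i, j, k)` (a multiplicative-congruential hash into
  `[1, 2^31 - 2]`), so any cell can be recomputed in isolation and
  interrupted grids resume without replaying completed cells.
* **Grid scale**: the full study design (5 datasets × 7 prior fractions ×
  1,000 replicates = 35,000 runs) is pure configuration. The bundled
  demonstration grid uses 2 synthetic datasets × 3 fractions
  (1%, 10%, 30%) × 20 replicates at `N = 500` — the scale at which the
  package's own tests and acceptance script exercise the complete pipeline
  in minutes while still reproducing the study's qualitative findings: the
  count estimate is almost never exactly right, the workable streak
  threshold differs by an order of magnitude between prevalence regimes,
  and no fraction threshold comfortably below the worst run achieves full
  recall on every run.

# Known limitations

Only the default naive-Bayes/TF-IDF pipeline is simulated; alternative
classifiers, feature sets and query strategies are out of scope, as are
reference-list snowballing, dual-reviewer error modelling and
statistically guaranteed stopping rules (e.g. hypergeometric-confidence
stopping) — the latter are the natural next step this package's trajectory
format is designed to support.

```{r}
library(screenstop)
co <- generate_corpus(synthetic_spec(N = 500, prevalence_pct = 7.6, seed = 1))
tr <- simulate_screening(co, f = 0.10, seed = 7)
trajectory_stats(tr)
```
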