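---
title: "Detecting emerging injury issues from EMS narratives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emerging injury issues from EMS narratives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurymine)
```

# The problem

Injury surveillance systems aggregate structured fields (cause codes,
demographics), but the free-text narrative a paramedic writes after each
ambulance response carries information about injury mechanisms that
structured fields miss — and it carries it *early*, before a new hazard is
common enough to earn its own code. `injurymine` implements a pipeline that
screens roughly a decade of such narratives for terms whose usage pattern
signals an emerging injury issue, and then maps the semantic context of the
highest-risk terms.

The pipeline has four stages:

1. **Preprocess** — tokenize narratives, build one term–document matrix per
   year, and drop terms appearing in fewer than `min_df = 10` incidents in
   that year. The DF threshold reflects the safety-management heuristic that
   about ten minor events precede one major one: a term attached to ten or
   more incidents in a year is a pattern, not an isolated event.
2. **Importance** — score each retained term per year by TF–IDF and keep the
   top `top_k = 300` terms by average annual weight as *candidate injury
   keywords*.
3. **Categorize** — summarize each candidate's yearly document-frequency
   trajectory by three indicators (average frequency, average acceleration,
   relative volatility), convert each to a 1–5 quintile score over the
   candidate pool, and assign categories by fixed score rules.
4. **Network** — around the *hazardous* keywords, build a phi-coefficient
   co-occurrence network, extract the ego network, filter weak links, and
   decompose it into Louvain communities.

# Term importance

Within a year with $N$ documents, for term $t$ and document $d$:

$$\mathrm{TF}_{t,d} = \frac{n_{t,d}}{\sum_{t'} n_{t',d}}, \qquad
  \mathrm{IDF}_t = \ln \frac{N}{\mathrm{DF}_t}, \qquad
  \mathrm{TFIDF}_t = \Bigl(\max_d \mathrm{TF}_{t,d}\Bigr)\,\mathrm{IDF}_t .$$

Two conventions matter:

* **Max-TF.** A term has one weight per year, computed from its most
  TF-intense document. This favors terms that dominate at least one
  narrative over terms diluted across many.
* **TF denominators are frozen before downsizing.** $\sum_{t'} n_{t',d}$
  counts every token the tokenizer produced for the narrative, including
  tokens of terms later removed by the DF filter; removing rare vocabulary
  must not inflate the TF of what remains.

The IDF uses the natural log with no smoothing: a term that passed the DF
filter can never have zero document frequency, and a term present in every
document is annihilated ($\mathrm{IDF}=0$), which is the desired behavior
for boilerplate vocabulary.

**Missing years.** A term absent (or DF-filtered) in some year has no weight
there. The default `zero_fill` policy averages over *all* study years,
counting absent years as zero; the alternative `observed` policy averages
only over observed years. Zero-fill is the default because it never inflates
a term that appeared briefly and vanished — the failure mode that matters
when ranking *emerging* issues. Ties in the ranking are broken
lexicographically after rounding the average to 12 decimals, so the top-300
cut is reproducible across platforms.

# Categorization

Each candidate's trajectory is the zero-filled series of yearly document
frequencies $f_1, \dots, f_Y$ ($Y$ study years). Trajectories are read from
the *raw* per-year matrices, so a year in which the term fell just below the
DF threshold still contributes its true count.

* **Average frequency** $= \sum_y f_y / Y$.
* **Average acceleration**: mean of the first differences
  $f_y - f_{y-1}$ accumulated from the first study year through the year of
  last appearance. The source methodology's description ("incremental
  acceleration accumulated until the year of the last appearance") is
  ambiguous between first and second differences; first differences are the
  default because they reproduce the qualitative facts the indicator is
  used for — declining terms get negative values, fast-growing terms large
  positive ones — while a `second_difference` variant is available via
  `accel_variant`. Trajectories spanning fewer than two years up to the last
  appearance are flagged and scored 0.
* **Relative volatility**: the term's trajectory SD divided by the mean SD
  of all candidates. The ratio discounts the corpus-wide growth of
  vocabulary over time. The population SD (divide by $Y$) over the
  zero-filled window is the default, consistent with the zero-fill mean; the
  sample SD is available via `sd_variant`. The denominator pool is the
  candidate set, not the full vocabulary, because the scores are defined
  relative to the candidates being ranked.

Each indicator is mapped to a quintile score: percentile rank $r/n$, score
$\lceil 5r/n \rceil$, so the top 20% score 5. Ties share the score of their
mean percentile rank; a fully tied column maps to the middle band, 3. Bands
are computed over all candidates *before* stoplist exclusion (exclusion is a
keyword-selection step, not a re-ranking step); excluded terms keep their
scores but receive no category.

Categories are fixed score rules:

| category   | frequency | acceleration | volatility |
|------------|-----------|--------------|------------|
| hazardous  | ≥ 4       | ≥ 4          | ≥ 4        |
| noteworthy | ≤ 2       | ≥ 3          | ≥ 3        |
| diffusion  | ≥ 4       | ≤ 2          | —          |

The rules are mutually exclusive by construction (frequency ≥ 4 vs ≤ 2,
acceleration ≥ 4 vs ≤ 2), which the test-suite verifies exhaustively over
all 125 score triples. Everything else is *unclassified*.

Stoplists (time-of-day, person, body-site vocabularies) ship empty by
default — the synthetic corpora contain none of these — and are supplied as
a named YAML mapping for real-language runs.

# Semantic network

For the sub-corpus of incidents mentioning at least one hazardous keyword,
the DF ≥ 10 downsizing is re-applied, and every term pair supported by at
least `min_cooccurrence = 10` joint incidents gets a link weighted by the
phi coefficient of its $2\times2$ presence table:

$$\varphi = \frac{AD - BC}{\sqrt{(A+B)(C+D)(A+C)(B+D)}},$$

which equals the Pearson correlation of the two binary presence indicators
(verified against that oracle to $10^{-12}$ in the tests). The $D$ cell
(documents containing neither term) is counted against the sub-corpus
total, since the coefficient is computed after sub-corpus selection. Pairs
with a degenerate marginal (a term in all or none of the documents) have no
defined correlation and are skipped with a logged count.

The hazardous keywords are applied as *egos*: the network keeps the egos,
their direct neighbors, and all links among the kept nodes (a 1.5-degree
ego network). Links with $\varphi < 0.05$ — below the conventional "weak
correlation" floor — are then dropped and isolated non-ego nodes removed.
Filtering after ego extraction is the default (`phi_filter_order =
"ego_first"`); the reverse order is selectable. Retained links are banded
weak $[0.05, 0.10)$, moderate $[0.10, 0.15)$, strong $[0.15, 0.25)$ and
very strong $[0.25, \infty)$. Negative-phi links never survive the 0.05
floor, so community detection always runs on non-negative weights.

**Communities.** Louvain modularity optimization runs on the phi-weighted
graph through `igraph::cluster_louvain()`. Because the heuristic is
greedy and order-dependent, `louvain_communities()` performs a fixed number
of restarts (default 10) under seeds derived deterministically from the
user's seed and keeps the best-modularity partition, with ties going to the
earliest restart and community ids renumbered in lexicographic vertex
order. On small graphs (≤ 8 nodes) this reliably attains the exhaustive
modularity maximum, which the tests check against a brute-force enumeration
of all set partitions. An unweighted mode is available via `weighted =
FALSE`. An edgeless graph yields singletons with modularity 0.

# The synthetic corpus generator

No national EMS narrative collection is publicly deposited, so validation
runs on synthetic corpora with planted ground truth. The generator emulates
the *statistical* structure the pipeline consumes — not clinical language:

* Documents are bags of tokens joined with single spaces, so the default
  tokenizer inverts generation exactly and preprocessing is loss-free in
  tests (a round-trip property the suite asserts).
* A **planted trajectory term** of kind $k$ is present in each of year $y$'s
  documents independently with probability
  $p_y = \min\{0.95,\; b\,(1 + g\,(y - \bar y))\,\epsilon_y / n\}$, where
  $b$ is the base rate (expected documents/year), $g$ the relative slope
  centred on the window midpoint $\bar y$ (so the mean rate stays $b$),
  $n$ the incidents per year, and
  $\epsilon_y = \exp(\sigma Z_y - \sigma^2/2)$ a mean-one lognormal year
  effect that injects volatility without moving the mean. Kind defaults
  (at the default scale of 200 incidents/year): hazardous
  $b=60, g=+0.18, \sigma=0.4$; noteworthy $b=12, g=+0.15, \sigma=0.4$;
  diffusion $b=60, g=-0.15, \sigma=0.08$; flat $b=30, g=0, \sigma=0.08$.
  These realize the intended signatures: hazardous terms are frequent,
  fast-growing and volatile; noteworthy terms rare but rising and volatile;
  diffusion terms frequent but declining.
* **Background vocabulary** (`bg0001`, …) fills documents with presence
  rates declining geometrically from 14% to 5% of documents, rescaled so
  the expected background tokens per document equal `doc_length_mean`. The
  defaults (200 background terms, mean 17 background tokens) keep the
  candidate pool below the top-300 cut at the default corpus scale, so
  every planted term is assessed; narrative length carries no signal in
  this design, and the default is chosen for test power, not linguistic
  realism.
* **Planted co-occurrence blocks** cannot be realized by independent
  Bernoulli terms: independence forces the between-block co-occurrence to
  the product of marginals, which is inconsistent with targets like
  within 0.3 / between 0.02. Instead each document is assigned uniformly to
  one of the $B$ blocks; members of the assigned block are present with
  probability $s$ and members of other blocks leak in with probability $v$,
  solved from
  $$\text{within} = \tfrac{s^2}{B} + \tfrac{(B-1)v^2}{B}, \qquad
    \text{between} = \tfrac{2sv + (B-2)v^2}{B}$$
  by fixed-point iteration (for $B=3$, within 0.3, between 0.02:
  $s \approx 0.95$, $v \approx 0.03$). Infeasible targets raise an error
  naming the constraint.
* **Determinism**: one integer seed drives the corpus; per-year substream
  seeds are drawn once from it, so the same spec and seed give
  byte-identical corpora.

What passing the recovery tests shows — and does not show: the pipeline
correctly identifies trajectory and co-occurrence structure *when it is
present at the planted effect sizes*, under clean tokenization. It says
nothing about morphological analysis quality, OCR noise, spelling variation
or category prevalence in real narratives, all of which sit upstream of
this machinery (the tokenizer is pluggable for exactly that reason).

# Validation problem sizes

The validation corpus used by the test-suite and the acceptance script is
10 years × 200 incidents/year with 30 planted terms per trajectory kind and
three 6-term blocks — large enough that binomial noise does not dominate
the planted signals (the planted-rate checks use 3-SD binomial tolerances),
small enough to run in seconds. Recovery assertions are one-sided (≥ 90% of
planted hazardous and diffusion terms; adjusted Rand index ≥ 0.9 for
blocks) under fixed seeds. Noteworthy terms are intrinsically the hardest
category — rare, so their quintile positions sit near band boundaries — and
their recovery is reported but not gated; that mirrors their real-world
interpretation as terms whose trend is genuinely uncertain.

# Known limitations

* The default tokenizer is a language-agnostic word splitter. Korean
  narratives need a morphological noun extractor registered via
  `register_tokenizer()`; results on agglutinative languages with the
  default tokenizer are not meaningful.
* The acceleration indicator is scale-dependent (documents/year), so
  categories from corpora of very different sizes are not comparable
  without re-banding.
* Quintile banding makes every category *relative to the candidate pool*:
  a corpus of uniformly declining terms still yields "hazardous" labels for
  the least-declining quintile. Interpretation requires the metric values,
  not only the labels — both are reported.
* Ego-network extraction with many egos can retain a large fraction of the
  vocabulary; the phi floor, not the ego step, does most of the pruning.

# A worked run

```{r, eval = FALSE}
spec <- default_validation_spec(n_per_kind = 30, seed = 1)
corpus <- generate_corpus(spec)
res <- run_pipeline(pipeline_config(records = corpus, seed = 1))
res$summary
table(ground_truth(spec)$category,
      res$assessments$category[match(ground_truth(spec)$term,
                                     res$assessments$term)])
```
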