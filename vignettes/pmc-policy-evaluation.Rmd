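---
title: "Checklist-based policy consistency scoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checklist-based policy consistency scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcindex)
```

## The model

A policy document is evaluated against a two-level variable hierarchy:
primary dimensions $X_1, \dots, X_{10}$ (policy nature, effectiveness,
issuing agency, instruments, content, target, evaluation, objectives,
guarantees, disclosure), each decomposed into binary secondary
indicators $X_{t:j} \in \{0, 1\}$ of equal weight. An expert codes each
indicator 1 when the policy involves it and 0 otherwise. The score of a
scored primary is the mean of its indicators,

$$X_t = \frac{1}{T(X_t)} \sum_{j=1}^{T(X_t)} X_{t:j},$$

with $T(X_t)$ the dimension's cardinality, and the consistency index is
the equal-weight sum over the nine scored dimensions,

$$\mathrm{PMC} = \sum_{t=1}^{9} X_t \in [0, 9].$$

The indentation (concavity) index is the complement
$9 - \mathrm{PMC}$: the shortfall from a policy that scores 1 on every
dimension. $X_{10}$ is an indicator-only disclosure flag; it has no
secondary indicators, is excluded from the sum, and is carried as a
per-policy boolean. Grades partition the two-decimal display value:
8.00–9.00 Excellent, 6.00–7.99 Good, 4.00–5.99 Acceptable, below 4.00
Poor, with a parallel four-band classification of the indentation
index at 1.00, 3.00 and 5.00.

The default schema bundled with the package has secondary cardinalities
$(6, 3, 3, 3, 5, 5, 4, 5, 5)$ for $X_1 \dots X_9$ — 39 indicators in
total.

## Numerical choices

Every primary score is a ratio of small integers, so the package does
all index arithmetic on exact integer numerators over a common
denominator (the least common multiple of the cardinalities, 60 for the
default schema). Floating point enters only at display time. Display
rounding is half-up to two decimals, implemented with integer division
so that exact halves round up; base R's ties-to-even `round()` would
disagree on values such as 0.665. Grades are assigned on the rounded
display value because the published bands are themselves written to two
decimals with gaps (7.99 | 8.00).

Ranking sorts by descending exact index; ties break by policy code in
natural (numeric-suffix) order, so P9 precedes P25 at an equal index.

Missing coding cells are errors, never imputed as 0 — a silent zero
would fabricate a score. Values outside $\{0, 1\}$ are rejected with
the offending cell named.

## The bundled 28-policy evaluation set

The package ships a worked evaluation of 28 national medical and
older-adult-care integration policies (2015–2024): metadata (code,
title, publication date in the dotted `YYYY.MM.DD` registry dialect),
a binary coding matrix over the 39 indicators, and the published
per-primary reference scores.

The binary cells are a synthetic reconstruction: the expert coding
sheet itself was not published, so for each policy and primary with
cardinality $m$ and published mean $v$, the first $\mathrm{round}(v
\cdot m)$ indicators are set to 1. This reproduces every published
per-primary mean with one exception. Policy P26's $X_6$ is published as
0.67, which no ones-count over the five $X_6$ indicators can produce
(the reachable values are multiples of 0.2). The value 2/3 — as if the
cell were scored over three indicators — reproduces both the published
0.67 and P26's published index of 4.40 exactly, so the fixture stores
the best binary approximation (3/5) in the matrix and carries an
explicit score override (numerator 2, denominator 3) that
`score_policies()` applies. `validate_coding_means()`, which
deliberately ignores overrides, reports exactly that one cell. The
package does not guess which coding was intended; the override is
labelled as a reconstruction of a printed value.

A second published inconsistency is left unreproduced on purpose: the
pre/post cohort comparison prints group means 6.55/6.40 and SDs
0.77/1.03, but recomputing from the published per-policy indices under
standard conventions gives means 6.60/6.37, and no SD convention
($n$ or $n-1$, rounded or unrounded inputs) recovers the printed SDs.
The cohort module therefore treats only the counts, extremes and
one-decimal medians as reproducible targets; means and SDs are covered
by property tests (partition and order-statistic identities) instead.

## Cohort comparison

`split_by_date()` partitions scored policies at a cutoff date (`pre`
strictly before, `post` on or after; the default comparison uses
2019-12-01, the pandemic onset). `cohort_summary()` reports mean,
median (midpoint of the central order statistics for even $n$), sample
SD ($n-1$ denominator), minimum and maximum, computed on the
two-decimal display values — the scale the published comparison
consumed. A single-member cohort has no dispersion; its SD is reported
as 0 with `sd_defined = FALSE` rather than `NA`, so downstream tables
stay numeric.

## Text mining

The preprocessing pipeline mirrors standard policy-corpus practice:
metadata-line removal (configurable regular expressions for
boilerplate such as document numbers and issuing departments),
tokenization (a pluggable segmenter; the default lowercasing
word-regex tokenizer suits space-delimited text, and a CJK segmenter
can be passed in its place), synonym canonicalisation (e.g. mapping
"mechanism" onto "system"), stopword removal, and ranked frequency
counting truncated to the top $N$ (default 30). Frequency ties break
lexicographically so rankings are deterministic. Synonym
canonicalisation is the only "stemming" performed: the motivating
corpora are Chinese policy texts, which have no inflectional
morphology, so a morphological stemmer would be meaningless.

The co-occurrence network connects two retained terms with weight
equal to the number of windows containing both at least once. The
window is the sentence, split on a configurable delimiter set that
defaults to both CJK and Latin sentence enders (。！？；.!?;). Sentence
windows are a declared default, not an inherited convention — the
choice of window (sentence, paragraph, adjacency) is genuinely open,
and the delimiter set is a config field so other windows can be
emulated. Terms that never co-occur remain isolated vertices, because
a term's absence from the network is itself informative. Graphs are
`igraph` objects and export to GraphML or edge-list CSV.

## The synthetic generators

`synth_corpus()` emulates the statistical shape of a policy corpus —
documents of i.i.d. tokens drawn from a Zipf law over a controlled
vocabulary, with sentence breaks at fixed intervals — and
`synth_coding()` emulates coding matrices with per-primary Bernoulli
fill probabilities, returning the analytic expected index
$E[\mathrm{PMC}] = \sum_t p_t$ alongside the data so tests never
re-derive ground truth from generator internals. The defaults (28
policies, 80-term vocabulary, exponent 1, 400 tokens per document,
fill 0.7) are sized to the bundled evaluation set: 28 documents is the
real corpus size, and fill 0.7 puts the expected index near the
observed mid-6 range.

What the generators do **not** emulate: real policy prose (no syntax,
no topical structure, no CJK segmentation ambiguity), correlated
indicators (real codings are strongly correlated within a dimension),
or drift of coding practice over time. Passing tests on synthetic data
therefore demonstrate counting, scoring and network arithmetic, not
linguistic adequacy of the default tokenizer on real corpora.

Test problem sizes are the package's own choices: oracle equivalence
runs 200 random 10-policy matrices against a nested-loop
reimplementation; Zipf-slope calibration uses a 50 000-token corpus
and checks the top-20 log–log slope within 0.15 of the exponent; fill
recovery uses 1 000 policies within 0.05.

## Visualisation

`surface_matrix()` arranges the nine primary scores row-major in a
3×3 grid ($X_1 X_2 X_3$ / $X_4 X_5 X_6$ / $X_7 X_8 X_9$); the surface
diagram is this grid rendered as a 3-D sheet, concave where the policy
is weak. The sheet is bilinearly interpolated to a 30×30 grid before
rendering — purely cosmetic smoothing, configurable, never applied to
scores. Renders use fixed perspective settings so identical inputs
give byte-identical files; tests assert smoke and determinism only,
since pixel content is renderer-dependent. The radar chart plots the
nine column means on $[0, 1]$ axes without renormalisation.

## Worked example

```{r example}
fix <- integration_policies()
scores <- score_policies(fix$coding)
head(scores$results[, c("rank", "code", "pmc_display", "grade",
                        "indentation_display")])
round_half_up(scores$column_means, 2)
compare_cohorts(scores, "2019-12-01")
```

## Known limitations

* Equal weights are an assumption of the model, not a finding;
  alternative weighting (MCDA, Delphi) is out of scope.
* The binary coding step itself is expert judgement and is an input
  here, not computed: the package validates and scores codings, it
  does not produce them from text.
* The bundled coding matrix is reconstructed from published means; it
  matches them cell-for-cell (one overridden cell) but is not the
  original coding sheet, and different bit placements with the same
  ones-counts are indistinguishable to the index.
* The default tokenizer does not segment CJK text; supply a segmenter
  for such corpora.
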