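---
title: "Measuring lexical alignment in dyadic conversation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lexical alignment in dyadic conversation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadalign)
```

## The measurement problem

When two people talk, they gradually calibrate the words they choose to one
another — pleasantness, concreteness, frequency, length. `dyadalign`
measures this *lexical alignment* from plain transcripts by scoring each
turn on published-style word norms and comparing the two speakers' per-turn
score series. Two constructs are deliberately kept apart:

* **Proximity** — how far apart the two speakers' scores are at each point
  in the conversation, summarized by the area under the absolute-difference
  curve (dAUC). Two people can move in perfect unison yet remain far apart
  (one swears, the other is mild); proximity sees that distance.
* **Synchrony** — whether the speakers *move together* turn by turn,
  summarized by (possibly lead/lagged) correlations. Two people can sit at
  identical mean levels without ever responding to one another; synchrony
  sees that absence.

Sham (permutation) dyads close the inferential gap between the two: they
preserve each speaker's marginal word use while destroying turn order, so a
real conversation that out-scores its shams on synchrony exhibits genuine
turn-to-turn contingency, not just baseline similarity.

## Pipeline and conventions

1. **Reading** (`read_dyads`). One file per conversation (`.csv` with
   `participant_id`/`text` columns, or `.txt` with `Speaker: utterance`
   lines split on the *first* colon). The filename stem becomes `event_id`,
   kept verbatim. Lines without a colon continue the previous utterance —
   transcripts wrap long turns this way; the choice is logged. Metadata
   columns ride along untouched; collisions with reserved column names are
   errors rather than silent renames. Files are decoded as UTF-8 with a
   logged latin1 fallback.
2. **Turn structure** (`mark_turns`). A turn is a maximal same-speaker run;
   the counter increments at every change of speaker and restarts per
   conversation; `exchange = ceiling(turn / 2)`. Only dyads are accepted:
   any conversation without exactly two speakers is an error naming the
   event. Consecutive rows by the same speaker keep separate rows but share
   a turn — merging happens only at aggregation.
3. **Cleaning** (`normalize_string`, `expand_contractions`, `tokenize`).
   Deterministic and dictionary-driven: lowercase; typographic apostrophes
   to ASCII; zero-width/control characters stripped; hyphens split (this
   maximizes lexicon hits and is logged); all other symbols removed;
   contractions expanded token-wise from a packaged static map that
   includes apostrophe-less variants ("dont"); possessive `'s` stripped
   after expansion; optional lemmatization from a packaged static
   dictionary (irregular verbs and common inflections; unknown forms pass
   through). Stopwords are *flagged, never dropped* at this stage, so raw
   token counts are conserved and retention is well-defined.
4. **Stopword tiers.** Four nested lists: `none` ⊂ `minimal` (articles +
   fillers) ⊂ `default` (adds determiners, adpositions, pronouns,
   auxiliaries, modals, conjunctions, numerals 0–12, greetings/idioms,
   matched as phrases) ⊂ `strict` (adds degree adverbs, light verbs,
   discourse markers). The published lists this emulates are hosted
   externally; ours reproduce the *described* coverage, and exact
   membership is a re-implementation — results that hinge on a specific
   list should supply it via `cleaning_config(stopword_list = <vector>)`.
5. **Norm lookup** (`load_lexicon`, `join_norms`). Exact string left-join
   on the cleaned (post-lemmatization, when enabled) token; 1–3 dimensions
   per analysis. Stopwords and out-of-lexicon words become `NA` — there is
   deliberately no fuzzy matching and no homograph disambiguation (the
   lexicon carries one row per headword, betting on the dominant sense).
   Report `missingness_report()` alongside results.
6. **Aggregation** (`aggregate_turns`). Slot value = unweighted mean of the
   turn's non-`NA` token values (median alternatives are out of scope).
   Series are indexed by *exchange*, one slot per speaker: the exchange
   definition and the lag-1 re-pairing both presuppose exchange-wise
   pairing, and a trailing odd turn leaves a flagged `NA` in the partner's
   final slot rather than silently dropping data.
7. **Missing slots** (`fill_missing`). Edges take the nearest observed
   value; interior runs are linearly interpolated; flags record provenance
   (`observed` / `edge_filled` / `interpolated`) and filling is idempotent.
   When backchannel *removal* is requested instead
   (`drop_backchannel_turns`), fully-`NA` turns are deleted and flanking
   same-speaker turns merged, then turns are renumbered; merging happens
   *before* filling (the alternative order is not distinguishable from the
   published description; this one is documented and tested).

## The indices

With filled series $a_i, b_i$ ($i = 1 \dots n$ exchange slots, $T$ observed
turns):

$$\mathrm{dAUC} = \sum_{i=1}^{n-1} \frac{d_i + d_{i+1}}{2}, \qquad
  d_i = |a_i - b_i|, \qquad
  \mathrm{dAUC_{norm}} = \mathrm{dAUC}\times\frac{50}{T}.$$

Unit spacing on the slot index is a choice (the turn-vs-exchange axis is
not pinned down by the published account); it cancels in any comparison of
like-prepared conversations. The normalization denominator is the observed
*turn* count, per the printed standardization rule, even though $n$ slots
≠ $T$ turns when $T$ is odd. The lag-1 dAUC re-pairs exchanges so the
second speaker precedes the first ($d_i = |a_{i+1} - b_i|$, ends trimmed)
and is normalized by the same observed $T$; the first speaker's label is
reported so directionality can be tracked.

Correlations shift the **first** speaker's series: offset $k$ pairs
$a_{i+k}$ with $b_i$, non-overlapping ends trimmed (no wraparound, no NA
padding). Positive $k$ (lag) emphasizes the first speaker's responses;
negative $k$ (lead) their initiations. Spearman converts both overlap
windows to average ranks immediately before the product-moment step.
Overlaps shorter than 3 slots and zero-variance overlaps yield `NA` with a
warning — never an exception, and never a forced ±1. Conversations under
50 turns trigger a warning at read time; alignment estimates there are
noisy, and the standardization extrapolates rather than interpolates.

## The synthetic world

`simulate_dyad` generates the minimal model with separately tunable global
similarity and turn-wise synchrony:
$a_t = \rho\, a_{t-1} + \varepsilon_t$ (stationary AR(1) leader),
$b_t = \beta\, a_{t-\mathrm{delay}} + \eta_t$ (coupled follower).
Defaults: $n = 200$ slots, $\beta = 0.8$, delay 1, noise sd 0.5 — the
regime the acceptance criteria state. $\rho = 0.4$ is our one free choice:
moderate autocorrelation typical of slowly drifting affective tone, high
enough that leads/lags are distinguishable, low enough that series are not
trend-dominated. The follower's own noise defaults to the shared
`noise_sd`; it is separately settable because the perfect-echo limit
($r \to 1$) requires the follower's noise to shrink *relative to the
leader's variance* — a Pearson correlation is invariant to a common noise
scale, so "noise → 0" on both sides leaves $r$ fixed (≈ 0.74 at the
defaults).

`realize_transcript` turns a series into words by picking, per slot, the
lexicon words nearest the target value, so the whole text path is exercised
end-to-end; the reported quantization error bounds the reconstruction gap.
What the generator does **not** emulate: real lexical statistics (Zipfian
frequencies, topicality, repetition), syntax, disfluencies, unequal turn
lengths, nonstationary coupling, and any relation between dimensions. A
green test therefore establishes the *computational* correctness and
calibration of the pipeline, not that any effect exists in real speech.

The fixture lexicon is generated in code (`build_fixture_lexicon`),
deterministic, and **synthetic**: anchor words are directionally sensible
(high-valence "happy", concrete "dog") and scales match convention
(valence 1–9, concreteness 1–5), but no value is a published norm. The
shipped `lexicon_synthetic.csv` is byte-equivalent to the generator and is
labelled synthetic in name and docs.

## Sham controls

`generate_shams` permutes each speaker's turn order independently within
each conversation, preserving speaker-per-slot structure and per-speaker
turn multisets exactly. Shuffling operates on whole turns (values travel
with their turn), after full preparation — shuffling before backchannel
merging would let the merge depend on the permutation. Each conversation
draws from an RNG stream derived from the master seed and a hash of its
`event_id`, so adding a conversation to a corpus never changes another's
permutation, and the same seed reproduces shams byte-for-byte.

## Numerical and degenerate-input choices

* Trapezoid, interpolation, ranks and correlations are plain double
  arithmetic; oracle tests pin them to independent routes at 1e-10.
* Ties in Spearman take average ranks.
* An all-`NA` speaker series is an error naming the event and dimension
  (there is nothing to fill from); a turn emptied by cleaning simply
  contributes an `NA` slot.
* `dauc_raw` needs ≥ 2 slots, `dauc_lag1` ≥ 3; shorter series error with
  "insufficient turns".
* Duplicate lexicon headwords collapse to first occurrence (warned);
  non-numeric cells become `NA` (warned).
* Sample (n−1) standard deviation throughout the analytics table.

## Limitations

Single-word lookup ignores context: homographs and polysemes get the
dominant-sense value; negation ("not happy") is not propagated to the
content word. English only, as shipped. One summary value per conversation
(per offset) — no windowed or time-varying alignment, no change-point
detection, and no multiple-comparison correction across dimensions: choose
few, theoretically motivated dimensions up front. Short conversations
(< 50 turns) and heavily backchannel-laden ones are flagged but not fixed —
treat them as a design problem, not a post-processing one.
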