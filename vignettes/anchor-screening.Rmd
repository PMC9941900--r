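---
title: "Anchor-based screening: model, calibration, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based screening: model, calibration, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorscreen)
```

## The screening model

`anchorscreen` flags short texts (tweets, in the motivating application)
that repeat known false health claims. The supervision signal is not a
labeled training set but a small collection of *anchor quotes*: verbatim
exemplars of misinformation, such as the misleading promotional
statements that FDA Warning Letters quote back to CBD sellers. Both the
corpus and the anchors are mapped to fixed-dimension sentence vectors by
an encoder, and each text is scored by its cosine distance
$d(A, B) = 1 - \frac{A\cdot B}{\lVert A\rVert \lVert B\rVert}$
to each anchor. A text is **captured** by an anchor at threshold $t$
when $d \le t$; for a set of anchors, when its *minimum* distance over
the set is $\le t$ (the union of the per-anchor capture sets).

The model's assumptions are deliberately minimal:

* **Semantic locality.** Texts repeating an anchor's claim lie closer to
  that anchor in embedding space than unrelated chatter. This holds in
  proportion to the encoder's quality; the framework itself is
  encoder-agnostic.
* **Exemplar coverage.** The anchor set spans the claims of interest. A
  claim with no nearby anchor is invisible to the screen — adding anchors
  is the remedy, and is purely a data change.
* **Labels for calibration only.** Annotated data is needed once, to
  choose the operating threshold; screening new data afterwards requires
  no labels.

## Calibration

Capture is monotone in $t$: the captured set at a smaller threshold is
nested in the captured set at a larger one, so recall never decreases
while precision typically decays toward the corpus prevalence. Given a
labeled corpus, `sweep_thresholds()` evaluates every grid point and
`optimal_threshold()` selects the **largest** grid threshold whose
precision is defined and at or above a floor. That rule maximises
capture subject to the precision constraint; an empty capture has
*undefined* precision (`NA`) and is never treated as passing the floor.
`rank_anchors()` orders anchors by the recall achieved at their own
optimal thresholds (ties: precision, then anchor id), and
`pooled_capture()` evaluates a multi-anchor scope by minimum distance.
Recall is always counted against the corpus-wide number of labeled
positives, also for single-anchor scopes; per-anchor recalls are
therefore comparable and sum-bounded by the pooled recall.

Tunable parameters, with defaults:

| Parameter | Default | Meaning |
|---|---|---|
| `grid` | 0 to 1 by 0.001 | cosine-distance thresholds evaluated; distances are unitless in $[0, 2]$, and in $[0, 1]$ for non-negative encodings |
| `precision_floor` | 0.80 | minimum acceptable share of true misinformation in the capture set — a standard operating point for screens feeding human review |
| `top_k` | 5 | anchors shown in the ranked table |
| `exemplar_k` | 2 | nearest/farthest texts reported per anchor |

## Encoders

The **reference encoder** is a bag-of-words count vectorizer over an
explicit, lexicographically sorted vocabulary (lower-casing, splitting on
non-alphanumerics), L2-normalized. It is a pure function of its inputs —
repeated calls are bit-identical — and collision-free, so cosine values
have closed forms: two texts sharing $k$ distinct tokens out of $m$ and
$n$ have similarity $k/\sqrt{mn}$ when tokens are unrepeated. Every
numerical claim in the test suite is checked against such closed forms or
against brute-force recomputation.

The **external adapter** (`encoder_config(backend = "external",
encode_fn = ...)`) wraps any production sentence encoder exposing
*character vector → numeric matrix*; the documented target is a
transformer sentence model with 768-dimension vectors. The adapter must
return one finite row per input text in input order; violations raise
errors rather than silently degrading. No model weights are bundled or
required by the tests — the adapter contract is verified with a mock.

A text whose tokens are all out-of-vocabulary encodes to a zero vector.
It is *kept* (a screen must not silently lose records), flagged with a
warning, and assigned similarity 0 — distance 1 — to every anchor.

## The synthetic corpus generator

Real annotated tweet corpora of this kind are generally not
redistributable, so validation runs on synthetic corpora whose relevant structure is planted
and therefore known. `synthetic_config()` describes a corpus with:

* `n_pos` misinformation texts and `n_neg` background texts (defaults
  190/810: a 19% minority positive class, the prevalence regime the
  screen is designed for);
* 27 auto-generated anchors, each with a distinctive claim vocabulary of
  15 token types; positives are assigned to anchors round-robin and draw
  each token from their anchor's token multiset with probability
  $\theta$ (default 0.9) and from a 500-type background vocabulary
  otherwise; negatives draw purely from the background;
* 3 simulated annotators, each flipping the ground-truth label
  independently with probability $\varepsilon$ (default 0.02, giving
  majority-label error of order $3\varepsilon^2$);
* Poisson(12) text lengths (minimum 3) and timestamps uniform over
  2020-01-01 to 2021-04-28, the collection window typical of a pandemic
  tweet corpus.

By default the anchors' claim vocabularies are disjoint from the
background vocabulary: separation is *planted*, so a calibrated
threshold has a genuine margin and transfers to fresh corpora from the
same configuration. This is the regime the generator is for —
end-to-end validation of tokenization, encoding, distance, and
calibration with known ground truth. The `anchor_bg_mix` knob blurs
anchors into the background chatter; as it grows, the precision curve
decays smoothly through any floor, the largest-feasible-threshold rule
lands on a knife edge, and calibration ceases to transfer. That failure
mode is worth studying, but it is a property of weak separation, not a
default testing condition.

What the generator does **not** emulate: real tweet language (hashtags,
handles, spelling noise), bursty topical dynamics, bot duplication,
correlated annotator errors, and — most importantly — the soft semantic
gradient of a real embedding model, where near-misses and paraphrases
populate the distance range continuously. Passing the synthetic suite
therefore shows the *machinery* is correct (metrics, monotonicity,
threshold selection, determinism), not that any particular encoder will
achieve any particular precision on real data; that depends on the
encoder and anchors chosen.

`recovery_experiment()` is the validation harness: for each of (by
default) 20 train seeds it generates a corpus, calibrates the pooled
threshold at the floor, and evaluates that threshold on freshly
generated held-out corpora, holding the anchor set fixed across all
corpora as a deployment would. `glance()` summarises feasibility, mean
held-out precision/recall, and the fraction of seeds whose held-out
precision meets the floor. Infeasible calibrations are recorded as
`NA` rows, not errors.

## Numerical conventions

* Capture is **inclusive** (distance $\le t$), so grid endpoints are
  exact and the endpoint of the default grid always captures the full
  corpus under the reference encoder.
* Distances are computed in double precision as $1 - A_u B_u^\top$ on
  unit-normalized rows, clamped to $[0, 2]$ against sign noise of order
  machine epsilon; equality with the naive per-pair loop is tested to
  $10^{-12}$.
* Report percentages round **half-up** to 1 decimal (so 18.999…% prints
  as 19.0, 0.34435 as 34.4); exemplar distances render at 6 decimals,
  half-up. Base R's round-half-even is deliberately not used for
  report rendering.
* Ranking ties break deterministically: by text id in exemplar reports,
  by precision then anchor id in anchor ranking.
* Majority votes require an odd number of votes; ties are rejected, not
  broken, since a 3-annotator design cannot produce them.
* Intercoder agreement is the fraction of records with fully unanimous
  votes — the simplest statistic consistent with a single quoted
  agreement percentage. The mean-pairwise-agreement alternative reads
  differently on split votes; with 3 annotators a record is either
  unanimous (pairwise 1) or 2–1 (pairwise 1/3), so the two are related
  by an affine map and neither is testable against the other without
  per-record data.
* The generator is a pure function of its config and seed: RNG kind is
  pinned (Mersenne-Twister, rejection sampling) and the caller's RNG
  state is restored.

## Design choices on open points

* **Multi-anchor curves.** Both readings of a multi-anchor analysis are
  provided: per-anchor curves overlaid (the default `autoplot()`
  rendering) and a pooled minimum-distance scope (`pooled = TRUE`,
  `pooled_capture()`). Pooled recall dominates every member anchor's
  recall at the same threshold; the overlay preserves per-anchor
  attribution.
* **Duplicates.** Exact duplicate texts are retained by default —
  re-posted spam is signal for a screen — with `dedup_text = TRUE`
  available where duplicates would distort calibration.
* **Preprocessing.** The reference encoder folds case and nothing else;
  the adapter path passes raw text through untouched, since transformer
  encoders handle their own normalisation. The n-gram module, whose job
  is descriptive rather than geometric, additionally strips URLs and
  user handles and removes `#` so hashtag words count as ordinary
  tokens.
* **Problem sizes.** The test suite validates on corpora of 50–1000
  texts with up to 27 anchors and the recovery experiment on 20 x 2
  corpora of 500 texts; at these sizes exact dense distance computation
  is instantaneous, which is why no approximate nearest-neighbour
  indexing is provided or needed for corpora in the thousands.

## Limitations

The screen inherits the anchor set's blind spots and the encoder's
biases; it measures semantic similarity, not veracity, so a tweet
*debunking* a claim can sit close to the claim's anchor (the
nearest-exemplar reports exist precisely to audit this). Calibration
assumes the labeled corpus and the screening stream are exchangeable;
topic drift moves the precision curve and warrants recalibration.
Agreement and majority-vote helpers assume annotators are independent
and interchangeable.
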