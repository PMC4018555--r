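---
title: "Learning grammatical constructions with echo state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning grammatical constructions with echo state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnlang)
```

## The model

Both models in this package are leaky echo state networks: a fixed random
recurrent network (the *reservoir*) driven by the input sequence, and a
linear *readout*, the only trained component. The state update is

$$x(t+1) = (1-\alpha)\,x(t) + \alpha\,\tanh\!\big(W_{res}\,x(t) + W_{in}\,u(t+1)\big),$$

from the all-zero initial state, with readout $y(t) = W_{out}\,[x(t);1]$.
$W_{res}$ is standard-normal and rescaled to a prescribed spectral radius;
$W_{in}$ is fully dense with entries $\pm$ *input scaling* (a two-valued
choice with probability 1/2 each; a uniform alternative is available via
`win_dist = "uniform"`). The leak rate $\alpha$ sets the integration time
constant $1/\alpha$. The readout is fitted in one shot by least squares over
all time steps of all training sequences — the Moore–Penrose pseudo-inverse
(minimum-norm) solution at `ridge = 0`, or ridge-regularized normal
equations otherwise. Because states are bounded by the $\tanh$ and the leaky
convex combination, every activation stays strictly inside $(-1, 1)$.

The linguistic assumption is that a *grammatical construction* — a pairing
of a sentence's surface form with its meaning — is identified by the ordered
pattern of closed-class (function) words alone. Every open-class (content)
word is replaced by a generic `SW` marker before the network sees the
sentence, and pushed onto a FIFO working memory. The network therefore never
sees content-word identity; after decoding, roles are re-bound to the FIFO.
Two consequences are load-bearing:

* *Surface invariance*: sentences with the same token pattern are the same
  input. Generalization to new content words in a known construction is
  exact by construction.
* *Construction functionality*: a corpus is learnable without error only if
  each surface pattern maps to a single role assignment. Where two
  assignments compete, least squares favors the more frequent one and the
  minority reading is lost — the behavior probed by the ambiguity tests.

## Comprehension (action performing)

A sentence is tokenized (lowercased, whitespace-split, punctuation stripped
except a terminal "." when the lexicon contains one), reduced to its
grammatical form, and coded one-hot, one time step per token with no
inter-word gap. Sentences are left-padded to the longest sentence of the
session so the final meaning is always read at the same last step, and a
short end-of-sentence pause (`pause_len`, default 1 step) marks completion.
The meaning is a 6 × 3 × 2 grid: up to six content words, three roles
(predicate, agent, location), up to two actions in *execution* order. The
teacher clamps the active cells to 1 from the first word of the sentence
through the end of the pause — clamping from onset is what produces the
predictive, any-time readout trajectories. Decoding thresholds the final
readout at 0.5, then keeps the maximal surviving role per (word, action)
(ties break toward the lowest role index); an action is emitted only if a
predicate cell survives, and argument cells without a predicate raise an
*incomplete meaning* flag that evaluation counts as an error rather than a
crash. Defaults are 100 units, $\alpha = 1/6$, spectral radius 1, input
scaling 0.75, giving input dimension $|\text{lexicon}| + 1$ and output
dimension 36.

Repeated content words bind left-to-right: each meaning word consumes the
first unconsumed FIFO occurrence and falls back to re-using the first
occurrence once all are consumed. This one rule covers ordinary repetition
("grasp the circle and grasp the cross"), repetition markers ("point the
cross **twice**" — one surface verb, two predications), and anaphora ("grasp
the circle and then point to **it**").

## Production (scene description)

The inverse mapping: a coded meaning (the same 36-cell grid) is presented as
a constant input for the whole trial, together with the canonical /
non-canonical choice which is folded into the coding via four construction
patterns — `SW2(SW1,SW3)`, `SW1(SW3,SW2)`, and their double-relation
variants with a shared agent. The readout is trained to trace the word
sequence: each word a 5-step square wave followed by a 5-step pause, all
teachers padded to the longest sentence, the trailing gap acting as the
final pause. Decoding scans the trace per step for the supra-threshold
maximum, collapses runs of identical winners into one token, and discards
runs shorter than `min_run` (default 2) steps as noise — clean teachers
survive `min_run` up to the word length. The i-th decoded `SW` marker is
replaced by the i-th FIFO word; a count mismatch is a *malformed
production*. Defaults are 500 units, $\alpha = 0.75$, spectral radius 2,
input scaling 0.01 — a near-autonomous regime in which the tiny constant
input selects among rich internal trajectories. Output dimension is 7 (six
closed-class words including an optional terminal ".", unused by the
default templates, plus the marker).

Only the four trained construction shapes are supported on the meaning side;
production generalization to unseen construction patterns is out of scope
here, so the tests probe recall and the re-use of trained patterns with new
content words.

## The synthetic corpus generators

`generate_ap_corpus()` emulates the structure of a multi-subject command
corpus: a fixed behavior inventory (default 5 single and 33 double actions,
as if all subjects watched the same movie) described by each of 5 subjects
in a simple and an elaborate style — 380 pairs. The frozen template
inventory covers fronted locations, politeness fillers ("please", "could
you", "i want you to"), chained doubles ("and", "then", "and then"),
repetition ("twice", "two times"), anaphoric "it", and the temporal
constructions: sentence-initial "before" and verb-medial "after" invert
execution order relative to surface order; sentence-initial "after" and
verb-medial "before" preserve it. Meanings are annotated in execution
order. Closed-class lexicons are extracted from the corpus by exclusion
(every sentence word that never appears in a meaning), the same rule one
must use on transcripts where the function-word inventory is unknown.

Two generator choices deserve justification:

* **Template balance.** Templates are assigned in balanced blocks within
  each (style, behavior-type, argument-shape) stratum, using at most
  ⌊stratum/3⌋ of the applicable templates, so every emitted construction
  recurs at least three times. A construction with a single exemplar is
  untestable under leave-one-out; balance makes the generalization protocol
  measure the model, not sampling accidents.
* **Word-disjoint independent doubles.** The two actions of an independent
  double behavior share no word. A shared word would make left-to-right
  FIFO binding inconsistent with surface order under the *inverted*
  temporal constructions, silently creating a one-form/two-meanings
  ambiguity. Word sharing is instead exercised deliberately by the
  repetition and anaphora constructions, which are chronological and bind
  consistently.

Optional knobs reintroduce real-transcript messiness on demand:
`distractor_rate` adds role-less "on my *location*" phrases (the classic
source of construction ambiguity against "put ... on my *location*"), and
`illformed_rate` injects pairs whose meanings use out-of-vocabulary
predicates, which `codable_pairs()` filters the way unprocessable
transcript sentences are removed before evaluation.

What the generator does **not** emulate: speech-recognition noise,
subject-specific idiolects beyond template choice, gerund constructions
(a gerund is closed-class by exclusion, so a meaning predicate realized only
as a gerund would be unbindable), and genuinely novel constructions absent
from the inventory. A clean generated corpus is therefore *learnable by
construction*; passing tests on it validate the machinery (coding,
training, decoding, protocols), not robustness to natural speech.

`generate_sd_corpus()` emits spatial-relation scenes in both sentence
forms. One coded meaning must map to one surface form, so the canonical
single-relation frame is fixed to "the X is to the R of the Y" (the frame
also used by the double relations), rather than the shorter "the X is R of
the Y" variant; supporting both for the same coded meaning would make the
production target one-to-many.

## Evaluation protocols

`learnability_test()` trains and tests on the same corpus: a sentence that
cannot even be memorized is an outlier or part of an ambiguous construction
set, and the learnability error is the floor for generalization.
`leave_one_out()` retrains with one pair held out per fold, padding
computed over the full session (the deployed situation: a trained system
receives one new sentence). Both run over `n_instances` reservoir
instances, instance *i* seeded with `base_seed + i`; reports carry
per-instance rates, their mean and sample standard deviation, and the
"best" (common-failure) error — the fraction failing in *every* instance,
an oracle combination of instances. Per-category cells (style ×
action count) report the same statistics plus the single best instance per
cell, covering both readings of a per-category "best".

A pair fails if decoding raises any failure signal or the decoded meaning
differs anywhere from the annotation (position-by-position, in execution
order); no partial credit.

## Numerical choices

* Pseudo-inverse via SVD with tolerance `max(dim) * eps * max(singular
  value)`; rank-deficient systems get the minimum-norm solution rather than
  an error.
* Leave-one-out reuses reservoir states across folds (states are
  independent of the training subset) and solves each fold by downdating
  the Gram matrix ($G - X_i^\top X_i$) with a Cholesky solve, falling back
  to the full minimum-norm retrain when the downdated system is not
  positive definite. Equivalence with naive per-fold retraining is asserted
  in the test suite.
* Spectral-radius rescaling divides by the largest eigenvalue modulus and
  is verified to 1e-6 relative tolerance; a degenerate draw (numerically
  zero radius) is resampled with an incremented seed and a warning.
* Weight generation is deterministic given the seed; readout training is
  pure linear algebra and seed-independent. All computation is double
  precision.
* Decoding order is threshold-then-max, matching the stated decision rule;
  ties break deterministically (lowest role index; first maximum per step
  in word traces).

## Problem sizes

The test suite and the acceptance script exercise: exact-recall corpora of
20 pairs in the interpolation regime (more units than state rows, where the
consistent linear system is solved exactly, so recall is structural rather
than statistical — 300 units for comprehension, 1500 for production);
leave-one-out on a 200-pair corpus with 500 units; and learnability of the
full 380-pair default corpus with 1000 units over two instances. These
sizes were chosen to probe each regime — interpolation, generalization,
memorization at scale — while keeping a complete run in the minutes range
on one CPU. The protocols themselves accept any corpus and reservoir size;
transcript-scale studies (thousands of folds at 1000–3000 units) use the
same code paths unchanged.

## Known limitations

* At most two predications and six content words per sentence; meanings are
  flat predicate–argument structures without nesting or relative clauses.
* The closed/open distinction is given (by lexicon or by exclusion), not
  learned; prosody and speech input are out of scope.
* Production covers the four trained construction shapes and a single
  binary form distinction; no paraphrase sampling or focus selection.
* The "best" statistic is an oracle over instances, not a deployable
  combiner — it upper-bounds what instance combination could achieve.
* One-shot pseudo-inverse training is offline; incremental construction
  learning during an interaction would require recursive least squares,
  deliberately not implemented here.
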