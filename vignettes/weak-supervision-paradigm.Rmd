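---
title: "The weak-supervision text classification paradigm: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The weak-supervision text classification paradigm: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weaktext)
```

## The paradigm

`weaktext` trains clinical text classifiers without hand-labeled training
data. A deterministic rule set λ (the *labeling function*) assigns a weak
label Λ to every document of an unlabeled corpus; documents are mapped to
dense features; a classifier is fitted to the weak labels; and the result is
evaluated on a small gold-annotated test set — against the truth and against
the rules themselves. The interesting regime is where the learned model
*beats its teacher*: embeddings place cue variants the rules never encoded
(misspellings, morphological variants) next to the forms they did encode, so
the classifier generalizes where the rules fall through to their default.

This vignette records the modeling assumptions, the tunable parameters and
their defaults, the design decisions taken where the design was genuinely
open, and what the synthetic experiments do and do not establish.

## The rule engine

A rule set is an ordered list of regular-expression rules, each bound to a
category (or a `keyword`/`modifier` role for co-occurrence rule sets), plus
a precedence order and a default category. Matching decisions:

* **Case-insensitive matching.** The built-in tables mix cases freely in
  real notes ("No smoking", "Fx"); all matching is case-folded.
* **Word boundaries.** Every top-level alternative of a pattern is wrapped
  in `\b…\b`. This prevents `smokers?` from firing inside "nonsmoker" while
  leaving composite printed patterns (internal `\W*`, groups, `?`) intact.
* **Sentence delimiters** are `.`, `!`, `?`, `;` and newline. The semicolon
  is load-bearing for radiology lines such as
  `"R hip inj; fx femur neck nos closed"`, where the keyword/modifier
  co-occurrence must be judged within the post-semicolon segment. Colons are
  deliberately *not* delimiters, so semi-structured lines like
  `"tobacco: no"` stay one sentence.
* **Precedence.** Negation categories are checked first (non-smoker before
  smoker; past before current before non-smoker in the four-way task):
  specific negated patterns subsume the bare keywords they contain, so
  "No smoking after age 40" is non-smoker even though "smoking" alone is a
  smoker keyword. The default category may itself carry patterns (the
  binary smoking task's non-smoker rules), so precedence covers every
  category with rules and the default also serves as the no-match fallback.
* **Co-occurrence.** The fracture rule set labels `fracture` only when at
  least one anatomical keyword and one fracture modifier match *within the
  same sentence*. Permuting sentences never changes the label; moving a
  modifier into a keyword's sentence can only turn a negative into a
  positive.
* **Trochanteric entry.** The printed keyword `(inter|per|intra)
  trochanteric` is compiled with an optional space or hyphen
  (`[ -]?`) by default so that "intertrochanteric" — itself a task keyword —
  is covered; `load_builtin(..., strict_trochanteric = TRUE)` restores the
  literal spaced reading.
* **Defaults.** Binary smoking defaults to non-smoker when nothing fires
  (the stated behavior of the deployed algorithm), fracture to no-fracture,
  and the four-way task to unknown; the latter two follow from the task
  structure (absence of evidence is the majority outcome).

Two printed error-analysis snippets from the source rule tables'
documentation are deliberately *not* regression fixtures: applied to the
printed (ellipsis-truncated) text, the printed rules do not reproduce the
reported outputs ("tobaco" falls through to the default, which is the gold
label; "Tobacco current use: No never used any" contains the bare keyword
"tobacco", and the `\W*` in the negation pattern does not span the
intervening words). The deployed rules or the full notes evidently differed
from what was printed; the package tests only the unambiguous cases.

## Features

* **Mean-pooled embeddings** (the paradigm's deep representation):
  x = (1/M′) Σ xᵢ over the M′ in-vocabulary tokens, default k = 100.
  Out-of-vocabulary tokens are *skipped*, not zero-imputed: skipping
  preserves the feature scale, and an all-OOV document gets the zero vector
  (the neutral element for linear models) plus a `degenerate` flag. The
  tokenizer lowercases and splits on non-alphanumeric runs; punctuation
  belongs to the rule engine, not the featurizer.
* **tf-idf baseline**: `tf(w, d) · (ln((1 + N)/(1 + df(w))) + 1)` with L2
  row normalization — the smoothed form avoids division by zero and is the
  common default where no variant is stated. Unseen words contribute 0 at
  transform time.
* **Topic baseline**: latent Dirichlet allocation with K = 100 topics
  (matching the embedding dimension), symmetric priors α = 50/K and
  η = 0.01, fitted by a seeded collapsed Gibbs sampler implemented in the
  package (150 sweeps by default; all of α, η, K, iterations are
  arguments). The per-document feature is the mean over in-vocabulary
  tokens of the word's topic mixture p(topic | word), so features lie on
  the probability simplex. Dirichlet priors are genuinely hard to pin for a
  given corpus; these are documented defaults, not tuned values.

## Classifiers

Hyperparameters are fixed, not searched: linear SVM with C = 10 (via
e1071/libsvm), random forest with 5 trees (via randomForest), a
single-hidden-layer MLP with 15 rectified-linear units, and a text CNN —
embedding layer initialized from the pre-trained table (trainable by
default; `freeze_embeddings` available), one width-3 convolution with 128
ReLU filters, global max pooling, and a softmax output trained with
categorical cross-entropy and RMSprop. The MLP and CNN are implemented
natively in the package (no installed R package provides these exact
architectures); the CNN's backward pass is validated against numerical
differentiation in the test suite. Sequence length for the CNN is 100
tokens (snippets are short; padding index 0 maps OOV and padding to a fixed
zero vector). Epochs (30), batch size (32) and learning rate (0.01) are
documented defaults, not reported values. Class imbalance is not
reweighted. Seeds are mandatory for every stochastic trainer, and training
is reproducible given (data, spec, seed).

## Evaluation

Precision, recall and F1 come from the confusion matrix; per-class values
are always reported and the aggregate defaults to the micro average (for
single-label tasks micro-P = micro-R = micro-F1 = accuracy — an identity
the tests assert). Zero-denominator cells are 0 with a flag.

The significance test is a paired bootstrap on the F1 difference: the test
set is resampled `n_boot` times (default 1000), the per-resample difference
A − B is computed, and the statistic is the mean difference divided by the
bootstrap standard deviation, referred to a t distribution with n − 1
degrees of freedom. The bootstrap standard deviation estimates the sampling
variability of the one observed test set, so it is *not* divided by
√n_boot — doing so would shrink the null rejection threshold without bound
as resamples are added and reject for matched systems almost always. The
calibration is itself property-tested: over 200 simulated pairs of
equal-accuracy systems, the rejection rate at the 5% level must sit within
three binomial standard errors of 0.05.

`disagreement_report()` reproduces the "model right on 5 of 7
disagreements" style of error analysis: it lists exactly the documents
where rules and model differ and tallies which system was right, with
`model_right + rules_right + both_wrong = disagreements` by construction.

## The weak-label theory and its simulator

With m independent rules, rule i correct with probability φᵢ, and uniform
binary labels, the weak label agrees with the truth with probability

q = Πφᵢ / (Πφᵢ + Π(1 − φᵢ)).

The true empirical loss is the ridge-regularized logistic loss; the weak
loss replaces each per-document term by its conditional expectation given
the observed weak label, computed in closed form via q (exact under the
binary/uniform assumptions — no Monte Carlo needed):

q·log(1 + exp(−wᵀf(d)Λ_d)) + (1 − q)·log(1 + exp(+wᵀf(d)Λ_d)).

The gap satisfies |L(w) − L_φ(w)| ≤ c‖w‖ε/2 with ε = |D|^(−1/2), alongside
the norm condition ‖w‖ ≤ 1/(2ρ). `verify_bound()` checks all three pieces
empirically. Two design choices matter:

* **Generative direction.** The conditional expectation in the weak loss is
  over Y given Λ. The simulator therefore derives Λ deterministically from
  the features (Λ = sign(w₀ᵀf), playing the role of a rule set reading the
  document) and draws Y by flipping Λ with probability 1 − q. Under this —
  the theory's own — generative model, the fitted weights depend only on Λ,
  never on Y, so the empirical gap at the fit is a mean of independent
  mean-zero bounded terms and shrinks like ε. Had the simulator generated Y
  from the features and flipped it to get Λ, the conditional-independence
  assumption behind the weak loss would be violated (features carry
  information about Y beyond Λ) and an O(1) population gap would remain —
  a regime the bound does not claim to cover.
* **Feature normalization.** Synthetic feature vectors are L2-normalized to
  ‖f‖ ≤ 1. At any stationary point of the regularized weak loss,
  2ρ‖ŵ‖ = ‖mean gradient of the data term‖ ≤ mean‖f‖ ≤ 1, so the norm
  condition ‖ŵ‖ ≤ 1/(2ρ) is a theorem rather than an aspiration; the check
  in the reports (tolerance 1e-6) guards the optimizer, not the theory.

The optimizer is deterministic full-batch gradient descent with Armijo
backtracking, tolerance 1e-8 on the gradient max-norm, and a 10⁴ iteration
cap; non-convergence is flagged in the report, never silent. The constant c
is always an empirical output ĉ = 2|L − L_φ|/(‖ŵ‖ε), never an input.

The default verification grid — |D| ∈ {400, 1600, 6400}, φ = 0.9, ρ = 0.1,
20 replicates, feature dimension 10 — gives a median gap that falls roughly
twofold per fourfold increase in |D| and a ĉ that fluctuates around 0.1
without trend; it runs in seconds.

## The synthetic-note generator

The generator exists to exercise the paradigm's mechanics, not to fool
clinicians. Its defaults are the study conditions under which every
empirical claim in the package is made:

* **Templates** draw their cue words from the built-in rule tables'
  own keywords plus a deterministic filler vocabulary (200 pseudo-words,
  independent of the seed so separately generated corpora share filler
  tokens). Smoker documents carry one affirmative cue; non-smoker documents
  carry a negated cue, a semi-structured `"tobacco: no"` line (rate
  `p_semi = 0.1`), or no cue at all. With no corruption the matching rule
  set reproduces the gold labels exactly — corruption rates alone control
  rule accuracy.
* **Misspelling operator** (`p_miss`, per cue token): a single-character
  deletion or adjacent swap that never touches the first character (keeping
  variants human-plausible, e.g. tobacco → tobaco) and is retried until it
  matches *no* rule pattern, so a misspelled cue always falls through the
  rules. Rejections are logged; gold labels are assigned before corruption
  and recoverable from the provenance log alone.
* **Cross-sentence splits** (`p_cross`, fracture positives only): the
  keyword and modifier are placed in different sentences, so the
  sentence-scoped co-occurrence rule misses exactly the split documents.
* **Class proportions** default to balanced for the binary tasks and to the
  printed 35/66/36/252 mix for the four-way task, so its imbalance failure
  mode is reproducible.
* **Embeddings**: every lexicon concept gets a random center
  (entries ~ N(0, 1/k), unit-scale norms); each surface form — including
  misspellings — gets the center plus isotropic noise of scale
  `cluster_sd = 0.15`, giving within-concept cosines near 0.98 against
  near-orthogonal between-concept pairs. This emulates the one property of
  pre-trained clinical embeddings the paradigm relies on: corrupted
  surface forms lie near their correct forms.

## Problem sizes and runtime

The test suite and the acceptance script use desk-scale sizes chosen as the
package's own defaults: paradigm runs on 2,000 training / 400 test
documents with k = 100 embeddings, repeated over 10 seeds; the bound grid
above; 10,000 draws for sampler calibration. The full suite runs in about
two minutes on one CPU; the acceptance script in a few minutes.

## What the synthetic experiments show — and what they do not

Passing on synthetic corpora establishes the *mechanics*: the rule engine
implements the printed tables faithfully; the weak-supervision pipeline
reduces exactly to supervised learning when the rules are perfect; under
cue misspellings the weak-trained classifier strictly beats the rules that
taught it (because the embedding space is constructed to cluster variants);
and the loss-gap theory behaves as stated under its own generative model.

It does not establish performance on real clinical text. Real notes have
section structure, negation scopes, abbreviation ambiguity and label noise
that the templates do not model; real embedding spaces cluster misspellings
only when the misspellings are frequent enough in the pretraining corpus;
and real rule sets err in ways other than falling through to the default.
One instructive synthetic result: with cross-sentence splits (rather than
misspellings) as the corruption, the mean-pooled SVM does *not* recover —
split documents form their own lexical cluster that is consistently
mislabeled by the rules, so the model learns the rules' error. Weak
supervision repairs noise that is *feature-invisible*; it faithfully
reproduces noise that is feature-visible and systematic.

Other known limitations: the weak-label theory is binary (the four-way task
is handled by the pipeline but not by the bound); negation handling is only
what the printed patterns encode; the CNN's epoch count, batch size and
learning rate are conventional guesses; and the LDA sampler is desk-scale —
for corpora beyond tens of thousands of tokens a compiled implementation
would be preferable.
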