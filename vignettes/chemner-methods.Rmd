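---
title: "Models and methods behind chemner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models the package implements, the assumptions
they make, the parameters worth knowing about, and the design decisions
taken where more than one reasonable choice existed. It states no numbers
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The task and its encoding

Chemical entity mention recognition is cast as per-token sequence labeling
under the BIO scheme: each token of a sentence receives `B` (first token of
a mention), `I` (inside) or `O` (outside). Mentions are character spans in
a section (title and abstract are separately indexed, 0-based, half-open),
and the package treats offset faithfulness as a hard invariant: every
decoded mention's text must equal the source substring at its offsets. The
tokenizer therefore never normalizes text — it only splits — and
`realign()` verifies (or re-establishes) offsets against the original
section before post-processing. An optional typed label alphabet (one B/I
pair per entity class, 17 labels) is available behind
`training_config(typed = TRUE)`; the default is the untyped 3-label scheme,
since span-level evaluation ignores the class.

### Preprocessing

Sentence splitting and tokenization are deliberately rule-based and
deterministic. A sentence boundary requires `[.?!]` followed by whitespace
and an uppercase letter or digit, vetoed by a small abbreviation guard
(`et al.`, `i.e.`, single capitals, ...). Tokenization splits on
whitespace, then isolates punctuation as single-character tokens — hyphens
included, so `N-acetyl-L cysteine` yields six tokens — with one exception:
`.` and `,` flanked by digits stay inside their token, keeping decimals
(`7.4`) and locants (`1,2`) whole. Greek letters and other non-ASCII
characters remain attached to their word and no Unicode normalization is
applied, because any rewriting would break the offset invariant. Rule-based
tokenizers lose mentions whose gold boundaries fall strictly inside a
token; such mentions are labeled whole-token with a warning. On the
synthetic corpus this never happens by construction; on real text it bounds
attainable recall.

## Features

All features are binary presence features, namespaced by family, with set
semantics — the standard shape for linear sequence-model templates. The
seven families:

* **bow** — uni/bi/trigrams of lowercased tokens over a `[-2, 2]` window;
  out-of-range positions contribute a boundary symbol `<s>` so feature
  structure is position-stable near sentence edges.
* **ortho** — sixteen word-formation regexes (all-caps, digit patterns,
  dashes, Roman numerals, case mixtures), evaluated verbatim on the raw
  token.
* **morph** — prefixes/suffixes of lengths 2–5 (emitted only when the token
  is long enough) plus the `A/a/0/x` word shape and its run-collapsed form.
* **pos** — the same windowed n-grams over POS tags. The tagger is
  pluggable; the bundled fallback is a deterministic heuristic cascade
  (closed-class word lists, suffix rules, digit/punctuation classes). It is
  not a linguistic tagger, and a real tagger can be passed as a function.
* **struct** — a single "token is in the title" flag.
* **domain** — chemical-name affix tables (20 prefixes, 11 suffixes), the
  118 element symbols and names, and any user-supplied one-term-per-line
  lexicons.
* **wr** — discrete features from unsupervised word representations, below.

Bag-of-word features are lowercased; orthographic and morphological
features see the raw token, since case is the information they encode.

## Word representations

Three models train on unlabeled, whitespace-tokenized, lowercased text and
expose *discrete* per-word features (raw vectors are exportable but never
fed to the taggers):

* **Brown clustering** — greedy agglomerative merging of word clusters
  maximizing the average mutual information of adjacent-cluster bigrams,
  with the classic frequency-sorted merge window: the `n_clusters` most
  frequent words seed singleton clusters, remaining words enter one at a
  time, and after each insertion the least-harmful pair merges. All merges
  form a binary tree; a word's feature is its bit-path prefix at lengths
  4, 6, 10 and 20 (shorter paths emit what exists). Merge ties break on the
  smallest contained word id, making training deterministic. The greedy
  step is tested against brute-force enumeration for small vocabularies.
* **Random indexing** — each word gets a fixed sparse ternary index vector
  (`k` nonzeros, balanced `±1`, seed-generated); a word's context vector is
  the sum of neighboring words' index vectors over all its occurrences
  within the window. The construction is exactly linear in the corpus,
  which the tests exploit.
* **Skip-gram** — negative-sampling objective, plain SGD over all
  (center, context) pairs, noise words drawn from the unigram distribution
  to the 3/4 power. The per-pair loss/gradient is exposed separately
  (`sg_pair_loss_grad`) and checked against central finite differences.

Random-indexing and skip-gram vectors are discretized by k-means (fixed
seed, capped iterations); features are cluster ids. Defaults — Brown 100
classes; RI `d = 100, k = 8`, window 2; skip-gram `d = 50`, window 5, 5
negatives, 5 epochs, constant learning rate 0.025; 50 k-means clusters —
are sized for desk-scale corpora of a few hundred documents. Out-of-vocabulary
words emit an explicit `UNK` feature per model rather than nothing, so the
tagger can learn that unknown-to-the-WR-corpus is itself informative.

## The two learners

Both share one linear parameterization (emission weights per feature and
label, transition weights per label pair) and the same inference code.

**CRF.** Negative conditional log-likelihood plus `0.5 * l2 * ‖θ‖²`,
minimized by L-BFGS (`stats::optim`) from a zero start; gradients are
expected-minus-empirical feature counts from forward–backward. The
recursions run in log space, and — an implementation point that matters for
pure-R performance — in lock step across all sequences, one vectorized step
per position. Default `l2 = 1.0`; the objective is convex, so the optimum
is unique and training is deterministic given data order.

**SSVM.** Margin-rescaled structured hinge objective with
`λ = 1/(C·N)`, minimized by stochastic subgradient descent: per sequence,
loss-augmented Viterbi (Hamming cost folded into emissions) finds the most
violating labeling; updates move weights toward gold and away from the
violator after Pegasos-style scalar L2 shrinkage. Epoch order is shuffled
under the configured seed, the step size decays mildly across epochs, and
the returned model averages the per-epoch weight snapshots — averaging is
what makes the subgradient path stable enough to compare fairly with the
CRF. Defaults `C = 0.1`, 10 epochs. The cutting-plane optimizer of the
classic SVM-for-sequences implementations is intentionally out of scope:
the objective, not the optimizer, defines the model, and the per-epoch
objective trace is recorded so tests can assert the descent trend.

**Decoding and confidences.** Viterbi ties break toward the smaller label
index (`B < I < O`), and a structural mask (on by default) forbids `I` at
sentence start and after `O`; any orphan `I` that still appears (e.g. in
unmasked decoding) is repaired to `B` at span-decoding time. Confidence
scores, which the prediction format requires but the models do not define,
are: CRF — mean forward–backward marginal of the decoded labels over the
mention's tokens; SSVM — logistic-squashed mean per-token flip margin (the
score drop from switching one token's label, neighbors fixed). Both live in
`[0, 1]`; ranking ties break by section then start offset.

## Post-processing

Four deterministic repair rules run in the order 2, 3, 4, 1, then 2 again:
drop mentions with no letters; extend left over an unmatched `)` to the
previous `(` in the source; extend right over an unmatched `(` to the next
`)`; merge mentions where one starts exactly where another ends. Bracket
matching is plain counter balance over parentheses only. Because an
extension can expose a further unmatched bracket, and a merge can in
principle unbalance a span, the cycle iterates to a fixpoint — this is what
makes the whole pass idempotent, which the suite checks on random inputs.
When no matching bracket exists in the source, the mention is left
unchanged. Every modification is logged with its rule id and is dumpable as
TSV for audit.

## Evaluation

Micro precision, recall and F over exact span matches pooled across
documents: `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F = 2PR/(P+R)`. Duplicate
identical predictions are deduplicated before matching; entity type is
ignored unless strict-typed mode is requested; `0/0` denominators yield 0;
percentages are rounded half-up to two decimals. `f_from_pr()` applies the
harmonic mean to already-printed percentage pairs — useful for checking
published tables, with the caveat that a table whose F was computed from
unrounded P/R can disagree with the printed-value recomputation in the last
digit.

## The synthetic corpus

The generator stands in for the (non-redistributable) annotated challenge
corpus. What it emulates: documents with a one-sentence title and 2–4
abstract sentences; eight entity classes mixed in the proportions of a real
annotated training split (about 30% trivial names, 23% systematic, 15%
each formulas and abbreviations, ...); roughly one mention per sentence;
entity surfaces built from the same affix morphology the domain features
know — systematic names as multiplier/size prefix + stem + chemical suffix
with optional `1,2-`-style locants, plural families, element-digit
formulas, capital abbreviations, letter-digit identifiers, two names joined
by `and` for the multi-entity class. Carrier text is a closed list of
common scientific English screened against the chemical affix tables, with
a few cue words (`containing`, `solution`, ...) preferentially flanking
entities so that distributional word representations have a real signal.

A held-out stem list is excluded from labeled training corpora and switched
in (`use_holdout_stems = TRUE`) for test corpora, so held-out evaluation
genuinely probes generalization to unseen chemical cores; the unlabeled
text for WR training always includes all stems, mirroring the situation
where unsupervised text covers vocabulary the annotated set lacks.

What it does not emulate: real PubMed syntax and vocabulary breadth,
annotation-guideline subtleties (nested or discontinuous mentions,
boundary conventions), tokenizer-hostile mentions, class imbalance within
sentences, or OCR/encoding noise. Consequently, passing the recovery tests
shows the estimators and pipeline are correct and learnable signals are
exploited — it does not predict absolute scores on real corpora, where
state-of-the-art systems lose 10–15 F points relative to this corpus's
near-ceiling separability (by design, token-level affix+shape signatures
here leave an empirical Bayes error under 5%).

## Study sizes and protocol

The recovery study used throughout (tests and the acceptance script):
training corpus of 500 documents (seed 42), held-out test corpus of 200
documents (seed 43, held-out stems on), unlabeled WR corpus from 300
documents — all regenerated at run time from the seed. Both learners train
with default regularization; WR variants add all three feature families.
These sizes were chosen once as a desk-scale study a single CPU handles in
minutes. The regularization defaults (`l2 = 1.0`, `C = 0.1`) are
conventional midrange values fixed a priori; `grid_search()` implements the
train/dev tuning protocol for users who want to optimize them on a
development split rather than trust the defaults.

## Numerical choices and degenerate inputs

Log-space forward–backward throughout; `log-sum-exp` guards `-Inf` rows.
L-BFGS stops at a relative function-reduction tolerance of `1e-6` (the
decode is insensitive to tighter optima). Empty documents, empty sections,
sentences of one token, mentions at section boundaries, and all-`O`
sequences are all exercised by tests. k-means falls back to
one-cluster-per-distinct-vector when asked for as many clusters as there
are distinct points. Seeds: every stochastic component (corpus generation,
index vectors, SGD shuffling and negatives, k-means, SSVM epoch order)
takes an explicit integer seed and restores the caller's RNG state.

## Known limitations

* The heuristic POS tagger is crude; plug in a real tagger for real text.
* Mentions crossing token boundaries are labeled whole-token (warned), so
  gold spans not aligned to the tokenizer cannot be predicted exactly.
* The SSVM subgradient optimizer reaches the regularized optimum only
  approximately; it is compared on equal footing with the CRF through the
  shared feature space, not through objective values.
* Brown clustering's merge window makes the tree greedy and
  frequency-biased, as in the classic formulation; it is not a global
  optimum.
* Confidence scores are calibrated only in the weak sense of being
  monotone in the model's own margins.
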