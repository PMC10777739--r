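---
title: "Condition-contrastive pretraining for reaction yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-contrastive pretraining for reaction yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rxnyield` treats a reaction as one string, `reactants>conditions>products`,
with dot-separated fragments inside each segment. Reagents, solvents, and
catalysts are pooled into the middle segment; their roles are carried in
metadata (the condition catalog), not in the string. The anchor
representation is the canonical form: every fragment rewritten by RDKit's
canonical SMILES algorithm and fragments sorted lexicographically (byte
order) within each segment, which makes the map idempotent and gives every
reaction exactly one anchor string.

The encoder is a BERT-style post-layer-norm transformer over the tokenized
string. Tokenization follows the standard SMILES regex convention: bracket
atoms `[...]` are single tokens, `Br`/`Cl` stay intact, `%nn` ring closures
are one token, every other recognized character is its own token, and `>`
is a token, so the three segments live in one sequence. Joining the tokens
reproduces the input byte-for-byte; unknown characters are an error, never
silently dropped. Sequences are framed by `[CLS]`/`[SEP]`, and the final
hidden vector at `[CLS]` is the reaction embedding. `[CLS]` pooling (rather
than mean pooling) follows the reaction-fingerprint BERT lineage this model
extends; it is isolated in one place (`encode()`), so switching the pooling
rule is a local change.

Pretraining has two stages:

* **Stage 1 — masked language modeling.** `round(rate * n_maskable)`
  non-special positions are selected (exact count, not per-token Bernoulli,
  so tests can assert counts); of the selected, 80% become `[MASK]`, 10% a
  random vocabulary token, 10% stay unchanged. The loss is the mean
  cross-entropy of the decoder (tied to the token-embedding matrix) at the
  selected positions.
* **Stage 2 — MLM plus condition-contrastive learning.** For each anchor,
  positives are randomized atom-order re-serializations of every molecule
  (they canonicalize back to the anchor), and negatives replace between 1
  and all condition fragments — count drawn uniformly — with same-role
  catalog entries not already present; reactant and product segments are
  byte-identical to the anchor. The contrastive loss is
  `alpha * sum cos(anchor, negative) + sum (1 - cos(anchor, positive)) / 2`,
  written as a sum over the batch; the stage-2 objective is the exact sum
  of the MLM term and this loss. The anchor embedding in the contrastive
  term comes from a clean (unmasked) forward pass.

Fine-tuning copies the pretrained encoder and trains a small feedforward
head on the `[CLS]` embedding: a sigmoid output for yield regression on the
fractional scale `[0,1]`, or a 4-way softmax over the yield classes
extremely low `[0,30)`, low `[30,50)`, medium `[50,80)`, high `[80,100]`
percent. Bin boundaries are left-closed (50% is medium) with the top class
closed at 100; the source ranges state no boundary rule, so this convention
is declared once here and used everywhere.

## Parameters that matter

* `alpha` (contrastive balance, default 0.02 of the candidate set
  {0.02, 0.05, 1}) — the value with the most stable convergence; it scales
  the push on negatives, whose per-pair term lives in `[-alpha, alpha]`,
  against the positive term in `[0, 1]`.
* `n_pos = 1`, `n_neg = 2` per anchor — counts are not prescribed by the
  task definition; these defaults keep a stage-2 step at five forward
  passes per anchor.
* Masking `rate = 0.15` with the 80/10/10 replacement split — the standard
  masked-LM recipe; the task definition leaves MLM hyperparameters open.
* Architecture defaults 12 layers, 4 heads, hidden 256, max length 512,
  with stage epochs 50 and 10 — the full-scale profile; all tests and
  examples use 1–2 layers and hidden 16–64, which the config takes without
  special-casing.
* Optimization — Adam with linear warmup (10 steps by default), learning
  rate `1e-3` (`2e-3` for the short fine-tuning runs in the tests, where
  few epochs must suffice). The optimizer is a package choice; the source
  method does not state one.
* Meta-learning (`meta_config`) — first-order initialization learning
  (Reptile): 60 episodes, 6 inner Adam steps on support batches of 8,
  inner rate `2e-3`, outer interpolation 0.5. Chosen as desk-scale settings
  that let the initialization absorb the structure shared across
  categories; all are configurable. The category layout (7 data-rich
  classes for meta-training, 5 low-data classes for meta-testing) follows
  the 12-category convention of curated multi-condition yield data.
* Yield-incorporated prior — multiplicative by default:
  `template_prior * expected_yield / 100`, with expected yield the
  probability-weighted bin midpoint (15, 40, 65, 90). Multiplication
  preserves `[0,1]`, is monotone in both arguments, and reduces to the
  template prior at 100% expected yield. How exactly a yield predictor
  should enter a route-search prior is not specified by the source method;
  a weighted-geometric rule ships as the config alternative, and bin
  midpoints are this package's declared mapping from classes to scalars.

## The synthetic corpus

Real multi-condition yield data cannot ship with the package, so the
generator builds corpora with the statistical structure the method relies
on: reaction groups (one reactant pair and product, drawn from a built-in
library of small molecules) whose members differ only in conditions; a
role-keyed condition catalog (reagents, solvents, catalysts — mutually
disjoint, single-fragment SMILES so each condition stays one unit of the
middle segment); additive yields
`clip(group base + sum of per-condition effects + noise, 0, 100)` with the
per-condition effects and noise draws returned as ground truth; a base-yield
distribution skewed toward high yields with a low-yield tail
(`Beta(5, long_tail_skew)` over the configured range); and 12 category
labels with long-tailed sizes. A `deterministic_bins` mode ties the yield
class to one of four marker reagents (sampled 0.08/0.17/0.30/0.45 so
low-yield classes are rare), giving corpora where the class is exactly
recoverable from one condition token.

What the generator does *not* emulate: chemically meaningful
transformations (products are sampled, not derived), correlations between
category and chemistry (labels are independent of the molecules, since the
category assignment of real data comes from an external classifier), and
condition interactions (effects are additive). Passing tests therefore show
that the machinery learns condition-yield structure when it exists and that
the contrastive mechanism behaves as designed — not that the model matches
full-scale benchmark numbers on real reaction data, which require
proprietary corpora and large-scale pretraining.

## Numerical choices and degenerate inputs

* Layer norm uses eps `1e-5`; GELU is exact (`x * pnorm(x)`). Backward
  passes are hand-derived and checked against central finite differences in
  the test suite.
* Padding ids are excluded from attention keys, so a padded sequence yields
  bitwise the embedding of its unpadded content; over-length sequences are
  an error, never truncated silently.
* Cosine similarity of a zero vector is an error (`rxy_zero_vector_error`),
  as is a triplet without positives or negatives, an MLM loss without
  masked positions, and R² of a constant target.
* Group-stratified splitting apportions each group by largest remainder
  (ties broken train, then validation, then test) and then assigns members
  by a seeded shuffle; groups smaller than the number of splits go entirely
  to train. A consequence worth knowing: at 8:1:1 the test split receives
  its first member only from groups of size 7, so small-group experiments
  here use the 6:2:2 ratio.
* Ranking ties break by template prior, then input order; candidates whose
  scoring fails are demoted to the end with the failure recorded, never
  dropped.
* All randomness flows through explicit integer seeds; seeded sections
  save and restore the caller's RNG state. Randomized SMILES are generated
  by RDKit under a per-request seed, so augmentation is reproducible
  end-to-end.

## Open design points, decided here

* "Stratified sampling based on reaction groups" is read as *within-group*
  apportionment (a group can span splits), because the group-size test-set
  protocol selects test reactions by the sizes their groups have in the
  training set — which requires groups to appear on both sides.
* Whether the contrastive loss is averaged over the batch is exposed as
  `reduction` (`"sum_as_written"` default, `"mean"` optional).
* The meta-optimization algorithm is not prescribed by the source method;
  first-order Reptile was chosen over second-order MAML because it needs no
  second derivatives, matches the "optimize the initial parameters" intent,
  and is substitutable behind `meta_train()`.
* Negatives are only the generated condition-replacement strings — no
  in-batch negatives — because the loss indexes negatives per reaction.

## Problem sizes

The shipped tests and the acceptance script run on corpora of roughly
30–100 reaction groups (130–450 records), encoders of 1–2 layers with
hidden size 16–64, two stage-1 epochs, up to three stage-2 epochs, and
4–25 fine-tuning epochs; the paired stage-2 versus MLM-only comparison uses
five seeds. These sizes are the package's chosen toy profiles: large enough
for every mechanism to be measurable (the contrastive cosine gap, marker
recovery, the meta-learning gain), small enough that the whole suite runs
on one CPU in minutes.

## Known limitations

* Reaction conditions carry no stoichiometry, temperature, time, or
  pressure; only reagent/solvent/catalyst identity enters the string.
* The pure-R encoder is intended for method study and small corpora, not
  for pretraining at the scale of millions of reactions.
* The condition-role lookup during negative generation falls back to
  any-role replacement (with a warning) when a condition is not in the
  catalog; role fidelity is only as good as the catalog.
* Checkpoints are R serializations tied to this package's parameter layout;
  there is no interchange format for weights from other implementations.
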