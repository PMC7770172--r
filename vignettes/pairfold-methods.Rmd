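---
title: "Methods: score-matrix RNA folding with hard constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score-matrix RNA folding with hard constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairfold)
```

## The problem and the representation

An RNA secondary structure is the set of base pairs a sequence forms by
folding on itself. `pairfold` represents a structure as a symmetric N×N
0/1 pairing matrix with zero diagonal and row sums at most one. Unlike a
single dot-bracket string, the matrix representation expresses crossing
pairs — pseudoknots, pairs (i, j) and (k, l) with i < k < j < l — without
any extra machinery, and it makes structure comparison a cell-wise
matrix comparison. The package still reads and writes dot-bracket for
display, using additional bracket tiers (`[]`, `{}`, `<>`, `Aa`…) for
crossing pairs, assigned greedily by ascending opening index.

## Network

The score network maps a sequence to a symmetric N×N real matrix S whose
entry (i, j) scores the propensity of bases i and j to pair.

* **Input encoding.** One-hot rows (A, U, C, G; the unknown base N is
  all-zero) are lifted to d dimensions by a 1-D convolution (kernel width
  3, same padding), and summed with a position embedding: the 2-column
  matrix [i, i/N] is projected to N×d by a learned linear map. The
  projection is learned with the rest of the model; whether to learn it
  was genuinely open, and learning it costs 2d parameters while letting
  the model choose its own positional scale for both the absolute and the
  relative channel.
* **Encoder.** `n_blocks` identical blocks (default 3); each applies
  multi-head scaled dot-product attention (default 4 heads) with a
  residual connection and layer normalization, then a position-wise
  feed-forward layer (width `d_ff`, default 2d) with its own residual and
  layer normalization. Attention logits are divided by sqrt(d_head) by
  default; the alternative divisor d_head is available as
  `attention_scale = "d"` since both conventions appear in the
  literature and differ only by a constant factor in the logits.
* **Pairwise assembly.** Feature vector of cell (i, j) is the
  concatenation of rows i and j of (encoder output + projected
  positions), averaged with its (j, i) counterpart so features are
  exactly symmetric. Note the average makes the two halves of the
  concatenation identical — the construction is equivalent to the
  symmetric combination (hᵢ + hⱼ)/2 duplicated across 2d channels. We
  keep the 2d-channel layout for the stated construction; it costs one
  redundant convolution width and nothing else.
* **Decoder.** Three 2-D convolution stages (3×3 kernels, default
  channels 32→16→1) with channel normalization and ReLU after the first
  two, a linear single-channel output, and symmetrization
  (M + Mᵀ)/2.

Sequences are processed one at a time; a training batch is a
gradient-accumulation group. This sidesteps padding entirely (no masked
cells ever enter a loss or a normalization statistic) and means the
decoder's normalization uses the spatial statistics of one score map —
an instance-normalization flavour of batch normalization, appropriate at
batch size one per sequence.

All gradients are analytic (hand-written backpropagation through every
layer) and are verified against central finite differences in the test
suite to a relative error of 1e-4 at sampled coordinates across every
parameter group.

## Hard-constraint decoding

A valid structure obeys three hard constraints: (1) only A-U, G-C and
G-U pairs; (2) |i − j| ≥ 4, equivalently hairpin loops of at least three
unpaired bases; (3) at most one partner per base. Constraints 1–2 are
precomputed 0/1 masks (`canonical_mask`, `distance_mask`) multiplied
into the relaxed pairing variable. Constraint 3 becomes the penalty
`sum relu(rowsum − 1)`, zero exactly on feasible matrices.

Decoding minimizes

    −( ½ Σ (S − s)∘a  −  w Σ relu(rowsum(a) − 1)  −  ρ Σ |a| )

over a = mask ∘ sigmoid(U). The printed sign layout of this objective in
the literature this follows would *reward* the last two terms under
maximization; we implement them as penalties, which matches their
description as penalty terms, and keep the literal layout behind
`signs = "as_printed"` for comparison.

Numerical choices, all configurable through `decode_config()`:

* **Threshold s = 0.5 with `squash = TRUE`**: raw network scores pass
  through a sigmoid first, so the threshold sits at raw score zero. The
  threshold may also be supplied per use as any scalar (a per-cell
  matrix variant is expressible by subtracting it from S beforehand).
* **Initialization** U₀ = 4·(S − s): the starting point is a
  sigmoid-squashed copy of the score matrix centred on the threshold, so
  cells above threshold start active and cells below start inactive.
* **Step size 3, 300 iterations.** The penalty phase must drain the
  pairing mass of every over-committed row before the iteration budget
  runs out; with timid steps the optimizer is still inside the penalty
  transient when iterations end and everything binarizes to zero. The
  defaults were chosen by tracing convergence on noiseless ±1 score
  matrices (where the true structure is the unique optimum) across
  lengths up to ~100; they recover those optima exactly.
* **Discrete cleanup.** After binarization at 0.5: greedy conflict
  resolution (a base with several partners keeps its highest-scoring
  pair, ties to the lexicographically smaller pair), then greedy
  completion (add any allowed pair with positive net score whose bases
  are free, in descending score order), then a 1-swap local search
  (drop one pair, refill greedily, keep strict improvements). Each step
  preserves feasibility and never decreases the fit term. The relu
  penalty only discourages multi-pairing — it never forbids it — so a
  discrete cleanup is required for exact feasibility; the completion and
  swap passes additionally close the small gap the relaxation leaves on
  weakly-scored pairs, which is visible against the brute-force oracle.
* **Degenerate input** (every cell masked, e.g. N ≤ 4 where the distance
  mask bans everything) yields the empty structure, not an error.

`brute_force_decode()` enumerates all matchings over allowed
positive-net-score pairs (N ≤ 14) with branch-and-bound pruning and a
lexicographic tie-break, and is the independent optimality oracle: on
random instances the gradient decoder attains ≥ 95% of the enumerated
optimum per instance and the exact optimum on the large majority.

## Metrics

2-D mode compares unordered position pairs (exact-partner matching); 1-D
mode compares per-base paired status. TP+FN+FP+TN equals C(N,2) cells in
2-D mode and N in 1-D mode. TN never enters a headline score (unpaired
cells dominate). Degenerate conventions: empty-vs-empty scores 1; a zero
denominator with the opposing error present scores 0. Because partner
agreement implies status agreement, 1-D F1 ≥ 2-D F1 on every instance —
the mechanism by which per-base scoring inflates apparent accuracy, and
a property test in the suite. Aggregation over families offers
`mean_per_structure` (default; every structure weighted equally) and
`pooled_counts` (sum the confusion tables first); the two differ
whenever structure sizes or difficulties vary within a family, and
published family tables are not always explicit about which was used —
hence both.

## Synthetic data

The generator emulates the structural rules the decoder enforces:
recursively placed nested stems (2–6 pairs), occasional multi-branch
splits, every pair at distance ≥ 4, one partner per base; with
probability `pk_prob` one H-type crossing stem is threaded through a
hairpin loop. Sequences realize pairs from {A-U, G-C, G-U} (G-U with
probability `gu_prob`, default 0.2; orientation random) and draw
unpaired positions uniformly. Score-matrix fixtures put +1 at true-pair
cells and −1 elsewhere plus Gaussian noise, then symmetrize; with zero
noise the true structure is the unique decoding optimum by construction,
which makes exact-recovery tests meaningful.

What the generator does **not** emulate: thermodynamic stability,
family-specific architectures (clover-leaf tRNA, rRNA domains),
covariation signal, non-canonical pairs, or realistic loop-length
distributions. Passing tests on synthetic data therefore demonstrate
correctness of the machinery (encodings, decoding, constraints, metrics,
training), not biological accuracy on natural RNA; the latter requires
training on a real corpus at full scale, which is out of scope here.

## Training

Default loss is masked binary cross-entropy between sigmoid(S) and the
true pairing matrix, restricted to constraint-allowed cells, with a
per-sequence positive-class weight (`pos_weight = "auto"`) because true
pairs are a ~20:1 minority among allowed cells. An objective-based
alternative (the decoding objective evaluated at the true structure,
whose penalty terms vanish) is provided for fidelity experiments. The
optimizer is Adam (default learning rate 1e-3; the toy experiments below
use 3e-3). The constrained decoder is applied at evaluation time only
and is not differentiated through. Divergence (non-finite loss) aborts
with the epoch and offending sequence.

Validation-split support retains the parameters with the best tracked
F1; with `val_fraction = 0` the training-set F1 is tracked instead, which
is what the overfitting experiment wants.

### Problem sizes used by the tests and the acceptance script

Chosen as desk-scale experiments a reviewer can rerun: the toy
end-to-end run trains a reduced model (d = 32, 2 blocks, 4 heads,
channels 32→16→1) on 30 synthetic sequences of length 20–40 for 200
epochs, reaching training-set 2-D F1 ≥ 0.9 in a few minutes on one CPU;
decoder property checks use hundreds to a thousand instances at lengths
8–100. The package defaults (d = 64, 3 blocks) describe the full-scale
configuration; nothing in the code ties correctness to the reduced
sizes.

## Known limitations

* The gradient decoder is a heuristic: optimality is certified only
  against the enumeration oracle at N ≤ 14; at larger N it is validated
  by exact recovery of planted optima.
* Scores are dense N×N, so memory and decode time grow quadratically;
  the default length filter of 512 reflects that.
* The training loop is plain R + BLAS; it is meant for desk-scale
  experiments and method development, not for corpus-scale training.
* One H-type crossing stem per synthetic structure; complex knot
  topologies are not generated (the decoder itself has no such limit).
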