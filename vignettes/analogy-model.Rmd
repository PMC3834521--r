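---
title: "A recurrent pattern-completion model of binary-choice verbal analogy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent pattern-completion model of binary-choice verbal analogy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(analogynet)
```

## The problem

Forced-choice verbal analogies (A:B::C:\[D1|D2\]) pit two sources of
evidence against each other. The *relational* route asks which candidate D
stands in the same relation to C that B stands in to A; the *associative*
route simply asks which candidate co-occurs more strongly with C. In
development, children shift from associative to relational responding as
domain knowledge accumulates; in frontotemporal lobar degeneration (FTLD),
frontal-variant patients fall back to associative responding while
temporal-variant patients degrade across the board. `analogynet` implements
a connectionist account on which all three patterns emerge from a single
mechanism: a recurrent network that learns to complete item-relation-item
propositions, tested with a weight-tied twin architecture in which both
halves of the analogy jointly constrain a shared relation representation.

Nothing in training ever mentions analogy. The analogy capability — and its
developmental and neuropsychological signatures — are by-products of
pattern completion over learned propositional knowledge.

## The training network

Four pools of logistic units: localist first-role items (A), localist
second-role items (B), a 128-unit distributed relation pool (R), and a
hidden integrating pool (H). Each visible pool connects bidirectionally
with H. Unclamped units start at the logistic of their bias and relax
toward the logistic of their net input,

$$ a_i(t) = a_i(t-1) + \lambda\,\big(\sigma(\mathrm{net}_i(t)) - a_i(t-1)\big), $$

with synchronous updates, step size $\lambda$ per tick, and a fixed shared
hidden bias of $-2$ (the value the frontal lesion later reduces). Each
training trial clamps two pools of a proposition and lets the network
settle for `n_ticks`; backpropagation through the unrolled dynamics trains
the network so that, over the final `target_ticks` ticks, the missing
pool's activations reproduce the missing element and the logistic readout
of every clamped pool's net input reproduces the clamped element.

Two design choices deserve emphasis, because both were forced by failure
modes we could reproduce at will in pilot runs:

* **All pools are trained in every trial.** If only the missing pool
  receives error, the hidden-to-visible readout of a pool is trained only
  from states in which that pool is being completed, never from states in
  which it is part of the given context. The twin test (below) probes
  exactly such joint states, and a network trained the narrow way answers
  from an essentially untrained readout: its echoes saturate and the
  forced choice collapses toward the associative baseline. Training each
  clamped pool's readout to reproduce its clamp makes the network store
  complete propositions as attractors, which is what the test procedure
  assumes.
* **Error has a zero-error margin.** Errors are squared deviations beyond
  a margin of 0.1: a unit within 0.1 of its target contributes nothing.
  Training therefore deepens an attractor only until its completion is
  reliable, then stops. Without the margin, high-frequency propositions
  keep deepening indefinitely, weights saturate, and the echo measure
  loses the graded differences the choice rule depends on. With it, the
  strength of low- and high-frequency attractors *equalises*
  asymptotically — which is precisely the mechanism by which the model's
  late, relationally-driven responding overcomes early frequency-driven
  responding.

Visible-hidden projection pairs are kept symmetric
(`tie_weights = TRUE`): the matrix from H to a pool is the transpose of
the matrix from the pool to H. Settling is then constraint satisfaction
over one consistent set of pairwise constraints, and the knowledge that
completes a relation from two items is the same knowledge that completes
an item from an item and a relation. In pilot runs, untied networks
satisfied training nearly as well but supported markedly worse analogy
performance: the two directions of each projection learned different
solutions, so at test the relation pattern completed by one half could
not be consumed by the other half's readout. The option is exposed for
experimentation.

Updates are taken on shuffled mini-batches (default 32 trials,
homogeneous in input combination) using the mean gradient; this is a
computational-throughput choice, not a scientific one, and the update
grain interacts only with the effective learning rate.

## The training environment

The environment generator emulates a counterbalanced corpus of
propositions organised into *cells*. A cell holds one source proposition
A:R1:B, one relational target C:R1′:D1 whose relation is another instance
of the source's prototype, and three foil propositions C:R2:D2, C:R3:D3,
C:R4:D4 from three other prototypes, trained at weak (1), moderate (3)
and strong (9) frequency per epoch per input combination; source and
target use the moderate frequency. Each cell yields three questions that
share a, b, c, d1 and differ in the foil: the weak foil gives a
positive-SFI question (the correct answer is also the more associated
one), the moderate foil a zero-SFI question, the strong foil a
negative-SFI question (the foil is three times more associated than the
correct answer). The 1/3/9 geometric ladder gives the strong foil a
large early associative advantage, which is what drives the below-chance
phase of the negative-SFI curve.

Relational prototypes are eight disjoint 16-unit blocks of the 128
relation units (a seeded permutation chunked into blocks); an instance
turns two of its prototype's active units off, so instances carry 14
active units and two same-prototype instances with disjoint off-pairs
share exactly 12. Each prototype's instances cycle through a fixed random
partition of its active units into eight disjoint off-pairs.

Counterbalancing matters more than it may appear, and two properties of
the generator were forced by identifiability arguments rather than taste:

* **Item-pair uniqueness.** Groups of five cells share five first-role
  and five second-role items, with second-role items rotating through the
  roles B/D1/weak/moderate/strong as a Latin square. If the C items of a
  group are drawn from the *same* group's A items, one can show by a
  pigeonhole argument over role offsets that every source pair (A,B) must
  collide with some other cell's (C,D) pair, handing the same item pair
  two different target relations — an irreducible completion error.
  Drawing each group's C items from the next group's first-role items
  removes every collision while preserving all frequency tallies (each
  first-role item trains 3 as A plus 16 as C; each second-role item 19;
  each prototype equally per eight-cell window).
* **Instance reuse.** If every relation instance appears in exactly one
  proposition, the completions "item1 + relation → item2" are solvable
  from the relation pattern alone, and gradient descent duly ignores the
  item cue — at which point the twin test fails, because the shared
  relation pool then retrieves the *source* proposition's completion
  regardless of C. Cycling the off-pair partition makes instance patterns
  recur across propositions with different items, forcing conjunctive
  item-relation coding.

Per epoch, every proposition of frequency $f$ contributes $f$ trials of
each of the three input combinations (AB→R, AR→B, BR→A); the default
40-cell environment therefore presents 2,280 trials per epoch in a
seed-derived shuffled order.

## The twin test and the echo measure

Questions are answered by two copies of the trained network — pools
A,B,H1 and C,D,H2 — sharing the relation pool and reading the *same*
weight values (the A↔H1 matrices are the C↔H2 matrices, and so on).
Because two agreeing halves would deliver twice the trained net input to
R, each half's hidden-to-relation drive is halved; the relation-to-hidden
direction keeps full strength. For each candidate D the probe clamps a,
b, c and d for `phase1_ticks` (default 10), then releases the D clamp —
retaining its state — for `phase2_ticks` (default 20) while a, b, c stay
clamped. The *echo* is the candidate unit's activation at the final tick;
the candidate with the stronger echo is chosen (a deterministic coin,
hashed from the item ids, breaks exact ties). The two echo trials of a
question differ only in the D clamp.

The tick counts trade off two races. During phase 1 the two halves fill
the shared relation pool jointly; too short a phase leaves the top half's
relational evidence unexpressed. During phase 2 the candidate must be
maintained by the network rather than by its clamp; too short a phase
reads back the clamp itself, too long a phase lets the slow drift toward
the source instance's exact pattern erode the correct candidate's
support. The defaults sit in the wide plateau between the two failure
modes in pilot runs.

## Lesions

The frontal lesion replaces the fixed H1 bias (−2) with −6.5 in the A:B
half only, degrading maintenance of the A:B context; every weight is
untouched, so the lesion is one scalar and fully reversible. With the
context half silenced, the relation pool is driven almost entirely by the
C:D half and responding reverts to association — sparing positive-SFI
questions and collapsing negative-SFI ones. The temporal lesion zeroes
each entry of the six directional matrices independently with probability
0.42 (biases are spared: they are not projections); because the twin
shares weights, the removal pattern is identical in both halves by
construction. Pattern completion degrades across the board. Lesions are
applied to fully trained networks at test time; lesioned networks are
evaluated, never retrained.

## Simulations and their scale

`simulation1()` trains five independently seeded networks on five
independently generated default environments for 350 epochs, evaluating
all 120 questions before training and every 10 epochs. `simulation2()`
evaluates each trained network intact, under the frontal lesion, and
under five independent temporal-lesion draws (25 lesioned networks). The
package defaults (96 hidden units, learning rate 0.05, $\lambda = 0.2$,
20 settling ticks with error on the last 5, margin 0.1, batch 16, probe
12 + 24 ticks) were chosen in pilot runs as the configuration that best
balances end-of-training accuracy, the timing of the relational shift
and the lesion pattern; none of the environment's structural constants
(128/8/16/2 relation code, 1/3/9 frequencies, 8 groups, 5 networks, 350
epochs, bias −2 → −6.5, removal probability 0.42, 5 draws) is tuned.
With these defaults a full developmental simulation (5 networks, 350
epochs, evaluations every 10 epochs) runs in minutes on one CPU core,
and the lesion study in well under a minute.

What the generator does *not* emulate is worth stating: items are
localist and therefore carry no surface similarity; association is pure
co-occurrence frequency with a perfectly counterbalanced margin, far
cleaner than corpus statistics; and relation representations are fixed
by construction rather than learned. Passing tests on this synthetic
environment show that the mechanism produces the claimed phenomena under
the stated statistics — not that the same magnitudes would arise from
naturalistic input.

## Numerical notes

* Activations live strictly inside (0, 1); unclamped pools start at the
  logistic of their bias, which gives a closed-form zero-weight limit
  used in the unit tests.
* BPTT gradients are verified against central finite differences of an
  independently written scalar-level settle on an 11-unit network, to a
  relative tolerance of 1e-4 (observed agreement is ~1e-7).
* The per-epoch trial multiset is fixed; seeds only permute order.
  Training in chunks is bit-identical to one long run, which the history
  and evaluation cadence rely on.
* Exact echo ties (possible for a fully severed network, probability-1
  absent under training) are broken by a deterministic hash of the item
  ids, keeping reruns identical.
* Degenerate configurations fail fast with typed conditions:
  non-tileable prototype requests, off-pair exhaustion (a 9th disjoint
  pair from a 16-active prototype), frequency ladders that are not
  strictly increasing, clamps on unknown pools, lesion probabilities
  outside [0, 1], and retraining of lesioned networks.

## Known limitations

The model inherits the scope of its design: binary choice only, no
learning of relation representations, no attentional switching, no
mapping of pools onto anatomy. The relational shift's timing in epochs is
calibrated by the learning rate and has no privileged unit conversion to
age. Echo magnitudes are meaningful only comparatively within a question;
they are not confidence estimates.

Two quantitative limits of the default configuration are worth knowing
(the acceptance suite measures both). The negative-SFI condition, while
clearly relational by late training, converges below the ceiling the
positive and zero conditions reach: against a foil trained at three
times the target's frequency, a minority of questions keep hairline echo
margins however long training runs. Downstream, this keeps the intact
networks' association sensitivity (positive minus negative accuracy)
above zero, so the temporal lesion's sensitivity — which the frontal
lesion dwarfs in any case — ties rather than exceeds the control's. Both
limits trace to the same residual associative pull and are stable across
every learning rate, capacity, margin, batch and probe setting we
piloted; the training corpus details that would discharge them are
exactly the ones the original environment specification leaves open.
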