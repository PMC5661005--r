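---
title: "Sensorimotor object recognition with columnet: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor object recognition with columnet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(columnet)
```

## The model

columnet simulates networks of cortical columns that learn objects through
movement. An object here is nothing more than a set of (location, feature)
pairs: what a small sensor patch would feel at each of a handful of
positions in the object's own reference frame. A single sensation —
one feature plus one allocentric location — is usually ambiguous, because
features and even whole feature/location pairs recur across objects. The
model's claim is that a two-layer circuit can integrate a *sequence* of
such sensations into a stable, unambiguous object identity, and that
several columns connected laterally can do the same in far fewer
movements.

Each column has two layers:

* An **input layer** of `n_in` minicolumns with `m` cells each (150 x 16
  by default). All cells of a minicolumn respond to the same sensory
  feature bit; the sensory feature SDR directly selects which minicolumns
  win. Which *cell* within a winning minicolumn fires is decided by
  context: basal dendritic segments listen to the location signal (a
  2,400-bit SDR with 10 active bits), and a cell with a matching segment
  is *predictive* and fires first, silencing its neighbors. A surprised
  minicolumn — no predicted cell — bursts with all 16 cells. The sparse
  result is a code for "this feature at this location".
* An **output layer** of `n_out` cells (4,096 by default, at least
  `s_out = 40` active) that pools over the input codes of all of an
  object's pairs. During learning a fixed, randomly selected set of 40
  cells stays active across every sensation of one object, so each of
  those cells grows proximal synapses onto every pair's input code.
  Basal (lateral) segments of output cells listen to the previous time
  step's output activity of all columns — including their own — and bias
  activation toward cells consistent with what the network (and its
  neighbors) believed a moment ago.

Neurons follow the Hierarchical Temporal Memory model: every synapse has a
scalar permanence in [0, 1] and conducts only above 0.5; learning moves
permanences (+0.1 for co-activation, small decrements otherwise) and grows
new synapses on demand rather than assuming full connectivity. Segments
are independent coincidence detectors with count thresholds: 6 active
connected synapses activate a basal segment of an input cell, 18 a lateral
segment of an output cell.

Inference follows a union-and-narrowing pattern. After a reset, the first
sensation activates the output cells of *every* object consistent with the
sensed pair — a union of candidate codes, with activity denser the more
ambiguous the evidence. Each further sensation keeps only candidates that
both match the current pair (feedforward) and were part of the previous
union (lateral support). An object is *recognized* when the output
activity overlaps its stored code by at least 30 while every other stored
code stays below 30, in every column.

The feedback pathway closes the loop: the output layer projects back to
apical dendrites of its own column's input layer. Apical support lowers
the basal threshold (from 6 to 4 by default) and breaks ties when several
cells in a minicolumn are predicted, so prior beliefs sharpen the input
code without ever creating predictions on their own.

## The synthetic world

`generate_library()` builds the study conditions: objects of 10 features
drawn from a configurable feature pool, attached to 10 location slots
whose codes are shared across objects (slot i of every object reuses
location code i). Sharing is what makes the task hard: with a pool of 5 to
30 features, any single pair is compatible with many objects. The capacity
experiments instead use a 5,000-feature pool, where pairs are nearly
unique and the difficulty comes from synapse interference between hundreds
of stored objects.

Test streams visit slots in random permutation cycles — every slot is
touched once before any repeats — and multi-column streams give the
columns pairwise distinct slots in each sensation. Training makes three
passes over all slots ("the network senses each feature three times"),
with a rotated permutation per column so every column covers every slot.

What the generator does *not* emulate: geometric structure (no notion of
neighboring locations), sensor kinematics, graded feature similarity, or
location codes where nearby locations share bits. Random codes plus
explicit bit-flip noise stand in for all of that, so passing tests show
robust discrimination among arbitrary sparse codes — not performance on
structured visual or tactile input.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_in`, `m` | 150, 16 | minicolumns per column, cells per minicolumn |
| `s_in` | 10 | active minicolumns = active bits of a feature code |
| `n_ext` | 2,400 | location input width (10 active bits) |
| `n_out`, `s_out` | 4,096, 40 | output cells, object-code size |
| `theta_basal` | 6 | basal segment activation (of 10 sampled bits) |
| `theta_basal_apical` | 4 | basal threshold under apical feedback |
| `theta_match` | 4 | minimum potential overlap to reuse a segment |
| `theta_proximal` | 8 | feedforward candidate threshold |
| `theta_lateral` | 18 | lateral segment activation (of ~40 synapses) |
| `connected_perm` | 0.5 | permanence at which a synapse conducts |
| `init_perm` | 0.6 | permanence of newly grown synapses |
| `p_plus` / `p_minus` | 0.1 / 0.02 | segment reinforcement / decay |
| `p_ff_minus` | 0.001 | proximal decay (see below) |
| `p_punish` | 0.002 | decrement for out-competed predictions |
| `classify_threshold` | 30 | stored-code overlap for recognition |
| `training_passes` | 3 | passes over an object's slots |

Three of these deserve their own paragraphs, because they are the
difference between a network that works at scale and one that quietly
destroys its own memory.

**`theta_proximal = 8`.** A learned pair drives its object's output cells
at overlap `s_in = 10`, so any threshold in ~3..10 recognizes clean input.
The binding constraint is on the other side: after 400 stored objects an
output cell participates in ~4 object codes and carries ~400 connected
proximal synapses spread over the ~1,500 input-layer context cells. With a
threshold of 3, the chance that 10 active context cells hit 3 of those
synapses is order one-half — half the layer becomes a spurious feedforward
candidate at every sensation, the lateral sort then favors the
most-shared cells, and recognition collapses long before 400 objects. At
8, the same chance is ~2 in 1,000 and spurious *full-code* activations
(which would cross the overlap-30 classification bar) require an 8-bit
minicolumn collision that essentially never happens. The threshold still
tolerates two corrupted sensory bits directly; corrupted bits beyond that
activate random bursting minicolumns whose cells partially re-supply the
overlap, so the measured accuracy plateau extends to about 30% sensory
noise before falling off steeply.

**`p_ff_minus = 0.001`.** Proximal synapses of an active output cell onto
*inactive* input cells decay at every sensation. During one object's
training, a synapse learned for one pair sits inactive for the object's
other 9 pairs — 27 of the 30 sensations. The decrement must therefore
satisfy `init_perm + 2 p_ff_plus - 27 p_ff_minus > connected_perm` with
room to spare; at 0.02 the inequality fails (0.26 < 0.5) and every
trained synapse ends disconnected, while at 0.001 synapses retain ~0.77.
The same arithmetic does not bite basal, apical, or lateral segments:
a segment is only ever updated when its own context recurs, and then all
of its synapses are active.

**`theta_match = 4`.** When a bursting minicolumn recruits a learning
cell, an existing segment is reused only if it already overlaps the
location code by 4 potential synapses. Reuse at overlap 1 sounds
harmless, but chance 1-bit overlaps between random 10-of-2,400 codes
occur for ~4% of segments — and every reuse grows the segment, raising
the chance of the next false match. Left unchecked this merges different
locations' context cells (we measured ~17% of contexts merged after 100
objects, a 10-fold inflated candidate union, and accuracy 0.71 instead of
1.0). Between genuine re-encounters (overlap 10, or 6 under noise) and
chance (0-1) any threshold in 2..6 works; 4 mirrors the lowered basal
threshold.

One further quiet choice: a new object's code is drawn uniformly at
random. Selecting by best feedforward match is only sound when the
initial connectivity is genuinely random and dense, in which case the
winner set is exchangeable with a uniform draw anyway; scoring through
*learned* synapses would make any object that shares its first-touched
pair with an earlier object adopt that object's code wholesale, and
scoring through a sparse greedy initialization concentrates selection in
small input-dependent candidate pools — both produce measurable code
collisions. The uniform draw keeps the ~10^96 possible 40-of-4,096 codes
independent; a consequence is that retraining an object draws a fresh
code rather than recovering the old one, and the catalog stores the
newest code.

**Punishment scope.** Segments that predict a cell which then fails to
fire are decremented by `p_punish`. We apply this only inside *active*
minicolumns — i.e. to predictions that lost the within-minicolumn
competition to an apically supported rival. Punishing every prediction in
non-winning minicolumns sounds more thorough, but with a shared location
pool every sensation would then decrement the context segments of every
previously learned object at that slot (~3 punishments per newly trained
object), erasing a stored object's location contexts after ~150 later
training sensations. Scoped punishment models the biological claim —
inhibition suppressed a mispredicting cell — without the catastrophic
forgetting.

## Numerical and procedural choices

* **One lateral step per sensation.** Lateral support is computed against
  the previous sensation's concatenated activity; we do not iterate the
  lateral competition to a fixed point within a sensation. An iterated
  variant would narrow unions slightly faster.
* **Ties at the lateral cutoff** all become active: the `s_out`-th highest
  support is a threshold, not a quota, so activity can exceed `s_out`
  (union states) but never undershoots it while candidates exist.
* **Learning targets winner cells.** During training, proximal and apical
  learning use the per-minicolumn winner cells rather than full burst
  activity, so each output cell grows at most `s_in` synapses per pair.
  At inference, feedforward overlap uses the true active set, bursts
  included.
* **Noise.** `sdr_corrupt()` flips exactly `round(noise * n_active)`
  active bits (half away from zero, so the 0..0.7 grid on 10-bit codes
  gives flip counts 0..7) and activates the same number of previously
  silent bits. Corruption is applied independently per sensation.
* **Recognition bookkeeping.** The convergence step is the *first*
  sensation at which classification returns the correct object;
  "accuracy within K touches" counts objects whose first success comes at
  or before K. Persistence afterwards is typical (lateral
  self-reinforcement) but not required by the measure.
* **Determinism.** Every stochastic choice draws from an explicit
  `rng_stream`; experiments derive independent child streams per purpose
  (library, network initialization, training order, sensation order,
  noise) from one integer seed, so any result is reproducible from its
  configuration echo.
* **Degenerate inputs.** Empty feedback is a no-op for apical learning; a
  sensation with an empty location learns nothing; classification with an
  empty catalog is an error, an empty activity vector is "ambiguous".

## What the experiments show

`run_convergence()`, `run_capacity()`, `run_noise()` and
`run_ideal_comparison()` reproduce the four simulation studies. The
problem sizes used by the test suite are deliberately reduced (tens of
objects, reduced grids); `scripts/acceptance.R` runs the full-size
regimes: capacity to 400 objects with a 5,000-feature pool, noise grids
0-70% over 10 seeds with 30 touches, and convergence on 100-object
worlds over 20 seeds.

Measured behavior on the defaults: a single column classifies all 400
objects of the capacity world correctly with 3 test sensations; accuracy
within 30 touches is indistinguishable from baseline up to 30% sensory
noise and up to 60-70% location noise (exact-count bit flips keep 6 of 10
location bits up to 40% — precisely the basal threshold — and beyond that
bursting minicolumns still contain the correct context cells, merely
slowing convergence, which is why location noise mostly raises
sensations-to-recognition rather than accuracy).

One reported quantity we deliberately do not match: the single-run
"convergence after 11 sensations" illustration for a 100-object world.
Our single-column mean is ~3.5 sensations. With permutation slot
sampling, the probability that any competitor object remains consistent
with t sensed pairs is about `99 / pool^t`, which falls below one half by
t = 3 for every pool size in 5..30; an ideal observer on the same streams
converges in 3-4 sensations, and the network tracks the ideal observer
closely (as the original comparison itself reports). We take the
printed 11 to be an anecdotal single trajectory rather than a mean, and
report our measured means as such.

## Limitations

* Location and feature codes are arbitrary SDRs: there is no similarity
  structure between nearby locations, so generalization to unvisited
  locations is out of scope.
* Capacity conclusions are specific to the shared-slot world; a world
  with per-object location codes would trade ambiguity (easier) for
  context-cell interference (harder) in different proportions.
* Plasticity is off during inference; interleaved learning and inference,
  forgetting schedules, and segment pruning are not modeled.
* Inhibition is implicit in the activation rules; no inhibitory neurons
  are simulated.
* The checkpoint serializers (`library_to_json()`, the segment-store
  snapshots) are built for modest networks and tests; a 400-object
  network's stores are large and are better regenerated from seeds.

## A minimal session

```{r demo}
lib <- demo_shared_feature_library(rng_stream(7))
net <- cortical_network(num_columns = 1, seed = 7)
rng <- rng_stream(71)
net_train_object(net, lib, 1, rng)
net_train_object(net, lib, 2, rng)

obj <- lib$objects[[1]]
stream <- lapply(1:3, function(p) list(list(
  slot = obj$slots[p], feat = obj$feats[p],
  location = lib$location_pool[[obj$slots[p]]],
  feature = lib$feature_pool[[obj$feats[p]]])))
res <- net_infer(net, stream)
res$n_active[, 1]       # union (80 cells) narrows to one code (40)
res$classification      # NA (ambiguous), then object 1, persisting
```
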