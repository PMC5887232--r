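---
title: "Identifying the phenotype control kernel of a Boolean network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the phenotype control kernel of a Boolean network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pckernel)
```

## The control problem

A Boolean network model assigns each molecular species a 0/1 state and a
logical update rule over its regulators; under synchronous updating the
network state moves deterministically and eventually enters an attractor
(a fixed point or a cycle).  Cellular phenotypes correspond to
attractors, and usually to the values of a few designated *phenotype
nodes* rather than the full state.  The control question this package
answers is *any-to-multiple* target control: which minimal sets of nodes
can be clamped to fixed values so that **every** initial state reaches an
attractor in which the phenotype nodes take their desired values?  The
collection of all such minimal clamp sets is the *phenotype control
kernel* (PCK).  Clamping is a permanent rule override, the standard model
of pinning a node with an external input, a constitutive mutation, or a
saturating drug.

Unlike any-to-one attractor control, the target attractors need not
exist before control is applied, and different initial states may land
in different attractors as long as all of them carry the desired
phenotype values.

## The procedure

Identification runs in two stages.

**Layered network.**  Layer 0 is the set of phenotype nodes; layer
$k+1$ collects the regulators (read from the update rules, so topology
and dynamics cannot disagree) of layer-$k$ nodes not placed in any
earlier layer.  The construction is deterministic and unique, a node's
layer index equals the length of its shortest regulatory path to a
phenotype node, and nodes in no layer can never influence the
phenotype — they are excluded as control candidates outright
(`build_layered_network()`, `influential_partition()`).  The layer index
also bounds search depth: a control set containing node $N$ cannot
appear in the tree before level `layer_of(N)`, which is what
`find_sets_containing()` exploits.

**Converging tree.**  The root is the desired phenotype assignment
$\{(P_1,\dots,P_\ell) = (d_1,\dots,d_\ell)\}$.  For a parent set, each
coordinate $N_m = n_m$ contributes the *solutions* of its Boolean
equation $n_m = f_{N_m}(\cdot)$ — the minimal partial assignments of the
rule's direct inputs that force the output to $n_m$ for every completion
(the prime implicants of the indicator $[f = n_m]$, computed by truth
table in `forcing_solutions()`) — plus the trivial self-perturbation
$\{N_m = n_m\}$, i.e. keeping that coordinate clamped while upstream
causes cover the rest.  Children are the conflict-free unions of one
solution per coordinate, filtered to subset-minimal elements
(`system_solutions()`); for a singleton parent $\{K = v\}$ below the
root, solutions re-assigning $K$ are excluded.  Two removal rules prune
the tree:

1. a candidate *included* in an already-found set (containing it as a
   sub-assignment with equal values) is redundant and removed — equal
   sets count, so a re-discovered set yields to its earlier copy;
2. a candidate assigning any node the *opposite* of its value in the
   assignments it was derived under (parent and ancestors) would break
   its own derivation chain and is removed.

When a new child is strictly *smaller* than an existing set, the larger
set is superseded: it is removed with its descendants, and if it lies on
the new child's own ancestor chain the tree is rebuilt from the lowest
affected level, the child taking the superseded set's place.  A
visited-configuration hash guards against restructuring cycles (status
`aborted`; never observed on the test suites, but the guard is load
bearing for arbitrary inputs).  Construction stops when every frontier
set is a leaf (`complete`), at an optional level cap (`level_capped`),
or at the safety cap of `n_nodes + 1` levels.  The surviving non-root
sets are the PCK (`extract_pck()`).

```{r example}
net <- example_network()
tree <- build_converging_tree(net, c(P = 0))
tree
extract_pck(tree)
```

## Derivation contexts and restructuring

Rule 2 is chain-relative, and restructuring rewires chains.  Every set
therefore stores the union of ancestor assignments it was *derived*
under, and a set moved during restructuring keeps its original context:
those values are still what make it a control set, and a child clamping
one of them oppositely must still be removed.  Without this bookkeeping
a moved set's children can silently break the hidden part of its
mechanism; with it, every surviving set's forcing chain is intact, and
exhaustive verification of all kernel members over the packaged test
suites passes without exception.

## Verification semantics

`verify_control_set()` is the ground-truth oracle: clamp the control
set, enumerate all $2^{n_\text{free}}$ states (or sample trajectories
for large models), and require the desired value of every phenotype node
in **every** state of every attractor — an oscillating phenotype is a
failure, the strict reading of a steady-state value.  If a control set
clamps a phenotype node itself, the node's original rule must *generate*
the desired value on every attractor state; a value merely imposed by
the clamp while the circuit drives the opposite one does not count.
Under that convention, enumerating all 14 single-node clamps of the
example network returns exactly the six kernel singletons.
`brute_force_kernel()` searches all small clamp sets over non-phenotype
nodes by default (the method's own setting restricts control to
non-phenotype nodes), with `include_phenotype = TRUE` for the full
enumeration.

For a multi-node phenotype, joint solutions may hold *some* phenotype
coordinates by their own clamps (e.g. `{A=0, P2=0}`).  Such sets achieve
the phenotype in the perturbation sense but fail the strict generation
check above; users restricting control to non-phenotype nodes should
filter them from the kernel.

## What the synthetic generator emulates

`random_network()` draws connected networks in which every node has a
regulatory path to the phenotype node — the regime where kernel
questions are non-trivial — with in-degrees 1–3 by default, matching the
sparse regulation of curated logical models.  Rule families: `nested`
(read-once AND/OR trees with random leaf negations; every listed
regulator provably essential), `table` (uniform random truth tables
restricted to essential inputs), `threshold` (signed ±1/±2 weights).
What it does *not* emulate: the long chains and modular organisation of
real signalling maps, canalising-function bias, or input stimuli held as
experimental conditions.  Passing tests on these networks therefore
validate the algorithmic machinery, not biological realism.

## What the tests show — and the method's intrinsic limits

Three properties are measured on a fixed suite of 200 seeded random
networks (7–10 nodes, mixed rule families), with exhaustive state-space
enumeration as the oracle:

* **Soundness holds universally.**  Every kernel member drives every
  initial state to attractors with the desired phenotype — the method's
  central guarantee, and the one the package treats as non-negotiable.
* **Strict dynamical minimality and completeness do not.**  The tree
  derives control sets through chains of one-step forcing solutions —
  equivalently, through iterated substitution of fixed values into the
  rules.  Synchronous dynamics admits control sets invisible to any such
  chain: a set can force the phenotype only because a feedback loop
  locks in downstream of it (for instance a pair whose mechanism needs
  the phenotype's own value to feed back and silence an upstream
  activator).  The brute-force oracle finds those sets; the tree instead
  keeps a larger substitution-derivable substitute, so some members are
  not subset-minimal under full dynamics (roughly 57% of small members
  are strictly minimal on this suite) and some brute-force minimal sets
  contain no kernel member (roughly 74% containment).  A second, smaller
  loss channel is path pruning: the equal-set rule keeps only the
  earliest derivation of a set, and since rule 2 is chain-relative, a
  valid deeper set may be derivable only along a pruned path (on the
  order of 3% of small substitution-minimal sets on this suite).  Under
  the method's own substitution semantics the implementation is
  near-exact: every member generates the phenotype by substitution and
  over 99% are substitution-minimal.

These rates are recomputed, not asserted, by `scripts/acceptance.R`;
the acceptance test states the idealised claims and records honestly
where the measured rates fall short.

## Numerical and design choices

* Updating is synchronous and deterministic throughout; the converging
  tree's substitution logic assumes a deterministic next-state map.
  Asynchronous and probabilistic schemes are out of scope.
* Threshold rules fire on a strictly positive weighted sum; a sum of
  exactly zero is decided by `tie_policy` (`"zero"`, the default, gives
  0; `"retain"` keeps the current value and makes the node self-input).
* Truth-table enumeration caps rule in-degree at 16; exhaustive
  attractor search refuses beyond 22 free nodes (sampled mode, with an
  explicit recorded seed, is the fallback); brute-force kernel search
  refuses beyond 12 free nodes or sets larger than 3.
* Input nodes without a clamp would silently multiply the state space,
  so dynamics refuse to run until they are fixed.
* All collections are kept in a canonical order (assignments sorted by
  node name; solution lists by size, then names, then values), so runs
  are byte-for-byte reproducible and serialized trees are diffable.
* Constant propagation (`propagate_constants()`) is purely algebraic
  folding; a rule that is semantically constant but not syntactically so
  stays unfixed.  This cannot produce wrong kernels (the solver works
  semantically) — at worst a larger simplified model.
* Mutations override their own rules; a given value whose discarded rule
  folds to the opposite constant aborts with the derivation chain unless
  `conflict = "override"` is requested.

## Problem sizes

The shipped test suite and acceptance script use: the 7-node worked
example (exhaustive, $2^7$ states); 200 networks of 7–10 nodes for the
kernel-property suite (exhaustive verification at up to $2^{10}$ states
each, with brute force over all clamp sets of size ≤ 2); 1000+ random
rules of up to 4 inputs for the solver oracle; sampled attractor checks
at 4096 trajectories.  These sizes keep the full suite and the
acceptance script each within a few minutes on a single core while
leaving the oracles exhaustive wherever they are used.

## Known limitations

* Kernel completeness and strict minimality are relative to the
  substitution hierarchy, as discussed above.
* The two published disease models the method was demonstrated on are
  spreadsheet supplements; `mapk_fixture()` / `cancer_fixture()` load a
  user-supplied transcription and refuse to fabricate one.
* Sequential (time-varying) control policies, edge deletions, and
  attractor-specific (any-to-one) control are out of scope.
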