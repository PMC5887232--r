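# pckernel

Phenotype control kernel identification for Boolean network models of
molecular regulatory networks.

## The problem

Cell phenotypes correspond to attractors of the underlying regulatory
network, and typically to the steady values of a few designated
*phenotype nodes* (Apoptosis, Proliferation, ...) rather than the full
state.  A practical control question for such models is: which minimal
sets of molecules, pinned to fixed 0/1 values (a constitutive mutation,
a saturating inhibitor), drive **every** initial state of the network
into an attractor with the desired phenotype values?  This is
*any-to-multiple* target control — the target attractors need not exist
before the intervention, and different initial states may reach
different attractors as long as all of them carry the desired phenotype.

The **phenotype control kernel (PCK)** is the collection of all minimal
such clamp sets.  `pckernel` computes it for synchronous Boolean
networks with logic rules (`&`, `|`, `!`) or signed-threshold rules, and
is aimed at systems biologists who work with logical models and want the
complete menu of intervention targets rather than a single driver-node
set.

## The method

For phenotype nodes $P_1,\dots,P_\ell$ with desired values
$d_1,\dots,d_\ell$:

1. **Layered network.**  Layer 0 is the phenotype set; layer $k+1$
   holds the not-yet-placed regulators of layer $k$.  Nodes in no layer
   cannot influence the phenotype and are excluded as candidates; a
   node's layer index (its shortest regulatory path length to the
   phenotype) lower-bounds the tree level at which it can appear in a
   control set.
2. **Converging tree.**  The root is
   $\{(P_1,\dots,P_\ell)=(d_1,\dots,d_\ell)\}$.  A parent set's children
   combine, for each coordinate $N_m = n_m$, either a minimal forcing
   solution of the Boolean equation $n_m = f_{N_m}(\cdot)$ (a prime
   implicant of $[f_{N_m} = n_m]$ over the rule's direct inputs) or the
   coordinate's own clamp, merged across coordinates and filtered to
   minimal, conflict-free assignments.  Two removal rules prune the
   search: sets *included* in an already-found set (a superset
   perturbation) and sets *contradicting* an ancestor value are removed;
   a newly found smaller set supersedes the larger sets that contain it,
   restructuring the tree if they lie on its own ancestry.
3. **PCK.**  The surviving non-root sets.  Every member provably forces
   the phenotype: an exhaustive state-space verifier
   (`verify_control_set()`) and a brute-force minimal-set enumerator
   (`brute_force_kernel()`) are built in as independent oracles.

## Worked example

The packaged seven-node example network has one phenotype node `P`; the
goal is `P = 0`.

```r
library(pckernel)
net <- example_network()
net
#> Boolean network: 7 nodes, 7 rules, 0 input nodes
#>   A* = F
#>   B* = C & !F
#>   C* = !B & D & E
#>   D* = A
#>   E* = D | F
#>   F* = C & D
#>   P* = C & E

build_layered_network(net, "P")
#> Layered network: 7 layered nodes in 4 layers
#>   layer 0: P
#>   layer 1: C, E
#>   layer 2: B, D, F
#>   layer 3: A

extract_pck(build_converging_tree(net, c(P = 0)))
#> Phenotype control kernel (complete): 6 minimal control sets
#>   {C=0}  (level 1)
#>   {E=0}  (level 1)
#>   {B=1}  (level 2)
#>   {D=0}  (level 2)
#>   {A=0}  (level 3)
#>   {F=0}  (level 4)

verify_control_set(net, c(B = 1), c(P = 0))
#> Verification (exhaustive): control {B=1}, phenotype {P=0} -> HOLDS
```

Reading the output: every layer-1 clamp acts on a direct regulator of
`P` (`C* ` and `E*` feed `P* = C & E`, so either `{C=0}` or `{E=0}`
kills it in one step), while deeper members act indirectly — `{B=1}`
shuts `C` off via `C* = !B & D & E`, and `{F=0}` works through the
four-step chain `F → A → D → {C, E} → P`.  The kernel says there are
exactly six single-node interventions that stop `P` from every initial
condition, and no multi-node set is needed.

Model reduction for condition-specific analysis (fixed inputs,
mutations) is available as `propagate_constants()`, and
`find_sets_containing(net, pheno, node)` answers "is there a control set
using this node, and how deep must the tree be built to find it?"
without building the tree when the layered network already rules the
node out.

## Command line

A thin CLI over the same functions ships in `inst/exec/pckernel`:

```sh
Rscript inst/exec/pckernel pck --model example_network.bnet --phenotype P=0
Rscript inst/exec/pckernel layers --model model.csv --format threshold --phenotype Apoptosis=1
Rscript inst/exec/pckernel verify --model model.bnet --phenotype P=0 --control C=0
```

Subcommands: `attractors`, `simplify`, `layers`, `tree`, `pck`,
`verify`, `generate`.  Output is deterministic JSON (DOT export for
trees and layerings); logs go to stderr.

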