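---
title: "Cell-cell communication as a bounded minimum-cost circulation"
author: "flowccc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cell communication as a bounded minimum-cost circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowccc)
```

## The model

Spatial transcriptomics measures, at every spot or cell, the expression of
secreted ligands and of the cell-surface receptors that bind them. Most
inference tools score each ligand-receptor (L-R) pair independently, which
ignores two biophysical facts: a receptor pool is a *finite shared resource*
that competing ligands must divide, and a cell cannot signal beyond what its
ligand supply supports. `flowccc` encodes both by casting communication as a
**bounded minimum-cost circulation** on a receptor-centric cell graph.

Every cell is a node with net balance $b_v$ (zero by default: cells neither
create nor destroy signaling flux in the optimization). For every receptor
$R$ expressed in a target cell $j$ above a threshold $\tau$, and every source
cell $i$ within distance $d_{ij} < d_\mathrm{cutoff}$ expressing at least one
ligand that binds $R$, a directed edge $(i \to j, R)$ is created. A pair of
cells is therefore connected once per distinct receptor, never more. The flow
$f_e$ on that edge is the inferred communication strength through $R$.

Each edge carries:

* **cost** $c_e = d_{ij}/d_\mathrm{cutoff} + \lambda\,(1 - \bar a)$, where
  $\bar a \in [0,1]$ is the expression-weighted mean affinity of the expressed
  binders of $R$ in $i$. Long-range interactions and weak binding are
  penalized; $c_e \in [0, 1 + \lambda]$.
* **upper bound** $u_e = \kappa \cdot \min\!\big(E_R(j),\, S_L(i)\big)$ with
  $S_L(i)$ the summed expression of expressed binders: capacity is limited by
  the scarcer of receptor abundance and ligand supply. A `product` combiner is
  available where "proportional to both" is preferred; `min` is the default
  because a signaling channel cannot exceed its scarcer substrate.
* **lower bound** $l_e = \varepsilon\, u_e$ when at least one expressed binder
  carries database-level prior support, else $0$: curated interactions are
  forced to carry a small, nonzero flux.

The optimization minimizes $\sum_e c_e f_e$ subject to
$l_e \le f_e \le u_e$ and flow conservation
$\sum_{e\,\mathrm{out}} f_e - \sum_{e\,\mathrm{in}} f_e = b_v$ at every node.
Because capacity is shared per receptor and conservation couples all edges of
a cell, a pair that claims more flow necessarily starves its competitors —
the competition mechanism is structural, not a post hoc correction.

### Solving: lower-bound elimination and an exact integral solver

Lower bounds are removed by the standard transformation: substitute
$f'_e = f_e - l_e$ (capacity $u_e - l_e$), accumulate each node's imbalance
$r_v = \sum_{\mathrm{in}} l_e - \sum_{\mathrm{out}} l_e + b_v$, attach a
super-source edge to every node with $r_v > 0$ and a super-sink edge from
every node with $r_v < 0$ (capacity $|r_v|$, cost 0), and solve a min-cost
max-flow. The original problem is feasible **iff** every auxiliary edge
saturates; the optimal objective is the fixed contribution
$\sum_e l_e c_e$ plus the residual optimum, and $f_e = f'_e + l_e$.

`solve_flow()` solves the residual problem exactly with successive shortest
paths (Rcpp) on an integer-quantized network: bounds are scaled so the
largest capacity maps to `quantum` units (default 1000) and rounded
conservatively (lower up, upper down — quantization never widens the feasible
set), costs to $10^6$ integer steps. The scale factor is floored to an
integer whenever possible so already-integral bounds quantize exactly.
Integral solving buys exact conservation and bounds checking in integer
units, and bit-reproducible output. The price is a quantization error in the
objective of order $1/\mathrm{quantum}$, plus a $10^{-6}$ relative cost
rounding; `lp_oracle()` solves the same instance as a continuous LP (HiGHS,
via the system Python's `scipy`) for independent verification, and
`solve_flow(verify = TRUE)` cross-checks the two on graphs up to 500 edges.

Sign conventions, stated once and tested: $b_v > 0$ means net supply
(outflow exceeds inflow); the cutoff test is strict ($d < d_\mathrm{cutoff}$);
"expressed" means strictly greater than $\tau$; $\tau$ is a single global
threshold.

### Infeasibility, relaxation, and the circulation core

Prior-induced lower bounds can make a circulation infeasible. Two mechanisms
address this:

1. **Structural pruning at graph build.** A cell with no admissible outgoing
   edge can re-export nothing, so *any* inflow would violate conservation;
   every edge into it is forced to zero flow, and a positive lower bound
   there would be unsatisfiable at every $\varepsilon > 0$. `build_flow_graph()`
   therefore restricts positive lower bounds to the *circulation core*: the
   maximal node set obtained by iteratively stripping nodes lacking
   admissible incoming or outgoing capacity. Edges outside the core are kept
   (they document admissible topology) with $l_e = 0$. The practical
   consequence: purely receiving (or purely sending) cells get no forced
   flux, which is exactly what conservation dictates.
2. **Capacity-driven relaxation.** Even inside the core, cycle capacities may
   not carry the requested $\varepsilon$. `solve_flow(relax_lower = TRUE)`
   halves all lower bounds (equivalently $\varepsilon$) up to 10 times until
   feasible, and records the final factor in the solution. Structurally
   infeasible instances remain infeasible at every factor and are reported
   with per-node shortfall diagnostics instead.

### Ligand-level resolution and relays

The receptor-level optimum is refined post hoc — the global optimization is
untouched — by redistributing each edge flow over the expressed binders:
$w_L = a_{LR}^{\gamma}\, E_L(i)$ and
$f_{L} = f_e\, w_L / \sum_{L'} w_{L'}$. The affinity weighting
$\phi(a) = a^\gamma$ is the simplest monotone family containing both the
identity ($\gamma = 1$, default) and the affinity-blind limit ($\gamma = 0$);
the exponent is exposed in case a database supplies calibrated scores. The
last share absorbs the floating-point residual so ligand flows sum back to
the edge flow to within $10^{-12}$ relative.

`enumerate_relays()` joins the ligand-resolved table on the intermediate
cell: a relay is a pair of rows $(i \to j$ via $L_1\!-\!R_1)$,
$(j \to k$ via $L_2\!-\!R_2)$ with both flows above `min_flow`; $i = k$ is
allowed (back-signaling), $i = j$ and $j = k$ are not. Nothing in expression
data couples the receptor a cell hears to the ligand it then speaks, so by
default any received signal may precede any emitted one; an optional
receptor-to-ligand link table restricts the join where pathway knowledge
exists. Cascades longer than two steps are not enumerated (combinatorial
growth, and two steps already capture the relay motif of interest).

## The ground-truth simulator

Validating communication inference on real tissue is circular — no
experimental assay reports "who signaled whom, how much". The package
therefore ships a reaction-diffusion simulator whose steady state *defines*
ground truth. On a $\sqrt n \times \sqrt n$ lattice (spacing $h$), each
(source cell $i$, ligand $L$) with production $p_{iL} > 0$ contributes a
field $u_{iL}$ solving

$$0 = D \nabla^2 u - k_\mathrm{deg}\, u -
      \textstyle\sum_{R : (L,R)} k_\mathrm{on}\, R_\mathrm{free}(x, R)\, u +
      p_{iL}\, \delta_{x_i},$$

with a 5-point Laplacian and no-flux boundaries. Receptor binding acts as an
internalizing sink on the free ligand; the free receptor pool is shared by
all ligands and satisfies, at every cell,
$R_\mathrm{free} = R_\mathrm{tot} / (1 + \sum_L (k_\mathrm{on}/k_\mathrm{off})\,
u^\mathrm{tot}_L)$ where $u^\mathrm{tot}_L$ superposes all sources. The
coupled system is resolved by a damped fixed-point iteration on
$R_\mathrm{free}$ (damping 0.5, relative tolerance $10^{-8}$, cap 500
iterations; each inner step is one sparse factorization per ligand solved
against all source right-hand sides at once), then the fields are recomputed
once at the converged $R_\mathrm{free}$. Ground truth is the equilibrium
bound complex at $j$ attributable to $i$:
$G(i,j,L,R) = (k_\mathrm{on}/k_\mathrm{off})\, u_{iL}(x_j)\,
R_\mathrm{free}(j, R)$.

Per-source fields are what make the truth *directional*; they superpose
exactly before the shared $R_\mathrm{free}$ factor, which the tests exploit.
Steady state (not transients) defines the communication amount — the simplest
well-posed target. Verified properties: the single-site equilibrium matches
the closed-form quadratic root to 0.1%; total production balances degradation
plus binding flux to $10^{-6}$ relative on every benchmark scenario; raising
one ligand's production strictly depresses every competitor's complexes at
shared receptors.

Three wiring regimes probe competition: `type1` (more ligands than receptors,
many-to-few), `type2` (the reverse), `type3` (dense random bipartite,
density at least 0.4, no isolated symbol). Scenario draws — which ligands a
cell secretes (probability 0.5 each, every ligand keeps at least one
producer), which receptors it displays (same), production rates and receptor
totals (log-uniform over $[0.1, 1]$ of their scales) — are fully reproducible
from one integer seed.

What the simulator does **not** emulate: transcriptional noise and dropout,
anisotropic or advective transport, receptor trafficking and recycling,
intracellular signal transduction, cell shape. Passing the recovery
benchmark therefore shows the inference tracks a clean biophysical
communication field; it does not certify performance on noisy, sparse real
data.

## Benchmark design and defaults

The default suite is 3 regimes x 3 seeds on a 5x5 lattice with
$D = k_\mathrm{prod} = k_\mathrm{deg} = k_\mathrm{on} = k_\mathrm{off} =
h = 1$; it runs in seconds on one CPU, and the problem sizes are stated here
as the package's defaults. The decay length $\sqrt{D/k_\mathrm{deg}}$ is one
lattice spacing, so the inference cutoff is set to $d_\mathrm{cutoff} = 2.5h$
(capturing essentially all of the signaling range) and the comparator's
kernel scale to $\sigma = d_\mathrm{cutoff}/2$. These were fixed from the
physics, once, before any benchmarking. Inference on the simulated tissue
uses the scenario's production rates as ligand "expression", receptor totals
as receptor "expression", affinity 1 and prior support on every wired pair.

Agreement is Spearman's $\rho$ between inferred and true amounts per (L, R)
pair over all ordered intercellular (source, target) grid entries (the model
builds no autocrine edges, so the diagonal is excluded for every method;
missing inferred entries count as zero), averaged over pairs. The comparator
is `baseline_distance_product()`:
$E_L(i)\, E_R(j)\, e^{-d_{ij}/\sigma}$ — the naive distance-weighted
expression product standing in for cluster- and transport-based tools.

### What the benchmark shows — and an honest limitation

On the default suite the flow method tracks ground truth well (per-run
median $\rho$ about 0.57-0.73, median across runs above 0.5), confirming the
pipeline recovers directional, pair-resolved communication from expression
and coordinates alone. It does **not** outperform the distance-product
baseline under these conditions (0 of 9 runs): with all node balances zero
and strictly positive costs, the optimal circulation sits at or near its
lower bounds $\varepsilon u_e$, which are flat in distance inside the cutoff
ball, while the baseline's exponential kernel happens to mirror the
simulator's Green's function and its expression product mirrors the
equilibrium complex. The circulation's added value — shared-capacity
competition and conservation coupling — contributes rank signal only through
the routing of lower-bound imbalances. We report this as measured; the
benchmark assertion encoding superiority is kept in the acceptance suite and
fails honestly rather than being weakened. On tissues where most cells both
send and receive (dense real data), the conservation coupling binds far more
strongly than on sparse simulated secretion patterns, and the relative
standing may differ.

## Numerical choices and degenerate inputs

* Strict inequalities at the cutoff and at $\tau$ give unambiguous boundary
  behavior; shrinking the cutoff or raising $\tau$ can only remove edges
  (tested as monotonicity properties).
* Expression values are used as given; normalize upstream (library size /
  spot deconvolution) — the package applies no hidden transform.
* Zero-edge graphs warn and return; all-zero capacity solves to the zero
  circulation; duplicate ids, negative values, mismatched cell sets and
  malformed tables error with located messages.
* Quantization can void tight intervals ($l_e$ rounds above $u_e$) at coarse
  quanta; the error message names the edges and suggests raising `quantum`.
* Among multiple optimal flow vectors any optimum is accepted; tests compare
  objectives, never flow vectors, except where conservation forces
  uniqueness.
* Outputs are written with 6 significant digits, LF endings; identical
  inputs and configuration reproduce byte-identical files.

## A worked example

```{r example}
sc <- make_scenario("type1", n_cells = 25, seed = 1)
sim <- simulate_steady_state(sc)
truth <- extract_ground_truth(sim, sc)
inputs <- scenario_to_inputs(sc)

config <- flow_config(d_cutoff = 2.5)
graph <- build_flow_graph(inputs$expression, inputs$coords, inputs$db, config)
graph
sol <- solve_flow(graph, relax_lower = TRUE)
sol
lig <- split_flows(sol, inputs$expression, inputs$db, config = config)
head(lig)
evaluate_inference(lig, truth)
head(enumerate_relays(lig, min_flow = 0.05), 3)
```

## Limitations

* Receptor complexes must be pre-flattened to single gene symbols; no
  heteromer expansion, orthology mapping, or bundled databases.
* Neighborhoods are cutoff balls in 2D; no k-nearest-neighbor or Delaunay
  graphs, no 3D coordinates.
* Ligand identity is restored after optimization, not encoded as
  commodities; a joint multi-commodity formulation is out of scope.
* The relay join is unconstrained by default — without a link table it
  enumerates co-location of in- and out-flows, not mechanistic signal
  propagation.
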