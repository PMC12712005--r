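---
title: "Exact minimum flow decomposition on cyclic graphs: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact minimum flow decomposition on cyclic graphs: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowdec)
```

## The problem

A flow network here is a weakly connected digraph with a unique source $s$
(in-degree 0), unique sink $t$ (out-degree 0), and a positive integer flow
$f_{uv}$ on every edge satisfying conservation at internal nodes. A
$k$-flow decomposition is a set of at most $k$ elements $W_i$ with positive
integer weights $w_i$ such that $\sum_i w_i\,W_i(u,v) = f_{uv}$ on every
edge, where $W_i(u,v)$ is the element's traversal count of $(u,v)$.
Minimizing $k$ is NP-hard even on DAGs; on cyclic graphs the package solves
three variants exactly, differing in what an element may be:

* **paths or cycles** (`fdpc`) — no node repeats (a cycle repeats only its
  endpoint);
* **trails** (`fdt`) — node repeats allowed, edge repeats not;
* **walks** (`fdw`) — both allowed.

Every variant is reduced to a sequence of MILP *feasibility* probes over
$k$ (no objective); each element is an auxiliary unit flow on binary or
integer edge variables $x_{uvi}$, and the products $w_i x_{uvi}$ are
linearized. Not every network admits a trail decomposition — the package's
`fig2_network()` (a weight-1 path sharing a node with a weight-2 cycle) is
the canonical counterexample — whereas paths-or-cycles and walks
decompositions always exist with at most $m$ elements, which bounds the
search.

## Element encodings

**Paths or cycles.** Binary $x_{uvi}$ with at most one edge out of $s$,
balance at internal nodes, and a per-node out-degree cap. Cycles are
admitted by a modified sequential (node-ordering) constraint: integer ranks
$d_{vi}\in[1,n]$ and binary cycle-start flags $c_{vi}$ on internal nodes,
with
$$d_{vi} \ge d_{ui} + 1 + (n-1)(x_{uvi} - 1 - c_{vi})$$
for every edge between internal nodes, and
$\sum_v x_{svi} + \sum_v c_{vi} \le 1$: an element is a single $s$-$t$ path,
a single cycle, or empty. Two notes on this encoding as implemented:

* *Terminal edges are exempt from the ordering constraint.* A cycle can
  never contain $s$ (no in-edges) or $t$ (no out-edges), so ordering is
  only ever needed between internal nodes; exempting edges at $s$ and $t$
  avoids pinning rank values that the argument never uses. The choice is
  covered by the oracle-equivalence tests.
* *The out-degree cap is redundant but kept.* The start constraint implies
  it; it is retained as a relaxation tightener behind `degree_cap = TRUE`,
  and the test suite checks the minimum is unchanged without it.

**Trails by constraint generation.** With binary $x$ and (weak)
conservation, the only failure mode is an element whose support contains a
strongly connected component (SCC) that never reaches $t$. A set of edges
can be ordered into one $s$-$t$ trail iff (1) signed conservation holds
($-1$ at $s$, $+1$ at $t$, $0$ elsewhere) and (2) every SCC of the induced
subgraph other than $\{t\}$ has a selected edge leaving its edge set. The
solver loop: solve, detect offending SCCs per element (adding an auxiliary
$(t,s)$ edge and computing strong components — exactly one component iff
the support is orderable), add for each offending component $C$ the
disjunction "some internal edge of $C$ unselected **or** some edge leaving
$C$ selected", linearized with a binary selector $\beta_{Ci}$ and
$M = |C|$ (its internal edge count), and repeat. Termination is guaranteed
(finitely many edge subsets). Generated cuts are valid for *every* trail
regardless of $k$ — the last edge of $C$ visited by a trail must be
followed by an edge leaving $C$'s edge set — so one cut pool is shared
across the probes of a minimum-$k$ search (`reuse_pool = TRUE`; an
equivalence test covers pool sharing versus fresh pools).

**Trails and walks by reachability.** An edge multiset is one $s$-$t$ walk
iff signed conservation holds and every incident node is reachable from
$s$ inside the multiset. Reachability is certified by a spanning tree:
binary $y_{uvi} \le x_{uvi}$ pick at most one incoming tree edge per node,
ranks $d_{vi} \in [0,n]$ with $d_{si}=1$ and $d_{vi}=0$ for unselected
nodes must strictly increase along tree edges, through the linearized
products $\phi_{uvi} = y_{uvi}(d_{vi}-d_{ui})$. Following tree parents
strictly decreases the rank, so every chain ends at the source. Binary $x$
gives trails; integer $x_{uvi} \in [0, f_{uv}]$ gives walks (an optional
`edge_cap` tightens the multiplicity bound). Solutions are spliced into an
explicit element by a Hierholzer-style Eulerian walk over the edge
multiplicities, with deterministic lexicographic tie-breaking.

*A literal-versus-corrected mode.* The conditional constraints "if $v$ is
selected then it has exactly one tree parent with a positive rank gap" can
be written several ways. The package's default (`formulation_mode =
"corrected"`) implements the conditionals directly:
$d_{vi} \le n \sum_{(u,v)} x_{uvi}$,
$\sum_{(u,v)} x_{uvi} \le B_v \sum_{(u,v)} y_{uvi}$ with $B_v$ the
in-degree (binary $x$) or the total in-flow (integer $x$),
$\sum_{(u,v)} y_{uvi} \le 1$, and
$\sum_{(u,v)} \phi_{uvi} \ge \sum_{(u,v)} y_{uvi}$.
An alternative pair of printed inequalities sometimes seen for this
construction — $\sum_{(u,v)} x_{uvi} \ge d_{vi}$ together with
$\sum_{(u,v)} x_{uvi} \le \sum_{(u,v)} \phi_{uvi}$ — simultaneously caps a
node's rank by its visit count and requires ranks to grow along the tree;
already on a three-edge path the third node would need rank at least 3 and
at most 1. That variant is kept behind
`formulation_mode = "literal"` for study, and a test documents its
overconstraint; it is not used by any solver path.

## Linearizations and big-M values

All products reduce to *binary × bounded integer*:
$p = b\cdot z$ with $z \in [\ell, h]$ uses the four standard inequalities
with $M = h$ when $\ell \ge 0$ and $M = \max(|\ell|, h)$ otherwise
(rank-gap products use $M = n$). Integer multiplicities are expanded in
power-of-two bits, $x = \sum_j 2^j b_j$ with
$j \le \lfloor\log_2 f_{uv}\rfloor$, so the weight product becomes a short
sum of binary products. The flow-fit product $\pi_{uvi} = w_i x_{uvi}$ is
bounded by $[0, f_{uv}]$ and uses **two different M values**:
$\pi \le f_{uv}\,x$ (the product can never exceed the edge flow), but the
activation bound $\pi \ge w - (1-x)M$ needs $M \ge \bar W$, the weight
upper bound — using $f_{uv}$ there would force every element's weight below
the flow of every edge it does *not* use, wrongly making the worked
example's paths-or-cycles minimum infeasible at $k=2$ (its cycle weight 2
exceeds the unused source edge's flow 1).

The weight bound itself is variant-specific: an $s$-$t$ element leaves the
source exactly once, so $\bar W = \max_{(s,v)} f_{sv}$ for trails and
walks; a cycle element never passes the source, so the paths-or-cycles
model uses the global maximum flow. Unused elements (all $x = 0$) keep
$w_i \in [1, \bar W]$ harmlessly, since all their products vanish —
weights stay strictly positive as the decomposition definition requires.
Optional symmetry breaking $w_1 \le \dots \le w_k$ is off by default
(reordering any solution by weight shows it never changes feasibility; a
test confirms the minimum is unchanged).

## Numerical policy

The backend is the HiGHS solver through `scipy.optimize.milp` (reticulate),
behind a minimal model container: integer variables with explicit finite
bounds, integer-coefficient linear constraints, constant-zero objective.
Solver output is rounded to integers with tolerance $10^{-5}$ — a larger
deviation is an error, not a warning — and every constraint is then
re-evaluated on the rounded assignment in exact integer arithmetic, so
reported feasibility never rests on floating-point slack. All verification
(`check_decomposition()`, the residuals, the set characterizations) is
pure integer arithmetic with no tolerances. HiGHS is deterministic for a
fixed model, so results are reproducible end to end from the seeds.

Degenerate inputs are handled at the boundaries: the empty model is
trivially feasible; empty elements are dropped at extraction ("at most
$k$" semantics; `exact_k = TRUE` switches to signed conservation forms
that force $k$ nonempty elements); self-loops, parallel edges, multiple
sources or sinks, and non-integral or non-positive flows are rejected at
load with a full violation report (`validate_flow_network()`).

## Search drivers

`min_k_linear()` probes $k = 1, 2, 3, \dots$; `min_k_doubling()` probes
$1, 2, 4, \dots$ (capped at $m$) and then scans the bracketing interval
(or bisects it with `binary_refine = TRUE`; feasibility is monotone in
$k$, so both refinements agree). Since any flow decomposes into at most
$m$ paths or cycles, only the trail variant can be globally infeasible,
certified once $k = m$ fails. Per-probe time budgets divide a global
limit; a timeout aborts the search rather than reporting a possibly wrong
minimum.

## The brute-force oracle

`brute_force_min_k()` is the independent ground truth for tiny instances
(guarded to $m \le 10$, flows $\le 8$, $k \le 6$): backtracking over
(element, weight) choices against the residual flow. Candidate elements
are enumerated as usage vectors by a state-space search over (node,
usage-so-far) states, which collapses the factorially many orderings of
one multiset into a single candidate; the first positive-residual edge
must be covered by the next element chosen (every remaining decomposition
covers it and element order is immaterial, so this is a sound symmetry
cut); failed (residual, remaining-$k$) states are memoized. The oracle
shares no code with the MILP path.

## The synthetic generator

`sim_flow_network()` plants a known decomposition and superposes it:
internal nodes split into a path pool, kept in a fixed topological order
so paths alone never create cycles, and fresh per-cycle detour nodes.
Cyclic content is anchored at a node of a planted path — a free-floating
cycle would disconnect the network — appearing as a separate cycle element
(`fdpc`), a once-spliced detour (`fdt`), or a detour traversed twice or
more (`fdw`). The planted decomposition verifies with zero residual by
construction and upper-bounds the true minimum (superposition can merge,
so equality is not asserted). The `lasso_network()` template generalizes
the worked example to produce trail-infeasible instances on demand: with
cycle weight above path weight, single-use elements cannot cover the
cycle.

What the generator does **not** emulate: the degree distributions, scale
(hundreds of nodes), or flow magnitudes of real splice graphs, genome
graphs, or road networks. Passing the suite demonstrates correctness of
the formulations and searches on exhaustively verifiable instances, not
solver performance at application scale.

## Test-suite conditions

The shared suite used by the verification tests and by
`scripts/acceptance.R` is 100 instances per variant with planted sizes
1–3, weights up to 6 (4 for walks, whose detours double edge flows), one
detour cycle on every second instance, and derived per-instance seeds —
sized so that every instance stays inside the oracle guard and the whole
suite cross-checks (oracle agreement, trail-formulation agreement, search
equivalence, upper bound $k = m$, greedy dominance) in about a minute on
one CPU. On these sizes the greedy baselines happen to match the exact
minimum; their known weakness (decompositions up to exponentially larger
than optimal) only materializes on larger, adversarial instances.

## Limitations

* No subpath constraints and no inexact/imperfect flow fitting; the flow
  must be matched exactly.
* No warm starts across probes and no solver-side lazy-constraint
  callbacks (the generation loop is a portable re-solve).
* One solver backend (HiGHS via scipy); the model container is
  backend-agnostic but no other binding ships.
* The oracle is deliberately unusable beyond tiny instances; at
  application scale the only correctness checks are the exact residual
  re-verification and cross-formulation agreement.
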