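# flowdec

Exact **minimum flow decomposition (MFD) on directed graphs with cycles**,
via integer linear programming.

Flow decomposition asks to express the flow of a network — a weakly
connected digraph with a unique source *s*, a unique sink *t*, and positive
integer flow values `f_uv` obeying conservation at every internal node — as
a weighted superposition of elements:

```
sum_i  w_i · W_i(u,v)  =  f_uv        for every edge (u,v),
```

where `W_i(u,v)` counts how often element `W_i` traverses `(u,v)` and each
weight `w_i` is a positive integer. Minimizing the number of elements *k*
is NP-hard already on DAGs, but it is the workhorse model for RNA transcript
assembly from splice graphs, strain deconvolution on genome graphs, and
traffic-route recovery in transportation networks — settings where the graph
often **contains cycles** and the classical DAG machinery does not apply.

`flowdec` solves the three natural cyclic variants exactly:

| variant | elements | formulation |
|---|---|---|
| `fdpc` | s-t paths **or cycles** (no repeated nodes) | sequential node-ordering constraints `d_vi ≥ d_ui + 1 + (n−1)(x_uvi − 1 − c_vi)` with per-node cycle-start flags `c_vi` |
| `fdt` | s-t trails (nodes may repeat, edges may not) | either iterative **constraint generation** over strongly-connected-component cuts, or a reachability model |
| `fdw` | s-t walks (nodes and edges may repeat) | reachability model: a spanning tree `y_uvi` rooted at *s* with rank variables `d_vi` certifies every selected node is reached by the element's own edges; integer edge multiplicities enter the flow-fit products through a power-of-two bit expansion |

Each element is encoded as an auxiliary unit flow `x_uvi`; the weight
products `w_i · x_uvi` are linearized with big-M inequalities, and the
minimum *k* is found by repeated feasibility probes (linear or
doubling-then-refine search). Everything is re-checked after solving in
exact integer arithmetic. Greedy shortest-path / widest-path baselines, an
exhaustive brute-force oracle for tiny instances, a planted-decomposition
instance generator, and the Catfish-style `.graph` format reader/writer are
included. The MILP backend is HiGHS, reached through
`scipy.optimize.milp` via reticulate; models are plain feasibility programs
with explicit finite bounds.

## Worked example

The five-edge cyclic network printed in the package as `fig2_network()`
(flows `s→a:1, a→b:2, b→c:2, c→a:2, a→t:1`):

```r
library(flowdec)
net <- read_flow_graphs(text = "# fig2\n5\ns a 1\na b 2\nb c 2\nc a 2\na t 1\n")[[1]]

mfd(net, "fdpc")
#> <mfd_result> fig2 [fdpc, cg/linear]: feasible, k = 2, iterations = 1, 0.05s
#>   [1] cycle w=2  a -> b -> c -> a
#>   [2] path  w=1  s -> a -> t

mfd(net, "fdw")
#> <mfd_result> fig2 [fdw, cg/linear]: feasible, k = 1, iterations = 1, 0.01s
#>   [1] walk  w=1  s -> a -> b -> c -> a -> b -> c -> a -> t

mfd(net, "fdt")
#> <mfd_result> fig2 [fdt, cg/linear]: infeasible, 0.05s
```

Read: two weighted elements (a cycle of weight 2 plus a path of weight 1)
fit the flow exactly; a *single* weight-1 walk that loops the cycle twice
also fits it; but **no set of trails ever can** — each trail may use a cycle
edge at most once, while the total element weight is capped at 1 by the
source edge. The brute-force oracle (`brute_force_min_k()`) confirms all
three answers by exhaustive search.

Results are tibble-friendly: `tidy(res)` returns one row per element,
`glance(res)` a one-row summary, and `autoplot(net)` /
`autoplot(res, net)` draw the network and the per-edge composition.

A thin command-line wrapper ships in `inst/cli/flowdec`:

```sh
Rscript inst/cli/flowdec solve --input fig2.graph --variant fdt --search doubling
Rscript inst/cli/flowdec generate --output synth.graph --planted-k 3 --seed 1
Rscript inst/cli/flowdec verify --input fig2.graph --decomposition out.json
```

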