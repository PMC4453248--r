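# evograph

Exact birth–death (Moran) fixation probabilities and structural metrics for
small weighted directed graphs.

## The problem

In evolutionary graph theory a structured population is a digraph: each
vertex carries one individual, and the weight `w_ij` is the probability
that, when vertex `i` reproduces, its offspring replaces the individual at
vertex `j`. Under birth–death updating a reproducer is drawn proportional
to fitness (residents 1, mutants `r`), and the population state is a binary
occupancy vector over the `N` vertices. The probability `x_v` that a state
`v` eventually reaches all-mutant fixation satisfies the master equations

```
[r a(v)·v' + b(v)·v] x_v = r Σ_i a_i(v) v'_i x_{v+e_i} + Σ_i b_i(v) v_i x_{v-e_i}
```

with `a(v) = v W`, `b(v) = v' W` (`v'` the complement), boundary conditions
`x_0 = 0`, `x_fix = 1` — a sparse linear system over the `2^N − 2` interior
states. The reference point is the Moran probability on the complete graph,

```
ρ_M = (1 − 1/r) / (1 − 1/r^N),
```

attained exactly on any graph whose weight matrix is doubly stochastic
("isothermal": every vertex has total incoming weight, *temperature*, 1).
Whether a graph *amplifies* or *suppresses* selection relative to `ρ_M` —
and how that depends on the fitness `r` — is the quantity of interest.

`evograph` solves these systems exactly (sparse LU, plus an exact
big-rational backend), constructs four structured families — biased cycles,
dual circular flows, partial bipartite and single-link graphs — and
computes the structural measures that track fixation behaviour: stationary
distributions, the weighted graph Laplacian
`Δ = Φ^{1/2}(I − W)Φ^{−1/2}` and its antisymmetric part (a measure of
directional bias), closed-form characteristic polynomials, subset and graph
conductance (Cheeger constant), Estrada communicability `e^W`, and
Kemeny–Snell expected hitting times. A temperature-tuning solver inverts
the flow construction: given level sizes and a target temperature profile
it returns the exact affine family of edge weights realizing it, with exact
feasibility intervals.

It is aimed at researchers studying amplifiers/suppressors of selection,
information spread in polarized populations, and the relationship between
spectral/structural graph parameters and fixation.

## Worked example

The `(1,2,3)` dual circular flow is a ring of three levels (sizes 1, 2, 3);
each vertex sends total weight `p` to the level below and `1 − p` to the
level above. At `p = 1` (funnel) it amplifies selection only for a window
of fitnesses:

```r
library(evograph)

g <- dual_circular_flow(c(1, 2, 3), 1)
solve_fixation(g, r = 2)
#> <fixation_solution> N=6 r=2 backend=double
#>   single-vertex: v1=0.410857 v2=0.346328 v3=0.346328 v4=0.675927 v5=0.675927 v6=0.675927
#>   rho = 0.52188265  (Moran rho_M = 0.50793651)

# where does the amplification end?
crossing_finder(mode = "fitness", target = "moran", solver = "lumped",
                sizes = c(1, 2, 3), p = 1, bracket = c(1.01, 20), tol = 1e-6)
#> [1] 5.369515
```

So a mutant of fitness `r = 2` fixes with probability 0.5219 (vs the Moran
0.5079), but the advantage disappears beyond `r ≈ 5.3695`.

Tuning the same level structure to the isothermal profile forces a unique
weight assignment, which then has exactly the Moran fixation probability:

```r
isothermal_tuning(c(1, 2, 3))
#> <tuning_solution> sizes = 1,2,3  t = 1,1,1
#>   p_0 = -1 + 3 * p_2
#>   p_1 = -1 + 3/2 * p_2
#>   p_2 = 0 + 1 * p_2
#>   feasible: p_2 in [2/3, 2/3]

g_iso <- tuning_graph(isothermal_tuning(c(1, 2, 3)))   # p = (1, 0, 2/3)
solve_fixation(g_iso, 2)$rho - moran_probability(6, 2)
#> [1] -3.330669e-16
```

Structural metrics on a partial bipartite graph (two all-to-all coupled
blocks with intra-weights `p`, `q`):

```r
g <- partial_bipartite(3, 4, 1/3, 1/2)
spectral_report(g)$eigenvalues      # 0 and a sixfold eigenvalue 7/6
#> [1] 1.387779e-16 1.166667e+00 1.166667e+00 1.166667e+00 1.166667e+00
#> [6] 1.166667e+00 1.166667e+00
eigenvalue_equality_point(3, 4)$point  # the (p, q) where that happens
#>         p         q
#> 0.3333333 0.5000000
```

A thin command line sits over the same functions:

```sh
exec/evograph build --family cycle --N 5 --p 0.7 --out cycle.json
exec/evograph fixation --graph cycle.json --r 2
exec/evograph tune --sizes 1,2,3 --t 1,1,1
```

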