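---
title: "Methods: exact birth–death fixation on weighted digraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact birth–death fixation on weighted digraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evograph)
```

## The model

A population of fixed size $N$ lives on a digraph with row-stochastic
weight matrix $W$; $w_{ij}$ is the probability that vertex $i$'s offspring
replaces the individual at vertex $j$. Individuals are binary: residents
(fitness $1$) or mutants (fitness $r$). Each step of the birth–death
process selects a reproducer with probability proportional to fitness and
places the offspring along an out-edge drawn from the reproducer's row of
$W$. The model assumes constant $N$, global (fitness-proportional)
selection of the reproducer, and state-independent edge weights.

A state is the occupancy vector $v \in \{0,1\}^N$. Writing
$a(v) = vW$ (weight flowing from mutants into each vertex),
$b(v) = v'W$ with $v' = 1 - v$, and $m$ for the mutant count, the fixation
probability $x_v$ satisfies, for every interior state,

$$\big[N + (r-1)m - r\,a(v)\!\cdot\! v - b(v)\!\cdot\! v'\big] x_v
  - r\sum_i a_i(v)\,v'_i\,x_{v + e_i}
  - \sum_i b_i(v)\,v_i\,x_{v - e_i} = 0 ,$$

with $x$ at the extinction and fixation states substituted as $0$ and $1$.
The bracket equals the total rate of state-changing events
$r\,a\cdot v' + b\cdot v$ (total fitness minus the self-replacements); the
assembly uses the second form and the test suite cross-checks the
equivalence against an independent dense assembly. $m$ enters only through
that normalization, which is why the equation is homogeneous in it.

**State indexing.** Internally the state index is
$\sum_k v_k 2^{k-1}$ (vertex $k$ on bit $k-1$). Single-mutant states have
index $2^{k-1}$ under both this and the big-endian convention
($\sum_k v_k 2^{N-k}$), so the familiar labels $x_1, x_2, x_4, x_8, \dots$
for "one mutant at vertex $k$" are unambiguous; `bigendian_state_index()`
converts multi-mutant indices between the two bit orders.

**Solvers.** The interior system is sparse (each row has at most $N+1$
nonzeros) and is solved by sparse LU (`Matrix`). The default cap is
$N \le 12$ ($4094$ unknowns), beyond which the lumped flow solver is the
intended route. Before solving, a reachability sweep over the $2^N$ state
graph detects states that can reach neither absorbing state; such states
make the system singular (the graph is reducible) and produce an explicit
error naming examples, rather than garbage from a near-singular solve.

The `"rational"` backend re-assembles the same system over exact rationals
(fraction strings such as `"2/3"` are kept exact; every numeric double is a
dyadic rational, so nothing is approximated) and eliminates it
fraction-free (Bareiss) over arbitrary-precision integers implemented in
the package. It is practical through $N = 6$ (62 unknowns, a few seconds)
and returns exact fractions — e.g. the biased 5-cycle at $r = 2$ yields
exactly $16/31$ for every vertex.

**Average fixation probability.** `solve_fixation()$rho` is the plain mean
of the $N$ single-vertex probabilities, which equals the
multiplicity-weighted mean over symmetry classes (for the $(1,2,3)$ flow,
$(x_1 + 2x_2 + 3x_8)/6$).

## Graph families and orientation conventions

*Biased cycle* `biased_cycle(N, p)`: vertices numbered clockwise; each
vertex sends $p$ counter-clockwise (previous index, mod $N$) and $1-p$
clockwise. Two statements forced this orientation: it makes
`dual_circular_flow` at unit level sizes coincide *entrywise* with the
cycle, and it puts the argmax over $p$ of the one-step hitting time
$h_{1,2}$ of the 5-cycle at $0.68806$ (the tipping point between taking the
direct step and travelling the other $N-1$ edges), with the mirrored vertex
peaking at $1 - 0.68806$. The matrix is doubly stochastic for every $p$,
so fixation is Moran regardless of bias.

*Dual circular flow* `dual_circular_flow(sizes, p)`: a ring of $k+1$
levels; a level-$i$ vertex spreads $p_i$ uniformly over level $i-1$ and
$1-p_i$ over level $i+1$ (no intra-level edges). The per-edge division by
the *target* level size is pinned down by two consistency requirements:
the vertex temperature (column sum) must equal
$t_i = (n_{i+1}p_{i+1} + n_{i-1}(1-p_{i-1}))/n_i$, and the lumped master
equations over per-level mutant counts must agree with the full
state-space solver — both are asserted in the tests. $p \equiv 0$ is the
cascade, $p \equiv 1$ the funnel.

*Partial bipartite* `partial_bipartite(s, n, p, q)`: intra-weights
$p/(s-1)$, $q/(n-1)$; cross-weights $(1-p)/n$, $(1-q)/s$; $p=q=0$ is
$K_{s,n}$. *Single-link* `single_link(s, n, p, q)`: internally complete
components joined through one linking vertex on each side; vertex order is
the $s-1$ non-linkers, the two linkers, the $n-1$ non-linkers.

Endpoints $p, q \in \{0, 1\}$ are legal at construction; operations that
become singular there (stationary distribution, Laplacian, hitting times,
fixation on reducible graphs) detect the condition and raise targeted
errors instead.

## The lumped flow solver

For uniform $p$, exchangeability within levels lumps the $2^N$ states to
mutant-count vectors $(m_0,\dots,m_k)$, $\prod (n_i + 1) - 2$ interior
unknowns. The transition rates are
$m_i \to m_i + 1$ at $r\,(n_i - m_i)\,[m_{i+1}p + m_{i-1}(1-p)]/n_i$ and
$m_i \to m_i - 1$ at $m_i\,[(n_{i+1}-m_{i+1})p + (n_{i-1}-m_{i-1})(1-p)]/n_i$.
Agreement with the full solver to $10^{-10}$ over profiles, weights and
fitnesses is part of the acceptance suite. Per-level weights are not
lumped (the symmetry argument needs uniform $p$); the full solver covers
that case.

## Closed form for complete bipartite graphs

For $K_{s,n}$ the lumped process is the pair $(i, j)$ of mutant counts, and
$M = a^i b^j$ with

$$a = \frac{nr+s}{r(sr+n)}, \qquad b = \frac{sr+n}{r(nr+s)}$$

is an exact martingale of the embedded jump chain (the two balance
conditions on the coefficients have exactly this solution, with
$ab = r^{-2}$). Optional stopping gives
$x_{ij} = (1 - a^i b^j)/(1 - a^s b^n)$ and the single-vertex average

$$\rho_{K_{s,n}} \;=\;
\frac{r^{n+s-1}(r^2-1)\,(snr + n^2 - sn + s^2)\,(nr+s)^{n-s-1}}
     {(sr+n)\,\big[r^{n+s}(nr+s)^{n-s} - (sr+n)^{n-s}\big]}.$$

At $s = n$ this collapses to the Moran probability (the graph is doubly
stochastic), and $r \to 1$ gives $1/(s+n)$. The derivation is independent
of the state-space solver, and the two agree to $10^{-10}$ on
$(s,n) \in \{(1,3),(2,3),(2,5),(3,4)\}$ across fitnesses — that agreement
is what qualifies the formula for use.

## Spectral structure

The Laplacian is $\Delta = \Phi^{1/2}(I - W)\Phi^{-1/2}$ with $\Phi$ the
diagonal of the stationary vector $\phi W = \phi$ (computed by a direct
linear solve with the normalization row; irreducibility is checked first).
$\Delta$ is similar to $I - W$, so every closed-form characteristic
polynomial below is equivalently a statement about the spectrum of $W$;
$\Delta$ itself is still formed because its antisymmetric part
$\Delta_A = (\Delta - \Delta^{\mathsf T})/2$ measures directional bias.

*Cycles.* $\Delta = I - W$ exactly (uniform $\phi$). The characteristic
polynomial is the alternating expansion in powers of $(\lambda - 1)$ with
Lucas-type coefficients $C^N_k = \frac{N}{N-k}\binom{N-k}{k}$ (satisfying
$C^N_k = C^{N-1}_k + C^{N-2}_{k-1}$, $C^N_0 = 1$, $C^N_1 = N$) and a
parity tail: $+\,p^N + (1-p)^N$ for odd $N$, $-\,K_N$ for even $N$ with
$K_N = (p^{N/2} \mp (1-p)^{N/2})^2$ according to $N \bmod 4$ — the sign
split was validated against numeric spectra for $N = 4, 6, 8$ before being
adopted. At $p \in \{0,1\}$ the eigenvalues are $1 \pm e^{2\pi i k/N}$.
$\Delta_A = \tfrac{1-2p}{2}(P^{\mathsf T} - P)$ for the cyclic shift $P$,
so all its eigenvalues are imaginary with an exact $(1-2p)$ factor.

*Flows.* The $\phi^{1/2}$-weighted level indicators have equal norms
(level mass is uniform because the level quotient is doubly stochastic),
so $\Delta$ restricted to that subspace is *exactly* the $(k+1)$-cycle
Laplacian, and both $\Delta$ and $\Delta^{\mathsf T}$ act as the identity
on its orthogonal complement. Hence the characteristic polynomial of
$\Delta$ is $(\lambda-1)^{N-k-1}$ times the $(k+1)$-cycle polynomial
(degree bookkeeping fixes the cycle factor at $k+1$ vertices), and
$\Delta_A$ is $\lambda^{N-k-1}$ times the cycle's antisymmetric-part
polynomial — in particular the $(1-2p)$ bias factor survives lumping
unchanged, which the tests verify on full vertex-level matrices.

*Partial bipartite.* Eigenvalues $0$, $(s-1+p)/(s-1)$ ($\times\,s{-}1$),
$(n-1+q)/(n-1)$ ($\times\,n{-}1$), $2-p-q$; all three non-zero values
coincide exactly at $(p,q) = (s-1, n-1)/(n+s-1)$
(`eigenvalue_equality_point()`), which is also the exact minimizer of
$\mathrm{Tr}(e^W)$. A point worth flagging: the stationary-weighted chain
satisfies detailed balance ($\phi_i w_{ij} = \phi_j w_{ji}$ — both cross
products equal $(1-p)(1-q)$ up to the common normalization), so $\Delta$
is *symmetric* and $\Delta_A \equiv 0$. Published block forms giving this
family a non-zero imaginary pair do not survive the numeric oracle;
`closed_form_spectra()` reports the reversibility verdict in its
`findings`.

*Single-link.* Fixed factors $(\lambda - \frac{s}{s-1})^{s-2}$ and
$(\lambda - \frac{n}{n-1})^{n-2}$ come from the within-component
complement spaces; the remaining four eigenvalues are those of the exact
$4\times 4$ exchangeability quotient (non-linkers/linker on each side),
whose characteristic polynomial is computed by Faddeev–LeVerrier in exact
rational arithmetic and factors as $\lambda$ times a cubic.

## Structural metrics

*Conductance.* $C(S) = \frac{N}{|S||V\setminus S|}\sum_{i\in S, j\notin S} w_{ij}$,
directed (no symmetry between $S$ and its complement is assumed). The
global Cheeger constant is an exhaustive minimum over proper subsets,
capped at $N \le 20$.

*Communicability.* $V = e^W$ by scaling-and-squaring, or the literal
sixth-order series $I + W + \dots + W^6/720$ (`mode = "series6"`); for
row-stochastic $W$ the truncation remainder is bounded by
$\sum_{k\ge 7} 1/k! \approx 2.3\times 10^{-4}$ per entry, and the $3\times
10^{-4}$ agreement between modes is asserted on every family.

*Hitting times.* Kemeny–Snell: $Z = (I - (W - A))^{-1}$ with
$A = \mathbf 1 \phi^{\mathsf T}$ (every row the stationary vector), and
$M = (I - Z + J\,\mathrm{diag}(Z))\,D$ with $D = \mathrm{diag}(1/\phi_j)$,
so $h_{ij} = (z_{jj} - z_{ij})/\phi_j$ off the diagonal and expected
return times $1/\phi_i$ on it. Both the choice of $D$ and the
row-orientation of $A$ were fixed by requiring agreement with an
independent first-step-analysis solve (for each target $j$, solve
$h_{ij} = 1 + \sum_k w_{ik}h_{kj}$ over $i \ne j$); the transposed
("columns") reading reproduces nothing and was rejected. The two routes
share no code and agree to $10^{-9}$ on every family tested.

*Reference closed forms.* `closed_form_metrics()` evaluates exact
expressions for the two-component families: between-class hitting times
derived by two-unknown first-step analysis under exchangeability,
communicability blocks from the $2\times 2$ quotient of $W$, the
spectral form of $\mathrm{Tr}(e^W)$, the component conductances, and (for
the $(3,4)$ single-link graph) the full pairwise hitting-time table and
the equality conditions between naturally paired entries. Every
expression is gated on oracle agreement. Where commonly printed versions
of these formulas fail the oracle, the corrected form is used and the
discrepancy is recorded in the returned `findings` — among them: the
between-component hitting-time denominators $(1-p)(n-1+q)$ /
$(1-q)(s-1+p)$ (not $s$ and $n$ swapped); diagonal communicabilities need
the within-block term $(1-\frac1s)e^{-p/(s-1)}$; the single-link $h_{41}$
denominator is $3p(1-q)$; $h_{54} = n - 1 = 3$ (the widely quoted $4$
contradicts the same table's identity $h_{53} = h_{54} + h_{43} =
4/(1-q)$); and the equality condition $q = 3p/(4-p)$ belongs to
$h_{34}/h_{43}$ only ($h_{53} = h_{14}$ holds on $q = (4p-1)/3$).

The average communicability of the $(3,4)$ single-link graph has a single
interior stationary point, a saddle, at $(p, q) = (0.5542, 0.3734)$
(series6; $(0.5541, 0.3734)$ exact). `saddle_point_search()` locates and
classifies such points by damped Newton iteration on a central-difference
gradient from a grid of starts, classifying via the numeric Hessian.

## Temperature tuning

Matching a target temperature profile $t$ on level sizes $n$ means solving
the cyclic stride-2 system
$n_{i+1}p_{i+1} - n_{i-1}p_{i-1} = t_i n_i - n_{i-1}$. The package solves
it by chain propagation in exact rational arithmetic: with an odd number of
levels one chain covers all weights (free parameter: the highest-index
$p_k$); with an even number the even- and odd-index weights decouple into
two chains (free: the two highest indices), each with a closure constraint
(an alternating sum condition on $t$) whose violation is reported as
structural infeasibility with the exact residual. Conservation
$\sum t_i n_i = N$ is checked first. Feasibility is the exact
intersection of the interval constraints $0 \le \alpha_i + \beta_i p \le 1$
(all $\beta_i > 0$ by construction), reported with exact endpoints; the
$(1,2,3)$ isothermal problem collapses to the single point $p_2 = 2/3$,
forcing $(p_0, p_1) = (1, 0)$. Realized graphs re-verify their profile in
rational arithmetic before being returned. Temperature does not determine
fixation: the profile $(2, \frac32, \frac13)$ on $(1,2,3)$ admits a
one-parameter family of graphs whose fixation probabilities at $r = 2$
differ by more than $10^{-2}$ — tuning controls replacement rates, not the
full flow structure.

## Numerical choices

* Row-stochasticity tolerance $10^{-12}$ at construction; stationary
  residual tolerance likewise.
* Bisection: default tolerance $10^{-7}$ on parameters ($10^{-5}$ to
  $10^{-6}$ in the reproduction scripts, matching the precision of the
  values they target); brackets are required to change sign, with an
  explicit error otherwise. A hook lets a caller substitute a
  higher-precision comparator when the float difference falls below
  $10^{-12}$; at the bisection tolerances used here the float path never
  comes close to that regime (differences near the root are
  $\gtrsim 10^{-8}$).
* Singular boundaries: at endpoints such as $(p, q) = (1, 0)$ in the
  $(2,5)$ partial bipartite graph, part of the graph is never replaced,
  fixation from any single mutant is impossible, and the interior solution
  has a removable limit. `boundary_limit_fixation()` solves at
  $\varepsilon = 10^{-6}, 10^{-8}$ off the boundary and extrapolates
  linearly; the two offsets already agree to $10^{-6}$ in the resulting
  crossing, and the same pipeline reproduces the neighbouring regular
  value ($p = 0.875$) without extrapolation.
* Degenerate inputs: reducible graphs error with named unreachable states;
  zero stationary mass blocks the Laplacian with a targeted message;
  divergent hitting times at endpoints are reported as `Inf`.
* Exact arithmetic: base-$2^{20}$ limb integers (all limb products exact in
  doubles), Knuth division, Euclid GCD; rational reduction after every
  operation; Bareiss elimination keeps matrix entries integral with exact
  divisions only.

## What the random fixtures do and do not cover

`fixture_graphs()` generates seeded row-stochastic matrices (uniform
positive rows) and doubly stochastic matrices (convex combinations of
random derangements). They exercise the solver and the isothermal theorem
on unstructured weight patterns, but they are dense and homogeneous: they
do not emulate sparse real interaction networks, degree heterogeneity,
or near-reducible bottlenecks, so passing the property suites on them says
nothing about numerical behaviour at those extremes beyond what the
structured families (which do include bottlenecks and boundary-singular
cases) test directly.

## Problem sizes

The test and reproduction workloads were chosen to keep every individual
solve well inside dense/sparse direct-solver comfort: full state spaces up
to $N = 7$ (126 unknowns) in the property suites, $N = 6$ for the exact
rational backend, lumped flows with 22 interior states for the crossing
searches, and 126-state solves inside the boundary-limit bisections. The
equality-line suite performs a few hundred such solves; everything else is
single solves or small grids.

## Known limitations

* Full state-space solves are capped at $N = 12$; no approximate or
  Monte Carlo fallback is provided for larger graphs.
* The lumped solver requires uniform inter-level weights.
* Death–birth and voter updating, time-to-fixation distributions, and
  statistical ensembles of random/small-world graphs are out of scope.
* The exhaustive Cheeger minimization is exponential and practical only to
  $N \approx 16$–20.
* The exact rational backend's cost grows quickly with the bit-size of
  intermediate minors; beyond $N = 6$ use the float path.
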