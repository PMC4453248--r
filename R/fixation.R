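# Birth-death fixation probabilities from the full state-space master
# equations.
#
# A population state is a binary occupancy vector v (1 = mutant).  The
# internal canonical state index is sum_k v_k 2^(k-1), so bit k-1 of the
# index corresponds to vertex k.  Single-mutant states have the same label
# under both this convention and the big-endian "x_{2^(k-1)}" labelling;
# for multi-mutant states the two bit orders differ and
# [bigendian_state_index()] converts.
#
# For an interior state v with mutant count m, propagation vectors
# a(v) = v W and b(v) = v' W (v' the complement), the master equation is
#   [r a.v' + b.v] x_v = r sum_i a_i v'_i x_{v + e_i} + sum_i b_i v_i x_{v - e_i}
# with boundary conditions x_0 = 0 (extinction) and x_all-ones = 1
# (fixation) substituted, never solved for.  The diagonal coefficient
# equals N + (r-1)m - r a.v - b.v' (total fitness minus the no-change
# events), which is the form the assembly asserts.

# bits of states 0..2^N-1 as a (2^N x N) 0/1 matrix; column k is vertex k
state_bit_matrix <- function(N) {
  S <- 2^N
  V <- matrix(0, S, N)
  idx <- 0:(S - 1)
  for (k in seq_len(N)) V[, k] <- idx %/% 2^(k - 1) %% 2
  V
}

#' Population state descriptor
#'
#' @param v binary occupancy vector (1 = mutant), vertex k in position k
#' @return list with the occupancy vector `v`, the internal state index
#'   (`sum v_k 2^(k-1)`), the big-endian index (`sum v_k 2^(N-k)`), the
#'   mutant count `m`, and the complement vector
#' @export
population_state <- function(v) {
  stopifnot(all(v %in% c(0, 1)))
  N <- length(v)
  list(v = v,
       index = sum(v * 2^(seq_len(N) - 1)),
       index_bigendian = sum(v * 2^(N - seq_len(N))),
       m = sum(v),
       complement = 1 - v)
}

#' Convert an internal state index to the big-endian index
#'
#' The internal canonical order puts vertex k on bit k-1; the big-endian
#' order writes the occupancy vector as a binary numeral with vertex 1 as
#' the most significant bit.  Single-mutant states coincide under both.
#'
#' @param index internal state index (0-based)
#' @param N number of vertices
#' @return big-endian index
#' @export
bigendian_state_index <- function(index, N) {
  v <- index %/% 2^(0:(N - 1)) %% 2
  sum(v * 2^(N - seq_len(N)))
}

# forward transitions for all states: list(up = rate matrix 2^N x N,
# down = rate matrix), up[v+1, i] = rate of flipping vertex i on
state_rates <- function(graph, r) {
  N <- graph$N
  V <- state_bit_matrix(N)
  A <- V %*% graph$W        # a_j(v) = weight from mutants into j
  B <- (1 - V) %*% graph$W
  list(V = V, up = r * A * (1 - V), down = B * V)
}

# states (other than the absorbing pair) that can reach neither absorbing
# state: these make the master system singular
unreachable_states <- function(graph, r = 2) {
  N <- graph$N
  S <- 2^N
  rt <- state_rates(graph, r)
  can_reach <- function(target) {
    seen <- logical(S)
    seen[target + 1L] <- TRUE
    queue <- target
    while (length(queue)) {
      w <- queue[[1L]]
      queue <- queue[-1L]
      wv <- rt$V[w + 1L, ]
      for (i in seq_len(N)) {
        # predecessor differing in bit i
        v <- if (wv[i] == 1) w - 2^(i - 1) else w + 2^(i - 1)
        if (seen[v + 1L]) next
        rate <- if (wv[i] == 1) rt$up[v + 1L, i] else rt$down[v + 1L, i]
        if (rate > 0) {
          seen[v + 1L] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
    seen
  }
  ok <- can_reach(S - 1L) | can_reach(0L)
  setdiff(which(!ok) - 1L, c(0L, S - 1L))
}

#' Assemble the master-equation linear system
#'
#' Builds the sparse `(2^N - 2)`-dimensional linear system for the interior
#' fixation probabilities, with the extinction and fixation boundary values
#' substituted (fixation contributions move to the right-hand side).
#'
#' @param graph a `weighted_digraph`
#' @param r mutant fitness (positive)
#' @return list with the sparse coefficient matrix `A`, right-hand side
#'   `rhs`, the interior state indices `states` (internal convention), the
#'   fitness `r`, and the propagation-rate matrices
#' @export
build_master_system <- function(graph, r) {
  stopifnot(inherits(graph, "weighted_digraph"), r > 0)
  N <- graph$N
  S <- 2^N
  if (N > 25) stop("state space 2^N too large")
  rt <- state_rates(graph, r)
  interior <- 1:(S - 2)              # internal indices of interior states
  D <- rowSums(rt$up) + rowSums(rt$down)
  # spec-form diagonal for cross-checking: N + (r-1)m - r a.v - b.v'
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(S - 2)
  for (i in seq_len(N)) {
    bit <- 2^(i - 1)
    up_rate <- rt$up[interior + 1L, i]
    sel <- which(up_rate > 0)
    if (length(sel)) {
      src <- interior[sel]
      tgt <- src + bit
      fix <- tgt == S - 1
      if (any(fix)) rhs[src[fix]] <- rhs[src[fix]] + up_rate[sel][fix]
      keep <- !fix
      ii <- c(ii, src[keep]); jj <- c(jj, tgt[keep])
      xx <- c(xx, -up_rate[sel][keep])
    }
    down_rate <- rt$down[interior + 1L, i]
    sel <- which(down_rate > 0)
    if (length(sel)) {
      src <- interior[sel]
      tgt <- src - bit
      keep <- tgt != 0                # x_0 = 0 drops out
      ii <- c(ii, src[keep]); jj <- c(jj, tgt[keep])
      xx <- c(xx, -down_rate[sel][keep])
    }
  }
  ii <- c(ii, interior); jj <- c(jj, interior)
  xx <- c(xx, D[interior + 1L])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(S - 2, S - 2))
  list(A = A, rhs = rhs, states = interior, r = r, rates = rt, N = N)
}

# exact assembly + solve over rationals (dense, Bareiss); N small
solve_fixation_rational <- function(graph, r) {
  N <- graph$N
  S <- 2^N
  if (S - 2 > 70)
    stop("rational backend supports N <= 6 (dense exact elimination); ",
         "use backend = \"double\"")
  Wq <- graph_exact_matrix(graph)
  rq <- as_q(r)
  V <- state_bit_matrix(N)
  n_int <- S - 2
  A <- qm_new(n_int, n_int)
  rhs <- rep(list(q_zero()), n_int)
  for (v in 1:(S - 2)) {
    bits <- V[v + 1L, ]
    aq <- vector("list", N); bq <- vector("list", N)
    for (j in seq_len(N)) {
      sa <- q_zero(); sb <- q_zero()
      for (i in seq_len(N)) {
        w <- qm_get(Wq, i, j)
        if (q_is_zero(w)) next
        if (bits[i] == 1) sa <- q_add(sa, w) else sb <- q_add(sb, w)
      }
      aq[[j]] <- sa; bq[[j]] <- sb
    }
    diagq <- q_zero()
    for (i in seq_len(N)) {
      if (bits[i] == 0) {
        rate <- q_mul(rq, aq[[i]])
        if (q_is_zero(rate)) next
        diagq <- q_add(diagq, rate)
        tgt <- v + 2^(i - 1)
        if (tgt == S - 1) rhs[[v]] <- q_add(rhs[[v]], rate)
        else A <- qm_set(A, v, tgt, q_sub(qm_get(A, v, tgt), rate))
      } else {
        rate <- bq[[i]]
        if (q_is_zero(rate)) next
        diagq <- q_add(diagq, rate)
        tgt <- v - 2^(i - 1)
        if (tgt != 0) A <- qm_set(A, v, tgt, q_sub(qm_get(A, v, tgt), rate))
      }
    }
    A <- qm_set(A, v, v, diagq)
  }
  q_solve(A, rhs)
}

#' Solve for fixation probabilities from every initial state
#'
#' Assembles and solves the master equations, returning the fixation
#' probability of every state of the `2^N` state space.  The `"rational"`
#' backend performs fraction-free exact elimination over big rationals
#' (dense; practical for `N <= 6`) and returns exact fractions alongside
#' their numeric values.
#'
#' @param graph a `weighted_digraph`
#' @param r mutant fitness; numeric, fraction string, or `rational`
#' @param backend `"double"` (sparse LU) or `"rational"` (exact)
#' @param cap largest N accepted for the full state-space solve
#' @return object of class `fixation_solution`: a list with `x` (numeric
#'   vector of length `2^N`, position `v + 1` holding `x_v` for internal
#'   state index `v`), `single_vertex` (the `x_{2^(k-1)}`), `rho` (their
#'   average), `backend`, and for the rational backend `x_exact` (character
#'   fractions)
#' @export
solve_fixation <- function(graph, r, backend = c("double", "rational"),
                           cap = 12) {
  backend <- match.arg(backend)
  stopifnot(inherits(graph, "weighted_digraph"))
  rnum <- if (is.numeric(r)) r else q_to_num(as_q(r))
  stopifnot(rnum > 0)
  N <- graph$N
  if (N > cap)
    stop("N = ", N, " exceeds the full state-space cap (", cap, "); ",
         "for circular flows use lumped_flow_fixation()")
  bad <- unreachable_states(graph, rnum)
  if (length(bad))
    stop("master system is singular: ", length(bad), " state(s) can reach ",
         "neither absorbing state (graph is reducible); e.g. internal ",
         "state indices ", paste(utils::head(bad, 5), collapse = ", "))
  S <- 2^N
  x <- numeric(S)
  x[S] <- 1
  exact <- NULL
  if (backend == "rational") {
    xs <- solve_fixation_rational(graph, r)
    x[2:(S - 1)] <- vapply(xs, q_to_num, 0)
    exact <- c("0", vapply(xs, q_format, ""), "1")
  } else {
    sys <- build_master_system(graph, rnum)
    sol <- tryCatch(Matrix::solve(sys$A, sys$rhs),
                    error = function(e)
                      stop("master system solve failed (singular or ",
                           "ill-conditioned): ", conditionMessage(e)))
    x[2:(S - 1)] <- as.numeric(sol)
  }
  sv <- x[2^(seq_len(N) - 1) + 1L]
  names(sv) <- graph$vertex_labels
  structure(list(x = x, single_vertex = sv, rho = mean(sv),
                 N = N, r = rnum, backend = backend, x_exact = exact),
            class = "fixation_solution")
}

#' @export
print.fixation_solution <- function(x, ...) {
  cat(sprintf("<fixation_solution> N=%d r=%g backend=%s\n",
              x$N, x$r, x$backend))
  cat("  single-vertex:", paste(sprintf("%s=%.6g", names(x$single_vertex),
                                        x$single_vertex), collapse = " "), "\n")
  cat(sprintf("  rho = %.8g  (Moran rho_M = %.8g)\n", x$rho,
              moran_probability(x$N, x$r)))
  invisible(x)
}

#' Moran fixation probability on the complete graph
#'
#' `rho_M,k = (r^(N-1) + ... + r^(N-k)) / (1 + r + ... + r^(N-1))`, the
#' probability that `k` initial mutants of fitness `r` fix in a well-mixed
#' population of size `N`.  `k = 1` gives the classical
#' `(1 - 1/r) / (1 - 1/r^N)`; `r = 1` gives `k/N` (neutral limit).
#'
#' @param N population size
#' @param r mutant fitness (positive)
#' @param k number of initial mutants (`0 <= k <= N`)
#' @return fixation probability
#' @examples
#' moran_probability(5, 2)       # 16/31
#' moran_probability(3, 2, k = 2) # 6/7
#' @export
moran_probability <- function(N, r, k = 1) {
  stopifnot(N >= 1, r > 0, k >= 0, k <= N)
  if (k == 0) return(0)
  if (abs(r - 1) < 1e-14) return(k / N)
  pw <- r^(0:(N - 1))
  sum(pw[(N - k + 1):N]) / sum(pw)
}

#' Closed-form single-vertex fixation probability for complete bipartite
#' graphs
#'
#' For `K_{s,n}` under birth-death updating the lumped mutant-count process
#' `(i, j)` admits the exact product martingale `a^i b^j` with
#' `a = (nr+s)/(r(sr+n))` and `b = (sr+n)/(r(nr+s))`, giving
#' `x_{ij} = (1 - a^i b^j) / (1 - a^s b^n)`.  Averaging the two
#' single-mutant states over component sizes yields
#' \deqn{\rho = \frac{r^{n+s-1}(r^2-1)(snr + n^2 - sn + s^2)(nr+s)^{n-s-1}}
#'              {(sr+n)\,[r^{n+s}(nr+s)^{n-s} - (sr+n)^{n-s}]}.}
#' When `s = n` this reduces to the Moran probability (the graph is doubly
#' stochastic); `r = 1` gives the neutral `1/(s+n)`.
#'
#' @param s,n component sizes (at least 1)
#' @param r mutant fitness
#' @return single-vertex fixation probability
#' @examples
#' bipartite_fixation_closed_form(2, 3, 2)
#' @export
bipartite_fixation_closed_form <- function(s, n, r) {
  stopifnot(s >= 1, n >= 1, r > 0)
  if (abs(r - 1) < 1e-12) {
    # analytic limit: expand 1 - a^i b^j to first order in (r - 1)
    return(1 / (s + n))
  }
  a <- (n * r + s) / (r * (s * r + n))
  b <- (s * r + n) / (r * (n * r + s))
  asbn <- a^s * b^n
  x10 <- (1 - a) / (1 - asbn)
  x01 <- (1 - b) / (1 - asbn)
  (s * x10 + n * x01) / (s + n)
}

#' Fixation probabilities of a dual circular flow via the lumped state space
#'
#' For a flow with uniform inter-level weight `p`, states lump to mutant
#' counts per level `m = (m_0, ..., m_k)` with `0 <= m_i <= n_i`; the
#' master equations reduce to `prod(n_i + 1) - 2` interior equations.  The
#' transition rates are: level-`i` count increases at rate
#' `r (n_i - m_i) [m_{i+1} p + m_{i-1} (1 - p)] / n_i` and decreases at rate
#' `(n_i - m_i ... )` read with mutants and residents exchanged.  Agrees
#' with [solve_fixation()] on the full `2^N` space.
#'
#' @param sizes level sizes `(n_0, ..., n_k)`
#' @param p uniform inter-level weight toward the lower level
#' @param r mutant fitness
#' @return list with `x` (named by comma-separated level counts), the
#'   per-level single-vertex probabilities `single_level`, and the
#'   multiplicity-weighted average `rho`
#' @export
lumped_flow_fixation <- function(sizes, p, r) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1), p >= 0, p <= 1, r > 0)
  k1 <- length(sizes)
  N <- sum(sizes)
  dims <- sizes + 1
  S <- prod(dims)
  # mixed-radix enumeration of level counts; state id 1..S
  counts <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1))))
  colnames(counts) <- NULL
  id_of <- function(m) 1 + sum(m * cumprod(c(1, dims))[seq_len(k1)])
  interior <- 2:(S - 1)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(S - 2)
  rowpos <- function(id) id - 1L       # interior row index
  for (sid in interior) {
    m <- counts[sid, ]
    dsum <- 0
    for (i in seq_len(k1)) {
      up_m <- m[(i %% k1) + 1L]            # level i+1 (1-based wrap)
      lo_m <- m[((i - 2L) %% k1) + 1L]     # level i-1
      up_n <- sizes[(i %% k1) + 1L]
      lo_n <- sizes[((i - 2L) %% k1) + 1L]
      inc <- r * (sizes[i] - m[i]) * (up_m * p + lo_m * (1 - p)) / sizes[i]
      dec <- m[i] * ((up_n - up_m) * p + (lo_n - lo_m) * (1 - p)) / sizes[i]
      dsum <- dsum + inc + dec
      if (inc > 0) {
        m2 <- m; m2[i] <- m2[i] + 1L
        t2 <- id_of(m2)
        if (t2 == S) rhs[rowpos(sid)] <- rhs[rowpos(sid)] + inc
        else { ii <- c(ii, rowpos(sid)); jj <- c(jj, rowpos(t2)); xx <- c(xx, -inc) }
      }
      if (dec > 0) {
        m2 <- m; m2[i] <- m2[i] - 1L
        t2 <- id_of(m2)
        if (t2 != 1) { ii <- c(ii, rowpos(sid)); jj <- c(jj, rowpos(t2)); xx <- c(xx, -dec) }
      }
    }
    ii <- c(ii, rowpos(sid)); jj <- c(jj, rowpos(sid)); xx <- c(xx, dsum)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(S - 2, S - 2))
  sol <- as.numeric(Matrix::solve(A, rhs))
  x <- c(0, sol, 1)
  names(x) <- apply(counts, 1, paste, collapse = ",")
  single <- numeric(k1)
  for (i in seq_len(k1)) {
    m <- rep(0L, k1); m[i] <- 1L
    single[i] <- x[id_of(m)]
  }
  rho <- sum(sizes * single) / N
  list(x = x, single_level = single, rho = rho, sizes = sizes, p = p, r = r)
}

#' Bisection root/crossing finder
#'
#' Locates a sign change of `f` inside `bracket` by bisection.  When an
#' optional high-precision evaluator is supplied, it is consulted whenever
#' `|f(mid)|` falls below `exact_threshold`, so that the bracketing
#' decision near machine-zero residuals is made by the more precise route
#' (for instance an exact-rational solve).
#'
#' @param f scalar function
#' @param bracket length-2 numeric, with `f` of opposite signs at the ends
#' @param tol absolute tolerance on the root location
#' @param f_exact optional high-precision replacement for `f`
#' @param exact_threshold |f| below which `f_exact` is used
#' @return the located crossing (midpoint of the final bracket)
#' @export
bisect_crossing <- function(f, bracket, tol = 1e-7, f_exact = NULL,
                            exact_threshold = 1e-12) {
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop(sprintf("no sign change on bracket [%g, %g]: f = %g and %g",
                 lo, hi, flo, fhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (!is.null(f_exact) && abs(fm) < exact_threshold) fm <- f_exact(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Find where a fixation-probability comparison changes sign
#'
#' Two modes: `mode = "fitness"` bisects in the fitness `r` with the graph
#' fixed; `mode = "parameter"` bisects in a graph parameter with `r` fixed
#' (the caller supplies a single-parameter graph factory).  Two targets:
#' `target = "moran"` compares the average single-vertex fixation
#' probability with the Moran probability; `target = "pair"` compares the
#' single-vertex probabilities of two chosen vertices.
#'
#' @param factory for `mode = "fitness"` a zero-argument function returning
#'   the graph (or a fixed `weighted_digraph`); for `mode = "parameter"` a
#'   one-argument function mapping the scanned parameter to a graph
#' @param mode `"fitness"` or `"parameter"`
#' @param target `"moran"` or `"pair"`
#' @param pair for `target = "pair"`, the two vertex numbers to compare
#' @param r fitness (fixed when `mode = "parameter"`)
#' @param bracket search interval
#' @param tol bisection tolerance
#' @param solver either `"full"` or `"lumped"`; `"lumped"` requires the
#'   factory/graph to be a uniform flow and is much faster
#' @param sizes,p lumped-solver description (level sizes and uniform weight)
#'   when `solver = "lumped"`
#' @return the crossing location (fitness or parameter value)
#' @export
crossing_finder <- function(factory, mode = c("fitness", "parameter"),
                            target = c("moran", "pair"), pair = NULL,
                            r = NULL, bracket, tol = 1e-7,
                            solver = c("full", "lumped"),
                            sizes = NULL, p = NULL) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  solver <- match.arg(solver)
  eval_diff <- function(graph_or_desc, rr) {
    if (solver == "lumped") {
      fit <- lumped_flow_fixation(graph_or_desc$sizes, graph_or_desc$p, rr)
      if (target == "moran")
        return(fit$rho - moran_probability(sum(graph_or_desc$sizes), rr))
      stopifnot(length(pair) == 2)
      return(fit$single_level[pair[1]] - fit$single_level[pair[2]])
    }
    fit <- solve_fixation(graph_or_desc, rr)
    if (target == "moran")
      return(fit$rho - moran_probability(graph_or_desc$N, rr))
    stopifnot(length(pair) == 2)
    fit$single_vertex[pair[1]] - fit$single_vertex[pair[2]]
  }
  if (mode == "fitness") {
    fixed <- if (solver == "lumped") list(sizes = sizes, p = p)
             else if (inherits(factory, "weighted_digraph")) factory
             else factory()
    f <- function(rr) eval_diff(fixed, rr)
  } else {
    stopifnot(!is.null(r))
    f <- function(theta) {
      g <- if (solver == "lumped") list(sizes = sizes, p = theta)
           else factory(theta)
      eval_diff(g, r)
    }
  }
  bisect_crossing(f, bracket, tol)
}
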