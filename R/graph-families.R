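# Row-stochastic weighted digraphs and the four structured families:
# biased cycles, dual circular flows, partial bipartite and single-link
# graphs.  Every constructor also records an exact rational copy of the
# weight matrix (numeric parameters are dyadic rationals, so this is always
# possible; fraction strings like "2/3" are kept exactly), which feeds the
# exact solver backend and the exact characteristic polynomials.

#' Weighted digraph container
#'
#' Wraps an `N x N` row-stochastic matrix of edge weights `w_ij`, the
#' probability that vertex `i` propagates its state to vertex `j` under
#' birth-death updating.  Row sums must equal 1 (within `1e-12`); weights
#' lie in `[0, 1]`.  Self-loops (`w_ii > 0`) are accepted for generic
#' matrices but flagged, since none of the structured families has them.
#'
#' @param W numeric matrix of non-negative edge weights with unit row sums
#' @param family one of `"cycle"`, `"flow"`, `"partial_bipartite"`,
#'   `"single_link"`, `"generic"`
#' @param params named list of family parameters (kept for provenance)
#' @param vertex_labels character labels fixing which vertex is "vertex k";
#'   defaults to `v1 ... vN`
#' @param W_exact optional exact rational copy of `W` (internal list-matrix)
#' @return an object of class `weighted_digraph`
#' @export
weighted_digraph <- function(W, family = "generic", params = list(),
                             vertex_labels = NULL, W_exact = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(W) >= 2)
  N <- nrow(W)
  if (any(!is.finite(W)) || any(W < -1e-15) || any(W > 1 + 1e-12))
    stop("edge weights must lie in [0, 1]")
  W[W < 0] <- 0
  rs <- rowSums(W)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad))
    stop("rows are not stochastic (sum != 1): ",
         paste(bad, collapse = ", "))
  if (is.null(vertex_labels)) vertex_labels <- paste0("v", seq_len(N))
  stopifnot(length(vertex_labels) == N)
  family <- match.arg(family,
                      c("cycle", "flow", "partial_bipartite",
                        "single_link", "generic"))
  self_loops <- any(diag(W) > 0)
  if (self_loops && family != "generic")
    stop("family '", family, "' must not have self-loops")
  structure(list(N = N, W = W, family = family, params = params,
                 vertex_labels = vertex_labels, W_exact = W_exact,
                 self_loops = self_loops),
            class = "weighted_digraph")
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat(sprintf("<weighted_digraph> family=%s N=%d%s\n", x$family, x$N,
              if (x$self_loops) " [self-loops]" else ""))
  if (length(x$params)) {
    p <- vapply(x$params, function(v)
      paste(format(unlist(v)), collapse = ","), "")
    cat("  params:", paste(names(p), p, sep = "=", collapse = " "), "\n")
  }
  if (x$N <= 10) print(round(x$W, 4)) else cat("  (matrix suppressed)\n")
  invisible(x)
}

# parameter helper: numeric, fraction string or rational -> both forms
.param <- function(x) {
  q <- as_q(x)
  list(num = q_to_num(q), q = q)
}

# exact complement 1 - x
.q_compl <- function(q) q_sub(q_one(), q)

qm_from_entries <- function(N, entries) {
  A <- qm_new(N, N)
  for (e in entries) A <- qm_set(A, e[[1]], e[[2]], e[[3]])
  A
}

#' Biased cycle
#'
#' An `N`-cycle with vertices numbered clockwise, in which each vertex
#' propagates counter-clockwise -- to the previous-indexed vertex, mod `N`
#' -- with probability `p` and clockwise (next index) with probability
#' `1 - p`.  This orientation makes the construction coincide entrywise
#' with [dual_circular_flow()] at unit level sizes (where `p` propagates
#' toward the lower level), and puts the one-step tipping point of the
#' `N = 5` cycle -- the `p` maximizing the expected hitting time
#' `h_{1,2}` to the next-numbered vertex -- at `p ~ 0.68806`, with the
#' mirrored vertex peaking at `1 - 0.68806`.
#'
#' The weight matrix is doubly stochastic, so by the isothermal theorem the
#' single-vertex fixation probability equals the Moran probability for all
#' `p`.
#'
#' @param N number of vertices (at least 3; a 2-cycle is degenerate because
#'   both neighbours coincide)
#' @param p counter-clockwise transition probability in `[0, 1]`; numeric or
#'   fraction string (`"7/10"`)
#' @return a `weighted_digraph` with `family = "cycle"`
#' @examples
#' biased_cycle(5, 0.7)
#' @export
biased_cycle <- function(N, p) {
  stopifnot(N >= 3, N == trunc(N))
  pp <- .param(p)
  if (pp$num < 0 || pp$num > 1) stop("p must lie in [0, 1]")
  W <- matrix(0, N, N)
  Wq <- qm_new(N, N)
  for (i in seq_len(N)) {
    fw <- if (i == N) 1L else i + 1L   # clockwise neighbour
    bw <- if (i == 1L) N else i - 1L   # counter-clockwise neighbour
    W[i, bw] <- pp$num
    W[i, fw] <- 1 - pp$num
    Wq <- qm_set(Wq, i, bw, pp$q)
    Wq <- qm_set(Wq, i, fw, .q_compl(pp$q))
  }
  weighted_digraph(W, "cycle", list(N = N, p = pp$num), W_exact = Wq)
}

#' Dual circular flow
#'
#' A ring of `k + 1` vertex levels with sizes `n_0, ..., n_k`.  A vertex at
#' level `i` propagates with total probability `p_i` spread uniformly over
#' the `n_{i-1}` vertices of level `i - 1` (mod `k + 1`) and with total
#' probability `1 - p_i` spread uniformly over level `i + 1`; there are no
#' intra-level edges.  `p = 0` everywhere gives the cascade, `p = 1` the
#' funnel.  With unit level sizes the construction reduces to
#' [biased_cycle()].
#'
#' The column sum (temperature) of a level-`i` vertex is
#' `(n_{i+1} p_{i+1} + n_{i-1} (1 - p_{i-1})) / n_i`.
#'
#' Vertices are ordered level 0 first, then level 1, and so on.
#'
#' @param sizes positive integer vector `(n_0, ..., n_k)`, `k >= 1`
#' @param p back-propagation probability: a scalar (uniform) or one value
#'   per level; numeric or fraction strings
#' @return a `weighted_digraph` with `family = "flow"`
#' @examples
#' dual_circular_flow(c(1, 2, 3), 0.25)
#' dual_circular_flow(c(1, 2, 3), c(1, 0, "2/3"))  # an isothermal tuning
#' @export
dual_circular_flow <- function(sizes, p) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1), all(sizes == trunc(sizes)))
  k1 <- length(sizes)
  if (length(p) == 1L) p <- rep(list(p), k1) else stopifnot(length(p) == k1)
  pp <- lapply(p, .param)
  for (x in pp) if (x$num < 0 || x$num > 1) stop("weights must lie in [0, 1]")
  N <- sum(sizes)
  offs <- cumsum(c(0, sizes))        # level i occupies offs[i] + 1 .. offs[i+1]
  lev_idx <- function(i) (offs[i + 1L] + 1L):offs[i + 2L]  # i is 0-based
  W <- matrix(0, N, N)
  Wq <- qm_new(N, N)
  for (i in seq_len(k1) - 1L) {
    lo <- (i - 1L) %% k1
    hi <- (i + 1L) %% k1
    wb_q <- q_div(pp[[i + 1L]]$q, q_from_num(sizes[lo + 1L]))
    wf_q <- q_div(.q_compl(pp[[i + 1L]]$q), q_from_num(sizes[hi + 1L]))
    wb <- q_to_num(wb_q)
    wf <- q_to_num(wf_q)
    for (v in lev_idx(i)) {
      for (u in lev_idx(lo)) {
        W[v, u] <- W[v, u] + wb
        if (wb > 0) Wq <- qm_set(Wq, v, u, q_add(qm_get(Wq, v, u), wb_q))
      }
      for (u in lev_idx(hi)) {
        W[v, u] <- W[v, u] + wf
        if (wf > 0) Wq <- qm_set(Wq, v, u, q_add(qm_get(Wq, v, u), wf_q))
      }
    }
  }
  # a 2-level ring would route both directions onto the same level; the
  # accumulation above handles it, but self-edges would appear if a level
  # has size 1 and is its own neighbour -- only possible when k1 == 2
  if (k1 == 2 && any(diag(W) > 0))
    stop("2-level flows with a size-1 level create self-loops; use sizes >= 2")
  weighted_digraph(W, "flow",
                   list(sizes = sizes, p = vapply(pp, `[[`, 0, "num")),
                   W_exact = Wq)
}

#' Partial bipartite graph
#'
#' Two all-to-all coupled components `V_s` (listed first) and `V_n`.  Within
#' `V_s` every ordered pair carries weight `p / (s - 1)`; within `V_n`,
#' `q / (n - 1)`; every `V_s` vertex sends `(1 - p) / n` to each `V_n`
#' vertex and every `V_n` vertex sends `(1 - q) / s` to each `V_s` vertex.
#' `p = q = 0` is the complete bipartite graph `K_{s,n}`.
#'
#' @param s,n component sizes (`>= 2`; `s = 1` is allowed only with `p = 0`,
#'   giving the star-like case, and symmetrically for `n`)
#' @param p,q intra-component total weights in `[0, 1]`
#' @return a `weighted_digraph` with `family = "partial_bipartite"`
#' @examples
#' partial_bipartite(3, 4, 0.2, 0.5)
#' partial_bipartite(2, 5, 0, 0)   # K_{2,5}
#' @export
partial_bipartite <- function(s, n, p, q) {
  stopifnot(s >= 1, n >= 1, s == trunc(s), n == trunc(n))
  pp <- .param(p); qq <- .param(q)
  if (pp$num < 0 || pp$num > 1 || qq$num < 0 || qq$num > 1)
    stop("p and q must lie in [0, 1]")
  if (s == 1 && pp$num != 0)
    stop("s = 1 requires p = 0 (intra-component weight divides by s - 1)")
  if (n == 1 && qq$num != 0)
    stop("n = 1 requires q = 0 (intra-component weight divides by n - 1)")
  N <- s + n
  W <- matrix(0, N, N)
  Wq <- qm_new(N, N)
  is_s <- seq_len(s)
  is_n <- s + seq_len(n)
  w_ss <- if (s > 1) q_div(pp$q, q_from_num(s - 1)) else q_zero()
  w_nn <- if (n > 1) q_div(qq$q, q_from_num(n - 1)) else q_zero()
  w_sn <- q_div(.q_compl(pp$q), q_from_num(n))
  w_ns <- q_div(.q_compl(qq$q), q_from_num(s))
  fill <- function(rows, cols, wq) {
    wnum <- q_to_num(wq)
    for (i in rows) for (j in cols) if (i != j) {
      W[i, j] <<- wnum
      Wq <<- qm_set(Wq, i, j, wq)
    }
  }
  fill(is_s, is_s, w_ss)
  fill(is_n, is_n, w_nn)
  fill(is_s, is_n, w_sn)
  fill(is_n, is_s, w_ns)
  weighted_digraph(W, "partial_bipartite",
                   list(s = s, n = n, p = pp$num, q = qq$num),
                   W_exact = Wq)
}

#' Single-link graph
#'
#' Two internally complete components joined by one directed edge in each
#' direction through a linking vertex on each side.  Vertex order: the
#' `s - 1` non-linking `V_s` vertices, the `V_s` linking vertex, the `V_n`
#' linking vertex, then the `n - 1` non-linking `V_n` vertices (so for
#' `(3, 4)`: `v1, v2` non-linking, `v3` and `v4` the linkers, `v5..v7`
#' non-linking).
#'
#' Non-linking vertices spread weight `1/(s-1)` (resp. `1/(n-1)`) uniformly
#' over the other vertices of their component, including the linker.  The
#' `V_s` linker sends `p/(s-1)` to each other `V_s` vertex and `1 - p`
#' across to the `V_n` linker; symmetrically with `q` on the other side.
#'
#' @param s,n component sizes, both at least 2
#' @param p,q linking-vertex retention probabilities in `[0, 1]`
#' @return a `weighted_digraph` with `family = "single_link"`
#' @examples
#' single_link(3, 4, 0.5, 0.5)
#' @export
single_link <- function(s, n, p, q) {
  stopifnot(s >= 2, n >= 2, s == trunc(s), n == trunc(n))
  pp <- .param(p); qq <- .param(q)
  if (pp$num < 0 || pp$num > 1 || qq$num < 0 || qq$num > 1)
    stop("p and q must lie in [0, 1]")
  N <- s + n
  vs_non <- seq_len(s - 1L)
  vs_link <- s
  vn_link <- s + 1L
  vn_non <- if (n > 1) (s + 2L):N else integer(0)
  W <- matrix(0, N, N)
  Wq <- qm_new(N, N)
  set <- function(i, j, wq) {
    W[i, j] <<- q_to_num(wq)
    Wq <<- qm_set(Wq, i, j, wq)
  }
  w_s <- q_div(q_one(), q_from_num(s - 1))
  w_n <- q_div(q_one(), q_from_num(n - 1))
  for (i in vs_non) for (j in c(vs_non, vs_link)) if (i != j) set(i, j, w_s)
  for (j in vs_non) set(vs_link, j, q_div(pp$q, q_from_num(s - 1)))
  set(vs_link, vn_link, .q_compl(pp$q))
  for (j in vn_non) set(vn_link, j, q_div(qq$q, q_from_num(n - 1)))
  set(vn_link, vs_link, .q_compl(qq$q))
  for (i in vn_non) for (j in c(vn_link, vn_non)) if (i != j) set(i, j, w_n)
  weighted_digraph(W, "single_link",
                   list(s = s, n = n, p = pp$num, q = qq$num),
                   W_exact = Wq)
}

# exact weight matrix, reconstructing from W when no exact copy was stored
# (every numeric is a dyadic rational, so this is still exact)
graph_exact_matrix <- function(graph) {
  if (!is.null(graph$W_exact)) return(graph$W_exact)
  N <- graph$N
  Wq <- qm_new(N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    if (graph$W[i, j] != 0) Wq <- qm_set(Wq, i, j, q_from_num(graph$W[i, j]))
  Wq
}

#' Test whether a graph's weight matrix is doubly stochastic
#'
#' Doubly stochastic weight matrices are exactly the isothermal graphs
#' (all vertex temperatures equal 1), whose single-vertex fixation
#' probability equals the Moran probability.
#'
#' @param graph a `weighted_digraph`
#' @param tol tolerance on the column sums
#' @return logical
#' @export
is_doubly_stochastic <- function(graph, tol = 1e-12) {
  all(abs(colSums(graph$W) - 1) <= tol)
}
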