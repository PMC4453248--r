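# Vertex temperatures and the inverse problem: choosing per-level weights
# of a generalized dual circular flow to match a prescribed temperature
# profile.  All algebra is exact rational; feasibility intervals have exact
# endpoints.
#
# The temperature of a level-i vertex is
#   t_i = (n_{i+1} p_{i+1} + n_{i-1}(1 - p_{i-1})) / n_i   (indices mod k+1)
# so matching a profile t means solving the cyclic stride-2 system
#   n_{i+1} p_{i+1} - n_{i-1} p_{i-1} = t_i n_i - n_{i-1}.
# With an odd number of levels the system couples all weights into one
# chain (one free parameter); with an even number it splits into two
# independent alternating chains (two free parameters), each subject to a
# closure (sum) constraint.  The free parameter of each chain is its
# highest-index weight.

#' Vertex temperatures
#'
#' The temperature of a vertex is its total incoming edge weight (column
#' sum of `W`); hot vertices are replaced often.  A graph is isothermal
#' (all temperatures 1, `W` doubly stochastic) exactly when its fixation
#' probability is the Moran probability.  For flows the per-level profile
#' is returned as well.
#'
#' @param graph a `weighted_digraph`
#' @return list with `by_vertex` (column sums) and, for flows, `by_level`
#' @export
temperatures <- function(graph) {
  tv <- colSums(graph$W)
  names(tv) <- graph$vertex_labels
  out <- list(by_vertex = tv)
  if (graph$family == "flow") {
    sizes <- graph$params$sizes
    offs <- cumsum(c(0, sizes))
    out$by_level <- tv[offs[seq_along(sizes)] + 1]
    names(out$by_level) <- paste0("level", seq_along(sizes) - 1)
  }
  out
}

# one affine form alpha + beta * p_free (rationals)
.affine <- function(alpha, beta, free) list(alpha = alpha, beta = beta,
                                            free = free)

#' Tune a flow's per-level weights to a target temperature profile
#'
#' Solves the cyclic linear system relating per-level weights
#' `p_0, ..., p_k` to a target temperature profile `t` for level sizes
#' `n_0, ..., n_k`, entirely in exact rational arithmetic.  The solution is
#' an affine family: with an odd number of levels, every `p_i` is an exact
#' affine function of the single free parameter `p_k`; with an even number
#' the even- and odd-index weights form two independent chains
#' parameterized by the two highest-index weights, and each chain carries a
#' closure constraint on `t` (violation raises a structural-infeasibility
#' error).  The necessary conservation condition `sum(t_i n_i) = N` is
#' checked first.
#'
#' Feasibility (`all p_i in [0, 1]`) intersects to an exact interval per
#' free parameter; an empty interval is reported as infeasible with the
#' binding constraint named.
#'
#' @param sizes positive integer level sizes `(n_0, ..., n_k)`
#' @param t target temperatures, one per level (numerics, fraction strings,
#'   or `rational`s)
#' @return object of class `tuning_solution`: `affine` (per weight index,
#'   exact `alpha`, `beta`, free index), `feasible` (exact interval per free
#'   parameter, or `NULL` if empty), `feasible_chr` / `affine_chr` readable
#'   forms, and `realize(values)` is available through [tuning_graph()]
#' @examples
#' tune_profile(c(1, 2, 3), c(1, 1, 1))        # unique: p = (1, 0, 2/3)
#' tune_profile(c(1, 2, 3), c(2, "3/2", "1/3"))
#' @export
tune_profile <- function(sizes, t) {
  k1 <- length(sizes)
  stopifnot(k1 >= 2, all(sizes >= 1), length(t) == k1)
  n_q <- lapply(sizes, q_from_num)
  t_q <- lapply(t, as_q)
  for (tq in t_q) if (q_cmp(tq, q_zero()) < 0)
    stop("temperatures must be non-negative")
  # conservation: sum t_i n_i = N
  tot <- Reduce(q_add, Map(q_mul, t_q, n_q), q_zero())
  Nq <- q_from_num(sum(sizes))
  if (!q_eq(tot, Nq))
    stop("inconsistent profile: sum(t_i n_i) = ", q_format(tot),
         " but total weight is N = ", q_format(Nq))
  idx <- function(i) (i %% k1) + 1L          # 0-based level -> R index
  affine <- vector("list", k1)               # by 0-based weight index + 1
  if (k1 == 2) {
    # both directions collapse onto the other level: temperatures are
    # fixed at n_{1-i}/n_i and every (p_0, p_1) works when they match
    for (i in 0:1) {
      want <- q_div(n_q[[idx(i + 1)]], n_q[[i + 1]])
      if (!q_eq(t_q[[i + 1]], want))
        stop("structural infeasibility: a 2-level ring forces t_", i,
             " = n_", 1 - i, "/n_", i, " = ", q_format(want))
      affine[[i + 1]] <- .affine(q_zero(), q_one(), i)   # p_i free
    }
    chains <- list(0L, 1L)
  } else if (k1 %% 2 == 1) {
    chains <- list(seq(0L, k1 - 1L))
  } else {
    chains <- list(seq(0L, k1 - 1L)[seq(0L, k1 - 1L) %% 2L == (k1 - 2L) %% 2L],
                   seq(0L, k1 - 1L)[seq(0L, k1 - 1L) %% 2L == (k1 - 1L) %% 2L])
  }
  if (k1 > 2) {
    for (chain in chains) {
      f <- max(chain)                        # free parameter: highest index
      affine[[f + 1L]] <- .affine(q_zero(), q_one(), f)
      j <- f
      repeat {
        jm2 <- (j - 2L) %% k1
        if (jm2 == f) {
          # closure: the equation E_{f-1} links p_f back to itself
          cur <- affine[[j + 1L]]
          rhs_c <- q_sub(q_mul(t_q[[idx(j - 1L)]], n_q[[idx(j - 1L)]]),
                         n_q[[jm2 + 1L]])
          alpha <- q_div(q_sub(q_mul(n_q[[j + 1L]], cur$alpha), rhs_c),
                         n_q[[jm2 + 1L]])
          beta <- q_div(q_mul(n_q[[j + 1L]], cur$beta), n_q[[jm2 + 1L]])
          if (!q_eq(beta, q_one()) || !q_is_zero(alpha))
            stop("structural infeasibility: the chain through p_", f,
                 " does not close (closure residual ", q_format(alpha),
                 "); the alternating sum constraint on t is violated")
          break
        }
        # E_{j-1}: n_j p_j - n_{j-2} p_{j-2} = t_{j-1} n_{j-1} - n_{j-2}
        cur <- affine[[j + 1L]]
        rhs_c <- q_sub(q_mul(t_q[[idx(j - 1L)]], n_q[[idx(j - 1L)]]),
                       n_q[[jm2 + 1L]])
        alpha <- q_div(q_sub(q_mul(n_q[[j + 1L]], cur$alpha), rhs_c),
                       n_q[[jm2 + 1L]])
        beta <- q_div(q_mul(n_q[[j + 1L]], cur$beta), n_q[[jm2 + 1L]])
        affine[[jm2 + 1L]] <- .affine(alpha, beta, f)
        j <- jm2
      }
    }
  }
  # feasibility: 0 <= alpha + beta p_f <= 1, beta > 0
  feas <- list()
  binding <- list()
  for (chain in chains) {
    f <- max(chain)
    lo <- q_zero(); hi <- q_one()
    lo_who <- "0 <= p"; hi_who <- "p <= 1"
    for (j in chain) {
      a <- affine[[j + 1L]]
      stopifnot(q_cmp(a$beta, q_zero()) > 0)
      cand_lo <- q_div(q_neg(a$alpha), a$beta)
      cand_hi <- q_div(q_sub(q_one(), a$alpha), a$beta)
      if (q_cmp(cand_lo, lo) > 0) { lo <- cand_lo; lo_who <- paste0("p_", j, " >= 0") }
      if (q_cmp(cand_hi, hi) < 0) { hi <- cand_hi; hi_who <- paste0("p_", j, " <= 1") }
    }
    key <- paste0("p_", f)
    if (q_cmp(lo, hi) > 0) {
      feas[[key]] <- NULL
      binding[[key]] <- paste0("infeasible: ", lo_who, " needs ", key,
                               " >= ", q_format(lo), " but ", hi_who,
                               " needs ", key, " <= ", q_format(hi))
    } else {
      feas[[key]] <- list(lower = lo, upper = hi)
    }
  }
  aff_chr <- vapply(seq_len(k1), function(i) {
    a <- affine[[i]]
    sprintf("p_%d = %s + %s * p_%d", i - 1L, q_format(a$alpha),
            q_format(a$beta), a$free)
  }, "")
  feas_chr <- vapply(names(feas), function(nm) {
    iv <- feas[[nm]]
    sprintf("%s in [%s, %s]", nm, q_format(iv$lower), q_format(iv$upper))
  }, "")
  structure(list(sizes = sizes, t = t_q,
                 t_num = vapply(t_q, q_to_num, 0),
                 affine = affine, chains = chains,
                 free = vapply(chains, max, 0L),
                 feasible = feas, feasible_chr = feas_chr,
                 infeasible = length(binding) > 0,
                 binding = binding, affine_chr = aff_chr),
            class = "tuning_solution")
}

#' @export
print.tuning_solution <- function(x, ...) {
  cat("<tuning_solution> sizes =", paste(x$sizes, collapse = ","),
      " t =", paste(vapply(x$t, q_format, ""), collapse = ","), "\n")
  for (s in x$affine_chr) cat(" ", s, "\n")
  if (x$infeasible) {
    for (b in x$binding) cat("  ", b, "\n")
  } else {
    for (s in x$feasible_chr) cat("  feasible:", s, "\n")
  }
  invisible(x)
}

#' Realize a tuned flow graph from a tuning solution
#'
#' Substitutes exact values for the free parameter(s) of a
#' [tune_profile()] solution, checks feasibility of every implied weight,
#' and constructs the corresponding [dual_circular_flow()].  The realized
#' graph reproduces the target temperature profile exactly (asserted in
#' rational arithmetic).
#'
#' @param solution a `tuning_solution`
#' @param values named list/vector of values for the free parameters (names
#'   `p_k` etc.; numerics, fraction strings, or `rational`s); may be
#'   omitted when the solution is unique (degenerate feasibility interval)
#' @return a `weighted_digraph` flow
#' @export
tuning_graph <- function(solution, values = NULL) {
  stopifnot(inherits(solution, "tuning_solution"))
  if (solution$infeasible)
    stop("tuning solution is infeasible: ",
         paste(unlist(solution$binding), collapse = "; "))
  vals <- list()
  for (key in names(solution$feasible)) {
    iv <- solution$feasible[[key]]
    if (!is.null(values) && key %in% names(values)) {
      v <- as_q(values[[key]])
      if (q_cmp(v, iv$lower) < 0 || q_cmp(v, iv$upper) > 0)
        stop(key, " = ", q_format(v), " outside the feasibility interval [",
             q_format(iv$lower), ", ", q_format(iv$upper), "]")
      vals[[key]] <- v
    } else if (q_eq(iv$lower, iv$upper)) {
      vals[[key]] <- iv$lower
    } else {
      stop("free parameter ", key, " must be supplied (feasible range [",
           q_format(iv$lower), ", ", q_format(iv$upper), "])")
    }
  }
  k1 <- length(solution$sizes)
  p_q <- vector("list", k1)
  for (i in seq_len(k1)) {
    a <- solution$affine[[i]]
    pf <- vals[[paste0("p_", a$free)]]
    p_q[[i]] <- q_add(a$alpha, q_mul(a$beta, pf))
  }
  g <- dual_circular_flow(solution$sizes,
                          lapply(p_q, function(q) structure(q, class = "rational")))
  # exact temperature verification: t_i = (n_{i+1} p_{i+1} + n_{i-1}(1-p_{i-1}))/n_i
  n_q <- lapply(solution$sizes, q_from_num)
  for (i in seq_len(k1) - 1L) {
    up <- (i + 1L) %% k1; dn <- (i - 1L) %% k1
    ti <- q_div(q_add(q_mul(n_q[[up + 1L]], p_q[[up + 1L]]),
                      q_mul(n_q[[dn + 1L]],
                            q_sub(q_one(), p_q[[dn + 1L]]))),
                n_q[[i + 1L]])
    stopifnot(q_eq(ti, solution$t[[i + 1L]]))
  }
  g
}

#' Isothermal tuning: all temperatures equal to one
#'
#' [tune_profile()] with target `t = (1, ..., 1)`.  Any realized solution
#' is doubly stochastic, hence by the isothermal theorem its single-vertex
#' fixation probability equals the Moran probability.  With an even number
#' of levels this requires the alternating size sums to match (e.g. four
#' levels need `n_0 + n_2 = n_1 + n_3`), otherwise a structural
#' infeasibility error is raised.
#'
#' @param sizes level sizes
#' @return a `tuning_solution`
#' @examples
#' isothermal_tuning(c(1, 2, 3))   # forces (p_0, p_1, p_2) = (1, 0, 2/3)
#' @export
isothermal_tuning <- function(sizes) {
  tune_profile(sizes, rep(1, length(sizes)))
}
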