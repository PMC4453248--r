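# Reproduction helpers: the biased-cycle tipping point, fixation at
# singular parameter boundaries by extrapolation, fitness-pattern
# classification, and desk-scale report tables.

#' Tipping point of the biased cycle's one-step hitting time
#'
#' For the `N`-vertex biased cycle, the expected hitting time from vertex 1
#' to vertex 2 (whose direct edge carries weight `1 - p`) rises and falls
#' in `p`; its argmax is the tipping point between reaching the target by
#' the direct step and travelling the `N - 1` steps around the ring.  For
#' `N = 5` the argmax is `p ~ 0.68806`; by mirror symmetry the hitting time
#' to vertex `N` peaks at one minus that value.
#'
#' @param N cycle length
#' @param tol tolerance on the argmax location
#' @return list with `p_star` (argmax for the `h_12` transition),
#'   `p_star_mirror` (argmax for `h_1N`), and the peak value
#' @export
cycle_tipping_point <- function(N = 5, tol = 1e-6) {
  h <- function(p, target) hitting_times(biased_cycle(N, p))$M[1, target]
  opt <- stats::optimize(function(p) h(p, 2), c(1e-3, 1 - 1e-3),
                         maximum = TRUE, tol = tol)
  optm <- stats::optimize(function(p) h(p, N), c(1e-3, 1 - 1e-3),
                          maximum = TRUE, tol = tol)
  list(p_star = opt$maximum, peak = opt$objective,
       p_star_mirror = optm$maximum)
}

#' Fixation probabilities at a singular parameter boundary, by
#' extrapolation
#'
#' At parameter endpoints (for example `p = 1, q = 0` in a partial
#' bipartite graph) some vertices lose all incoming weight, the chain
#' becomes reducible, and the master system is singular: the fixation
#' probability of every single-mutant state is then 0 and the quantity of
#' interest is the (removable) limit of the interior solution.  Since the
#' solved probabilities are rational functions of the parameter, the limit
#' is recovered by solving at two small offsets `eps` from the boundary and
#' extrapolating linearly (Richardson).
#'
#' @param factory one-argument function: `factory(eps)` returns the graph
#'   at distance `eps` from the boundary
#' @param r mutant fitness
#' @param eps the two offsets used for extrapolation
#' @return list with extrapolated `rho`, `single_vertex`, and the two raw
#'   solutions
#' @export
boundary_limit_fixation <- function(factory, r, eps = c(1e-6, 1e-8)) {
  stopifnot(length(eps) == 2, all(eps > 0), eps[1] > eps[2])
  f1 <- solve_fixation(factory(eps[1]), r)
  f2 <- solve_fixation(factory(eps[2]), r)
  w <- eps[1] / (eps[1] - eps[2])
  extrap <- function(a, b) b + (b - a) * (eps[2] / (eps[1] - eps[2]))
  list(rho = extrap(f1$rho, f2$rho),
       single_vertex = extrap(f1$single_vertex, f2$single_vertex),
       at_eps = list(f1, f2), weight = w)
}

#' Classify the fitness-dependence pattern of a two-component graph
#'
#' Compares the average single-vertex fixation probability with the Moran
#' probability across fitness regimes and classifies the sign pattern on
#' `(0, 1)`, `(1, r_max)` and `(r_max, infinity)`:
#' pattern A = suppressed below `r = 1`, enhanced above;
#' B = suppressed, enhanced, suppressed (with finite upper crossing
#' `r_max`); C = enhanced, suppressed, enhanced; D = enhanced below 1,
#' suppressed above.  Where a finite `r_max` exists it is located by
#' bisection.
#'
#' @param s,n,p,q partial bipartite parameters (`p` may sit at the boundary
#'   `1`, handled by [boundary_limit_fixation()])
#' @param r_low fitness used to probe the sub-neutral regime
#' @param r_hi upper end of the fitness scan
#' @param tol bisection tolerance for `r_max`
#' @return list with `pattern` (`"A"`, `"B"`, `"C"`, `"D"`), `r_max` (`NA`
#'   when the pattern has no finite re-crossing), and the backend used
#' @export
classify_fitness_pattern <- function(s, n, p, q, r_low = 0.5, r_hi = 30,
                                     tol = 1e-5) {
  fdiff <- function(r) {
    if (p >= 1 || q >= 1) {
      boundary_limit_fixation(function(eps)
        partial_bipartite(s, n, min(p, 1 - eps), min(q, 1 - eps)), r)$rho -
        moran_probability(s + n, r)
    } else {
      solve_fixation(partial_bipartite(s, n, p, q), r)$rho -
        moran_probability(s + n, r)
    }
  }
  below <- fdiff(r_low) > 0
  # scan for a sign change above 1
  grid <- exp(seq(log(1.02), log(r_hi), length.out = 25))
  vals <- vapply(grid, fdiff, 0)
  flip <- which(diff(sign(vals)) != 0)
  r_max <- NA_real_
  if (length(flip))
    r_max <- bisect_crossing(fdiff, c(grid[flip[1]], grid[flip[1] + 1]), tol)
  just_above <- vals[1] > 0
  pattern <- if (!below && just_above && is.na(r_max)) "A"
             else if (!below && just_above) "B"
             else if (below && !just_above && !is.na(r_max)) "C"
             else "D"
  list(pattern = pattern, r_max = r_max, backend = "double")
}

#' Desk-scale reproduction reports
#'
#' Emits machine-readable tables for the quantitative statements the
#' package reproduces:
#'
#' * `"flow_crossings"`: the fitness values where the `(1,2,3)` funnel
#'   (`p = 1`) and cascade (`p = 0`) average fixation probabilities cross
#'   the Moran probability, plus the level-pair crossings at `p = 0.25`
#'   and `p = 0.9`.
#' * `"t1_patterns"`: pattern classification (A-D with `r_max`) for the
#'   `(2, 5)` partial bipartite graph along a `p` grid at fixed `q`.
#' * `"bipartite_lines"`: solver-determined equality points of the two
#'   component single-vertex probabilities against the conductance-balance
#'   lines `q = (1+3p)/4` (for `(3,4)`) and `q = (3+2p)/5` (for `(2,5)`).
#' * `"singlelink_saddle"`: the stationary point of the average
#'   communicability of the `(3,4)` single-link graph, with the order-6
#'   series and with the exact exponential.
#'
#' @param table report name
#' @param p_grid parameter grid (used by `t1_patterns`, `bipartite_lines`)
#' @param q fixed `q` for `t1_patterns`
#' @param r_values fitness values for `bipartite_lines`
#' @param out optional CSV path to write the report to
#' @return a data.frame; every row carries the solver backend used
#' @export
reproduce <- function(table = c("flow_crossings", "t1_patterns",
                                "bipartite_lines", "singlelink_saddle"),
                      p_grid = NULL, q = 0, r_values = c(5/4, 3/2, 2),
                      out = NULL) {
  table <- match.arg(table)
  df <- switch(
    table,
    flow_crossings = {
      rows <- list(
        c(case = "funnel_p1_vs_moran",
          value = crossing_finder(mode = "fitness", target = "moran",
                                  solver = "lumped", sizes = c(1, 2, 3),
                                  p = 1, bracket = c(1.01, 20), tol = 1e-6)),
        c(case = "cascade_p0_vs_moran",
          value = crossing_finder(mode = "fitness", target = "moran",
                                  solver = "lumped", sizes = c(1, 2, 3),
                                  p = 0, bracket = c(1.01, 20), tol = 1e-6)),
        c(case = "x2_eq_x8_p0.25",
          value = crossing_finder(mode = "fitness", target = "pair",
                                  pair = c(2, 3), solver = "lumped",
                                  sizes = c(1, 2, 3), p = 0.25,
                                  bracket = c(1.5, 10), tol = 1e-6)),
        c(case = "x2_eq_x1_p0.9",
          value = crossing_finder(mode = "fitness", target = "pair",
                                  pair = c(2, 1), solver = "lumped",
                                  sizes = c(1, 2, 3), p = 0.9,
                                  bracket = c(1.5, 10), tol = 1e-6)))
      data.frame(case = vapply(rows, `[[`, "", "case"),
                 r_star = as.numeric(vapply(rows, `[[`, "", "value")),
                 backend = "lumped")
    },
    t1_patterns = {
      if (is.null(p_grid)) p_grid <- c(0.3, 0.5, 0.75, 1)
      rows <- lapply(p_grid, function(p) {
        cl <- classify_fitness_pattern(2, 5, p, q)
        data.frame(p = p, q = q, pattern = cl$pattern, r_max = cl$r_max,
                   backend = cl$backend)
      })
      do.call(rbind, rows)
    },
    bipartite_lines = {
      if (is.null(p_grid)) p_grid <- c(0.1, 0.25, 0.4, 0.55, 0.7)
      rows <- list()
      for (cfg in list(list(s = 3, n = 4, v2 = 4,
                            line = function(p) (1 + 3 * p) / 4),
                       list(s = 2, n = 5, v2 = 3,
                            line = function(p) (3 + 2 * p) / 5))) {
        for (r in r_values) for (p in p_grid) {
          f <- function(qq) {
            fit <- solve_fixation(partial_bipartite(cfg$s, cfg$n, p, qq), r)
            fit$single_vertex[1] - fit$single_vertex[cfg$v2]
          }
          qstar <- bisect_crossing(f, c(1e-4, 1 - 1e-4), 1e-9)
          rows[[length(rows) + 1]] <-
            data.frame(s = cfg$s, n = cfg$n, r = r, p = p, q_star = qstar,
                       q_line = cfg$line(p), backend = "double")
        }
      }
      do.call(rbind, rows)
    },
    singlelink_saddle = {
      res <- lapply(c("series6", "exact"), function(md) {
        sp <- saddle_point_search(function(x)
          communicability(single_link(3, 4, x[1], x[2]), mode = md)$average)
        data.frame(mode = md, p = sp$point[1], q = sp$point[2],
                   classification = sp$classification, backend = "double")
      })
      do.call(rbind, res)
    })
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
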