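test_that("state indexing conventions and conversion", {
  st <- population_state(c(1, 0, 1))
  expect_equal(st$index, 5)              # internal: bit k-1 <-> vertex k
  expect_equal(st$index_bigendian, 5)    # palindrome here
  st2 <- population_state(c(1, 1, 0, 0))
  expect_equal(st2$index, 3)
  expect_equal(st2$index_bigendian, 12)
  expect_equal(bigendian_state_index(3, 4), 12)
  expect_equal(st2$m, 2)
  # single-mutant labels coincide under both conventions
  for (k in 1:5) {
    v <- numeric(5); v[k] <- 1
    expect_equal(population_state(v)$index, 2^(k - 1))
    expect_equal(population_state(v)$index_bigendian, 2^(5 - k))
  }
})

test_that("master system has dimension 2^N - 2 and matches a dense independent assembly", {
  W <- matrix(1 / 2, 3, 3); diag(W) <- 0
  g <- weighted_digraph(W)
  sys <- build_master_system(g, 2)
  expect_equal(dim(sys$A), c(6, 6))
  sys5 <- build_master_system(biased_cycle(5, 0.3), 2)
  expect_equal(dim(sys5$A), c(30, 30))
  set.seed(5)
  for (i in 1:5) {
    g <- fixture_graphs("row_stochastic", 4, seed = i)
    r <- runif(1, 0.5, 3)
    x_pkg <- solve_fixation(g, r)$x
    x_oracle <- dense_fixation_oracle(g$W, r)
    expect_lt(max(abs(x_pkg - x_oracle)), 1e-12)
  }
})

test_that("complete graph single-vertex fixation is (1-1/2)/(1-1/8) = 4/7 at r = 2", {
  W <- matrix(1 / 2, 3, 3); diag(W) <- 0
  fit <- solve_fixation(weighted_digraph(W), 2)
  expect_equal(unname(fit$single_vertex), rep(4 / 7, 3), tolerance = 1e-12)
})

test_that("moran probability closed forms", {
  expect_equal(moran_probability(5, 2), 16 / 31)
  expect_equal(moran_probability(3, 2, k = 2), 6 / 7)
  expect_equal(moran_probability(7, 1, k = 3), 3 / 7)
  expect_equal(moran_probability(4, 0.5), (1 - 2) / (1 - 2^4))
})

test_that("isothermal theorem on the biased cycle: 16/31 regardless of bias", {
  for (p in c(0.3, 0.8)) {
    fit <- solve_fixation(biased_cycle(5, p), 2)
    expect_lt(max(abs(fit$single_vertex - 16 / 31)), 1e-12)
  }
})

test_that("bipartite closed form matches the exact solver across sizes and fitnesses", {
  for (sn in list(c(1, 3), c(2, 3), c(2, 5), c(3, 4))) {
    for (r in c(0.8, 1.5, 2, 5)) {
      fit <- solve_fixation(partial_bipartite(sn[1], sn[2], 0, 0), r)
      expect_equal(fit$rho,
                   bipartite_fixation_closed_form(sn[1], sn[2], r),
                   tolerance = 1e-10)
    }
  }
  # neutral limit and doubly stochastic special case
  expect_equal(bipartite_fixation_closed_form(2, 3, 1), 1 / 5)
  expect_equal(bipartite_fixation_closed_form(3, 3, 2),
               moran_probability(6, 2), tolerance = 1e-12)
})

test_that("lumped flow solver agrees with the full state-space solver", {
  for (sizes in list(c(1, 2, 3), c(2, 3), c(1, 1, 2, 2))) {
    offs <- cumsum(c(0, sizes))
    for (p in c(0, 0.3, 0.5, 0.8, 1)) {
      for (r in c(0.8, 2)) {
        lum <- lumped_flow_fixation(sizes, p, r)
        full <- solve_fixation(dual_circular_flow(sizes, p), r)
        sv_full <- full$single_vertex[offs[seq_along(sizes)] + 1]
        expect_lt(max(abs(lum$single_level - sv_full)), 1e-10)
        expect_lt(abs(lum$rho - full$rho), 1e-10)
      }
    }
  }
  # state counting: (1,2,3) lumps 62 interior states to 22
  lum <- lumped_flow_fixation(c(1, 2, 3), 0.5, 2)
  expect_equal(length(lum$x), 24)
})

test_that("rational backend reproduces the float backend and returns exact fractions", {
  g <- biased_cycle(5, "3/10")
  fr <- solve_fixation(g, "2", backend = "rational")
  fd <- solve_fixation(g, 2)
  expect_lt(max(abs(fr$x - fd$x)), 1e-12)
  expect_identical(fr$x_exact[2], "16/31")
  g6 <- dual_circular_flow(c(1, 2, 3), "1/4")
  fr6 <- solve_fixation(g6, "3/2", backend = "rational")
  fd6 <- solve_fixation(g6, 1.5)
  expect_lt(max(abs(fr6$x - fd6$x)), 1e-12)
})

test_that("fixation probabilities are monotone under adding mutants (exhaustive, N <= 5)", {
  set.seed(13)
  for (g in list(biased_cycle(5, 0.3),
                 partial_bipartite(2, 3, 0.4, 0.2),
                 fixture_graphs("row_stochastic", 5, seed = 2))) {
    for (r in c(0.8, 2)) {
      x <- solve_fixation(g, r)$x
      N <- g$N
      for (v in 0:(2^N - 1)) for (i in 1:N) {
        if (v %/% 2^(i - 1) %% 2 == 0) {
          expect_gte(x[v + 2^(i - 1) + 1], x[v + 1] - 1e-12)
        }
      }
      expect_true(all(x >= -1e-12 & x <= 1 + 1e-12))
    }
  }
})

test_that("reducible graphs are rejected with a diagnostic naming unreachable states", {
  g <- partial_bipartite(2, 5, 1, 0)   # V_n vertices have zero in-weight
  expect_error(solve_fixation(g, 2), "reach neither absorbing")
  expect_error(solve_fixation(biased_cycle(20, 0.5), 2), "exceeds")
})

test_that("boundary-limit extrapolation recovers the interior solution where both are defined", {
  fac <- function(eps) partial_bipartite(2, 5, 1 - eps, 0)
  lim <- boundary_limit_fixation(fac, 2)
  direct <- solve_fixation(partial_bipartite(2, 5, 1 - 1e-8, 0), 2)
  expect_lt(abs(lim$rho - direct$rho), 1e-5)
})

test_that("crossing finder brackets and errors", {
  expect_error(bisect_crossing(function(x) x^2 + 1, c(-1, 1)), "no sign change")
  expect_equal(bisect_crossing(function(x) x - 0.25, c(0, 1), tol = 1e-10),
               0.25, tolerance = 1e-9)
})
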