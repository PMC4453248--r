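test_that("subset conductance closed forms: cycle blocks, bipartite components, flow levels", {
  # a length-k block of an N-cycle has conductance N/(k(N-k))
  for (N in c(5, 8)) for (k in 1:(N - 1)) {
    g <- biased_cycle(N, 0.37)
    expect_equal(subset_conductance(g, seq_len(k))$value, N / (k * (N - k)),
                 tolerance = 1e-12)
  }
  # partial bipartite: C(V_s) = N(1-p)/n, C(V_n) = N(1-q)/s
  g <- partial_bipartite(3, 4, 0.2, 0.6)
  expect_equal(subset_conductance(g, 1:3)$value, 7 * 0.8 / 4, tolerance = 1e-12)
  expect_equal(subset_conductance(g, 4:7)$value, 7 * 0.4 / 3, tolerance = 1e-12)
  # flow level s has conductance N/(N - n_s)
  sizes <- c(2, 3, 5)
  g2 <- dual_circular_flow(sizes, 0.3)
  offs <- cumsum(c(0, sizes))
  for (s in seq_along(sizes)) {
    S <- (offs[s] + 1):offs[s + 1]
    expect_equal(subset_conductance(g2, S)$value, 10 / (10 - sizes[s]),
                 tolerance = 1e-12)
  }
  # single-link conductances
  g3 <- single_link(3, 4, 0.25, 0.65)
  cf <- closed_form_metrics("single_link", list(s = 3, n = 4, p = 0.25, q = 0.65))
  expect_equal(subset_conductance(g3, 1:2)$value, cf$C_Vs_minus_link, tolerance = 1e-12)
  expect_equal(subset_conductance(g3, 5:7)$value, cf$C_Vn_minus_link, tolerance = 1e-12)
  expect_equal(subset_conductance(g3, 3)$value, cf$C_vs, tolerance = 1e-12)
  expect_equal(subset_conductance(g3, 4)$value, cf$C_vn, tolerance = 1e-12)
  expect_equal(subset_conductance(g3, 1:3)$value, cf$C_Vs, tolerance = 1e-12)
  expect_equal(subset_conductance(g3, 4:7)$value, cf$C_Vn, tolerance = 1e-12)
  expect_error(subset_conductance(g3, 1:7), "proper")
})

test_that("graph conductance minimization agrees with brute force and handles disconnection", {
  g <- biased_cycle(5, 0.5)
  got <- graph_conductance(g)
  want <- brute_force_conductance(g$W)
  expect_equal(got$value, want$value, tolerance = 1e-12)
  # minimized at a contiguous block
  d <- diff(sort(got$S))
  expect_true(all(d == 1) || all(diff(sort(setdiff(1:5, got$S))) == 1))
  expect_equal(graph_conductance(partial_bipartite(3, 4, 1, 1))$value, 0)
  expect_error(graph_conductance(biased_cycle(21, 0.5)), "cap")
})

test_that("communicability: series6 within the truncation bound of exact; cycle trace symmetric in p", {
  set.seed(21)
  gs <- list(biased_cycle(6, 0.3), partial_bipartite(3, 4, 0.2, 0.7),
             single_link(3, 4, 0.5, 0.3), dual_circular_flow(c(1, 2, 3), 0.4),
             fixture_graphs("row_stochastic", 5, seed = 4))
  for (g in gs) {
    ex <- communicability(g, "exact")
    s6 <- communicability(g, "series6")
    expect_lt(max(abs(ex$V - s6$V)), 3e-4)
    expect_true(all(ex$V >= 0))
  }
  tr <- function(p) communicability(biased_cycle(5, p))$average
  for (p in c(0.1, 0.35)) expect_equal(tr(p), tr(1 - p), tolerance = 1e-12)
  expect_gt(tr(0.5), tr(0.3))
  expect_gt(tr(0.5), tr(0.7))
})

test_that("hitting times: fundamental matrix equals first-step analysis on all families", {
  set.seed(31)
  gs <- list(biased_cycle(5, 0.3), biased_cycle(9, 0.8),
             partial_bipartite(3, 4, 0.25, 0.5), partial_bipartite(2, 5, 0.6, 0.1),
             single_link(3, 4, 0.4, 0.7), dual_circular_flow(c(1, 2, 3), 0.3),
             dual_circular_flow(c(2, 3, 4), 0.7),
             fixture_graphs("row_stochastic", 7, seed = 6))
  for (g in gs) {
    M <- hitting_times(g)$M
    O <- hitting_times_first_step(g)
    offdiag <- M; diag(offdiag) <- 0
    expect_lt(max(abs(offdiag - O)), 1e-9)
    # diagonal: expected return times 1/phi
    expect_lt(max(abs(diag(M) - 1 / stationary_distribution(g))), 1e-9)
  }
})

test_that("hitting-time base cases: adjacent balanced cycle and the deterministic cycle", {
  M3 <- hitting_times(biased_cycle(3, 0.5))$M
  expect_equal(M3[1, 2], 2, tolerance = 1e-12)    # h = 1 + h/2 twice
  Md <- hitting_times(biased_cycle(5, 1))$M       # deterministic ccw cycle
  expect_equal(Md[2, 1], 1, tolerance = 1e-10)    # one step in the favoured direction
  expect_equal(Md[1, 2], 4, tolerance = 1e-10)
})

test_that("cycle tipping point is symmetric between mirrored vertices", {
  tp <- cycle_tipping_point(5, tol = 1e-7)
  expect_equal(tp$p_star + tp$p_star_mirror, 1, tolerance = 1e-4)
})

test_that("partial bipartite closed-form metrics match numerics on (s,n) grids", {
  for (sn in list(c(2, 3), c(3, 4), c(2, 5), c(3, 5), c(4, 5))) {
    for (p in c(0.2, 0.5)) for (q in c(0.2, 0.5)) {
      s <- sn[1]; n <- sn[2]
      g <- partial_bipartite(s, n, p, q)
      O <- hitting_times_first_step(g)
      V <- communicability(g)$V
      cf <- closed_form_metrics("partial_bipartite",
                                list(s = s, n = n, p = p, q = q))
      expect_equal(O[1, 2], cf$h_ss, tolerance = 1e-8)
      expect_equal(O[s + 1, s + 2], cf$h_nn, tolerance = 1e-8)
      expect_equal(O[1, s + 1], cf$h_sn, tolerance = 1e-8)
      expect_equal(O[s + 1, 1], cf$h_ns, tolerance = 1e-8)
      expect_equal(V[1, 1], cf$V_ss, tolerance = 1e-10)
      expect_equal(V[s + 1, s + 1], cf$V_nn, tolerance = 1e-10)
      expect_equal(V[1, s + 1], cf$V_sn, tolerance = 1e-10)
      expect_equal(V[s + 1, 1], cf$V_ns, tolerance = 1e-10)
      expect_equal(sum(diag(V)), cf$trace_expW, tolerance = 1e-10)
      expect_gt(length(cf$findings), 0)
    }
  }
})

test_that("h(s,s) limiting behaviour: with p = q^k, h(s,s) -> (1+k)(s-1) as q -> 1", {
  for (k in c(2, 3)) {
    q <- 1 - 1e-6
    cf <- closed_form_metrics("partial_bipartite",
                              list(s = 3, n = 4, p = q^k, q = q))
    expect_equal(cf$h_ss, (1 + k) * 2, tolerance = 1e-4)
  }
})

test_that("single-link hitting-time table matches the numeric oracle (with corrected h41, h54)", {
  for (pq in list(c(0.3, 0.6), c(0.5, 0.5), c(0.7, 0.2))) {
    p <- pq[1]; q <- pq[2]
    g <- single_link(3, 4, p, q)
    O <- hitting_times_first_step(g)
    Mret <- hitting_times(g)$M
    cf <- closed_form_metrics("single_link", list(s = 3, n = 4, p = p, q = q))
    num <- c(h11 = Mret[1, 1], h33 = Mret[3, 3], h55 = Mret[5, 5],
             h44 = Mret[4, 4], h12 = O[1, 2], h56 = O[5, 6], h13 = O[1, 3],
             h31 = O[3, 1], h14 = O[1, 4], h41 = O[4, 1], h15 = O[1, 5],
             h51 = O[5, 1], h34 = O[3, 4], h43 = O[4, 3], h35 = O[3, 5],
             h53 = O[5, 3], h45 = O[4, 5], h54 = O[5, 4])
    expect_lt(max(abs(num[names(cf$h)] - cf$h)), 1e-8)
    expect_gt(length(cf$findings), 0)
  }
  # structural identity that pins down h54: every 5 -> 3 path passes vertex 4
  p <- 0.3; q <- 0.6
  cf <- closed_form_metrics("single_link", list(s = 3, n = 4, p = p, q = q))
  expect_equal(cf$h["h53"], cf$h["h54"] + cf$h["h43"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("divergent hitting times at parameter endpoints are reported as Inf", {
  cf <- closed_form_metrics("single_link", list(s = 3, n = 4, p = 0, q = 0.5))
  expect_true(is.infinite(cf$h["h11"]))
  expect_true(is.infinite(cf$h["h41"]))
  expect_equal(unname(cf$h["h13"]), 2)
})

test_that("single-link hitting-time equality conditions hold numerically", {
  num_h <- function(p, q) {
    g <- single_link(3, 4, p, q)
    O <- hitting_times_first_step(g)
    M <- hitting_times(g)$M
    c(h11 = M[1, 1], h55 = M[5, 5], h33 = M[3, 3], h44 = M[4, 4],
      h31 = O[3, 1], h45 = O[4, 5], h53 = O[5, 3], h14 = O[1, 4],
      h12 = O[1, 2], h56 = O[5, 6], h34 = O[3, 4], h43 = O[4, 3],
      h41 = O[4, 1], h35 = O[3, 5], h15 = O[1, 5], h51 = O[5, 1])
  }
  for (p in c(0.3, 0.6)) {
    h_eq <- num_h(p, single_link_equality_q("h11_h55", p))
    expect_equal(h_eq["h11"], h_eq["h55"], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(h_eq["h33"], h_eq["h44"], tolerance = 1e-8, ignore_attr = TRUE)
    h34 <- num_h(p, single_link_equality_q("h34_h43", p))
    expect_equal(h34["h34"], h34["h43"], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(single_link_equality_q("h34_h43", p), 3 * p / (4 - p))
    h31 <- num_h(p, single_link_equality_q("h31_h45", p))
    expect_equal(h31["h31"], h31["h45"], tolerance = 1e-7, ignore_attr = TRUE)
    h53 <- num_h(p, single_link_equality_q("h53_h14", p))
    expect_equal(h53["h53"], h53["h14"], tolerance = 1e-8, ignore_attr = TRUE)
    h12 <- num_h(p, single_link_equality_q("h12_h56", p))
    expect_equal(h12["h12"], h12["h56"], tolerance = 1e-8, ignore_attr = TRUE)
    h41 <- num_h(p, single_link_equality_q("h41_h35", p))
    expect_equal(h41["h41"], h41["h35"], tolerance = 1e-7, ignore_attr = TRUE)
    h15 <- num_h(p, single_link_equality_q("h15_h51", p))
    expect_equal(h15["h15"], h15["h51"], tolerance = 1e-7, ignore_attr = TRUE)
  }
  # the printed attribution of q = 3p/(4-p) to the h53/h14 pair fails
  cf <- closed_form_metrics("single_link", list(s = 3, n = 4,
                                                p = 0.3, q = 3 * 0.3 / 3.7))
  expect_gt(abs(cf$h["h53"] - cf$h["h14"]), 1e-3)
})

test_that("saddle point search: classification on a quadratic and the bipartite trace minimum", {
  sp <- saddle_point_search(function(x) x[1]^2 - x[2]^2,
                            box = list(lower = c(-0.5, -0.5),
                                       upper = c(0.5, 0.5)))
  expect_equal(sp$point, c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(sp$classification, "saddle")
  spm <- saddle_point_search(function(x)
    communicability(partial_bipartite(3, 4, x[1], x[2]))$average)
  expect_equal(spm$point, c(1 / 3, 1 / 2), tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(spm$classification, "minimum")
})

test_that("single-link communicability stationary point: saddle, series6 close to exact", {
  sp6 <- saddle_point_search(function(x)
    communicability(single_link(3, 4, x[1], x[2]), mode = "series6")$average)
  spx <- saddle_point_search(function(x)
    communicability(single_link(3, 4, x[1], x[2]))$average)
  expect_identical(sp6$classification, "saddle")
  expect_identical(spx$classification, "saddle")
  expect_lt(max(abs(sp6$point - spx$point)), 1e-3)
  expect_lt(sp6$gradient_norm, 1e-8)
})
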