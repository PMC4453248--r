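test_that("stationary distribution: doubly stochastic gives uniform; reducible graphs error", {
  expect_lt(max(abs(stationary_distribution(biased_cycle(7, 0.3)) - 1 / 7)),
            1e-12)
  g <- fixture_graphs("doubly_stochastic", 5, seed = 3)
  expect_lt(max(abs(stationary_distribution(g) - 1 / 5)), 1e-12)
  expect_error(stationary_distribution(partial_bipartite(3, 4, 1, 1)),
               "reducible")
  # residual property on generic graphs
  g2 <- fixture_graphs("row_stochastic", 6, seed = 9)
  phi <- stationary_distribution(g2)
  expect_lt(max(abs(phi %*% g2$W - phi)), 1e-12)
})

test_that("Laplacian of a biased cycle is I - W; balanced cycle has symmetric Delta", {
  g <- biased_cycle(6, 0.3)
  lap <- laplacian(g)
  expect_equal(lap$Delta, diag(6) - g$W, tolerance = 1e-12)
  lap5 <- laplacian(biased_cycle(5, 0.5))
  expect_lt(max(abs(lap5$Delta_A)), 1e-14)
})

test_that("cycle characteristic polynomial: recurrence, closed form, and vanishing on spectra", {
  # Lucas-type recurrence C^N_k = C^(N-1)_k + C^(N-2)_(k-1)
  for (N in 5:9) {
    ck <- evograph:::cycle_coefficients(N)
    c1 <- evograph:::cycle_coefficients(N - 1)
    c2 <- evograph:::cycle_coefficients(N - 2)
    for (k in 1:floor((N - 2) / 2)) {
      expect_equal(ck[[k + 1]],
                   (if (k + 1 <= length(c1)) c1[[k + 1]] else 0) + c2[[k]])
    }
    expect_equal(ck[[1]], 1); expect_equal(ck[[2]], N)
  }
  # closed forms (including the even-N correction split by N mod 4) vanish
  # on the numeric spectrum
  for (N in c(4, 5, 6, 7, 8)) for (p in c(0.1, 0.3, 0.7, 0.9)) {
    cp <- closed_form_spectra("cycle", list(N = N, p = p))
    ev <- spectral_report(biased_cycle(N, p))$eigenvalues
    expect_lt(max(abs(vapply(ev, function(l) abs(cp$eval(l)), 0))), 1e-8)
  }
})

test_that("deterministic cycles have eigenvalues on the unit circle about 1", {
  for (N in c(4, 5)) for (p in c(0, 1)) {
    cp <- closed_form_spectra("cycle", list(N = N, p = p))
    ev <- spectral_report(biased_cycle(N, p))$eigenvalues
    expect_lt(max(abs(sort(Re(ev)) - sort(Re(cp$eigenvalues)))), 1e-10)
    expect_lt(max(abs(Mod(ev - 1) - 1)), 1e-10)
  }
})

test_that("flow spectrum = (N - k - 1) ones + the (k+1)-cycle factor", {
  for (sizes in list(c(1, 2, 3), c(2, 3, 5), c(1, 2, 3, 4))) {
    k1 <- length(sizes); N <- sum(sizes)
    for (p in c(0.2, 0.6)) {
      sr <- spectral_report(dual_circular_flow(sizes, p))
      cp <- closed_form_spectra("flow", list(sizes = sizes, p = p))
      expect_lt(max(abs(vapply(sr$eigenvalues,
                               function(l) abs(cp$eval(l)), 0))), 1e-8)
      expect_gte(sum(Mod(sr$eigenvalues - 1) < 1e-8), N - k1)
      cyc_ev <- spectral_report(biased_cycle(max(k1, 3), p))$eigenvalues
      if (k1 >= 3) {
        got <- sr$eigenvalues[order(Mod(sr$eigenvalues - 1),
                                    decreasing = TRUE)][seq_len(k1)]
        expect_lt(max(abs(sort(Re(got)) - sort(Re(cyc_ev)))), 1e-8)
      }
    }
  }
})

test_that("partial bipartite spectrum matches the factored closed form", {
  for (p in c(0.2, 0.6)) for (q in c(0.3, 0.7)) {
    sr <- spectral_report(partial_bipartite(3, 4, p, q))
    expect_lt(max(abs(Im(sr$eigenvalues))), 1e-10)
    got <- sort(Re(sr$eigenvalues))
    want <- sort(c(0, rep((2 + p) / 2, 2), rep((3 + q) / 3, 3), 2 - p - q))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("partial bipartite Laplacian is symmetric (detailed balance), so Delta_A = 0", {
  for (pq in list(c(0.2, 0.3), c(0.6, 0.7))) {
    g <- partial_bipartite(3, 4, pq[1], pq[2])
    phi <- stationary_distribution(g)
    # detailed balance of the stationary-weighted chain
    expect_lt(max(abs(diag(phi) %*% g$W - t(diag(phi) %*% g$W))), 1e-14)
    lap <- laplacian(g)
    expect_lt(max(abs(lap$Delta_A)), 1e-14)
    # the closed-form report records this and flags the printed pair
    cp <- closed_form_spectra("partial_bipartite",
                              list(s = 3, n = 4, p = pq[1], q = pq[2]))
    expect_identical(cp$Delta_A_pair, c(0, 0))
    expect_match(cp$findings, "reversible")
  }
})

test_that("single-link characteristic polynomial factors correctly", {
  for (p in c(0.25, 0.8)) for (q in c(0.1, 0.6)) {
    for (sn in list(c(3, 4), c(4, 5))) {
      cp <- closed_form_spectra("single_link",
                                list(s = sn[1], n = sn[2], p = p, q = q))
      ev <- spectral_report(single_link(sn[1], sn[2], p, q))$eigenvalues
      expect_lt(max(abs(vapply(ev, function(l) abs(cp$eval(l)), 0))), 1e-8)
      # fixed factors: s-2 roots at s/(s-1), n-2 roots at n/(n-1), one 0
      s <- sn[1]; n <- sn[2]
      expect_gte(sum(Mod(ev - s / (s - 1)) < 1e-8), s - 2)
      expect_gte(sum(Mod(ev - n / (n - 1)) < 1e-8), n - 2)
      expect_equal(sum(Mod(ev) < 1e-10), 1)
    }
  }
})

test_that("Delta_A eigenvalues carry the (1 - 2p) bias factor for cycles and flows", {
  for (builder in list(function(p) biased_cycle(6, p),
                       function(p) biased_cycle(9, p),
                       function(p) dual_circular_flow(c(1, 2, 3), p),
                       function(p) dual_circular_flow(c(2, 3, 5), p))) {
    base <- NULL
    for (p in c(0.1, 0.3, 0.7, 0.9)) {
      evA <- spectral_report(builder(p))$eigenvalues_A
      expect_lt(max(abs(Re(evA))), 1e-10)          # purely imaginary or zero
      scaled <- sort(abs(Im(evA))) / abs(1 - 2 * p)
      if (is.null(base)) base <- scaled
      else expect_lt(max(abs(scaled - base)), 1e-9)
    }
    expect_lt(max(Mod(spectral_report(builder(0.5))$eigenvalues_A)), 1e-12)
  }
})

test_that("spectrum bounds: real parts in [0, 2], complex cases on |lambda - 1| <= 1", {
  set.seed(3)
  gs <- list(biased_cycle(7, runif(1)),
             dual_circular_flow(c(1, 2, 3), runif(1)),
             partial_bipartite(3, 4, runif(1), runif(1)),
             single_link(3, 4, runif(1), runif(1)))
  for (g in gs) {
    ev <- spectral_report(g)$eigenvalues
    expect_gte(min(Re(ev)), -1e-10)
    expect_lte(max(Re(ev)), 2 + 1e-10)
    expect_lte(max(Mod(ev - 1)), 1 + 1e-10)
  }
})

test_that("eigenvalue equality point is exactly (s-1, n-1)/(n+s-1)", {
  pt <- eigenvalue_equality_point(3, 4)
  expect_identical(as.character(pt$p), "1/3")
  expect_identical(as.character(pt$q), "1/2")
  pt2 <- eigenvalue_equality_point(2, 5)
  expect_identical(as.character(pt2$p), "1/6")
  expect_identical(as.character(pt2$q), "2/3")   # 4/6 reduced
  pt3 <- eigenvalue_equality_point(4, 4)
  expect_identical(as.character(pt3$p), as.character(pt3$q))
  # the three non-zero eigenvalues coincide there
  p <- pt$point["p"]; q <- pt$point["q"]
  vals <- c((3 - 1 + p) / 2, (4 - 1 + q) / 3, 2 - p - q)
  expect_lt(diff(range(vals)), 1e-14)
})
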