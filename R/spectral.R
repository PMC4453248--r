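# Stationary distributions, the similarity-transformed graph Laplacian
# Delta = Phi^(1/2) (I - W) Phi^(-1/2) and its antisymmetric part, numeric
# spectra, and closed-form characteristic polynomials for the structured
# families.  Delta is similar to I - W whenever the stationary vector is
# strictly positive, so every closed form below is ultimately a statement
# about the spectrum of W; the similarity form is still computed because
# its antisymmetric part (Delta - Delta^T)/2 measures directional bias.

# ---- exact polynomial helpers (coefficients ascending, rational) ----------

qp_add <- function(a, b) {
  n <- max(length(a), length(b))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ai <- if (i <= length(a)) a[[i]] else q_zero()
    bi <- if (i <= length(b)) b[[i]] else q_zero()
    out[[i]] <- q_add(ai, bi)
  }
  out
}

qp_scale <- function(a, s) lapply(a, function(c) q_mul(c, s))

qp_mul <- function(a, b) {
  out <- rep(list(q_zero()), length(a) + length(b) - 1L)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    k <- i + j - 1L
    out[[k]] <- q_add(out[[k]], q_mul(a[[i]], b[[j]]))
  }
  out
}

qp_pow <- function(a, k) {
  out <- list(q_one())
  while (k > 0) { out <- qp_mul(out, a); k <- k - 1 }
  out
}

qp_to_num <- function(a) vapply(a, q_to_num, 0)

# evaluate a numeric coefficient vector (ascending) at complex lambda
poly_eval <- function(coefs, lambda) {
  out <- 0 + 0i
  for (i in rev(seq_along(coefs))) out <- out * lambda + coefs[i]
  out
}

# exact matrix product / trace on qm list-matrices
qm_mul <- function(A, B) {
  da <- attr(A, "qdim"); db <- attr(B, "qdim")
  stopifnot(da[2] == db[1])
  out <- qm_new(da[1], db[2])
  for (i in seq_len(da[1])) for (j in seq_len(db[2])) {
    acc <- q_zero()
    for (k in seq_len(da[2])) {
      x <- qm_get(A, i, k); y <- qm_get(B, k, j)
      if (!q_is_zero(x) && !q_is_zero(y)) acc <- q_add(acc, q_mul(x, y))
    }
    out <- qm_set(out, i, j, acc)
  }
  out
}

qm_trace <- function(A) {
  n <- attr(A, "qdim")[1]
  acc <- q_zero()
  for (i in seq_len(n)) acc <- q_add(acc, qm_get(A, i, i))
  acc
}

# characteristic polynomial det(lambda I - M) of an exact matrix via
# Faddeev-LeVerrier; returns ascending rational coefficients (length n+1)
qm_charpoly <- function(M) {
  n <- attr(M, "qdim")[1]
  B <- qm_new(n, n)
  for (i in seq_len(n)) B <- qm_set(B, i, i, q_one())
  d <- vector("list", n)
  for (k in seq_len(n)) {
    C <- qm_mul(M, B)
    d[[k]] <- q_neg(q_div(qm_trace(C), q_from_num(k)))
    for (i in seq_len(n)) C <- qm_set(C, i, i, q_add(qm_get(C, i, i), d[[k]]))
    B <- C
  }
  coefs <- vector("list", n + 1L)
  coefs[[n + 1L]] <- q_one()
  for (k in seq_len(n)) coefs[[n + 1L - k]] <- d[[k]]
  coefs
}

# ---- stationary distribution and Laplacian --------------------------------

# strong connectivity of the positive-weight digraph
is_irreducible <- function(W) {
  N <- nrow(W)
  reach <- function(M) {
    seen <- logical(N); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(M[i, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    all(seen)
  }
  reach(W) && reach(t(W))
}

#' Stationary distribution of the edge-weight matrix
#'
#' Solves `phi W = phi` with `sum(phi) = 1`.  Requires an irreducible
#' weight matrix for uniqueness; a reducible graph raises an error naming
#' the problem.
#'
#' @param graph a `weighted_digraph`
#' @param tol residual tolerance
#' @return numeric stationary row vector `phi`
#' @export
stationary_distribution <- function(graph, tol = 1e-12) {
  W <- graph$W
  N <- nrow(W)
  if (!is_irreducible(W))
    stop("weight matrix is reducible: the stationary distribution is not ",
         "unique (some vertices are unreachable or absorbing)")
  A <- t(W) - diag(N)
  A[N, ] <- 1
  b <- c(numeric(N - 1), 1)
  phi <- tryCatch(solve(A, b), error = function(e)
    stop("stationary solve failed: ", conditionMessage(e)))
  resid <- max(abs(phi %*% W - phi))
  if (resid > tol * max(1, max(abs(phi))) * 100)
    stop("stationary residual too large: ", format(resid))
  if (any(phi < -1e-12))
    stop("stationary solve produced negative mass (reducible graph?)")
  phi[phi < 0] <- 0
  as.numeric(phi / sum(phi))
}

#' Graph Laplacian and its antisymmetric part
#'
#' `Delta = Phi^(1/2) (I - W) Phi^(-1/2)` with `Phi = diag(phi)` built from
#' the stationary distribution, and `Delta_A = (Delta - t(Delta))/2`.  The
#' similarity transform requires every vertex to carry positive stationary
#' mass; parameter endpoints that starve a vertex (zero in-weight) are
#' rejected with a targeted message.  For doubly stochastic families
#' (biased cycles) `Delta` reduces to `I - W` exactly.
#'
#' @param graph a `weighted_digraph`
#' @return list with `Delta`, `Delta_A`, and `phi`
#' @export
laplacian <- function(graph) {
  phi <- stationary_distribution(graph)
  if (any(phi <= 1e-14))
    stop("some vertices carry (numerically) zero stationary mass; ",
         "Phi^(1/2) is singular there and the Laplacian is undefined")
  N <- graph$N
  sq <- sqrt(phi)
  Delta <- (diag(sq) %*% (diag(N) - graph$W)) %*% diag(1 / sq)
  Delta_A <- (Delta - t(Delta)) / 2
  list(Delta = Delta, Delta_A = Delta_A, phi = phi)
}

#' Spectral summary of a weighted digraph
#'
#' Eigenvalues of the Laplacian `Delta` (sorted by real part, then
#' imaginary part) and of its antisymmetric part (purely imaginary pairs
#' and zeros), the stationary vector, and the multiplicity of the zero
#' eigenvalue (the number of connected components for the families
#' considered).
#'
#' @param graph a `weighted_digraph`
#' @param zero_tol magnitude below which an eigenvalue counts as zero
#' @return object of class `spectral_report`
#' @export
spectral_report <- function(graph, zero_tol = 1e-10) {
  lap <- laplacian(graph)
  ev <- eigen(lap$Delta, only.values = TRUE)$values
  ev <- ev[order(Re(ev), Im(ev))]
  evA <- eigen(lap$Delta_A, only.values = TRUE)$values
  evA <- evA[order(Re(evA), Im(evA))]
  structure(list(phi = lap$phi, Delta = lap$Delta, Delta_A = lap$Delta_A,
                 eigenvalues = ev, eigenvalues_A = evA,
                 n_zero = sum(Mod(ev) < zero_tol)),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("<spectral_report>\n  eigenvalues of Delta:\n")
  print(signif(x$eigenvalues, 6))
  cat("  zero multiplicity:", x$n_zero, "\n")
  invisible(x)
}

# Lucas-type coefficients of the biased-cycle characteristic polynomial:
# C^N_0 = 1, C^N_1 = N, C^N_k = C^(N-1)_k + C^(N-2)_(k-1), with closed form
# C^N_k = N/(N-k) choose(N-k, k)
cycle_coefficients <- function(N) {
  k <- 0:floor(N / 2)
  out <- N / (N - k) * choose(N - k, k)
  out[1] <- 1
  names(out) <- k
  out
}

# exact characteristic polynomial of a biased cycle's Delta = I - W, as
# ascending rational coefficients in lambda
cycle_charpoly_q <- function(N, p_q) {
  c_q <- q_mul(p_q, q_sub(q_one(), p_q))      # p(1-p)
  lm1 <- list(q_neg(q_one()), q_one())        # (lambda - 1)
  Ck <- cycle_coefficients(N)
  poly <- list(q_zero())
  for (k in 0:floor((N - if (N %% 2 == 0) 2 else 1) / 2)) {
    coef <- q_from_num((-1)^k * Ck[[k + 1]])
    coef <- q_mul(coef, q_pow_int(c_q, k))
    poly <- qp_add(poly, qp_scale(qp_pow(lm1, N - 2 * k), coef))
  }
  if (N %% 2 == 1) {
    tail <- q_add(q_pow_int(p_q, N), q_pow_int(q_sub(q_one(), p_q), N))
    poly <- qp_add(poly, list(tail))
  } else {
    ph <- q_pow_int(p_q, N / 2)
    qh <- q_pow_int(q_sub(q_one(), p_q), N / 2)
    K <- if (N %% 4 == 0) q_pow_int(q_sub(ph, qh), 2)
         else q_pow_int(q_add(ph, qh), 2)
    poly <- qp_add(poly, list(q_neg(K)))
  }
  poly
}

q_pow_int <- function(a, k) {
  out <- q_one()
  while (k > 0) { out <- q_mul(out, a); k <- k - 1 }
  out
}

# exact 4x4 exchangeability quotient of I - W for a single-link graph
single_link_quotient_q <- function(s, n, p_q, q_q) {
  B <- qm_new(4, 4)
  one <- q_one()
  set <- function(i, j, v) B <<- qm_set(B, i, j, v)
  if (s > 2) set(1, 1, q_div(q_from_num(s - 2), q_from_num(s - 1)))
  set(1, 2, q_div(one, q_from_num(s - 1)))
  set(2, 1, p_q)
  set(2, 3, q_sub(one, p_q))
  set(3, 2, q_sub(one, q_q))
  set(3, 4, q_q)
  set(4, 3, q_div(one, q_from_num(n - 1)))
  if (n > 2) set(4, 4, q_div(q_from_num(n - 2), q_from_num(n - 1)))
  # I - B
  M <- qm_new(4, 4)
  for (i in 1:4) for (j in 1:4) {
    v <- q_neg(qm_get(B, i, j))
    if (i == j) v <- q_add(v, one)
    M <- qm_set(M, i, j, v)
  }
  M
}

#' Closed-form characteristic polynomials and spectra by family
#'
#' Returns the family's exact characteristic polynomial of the Laplacian
#' (equivalently of `I - W`, to which it is similar) together with any
#' closed-form eigenvalues:
#'
#' * `cycle`: the alternating expansion in powers of `(lambda - 1)` with
#'   Lucas-type coefficients `C^N_k = N/(N-k) choose(N-k,k)` (satisfying
#'   `C^N_k = C^(N-1)_k + C^(N-2)_(k-1)`), plus the parity tail
#'   (`p^N + (1-p)^N` for odd `N`, `-K_N` for even `N` with
#'   `K_N = (p^(N/2) -+ (1-p)^(N/2))^2` split by `N mod 4`).  At `p` in
#'   `{0, 1}` the eigenvalues are `1 + exp(2 pi i k/N)` (N even) or
#'   `1 - exp(2 pi i k/N)` (N odd).
#' * `flow`: `(lambda - 1)^(N - k - 1)` times the characteristic polynomial
#'   of the `(k+1)`-vertex biased cycle (the exchangeability quotient over
#'   levels).
#' * `partial_bipartite`: eigenvalues `0`, `(s-1+p)/(s-1)` (multiplicity
#'   `s-1`), `(n-1+q)/(n-1)` (multiplicity `n-1`), `2-p-q`.  The
#'   stationary-weighted chain satisfies detailed balance, so the Laplacian
#'   is symmetric and its antisymmetric part vanishes identically
#'   (`Delta_A_pair = c(0, 0)`; `findings` records the non-zero pair printed
#'   in the source, which fails the numeric oracle).
#' * `single_link`: factors `(lambda - s/(s-1))^(s-2)`,
#'   `(lambda - n/(n-1))^(n-2)`, `lambda`, and an exact cubic obtained from
#'   the 4-class exchangeability quotient.
#'
#' Coefficients are computed in exact rational arithmetic when the
#' parameters are rational (which includes every numeric double) and
#' reported as numerics alongside.
#'
#' @param family one of `"cycle"`, `"flow"`, `"partial_bipartite"`,
#'   `"single_link"`
#' @param params named list: `cycle` needs `N, p`; `flow` needs `sizes, p`;
#'   the two-component families need `s, n, p, q`
#' @return object of class `charpoly` with ascending coefficients `coef`
#'   (numeric), exact coefficients `coef_exact` (character fractions), an
#'   evaluator `eval(lambda)`, and family-specific fields (`eigenvalues`,
#'   `multiplicities`, `cycle_coefficients`, `Delta_A_pair`, `cubic`)
#' @export
closed_form_spectra <- function(family, params) {
  family <- match.arg(family, c("cycle", "flow", "partial_bipartite",
                                "single_link"))
  out <- list(family = family, params = params)
  if (family == "cycle") {
    N <- params$N
    p_q <- as_q(params$p)
    stopifnot(N >= 3)
    poly <- cycle_charpoly_q(N, p_q)
    out$cycle_coefficients <- cycle_coefficients(N)
    out$coef_exact <- vapply(poly, q_format, "")
    out$coef <- qp_to_num(poly)
    pnum <- q_to_num(p_q)
    if (pnum %in% c(0, 1)) {
      k <- 0:(N - 1)
      out$eigenvalues <- if (N %% 2 == 0) 1 + exp(2i * pi * k / N)
                         else 1 - exp(2i * pi * k / N)
    }
  } else if (family == "flow") {
    sizes <- params$sizes
    k1 <- length(sizes)
    N <- sum(sizes)
    p_q <- as_q(params$p)
    cyc <- if (k1 >= 3) {
      cycle_charpoly_q(k1, p_q)
    } else {
      # 2-level ring: both directions collapse onto the other level, the
      # quotient is the 2-state swap chain and I - B has eigenvalues 0, 2
      qp_mul(list(q_zero(), q_one()), list(q_neg(q_from_num(2)), q_one()))
    }
    lm1 <- list(q_neg(q_one()), q_one())
    poly <- qp_mul(qp_pow(lm1, N - k1), cyc)
    out$coef_exact <- vapply(poly, q_format, "")
    out$coef <- qp_to_num(poly)
    out$cycle_factor <- qp_to_num(cyc)
  } else if (family == "partial_bipartite") {
    s <- params$s; n <- params$n
    p <- q_to_num(as_q(params$p)); q <- q_to_num(as_q(params$q))
    ev <- c(0, rep((s - 1 + p) / (s - 1), s - 1),
            rep((n - 1 + q) / (n - 1), n - 1), 2 - p - q)
    out$eigenvalues <- sort(ev)
    out$multiplicities <- c(`0` = 1, `(s-1+p)/(s-1)` = s - 1,
                            `(n-1+q)/(n-1)` = n - 1, `2-p-q` = 1)
    coefs <- 1
    for (e in ev) coefs <- convolve_poly(coefs, c(-e, 1))
    out$coef <- coefs
    # the graph satisfies detailed balance (phi_i w_ij = phi_j w_ji =
    # (1-p)(1-q)/N-type products), so Delta is symmetric and Delta_A = 0
    out$Delta_A_pair <- c(0, 0)
    out$findings <- paste(
      "the source's antisymmetric-part block form (pair",
      "+-i(n-s)sqrt((1-p)(1-q)/(sn))) fails the numeric oracle:",
      "the stationary-weighted graph is reversible, so Delta_A vanishes")
  } else {
    s <- params$s; n <- params$n
    p_q <- as_q(params$p); q_q <- as_q(params$q)
    M <- single_link_quotient_q(s, n, p_q, q_q)
    quart <- qm_charpoly(M)
    # divide by lambda: constant term must vanish (row sums of I - B are 0)
    stopifnot(q_is_zero(quart[[1]]))
    cubic <- quart[-1]
    out$cubic_exact <- vapply(cubic, q_format, "")
    out$cubic <- qp_to_num(cubic)
    poly <- cubic
    poly <- qp_mul(poly, list(q_zero(), q_one()))           # lambda factor
    rs <- q_div(q_from_num(s), q_from_num(s - 1))
    rn <- q_div(q_from_num(n), q_from_num(n - 1))
    poly <- qp_mul(poly, qp_pow(list(q_neg(rs), q_one()), s - 2))
    poly <- qp_mul(poly, qp_pow(list(q_neg(rn), q_one()), n - 2))
    out$coef_exact <- vapply(poly, q_format, "")
    out$coef <- qp_to_num(poly)
    out$eigenvalues_fixed <- c(rep(s / (s - 1), s - 2), rep(n / (n - 1), n - 2), 0)
  }
  out$degree <- length(out$coef) - 1L
  cf <- out$coef
  out$eval <- function(lambda) poly_eval(cf, lambda)
  class(out) <- "charpoly"
  out
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' @export
print.charpoly <- function(x, ...) {
  cat(sprintf("<charpoly> family=%s degree=%d\n", x$family, x$degree))
  if (!is.null(x$coef)) cat("  coef (ascending):", signif(x$coef, 6), "\n")
  invisible(x)
}

#' Parameter point where all non-zero Laplacian eigenvalues coincide
#'
#' For the `(s, n)` partial bipartite graph, solves
#' `(s-1+p)/(s-1) = (n-1+q)/(n-1) = 2-p-q` exactly, giving
#' `(p, q) = (s-1, n-1)/(n+s-1)`.  This is also the minimizer of the
#' average communicability `Tr(e^W)/N`.
#'
#' @param s,n component sizes (at least 2)
#' @return list with exact `rational` coordinates `p`, `q` and the numeric
#'   pair `point`
#' @examples
#' eigenvalue_equality_point(3, 4)  # (1/3, 1/2)
#' @export
eigenvalue_equality_point <- function(s, n) {
  stopifnot(s >= 2, n >= 2)
  den <- q_from_num(n + s - 1)
  p <- q_div(q_from_num(s - 1), den)
  q <- q_div(q_from_num(n - 1), den)
  list(p = structure(p, class = "rational"),
       q = structure(q, class = "rational"),
       point = c(p = q_to_num(p), q = q_to_num(q)))
}
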