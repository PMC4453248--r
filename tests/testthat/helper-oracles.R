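# Shared helpers: independent brute-force oracles kept deliberately naive.

# exhaustive conductance minimum by direct subset enumeration
brute_force_conductance <- function(W) {
  N <- nrow(W)
  best <- Inf; bestS <- NULL
  for (mask in 1:(2^N - 2)) {
    S <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0)
    comp <- setdiff(seq_len(N), S)
    v <- N / (length(S) * length(comp)) * sum(W[S, comp, drop = FALSE])
    if (v < best) { best <- v; bestS <- S }
  }
  list(value = best, S = bestS)
}

# direct dense assembly of the master system from the defining transition
# rates (independent of build_master_system's sparse path)
dense_fixation_oracle <- function(W, r) {
  N <- nrow(W)
  S <- 2^N
  bits <- function(v) v %/% 2^(0:(N - 1)) %% 2
  A <- matrix(0, S - 2, S - 2)
  b <- numeric(S - 2)
  for (v in 1:(S - 2)) {
    vb <- bits(v)
    a <- as.numeric(vb %*% W)
    bb <- as.numeric((1 - vb) %*% W)
    diag_c <- 0
    for (i in 1:N) {
      if (vb[i] == 0) {
        rate <- r * a[i]
        if (rate == 0) next
        diag_c <- diag_c + rate
        t <- v + 2^(i - 1)
        if (t == S - 1) b[v] <- b[v] + rate else A[v, t] <- A[v, t] - rate
      } else {
        rate <- bb[i]
        if (rate == 0) next
        diag_c <- diag_c + rate
        t <- v - 2^(i - 1)
        if (t != 0) A[v, t] <- A[v, t] - rate
      }
    }
    A[v, v] <- diag_c
  }
  x <- solve(A, b)
  c(0, x, 1)
}
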