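# Arbitrary-precision signed integers on numeric limb vectors.
#
# Representation: list(s = sign in {-1, 0, 1}, d = little-endian limbs in
# base 2^20).  Base 2^20 keeps every intermediate product below 2^53 so all
# limb arithmetic is exact in doubles.  These are plain lists, not S3
# objects: they sit on the hot path of the fraction-free (Bareiss)
# elimination used by the exact solver backend.

.BI_BASE <- 2^20

bi_zero <- function() list(s = 0L, d = numeric(0))

bi_is_zero <- function(a) a$s == 0L

# trim high zero limbs
bi_trim <- function(d) {
  n <- length(d)
  while (n > 0L && d[n] == 0) n <- n - 1L
  if (n == length(d)) d else d[seq_len(n)]
}

# propagate carries in a non-negative digit vector (entries < 2^53)
bi_carry <- function(d) {
  repeat {
    q <- d %/% .BI_BASE
    nz <- which(q > 0)
    if (!length(nz)) break
    d <- d - q * .BI_BASE
    if (max(nz) + 1L > length(d)) d <- c(d, numeric(max(nz) + 1L - length(d)))
    idx <- nz + 1L
    d[idx] <- d[idx] + q[nz]
  }
  bi_trim(d)
}

bi_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x == trunc(x),
            abs(x) < 2^53)
  if (x == 0) return(bi_zero())
  s <- if (x < 0) -1L else 1L
  x <- abs(x)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  list(s = s, d = d)
}

bi_cmp_mag_d <- function(da, db) {
  if (length(da) != length(db)) return(sign(length(da) - length(db)))
  if (length(da) == 0L) return(0)
  neq <- which(da != db)
  if (!length(neq)) return(0)
  i <- max(neq)
  sign(da[i] - db[i])
}

bi_add_mag_d <- function(da, db) {
  n <- max(length(da), length(db))
  length(da) <- n; length(db) <- n
  da[is.na(da)] <- 0; db[is.na(db)] <- 0
  bi_carry(da + db)
}

# da >= db assumed
bi_sub_mag_d <- function(da, db) {
  n <- length(da)
  length(db) <- n
  db[is.na(db)] <- 0
  d <- da - db
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BI_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  bi_trim(d)
}

bi_neg <- function(a) {
  a$s <- -a$s
  a
}

bi_add <- function(a, b) {
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (a$s == b$s) return(list(s = a$s, d = bi_add_mag_d(a$d, b$d)))
  cm <- bi_cmp_mag_d(a$d, b$d)
  if (cm == 0) return(bi_zero())
  if (cm > 0) list(s = a$s, d = bi_sub_mag_d(a$d, b$d))
  else list(s = b$s, d = bi_sub_mag_d(b$d, a$d))
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$s == 0L || b$s == 0L) return(bi_zero())
  da <- a$d; db <- b$d
  if (length(da) < length(db)) { tmp <- da; da <- db; db <- tmp }
  conv <- numeric(length(da) + length(db) - 1L)
  ia <- seq_along(da)
  for (i in seq_along(db)) {
    idx <- ia + (i - 1L)
    conv[idx] <- conv[idx] + db[i] * da
  }
  list(s = a$s * b$s, d = bi_carry(conv))
}

# compare signed values
bi_cmp <- function(a, b) {
  if (a$s != b$s) return(sign(a$s - b$s))
  if (a$s == 0L) return(0)
  a$s * bi_cmp_mag_d(a$d, b$d)
}

# magnitude division (Knuth algorithm D); returns list(q, r) digit vectors
bi_divmod_mag <- function(da, db) {
  B <- .BI_BASE
  if (!length(db)) stop("bigint division by zero")
  cm <- bi_cmp_mag_d(da, db)
  if (cm < 0) return(list(q = numeric(0), r = da))
  if (cm == 0) return(list(q = 1, r = numeric(0)))
  n <- length(db)
  if (n == 1L) {
    v <- db[1]
    q <- numeric(length(da)); rem <- 0
    for (i in rev(seq_along(da))) {
      cur <- rem * B + da[i]
      q[i] <- cur %/% v
      rem <- cur %% v
    }
    return(list(q = bi_trim(q), r = if (rem > 0) rem else numeric(0)))
  }
  # normalize so the top divisor limb is >= B/2
  f <- B %/% (db[n] + 1)
  u <- bi_carry(da * f)
  v <- bi_carry(db * f)
  stopifnot(length(v) == n, v[n] >= B / 2)
  m <- length(u) - n
  u <- c(u, 0)                      # u has m + n + 1 limbs
  q <- numeric(m + 1L)
  for (j in seq(m, 0)) {
    top2 <- u[j + n + 1L] * B + u[j + n]
    qhat <- top2 %/% v[n]
    rhat <- top2 %% v[n]
    repeat {
      if (qhat >= B || qhat * v[n - 1L] > rhat * B + u[j + n - 1L]) {
        qhat <- qhat - 1
        rhat <- rhat + v[n]
        if (rhat < B) next
      }
      break
    }
    if (qhat > 0) {
      seg <- u[(j + 1L):(j + n + 1L)]
      prod <- bi_carry(v * qhat)
      length(prod) <- n + 1L
      prod[is.na(prod)] <- 0
      t <- seg - prod
      for (i in seq_len(n)) {
        if (t[i] < 0) {
          borrow <- ceiling(-t[i] / B)
          t[i] <- t[i] + borrow * B
          t[i + 1L] <- t[i + 1L] - borrow
        }
      }
      if (t[n + 1L] < 0) {          # qhat one too large: add divisor back
        qhat <- qhat - 1
        t <- t + c(v, 0)
        for (i in seq_len(n)) {
          if (t[i] >= B) {
            t[i] <- t[i] - B
            t[i + 1L] <- t[i + 1L] + 1
          }
        }
      }
      u[(j + 1L):(j + n + 1L)] <- t
    }
    q[j + 1L] <- qhat
  }
  r <- bi_trim(u[seq_len(n)])
  # undo normalization of the remainder
  if (length(r)) {
    rr <- bi_divmod_mag(r, f)
    stopifnot(!length(rr$r))
    r <- rr$q
  }
  list(q = bi_trim(q), r = r)
}

# truncated-toward-zero signed division
bi_divmod <- function(a, b) {
  if (b$s == 0L) stop("bigint division by zero")
  if (a$s == 0L) return(list(q = bi_zero(), r = bi_zero()))
  qr <- bi_divmod_mag(a$d, b$d)
  q <- if (length(qr$q)) list(s = a$s * b$s, d = qr$q) else bi_zero()
  r <- if (length(qr$r)) list(s = a$s, d = qr$r) else bi_zero()
  list(q = q, r = r)
}

# exact division: stops if b does not divide a
bi_div_exact <- function(a, b) {
  qr <- bi_divmod(a, b)
  if (!bi_is_zero(qr$r)) stop("bigint division not exact")
  qr$q
}

bi_gcd <- function(a, b) {
  da <- a$d; db <- b$d
  while (length(db)) {
    r <- bi_divmod_mag(da, db)$r
    da <- db
    db <- r
  }
  if (!length(da)) bi_zero() else list(s = 1L, d = da)
}

bi_abs <- function(a) {
  if (a$s < 0L) a$s <- 1L
  a
}

bi_one <- function() list(s = 1L, d = 1)

# may lose precision above 2^53; used for diagnostics and conversions only
bi_to_num <- function(a) {
  if (a$s == 0L) return(0)
  a$s * sum(a$d * .BI_BASE^(seq_along(a$d) - 1))
}

bi_to_string <- function(a) {
  if (a$s == 0L) return("0")
  d <- a$d
  out <- character(0)
  repeat {
    qr <- bi_divmod_mag(d, 1e6)
    rem <- if (length(qr$r)) qr$r else 0
    d <- qr$q
    if (length(d)) {
      out <- c(sprintf("%06d", rem), out)
    } else {
      out <- c(sprintf("%d", rem), out)
      break
    }
  }
  paste0(if (a$s < 0L) "-" else "", paste(out, collapse = ""))
}

bi_from_string <- function(x) {
  x <- trimws(x)
  s <- 1L
  if (startsWith(x, "-")) { s <- -1L; x <- substring(x, 2) }
  else if (startsWith(x, "+")) x <- substring(x, 2)
  stopifnot(grepl("^[0-9]+$", x))
  acc <- bi_zero()
  chunk <- 1e6
  pos <- 1L
  # leading group may be short
  lead <- nchar(x) %% 6L
  if (lead) {
    acc <- bi_from_num(as.numeric(substr(x, 1, lead)))
    pos <- lead + 1L
  }
  while (pos <= nchar(x)) {
    g <- as.numeric(substr(x, pos, pos + 5L))
    acc <- bi_add(bi_mul(acc, bi_from_num(chunk)), bi_from_num(g))
    pos <- pos + 6L
  }
  if (bi_is_zero(acc)) return(acc)
  acc$s <- s
  acc
}
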