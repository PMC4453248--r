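# Exact rational arithmetic over the bigint layer.
#
# Two levels: internal q_* functions on plain list(num =, den =) pairs
# (den > 0, fully reduced), and a thin scalar S3 class `rational` for
# user-facing exact values (tuning solutions, feasibility endpoints).

q_new <- function(num, den = bi_one()) {
  if (bi_is_zero(den)) stop("rational with zero denominator")
  if (bi_is_zero(num)) return(list(num = bi_zero(), den = bi_one()))
  s <- num$s * den$s
  num <- bi_abs(num); den <- bi_abs(den)
  g <- bi_gcd(num, den)
  if (!(length(g$d) == 1L && g$d[1] == 1)) {
    num <- bi_div_exact(num, g)
    den <- bi_div_exact(den, g)
  }
  num$s <- s
  list(num = num, den = den)
}

q_zero <- function() list(num = bi_zero(), den = bi_one())
q_one  <- function() list(num = bi_one(), den = bi_one())

q_is_zero <- function(a) bi_is_zero(a$num)

# exact conversion: doubles are dyadic rationals
q_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  e <- 0L
  while (x != trunc(x)) {
    x <- x * 2
    e <- e + 1L
    if (e > 80L || abs(x) >= 2^53)
      stop("numeric value is not exactly representable as a small rational; ",
           "pass a fraction string like \"2/3\" instead")
  }
  pow2 <- list(s = 1L, d = c(numeric(e %/% 20L), 2^(e %% 20L)))
  q_new(bi_from_num(x), pow2)
}

q_parse <- function(x) {
  x <- trimws(x)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    stopifnot(length(parts) == 2L)
    q_new(bi_from_string(parts[1]), bi_from_string(parts[2]))
  } else if (grepl("^[+-]?[0-9]+$", x)) {
    q_new(bi_from_string(x))
  } else {
    # decimal string: exact scaling by a power of ten
    stopifnot(grepl("^[+-]?[0-9]*\\.[0-9]+$", x))
    neg <- startsWith(x, "-")
    x <- sub("^[+-]", "", x)
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    intpart <- if (nzchar(parts[1])) parts[1] else "0"
    frac <- parts[2]
    num <- bi_from_string(paste0(intpart, frac))
    den <- bi_from_string(paste0("1", strrep("0", nchar(frac))))
    if (neg) num <- bi_neg(num)
    q_new(num, den)
  }
}

q_add <- function(a, b)
  q_new(bi_add(bi_mul(a$num, b$den), bi_mul(b$num, a$den)),
        bi_mul(a$den, b$den))

q_sub <- function(a, b) q_add(a, q_neg(b))

q_neg <- function(a) {
  a$num <- bi_neg(a$num)
  a
}

q_mul <- function(a, b) q_new(bi_mul(a$num, b$num), bi_mul(a$den, b$den))

q_div <- function(a, b) {
  if (q_is_zero(b)) stop("rational division by zero")
  q_new(bi_mul(a$num, b$den), bi_mul(a$den, b$num))
}

q_inv <- function(a) q_div(q_one(), a)

q_cmp <- function(a, b) bi_cmp(bi_mul(a$num, b$den), bi_mul(b$num, a$den))

q_eq <- function(a, b) q_cmp(a, b) == 0

q_to_num <- function(a) {
  v <- bi_to_num(a$num) / bi_to_num(a$den)
  if (is.finite(v)) return(v)
  # fall back through string conversion for very large parts
  as.numeric(bi_to_string(a$num)) / as.numeric(bi_to_string(a$den))
}

q_format <- function(a) {
  if (length(a$den$d) == 1L && a$den$d[1] == 1)
    bi_to_string(a$num)
  else
    paste0(bi_to_string(a$num), "/", bi_to_string(a$den))
}

q_min <- function(a, b) if (q_cmp(a, b) <= 0) a else b
q_max <- function(a, b) if (q_cmp(a, b) >= 0) a else b

# coerce numeric / character / rational to the internal pair
as_q <- function(x) {
  if (inherits(x, "rational")) return(unclass(x))
  if (is.character(x)) return(q_parse(x))
  if (is.numeric(x)) return(q_from_num(x))
  stop("cannot coerce to rational: ", paste(class(x), collapse = "/"))
}

#' Exact rational numbers
#'
#' A minimal exact rational scalar used wherever the package does exact
#' algebra: temperature-profile tuning, feasibility interval endpoints, and
#' the exact (fraction-free) linear-solver backend.  Construct from a pair
#' of integers, a fraction string (`"2/3"`), a decimal string, or a numeric
#' that is exactly representable (integers, dyadic fractions).
#'
#' Standard arithmetic (`+`, `-`, `*`, `/`, `^` with integer exponent) and
#' comparison operators are available, always exact.
#'
#' @param num numerator (integer-valued numeric, or a string to parse)
#' @param den denominator (integer-valued numeric, default 1)
#' @return an object of class `rational`
#' @examples
#' rational(2, 3) + rational("1/6")   # 5/6
#' rational("1/3") == rational(1, 3)  # TRUE
#' @export
rational <- function(num, den = 1) {
  a <- as_q(num)
  if (!(is.numeric(den) && length(den) == 1L && den == 1))
    a <- q_div(a, as_q(den))
  structure(a, class = "rational")
}

#' Coerce to a rational
#' @param x a `rational`, fraction string, or exactly-representable numeric
#' @return a `rational`
#' @export
as_rational <- function(x) structure(as_q(x), class = "rational")

#' @export
format.rational <- function(x, ...) q_format(unclass(x))

#' @export
print.rational <- function(x, ...) {
  cat(q_format(unclass(x)), "\n")
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) q_format(unclass(x))

#' @export
as.double.rational <- function(x, ...) q_to_num(unclass(x))

#' @export
Ops.rational <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "/", "^", "==", "!=", "<", ">",
                      "<=", ">=")) {
    if (missing(e2)) {
      # unary
      a <- as_q(e1)
      return(switch(.Generic,
                    "+" = structure(a, class = "rational"),
                    "-" = structure(q_neg(a), class = "rational"),
                    stop("unsupported unary op for rational: ", .Generic)))
    }
    if (.Generic == "^") {
      a <- as_q(e1)
      k <- e2
      stopifnot(is.numeric(k), k == trunc(k))
      neg <- k < 0
      k <- abs(k)
      out <- q_one()
      while (k > 0) {
        out <- q_mul(out, a)
        k <- k - 1
      }
      if (neg) out <- q_inv(out)
      return(structure(out, class = "rational"))
    }
    a <- as_q(e1); b <- as_q(e2)
    cm <- function() q_cmp(a, b)
    out <- switch(.Generic,
                  "+" = q_add(a, b),
                  "-" = q_sub(a, b),
                  "*" = q_mul(a, b),
                  "/" = q_div(a, b),
                  "==" = return(cm() == 0),
                  "!=" = return(cm() != 0),
                  "<"  = return(cm() < 0),
                  ">"  = return(cm() > 0),
                  "<=" = return(cm() <= 0),
                  ">=" = return(cm() >= 0))
    return(structure(out, class = "rational"))
  }
  stop("unsupported operation for rational: ", .Generic)
}

# ---- exact linear algebra on list-matrices of q pairs ---------------------

# qm: list of length n*m with dim attribute, entries q pairs
qm_new <- function(n, m, fill = q_zero()) {
  out <- vector("list", n * m)
  for (i in seq_along(out)) out[[i]] <- fill
  attr(out, "qdim") <- c(n, m)
  out
}

qm_get <- function(A, i, j) A[[i + (j - 1L) * attr(A, "qdim")[1]]]
qm_set <- function(A, i, j, v) {
  A[[i + (j - 1L) * attr(A, "qdim")[1]]] <- v
  A
}

bi_lcm <- function(a, b) {
  if (bi_is_zero(a)) return(bi_abs(b))
  if (bi_is_zero(b)) return(bi_abs(a))
  bi_abs(bi_mul(bi_div_exact(a, bi_gcd(a, b)), b))
}

# Solve A x = b exactly (A: qm n x n, b: list of n q pairs) by clearing
# denominators row-wise and running fraction-free Bareiss elimination on
# bigints, then back-substituting in rationals.  Stops on a structurally
# singular system.
q_solve <- function(A, b) {
  n <- attr(A, "qdim")[1]
  stopifnot(attr(A, "qdim")[2] == n, length(b) == n)
  # integer augmented matrix
  M <- vector("list", n * (n + 1L))
  dimM <- c(n, n + 1L)
  getM <- function(i, j) M[[i + (j - 1L) * n]]
  for (i in seq_len(n)) {
    L <- bi_one()
    for (j in seq_len(n)) L <- bi_lcm(L, qm_get(A, i, j)$den)
    L <- bi_lcm(L, b[[i]]$den)
    for (j in seq_len(n)) {
      e <- qm_get(A, i, j)
      M[[i + (j - 1L) * n]] <- bi_mul(e$num, bi_div_exact(L, e$den))
    }
    M[[i + n * n]] <- bi_mul(b[[i]]$num, bi_div_exact(L, b[[i]]$den))
  }
  prev <- bi_one()
  for (k in seq_len(n - 1L)) {
    # pivot: first row with nonzero entry in column k
    piv <- 0L
    for (i in k:n) if (!bi_is_zero(getM(i, k))) { piv <- i; break }
    if (piv == 0L) stop("exact solve: singular system")
    if (piv != k) {
      for (j in k:(n + 1L)) {
        tmp <- getM(k, j)
        M[[k + (j - 1L) * n]] <- getM(piv, j)
        M[[piv + (j - 1L) * n]] <- tmp
      }
    }
    pkk <- getM(k, k)
    for (i in (k + 1L):n) {
      mik <- getM(i, k)
      for (j in (k + 1L):(n + 1L)) {
        v <- bi_sub(bi_mul(pkk, getM(i, j)), bi_mul(mik, getM(k, j)))
        M[[i + (j - 1L) * n]] <- bi_div_exact(v, prev)
      }
      M[[i + (k - 1L) * n]] <- bi_zero()
    }
    prev <- pkk
  }
  if (bi_is_zero(getM(n, n))) stop("exact solve: singular system")
  x <- vector("list", n)
  for (i in seq(n, 1L)) {
    acc <- q_new(getM(i, n + 1L))
    for (j in seq_len(n)) {
      if (j > i && !q_is_zero(x[[j]]) && !bi_is_zero(getM(i, j)))
        acc <- q_sub(acc, q_mul(q_new(getM(i, j)), x[[j]]))
    }
    x[[i]] <- q_div(acc, q_new(getM(i, i)))
  }
  x
}
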