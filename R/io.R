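# Graph document I/O (JSON, edge-list TSV, dense CSV) and seeded random
# fixtures.  User-facing files use 1-based vertex ids; weights are
# serialized as decimal strings with 17 significant digits, or as exact
# fraction strings when an exact matrix is available, so that documents
# round-trip losslessly.

fmt_weight <- function(x) sprintf("%.17g", x)

#' Write a weighted digraph as a JSON document
#'
#' The document carries a schema version, the family and its parameters,
#' `N`, vertex labels, the row-major weight matrix as decimal strings (or
#' exact fraction strings when requested and available), and provenance
#' (timestamp, optional command and seed).
#'
#' @param graph a `weighted_digraph`
#' @param path output file
#' @param exact serialize weights as exact fractions (uses the exact matrix)
#' @param provenance optional named list merged into the provenance block
#' @return `path`, invisibly
#' @export
write_graph_json <- function(graph, path, exact = FALSE, provenance = list()) {
  W_chr <- if (exact) {
    Wq <- graph_exact_matrix(graph)
    N <- graph$N
    out <- character(N * N)
    for (i in seq_len(N)) for (j in seq_len(N))
      out[(i - 1) * N + j] <- q_format(qm_get(Wq, i, j))
    out
  } else {
    vapply(as.vector(t(graph$W)), fmt_weight, "")
  }
  doc <- list(schema = "evograph-graph/1",
              family = graph$family,
              params = graph$params,
              N = graph$N,
              vertex_labels = graph$vertex_labels,
              W = W_chr,
              provenance = c(list(timestamp = format(Sys.time(), tz = "UTC"),
                                  encoding = if (exact) "fraction" else "decimal17"),
                             provenance))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

parse_weight <- function(s) {
  if (grepl("/", s, fixed = TRUE)) q_to_num(q_parse(s)) else as.numeric(s)
}

#' Read a weighted digraph from a JSON document
#'
#' @param path file written by [write_graph_json()]
#' @return a `weighted_digraph` (validated: row sums, weight bounds)
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- doc$N
  vals <- vapply(as.character(doc$W), parse_weight, 0, USE.NAMES = FALSE)
  if (length(vals) != N * N)
    stop("graph document has ", length(vals), " weights, expected N^2 = ",
         N * N)
  W <- matrix(vals, N, N, byrow = TRUE)
  Wq <- NULL
  if (any(grepl("/", doc$W, fixed = TRUE))) {
    Wq <- qm_new(N, N)
    k <- 1L
    for (i in seq_len(N)) for (j in seq_len(N)) {
      Wq <- qm_set(Wq, i, j, q_parse(as.character(doc$W[k])))
      k <- k + 1L
    }
  }
  weighted_digraph(W, family = doc$family %||% "generic",
                   params = as.list(doc$params),
                   vertex_labels = doc$vertex_labels,
                   W_exact = Wq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an edge-list TSV (1-based vertex ids)
#'
#' Columns `i`, `j`, `w`; only nonzero weights are written.  Reading
#' validates row-stochasticity and names offending rows.
#'
#' @param graph a `weighted_digraph`
#' @param path file path
#' @return `path` (write) or a `weighted_digraph` (read)
#' @export
write_graph_tsv <- function(graph, path) {
  idx <- which(graph$W != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   w = vapply(graph$W[idx], fmt_weight, ""))
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param N number of vertices (optional for TSV; inferred from max id)
#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path, N = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "integer", "character"))
  if (is.null(N)) N <- max(df$i, df$j)
  W <- matrix(0, N, N)
  for (k in seq_len(nrow(df)))
    W[df$i[k], df$j[k]] <- W[df$i[k], df$j[k]] + parse_weight(df$w[k])
  rs <- rowSums(W)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad))
    stop("edge list is not row-stochastic: row(s) ",
         paste(bad, collapse = ", "), " sum to ",
         paste(signif(rs[bad], 6), collapse = ", "))
  weighted_digraph(W)
}

#' Write a dense weight-matrix CSV
#'
#' @param graph a `weighted_digraph`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_graph_csv <- function(graph, path) {
  M <- matrix(vapply(t(graph$W), fmt_weight, ""), graph$N, graph$N,
              byrow = TRUE)
  utils::write.table(M, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
read_graph_csv <- function(path) {
  M <- as.matrix(utils::read.table(path, sep = ",", colClasses = "character"))
  W <- apply(M, c(1, 2), parse_weight)
  dimnames(W) <- NULL
  weighted_digraph(W)
}

# sample a zero-diagonal permutation (derangement) by rejection
sample_derangement <- function(N) {
  repeat {
    perm <- sample.int(N)
    if (all(perm != seq_len(N))) return(perm)
  }
}

#' Seeded random graph fixtures
#'
#' `kind = "row_stochastic"`: positive uniform rows, zero diagonal,
#' normalized.  `kind = "doubly_stochastic"`: a random positive convex
#' combination of at least `N` random derangement permutation matrices
#' (each zero-diagonal), verified on both marginals to `1e-12` --- these
#' are the isothermal test graphs: by the isothermal theorem their
#' single-vertex fixation probability must equal the Moran probability.
#' Deterministic given `seed`.
#'
#' @param kind `"row_stochastic"` or `"doubly_stochastic"`
#' @param N number of vertices (at most 10)
#' @param seed integer seed
#' @return a `weighted_digraph` (family `"generic"`)
#' @export
fixture_graphs <- function(kind = c("row_stochastic", "doubly_stochastic"),
                           N, seed) {
  kind <- match.arg(kind)
  stopifnot(N >= 3, N <= 10)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (kind == "row_stochastic") {
    W <- matrix(stats::runif(N * N, 0.05, 1), N, N)
    diag(W) <- 0
    W <- W / rowSums(W)
  } else {
    m <- N + 2L
    wts <- stats::runif(m, 0.2, 1)
    wts <- wts / sum(wts)
    W <- matrix(0, N, N)
    for (k in seq_len(m)) {
      perm <- sample_derangement(N)
      W[cbind(seq_len(N), perm)] <- W[cbind(seq_len(N), perm)] + wts[k]
    }
    stopifnot(max(abs(rowSums(W) - 1)) < 1e-12,
              max(abs(colSums(W) - 1)) < 1e-12)
  }
  weighted_digraph(W, "generic", params = list(kind = kind, seed = seed))
}
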