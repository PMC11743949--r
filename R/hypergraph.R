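#' Construct a hypergraph
#'
#' A hypergraph couples any number of vertices through a hyperedge, which is
#' how many-to-many training interactions (sparring units, passing drills,
#' defensive sets) are modelled: each athlete is a vertex, each interaction
#' group a hyperedge with a positive weight.
#'
#' @param n_vertices number of vertices.
#' @param hyperedges list of integer vectors of 1-based vertex indices; every
#'   hyperedge must be non-empty. Duplicate hyperedges are retained and count
#'   with multiplicity in all degree computations.
#' @param weights positive hyperedge weights; default 1 for every hyperedge.
#' @return object of class `hypergraph`.
#' @export
hypergraph <- function(n_vertices, hyperedges, weights = NULL) {
  n_vertices <- check_count(n_vertices, "n_vertices")
  if (!is.list(hyperedges) || length(hyperedges) == 0L) {
    abort("`hyperedges` must be a non-empty list of vertex-index vectors.",
          class = "wpinjury_invalid_hypergraph")
  }
  hyperedges <- lapply(hyperedges, function(e) {
    e <- sort(unique(as.integer(e)))
    if (length(e) == 0L || any(e < 1L) || any(e > n_vertices)) {
      abort("every hyperedge must be a non-empty subset of 1..n_vertices.",
            class = "wpinjury_invalid_hypergraph")
    }
    e
  })
  weights <- if (is.null(weights)) rep(1, length(hyperedges)) else as.numeric(weights)
  if (length(weights) != length(hyperedges) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    abort("`weights` must be positive, one per hyperedge.",
          class = "wpinjury_invalid_hypergraph")
  }
  structure(list(n_vertices = n_vertices, hyperedges = hyperedges,
                 weights = weights),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("# Hypergraph: %d vertices, %d hyperedges (sizes %s)\n",
              x$n_vertices, length(x$hyperedges),
              paste(range(lengths(x$hyperedges)), collapse = "-")))
  invisible(x)
}

#' Tidy a hypergraph into a vertex-hyperedge membership table
#'
#' @param x a `hypergraph`.
#' @param ... unused.
#' @return tibble with one row per (hyperedge, vertex) incidence, plus the
#'   hyperedge weight and size.
#' @export
tidy.hypergraph <- function(x, ...) {
  tibble::tibble(
    hyperedge = rep(seq_along(x$hyperedges), lengths(x$hyperedges)),
    vertex = unlist(x$hyperedges),
    weight = rep(x$weights, lengths(x$hyperedges)),
    size = rep(lengths(x$hyperedges), lengths(x$hyperedges))
  )
}

#' Build a k-nearest-neighbour hypergraph from feature vectors
#'
#' Standard construction for feature-derived hypergraphs: one hyperedge per
#' vertex consisting of the vertex itself plus its `k` nearest neighbours by
#' Euclidean distance. Distance ties are broken towards the lower vertex
#' index so builds are deterministic. All weights are 1.
#'
#' @param features numeric matrix (or `athlete_cohort`), one row per vertex.
#' @param k number of neighbours; must satisfy `1 <= k <= n - 1`.
#' @return a `hypergraph` with exactly `n` hyperedges of size `k + 1`.
#' @examples
#' g <- build_knn_hypergraph(matrix(c(0, 1, 10), ncol = 1), k = 1)
#' g$hyperedges
#' @export
build_knn_hypergraph <- function(features, k) {
  if (inherits(features, "athlete_cohort")) features <- cohort_features(features)
  features <- as.matrix(features)
  if (anyNA(features)) {
    abort("`features` must not contain missing values.",
          class = "wpinjury_invalid_parameter")
  }
  n <- nrow(features)
  k <- check_count(k, "k")
  if (k >= n) {
    abort(sprintf("`k` (%d) must be smaller than the number of vertices (%d).", k, n),
          class = "wpinjury_invalid_parameter")
  }
  d2 <- as.matrix(stats::dist(features))
  hyperedges <- lapply(seq_len(n), function(v) {
    ord <- order(d2[v, -v], setdiff(seq_len(n), v))[seq_len(k)]
    sort(c(v, setdiff(seq_len(n), v)[ord]))
  })
  hypergraph(n, hyperedges)
}

#' Incidence matrix of a hypergraph
#'
#' @param g a `hypergraph`.
#' @return binary matrix `H` of dimension n_vertices x n_hyperedges with
#'   `H[v, e] = 1` iff vertex `v` belongs to hyperedge `e`.
#' @export
incidence_matrix <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  h <- matrix(0, g$n_vertices, length(g$hyperedges))
  for (e in seq_along(g$hyperedges)) h[g$hyperedges[[e]], e] <- 1
  h
}

#' Vertex and hyperedge degrees
#'
#' Vertex degree is the weighted count of hyperedges containing the vertex,
#' `Dv(v) = sum_e w_e h(v, e)`; hyperedge degree is its size,
#' `De(e) = sum_v h(v, e)`.
#'
#' @param g a `hypergraph`.
#' @return list with numeric vectors `Dv` (length n_vertices) and `De`
#'   (length n_hyperedges).
#' @export
hypergraph_degrees <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  dv <- numeric(g$n_vertices)
  for (e in seq_along(g$hyperedges)) {
    dv[g$hyperedges[[e]]] <- dv[g$hyperedges[[e]]] + g$weights[e]
  }
  list(Dv = dv, De = as.numeric(lengths(g$hyperedges)))
}

#' Vertex-space hypergraph Laplacian (clique expansion)
#'
#' Builds the weighted clique-expansion adjacency
#' `A[i, j] = sum_e w_e h(i, e) h(j, e) / De(e)` (zero diagonal) and the
#' Laplacian `L = D_A - A` with `D_A = diag(rowSums(A))`. `L` is symmetric
#' positive semi-definite with zero row sums, acts on vertex embeddings, and
#' reduces to the ordinary graph Laplacian when every hyperedge is a pair.
#' An edge-space operator of dimension |E| x |E| is available separately as
#' [edge_space_laplacian()] for audit.
#'
#' @param g a `hypergraph`.
#' @return object of class `laplacian_bundle`: list with adjacency `A`,
#'   Laplacian `L`, and degree vectors `Dv`, `De`.
#' @export
hypergraph_laplacian <- function(g) {
  stopifnot(inherits(g, "hypergraph"))
  h <- incidence_matrix(g)
  deg <- hypergraph_degrees(g)
  m <- h %*% (g$weights / deg$De * t(h))
  a <- m - diag(diag(m), nrow = nrow(m))
  l <- diag(rowSums(a), nrow = nrow(a)) - a
  structure(list(A = a, L = l, Dv = deg$Dv, De = deg$De),
            class = "laplacian_bundle")
}

#' Edge-space hypergraph operator De - H'WH
#'
#' The literal |E| x |E| reading of the hypergraph Laplacian. Note the
#' expression only conforms if the weight matrix sandwiched between the
#' incidence factors acts on vertex space; with unit vertex weights it is
#' `De - t(H) %*% H`. The operator lives on hyperedge space and is provided
#' for audit only; the smoothness functional over vertex embeddings uses
#' the vertex-space [hypergraph_laplacian()] instead.
#'
#' @param g a `hypergraph`.
#' @param vertex_weights optional positive vertex weights (default 1).
#' @return numeric matrix of dimension n_hyperedges x n_hyperedges.
#' @export
edge_space_laplacian <- function(g, vertex_weights = NULL) {
  stopifnot(inherits(g, "hypergraph"))
  h <- incidence_matrix(g)
  w <- vertex_weights %||% rep(1, g$n_vertices)
  diag(as.numeric(lengths(g$hyperedges)), nrow = length(g$hyperedges)) -
    t(h) %*% (w * h)
}

#' Laplacian smoothness of a vertex embedding
#'
#' The quadratic form `0.5 * trace(t(X) %*% L %*% X)`, equal to
#' `0.25 * sum_ij A[i, j] * ||X[i, ] - X[j, ]||^2` over ordered pairs: small
#' values mean athletes that share training groups have similar embeddings.
#'
#' @param x numeric embedding matrix with one row per vertex.
#' @param bundle a `laplacian_bundle` from [hypergraph_laplacian()].
#' @return non-negative scalar.
#' @export
smoothness <- function(x, bundle) {
  stopifnot(inherits(bundle, "laplacian_bundle"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(bundle$L)) {
    abort("`x` must have one row per hypergraph vertex.",
          class = "wpinjury_shape_error")
  }
  0.5 * sum(x * (bundle$L %*% x))
}

#' Serialize a hypergraph to JSON
#'
#' Vertex indices are written zero-based in the JSON form for
#' interoperability; [read_hypergraph_json()] restores the 1-based in-memory
#' representation, and the round trip is lossless.
#'
#' @param g a `hypergraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypergraph_json <- function(g, path) {
  stopifnot(inherits(g, "hypergraph"))
  payload <- list(
    n_vertices = g$n_vertices,
    hyperedges = lapply(g$hyperedges, function(e) as.integer(e - 1L)),
    weights = g$weights
  )
  atomic_write(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}

#' Read a hypergraph from its JSON serialization
#'
#' @param path path to a JSON file written by [write_hypergraph_json()].
#' @return a `hypergraph`.
#' @export
read_hypergraph_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- payload$hyperedges
  if (is.matrix(edges)) edges <- split(edges, row(edges))
  if (!is.list(edges)) edges <- as.list(edges)
  hypergraph(payload$n_vertices,
             unname(lapply(edges, function(e) as.integer(e) + 1L)),
             payload$weights)
}
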