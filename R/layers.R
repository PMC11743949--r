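#' Parameters of one network layer
#'
#' @param weight numeric matrix, `d_in x d_out`.
#' @param bias numeric vector of length `d_out`.
#' @param activation one of `"relu"`, `"sigmoid"`, `"identity"`.
#' @return object of class `layer_params`.
#' @export
layer_params <- function(weight, bias, activation = c("relu", "sigmoid", "identity")) {
  activation <- match.arg(activation)
  weight <- as.matrix(weight)
  bias <- as.numeric(bias)
  if (length(bias) != ncol(weight)) {
    abort("`bias` length must equal ncol(weight).", class = "wpinjury_shape_error")
  }
  structure(list(weight = weight, bias = bias, activation = activation),
            class = "layer_params")
}

#' Glorot-style uniform initialisation of a layer
#'
#' Weights are drawn uniformly in `±sqrt(6 / (d_in + d_out))`, biases start
#' at zero; fully determined by `seed`.
#'
#' @param d_in,d_out layer dimensions.
#' @param activation activation name, see [layer_params()].
#' @param seed integer seed.
#' @return a `layer_params`.
#' @export
init_layer_params <- function(d_in, d_out, activation = "relu", seed = 1L) {
  withr::local_seed(seed)
  lim <- sqrt(6 / (d_in + d_out))
  layer_params(matrix(runif(d_in * d_out, -lim, lim), d_in, d_out),
               rep(0, d_out), activation)
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         identity = z)
}

activation_grad <- function(pre, post, activation) {
  switch(activation,
         relu = (pre > 0) * 1,
         sigmoid = post * (1 - post),
         identity = array(1, dim(pre)))
}

#' Per-node feature embedding
#'
#' Maps each node's feature vector through one affine layer and activation:
#' row `i` of the result is `sigma(t(W) %*% x_i + b)`.
#'
#' @param x numeric feature matrix, one row per node.
#' @param p a `layer_params` whose weight has `ncol(x)` rows.
#' @return embedding matrix with `ncol(p$weight)` columns.
#' @export
embed_nodes <- function(x, p) {
  stopifnot(inherits(p, "layer_params"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(p$weight)) {
    abort(sprintf("feature dimension %d does not match weight rows %d.",
                  ncol(x), nrow(p$weight)),
          class = "wpinjury_shape_error")
  }
  apply_activation(x %*% p$weight + rep(1, nrow(x)) %o% p$bias, p$activation)
}

#' Hypergraph aggregation operator
#'
#' The dense vertex-to-vertex operator `Q[v, u] = sum_{e: v,u in e} 1 / |e|`
#' implied by size-normalised message passing over hyperedges incident to
#' each vertex. `Q` is symmetric; a vertex in no hyperedge has a zero row.
#'
#' @param g a `hypergraph`.
#' @param normalize if `TRUE`, return the symmetrically degree-normalised
#'   operator `D^{-1/2} Q D^{-1/2}` with `D = diag(rowSums(Q))`, whose
#'   spectral radius does not grow with vertex degree; the raw operator
#'   scales each output row by roughly the vertex degree.
#' @return numeric `n x n` matrix.
#' @export
aggregation_matrix <- function(g, normalize = FALSE) {
  stopifnot(inherits(g, "hypergraph"))
  h <- incidence_matrix(g)
  q <- h %*% (t(h) / lengths(g$hyperedges))
  if (normalize) {
    d <- rowSums(q)
    inv <- ifelse(d > 0, 1 / sqrt(d), 0)
    q <- q * inv * rep(inv, each = nrow(q))
  }
  q
}

#' One hypergraph convolution layer
#'
#' Updates every vertex embedding by averaging over its incident hyperedges:
#' `out[v, ] = sigma( sum_{e contains v} (1/|e|) sum_{u in e} t(W) %*% X[u, ] + b )`,
#' i.e. `sigma(Q X W + 1 b')` with `Q` from [aggregation_matrix()]. A vertex
#' belonging to no hyperedge receives `sigma(b)` and a warning is emitted.
#'
#' @param g a `hypergraph`.
#' @param x embedding matrix with `g$n_vertices` rows.
#' @param p a `layer_params`.
#' @param normalize use the degree-normalised aggregation operator (see
#'   [aggregation_matrix()]); default `FALSE`, the size-normalised sum over
#'   incident hyperedges.
#' @return updated embedding matrix.
#' @export
hyperconv_layer <- function(g, x, p, normalize = FALSE) {
  stopifnot(inherits(g, "hypergraph"), inherits(p, "layer_params"))
  x <- as.matrix(x)
  if (nrow(x) != g$n_vertices) {
    abort("`x` must have one row per hypergraph vertex.",
          class = "wpinjury_shape_error")
  }
  deg <- hypergraph_degrees(g)
  if (any(deg$Dv == 0)) {
    warn(sprintf("%d vertex/vertices belong to no hyperedge; their output is sigma(bias).",
                 sum(deg$Dv == 0)))
  }
  agg <- aggregation_matrix(g, normalize) %*% x
  apply_activation(agg %*% p$weight + rep(1, nrow(x)) %o% p$bias, p$activation)
}

#' Forward pass through a stack of hypergraph convolution layers
#'
#' @param g a `hypergraph`.
#' @param x0 input feature matrix, one row per vertex.
#' @param stack list of `layer_params`; an empty stack returns `x0` with a
#'   warning.
#' @return final embedding matrix.
#' @export
hgnn_forward <- function(g, x0, stack) {
  if (length(stack) == 0L) {
    warn("empty layer stack; returning the input unchanged.")
    return(as.matrix(x0))
  }
  Reduce(function(x, p) hyperconv_layer(g, x, p), stack, init = as.matrix(x0))
}
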