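#' Aggregate node embeddings over one hyperedge
#'
#' The hyperedge embedding is the (optionally weighted) mean of the
#' embeddings of its member vertices.
#'
#' @param z embedding matrix, one row per vertex.
#' @param e integer vector of member vertex indices; must be non-empty.
#' @param method `"mean"` or `"weighted_mean"`.
#' @param weights per-member positive weights, required for
#'   `"weighted_mean"`.
#' @return numeric vector of length `ncol(z)`.
#' @export
aggregate_hyperedge <- function(z, e, method = c("mean", "weighted_mean"),
                                weights = NULL) {
  method <- match.arg(method)
  z <- as.matrix(z)
  e <- as.integer(e)
  if (length(e) == 0L) {
    abort("cannot aggregate an empty hyperedge.", class = "wpinjury_invalid_hypergraph")
  }
  rows <- z[e, , drop = FALSE]
  if (method == "mean") return(colMeans(rows))
  if (is.null(weights) || length(weights) != length(e) || any(weights <= 0)) {
    abort("`weights` must be positive and match the hyperedge size.",
          class = "wpinjury_invalid_parameter")
  }
  colSums(rows * weights) / sum(weights)
}

#' Reconstruction loss between hyperedge embeddings and pattern outputs
#'
#' `sum_j || a_j - p_j ||^2`, the training signal of the pattern model: the
#' decoder must reproduce each hyperedge embedding from itself, forcing the
#' encoder to organise hyperedges along reconstructible directions.
#'
#' @param a matrix of hyperedge embeddings (targets).
#' @param p matrix of pattern outputs (reconstructions), same shape.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(a, p) {
  a <- as.matrix(a); p <- as.matrix(p)
  if (!all(dim(a) == dim(p))) {
    abort("`a` and `p` must have identical shapes.", class = "wpinjury_shape_error")
  }
  sum((a - p)^2)
}

# m x n row-normalised hyperedge aggregation operator (mean pooling).
hyperedge_pool_matrix <- function(g) {
  b <- t(incidence_matrix(g))
  b / lengths(g$hyperedges)
}

#' Train the hypergraph pattern model
#'
#' Jointly trains the encoder — a per-node embedding layer followed by one
#' degree-normalised hypergraph convolution — and a multilayer-perceptron
#' decoder (hidden sizes 64 and 32, ReLU; sigmoid output) to minimise the
#' reconstruction loss between hyperedge embeddings (means of the convolved
#' node embeddings over each hyperedge) and their decoded reproduction.
#' Hyperedges are the cohort's latent training groups. Because the sigmoid
#' head is bounded, targets are min-max scaled to (0, 1) per embedding
#' dimension using the initial epoch's range, which is then held fixed. A
#' seeded 20% hyperedge split provides validation loss for early stopping
#' with best-epoch checkpointing.
#'
#' @param cohort an `athlete_cohort`.
#' @param g a `hypergraph` over the cohort's athletes; defaults to one
#'   hyperedge per latent training group.
#' @param settings a [train_settings()]; default Adam, lr 0.001, 100 epochs,
#'   patience 10.
#' @param hgnn_dims hidden widths of the encoder stack (default 64, 32).
#' @param aggregation hyperedge aggregation, `"mean"` or `"weighted_mean"`
#'   (the latter weights members by hyperedge weight-normalised degree).
#' @return object of class `pattern_model` with elements `hgnn_stack`, `mlp`,
#'   `scaling`, `trace` (tibble `epoch, train_loss, val_loss`), `best_epoch`,
#'   `embeddings` (per-node embedding-layer output at the checkpointed
#'   parameters — the node-level representation used for 2-D visualisation),
#'   `conv_embeddings` (the convolved embeddings that feed the hyperedge
#'   aggregation), and the training `hypergraph`.
#' @export
train_pattern_model <- function(cohort, g = NULL,
                                settings = train_settings(),
                                hgnn_dims = c(64L, 32L),
                                aggregation = c("mean", "weighted_mean")) {
  aggregation <- match.arg(aggregation)
  x0 <- cohort_features(cohort)
  if (is.null(g)) {
    groups <- cohort_groups(cohort)
    if (is.null(groups)) {
      abort("`g` is missing and the cohort carries no interaction groups.",
            class = "wpinjury_invalid_hypergraph")
    }
    g <- hypergraph(nrow(x0), groups)
  }
  if (g$n_vertices != nrow(x0)) {
    abort("hypergraph must be built over the cohort's athletes.",
          class = "wpinjury_shape_error")
  }
  n <- nrow(x0); d0 <- ncol(x0)
  d1 <- as.integer(hgnn_dims[1]); d2 <- as.integer(hgnn_dims[2])
  m <- length(g$hyperedges)
  withr::local_seed(derive_seed(settings$seed, "pattern"))

  q <- aggregation_matrix(g, normalize = TRUE)
  b <- hyperedge_pool_matrix(g)

  lim <- function(di, do) sqrt(6 / (di + do))
  par <- list(
    W1 = matrix(runif(d0 * d1, -lim(d0, d1), lim(d0, d1)), d0, d1), b1 = rep(0, d1),
    W2 = matrix(runif(d1 * d2, -lim(d1, d2), lim(d1, d2)), d1, d2), b2 = rep(0, d2),
    M1 = matrix(runif(d2 * 64, -lim(d2, 64), lim(d2, 64)), d2, 64), m1 = rep(0, 64),
    M2 = matrix(runif(64 * 32, -lim(64, 32), lim(64, 32)), 64, 32), m2 = rep(0, 32),
    M3 = matrix(runif(32 * d2, -lim(32, d2), lim(32, d2)), 32, d2), m3 = rep(0, d2)
  )

  # Validation split over hyperedges.
  n_val <- floor(settings$validation_fraction * m)
  val_idx <- if (n_val >= 1L) sort(sample.int(m, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(m), val_idx)
  if (length(train_idx) == 0L) {
    abort("validation split left no training hyperedges.",
          class = "wpinjury_invalid_config")
  }

  # Encoder: per-node embedding layer, then one hypergraph convolution over
  # the degree-normalised aggregation operator.
  fwd <- function(par) {
    a1 <- x0 %*% par$W1 + rep(1, n) %o% par$b1; z1 <- pmax(a1, 0)
    a2 <- q %*% (z1 %*% par$W2) + rep(1, n) %o% par$b2; z2 <- pmax(a2, 0)
    araw <- b %*% z2
    list(a1 = a1, z1 = z1, a2 = a2, z2 = z2, araw = araw)
  }

  # Min-max scaling bounds from the initial hyperedge embeddings, held
  # fixed; constant embedding dimensions map to the sigmoid midpoint 0.5.
  araw0 <- fwd(par)$araw
  lo <- apply(araw0, 2, min)
  span <- apply(araw0, 2, max) - lo
  degenerate <- span < 1e-8
  lo[degenerate] <- lo[degenerate] - 0.5
  span[degenerate] <- 1
  scale_rows <- function(araw) sweep(sweep(araw, 2, lo), 2, span, "/")

  mask <- rep(0, m); mask[train_idx] <- 1

  state <- adam_init(par)
  trace <- tibble::tibble(epoch = integer(), train_loss = double(),
                          val_loss = double())
  best <- list(loss = Inf, par = par, epoch = 0L)
  since_best <- 0L

  for (epoch in seq_len(settings$max_epochs)) {
    f <- fwd(par)
    atil <- scale_rows(f$araw)
    h1p <- atil %*% par$M1 + rep(1, m) %o% par$m1; h1 <- pmax(h1p, 0)
    h2p <- h1 %*% par$M2 + rep(1, m) %o% par$m2; h2 <- pmax(h2p, 0)
    h3p <- h2 %*% par$M3 + rep(1, m) %o% par$m3; p <- 1 / (1 + exp(-h3p))

    resid <- atil - p
    train_loss <- sum(resid[train_idx, , drop = FALSE]^2)
    val_loss <- if (length(val_idx)) sum(resid[val_idx, , drop = FALSE]^2) else train_loss
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      abort(sprintf("non-finite reconstruction loss at epoch %d.", epoch),
            class = "wpinjury_training_error")
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss))

    if (val_loss < best$loss) {
      best <- list(loss = val_loss, par = par, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= settings$patience) break
    }

    rm_ <- resid * mask
    d_p <- -2 * rm_
    d_atil_direct <- 2 * rm_
    d_h3p <- d_p * p * (1 - p)
    g_M3 <- t(h2) %*% d_h3p; g_m3 <- colSums(d_h3p)
    d_h2 <- d_h3p %*% t(par$M3) * (h2p > 0)
    g_M2 <- t(h1) %*% d_h2; g_m2 <- colSums(d_h2)
    d_h1 <- d_h2 %*% t(par$M2) * (h1p > 0)
    g_M1 <- t(atil) %*% d_h1; g_m1 <- colSums(d_h1)
    d_atil <- d_atil_direct + d_h1 %*% t(par$M1)
    d_araw <- sweep(d_atil, 2, span, "/")
    d_z2 <- t(b) %*% d_araw
    d_a2 <- d_z2 * (f$a2 > 0)
    g_W2 <- t(f$z1) %*% (q %*% d_a2); g_b2 <- colSums(d_a2)
    d_z1 <- (q %*% d_a2) %*% t(par$W2)
    d_a1 <- d_z1 * (f$a1 > 0)
    g_W1 <- t(x0) %*% d_a1; g_b1 <- colSums(d_a1)

    grads <- list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2,
                  M1 = g_M1, m1 = g_m1, M2 = g_M2, m2 = g_m2,
                  M3 = g_M3, m3 = g_m3)
    if (settings$optimizer == "adam") {
      upd <- adam_step(par, grads, state, settings$learning_rate)
      par <- upd$params; state <- upd$state
    } else {
      par <- sgd_step(par, grads, settings$learning_rate)
    }
  }

  par <- best$par
  f_best <- fwd(par)
  structure(list(
    hgnn_stack = list(layer_params(par$W1, par$b1, "relu"),
                      layer_params(par$W2, par$b2, "relu")),
    mlp = list(layer_params(par$M1, par$m1, "relu"),
               layer_params(par$M2, par$m2, "relu"),
               layer_params(par$M3, par$m3, "sigmoid")),
    scaling = list(lo = lo, span = span),
    aggregation = aggregation,
    trace = trace,
    best_epoch = best$epoch,
    best_val_loss = best$loss,
    embeddings = f_best$z1,
    conv_embeddings = f_best$z2,
    hypergraph = g,
    settings = settings
  ), class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("# Pattern model: %d epochs run, best epoch %d (val loss %.4g)\n",
              nrow(x$trace), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Tidy the loss trace of a pattern model
#' @param x a `pattern_model`.
#' @param ... unused.
#' @return tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.pattern_model <- function(x, ...) x$trace

#' One-row summary of a pattern-model fit
#' @param x a `pattern_model`.
#' @param ... unused.
#' @return one-row tibble: epochs run, best epoch, best validation loss and
#'   final training loss.
#' @export
glance.pattern_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$trace),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$trace$train_loss[nrow(x$trace)]
  )
}

#' Plot the training and validation loss of a pattern model
#' @param object a `pattern_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pattern_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = "reconstruction loss", colour = NULL,
                  title = "Pattern-model training") +
    ggplot2::theme_minimal()
}

#' Project embeddings to two dimensions
#'
#' Deterministic principal-component projection: coordinates are centred,
#' component 1 carries the largest variance, and each axis sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param z embedding matrix with at least 3 rows and 2 columns.
#' @param method currently `"pca"`.
#' @return n x 2 matrix of coordinates.
#' @export
project_2d <- function(z, method = "pca") {
  z <- as.matrix(z)
  if (nrow(z) < 3L) {
    abort("need at least 3 rows to project.", class = "wpinjury_shape_error")
  }
  if (ncol(z) < 2L) {
    abort("need at least 2 embedding dimensions.", class = "wpinjury_shape_error")
  }
  method <- match.arg(method, "pca")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(j) {
    v <- rot[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  coords <- pc$x[, 1:2, drop = FALSE] %*% diag(flip, 2)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Compactness of grouped 2-D coordinates
#'
#' Quantifies how tightly each group clusters in a 2-D projection: the mean
#' within-group pairwise Euclidean distance per group and the mean silhouette
#' coefficient (per group and overall). Groups with a single member have no
#' defined silhouette and are reported as `NA`.
#'
#' @param coords n x 2 coordinate matrix.
#' @param grouping vector of group labels, length n; at least two groups.
#' @return tibble with one row per group (`group`, `n`,
#'   `mean_within_distance`, `silhouette`) and attribute
#'   `overall_silhouette`.
#' @export
compactness_stats <- function(coords, grouping) {
  coords <- as.matrix(coords)
  grouping <- as.character(grouping)
  if (nrow(coords) != length(grouping)) {
    abort("`grouping` must have one label per row of `coords`.",
          class = "wpinjury_shape_error")
  }
  groups <- sort(unique(grouping))
  if (length(groups) < 2L) {
    abort("need at least two groups.", class = "wpinjury_invalid_parameter")
  }
  d <- stats::dist(coords)
  sil <- cluster::silhouette(as.integer(factor(grouping, levels = groups)), d)
  sil_widths <- sil[, "sil_width"]
  dm <- as.matrix(d)
  out <- purrr::map_dfr(groups, function(gr) {
    idx <- which(grouping == gr)
    wd <- if (length(idx) >= 2L) {
      mean(dm[idx, idx][upper.tri(dm[idx, idx])])
    } else 0
    tibble::tibble(
      group = gr, n = length(idx),
      mean_within_distance = wd,
      silhouette = if (length(idx) >= 2L) mean(sil_widths[idx]) else NA_real_
    )
  })
  sizes <- table(grouping)
  attr(out, "overall_silhouette") <- mean(sil_widths[sizes[grouping] >= 2])
  out
}

# Structural summary of one hypergraph: isolated vertices (no co-membership
# with any other vertex), mean pairwise hyperedge overlap, and number of
# connected components of the clique expansion.
hypergraph_structure <- function(g) {
  a <- hypergraph_laplacian(g)$A
  isolated <- sum(rowSums(a > 0) == 0)
  m <- length(g$hyperedges)
  overlap <- if (m >= 2L) {
    pairs <- utils::combn(m, 2)
    mean(vapply(seq_len(ncol(pairs)), function(i) {
      length(intersect(g$hyperedges[[pairs[1, i]]], g$hyperedges[[pairs[2, i]]]))
    }, numeric(1)))
  } else NA_real_
  gr <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
  tibble::tibble(
    n_vertices = g$n_vertices,
    n_hyperedges = m,
    isolated_vertices = isolated,
    mean_hyperedge_overlap = overlap,
    n_components = igraph::components(gr)$no
  )
}

#' Compare the structure of two hypergraphs over the same vertices
#'
#' Summarises both hypergraphs (isolated-vertex count, mean pairwise
#' hyperedge overlap, connected components of the clique expansion) so that
#' structural cohesion before and after a training-regime change can be
#' compared quantitatively.
#'
#' @param g_pre,g_post `hypergraph`s with the same vertex count.
#' @return tibble with rows `pre` and `post`.
#' @export
structure_report <- function(g_pre, g_post) {
  if (g_pre$n_vertices != g_post$n_vertices) {
    abort("both hypergraphs must share the vertex set.",
          class = "wpinjury_shape_error")
  }
  dplyr::bind_rows(
    dplyr::mutate(hypergraph_structure(g_pre), graph = "pre", .before = 1),
    dplyr::mutate(hypergraph_structure(g_post), graph = "post", .before = 1)
  )
}
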