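#' Regularisation weights of the hypergraph classifier
#'
#' `lam` scales the whole structural penalty in the training objective,
#' `alpha` weighs its Laplacian smoothness component and `beta` the
#' embedding weight decay. Defaults are the classifier's published operating
#' point (`lam = 0.2`, `alpha = 0.03`, `beta = 0.005`).
#'
#' @param lam,alpha,beta non-negative reals.
#' @return object of class `regularizer_config`.
#' @export
regularizer_config <- function(lam = 0.2, alpha = 0.03, beta = 0.005) {
  structure(list(lam = check_scalar(lam, "lam", 0),
                 alpha = check_scalar(alpha, "alpha", 0),
                 beta = check_scalar(beta, "beta", 0)),
            class = "regularizer_config")
}

#' Structural regulariser of vertex embeddings
#'
#' `omega(X) = alpha * sum_ij A[i,j] ||X[i,]-X[j,]||^2 + beta * sum_i ||X[i,]||^2`
#' over ordered pairs, with `A` the non-negative clique-expansion adjacency.
#' The first term encourages athletes who share training groups to receive
#' similar embeddings; the second is weight decay on the embedding itself.
#'
#' @param x embedding matrix, one row per vertex.
#' @param a symmetric non-negative adjacency matrix.
#' @param cfg a [regularizer_config()].
#' @return non-negative scalar.
#' @export
omega <- function(x, a, cfg = regularizer_config()) {
  stopifnot(inherits(cfg, "regularizer_config"))
  x <- as.matrix(x); a <- as.matrix(a)
  if (any(a < 0)) {
    abort("adjacency entries must be non-negative.", class = "wpinjury_invalid_parameter")
  }
  if (nrow(x) != nrow(a)) {
    abort("`x` must have one row per vertex of `a`.", class = "wpinjury_shape_error")
  }
  sq <- rowSums(x^2)
  pairwise <- 2 * sum(rowSums(a) * sq) - 2 * sum(x * (a %*% x))
  cfg$alpha * pairwise + cfg$beta * sum(sq)
}

# Numerically stable sum of elementwise binary cross-entropies from logits.
bce_from_logits <- function(logits, y) {
  sum(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

#' Full training objective of the regularised hypergraph classifier
#'
#' `cross-entropy(logits, y) + lam * (0.5 * trace(t(X) L X) + omega(X))`:
#' a supervised multi-label cross-entropy plus the structural penalty —
#' Laplacian smoothness of the final embedding and the
#' smoothness-plus-weight-decay regulariser — scaled as a whole by the
#' regularisation parameter `lam`.
#'
#' @param logits matrix of per-site logits.
#' @param y binary label matrix, same shape as `logits`.
#' @param x final-layer embedding matrix, one row per vertex.
#' @param bundle a `laplacian_bundle` over the same vertices.
#' @param cfg a [regularizer_config()].
#' @param include_laplacian set `FALSE` to drop the
#'   `0.5 * trace(t(X) L X)` smoothness term (the unregularised
#'   configuration zeroes this flag together with `lam`).
#' @return scalar objective value.
#' @export
total_objective <- function(logits, y, x, bundle, cfg = regularizer_config(),
                            include_laplacian = TRUE) {
  logits <- as.matrix(logits); y <- as.matrix(y)
  if (!all(dim(logits) == dim(y))) {
    abort("`logits` and `y` must have identical shapes.", class = "wpinjury_shape_error")
  }
  if (any(!is.finite(logits)) || any(!is.finite(as.matrix(x)))) {
    abort("non-finite inputs to the objective.", class = "wpinjury_training_error")
  }
  ce <- bce_from_logits(logits, y)
  smooth <- if (include_laplacian) cfg$lam * smoothness(x, bundle) else 0
  ce + smooth + cfg$lam * omega(x, bundle$A, cfg)
}

# Column-standardise a feature matrix; constant columns are left centred.
standardize_features <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

# Core trainer for the injury-type classifiers. Architecture: a per-node
# embedding layer (ReLU, no mixing), one hypergraph convolution over the
# degree-normalised aggregation operator `qs` (identity for the MLP
# baseline), and a per-site linear head on the convolved embedding.
# Full-batch gradient descent (heavy-ball SGD with step decay, or Adam) on
# the training objective; the structural terms use the clique-expansion
# Laplacian in `bundle` and apply to the final embedding. Supervision is
# restricted to `train_idx` rows and to sites with both classes present
# there (others are skipped with a warning).
fit_hg_classifier <- function(x0, y, qs, bundle, cfg, hidden, train_idx,
                              settings, include_laplacian, decay_every = 50L,
                              decay_factor = 0.5) {
  n <- nrow(x0); s <- ncol(y)
  d0 <- ncol(x0); d1 <- as.integer(hidden[1]); d2 <- as.integer(hidden[2])
  withr::local_seed(derive_seed(settings$seed, "classifier"))

  trained_sites <- which(vapply(seq_len(s), function(j) {
    v <- y[train_idx, j]; any(v == 1) && any(v == 0)
  }, logical(1)))
  if (length(trained_sites) == 0L) {
    abort("no injury site has both classes among the training athletes.",
          class = "wpinjury_training_error")
  }
  if (length(trained_sites) < s) {
    warn(sprintf("%d site(s) have a single class among training athletes and are skipped.",
                 s - length(trained_sites)))
  }

  lim <- function(di, do) sqrt(6 / (di + do))
  par <- list(
    W1 = matrix(runif(d0 * d1, -lim(d0, d1), lim(d0, d1)), d0, d1), b1 = rep(0, d1),
    W2 = matrix(runif(d1 * d2, -lim(d1, d2), lim(d1, d2)), d1, d2), b2 = rep(0, d2),
    W3 = matrix(runif(d2 * s, -lim(d2, s), lim(d2, s)), d2, s), b3 = rep(0, s)
  )

  mask <- matrix(0, n, s)
  mask[train_idx, trained_sites] <- 1
  # Objective rescaled per labelled athlete so the stated learning rate is
  # meaningful at any cohort size; relative term weights are unchanged.
  scale_c <- 1 / length(train_idx)
  use_reg <- !is.null(bundle) && cfg$lam > 0
  state <- adam_init(par)
  vel <- lapply(par, function(p) p * 0)
  trace <- tibble::tibble(epoch = integer(), objective = double(),
                          cross_entropy = double())

  forward <- function(par) {
    a1 <- x0 %*% par$W1 + rep(1, n) %o% par$b1; z1 <- pmax(a1, 0)
    a2 <- qs %*% (z1 %*% par$W2) + rep(1, n) %o% par$b2; z2 <- pmax(a2, 0)
    logits <- z2 %*% par$W3 + rep(1, n) %o% par$b3
    list(a1 = a1, z1 = z1, a2 = a2, z2 = z2, logits = logits,
         p = 1 / (1 + exp(-logits)))
  }

  for (epoch in seq_len(settings$max_epochs)) {
    f <- forward(par)
    ce_tr <- bce_from_logits(f$logits[train_idx, trained_sites, drop = FALSE],
                             y[train_idx, trained_sites, drop = FALSE])
    obj <- ce_tr + (if (use_reg) {
      (if (include_laplacian) cfg$lam * smoothness(f$z2, bundle) else 0) +
        cfg$lam * omega(f$z2, bundle$A, cfg)
    } else 0)
    if (!is.finite(obj)) {
      abort(sprintf("non-finite objective at epoch %d.", epoch),
            class = "wpinjury_training_error")
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      epoch = epoch, objective = obj, cross_entropy = ce_tr))

    g_logits <- (f$p - y) * mask * scale_c
    g_W3 <- t(f$z2) %*% g_logits; g_b3 <- colSums(g_logits)
    d_z2 <- g_logits %*% t(par$W3)
    if (use_reg) {
      lz <- bundle$L %*% f$z2
      d_z2 <- d_z2 + cfg$lam * scale_c *
        ((if (include_laplacian) lz else 0) +
           4 * cfg$alpha * lz + 2 * cfg$beta * f$z2)
    }
    d_a2 <- d_z2 * (f$a2 > 0)
    g_W2 <- t(f$z1) %*% (qs %*% d_a2); g_b2 <- colSums(d_a2)
    d_a1 <- ((qs %*% d_a2) %*% t(par$W2)) * (f$a1 > 0)
    g_W1 <- t(x0) %*% d_a1; g_b1 <- colSums(d_a1)
    grads <- list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2,
                  W3 = g_W3, b3 = g_b3)

    if (settings$optimizer == "adam") {
      upd <- adam_step(par, grads, state, settings$learning_rate)
      par <- upd$params; state <- upd$state
    } else {
      lr <- settings$learning_rate *
        decay_factor^floor((epoch - 1) / decay_every)
      for (nm in names(par)) {
        vel[[nm]] <- settings$momentum * vel[[nm]] + grads[[nm]]
        par[[nm]] <- par[[nm]] - lr * vel[[nm]]
      }
    }
  }

  f <- forward(par)
  list(par = par, trace = trace, trained_sites = trained_sites,
       embeddings = f$z2, logits = f$logits, probabilities = f$p)
}

#' Default training protocol of the injury classifier
#'
#' Full-batch heavy-ball SGD at the published learning rate 0.01, run for
#' 200 epochs so the step decay anneals the schedule.
#'
#' @param seed integer seed.
#' @return a [train_settings()].
#' @export
classifier_settings <- function(seed = 1L) {
  train_settings(optimizer = "sgd", learning_rate = 0.01, max_epochs = 200,
                 patience = 200, seed = seed)
}

#' Train the regularised hypergraph injury classifier (rHGNN)
#'
#' Builds a k-nearest-neighbour hypergraph from the cohort's (column-
#' standardised) feature vectors, then trains the hypergraph network — a
#' per-node embedding layer, one degree-normalised hypergraph convolution,
#' and a per-site logistic head — by full-batch SGD (learning rate 0.01,
#' momentum 0.9, halved every `decay_every` epochs) on the objective of
#' [total_objective()]: multi-label cross-entropy over the labelled
#' athletes plus the `lam`-weighted structural penalty (Laplacian
#' smoothness and embedding weight decay) over all athletes. Training is
#' transductive: held-out athletes participate in the hypergraph and the
#' structural terms, never in the supervised term.
#'
#' @param cohort an `athlete_cohort`.
#' @param regularizer a [regularizer_config()].
#' @param knn_k neighbourhood size of the hypergraph (default 5).
#' @param settings a [train_settings()]; defaults to SGD, learning rate
#'   0.01, 200 epochs.
#' @param hidden hidden widths of the network (default 64, 32).
#' @param include_laplacian include the Laplacian smoothness term.
#' @param train_idx indices of labelled athletes (default: all).
#' @param decay_every,decay_factor step-decay schedule of the SGD learning
#'   rate.
#' @return object of class `rhgnn_model`.
#' @export
train_classifier <- function(cohort, regularizer = regularizer_config(),
                             knn_k = 5L, settings = classifier_settings(),
                             hidden = c(64L, 32L), include_laplacian = TRUE,
                             train_idx = NULL, decay_every = 50L,
                             decay_factor = 0.5) {
  x0 <- standardize_features(cohort_features(cohort))
  y <- cohort_labels(cohort)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(x0))
  g <- build_knn_hypergraph(x0, knn_k)
  bundle <- hypergraph_laplacian(g)
  qs <- aggregation_matrix(g, normalize = TRUE)
  fit <- fit_hg_classifier(x0, y, qs, bundle, regularizer, hidden, train_idx,
                           settings, include_laplacian, decay_every,
                           decay_factor)
  structure(list(
    embed_layer = layer_params(fit$par$W1, fit$par$b1, "relu"),
    conv_layer = layer_params(fit$par$W2, fit$par$b2, "relu"),
    head = layer_params(fit$par$W3, fit$par$b3, "identity"),
    knn_k = knn_k,
    regularizer = regularizer,
    hypergraph = g,
    bundle = bundle,
    sites = colnames(y),
    trained_sites = fit$trained_sites,
    trace = fit$trace,
    embeddings = fit$embeddings,
    probabilities = fit$probabilities,
    train_idx = train_idx,
    settings = settings
  ), class = "rhgnn_model")
}

#' @export
print.rhgnn_model <- function(x, ...) {
  cat(sprintf("# rHGNN classifier: k=%d, lambda=%g, alpha=%g, beta=%g; %d/%d sites trained\n",
              x$knn_k, x$regularizer$lam, x$regularizer$alpha,
              x$regularizer$beta, length(x$trained_sites), length(x$sites)))
  invisible(x)
}

#' Predicted injury probabilities or classes
#'
#' The classifier is transductive: predictions are read off for the athletes
#' of the cohort the model was trained on (labelled and held-out alike).
#'
#' @param object an `rhgnn_model`.
#' @param type `"prob"` for per-site probabilities, `"class"` for 0/1 calls
#'   at threshold 0.5.
#' @param ... unused.
#' @return numeric (or integer) matrix, athletes x sites.
#' @export
predict.rhgnn_model <- function(object, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- object$probabilities
  colnames(p) <- object$sites
  if (type == "prob") p else (p > 0.5) * 1L
}

#' Tidy the objective trace of a classifier fit
#' @param x an `rhgnn_model`.
#' @param ... unused.
#' @return tibble with `epoch`, `objective`, `cross_entropy`.
#' @export
tidy.rhgnn_model <- function(x, ...) x$trace

#' One-row summary of a classifier fit
#' @param x an `rhgnn_model`.
#' @param ... unused.
#' @return one-row tibble with the final objective, final cross-entropy and
#'   the number of trained sites.
#' @export
glance.rhgnn_model <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$trace),
    final_objective = x$trace$objective[nrow(x$trace)],
    final_cross_entropy = x$trace$cross_entropy[nrow(x$trace)],
    n_trained_sites = length(x$trained_sites)
  )
}

# Stratified fold assignment: athletes ranked by injury burden are dealt
# round-robin into folds; redraw (seeded) if some fold's training portion
# has no positive label at all.
make_folds <- function(y, folds, seed) {
  n <- nrow(y)
  withr::local_seed(derive_seed(seed, "folds"))
  for (attempt in seq_len(100L)) {
    ord <- order(rowSums(y), runif(n))
    fold <- integer(n)
    fold[ord] <- rep_len(sample.int(folds), n)
    ok <- all(vapply(seq_len(folds), function(f) {
      sum(y[fold != f, , drop = FALSE]) > 0 && any(fold == f)
    }, logical(1)))
    if (ok) return(fold)
    inform(sprintf("fold draw %d left a fold without positives; redrawing.", attempt))
  }
  fold
}

fold_macro_metrics <- function(y_true, y_pred, sites) {
  per_site <- purrr::map_dfr(sites, function(j) {
    yt <- y_true[, j]; yp <- y_pred[, j]
    cm <- confusion_counts(tp = sum(yt == 1 & yp == 1),
                           fp = sum(yt == 0 & yp == 1),
                           tn = sum(yt == 0 & yp == 0),
                           fn = sum(yt == 1 & yp == 0))
    confusion_metrics(cm)
  })
  dplyr::summarise(per_site, dplyr::across(dplyr::everything(),
                                           ~ mean(.x, na.rm = TRUE)))
}

#' Repeated stratified cross-validation of injury-type classifiers
#'
#' Evaluates one of four methods — the regularised hypergraph classifier
#' (`"rhgnn"`), its unregularised counterpart (`"hgnn"`, all structural
#' terms off), a feedforward MLP with the same hidden sizing, or an
#' RBF-kernel SVM — by repeated stratified k-fold cross-validation. Per
#' fold, each injury site is scored one-vs-rest on the held-out athletes
#' and the per-site metrics (accuracy, positive/negative predictive value,
#' sensitivity, specificity) are macro-averaged; the table reports
#' mean ± sd across folds and repeats. Sites with a single class among the
#' fold's training athletes are skipped for that fold.
#'
#' @param cohort an `athlete_cohort`.
#' @param method one of `"rhgnn"`, `"hgnn"`, `"mlp"`, `"svm"`.
#' @param folds number of folds (>= 2).
#' @param repeats number of repetitions with fresh fold draws.
#' @param seed integer seed.
#' @param knn_k hypergraph neighbourhood size.
#' @param regularizer a [regularizer_config()] (hypergraph methods only).
#' @param settings optional [train_settings()] override.
#' @return a `metric_table` tibble: one row per method with `mean±sd`
#'   summary strings and numeric `<metric>_mean` / `<metric>_sd` columns;
#'   per-fold metrics are attached as attribute `fold_metrics`.
#' @export
cross_validate <- function(cohort, method = c("rhgnn", "hgnn", "mlp", "svm"),
                           folds = 5L, repeats = 1L, seed = 1L, knn_k = 5L,
                           regularizer = regularizer_config(),
                           settings = NULL) {
  method <- match.arg(method)
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats")
  x0 <- standardize_features(cohort_features(cohort))
  y <- cohort_labels(cohort)
  n <- nrow(x0)

  if (method %in% c("rhgnn", "hgnn")) {
    g <- build_knn_hypergraph(x0, knn_k)
    bundle <- hypergraph_laplacian(g)
    qs <- aggregation_matrix(g, normalize = TRUE)
  }
  if (method == "hgnn") regularizer <- regularizer_config(0, 0, 0)

  rows <- purrr::map_dfr(seq_len(repeats), function(r) {
    fold <- make_folds(y, folds, derive_seed(seed, paste0("rep", r)))
    purrr::map_dfr(seq_len(folds), function(f) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      fit_seed <- derive_seed(seed, sprintf("rep%d_fold%d", r, f))
      pred <- switch(method,
        rhgnn = ,
        hgnn = {
          st <- settings %||% classifier_settings(fit_seed)
          st$seed <- fit_seed
          fit <- suppressWarnings(fit_hg_classifier(
            x0, y, qs, bundle, regularizer, c(64L, 32L), train_idx, st,
            include_laplacian = method == "rhgnn"))
          list(yhat = (fit$probabilities > 0.5) * 1L, sites = fit$trained_sites)
        },
        mlp = {
          st <- settings %||% train_settings(optimizer = "adam",
                                             learning_rate = 0.001,
                                             max_epochs = 200, patience = 200,
                                             seed = fit_seed)
          st$seed <- fit_seed
          fit <- suppressWarnings(fit_hg_classifier(
            x0, y, diag(n), NULL, regularizer_config(0, 0, 0), c(64L, 32L),
            train_idx, st, include_laplacian = FALSE))
          list(yhat = (fit$probabilities > 0.5) * 1L, sites = fit$trained_sites)
        },
        svm = svm_predict_sites(x0, y, train_idx, fit_seed)
      )
      if (length(pred$sites) == 0L) return(NULL)
      out <- fold_macro_metrics(y[test_idx, , drop = FALSE],
                                pred$yhat[test_idx, , drop = FALSE],
                                pred$sites)
      dplyr::mutate(out, repeat_ = r, fold = f, .before = 1)
    })
  })

  new_metric_table(method_label(method), rows)
}

svm_predict_sites <- function(x0, y, train_idx, seed) {
  withr::local_seed(seed)
  n <- nrow(x0); s <- ncol(y)
  yhat <- matrix(0L, n, s)
  sites <- integer(0)
  for (j in seq_len(s)) {
    yt <- y[train_idx, j]
    if (!(any(yt == 1) && any(yt == 0))) next
    fit <- e1071::svm(x = x0[train_idx, , drop = FALSE],
                      y = factor(yt, levels = c(0, 1)), kernel = "radial")
    yhat[, j] <- as.integer(as.character(predict(fit, x0)))
    sites <- c(sites, j)
  }
  list(yhat = yhat, sites = sites)
}

method_label <- function(method) {
  switch(method,
         rhgnn = "rHGNN",
         hgnn = "HGNN (unregularised)",
         mlp = "MLP",
         svm = "SVM",
         method)
}

new_metric_table <- function(label, fold_rows) {
  metrics <- c("acc", "ppv", "npv", "sen", "spec")
  if (nrow(fold_rows) == 0L) {
    abort("no fold produced evaluable sites.", class = "wpinjury_training_error")
  }
  summ <- purrr::map(metrics, function(m) {
    v <- fold_rows[[m]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v[!is.na(v)]))
  })
  names(summ) <- metrics
  row <- tibble::tibble(method = label)
  for (m in metrics) {
    mu <- summ[[m]]["mean"]; sdv <- summ[[m]]["sd"]
    if (is.na(sdv)) sdv <- 0
    row[[m]] <- sprintf("%.5f±%.4f", mu, sdv)
    row[[paste0(m, "_mean")]] <- unname(mu)
    row[[paste0(m, "_sd")]] <- unname(sdv)
  }
  structure(row, fold_metrics = fold_rows,
            class = c("metric_table", class(tibble::tibble())))
}

#' Combine metric tables
#' @param ... `metric_table` rows.
#' @return a `metric_table` with the rows stacked in order.
#' @export
bind_metric_tables <- function(...) {
  tabs <- list(...)
  out <- dplyr::bind_rows(lapply(tabs, function(t) tibble::as_tibble(t)))
  structure(out,
            fold_metrics = dplyr::bind_rows(
              lapply(tabs, function(t) {
                fm <- attr(t, "fold_metrics")
                if (!is.null(fm)) dplyr::mutate(fm, method = t$method[1], .before = 1)
              })),
            class = c("metric_table", class(tibble::tibble())))
}

#' Plot a metric table
#' @param object a `metric_table`.
#' @param ... unused.
#' @return a ggplot object: mean with ± sd error bars per method and metric.
#' @export
autoplot.metric_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "method",
                  dplyr::ends_with("_mean"), dplyr::ends_with("_sd")),
    -"method", names_to = c("metric", "stat"), names_sep = "_",
    values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "stat", values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$metric, y = .data$mean,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL,
                  title = "Cross-validated classification metrics") +
    ggplot2::theme_minimal()
}

#' Hyperparameter ablation of the regularised classifier
#'
#' Evaluates the classifier at its default operating point and at single-
#' parameter variations over the standard grids `lam` in \{0.01, 0.1, 1.0\},
#' `alpha` in \{0.001, 0.01, 0.1\} and `beta` in \{0.0001, 0.001, 0.01\}
#' (all other parameters at their defaults), each by the same repeated
#' stratified cross-validation as [cross_validate()]. Row order is fixed:
#' the full default model first, then the `lam`, `alpha` and `beta` rows in
#' grid order.
#'
#' @param cohort an `athlete_cohort`.
#' @param lam_grid,alpha_grid,beta_grid numeric grids of single-parameter
#'   variations.
#' @param folds,repeats,seed,knn_k,settings passed to [cross_validate()].
#' @return a `metric_table` with one row per configuration.
#' @export
ablation_grid <- function(cohort, lam_grid = c(0.01, 0.1, 1.0),
                          alpha_grid = c(0.001, 0.01, 0.1),
                          beta_grid = c(0.0001, 0.001, 0.01),
                          folds = 5L, repeats = 1L, seed = 1L, knn_k = 5L,
                          settings = NULL) {
  default <- regularizer_config()
  configs <- c(
    list(list(label = "rHGNN (full)", cfg = default)),
    lapply(lam_grid, function(v) list(
      label = sprintf("lambda=%g", v),
      cfg = regularizer_config(lam = v, alpha = default$alpha, beta = default$beta))),
    lapply(alpha_grid, function(v) list(
      label = sprintf("alpha=%g", v),
      cfg = regularizer_config(lam = default$lam, alpha = v, beta = default$beta))),
    lapply(beta_grid, function(v) list(
      label = sprintf("beta=%g", v),
      cfg = regularizer_config(lam = default$lam, alpha = default$alpha, beta = v)))
  )
  tabs <- lapply(configs, function(cc) {
    tab <- cross_validate(cohort, method = "rhgnn", folds = folds,
                          repeats = repeats, seed = seed, knn_k = knn_k,
                          regularizer = cc$cfg, settings = settings)
    tab$method <- cc$label
    tab
  })
  do.call(bind_metric_tables, tabs)
}
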