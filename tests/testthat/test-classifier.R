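test_that("the structural regulariser matches hand-derived values", {
  a <- matrix(c(0, 0.5, 0.5, 0), 2)
  cfg11 <- regularizer_config(lam = 1, alpha = 1, beta = 1)
  expect_equal(omega(matrix(0, 2, 3), a, cfg11), 0)
  expect_equal(omega(matrix(1, 2, 3), a, regularizer_config(1, 1, 0)), 0)
  # alpha * (A12 + A21) * 1 + beta * (0 + 1) = 2
  expect_equal(omega(matrix(c(0, 1), 2), a, cfg11), 2)
  expect_error(omega(matrix(0, 2, 2), -a, cfg11),
               class = "wpinjury_invalid_parameter")
})

test_that("omega identities: homogeneity and the alpha -> 0 limit", {
  g <- random_hypergraph(21)
  a <- hypergraph_laplacian(g)$A
  withr::with_seed(3, x <- matrix(rnorm(g$n_vertices * 4), g$n_vertices))
  cfg <- regularizer_config(lam = 0.2, alpha = 0.03, beta = 0.005)
  expect_gte(omega(x, a, cfg), 0)
  expect_equal(omega(3 * x, a, cfg), 9 * omega(x, a, cfg), tolerance = 1e-10)
  decay_only <- regularizer_config(lam = 0.2, alpha = 0, beta = 0.005)
  expect_equal(omega(x, a, decay_only), 0.005 * sum(x^2), tolerance = 1e-10)
})

test_that("the total objective decomposes into its term oracles", {
  g <- random_hypergraph(31)
  n <- g$n_vertices
  bundle <- hypergraph_laplacian(g)
  withr::with_seed(5, {
    x <- matrix(rnorm(n * 3), n)
    logits <- matrix(rnorm(n * 2), n)
    y <- matrix(rbinom(n * 2, 1, 0.5), n)
  })
  cfg <- regularizer_config()   # published defaults
  got <- total_objective(logits, y, x, bundle, cfg)
  p <- 1 / (1 + exp(-logits))
  ce <- -sum(y * log(p) + (1 - y) * log(1 - p))
  want <- ce + cfg$lam * smoothness(x, bundle) + cfg$lam * omega(x, bundle$A, cfg)
  expect_equal(got, want, tolerance = 1e-8)

  # all structural terms off: cross-entropy alone
  off <- regularizer_config(0, 0, 0)
  expect_equal(total_objective(logits, y, x, bundle, off,
                               include_laplacian = FALSE), ce,
               tolerance = 1e-8)

  # perfect confident predictions with zero embedding: near-zero objective
  big <- 40 * (2 * y - 1)
  expect_lt(total_objective(big, y, matrix(0, n, 3), bundle, cfg), 1e-10)
})

test_that("classifier training is deterministic and reduces to CE unregularised", {
  co <- tiny_cohort(seed = 9)   # one rare site is all-zero here; skipped
  m1 <- suppressWarnings(
    train_classifier(co, settings = classifier_settings_for_tests(9)))
  m2 <- suppressWarnings(
    train_classifier(co, settings = classifier_settings_for_tests(9)))
  expect_identical(m1$probabilities, m2$probabilities)
  expect_s3_class(tidy(m1), "tbl_df")
  expect_equal(nrow(glance(m1)), 1)

  m0 <- suppressWarnings(
    train_classifier(co, regularizer = regularizer_config(0, 0, 0),
                     include_laplacian = FALSE,
                     settings = classifier_settings_for_tests(9)))
  expect_equal(m0$trace$objective, m0$trace$cross_entropy)
  # regularised objective strictly exceeds its own cross-entropy part
  expect_true(all(m1$trace$objective >= m1$trace$cross_entropy))
})

test_that("single-class sites are skipped with a warning", {
  co <- tiny_cohort(seed = 2, rates = c(0.5, 0, rep(0.5, 7)))
  expect_warning(
    m <- train_classifier(co, settings = classifier_settings_for_tests(2)),
    "single class")
  expect_false(2L %in% m$trained_sites)
})

test_that("cross-validation reports five mean±sd metric columns", {
  co <- tiny_cohort(seed = 4)
  tab <- cross_validate(co, "rhgnn", folds = 3, seed = 4,
                        settings = classifier_settings_for_tests(4))
  expect_s3_class(tab, "metric_table")
  for (m in c("acc", "ppv", "npv", "sen", "spec")) {
    expect_match(tab[[m]], "^[0-9.]+±[0-9.]+$")
    expect_true(is.numeric(tab[[paste0(m, "_mean")]]))
    expect_true(is.numeric(tab[[paste0(m, "_sd")]]))
    expect_true(tab[[paste0(m, "_mean")]] >= 0 && tab[[paste0(m, "_mean")]] <= 1)
  }
  expect_s3_class(attr(tab, "fold_metrics"), "tbl_df")
})

test_that("all methods approach the ceiling on an easy low-dimensional cohort", {
  # two well-separated sites keep the label-combination clusters large, so
  # every method has enough signal to saturate
  co <- generate_cohort(simulation_config(n_athletes = 60, n_features = 20,
                                          n_sites = 2, class_separation = 8,
                                          site_rates = 0.5, seed = 8))
  for (meth in c("rhgnn", "hgnn", "mlp", "svm")) {
    tab <- cross_validate(co, meth, folds = 3, seed = 8,
                          settings = if (meth %in% c("rhgnn", "hgnn"))
                            classifier_settings_for_tests(8) else NULL)
    expect_gt(tab$acc_mean, 0.95)
  }
})

test_that("label-permuted cohorts score at chance", {
  co <- tiny_cohort(seed = 6, rates = 0.5)
  # decouple labels from features by regenerating them independently
  labs <- cohort_labels(co)
  withr::with_seed(99, permuted <- apply(labs, 2, sample))
  co[, paste0("inj_", colnames(labs))] <- permuted
  tab <- cross_validate(co, "rhgnn", folds = 3, seed = 6,
                        settings = classifier_settings_for_tests(6))
  # every held-out label is an independent fair coin: binomial band
  n_preds <- 26 * 9
  expect_lt(abs(tab$acc_mean - 0.5), 1.96 * sqrt(0.25 / n_preds) + 0.02)
})

test_that("the ablation grid covers the default plus nine variations in order", {
  co <- tiny_cohort(seed = 12, n = 20)
  tab <- ablation_grid(co, folds = 2, seed = 12,
                       settings = classifier_settings_for_tests(12))
  expect_equal(tab$method,
               c("rHGNN (full)", "lambda=0.01", "lambda=0.1", "lambda=1",
                 "alpha=0.001", "alpha=0.01", "alpha=0.1",
                 "beta=0.0001", "beta=0.001", "beta=0.01"))
  tab2 <- ablation_grid(co, folds = 2, seed = 12,
                        settings = classifier_settings_for_tests(12))
  expect_identical(tibble::as_tibble(tab), tibble::as_tibble(tab2))
})

test_that("the regularised model outperforms the matched MLP baseline", {
  diffs <- vapply(1:6, function(seed) {
    co <- tiny_cohort(seed = seed)
    r <- cross_validate(co, "rhgnn", folds = 3, seed = seed,
                        settings = classifier_settings_for_tests(seed))
    m <- cross_validate(co, "mlp", folds = 3, seed = seed)
    r$acc_mean - m$acc_mean
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
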