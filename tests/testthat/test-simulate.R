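test_that("default cohort matches the squad's dimensions and positions", {
  co <- generate_cohort(simulation_config(seed = 7))
  expect_equal(nrow(co), 26)
  expect_equal(dim(cohort_features(co)), c(26, 320))
  expect_equal(dim(cohort_labels(co)), c(26, 9))
  expect_equal(sort(unique(co$regime)), c("maft", "traditional"))
  expect_equal(as.integer(table(co$position)[c("center", "defensive_center",
                                               "perimeter", "goalkeeper")]),
               c(3L, 3L, 15L, 5L))
  expect_true(all(cohort_labels(co) %in% c(0L, 1L)))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(cohort_groups(a), cohort_groups(b))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_athletes = 0), class = "wpinjury_invalid_config")
  expect_error(simulation_config(noise_sd = 0), class = "wpinjury_invalid_config")
  expect_error(simulation_config(group_size_range = c(5, 2)),
               class = "wpinjury_invalid_config")
  expect_error(simulation_config(site_rates = c(rep(0.5, 8), 1.2)),
               class = "wpinjury_invalid_rate")
  expect_error(generate_cohort(list(n_athletes = 26)),
               class = "wpinjury_invalid_config")
})

test_that("interaction groups are within-regime, covering, and size-bounded", {
  for (seed in 1:5) {
    co <- generate_cohort(simulation_config(seed = seed))
    groups <- cohort_groups(co)
    expect_gt(length(groups), 0)
    sizes <- lengths(groups)
    expect_true(all(sizes >= 3 & sizes <= 6))
    regime <- co$regime
    same_regime <- vapply(groups, function(g) length(unique(regime[g])) == 1,
                          logical(1))
    expect_true(all(same_regime))
    expect_setequal(sort(unique(unlist(groups))), seq_len(26))
  }
})

test_that("features carry label signal at high separation and none at zero", {
  acc_for <- function(sep, seed) {
    co <- generate_cohort(simulation_config(n_athletes = 500,
                                            class_separation = sep,
                                            site_rates = 0.5, seed = seed))
    x <- cohort_features(co); y <- cohort_labels(co)[, 1]
    withr::with_seed(seed, idx <- sample(500, 150))
    fit <- glmnet::glmnet(x[-idx, ], y[-idx], family = "binomial",
                          alpha = 0, lambda = 0.05)
    mean((predict(fit, x[idx, ], type = "response") > 0.5) == y[idx])
  }
  expect_gt(acc_for(3, 11), 0.9)
  # chance band: 150 held-out coin-flip labels, 95% binomial band around 0.5
  acc0 <- acc_for(0, 11)
  expect_lt(abs(acc0 - 0.5), 1.96 * sqrt(0.25 / 150) + 1e-9)
})

test_that("maft athletes are more compact in feature space in expectation", {
  diffs <- vapply(1:20, function(seed) {
    co <- generate_cohort(simulation_config(seed = seed))
    x <- cohort_features(co)
    dm <- as.matrix(dist(x))
    wd <- function(idx) mean(dm[idx, idx][upper.tri(dm[idx, idx])])
    wd(which(co$regime == "traditional")) - wd(which(co$regime == "maft"))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 18)
})

test_that("the squad's injury table fixture holds the printed counts", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 9)
  expect_equal(attr(t1, "n_per_mode"), 26L)
  expect_equal(t1$traditional[t1$site == "shoulder"], 9L)
  expect_equal(t1$maft[t1$site == "shoulder"], 11L)
  expect_equal(t1$traditional[t1$site == "knee"], 11L)
  expect_equal(t1$maft[t1$site == "elbow_wrist"], 7L)
  expect_equal(t1$traditional[t1$site == "forearm_ulnar"], 0L)
})

test_that("simulated injury counts follow the binomial model", {
  cfg <- simulation_config(seed = 1)
  zeros <- sample_injury_counts(cfg, list(traditional = rep(0, 9),
                                          maft = rep(0, 9)))
  expect_true(all(zeros$traditional == 0) && all(zeros$maft == 0))
  ones <- sample_injury_counts(cfg, list(traditional = rep(1, 9),
                                         maft = rep(1, 9)))
  expect_true(all(ones$traditional == 26) && all(ones$maft == 26))
  # E[count] = n * p: shoulder-like rate 0.346 at n = 26 gives 9.0
  reps <- vapply(1:2000, function(i) {
    t <- sample_injury_counts(simulation_config(seed = i),
                              list(traditional = 0.346, maft = 0.346))
    t$traditional[1]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 26 * 0.346), 0.2)
  expect_error(sample_injury_counts(cfg, list(traditional = rep(2, 9),
                                              maft = rep(0.5, 9))),
               class = "wpinjury_invalid_rate")
})
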