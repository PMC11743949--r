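#' The nine injury sites of the squad's epidemiology table
#'
#' Canonical injury-site identifiers, in report order: neck, shoulder,
#' elbow & wrist, chest & back, lumbar/sacral/hip, knee, ankle, ulnar side of
#' the forearm, sternoclavicular joint.
#'
#' @return character vector of length 9.
#' @export
injury_sites <- function() {
  c("neck", "shoulder", "elbow_wrist", "chest_back", "lumbar_sacral_hip",
    "knee", "ankle", "forearm_ulnar", "sternoclavicular")
}

position_quota <- c(center = 3, defensive_center = 3, perimeter = 15, goalkeeper = 5)

#' Configuration for the synthetic-cohort generator
#'
#' Defines the statistical structure of a simulated elite women's water polo
#' squad: cohort size, feature dimension, per-site injury prevalence, the
#' separation between injured and uninjured athletes in feature space, and the
#' relative within-regime spread of the two training modes (traditional
#' same-gender training vs male-assisted female training, MAFT).
#'
#' @param n_athletes cohort size; defaults to the 26-athlete national squad.
#' @param n_features feature dimension D; defaults to 320 standardised
#'   training-load, psychological and physiological scores per athlete.
#' @param n_sites number of injury-site labels (default 9).
#' @param class_separation distance, in units of `noise_sd`, between the
#'   feature-space means of injured and uninjured athletes at each site.
#' @param noise_sd standard deviation of the isotropic feature noise for the
#'   traditional regime.
#' @param regime_compactness_ratio ratio of within-regime feature spread,
#'   traditional : MAFT. Values above 1 make the MAFT group more compact,
#'   emulating the tighter, more organised distributions seen after
#'   male-assisted training is introduced.
#' @param group_size_range integer pair: smallest and largest allowed size of
#'   a latent training group (the groups become hyperedges).
#' @param site_rates per-site injury prevalence. Either a single numeric
#'   vector of length `n_sites` (shared by both regimes) or a named list with
#'   components `traditional` and `maft`. `NULL` uses the pooled observed
#'   prevalences of the squad's injury table.
#' @param seed integer seed; identical configurations produce bit-identical
#'   cohorts.
#' @return an object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_athletes = 26, n_features = 320, n_sites = 9,
                              class_separation = 1.5, noise_sd = 1,
                              regime_compactness_ratio = 2,
                              group_size_range = c(3L, 6L),
                              site_rates = NULL, seed = 1L) {
  cfg <- list(
    n_athletes = check_count(n_athletes, "n_athletes", min = 2L),
    n_features = check_count(n_features, "n_features"),
    n_sites = check_count(n_sites, "n_sites"),
    class_separation = check_scalar(class_separation, "class_separation", 0),
    noise_sd = check_scalar(noise_sd, "noise_sd", 0, strict = TRUE),
    regime_compactness_ratio = check_scalar(regime_compactness_ratio,
                                            "regime_compactness_ratio", 0,
                                            strict = TRUE),
    seed = check_count(seed, "seed", min = -2147483647)
  )
  if (length(group_size_range) != 2L || any(group_size_range < 1L) ||
      group_size_range[2] < group_size_range[1]) {
    abort("`group_size_range` must be an increasing pair of positive integers.",
          class = "wpinjury_invalid_config")
  }
  cfg$group_size_range <- as.integer(group_size_range)
  cfg$site_rates <- normalise_site_rates(site_rates, cfg$n_sites)
  structure(cfg, class = "simulation_config")
}

# Pooled per-site prevalence observed across both training modes of the squad
# (counts over 2 x 26 athlete-seasons).
default_site_rates <- function(n_sites) {
  if (n_sites == 9L) {
    t1 <- table1_fixture()
    (t1$traditional + t1$maft) / (2 * attr(t1, "n_per_mode"))
  } else {
    rep(0.3, n_sites)
  }
}

normalise_site_rates <- function(site_rates, n_sites) {
  if (is.null(site_rates)) site_rates <- default_site_rates(n_sites)
  if (is.list(site_rates)) {
    if (!all(c("traditional", "maft") %in% names(site_rates))) {
      abort("list `site_rates` needs components 'traditional' and 'maft'.",
            class = "wpinjury_invalid_config")
    }
    out <- rbind(traditional = as.numeric(site_rates$traditional),
                 maft = as.numeric(site_rates$maft))
  } else {
    out <- rbind(traditional = as.numeric(site_rates),
                 maft = as.numeric(site_rates))
  }
  if (ncol(out) == 1L) out <- out[, rep(1L, n_sites), drop = FALSE]
  if (ncol(out) != n_sites || anyNA(out) || any(out < 0) || any(out > 1)) {
    abort("`site_rates` must lie in [0, 1] and match `n_sites`.",
          class = "wpinjury_invalid_rate")
  }
  out
}

site_names_for <- function(n_sites) {
  if (n_sites == 9L) injury_sites() else paste0("site", seq_len(n_sites))
}

#' Generate a synthetic athlete cohort
#'
#' Draws a cohort with the dependence structure the downstream analyses
#' assume: per-site injury labels are Bernoulli at the configured prevalence,
#' features are class-conditional Gaussians whose positive-class mean is
#' offset by `class_separation * noise_sd` along a site-specific random
#' direction, MAFT-regime athletes have their within-regime spread shrunk by
#' `1 / regime_compactness_ratio`, and latent training groups (future
#' hyperedges) are sampled within regime with sizes in `group_size_range`.
#'
#' @param config a [simulation_config()].
#' @return a tibble of class `athlete_cohort` with columns `athlete_id`,
#'   `position`, `regime`, feature columns `f0 ... f{D-1}` and one binary
#'   `inj_<site>` column per site. The latent training groups are attached as
#'   attribute `interaction_groups` (a list of integer athlete-id vectors) and
#'   the generating configuration as attribute `config`.
#' @examples
#' cohort <- generate_cohort(simulation_config(seed = 7))
#' dim(cohort_features(cohort))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created with simulation_config().",
          class = "wpinjury_invalid_config")
  }
  n <- config$n_athletes
  d <- config$n_features
  s <- config$n_sites
  withr::local_seed(config$seed)

  position <- assign_positions(n)
  regime <- rep("maft", n)
  regime[sample.int(n, ceiling(n / 2))] <- "traditional"

  rates <- config$site_rates
  labels <- matrix(0L, n, s)
  for (j in seq_len(s)) {
    labels[, j] <- rbinom(n, 1L, rates[ifelse(regime == "maft", 2L, 1L), j])
  }

  # One random unit direction per injury site; the positive class mean is
  # offset along it by class_separation * noise_sd.
  u <- matrix(rnorm(d * s), d, s)
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  spread <- ifelse(regime == "maft",
                   config$noise_sd / config$regime_compactness_ratio,
                   config$noise_sd)
  feats <- matrix(rnorm(n * d), n, d) * spread +
    labels %*% t(u) * (config$class_separation * config$noise_sd)

  groups <- c(
    sample_groups(which(regime == "traditional"), config$group_size_range),
    sample_groups(which(regime == "maft"), config$group_size_range)
  )

  site_nm <- site_names_for(s)
  colnames(feats) <- paste0("f", seq_len(d) - 1L)
  colnames(labels) <- paste0("inj_", site_nm)
  cohort <- dplyr::bind_cols(
    tibble::tibble(athlete_id = seq_len(n), position = position, regime = regime),
    tibble::as_tibble(feats),
    tibble::as_tibble(labels)
  )
  new_athlete_cohort(cohort, groups = groups, config = config)
}

new_athlete_cohort <- function(tbl, groups, config = NULL) {
  structure(tbl,
            interaction_groups = groups,
            config = config,
            class = c("athlete_cohort", class(tibble::as_tibble(tbl))))
}

# Positions allocated by largest remainder against the squad's 3/3/15/5 quota,
# then shuffled.
assign_positions <- function(n) {
  share <- position_quota / sum(position_quota) * n
  counts <- floor(share)
  rem <- n - sum(counts)
  if (rem > 0) {
    counts[order(share - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(share - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(names(position_quota), counts))
}

# sample() treats a length-1 numeric as 1:x; this keeps set semantics.
sample_vec <- function(x, size) x[sample.int(length(x), size)]

# Uniform within-regime group sampling; every athlete ends up in at least one
# group and every group size stays inside `range`.
sample_groups <- function(members, range) {
  m <- length(members)
  if (m == 0L) return(list())
  lo <- min(range[1], m)
  hi <- min(range[2], m)
  n_groups <- max(1L, ceiling(m / mean(c(lo, hi))) + 1L)
  groups <- lapply(seq_len(n_groups), function(i) {
    size <- if (hi > lo) sample(seq(lo, hi), 1L) else lo
    sort(sample_vec(members, size))
  })
  uncovered <- setdiff(members, unlist(groups))
  while (length(uncovered) > 0L) {
    take <- utils::head(uncovered, hi)
    if (length(take) < lo) {
      top_up <- sample_vec(setdiff(members, take), lo - length(take))
      take <- c(take, top_up)
    }
    groups <- c(groups, list(sort(take)))
    uncovered <- setdiff(uncovered, take)
  }
  groups
}

#' @export
print.athlete_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("# Athlete cohort: %d athletes, %d features, %d injury sites, %d training groups\n",
              nrow(x), length(feature_cols(x)), length(label_cols(x)),
              length(attr(x, "interaction_groups"))))
  NextMethod()
}

feature_cols <- function(cohort) grep("^f[0-9]+$", names(cohort), value = TRUE)
label_cols <- function(cohort) grep("^inj_", names(cohort), value = TRUE)

#' Extract the feature matrix of a cohort
#' @param cohort an `athlete_cohort`.
#' @return numeric matrix, athletes x features.
#' @export
cohort_features <- function(cohort) {
  as.matrix(cohort[, feature_cols(cohort), drop = FALSE])
}

#' Extract the binary injury-label matrix of a cohort
#' @param cohort an `athlete_cohort`.
#' @return integer matrix, athletes x sites, entries in \{0, 1\}.
#' @export
cohort_labels <- function(cohort) {
  m <- as.matrix(cohort[, label_cols(cohort), drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- sub("^inj_", "", colnames(m))
  m
}

#' Latent training groups of a cohort
#' @param cohort an `athlete_cohort`.
#' @return list of integer vectors of athlete ids.
#' @export
cohort_groups <- function(cohort) attr(cohort, "interaction_groups")

#' Observed per-site injury counts of the squad
#'
#' The published injury table of the 26-athlete national women's water polo
#' squad: per-site injury counts under the traditional same-gender regime and
#' under male-assisted female training, each over 26 athletes.
#'
#' @return an `injury_count_table` tibble with columns `site`, `traditional`
#'   and `maft`, and attribute `n_per_mode = 26`.
#' @examples
#' injury_proportions(table1_fixture())
#' @export
table1_fixture <- function() {
  injury_count_table(
    sites = injury_sites(),
    traditional = c(2L, 9L, 2L, 1L, 7L, 11L, 4L, 0L, 0L),
    maft = c(1L, 11L, 7L, 1L, 9L, 6L, 3L, 1L, 1L),
    n_per_mode = 26L
  )
}

#' Construct a per-site injury count table
#'
#' @param sites character vector of site names.
#' @param traditional,maft integer counts per site, one per training mode.
#' @param n_per_mode number of athletes observed under each mode.
#' @return tibble of class `injury_count_table`.
#' @export
injury_count_table <- function(sites, traditional, maft, n_per_mode = 26L) {
  n_per_mode <- check_count(n_per_mode, "n_per_mode")
  counts <- cbind(traditional, maft)
  if (any(counts < 0) || any(counts > n_per_mode) || any(counts != floor(counts))) {
    abort("counts must be integers in [0, n_per_mode].",
          class = "wpinjury_invalid_counts")
  }
  structure(
    tibble::tibble(site = as.character(sites),
                   traditional = as.integer(traditional),
                   maft = as.integer(maft)),
    n_per_mode = n_per_mode,
    class = c("injury_count_table", class(tibble::tibble()))
  )
}

#' Simulate a stochastic twin of the squad's injury table
#'
#' Draws per-site injury counts for both training modes as independent
#' binomials with denominator `config$n_athletes`, e.g. for power analyses of
#' the mode comparison.
#'
#' @param config a [simulation_config()]; supplies the denominator and seed.
#' @param site_rates a named list with numeric components `traditional` and
#'   `maft`, each of per-site injury probabilities in `[0, 1]`.
#' @return an `injury_count_table`.
#' @export
sample_injury_counts <- function(config, site_rates) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created with simulation_config().",
          class = "wpinjury_invalid_config")
  }
  if (!is.list(site_rates) || !all(c("traditional", "maft") %in% names(site_rates))) {
    abort("`site_rates` must be a list with 'traditional' and 'maft' rates.",
          class = "wpinjury_invalid_rate")
  }
  rates <- normalise_site_rates(site_rates, config$n_sites)
  withr::local_seed(derive_seed(config$seed, "injury_counts"))
  n <- config$n_athletes
  injury_count_table(
    sites = site_names_for(config$n_sites),
    traditional = rbinom(config$n_sites, n, rates["traditional", ]),
    maft = rbinom(config$n_sites, n, rates["maft", ]),
    n_per_mode = n
  )
}
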