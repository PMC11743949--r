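#' Confusion counts of a binary classifier
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion counts must be non-negative integers.",
          class = "wpinjury_invalid_counts")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, positive predictive value `TP/(TP+FP)`,
#' negative predictive value `TN/(TN+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`. A metric with a zero denominator is undefined
#' and reported as `NA` rather than 0, so macro averages are not silently
#' biased.
#'
#' @param c a [confusion_counts()].
#' @return one-row tibble with columns `acc`, `ppv`, `npv`, `sen`, `spec`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) {
    abort("all confusion counts are zero.", class = "wpinjury_invalid_counts")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    acc = (c$tp + c$tn) / total,
    ppv = ratio(c$tp, c$tp + c$fp),
    npv = ratio(c$tn, c$tn + c$fn),
    sen = ratio(c$tp, c$tp + c$fn),
    spec = ratio(c$tn, c$tn + c$fp)
  )
}

#' Per-site injury proportions by training mode
#'
#' Converts per-site injury counts into percentages of the athletes observed
#' under each mode, rounded half-up to one decimal to match how such tables
#' are reported (9 of 26 athletes is 34.6%).
#'
#' @param t an `injury_count_table`.
#' @return tibble in long format: `site`, `mode`, `count`, `n`, `pct`.
#' @examples
#' injury_proportions(table1_fixture())
#' @export
injury_proportions <- function(t) {
  stopifnot(inherits(t, "injury_count_table"))
  n <- attr(t, "n_per_mode")
  if (is.null(n) || n <= 0) {
    abort("`n_per_mode` must be a positive denominator.",
          class = "wpinjury_invalid_counts")
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(t), c("traditional", "maft"),
                              names_to = "mode", values_to = "count")
  dplyr::mutate(long, n = n, pct = round_half_up(100 * .data$count / n, 1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed test of association under the hypergeometric null with
#' fixed margins. The two-tailed p-value follows the probability-mass
#' convention: the sum of the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a 1e-7 relative slack against floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-tailed p-value in (0, 1].
#' @examples
#' fisher_exact(matrix(c(2, 7, 24, 19), 2)) # elbow & wrist, 26 per mode
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort("`table` must be 2x2.", class = "wpinjury_shape_error")
  }
  if (any(table < 0) || any(table != floor(table)) || anyNA(table)) {
    abort("counts must be non-negative integers.", class = "wpinjury_invalid_counts")
  }
  if (sum(table) == 0) {
    abort("the table is empty.", class = "wpinjury_invalid_counts")
  }
  m <- sum(table[1, ])          # row-1 margin
  n2 <- sum(table[2, ])         # row-2 margin
  k <- sum(table[, 1])          # column-1 margin
  support <- max(0L, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(table[1, 1], m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare injury proportions between training modes
#'
#' For each injury site, forms the 2x2 table of injured vs uninjured
#' athletes under the two training modes and applies [fisher_exact()];
#' a site is flagged significant when `p < alpha` (two-tailed).
#'
#' @param t an `injury_count_table`.
#' @param alpha significance level (default 0.05).
#' @return tibble with one row per site: counts, percentages per mode,
#'   `p_value` and `significant`.
#' @examples
#' compare_modes(table1_fixture())
#' @export
compare_modes <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "injury_count_table"))
  n <- attr(t, "n_per_mode")
  props <- tidyr::pivot_wider(injury_proportions(t), id_cols = "site",
                              names_from = "mode", values_from = "pct",
                              names_glue = "pct_{mode}")
  res <- purrr::map_dbl(seq_len(nrow(t)), function(i) {
    fisher_exact(matrix(c(t$traditional[i], n - t$traditional[i],
                          t$maft[i], n - t$maft[i]),
                        nrow = 2, byrow = TRUE))
  })
  out <- dplyr::left_join(tibble::as_tibble(t), props, by = "site")
  dplyr::mutate(out, p_value = res, significant = res < alpha)
}

#' Read a per-site injury count table from CSV
#'
#' Expects columns `site`, `traditional`, `maft`.
#'
#' @param path CSV file path.
#' @param n_per_mode denominator (athletes per mode), default 26.
#' @return an `injury_count_table`.
#' @export
read_injury_counts <- function(path, n_per_mode = 26L) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("site", "traditional", "maft"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("counts file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "wpinjury_schema_error")
  }
  injury_count_table(df$site, df$traditional, df$maft, n_per_mode)
}

#' Write a per-site injury count table to CSV
#' @param t an `injury_count_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_injury_counts <- function(t, path) {
  stopifnot(inherits(t, "injury_count_table"))
  atomic_write(function(tmp) {
    readr::write_csv(tibble::as_tibble(t), tmp)
  }, path)
}

#' Plot per-site injury proportions by training mode
#' @param object an `injury_count_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.injury_count_table <- function(object, ...) {
  df <- injury_proportions(object)
  df$site <- factor(df$site, levels = object$site)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$pct,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "injured athletes (%)", fill = "training mode",
                  title = "Per-site injury proportions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
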