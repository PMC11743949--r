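#' Round half away from zero
#'
#' Percentage tables in sports-epidemiology reports round 34.65 to 34.7, not
#' to the IEEE banker's value; this helper applies decimal round-half-up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Deterministically derive a stream-specific child seed from a root seed.
# Keeps all derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(as.numeric(seed)) * 1103 + h * 12347) %% 2147483587) + 1L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "wpinjury_invalid_config")
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    abort(sprintf("`%s` must be a finite scalar %s %s.", name,
                  if (strict) ">" else ">=", format(lower)),
          class = "wpinjury_invalid_config")
  }
  as.numeric(x)
}

# Atomic write: materialise in a sibling temp file, then rename.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("failed to move temporary output into place at '%s'", path))
  }
  invisible(path)
}
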