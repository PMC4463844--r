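# internal helpers shared across modules

# set the RNG seed only when the caller supplies one; callers that pass NULL
# inherit the session RNG stream
with_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number or NULL.")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite (got %s).", name,
                  paste(utils::head(x, 3), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# normalise chromosome lengths to a named numeric vector
chrom_length_vector <- function(chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    stats::setNames(as.numeric(chrom_lengths$length_bp), chrom_lengths$chrom)
  } else if (!is.null(names(chrom_lengths))) {
    chrom_lengths
  } else {
    abort("`chrom_lengths` must be a named vector or a tibble with columns `chrom`, `length_bp`.")
  }
}

# index of the first/last sorted position inside [lo, hi]
range_indices <- function(pos, lo, hi) {
  i0 <- findInterval(lo - 1, pos) + 1L
  i1 <- findInterval(hi, pos)
  list(lo = i0, hi = i1, n = pmax(i1 - i0 + 1L, 0L))
}

# windowed mean of `v` (aligned with sorted positions) via cumulative sums
windowed_mean <- function(v, lo, hi, n) {
  cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
  out <- (cs[hi + 1L] - cs[lo]) / n
  out[n == 0L] <- NA_real_
  out
}

windowed_sum <- function(v, lo, hi, n) {
  cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
  out <- cs[hi + 1L] - cs[lo]
  out[n == 0L] <- NA_real_
  out
}
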