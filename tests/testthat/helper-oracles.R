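# Independent oracles used to cross-check the package implementations.
# These deliberately use naive enumeration, not the package's algorithms.

# random sequence with roughly the requested GC fraction
random_dna <- function(n, gc = 0.5, with_n = FALSE) {
  letters <- c("G", "C", "A", "T")
  probs <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  if (with_n) {
    letters <- c(letters, "N")
    probs <- c(probs * 0.95, 0.05)
  }
  paste(sample(letters, n, replace = TRUE, prob = probs), collapse = "")
}

# enumerate every window start and count A/T symbols directly
naive_window_count <- function(seq, len, min_at) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  if (n < len) {
    return(c(overlapping = 0L, disjoint = 0L))
  }
  qualifies <- vapply(seq_len(n - len + 1L), function(s) {
    sum(x[s:(s + len - 1L)] %in% c("A", "T")) >= min_at
  }, logical(1))
  starts <- which(qualifies)
  c(overlapping = length(starts), disjoint = exact_max_disjoint(starts, len))
}

# exact maximum independent set of equal-length intervals by recursion
# (include/exclude each interval), memoised; independent of the greedy rule
exact_max_disjoint <- function(starts, len) {
  m <- length(starts)
  if (m == 0L) {
    return(0L)
  }
  memo <- rep(NA_integer_, m + 1L)
  f <- function(i) {
    if (i > m) {
      return(0L)
    }
    if (!is.na(memo[i])) {
      return(memo[i])
    }
    j <- i + 1L
    while (j <= m && starts[j] < starts[i] + len) j <- j + 1L
    best <- max(f(i + 1L), 1L + f(j))
    memo[i] <<- best
    best
  }
  f(1L)
}

# exact two-sided Mann-Whitney p by enumerating every group-a subset of the
# pooled observations (no-ties case)
enum_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(length(pooled), na)
  us <- apply(subsets, 2L, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# brute-force upper binomial tail by direct density summation
sum_binom_tail <- function(k, n, p0) {
  if (k == 0L) {
    return(1)
  }
  sum(stats::dbinom(k:n, n, p0))
}
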