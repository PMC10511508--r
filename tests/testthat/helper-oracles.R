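# Independent oracles, deliberately naive: direct per-value loops over the
# pooled multiset, no shared code with the package internals.

# discrete two-sample AD: direct evaluation of the EDF integrand at every
# pooled distinct value, right-continuous EDFs, H = 1 point excluded
ad_oracle <- function(left, right) {
  n <- length(left); m <- length(right); N <- n + m
  pool <- c(left, right)
  s <- 0
  for (v in sort(unique(pool))) {
    Fv <- sum(left <= v) / n
    Gv <- sum(right <= v) / m
    Hv <- sum(pool <= v) / N
    lv <- sum(pool == v)
    if (Hv > 0 && Hv < 1)
      s <- s + (Fv - Gv)^2 / (Hv * (1 - Hv)) * (lv / N)
  }
  (n * m / N) * s
}

# classical continuous-data two-sample AD over pooled order statistics
# (valid when all values are distinct)
ad_continuous_oracle <- function(left, right) {
  n <- length(left); m <- length(right); N <- n + m
  pooled <- sort(c(left, right))
  s <- 0
  for (j in 1:(N - 1)) {
    Mj <- sum(left <= pooled[j])
    s <- s + (N * Mj - j * n)^2 / (j * (N - j))
  }
  s / (n * m)
}

# trimmed mean by explicit sort-and-drop
trimmed_mean_oracle <- function(x, trim = 0.1) {
  k <- floor(trim * length(x))
  xs <- sort(x)
  mean(xs[(k + 1):(length(x) - k)])
}

# brute-force best split by scoring every cut with the oracle statistic
best_split_oracle <- function(x, min_size = 1) {
  L <- length(x)
  cand <- seq.int(min_size, L - min_size)
  ads <- vapply(cand, function(i) ad_oracle(x[1:i], x[(i + 1):L]), numeric(1))
  list(split_index = cand[which.max(ads)], ad = max(ads))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
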