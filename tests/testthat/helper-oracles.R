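# Independent brute-force oracles used to validate the fast implementations.
# Everything here is written with explicit loops and textbook formulas on
# purpose; none of it shares code with the package internals.

# Pearson correlation from the definition
oracle_pearson <- function(a, b) {
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# average ranks from the definition (count smaller + half the ties)
oracle_rank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

# rank-scaled RDM: loops over pairs, 1 - Pearson, average ranks, min-max
oracle_rdm <- function(patterns) {
  n <- nrow(patterns)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- 1 - oracle_pearson(patterns[i, ], patterns[j, ])
  v <- d[lower.tri(d)]
  r <- oracle_rank(v)
  sc <- if (max(r) == min(r)) rep(0.5, length(r))
        else (r - min(r)) / (max(r) - min(r))
  out <- matrix(0, n, n)
  out[lower.tri(out)] <- sc
  out + t(out)
}

# 1 - Spearman over lower triangles, Spearman as Pearson of average ranks
oracle_rdm_distance <- function(a, b) {
  va <- a[lower.tri(a)]; vb <- b[lower.tri(b)]
  1 - oracle_pearson(oracle_rank(va), oracle_rank(vb))
}

# exhaustive-split change point: lm per segment, every admissible split
oracle_changepoint <- function(y, min_seg = 5, min_improvement = 0.1) {
  n <- length(y)
  x <- seq_len(n)
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(resid(lm(y[idx] ~ x[idx]))^2)
  }
  sse0 <- sse(seq_len(n))
  taus <- min_seg:(n - min_seg)
  tot <- vapply(taus, function(tau)
    sse(1:tau) + sse((tau + 1):n), numeric(1))
  best <- which(tot <= min(tot) + 1e-10 * (sse0 + 1))[1]
  scale <- sum((y - mean(y))^2)
  if (scale == 0 || sse0 <= 1e-10 * scale) return(NA_integer_)
  if ((sse0 - tot[best]) / sse0 < min_improvement) return(NA_integer_)
  as.integer(taus[best])
}

# Morlet power by direct convolution sums at every requested sample
oracle_morlet_power <- function(x, fs, freq, cycles, times) {
  sigma <- cycles / (2 * pi * freq)
  h <- ceiling(3 * sigma * fs)
  if (h > length(x) - 1) h <- length(x) - 1
  u <- (-h):h
  g <- exp(-(u / fs)^2 / (2 * sigma^2))
  w <- complex(modulus = g, argument = 2 * pi * freq * u / fs) * 2 / sum(g)
  xp <- c(rep(0, h), x, rep(0, h))
  vapply(times, function(t0)
    Mod(sum(w * xp[t0 + h + u]))^2, numeric(1))
}

# tiny protocol + layout shared by several files
tiny_layout <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- searchlight_layout()
    cache
  }
})
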