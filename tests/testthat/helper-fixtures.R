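# Shared fixture builders; everything is generated in code at test time.

# density grid from an explicit value matrix (bypasses rasterization)
grid_from_matrix <- function(values, pixel_size_nm = 1) {
  structure(list(values = values, pixel_size_nm = pixel_size_nm,
                 origin = c(0, 0),
                 n_points = sum(values) * pixel_size_nm^2),
            class = "density_grid")
}

# brute-force Eq.-style cross-correlation at a single displacement
xcorr_at <- function(v1, v2, dx, dy) {
  m1 <- mean(v1); m2 <- mean(v2)
  d1 <- v1 - m1; d2 <- v2 - m2
  s <- 0; n <- 0
  for (i in seq_len(nrow(v1))) for (j in seq_len(ncol(v1))) {
    ii <- i + dx; jj <- j + dy
    if (ii >= 1 && ii <= nrow(v1) && jj >= 1 && jj <= ncol(v1)) {
      s <- s + d1[i, j] * d2[ii, jj]; n <- n + 1
    }
  }
  (s / n) / (m1 * m2)
}

# exhaustive hypergeometric upper tail by enumeration over overlap counts
hyper_upper_enum <- function(N, K, n, k) {
  ks <- max(0, K + n - N):min(K, n)
  sum(sapply(ks[ks >= k], function(x)
    choose(K, x) * choose(N - K, n - x))) / choose(N, n)
}

# independent running-sum ES evaluation (explicit loop, no vectorization);
# same declared tie rule: positive extremum wins magnitude ties (at 1e-9)
es_bruteforce <- function(stats, hit, weight = 1) {
  n <- length(stats)
  nh <- sum(hit)
  if (nh == n) return(1)
  denom <- sum(abs(stats[hit])^weight)
  run <- 0; runs <- numeric(n)
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(stats[i])^weight / denom else -1 / (n - nh)
    runs[i] <- run
  }
  hi <- max(runs); lo <- min(runs)
  if (hi >= abs(lo) - 1e-9) hi else lo
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(rank(c(x, y))[seq_along(x)]) -
    length(x) * (length(x) + 1) / 2
  obs <- u_stat(a, b)
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu))
}
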