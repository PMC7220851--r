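# Independent brute-force oracles. Each re-derives a quantity from its
# definition, by enumeration or hand arithmetic, without touching the code
# paths it checks.

# Centered box mean with half-width h, truncated at the vector ends.
oracle_box_smooth <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(x[w])
  }, numeric(1))
}

# Maximal runs of x >= t: exhaustive enumeration.
oracle_runs <- function(x, t) {
  above <- x >= t
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             peak = vapply(keep, function(k)
               max(x[starts[k]:ends[k]]), numeric(1)))
}

# Spearman rho as Pearson on average ranks, from the covariance formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Benjamini-Hochberg step-up from its definition: reject the k smallest
# p-values where k is the largest index with p_(k) <= k/m * alpha.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) / m * alpha)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# Product-limit estimator by hand: loop over distinct event times.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (t in tt) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Logrank chi-square from hand-built risk tables at each event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  tt <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in tt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Median-of-ratios size factors from the definition.
oracle_size_factors <- function(counts) {
  gm <- apply(counts, 1, function(r) prod(r)^(1 / length(r)))
  use <- gm > 0
  apply(counts, 2, function(col) median(col[use] / gm[use]))
}
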