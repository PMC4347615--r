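## Independent brute-force oracles, written as literal loops over the
## defining sums so they share no code with the package implementations.

oracle_global_density <- function(r) {
  s <- 0
  for (i in seq_along(r)) s <- s + r[i]
  s / length(r)
}

oracle_boundary_length <- function(L, d) min(L, max(1, floor(d / 100 * L)))

oracle_osd <- function(r, step = 5, maxd = 75) {
  L <- length(r)
  ds <- seq(step, maxd, by = step)
  left <- right <- numeric(length(ds))
  for (q in seq_along(ds)) {
    b <- oracle_boundary_length(L, ds[q])
    s <- 0
    for (i in 1:b) s <- s + r[i]
    left[q] <- s
    s <- 0
    for (i in (L - b + 1):L) s <- s + r[i]
    right[q] <- s
  }
  c(oracle_global_density(r), left, right)
}

oracle_osa <- function(r, step = 10, maxd = 70, DF = 10) {
  L <- length(r)
  ds <- seq(step, maxd, by = step)
  block <- function(x, D) {
    out <- numeric(DF)
    for (i in 1:DF) {
      if (D - i <= 0) { out[i] <- 0; next }
      s <- 0
      for (j in 1:(D - i)) s <- s + x[j] * x[j + i]
      out[i] <- s / (D - i)
    }
    out
  }
  left <- right <- NULL
  for (d in ds) {
    b <- oracle_boundary_length(L, d)
    left <- c(left, block(r, b))
    right <- c(right, block(rev(r), b))
  }
  c(left, right, block(r, L))
}

oracle_sc <- function(P) {
  out <- numeric(20)
  for (j in 1:20) {
    s <- 0
    for (i in seq_len(nrow(P))) s <- s + P[i, j]
    out[j] <- s / nrow(P)
  }
  out
}

oracle_ac <- function(P, DF = 10) {
  L <- nrow(P)
  out <- NULL
  for (j in 1:20) {
    m <- 0
    for (i in 1:L) m <- m + P[i, j]
    m <- m / L
    for (k in 1:DF) {
      s <- 0
      for (i in 1:(L - k)) s <- s + (P[i, j] - m) * (P[i + k, j] - m)
      out <- c(out, s / (L - k))
    }
  }
  as.numeric(out)
}

## Random row-stochastic matrix via independent gamma normalization.
random_probs <- function(L, seed) {
  set.seed(seed)
  g <- matrix(rgamma(L * 20, shape = 0.7), L, 20)
  g / rowSums(g)
}

random_attr_seq <- function(L, seed) {
  set.seed(seed)
  runif(L)
}
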