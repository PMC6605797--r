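# Independent brute-force reference implementations, written as plain loops
# over pixels. They exist only to cross-check the package's algorithms and
# share no code with them.

oracle_isodata <- function(m, tol = 1e-6) {
  v <- as.vector(m)
  t_cur <- (min(v) + max(v)) / 2
  repeat {
    lo_sum <- 0; lo_n <- 0; hi_sum <- 0; hi_n <- 0
    for (x in v) {
      if (x <= t_cur) { lo_sum <- lo_sum + x; lo_n <- lo_n + 1 }
      else            { hi_sum <- hi_sum + x; hi_n <- hi_n + 1 }
    }
    if (hi_n == 0) {
      mx <- max(v)
      t_next <- (mean(v[v < mx]) + mx) / 2
    } else if (lo_n == 0) {
      mn <- min(v)
      t_next <- (mn + mean(v[v > mn])) / 2
    } else {
      t_next <- (lo_sum / lo_n + hi_sum / hi_n) / 2
    }
    if (abs(t_next - t_cur) < tol) return(t_next)
    t_cur <- t_next
  }
}

oracle_max_entropy <- function(m, n_bins = 256) {
  v <- as.vector(m)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  counts <- rep(0, n_bins)
  for (x in v) {
    b <- n_bins
    for (i in 1:n_bins) if (x <= breaks[i + 1]) { b <- i; break }
    counts[b] <- counts[b] + 1
  }
  p <- counts / length(v)
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    p0 <- sum(p[1:t]); p1 <- sum(p[(t + 1):n_bins])
    if (p0 <= 0 || p1 <= 0) next
    h0 <- 0
    for (i in 1:t) if (p[i] > 0) h0 <- h0 - (p[i] / p0) * log(p[i] / p0)
    h1 <- 0
    for (i in (t + 1):n_bins) if (p[i] > 0) h1 <- h1 - (p[i] / p1) * log(p[i] / p1)
    if (h0 + h1 > best) { best <- h0 + h1; best_t <- t }
  }
  breaks[best_t + 1]
}

oracle_bernsen <- function(m, radius, contrast) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    lo <- Inf; hi <- -Inf
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr * dr + dc * dc > radius * radius) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- m[rr, cc]
      if (v < lo) lo <- v
      if (v > hi) hi <- v
    }
    if (hi - lo >= contrast && m[r, c] > (hi + lo) / 2) out[r, c] <- 1L
  }
  out
}

oracle_median_filter <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) {          # mirror without edge repetition
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr * dr + dc * dc > radius * radius) next
      vals <- c(vals, m[reflect(r + dr, nr), reflect(c + dc, nc)])
    }
    out[r, c] <- median(vals)
  }
  out
}

oracle_distance_map <- function(mask, clip = 255) {
  idx <- which(mask == 1, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    out[r, c] <- min(sqrt((idx[, 1] - r)^2 + (idx[, 2] - c)^2), clip)
  }
  out
}

random_test_image <- function(seed, n = 16, levels = 8) {
  set.seed(seed)
  matrix(sample(seq(0, 255, length.out = levels), n * n, replace = TRUE), n, n)
}
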