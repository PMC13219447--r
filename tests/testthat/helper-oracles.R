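# Independent oracles used across the suite.

# Brute-force three-class Otsu: maximize between-class variance over all
# ordered threshold pairs on the same fixed-width histogram the package
# uses. Independent formulation (between-class maximization, plain loops)
# of the criterion the implementation minimizes within-class.
oracle_otsu3 <- function(x, levels = 64L) {
  x <- as.numeric(x)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), levels)
  h <- tabulate(idx, nbins = levels)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  p <- h / sum(h)
  mu_t <- sum(p * mids)
  best <- -Inf; best_ij <- c(NA, NA)
  for (i in 1:(levels - 2)) {
    for (j in (i + 1):(levels - 1)) {
      w1 <- sum(p[1:i]); w2 <- sum(p[(i + 1):j]); w3 <- sum(p[(j + 1):levels])
      m1 <- if (w1 > 0) sum(p[1:i] * mids[1:i]) / w1 else 0
      m2 <- if (w2 > 0) sum(p[(i + 1):j] * mids[(i + 1):j]) / w2 else 0
      m3 <- if (w3 > 0) sum(p[(j + 1):levels] * mids[(j + 1):levels]) / w3 else 0
      sb <- w1 * (m1 - mu_t)^2 + w2 * (m2 - mu_t)^2 + w3 * (m3 - mu_t)^2
      if (sb > best) { best <- sb; best_ij <- c(i, j) }
    }
  }
  c(low = edges[best_ij[1] + 1L], high = edges[best_ij[2] + 1L])
}

# Tukey HSD adjusted p-values from first principles (studentized range).
oracle_tukey_p <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / (N - k)
  out <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    out <- c(out, stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  }
  out
}

# deterministic two-Gaussian test trace on an integer scan grid
gauss_trace <- function(centers, heights, sigma = 2.5, n = 600) {
  grid <- seq_len(n)
  y <- rep(0, n)
  for (k in seq_along(centers)) {
    y <- y + heights[k] * exp(-(grid - centers[k])^2 / (2 * sigma^2))
  }
  tibble::tibble(migration = grid, rfu = y)
}

# render a disk into a matrix
add_disk <- function(img, row, col, radius, value) {
  rr <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cc <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  sel <- (rr - row)^2 + (cc - col)^2 <= radius^2
  img[sel] <- img[sel] + value
  img
}
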