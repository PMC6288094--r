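# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Moore-neighbourhood flood fill: returns sorted patch sizes.
flood_fill_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# Exact pinball-loss linear quantile regression by enumerating the lines
# through every pair of points (an optimal basic solution always
# interpolates two observations).
pinball_fit_oracle <- function(t, y, tau) {
  best <- NULL; best_loss <- Inf
  n <- length(y)
  loss <- function(a, b) {
    r <- y - a - b * t
    sum(r * (tau - (r < 0)))
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (t[i] == t[j]) next
    b <- (y[j] - y[i]) / (t[j] - t[i])
    a <- y[i] - b * t[i]
    l <- loss(a, b)
    if (l < best_loss - 1e-12) {
      best_loss <- l; best <- c(a, b)
    }
  }
  list(intercept = best[1], slope = best[2], loss = best_loss)
}

# Direct central-moment skewness.
skew_oracle <- function(v) {
  m <- mean(v)
  mean((v - m)^3) / mean((v - m)^2)^1.5
}

# Analytic tail CDF of the continuous power law.
ppl_oracle <- function(q, alpha, x_min) 1 - (q / x_min)^(1 - alpha)

# A tiny deterministic patch census for series tests.
make_census <- function(sizes, year, threshold = 30, region = "R1") {
  land <- matrix(FALSE, 40, sum(sizes) + 2 * length(sizes) + 40)
  col <- 1L
  for (s in sizes) {
    land[3, col:(col + s - 1L)] <- TRUE
    col <- col + s + 2L  # gap of 2 keeps patches disconnected
  }
  cov <- matrix(0, nrow(land), ncol(land))
  cov[land] <- 80
  cen <- label_patches(binarize(cover_raster(cov, region_id = region,
                                             year = year), threshold))
  cen
}
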