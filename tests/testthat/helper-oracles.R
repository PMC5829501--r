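# Independent brute-force oracles: explicit per-pixel loops, kept free of any
# package internals so they can arbitrate the vectorised implementations.

# annulus statistics by exhaustive distance test over every pixel
oracle_annulus <- function(frame, center, r_in, r_out) {
  vals <- c()
  for (y in seq_len(nrow(frame))) {
    for (x in seq_len(ncol(frame))) {
      d <- sqrt((y - center[1])^2 + (x - center[2])^2)
      if (d > r_in && d <= r_out) vals <- c(vals, frame[y, x])
    }
  }
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / length(vals)),
       n = length(vals))
}

# seed-connected component of mask (8-connectivity) by stack-based flood fill
oracle_flood_fill <- function(mask, seed) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!mask[seed[1], seed[2]]) return(integer(0))
  seen <- matrix(FALSE, nr, nc)
  stack <- list(seed)
  seen[seed[1], seed[2]] <- TRUE
  out <- c()
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    out <- c(out, (p[2] - 1) * nr + p[1])
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      y <- p[1] + dy; x <- p[2] + dx
      if (y >= 1 && y <= nr && x >= 1 && x <= nc && mask[y, x] && !seen[y, x]) {
        seen[y, x] <- TRUE
        stack[[length(stack) + 1]] <- c(y, x)
      }
    }
  }
  sort(out)
}

# a random frame: Gaussian background plus an optional rectangular bright blob
random_frame <- function(ny, nx, bg_mean = 100, bg_sd = 10, blob = TRUE) {
  f <- matrix(rnorm(ny * nx, bg_mean, bg_sd), ny, nx)
  if (blob) {
    cy <- sample(12:(ny - 11), 1); cx <- sample(12:(nx - 11), 1)
    h <- sample(1:3, 1); w <- sample(1:3, 1)
    f[(cy - h):(cy + h), (cx - w):(cx + w)] <-
      f[(cy - h):(cy + h), (cx - w):(cx + w)] + runif(1, 50, 200)
    attr(f, "blob_center") <- c(cy, cx)
  }
  f
}

# noiseless single-spot movie: anterior centrosome only, zero-noise camera
single_spot_sim <- function(truth = kinetic_truth(), n_frames = 90, seed = 1,
                            noise = zero_noise()) {
  preset <- condition_preset("wild_type",
                             anterior = truth,
                             posterior = kinetic_truth(m_peak = 0))
  render_movie(preset, noise = noise, n_frames = n_frames, seed = seed)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), 1))
}
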