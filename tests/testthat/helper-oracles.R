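# Independently coded brute-force oracles. These deliberately use plain
# nested loops and straight-line arithmetic, not the package's vectorised
# code paths.

oracle_dark_channel <- function(arr, patch) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  h <- dim(arr)[1]; w <- dim(arr)[2]; nc <- dim(arr)[3]
  r <- (patch - 1) / 2
  out <- matrix(Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (ii in max(1, i - r):min(h, i + r))
      for (jj in max(1, j - r):min(w, j + r))
        for (cc in seq_len(nc))
          out[i, j] <- min(out[i, j], arr[ii, jj, cc])
  }
  out
}

oracle_atmospheric_light <- function(arr, dark, fraction) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  npick <- max(1, ceiling(fraction * length(dark)))
  idx <- order(as.vector(dark), decreasing = TRUE)[seq_len(npick)]
  sapply(seq_len(dim(arr)[3]), function(cc) {
    plane <- arr[, , cc]
    mean(as.vector(plane)[idx])
  })
}

oracle_local_stats <- function(m, win) {
  h <- nrow(m); w <- ncol(m); r <- (win - 1) / 2
  mu <- matrix(0, h, w); sd_ <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (ii in max(1, i - r):min(h, i + r))
      for (jj in max(1, j - r):min(w, j + r))
        vals <- c(vals, m[ii, jj])
    mu[i, j] <- mean(vals)
    sd_[i, j] <- sqrt(mean((vals - mu[i, j])^2))
  }
  list(mean = mu, sd = sd_)
}

# Row-by-row transcription of the binomial activation keep rule.
oracle_activation_kept <- function(X) {
  n <- nrow(X)
  kept <- logical(ncol(X))
  margins <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    lo <- min(col); hi <- max(col)
    z <- if (hi > lo) (col - lo) / (hi - lo) else rep(0.5, n)
    p_hat <- mean(z)
    k <- 0
    for (i in seq_len(n)) if (z[i] >= 0.5) k <- k + 1
    prob <- choose(n, k) * p_hat^k * (1 - p_hat)^(n - k)
    if (p_hat == 0 && k == 0) prob <- 1
    if (p_hat == 1 && k == n) prob <- 1
    kept[j] <- p_hat >= prob
    margins[j] <- p_hat - prob
  }
  if (!any(kept)) kept[which.max(margins)] <- TRUE
  kept
}

# Straight-line transcription of one EO move (same RNG consumption order
# as eo_step: lambda, r, pool candidate, v1, v2 per particle).
oracle_eo_step_positions <- function(positions, pool_positions, iter, params) {
  t <- (1 - iter / params$max_iters)^(params$a2 * iter / params$max_iters)
  out <- positions
  for (i in seq_len(nrow(positions))) {
    d <- ncol(positions)
    lambda <- runif(d)
    r <- runif(d)
    cand <- sample.int(5L, 1L)
    v1 <- runif(1)
    v2 <- runif(1)
    C <- positions[i, ]
    Ceq <- pool_positions[cand, ]
    F <- params$a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)
    gate <- if (params$gcp_condition == "v2_ge_gp") v2 >= params$gp
            else v1 * v2 > params$gp
    GCP <- if (gate) params$gcp_scale * v1 else 0
    G <- GCP * (Ceq - lambda * C) * F
    Cnew <- Ceq + (C - Ceq) * F + (G / lambda) * (1 - F)
    out[i, ] <- pmin(pmax(Cnew, params$lower), params$upper)
  }
  out
}

# A tiny two-cluster dataset that 1-NN separates perfectly.
separable_data <- function(n_per_class = 10, d_noise = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- factor(rep(c("a", "b"), each = n_per_class))
  x1 <- c(rnorm(n_per_class, -5, 0.3), rnorm(n_per_class, 5, 0.3))
  X <- cbind(x1, if (d_noise > 0) matrix(rnorm(n * d_noise), n))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(X = X, y = y)
}

random_image <- function(h, w, c = 1, seed = 1) {
  set.seed(seed)
  intensity_image(array(runif(h * w * c), c(h, w, c)))
}
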