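#' @keywords internal
"_PACKAGE"

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a stage seed from a master seed
#'
#' All randomised stages draw their seed deterministically from one master
#' seed so a single integer reproduces an entire run. Seeds stay below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"simulate"`, `"select"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offsets <- c(
    simulate = 101L, enhance = 211L, augment = 307L, extract = 401L,
    fuse = 503L, select = 601L, classify = 701L, protocol = 809L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) * 7919 + off) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards (so deterministic helpers do not perturb user streams).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated (edge-shrinking) sliding-window minimum over matrix rows.
# Window length k (odd); out-of-range positions simply do not contribute.
slide_min_rows <- function(m, k) {
  r <- (k - 1L) %/% 2L
  n <- ncol(m)
  out <- m
  for (off in seq_len(r)) {
    left <- cbind(m[, -seq_len(off), drop = FALSE],
                  matrix(Inf, nrow(m), off))
    right <- cbind(matrix(Inf, nrow(m), off),
                   m[, seq_len(n - off), drop = FALSE])
    out <- pmin(out, left, right)
  }
  out
}

# Truncated sliding-window sum over matrix rows (used for box statistics).
slide_sum_rows <- function(m, k) {
  r <- (k - 1L) %/% 2L
  n <- ncol(m)
  out <- m
  for (off in seq_len(r)) {
    left <- cbind(m[, -seq_len(off), drop = FALSE],
                  matrix(0, nrow(m), off))
    right <- cbind(matrix(0, nrow(m), off),
                   m[, seq_len(n - off), drop = FALSE])
    out <- out + left + right
  }
  out
}

# Separable truncated box filter: windowed sum and window pixel count.
box_stats <- function(m, k) {
  s <- t(slide_sum_rows(t(slide_sum_rows(m, k)), k))
  cnt <- t(slide_sum_rows(t(slide_sum_rows(matrix(1, nrow(m), ncol(m)), k)), k))
  list(sum = s, count = cnt)
}

# Windowed mean and (population) standard deviation with truncated windows.
local_mean_sd <- function(m, k) {
  b1 <- box_stats(m, k)
  b2 <- t(slide_sum_rows(t(slide_sum_rows(m * m, k)), k))
  mu <- b1$sum / b1$count
  v <- pmax(b2 / b1$count - mu * mu, 0)
  list(mean = mu, sd = sqrt(v))
}

check_odd_window <- function(k, what) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k %% 2 != 1)
    stop(what, " must be an odd positive integer, got ", k)
  as.integer(k)
}
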