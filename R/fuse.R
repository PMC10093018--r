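#' Serial (columnwise) feature fusion
#'
#' Concatenates two feature matrices of the same samples side by side:
#' an N x a matrix fused with an N x b matrix gives N x (a + b), columns of
#' the first source preceding the second. A per-column source map records
#' where each fused column came from.
#'
#' @param A,B [feature_matrix()]s with equal row counts and identical
#'   rowwise labels.
#' @return a list of class `fused_matrix` with elements `base` (a
#'   [feature_matrix()]) and `source_map` (data.frame with columns `source`
#'   in `{first, second}` and `index`).
#' @export
serial_concat <- function(A, B) {
  stopifnot(inherits(A, "feature_matrix"), inherits(B, "feature_matrix"))
  if (nrow(A$values) != nrow(B$values))
    stop("row counts differ between the two feature matrices")
  if (!identical(is.null(A$labels), is.null(B$labels)) ||
      (!is.null(A$labels) && !all(as.character(A$labels) == as.character(B$labels))))
    stop("labels differ rowwise between the two feature matrices")
  tag <- function(prefix, ids)
    if (length(ids)) paste0(prefix, ids) else character(0)
  ids <- c(tag("a.", A$feature_ids), tag("b.", B$feature_ids))
  vals <- cbind(A$values, B$values)
  colnames(vals) <- ids
  source_map <- data.frame(
    source = rep(c("first", "second"), c(ncol(A$values), ncol(B$values))),
    index = c(seq_len(ncol(A$values)), seq_len(ncol(B$values))))
  structure(list(base = feature_matrix(vals, labels = A$labels,
                                       feature_ids = ids),
                 source_map = source_map),
            class = "fused_matrix")
}

#' @export
print.fused_matrix <- function(x, ...) {
  cat(sprintf("<fused_matrix: %d samples x %d columns (%d + %d)>\n",
              nrow(x$base$values), ncol(x$base$values),
              sum(x$source_map$source == "first"),
              sum(x$source_map$source == "second")))
  invisible(x)
}

#' Binomial probability mass function
#'
#' `C(n, k) p^k (1 - p)^(n - k)`, evaluated in log space for numerical
#' safety; vectorised over `k`.
#'
#' @param k integer number of successes, `0 <= k <= n`.
#' @param n integer number of trials.
#' @param p success probability in \[0, 1\].
#' @return probability in \[0, 1\].
#' @export
binomial_pmf <- function(k, n, p) {
  r <- cbind(k, n, p)  # recycle arguments jointly
  k <- r[, 1]; n <- r[, 2]; p <- r[, 3]
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  # the ifelse guards give the exact limits at p = 0 and p = 1
  lg <- lchoose(n, k) +
    ifelse(k == 0, 0, k * log(p)) +
    ifelse(k == n, 0, (n - k) * log1p(-p))
  unname(pmin(pmax(exp(lg), 0), 1))
}

#' Binomial-probability activation column selection
#'
#' The column-level activation rule applied after serial fusion. For each
#' fused column: min-max normalise over rows to \[0, 1\] (zero-range
#' columns map to 0.5 by convention); `p_hat` = mean of the normalised
#' values; `k` = number of rows at or above 0.5; `n` = row count;
#' `prob = binomial_pmf(k, n, p_hat)`. The column is kept iff its
#' normalised mean is at least `prob`. If no column passes, the single
#' column with the largest `mean - prob` margin is kept so the output is
#' never empty.
#'
#' @param F a `fused_matrix` (or [feature_matrix()]).
#' @return a list with elements `features` (kept columns, a
#'   [feature_matrix()]), `activation` (list with `n`, `p_hat`, `k`,
#'   `prob`, `kept`) and `source_map` (filtered, when the input carried
#'   one).
#' @export
binomial_activation <- function(F) {
  source_map <- NULL
  if (inherits(F, "fused_matrix")) {
    source_map <- F$source_map
    F <- F$base
  }
  stopifnot(inherits(F, "feature_matrix"))
  X <- F$values
  if (!nrow(X) || !ncol(X)) stop("fused matrix is empty")
  n <- nrow(X)
  norm <- apply(X, 2L, function(col) {
    rng <- range(col)
    if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
  })
  norm <- matrix(norm, nrow = n)
  p_hat <- colMeans(norm)
  k <- colSums(norm >= 0.5)
  prob <- binomial_pmf(k, n, p_hat)
  kept <- p_hat >= prob
  if (!any(kept)) kept[which.max(p_hat - prob)] <- TRUE
  out <- feature_matrix(X[, kept, drop = FALSE], labels = F$labels,
                        feature_ids = F$feature_ids[kept])
  if (!is.null(source_map)) source_map <- source_map[kept, , drop = FALSE]
  list(features = out,
       activation = list(n = n, p_hat = p_hat, k = k, prob = prob,
                         kept = kept),
       source_map = source_map)
}
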