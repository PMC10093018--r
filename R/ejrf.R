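#' Parameters of the hybrid Equilibrium-Jaya optimizer
#'
#' Controls the wrapper feature selector and the underlying continuous
#' optimizer. Exploration constant `a1` and exploitation constant `a2`
#' follow the standard Equilibrium Optimizer settings (2 and 1); the
#' generation-rate gate fires with scale 0.65 when the second uniform draw
#' reaches the generation probability `gp`.
#'
#' @param pop_size number of particles (>= 5; the equilibrium pool needs
#'   the four best plus their average).
#' @param max_iters iteration budget (ITmax).
#' @param a1 exploration constant.
#' @param a2 exploitation constant.
#' @param gp generation probability in \[0, 1\].
#' @param gcp_scale scale of the generation-rate control parameter.
#' @param lower,upper position bounds.
#' @param binarize_tau threshold mapping continuous positions to a binary
#'   feature mask.
#' @param rf_tol improvement below which an iteration counts as stalled.
#' @param rf_window number of consecutive sub-tolerance improvements that
#'   declare a stall.
#' @param seed master RNG seed for the optimizer.
#' @param phase_mode `"interleaved"` (EO move then Jaya refinement inside
#'   each iteration, the default) or `"sequential"` (an EO phase to
#'   termination, then a Jaya phase).
#' @param gcp_condition gate condition: `"v2_ge_gp"` (default) fires the
#'   generation term when `v2 >= gp`; `"v1v2_gt_gp"` when `v1 * v2 > gp`.
#' @param jaya_abs use absolute-value positions in the Jaya move
#'   (canonical variant) instead of the plain printed form (default FALSE).
#' @param early_stop apply the stall and Regula Falsi convergence triggers
#'   (default). With `FALSE` only the iteration budget terminates the run,
#'   for fixed-budget benchmarking.
#' @return a list of class `eo_params`.
#' @export
eo_params <- function(pop_size = 20L, max_iters = 50L, a1 = 2, a2 = 1,
                      gp = 0.5, gcp_scale = 0.65, lower = 0, upper = 1,
                      binarize_tau = 0.5, rf_tol = 1e-4, rf_window = 3L,
                      seed = 0L,
                      phase_mode = c("interleaved", "sequential"),
                      gcp_condition = c("v2_ge_gp", "v1v2_gt_gp"),
                      jaya_abs = FALSE, early_stop = TRUE) {
  if (pop_size < 5) stop("pop_size must be >= 5 (pool needs 4 + average)")
  if (gp < 0 || gp > 1) stop("gp must lie in [0, 1]")
  if (upper < lower) stop("upper must be >= lower")
  structure(list(pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters), a1 = a1, a2 = a2,
                 gp = gp, gcp_scale = gcp_scale, lower = lower,
                 upper = upper, binarize_tau = binarize_tau,
                 rf_tol = rf_tol, rf_window = as.integer(rf_window),
                 seed = as.integer(seed),
                 phase_mode = match.arg(phase_mode),
                 gcp_condition = match.arg(gcp_condition),
                 jaya_abs = isTRUE(jaya_abs),
                 early_stop = isTRUE(early_stop)),
            class = "eo_params")
}

#' Fitness-evaluation protocol for wrapper selection
#'
#' The wrapper fitness is the misclassification rate of a fine KNN
#' (1-nearest-neighbour, Euclidean) on a stratified holdout split; the
#' split is fixed by `seed` so every candidate mask is scored on the same
#' partition.
#'
#' @param k_neighbors neighbour count (1 = fine KNN).
#' @param holdout_fraction fraction of samples held out for scoring.
#' @param stratified stratify the split by class.
#' @param seed split RNG seed.
#' @return a list of class `fitness_protocol`.
#' @export
fitness_protocol <- function(k_neighbors = 1L, holdout_fraction = 0.3,
                             stratified = TRUE, seed = 0L) {
  if (!(holdout_fraction > 0 && holdout_fraction < 1))
    stop("holdout_fraction must be in (0, 1)")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 holdout_fraction = holdout_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "fitness_protocol")
}

#' Initialise the particle population
#'
#' Each particle position is `lower + (upper - lower) * v` with `v` drawn
#' uniformly from the current RNG stream; fitness starts unevaluated (NA).
#' Draws are consumed particle by particle (d values each).
#'
#' @param params an [eo_params()].
#' @param d problem dimensionality.
#' @return a list of class `population` with elements `positions`
#'   (pop_size x d matrix), `fitness` (NA vector), `best_position`,
#'   `best_fitness` (Inf), `iteration` (0).
#' @export
init_population <- function(params, d) {
  stopifnot(inherits(params, "eo_params"))
  if (d < 1) stop("d must be >= 1")
  pos <- matrix(0, params$pop_size, d)
  for (i in seq_len(params$pop_size))
    pos[i, ] <- params$lower + (params$upper - params$lower) * stats::runif(d)
  structure(list(positions = pos,
                 fitness = rep(NA_real_, params$pop_size),
                 best_position = NULL, best_fitness = Inf,
                 iteration = 0L),
            class = "population")
}

evaluate_population <- function(pop, fitness_fn) {
  for (i in seq_len(nrow(pop$positions))) {
    if (is.na(pop$fitness[i])) pop$fitness[i] <- fitness_fn(pop$positions[i, ])
    if (pop$fitness[i] < pop$best_fitness) {
      pop$best_fitness <- pop$fitness[i]
      pop$best_position <- pop$positions[i, ]
    }
  }
  pop
}

#' Binarize a continuous position into a feature mask
#'
#' Positions at or above `tau` select their feature; an all-below-threshold
#' position falls back to the single largest component so the mask is never
#' empty.
#'
#' @param position numeric vector.
#' @param tau threshold.
#' @return a logical vector of the same length.
#' @export
position_to_mask <- function(position, tau = 0.5) {
  mask <- position >= tau
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Fine-KNN wrapper fitness of a candidate position
#'
#' Binarizes the position at `tau`, keeps the masked columns, fits a
#' 1-nearest-neighbour classifier on the stratified training split and
#' returns the holdout misclassification rate (0 is best). Deterministic
#' given the protocol seed; the global RNG stream is left untouched.
#'
#' @param position numeric vector, one entry per feature.
#' @param X a [feature_matrix()] or numeric matrix.
#' @param y class labels (at least 2 classes).
#' @param protocol a [fitness_protocol()].
#' @param tau binarization threshold.
#' @return misclassification rate in \[0, 1\].
#' @export
knn_fitness <- function(position, X, y, protocol = fitness_protocol(),
                        tau = 0.5) {
  if (inherits(X, "feature_matrix")) X <- X$values
  y <- factor(y)
  if (nlevels(y) < 2) stop("fitness protocol requires at least 2 classes")
  mask <- position_to_mask(position, tau)
  split <- holdout_split(length(y), y, protocol)
  Xtr <- X[split$train, mask, drop = FALSE]
  Xte <- X[split$test, mask, drop = FALSE]
  pred <- class::knn(Xtr, Xte, y[split$train], k = protocol$k_neighbors)
  mean(pred != y[split$test])
}

# Deterministic stratified holdout indices from the protocol seed.
holdout_split <- function(n, y, protocol) {
  with_seed(protocol$seed, {
    test <- integer(0)
    if (protocol$stratified) {
      for (lev in levels(y)) {
        idx <- which(y == lev)
        ntest <- max(1L, round(protocol$holdout_fraction * length(idx)))
        test <- c(test, sample(idx, ntest))
      }
    } else {
      test <- sample.int(n, max(1L, round(protocol$holdout_fraction * n)))
    }
    list(train = setdiff(seq_len(n), test), test = sort(test))
  })
}

#' Equilibrium pool of a population
#'
#' The four lowest-fitness particles (ties broken by particle index) plus
#' their positionwise arithmetic mean, sorted ascending by fitness.
#'
#' @param pop an evaluated `population`.
#' @return a list of class `equilibrium_pool` with `positions` (5 x d:
#'   four best then the average), `fitness` (length 4).
#' @export
equilibrium_pool <- function(pop) {
  if (anyNA(pop$fitness)) stop("population fitness not fully evaluated")
  ord <- order(pop$fitness)[1:4]
  four <- pop$positions[ord, , drop = FALSE]
  pos <- rbind(four, colMeans(four))
  dimnames(pos) <- NULL
  structure(list(positions = pos, fitness = pop$fitness[ord]),
            class = "equilibrium_pool")
}

#' One Equilibrium Optimizer step
#'
#' For each particle, in order: draw the turnover vector `lambda` and the
#' sign vector source `r` (d uniforms each), pick one of the five pool
#' candidates uniformly, then draw `v1`, `v2` for the generation-rate gate.
#' The time coefficient is `t = (1 - iter/ITmax)^(a2 * iter/ITmax)`; the
#' exponential term is `F = a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)`
#' (the closed form of `exp(-lambda (t - t0))` with the standard `t0`);
#' the generation rate is `G = GCP * (C_eq - lambda * C) * F` with
#' `GCP = gcp_scale * v1` when the gate fires, else 0. The new position is
#' `C_eq + (C - C_eq) * F + (G / lambda) * (1 - F)` (unit control volume),
#' clipped to the bounds, then re-evaluated; the incumbent best is updated.
#'
#' @param pop an evaluated `population`.
#' @param pool an [equilibrium_pool()].
#' @param iter 0-based iteration index.
#' @param params an [eo_params()].
#' @param fitness_fn function mapping a position vector to a fitness value.
#' @return the updated `population`.
#' @export
eo_step <- function(pop, pool, iter, params, fitness_fn) {
  d <- ncol(pop$positions)
  t <- eo_time_coefficient(iter, params)
  for (i in seq_len(nrow(pop$positions))) {
    lambda <- stats::runif(d)
    r <- stats::runif(d)
    cand <- sample.int(5L, 1L)
    v1 <- stats::runif(1)
    v2 <- stats::runif(1)
    C <- pop$positions[i, ]
    Ceq <- pool$positions[cand, ]
    F <- params$a1 * sign(r - 0.5) * (exp(-lambda * t) - 1)
    gate <- if (params$gcp_condition == "v2_ge_gp") v2 >= params$gp
            else v1 * v2 > params$gp
    GCP <- if (gate) params$gcp_scale * v1 else 0
    G0 <- GCP * (Ceq - lambda * C)
    G <- G0 * F
    Cnew <- Ceq + (C - Ceq) * F + (G / lambda) * (1 - F)
    Cnew <- pmin(pmax(Cnew, params$lower), params$upper)
    pop$positions[i, ] <- Cnew
    pop$fitness[i] <- fitness_fn(Cnew)
    if (pop$fitness[i] < pop$best_fitness) {
      pop$best_fitness <- pop$fitness[i]
      pop$best_position <- Cnew
    }
  }
  pop
}

#' Equilibrium Optimizer time coefficient
#'
#' `t = (1 - iter/ITmax)^(a2 * iter/ITmax)`: equals 1 at iteration 0 and
#' decays towards 0 as the budget is spent, shifting the search from
#' exploration to exploitation.
#'
#' @param iter 0-based iteration index.
#' @param params an [eo_params()].
#' @return a scalar in \[0, 1\].
#' @export
eo_time_coefficient <- function(iter, params) {
  (1 - iter / params$max_iters)^(params$a2 * iter / params$max_iters)
}

#' One Jaya refinement step with greedy acceptance
#'
#' With the population best and worst fixed at entry, each particle moves
#' as `V' = V + z1 * (V_best - V) - z2 * (V_worst - V)` with `z1`, `z2`
#' uniform per dimension (d draws each, consumed per particle in order);
#' the move is kept only when its fitness is not worse, so the population
#' best never degrades.
#'
#' @param pop an evaluated `population`.
#' @param params an [eo_params()].
#' @param fitness_fn function mapping a position vector to a fitness value.
#' @return the updated `population`.
#' @export
jaya_step <- function(pop, params, fitness_fn) {
  if (anyNA(pop$fitness)) stop("population fitness not fully evaluated")
  d <- ncol(pop$positions)
  ib <- which.min(pop$fitness)
  iw <- which.max(pop$fitness)
  Vbest <- pop$positions[ib, ]
  Vworst <- pop$positions[iw, ]
  for (i in seq_len(nrow(pop$positions))) {
    z1 <- stats::runif(d)
    z2 <- stats::runif(d)
    V <- pop$positions[i, ]
    Vref <- if (params$jaya_abs) abs(V) else V
    Vp <- V + z1 * (Vbest - Vref) - z2 * (Vworst - Vref)
    Vp <- pmin(pmax(Vp, params$lower), params$upper)
    fp <- fitness_fn(Vp)
    if (fp <= pop$fitness[i]) {
      pop$positions[i, ] <- Vp
      pop$fitness[i] <- fp
      if (fp < pop$best_fitness) {
        pop$best_fitness <- fp
        pop$best_position <- Vp
      }
    }
  }
  pop
}

#' Regula Falsi (false position) root estimate
#'
#' `x0 - f0 * (x1 - x0) / (f1 - f0)`; exact for linear functions.
#'
#' @param x0,x1 abscissae.
#' @param f0,f1 function values at `x0`, `x1` (must differ).
#' @return the secant root estimate.
#' @export
regula_falsi <- function(x0, x1, f0, f1) {
  if (f0 == f1) stop("degenerate secant: f0 == f1")
  x0 - f0 * (x1 - x0) / (f1 - f0)
}

#' Convergence test over the best-fitness history
#'
#' Let `g(i) = history(i-1) - history(i)` be the per-iteration improvement.
#' Termination fires when (a) the last `rf_window` improvements are all
#' below `rf_tol` (reason `"stall"`); or (b) the two most recent
#' improvements are strictly decreasing and the Regula Falsi root of the
#' improvement line — the iteration at which improvement is extrapolated to
#' hit zero — is at most `iter + 1` (reason `"regula_falsi"`); or (c) the
#' iteration budget is reached (reason `"max_iters"`).
#'
#' @param history numeric vector of best fitness per iteration (element 1 =
#'   the initial population best), length `iter + 1`.
#' @param iter 0-based index of the last completed iteration.
#' @param params an [eo_params()].
#' @return list with `stop` (logical) and `reason` (`"stall"`,
#'   `"regula_falsi"`, `"max_iters"`, or `NA`).
#' @export
should_terminate <- function(history, iter, params) {
  if (length(history) != iter + 1)
    stop("history length must equal iter + 1")
  if (!params$early_stop) {
    if (iter + 1 >= params$max_iters)
      return(list(stop = TRUE, reason = "max_iters"))
    return(list(stop = FALSE, reason = NA_character_))
  }
  g <- if (length(history) >= 2) -diff(history) else numeric(0)
  if (length(g) >= params$rf_window &&
      all(utils::tail(g, params$rf_window) < params$rf_tol))
    return(list(stop = TRUE, reason = "stall"))
  if (length(g) >= 2) {
    g1 <- g[length(g) - 1L]  # improvement at iteration iter - 1
    g2 <- g[length(g)]       # improvement at iteration iter
    if (g1 > g2) {
      root <- regula_falsi(iter - 1, iter, g1, g2)
      if (root <= iter + 1 + 1e-9)
        return(list(stop = TRUE, reason = "regula_falsi"))
    }
  }
  if (iter + 1 >= params$max_iters)
    return(list(stop = TRUE, reason = "max_iters"))
  list(stop = FALSE, reason = NA_character_)
}

#' Run the hybrid Equilibrium-Jaya optimizer on an arbitrary objective
#'
#' The continuous core shared by the feature selector: initialise a seeded
#' population, then iterate pool construction, an EO move, a Jaya
#' refinement with greedy acceptance, and the Regula Falsi convergence test
#' over the best-fitness history. The incumbent best is elitist, so the
#' history is monotone non-increasing.
#'
#' @param fn objective function (position vector -> scalar, lower is
#'   better).
#' @param d dimensionality.
#' @param params an [eo_params()].
#' @return list with `best_position`, `best_fitness`, `history`
#'   (length `iterations_run + 1`, starting at the initial best),
#'   `iterations_run`, `termination`.
#' @export
ejrf_optimize <- function(fn, d, params = eo_params()) {
  with_seed(params$seed, {
    pop <- init_population(params, d)
    pop <- evaluate_population(pop, fn)
    history <- pop$best_fitness
    iter <- 0L
    reason <- "max_iters"
    if (params$max_iters < 1) {
      return(list(best_position = pop$best_position,
                  best_fitness = pop$best_fitness, history = history,
                  iterations_run = 0L, termination = "max_iters"))
    }
    jaya_phase <- params$phase_mode == "interleaved"
    repeat {
      pool <- equilibrium_pool(pop)
      pop <- eo_step(pop, pool, iter, params, fn)
      if (jaya_phase) pop <- jaya_step(pop, params, fn)
      history <- c(history, pop$best_fitness)
      term <- should_terminate(history, iter + 1L, params)
      iter <- iter + 1L
      if (term$stop) { reason <- term$reason; break }
    }
    if (params$phase_mode == "sequential") {
      # second phase: Jaya-only refinement under the same termination rule
      hist2 <- pop$best_fitness
      j <- 0L
      repeat {
        pop <- jaya_step(pop, params, fn)
        hist2 <- c(hist2, pop$best_fitness)
        history <- c(history, pop$best_fitness)
        term <- should_terminate(hist2, j + 1L, params)
        iter <- iter + 1L
        j <- j + 1L
        if (term$stop) { reason <- term$reason; break }
      }
    }
    list(best_position = pop$best_position,
         best_fitness = pop$best_fitness, history = history,
         iterations_run = iter, termination = reason)
  })
}

#' Wrapper feature selection with the Equilibrium-Jaya optimizer
#'
#' Runs [ejrf_optimize()] over continuous positions in \[lower, upper\]^d
#' with the fine-KNN holdout error of the thresholded mask as the
#' objective, and returns the binarized incumbent-best mask. Fully
#' reproducible from `params$seed`.
#'
#' @param X a [feature_matrix()] or numeric matrix with >= 2 columns.
#' @param y class labels (>= 2 classes).
#' @param params an [eo_params()].
#' @param protocol a [fitness_protocol()].
#' @return a list of class `selection_result` with `mask` (logical, >= 1
#'   TRUE), `best_position`, `history` (non-increasing), `iterations_run`,
#'   `termination`, `fitness` (best holdout error).
#' @export
select_features <- function(X, y, params = eo_params(),
                            protocol = fitness_protocol()) {
  Xm <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (ncol(Xm) < 2) stop("X must have at least 2 columns")
  y <- factor(y)
  if (nlevels(y) < 2) stop("at least 2 classes required")
  fn <- function(pos) knn_fitness(pos, Xm, y, protocol, params$binarize_tau)
  res <- ejrf_optimize(fn, ncol(Xm), params)
  mask <- position_to_mask(res$best_position, params$binarize_tau)
  structure(list(mask = mask, best_position = res$best_position,
                 history = res$history,
                 iterations_run = res$iterations_run,
                 termination = res$termination,
                 fitness = res$best_fitness),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result: %d/%d features, holdout error ",
                     "%.4f, %d iterations, termination: %s>\n"),
              sum(x$mask), length(x$mask), x$fitness, x$iterations_run,
              x$termination))
  invisible(x)
}
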