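sphere <- function(x) sum(x^2)

test_that("population initialisation is seeded, bounded and uniform-stream", {
  p <- eo_params(pop_size = 20, seed = 0)
  pop1 <- with_seed(0, init_population(p, 10))
  pop2 <- with_seed(0, init_population(p, 10))
  expect_identical(pop1$positions, pop2$positions)
  expect_true(all(pop1$positions >= 0 & pop1$positions <= 1))

  # matches an independently seeded uniform stream, row by row
  oracle <- with_seed(0, t(sapply(1:20, function(i) runif(10))))
  expect_equal(pop1$positions, oracle, ignore_attr = TRUE)

  pd <- eo_params(pop_size = 5, lower = 0.5, upper = 0.5)
  popd <- init_population(pd, 4)
  expect_true(all(popd$positions == 0.5))
  expect_error(eo_params(pop_size = 4), "pop_size")
})

test_that("fine-KNN fitness separates separable data and falls back safely", {
  d <- separable_data(n_per_class = 15, d_noise = 3)
  pr <- fitness_protocol(seed = 1)
  expect_equal(knn_fitness(c(1, 0, 0, 0), d$X, d$y, pr), 0)
  expect_equal(knn_fitness(rep(1, 4), d$X, d$y, pr), 0)

  # all-below-threshold position uses the top-1 fallback mask
  expect_equal(sum(position_to_mask(c(0.1, 0.4, 0.2, 0.3))), 1)
  expect_true(position_to_mask(c(0.1, 0.4, 0.2, 0.3))[2])
  expect_equal(knn_fitness(c(0.9, 0.1, 0.1, 0.1), d$X, d$y, pr),
               knn_fitness(c(0.9, 0, 0, 0), d$X, d$y, pr))

  expect_error(knn_fitness(c(1, 1, 1, 1), d$X, rep("a", 30), pr),
               "2 classes")
})

test_that("random labels give chance-level fitness", {
  errs <- sapply(1:20, function(seed) {
    set.seed(seed + 100)
    X <- matrix(rnorm(100 * 5), 100)
    y <- factor(sample(rep(c("a", "b"), 50)))
    knn_fitness(rep(1, 5), X, y, fitness_protocol(seed = seed))
  })
  expect_true(all(abs(errs - 0.5) <= 0.2))
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("equilibrium pool holds the four best plus their average", {
  p <- eo_params(pop_size = 5)
  pop <- init_population(p, 3)
  pop$positions <- matrix(seq(0.1, 1.5, length.out = 15), 5, 3)
  pop$fitness <- c(0.3, 0.1, 0.9, 0.2, 0.4)
  pool <- equilibrium_pool(pop)
  expect_equal(pool$fitness, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(pool$positions[1, ], pop$positions[2, ])
  expect_equal(pool$positions[5, ], colMeans(pop$positions[c(2, 4, 1, 5), ]))

  pop$fitness <- rep(0.5, 5)  # degenerate: ties broken by index
  pool <- equilibrium_pool(pop)
  expect_equal(pool$positions[1:4, ], pop$positions[1:4, ])

  pop$fitness[2] <- NA
  expect_error(equilibrium_pool(pop), "not fully evaluated")
})

test_that("EO step matches a straight-line transcription oracle", {
  for (seed in c(0, 1, 2)) {
    p <- eo_params(pop_size = 5, seed = seed)
    pop <- with_seed(seed, init_population(p, 3))
    pop$fitness <- c(0.5, 0.2, 0.8, 0.1, 0.4)
    pool <- equilibrium_pool(pop)
    got <- with_seed(seed + 50,
                     eo_step(pop, pool, 2, p, function(x) sum(x)))
    want <- with_seed(seed + 50,
                      oracle_eo_step_positions(pop$positions,
                                               pool$positions, 2, p))
    expect_equal(got$positions, want)
    expect_true(all(got$positions >= 0 & got$positions <= 1))
  }
})

test_that("EO step at iteration 0 has unit time coefficient and relaxes
          toward the pool candidate when the generation term is off", {
  p <- eo_params(pop_size = 5, gcp_scale = 0)
  expect_equal(eo_time_coefficient(0, p), 1)
  pop <- with_seed(3, init_population(p, 4))
  pop$fitness <- rep(0.5, 5)
  # degenerate pool: every candidate is the same point
  pool <- equilibrium_pool(pop)
  for (k in 1:5) pool$positions[k, ] <- pop$positions[1, ]
  # the particle sitting at the candidate is a fixed point
  pop2 <- with_seed(4, eo_step(pop, pool, 0, p, function(x) 0.5))
  expect_equal(pop2$positions[1, ], pop$positions[1, ])
  # closed-form relaxation: C_new = C_eq + (C - C_eq) * F (clipped)
  Ceq <- pop$positions[1, ]
  want <- with_seed(4, {
    out <- pop$positions
    for (i in 1:5) {
      lambda <- runif(4); r <- runif(4); sample.int(5, 1); runif(2)
      F <- p$a1 * sign(r - 0.5) * (exp(-lambda * 1) - 1)
      out[i, ] <- pmin(pmax(Ceq + (pop$positions[i, ] - Ceq) * F, 0), 1)
    }
    out
  })
  expect_equal(pop2$positions, want)
})

test_that("Jaya step is greedy and respects its fixed points", {
  p <- eo_params(pop_size = 5, lower = -1, upper = 1)
  pop <- with_seed(5, init_population(p, 2))
  # degenerate: best = worst = everyone
  pop$positions <- matrix(0.3, 5, 2)
  pop$fitness <- rep(sphere(c(0.3, 0.3)), 5)
  pop$best_fitness <- pop$fitness[1]
  pop$best_position <- pop$positions[1, ]
  pop2 <- with_seed(6, jaya_step(pop, p, sphere))
  expect_equal(pop2$positions, pop$positions)

  # hand-stepped oracle on a quadratic objective with greedy acceptance
  pop <- with_seed(7, init_population(p, 1))
  pop$fitness <- apply(pop$positions, 1, sphere)
  pop$best_fitness <- min(pop$fitness)
  pop$best_position <- pop$positions[which.min(pop$fitness), ]
  got <- with_seed(8, jaya_step(pop, p, sphere))
  want_pos <- with_seed(8, {
    ib <- which.min(pop$fitness); iw <- which.max(pop$fitness)
    out <- pop$positions; fit <- pop$fitness
    for (i in 1:5) {
      z1 <- runif(1); z2 <- runif(1)
      V <- pop$positions[i, ]
      Vp <- V + z1 * (pop$positions[ib, ] - V) -
        z2 * (pop$positions[iw, ] - V)
      Vp <- pmin(pmax(Vp, -1), 1)
      if (sphere(Vp) <= fit[i]) { out[i, ] <- Vp; fit[i] <- sphere(Vp) }
    }
    out
  })
  expect_equal(got$positions, want_pos)
  expect_lte(min(got$fitness), min(pop$fitness))
})

test_that("Regula Falsi is exact on lines and rejects flat secants", {
  expect_equal(regula_falsi(0, 3, -4, 2), 2)       # f(x) = 2x - 4
  expect_equal(regula_falsi(1, 3, -3, 5), 1.75)    # f(x) = x^2 - 4
  expect_error(regula_falsi(0, 1, 2, 2), "degenerate")
})

test_that("termination fires on stalls, improvement collapse and budget", {
  p <- eo_params(rf_tol = 1e-4, rf_window = 3, max_iters = 50)
  # constant history stalls once the window fills
  h <- rep(0.5, 4)
  expect_equal(should_terminate(h, 3, p)$reason, "stall")
  expect_false(should_terminate(rep(0.5, 3), 2, p)$stop)

  # improvements 0.10 then 0.05: root of the improvement line = iter + 1
  h <- c(0.50, 0.40, 0.35)
  out <- should_terminate(h, 2, p)
  expect_true(out$stop)
  expect_equal(out$reason, "regula_falsi")

  # healthy constant improvement runs to the budget
  p2 <- eo_params(max_iters = 5, rf_tol = 1e-4, rf_window = 3)
  h <- seq(1, by = -0.1, length.out = 4)
  expect_false(should_terminate(h, 3, p2)$stop)
  h <- seq(1, by = -0.1, length.out = 5)
  expect_equal(should_terminate(h, 4, p2)$reason, "max_iters")

  expect_error(should_terminate(c(1, 0.9), 3, p), "length")

  # early_stop = FALSE leaves only the budget rule
  p3 <- eo_params(max_iters = 10, early_stop = FALSE)
  expect_false(should_terminate(c(0.5, 0.4, 0.35), 2, p3)$stop)
})

test_that("optimizer is reproducible, bounded and monotone", {
  p <- eo_params(pop_size = 8, max_iters = 10, seed = 3, lower = -1,
                 upper = 1)
  r1 <- ejrf_optimize(sphere, 4, p)
  r2 <- ejrf_optimize(sphere, 4, p)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) <= 0))
  expect_true(all(abs(r1$best_position) <= 1))
  expect_equal(length(r1$history), r1$iterations_run + 1)

  # sequential phase mode also runs and improves monotonically
  ps <- eo_params(pop_size = 8, max_iters = 8, seed = 3, lower = -1,
                  upper = 1, phase_mode = "sequential")
  rs <- ejrf_optimize(sphere, 4, ps)
  expect_true(all(diff(rs$history) <= 0))
})

test_that("selection finds a perfectly separating column", {
  d <- separable_data(n_per_class = 15, d_noise = 10, seed = 0)
  p <- eo_params(pop_size = 10, max_iters = 15, seed = 0)
  sel <- select_features(d$X, d$y, p, fitness_protocol(seed = 0))
  expect_equal(sel$fitness, 0)
  expect_true(sel$mask[1])
  expect_true(all(diff(sel$history) <= 0))
})

test_that("selection reduces width and reproduces from its seed", {
  for (seed in 0:2) {
    s <- make_synthetic_features(tabular_synthesis_spec(seed = seed))
    sel <- select_features(s$features, s$labels,
                           eo_params(seed = seed, max_iters = 15),
                           fitness_protocol(seed = seed))
    expect_lt(sum(sel$mask), ncol(s$features$values))
    expect_gte(sum(sel$mask), 1)
  }
  s <- make_synthetic_features(tabular_synthesis_spec(seed = 0))
  a <- select_features(s$features, s$labels, eo_params(seed = 5),
                       fitness_protocol(seed = 5))
  b <- select_features(s$features, s$labels, eo_params(seed = 5),
                       fitness_protocol(seed = 5))
  expect_identical(a$mask, b$mask)
  expect_identical(a$history, b$history)
})
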