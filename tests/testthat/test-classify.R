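test_that("stratified 50/50 split keeps class proportions", {
  set.seed(1)
  X <- matrix(rnorm(200), 100)
  y <- rep(c("a", "b"), each = 50)
  sp <- split_protocol(X, y, seed = 0)
  expect_equal(as.vector(table(y[sp$train])), c(25, 25))
  expect_equal(as.vector(table(y[sp$test])), c(25, 25))
  expect_identical(sp, split_protocol(X, y, seed = 0))

  y2 <- rep(c("a", "b"), c(51, 50))
  X2 <- matrix(rnorm(202), 101)
  sp2 <- split_protocol(X2, y2, seed = 0)
  expect_equal(length(sp2$train), 51)
  expect_equal(length(sp2$test), 50)
  tab <- table(y2[sp2$train]) / length(sp2$train) -
    table(y2) / length(y2)
  expect_true(all(abs(tab) < 1 / length(sp2$train) + 1e-9))

  expect_error(split_protocol(X2, c("a", rep("b", 100)), 0), "at least 2")
})

test_that("classifiers are perfect on separable data and degrade gracefully", {
  d <- separable_data(n_per_class = 20, d_noise = 2, seed = 3)
  sp <- split_protocol(d$X, d$y, seed = 0)
  for (name in c("fine_knn", "weighted_knn", "linear_svm", "narrow_nn")) {
    ts <- train_and_score(classifier_spec(name), d$X, d$y, sp, seed = 0)
    expect_equal(sum(ts$confusion) - sum(diag(ts$confusion)), 0,
                 info = name)
  }
  # constant features predict a single class
  Xc <- matrix(1, 40, 3)
  ts <- train_and_score(classifier_spec("fine_knn"), Xc, d$y, sp, seed = 0)
  expect_equal(sum(colSums(ts$confusion) > 0), 1)

  expect_error(classifier_spec("my_svm"), "unknown")
})

test_that("fine KNN is accurate on the synthetic tabular fixture", {
  accs <- vapply(0:4, function(seed) {
    s <- make_synthetic_features(tabular_synthesis_spec(seed = seed))
    sp <- split_protocol(s$features, s$labels, seed = seed)
    ts <- train_and_score(classifier_spec("fine_knn"), s$features,
                          s$labels, sp, seed = seed)
    sum(diag(ts$confusion)) / sum(ts$confusion)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
  expect_gte(min(accs), 0.85)
})

test_that("macro metrics reproduce hand-computed confusion arithmetic", {
  cm <- matrix(c(9, 2, 1, 8), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$sensitivity_pct, 85.0)
  expect_equal(rep$precision_pct, mean(c(9 / 11, 8 / 9)) * 100,
               tolerance = 1e-9)
  expect_equal(rep$accuracy_pct, 85.0)
  expect_equal(rep$fnr_pct, 15.0)
  expect_equal(rep$f1_pct,
               2 * rep$sensitivity_pct * rep$precision_pct /
                 (rep$sensitivity_pct + rep$precision_pct))

  perfect <- diag(c(10, 15))
  rp <- metrics_from_confusion(perfect)
  expect_equal(rp$sensitivity_pct, 100)
  expect_equal(rp$precision_pct, 100)
  expect_equal(rp$f1_pct, 100)
  expect_equal(rp$fnr_pct, 0)
  expect_equal(rp$accuracy_pct, 100)
})

test_that("metrics are invariant to class renaming and warn on absent classes", {
  cm <- matrix(c(7, 3, 2, 8), 2, 2, dimnames = list(1:2, 1:2))
  cm2 <- cm[2:1, 2:1]
  r1 <- metrics_from_confusion(cm)
  r2 <- metrics_from_confusion(cm2)
  expect_equal(r1$sensitivity_pct, r2$sensitivity_pct)
  expect_equal(r1$precision_pct, r2$precision_pct)

  cm3 <- matrix(c(5, 0, 1, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_warning(metrics_from_confusion(cm3), "absent")
})

test_that("rank AUC agrees with the reference implementation", {
  set.seed(9)
  truth <- factor(rep(c("neg", "pos"), each = 25))
  scores <- rnorm(50) + (truth == "pos") * 1.2
  scores[c(3, 30)] <- scores[c(4, 31)]  # inject ties
  got <- mammofuse:::rank_auc(scores, truth == "pos")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("worked F1 and FNR arithmetic matches the reporting convention", {
  expect_equal(round(f1_from_rates(95.4, 95.35), 2), 95.37)
  expect_equal(fnr_from_sensitivity(99.4), 0.6)
})

test_that("benchmark table is deterministic with sane invariants", {
  s <- make_synthetic_features(tabular_synthesis_spec(
    n_samples = 60, d_informative = 4, d_redundant = 2, d_noise = 6,
    seed = 1))
  roster <- c("fine_knn", "weighted_knn", "linear_svm", "quadratic_svm",
              "medium_gaussian_svm", "narrow_nn", "bilayer_nn",
              "ensemble_subspace_knn", "ensemble_bagged_trees")
  tab <- run_benchmark(s$features, s$labels, roster, seed = 0)
  expect_equal(nrow(tab), length(roster))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  expect_equal(tab$fnr + tab$sensitivity, rep(100, nrow(tab)))
  expect_true(all(diff(tab$accuracy) <= 0))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))

  tab2 <- run_benchmark(s$features, s$labels, roster, seed = 0)
  expect_equal(tab$accuracy, tab2$accuracy)
  expect_equal(tab$f1, tab2$f1)

  one <- run_benchmark(s$features, s$labels, "fine_knn", seed = 0)
  expect_equal(nrow(one), 1)
})
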