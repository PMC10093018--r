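#' Specify a classifier from the benchmark roster
#'
#' The roster mirrors the conventional "fine/medium/wide" preset families:
#' fine KNN (k = 1, Euclidean), weighted KNN (k = 10, inverse-distance
#' votes), an ensemble of 30 subspace 1-NN learners on random halves of the
#' features, linear/quadratic/cubic polynomial and medium-Gaussian SVMs
#' (kernel scale sqrt(d)), single-hidden-layer neural networks of 10/25/100
#' units (narrow/medium/wide), two- and three-layer 10-unit networks, and
#' 30 bagged trees. Features are standardised with training-half statistics
#' before SVM and neural-network fits; KNN variants use raw features.
#'
#' @param name roster name; see Details.
#' @param ... hyperparameter overrides (`k`, `n_learners`, `hidden`,
#'   `ntree`, `maxit`, `decay`).
#' @return a list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, ...) {
  roster <- classifier_roster()
  if (!name %in% roster) stop("unknown classifier: ", name)
  defaults <- switch(name,
    fine_knn = list(k = 1L),
    weighted_knn = list(k = 10L),
    ensemble_subspace_knn = list(k = 1L, n_learners = 30L),
    linear_svm = list(kernel = "linear"),
    quadratic_svm = list(kernel = "polynomial", degree = 2L),
    cubic_svm = list(kernel = "polynomial", degree = 3L),
    medium_gaussian_svm = list(kernel = "radial"),
    narrow_nn = list(hidden = 10L, maxit = 300L, decay = 1e-4),
    medium_nn = list(hidden = 25L, maxit = 300L, decay = 1e-4),
    wide_nn = list(hidden = 100L, maxit = 300L, decay = 1e-4),
    bilayer_nn = list(hidden = c(10L, 10L), maxit = 300L, decay = 1e-4),
    trilayer_nn = list(hidden = c(10L, 10L, 10L), maxit = 300L, decay = 1e-4),
    ensemble_bagged_trees = list(ntree = 30L)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyperparameters = hp),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
classifier_roster <- function() {
  c("fine_knn", "weighted_knn", "ensemble_subspace_knn", "linear_svm",
    "quadratic_svm", "cubic_svm", "medium_gaussian_svm", "narrow_nn",
    "medium_nn", "wide_nn", "bilayer_nn", "trilayer_nn",
    "ensemble_bagged_trees")
}

#' Stratified 50/50 train/test split
#'
#' Each class is split in half (the training half takes the ceiling for
#' odd class sizes), so class proportions in either half are within one
#' sample of the full data. Any internal model selection is expected to
#' cross-validate inside the training half; final metrics come from the
#' untouched test half.
#'
#' @param X a [feature_matrix()] or matrix.
#' @param y class labels, at least 2 samples per class.
#' @param seed RNG seed for the shuffle.
#' @param train_fraction training share (default 0.5).
#' @return list with integer index vectors `train`, `test`.
#' @export
split_protocol <- function(X, y, seed = 0L, train_fraction = 0.5) {
  y <- factor(y)
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  with_seed(seed, {
    train <- integer(0)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      ntr <- ceiling(train_fraction * length(idx))
      train <- c(train, sample(idx, ntr))
    }
    list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
  })
}

# Distance-based KNN with optional inverse-distance weighting; returns
# predicted labels and per-class vote scores.
knn_predict <- function(Xtr, ytr, Xte, k = 1L, weighted = FALSE) {
  ytr <- factor(ytr)
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  d2 <- pmax(d2, 0)
  lev <- levels(ytr)
  scores <- matrix(0, nrow(Xte), length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(nrow(Xte))) {
    ord <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
    w <- if (weighted) 1 / (sqrt(d2[i, ord]) + 1e-8) else rep(1, length(ord))
    for (j in seq_along(ord)) {
      cl <- as.character(ytr[ord[j]])
      scores[i, cl] <- scores[i, cl] + w[j]
    }
    scores[i, ] <- scores[i, ] / sum(scores[i, ])
  }
  pred <- factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  list(pred = pred, scores = scores)
}

# Minimal multi-hidden-layer perceptron (tanh hidden, softmax output)
# trained with BFGS on the cross-entropy loss; used for the two- and
# three-layer roster entries, which single-hidden-layer fitters cannot
# express.
mlp_fit <- function(X, y, hidden, decay = 1e-4, maxit = 300L) {
  y <- factor(y)
  K <- nlevels(y)
  sizes <- c(ncol(X), hidden, K)
  nw <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  unpack <- function(w) {
    out <- list(); pos <- 0L
    for (l in seq_len(length(sizes) - 1L)) {
      nin <- sizes[l] + 1L; nout <- sizes[l + 1L]
      out[[l]] <- matrix(w[pos + seq_len(nin * nout)], nin, nout)
      pos <- pos + nin * nout
    }
    out
  }
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  fwd <- function(W) {
    acts <- list(X)
    a <- X
    for (l in seq_along(W)) {
      z <- cbind(1, a) %*% W[[l]]
      a <- if (l < length(W)) tanh(z) else z
      acts[[l + 1L]] <- a
    }
    zs <- acts[[length(acts)]]
    zs <- zs - apply(zs, 1, max)
    P <- exp(zs) / rowSums(exp(zs))
    list(acts = acts, P = P)
  }
  loss <- function(w) {
    W <- unpack(w)
    f <- fwd(W)
    -sum(Y * log(pmax(f$P, 1e-12))) / nrow(X) +
      decay * sum(w^2)
  }
  grad <- function(w) {
    W <- unpack(w)
    f <- fwd(W)
    delta <- (f$P - Y) / nrow(X)
    gl <- vector("list", length(W))
    for (l in rev(seq_along(W))) {
      a_in <- cbind(1, f$acts[[l]])
      gl[[l]] <- t(a_in) %*% delta
      if (l > 1L) {
        back <- delta %*% t(W[[l]][-1L, , drop = FALSE])
        delta <- back * (1 - f$acts[[l]]^2)
      }
    }
    unlist(gl) + 2 * decay * w
  }
  w0 <- stats::runif(nw, -0.5, 0.5)
  opt <- stats::optim(w0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  structure(list(W = unpack(opt$par), levels = levels(y)), class = "mf_mlp")
}

mlp_predict <- function(model, X) {
  a <- X
  for (l in seq_along(model$W)) {
    z <- cbind(1, a) %*% model$W[[l]]
    a <- if (l < length(model$W)) tanh(z) else z
  }
  z <- a - apply(a, 1, max)
  P <- exp(z) / rowSums(exp(z))
  colnames(P) <- model$levels
  pred <- factor(model$levels[max.col(P, ties.method = "first")],
                 levels = model$levels)
  list(pred = pred, scores = P)
}

#' Train a classifier and score the test half
#'
#' Fits the given roster classifier on the training rows and returns the
#' confusion matrix plus continuous class scores (class probabilities or
#' decision values) on the test rows. Deterministic given `seed`.
#'
#' @param spec a [classifier_spec()].
#' @param X a [feature_matrix()] or matrix.
#' @param y class labels.
#' @param split a list with `train`/`test` indices
#'   (see [split_protocol()]).
#' @param seed RNG seed for any stochastic fit.
#' @return list with `confusion` (K x K table, rows = truth), `scores`
#'   (matrix of per-class scores on the test rows), `pred`, `truth`.
#' @export
train_and_score <- function(spec, X, y, split, seed = 0L) {
  stopifnot(inherits(spec, "classifier_spec"))
  Xm <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  y <- factor(y)
  hp <- spec$hyperparameters
  Xtr <- Xm[split$train, , drop = FALSE]
  Xte <- Xm[split$test, , drop = FALSE]
  ytr <- droplevels(y[split$train])
  yte <- y[split$test]
  needs_scaling <- grepl("svm|nn$", spec$name)
  if (needs_scaling) {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- scale(Xte, mu, sdv)
  }
  res <- with_seed(seed, {
    switch(spec$name,
      fine_knn = knn_predict(Xtr, ytr, Xte, k = hp$k),
      weighted_knn = knn_predict(Xtr, ytr, Xte, k = hp$k, weighted = TRUE),
      ensemble_subspace_knn = {
        d <- ncol(Xtr)
        lev <- levels(ytr)
        votes <- matrix(0, nrow(Xte), length(lev),
                        dimnames = list(NULL, lev))
        for (b in seq_len(hp$n_learners)) {
          cols <- sample.int(d, max(1L, ceiling(d / 2)))
          p <- knn_predict(Xtr[, cols, drop = FALSE], ytr,
                           Xte[, cols, drop = FALSE], k = hp$k)
          votes <- votes + p$scores
        }
        votes <- votes / hp$n_learners
        list(pred = factor(lev[max.col(votes, ties.method = "first")],
                           levels = lev),
             scores = votes)
      },
      linear_svm = ,
      quadratic_svm = ,
      cubic_svm = ,
      medium_gaussian_svm = {
        gam <- 1 / ncol(Xtr)  # kernel scale sqrt(d)
        args <- list(x = Xtr, y = ytr, kernel = hp$kernel, gamma = gam,
                     probability = TRUE, scale = FALSE)
        if (!is.null(hp$degree)) { args$degree <- hp$degree; args$coef0 <- 1 }
        fit <- do.call(e1071::svm, args)
        pr <- stats::predict(fit, Xte, probability = TRUE)
        sc <- attr(pr, "probabilities")[, levels(ytr), drop = FALSE]
        list(pred = factor(as.character(pr), levels = levels(ytr)),
             scores = sc)
      },
      narrow_nn = ,
      medium_nn = ,
      wide_nn = {
        fit <- nnet::nnet(Xtr, class.ind(ytr), size = hp$hidden,
                          decay = hp$decay, maxit = hp$maxit,
                          softmax = TRUE, trace = FALSE,
                          MaxNWts = 1e5)
        sc <- stats::predict(fit, Xte)
        colnames(sc) <- levels(ytr)
        list(pred = factor(levels(ytr)[max.col(sc, ties.method = "first")],
                           levels = levels(ytr)),
             scores = sc)
      },
      bilayer_nn = ,
      trilayer_nn = {
        fit <- mlp_fit(Xtr, ytr, hidden = hp$hidden, decay = hp$decay,
                       maxit = hp$maxit)
        mlp_predict(fit, Xte)
      },
      ensemble_bagged_trees = {
        fit <- randomForest::randomForest(Xtr, ytr, ntree = hp$ntree,
                                          mtry = ncol(Xtr))
        sc <- stats::predict(fit, Xte, type = "prob")[, levels(ytr),
                                                      drop = FALSE]
        list(pred = stats::predict(fit, Xte), scores = sc)
      }
    )
  })
  pred <- factor(as.character(res$pred), levels = levels(y))
  confusion <- table(truth = yte, predicted = pred)
  scores <- matrix(0, length(yte), nlevels(y),
                   dimnames = list(NULL, levels(y)))
  scores[, colnames(res$scores)] <- res$scores
  list(confusion = confusion, scores = scores, pred = pred, truth = yte)
}

class.ind <- function(y) {
  y <- factor(y)
  m <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  colnames(m) <- levels(y)
  m
}

#' Benchmark a roster of classifiers
#'
#' Splits the data with [split_protocol()], trains every roster entry on
#' the same training half and reports one metrics row per classifier plus
#' wall-clock seconds, sorted by accuracy (descending).
#'
#' @param X a [feature_matrix()] or matrix.
#' @param y class labels.
#' @param roster character vector of roster names or list of
#'   [classifier_spec()]s (default: the full roster).
#' @param seed RNG seed for split and fits.
#' @return a data.frame with columns classifier, sensitivity, precision,
#'   f1, auc, accuracy, fnr, seconds.
#' @export
run_benchmark <- function(X, y, roster = classifier_roster(), seed = 0L) {
  if (!length(roster)) stop("roster must be non-empty")
  specs <- lapply(roster, function(s)
    if (inherits(s, "classifier_spec")) s else classifier_spec(s))
  split <- split_protocol(X, y, seed = seed)
  rows <- lapply(specs, function(sp) {
    t0 <- proc.time()[["elapsed"]]
    ts <- train_and_score(sp, X, y, split, seed = seed)
    rep <- metrics_from_confusion(ts$confusion, scores = ts$scores,
                                  truth = ts$truth)
    data.frame(classifier = sp$name,
               sensitivity = rep$sensitivity_pct,
               precision = rep$precision_pct, f1 = rep$f1_pct,
               auc = rep$auc, accuracy = rep$accuracy_pct,
               fnr = rep$fnr_pct,
               seconds = proc.time()[["elapsed"]] - t0)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy), , drop = FALSE]
}
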