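#' Construct a feature matrix
#'
#' Samples x features table with per-row labels and per-column identifiers;
#' the common currency between the extraction, fusion, selection and
#' classification stages.
#'
#' @param values numeric matrix (rows = samples).
#' @param labels optional vector of class labels, length `nrow(values)`.
#' @param feature_ids optional character vector of column identifiers;
#'   defaults to existing column names or `f1..fd`.
#' @return a list of class `feature_matrix` with elements `values`,
#'   `labels`, `feature_ids`.
#' @export
feature_matrix <- function(values, labels = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids))
      feature_ids <- as.character(sprintf("f%d", seq_len(ncol(values))))
  }
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length must equal column count")
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("labels length must equal row count")
  colnames(values) <- feature_ids
  structure(list(values = values, labels = labels,
                 feature_ids = feature_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' Write/read a feature matrix as CSV
#'
#' Header row holds the feature identifiers plus a final `label` column;
#' row order is sample order.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (write); a [feature_matrix()] (read).
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df$label <- if (is.null(fm$labels)) NA else as.character(fm$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV lacks a label column")
  labels <- df$label
  df$label <- NULL
  if (all(is.na(labels))) labels <- NULL
  feature_matrix(as.matrix(df), labels = labels, feature_ids = names(df))
}

#' Describe a feature extractor
#'
#' Two kinds exist: `"filterbank"`, a deterministic oriented band-pass
#' texture descriptor computable on any machine, and
#' `"pretrained_backbone"`, the contract for a deep convolutional feature
#' extractor read at its global-average-pool layer. The backbone is a
#' pluggable capability: without a supplied `forward` function,
#' [extract_features()] raises a capability error directing to the
#' filterbank.
#'
#' @param kind `"filterbank"` or `"pretrained_backbone"`.
#' @param scales,orientations,bins filterbank geometry (see
#'   [filterbank_features()]).
#' @param backbone architecture name for the pretrained kind.
#' @param layer layer the features are read from.
#' @param output_width feature width; computed automatically for both kinds.
#' @param finetune optional fine-tuning record
#'   (`learning_rate`, `momentum`, `epochs`, `optimizer`, `replaced_layers`).
#' @param forward optional function `(list of images) -> matrix` implementing
#'   the backbone forward pass (plug-in point).
#' @return a list of class `extractor_spec`.
#' @export
extractor_spec <- function(kind = c("filterbank", "pretrained_backbone"),
                           scales = 2L, orientations = 4L, bins = 8L,
                           backbone = "efficientnet-b0",
                           layer = "global_average_pool",
                           output_width = NULL, finetune = NULL,
                           forward = NULL) {
  kind <- match.arg(kind)
  if (kind == "filterbank") {
    if (scales < 1 || orientations < 1 || bins < 1)
      stop("scales, orientations and bins must be >= 1")
    output_width <- as.integer(scales * orientations * bins + 4L)
  } else if (is.null(output_width)) {
    output_width <- backbone_gap_width(backbone_config(backbone))
  }
  if (output_width <= 0) stop("output_width must be positive")
  structure(list(kind = kind, scales = as.integer(scales),
                 orientations = as.integer(orientations),
                 bins = as.integer(bins), backbone = backbone,
                 layer = layer, output_width = as.integer(output_width),
                 finetune = finetune, forward = forward),
            class = "extractor_spec")
}

#' Default fine-tuning hyperparameters for the backbone
#'
#' SGD with learning rate 0.005, momentum 0.703, 100 epochs, and the last
#' three layers replaced by fully-connected + softmax + classification
#' output.
#'
#' @param learning_rate,momentum,epochs,optimizer,replaced_layers fields of
#'   the fine-tune record.
#' @return a named list.
#' @export
finetune_record <- function(learning_rate = 0.005, momentum = 0.703,
                            epochs = 100L, optimizer = "sgdm",
                            replaced_layers = 3L) {
  list(learning_rate = learning_rate, momentum = momentum,
       epochs = as.integer(epochs), optimizer = optimizer,
       replaced_layers = as.integer(replaced_layers))
}

#' Filterbank texture features of one image
#'
#' Deterministic descriptor: the grayscale image is smoothed at `scales`
#' dyadic Gaussian scales; at each scale, directional-derivative responses
#' are taken along `orientations` evenly spaced angles; each response map is
#' standardised (zero mean, unit sd) and histogrammed into `bins` standard
#' normal quantile bins; the relative bin masses are the features, followed
#' by 4 global moments of the grayscale image (mean, sd, skewness,
#' kurtosis; skewness/kurtosis are 0 for constant images). Output length is
#' `scales * orientations * bins + 4`.
#'
#' @param image an [intensity_image()].
#' @param scales number of dyadic smoothing scales, >= 1.
#' @param orientations number of derivative orientations, >= 1.
#' @param bins number of histogram bins per filter, >= 1.
#' @return a numeric vector.
#' @export
filterbank_features <- function(image, scales = 2L, orientations = 4L,
                                bins = 8L) {
  if (scales < 1 || orientations < 1 || bins < 1)
    stop("scales, orientations and bins must be >= 1")
  g <- to_grayscale(intensity_image(im_array_any(image)))
  edges <- if (bins > 1) stats::qnorm(seq_len(bins - 1) / bins) else numeric()
  feats <- numeric(0)
  for (s in seq_len(scales)) {
    sigma <- 2^(s - 1)
    sm <- gaussian_smooth(g, sigma)
    gx <- filt_cols(sm, c(-0.5, 0, 0.5))
    gy <- filt_rows(sm, c(-0.5, 0, 0.5))
    for (o in seq_len(orientations)) {
      th <- (o - 1) * pi / orientations
      resp <- cos(th) * gx + sin(th) * gy
      sdr <- stats::sd(as.vector(resp))
      z <- if (is.na(sdr) || sdr == 0) resp * 0 else (resp - mean(resp)) / sdr
      h <- tabulate(findInterval(as.vector(z), edges) + 1L, nbins = bins)
      feats <- c(feats, h / length(z))
    }
  }
  mu <- mean(g); sdg <- stats::sd(as.vector(g))
  if (is.na(sdg)) sdg <- 0
  if (sdg > 0) {
    zc <- (g - mu) / sdg
    mom <- c(mu, sdg, mean(zc^3), mean(zc^4))
  } else mom <- c(mu, 0, 0, 0)
  c(feats, mom)
}

# Centered 1-d filtering along columns (horizontal neighbours) with
# replicate-edge padding, so constant images stay constant; k has odd
# length.
filt_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[j] * m[, idx, drop = FALSE]
  }
  out
}

filt_rows <- function(m, k) t(filt_cols(t(m), k))

gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2)); k <- k / sum(k)
  filt_rows(filt_cols(m, k), k)
}

#' Extract features from a list of images
#'
#' One row per image, exactly `spec$output_width` columns, rows in input
#' order; labels pass through untouched.
#'
#' @param images non-empty list of [intensity_image()]s.
#' @param spec an [extractor_spec()].
#' @param labels optional per-image labels.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(images, spec = extractor_spec(), labels = NULL) {
  if (!length(images)) stop("images must be non-empty")
  stopifnot(inherits(spec, "extractor_spec"))
  if (spec$kind == "pretrained_backbone") {
    if (is.null(spec$forward))
      stop("capability error: no deep-learning backbone is available; ",
           "use the filterbank extractor (extractor_spec(kind = \"filterbank\")) ",
           "or supply a forward function")
    vals <- spec$forward(images)
    if (ncol(vals) != spec$output_width)
      stop("backbone forward pass returned width ", ncol(vals),
           ", expected ", spec$output_width)
  } else {
    vals <- t(vapply(images, filterbank_features, numeric(spec$output_width),
                     scales = spec$scales, orientations = spec$orientations,
                     bins = spec$bins))
  }
  prefix <- if (spec$kind == "filterbank") "fb" else "dp"
  feature_matrix(vals, labels = labels,
                 feature_ids = paste0(prefix, seq_len(ncol(vals))))
}

#' Fine-tune the backbone extractor
#'
#' Replaces the final `replaced_layers` layers with a fully-connected +
#' softmax + classification head sized to the number of classes and trains
#' with the recorded hyperparameters. Training is an optional deep-learning
#' capability: with `epochs = 0` the spec round-trips unchanged apart from
#' the head sizing; any positive epoch count without a training plug-in
#' raises a capability error.
#'
#' @param train an `augmented_set` (see [augment_dataset()]).
#' @param spec an [extractor_spec()] with `kind = "pretrained_backbone"` and
#'   a `finetune` record.
#' @param seed integer RNG seed.
#' @return an updated [extractor_spec()] whose `finetune$head_classes`
#'   records the class count.
#' @export
finetune_backbone <- function(train, spec, seed = 0L) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (spec$kind != "pretrained_backbone")
    stop("finetune_backbone requires a pretrained_backbone spec")
  if (is.null(spec$finetune)) stop("spec lacks a finetune record")
  spec$finetune$head_classes <- length(unique(train$labels))
  if (spec$finetune$epochs == 0L) return(spec)
  stop("capability error: backbone training requires a deep-learning ",
       "plug-in, which is not available")
}
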