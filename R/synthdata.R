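#' Specification for synthetic hazed lesion images
#'
#' Describes low-contrast, haze-veiled grayscale patches containing
#' class-dependent lesions on a pink-noise texture: benign lesions are
#' smooth elliptical intensity bumps, malignant lesions are star-shaped
#' (spiculated) bumps whose radius is modulated by a spike pattern. A
#' spatially smooth haze veil is applied with the forward image-formation
#' model `H = Y t + A (1 - t)`, so the enhancement stage's dehazing attacks
#' exactly the degradation the generator introduces.
#'
#' @param n_per_class images per class.
#' @param side image side in pixels (>= 32).
#' @param haze_strength peak veil opacity in \[0, 1).
#' @param background_spectrum_exponent pink-noise spectral exponent.
#' @param noise_sigma additive Gaussian pixel noise sd.
#' @param benign,malignant per-class lesion records (count range, radius
#'   range in px, eccentricity range, intensity offset; malignant adds
#'   spike count range and spike amplitude).
#' @param airlight atmospheric light of the forward haze model.
#' @param seed RNG seed.
#' @return a list of class `image_synthesis_spec`.
#' @export
image_synthesis_spec <- function(n_per_class = 10L, side = 128L,
                                 haze_strength = 0.5,
                                 background_spectrum_exponent = 1.5,
                                 noise_sigma = 0.01,
                                 benign = list(count = c(1L, 2L),
                                               radius = c(8, 16),
                                               eccentricity = c(1, 1.8),
                                               offset = 0.25),
                                 malignant = list(count = c(1L, 2L),
                                                  radius = c(8, 16),
                                                  eccentricity = c(1, 1.8),
                                                  spikes = c(8L, 12L),
                                                  spike_amplitude = 0.5,
                                                  offset = 0.3),
                                 airlight = 0.95, seed = 0L) {
  if (side < 32) stop("side must be >= 32")
  if (!(haze_strength >= 0 && haze_strength < 1))
    stop("haze_strength must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 side = as.integer(side), haze_strength = haze_strength,
                 background_spectrum_exponent = background_spectrum_exponent,
                 noise_sigma = noise_sigma, benign = benign,
                 malignant = malignant, airlight = airlight,
                 seed = as.integer(seed)),
            class = "image_synthesis_spec")
}

# Pink-noise field via spectral shaping of white noise; zero mean, unit sd.
pink_noise <- function(side, exponent) {
  w <- matrix(stats::rnorm(side * side), side, side)
  f <- stats::fft(w)
  fx <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  rad <- sqrt(outer(fx^2, fx^2, "+"))
  rad[1, 1] <- Inf  # kill DC
  shaped <- Re(stats::fft(f / rad^(exponent / 2), inverse = TRUE)) / side^2
  (shaped - mean(shaped)) / stats::sd(as.vector(shaped))
}

# Smooth random field min-max normalised to [0, 1] (haze veil shape).
smooth_field <- function(side) {
  f <- pink_noise(side, 3)
  (f - min(f)) / (max(f) - min(f))
}

runifr <- function(rng) stats::runif(1, rng[1], rng[2])

# Add one lesion bump; returns the updated image and the lesion mask.
add_lesion <- function(img, radius, ecc, offset, spikes = 0L,
                       spike_amplitude = 0) {
  side <- nrow(img)
  cx <- stats::runif(1, 0.25 * side, 0.75 * side)
  cy <- stats::runif(1, 0.25 * side, 0.75 * side)
  angle <- stats::runif(1, 0, pi)
  xs <- matrix(rep(seq_len(side), side), side)
  ys <- t(xs)
  dx <- xs - cx; dy <- ys - cy
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  r <- sqrt((u / ecc)^2 + v^2)
  theta <- atan2(v, u / ecc)
  reff <- radius
  if (spikes > 0)
    reff <- radius * (1 + spike_amplitude * cos(spikes * theta)^2)
  bump <- offset * exp(-2 * (r / reff)^2)
  list(img = img + bump, mask = r < reff)
}

#' Generate synthetic hazed lesion images
#'
#' Produces `2 * n_per_class` grayscale images (benign then malignant by
#' construction order is interleaved: benign/malignant alternating), their
#' labels, and per-image ground-truth lesion masks. For each image a
#' pink-noise background is built, lesions are added as smooth bumps, the
#' forward haze veil is applied with a smooth transmission field
#' `t = 1 - haze_strength * veil`, Gaussian noise is added and values are
#' clipped to \[0, 1\]. Fully reproducible from `spec$seed`.
#'
#' @param spec an [image_synthesis_spec()].
#' @return a list with `images` (list of [intensity_image()]), `labels`
#'   (factor benign/malignant), `masks` (list of logical matrices),
#'   `pre_haze` (list of pre-veil radiance images, for contrast checks).
#' @export
make_synthetic_mammograms <- function(spec = image_synthesis_spec()) {
  stopifnot(inherits(spec, "image_synthesis_spec"))
  with_seed(spec$seed, {
    n <- 2L * spec$n_per_class
    labels <- factor(rep(c("benign", "malignant"), spec$n_per_class),
                     levels = c("benign", "malignant"))
    images <- vector("list", n)
    pre <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- as.character(labels[i])
      les <- if (cls == "benign") spec$benign else spec$malignant
      bg <- 0.35 + 0.08 * pink_noise(spec$side,
                                     spec$background_spectrum_exponent)
      img <- bg
      mask <- matrix(FALSE, spec$side, spec$side)
      count <- sample(seq(les$count[1], les$count[2]), 1L)
      for (l in seq_len(count)) {
        sp <- if (cls == "malignant")
          sample(seq(les$spikes[1], les$spikes[2]), 1L) else 0L
        amp <- if (cls == "malignant") les$spike_amplitude else 0
        res <- add_lesion(img, runifr(les$radius), runifr(les$eccentricity),
                          les$offset, spikes = sp, spike_amplitude = amp)
        img <- res$img
        mask <- mask | res$mask
      }
      Y <- clip01(img)
      t <- 1 - spec$haze_strength * smooth_field(spec$side)
      H <- Y * t + spec$airlight * (1 - t)
      H <- H + stats::rnorm(length(H), 0, spec$noise_sigma)
      images[[i]] <- intensity_image(clip01(H))
      pre[[i]] <- intensity_image(clip01(Y +
        stats::rnorm(length(Y), 0, spec$noise_sigma)))
      masks[[i]] <- mask
    }
    list(images = images, labels = labels, masks = masks, pre_haze = pre)
  })
}

#' Specification for synthetic labelled feature matrices
#'
#' A stand-in for fused deep-feature matrices with known structure:
#' informative columns are class-conditional normals with means separated
#' by `effect_size` (in noise-sd units), redundant columns are random
#' positive combinations of the informative ones plus Gaussian noise, and
#' noise columns are independent standard normals.
#'
#' @param n_samples total sample count (labels balanced).
#' @param d_informative,d_redundant,d_noise column counts
#'   (`d_informative >= 1`).
#' @param effect_size class-mean separation in noise-sd units.
#' @param redundancy_noise sd of the noise added to redundant columns.
#' @param seed RNG seed.
#' @return a list of class `tabular_synthesis_spec`.
#' @export
tabular_synthesis_spec <- function(n_samples = 120L, d_informative = 8L,
                                   d_redundant = 8L, d_noise = 48L,
                                   effect_size = 2.0,
                                   redundancy_noise = 0.5, seed = 0L) {
  if (d_informative < 1) stop("d_informative must be >= 1")
  if (d_redundant < 0 || d_noise < 0) stop("dimensions must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 d_informative = as.integer(d_informative),
                 d_redundant = as.integer(d_redundant),
                 d_noise = as.integer(d_noise), effect_size = effect_size,
                 redundancy_noise = redundancy_noise,
                 seed = as.integer(seed)),
            class = "tabular_synthesis_spec")
}

#' Generate a synthetic labelled feature matrix
#'
#' Columns are ordered informative, redundant, noise; the returned truth
#' mask flags the informative block. Labels alternate between the two
#' classes so balance is exact for even `n_samples` and within 1
#' otherwise. Bit-identical given the same spec and seed.
#'
#' @param spec a [tabular_synthesis_spec()].
#' @return a list with `features` (a [feature_matrix()] with labels),
#'   `labels`, and `truth_mask` (logical, TRUE = informative column).
#' @export
make_synthetic_features <- function(spec = tabular_synthesis_spec()) {
  stopifnot(inherits(spec, "tabular_synthesis_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    labels <- factor(rep(c("benign", "malignant"), length.out = n),
                     levels = c("benign", "malignant"))
    sign_ <- ifelse(labels == "malignant", 1, -1)
    inf <- matrix(stats::rnorm(n * spec$d_informative), n) +
      sign_ * spec$effect_size / 2
    red <- NULL
    if (spec$d_redundant > 0) {
      W <- matrix(stats::runif(spec$d_informative * spec$d_redundant,
                               0.2, 1), spec$d_informative)
      W <- sweep(W, 2, colSums(W), "/")
      red <- inf %*% W +
        matrix(stats::rnorm(n * spec$d_redundant, 0, spec$redundancy_noise),
               n)
    }
    noi <- if (spec$d_noise > 0)
      matrix(stats::rnorm(n * spec$d_noise), n) else NULL
    X <- cbind(inf, red, noi)
    ids <- c(paste0("inf", seq_len(spec$d_informative)),
             if (spec$d_redundant > 0) paste0("red", seq_len(spec$d_redundant)),
             if (spec$d_noise > 0) paste0("noise", seq_len(spec$d_noise)))
    truth <- c(rep(TRUE, spec$d_informative),
               rep(FALSE, spec$d_redundant + spec$d_noise))
    list(features = feature_matrix(X, labels = labels, feature_ids = ids),
         labels = labels, truth_mask = truth)
  })
}
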