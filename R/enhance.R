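#' Parameters for haze-reduced local-global enhancement
#'
#' Bundles every tunable of the HRLG enhancement stage. Defaults follow the
#' common dark-channel-prior dehazing settings (15-pixel patch, omega 0.95,
#' transmission floor 0.1, top 0.1% of dark-channel pixels for the
#' atmospheric light) with moderate global/local contrast gains.
#'
#' @param patch_size odd window side for the dark channel minimum filter.
#' @param omega haze retention weight in the transmission estimate, in (0, 1].
#' @param t_floor lower bound on the transmission used during radiance
#'   recovery, in (0, 1).
#' @param airlight_fraction top fraction of dark-channel pixels averaged for
#'   the atmospheric light (at least one pixel is always used).
#' @param global_gain global contrast gain factor (Ck), >= 0.
#' @param local_gain local contrast gain (LC), >= 0.
#' @param local_window odd window side for local mean/sd statistics.
#' @param local_alpha stabiliser added to the local sd before division, > 0.
#' @param clip_output clip each stage output back into \[0, 1\].
#' @param global_reading parenthesization used for the global-contrast
#'   formula: `"gain_about_mean"` computes
#'   `(1 + Ck) * (g - mean) + sd` (default), `"literal"` computes
#'   `1 + Ck * g - mean + sd`.
#' @return a list of class `enhance_params`.
#' @export
enhance_params <- function(patch_size = 15L, omega = 0.95, t_floor = 0.1,
                           airlight_fraction = 0.001, global_gain = 0.5,
                           local_gain = 0.5, local_window = 11L,
                           local_alpha = 0.01, clip_output = TRUE,
                           global_reading = c("gain_about_mean", "literal")) {
  patch_size <- check_odd_window(patch_size, "patch_size")
  local_window <- check_odd_window(local_window, "local_window")
  if (!(omega > 0 && omega <= 1)) stop("omega must be in (0, 1]")
  if (!(t_floor > 0 && t_floor < 1)) stop("t_floor must be in (0, 1)")
  if (!(airlight_fraction > 0 && airlight_fraction <= 1))
    stop("airlight_fraction must be in (0, 1]")
  if (local_alpha <= 0) stop("local_alpha must be > 0")
  if (global_gain < 0 || local_gain < 0) stop("gains must be >= 0")
  structure(list(
    patch_size = patch_size, omega = omega, t_floor = t_floor,
    airlight_fraction = airlight_fraction, global_gain = global_gain,
    local_gain = local_gain, local_window = local_window,
    local_alpha = local_alpha, clip_output = isTRUE(clip_output),
    global_reading = match.arg(global_reading)
  ), class = "enhance_params")
}

#' Dark channel of an image
#'
#' Per-pixel minimum over channels and over a `patch_size` x `patch_size`
#' window centred at the pixel; windows shrink at the borders rather than
#' pad, so no artificial values enter the minimum.
#'
#' @param image an [intensity_image()] (or numeric array; values need not be
#'   in \[0,1\] when called on a light-normalised image).
#' @param patch_size odd window side.
#' @return a numeric matrix of windowed minima, height x width.
#' @export
dark_channel <- function(image, patch_size) {
  patch_size <- check_odd_window(patch_size, "patch_size")
  a <- im_array_any(image)
  chan_min <- a[, , 1L]
  if (dim(a)[3] > 1L) for (c in 2:dim(a)[3]) chan_min <- pmin(chan_min, a[, , c])
  # min filter is separable: rows then columns
  t(slide_min_rows(t(slide_min_rows(chan_min, patch_size)), patch_size))
}

# Accept intensity_image, matrix or array without the [0,1] constraint
# (transmission estimation divides by the light first).
im_array_any <- function(image) {
  a <- unclass(image)
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (!is.array(a) || length(dim(a)) != 3L) stop("expected image-like array")
  if (dim(a)[1] < 1 || dim(a)[2] < 1) stop("empty image")
  a
}

#' Estimate the atmospheric light
#'
#' Per-channel mean of the image over the `ceil(fraction * npixels)` pixels
#' with the largest dark-channel values.
#'
#' @param image an [intensity_image()].
#' @param dark dark-channel matrix of the same height/width.
#' @param fraction top fraction of pixels to average, in (0, 1].
#' @return numeric vector of length `channels`, each component in \[0, 1\].
#' @export
atmospheric_light <- function(image, dark, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  a <- im_array_any(image)
  if (!all(dim(a)[1:2] == dim(dark))) stop("dark channel shape mismatch")
  npick <- max(1L, ceiling(fraction * length(dark)))
  idx <- order(dark, decreasing = TRUE)[seq_len(npick)]
  vapply(seq_len(dim(a)[3]), function(c) mean(a[, , c][idx]), numeric(1))
}

#' Estimate the transmission map
#'
#' `t(x) = 1 - omega * dark_channel(image / light)`, clamped to \[0, 1\].
#' A transmission of 1 means no haze at that pixel.
#'
#' @param image an [intensity_image()].
#' @param light atmospheric light vector (one value per channel), all > 0.
#' @param omega haze retention weight in (0, 1].
#' @param patch_size odd dark-channel window side.
#' @return a height x width matrix with values in \[0, 1\].
#' @export
transmission_map <- function(image, light, omega, patch_size) {
  a <- im_array_any(image)
  if (length(light) != dim(a)[3]) stop("light length must match channels")
  if (any(light <= 0)) stop("atmospheric light has a zero component")
  norm <- a
  for (c in seq_len(dim(a)[3])) norm[, , c] <- a[, , c] / light[c]
  clip01(1 - omega * dark_channel(norm, patch_size))
}

#' Recover scene radiance from a hazy observation
#'
#' Inverts the haze image-formation model `H = Y t + A (1 - t)`:
#' `Y = (H - A) / max(t, t_floor) + A`, per pixel and channel.
#'
#' @param observed hazy [intensity_image()].
#' @param t transmission matrix (height x width).
#' @param light atmospheric light vector.
#' @param t_floor transmission lower bound in (0, 1).
#' @param clip_output clip the result to \[0, 1\].
#' @return an [intensity_image()] (clipped) or plain array (unclipped).
#' @export
recover_radiance <- function(observed, t, light, t_floor, clip_output = TRUE) {
  if (!(t_floor > 0 && t_floor < 1)) stop("t_floor must be in (0, 1)")
  a <- im_array_any(observed)
  if (!all(dim(a)[1:2] == dim(t))) stop("transmission shape mismatch")
  if (length(light) != dim(a)[3]) stop("light length must match channels")
  td <- pmax(t, t_floor)
  out <- a
  for (c in seq_len(dim(a)[3]))
    out[, , c] <- (a[, , c] - light[c]) / td + light[c]
  if (clip_output) intensity_image(clip01(out)) else out
}

#' Global contrast enhancement
#'
#' With `kmean` the global mean and `sigma` the global standard deviation of
#' the dehazed image, each pixel maps to
#' `(1 + Ck) * (g - kmean) + sigma` (default reading) or to the literal
#' `1 + Ck * g - kmean + sigma`, then is clipped to \[0, 1\].
#'
#' @param dehazed an [intensity_image()] or matrix.
#' @param global_gain gain factor Ck, >= 0.
#' @param reading `"gain_about_mean"` or `"literal"`.
#' @param clip_output clip the result to \[0, 1\].
#' @return object of the same shape; an [intensity_image()] when clipped.
#' @export
global_contrast_enhance <- function(dehazed, global_gain,
                                    reading = c("gain_about_mean", "literal"),
                                    clip_output = TRUE) {
  reading <- match.arg(reading)
  a <- im_array_any(dehazed)
  kmean <- mean(a)
  sigma <- sqrt(mean((a - kmean)^2))  # population sd over all pixels
  out <- if (reading == "gain_about_mean")
    (1 + global_gain) * (a - kmean) + sigma
  else
    1 + global_gain * a - kmean + sigma
  if (clip_output) intensity_image(clip01(out)) else out
}

#' Local contrast enhancement
#'
#' Works on the grayscale dehazed image `phi`; each pixel maps to
#' `phi + (LC / (sd_local + alpha)) * (phi - mean_local)` where the local
#' statistics are taken over a truncated `local_window` square.
#'
#' @param dehazed an [intensity_image()] or matrix.
#' @param local_gain local contrast gain LC, >= 0.
#' @param local_alpha stabiliser added to the local sd, > 0.
#' @param local_window odd window side.
#' @param clip_output clip the result to \[0, 1\].
#' @return a grayscale result (matrix, or [intensity_image()] when clipped).
#' @export
local_contrast_enhance <- function(dehazed, local_gain, local_alpha,
                                   local_window, clip_output = TRUE) {
  if (local_alpha <= 0) stop("local_alpha must be > 0")
  local_window <- check_odd_window(local_window, "local_window")
  phi <- if (is.matrix(dehazed)) dehazed else to_grayscale(intensity_image(im_array_any(dehazed)))
  st <- local_mean_sd(phi, local_window)
  out <- phi + (local_gain / (st$sd + local_alpha)) * (phi - st$mean)
  if (clip_output) intensity_image(clip01(out)) else out
}

#' Haze-reduced local-global (HRLG) contrast enhancement
#'
#' Full enhancement stage: dehaze the input with the dark channel prior,
#' compute a global-contrast image `g` and a local-contrast image `L` from
#' the dehazed radiance, then fuse with the untouched original `I` as
#' `CF = g + L - I`, clipped to \[0, 1\]. Mammograms are processed as a
#' single luminance channel; 3-channel inputs are converted before
#' enhancement and replicated back to 3 channels on output.
#'
#' @param original an [intensity_image()].
#' @param params an [enhance_params()] object.
#' @param keep_stages also return the dehazed/global/local intermediates.
#' @return an [intensity_image()]; when `keep_stages` is TRUE, a list with
#'   elements `enhanced`, `dehazed`, `global`, `local`, `transmission`,
#'   `light`.
#' @export
hrlg_enhance <- function(original, params = enhance_params(),
                         keep_stages = FALSE) {
  stopifnot(inherits(params, "enhance_params"))
  orig <- intensity_image(im_array_any(original))
  nchan <- im_channels(orig)
  gray <- to_grayscale(orig)
  gimg <- intensity_image(gray)

  dc <- dark_channel(gimg, params$patch_size)
  light <- atmospheric_light(gimg, dc, params$airlight_fraction)
  light <- pmax(light, 1e-6)
  t <- transmission_map(gimg, light, params$omega, params$patch_size)
  dehazed <- recover_radiance(gimg, t, light, params$t_floor,
                              clip_output = params$clip_output)
  dh <- to_grayscale(intensity_image(im_array_any(dehazed)))

  g <- im_array_any(global_contrast_enhance(
    dh, params$global_gain, params$global_reading,
    clip_output = params$clip_output))[, , 1L]
  L <- im_array_any(local_contrast_enhance(
    dh, params$local_gain, params$local_alpha, params$local_window,
    clip_output = params$clip_output))[, , 1L]

  cf <- clip01(g + L - gray)
  enhanced <- gray_to_channels(cf, nchan)
  if (!keep_stages) return(enhanced)
  list(enhanced = enhanced, dehazed = intensity_image(dh),
       global = intensity_image(g), local = intensity_image(L),
       transmission = t, light = light)
}

#' Root-mean-square contrast of an image
#'
#' Standard deviation of the grayscale pixel values; the contrast measure
#' used to check that enhancement increases contrast.
#'
#' @param img an [intensity_image()].
#' @return a single number.
#' @export
rms_contrast <- function(img) stats::sd(as.vector(to_grayscale(intensity_image(im_array_any(img)))))
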