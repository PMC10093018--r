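#' EfficientNet-style backbone architecture descriptor
#'
#' Encodes the compound-scaling rule of the EfficientNet family: a base
#' stage plan (the b0 plan: stem 32; MBConv stages 16, 24, 40, 80, 112,
#' 192, 320; head = 4 x last stage) whose channel counts are scaled by a
#' width coefficient and snapped to a divisor, and whose final 1x1
#' convolution feeds the global average pool. The descriptor carries no
#' weights; it defines the feature-width contract a deep extractor must
#' honour.
#'
#' @param name architecture name; `"efficientnet-b0"` is the only built-in.
#' @param width_coefficient channel multiplier (1.0 for b0).
#' @param depth_coefficient layer-repeat multiplier (1.0 for b0); carried
#'   for completeness.
#' @param resolution expected input side in pixels (224 for b0).
#' @param divisor channel rounding divisor (8).
#' @return a list of class `backbone_config` with the scaled `stage_widths`
#'   and `head_width`.
#' @export
backbone_config <- function(name = "efficientnet-b0",
                            width_coefficient = 1.0,
                            depth_coefficient = 1.0,
                            resolution = 224L, divisor = 8L) {
  if (!identical(name, "efficientnet-b0"))
    stop("unknown backbone architecture: ", name)
  base_stem <- 32L
  base_stages <- c(16L, 24L, 40L, 80L, 112L, 192L, 320L)
  base_head <- 4L * base_stages[length(base_stages)]  # 1x1 conv before GAP
  rf <- function(ch) round_filters(ch, width_coefficient, divisor)
  structure(list(
    name = name,
    width_coefficient = width_coefficient,
    depth_coefficient = depth_coefficient,
    resolution = as.integer(resolution),
    stem_width = rf(base_stem),
    stage_widths = vapply(base_stages, rf, integer(1)),
    head_width = rf(base_head)
  ), class = "backbone_config")
}

# Canonical EfficientNet channel rounding: scale, snap to the nearest
# multiple of `divisor`, never drop below 90% of the scaled value.
round_filters <- function(channels, width_coefficient, divisor = 8L) {
  ch <- channels * width_coefficient
  new_ch <- max(divisor, as.integer(ch + divisor / 2) %/% divisor * divisor)
  if (new_ch < 0.9 * ch) new_ch <- new_ch + divisor
  as.integer(new_ch)
}

#' Width of the backbone's global-average-pool output
#'
#' The global average pool collapses the spatial dimensions of the head
#' convolution, so the pooled feature width equals the head channel count
#' (1280 for efficientnet-b0).
#'
#' @param config a [backbone_config()].
#' @return an integer.
#' @export
backbone_gap_width <- function(config = backbone_config()) {
  stopifnot(inherits(config, "backbone_config"))
  config$head_width
}
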