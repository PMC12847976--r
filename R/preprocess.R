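#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as the
#' grayscale morphological opening with a disc structuring element of the
#' given radius (the rolling-ball family: the ball rolled under the
#' intensity surface), and subtracts it.  Structures wider than about twice
#' the radius are treated as background and attenuated; narrower
#' structures, such as vessels, pass through essentially unchanged.
#'
#' @param image A [chip_image()].
#' @param radius Ball radius in pixels (>= 1); must exceed the widest
#'   vessel of interest.  Default 50.
#' @param smooth_sigma Optional Gaussian pre-smoothing (pixels) applied to
#'   the background estimate input only; 0 (default) disables it.
#' @return A background-subtracted [chip_image()] (non-negative).
#' @export
rolling_ball_subtract <- function(image, radius = 50, smooth_sigma = 0) {
  if (radius < 1) stop("ball radius must be >= 1")
  img <- image$intensity
  if (radius > nrow(img) && radius > ncol(img))
    stop("ball radius exceeds both image dimensions")
  bg <- rolling_ball_background(img, radius, smooth_sigma)
  out <- pmax(img - bg, 0)
  chip_image(out, bitdepth = image$bitdepth, pixel_size = image$pixel_size,
             geometry = image$geometry)
}

#' Rolling-ball background estimate
#'
#' The background surface removed by [rolling_ball_subtract()]:
#' grayscale opening (erosion then dilation) with a disc of the given
#' radius.
#'
#' @inheritParams rolling_ball_subtract
#' @param img Numeric intensity matrix.
#' @return Numeric matrix of the same shape.
#' @export
rolling_ball_background <- function(img, radius = 50, smooth_sigma = 0) {
  if (smooth_sigma > 0) {
    sz <- 2L * ceiling(3 * smooth_sigma) + 1L
    img <- EBImage::gblur(img, sigma = smooth_sigma, radius = sz)
  }
  brush <- EBImage::makeBrush(2L * floor(radius) + 1L, shape = "disc")
  # grayscale morphology operates on the [0, 1] scale
  scale <- max(img, 1)
  EBImage::dilate(EBImage::erode(img / scale, brush), brush) * scale
}
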