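#' Global histogram equalization
#'
#' Pre-processing stage applied before the network, at training and
#' prediction time alike. It flattens the gray-level histogram and thereby
#' homogenises uneven illumination across a micrograph. The mapping is the
#' classical CDF stretch
#' \deqn{h(v) = \mathrm{round}\left(\frac{cdf(v) - cdf_{\min}}{N - cdf_{\min}} \times 255\right)}
#' where \eqn{cdf} is the cumulative pixel-count function over gray levels
#' 0..255, \eqn{cdf_{\min}} its smallest nonzero value and \eqn{N} the pixel
#' count. The mapping is monotone non-decreasing, so pixel rank order is
#' preserved. Equalization is global (whole-image), not adaptive (CLAHE),
#' and is applied per image, not per stack.
#'
#' A constant image has \eqn{N = cdf_{\min}}; it is returned unchanged with
#' a warning rather than dividing by zero.
#'
#' @param img A [gray_image] or integer intensity matrix in `[0, 255]`.
#' @return The equalized image, same class as the input.
#' @export
equalize_histogram <- function(img) {
  px <- as_pixels(img)
  counts <- tabulate(as.vector(px) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(px)
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) {
    warn("constant image: histogram equalization is degenerate, returning input unchanged")
    return(img)
  }
  lut <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  lut[lut < 0L] <- 0L
  out <- matrix(lut[px + 1L], nrow = nrow(px))
  if (inherits(img, "gray_image")) {
    gray_image(out, img$pixel_size_nm)
  } else {
    storage.mode(out) <- "integer"
    out
  }
}
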