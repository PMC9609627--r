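#' Microscope optics specification
#'
#' Converts pixel measurements to physical length. One pixel corresponds to
#' (field-of-view width / horizontal resolution) / objective_factor
#' micro-metres: a 1600 px sensor viewing 7.04 mm gives 4.4 um/px, and an
#' additional 4x objective with a 0.5x adapter (factor 2) gives 2.2 um/px.
#'
#' @param resolution Integer vector c(width, height) in pixels.
#' @param fov_mm Numeric vector c(width, height) of the field of view in mm.
#' @param objective_factor Extra optical magnification factor (default 1).
#' @return An object of class `optics_spec`.
#' @examples
#' optics_spec(c(1600, 1200), c(7.04, 5.28), objective_factor = 4 * 0.5)
#' @export
optics_spec <- function(resolution = c(1600, 1200), fov_mm = c(7.04, 5.28),
                        objective_factor = 1) {
  stopifnot(length(resolution) == 2, length(fov_mm) == 2,
            all(resolution > 0), all(fov_mm > 0), objective_factor > 0)
  structure(list(resolution = as.integer(resolution), fov_mm = fov_mm,
                 objective_factor = objective_factor),
            class = "optics_spec")
}

#' Micron length of one pixel
#'
#' @param optics An [optics_spec()].
#' @return um per pixel (scalar).
#' @export
micron_per_pixel <- function(optics) {
  stopifnot(inherits(optics, "optics_spec"))
  (optics$fov_mm[1] * 1e3 / optics$resolution[1]) / optics$objective_factor
}

#' Convert a pixel distance to micro-metres
#'
#' @param px Pixel count (vectorised).
#' @param optics An [optics_spec()].
#' @return Length in um.
#' @export
pixel_to_micron <- function(px, optics) {
  px * micron_per_pixel(optics)
}

#' Render a synthetic image of the sensing tube
#'
#' Draws a dark horizontal tube on a bright background, ending at
#' `tip_px = c(x, y)` (x column, y row, 1-based; y is the tube centreline).
#' Optional additive Gaussian pixel noise, clipped to \[0, 1\]. This is the
#' package's stand-in for the camera: a synthetic fixture generator, not a
#' model of real microscope optics.
#'
#' @param tip_px Integer c(x, y) tip position, at least `tube_width_px`
#'   away from every frame edge.
#' @param size_px Image size c(width, height) (default 400 x 300).
#' @param tube_width_px Tube thickness in px (default 20).
#' @param noise_level Gaussian noise sd as a fraction of dynamic range.
#' @param fg,bg Tube and background gray levels in \[0, 1\].
#' @param seed Optional seed; rendering is deterministic given the seed.
#' @return Numeric matrix (height x width) of gray values in \[0, 1\].
#' @export
render_tube_image <- function(tip_px, size_px = c(400, 300),
                              tube_width_px = 20, noise_level = 0,
                              fg = 0.15, bg = 0.85, seed = NULL) {
  w <- size_px[1]; h <- size_px[2]
  x_t <- round(tip_px[1]); y_t <- round(tip_px[2])
  m <- tube_width_px
  if (x_t <= m || x_t > w - m || y_t <= m || y_t > h - m) {
    stop("tip must lie at least one tube width inside the frame", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(bg, nrow = h, ncol = w)
  half <- floor(tube_width_px / 2)
  rows <- max(1, y_t - half):min(h, y_t + half)
  img[rows, 1:x_t] <- fg
  if (noise_level > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, noise_level), h, w)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  img
}

# Harris corner response of a (smoothed) image; k is the standard Harris
# sensitivity constant. Returns a response matrix the size of the image.
harris_response <- function(img, k = 0.04, window = 3) {
  sm <- EBImage::makeBrush(window, shape = "box")
  sm <- sm / sum(sm)
  gx <- matrix(c(-1, 0, 1), 1, 3) / 2
  gy <- t(gx)
  # EBImage images are x-by-y; transpose our row-col matrix
  im <- EBImage::Image(t(img))
  Ix <- EBImage::filter2(im, gx)
  Iy <- EBImage::filter2(im, gy)
  Sxx <- EBImage::filter2(Ix^2, sm)
  Syy <- EBImage::filter2(Iy^2, sm)
  Sxy <- EBImage::filter2(Ix * Iy, sm)
  R <- Sxx * Syy - Sxy^2 - k * (Sxx + Syy)^2
  t(EBImage::imageData(R))
}

#' Detect the sensing-tube tip in a grayscale image
#'
#' Pipeline: Otsu binarisation (tube = dark component), one 3x3 grayscale
#' dilation of the tube mask to suppress binarisation speckle, Harris
#' corner response on the smoothed mask, then selection of the rightmost
#' corner inside the tube component (ties broken by Harris response) - the
#' free end of a horizontal cantilever is its rightmost feature. The tip
#' row is refined to the tube-component centre in the tip column so the
#' returned point sits on the tube axis.
#'
#' @param img Numeric matrix in \[0, 1\] (rows = y, cols = x).
#' @param k,window Harris sensitivity and smoothing window.
#' @param response_frac Corners must exceed this fraction of the peak
#'   Harris response (default 0.01).
#' @return Tibble with `x_t`, `y_t` (pixels) and `ok`; when no corner is
#'   found, `ok` is FALSE and coordinates are NA (detection failure,
#'   not an error).
#' @export
detect_tip <- function(img, k = 0.04, window = 3, response_frac = 0.01) {
  fail <- tibble::tibble(x_t = NA_real_, y_t = NA_real_, ok = FALSE)
  rng <- range(img)
  if (diff(rng) < 1e-6) return(fail)     # blank frame
  thr <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1))
  tube <- img < thr                      # dark tube is foreground
  if (!any(tube) || all(tube)) return(fail)
  tube_d <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(tube * 1)), EBImage::makeBrush(3, shape = "box")))) > 0.5
  R <- harris_response(tube_d * 1, k = k, window = window)
  R[!tube_d] <- -Inf
  peak <- max(R)
  if (!is.finite(peak) || peak <= 0) return(fail)
  cand <- which(R >= response_frac * peak, arr.ind = TRUE)
  if (nrow(cand) == 0) return(fail)
  xmax <- max(cand[, 2])
  at_x <- cand[cand[, 2] == xmax, , drop = FALSE]
  best <- at_x[which.max(R[at_x]), ]
  x_t <- unname(best[2])
  rows_in_col <- which(tube_d[, min(x_t, ncol(tube_d))])
  y_t <- if (length(rows_in_col)) mean(range(rows_in_col)) else unname(best[1])
  tibble::tibble(x_t = x_t, y_t = y_t, ok = TRUE)
}

#' Tip-position noise stream in micro-metres
#'
#' Gaussian pixel jitter of the detected tip corner (the PBS-solution
#' fluctuation seen in live tracking), converted to um through the optics.
#' The draw is deterministic given the seed.
#'
#' @param sigma_px Pixel standard deviation of the jitter (>= 0).
#' @param optics An [optics_spec()].
#' @param n Number of samples.
#' @param seed Optional seed.
#' @return Numeric vector of um offsets (zero-mean).
#' @export
tip_noise_sampler <- function(sigma_px, optics, n, seed = NULL) {
  stopifnot(sigma_px >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, 0, sigma_px) * micron_per_pixel(optics)
}
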