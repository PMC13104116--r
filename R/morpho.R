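#' Sholl profile of a binary cell mask
#'
#' Counts process intersections with concentric circles around the soma
#' centre, the classic morphological-complexity measure for microglia.
#' Each circle is rasterized at sub-pixel angular resolution and the count
#' at a radius is the number of connected runs of foreground pixels along
#' the circle (circularly closed), which avoids double counting thick or
#' diagonal processes.
#'
#' @param mask Binary matrix (0 background, nonzero foreground).
#' @param center Length-2 numeric, soma centre as (row, col) in pixels.
#'   Chosen by the analyst; no soma detection is attempted.
#' @param step Radial step in micrometres (default 2).
#' @param r_max Largest radius in micrometres; defaults to the distance from
#'   the centre to the most distal foreground pixel.
#' @param pixel_size Micrometres per pixel.
#' @return A data frame of class `sholl_profile` with columns `radius`
#'   (micrometres) and `crossings` (integer counts), and attributes `center`,
#'   `step`, `pixel_size`.
#' @examples
#' img <- simulate_cell_image(6, 40, 5, c(128, 128), 1, seed = 1)
#' prof <- sholl_profile(img$mask, img$center, step = 2)
#' sholl_metrics(prof)
#' @export
sholl_profile <- function(mask, center, step = 2, r_max = NULL,
                          pixel_size = 1) {
  if (step <= 0) stop("step must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  nr <- nrow(mask); nc <- ncol(mask)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("center lies outside the image")
  fg <- which(mask != 0, arr.ind = TRUE)
  if (is.null(r_max)) {
    r_max <- if (nrow(fg) == 0) step else
      max(sqrt((fg[, 1] - center[1])^2 + (fg[, 2] - center[2])^2)) * pixel_size
  }
  radii <- seq(step, r_max, by = step)
  # a sample point is foreground if any pixel, treated as a closed unit
  # square with a small tolerance, contains it; the tolerance keeps
  # crossings that pass near pixel-cell corners from being missed
  tol <- 0.15
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- logical(length(rr))
    v[ok] <- mask[cbind(rr[ok], cc[ok])] != 0
    v
  }
  crossings <- vapply(radii, function(r_um) {
    r <- r_um / pixel_size
    n_theta <- max(16L, ceiling(2 * pi * r / 0.25))
    th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
    y <- center[1] + r * sin(th)
    x <- center[2] + r * cos(th)
    r1 <- floor(y + 0.5 - tol); r2 <- floor(y + 0.5 + tol)
    c1 <- floor(x + 0.5 - tol); c2 <- floor(x + 0.5 + tol)
    v <- at(r1, c1) | at(r1, c2) | at(r2, c1) | at(r2, c2)
    nxt <- c(v[-1], v[1])
    runs <- sum(v & !nxt)
    if (runs == 0L && all(v)) runs <- 1L
    as.integer(runs)
  }, integer(1))
  out <- data.frame(radius = radii, crossings = crossings)
  attr(out, "center") <- center
  attr(out, "step") <- step
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Summary metrics of a Sholl profile
#'
#' The two headline morphology statistics: the maximum intersection count
#' over all radii, and the area under the intersection-vs-radius curve
#' (trapezoidal rule, units count x micrometre).
#'
#' @param profile A [sholl_profile()] result.
#' @return Named list with `max_intersections` and `auc`.
#' @export
sholl_metrics <- function(profile) {
  stopifnot(inherits(profile, "sholl_profile"))
  if (nrow(profile) == 0) stop("empty profile")
  r <- profile$radius; y <- profile$crossings
  auc <- if (length(r) < 2) 0 else
    sum((y[-1] + y[-length(y)]) / 2 * diff(r))
  list(max_intersections = max(y), auc = auc)
}

#' Mean fluorescence intensity
#'
#' Arithmetic mean of pixel intensities, optionally restricted to a region
#' of interest.
#'
#' @param image Numeric matrix (arbitrary units, finite, >= 0).
#' @param roi Optional logical/binary matrix of the same size; the mean is
#'   taken over `roi` pixels.
#' @return Scalar mean intensity.
#' @export
mean_intensity <- function(image, roi = NULL) {
  if (any(!is.finite(image)) || any(image < 0))
    stop("image intensities must be finite and >= 0")
  if (is.null(roi)) return(mean(image))
  if (!all(dim(roi) == dim(image))) stop("roi must match image dimensions")
  sel <- roi != 0
  if (!any(sel)) stop("roi is empty")
  mean(image[sel])
}

#' Fraction of image area above a threshold
#'
#' The positive-area statistic: the fraction of pixels strictly above an
#' intensity threshold. The threshold is either fixed or derived from a
#' declared background region as `mean(background) + k * sd(background)`
#' (default `k = 2`).
#'
#' @param image Numeric matrix.
#' @param threshold Fixed threshold, or `NULL` to use the background rule.
#' @param background Logical/binary matrix marking background pixels
#'   (required when `threshold` is `NULL`).
#' @param k Multiplier on the background SD (default 2).
#' @return Fraction in `[0, 1]`.
#' @export
positive_area_fraction <- function(image, threshold = NULL,
                                   background = NULL, k = 2) {
  if (is.null(threshold)) {
    if (is.null(background))
      stop("background rule requires a background region")
    sel <- background != 0
    if (!any(sel)) stop("background region is empty")
    threshold <- mean(image[sel]) + k * stats::sd(image[sel])
  }
  mean(image > threshold)
}

#' Cell density
#'
#' @param centers Matrix or data frame of soma centres (one row per cell),
#'   or an integer cell count.
#' @param area_mm2 Field area in square millimetres (> 0).
#' @return Density in cells per square millimetre.
#' @export
cell_density <- function(centers, area_mm2) {
  if (area_mm2 <= 0) stop("area must be positive")
  n <- if (is.numeric(centers) && length(centers) == 1) centers else
    nrow(as.matrix(centers))
  if (is.null(n)) n <- 0
  n / area_mm2
}

#' Read a single-plane TIFF image as a matrix
#' @param path File path.
#' @return Numeric matrix (first plane if multi-channel).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a matrix as a single-plane TIFF image
#'
#' Values are clamped to `[0, 1]` as required by the TIFF writer; binary
#' masks and normalized intensity images round-trip exactly.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
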