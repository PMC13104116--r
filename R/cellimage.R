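#' Simulate a binary star-shaped cell image
#'
#' Draws an analytic microglia-like cell: a filled disk soma plus
#' `n_processes` straight one-pixel-wide rays at distinct angles (evenly
#' spaced with a seeded random rotation offset). Because the geometry is
#' analytic, the Sholl intersection count is known exactly: `n_processes`
#' at every radius strictly between the soma radius and the ray tip.
#'
#' @param n_processes Number of rays (>= 0).
#' @param process_length Ray length from the centre, micrometres; must
#'   exceed `soma_radius`.
#' @param soma_radius Soma radius, micrometres (>= 1 pixel).
#' @param image_size Length-2 integer, image size in pixels (rows, cols).
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed for the rotation offset.
#' @return List with `mask` (binary integer matrix), `center` (row, col in
#'   pixels), `pixel_size`, and the generating parameters.
#' @examples
#' img <- simulate_cell_image(6, 40, 5, c(128, 128), 1, seed = 1)
#' sum(img$mask)
#' @export
simulate_cell_image <- function(n_processes, process_length, soma_radius,
                                image_size = c(128L, 128L), pixel_size = 1,
                                seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  soma_px <- soma_radius / pixel_size
  len_px <- process_length / pixel_size
  if (soma_px < 1) stop("soma_radius must be at least one pixel")
  if (len_px <= soma_px) stop("process_length must exceed soma_radius")
  if (n_processes < 0) stop("n_processes must be >= 0")
  set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (len_px > min(center[1], center[2], nr - center[1], nc - center[2]))
    stop("rays exceed image bounds; enlarge image_size or shorten processes")
  mask <- matrix(0L, nr, nc)
  # soma disk
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask[(rr - center[1])^2 + (cc - center[2])^2 <= soma_px^2] <- 1L
  angles <- numeric(0)
  if (n_processes > 0) {
    offset <- stats::runif(1, 0, 2 * pi)
    angles <- offset + 2 * pi * (seq_len(n_processes) - 1) / n_processes
    ts <- seq(0, len_px, by = 0.25)
    for (a in angles) {
      pr <- floor(center[1] + ts * sin(a) + 0.5)
      pc <- floor(center[2] + ts * cos(a) + 0.5)
      mask[cbind(pr, pc)] <- 1L
    }
  }
  list(mask = mask, center = center, pixel_size = pixel_size,
       n_processes = n_processes, process_length = process_length,
       soma_radius = soma_radius, angles = angles)
}
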