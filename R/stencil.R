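#' Bilateral filter parameters
#'
#' Configuration of the edge-preserving filter applied to the z-map.  The
#' kernels are Gaussian in the parameterisation
#' `f_r(x) = exp(-x^2 / sigma_r)` and `g_s(x) = exp(-x^2 / sigma_s)` (note:
#' the denominator is `sigma`, not `2 sigma^2`; the defaults are calibrated
#' to this form).
#'
#' @param sigma_s spatial kernel scale, in voxels (default 2.0).
#' @param sigma_r range kernel scale, in units of the scaled statistic
#'   (default 2.0).
#' @param radius neighbourhood half-width in voxels (default 2, giving the
#'   117-voxel stencil).
#' @param iterations number of filter passes (default 2).
#' @param distance `"voxel"` (default; neighbourhood geometry in voxel
#'   units, ignoring anisotropy) or `"mm"` (Euclidean distance in mm).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(sigma_s = 2.0, sigma_r = 2.0, radius = 2L,
                          iterations = 2L, distance = c("voxel", "mm")) {
  distance <- match.arg(distance)
  stopifnot(sigma_s > 0, sigma_r > 0, radius >= 0, iterations >= 1)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 radius = as.integer(radius),
                 iterations = as.integer(iterations), distance = distance),
            class = "filter_params")
}

#' Build a neighbourhood stencil
#'
#' The stencil at radius `r` is the `(2r+1)^3` cube of voxel offsets minus
#' its 8 corners (the offsets with all three components equal to `r` in
#' absolute value).  At the default radius 2 this yields exactly 117
#' offsets, the "spherical neighbourhood" of the method; at radius 1 it
#' yields the 19-voxel set (centre plus the 18 face/edge neighbours) that
#' the boundary median rule uses.
#'
#' @param radius neighbourhood half-width in voxels.
#' @param sigma_s spatial kernel scale.
#' @param voxel_size physical voxel size, used when `distance = "mm"`.
#' @param distance `"voxel"` or `"mm"`.
#' @return A list of class `lisa_stencil` with integer `offsets` (K x 3)
#'   and `spatial_weights` (`g_s` evaluated at each offset's Euclidean
#'   length).
#' @examples
#' st <- build_stencil(2)
#' nrow(st$offsets)  # 117
#' @export
build_stencil <- function(radius = 2L, sigma_s = 2.0, voxel_size = c(1, 1, 1),
                          distance = c("voxel", "mm")) {
  distance <- match.arg(distance)
  stopifnot(radius >= 0, sigma_s > 0)
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  if (r >= 1L) {
    corner <- abs(g[, 1]) == r & abs(g[, 2]) == r & abs(g[, 3]) == r
    g <- g[!corner, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  scale <- if (distance == "mm") as.numeric(voxel_size) else c(1, 1, 1)
  d <- sqrt((g[, 1] * scale[1])^2 + (g[, 2] * scale[2])^2 +
            (g[, 3] * scale[3])^2)
  structure(list(offsets = g, spatial_weights = exp(-d^2 / sigma_s),
                 radius = r, sigma_s = sigma_s, distance = distance),
            class = "lisa_stencil")
}

#' @export
print.lisa_stencil <- function(x, ...) {
  cat(sprintf("<lisa_stencil> radius %d, %d offsets, sigma_s = %g (%s units)\n",
              x$radius, nrow(x$offsets), x$sigma_s, x$distance))
  invisible(x)
}

stencil_from_params <- function(params, voxel_size = c(1, 1, 1)) {
  build_stencil(params$radius, params$sigma_s, voxel_size, params$distance)
}
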