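#' Scale maps by the null standard deviation
#'
#' The range kernel scale `sigma_r` is meaningful only relative to the
#' spread of the input values, so before filtering, the observed map and
#' every permuted map are divided by one common factor: the standard
#' deviation of the in-mask values of the first `n_scale` permuted maps,
#' pooled.
#'
#' @param observed a [stat_volume()].
#' @param permuted list of [stat_volume()]s (or 3D arrays on the observed
#'   grid), at least `n_scale` of them.
#' @param n_scale how many permuted maps define the factor (default 30).
#'   Only these maps influence the result.
#' @param mask optional logical array; defaults to the observed map's mask.
#' @return list with `observed`, `permuted` (both rescaled) and `scale`.
#' @export
scale_by_null_sd <- function(observed, permuted, n_scale = 30L, mask = NULL) {
  if (is.null(mask)) mask <- observed$mask
  if (length(permuted) < n_scale)
    stop("need at least ", n_scale, " permuted maps to derive the scale ",
         "factor (got ", length(permuted), ")", call. = FALSE)
  vals <- function(m) if (inherits(m, "stat_volume")) m$values else m
  pooled <- unlist(lapply(permuted[seq_len(n_scale)],
                          function(m) vals(m)[mask]), use.names = FALSE)
  s <- sd(pooled)
  if (!is.finite(s) || s <= 0)
    stop("degenerate null: permuted maps have zero variance", call. = FALSE)
  rescale <- function(m) {
    if (inherits(m, "stat_volume")) { m$values <- m$values / s; m }
    else m / s
  }
  list(observed = rescale(observed), permuted = lapply(permuted, rescale),
       scale = s)
}

#' Edge-preserving bilateral filter
#'
#' Applies the post-test bilateral filter to a statistic map.  For each
#' in-mask voxel `i` whose stencil keeps at least half of its members in
#' the mask, the filtered value is
#' `lambda_i = sum_j z_j f_r(|z_i - z_j|) g_s(d(i,j)) / W_i` over in-mask
#' stencil members `j`, with `W_i` the sum of the weights.  Voxels with
#' more than half of the stencil outside the mask fall back to a median
#' over their in-mask 18-neighbourhood (centre included) when at least 9 of
#' those 18 neighbours are in-mask, and are discarded otherwise.  The
#' filter is applied `params$iterations` times; discarded voxels are
#' treated as out-of-mask by later iterations.
#'
#' @param volume a [stat_volume()] (already scaled, see
#'   [scale_by_null_sd()]).
#' @param params a [filter_params()].
#' @param kernel `"bilateral"` (default), `"gaussian"` (spatial weights
#'   only, i.e. the `sigma_r -> Inf` limit), or `"none"` (identity).
#' @param stencil optional precomputed [build_stencil()]; derived from
#'   `params` otherwise.
#' @param mask optional mask overriding the volume's own.
#' @return A [stat_volume()] of filtered values with attributes `status`
#'   (integer array: 0 outside, 1 filtered, 2 median fallback,
#'   3 discarded) and `evaluable` (logical array).
#' @export
bilateral_filter <- function(volume, params = filter_params(),
                             kernel = c("bilateral", "gaussian", "none"),
                             stencil = NULL, mask = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(mask)) mask <- volume$mask
  if (kernel == "none") {
    status <- array(ifelse(mask, VOX_FILTERED, VOX_OUTSIDE), dim(mask))
    out <- volume
    out$values[!mask] <- 0
    attr(out, "status") <- status
    attr(out, "evaluable") <- mask
    return(out)
  }
  if (is.null(stencil)) stencil <- stencil_from_params(params, volume$voxel_size)
  res <- cpp_filter(as.vector(volume$values), as.integer(mask),
                    dim(volume$values), stencil$offsets,
                    stencil$spatial_weights, params$sigma_r,
                    params$iterations, kernel == "bilateral")
  d <- dim(volume$values)
  status <- array(res$status, d)
  out <- stat_volume(array(res$values, d), mask = mask,
                     voxel_size = volume$voxel_size,
                     reference = attr(volume, "reference"))
  attr(out, "status") <- status
  attr(out, "evaluable") <- status == VOX_FILTERED | status == VOX_MEDIAN
  out
}

#' Separable Gaussian smoothing of a volume
#'
#' Conventional pre-test smoothing (as applied during preprocessing in
#' standard pipelines), used by the power harness's "pre-test Gaussian"
#' comparison arm.  The kernel is parameterised by its full width at half
#' maximum in mm and truncated at 4 standard deviations; weights are
#' renormalised over the in-mask support so edges are not darkened.
#'
#' @param volume a [stat_volume()] or 3D array.
#' @param fwhm full width at half maximum, in mm (default 6).
#' @param voxel_size voxel edge lengths in mm (taken from the volume if it
#'   is a `stat_volume`).
#' @return Object of the same kind as the input, smoothed.
#' @export
gaussian_smooth <- function(volume, fwhm = 6, voxel_size = NULL) {
  is_sv <- inherits(volume, "stat_volume")
  arr <- if (is_sv) volume$values else volume
  if (is.null(voxel_size))
    voxel_size <- if (is_sv) volume$voxel_size else c(1, 1, 1)
  sigma <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_size  # in voxels, per axis
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    out <- convolve_axis(out, k / sum(k), ax)
  }
  if (is_sv) { volume$values <- out; volume } else out
}

# 1D convolution along one axis with edge renormalisation
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- da[1]
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], ]
    wsum[ok] <- wsum[ok] + kernel[j]
  }
  out <- out / wsum
  aperm(array(out, da), order(perm))
}
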