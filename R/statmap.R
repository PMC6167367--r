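#' Convert t statistics to standardized z-scores
#'
#' Quantile transform `z = qnorm(pt(t, dof))`, evaluated in log-probability
#' space so the mapping does not saturate in the tails, and capped at
#' `|z| = cap` to keep maps finite.  The mapping is strictly monotone in
#' `t` (up to the cap) and sends `t = 0` to `z = 0` for any degrees of
#' freedom.
#'
#' @param t numeric vector of t statistics.
#' @param dof degrees of freedom.
#' @param cap cap on `|z|` (default 8.2).
#' @return numeric vector of z-scores.
#' @export
t_to_z <- function(t, dof, cap = Z_CAP) {
  stopifnot(dof > 0, cap > 0)
  cpp_t_to_z(as.numeric(t), dof, cap)
}

#' One-sample z-map across a group of contrast maps
#'
#' Voxelwise one-sample t-test (`t = mean / (sd / sqrt(n))`, `dof = n - 1`)
#' followed by the t-to-z quantile transform.  The orientation is
#' one-sided: a positive group mean yields a positive z (the null
#' hypothesis is that the group mean is not positive).  Within-subject
#' variance is ignored.
#'
#' @param sample a [group_sample()].
#' @param mask logical array; defaults to [derive_mask()] of the sample.
#' @param cap cap on `|z|`; voxels with zero sample variance are set to
#'   `sign(mean) * cap` with a warning.
#' @return A [stat_volume()] z-map with attributes `t` (3D array) and
#'   `dof`.
#' @export
onesample_z <- function(sample, mask = NULL, cap = Z_CAP) {
  if (is.null(mask)) mask <- derive_mask(sample)
  X <- sample_matrix(sample)
  res <- cpp_onesample_z(X, as.integer(mask), rep(1, length(sample$maps)), cap)
  if (res$n_zero_var > 0)
    warning(res$n_zero_var, " voxel(s) with zero sample variance; ",
            "z set to ±", cap, call. = FALSE)
  finish_testmap(res, sample, mask)
}

#' Two-sample z-map (pooled variance)
#'
#' Voxelwise pooled-variance two-sample t-test with
#' `dof = n1 + n2 - 2`, mapped to z as in [onesample_z()].  Positive z
#' means group 1 exceeds group 2.
#'
#' @inheritParams onesample_z
#' @return A [stat_volume()] z-map with attributes `t` and `dof`.
#' @export
twosample_z <- function(sample, mask = NULL, cap = Z_CAP) {
  if (is.null(sample$group_labels))
    stop("`sample` has no group labels; construct it with `group_labels`",
         call. = FALSE)
  if (is.null(mask)) mask <- derive_mask(sample)
  X <- sample_matrix(sample)
  res <- cpp_twosample_z(X, as.integer(mask),
                         as.integer(sample$group_labels), cap)
  if (res$n_zero_var > 0)
    warning(res$n_zero_var, " voxel(s) with zero pooled variance; ",
            "z set to ±", cap, call. = FALSE)
  finish_testmap(res, sample, mask)
}

finish_testmap <- function(res, sample, mask) {
  d <- dim(sample$maps[[1]]$values)
  out <- stat_volume(array(res$z, d), mask = mask,
                     voxel_size = sample$maps[[1]]$voxel_size,
                     reference = attr(sample$maps[[1]], "reference"))
  attr(out, "t") <- array(res$t, d)
  attr(out, "dof") <- res$dof
  out
}
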