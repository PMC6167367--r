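#' Statistic volume
#'
#' A `stat_volume` is a 3D scalar map on a voxel grid together with a
#' binary brain mask and the physical voxel dimensions.  It is the common
#' currency of the package: z-maps, filtered maps and FDR-score maps are all
#' stat volumes.
#'
#' @param values 3D numeric array of voxel values.
#' @param mask logical 3D array of the same shape (`TRUE` = in brain), or
#'   `NULL` for an all-`TRUE` mask.
#' @param voxel_size positive numeric vector of length 3, physical edge
#'   lengths in mm.
#' @param reference optional NIfTI image whose header (affine, orientation)
#'   is reused when the volume is written back to disk.
#' @return An object of class `stat_volume`.
#' @export
stat_volume <- function(values, mask = NULL, voxel_size = c(1, 1, 1),
                        reference = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  values <- array(as.double(values), dim(values))  # strip foreign attributes
  if (is.null(mask)) {
    mask <- array(TRUE, dim(values))
  } else {
    mask <- array(as.logical(mask), dim(mask))
    if (!identical(dim(mask), dim(values)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match values shape ",
           paste(dim(values), collapse = "x"), call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers", call. = FALSE)
  if (any(!is.finite(values[mask])))
    stop("volume contains non-finite values inside the mask", call. = FALSE)
  structure(list(values = values, mask = mask, voxel_size = voxel_size),
            reference = reference, class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_volume> %dx%dx%d voxels (%.3gx%.3gx%.3g mm), %d in mask\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], sum(x$mask)))
  v <- x$values[x$mask]
  cat(sprintf("  in-mask values: min %.4g, median %.4g, max %.4g\n",
              min(v), median(v), max(v)))
  invisible(x)
}

#' @export
dim.stat_volume <- function(x) dim(x$values)

#' Read a volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expect one of `"3d"` (a single statistic/contrast map) or `"4d"`
#'   (a time series; returned as a 4D array with attributes rather than a
#'   `stat_volume`).
#' @return For `expect = "3d"` a [stat_volume()]; for `expect = "4d"` a 4D
#'   array with attributes `voxel_size` and `tr`.
#' @export
read_volume <- function(path, expect = c("3d", "4d")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  if (expect == "3d") {
    if (length(d) == 4L && d[4] == 1L) {
      img2 <- array(as.array(img)[, , , 1], d[1:3])
    } else if (length(d) != 3L) {
      stop("expected a 3D volume but ", path, " has ",
           length(d), " dimensions", call. = FALSE)
    } else {
      img2 <- as.array(img)
    }
    return(stat_volume(img2, voxel_size = pix[1:3], reference = img))
  }
  if (length(d) != 4L)
    stop("expected a 4D time series but ", path, " has ",
         length(d), " dimensions", call. = FALSE)
  out <- array(as.double(img), d)
  attr(out, "voxel_size") <- pix[1:3]
  attr(out, "tr") <- if (length(pix) >= 4) pix[4] else NA_real_
  attr(out, "reference") <- img
  out
}

#' Write a volume to a NIfTI-1 file
#'
#' Values are stored as 64-bit floats so that a write/read round trip is
#' bit-exact.  If the volume carries a reference header (because it was read
#' from disk) the affine and orientation are preserved.
#'
#' @param volume a [stat_volume()] or 3D array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, default `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  if (inherits(volume, "stat_volume")) {
    arr <- volume$values
    ref <- attr(volume, "reference")
    vs <- volume$voxel_size
  } else {
    arr <- volume
    ref <- NULL
    vs <- attr(volume, "voxel_size")
  }
  img <- if (!is.null(ref)) RNifti::asNifti(arr, reference = ref)
         else RNifti::asNifti(arr)
  if (is.null(ref) && !is.null(vs)) RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Derive a brain mask
#'
#' A user-supplied mask always takes precedence.  Otherwise voxels whose
#' absolute value exceeds `threshold` are kept; for a group of maps the
#' criterion is applied to the voxelwise mean absolute value.  An explicit
#' mask file is recommended for real data.
#'
#' @param x a [stat_volume()] or [group_sample()].
#' @param threshold finite scalar; default 0.
#' @param mask optional user mask (logical array, [stat_volume()], or path
#'   to a NIfTI file); overrides thresholding.
#' @return logical 3D array.
#' @export
derive_mask <- function(x, threshold = 0, mask = NULL) {
  if (!is.null(mask)) {
    if (is.character(mask)) mask <- read_volume(mask)
    if (inherits(mask, "stat_volume")) mask <- mask$values != 0
    mask <- array(as.logical(mask), dim(mask))
    if (!any(mask)) stop("supplied mask is empty", call. = FALSE)
    return(mask)
  }
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  ref <- if (inherits(x, "group_sample")) {
    Reduce(`+`, lapply(x$maps, function(m) abs(m$values))) / length(x$maps)
  } else if (inherits(x, "stat_volume")) {
    abs(x$values)
  } else {
    abs(x)
  }
  out <- ref > threshold
  if (!any(out))
    stop("derived mask is empty: nothing to analyse ",
         "(all |values| <= ", threshold, ")", call. = FALSE)
  out
}

#' Group of contrast maps
#'
#' Bundles per-subject contrast maps that share one voxel grid, mask and
#' voxel size.  For a two-sample analysis, `group_labels` assigns each map
#' to group 1 or 2.
#'
#' @param maps list of [stat_volume()]s or 3D arrays (at least 2), or a 4D
#'   array whose 4th dimension indexes subjects.
#' @param group_labels optional vector of length `n` with two levels.
#' @param voxel_size used when `maps` are plain arrays.
#' @return An object of class `group_sample`.
#' @export
group_sample <- function(maps, group_labels = NULL, voxel_size = c(1, 1, 1)) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    maps <- lapply(seq_len(dim(maps)[4]), function(i) maps[, , , i])
  }
  maps <- lapply(maps, function(m) {
    if (inherits(m, "stat_volume")) m else stat_volume(m, voxel_size = voxel_size)
  })
  n <- length(maps)
  if (n < 2L) stop("a group sample needs at least 2 maps", call. = FALSE)
  d0 <- dim(maps[[1]]$values)
  for (m in maps) {
    if (!identical(dim(m$values), d0))
      stop("all maps must share the same grid shape", call. = FALSE)
    if (!identical(m$voxel_size, maps[[1]]$voxel_size))
      stop("all maps must share the same voxel size", call. = FALSE)
  }
  if (!is.null(group_labels)) {
    if (length(group_labels) != n)
      stop("`group_labels` must have one entry per map", call. = FALSE)
    lev <- sort(unique(group_labels))  # group 1 = first label in sort order
    if (length(lev) != 2L)
      stop("two-sample mode needs exactly 2 group labels", call. = FALSE)
    group_labels <- as.integer(factor(group_labels, levels = lev))
    if (min(tabulate(group_labels, 2L)) < 2L)
      stop("each group needs at least 2 maps", call. = FALSE)
  }
  structure(list(maps = maps, group_labels = group_labels),
            class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  d <- dim(x$maps[[1]]$values)
  cat(sprintf("<group_sample> %d maps on a %dx%dx%d grid%s\n",
              length(x$maps), d[1], d[2], d[3],
              if (is.null(x$group_labels)) ""
              else sprintf(" (two groups: %s)",
                           paste(tabulate(x$group_labels, 2L), collapse = " vs "))))
  invisible(x)
}

#' @export
length.group_sample <- function(x) length(x$maps)

# stack a group sample into the n x V matrix the C++ kernels expect
sample_matrix <- function(sample) {
  V <- length(sample$maps[[1]]$values)
  X <- matrix(0, nrow = length(sample$maps), ncol = V)
  for (i in seq_along(sample$maps)) X[i, ] <- as.vector(sample$maps[[i]]$values)
  X
}
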