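#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response: a positive response peaking at
#' 6 s minus an undershoot peaking at 16 s with amplitude ratio 1/6,
#' normalised to unit peak height.
#'
#' @param t time in seconds (vector).
#' @param peak time-to-peak of the positive lobe (s).
#' @param undershoot time-to-peak of the undershoot (s).
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector, the HRF evaluated at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(abs(h))
}

#' GLM specification for a single-subject analysis
#'
#' @param tr repetition time in seconds.
#' @param events an [event_table()].
#' @param contrast named numeric vector of signed weights over condition
#'   labels, e.g. `c(A = 1, B = -1)`; labels must occur in `events`.
#' @param drift_order polynomial drift order fitted per run (default 3;
#'   an intercept per run is always included).
#' @param run_lengths number of volumes in each run, in run order.  If
#'   `NULL`, a single run spanning the whole series is assumed.
#' @param ar1 if `TRUE`, a lag-1 autoregressive prewhitening step
#'   (Cochrane-Orcutt with a pooled rho estimate) is applied before the
#'   final fit.  Off by default: the label permutations, not the noise
#'   model, carry the inference.
#' @return An object of class `glm_spec`.
#' @export
glm_spec <- function(tr, events, contrast, drift_order = 3L,
                     run_lengths = NULL, ar1 = FALSE) {
  stopifnot(tr > 0)
  if (!inherits(events, "event_table")) validate_events(events)
  labs <- unique(events$trial_type)
  if (is.null(names(contrast)) || !all(names(contrast) %in% labs))
    stop("contrast names must be condition labels present in the events (",
         paste(labs, collapse = ", "), ")", call. = FALSE)
  structure(list(tr = tr, events = events, contrast = contrast,
                 drift_order = as.integer(drift_order),
                 run_lengths = run_lengths, ar1 = isTRUE(ar1)),
            class = "glm_spec")
}

# Design matrix: one regressor per condition (boxcars convolved with the
# canonical HRF, shared across runs) plus per-run intercept and polynomial
# drift columns.
build_design <- function(spec, n_volumes, events = spec$events) {
  runs <- unique(events$run)
  run_lengths <- spec$run_lengths
  if (is.null(run_lengths)) {
    if (length(runs) > 1L)
      stop("multiple runs in events require `run_lengths`", call. = FALSE)
    run_lengths <- n_volumes
  }
  if (sum(run_lengths) != n_volumes)
    stop("sum(run_lengths) = ", sum(run_lengths), " but the series has ",
         n_volumes, " volumes", call. = FALSE)
  if (length(run_lengths) != length(runs))
    stop("run_lengths has ", length(run_lengths), " entries but events ",
         "name ", length(runs), " run(s)", call. = FALSE)
  tr <- spec$tr
  labs <- sort(unique(events$trial_type))
  oversample <- 16L
  dt <- tr / oversample
  cond <- matrix(0, n_volumes, length(labs),
                 dimnames = list(NULL, labs))
  run_start <- cumsum(c(0, run_lengths[-length(run_lengths)]))
  for (ri in seq_along(runs)) {
    Tr <- run_lengths[ri]
    ev <- events[events$run == runs[ri], , drop = FALSE]
    if (any(ev$onset + ev$duration > Tr * tr + 1e-9))
      stop("events in run ", runs[ri], " extend past the scan", call. = FALSE)
    ngrid <- Tr * oversample
    tgrid <- (seq_len(ngrid) - 1) * dt
    hrf <- canonical_hrf(seq(0, 32, by = dt))
    for (lab in labs) {
      evl <- ev[ev$trial_type == lab, , drop = FALSE]
      if (nrow(evl) == 0L) next
      box <- numeric(ngrid)
      for (k in seq_len(nrow(evl))) {
        on <- evl$onset[k]; off <- on + evl$duration[k]
        box[tgrid >= on & tgrid < off] <- 1
      }
      conv <- convolve(box, rev(hrf), type = "open")[seq_len(ngrid)] * dt
      scan_idx <- 1L + (seq_len(Tr) - 1L) * oversample
      cond[run_start[ri] + seq_len(Tr), lab] <- conv[scan_idx]
    }
  }
  # per-run intercept + orthogonal polynomial drift
  drift_cols <- list()
  for (ri in seq_along(runs)) {
    Tr <- run_lengths[ri]
    blk <- matrix(0, n_volumes, 1 + spec$drift_order)
    rows <- run_start[ri] + seq_len(Tr)
    blk[rows, 1] <- 1
    if (spec$drift_order > 0)
      blk[rows, -1] <- stats::poly(seq_len(Tr), spec$drift_order)
    colnames(blk) <- paste0("run", runs[ri], "_",
                            c("intercept", paste0("drift", seq_len(spec$drift_order))))
    drift_cols[[ri]] <- blk
  }
  X <- cbind(cond, do.call(cbind, drift_cols))
  attr(X, "conditions") <- labs
  X
}

#' Single-subject GLM contrast z-map
#'
#' Fits an ordinary-least-squares GLM per voxel (boxcar regressors
#' convolved with the canonical double-gamma HRF, per-run polynomial
#' drift), forms the contrast t statistic
#' `t = c'b / sqrt(s2 c'(X'X)^-1 c)` and maps it to z as in
#' [onesample_z()].
#'
#' @param bold 4D array (x, y, z, time) or path to a 4D NIfTI file.
#' @param spec a [glm_spec()].
#' @param mask logical 3D array; default: voxels with non-zero temporal
#'   variance.
#' @param cap cap on `|z|`.
#' @return A [stat_volume()] z-map with attributes `t`, `dof` and
#'   `effect` (the contrast estimate map).
#' @export
glm_contrast_z <- function(bold, spec, mask = NULL, cap = Z_CAP) {
  if (is.character(bold)) bold <- read_volume(bold, expect = "4d")
  d <- dim(bold)
  if (length(d) != 4L) stop("`bold` must be 4D", call. = FALSE)
  nT <- d[4]
  X <- build_design(spec, nT)
  Y <- matrix(bold, prod(d[1:3]), nT)
  if (is.null(mask)) {
    mask <- array(matrixStats_rowVars(Y) > 0, d[1:3])
  }
  fit <- fit_glm_contrast(X, t(Y[as.vector(mask), , drop = FALSE]), spec, cap)
  zarr <- array(0, d[1:3]); zarr[mask] <- fit$z
  tarr <- array(0, d[1:3]); tarr[mask] <- fit$t
  earr <- array(0, d[1:3]); earr[mask] <- fit$effect
  vs <- attr(bold, "voxel_size"); if (is.null(vs)) vs <- c(1, 1, 1)
  out <- stat_volume(zarr, mask = mask, voxel_size = vs)
  attr(out, "t") <- tarr
  attr(out, "dof") <- fit$dof
  attr(out, "effect") <- earr
  out
}

# OLS contrast fit shared by the observed map and the permutation refits.
# Y is T x Vmask.
fit_glm_contrast <- function(X, Y, spec, cap = Z_CAP) {
  if (spec$ar1) {
    rho <- estimate_ar1(X, Y)
    n <- nrow(X)
    X <- X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE]
    Y <- Y[-1, , drop = FALSE] - rho * Y[-n, , drop = FALSE]
  }
  qrx <- qr(X)
  p <- ncol(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cw <- numeric(p)
  names(cw) <- colnames(X)
  cw[names(spec$contrast)] <- spec$contrast
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - p
  sigma2 <- colSums(res^2) / dof
  xtxinv_c <- backsolve(qr.R(qrx), forwardsolve(t(qr.R(qrx)), cw[qrx$pivot]))
  cvar <- sum(cw[qrx$pivot] * xtxinv_c)
  effect <- as.vector(crossprod(cw, beta))
  se <- sqrt(sigma2 * cvar)
  t <- effect / se
  # zero residual variance: exact fit (capped z) or an identically zero
  # contrast (z = 0)
  t[se == 0] <- sign(effect[se == 0]) * 1e10
  z <- cpp_t_to_z(t, dof, cap)
  list(t = t, z = z, dof = dof, effect = effect, beta = beta)
}

estimate_ar1 <- function(X, Y) {
  beta <- qr.coef(qr(X), Y)
  res <- Y - X %*% beta
  n <- nrow(res)
  num <- sum(res[-1, ] * res[-n, ])
  den <- sum(res[-n, ]^2)
  if (den <= 0) 0 else max(min(num / den, 0.95), -0.95)
}

# row variances without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}
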