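#' Spatially autocorrelated noise specification
#'
#' Stationary Gaussian noise whose target autocorrelation follows the
#' mixed Gaussian/exponential model popularised by AFNI's non-Gaussian ACF
#' fit: `ACF(r) = a exp(-r^2 / (2 b^2)) + (1 - a) exp(-r / c)` with `r`
#' in voxels.  The exponential component gives the heavy ACF tails seen in
#' real fMRI noise.
#'
#' @param a weight of the Gaussian component, in \[0, 1\].
#' @param b Gaussian width (voxels).
#' @param c exponential decay scale (voxels).
#' @param grid integer triple of grid dimensions.
#' @param voxel_size physical voxel size in mm (default 3 mm isotropic, a
#'   typical 3T acquisition).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(a = 0.5, b = 2, c = 2, grid = c(24, 24, 24),
                       voxel_size = c(3, 3, 3)) {
  stopifnot(a >= 0, a <= 1, b > 0, c > 0, length(grid) == 3, all(grid >= 4))
  structure(list(a = a, b = b, c = c, grid = as.integer(grid),
                 voxel_size = voxel_size),
            class = "noise_spec")
}

# target ACF at lag r (voxels)
acf_target <- function(spec, r) {
  spec$a * exp(-r^2 / (2 * spec$b^2)) + (1 - spec$a) * exp(-r / spec$c)
}

# spectral factor for synthesis; grids with odd dimensions are padded to
# even sizes and cropped after synthesis
noise_spectrum <- function(spec) {
  g <- spec$grid + spec$grid %% 2L
  ax <- lapply(g, function(n) pmin(0:(n - 1), n - (0:(n - 1))))  # min-image
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  K <- array(acf_target(spec, r), g)
  S <- Re(fft(K))
  # Periodising a truncated ACF can leave a little negative spectral mass;
  # clip it, warning only when it is substantial enough to distort the ACF.
  neg_mass <- -sum(S[S < 0])
  if (neg_mass > 1e-3 * sum(abs(S)))
    warning("ACF is not positive definite on this grid; ",
            signif(100 * neg_mass / sum(abs(S)), 2),
            "% of spectral mass clipped to zero", call. = FALSE)
  S[S < 0] <- 0
  # var(IFFT(sqrt(S) * FFT(white))) = mean(S)
  list(sqrt_S = sqrt(S), norm = sqrt(mean(S)), padded = g)
}

#' Simulate spatially autocorrelated Gaussian noise
#'
#' Spectral synthesis: the FFT of the target autocorrelation kernel is
#' square-rooted, used to modulate white Gaussian noise in the frequency
#' domain, and transformed back; the field is exactly Gaussian-marginal
#' and is normalised to unit variance.
#'
#' @param spec a [noise_spec()].
#' @param n number of independent realizations.
#' @param spectrum optional precomputed spectrum (from repeated calls with
#'   the same spec); computed on the fly otherwise.
#' @return A [stat_volume()] for `n = 1`, else a list of them.
#' @examples
#' v <- simulate_noise(noise_spec(grid = c(16, 16, 16)))
#' v
#' @export
simulate_noise <- function(spec, n = 1, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- noise_spectrum(spec)
  g <- spectrum$padded
  N <- prod(g)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- array(rnorm(N), g)
    y <- Re(fft(fft(w) * spectrum$sqrt_S, inverse = TRUE)) / N
    y <- y / spectrum$norm
    y <- y[seq_len(spec$grid[1]), seq_len(spec$grid[2]),
           seq_len(spec$grid[3]), drop = FALSE]
    out[[i]] <- stat_volume(array(y, spec$grid),
                            voxel_size = spec$voxel_size)
  }
  if (n == 1) out[[1]] else out
}

#' Synthetic signal specification
#'
#' Sphere- or stick-shaped activation supports.  A sphere contains every
#' voxel whose centre lies within Euclidean `radius` of `center` (closed
#' ball; radius 2 gives 33 voxels).  A stick is a 1-voxel-thick segment of
#' `length` voxels starting at `start` and stepping by `step` (an
#' axis-aligned or diagonal unit step with components in \{-1, 0, 1\}).
#'
#' @param shape `"sphere"` or `"stick"`.
#' @param amplitude added signal height in units of the noise SD (the
#'   SNR); study-mode simulations use values in \[0.4, 1.0\].
#' @param center,radius sphere parameters (voxel coordinates).
#' @param start,step,length stick parameters.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(shape = c("sphere", "stick"), amplitude,
                        center = NULL, radius = NULL, start = NULL,
                        step = c(1, 0, 0), length = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1)
  if (shape == "sphere") {
    stopifnot(!is.null(center), !is.null(radius), radius >= 0)
  } else {
    stopifnot(!is.null(start), !is.null(length), length >= 1,
              all(step %in% -1:1), any(step != 0))
  }
  structure(list(shape = shape, amplitude = amplitude, center = center,
                 radius = radius, start = start, step = step,
                 length = length),
            class = "signal_spec")
}

# voxel index matrix of a signal's support
signal_support <- function(sig, grid) {
  idx <- if (sig$shape == "sphere") {
    r <- ceiling(sig$radius)
    g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    g <- g[rowSums(g^2) <= sig$radius^2 + 1e-12, , drop = FALSE]
    sweep(g, 2, sig$center, `+`)
  } else {
    outer(0:(sig$length - 1), sig$step) +
      matrix(sig$start, sig$length, 3, byrow = TRUE)
  }
  if (any(idx < 1) || any(sweep(idx, 2, grid, `>`)))
    stop("signal support extends outside the grid", call. = FALSE)
  idx
}

#' Add synthetic signals to a noise volume
#'
#' @param noise a [stat_volume()].
#' @param signals list of [signal_spec()]s.  Overlapping supports have
#'   their amplitudes summed, with a warning.
#' @return list with `volume` (noise + signal) and `truth` (logical array,
#'   the union of supports).
#' @export
inject_signal <- function(noise, signals) {
  grid <- dim(noise$values)
  truth <- array(FALSE, grid)
  amp <- array(0, grid)
  for (sig in signals) {
    idx <- signal_support(sig, grid)
    if (any(truth[idx]))
      warning("overlapping signal supports; amplitudes sum", call. = FALSE)
    amp[idx] <- amp[idx] + sig$amplitude
    truth[idx] <- TRUE
  }
  noise$values <- noise$values + amp
  list(volume = noise, truth = truth)
}

#' Simulate a group of contrast maps
#'
#' Each map is an independent noise realization plus the identical signal,
#' emulating a group study in which every subject carries the same true
#' activation. The default of 26 maps matches a typical fMRI group-study
#' sample size.
#'
#' @param n_maps group size (default 26).
#' @param noise a [noise_spec()].
#' @param signals list of [signal_spec()]s (empty for a complete-null
#'   group).
#' @param seed optional integer seed.
#' @return A [group_sample()] with attribute `truth` (logical array; all
#'   `FALSE` when `signals` is empty).
#' @export
simulate_group <- function(n_maps = 26L, noise = noise_spec(),
                           signals = list(), seed = NULL) {
  stopifnot(n_maps >= 2)
  spectrum <- noise_spectrum(noise)
  with_seed(seed, {
    maps <- simulate_noise(noise, n = n_maps, spectrum = spectrum)
    truth <- array(FALSE, noise$grid)
    if (length(signals)) {
      maps <- lapply(maps, function(m) {
        inj <- inject_signal(m, signals)
        truth <<- inj$truth
        inj$volume
      })
    }
    out <- group_sample(maps)
    attr(out, "truth") <- truth
    out
  })
}

#' False-positive-rate harness under the complete null
#'
#' Simulates `n_datasets` signal-free groups of autocorrelated noise maps,
#' runs the full group pipeline on each, and reports how often anything at
#' all reaches significance.  Under the global null any discovery is
#' false, so FDR control implies the any-detection rate stays at or below
#' `fdr_q` (weak FWER control).
#'
#' @param n_datasets number of simulated datasets (default 100).
#' @param n_maps group size per dataset (default 20).
#' @param noise a [noise_spec()].
#' @param n_permutations permutations per dataset (default 500).
#' @param fdr_q significance level.
#' @param seed integer seed for the whole harness.
#' @param filter,kernel filter configuration, as in [lisa_group()].
#' @return A `data.frame` with one row per dataset (`any_detection`,
#'   `n_significant`, `fdp`) and attributes `prop_any` (proportion with at
#'   least one detection), `mean_fdp` and `mc_error` (binomial standard
#'   error of `prop_any`).
#' @export
run_fpr_harness <- function(n_datasets = 100L, n_maps = 20L,
                            noise = noise_spec(), n_permutations = 500L,
                            fdr_q = 0.05, seed = 1L,
                            filter = filter_params(),
                            kernel = "bilateral") {
  check_config(n_permutations, fdr_q)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * n_datasets),
                                  nrow = 2L))
  rows <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    grp <- simulate_group(n_maps, noise, signals = list(),
                          seed = seeds[1L, d])
    res <- lisa_group(grp, mask = NULL, n_permutations = n_permutations,
                      fdr_q = fdr_q, seed = seeds[2L, d], filter = filter,
                      kernel = kernel)
    nsig <- sum(res$significant)
    rows[[d]] <- data.frame(dataset = d, any_detection = nsig > 0L,
                            n_significant = nsig,
                            fdp = as.numeric(nsig > 0L))
  }
  out <- do.call(rbind, rows)
  p <- mean(out$any_detection)
  attr(out, "prop_any") <- p
  attr(out, "mean_fdp") <- mean(out$fdp)
  attr(out, "mc_error") <- sqrt(fdr_q * (1 - fdr_q) / n_datasets)
  out
}

#' Power harness comparing filtering pipelines
#'
#' Simulates groups with a known signal and measures the true-positive
#' rate at `FDR < fdr_q` for each requested pipeline, on the *same*
#' simulated data (paired comparison):
#' \describe{
#'   \item{`bilateral`}{post-test bilateral filter (the LISA pipeline);}
#'   \item{`gauss_post`}{the same machinery with the range kernel disabled
#'     (a linear spatial filter applied after the test);}
#'   \item{`gauss_pre`}{conventional Gaussian smoothing
#'     (`fwhm = pre_fwhm` mm) of each input map before the t-test, no
#'     post-test filter;}
#'   \item{`none`}{no spatial filtering.}
#' }
#' All four arms share the identical permutation-FDR machinery.
#'
#' @param scenarios `data.frame` with columns `shape` ("sphere"/"stick"),
#'   `size` (sphere radius or stick length, voxels) and `snr` (amplitude
#'   in noise-SD units).
#' @param methods subset of the four pipeline names.
#' @param n_reps simulated datasets per scenario (default 50).
#' @param n_maps group size (default 20).
#' @param noise a [noise_spec()].
#' @param n_permutations permutations per analysis.
#' @param fdr_q significance level.
#' @param seed integer seed.
#' @param pre_fwhm pre-test smoothing kernel fwhm in mm (default 6).
#' @param filter filter configuration shared by the post-test arms.
#' @return Long `data.frame` (scenario x method x rep) with `tpr` and
#'   `n_false`; attribute `summary` holds mean TPR per scenario/method.
#' @export
run_power_harness <- function(scenarios,
                              methods = c("bilateral", "gauss_post",
                                          "gauss_pre", "none"),
                              n_reps = 50L, n_maps = 20L,
                              noise = noise_spec(), n_permutations = 100L,
                              fdr_q = 0.05, seed = 1L, pre_fwhm = 6,
                              filter = filter_params()) {
  methods <- match.arg(methods, several.ok = TRUE)
  check_config(n_permutations, fdr_q)
  centre <- round(noise$grid / 2)
  seeds <- with_seed(seed, array(sample.int(.Machine$integer.max - 1L,
                                            2L * n_reps * nrow(scenarios)),
                                 c(2L, n_reps, nrow(scenarios))))
  rows <- list()
  for (sc in seq_len(nrow(scenarios))) {
    sig <- scenario_signal(scenarios[sc, ], centre)
    for (rep in seq_len(n_reps)) {
      grp <- simulate_group(n_maps, noise, signals = list(sig),
                            seed = seeds[1L, rep, sc])
      truth <- attr(grp, "truth")
      for (m in methods) {
        res <- run_method(m, grp, n_permutations, fdr_q,
                          seeds[2L, rep, sc], filter, pre_fwhm)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, shape = scenarios$shape[sc],
          size = scenarios$size[sc], snr = scenarios$snr[sc],
          method = m, rep = rep,
          tpr = mean(res$significant[truth]),
          n_false = sum(res$significant & !truth))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(tpr ~ scenario + shape + size +
                                             snr + method, out, mean)
  out
}

scenario_signal <- function(row, centre) {
  if (row$shape == "sphere")
    signal_spec("sphere", amplitude = row$snr, center = centre,
                radius = row$size)
  else
    signal_spec("stick", amplitude = row$snr,
                start = centre - c(floor(row$size / 2), 0, 0),
                step = c(1, 0, 0), length = row$size)
}

run_method <- function(method, grp, n_permutations, fdr_q, seed, filter,
                       pre_fwhm) {
  switch(method,
    bilateral = lisa_group(grp, n_permutations = n_permutations,
                           fdr_q = fdr_q, seed = seed, filter = filter,
                           kernel = "bilateral"),
    gauss_post = lisa_group(grp, n_permutations = n_permutations,
                            fdr_q = fdr_q, seed = seed, filter = filter,
                            kernel = "gaussian"),
    gauss_pre = {
      sm <- grp
      sm$maps <- lapply(sm$maps, gaussian_smooth, fwhm = pre_fwhm)
      lisa_group(sm, n_permutations = n_permutations, fdr_q = fdr_q,
                 seed = seed, filter = filter, kernel = "none")
    },
    none = lisa_group(grp, n_permutations = n_permutations, fdr_q = fdr_q,
                      seed = seed, filter = filter, kernel = "none"),
    stop("unknown method: ", method, call. = FALSE))
}
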