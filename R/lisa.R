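#' Group-level LISA analysis
#'
#' Full pipeline for a group of contrast maps: voxelwise one-sample
#' (sign-flip null) or two-sample (group-shuffle null) t-test converted to
#' a z-map, edge-preserving bilateral filtering of the z-map, and
#' permutation-based FDR control via the conservative two-component
#' mixture model.
#'
#' @param sample a [group_sample()]; supply `group_labels` for two-sample
#'   mode (selected automatically).
#' @param mask user mask (logical array, [stat_volume()] or file path);
#'   defaults to voxels where the mean absolute input exceeds 0 — an
#'   explicit mask is recommended for real data.
#' @param n_permutations number of random permutations (default 5000).
#' @param fdr_q significance level (default 0.05).
#' @param seed integer seed; two runs with the same configuration and seed
#'   produce identical output.
#' @param filter a [filter_params()].
#' @param kernel `"bilateral"` (default), `"gaussian"` or `"none"` — the
#'   latter two mainly serve the validation harnesses.
#' @param cap cap on |z|.
#' @param keep_null keep the pooled null values in the result (they can be
#'   large); default `FALSE` retains only summary quantiles.
#' @return An object of class `lisa_result` with elements `fdr`
#'   ([estimate_fdr()] map), `significant` (logical array at `fdr_q`),
#'   `lambda`, `z`, `scale`, `config`.
#' @examples
#' sig <- signal_spec("sphere", amplitude = 1, center = c(8, 8, 8), radius = 3)
#' grp <- simulate_group(12, noise_spec(grid = c(16, 16, 16)),
#'                       signals = list(sig), seed = 1)
#' res <- lisa_group(grp, n_permutations = 50, seed = 2)
#' res
#' mean(res$significant[attr(grp, "truth")])  # true-positive rate
#' @export
lisa_group <- function(sample, mask = NULL, n_permutations = 5000L,
                       fdr_q = 0.05, seed = NULL, filter = filter_params(),
                       kernel = c("bilateral", "gaussian", "none"),
                       cap = Z_CAP, keep_null = FALSE) {
  kernel <- match.arg(kernel)
  check_config(n_permutations, fdr_q)
  two <- !is.null(sample$group_labels)
  if (!is.null(mask) && !is.logical(mask))
    mask <- derive_mask(sample, mask = mask)
  nul <- build_null_ensemble(if (two) "group2" else "group1",
                             sample = sample, mask = mask,
                             n_permutations = n_permutations, seed = seed,
                             filter = filter, kernel = kernel, cap = cap)
  finish_lisa(nul, fdr_q, mode = if (two) "group2" else "group1",
              n_permutations = n_permutations, seed = seed, filter = filter,
              kernel = kernel, keep_null = keep_null)
}

#' Single-subject LISA analysis
#'
#' GLM contrast on a 4D time series converted to a z-map, bilateral
#' filtering, and FDR control against a task-label-permutation null
#' (labels are shuffled only within runs, preserving the temporal
#' structure of the data).
#'
#' @param bold 4D array or path to a 4D NIfTI file.
#' @param events an [event_table()] or path to a BIDS-style TSV.
#' @param contrast named weight vector over condition labels, or a string
#'   like `"A-B"`.
#' @param tr repetition time in seconds (taken from the NIfTI header when
#'   `bold` is a path and the header carries it).
#' @param run_lengths volumes per run (single run assumed if `NULL`).
#' @param drift_order per-run polynomial drift order.
#' @param resample_labels permute labels by independent resampling instead
#'   of a multiset shuffle.
#' @inheritParams lisa_group
#' @return A `lisa_result`.
#' @export
lisa_single <- function(bold, events, contrast, tr = NULL, mask = NULL,
                        n_permutations = 5000L, fdr_q = 0.05, seed = NULL,
                        filter = filter_params(), run_lengths = NULL,
                        drift_order = 3L, resample_labels = FALSE,
                        kernel = c("bilateral", "gaussian", "none"),
                        cap = Z_CAP, keep_null = FALSE) {
  kernel <- match.arg(kernel)
  check_config(n_permutations, fdr_q)
  if (is.character(bold)) bold <- read_volume(bold, expect = "4d")
  if (is.character(events)) events <- read_events(events)
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  if (is.null(tr)) {
    tr <- attr(bold, "tr")
    if (is.null(tr) || !is.finite(tr) || tr <= 0)
      stop("`tr` must be given (not present in the input header)",
           call. = FALSE)
  }
  spec <- glm_spec(tr, events, contrast, drift_order = drift_order,
                   run_lengths = run_lengths)
  nul <- build_null_ensemble("single", bold = bold, spec = spec, mask = mask,
                             n_permutations = n_permutations, seed = seed,
                             filter = filter, kernel = kernel, cap = cap,
                             resample_labels = resample_labels)
  finish_lisa(nul, fdr_q, mode = "single", n_permutations = n_permutations,
              seed = seed, filter = filter, kernel = kernel,
              keep_null = keep_null)
}

#' Generic LISA analysis
#'
#' Applies the filter-then-FDR machinery to a user-supplied unpermuted
#' statistic map plus a set of maps computed with the same statistic under
#' random permutations (e.g. MVPA weight maps under label shuffles).
#'
#' @param observed unpermuted map ([stat_volume()] or file path).
#' @param permuted list of maps, vector of file paths, or a 4D array; at
#'   least 30 are required (the filter scale factor derives from the first
#'   30).
#' @inheritParams lisa_group
#' @return A `lisa_result`.
#' @export
lisa_generic <- function(observed, permuted, mask = NULL, fdr_q = 0.05,
                         filter = filter_params(),
                         kernel = c("bilateral", "gaussian", "none"),
                         keep_null = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(fdr_q > 0, fdr_q < 1)
  nul <- build_null_ensemble("generic", observed = observed,
                             permuted = permuted, mask = mask,
                             filter = filter, kernel = kernel)
  finish_lisa(nul, fdr_q, mode = "generic",
              n_permutations = nul$ensemble$count, seed = NULL,
              filter = filter, kernel = kernel, keep_null = keep_null)
}

check_config <- function(n_permutations, fdr_q) {
  if (n_permutations < 30L)
    stop("`n_permutations` must be at least 30 (the filter scale factor ",
         "is estimated from the first 30 permuted maps)", call. = FALSE)
  if (!(fdr_q > 0 && fdr_q < 1))
    stop("`fdr_q` must lie in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

finish_lisa <- function(nul, fdr_q, mode, n_permutations, seed, filter,
                        kernel, keep_null) {
  fdr <- estimate_fdr(nul$lambda, nul$ensemble)
  sig <- threshold_fdr(fdr, fdr_q)
  ens <- nul$ensemble
  structure(list(
    fdr = fdr,
    significant = sig,
    lambda = nul$lambda,
    z = nul$z,
    scale = nul$scale,
    status = nul$status,
    null_summary = list(count = ens$count,
                        quantiles = if (ens$kind == "values")
                          quantile(ens$values, c(0, .01, .5, .99, 1))
                        else NULL),
    ensemble = if (keep_null) ens else NULL,
    config = list(mode = mode, n_permutations = n_permutations,
                  fdr_q = fdr_q, seed = seed, filter = filter,
                  kernel = kernel, scale = nul$scale)),
    class = "lisa_result")
}

#' @export
print.lisa_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lisa_result> mode %s, %d permutations, kernel %s\n",
              cfg$mode, cfg$n_permutations, cfg$kernel))
  cat(sprintf("  scale factor %.4g; %d evaluable voxels\n",
              x$scale, sum(x$fdr$evaluable)))
  cat(sprintf("  %d voxels significant at FDR < %g\n",
              sum(x$significant), cfg$fdr_q))
  invisible(x)
}

# "A-B" / "A" / "A+B" -> named weight vector
parse_contrast <- function(s) {
  s <- gsub(" ", "", s)
  toks <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  w <- ifelse(startsWith(toks, "-"), -1, 1)
  names(w) <- sub("^[+-]", "", toks)
  w
}
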