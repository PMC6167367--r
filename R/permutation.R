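# Run code with a private RNG state derived from `seed`, restoring the
# caller's stream afterwards.  All permutation records are therefore
# reproducible from the seed alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation plan
#'
#' Materialises the permutation records for one of the three
#' exchangeability schemes:
#' \describe{
#'   \item{`sign_flip`}{one-sample group mode: each contrast map is
#'     independently negated with probability 1/2 (whole maps, so spatial
#'     autocorrelation is preserved).  Draws are i.i.d.; repeats and the
#'     identity permutation may occur.}
#'   \item{`group_shuffle`}{two-sample mode: every map is reassigned to
#'     group 1 or 2 with probability 1/2; assignments leaving either group
#'     with fewer than 2 maps are redrawn.}
#'   \item{`label_shuffle`}{single-subject mode: within each run the
#'     multiset of task labels is preserved and reassigned uniformly at
#'     random across that run's trials.  With `resample_labels = TRUE`
#'     labels are instead drawn independently with replacement from the
#'     run's label pool.}
#' }
#'
#' @param scheme one of `"sign_flip"`, `"group_shuffle"`,
#'   `"label_shuffle"`.
#' @param n_permutations number of permutations (at least 30, because the
#'   filter's scale factor is derived from the first 30 permuted maps).
#' @param seed integer seed; the records are a pure function of it.
#' @param n_maps number of maps (sign_flip / group_shuffle).
#' @param events an [event_table()] (label_shuffle).
#' @param resample_labels use independent resampling instead of a
#'   multiset shuffle (label_shuffle only).
#' @return An object of class `permutation_plan` whose `records` matrix
#'   has one column per permutation.
#' @export
permutation_plan <- function(scheme = c("sign_flip", "group_shuffle",
                                        "label_shuffle"),
                             n_permutations, seed = NULL, n_maps = NULL,
                             events = NULL, resample_labels = FALSE) {
  scheme <- match.arg(scheme)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 30L)
    stop("at least 30 permutations are required (the scale factor is ",
         "estimated from the first 30 permuted maps)", call. = FALSE)
  records <- with_seed(seed, {
    switch(scheme,
      sign_flip = {
        stopifnot(!is.null(n_maps))
        matrix(sample(c(-1, 1), n_maps * n_permutations, replace = TRUE),
               n_maps, n_permutations)
      },
      group_shuffle = {
        stopifnot(!is.null(n_maps))
        if (n_maps < 4L)
          stop("two-sample permutation needs at least 4 maps", call. = FALSE)
        rec <- matrix(0L, n_maps, n_permutations)
        for (p in seq_len(n_permutations)) {
          repeat {
            g <- sample(c(1L, 2L), n_maps, replace = TRUE)
            if (min(tabulate(g, 2L)) >= 2L) break
          }
          rec[, p] <- g
        }
        rec
      },
      label_shuffle = {
        stopifnot(!is.null(events))
        runs <- events$run
        for (r in unique(runs))
          if (length(unique(events$trial_type[runs == r])) < 2L)
            stop("run ", r, " has a single condition label: no ",
                 "exchangeable null exists", call. = FALSE)
        rec <- matrix(NA_character_, nrow(events), n_permutations)
        for (p in seq_len(n_permutations)) {
          lab <- events$trial_type
          for (r in unique(runs)) {
            idx <- which(runs == r)
            lab[idx] <- if (resample_labels)
              sample(events$trial_type[idx], length(idx), replace = TRUE)
            else sample(events$trial_type[idx])
          }
          rec[, p] <- lab
        }
        rec
      })
  })
  structure(list(scheme = scheme, n_permutations = n_permutations,
                 seed = seed, records = records,
                 resample_labels = resample_labels),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> %s, %d permutations, seed %s\n",
              x$scheme, x$n_permutations,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Sign-flip a group sample
#'
#' Each map is negated as a whole with probability 1/2 (or according to an
#' explicit flip vector), preserving within-map spatial autocorrelation.
#'
#' @param sample a [group_sample()].
#' @param flips optional vector of +1/-1, one per map; drawn from the
#'   current RNG stream if missing.
#' @return A new [group_sample()] with attribute `flips`.
#' @export
sign_flip <- function(sample, flips = NULL) {
  n <- length(sample$maps)
  if (is.null(flips)) flips <- sample(c(-1, 1), n, replace = TRUE)
  stopifnot(length(flips) == n, all(flips %in% c(-1, 1)))
  out <- sample
  for (i in seq_len(n)) out$maps[[i]]$values <- flips[i] * out$maps[[i]]$values
  attr(out, "flips") <- flips
  out
}

#' Shuffle two-sample group labels
#'
#' Every map is reassigned to one of the two groups with probability 1/2;
#' degenerate assignments (a group with fewer than 2 maps) are redrawn.
#'
#' @param sample a [group_sample()] with `group_labels`.
#' @return integer vector of permuted labels (1/2).
#' @export
group_shuffle <- function(sample) {
  n <- length(sample$maps)
  repeat {
    g <- sample(c(1L, 2L), n, replace = TRUE)
    if (min(tabulate(g, 2L)) >= 2L) return(g)
  }
}

#' Shuffle task labels within runs
#'
#' Within each run, the multiset of condition labels is preserved and
#' redistributed uniformly at random over that run's trials; onsets and
#' durations are untouched and no label crosses a run boundary.
#'
#' @param events an [event_table()].
#' @param resample draw labels independently with replacement from the
#'   run's pool instead of permuting the multiset.
#' @return A permuted [event_table()].
#' @export
label_shuffle <- function(events, resample = FALSE) {
  for (r in unique(events$run)) {
    idx <- which(events$run == r)
    if (length(unique(events$trial_type[idx])) < 2L)
      stop("run ", r, " has a single condition label: no exchangeable null",
           call. = FALSE)
    events$trial_type[idx] <- if (resample)
      sample(events$trial_type[idx], length(idx), replace = TRUE)
    else sample(events$trial_type[idx])
  }
  events
}

#' Null ensemble of filtered permuted values
#'
#' Pools the in-mask, evaluable values of all filtered permuted maps into
#' one empirical estimate of the null distribution F0.  Values are kept
#' exactly up to `cap` entries; beyond that a fixed 10,000-bin histogram
#' spanning the pooled range is used (bin edges are retained).
#'
#' @param values numeric vector of pooled filtered permuted values.
#' @param cap maximum number of values stored exactly.
#' @return An object of class `null_ensemble`.
#' @export
null_ensemble <- function(values, cap = 2e7) {
  n <- length(values)
  if (n == 0L) stop("empty null ensemble", call. = FALSE)
  if (n <= cap) {
    structure(list(kind = "values", values = values, count = n),
              class = "null_ensemble")
  } else {
    brk <- seq(min(values), max(values), length.out = 10001L)
    h <- findInterval(values, brk, rightmost.closed = TRUE)
    counts <- tabulate(h, nbins = 10000L)
    structure(list(kind = "histogram", breaks = brk,
                   cum_ge = rev(cumsum(rev(counts))), count = n),
              class = "null_ensemble")
  }
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s of %d pooled values\n", x$kind, x$count))
  invisible(x)
}

# exceedance probability P(null >= q) for each q (ties count).  The pool is
# large and the query set small, so exceedances are counted by binning the
# pool against the sorted query values instead of sorting the pool.
tail_prob <- function(ensemble, q) {
  if (ensemble$kind == "values") {
    u <- sort(unique(q))
    m <- length(u)
    cx <- findInterval(ensemble$values, u)      # #{u_i <= x} per pool value
    cnt <- tabulate(cx + 1L, nbins = m + 1L)    # cx = 0..m
    suffix <- rev(cumsum(rev(cnt)))             # suffix[k+1] = #{cx >= k}
    ge <- suffix[findInterval(q, u) + 1L]       # #{x >= q}
    ge / ensemble$count
  } else {
    # histogram: whole bins above, plus a linear fraction of the bin q is in
    brk <- ensemble$breaks
    bin <- findInterval(q, brk, rightmost.closed = TRUE)
    bin <- pmax(pmin(bin, length(brk) - 1L), 1L)
    frac <- (q - brk[bin]) / (brk[bin + 1L] - brk[bin])
    ge_lower <- ensemble$cum_ge[bin]
    in_bin <- ge_lower - c(ensemble$cum_ge, 0)[bin + 1L]
    p <- (ge_lower - frac * in_bin) / ensemble$count
    p[q < brk[1]] <- 1
    p[q > brk[length(brk)]] <- 0
    p
  }
}

#' Build the null ensemble and the observed filtered map
#'
#' Orchestrates the full permutation pipeline for any mode: for each
#' permutation the statistic map is recomputed, scaled by the common
#' factor (pooled SD of the first 30 permuted z-maps), and filtered with
#' the identical parameters as the observed map; the in-mask evaluable
#' values are pooled into the ensemble.  The observed map goes through the
#' same scale-and-filter path with the identity permutation, but is not
#' added to the ensemble.
#'
#' @param mode `"group1"`, `"group2"`, `"single"` or `"generic"`.
#' @param sample a [group_sample()] (group modes).
#' @param bold,spec 4D series and [glm_spec()] (single mode).
#' @param observed,permuted observed map and list of permuted maps
#'   (generic mode).
#' @param mask logical array; derived from the inputs if `NULL`.
#' @param n_permutations,seed permutation count and seed (ignored in
#'   generic mode, where the permuted maps are supplied).
#' @param filter a [filter_params()].
#' @param kernel filter kernel passed to [bilateral_filter()].
#' @param cap z cap.
#' @param n_scale how many permuted maps set the scale factor.
#' @param resample_labels see [permutation_plan()].
#' @return list with `lambda` (observed filtered [stat_volume()]),
#'   `ensemble` ([null_ensemble()]), `z` (observed z-map), `scale`,
#'   `status`, `plan`.
#' @export
build_null_ensemble <- function(mode = c("group1", "group2", "single",
                                         "generic"),
                                sample = NULL, bold = NULL, spec = NULL,
                                observed = NULL, permuted = NULL,
                                mask = NULL, n_permutations = 5000L,
                                seed = NULL, filter = filter_params(),
                                kernel = c("bilateral", "gaussian", "none"),
                                cap = Z_CAP, n_scale = 30L,
                                resample_labels = FALSE) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  switch(mode,
    group1 = ,
    group2 = null_group(sample, mask, n_permutations, seed, filter, kernel,
                        cap, n_scale, two_sample = (mode == "group2")),
    single = null_single(bold, spec, mask, n_permutations, seed, filter,
                         kernel, cap, n_scale, resample_labels),
    generic = null_generic(observed, permuted, mask, filter, kernel, cap,
                           n_scale))
}

# ---- group modes: heavy lifting in C++ -------------------------------------

null_group <- function(sample, mask, n_permutations, seed, filter, kernel,
                       cap, n_scale, two_sample = FALSE) {
  if (two_sample && is.null(sample$group_labels))
    stop("two-sample mode needs `group_labels` in the sample", call. = FALSE)
  if (is.null(mask)) mask <- derive_mask(sample)
  d <- dim(sample$maps[[1]]$values)
  X <- sample_matrix(sample)
  n <- nrow(X)
  plan <- permutation_plan(if (two_sample) "group_shuffle" else "sign_flip",
                           n_permutations, seed, n_maps = n)
  stencil <- stencil_from_params(filter, sample$maps[[1]]$voxel_size)
  filter_kind <- switch(kernel, none = 0L, bilateral = 1L, gaussian = 2L)
  flips <- if (two_sample) matrix(1, n, 1) else plan$records
  groups <- if (two_sample) plan$records else matrix(1L, n, 1)
  storage.mode(groups) <- "integer"
  pool <- cpp_group_null_pool(X, as.integer(mask), dim(sample$maps[[1]]$values),
                              stencil$offsets, stencil$spatial_weights,
                              filter$sigma_r, filter$iterations, filter_kind,
                              two_sample, flips, groups, cap, n_scale, -1.0)
  # observed map: identity permutation through the identical pipeline
  zres <- if (two_sample)
    cpp_twosample_z(X, as.integer(mask), as.integer(sample$group_labels), cap)
  else cpp_onesample_z(X, as.integer(mask), rep(1, n), cap)
  zmap <- stat_volume(array(zres$z, d), mask = mask,
                      voxel_size = sample$maps[[1]]$voxel_size)
  attr(zmap, "t") <- array(zres$t, d)
  attr(zmap, "dof") <- zres$dof
  zscaled <- zmap
  zscaled$values <- zscaled$values / pool$scale
  lambda <- bilateral_filter(zscaled, filter, kernel, stencil = stencil,
                             mask = mask)
  status <- array(pool$status, d)
  stopifnot(identical(status, attr(lambda, "status")))
  list(lambda = lambda, ensemble = null_ensemble(pool$null_values),
       z = zmap, scale = pool$scale, status = status, plan = plan)
}

# ---- single-subject mode ----------------------------------------------------

null_single <- function(bold, spec, mask, n_permutations, seed, filter,
                        kernel, cap, n_scale, resample_labels) {
  if (is.character(bold)) bold <- read_volume(bold, expect = "4d")
  zmap <- glm_contrast_z(bold, spec, mask = mask, cap = cap)
  mask <- zmap$mask
  d <- dim(zmap$values)
  nT <- dim(bold)[4]
  Y <- t(matrix(bold, prod(d), nT)[as.vector(mask), , drop = FALSE])
  plan <- permutation_plan("label_shuffle", n_permutations, seed,
                           events = spec$events,
                           resample_labels = resample_labels)
  perm_zvals <- function(p) {
    ev <- spec$events
    ev$trial_type <- plan$records[, p]
    X <- build_design(spec, nT, events = ev)
    fit_glm_contrast(X, Y, spec, cap)$z
  }
  # scale factor from the first n_scale permuted maps (kept for reuse)
  first <- lapply(seq_len(n_scale), perm_zvals)
  scale <- sd(unlist(first, use.names = FALSE))
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate null: permuted maps have zero variance", call. = FALSE)
  stencil <- stencil_from_params(filter, zmap$voxel_size)
  filt <- function(zvals) {
    vol <- zmap
    vol$values[] <- 0
    vol$values[mask] <- zvals / scale
    bilateral_filter(vol, filter, kernel, stencil = stencil, mask = mask)
  }
  pooled <- vector("list", n_permutations)
  status <- NULL
  for (p in seq_len(n_permutations)) {
    zv <- if (p <= n_scale) first[[p]] else perm_zvals(p)
    fp <- filt(zv)
    if (is.null(status)) status <- attr(fp, "status")
    pooled[[p]] <- fp$values[attr(fp, "evaluable")]
  }
  lambda <- filt(zmap$values[mask])
  list(lambda = lambda,
       ensemble = null_ensemble(unlist(pooled, use.names = FALSE)),
       z = zmap, scale = scale, status = status, plan = plan)
}

# ---- generic mode -----------------------------------------------------------

null_generic <- function(observed, permuted, mask, filter, kernel, cap,
                         n_scale) {
  if (is.character(observed)) observed <- read_volume(observed)
  if (is.character(permuted) ||
      (is.list(permuted) && all(vapply(permuted, is.character, TRUE)))) {
    permuted <- lapply(permuted, read_volume)
  } else if (is.array(permuted) && length(dim(permuted)) == 4L) {
    permuted <- lapply(seq_len(dim(permuted)[4]),
                       function(i) permuted[, , , i])
  }
  if (length(permuted) < n_scale)
    stop("generic mode needs at least ", n_scale, " permuted maps (got ",
         length(permuted), ")", call. = FALSE)
  if (is.null(mask)) mask <- derive_mask(observed)
  sc <- scale_by_null_sd(observed, permuted, n_scale, mask)
  stencil <- stencil_from_params(filter, observed$voxel_size)
  filt <- function(m) {
    vol <- if (inherits(m, "stat_volume")) m
           else stat_volume(m, voxel_size = observed$voxel_size)
    bilateral_filter(vol, filter, kernel, stencil = stencil, mask = mask)
  }
  pooled <- lapply(sc$permuted, function(m) {
    fp <- filt(m)
    fp$values[attr(fp, "evaluable")]
  })
  lambda <- filt(sc$observed)
  list(lambda = lambda,
       ensemble = null_ensemble(unlist(pooled, use.names = FALSE)),
       z = observed, scale = sc$scale, status = attr(lambda, "status"),
       plan = NULL)
}
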