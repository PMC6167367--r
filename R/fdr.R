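#' Per-voxel FDR scores from the two-component mixture model
#'
#' Under the mixture `Fz = p0 F0 + p1 F1`, the tail-area false discovery
#' rate at level `lambda` is `Fdr(lambda) = p0 F0(lambda) / Fz(lambda)`.
#' `F0` is estimated from the pooled filtered permuted values and `Fz` from
#' the observed filtered map itself, both as empirical exceedance (right
#' tail) proportions: the method detects positive activations, so
#' exceedance is the operative tail (the literal left-tail form is
#' available for audit via `tail = "left"`).  `p0` is fixed at 1, the most
#' conservative choice.  Raw ratios are clipped to \[0, 1\] and then
#' monotonised q-value style — each voxel receives the smallest clipped
#' ratio attained at any threshold less than or equal to its own value —
#' so scores are monotone non-increasing in lambda and thresholding at any
#' level selects a single lambda cutoff.
#'
#' @param lambda the observed filtered map: a [stat_volume()] carrying the
#'   `evaluable` attribute set by [bilateral_filter()].
#' @param ensemble a [null_ensemble()].
#' @param p0 prior null probability (default 1, conservative).
#' @param tail `"right"` (exceedance, default) or `"left"` (the literal
#'   left-sided CDF ratio, for audit).
#' @return An object of class `fdr_map`: `scores` (3D array; discarded
#'   voxels carry 1, out-of-mask voxels `NA`), `evaluable` (logical
#'   array), plus bookkeeping fields.
#' @export
estimate_fdr <- function(lambda, ensemble, p0 = 1, tail = c("right", "left")) {
  tail <- match.arg(tail)
  stopifnot(p0 > 0, p0 <= 1)
  evaluable <- attr(lambda, "evaluable")
  if (is.null(evaluable)) evaluable <- lambda$mask
  lam <- lambda$values[evaluable]
  n <- length(lam)
  if (n == 0L) stop("no evaluable voxels", call. = FALSE)
  ord <- order(lam)
  sorted <- lam[ord]
  if (tail == "right") {
    # P(X >= lam), ties included on both sides
    s0 <- tail_prob(ensemble, sorted)
    n_lt <- findInterval(sorted, sorted, left.open = TRUE)
    sz <- (n - n_lt) / n
  } else {
    s0 <- 1 - tail_prob(ensemble, sorted) +
      exact_mass(ensemble, sorted)
    sz <- findInterval(sorted, sorted) / n
  }
  raw <- pmin(p0 * s0 / sz, 1)
  # q-value monotonisation: min of raw over all thresholds <= lambda
  qval <- if (tail == "right") cummin(raw) else rev(cummin(rev(raw)))
  scores <- numeric(n)
  scores[ord] <- qval
  d <- dim(lambda$values)
  out <- array(NA_real_, d)
  status <- attr(lambda, "status")
  if (!is.null(status)) out[status == VOX_DISCARDED] <- 1
  out[evaluable] <- scores
  structure(list(scores = out, evaluable = evaluable, p0 = p0, tail = tail,
                 n_null = ensemble$count, voxel_size = lambda$voxel_size),
            class = "fdr_map")
}

# P(X == q) for a value-backed ensemble (0 for histograms); keeps the
# left-tail CDF inclusive of ties, mirroring the right tail.  Audit path
# only, so sorting the pool here is acceptable.
exact_mass <- function(ensemble, q) {
  if (ensemble$kind != "values") return(0)
  v <- sort(ensemble$values)
  (findInterval(q, v) - findInterval(q, v, left.open = TRUE)) /
    ensemble$count
}

#' @export
print.fdr_map <- function(x, ...) {
  sc <- x$scores[x$evaluable]
  cat(sprintf("<fdr_map> %d evaluable voxels, null pool %d values (p0 = %g, %s tail)\n",
              sum(x$evaluable), x$n_null, x$p0, x$tail))
  cat(sprintf("  scores: min %.4g, median %.4g; %d voxels < 0.05\n",
              min(sc), median(sc), sum(sc < 0.05)))
  invisible(x)
}

#' Threshold an FDR map
#'
#' @param fdr an [estimate_fdr()] result.
#' @param q significance level in (0, 1\]; voxels with score `< q` that are
#'   evaluable are marked significant (at the degenerate `q = 1` every
#'   evaluable voxel passes).  Discarded voxels are never significant.
#' @return logical 3D array of significant voxels.
#' @export
threshold_fdr <- function(fdr, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  sig <- if (q >= 1) fdr$evaluable
         else !is.na(fdr$scores) & fdr$scores < q & fdr$evaluable
  array(sig, dim(fdr$scores))
}
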