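# Independent brute-force oracles, deliberately written with plain R loops
# and no shared code with the package internals.

# enumerate the radius-r cube-minus-corners stencil by brute force
oracle_stencil_offsets <- function(r) {
  out <- NULL
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (r >= 1 && abs(dx) == r && abs(dy) == r && abs(dz) == r) next
    out <- rbind(out, c(dx, dy, dz))
  }
  out
}

# naive O(V * |stencil|) edge-preserving filter with the full boundary logic
oracle_filter <- function(values, mask, offsets, gs, sigma_r, iterations,
                          use_range = TRUE) {
  d <- dim(values)
  K <- nrow(offsets)
  need <- ceiling(K / 2)
  n18 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  n18 <- n18[rowSums(n18^2) %in% c(1, 2), ]
  v <- mask
  z <- values
  z[!v] <- 0
  status <- array(0L, d)
  for (it in seq_len(iterations)) {
    newz <- array(0, d)
    newv <- v
    st <- array(0L, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (s in 1:d[3]) {
      if (!v[x, y, s]) next
      nb <- cbind(x + offsets[, 1], y + offsets[, 2], s + offsets[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      ok[ok] <- v[nb[ok, , drop = FALSE]]
      if (sum(ok) >= need) {
        zj <- z[nb[ok, , drop = FALSE]]
        w <- gs[ok]
        if (use_range) w <- w * exp(-(z[x, y, s] - zj)^2 / sigma_r)
        newz[x, y, s] <- sum(w * zj) / sum(w)
        st[x, y, s] <- 1L
      } else {
        nb2 <- cbind(x + n18[, 1], y + n18[, 2], s + n18[, 3])
        ok2 <- nb2[, 1] >= 1 & nb2[, 1] <= d[1] & nb2[, 2] >= 1 &
          nb2[, 2] <= d[2] & nb2[, 3] >= 1 & nb2[, 3] <= d[3]
        ok2[ok2] <- v[nb2[ok2, , drop = FALSE]]
        if (sum(ok2) >= 9) {
          newz[x, y, s] <- median(c(z[nb2[ok2, , drop = FALSE]], z[x, y, s]))
          st[x, y, s] <- 2L
        } else {
          st[x, y, s] <- 3L
          newv[x, y, s] <- FALSE
        }
      }
    }
    v <- newv
    z <- newz
    z[!v] <- 0
    status <- st
  }
  # a voxel discarded at any iteration stays discarded
  status[mask & !v] <- 3L
  list(values = z, status = status)
}

# direct quantile-transform t -> z
oracle_t_to_z <- function(t, dof, cap = 8.2) {
  z <- qnorm(pt(t, dof))
  pmin(pmax(z, -cap), cap)
}

# direct-counting tail-area Fdr at each observed value (no monotonisation)
oracle_raw_fdr <- function(obs, null, p0 = 1) {
  sapply(obs, function(l) {
    s0 <- mean(null >= l)
    sz <- mean(obs >= l)
    min(p0 * s0 / sz, 1)
  })
}

rand_volume <- function(dims, seed, mask_frac = 1) {
  set.seed(seed)
  vals <- array(rnorm(prod(dims)), dims)
  mask <- array(runif(prod(dims)) < mask_frac, dims)
  list(values = vals, mask = mask)
}

default_stencil <- function() build_stencil(2, 2.0)

# shorter correlation lengths keep the periodised ACF positive definite on
# the very small grids the unit tests use
tiny_noise <- function(grid = c(12, 12, 12))
  noise_spec(b = 1.5, c = 1.5, grid = grid)

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
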