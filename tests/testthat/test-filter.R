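make_vol <- function(values, mask = NULL)
  stat_volume(values, mask = mask, voxel_size = c(1, 1, 1))

test_that("filtering a constant map returns it unchanged (any iterations)", {
  d <- c(10, 10, 10)
  vol <- make_vol(array(3.7, d))
  for (iters in c(1L, 2L, 4L)) {
    for (kern in c("bilateral", "gaussian")) {
      out <- bilateral_filter(vol, filter_params(iterations = iters),
                              kernel = kern)
      ev <- attr(out, "evaluable")
      expect_true(any(ev))
      expect_equal(out$values[ev], rep(3.7, sum(ev)), tolerance = 1e-12)
    }
  }
})

test_that("a strong isolated spike survives a narrow range kernel", {
  d <- c(11, 11, 11)
  vals <- array(0, d)
  vals[6, 6, 6] <- 10
  out <- bilateral_filter(make_vol(vals), filter_params(sigma_r = 0.5),
                          kernel = "bilateral")
  expect_gt(out$values[6, 6, 6], 10 * 0.99)  # edge preservation
  # whereas the linear filter smears it heavily
  lin <- bilateral_filter(make_vol(vals), filter_params(), kernel = "gaussian")
  expect_lt(lin$values[6, 6, 6], 5)
})

test_that("sigma_r -> Inf recovers the spatially weighted linear average", {
  v <- rand_volume(c(9, 9, 9), seed = 41)
  vol <- make_vol(v$values)
  st <- default_stencil()
  lin <- bilateral_filter(vol, filter_params(iterations = 1),
                          kernel = "gaussian")
  prev <- NULL
  for (sr in c(10, 100, 1e4, 1e8)) {
    bi <- bilateral_filter(vol, filter_params(sigma_r = sr, iterations = 1),
                           kernel = "bilateral")
    dev <- max(abs(bi$values - lin$values))
    if (!is.null(prev)) expect_lte(dev, prev + 1e-12)  # monotone approach
    prev <- dev
  }
  expect_lt(prev, 1e-6)
})

test_that("filter matches the brute-force double-loop oracle", {
  st <- default_stencil()
  cases <- list(
    list(dims = c(9, 9, 9), frac = 1, iters = 1L),
    list(dims = c(8, 9, 10), frac = 0.75, iters = 2L),
    list(dims = c(10, 10, 10), frac = 0.9, iters = 2L))
  for (cs in seq_along(cases)) {
    cc <- cases[[cs]]
    v <- rand_volume(cc$dims, seed = 100 + cs, mask_frac = cc$frac)
    for (use_range in c(TRUE, FALSE)) {
      got <- bilateral_filter(make_vol(v$values, v$mask),
                              filter_params(iterations = cc$iters),
                              kernel = if (use_range) "bilateral" else "gaussian")
      want <- oracle_filter(v$values, v$mask, st$offsets, st$spatial_weights,
                            2.0, cc$iters, use_range)
      expect_identical(attr(got, "status"), want$status,
                       info = sprintf("case %d range %s", cs, use_range))
      ev <- want$status == 1L | want$status == 2L
      rel <- abs(got$values[ev] - want$values[ev]) /
        pmax(abs(want$values[ev]), 1e-12)
      expect_lt(max(rel), 1e-10)
    }
  }
})

test_that("boundary rule: median fallback and discard fire as specified", {
  # a 3x3x3 island inside a big empty volume: every island voxel keeps far
  # fewer than half of the 117-stencil, but its 18-neighbourhood is mostly
  # inside, so the centre uses the median rule
  d <- c(11, 11, 11)
  mask <- array(FALSE, d)
  mask[5:7, 5:7, 5:7] <- TRUE
  v <- rand_volume(d, seed = 7)
  out <- bilateral_filter(make_vol(v$values, mask), filter_params())
  status <- attr(out, "status")
  centre_18 <- sum(mask[cbind(6 + oracle_stencil_offsets(1)[, 1],
                              6 + oracle_stencil_offsets(1)[, 2],
                              6 + oracle_stencil_offsets(1)[, 3])]) - 1L
  expect_gte(centre_18, 9L)
  expect_equal(status[6, 6, 6], 2L)  # median fallback
  # median value matches a direct computation at iteration 1
  one <- bilateral_filter(make_vol(v$values, mask),
                          filter_params(iterations = 1))
  nb <- oracle_stencil_offsets(1) + matrix(6, 19, 3)
  vals <- v$values[nb][mask[nb]]
  expect_equal(one$values[6, 6, 6], median(vals))
  # island corners keep too few 18-neighbours and are discarded
  expect_equal(status[5, 5, 5], 3L)
  expect_false(attr(out, "evaluable")[5, 5, 5])
  # interior voxels of a full mask never enter the fallback
  full <- bilateral_filter(make_vol(v$values), filter_params())
  expect_true(all(attr(full, "status")[3:9, 3:9, 3:9] == 1L))
})

test_that("changing one voxel only affects an iterations*radius ball", {
  v <- rand_volume(c(13, 13, 13), seed = 9)
  p <- filter_params(iterations = 2)
  a <- bilateral_filter(make_vol(v$values), p)
  v2 <- v$values
  v2[7, 7, 7] <- v2[7, 7, 7] + 5
  b <- bilateral_filter(make_vol(v2), p)
  changed <- which(abs(a$values - b$values) > 1e-12, arr.ind = TRUE)
  cheb <- apply(abs(sweep(changed, 2, c(7, 7, 7))), 1, max)
  expect_lte(max(cheb), 2 * 2)  # iterations x radius
})

test_that("out-of-mask voxels never contribute", {
  v <- rand_volume(c(9, 9, 9), seed = 15, mask_frac = 0.8)
  a <- bilateral_filter(make_vol(v$values, v$mask), filter_params())
  v2 <- v$values
  v2[!v$mask] <- 99  # garbage outside the mask
  b <- bilateral_filter(make_vol(v2, v$mask), filter_params())
  expect_identical(a$values, b$values)
})

test_that("identity kernel returns the map restricted to the mask", {
  v <- rand_volume(c(6, 6, 6), seed = 3, mask_frac = 0.7)
  out <- bilateral_filter(make_vol(v$values, v$mask), kernel = "none")
  expect_equal(out$values[v$mask], v$values[v$mask])
  expect_identical(attr(out, "evaluable"), v$mask)
})

test_that("scale_by_null_sd pools exactly the first 30 permuted maps", {
  d <- c(5, 5, 5)
  obs <- make_vol(array(rnorm(125), d))
  # balanced +/-2 values: pooled sd exactly 2 (up to n-1 correction)
  base <- array(rep(c(-2, 2), length.out = 125), d)
  perms <- replicate(40, make_vol(base), simplify = FALSE)
  sc <- scale_by_null_sd(obs, perms)
  expect_equal(sc$scale, sd(rep(as.vector(base), 30)))
  expect_equal(sc$observed$values, obs$values / sc$scale)
  # altering map 31 leaves the factor unchanged
  perms2 <- perms
  perms2[[31]]$values <- perms2[[31]]$values * 100
  expect_equal(scale_by_null_sd(obs, perms2)$scale, sc$scale)
  # but altering map 30 changes it
  perms3 <- perms
  perms3[[30]]$values <- perms3[[30]]$values * 100
  expect_false(isTRUE(all.equal(scale_by_null_sd(obs, perms3)$scale,
                                sc$scale)))
  # maps already at unit sd stay (almost) unchanged
  set.seed(2)
  unit <- replicate(30, make_vol(array(rnorm(125), d)), simplify = FALSE)
  sc2 <- scale_by_null_sd(obs, unit)
  expect_equal(sc2$scale, 1, tolerance = 0.05)
  expect_error(scale_by_null_sd(obs, perms[1:10]), "at least 30")
  zero <- replicate(30, make_vol(array(0, d)), simplify = FALSE)
  expect_error(scale_by_null_sd(obs, zero), "degenerate")
})

test_that("gaussian_smooth preserves constants and total mass direction", {
  v <- make_vol(array(2.5, c(8, 8, 8)))
  out <- gaussian_smooth(v, fwhm = 6, voxel_size = c(3, 3, 3))
  expect_equal(out$values, v$values, tolerance = 1e-12)
  spike <- array(0, c(9, 9, 9)); spike[5, 5, 5] <- 1
  sm <- gaussian_smooth(make_vol(spike), fwhm = 6, voxel_size = c(3, 3, 3))
  expect_lt(sm$values[5, 5, 5], 1)
  expect_gt(sm$values[4, 5, 5], 0)
})
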