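# build a 1D "volume" carrying given lambda values, all evaluable
lambda_vol <- function(values) {
  d <- c(length(values), 1, 1)
  v <- stat_volume(array(values, d))
  attr(v, "evaluable") <- array(TRUE, d)
  attr(v, "status") <- array(1L, d)
  v
}

test_that("Fdr matches direct counting on a constructed toy", {
  # observed: 50 voxels at 0 and 50 at 60; null: 9,900 values at 0 and 100
  # at 70.  At lambda = 60: S0 = 100/10000 = 0.01 and Sz = 50/100 = 0.5,
  # so Fdr = 0.01 / 0.5 = 0.02.
  obs <- rep(c(0, 60), each = 50)
  null <- c(rep(0, 9900), rep(70, 100))
  fdr <- estimate_fdr(lambda_vol(obs), null_ensemble(null))
  expect_equal(fdr$scores[100, 1, 1], 1 * 0.01 / 0.5)
  # minimum observed value: S0 = Sz = 1 -> score = p0 = 1
  expect_equal(fdr$scores[1, 1, 1], 1)
  # on a generic random set, scores equal the counting oracle wherever the
  # raw ratio curve needs no monotonisation
  set.seed(1)
  obs2 <- sort(rnorm(200))
  null2 <- rnorm(6000)
  fdr2 <- estimate_fdr(lambda_vol(obs2), null_ensemble(null2))
  raw <- oracle_raw_fdr(obs2, null2)
  mono <- raw == cummin(raw)
  expect_true(any(mono))
  expect_equal(fdr2$scores[cbind(which(mono), 1, 1)], raw[mono])
})

test_that("scores live in [0,1] and are monotone non-increasing in lambda", {
  set.seed(2)
  for (rep in 1:5) {
    obs <- rnorm(400)
    null <- rnorm(20000)
    fdr <- estimate_fdr(lambda_vol(obs), null_ensemble(null))
    sc <- as.vector(fdr$scores)
    expect_true(all(sc >= 0 & sc <= 1))
    ord <- order(obs)
    expect_true(all(diff(sc[ord]) <= 1e-15))
  }
})

test_that("an observed map drawn from the null scores near 1", {
  set.seed(3)
  frac <- replicate(50, {
    obs <- rnorm(500)
    null <- rnorm(25000)
    fdr <- estimate_fdr(lambda_vol(obs), null_ensemble(null))
    mean(fdr$scores < 0.05)
  })
  expect_lte(mean(frac), 0.05 + 3 * sd(frac) / sqrt(50))
})

test_that("scores are rank-based: invariant under monotone relabelling", {
  set.seed(4)
  obs <- rnorm(300)
  null <- rnorm(9000)
  a <- estimate_fdr(lambda_vol(obs), null_ensemble(null))
  g <- function(x) exp(x)  # strictly monotone
  b <- estimate_fdr(lambda_vol(g(obs)), null_ensemble(g(null)))
  expect_equal(a$scores, b$scores)
})

test_that("p0 = 1 is the most conservative choice", {
  set.seed(5)
  obs <- c(rnorm(250), rnorm(50, mean = 3))
  null <- rnorm(10000)
  full <- estimate_fdr(lambda_vol(obs), null_ensemble(null), p0 = 1)
  part <- estimate_fdr(lambda_vol(obs), null_ensemble(null), p0 = 0.6)
  expect_true(all(full$scores >= part$scores - 1e-15))
})

test_that("adding one huge value cannot hurt any other voxel", {
  set.seed(6)
  obs <- rnorm(200)
  null <- rnorm(8000)
  base <- estimate_fdr(lambda_vol(obs), null_ensemble(null))
  ext <- estimate_fdr(lambda_vol(c(obs, 50)), null_ensemble(null))
  expect_true(all(ext$scores[seq_along(obs), 1, 1] <=
                    as.vector(base$scores) + 1e-15))
})

test_that("thresholding selects scores under q, never discarded voxels", {
  d <- c(3, 1, 1)
  fdr <- structure(list(scores = array(c(0.01, 0.04, 0.06), d),
                        evaluable = array(TRUE, d), p0 = 1, tail = "right",
                        n_null = 100, voxel_size = c(1, 1, 1)),
                   class = "fdr_map")
  expect_equal(as.vector(threshold_fdr(fdr, 0.05)), c(TRUE, TRUE, FALSE))
  expect_true(all(threshold_fdr(fdr, 1)))
  # a discarded voxel carries score 1 and is never significant
  fdr$evaluable[2, 1, 1] <- FALSE
  fdr$scores[2, 1, 1] <- 1
  expect_equal(as.vector(threshold_fdr(fdr, 0.5)), c(TRUE, FALSE, TRUE))
  expect_equal(as.vector(threshold_fdr(fdr, 1)), c(TRUE, FALSE, TRUE))
  expect_error(threshold_fdr(fdr, 0))
})

test_that("discarded voxels come out of the pipeline with score 1", {
  # mask with an isolated island produces discards at its corners
  d <- c(11, 11, 11)
  mask <- array(FALSE, d)
  mask[5:7, 5:7, 5:7] <- TRUE
  set.seed(8)
  vol <- stat_volume(array(rnorm(prod(d)), d), mask = mask)
  lam <- bilateral_filter(vol, filter_params())
  null <- rnorm(5000)
  fdr <- estimate_fdr(lam, null_ensemble(null))
  status <- attr(lam, "status")
  expect_true(any(status == 3L))
  expect_true(all(fdr$scores[status == 3L] == 1))
  expect_true(all(is.na(fdr$scores[status == 0L])))
  expect_false(any(threshold_fdr(fdr, 0.9999)[status == 3L]))
})

test_that("the left-tail audit variant mirrors the right tail", {
  set.seed(9)
  obs <- rnorm(300)
  null <- rnorm(9000)
  lt <- estimate_fdr(lambda_vol(obs), null_ensemble(null), tail = "left")
  sc <- as.vector(lt$scores)
  expect_true(all(sc >= 0 & sc <= 1))
  # left-tail scores are monotone non-DEcreasing in lambda: small lambda is
  # the significant direction there
  ord <- order(obs)
  expect_true(all(diff(sc[ord]) >= -1e-15))
  # negating everything swaps the tails
  rt <- estimate_fdr(lambda_vol(-obs), null_ensemble(-null), tail = "right")
  expect_equal(sc, as.vector(rt$scores))
})
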