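test_that("a nearly delta ACF yields white noise", {
  ns <- noise_spec(a = 1, b = 0.05, grid = c(16, 16, 16))
  set.seed(1)
  lag1 <- replicate(40, {
    v <- simulate_noise(ns)$values
    cor(as.vector(v[1:15, , ]), as.vector(v[2:16, , ]))
  })
  se <- 1 / sqrt(15 * 16 * 16)
  expect_lt(abs(mean(lag1)), 3 * se / sqrt(40) + 0.01)
})

test_that("the empirical ACF tracks the mixed Gaussian/exponential target", {
  ns <- noise_spec(a = 0.5, b = 2, c = 2, grid = c(32, 32, 32))
  spectrum <- lisar:::noise_spectrum(ns)
  set.seed(2)
  emp <- matrix(0, 200, 4)
  for (i in 1:200) {
    v <- simulate_noise(ns, spectrum = spectrum)$values
    for (L in 1:4)
      emp[i, L] <- cor(as.vector(v[1:(32 - L), , ]),
                       as.vector(v[(1 + L):32, , ]))
  }
  target <- lisar:::acf_target(ns, 1:4)
  got <- colMeans(emp)
  mc <- apply(emp, 2, sd) / sqrt(200)
  expect_true(all(abs(got - target) < 3 * mc + 0.02),
              info = paste("emp:", paste(round(got, 3), collapse = " "),
                           "target:", paste(round(target, 3), collapse = " ")))
})

test_that("noise fields have unit marginal variance and Gaussian shape", {
  ns <- noise_spec(grid = c(16, 16, 16))
  set.seed(3)
  vs <- simulate_noise(ns, n = 300)
  probe <- c(1, 777, 2048, 4096)
  M <- sapply(vs, function(m) m$values[probe])
  vars <- apply(M, 1, var)
  # var estimate SE ~ sqrt(2/(n-1))
  expect_true(all(abs(vars - 1) < 3 * sqrt(2 / 299) + 0.05))
  skew <- mean(sapply(vs[1:50], function(m) {
    x <- as.vector(m$values)
    mean((x - mean(x))^3) / sd(x)^3
  }))
  expect_lt(abs(skew), 0.1)
})

test_that("noise synthesis is reproducible and respects odd grids", {
  ns <- noise_spec(grid = c(15, 16, 17))
  a <- with_seed_local(99, simulate_noise(ns))
  b <- with_seed_local(99, simulate_noise(ns))
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(15L, 16L, 17L))
})

test_that("sphere supports enumerate the closed Euclidean ball", {
  ns <- noise_spec(grid = c(16, 16, 16))
  set.seed(4)
  v <- simulate_noise(ns)
  # radius 2 -> 33 lattice points
  inj <- inject_signal(v, list(signal_spec("sphere", 1, center = c(8, 8, 8),
                                           radius = 2)))
  expect_equal(sum(inj$truth), 33L)
  # brute-force enumeration oracle at radius 3
  inj3 <- inject_signal(v, list(signal_spec("sphere", 1, center = c(8, 8, 8),
                                            radius = 3)))
  cnt <- 0L
  for (x in 1:16) for (y in 1:16) for (z in 1:16)
    if ((x - 8)^2 + (y - 8)^2 + (z - 8)^2 <= 9) cnt <- cnt + 1L
  expect_equal(sum(inj3$truth), cnt)
})

test_that("sticks are 1-voxel-thick segments; zero amplitude is a no-op", {
  ns <- noise_spec(grid = c(16, 16, 16))
  set.seed(5)
  v <- simulate_noise(ns)
  stick <- signal_spec("stick", 0.8, start = c(4, 8, 8), step = c(1, 0, 0),
                       length = 7)
  inj <- inject_signal(v, list(stick))
  expect_equal(sum(inj$truth), 7L)
  expect_equal(which(inj$truth, arr.ind = TRUE)[, 2], rep(8L, 7),
               ignore_attr = TRUE)
  diag <- inject_signal(v, list(signal_spec("stick", 1, start = c(4, 4, 4),
                                            step = c(1, 1, 0), length = 5)))
  expect_equal(sum(diag$truth), 5L)
  null_sig <- inject_signal(v, list(signal_spec("sphere", 0,
                                                center = c(8, 8, 8),
                                                radius = 2)))
  expect_equal(null_sig$volume$values, v$values)
  expect_error(inject_signal(v, list(signal_spec("sphere", 1,
                                                 center = c(1, 1, 1),
                                                 radius = 3))),
               "outside the grid")
  expect_warning(inject_signal(v, list(stick, stick)), "overlap")
})

test_that("simulated groups: defaults, null mode, and signal recovery", {
  grp <- simulate_group(noise = tiny_noise(), seed = 6)
  expect_equal(length(grp), 26L)  # typical fMRI group size
  expect_false(any(attr(grp, "truth")))
  # law of large numbers at a signal voxel
  sig <- signal_spec("sphere", 0.7, center = c(6, 6, 6), radius = 1)
  big <- simulate_group(400, tiny_noise(), list(sig), seed = 7)
  at_sig <- sapply(big$maps, function(m) m$values[6, 6, 6])
  expect_lt(abs(mean(at_sig) - 0.7), 3 / sqrt(400))
  off_sig <- sapply(big$maps, function(m) m$values[2, 2, 2])
  expect_lt(abs(mean(off_sig)), 3 / sqrt(400))
})

test_that("power harness: monotone in SNR and honest accounting", {
  scen <- data.frame(shape = "sphere", size = 3, snr = c(0.3, 1.2))
  pw <- run_power_harness(scen, methods = "bilateral", n_reps = 4,
                          n_maps = 12, noise = tiny_noise(c(14, 14, 14)),
                          n_permutations = 40, seed = 3)
  s <- attr(pw, "summary")
  expect_equal(nrow(pw), 8L)
  expect_true(all(pw$tpr >= 0 & pw$tpr <= 1))
  expect_lte(s$tpr[s$snr == 0.3], s$tpr[s$snr == 1.2])
})
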