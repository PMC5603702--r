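test_that("noiseless signed IR data recover T1 essentially exactly", {
  geom <- small_geom()
  ir <- simulate_ir_series(geom)
  fit <- fit_t1(ir, mask = geom$masks$kidney)
  cx <- geom$masks$cortex; md <- geom$masks$medulla
  expect_equal(median(fit$t1$data[cx]), 1367, tolerance = 1e-5)
  expect_equal(median(fit$t1$data[md]), 1655, tolerance = 1e-5)
  expect_equal(median(fit$s0$data[cx]), 100, tolerance = 1e-5)
  # fitting demands >= 3 distinct TIs
  ir2 <- simulate_ir_series(geom, tis = c(300, 900))
  expect_error(fit_t1(ir2), "3 distinct")
})

test_that("magnitude-mode polarity restoration matches the exhaustive grid-search oracle", {
  ti <- default_tis()
  t1_true <- 1200          # zero-crossing 832 ms, inside the TI range
  s_signed <- 80 * (1 - 2 * exp(-ti / t1_true))
  s_mag <- abs(s_signed)
  oracle <- ir_gridsearch_oracle(s_mag, ti)
  expect_equal(oracle$t1, t1_true, tolerance = 1e-3)
  dat <- array(rep(s_mag, each = 4), c(2, 2, 1, length(ti)))
  series <- acquisition_series(dat, c(3, 3, 5), "IR",
                               data.frame(ti_ms = ti))
  fit <- fit_t1(series, magnitude_mode = TRUE)
  expect_equal(fit$t1$data[1, 1, 1], t1_true, tolerance = 1e-3 * t1_true)
  expect_equal(fit$t1$data[1, 1, 1], oracle$t1, tolerance = 1e-3 * t1_true)
})

test_that("T1 estimate is invariant to global S0 scaling and flags empty voxels", {
  ti <- default_tis()
  s <- 1 * (1 - 2 * exp(-ti / 1500))
  mk <- function(scale) {
    dat <- array(0, c(2, 1, 1, length(ti)))
    dat[1, 1, 1, ] <- scale * s        # voxel 2 stays all-zero
    acquisition_series(dat, c(3, 3, 5), "IR", data.frame(ti_ms = ti))
  }
  f1 <- fit_t1(mk(1)); f2 <- fit_t1(mk(1000))
  expect_equal(f1$t1$data[1, 1, 1], f2$t1$data[1, 1, 1], tolerance = 1e-8)
  expect_true(is.na(f1$t1$data[2, 1, 1]))   # flagged, not raised
})

test_that("median recovered T1 under Rician noise at SNR 50 is within 2% of truth", {
  set.seed(401)
  ti <- default_tis()
  t1_true <- 1655; s0 <- 100; sigma <- 2   # SNR 50
  n_vox <- 1000
  clean <- s0 * (1 - 2 * exp(-ti / t1_true))
  sig <- matrix(rep(clean, each = n_vox), n_vox, length(ti))
  noisy <- sqrt((sig + rnorm(length(sig), 0, sigma))^2 +
                  rnorm(length(sig), 0, sigma)^2)
  dat <- array(noisy, c(n_vox, 1, 1, length(ti)))
  series <- acquisition_series(dat, c(3, 3, 5), "IR",
                               data.frame(ti_ms = ti))
  fit <- fit_t1(series, magnitude_mode = TRUE)
  med <- median(fit$t1$data, na.rm = TRUE)
  expect_lt(abs(med - t1_true) / t1_true, 0.02)
})

test_that("noiseless multi-echo decay recovers T2* exactly with R2* its reciprocal", {
  tes <- default_tes()
  s <- 100 * exp(-tes / 50)
  dat <- array(rep(s, each = 2), c(2, 1, 1, length(tes)))
  series <- acquisition_series(dat, c(3, 3, 5), "MFFE",
                               data.frame(te_ms = tes))
  for (w in c(TRUE, FALSE)) {
    fit <- fit_t2star(series, weighted = w)
    expect_equal(fit$t2star$data[1, 1, 1], 50, tolerance = 1e-9)
    expect_equal(fit$r2star$data[1, 1, 1], 20, tolerance = 1e-9)
    expect_equal(fit$s0$data[1, 1, 1], 100, tolerance = 1e-9)
  }
  expect_error(fit_t2star(acquisition_series(
    dat[, , , 1:2, drop = FALSE], c(3, 3, 5), "MFFE",
    data.frame(te_ms = tes[1:2]))), "3 echoes")
})

test_that("R2* map is the elementwise reciprocal of T2* wherever finite", {
  geom <- small_geom()
  me <- add_rician_noise(simulate_mffe_series(geom), 2, seed = 5)
  fit <- fit_t2star(me, mask = geom$masks$kidney)
  ok <- is.finite(fit$t2star$data)
  expect_equal(fit$r2star$data[ok], 1000 / fit$t2star$data[ok])
  expect_equal(is.finite(fit$r2star$data), ok)
})

test_that("amplitude-weighted log fit is no more biased than the unweighted fit at SNR 20", {
  set.seed(402)
  tes <- default_tes()
  t2_true <- 29.7; s0 <- 100; sigma <- 5   # SNR 20, medulla-like decay
  n_vox <- 10000
  clean <- s0 * exp(-tes / t2_true)
  sig <- matrix(rep(clean, each = n_vox), n_vox, length(tes))
  noisy <- sqrt((sig + rnorm(length(sig), 0, sigma))^2 +
                  rnorm(length(sig), 0, sigma)^2)
  dat <- array(noisy, c(n_vox, 1, 1, length(tes)))
  series <- acquisition_series(dat, c(3, 3, 5), "MFFE",
                               data.frame(te_ms = tes))
  fw <- fit_t2star(series, weighted = TRUE)
  fu <- fit_t2star(series, weighted = FALSE)
  rmse <- function(x) sqrt(mean((x - t2_true)^2, na.rm = TRUE))
  # amplitude weighting trades a small positive bias for a substantial
  # variance reduction; its total error is smaller than the unweighted fit's
  expect_lt(rmse(fw$t2star$data), rmse(fu$t2star$data))
  expect_lt(abs(mean(fw$t2star$data, na.rm = TRUE) - t2_true) / t2_true,
            0.05)
  expect_lt(abs(mean(fu$t2star$data, na.rm = TRUE) - t2_true) / t2_true,
            0.05)
})

test_that("T2* estimate is invariant to S0 scaling", {
  tes <- default_tes()
  mk <- function(scale) {
    dat <- array(scale * 100 * exp(-tes / 35), c(1, 1, 1, length(tes)))
    acquisition_series(dat, c(3, 3, 5), "MFFE", data.frame(te_ms = tes))
  }
  expect_equal(fit_t2star(mk(1))$t2star$data[1, 1, 1],
               fit_t2star(mk(50))$t2star$data[1, 1, 1], tolerance = 1e-10)
})
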