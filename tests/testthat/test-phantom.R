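test_that("geometry produces disjoint non-empty cortex and medulla", {
  geom <- small_geom(c(64, 64, 5))
  expect_gt(sum(geom$masks$cortex), 0)
  expect_gt(sum(geom$masks$medulla), 0)
  expect_false(any(geom$masks$cortex & geom$masks$medulla))
  expect_true(all(geom$masks$kidney[geom$masks$cortex]))
  expect_true(all(geom$masks$kidney[geom$masks$medulla]))
  expect_error(make_geometry(c(16, 16, 3)), "too small")
})

test_that("two kidneys yield two connected components; vessel disc area is exact", {
  geom <- make_geometry(c(64, 64, 5), c(3, 3, 5), n_kidneys = 2,
                        vessel_radius = 5)
  vol <- kidney_volume(geom$masks$kidney, geom$voxel_size)
  expect_equal(vol$n_components, 2)
  disc <- geom$vessel[, , 1]
  expect_equal(sum(disc) * 3 * 3,
               sum(geom$labels[, , 1] == 3L) * 9)   # disc area = count*dx*dy
  expect_gt(sum(disc), 0)
})

test_that("inversion-recovery forward model has its analytic null and limit", {
  geom <- small_geom()
  tp <- default_tissue_params()
  tp$cortex$T1 <- 1000; tp$cortex$M0 <- 1
  # zero-crossing at T1 ln 2
  s <- simulate_ir_series(geom, tp, tis = 1000 * log(2))
  cx <- which(geom$labels == 1L)
  expect_lt(max(abs(s$data[, , , 1][cx])), 1e-12)
  # TI -> infinity recovers S0
  s_inf <- simulate_ir_series(geom, tp, tis = 1e7)
  expect_equal(unique(s_inf$data[, , , 1][cx]), 1, tolerance = 1e-12)
  # the standard protocol gives 13 frames
  expect_equal(dim(simulate_ir_series(geom)$data)[4], 13)
  # magnitude mode is |signed|
  sm <- simulate_ir_series(geom, tp, tis = c(300, 1500), signed = FALSE)
  ss <- simulate_ir_series(geom, tp, tis = c(300, 1500), signed = TRUE)
  expect_equal(sm$data, abs(ss$data))
})

test_that("multi-echo forward model decays exponentially from S0", {
  geom <- small_geom()
  tp <- default_tissue_params()
  cx <- which(geom$labels == 1L)
  # TE = T2* gives S0/e (cortex T2* 49.6 ms)
  s <- simulate_mffe_series(geom, tp, tes = tp$cortex$T2star)
  expect_equal(unique(s$data[, , , 1][cx]), tp$cortex$M0 / exp(1),
               tolerance = 1e-12)
  expect_equal(dim(simulate_mffe_series(geom)$data)[4], 12)
  expect_equal(simulate_mffe_series(geom)$encoding$te_ms,
               seq(5, 38, by = 3))
})

test_that("diffusion forward model: b = 0 gives S0; fp = 0 is mono-exponential", {
  geom <- small_geom()
  tp <- default_tissue_params()
  tp$cortex$fp <- 0; tp$cortex$D <- 2.3e-3
  s <- simulate_dwi_series(geom, tp)
  cx <- which(geom$labels == 1L)
  expect_equal(unique(s$data[, , , 1][cx]), tp$cortex$M0)
  k500 <- which(s$encoding$b == 500)
  expect_equal(unique(s$data[, , , k500][cx]),
               tp$cortex$M0 * exp(-1.15), tolerance = 1e-12)
  # bi-exponential cortex signal is monotone decreasing over the 11 b-values
  s2 <- simulate_dwi_series(geom)
  idx <- arrayInd(cx[1], dim(geom$labels))
  v <- s2$data[idx[1], idx[2], idx[3], ]
  expect_true(all(diff(v) < 0))
})

test_that("ASL simulation: f = 0 makes label equal control; pairs are identical without motion/noise", {
  geom <- small_geom()
  tp <- default_tissue_params()
  tp$cortex$f <- 0; tp$medulla$f <- 0; tp$vessel$f <- 0
  out <- simulate_asl_series(geom, tp, n_pairs = 3)
  enc <- out$series$encoding
  expect_equal(out$series$data[, , , enc$type == "label"],
               out$series$data[, , , enc$type == "control"])
  # with perfusion but no motion/noise, all difference images identical
  out2 <- simulate_asl_series(geom, n_pairs = 4)
  d <- out2$series$data
  diffs <- lapply(1:4, function(p) d[, , , 2 * p - 1] - d[, , , 2 * p])
  for (p in 2:4) expect_equal(diffs[[p]], diffs[[1]])
  expect_equal(diffs[[1]], out2$delta_m_truth$data)
})

test_that("phase-contrast simulation recovers the waveform and refuses aliasing", {
  geom <- make_geometry(c(48, 48, 3), c(1.2, 1.2, 6), vessel_radius = 4)
  s <- simulate_pc_series(geom$vessel, rep(10, 20), venc = 100,
                          voxel_size = c(1.2, 1.2, 6))
  expect_equal(dim(s$data)[4], 20)
  expect_true(all(s$data[, , , 5][geom$vessel] == 10))
  expect_true(all(s$data[, , , 5][!geom$vessel] == 0))
  expect_true(all(simulate_pc_series(geom$vessel, rep(0, 5), 100)$data == 0))
  expect_error(simulate_pc_series(geom$vessel, c(50, 120), venc = 100),
               "alias")
})

test_that("Rician noise: zero sigma is identity, seeded draws reproduce, zero-signal mean is sigma sqrt(pi/2)", {
  geom <- small_geom()
  s <- simulate_mffe_series(geom)
  expect_identical(add_rician_noise(s, 0)$data, s$data)
  n1 <- add_rician_noise(s, 2, seed = 11)
  n2 <- add_rician_noise(s, 2, seed = 11)
  expect_identical(n1$data, n2$data)
  expect_false(identical(add_rician_noise(s, 2, seed = 12)$data, n1$data))
  # background voxels are pure noise: Rician mean at S = 0 is sigma*sqrt(pi/2)
  bg <- geom$labels == 0L
  vals <- n1$data[, , , 1][bg]
  expect_equal(mean(vals), 2 * sqrt(pi / 2),
               tolerance = 0.05)
})

test_that("repeatability cohort follows its variance-component generating model", {
  mu <- c(perf = 255)
  z <- simulate_repeatability_cohort(mu, c(perf = 0), c(perf = 0),
                                     n_subjects = 5, n_sessions = 3,
                                     seed = 1)
  expect_true(all(z$tables$perf == 255))
  expect_warning(icc_2way_random_avg(z$tables$perf), "constant")
  cv <- cov_intra(z$tables$perf)
  expect_equal(cv$mean_pct, 0)
  # seeded reproducibility
  a <- simulate_repeatability_cohort(mu, c(perf = 70), c(perf = 20),
                                     n_subjects = 11, n_sessions = 3,
                                     seed = 7)
  b <- simulate_repeatability_cohort(mu, c(perf = 70), c(perf = 20),
                                     n_subjects = 11, n_sessions = 3,
                                     seed = 7)
  expect_identical(a$tables, b$tables)
  expect_equal(dim(a$tables$perf), c(11L, 3L))
})
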