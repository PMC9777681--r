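test_that("ring tensile generator is deterministic and starts at the origin", {
  geom <- ring_geometry()
  mat <- gel_material(1, d1 = 0.02)
  r1 <- generate_ring_tensile_record(mat, geom, noise_sd = 0, seed = 1)
  r2 <- generate_ring_tensile_record(mat, geom, noise_sd = 0, seed = 99)
  expect_identical(r1$force, r2$force)        # noiseless: seed irrelevant
  expect_identical(r1$time, r2$time)
  n1 <- generate_ring_tensile_record(mat, geom, noise_sd = 0.01, seed = 5)
  n2 <- generate_ring_tensile_record(mat, geom, noise_sd = 0.01, seed = 5)
  expect_identical(n1$force, n2$force)        # same seed: bitwise identical
  expect_equal(r1$displacement[1], 0)
  expect_equal(r1$force[1], 0)
  expect_true(all(diff(r1$force) > 0))        # strictly increasing to failure
  # displacement increments equal crosshead_speed / sample_rate
  expect_equal(unique(round(diff(r1$displacement), 12)), 1e-3 / 50)
})

test_that("ring generator ends where the closed-form damage integral reaches 1", {
  geom <- ring_geometry(initial_circumference = 60e-3, width = 5e-3)
  mat <- gel_material(1, d1 = 0.02)
  rec <- generate_ring_tensile_record(mat, geom)
  expect_false(attr(rec, "censored"))
  # independent oracle: with constant fracture strain d1, D = eps_p / d1, so
  # failure is where the plastic strain path crosses d1. Reconstruct the
  # plastic path from the recorded stress (eps_p = eps_true - sigma/E).
  eps_r <- 2 * rec$displacement / geom$initial_circumference
  eps_t <- log1p(eps_r)
  sig <- attr(rec, "true_stress")
  ep <- pmax(eps_t - sig / mat$E, 0)
  n <- length(ep)
  expect_gte(ep[n], mat$d1)                  # D >= 1 at the last sample
  expect_lt(ep[n - 1], mat$d1)               # but not one sample earlier
  # last-sample ring strain within one sampling step of the closed-form root
  dstep <- 2 * (1e-3 / 50) / geom$initial_circumference
  ix <- which(ep >= mat$d1)[1]
  expect_lte(abs(eps_r[n] - eps_r[ix]), dstep)
})

test_that("ring generator errors when damage parameters cannot fail", {
  geom <- ring_geometry()
  mat <- gel_material(1)                      # all damage constants zero
  expect_error(generate_ring_tensile_record(mat, geom), "damage parameters")
})

test_that("injected force noise has the configured scale and doubles with noise_sd", {
  geom <- ring_geometry()
  mat <- gel_material(2, d1 = 0.05)
  base <- generate_ring_tensile_record(mat, geom, sample_rate = 500)
  n1 <- generate_ring_tensile_record(mat, geom, sample_rate = 500,
                                     noise_sd = 0.01, seed = 3)
  resid <- n1$force - base$force
  expect_equal(mean(resid), 0, tolerance = 0.2 * 0.01 * max(base$force))
  expect_equal(sd(resid), 0.01 * max(base$force), tolerance = 0.2)
  n2 <- generate_ring_tensile_record(mat, geom, sample_rate = 500,
                                     noise_sd = 0.02, seed = 3)
  expect_equal(sd(n2$force - base$force) / sd(resid), 2, tolerance = 0.1)
})

test_that("round-trip closure: pipeline recovers configured failure points within 2 %", {
  geom <- ring_geometry()
  targets <- ring_failure_table()
  for (i in seq_len(nrow(targets))) {
    mat <- calibrate_ring_material(targets$stress[i], targets$strain[i], geom)
    rec <- generate_ring_tensile_record(mat, geom)
    ana <- analyze_ring_record(rec, geom)
    expect_equal(ana$failure$failure_stress, targets$stress[i], tolerance = 0.02)
    expect_equal(ana$failure$failure_strain, targets$strain[i], tolerance = 0.02)
  }
})

test_that("compression generator matches its configured failure point and is convex", {
  geom <- compression_geometry(diameter = 25.4e-3)
  rec <- generate_compression_record(geom, failure_strain = 0.33,
                                     peak_stress = 0.69e6)
  cur <- compression_curve(rec, geom)
  expect_equal(max(cur$strain), 0.8, tolerance = 1e-9)
  fail <- detect_failure(cur)
  expect_false(fail$censored)
  dstep <- (1e-3 / 50) / geom$initial_length
  expect_lte(abs(fail$failure_strain - 0.33), dstep)
  expect_equal(fail$failure_stress, 0.69e6, tolerance = 0.01)
  # second differences non-negative before failure (strain hardening)
  pre <- cur$stress[seq_len(fail$index)]
  expect_true(all(diff(diff(pre)) > -1e-6 * max(pre)))
  # degenerate and out-of-range configurations are rejected
  expect_error(generate_compression_record(geom, 0.33, 0), "positive")
  expect_error(generate_compression_record(geom, 0.9, 1e5), "0, 0.8")
})

test_that("LAOS waveform generator produces the configured signal", {
  w <- generate_laos_waveform(storage_modulus = 10e3, loss_modulus = 1e3,
                              strain_amplitude = 0.01, n_cycles = 4,
                              samples_per_cycle = 128)
  expect_equal(nrow(w), 4 * 128)
  # strain is a pure sinusoid of amplitude gamma0
  expect_equal(max(abs(w$strain + 0.01 * sin(2 * pi * w$time))), 0.01 * 2,
               tolerance = 1e-12)   # sanity: sinusoid bounded
  expect_equal(w$strain, 0.01 * sin(2 * pi * 1 * w$time), tolerance = 1e-12)
  # triangle inequality on the signal model
  w2 <- generate_laos_waveform(10e3, 1e3, 500, 200, strain_amplitude = 0.01)
  bound <- 0.01 * (10e3 + 1e3 + 500 + 200)
  expect_lte(max(abs(w2$stress)), bound)
  # fixed-seed reproducibility
  a <- generate_laos_waveform(10e3, 1e3, strain_amplitude = 0.01,
                              noise_sd = 5, seed = 2)
  b <- generate_laos_waveform(10e3, 1e3, strain_amplitude = 0.01,
                              noise_sd = 5, seed = 2)
  expect_identical(a$stress, b$stress)
})

test_that("speckle pair generator honors identity, translation and stretch", {
  # identity: deformed equals reference
  p0 <- generate_speckle_pair(64, seed = 1)
  expect_identical(p0$reference, p0$deformed)
  # pure translation: constant ground-truth field
  p1 <- generate_speckle_pair(96, translation = c(3, -2), seed = 1)
  tr <- p1$truth(c(20, 50, 70), c(30, 48, 60))
  expect_true(all(tr[, "u"] == 3))
  expect_true(all(tr[, "v"] == -2))
  # uniform stretch: horizontal strain 0.01 everywhere
  p2 <- generate_speckle_pair(96, gradient = diag(c(1.01, 1)), seed = 1)
  xs <- seq(20, 70, by = 10)
  u <- p2$truth(xs, rep(48, length(xs)))[, "u"]
  expect_equal(diff(u) / 10, rep(0.01, length(xs) - 1), tolerance = 1e-12)
  # determinism
  p3 <- generate_speckle_pair(96, translation = c(3, -2), seed = 1)
  expect_identical(p1$reference, p3$reference)
  expect_identical(p1$deformed, p3$deformed)
  # out-of-frame deformation is rejected
  expect_error(generate_speckle_pair(64, translation = c(40, 0), seed = 1),
               "out of the frame")
})
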