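test_that("compression stress and strain are force/area and displacement/length", {
  geom <- compression_geometry(diameter = 25.4e-3, initial_length = 20e-3)
  rec <- fd_record(time = 0:4, displacement = c(0, 1, 2, 3, 4) * 1e-3,
                   force = c(0, 2, 0, 6, 10), mode = "compression")
  cur <- compression_curve(rec, geom)
  expect_equal(attr(cur, "kind"), "engineering_compression")
  expect_equal(cur$stress[3], 0)                       # zero force -> zero stress
  expect_equal(cur$strain[5], 4e-3 / 20e-3)            # 4 mm of 20 mm -> 0.2
  expect_equal(cur$stress[5], 10 / (pi * 12.7e-3^2))   # ~19.74 kPa
  expect_equal(cur$stress[5] / 1e3, 19.735, tolerance = 1e-4)
  rec_over <- fd_record(0:1, c(0, 25e-3), c(0, 1), mode = "compression")
  expect_error(compression_curve(rec_over, geom), "over-compression")
})

test_that("ring kinematics: circumference, diameter, strain", {
  geom <- ring_geometry(pin_diameter = 6e-3, initial_circumference = 60e-3,
                        width = 5e-3, thickness = 5e-3)
  expect_equal(ring_circumference(geom, 0), 60e-3)
  expect_equal(ring_circumference(geom, 5e-3), 70e-3)
  ds <- seq(0, 10e-3, by = 1e-3)
  expect_true(all(diff(ring_circumference(geom, ds)) > 0))
  expect_error(ring_circumference(geom, -1e-3), "non-negative")

  expect_equal(ring_diameter(pi * 1e-3), 1e-3)
  expect_equal(ring_diameter(67.8e-3), 21.581e-3, tolerance = 1e-4)
  expect_equal(ring_diameter(60e-3), 19.099e-3, tolerance = 1e-4)
  expect_error(ring_diameter(0), "positive")

  expect_equal(ring_strain(60e-3, 60e-3), 0)
  expect_equal(ring_strain(1.13 * 60e-3, 60e-3), 0.13)
  expect_equal(ring_strain(1.08 * 60e-3, 60e-3), 0.08)
  expect_error(ring_strain(59e-3, 60e-3), "cannot shorten")
})

test_that("ring stress is Laplace wall stress, linear in force, inverse in w and Di", {
  geom <- ring_geometry(width = 5e-3)
  expect_equal(ring_stress(0, geom, 20e-3), 0)
  expect_equal(ring_stress(0.1, geom, 20e-3), 1000)
  expect_equal(ring_stress(0.2, geom, 20e-3), 2 * ring_stress(0.1, geom, 20e-3))
  # homogeneity: degree 1 in F, degree -1 in each of w and Di
  g2 <- ring_geometry(width = 10e-3)
  expect_equal(ring_stress(0.1, g2, 20e-3), ring_stress(0.1, geom, 20e-3) / 2)
  expect_equal(ring_stress(0.1, geom, 40e-3), ring_stress(0.1, geom, 20e-3) / 2)
  expect_error(ring_stress(-1, geom, 20e-3), "non-negative")
})

test_that("true-stress conversion matches direct evaluation and inverts exactly", {
  eng <- stress_strain_curve(c(0, 0.08, 0.13), c(1e6, 2.65e6, 1.82e6),
                             kind = "engineering_ring")
  tru <- to_true(eng)
  expect_equal(tru$stress[1], 1e6)                 # zero strain: stress unchanged
  expect_equal(tru$strain[1], 0)
  expect_equal(tru$stress[2] / 1e6, 2.862, tolerance = 1e-12)
  expect_equal(tru$strain[2], 0.0769610411, tolerance = 1e-8)
  expect_equal(tru$stress[3] / 1e6, 2.0566, tolerance = 1e-12)
  expect_equal(tru$strain[3], 0.1222176327, tolerance = 1e-8)
  # true stress >= engineering, true strain <= engineering for positive strain
  expect_true(all(tru$stress >= eng$stress))
  expect_true(all(tru$strain <= eng$strain))
  back <- to_engineering(tru)
  expect_equal(back$strain, eng$strain, tolerance = 1e-14)
  expect_equal(back$stress, eng$stress, tolerance = 1e-14)
})

test_that("Young's modulus is recovered from exact linear data", {
  eps <- seq(0, 0.1, length.out = 100)
  for (E in c(37891e3, 1e3)) {
    cur <- stress_strain_curve(eps, E * eps, kind = "true")
    expect_equal(youngs_modulus(cur), E, tolerance = 1e-12)
  }
  short <- stress_strain_curve(c(0, 1), c(0, 1), kind = "true")
  expect_error(youngs_modulus(short), "fewer than 5")
})

test_that("strain decomposition splits elastic and plastic parts consistently", {
  # purely linear curve: no plastic strain, no yield
  eps <- seq(0, 0.1, length.out = 50)
  lin <- stress_strain_curve(eps, 8388e3 * eps, kind = "true")
  d <- decompose_strain(lin, 8388e3)
  expect_equal(d$plastic_strain, rep(0, 50), tolerance = 1e-12)
  expect_gt(d$yield_index, 50)

  # direct arithmetic at a single sample
  cur <- stress_strain_curve(c(0, 0.12), c(0, 500e3), kind = "true")
  d2 <- decompose_strain(cur, 8388e3)
  expect_equal(d2$elastic_strain[2], 0.0596090, tolerance = 1e-5)
  expect_equal(d2$plastic_strain[2], 0.12 - 500e3 / 8388e3, tolerance = 1e-12)
  # conservation at every sample on a generated curve
  expect_equal(d2$elastic_strain + d2$plastic_strain, cur$strain)
  expect_error(decompose_strain(cur, -1), "positive")
})

test_that("failure detection finds the first sufficient drop", {
  tri <- stress_strain_curve(c(0, 0.05, 0.1, 0.15), c(0, 1e6, 2e6, 0.1e6),
                             kind = "engineering_ring")
  f <- detect_failure(tri)
  expect_false(f$censored)
  expect_equal(f$failure_stress, 2e6)
  expect_equal(f$failure_strain, 0.1)

  # two peaks: first drops 60 %, second higher; the first is failure
  s <- c(0, 1, 2, 0.7, 1.5, 2.5, 2.4) * 1e6
  two <- stress_strain_curve(seq(0, 0.6, by = 0.1), s, kind = "engineering_ring")
  f2 <- detect_failure(two)
  expect_equal(f2$index, 3)
  expect_equal(f2$failure_stress, 2e6)
  # brute-force scan of the rule agrees
  brute <- NA
  for (i in 2:(length(s) - 1)) {
    if (s[i] >= s[i - 1] && s[i] > s[i + 1]) {
      after <- s[(i + 1):length(s)]
      rise <- which(after > s[i])[1]
      upto <- if (is.na(rise)) length(after) else rise - 1
      if (upto >= 1 && any(after[seq_len(upto)] < 0.5 * s[i])) { brute <- i; break }
    }
  }
  expect_equal(f2$index, brute)

  # monotone curve: censored, global max returned
  mono <- stress_strain_curve(seq(0, 0.3, by = 0.1), c(0, 1, 2, 3) * 1e5,
                              kind = "engineering_ring")
  fm <- detect_failure(mono)
  expect_true(fm$censored)
  expect_equal(fm$failure_stress, 3e5)
})

test_that("shear modulus reproduces the printed values for all three gels", {
  tab <- gel_table()
  expect_equal(round(shear_modulus(tab$E, tab$poisson) / 1e3), tab$shear_kPa)
  expect_equal(shear_modulus(1000, 0), 500)
  expect_error(shear_modulus(1000, 0.6), "Poisson")
  expect_error(shear_modulus(-1, 0.3), "positive")
})

test_that("mechanics pipeline recovers generator E for the softest gel", {
  geom <- ring_geometry()
  mat <- gel_material(3, d1 = 0.05)
  rec <- generate_ring_tensile_record(mat, geom)
  ana <- analyze_ring_record(rec, geom)
  expect_equal(ana$youngs_modulus, mat$E, tolerance = 0.01)
})
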