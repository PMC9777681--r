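#' Synthetic ring tensile force-displacement record
#'
#' Forward model standing in for the texture analyzer: the crosshead (top
#' pin) moves at constant speed; ring strain follows from the pin separation
#' through the ring geometry; the true stress is integrated with the same
#' elastic / Johnson-Cook law the analysis pipeline fits (declared
#' self-consistency, so recovery tests are well-posed); ductile damage
#' accumulates as the integral of d(eps_p)/eps_f and the record terminates at
#' the sample where the damage reaches 1. Stress is mapped back to force via
#' the Laplace ring-stress geometry, and optional Gaussian force noise is
#' added.
#'
#' @param material A [jc_material] whose damage constants give a finite,
#'   positive fracture strain at the loading rate.
#' @param geometry A [ring_geometry].
#' @param crosshead_speed Pin speed (m/s), > 0. Default 1 mm/s.
#' @param sample_rate Sampling rate (1/s), > 0. Default 50 (mirrors a 50 fps
#'   camera).
#' @param noise_sd Force noise standard deviation as a fraction of the peak
#'   noiseless force, >= 0.
#' @param seed Integer seed; identical seeds give identical records.
#' @param max_strain Safety cap on engineering ring strain for censored
#'   materials (default 1).
#' @return An [fd_record] in ring-tensile mode, ending at the failure sample;
#'   the `failure_index` attribute marks it. The noiseless true stress and
#'   plastic strain paths are attached as attributes `"true_stress"`,
#'   `"plastic_strain"` and `"damage"` for closure testing.
#' @export
generate_ring_tensile_record <- function(material, geometry,
                                         crosshead_speed = 1e-3,
                                         sample_rate = 50,
                                         noise_sd = 0, seed = NULL,
                                         max_strain = 1) {
  stopifnot(inherits(material, "jc_material"), inherits(geometry, "ring_geometry"),
            crosshead_speed > 0, sample_rate > 0, noise_sd >= 0)
  # fail early if the damage law cannot fail at this loading rate
  rate0 <- 2 * crosshead_speed / geometry$initial_circumference
  jc_fracture_strain(material, 1 / 3, rate0)

  dt <- 1 / sample_rate
  C0 <- geometry$initial_circumference
  nmax <- ceiling(max_strain * C0 / (2 * crosshead_speed) * sample_rate)
  time <- dt * (0:nmax)
  ds <- crosshead_speed * time                 # pin elongation
  eps_r <- 2 * ds / C0                         # engineering ring strain
  eps_t <- log1p(eps_r)                        # true strain path

  n <- length(time)
  sigma_true <- numeric(n)
  eps_p <- numeric(n)
  D <- numeric(n)
  ef_prev <- NA_real_
  failed <- FALSE
  last <- n
  for (i in 2:n) {
    rate <- (eps_t[i] - eps_t[i - 1]) / dt     # nominal true strain rate
    dp <- jc_return_map(material, eps_t[i], eps_p[i - 1], rate)
    eps_p[i] <- eps_p[i - 1] + dp
    sigma_true[i] <- material$E * (eps_t[i] - eps_p[i])
    D[i] <- D[i - 1]
    if (dp > 0) {
      ef <- jc_fracture_strain(material, 1 / 3, rate)
      ef0 <- if (is.na(ef_prev)) ef else ef_prev
      st <- accumulate_damage(damage_state(D[i - 1]), dp, 2 / (1 / ef0 + 1 / ef))
      D[i] <- st$D
      ef_prev <- ef
      if (st$failed) { failed <- TRUE; last <- i; break }
    }
  }
  idx <- seq_len(last)
  # invert the ring-stress geometry: F = sigma_r * w * Di with
  # sigma_r = sigma_true / (1 + eps_r) and Di = C0 (1 + eps_r) / pi,
  # hence F = sigma_true * w * C0 / pi
  force <- sigma_true[idx] * geometry$width * C0 / pi
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    force <- force + rnorm(length(force), sd = noise_sd * max(force))
  }
  rec <- fd_record(time[idx], ds[idx], force, mode = "ring_tensile",
                   failure_index = if (failed) last else NULL)
  attr(rec, "true_stress") <- sigma_true[idx]
  attr(rec, "plastic_strain") <- eps_p[idx]
  attr(rec, "damage") <- D[idx]
  attr(rec, "censored") <- !failed
  rec
}

#' Calibrate a ring-tensile generator material to a failure target
#'
#' Builds a [jc_material] whose noiseless synthetic ring record fails at a
#' prescribed engineering failure stress and strain (e.g. measured failure
#' points of agarose-xanthan gels). The elastic modulus is set so that the
#' elastic part of the true failure strain is `1 - plastic_fraction` of the
#' total, the yield strength so that yielding starts at `yield_fraction` of
#' the true failure stress, and the hardening modulus B is solved numerically
#' so the hardening curve passes through the failure point at the test rate.
#' The fracture strain is constant (`d1` equal to the plastic strain at
#' failure, `d2 = d4 = 0`), so the damage integral reaches 1 exactly at the
#' target.
#'
#' @param failure_stress Target engineering ring failure stress (Pa).
#' @param failure_strain Target engineering ring failure strain.
#' @param geometry A [ring_geometry] (sets the strain rate for a given
#'   crosshead speed).
#' @param crosshead_speed Pin speed (m/s). Default 1 mm/s.
#' @param plastic_fraction Fraction of the true failure strain that is
#'   plastic (default 0.4).
#' @param yield_fraction Yield stress as a fraction of the true failure
#'   stress (default 0.6).
#' @param exponent_n Hardening exponent of the calibrated material.
#' @param rate_C,ref_rate Rate sensitivity and reference rate.
#' @return A [jc_material].
#' @export
calibrate_ring_material <- function(failure_stress, failure_strain, geometry,
                                    crosshead_speed = 1e-3,
                                    plastic_fraction = 0.4,
                                    yield_fraction = 0.6,
                                    exponent_n = 0.5,
                                    rate_C = 0.01, ref_rate = 1) {
  stopifnot(failure_stress > 0, failure_strain > 0,
            plastic_fraction > 0, plastic_fraction < 1,
            yield_fraction > 0, yield_fraction < 1)
  sig_f <- failure_stress * (1 + failure_strain)       # true failure stress
  eps_f <- log1p(failure_strain)                       # true failure strain
  ep_f <- plastic_fraction * eps_f                     # plastic strain there
  E <- sig_f / (eps_f - ep_f)
  # rate bracket at the loading rate near failure
  rate <- 2 * crosshead_speed / geometry$initial_circumference /
    (1 + failure_strain)
  br <- 1 + rate_C * log(rate / ref_rate)
  if (br <= 0) stop("rate bracket non-positive at the test rate; reduce rate_C")
  A <- yield_fraction * sig_f / br
  B <- (sig_f / br - A) / ep_f^exponent_n
  if (B < 0) stop("calibration gives negative hardening; raise yield_fraction")
  jc_material(E = E, yield_A = A, hardening_B = B, exponent_n = exponent_n,
              rate_C = rate_C, ref_rate = ref_rate, d1 = ep_f)
}

#' Synthetic uniaxial compression record
#'
#' Convex strain-hardening forward model sigma(eps) = k1 eps + k2 eps^p with
#' p > 1, calibrated so the stress reaches `peak_stress` at `failure_strain`;
#' beyond failure the stress drops by `drop_fraction` and plateaus while the
#' crosshead continues to 80 % strain.
#'
#' @param geometry A [compression_geometry].
#' @param failure_strain Engineering failure strain, in (0, 0.8).
#' @param peak_stress Stress at failure (Pa), > 0.
#' @param crosshead_speed Probe speed (m/s). Default 1 mm/s.
#' @param sample_rate Sampling rate (1/s). Default 50.
#' @param noise_sd Force noise SD as a fraction of peak force, >= 0.
#' @param drop_fraction Relative stress drop at failure (default 0.6).
#' @param hardening_exponent Exponent p of the convex term (default 2).
#' @param linear_fraction Initial slope k1 as a fraction of the secant
#'   modulus to the failure point (default 0.3).
#' @param seed Integer seed.
#' @return An [fd_record] in compression mode spanning strain \[0, 0.8\],
#'   `failure_index` set at the peak.
#' @export
generate_compression_record <- function(geometry, failure_strain, peak_stress,
                                        crosshead_speed = 1e-3,
                                        sample_rate = 50, noise_sd = 0,
                                        drop_fraction = 0.6,
                                        hardening_exponent = 2,
                                        linear_fraction = 0.3, seed = NULL) {
  stopifnot(inherits(geometry, "compression_geometry"),
            crosshead_speed > 0, sample_rate > 0, noise_sd >= 0,
            hardening_exponent > 1,
            linear_fraction > 0, linear_fraction < 1,
            drop_fraction > 0, drop_fraction < 1)
  if (failure_strain <= 0 || failure_strain >= 0.8)
    stop("failure strain must lie in (0, 0.8)")
  if (peak_stress <= 0)
    stop("peak stress must be positive (an all-zero record is not emitted)")
  L <- geometry$initial_length
  dt <- 1 / sample_rate
  t_end <- 0.8 * L / crosshead_speed
  time <- seq(0, t_end, by = dt)
  if (time[length(time)] < t_end) time <- c(time, t_end)
  eps <- pmin(crosshead_speed * time / L, 0.8)
  k1 <- linear_fraction * peak_stress / failure_strain
  k2 <- (peak_stress - k1 * failure_strain) / failure_strain^hardening_exponent
  stress <- k1 * eps + k2 * eps^hardening_exponent
  fail_idx <- which(eps >= failure_strain)[1]
  if (is.na(fail_idx)) fail_idx <- length(eps)
  post <- seq_along(eps) > fail_idx
  stress[post] <- (1 - drop_fraction) * stress[fail_idx]
  force <- stress * geometry$contact_area
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    force <- force + rnorm(length(force), sd = noise_sd * max(force))
  }
  fd_record(time, eps * L, force, mode = "compression",
            failure_index = fail_idx)
}

#' Synthetic LAOS waveform
#'
#' Oscillatory shear signal standing in for the rheometer: the strain is a
#' pure sinusoid gamma(t) = gamma0 sin(omega t); the stress carries the
#' first-harmonic moduli plus configurable third-harmonic distortion,
#' sigma(t) = gamma0 (G' sin wt + G'' cos wt + e3 sin 3wt + v3 cos 3wt),
#' with optional Gaussian noise. The third-harmonic coefficients are moduli
#' (Pa): the stress contribution is gamma0 times each.
#'
#' @param storage_modulus First-harmonic elastic modulus G' (Pa).
#' @param loss_modulus First-harmonic viscous modulus G'' (Pa).
#' @param third_harmonic_elastic,third_harmonic_viscous Third-harmonic
#'   moduli (Pa); sine-convention Fourier coefficients (a negative elastic
#'   coefficient corresponds to strain stiffening).
#' @param strain_amplitude Strain amplitude gamma0, > 0.
#' @param frequency Oscillation frequency (Hz), > 0.
#' @param n_cycles Number of cycles, >= 1.
#' @param samples_per_cycle Samples per cycle, >= 16.
#' @param noise_sd Stress noise SD (Pa), >= 0.
#' @param seed Integer seed.
#' @return An [oscillation_waveform].
#' @export
generate_laos_waveform <- function(storage_modulus, loss_modulus = 0,
                                   third_harmonic_elastic = 0,
                                   third_harmonic_viscous = 0,
                                   strain_amplitude, frequency = 1,
                                   n_cycles = 4, samples_per_cycle = 256,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(strain_amplitude > 0, frequency > 0,
            n_cycles >= 1, samples_per_cycle >= 16, noise_sd >= 0)
  n <- n_cycles * samples_per_cycle
  time <- (0:(n - 1)) / (frequency * samples_per_cycle)
  w <- 2 * pi * frequency
  strain <- strain_amplitude * sin(w * time)
  stress <- strain_amplitude * (
    storage_modulus * sin(w * time) + loss_modulus * cos(w * time) +
      third_harmonic_elastic * sin(3 * w * time) +
      third_harmonic_viscous * cos(3 * w * time))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    stress <- stress + rnorm(n, sd = noise_sd)
  }
  oscillation_waveform(time, strain, stress,
                       strain_amplitude = strain_amplitude,
                       frequency = frequency, n_cycles = n_cycles)
}

#' Synthetic LAOS strain sweep
#'
#' Amplitude sweep of the first-harmonic moduli with a soft linear plateau
#' followed by power-law thinning above a critical strain, emulating the
#' strain sweep used to locate the linear viscoelastic region of a gel.
#'
#' @param strain_levels Strain amplitudes, increasing (default 20
#'   log-spaced points over 1-100 %).
#' @param plateau_gp,plateau_gpp Linear-region moduli (Pa).
#' @param critical_strain Onset of softening.
#' @param thinning_exponent Power-law slope of G' beyond the onset
#'   (default -0.5).
#' @return A data frame of class `"strain_sweep"` with columns `strain`,
#'   `g_prime`, `g_double_prime`.
#' @export
generate_strain_sweep <- function(strain_levels = 10^seq(-2, 0, length.out = 20),
                                  plateau_gp = 20e3, plateau_gpp = 2e3,
                                  critical_strain = 0.1,
                                  thinning_exponent = -0.5) {
  stopifnot(!is.unsorted(strain_levels), all(strain_levels > 0),
            plateau_gp > 0, critical_strain > 0)
  soft <- pmax(strain_levels / critical_strain, 1)^thinning_exponent
  out <- data.frame(strain = strain_levels,
                    g_prime = plateau_gp * soft,
                    g_double_prime = plateau_gpp * soft^0.5)
  class(out) <- c("strain_sweep", "data.frame")
  out
}
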