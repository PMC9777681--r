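#' Oscillatory strain/stress waveform
#'
#' @param time Sample times (s), uniform.
#' @param strain Strain signal (dimensionless).
#' @param stress Stress signal (Pa).
#' @param strain_amplitude Strain amplitude gamma0. Estimated from the strain
#'   signal when omitted.
#' @param frequency Oscillation frequency (Hz). Required: the text formats do
#'   not carry it and it is not estimated from the signal.
#' @param n_cycles Number of full cycles contained in the record.
#'
#' @return An object of class `"oscillation_waveform"` (also a data frame).
#' @export
oscillation_waveform <- function(time, strain, stress,
                                 strain_amplitude = NULL, frequency = NULL,
                                 n_cycles = NULL) {
  n <- length(time)
  stopifnot(
    "time/strain/stress lengths differ" =
      length(strain) == n && length(stress) == n,
    "need at least 32 samples" = n >= 32
  )
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    stop("waveform must be uniformly sampled")
  if (is.null(strain_amplitude)) strain_amplitude <- max(abs(strain))
  if (is.null(frequency))
    stop("frequency must be supplied (it is not estimated)")
  if (is.null(n_cycles)) {
    n_cycles <- round(n * mean(dt) * frequency)
    if (abs(n * mean(dt) * frequency - n_cycles) > 1e-6)
      stop("record does not span an integer number of cycles")
  }
  if (max(abs(strain)) > 1.01 * strain_amplitude ||
      max(abs(strain)) < 0.97 * strain_amplitude)
    warning("strain amplitude differs from the peak of the strain signal")
  out <- data.frame(time = time, strain = strain, stress = stress)
  attr(out, "strain_amplitude") <- strain_amplitude
  attr(out, "frequency") <- frequency
  attr(out, "n_cycles") <- n_cycles
  class(out) <- c("oscillation_waveform", "data.frame")
  out
}

#' @export
print.oscillation_waveform <- function(x, ...) {
  cat(sprintf("Oscillation waveform: %d samples, %d cycles at %.3g Hz, gamma0 = %.3g\n",
              nrow(x), attr(x, "n_cycles"), attr(x, "frequency"),
              attr(x, "strain_amplitude")))
  invisible(x)
}

#' Odd-harmonic Fourier decomposition of a LAOS stress waveform
#'
#' Projects the stress onto sin(k omega t) and cos(k omega t) for odd k over
#' an integer number of cycles, discarding the first cycle as transient. For
#' uniformly sampled band-limited signals over full cycles the rectangle-rule
#' projection is exact. Moduli follow the sine convention relative to
#' gamma(t) = gamma0 sin(omega t): G'_k = a_k / gamma0, G''_k = b_k / gamma0
#' where a_k, b_k are the sine and cosine stress amplitudes.
#'
#' @param wave An [oscillation_waveform] with at least 2 full cycles.
#' @param max_harmonic Highest harmonic to report (odd, below Nyquist).
#' @return A data frame of class `"harmonic_spectrum"` with columns
#'   `harmonic`, `g_prime`, `g_double_prime`, `intensity`,
#'   `intensity_ratio` (I_k / I_1).
#' @export
harmonic_decompose <- function(wave, max_harmonic = 9) {
  stopifnot(inherits(wave, "oscillation_waveform"))
  ncyc <- attr(wave, "n_cycles")
  if (ncyc < 2) stop("need at least 2 full cycles (first is discarded)")
  if (max_harmonic %% 2 == 0) stop("max_harmonic must be odd")
  spc <- nrow(wave) / ncyc
  if (abs(spc - round(spc)) > 1e-9)
    stop("record does not contain an integer number of samples per cycle")
  spc <- round(spc)
  if (max_harmonic >= spc / 2)
    stop("max_harmonic is beyond the Nyquist limit for this sampling")
  keep <- (spc + 1):nrow(wave)                 # discard first cycle
  t <- wave$time[keep]
  s <- wave$stress[keep]
  g0 <- attr(wave, "strain_amplitude")
  w <- 2 * pi * attr(wave, "frequency")
  m <- length(keep)
  ks <- seq(1, max_harmonic, by = 2)
  a <- vapply(ks, function(k) 2 * mean(s * sin(k * w * t)), numeric(1))
  b <- vapply(ks, function(k) 2 * mean(s * cos(k * w * t)), numeric(1))
  intensity <- sqrt(a^2 + b^2)
  out <- data.frame(harmonic = ks, g_prime = a / g0, g_double_prime = b / g0,
                    intensity = intensity,
                    intensity_ratio = intensity / intensity[1])
  attr(out, "strain_amplitude") <- g0
  attr(out, "frequency") <- attr(wave, "frequency")
  attr(out, "mean_square_stress") <- mean(s^2)
  class(out) <- c("harmonic_spectrum", "data.frame")
  out
}

#' Lissajous-Bowditch loops of the final steady cycle
#'
#' Returns the last full cycle of the waveform as a closed elastic loop
#' (strain vs stress) and viscous loop (strain rate vs stress). The strain
#' rate is computed analytically from the fundamental,
#' gamma_dot = gamma0 omega cos(omega t), avoiding the noise amplification
#' of numerical differentiation.
#'
#' @param wave An [oscillation_waveform] with at least 2 full cycles.
#' @return A list of class `"lissajous_curve"` with data frames `elastic`
#'   (`strain`, `stress`) and `viscous` (`strain_rate`, `stress`), each
#'   closed (last point repeats the first).
#' @export
lissajous <- function(wave) {
  stopifnot(inherits(wave, "oscillation_waveform"))
  ncyc <- attr(wave, "n_cycles")
  if (ncyc < 2) stop("need at least 2 full cycles")
  spc <- round(nrow(wave) / ncyc)
  keep <- (nrow(wave) - spc + 1):nrow(wave)
  g0 <- attr(wave, "strain_amplitude")
  w <- 2 * pi * attr(wave, "frequency")
  gdot <- g0 * w * cos(w * wave$time[keep])
  close_idx <- c(seq_along(keep), 1L)
  elastic <- data.frame(strain = wave$strain[keep],
                        stress = wave$stress[keep])[close_idx, ]
  viscous <- data.frame(strain_rate = gdot,
                        stress = wave$stress[keep])[close_idx, ]
  rownames(elastic) <- rownames(viscous) <- NULL
  structure(list(elastic = elastic, viscous = viscous,
                 strain_amplitude = g0,
                 frequency = attr(wave, "frequency")),
            class = "lissajous_curve")
}

#' @export
print.lissajous_curve <- function(x, ...) {
  cat(sprintf("Lissajous-Bowditch loops (gamma0 = %.3g, %.3g Hz): %d points/loop\n",
              x$strain_amplitude, x$frequency, nrow(x$elastic) - 1))
  cat(sprintf("  elastic loop area %.4g Pa (= pi gamma0^2 G'' for a linear material)\n",
              loop_area(x$elastic$strain, x$elastic$stress)))
  invisible(x)
}

#' Signed area enclosed by a closed loop (shoelace formula)
#'
#' For the elastic Lissajous loop of a linear viscoelastic material the
#' magnitude equals pi gamma0^2 G''.
#'
#' @param x,y Coordinates of the closed polygon (first point repeated last,
#'   or not - the polygon is closed automatically).
#' @return Enclosed area (absolute value).
#' @export
loop_area <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  i <- seq_len(length(x) - 1)
  abs(sum(x[i] * y[i + 1] - x[i + 1] * y[i])) / 2
}

#' Nonlinearity metrics of a LAOS spectrum
#'
#' Third-harmonic intensity ratio I3/I1 and the strain-stiffening ratio
#' S = (G'_L - G'_M) / G'_L, where G'_M = sum_k k G'_k is the
#' minimum-strain (tangent) modulus at gamma = 0 and
#' G'_L = sum_k (-1)^((k-1)/2) G'_k is the large-strain (secant) modulus at
#' gamma = gamma0. S = 0 for a linear material, S > 0 for intracycle strain
#' stiffening.
#'
#' @param spectrum A `"harmonic_spectrum"` from [harmonic_decompose].
#' @return A list with `i3_over_i1` and `stiffening_ratio`.
#' @export
nonlinearity_metrics <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  k <- spectrum$harmonic
  gp <- spectrum$g_prime
  if (spectrum$intensity[1] <= 0) stop("zero first harmonic")
  i3 <- if (any(k == 3)) spectrum$intensity_ratio[k == 3] else 0
  gm <- sum(k * gp)
  gl <- sum((-1)^((k - 1) / 2) * gp)
  if (gl == 0) stop("large-strain modulus is zero; S undefined")
  list(i3_over_i1 = i3, stiffening_ratio = (gl - gm) / gl)
}

#' Critical strain of the linear viscoelastic region
#'
#' Scans a strain sweep for the first amplitude at which G' falls below
#' (1 - tolerance) times the plateau, taken as the median of the first three
#' sweep points.
#'
#' @param sweep A data frame with columns `strain` and `g_prime` (e.g. from
#'   [generate_strain_sweep]), at least 5 points, strain increasing.
#' @param tolerance Permitted relative drop of G' inside the LVR
#'   (default 0.1).
#' @return A list with `critical_strain` (NA when no drop occurs within the
#'   sweep), `index`, and logical `absent`.
#' @export
find_lvr <- function(sweep, tolerance = 0.1) {
  stopifnot(is.data.frame(sweep),
            all(c("strain", "g_prime") %in% names(sweep)))
  if (nrow(sweep) < 5) stop("need at least 5 sweep points")
  if (is.unsorted(sweep$strain)) stop("strain levels must increase")
  plateau <- median(sweep$g_prime[1:3])
  idx <- which(sweep$g_prime < (1 - tolerance) * plateau)[1]
  if (is.na(idx))
    return(list(critical_strain = NA_real_, index = NA_integer_, absent = TRUE))
  list(critical_strain = sweep$strain[idx], index = idx, absent = FALSE)
}
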