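#' Stress-strain curve container
#'
#' @param strain Dimensionless strain, non-decreasing.
#' @param stress Stress (Pa).
#' @param kind One of `"engineering_compression"`, `"engineering_ring"`,
#'   `"true"`.
#' @param failure_index Optional index of the failure sample.
#'
#' @return An object of class `"stress_strain_curve"` (also a data frame).
#' @export
stress_strain_curve <- function(strain, stress,
                                kind = c("engineering_ring",
                                         "engineering_compression", "true"),
                                failure_index = NULL) {
  kind <- match.arg(kind)
  stopifnot(
    "strain and stress lengths differ" = length(strain) == length(stress),
    "strain must be non-decreasing"    = !is.unsorted(strain)
  )
  if (!is.null(failure_index))
    stopifnot("failure_index out of bounds" =
                failure_index >= 1 && failure_index <= length(strain))
  out <- data.frame(strain = strain, stress = stress)
  attr(out, "kind") <- kind
  attr(out, "failure_index") <- failure_index
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve (%s): %d samples\n", attr(x, "kind"), nrow(x)))
  cat(sprintf("  strain range [%.4g, %.4g], peak stress %.4g kPa\n",
              min(x$strain), max(x$strain), max(x$stress) / 1e3))
  fi <- attr(x, "failure_index")
  if (!is.null(fi))
    cat(sprintf("  failure at sample %d: (%.4g, %.4g kPa)\n",
                fi, x$strain[fi], x$stress[fi] / 1e3))
  invisible(x)
}

#' Engineering compression stress-strain curve from a force record
#'
#' Compressive stress is force over the (constant) contact area,
#' sigma_c = F1 / A; compressive strain is the relative height reduction,
#' eps_c = dL / L.
#'
#' @param record An [fd_record] in compression mode.
#' @param geom A [compression_geometry].
#'
#' @return A [stress_strain_curve] of kind `"engineering_compression"`.
#' @export
compression_curve <- function(record, geom) {
  stopifnot(inherits(record, "fd_record"), inherits(geom, "compression_geometry"))
  if (attr(record, "mode") != "compression")
    stop("record is not a compression record")
  if (any(record$displacement > geom$initial_length))
    stop("displacement exceeds initial specimen length (over-compression)")
  stress_strain_curve(
    strain = record$displacement / geom$initial_length,
    stress = record$force / geom$contact_area,
    kind = "engineering_compression",
    failure_index = attr(record, "failure_index")
  )
}

#' Instantaneous inside circumference of a ring specimen
#'
#' Each increment of pin separation lengthens both straight segments of the
#' oval ring, so Ci = C0 + 2 * elongation.
#'
#' @param geom A [ring_geometry].
#' @param elongation Pin separation increase Ds (m), >= 0. Vectorised.
#' @return Instantaneous circumference Ci (m).
#' @export
ring_circumference <- function(geom, elongation) {
  stopifnot(inherits(geom, "ring_geometry"))
  if (any(elongation < 0)) stop("elongation must be non-negative")
  geom$initial_circumference + 2 * elongation
}

#' Instantaneous inside diameter of a ring specimen
#'
#' Di = Ci / pi, treating the stretched ring as an equivalent circle.
#'
#' @param circumference Instantaneous circumference Ci (m), > 0. Vectorised.
#' @return Diameter Di (m).
#' @export
ring_diameter <- function(circumference) {
  if (any(circumference <= 0)) stop("circumference must be positive")
  circumference / pi
}

#' Ring tensile stress
#'
#' Laplace's-law circumferential wall stress of the ring specimen:
#' sigma_r = F2 / (w * Di).
#'
#' @param force Measured tensile force F2 (N), >= 0. Vectorised.
#' @param geom A [ring_geometry] (supplies the width `w`).
#' @param diameter Instantaneous inside diameter Di (m), > 0.
#' @return Engineering ring stress (Pa).
#' @export
ring_stress <- function(force, geom, diameter) {
  stopifnot(inherits(geom, "ring_geometry"))
  if (any(force < 0)) stop("force must be non-negative")
  if (geom$width <= 0 || any(diameter <= 0))
    stop("width and diameter must be positive")
  force / (geom$width * diameter)
}

#' Ring tensile strain
#'
#' Engineering hoop strain of the stretched circumference,
#' eps_r = (Ci - C0) / C0.
#'
#' @param circumference Instantaneous circumference Ci (m). Vectorised.
#' @param initial_circumference Initial circumference C0 (m), > 0.
#' @return Engineering ring strain (dimensionless).
#' @export
ring_strain <- function(circumference, initial_circumference) {
  if (initial_circumference <= 0) stop("initial circumference must be positive")
  if (any(circumference < initial_circumference))
    stop("circumference below initial value: the ring cannot shorten")
  (circumference - initial_circumference) / initial_circumference
}

#' Engineering ring stress-strain curve from a force record
#'
#' Applies [ring_circumference], [ring_diameter], [ring_stress] and
#' [ring_strain] sample by sample.
#'
#' @param record An [fd_record] in ring-tensile mode.
#' @param geom A [ring_geometry].
#' @return A [stress_strain_curve] of kind `"engineering_ring"`.
#' @export
ring_curve <- function(record, geom) {
  stopifnot(inherits(record, "fd_record"), inherits(geom, "ring_geometry"))
  if (attr(record, "mode") != "ring_tensile")
    stop("record is not a ring tensile record")
  ci <- ring_circumference(geom, record$displacement)
  di <- ring_diameter(ci)
  stress_strain_curve(
    strain = ring_strain(ci, geom$initial_circumference),
    stress = ring_stress(pmax(record$force, 0), geom, di),
    kind = "engineering_ring",
    failure_index = attr(record, "failure_index")
  )
}

#' Convert an engineering ring curve to true stress and strain
#'
#' sigma_true = sigma_r (1 + eps_r); eps_true = log(1 + eps_r). The true
#' measures account for the cross-section change under large deformation and
#' are the input expected by the Johnson-Cook model.
#'
#' @param curve A [stress_strain_curve] of kind `"engineering_ring"`.
#' @return A [stress_strain_curve] of kind `"true"`.
#' @seealso [to_engineering] for the inverse.
#' @export
to_true <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (attr(curve, "kind") != "engineering_ring")
    stop("true-stress conversion is defined for engineering ring curves")
  if (any(curve$strain <= -1)) stop("engineering strain must exceed -1")
  stress_strain_curve(
    strain = log1p(curve$strain),
    stress = curve$stress * (1 + curve$strain),
    kind = "true",
    failure_index = attr(curve, "failure_index")
  )
}

#' Convert a true curve back to engineering ring measures
#'
#' Inverse of [to_true]: eps_r = exp(eps_true) - 1,
#' sigma_r = sigma_true / (1 + eps_r).
#'
#' @param curve A [stress_strain_curve] of kind `"true"`.
#' @return A [stress_strain_curve] of kind `"engineering_ring"`.
#' @export
to_engineering <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (attr(curve, "kind") != "true")
    stop("input must be a true stress-strain curve")
  eng <- expm1(curve$strain)
  stress_strain_curve(
    strain = eng,
    stress = curve$stress / (1 + eng),
    kind = "engineering_ring",
    failure_index = attr(curve, "failure_index")
  )
}

#' Young's modulus from the linear region of a stress-strain curve
#'
#' Origin-anchored least-squares slope over the initial linear region, taken
#' as the first `linear_fraction` of the pre-failure strain range.
#'
#' @param curve A [stress_strain_curve] (normally kind `"true"`).
#' @param linear_fraction Fraction of the pre-failure strain range used for
#'   the fit (default 0.4).
#' @return Young's modulus E (Pa).
#' @export
youngs_modulus <- function(curve, linear_fraction = 0.4) {
  stopifnot(inherits(curve, "stress_strain_curve"),
            linear_fraction > 0, linear_fraction <= 1)
  fi <- attr(curve, "failure_index")
  last <- if (is.null(fi)) nrow(curve) else fi
  emax <- curve$strain[last] * linear_fraction
  sel <- which(curve$strain <= emax & seq_len(nrow(curve)) <= last)
  if (length(sel) < 5)
    stop("fewer than 5 samples in the selected linear region")
  x <- curve$strain[sel]
  y <- curve$stress[sel]
  sum(x * y) / sum(x * x)   # least squares through the origin
}

#' Elastic/plastic decomposition of a true stress-strain curve
#'
#' Pointwise split eps_elastic = sigma_true / E (clipped at the total strain)
#' and eps_plastic = eps_total - eps_elastic. The yield point is the first
#' sample where the stress deviates from the elastic line E * eps by more
#' than `yield_tol` relative.
#'
#' @param curve A [stress_strain_curve] of kind `"true"`.
#' @param E Young's modulus (Pa), > 0.
#' @param yield_tol Relative deviation from the elastic line that marks yield
#'   (default 0.02).
#' @return A list of class `"strain_decomposition"` with `youngs_modulus`,
#'   `elastic_strain`, `plastic_strain`, `yield_index`.
#' @export
decompose_strain <- function(curve, E, yield_tol = 0.02) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (attr(curve, "kind") != "true")
    stop("decomposition is defined for true stress-strain curves")
  if (E <= 0) stop("Young's modulus must be positive")
  elastic <- pmin(curve$stress / E, curve$strain)
  plastic <- curve$strain - elastic
  linear <- E * curve$strain
  dev <- abs(curve$stress - linear) / pmax(abs(linear), .Machine$double.eps)
  dev[curve$strain == 0] <- 0
  yield_index <- which(dev > yield_tol)[1]
  if (is.na(yield_index)) yield_index <- nrow(curve) + 1L  # never yields
  structure(
    list(youngs_modulus = E,
         elastic_strain = elastic,
         plastic_strain = plastic,
         yield_index = yield_index),
    class = "strain_decomposition"
  )
}

#' @export
print.strain_decomposition <- function(x, ...) {
  n <- length(x$elastic_strain)
  cat(sprintf("Strain decomposition (E = %.4g kPa):\n", x$youngs_modulus / 1e3))
  if (x$yield_index > n) cat("  no yield detected (fully elastic)\n")
  else cat(sprintf("  yield at sample %d; final plastic strain %.4g\n",
                   x$yield_index, x$plastic_strain[n]))
  invisible(x)
}

#' Detect the failure point of a stress-strain curve
#'
#' Failure (complete separation of the specimen) is taken as the first local
#' stress maximum after which the stress drops by more than `drop_fraction`
#' of that peak. A curve with no such drop is censored: the global maximum is
#' returned with `censored = TRUE`.
#'
#' @param curve A [stress_strain_curve].
#' @param drop_fraction Minimum relative drop after a peak that qualifies as
#'   failure (default 0.5).
#' @param min_peak_fraction Peaks below this fraction of the global maximum
#'   are ignored (default 0.1), so that measurement noise around zero stress
#'   early in a run is not mistaken for failure.
#' @return A list with `failure_stress` (Pa), `failure_strain`, `index`, and
#'   logical `censored`.
#' @export
detect_failure <- function(curve, drop_fraction = 0.5,
                           min_peak_fraction = 0.1) {
  stopifnot(inherits(curve, "stress_strain_curve"),
            drop_fraction > 0, drop_fraction < 1)
  s <- curve$stress
  n <- length(s)
  if (n < 3) stop("need at least 3 samples to detect failure")
  floor_stress <- min_peak_fraction * max(s)
  # local maxima (first sample of any plateau counts)
  for (i in seq_len(n - 1)) {
    if (s[i] <= 0 || s[i] < floor_stress) next
    is_peak <- (i == 1 || s[i] >= s[i - 1]) && s[i] > s[i + 1]
    if (!is_peak) next
    # does the curve subsequently drop below (1 - drop_fraction) * peak
    # before exceeding the peak again?
    after <- s[(i + 1):n]
    rise <- which(after > s[i])[1]
    upto <- if (is.na(rise)) length(after) else rise - 1L
    if (upto >= 1 && any(after[seq_len(upto)] < (1 - drop_fraction) * s[i])) {
      return(list(failure_stress = s[i], failure_strain = curve$strain[i],
                  index = i, censored = FALSE))
    }
  }
  i <- which.max(s)
  list(failure_stress = s[i], failure_strain = curve$strain[i],
       index = i, censored = TRUE)
}

#' Shear modulus from Young's modulus and Poisson's ratio
#'
#' G = E / (2 (1 + nu)), the isotropic linear-elastic relation.
#'
#' @param E Young's modulus (any pressure unit; result is in the same unit).
#' @param poisson Poisson's ratio nu, in (-1, 0.5].
#' @return Shear modulus G.
#' @export
shear_modulus <- function(E, poisson) {
  if (any(E <= 0)) stop("Young's modulus must be positive")
  if (any(poisson <= -1) || any(poisson > 0.5))
    stop("Poisson's ratio must lie in (-1, 0.5]")
  E / (2 * (1 + poisson))
}

#' Summary analysis of a ring tensile record
#'
#' Full mechanics chain: engineering curve, true conversion, failure
#' detection, Young's modulus from the linear region, and the elastic/plastic
#' split at failure.
#'
#' @param record An [fd_record] in ring-tensile mode.
#' @param geom A [ring_geometry].
#' @param linear_fraction Passed to [youngs_modulus].
#' @param drop_fraction Passed to [detect_failure].
#' @return A list with the engineering and true curves, `youngs_modulus`
#'   (Pa), the failure point on both scales, and the strain decomposition.
#' @export
analyze_ring_record <- function(record, geom, linear_fraction = 0.4,
                                drop_fraction = 0.5) {
  eng <- ring_curve(record, geom)
  fail_eng <- detect_failure(eng, drop_fraction)
  attr(eng, "failure_index") <- fail_eng$index
  tru <- to_true(eng)
  fail_true <- detect_failure(tru, drop_fraction)
  E <- youngs_modulus(tru, linear_fraction)
  decomp <- decompose_strain(tru, E)
  list(
    engineering = eng, true = tru,
    youngs_modulus = E,
    failure = fail_eng, failure_true = fail_true,
    decomposition = decomp
  )
}
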