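#' Ring specimen geometry
#'
#' Geometry of an oval ring specimen stretched between two pins, the standard
#' grip-free tensile configuration for soft gels. All lengths in metres.
#'
#' @param pin_diameter Diameter `d` of each pin (m).
#' @param initial_circumference Initial inside circumference `C0` (m). Must be
#'   at least `pi * pin_diameter` (the ring must fit around one pin).
#' @param width Initial specimen width `w` (m), measured in the loading plane.
#' @param thickness Specimen thickness `Tr` (m), out of plane.
#'
#' @return An object of class `"ring_geometry"`.
#' @examples
#' ring_geometry(6e-3, 60e-3, 5e-3, 5e-3)
#' @export
ring_geometry <- function(pin_diameter = 6e-3, initial_circumference = 60e-3,
                          width = 5e-3, thickness = 5e-3) {
  stopifnot(
    "pin_diameter must be positive"          = pin_diameter > 0,
    "initial_circumference must be positive" = initial_circumference > 0,
    "width must be positive"                 = width > 0,
    "thickness must be positive"             = thickness > 0
  )
  if (initial_circumference < pi * pin_diameter)
    stop("initial_circumference must be >= pi * pin_diameter (ring must fit around the pin)")
  structure(
    list(pin_diameter = pin_diameter,
         initial_circumference = initial_circumference,
         width = width, thickness = thickness),
    class = "ring_geometry"
  )
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat("Ring specimen geometry:\n")
  cat(sprintf("  pin diameter d  : %.3f mm\n", 1e3 * x$pin_diameter))
  cat(sprintf("  circumference C0: %.3f mm\n", 1e3 * x$initial_circumference))
  cat(sprintf("  width w         : %.3f mm\n", 1e3 * x$width))
  cat(sprintf("  thickness Tr    : %.3f mm\n", 1e3 * x$thickness))
  invisible(x)
}

#' Uniaxial compression specimen geometry
#'
#' @param contact_area Contact area `A` between probe and specimen (m^2).
#' @param initial_length Initial specimen height `L` (m).
#' @param diameter Convenience alternative to `contact_area`: cylinder
#'   diameter (m), from which `A = pi d^2 / 4` is computed.
#'
#' @return An object of class `"compression_geometry"`.
#' @examples
#' compression_geometry(diameter = 25.4e-3, initial_length = 20e-3)
#' @export
compression_geometry <- function(contact_area = NULL, initial_length = 20e-3,
                                 diameter = NULL) {
  if (is.null(contact_area)) {
    if (is.null(diameter)) stop("give either contact_area or diameter")
    contact_area <- pi * diameter^2 / 4
  }
  stopifnot(
    "contact_area must be positive"   = contact_area > 0,
    "initial_length must be positive" = initial_length > 0
  )
  structure(
    list(contact_area = contact_area, initial_length = initial_length),
    class = "compression_geometry"
  )
}

#' @export
print.compression_geometry <- function(x, ...) {
  cat("Compression specimen geometry:\n")
  cat(sprintf("  contact area A  : %.2f mm^2\n", 1e6 * x$contact_area))
  cat(sprintf("  initial length L: %.2f mm\n", 1e3 * x$initial_length))
  invisible(x)
}

#' Force-displacement record
#'
#' A sampled record from a tensile or compression run: time (s), crosshead
#' displacement (m) and force (N).
#'
#' @param time Sample times (s), non-decreasing.
#' @param displacement Crosshead displacement (m).
#' @param force Measured force (N).
#' @param mode `"ring_tensile"` or `"compression"`.
#' @param failure_index Optional index of the failure sample.
#'
#' @return An object of class `"fd_record"` (also a data frame).
#' @export
fd_record <- function(time, displacement, force,
                      mode = c("ring_tensile", "compression"),
                      failure_index = NULL) {
  mode <- match.arg(mode)
  n <- length(time)
  stopifnot(
    "time/displacement/force lengths differ" =
      length(displacement) == n && length(force) == n,
    "record needs at least 2 samples" = n >= 2,
    "time must be non-decreasing"     = !is.unsorted(time)
  )
  if (!is.null(failure_index))
    stopifnot("failure_index out of bounds" =
                failure_index >= 1 && failure_index <= n)
  out <- data.frame(time = time, displacement = displacement, force = force)
  attr(out, "mode") <- mode
  attr(out, "failure_index") <- failure_index
  class(out) <- c("fd_record", "data.frame")
  out
}

#' @export
print.fd_record <- function(x, ...) {
  cat(sprintf("Force-displacement record (%s): %d samples, %.2f s\n",
              attr(x, "mode"), nrow(x), max(x$time)))
  cat(sprintf("  peak force %.4g N at displacement %.3f mm\n",
              max(x$force), 1e3 * x$displacement[which.max(x$force)]))
  if (!is.null(attr(x, "failure_index")))
    cat(sprintf("  failure at sample %d\n", attr(x, "failure_index")))
  invisible(x)
}
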