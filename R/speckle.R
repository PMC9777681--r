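#' Synthetic speckle image pair with known deformation
#'
#' Renders a random speckle pattern (dark Gaussian blobs on a light
#' background, as painted on a gel surface) and the same pattern under a
#' prescribed affine deformation about the image centre,
#' x = F (X - c) + c + t. Both images are rendered analytically by
#' evaluating the blob intensity field at (inverse-)mapped coordinates, so
#' the deformed image carries no interpolation error and the ground-truth
#' displacement field is exact to machine precision.
#'
#' Pixel coordinates are image convention: origin at the top-left pixel
#' centre (1, 1), x rightward along columns, y downward along rows.
#'
#' @param image_shape Image size in pixels, `c(rows, cols)` or a scalar;
#'   at least 64.
#' @param gradient 2x2 deformation-gradient matrix F (rows act on (x, y)).
#' @param translation Translation (tx, ty) in pixels.
#' @param speckle_density Expected speckles per pixel^2 (default 0.02).
#' @param speckle_radius Gaussian radius (SD) of each blob in pixels.
#' @param intensity_noise_sd Additive Gaussian intensity noise in gray
#'   levels of an 8-bit scale (0-255).
#' @param seed Integer seed; identical seeds give identical pairs.
#' @param quantize Quantize both images to 8-bit levels (default TRUE).
#' @return A list of class `"speckle_pair"`: `reference` and `deformed`
#'   (matrices in \[0, 1\], rows = y), `gradient`, `translation`, `center`,
#'   and `truth(x, y)` - a function returning the exact displacement (u, v)
#'   at reference coordinates.
#' @export
generate_speckle_pair <- function(image_shape = c(128, 128),
                                  gradient = diag(2),
                                  translation = c(0, 0),
                                  speckle_density = 0.02,
                                  speckle_radius = 2,
                                  intensity_noise_sd = 0,
                                  seed = NULL, quantize = TRUE) {
  if (length(image_shape) == 1) image_shape <- rep(image_shape, 2)
  stopifnot(all(image_shape >= 64), speckle_density > 0, speckle_radius > 0,
            intensity_noise_sd >= 0,
            is.matrix(gradient), all(dim(gradient) == c(2, 2)))
  if (abs(det(gradient)) < 1e-8) stop("deformation gradient is singular")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (!is.null(seed)) set.seed(seed)
  n_blob <- max(10L, round(speckle_density * nr * nc))
  margin <- 4 * speckle_radius + 2
  cx <- runif(n_blob, margin, nc - margin)
  cy <- runif(n_blob, margin, nr - margin)
  amp <- runif(n_blob, 0.5, 0.9)
  cen <- c((nc + 1) / 2, (nr + 1) / 2)
  # where do the speckles land after deformation?
  def_c <- gradient %*% rbind(cx - cen[1], cy - cen[2]) + cen + translation
  if (any(def_c[1, ] < 1) || any(def_c[1, ] > nc) ||
      any(def_c[2, ] < 1) || any(def_c[2, ] > nr))
    stop("deformation pushes speckles out of the frame")

  render <- function(px, py) {
    # intensity field: light background minus Gaussian blobs, evaluated at
    # arbitrary (possibly warped) coordinates px, py (matrices)
    img <- matrix(0.95, nr, nc)
    inv_2s2 <- 1 / (2 * speckle_radius^2)
    for (j in seq_len(n_blob)) {
      img <- img - amp[j] * exp(-((px - cx[j])^2 + (py - cy[j])^2) * inv_2s2)
    }
    pmin(pmax(img, 0), 1)
  }
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr), nr, nc)
  reference <- render(xg, yg)
  # deformed image: I_def(x) = I_ref(phi^{-1}(x))
  Finv <- solve(gradient)
  dx <- xg - cen[1] - translation[1]
  dy <- yg - cen[2] - translation[2]
  px <- Finv[1, 1] * dx + Finv[1, 2] * dy + cen[1]
  py <- Finv[2, 1] * dx + Finv[2, 2] * dy + cen[2]
  deformed <- render(px, py)
  if (intensity_noise_sd > 0) {
    reference <- reference + rnorm(length(reference), sd = intensity_noise_sd / 255)
    deformed <- deformed + rnorm(length(deformed), sd = intensity_noise_sd / 255)
    reference <- pmin(pmax(reference, 0), 1)
    deformed <- pmin(pmax(deformed, 0), 1)
  }
  if (quantize) {
    reference <- round(reference * 255) / 255
    deformed <- round(deformed * 255) / 255
  }
  g <- gradient; tr <- translation
  truth <- function(x, y) {
    ux <- g[1, 1] * (x - cen[1]) + g[1, 2] * (y - cen[2]) + cen[1] + tr[1] - x
    uy <- g[2, 1] * (x - cen[1]) + g[2, 2] * (y - cen[2]) + cen[2] + tr[2] - y
    cbind(u = ux, v = uy)
  }
  structure(list(reference = reference, deformed = deformed,
                 gradient = gradient, translation = translation,
                 center = cen, truth = truth),
            class = "speckle_pair")
}

#' @export
print.speckle_pair <- function(x, ...) {
  cat(sprintf("Speckle image pair: %d x %d px\n",
              nrow(x$reference), ncol(x$reference)))
  cat(sprintf("  gradient [%g %g; %g %g], translation (%g, %g) px\n",
              x$gradient[1, 1], x$gradient[1, 2], x$gradient[2, 1],
              x$gradient[2, 2], x$translation[1], x$translation[2]))
  invisible(x)
}
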