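#' DIC configuration
#'
#' @param subset_size Subset edge length in pixels, odd, >= 11.
#' @param grid_spacing Grid spacing in pixels, >= 1.
#' @param search_radius Integer search radius in pixels; must cover the
#'   largest expected displacement.
#' @param min_correlation Minimum acceptable zero-normalized
#'   cross-correlation peak, in (0, 1].
#' @return An object of class `"dic_config"`.
#' @export
dic_config <- function(subset_size = 21, grid_spacing = 10,
                       search_radius = 20, min_correlation = 0.5) {
  stopifnot(
    "subset_size must be odd and >= 11" =
      subset_size >= 11 && subset_size %% 2 == 1,
    "grid_spacing must be >= 1"   = grid_spacing >= 1,
    "search_radius must be >= 1"  = search_radius >= 1,
    "min_correlation in (0, 1]"   = min_correlation > 0 && min_correlation <= 1
  )
  structure(list(subset_size = subset_size, grid_spacing = grid_spacing,
                 search_radius = search_radius,
                 min_correlation = min_correlation),
            class = "dic_config")
}

# zero-normalized subset: subtract mean, scale to unit Frobenius norm
znorm <- function(m) {
  m <- m - mean(m)
  nrm <- sqrt(sum(m * m))
  if (nrm < .Machine$double.eps) return(NULL)   # flat subset: no texture
  m / nrm
}

# one-dimensional sub-pixel peak offset from three correlation samples.
# Log-parabola fit (exact for a Gaussian-shaped peak, which speckle
# autocorrelation approximates); falls back to a plain parabola when any
# sample is non-positive.
quad_peak <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    cm <- log(cm); c0 <- log(c0); cp <- log(cp)
  }
  den <- cm - 2 * c0 + cp
  if (den >= 0) return(0)              # not a proper maximum
  off <- 0.5 * (cm - cp) / den
  max(min(off, 0.5), -0.5)
}

# bilinear sample of a subset of img centered at fractional (cx, cy)
bilinear_subset <- function(img, cx, cy, half) {
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  wy0 <- (1 - fy); wy1 <- fy
  a <- img[y0, x0, drop = FALSE] * wy0 + img[y0 + 1, x0, drop = FALSE] * wy1
  b <- img[y0, x0 + 1, drop = FALSE] * wy0 + img[y0 + 1, x0 + 1, drop = FALSE] * wy1
  sweep(a, 2, 1 - fx, "*") + sweep(b, 2, fx, "*")
}

#' Track speckle subsets between a reference and a deformed image
#'
#' Subset-based digital image correlation: for each point of a regular grid,
#' the integer-pixel displacement maximizing the zero-normalized
#' cross-correlation (ZNCC) within the search window is found by exhaustive
#' scan, then refined to sub-pixel accuracy by a quadratic fit of the 3x3
#' correlation neighborhood followed by coordinate-descent maximization of
#' the ZNCC against a bilinearly interpolated deformed subset. Points whose
#' peak score falls below `min_correlation`, whose subset is textureless, or
#' whose search window leaves the image are masked.
#'
#' @param reference,deformed Grayscale image matrices of identical shape,
#'   values in \[0, 1\] (rows = y, columns = x).
#' @param cfg A [dic_config].
#' @return A data frame of class `"displacement_field"` with columns `x`,
#'   `y` (grid coordinates, px), `u`, `v` (displacements, px), `score`
#'   (ZNCC peak) and logical `masked`.
#' @export
track_subsets <- function(reference, deformed, cfg = dic_config()) {
  stopifnot(is.matrix(reference), is.matrix(deformed),
            all(dim(reference) == dim(deformed)),
            inherits(cfg, "dic_config"))
  nr <- nrow(reference); nc <- ncol(reference)
  half <- (cfg$subset_size - 1) %/% 2
  r <- cfg$search_radius
  margin <- half + r + 1
  if (2 * margin + 1 > min(nr, nc))
    stop("grid does not fit inside the image with this subset and search radius")
  xs <- seq(margin + 1, nc - margin, by = cfg$grid_spacing)
  ys <- seq(margin + 1, nr - margin, by = cfg$grid_spacing)
  grid <- expand.grid(x = xs, y = ys)
  np <- nrow(grid)
  u <- v <- score <- rep(NA_real_, np)
  masked <- rep(TRUE, np)
  shifts <- -r:r
  for (p in seq_len(np)) {
    gx <- grid$x[p]; gy <- grid$y[p]
    tmpl <- znorm(reference[(gy - half):(gy + half), (gx - half):(gx + half)])
    if (is.null(tmpl)) next
    cc <- matrix(-Inf, 2 * r + 1, 2 * r + 1)   # rows: dy, cols: dx
    for (iy in seq_along(shifts)) {
      dy <- shifts[iy]
      rows <- (gy + dy - half):(gy + dy + half)
      for (ix in seq_along(shifts)) {
        dx <- shifts[ix]
        w <- znorm(deformed[rows, (gx + dx - half):(gx + dx + half)])
        if (is.null(w)) next
        cc[iy, ix] <- sum(tmpl * w)
      }
    }
    pk <- arrayInd(which.max(cc), dim(cc))
    iy <- pk[1]; ix <- pk[2]
    pk_score <- cc[iy, ix]
    if (!is.finite(pk_score) || pk_score < cfg$min_correlation) next
    # peak on the search border cannot be refined; mask it
    if (iy == 1 || iy == 2 * r + 1 || ix == 1 || ix == 2 * r + 1) next
    du <- quad_peak(cc[iy, ix - 1], pk_score, cc[iy, ix + 1])
    dv <- quad_peak(cc[iy - 1, ix], pk_score, cc[iy + 1, ix])
    # refine against the interpolated deformed image
    zncc_at <- function(uu, vv) {
      w <- znorm(bilinear_subset(deformed, gx + uu, gy + vv, half))
      if (is.null(w)) -1 else sum(tmpl * w)
    }
    uu <- shifts[ix] + du; vv <- shifts[iy] + dv
    for (it in 1:2) {
      uu <- optimize(function(z) -zncc_at(z, vv),
                     c(uu - 0.55, uu + 0.55), tol = 1e-4)$minimum
      vv <- optimize(function(z) -zncc_at(uu, z),
                     c(vv - 0.55, vv + 0.55), tol = 1e-4)$minimum
    }
    u[p] <- uu
    v[p] <- vv
    score[p] <- zncc_at(uu, vv)
    masked[p] <- FALSE
  }
  if (all(masked)) stop("all grid points masked: no correlatable texture")
  out <- data.frame(x = grid$x, y = grid$y, u = u, v = v,
                    score = score, masked = masked)
  attr(out, "config") <- cfg
  class(out) <- c("displacement_field", "data.frame")
  out
}

#' @export
print.displacement_field <- function(x, ...) {
  ok <- !x$masked
  cat(sprintf("Displacement field: %d grid points (%d masked)\n",
              nrow(x), sum(x$masked)))
  if (any(ok))
    cat(sprintf("  mean (u, v) = (%.3f, %.3f) px, mean score %.3f\n",
                mean(x$u[ok]), mean(x$v[ok]), mean(x$score[ok])))
  invisible(x)
}

#' Strain field from a displacement field
#'
#' Local least-squares plane fit of u(x, y) and v(x, y) over a square window
#' of grid neighbors; the in-plane small-strain components follow from the
#' plane gradients: exx = du/dx, eyy = dv/dy, exy = (du/dy + dv/dx) / 2.
#' Strains are reported in image axes (x rightward, y downward).
#'
#' @param field A `"displacement_field"` from [track_subsets].
#' @param window Window half-width in grid points (default 1, i.e. a 3x3
#'   neighborhood).
#' @return A data frame of class `"strain_field"` with columns `x`, `y`,
#'   `exx`, `eyy`, `exy` and logical `masked` (points with fewer than 6
#'   unmasked neighbors, the minimum for a stable plane fit, are masked).
#' @export
strain_field <- function(field, window = 1) {
  stopifnot(inherits(field, "displacement_field"), window >= 1)
  cfg <- attr(field, "config")
  xs <- sort(unique(field$x)); ys <- sort(unique(field$y))
  h <- cfg$grid_spacing * window * 1.001          # neighbor radius (px)
  n <- nrow(field)
  exx <- eyy <- exy <- rep(NA_real_, n)
  masked <- rep(TRUE, n)
  ok <- !field$masked
  for (p in seq_len(n)) {
    nb <- which(ok &
                  abs(field$x - field$x[p]) <= h &
                  abs(field$y - field$y[p]) <= h)
    if (length(nb) < 6) next
    X <- cbind(1, field$x[nb] - field$x[p], field$y[nb] - field$y[p])
    fu <- lm.fit(X, field$u[nb])$coefficients
    fv <- lm.fit(X, field$v[nb])$coefficients
    if (anyNA(c(fu, fv))) next
    exx[p] <- fu[2]
    eyy[p] <- fv[3]
    exy[p] <- (fu[3] + fv[2]) / 2
    masked[p] <- FALSE
  }
  out <- data.frame(x = field$x, y = field$y,
                    exx = exx, eyy = eyy, exy = exy, masked = masked)
  class(out) <- c("strain_field", "data.frame")
  out
}

#' Construct a strain field from component vectors
#'
#' Builds a `"strain_field"` object directly, e.g. for summarizing an
#' externally computed or analytically prescribed field with
#' [strain_concentration_index].
#'
#' @param x,y Grid coordinates (px).
#' @param exx,eyy,exy Strain components.
#' @param masked Logical mask (default all unmasked).
#' @return A data frame of class `"strain_field"`.
#' @export
new_strain_field <- function(x, y, exx, eyy = 0, exy = 0,
                             masked = FALSE) {
  n <- length(x)
  out <- data.frame(x = x, y = y, exx = rep_len(exx, n),
                    eyy = rep_len(eyy, n), exy = rep_len(exy, n),
                    masked = rep_len(masked, n))
  class(out) <- c("strain_field", "data.frame")
  out
}

#' Strain concentration index
#'
#' Ratio of the maximum to the median of a strain component over the
#' unmasked field: near 1 for homogeneous deformation (as seen in gels early
#' in elongation), large when strain localizes at an incipient failure site.
#'
#' @param strains A `"strain_field"` from [strain_field].
#' @param component Strain component to summarize (default `"exx"`).
#' @return Dimensionless concentration index >= 1 (max / median).
#' @export
strain_concentration_index <- function(strains, component = "exx") {
  stopifnot(inherits(strains, "strain_field"),
            component %in% c("exx", "eyy", "exy"))
  vals <- strains[[component]][!strains$masked]
  if (length(vals) < 10) stop("need at least 10 unmasked strain points")
  med <- median(vals)
  if (med <= 0) stop("non-positive median strain; index undefined")
  max(vals) / med
}
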