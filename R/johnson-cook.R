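#' Johnson-Cook material description
#'
#' Elastic constants plus the Johnson-Cook hardening parameters
#' (A, B, n, C, eps0) and damage constants d1..d5. The thermal-softening
#' bracket of the full Johnson-Cook law is disabled throughout (frictional
#' heating in a slow gel test is negligible), and the trailing temperature
#' factor of the fracture-strain law is fixed at 1, so `d5` is stored but
#' inert.
#'
#' @param E Young's modulus (Pa).
#' @param poisson Poisson's ratio.
#' @param density Mass density (kg/m^3).
#' @param yield_A Initial yield strength A (Pa).
#' @param hardening_B Hardening modulus B (Pa), >= 0.
#' @param exponent_n Strain-hardening exponent n, >= 0.
#' @param rate_C Strain-rate sensitivity C (dimensionless).
#' @param ref_rate Reference plastic strain rate eps0 (1/s), > 0.
#' @param d1,d2,d3,d4,d5 Damage constants of the fracture-strain law.
#'
#' @return An object of class `"jc_material"`.
#' @examples
#' # pure agarose gel (1.5 % w/w)
#' jc_material(E = 37891e3, poisson = 0.48, yield_A = 2969e3,
#'             hardening_B = 2054e3, exponent_n = 0.00067, rate_C = 0.01)
#' @export
jc_material <- function(E, poisson = 0.48, density = 1000,
                        yield_A, hardening_B = 0, exponent_n = 0,
                        rate_C = 0, ref_rate = 1,
                        d1 = 0, d2 = 0, d3 = 0, d4 = 0, d5 = 0) {
  stopifnot(
    "E must be positive"           = E > 0,
    "yield_A must be positive"     = yield_A > 0,
    "hardening_B must be >= 0"     = hardening_B >= 0,
    "exponent_n must be >= 0"      = exponent_n >= 0,
    "ref_rate must be positive"    = ref_rate > 0,
    "Poisson's ratio out of range" = poisson > -1 && poisson <= 0.5
  )
  structure(
    list(E = E, poisson = poisson, density = density,
         yield_A = yield_A, hardening_B = hardening_B,
         exponent_n = exponent_n, rate_C = rate_C, ref_rate = ref_rate,
         d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5),
    class = "jc_material"
  )
}

#' @export
print.jc_material <- function(x, ...) {
  cat("Johnson-Cook material:\n")
  cat(sprintf("  E = %.4g kPa, nu = %.3g, G = %.4g kPa\n",
              x$E / 1e3, x$poisson, shear_modulus(x$E, x$poisson) / 1e3))
  cat(sprintf("  A = %.4g kPa, B = %.4g kPa, n = %.4g, C = %.4g, eps0 = %.3g /s\n",
              x$yield_A / 1e3, x$hardening_B / 1e3,
              x$exponent_n, x$rate_C, x$ref_rate))
  cat(sprintf("  damage d1..d5 = %.4g, %.4g, %.4g, %.4g, %.4g\n",
              x$d1, x$d2, x$d3, x$d4, x$d5))
  invisible(x)
}

# rate-sensitivity bracket, floored so the flow stress can never go
# non-positive at rates far below the reference rate
jc_rate_bracket <- function(mat, plastic_rate, bracket_floor = 0.05) {
  br <- 1 + mat$rate_C * log(plastic_rate / mat$ref_rate)
  if (any(br < bracket_floor)) {
    warning("rate bracket floored: plastic rate far below the reference rate")
    br <- pmax(br, bracket_floor)
  }
  br
}

#' Johnson-Cook flow stress
#'
#' sigma = (A + B * eps_p^n) * (1 + C * log(rate / eps0)), with 0^n defined
#' as 0 so the stress at zero plastic strain is A times the rate bracket.
#'
#' @param mat A [jc_material].
#' @param plastic_strain Equivalent plastic strain, >= 0. Vectorised.
#' @param plastic_rate Plastic strain rate (1/s), > 0.
#' @return Flow stress (Pa).
#' @export
jc_stress <- function(mat, plastic_strain, plastic_rate = mat$ref_rate) {
  stopifnot(inherits(mat, "jc_material"))
  if (any(plastic_strain < 0)) stop("plastic strain must be non-negative")
  if (any(plastic_rate <= 0)) stop("plastic rate must be positive")
  hard <- ifelse(plastic_strain == 0, 0,
                 mat$hardening_B * plastic_strain^mat$exponent_n)
  (mat$yield_A + hard) * jc_rate_bracket(mat, plastic_rate)
}

#' Johnson-Cook fracture strain
#'
#' eps_f = (d1 + d2 exp(-d3 * triaxiality)) * (1 + d4 log(rate / eps0)),
#' with the vestigial temperature factor fixed at 1. Triaxiality is the mean
#' stress over the equivalent stress (1/3 in uniaxial tension).
#'
#' @param mat A [jc_material].
#' @param triaxiality Stress triaxiality sigma_m / sigma_eq. Vectorised.
#' @param plastic_rate Plastic strain rate (1/s), > 0.
#' @return Fracture strain (dimensionless), guaranteed positive.
#' @export
jc_fracture_strain <- function(mat, triaxiality = 1 / 3,
                               plastic_rate = mat$ref_rate) {
  stopifnot(inherits(mat, "jc_material"))
  if (any(plastic_rate <= 0)) stop("plastic rate must be positive")
  ef <- (mat$d1 + mat$d2 * exp(-mat$d3 * triaxiality)) *
    (1 + mat$d4 * log(plastic_rate / mat$ref_rate))
  if (any(ef <= 0))
    stop(sprintf(paste0("non-positive fracture strain from damage parameters ",
                        "d1=%g, d2=%g, d3=%g, d4=%g at triaxiality %g, rate %g"),
                 mat$d1, mat$d2, mat$d3, mat$d4,
                 triaxiality[1], plastic_rate[1]))
  ef
}

#' Damage accumulator state
#'
#' @param D Accumulated damage, >= 0.
#' @return An object of class `"damage_state"` with fields `D` and `failed`
#'   (`failed` is `TRUE` iff `D >= 1`, with a relative guard of 1e-9 so that
#'   increments that sum to 1 analytically trigger failure despite rounding).
#' @export
damage_state <- function(D = 0) {
  stopifnot("damage must be non-negative" = D >= 0)
  structure(list(D = D, failed = D >= 1 - 1e-9), class = "damage_state")
}

#' Accumulate ductile damage over a plastic strain increment
#'
#' Implements the damage integral D = int d(eps_p) / eps_f incrementally:
#' D <- D + d_eps_p / eps_f. Failure is declared when D reaches 1.
#'
#' @param state A [damage_state].
#' @param d_plastic_strain Plastic strain increment, >= 0.
#' @param fracture_strain Fracture strain eps_f over the increment, > 0. Pass
#'   the harmonic mean of the endpoint values to make the accumulated D the
#'   trapezoidal integral of 1/eps_f.
#' @return The updated [damage_state].
#' @export
accumulate_damage <- function(state, d_plastic_strain, fracture_strain) {
  stopifnot(inherits(state, "damage_state"))
  if (d_plastic_strain < 0) stop("plastic strain increment must be >= 0")
  if (fracture_strain <= 0) stop("fracture strain must be positive")
  damage_state(state$D + d_plastic_strain / fracture_strain)
}

#' Loading program for the material-point simulator
#'
#' @param strain_rate Constant total true strain rate (1/s), > 0.
#' @param duration Total loading time (s), > 0.
#' @param step Time step (s), > 0 and <= duration.
#' @return An object of class `"loading_program"`.
#' @export
loading_program <- function(strain_rate, duration, step = NULL) {
  if (is.null(step)) step <- 1e-3 / strain_rate   # default 1e-3 strain per step
  stopifnot(
    "strain_rate must be positive" = strain_rate > 0,
    "duration must be positive"    = duration > 0,
    "step must be positive"        = step > 0,
    "step must not exceed duration" = step <= duration
  )
  structure(list(strain_rate = strain_rate, duration = duration, step = step),
            class = "loading_program")
}

# one return-mapping step: given total true strain at the end of the step and
# the previous plastic strain, find the plastic increment such that the
# elastic stress sits on the JC hardening surface. The rate bracket is
# evaluated at the nominal applied strain rate (post-yield the plastic rate
# tracks the total rate closely for E >> hardening modulus), which keeps the
# pre-yield response exactly elastic. Returns d_eps_p (0 for an elastic step).
jc_return_map <- function(mat, strain_new, eps_p_old, rate) {
  trial <- mat$E * (strain_new - eps_p_old)
  br <- jc_rate_bracket(mat, rate)
  yield_at <- function(ep) {
    hard <- if (ep == 0) 0 else mat$hardening_B * ep^mat$exponent_n
    (mat$yield_A + hard) * br
  }
  if (trial <= yield_at(eps_p_old)) return(0)
  f <- function(dp) trial - mat$E * dp - yield_at(eps_p_old + dp)
  # for n near zero the hardening curve is near-vertical at eps_p = 0; a
  # consistency root below resolution is an elastic step in practice
  lo <- 1e-12
  if (f(lo) <= 0) return(0)
  upper <- trial / mat$E          # full relaxation of the elastic stress
  if (f(upper) >= 0)
    stop("return mapping did not converge (residual stress at full relaxation); use a smaller step")
  uniroot(f, c(lo, upper), tol = 1e-15)$root
}

#' Strain-driven material-point tensile simulation
#'
#' Integrates a single material point under a constant true strain rate:
#' elastic predictor sigma = E (eps - eps_p), implicit return mapping onto
#' the Johnson-Cook hardening surface when the predictor exceeds it, and
#' ductile damage accumulated as the trapezoidal integral of
#' d(eps_p)/eps_f. The run stops at the first step where the damage reaches
#' 1 (failure) or at the end of the program (censored).
#'
#' @param mat A [jc_material]. Set `d1 = d2 = 0` impossible (fracture strain
#'   must stay positive); use a huge `d1` to disable failure in practice.
#' @param prog A [loading_program].
#' @param triaxiality Stress triaxiality driving the fracture strain
#'   (default 1/3, uniaxial tension).
#' @param damage Logical; set `FALSE` to integrate plasticity only.
#' @return A list of class `"jc_simulation"`: `curve` (a true
#'   [stress_strain_curve]), `plastic_strain`, `damage` (accumulated D per
#'   sample), `failed`, `failure_index`.
#' @export
simulate_tensile <- function(mat, prog, triaxiality = 1 / 3, damage = TRUE) {
  stopifnot(inherits(mat, "jc_material"), inherits(prog, "loading_program"))
  nstep <- ceiling(prog$duration / prog$step)
  dt <- prog$step
  strain <- prog$strain_rate * dt * (0:nstep)
  n <- nstep + 1L
  stress <- numeric(n)
  eps_p <- numeric(n)
  D <- numeric(n)
  ef_prev <- NA_real_
  failed <- FALSE
  last <- n
  for (i in 2:n) {
    dp <- jc_return_map(mat, strain[i], eps_p[i - 1], prog$strain_rate)
    eps_p[i] <- eps_p[i - 1] + dp
    stress[i] <- mat$E * (strain[i] - eps_p[i])
    D[i] <- D[i - 1]
    if (damage && dp > 0) {
      ef <- jc_fracture_strain(mat, triaxiality, prog$strain_rate)
      ef0 <- if (is.na(ef_prev)) ef else ef_prev
      # harmonic mean of endpoint fracture strains => trapezoid on 1/eps_f
      st <- accumulate_damage(damage_state(D[i - 1]), dp, 2 / (1 / ef0 + 1 / ef))
      D[i] <- st$D
      ef_prev <- ef
      if (st$failed) { failed <- TRUE; last <- i; break }
    }
  }
  idx <- seq_len(last)
  curve <- stress_strain_curve(strain[idx], stress[idx], kind = "true",
                               failure_index = if (failed) last else NULL)
  structure(
    list(curve = curve, plastic_strain = eps_p[idx], damage = D[idx],
         failed = failed, failure_index = if (failed) last else NA_integer_),
    class = "jc_simulation"
  )
}

#' @export
print.jc_simulation <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("Material-point tensile simulation: %d samples\n", n))
  if (x$failed)
    cat(sprintf("  failure at true strain %.4g, true stress %.4g kPa (D = %.4g)\n",
                x$curve$strain[n], x$curve$stress[n] / 1e3, x$damage[n]))
  else cat("  no failure (censored)\n")
  invisible(x)
}

#' Fit Johnson-Cook hardening parameters
#'
#' Nonlinear least squares of sigma = A + B * eps_p^n on true stress vs
#' plastic strain data measured at the reference strain rate (so the rate
#' bracket is 1). Solved by variable projection: A and B are profiled out
#' linearly for each candidate n, and n is located by golden-section search
#' on a log scale, followed by a Levenberg-Marquardt polish. This remains
#' exact when n is tiny (near-perfectly plastic data), where a joint
#' three-parameter descent is ill-conditioned.
#'
#' @param plastic_strain Plastic strain values, > 0, at least 10 of them.
#' @param stress True stress values (Pa).
#' @param n_range Search interval for the hardening exponent
#'   (default `c(1e-6, 2)`).
#' @return A list with `A`, `B`, `n`, `residual_norm` and `fitted`.
#' @export
fit_hardening <- function(plastic_strain, stress, n_range = c(1e-6, 2)) {
  keep <- plastic_strain > 0
  x <- plastic_strain[keep]
  y <- stress[keep]
  if (length(x) < 10)
    stop("need at least 10 post-yield samples (positive plastic strain)")
  lx <- log(x)
  # profiled linear fit of (A, B) at fixed n, constrained to A, B >= 0:
  # unconstrained least squares, falling back to the active-constraint
  # solutions when a coefficient goes negative
  ab_at <- function(n) {
    basis <- exp(n * lx)
    fit <- lm.fit(cbind(1, basis), y)
    ab <- fit$coefficients
    if (all(ab >= 0)) return(list(A = ab[1], B = ab[2],
                                  rss = sum(fit$residuals^2)))
    cand <- list(
      list(A = max(mean(y), 0), B = 0),                          # B pinned
      list(A = 0, B = max(sum(basis * y) / sum(basis^2), 0)))    # A pinned
    rss <- vapply(cand, function(p) sum((y - p$A - p$B * basis)^2), numeric(1))
    c(cand[[which.min(rss)]], rss = min(rss))
  }
  opt <- optimize(function(logn) ab_at(exp(logn))$rss, log(n_range), tol = 1e-12)
  n_hat <- exp(opt$minimum)
  sol <- ab_at(n_hat)
  A_hat <- sol$A
  B_hat <- sol$B
  fit <- list(residuals = y - A_hat - B_hat * exp(n_hat * lx))
  # polish with Levenberg-Marquardt from the varpro solution
  polished <- tryCatch({
    df <- data.frame(x = x, y = y)
    nf <- minpack.lm::nlsLM(
      y ~ A + B * x^n, data = df,
      start = list(A = A_hat, B = B_hat, n = n_hat),
      lower = c(A = 0, B = 0, n = n_range[1]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(nf)
    list(A = cf[["A"]], B = cf[["B"]], n = cf[["n"]],
         rss = sum(residuals(nf)^2))
  }, error = function(e) NULL)
  rss0 <- sum(fit$residuals^2)
  if (!is.null(polished) && polished$rss < rss0) {
    A_hat <- polished$A; B_hat <- polished$B; n_hat <- polished$n
    rss0 <- polished$rss
  }
  if (!is.finite(rss0))
    stop("hardening fit did not converge; residual norm is not finite")
  list(A = unname(A_hat), B = unname(B_hat), n = unname(n_hat),
       residual_norm = sqrt(rss0),
       fitted = unname(A_hat + B_hat * x^n_hat))
}

#' Fit Johnson-Cook damage constants
#'
#' Least-squares fit of the fracture-strain law
#' eps_f = (d1 + d2 exp(-d3 * triaxiality)) * (1 + d4 log(rate / eps0))
#' to observed fracture strains. Constants that the design cannot identify
#' must be frozen through `fixed`: fitting d3 requires at least two distinct
#' triaxialities, fitting d4 at least two distinct rates, and the number of
#' observations must reach the number of free constants.
#'
#' @param fracture_strain Observed fracture strains.
#' @param triaxiality Stress triaxiality of each observation.
#' @param rate Plastic strain rate of each observation (1/s).
#' @param ref_rate Reference strain rate eps0 (1/s).
#' @param fixed Named list of constants to hold fixed, e.g.
#'   `list(d4 = 0)`.
#' @return A list with `d1`, `d2`, `d3`, `d4` and `residual_norm`.
#' @export
fit_damage <- function(fracture_strain, triaxiality, rate,
                       ref_rate = 1, fixed = list()) {
  n <- length(fracture_strain)
  stopifnot(length(triaxiality) == n, length(rate) == n)
  free <- setdiff(c("d1", "d2", "d3", "d4"), names(fixed))
  if ("d3" %in% free && length(unique(triaxiality)) < 2)
    stop("d3 is unidentifiable from a single triaxiality; fix it via `fixed`")
  if ("d4" %in% free && length(unique(rate)) < 2)
    stop("d4 is unidentifiable from a single rate; fix it via `fixed`")
  if (n < length(free))
    stop(sprintf("%d observations cannot identify %d free constants",
                 n, length(free)))
  L <- log(rate / ref_rate)
  if (identical(free, "d1")) {             # closed form: d1 only
    base <- (1 + (fixed$d4 %||% 0) * L)
    resid_target <- fracture_strain / base -
      (fixed$d2 %||% 0) * exp(-(fixed$d3 %||% 0) * triaxiality)
    d1 <- mean(resid_target)
    est <- list(d1 = d1, d2 = fixed$d2 %||% 0, d3 = fixed$d3 %||% 0,
                d4 = fixed$d4 %||% 0)
    pred <- (est$d1 + est$d2 * exp(-est$d3 * triaxiality)) * (1 + est$d4 * L)
    return(c(est, list(residual_norm = sqrt(sum((fracture_strain - pred)^2)))))
  }
  start_all <- list(d1 = max(min(fracture_strain), 1e-4),
                    d2 = max(diff(range(fracture_strain)), 1e-4),
                    d3 = 1, d4 = 0)
  lower_all <- c(d1 = 0, d2 = 0, d3 = -50, d4 = -10)
  upper_all <- c(d1 = Inf, d2 = Inf, d3 = 50, d4 = 10)
  df <- data.frame(ef = fracture_strain, tri = triaxiality, L = L)
  form <- ef ~ (d1 + d2 * exp(-d3 * tri)) * (1 + d4 * L)
  # constants held fixed are resolved from the formula environment
  environment(form) <- list2env(fixed, parent = environment())
  fit <- minpack.lm::nlsLM(
    form, data = df, start = start_all[free],
    lower = lower_all[free], upper = upper_all[free],
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- as.list(coef(fit))
  est <- modifyList(modifyList(list(d1 = 0, d2 = 0, d3 = 0, d4 = 0), fixed), cf)
  pred <- (est$d1 + est$d2 * exp(-est$d3 * triaxiality)) * (1 + est$d4 * L)
  c(est[c("d1", "d2", "d3", "d4")],
    list(residual_norm = sqrt(sum((fracture_strain - pred)^2))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
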