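# Published gel properties for the three agarose:xanthan ratios
# (1:0, 0.75:0.25, 0.5:0.5): Young's modulus, Poisson's ratio, Johnson-Cook
# hardening constants, and the printed shear moduli used as a consistency
# check. Pressures in Pa.
gel_table <- function() {
  data.frame(
    ratio = c("1:0", "0.75:0.25", "0.5:0.5"),
    E = c(37891e3, 23619e3, 8388e3),
    poisson = 0.48,
    A = c(2969e3, 2183e3, 683e3),
    B = c(2054e3, 2487e3, 2339e3),
    n = c(0.00067, 0.0729, 0.081),
    C = 0.01,
    ref_rate = 1,
    shear_kPa = c(12801, 7979, 2834)
  )
}

# measured ring-tensile failure points for the same three gels
ring_failure_table <- function() {
  data.frame(
    ratio = c("1:0", "0.75:0.25", "0.5:0.5"),
    stress = c(2.65e6, 1.97e6, 1.82e6),
    strain = c(0.08, 0.09, 0.13)
  )
}

gel_material <- function(i, ...) {
  tab <- gel_table()
  jc_material(E = tab$E[i], poisson = tab$poisson[i], yield_A = tab$A[i],
              hardening_B = tab$B[i], exponent_n = tab$n[i],
              rate_C = tab$C[i], ref_rate = tab$ref_rate[i], ...)
}
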