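# Independent oracles used across the suite. These deliberately re-derive the
# physics through different algorithms than the package (Parratt recursion
# instead of transfer matrices; dense quadrature instead of fixed-order).

# Parratt recursive reflectance. slds in user units (1e-6 A^-2), thicknesses
# and roughnesses in Angstrom; slds ordered superphase, layers..., substrate;
# roughness[i] is the interface between medium i and i+1.
parratt_reflectivity <- function(q, slds, thicknesses, roughnesses) {
  slds <- slds * 1e-6
  nmed <- length(slds)
  sapply(q, function(qi) {
    k <- sqrt(as.complex((qi / 2)^2 - 4 * pi * (slds - slds[1])))
    # start at the deepest interface and recurse upwards
    rtot <- 0i
    for (i in seq(nmed - 1, 1)) {
      rf <- (k[i] - k[i + 1]) / (k[i] + k[i + 1]) *
        exp(-2 * k[i] * k[i + 1] * roughnesses[i]^2)
      if (i == nmed - 1) {
        rtot <- rf
      } else {
        phase <- exp(2i * k[i + 1] * thicknesses[i])
        rtot <- (rf + rtot * phase) / (1 + rf * rtot * phase)
      }
    }
    Mod(rtot)^2
  })
}

# Effective (hydration-mixed, spin-resolved) user-unit SLDs of a sample,
# recomputed independently of the package internals.
effective_slds <- function(sample, spin = "unpolarized") {
  sgn <- switch(spin, unpolarized = 0, up = 1, down = -1)
  lay <- vapply(sample$layers, function(l) {
    (1 - l$hydration) * (l$sld + sgn * l$magnetic_sld) +
      l$hydration * sample$solvent_sld
  }, numeric(1))
  c(sample$superphase_sld, lay, sample$substrate_sld)
}

sample_geometry <- function(sample) {
  list(thicknesses = vapply(sample$layers, `[[`, numeric(1), "thickness"),
       roughnesses = c(vapply(sample$layers, `[[`, numeric(1), "roughness"),
                       sample$substrate_roughness))
}

# Dense brute-force Gaussian smearing oracle: trapezoidal quadrature of the
# Gaussian kernel over +/- width sigma with n points.
dense_smear <- function(model_r, q, dq_over_q, n = 301, width = 3.5) {
  sigma <- dq_over_q / (2 * sqrt(2 * log(2)))
  x <- seq(-width, width, length.out = n)
  w <- dnorm(x)
  w <- w / sum(w)
  sapply(q, function(qi) sum(model_r(qi * (1 + sigma * x)) * w))
}

# Random <=5-layer stack with random roughness/hydration for property tests.
random_stack <- function(n_layers = sample(0:5, 1)) {
  layers <- lapply(seq_len(n_layers), function(i) {
    slab_layer(runif(1, 5, 300), runif(1, -0.5, 9),
               roughness = runif(1, 0, 6), hydration = runif(1, 0, 0.6))
  })
  slab_sample(layers,
              superphase_sld = runif(1, 0, 3),
              substrate_sld = runif(1, -0.56, 9),
              solvent_sld = runif(1, -0.56, 6.36),
              substrate_roughness = runif(1, 0, 6),
              scale = 1, background = 0, contrast_is_substrate = FALSE)
}

# Single-layer toy on silicon backed by silicon-matched water.
toy_one_layer <- function(thickness = 80, sld = 4, background = 1e-6) {
  slab_sample(list(slab_layer(thickness, sld, roughness = 3)),
              superphase_sld = 0, substrate_sld = 2.07, solvent_sld = 2.07,
              background = background, contrast_is_substrate = FALSE)
}

# Small shared flux profile for speed.
test_flux <- function(...) synthesize_flux(n_bins = 100, ...)
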