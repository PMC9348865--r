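#' Neutron momentum transfer
#'
#' Converts a neutron wavelength and a grazing measurement angle into the
#' specular momentum transfer Q = 4 pi sin(theta) / lambda.
#'
#' @param wavelength Neutron wavelength(s) in Angstrom. Must be > 0.
#' @param angle Grazing angle(s) of incidence in degrees, in `[0, 90)`.
#' @return Momentum transfer Q in inverse Angstrom (recycled to the common
#'   length of the inputs).
#' @examples
#' momentum_transfer(4 * pi, 30)  # 0.5
#' @export
momentum_transfer <- function(wavelength, angle) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("'wavelength' must be positive and finite", call. = FALSE)
  }
  if (any(angle < 0) || any(angle >= 90)) {
    stop("'angle' must lie in [0, 90) degrees", call. = FALSE)
  }
  4 * pi * sin(angle * pi / 180) / wavelength
}

#' Define a single slab layer
#'
#' A layer is a homogeneous slab characterized by its thickness, real (and
#' optionally imaginary and magnetic) scattering length density, interfacial
#' roughness with the medium above it, and solvent hydration.
#'
#' SLDs are given in the conventional units of 1e-6 inverse square Angstrom
#' throughout the user-facing interface; the conversion to absolute units
#' happens once inside the reflectivity kernel. Hydration is a solvent volume
#' fraction: the effective SLD is `(1 - hydration) * sld + hydration *
#' solvent_sld`, with the solvent SLD taken from the enclosing
#' [slab_sample()]. For polarized (non-spin-flip) channels the spin-up and
#' spin-down states see `sld + magnetic_sld` and `sld - magnetic_sld`
#' respectively, before hydration mixing.
#'
#' @param thickness Layer thickness in Angstrom, >= 0.
#' @param sld Real nuclear SLD (1e-6 A^-2).
#' @param roughness Gaussian (Nevot-Croce) roughness with the interface to the
#'   medium above, in Angstrom, >= 0.
#' @param hydration Solvent volume fraction in `[0, 1]`.
#' @param magnetic_sld Magnetic SLD offset (1e-6 A^-2), default 0.
#' @param isld Imaginary (absorption) SLD (1e-6 A^-2), default 0.
#' @param name Optional layer name.
#' @return An object of class `slab_layer`.
#' @export
slab_layer <- function(thickness, sld, roughness = 0, hydration = 0,
                       magnetic_sld = 0, isld = 0, name = NULL) {
  if (!is.finite(thickness) || thickness < 0) {
    stop("layer thickness must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(roughness) || roughness < 0) {
    stop("layer roughness must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(hydration) || hydration < 0 || hydration > 1) {
    stop("layer hydration must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(thickness = thickness, sld = sld, roughness = roughness,
         hydration = hydration, magnetic_sld = magnetic_sld, isld = isld,
         name = name),
    class = "slab_layer")
}

#' Define a layered sample
#'
#' A sample is an ordered stack of [slab_layer()]s between a semi-infinite
#' superphase (the medium the beam arrives through) and a semi-infinite
#' substrate, together with the experimental scale factor, a constant additive
#' background, and the solvent SLD used for hydration mixing.
#'
#' For solid-liquid cells the beam typically enters through the substrate
#' block (e.g. silicon), so the "superphase" is silicon and the backing medium
#' is the bulk solvent; setting `contrast_is_substrate = TRUE` (the default)
#' makes [set_contrast()] update both `solvent_sld` and `substrate_sld`.
#'
#' @param layers List of [slab_layer()] objects, ordered superphase to
#'   substrate. May be empty (a bare interface).
#' @param superphase_sld SLD of the incident medium (1e-6 A^-2).
#' @param substrate_sld SLD of the backing medium (1e-6 A^-2).
#' @param solvent_sld Solvent SLD used for hydration mixing (1e-6 A^-2).
#' @param substrate_roughness Roughness of the final layer/substrate
#'   interface in Angstrom.
#' @param scale Experimental scale factor, > 0.
#' @param background Constant background reflectivity, >= 0. Added after
#'   scaling and smearing: `R_tot = scale * R_smeared + background`.
#' @param contrast_is_substrate Should [set_contrast()] also replace the
#'   substrate SLD? Default `TRUE` (liquid-backed geometries).
#' @param name Optional sample name.
#' @return An object of class `slab_sample`.
#' @seealso [reflectivity()], [set_contrast()]
#' @export
slab_sample <- function(layers = list(), superphase_sld = 0, substrate_sld,
                        solvent_sld = substrate_sld, substrate_roughness = 0,
                        scale = 1, background = 0,
                        contrast_is_substrate = TRUE, name = NULL) {
  if (inherits(layers, "slab_layer")) layers <- list(layers)
  if (!all(vapply(layers, inherits, logical(1), "slab_layer"))) {
    stop("'layers' must be a list of slab_layer objects", call. = FALSE)
  }
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (!is.finite(background) || background < 0) {
    stop("background must be >= 0", call. = FALSE)
  }
  structure(
    list(layers = layers, superphase_sld = superphase_sld,
         substrate_sld = substrate_sld, solvent_sld = solvent_sld,
         substrate_roughness = substrate_roughness, scale = scale,
         background = background,
         contrast_is_substrate = isTRUE(contrast_is_substrate), name = name),
    class = "slab_sample")
}

#' @export
print.slab_sample <- function(x, ...) {
  cat("<slab_sample>", if (!is.null(x$name)) x$name else "", "\n")
  cat(sprintf("  superphase SLD %.3f | %d layer(s) | substrate SLD %.3f (1e-6 A^-2)\n",
              x$superphase_sld, length(x$layers), x$substrate_sld))
  for (l in x$layers) {
    cat(sprintf("  - %-12s t=%7.2f A  sld=%7.3f  rough=%5.2f  hydr=%.2f%s\n",
                if (is.null(l$name)) "layer" else l$name, l$thickness, l$sld,
                l$roughness, l$hydration,
                if (l$magnetic_sld != 0) sprintf("  msld=%.4f", l$magnetic_sld) else ""))
  }
  cat(sprintf("  solvent SLD %.3f | scale %.3g | background %.3g\n",
              x$solvent_sld, x$scale, x$background))
  invisible(x)
}

#' Set the solvent contrast of a sample
#'
#' Replaces the solvent SLD used for hydration mixing (and, for liquid-backed
#' samples, the substrate SLD) with a new bulk water contrast.
#'
#' @param sample A [slab_sample()].
#' @param sld New solvent SLD (1e-6 A^-2).
#' @return The modified sample.
#' @export
set_contrast <- function(sample, sld) {
  stopifnot(inherits(sample, "slab_sample"))
  sample$solvent_sld <- sld
  if (sample$contrast_is_substrate) sample$substrate_sld <- sld
  sample
}

# Effective per-medium complex SLDs (absolute A^-2) for one spin channel.
# Returns list(sld = complex vector superphase..substrate, thickness, roughness)
.sample_profile <- function(sample, spin = "unpolarized") {
  spin <- match.arg(spin, c("unpolarized", "up", "down"))
  sgn <- switch(spin, unpolarized = 0, up = 1, down = -1)
  nl <- length(sample$layers)
  sld <- complex(real = numeric(nl + 2), imaginary = numeric(nl + 2))
  sld[1] <- complex(real = sample$superphase_sld, imaginary = 0)
  if (nl > 0) {
    for (j in seq_len(nl)) {
      l <- sample$layers[[j]]
      if (l$thickness < 0) stop("negative layer thickness", call. = FALSE)
      nuc <- l$sld + sgn * l$magnetic_sld
      eff <- (1 - l$hydration) * nuc + l$hydration * sample$solvent_sld
      sld[j + 1] <- complex(real = eff, imaginary = (1 - l$hydration) * l$isld)
    }
  }
  sld[nl + 2] <- complex(real = sample$substrate_sld, imaginary = 0)
  list(sld = sld * 1e-6,
       thickness = vapply(sample$layers, `[[`, numeric(1), "thickness"),
       roughness = c(vapply(sample$layers, `[[`, numeric(1), "roughness"),
                     sample$substrate_roughness))
}

# Abeles transfer-matrix reflectance, vectorized over Q.
# sld: complex absolute A^-2 per medium; thickness: per internal layer;
# roughness: per interface (between medium i and i+1), Nevot-Croce factors.
.abeles <- function(q, sld, thickness, roughness) {
  nq <- length(q)
  nmed <- length(sld)
  k0sq <- (q / 2)^2
  kz <- matrix(0i, nq, nmed)
  for (m in seq_len(nmed)) {
    kz[, m] <- sqrt(as.complex(k0sq - 4 * pi * (sld[m] - sld[1])))
  }
  m11 <- rep(1 + 0i, nq); m12 <- rep(0i, nq)
  m21 <- rep(0i, nq);     m22 <- rep(1 + 0i, nq)
  for (i in seq_len(nmed - 1)) {
    ka <- kz[, i]; kb <- kz[, i + 1]
    r <- (ka - kb) / (ka + kb) * exp(-2 * ka * kb * roughness[i]^2)
    if (i == 1) {
      e <- rep(1 + 0i, nq)
    } else {
      e <- exp(1i * ka * thickness[i - 1])
    }
    a11 <- e; a12 <- r * e; a21 <- r / e; a22 <- 1 / e
    n11 <- m11 * a11 + m12 * a21
    n12 <- m11 * a12 + m12 * a22
    n21 <- m21 * a11 + m22 * a21
    n22 <- m21 * a12 + m22 * a22
    m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
  }
  Mod(m21 / m11)^2
}

#' Slab-model specular reflectivity
#'
#' Computes the specular reflectivity of a layered sample with the Abeles
#' transfer-matrix formalism, exact for stratified homogeneous slabs, with
#' Nevot-Croce Gaussian roughness factors at every interface. The returned
#' curve is `scale * R_bare + background` (no resolution smearing; see
#' [reflectivity_smeared()]).
#'
#' @param sample A [slab_sample()].
#' @param q Momentum-transfer values (A^-1), all > 0.
#' @param spin Spin channel: `"unpolarized"` (nuclear SLD only), `"up"`
#'   (nuclear + magnetic) or `"down"` (nuclear - magnetic).
#' @return Reflectivity values in `(0, scale + background]`.
#' @examples
#' si_d2o <- slab_sample(substrate_sld = 6.36, superphase_sld = 2.07,
#'                       contrast_is_substrate = FALSE)
#' reflectivity(si_d2o, c(0.01, 0.05, 0.2))
#' @export
reflectivity <- function(sample, q, spin = "unpolarized") {
  stopifnot(inherits(sample, "slab_sample"))
  if (length(q) == 0) stop("'q' must be non-empty", call. = FALSE)
  if (any(q <= 0)) stop("'q' values must be > 0", call. = FALSE)
  p <- .sample_profile(sample, spin)
  sample$scale * .abeles(q, p$sld, p$thickness, p$roughness) + sample$background
}

# Fixed-order Gauss-Legendre nodes/weights for Gaussian smearing, cached.
.smear_quad <- local({
  cache <- NULL
  function(n = 17, width = 3.5) {
    key <- sprintf("%d_%g", n, width)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n, -width, width)
      w <- gl$w * stats::dnorm(gl$x)
      cache[[key]] <<- list(x = gl$x, w = w / sum(w))
    }
    cache[[key]]
  }
})

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves a model reflectivity function with a Gaussian resolution kernel
#' of constant fractional width, interpreting `dq_over_q` as the full width at
#' half maximum of dQ/Q (the convention of standard reflectivity analysis
#' packages). The convolution uses fixed-order Gauss-Legendre quadrature (17
#' points over +/- 3.5 sigma) with weights normalized to sum to one, so a
#' constant curve is conserved exactly and `dq_over_q = 0` returns the
#' unsmeared model.
#'
#' @param model_r Function mapping a Q vector to reflectivity.
#' @param q Q values at which the smeared curve is wanted (A^-1).
#' @param dq_over_q Fractional resolution FWHM in `[0, 1)`; default 0.02
#'   (constant 2 percent dQ/Q).
#' @param n_quad Number of quadrature points.
#' @return Smeared reflectivity at `q`.
#' @export
smear <- function(model_r, q, dq_over_q = 0.02, n_quad = 17) {
  if (dq_over_q < 0 || dq_over_q >= 1) {
    stop("'dq_over_q' must lie in [0, 1)", call. = FALSE)
  }
  if (dq_over_q == 0) return(model_r(q))
  quad <- .smear_quad(n_quad)
  sigma <- dq_over_q / (2 * sqrt(2 * log(2)))  # FWHM -> sigma, fractional
  nq <- length(q)
  qq <- as.vector(outer(q, 1 + sigma * quad$x))  # column j: q * (1 + s x_j)
  rr <- matrix(model_r(qq), nrow = nq)
  as.vector(rr %*% quad$w)
}

#' Smeared total reflectivity of a sample
#'
#' Convenience wrapper combining the bare Abeles curve, Gaussian resolution
#' smearing and the scale/background model: the background is added to the
#' smeared, scaled reflectivity, matching data simulated without background
#' subtraction.
#'
#' @inheritParams reflectivity
#' @inheritParams smear
#' @return Total reflectivity `scale * smear(R_bare) + background` at `q`.
#' @export
reflectivity_smeared <- function(sample, q, dq_over_q = 0.02,
                                 spin = "unpolarized") {
  stopifnot(inherits(sample, "slab_sample"))
  if (length(q) == 0) stop("'q' must be non-empty", call. = FALSE)
  if (any(q <= 0)) stop("'q' values must be > 0", call. = FALSE)
  p <- .sample_profile(sample, spin)
  bare <- function(qv) .abeles(qv, p$sld, p$thickness, p$roughness)
  sample$scale * smear(bare, q, dq_over_q) + sample$background
}

#' Critical momentum transfer of an interface
#'
#' Total external reflection occurs below `Qc = 4 sqrt(pi * delta_rho)` for a
#' substrate of higher SLD than the incident medium.
#'
#' @param superphase_sld,substrate_sld SLDs in 1e-6 A^-2.
#' @return Qc in A^-1 (0 if the contrast is non-positive).
#' @export
critical_edge <- function(superphase_sld, substrate_sld) {
  d <- (substrate_sld - superphase_sld) * 1e-6
  if (d <= 0) return(0)
  4 * sqrt(pi * d)
}
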