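#' Incident flux profile of a time-of-flight instrument
#'
#' A flux profile records the incident neutron rate in each wavelength bin at
#' a reference measurement angle `theta_ref` with the (constant) reference
#' footprint absorbed into its normalization. Both apertures of the instrument
#' are assumed to scale linearly with measurement angle to keep a constant
#' footprint on the sample, which scales the incident flux by
#' `(angle / theta_ref)^2`; see [angle_scaled_flux()].
#'
#' @param wavelength Bin-centre wavelengths in Angstrom, strictly increasing.
#' @param flux Incident rate per bin (neutrons per second), >= 0, same length
#'   as `wavelength`.
#' @param theta_ref Reference angle in degrees at which the rates were
#'   recorded.
#' @param polarized Flag: is this a polarized-beam profile?
#' @return An object of class `flux_profile` with derived bin `edges`.
#' @export
flux_profile <- function(wavelength, flux, theta_ref = 0.3, polarized = FALSE) {
  if (length(wavelength) != length(flux)) {
    stop("'wavelength' and 'flux' must have the same length", call. = FALSE)
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("'wavelength' must be strictly increasing", call. = FALSE)
  }
  if (any(flux < 0)) stop("'flux' must be non-negative", call. = FALSE)
  n <- length(wavelength)
  if (n < 2) stop("a flux profile needs at least two bins", call. = FALSE)
  mid <- (wavelength[-1] + wavelength[-n]) / 2
  edges <- c(2 * wavelength[1] - mid[1], mid, 2 * wavelength[n] - mid[n - 1])
  structure(
    list(wavelength = wavelength, flux = flux, edges = edges,
         theta_ref = theta_ref, polarized = isTRUE(polarized)),
    class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat(sprintf("<flux_profile> %d bins over [%.3g, %.3g] A, %.4g n/s total at theta_ref=%.2f deg%s\n",
              length(x$flux), x$edges[1], x$edges[length(x$edges)],
              sum(x$flux), x$theta_ref,
              if (x$polarized) " (polarized)" else ""))
  invisible(x)
}

#' Synthesize a smooth time-of-flight flux profile
#'
#' Generates a Maxwellian-like moderator spectrum over a wavelength band, as a
#' stand-in for a measured instrument flux table. The spectral shape is
#' `lambda^-5 * exp(-(lambda_peak^2 * 5/2) / lambda^2)`, peaked at
#' `peak_wavelength`, binned and normalized so the bin rates integrate to
#' `total_rate`. Polarized profiles are multiplied by a smooth logistic
#' transmission below a cut-on wavelength, emulating the reduced low-wavelength
#' flux of polarizing systems.
#'
#' @param band Wavelength band `c(lo, hi)` in Angstrom; default `c(1, 14)`, a
#'   typical white-beam band.
#' @param total_rate Integrated incident rate at the reference angle
#'   (neutrons/s), > 0.
#' @param polarized Apply the polarizer transmission?
#' @param n_bins Number of uniform wavelength bins.
#' @param theta_ref Reference angle (degrees).
#' @param peak_wavelength Spectrum peak in Angstrom.
#' @param cuton_wavelength,cuton_width Logistic polarizer transmission
#'   midpoint and width in Angstrom.
#' @return A [flux_profile()].
#' @export
synthesize_flux <- function(band = c(1, 14), total_rate = 5e5,
                            polarized = FALSE, n_bins = 200, theta_ref = 0.3,
                            peak_wavelength = 2.5, cuton_wavelength = 2.5,
                            cuton_width = 0.5) {
  if (band[1] <= 0 || band[2] <= band[1]) {
    stop("'band' must satisfy 0 < lo < hi", call. = FALSE)
  }
  if (total_rate <= 0) stop("'total_rate' must be > 0", call. = FALSE)
  edges <- seq(band[1], band[2], length.out = n_bins + 1)
  centre <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  a <- 5 * peak_wavelength^2 / 2
  shape <- centre^-5 * exp(-a / centre^2)
  if (polarized) {
    shape <- shape / (1 + exp(-(centre - cuton_wavelength) / cuton_width))
  }
  rate <- shape / sum(shape) * total_rate
  flux_profile(centre, rate, theta_ref = theta_ref, polarized = polarized)
}

#' Scale a flux profile to a measurement angle
#'
#' With both collimating apertures opened linearly with angle to maintain a
#' constant sample footprint, the incident flux scales with the angle squared.
#'
#' @param profile A [flux_profile()].
#' @param angle Measurement angle in degrees, > 0.
#' @return Per-bin rates at `angle` (neutrons/s).
#' @export
angle_scaled_flux <- function(profile, angle) {
  stopifnot(inherits(profile, "flux_profile"))
  if (angle <= 0) stop("'angle' must be > 0", call. = FALSE)
  profile$flux * (angle / profile$theta_ref)^2
}

#' One cell of an experiment design
#'
#' A measurement condition is one (angle, counting time, solvent contrast,
#' spin channel) combination together with the number of Q points the
#' time-of-flight band is binned into.
#'
#' @param angle Measurement angle in degrees.
#' @param time Counting time in seconds, >= 0.
#' @param n_points Number of Q bins across the wavelength band, >= 1;
#'   default 100 points per angle.
#' @param contrast_sld Solvent contrast SLD (1e-6 A^-2) applied to the sample
#'   via [set_contrast()], or `NA` to use the sample as given.
#' @param spin Spin channel, as in [reflectivity()].
#' @return An object of class `measurement_condition`.
#' @export
measurement_condition <- function(angle, time, n_points = 100,
                                  contrast_sld = NA_real_,
                                  spin = "unpolarized") {
  if (time < 0) stop("'time' must be >= 0", call. = FALSE)
  if (n_points < 1) stop("'n_points' must be >= 1", call. = FALSE)
  spin <- match.arg(spin, c("unpolarized", "up", "down"))
  structure(
    list(angle = angle, time = time, n_points = as.integer(n_points),
         contrast_sld = contrast_sld, spin = spin),
    class = "measurement_condition")
}

#' Q bin edges for one measurement condition
#'
#' At fixed angle every wavelength maps to a single momentum transfer, so a
#' wavelength band maps to the Q interval
#' `[4 pi sin(theta) / lambda_hi, 4 pi sin(theta) / lambda_lo]`. The interval
#' is divided into `n_points` logarithmically spaced bins (the conventional
#' spacing for time-of-flight reflectometry).
#'
#' @param condition A [measurement_condition()].
#' @param band Wavelength band `c(lo, hi)` in Angstrom.
#' @return Strictly increasing vector of `n_points + 1` Q bin edges (A^-1).
#' @export
q_binning <- function(condition, band) {
  stopifnot(inherits(condition, "measurement_condition"))
  if (band[1] <= 0 || band[2] <= band[1]) {
    stop("invalid wavelength band", call. = FALSE)
  }
  qlo <- momentum_transfer(band[2], condition$angle)
  qhi <- momentum_transfer(band[1], condition$angle)
  exp(seq(log(qlo), log(qhi), length.out = condition$n_points + 1))
}

# Integrated incident rate (n/s at theta_ref) over wavelength intervals
# [a_i, b_i], treating the profile as piecewise-constant bin densities.
# Vectorized over intervals: returns one rate per interval.
.band_rates <- function(profile, a, b) {
  e <- profile$edges
  elo <- e[-length(e)]; ehi <- e[-1]
  dens <- profile$flux / (ehi - elo)
  # overlap of interval i with profile bin j
  lo <- outer(a, elo, pmax)
  hi <- outer(b, ehi, pmin)
  as.vector(pmax(hi - lo, 0) %*% dens)
}

#' Incident counts per Q bin
#'
#' Maps each Q bin of a condition back to its wavelength sub-interval and
#' integrates the (angle-scaled) flux profile over it, multiplied by the
#' counting time.
#'
#' @param profile A [flux_profile()].
#' @param condition A [measurement_condition()].
#' @param band Wavelength band `c(lo, hi)` in Angstrom; must lie within the
#'   support of the profile.
#' @return List with Q bin `edges`, bin-centre `q` (geometric means) and
#'   `incident` counts per bin.
#' @export
incident_counts <- function(profile, condition, band = NULL) {
  stopifnot(inherits(profile, "flux_profile"))
  if (is.null(band)) {
    band <- c(profile$edges[1], profile$edges[length(profile$edges)])
  }
  support <- c(profile$edges[1], profile$edges[length(profile$edges)])
  if (band[1] < support[1] - 1e-9 || band[2] > support[2] + 1e-9) {
    stop("wavelength band outside flux profile support", call. = FALSE)
  }
  edges <- q_binning(condition, band)
  k <- 4 * pi * sin(condition$angle * pi / 180)
  lam_hi <- k / edges[-length(edges)]   # low-Q edge -> long wavelength
  lam_lo <- k / edges[-1]
  rate <- .band_rates(profile, lam_lo, lam_hi)
  scale <- (condition$angle / profile$theta_ref)^2
  list(edges = edges,
       q = sqrt(edges[-length(edges)] * edges[-1]),
       incident = rate * scale * condition$time)
}

#' Read / write a two-column flux table
#'
#' Plain whitespace-separated ASCII with `#` comment lines: column 1 the
#' wavelength bin centre (Angstrom), column 2 the incident rate in that bin
#' (neutrons/s) at the reference angle. Values round-trip bit-exactly through
#' 17 significant digits.
#'
#' @param path File path.
#' @param profile A [flux_profile()].
#' @param theta_ref,polarized Metadata applied on read (also parsed from the
#'   header if the file was written by [write_flux_table()]).
#' @return `read_flux_table()` returns a [flux_profile()];
#'   `write_flux_table()` returns `path` invisibly.
#' @export
read_flux_table <- function(path, theta_ref = 0.3, polarized = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("theta_ref\\s*=\\s*([0-9.eE+-]+)", hdr))
  for (g in m) if (length(g) == 2) theta_ref <- as.numeric(g[2])
  if (any(grepl("polarized\\s*=\\s*TRUE", hdr))) polarized <- TRUE
  dat <- utils::read.table(text = lines, comment.char = "#",
                           col.names = c("wavelength", "flux"))
  flux_profile(dat$wavelength, dat$flux, theta_ref = theta_ref,
               polarized = polarized)
}

#' @rdname read_flux_table
#' @export
write_flux_table <- function(profile, path) {
  stopifnot(inherits(profile, "flux_profile"))
  hdr <- c("# incident flux table: wavelength bin centre (A), rate (n/s)",
           sprintf("# theta_ref = %.17g", profile$theta_ref),
           sprintf("# polarized = %s", profile$polarized))
  body <- sprintf("%.17g %.17g", profile$wavelength, profile$flux)
  writeLines(c(hdr, body), path)
  invisible(path)
}
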