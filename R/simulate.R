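#' Expected neutron counts per Q bin
#'
#' Combines a sample model, a measurement condition and an instrument flux
#' profile into the expected (Poisson-mean) neutron counts per Q bin:
#' `lambda_k = R_tot(Q_k) * incident_k`, where `incident_k` integrates the
#' angle-scaled flux over the wavelength sub-interval of bin k times the
#' counting time, and `R_tot` is the smeared, scaled reflectivity plus
#' background. Expected counts are exactly linear in counting time.
#'
#' @param sample A [slab_sample()] (the condition's `contrast_sld`, if not
#'   `NA`, is applied with [set_contrast()] first).
#' @param condition A [measurement_condition()].
#' @param profile A [flux_profile()].
#' @param band Wavelength band in Angstrom (default: full profile support).
#' @param dq_over_q Fractional resolution FWHM; default 0.02.
#' @return An object of class `counts_model`: list with `q`, `dq` (resolution
#'   FWHM per point), `incident`, `expected`, and the condition.
#' @export
expected_counts <- function(sample, condition, profile, band = NULL,
                            dq_over_q = 0.02) {
  stopifnot(inherits(sample, "slab_sample"),
            inherits(condition, "measurement_condition"))
  if (!is.na(condition$contrast_sld)) {
    sample <- set_contrast(sample, condition$contrast_sld)
  }
  inc <- incident_counts(profile, condition, band)
  r_tot <- reflectivity_smeared(sample, inc$q, dq_over_q = dq_over_q,
                                spin = condition$spin)
  structure(
    list(q = inc$q, dq = dq_over_q * inc$q, incident = inc$incident,
         expected = r_tot * inc$incident, r_model = r_tot,
         condition = condition),
    class = "counts_model")
}

#' Poisson realization of a simulated measurement
#'
#' Draws observed counts `n_k ~ Poisson(lambda_k)` per Q bin and converts
#' them to a reflectivity dataset with `r = n / incident` and
#' `dr = sqrt(n) / incident`. Zero-count bins are retained, with their
#' uncertainty set by a single-count floor (`dr = 1 / incident`) so the
#' points remain usable in log-scale fitting.
#'
#' @param counts_model A `counts_model` from [expected_counts()].
#' @param seed Integer random seed; required, so simulated datasets are
#'   reproducible by construction.
#' @return An object of class `refl_dataset`: data frame columns `q`, `r`,
#'   `dr`, `dq` plus a `metadata` attribute (angle, time, contrast, spin,
#'   seed).
#' @export
realize <- function(counts_model, seed) {
  stopifnot(inherits(counts_model, "counts_model"))
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  set.seed(seed)
  n <- stats::rpois(length(counts_model$expected), counts_model$expected)
  inc <- counts_model$incident
  ok <- inc > 0
  r <- ifelse(ok, n / inc, 0)
  dr <- ifelse(ok, pmax(sqrt(n), 1) / inc, Inf)
  refl_dataset(counts_model$q, r, dr, dq = counts_model$dq,
               metadata = list(angle = counts_model$condition$angle,
                               time = counts_model$condition$time,
                               contrast_sld = counts_model$condition$contrast_sld,
                               spin = counts_model$condition$spin,
                               seed = seed),
               counts = n)
}

#' Reflectivity dataset container
#'
#' @param q,r,dr,dq Numeric vectors of equal length (momentum transfer,
#'   reflectivity, its uncertainty, resolution FWHM; `dq` may be `NULL`).
#' @param metadata Named list of acquisition metadata.
#' @param counts Optional raw counts per point.
#' @return An object of classes `refl_dataset` and `data.frame`.
#' @export
refl_dataset <- function(q, r, dr, dq = NULL, metadata = list(),
                         counts = NULL) {
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  d <- data.frame(q = q, r = r, dr = dr)
  if (!is.null(dq)) d$dq <- dq
  attr(d, "metadata") <- metadata
  if (!is.null(counts)) attr(d, "counts") <- counts
  class(d) <- c("refl_dataset", "data.frame")
  d
}

#' Write / read a reflectivity dataset as 3/4-column ASCII
#'
#' The format is whitespace-separated `q r dr [dq]` with `#`-prefixed header
#' lines carrying metadata as `# key: value`. Values are written with 17
#' significant digits, so a write/read round trip is lossless well beyond the
#' 12 significant digits contract.
#'
#' @param dataset A [refl_dataset()].
#' @param path File path.
#' @return `read_refl_dat()` returns a [refl_dataset()] (with `dq` absent for
#'   3-column files); `write_refl_dat()` returns `path` invisibly.
#' @export
write_refl_dat <- function(dataset, path) {
  stopifnot(inherits(dataset, "refl_dataset"))
  md <- attr(dataset, "metadata")
  hdr <- c("# reflectivity dataset: q (1/A), r, dr" ,
           if (!is.null(dataset$dq)) "# column 4: dq (FWHM, 1/A)")
  for (k in names(md)) {
    v <- md[[k]]
    if (is.null(v) || length(v) != 1) next
    hdr <- c(hdr, if (is.numeric(v)) sprintf("# %s: %.17g", k, v)
             else sprintf("# %s: %s", k, as.character(v)))
  }
  cols <- if (is.null(dataset$dq)) {
    sprintf("%.17g %.17g %.17g", dataset$q, dataset$r, dataset$dr)
  } else {
    sprintf("%.17g %.17g %.17g %.17g", dataset$q, dataset$r, dataset$dr,
            dataset$dq)
  }
  writeLines(c(hdr, cols), path)
  invisible(path)
}

#' @rdname write_refl_dat
#' @export
read_refl_dat <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) < 3 || length(v) > 4 || any(is.na(v))) {
      stop(sprintf("malformed data line %d in '%s'",
                   i + length(hdr), path), call. = FALSE)
    }
    v
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1) {
    stop(sprintf("inconsistent column count in '%s'", path), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  md <- list()
  keyed <- regmatches(hdr, regexec("^\\s*#\\s*([A-Za-z_]+):\\s*(\\S+)\\s*$", hdr))
  for (g in keyed) {
    if (length(g) != 3) next
    num <- suppressWarnings(as.numeric(g[3]))
    md[[g[2]]] <- if (is.na(num) && !identical(g[3], "NA")) g[3] else num
  }
  refl_dataset(m[, 1], m[, 2], m[, 3],
               dq = if (ncols == 4) m[, 4] else NULL, metadata = md)
}

#' Split a time budget across measurement conditions
#'
#' Renormalizes non-negative fractions onto the probability simplex and
#' multiplies by the total budget, so the returned times sum to the budget
#' exactly.
#'
#' @param fractions Non-negative weights, not all zero.
#' @param total_time Total counting-time budget (seconds).
#' @return Per-condition times summing to `total_time`.
#' @export
time_budget_split <- function(fractions, total_time) {
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  s <- sum(fractions)
  if (s <= 0) stop("at least one fraction must be positive", call. = FALSE)
  fractions / s * total_time
}

#' Simulate a multi-condition experiment
#'
#' Convenience wrapper producing one realized dataset per condition.
#' Multi-angle experiments stay as lists of per-condition datasets (no
#' stitching or rebinning); downstream information measures sum over them.
#'
#' @param sample A [slab_sample()].
#' @param conditions List of [measurement_condition()]s.
#' @param profile A [flux_profile()].
#' @param seed Integer seed; condition i uses `seed + i - 1`.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @return List of [refl_dataset()]s.
#' @export
simulate_experiment <- function(sample, conditions, profile, seed,
                                band = NULL, dq_over_q = 0.02) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  lapply(seq_along(conditions), function(i) {
    cm <- expected_counts(sample, conditions[[i]], profile, band, dq_over_q)
    realize(cm, seed + i - 1)
  })
}
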