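#' Gaussian log-likelihood of a reflectivity dataset under a model
#'
#' `-1/2 * sum_i ((r_i - R_model(q_i)) / dr_i)^2`, with the model curve
#' computed at the dataset's Q points via [reflectivity_smeared()]. The
#' additive normalization constant is omitted: it cancels in every likelihood
#' ratio the package uses.
#'
#' @param dataset A [refl_dataset()]; all `dr` must be > 0.
#' @param sample A [slab_sample()] or [parametric_model()] (built at its
#'   current parameter values).
#' @param dq_over_q Fractional resolution FWHM; default 0.02.
#' @param spin Spin channel; default: the dataset's metadata, else
#'   unpolarized.
#' @return Scalar log-likelihood (maximal, 0, when the model reproduces the
#'   data exactly).
#' @export
log_likelihood <- function(dataset, sample, dq_over_q = 0.02, spin = NULL) {
  stopifnot(inherits(dataset, "refl_dataset"))
  if (inherits(sample, "parametric_model")) sample <- model_sample(sample)
  if (any(!is.finite(dataset$dr)) || any(dataset$dr <= 0)) {
    stop("all 'dr' must be positive and finite", call. = FALSE)
  }
  if (is.null(spin)) {
    md <- attr(dataset, "metadata")
    spin <- if (!is.null(md$spin)) md$spin else "unpolarized"
  }
  rm <- reflectivity_smeared(sample, dataset$q, dq_over_q = dq_over_q,
                             spin = spin)
  -0.5 * sum(((dataset$r - rm) / dataset$dr)^2)
}

#' Log likelihood ratio between two models on shared data
#'
#' @param dataset A [refl_dataset()] (or list of them; summed).
#' @param sample_a,sample_b Models to compare.
#' @inheritParams log_likelihood
#' @return `log L(a) - log L(b)`.
#' @export
log_likelihood_ratio <- function(dataset, sample_a, sample_b,
                                 dq_over_q = 0.02, spin = NULL) {
  if (inherits(dataset, "refl_dataset")) dataset <- list(dataset)
  sum(vapply(dataset, function(d) {
    log_likelihood(d, sample_a, dq_over_q, spin) -
      log_likelihood(d, sample_b, dq_over_q, spin)
  }, numeric(1)))
}

#' Model-discrimination scan versus counting time
#'
#' Simulates polarized data from the alternative model (e.g. the stack with
#' an induced magnetic moment) at a series of total counting times and
#' reports the mean and standard deviation over replicates of the log
#' likelihood ratio between the alternative and the null model, summed over
#' all angles and both non-spin-flip channels. Under data generated from the
#' alternative, the expected log ratio is non-negative and grows with
#' counting time, so the scan reads off the statistics needed to discriminate
#' the two models.
#'
#' @param model_alt,model_null [parametric_model()]s or [slab_sample()]s
#'   sharing the measurement geometry; data are simulated from `model_alt`.
#' @param times Total counting times per measured spin state, in seconds.
#' @param profile A [flux_profile()] (typically polarized).
#' @param angles Measurement angles (degrees).
#' @param angle_times Relative time weights per angle (renormalized; default
#'   the 30/60/120-minute polarized schedule ratio).
#' @param n_points Q points per angle.
#' @param n_reps Poisson replicates per time point.
#' @param seed Integer seed (required).
#' @param spins Spin channels measured.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @return An object of classes `likelihood_scan` and `data.frame` with
#'   columns `time`, `mean_log_ratio`, `sd_log_ratio`.
#' @export
likelihood_ratio_vs_time <- function(model_alt, model_null, times, profile,
                                     angles = c(0.5, 1.0, 2.0),
                                     angle_times = c(30, 60, 120),
                                     n_points = 100, n_reps = 50, seed,
                                     spins = c("up", "down"), band = NULL,
                                     dq_over_q = 0.02) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  if (any(times <= 0)) stop("'times' must be > 0", call. = FALSE)
  s_alt <- if (inherits(model_alt, "parametric_model")) {
    model_sample(model_alt)
  } else {
    model_alt
  }
  s_null <- if (inherits(model_null, "parametric_model")) {
    model_sample(model_null)
  } else {
    model_null
  }
  frac <- angle_times / sum(angle_times)
  # per-condition unit-time incident counts and model curves
  cells <- list()
  for (j in seq_along(angles)) {
    for (sp in spins) {
      cond <- measurement_condition(angles[j], frac[j], n_points = n_points,
                                    spin = sp)
      cm_alt <- expected_counts(s_alt, cond, profile, band, dq_over_q)
      cm_null <- expected_counts(s_null, cond, profile, band, dq_over_q)
      cells[[length(cells) + 1]] <-
        list(inc1 = cm_alt$incident, r_alt = cm_alt$r_model,
             r_null = cm_null$r_model)
    }
  }
  set.seed(seed)
  out <- data.frame(time = times, mean_log_ratio = NA_real_,
                    sd_log_ratio = NA_real_)
  for (ti in seq_along(times)) {
    ratios <- vapply(seq_len(n_reps), function(rep) {
      lr <- 0
      for (cell in cells) {
        inc <- cell$inc1 * times[ti]
        lam <- cell$r_alt * inc
        n <- stats::rpois(length(lam), lam)
        w <- pmax(n, 1)  # chi^2 weights from counting errors, one-count floor
        lr <- lr + 0.5 * sum((n - cell$r_null * inc)^2 / w) -
                   0.5 * sum((n - cell$r_alt * inc)^2 / w)
      }
      lr
    }, numeric(1))
    out$mean_log_ratio[ti] <- mean(ratios)
    out$sd_log_ratio[ti] <- stats::sd(ratios)
  }
  class(out) <- c("likelihood_scan", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Brute-force grid posterior over two parameters
#'
#' Evaluates the Gaussian likelihood of one or more datasets on a rectangular
#' parameter grid under flat priors, normalizes the posterior to sum to one,
#' and returns the marginal means and standard deviations. Used as an
#' independent ground truth against the Cramer-Rao bounds from the Fisher
#' information.
#'
#' @param datasets A [refl_dataset()] or list of them (independent; their
#'   log-likelihoods add).
#' @param model A two-parameter [parametric_model()].
#' @param grid_1,grid_2 Grid values for the first and second parameter.
#' @inheritParams log_likelihood
#' @return List with `grid_1`, `grid_2`, `posterior` (matrix, rows = grid_1,
#'   summing to 1), `mean` and `sd` (named by the model's parameters). A
#'   warning is raised when more than 1 percent of the posterior mass sits on
#'   the grid boundary.
#' @export
grid_posterior <- function(datasets, model, grid_1, grid_2,
                           dq_over_q = 0.02) {
  stopifnot(inherits(model, "parametric_model"))
  if (length(model$theta) != 2) {
    stop("grid_posterior requires exactly 2 free parameters", call. = FALSE)
  }
  if (inherits(datasets, "refl_dataset")) datasets <- list(datasets)
  pn <- names(model$theta)
  ll <- matrix(NA_real_, length(grid_1), length(grid_2))
  for (i in seq_along(grid_1)) {
    for (j in seq_along(grid_2)) {
      th <- stats::setNames(c(grid_1[i], grid_2[j]), pn)
      s <- model$build(th)
      ll[i, j] <- sum(vapply(datasets, log_likelihood, numeric(1),
                             sample = s, dq_over_q = dq_over_q))
    }
  }
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  edge <- sum(post[c(1, nrow(post)), ]) + sum(post[, c(1, ncol(post))]) -
    sum(post[c(1, nrow(post)), c(1, ncol(post))])
  if (edge > 0.01) {
    warning(sprintf("%.1f%% of posterior mass on the grid boundary",
                    100 * edge), call. = FALSE)
  }
  m1 <- rowSums(post); m2 <- colSums(post)
  mu1 <- sum(grid_1 * m1); mu2 <- sum(grid_2 * m2)
  sd1 <- sqrt(sum((grid_1 - mu1)^2 * m1))
  sd2 <- sqrt(sum((grid_2 - mu2)^2 * m2))
  list(grid_1 = grid_1, grid_2 = grid_2, posterior = post,
       mean = stats::setNames(c(mu1, mu2), pn),
       sd = stats::setNames(c(sd1, sd2), pn))
}
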