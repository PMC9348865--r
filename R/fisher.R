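#' Parametric sample model
#'
#' Binds a builder function to a named vector of varying parameter values,
#' giving the differentiable model surface that the Fisher information is
#' computed over. Built-in sample factories ([contrast_bilayer()],
#' [apm_monolayer()], [magnetic_stack()]) return objects of this class; plain
#' samples can be wrapped with [vary_parameters()].
#'
#' @param build Function mapping a full named parameter vector to a
#'   [slab_sample()].
#' @param theta Named numeric vector of current (varying) parameter values.
#' @param lower,upper Optional named bounds (native units).
#' @param importance Optional positive importance weights, one per parameter.
#'   When omitted, [fisher_matrix()] defaults to `abs(theta)` (equal
#'   importance per fractional change).
#' @param name Optional model name.
#' @return An object of class `parametric_model`.
#' @export
parametric_model <- function(build, theta, lower = NULL, upper = NULL,
                             importance = NULL, name = NULL) {
  stopifnot(is.function(build), is.numeric(theta))
  if (is.null(names(theta)) || any(!nzchar(names(theta)))) {
    stop("'theta' must be fully named", call. = FALSE)
  }
  structure(
    list(build = build, theta = theta, lower = lower, upper = upper,
         importance = importance, name = name),
    class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", if (!is.null(x$name)) x$name else "", "\n")
  print(x$theta)
  invisible(x)
}

#' Build the sample at a parameter vector
#'
#' @param model A [parametric_model()].
#' @param theta Parameter vector (defaults to the model's current values).
#' @return A [slab_sample()].
#' @export
model_sample <- function(model, theta = model$theta) {
  stopifnot(inherits(model, "parametric_model"))
  model$build(theta)
}

# Set one addressable field of a slab_sample. spec: "layerN.field" or a
# top-level sample field name.
.set_sample_field <- function(sample, spec, value) {
  m <- regmatches(spec, regexec("^layer([0-9]+)\\.([a-z_]+)$", spec))[[1]]
  if (length(m) == 3) {
    i <- as.integer(m[2])
    if (i < 1 || i > length(sample$layers)) {
      stop(sprintf("no layer %d in sample", i), call. = FALSE)
    }
    sample$layers[[i]][[m[3]]] <- value
  } else {
    if (!spec %in% names(sample)) {
      stop(sprintf("unknown sample field '%s'", spec), call. = FALSE)
    }
    sample[[spec]] <- value
  }
  sample
}

.get_sample_field <- function(sample, spec) {
  m <- regmatches(spec, regexec("^layer([0-9]+)\\.([a-z_]+)$", spec))[[1]]
  if (length(m) == 3) sample$layers[[as.integer(m[2])]][[m[3]]]
  else sample[[spec]]
}

#' Wrap a plain sample as a parametric model
#'
#' Declares which fields of a [slab_sample()] vary, addressed as
#' `"layer<i>.<field>"` (e.g. `"layer2.thickness"`) or a top-level field name
#' (`"background"`, `"scale"`, `"substrate_roughness"`, ...).
#'
#' @param sample A [slab_sample()].
#' @param vary Character vector of field specs, or a named character vector
#'   (names become parameter names).
#' @inheritParams parametric_model
#' @return A [parametric_model()].
#' @export
vary_parameters <- function(sample, vary, lower = NULL, upper = NULL,
                            importance = NULL) {
  stopifnot(inherits(sample, "slab_sample"))
  specs <- unname(vary)
  pnames <- if (!is.null(names(vary)) && all(nzchar(names(vary)))) {
    names(vary)
  } else {
    gsub("\\.", "_", specs)
  }
  theta <- vapply(specs, function(s) .get_sample_field(sample, s), numeric(1))
  names(theta) <- pnames
  build <- function(th) {
    s <- sample
    for (j in seq_along(specs)) s <- .set_sample_field(s, specs[j], th[[j]])
    s
  }
  parametric_model(build, theta, lower = lower, upper = upper,
                   importance = importance, name = sample$name)
}

# Incident-count cells per condition (theta-independent, computed once).
.condition_cells <- function(conditions, profile, band) {
  lapply(conditions, function(cond) {
    inc <- incident_counts(profile, cond, band)
    list(q = inc$q, incident = inc$incident, condition = cond)
  })
}

# Concatenated expected counts over all condition cells at theta.
.lambda_from_cells <- function(model, theta, cells, dq_over_q) {
  sample <- model$build(theta)
  unlist(lapply(cells, function(cell) {
    s <- if (!is.na(cell$condition$contrast_sld)) {
      set_contrast(sample, cell$condition$contrast_sld)
    } else {
      sample
    }
    reflectivity_smeared(s, cell$q, dq_over_q = dq_over_q,
                         spin = cell$condition$spin) * cell$incident
  }), use.names = FALSE)
}

#' Fisher information matrix of a simulated experiment
#'
#' For independent Poisson-distributed counts with expectations
#' `lambda_k(theta)` over all Q bins of all conditions, the Fisher information
#' is `G_ij = sum_k (1/lambda_k) (d lambda_k / d theta_i)
#' (d lambda_k / d theta_j)`. Derivatives are taken by central finite
#' differences with a relative step of `step_rel` (absolute floor
#' `step_abs`). Bins with zero expected counts contribute zero information
#' (the Poisson limit), and the matrix is additive over independent
#' conditions and exactly linear in total counting time.
#'
#' The returned result also carries the importance-scaled matrix
#' `D G D, D = diag(w)`, which puts parameters of different units on a common
#' (fractional) scale so that its eigenvalues are comparable; the minimum
#' eigenvalue of the scaled matrix is the maximin design objective.
#'
#' @param model A [parametric_model()] (or a [slab_sample()] plus `vary`
#'   passed on to [vary_parameters()]).
#' @param conditions A [measurement_condition()] or list of them.
#' @param profile A [flux_profile()].
#' @param importance Positive weights, one per parameter; default the model's
#'   `importance`, else `abs(theta)`.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @param step_rel,step_abs Finite-difference step control.
#' @param vary Optional field specs when `model` is a plain sample.
#' @return An object of class `fisher_result`: `parameters`, `raw_matrix`
#'   (nats per native-unit^2), `matrix` (importance-scaled), `importance`,
#'   `eigenvalues` (ascending), `min_eigenvalue`.
#' @export
fisher_matrix <- function(model, conditions, profile, importance = NULL,
                          band = NULL, dq_over_q = 0.02, step_rel = 1e-3,
                          step_abs = 1e-8, vary = NULL) {
  if (inherits(model, "slab_sample")) {
    if (is.null(vary)) stop("plain samples need 'vary'", call. = FALSE)
    model <- vary_parameters(model, vary)
  }
  stopifnot(inherits(model, "parametric_model"))
  if (inherits(conditions, "measurement_condition")) conditions <- list(conditions)
  theta <- model$theta
  np <- length(theta)
  if (np < 1) stop("at least one varying parameter is required", call. = FALSE)
  cells <- .condition_cells(conditions, profile, band)
  lam <- .lambda_from_cells(model, theta, cells, dq_over_q)
  if (any(lam < 0)) stop("negative expected counts", call. = FALSE)
  grads <- matrix(0, length(lam), np,
                  dimnames = list(NULL, names(theta)))
  for (i in seq_len(np)) {
    h <- max(step_rel * abs(theta[[i]]), step_abs)
    tp <- theta; tp[[i]] <- theta[[i]] + h
    tm <- theta; tm[[i]] <- theta[[i]] - h
    lp <- .lambda_from_cells(model, tp, cells, dq_over_q)
    lm <- .lambda_from_cells(model, tm, cells, dq_over_q)
    g <- (lp - lm) / (2 * h)
    if (any(!is.finite(g))) {
      stop(sprintf("non-finite gradient for parameter '%s'", names(theta)[i]),
           call. = FALSE)
    }
    grads[, i] <- g
  }
  ok <- lam > 0
  w <- grads[ok, , drop = FALSE] / sqrt(lam[ok])
  raw <- crossprod(w)
  if (is.null(importance)) importance <- model$importance
  if (is.null(importance)) {
    importance <- abs(theta)
    if (any(importance == 0)) {
      stop("default importance |theta| is zero for some parameter; supply 'importance'",
           call. = FALSE)
    }
  }
  new_fisher_result(raw, importance, theta)
}

# Assemble a fisher_result from a raw matrix, weights and parameter values.
new_fisher_result <- function(raw, importance, theta) {
  if (any(importance <= 0)) stop("importance weights must be > 0", call. = FALSE)
  scaled <- importance_scale(raw, importance)
  es <- eigen((scaled + t(scaled)) / 2, symmetric = TRUE)
  structure(
    list(parameters = theta, importance = importance, raw_matrix = raw,
         matrix = scaled, eigenvalues = rev(es$values),
         min_eigenvalue = min(es$values)),
    class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result> %d parameter(s); min eigenvalue %.6g\n",
              length(x$parameters), x$min_eigenvalue))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Importance scaling of a Fisher information matrix
#'
#' Congruence transform `D G D` with `D = diag(weights)`, mapping information
#' per native-unit^2 to information per (weighted) fractional unit^2.
#' Positive semidefiniteness is preserved; all-unit weights return the matrix
#' unchanged.
#'
#' @param raw_matrix Symmetric FI matrix.
#' @param weights Positive weights, one per row/column.
#' @return The scaled matrix.
#' @export
importance_scale <- function(raw_matrix, weights) {
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("importance weights must be positive and finite", call. = FALSE)
  }
  if (length(weights) != nrow(raw_matrix)) {
    stop("one weight per parameter is required", call. = FALSE)
  }
  raw_matrix * tcrossprod(weights)
}

#' Minimum eigenvalue of (the scaled matrix of) a Fisher result
#'
#' The maximin design objective: larger values mean the worst-determined
#' linear combination of parameters is better determined. For a minimizing
#' optimizer use the negative of this value.
#'
#' @param x A `fisher_result` or a symmetric matrix.
#' @return Smallest eigenvalue.
#' @export
min_eigenvalue <- function(x) {
  if (inherits(x, "fisher_result")) return(x$min_eigenvalue)
  min(eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Cramer-Rao uncertainty bounds from a Fisher result
#'
#' Per-parameter lower-bound standard deviations are
#' `sigma_i = sqrt([(G_raw)^-1]_ii)` in native parameter units; the
#' worst-combination bound, on the importance-scaled (fractional) scale, is
#' `1 / sqrt(min eigenvalue)`. A 100-fold increase of the minimum eigenvalue
#' (e.g. 100x counting time) therefore tightens the worst-combination bound
#' by a factor of 10.
#'
#' @param result A `fisher_result`.
#' @return List with `per_parameter` (named sigmas; `Inf` with a warning when
#'   the matrix is singular) and `worst_combination`.
#' @export
crb_uncertainties <- function(result) {
  stopifnot(inherits(result, "fisher_result"))
  worst <- if (result$min_eigenvalue > 0) {
    1 / sqrt(result$min_eigenvalue)
  } else {
    Inf
  }
  per <- tryCatch(sqrt(diag(solve(result$raw_matrix))),
                  error = function(e) {
                    warning("singular Fisher matrix: per-parameter bounds unbounded",
                            call. = FALSE)
                    rep(Inf, length(result$parameters))
                  })
  names(per) <- names(result$parameters)
  list(per_parameter = per, worst_combination = worst)
}

#' Fisher information of a kinetic measurement series
#'
#' For a sample that evolves during the measurement (e.g. a degrading
#' monolayer tracked through its area per molecule), data simulated at each
#' snapshot are independent, so the information about the tracked parameter
#' over the full experiment is the sum of the per-snapshot single-parameter
#' Fisher informations, each evaluated at the snapshot's own parameter value.
#'
#' @param models List of single-parameter [parametric_model()]s, one per
#'   snapshot (see [kinetic_series()]).
#' @param conditions Either one [measurement_condition()] template applied to
#'   every snapshot, or a list (length of `models`) of conditions/lists of
#'   conditions per snapshot.
#' @inheritParams fisher_matrix
#' @return Scalar Fisher information (nats per native-unit^2).
#' @export
kinetic_fisher <- function(models, conditions, profile, band = NULL,
                           dq_over_q = 0.02, step_rel = 1e-3,
                           step_abs = 1e-8) {
  if (length(models) == 0) stop("empty snapshot sequence", call. = FALSE)
  if (inherits(conditions, "measurement_condition")) {
    conditions <- rep(list(conditions), length(models))
  }
  if (length(conditions) != length(models)) {
    stop("'conditions' must match the number of snapshots", call. = FALSE)
  }
  total <- 0
  for (i in seq_along(models)) {
    m <- models[[i]]
    stopifnot(inherits(m, "parametric_model"))
    if (length(m$theta) != 1) {
      stop("kinetic_fisher tracks exactly one parameter", call. = FALSE)
    }
    fr <- fisher_matrix(m, conditions[[i]], profile,
                        importance = 1,  # scalar: scaling immaterial
                        band = band, dq_over_q = dq_over_q,
                        step_rel = step_rel, step_abs = step_abs)
    total <- total + fr$raw_matrix[1, 1]
  }
  total
}
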