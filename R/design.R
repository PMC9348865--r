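#' Experimental design space
#'
#' Bounds and structure of the searchable measurement conditions. Defaults
#' are the physically motivated intervals for a white-beam reflectometer and
#' liquid-backed samples: angles `[0.2, 4.0]` degrees, water contrasts
#' `[-0.56, 6.36]` (pure H2O to pure D2O, computed from composition),
#' underlayer SLD `[1, 9]` (1e-6 A^-2) and thickness `[0, 500]` Angstrom.
#' Counting-time fractions live on the probability simplex. All contrasts are
#' measured with the same angles and the same proportion of time between
#' angles.
#'
#' @param angle_bounds,contrast_bounds,underlayer_sld_bounds,underlayer_thickness_bounds
#'   Two-element numeric intervals.
#' @param time_budget Total counting time in seconds.
#' @param shared_angles_across_contrasts Flag (kept for provenance; the
#'   bundled optimizers always share angles across contrasts).
#' @return An object of class `design_space`.
#' @export
design_space <- function(angle_bounds = c(0.2, 4.0),
                         contrast_bounds = c(water_sld(0), water_sld(1)),
                         underlayer_sld_bounds = c(1, 9),
                         underlayer_thickness_bounds = c(0, 500),
                         time_budget = 1e5,
                         shared_angles_across_contrasts = TRUE) {
  chk <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2]) {
      stop(sprintf("'%s' must be an increasing interval", nm), call. = FALSE)
    }
  }
  chk(angle_bounds, "angle_bounds"); chk(contrast_bounds, "contrast_bounds")
  chk(underlayer_sld_bounds, "underlayer_sld_bounds")
  chk(underlayer_thickness_bounds, "underlayer_thickness_bounds")
  structure(
    list(angle_bounds = angle_bounds, contrast_bounds = contrast_bounds,
         underlayer_sld_bounds = underlayer_sld_bounds,
         underlayer_thickness_bounds = underlayer_thickness_bounds,
         time_budget = time_budget,
         shared_angles_across_contrasts = isTRUE(shared_angles_across_contrasts)),
    class = "design_space")
}

#' Build the condition grid of a contrast/angle experiment
#'
#' One [measurement_condition()] per (contrast, angle) pair, with the time
#' budget first split across contrasts and then, within each contrast, across
#' angles (shared angle proportions).
#'
#' @param contrasts Contrast SLDs (may be `NA` for contrast-free samples).
#' @param contrast_fractions,angle_fractions Non-negative time weights
#'   (renormalized).
#' @param angles Measurement angles in degrees.
#' @param budget Total counting time (seconds).
#' @param n_points Q points per angle.
#' @param spins Spin channel(s); conditions are replicated per spin with the
#'   time split evenly across spin states.
#' @return List of conditions.
#' @export
build_conditions <- function(contrasts, contrast_fractions, angles,
                             angle_fractions, budget, n_points = 100,
                             spins = "unpolarized") {
  tc <- time_budget_split(contrast_fractions, budget)
  conds <- list()
  for (i in seq_along(contrasts)) {
    ta <- time_budget_split(angle_fractions, tc[i]) / length(spins)
    for (j in seq_along(angles)) {
      for (sp in spins) {
        conds[[length(conds) + 1]] <-
          measurement_condition(angles[j], ta[j], n_points = n_points,
                                contrast_sld = contrasts[i], spin = sp)
      }
    }
  }
  conds
}

#' Differential evolution minimizer
#'
#' A bounded best/1/bin differential-evolution search, used (on the negative
#' minimum eigenvalue) for joint optimization of measurement conditions.
#' Non-finite objective values are penalized, logged and never fatal.
#'
#' @param fn Objective to minimize, `fn(x)` with `x` of length
#'   `length(lower)`.
#' @param lower,upper Bounds.
#' @param seed Integer seed (required: searches are reproducible by
#'   construction).
#' @param control List: `pop` (default `15 * dim`), `maxiter` (200),
#'   `tol` (0.01, relative population-spread convergence), `F` (0.8
#'   differential weight), `CR` (0.9 crossover rate).
#' @return List with `par`, `value`, `trace` (best value per generation),
#'   `iterations`, `evaluations`, `n_penalized`.
#' @export
de_optimize <- function(fn, lower, upper, seed, control = list()) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  ctrl <- utils::modifyList(
    list(pop = 15 * d, maxiter = 200, tol = 0.01, F = 0.8, CR = 0.9), control)
  np <- max(ctrl$pop, 4)
  set.seed(seed)
  n_pen <- 0L
  safe_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) NaN)
    if (!is.finite(v)) { n_pen <<- n_pen + 1L; v <- 1e30 }
    v
  }
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  fv <- apply(pop, 1, safe_fn)
  nev <- np
  trace <- numeric(0)
  iter <- 0L
  for (iter in seq_len(ctrl$maxiter)) {
    best <- pop[which.min(fv), ]
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 2)
      mut <- best + ctrl$F * (pop[r[1], ] - pop[r[2], ])
      mut <- pmin(pmax(mut, lower), upper)
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < ctrl$CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      ft <- safe_fn(trial)
      nev <- nev + 1L
      if (ft <= fv[i]) { pop[i, ] <- trial; fv[i] <- ft }
    }
    trace <- c(trace, min(fv))
    if (stats::sd(fv) <= ctrl$tol * abs(mean(fv)) + 1e-300) break
  }
  ibest <- which.min(fv)
  list(par = pop[ibest, ], value = fv[ibest], trace = trace,
       iterations = iter, evaluations = nev, n_penalized = n_pen)
}

#' One- and two-dimensional design landscapes
#'
#' Evaluates a design objective (typically a minimum-eigenvalue factory from
#' [contrast_objective()] and friends) over a grid. Landscapes are computed
#' from noise-free expected counts, so they are deterministic and
#' bit-reproducible.
#'
#' @param f Objective function; for `scan_1d` `f(x)`, for `scan_2d`
#'   `f(x, y)`.
#' @param grid,grid_x,grid_y Grid values.
#' @return `scan_1d`: data frame with `value` and `objective`. `scan_2d`:
#'   list with `x`, `y` and an `objective` matrix (`x` by rows).
#' @export
scan_1d <- function(f, grid) {
  data.frame(value = grid,
             objective = vapply(grid, f, numeric(1)))
}

#' @rdname scan_1d
#' @export
scan_2d <- function(f, grid_x, grid_y) {
  obj <- outer(seq_along(grid_x), seq_along(grid_y),
               Vectorize(function(i, j) f(grid_x[i], grid_y[j])))
  list(x = grid_x, y = grid_y, objective = obj)
}

#' Minimum-eigenvalue objective over contrast choices
#'
#' Factory returning the design objective for simultaneous contrast choice:
#' given contrast SLDs and their time fractions, build the condition grid,
#' compute the importance-scaled Fisher matrix from noise-free expected
#' counts and return its minimum eigenvalue.
#'
#' @param model A [parametric_model()] accepting solvent contrasts.
#' @param profile A [flux_profile()].
#' @param angles,angle_fractions Shared angles and their time proportions
#'   (defaults: 0.7 and 2.3 degrees at a 15:60 split).
#' @param budget Total time budget (seconds).
#' @param n_points Q points per angle.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @return Function `(contrasts, contrast_fractions)` returning the minimum
#'   eigenvalue.
#' @export
contrast_objective <- function(model, profile, angles = c(0.7, 2.3),
                               angle_fractions = c(15, 60), budget = 1e5,
                               n_points = 100, band = NULL,
                               dq_over_q = 0.02) {
  force(model); force(profile)
  function(contrasts, contrast_fractions = rep(1, length(contrasts))) {
    conds <- build_conditions(contrasts, contrast_fractions, angles,
                              angle_fractions, budget, n_points)
    fisher_matrix(model, conds, profile, band = band,
                  dq_over_q = dq_over_q)$min_eigenvalue
  }
}

#' Minimum-eigenvalue objective over an added underlayer
#'
#' Factory for the underlayer landscape: the bilayer is rebuilt with a single
#' underlayer of the given SLD and thickness (nuisance parameters, excluded
#' from the objective) and measured in the given contrasts.
#'
#' @inheritParams contrast_objective
#' @param contrasts,contrast_fractions Contrasts measured (default pure D2O
#'   and H2O, equal time).
#' @return Function `(sld, thickness)` returning the minimum eigenvalue.
#' @export
underlayer_objective <- function(model, profile,
                                 contrasts = c(water_sld(1), water_sld(0)),
                                 contrast_fractions = c(1, 1),
                                 angles = c(0.7, 2.3),
                                 angle_fractions = c(15, 60), budget = 1e5,
                                 n_points = 100, band = NULL,
                                 dq_over_q = 0.02) {
  force(model); force(profile)
  function(sld, thickness) {
    m <- add_underlayers(model, list(underlayer(sld, thickness)))
    conds <- build_conditions(contrasts, contrast_fractions, angles,
                              angle_fractions, budget, n_points)
    fisher_matrix(m, conds, profile, band = band,
                  dq_over_q = dq_over_q)$min_eigenvalue
  }
}

#' Kinetic-series information objective for a monolayer
#'
#' Factory returning, as a function of the water contrast SLD (and optionally
#' the angle), the Fisher information in the area per molecule summed over a
#' degradation snapshot series measured under a fixed total time budget with
#' equal time per snapshot.
#'
#' @param model An [apm_monolayer()] model.
#' @param profile A [flux_profile()].
#' @param angle Measurement angle in degrees.
#' @param budget Total series time in seconds (default 150 minutes).
#' @param n_steps,apm_start,apm_end Snapshot series (defaults 20 snapshots,
#'   54.1 to 500 A^2).
#' @param n_points Q points per snapshot.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @return Function `(contrast_sld, angle = angle)` returning the scalar
#'   kinetic Fisher information.
#' @export
kinetic_objective <- function(model, profile, angle = 0.8, budget = 150 * 60,
                              n_steps = 20, apm_start = 54.1, apm_end = 500,
                              n_points = 100, band = NULL, dq_over_q = 0.02) {
  force(model); force(profile)
  series <- kinetic_series(model, apm_start, apm_end, n_steps)
  function(contrast_sld, angle_deg = angle) {
    cond <- measurement_condition(angle_deg, budget / n_steps,
                                  n_points = n_points,
                                  contrast_sld = contrast_sld)
    kinetic_fisher(series, cond, profile, band = band,
                   dq_over_q = dq_over_q)
  }
}

#' Magnetic-moment information objective over stack thicknesses
#'
#' Factory returning the Fisher information in the induced magnetic SLD of a
#' [magnetic_stack()] as a function of the garnet-film and platinum-cap
#' thicknesses, measured in both non-spin-flip channels.
#'
#' @param profile A polarized [flux_profile()].
#' @param angles,times Polarized measurement schedule (defaults 0.5/1.0/2.0
#'   degrees at 30/60/120 minutes per spin state).
#' @param n_points Q points per angle.
#' @param band,dq_over_q Passed to [expected_counts()].
#' @param ... Stack overrides forwarded to [magnetic_stack()].
#' @return Function `(yig_thickness, pt_thickness)` returning the scalar
#'   Fisher information in the magnetic SLD.
#' @export
magnetic_objective <- function(profile, angles = c(0.5, 1.0, 2.0),
                               times = c(30, 60, 120) * 60, n_points = 100,
                               band = NULL, dq_over_q = 0.02, ...) {
  force(profile)
  extra <- list(...)
  function(yig_thickness, pt_thickness) {
    m <- do.call(magnetic_stack,
                 c(list(yig_thickness = yig_thickness,
                        pt_thickness = pt_thickness), extra))
    conds <- list()
    for (j in seq_along(angles)) {
      for (sp in c("up", "down")) {
        conds[[length(conds) + 1]] <-
          measurement_condition(angles[j], times[j], n_points = n_points,
                                spin = sp)
      }
    }
    fisher_matrix(m, conds, profile, importance = 1, band = band,
                  dq_over_q = dq_over_q)$raw_matrix[1, 1]
  }
}

# Merge (near-)identical contrast SLDs, summing their time fractions.
.merge_contrasts <- function(slds, fractions, tol = 0.05) {
  o <- order(slds)
  slds <- slds[o]; fractions <- fractions[o]
  grp <- cumsum(c(1, diff(slds) > tol))
  ms <- vapply(split(seq_along(slds), grp), function(ix) {
    stats::weighted.mean(slds[ix], pmax(fractions[ix], 1e-12))
  }, numeric(1))
  mf <- vapply(split(fractions, grp), sum, numeric(1))
  list(slds = unname(ms), fractions = unname(mf / sum(mf)))
}

#' Jointly optimize contrast choices and their time split
#'
#' Differential-evolution search over `n_contrasts` water-contrast SLDs and
#' the simplex split of the time budget between them (angles and the angle
#' time proportions are held fixed and shared across contrasts), maximizing
#' the minimum eigenvalue of the importance-scaled Fisher matrix computed
#' from noise-free expected counts. Near-identical returned contrasts (SLDs
#' within `merge_tol`) are merged with their time fractions summed, and the
#' objective is recomputed for the reported (merged) conditions.
#'
#' @param model A [parametric_model()] over a contrast-parameterized sample.
#' @param profile A [flux_profile()].
#' @param n_contrasts Number of contrasts to optimize.
#' @param space A [design_space()].
#' @param seed Integer seed for the optimizer.
#' @param angles,angle_fractions,n_points As in [contrast_objective()].
#' @param control DE control list (see [de_optimize()]).
#' @param merge_tol Contrast merge tolerance (1e-6 A^-2).
#' @param band,dq_over_q Passed to [expected_counts()].
#' @return An object of class `design_result`: `contrasts`,
#'   `time_fractions`, `objective` (minimum eigenvalue, recomputed from the
#'   returned conditions), `trace`, `seed`, plus the raw optimizer output.
#' @export
optimize_contrasts <- function(model, profile, n_contrasts = 2,
                               space = design_space(), seed,
                               angles = c(0.7, 2.3),
                               angle_fractions = c(15, 60), n_points = 100,
                               control = list(), merge_tol = 0.05,
                               band = NULL, dq_over_q = 0.02) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  obj <- contrast_objective(model, profile, angles, angle_fractions,
                            space$time_budget, n_points, band, dq_over_q)
  n <- n_contrasts
  lower <- c(rep(space$contrast_bounds[1], n), rep(0.01, n))
  upper <- c(rep(space$contrast_bounds[2], n), rep(1, n))
  fn <- function(x) -obj(x[seq_len(n)], x[n + seq_len(n)])
  de <- de_optimize(fn, lower, upper, seed = seed, control = control)
  slds <- de$par[seq_len(n)]
  fracs <- de$par[n + seq_len(n)]
  fracs <- fracs / sum(fracs)
  merged <- .merge_contrasts(slds, fracs, tol = merge_tol)
  structure(
    list(contrasts = merged$slds, time_fractions = merged$fractions,
         objective = obj(merged$slds, merged$fractions),
         trace = -de$trace, seed = seed, optimizer = de,
         angles = angles, angle_fractions = angle_fractions / sum(angle_fractions)),
    class = "design_result")
}

#' Jointly optimize measurement angles and their time split
#'
#' As [optimize_contrasts()], but searching over `n_angles` measurement
#' angles and the angle time split while the contrasts (default pure D2O and
#' H2O, equal time) are held fixed.
#'
#' @inheritParams optimize_contrasts
#' @param n_angles Number of angles to optimize.
#' @param contrasts,contrast_fractions Fixed contrasts and their time split.
#' @return A `design_result` with `angles` and `time_fractions`.
#' @export
optimize_angles <- function(model, profile, n_angles = 2,
                            space = design_space(), seed,
                            contrasts = c(water_sld(1), water_sld(0)),
                            contrast_fractions = c(1, 1), n_points = 100,
                            control = list(), band = NULL, dq_over_q = 0.02) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  n <- n_angles
  fn <- function(x) {
    conds <- build_conditions(contrasts, contrast_fractions,
                              x[seq_len(n)], x[n + seq_len(n)],
                              space$time_budget, n_points)
    -fisher_matrix(model, conds, profile, band = band,
                   dq_over_q = dq_over_q)$min_eigenvalue
  }
  lower <- c(rep(space$angle_bounds[1], n), rep(0.01, n))
  upper <- c(rep(space$angle_bounds[2], n), rep(1, n))
  de <- de_optimize(fn, lower, upper, seed = seed, control = control)
  ang <- de$par[seq_len(n)]
  fracs <- de$par[n + seq_len(n)]
  o <- order(ang)
  structure(
    list(angles = ang[o], time_fractions = (fracs / sum(fracs))[o],
         contrasts = contrasts, objective = -de$value, trace = -de$trace,
         seed = seed, optimizer = de),
    class = "design_result")
}

#' Optimize added underlayer SLDs and thicknesses
#'
#' Differential-evolution search over the SLD and thickness of
#' `n_underlayers` films inserted below the bilayer, with the contrasts and
#' angles fixed; underlayer parameters are nuisance parameters and do not
#' enter the Fisher parameter set.
#'
#' @inheritParams optimize_angles
#' @param n_underlayers Number of underlayers (1 to 3).
#' @param angles,angle_fractions Fixed angle schedule.
#' @return A `design_result` with an `underlayers` list.
#' @export
optimize_underlayers <- function(model, profile, n_underlayers = 1,
                                 space = design_space(), seed,
                                 contrasts = c(water_sld(1), water_sld(0)),
                                 contrast_fractions = c(1, 1),
                                 angles = c(0.7, 2.3),
                                 angle_fractions = c(15, 60), n_points = 100,
                                 control = list(), band = NULL,
                                 dq_over_q = 0.02) {
  if (missing(seed)) stop("an explicit 'seed' is required", call. = FALSE)
  n <- n_underlayers
  stopifnot(n >= 1, n <= 3)
  fn <- function(x) {
    uls <- lapply(seq_len(n), function(i) {
      underlayer(x[2 * i - 1], x[2 * i])
    })
    m <- add_underlayers(model, uls)
    conds <- build_conditions(contrasts, contrast_fractions, angles,
                              angle_fractions, space$time_budget, n_points)
    -fisher_matrix(m, conds, profile, band = band,
                   dq_over_q = dq_over_q)$min_eigenvalue
  }
  lower <- rep(c(space$underlayer_sld_bounds[1],
                 space$underlayer_thickness_bounds[1]), n)
  upper <- rep(c(space$underlayer_sld_bounds[2],
                 space$underlayer_thickness_bounds[2]), n)
  de <- de_optimize(fn, lower, upper, seed = seed, control = control)
  uls <- lapply(seq_len(n), function(i) {
    underlayer(de$par[2 * i - 1], de$par[2 * i])
  })
  structure(
    list(underlayers = uls, contrasts = contrasts, angles = angles,
         objective = -de$value, trace = -de$trace, seed = seed,
         optimizer = de),
    class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> objective (min eigenvalue):",
      format(x$objective, digits = 6), "\n")
  if (!is.null(x$contrasts)) {
    cat("  contrasts (1e-6 A^-2):",
        paste(sprintf("%.2f", x$contrasts), collapse = ", "), "\n")
  }
  if (!is.null(x$time_fractions)) {
    cat("  time split (%):",
        paste(sprintf("%.1f", 100 * x$time_fractions), collapse = ", "), "\n")
  }
  if (!is.null(x$angles)) {
    cat("  angles (deg):",
        paste(sprintf("%.2f", x$angles), collapse = ", "), "\n")
  }
  if (!is.null(x$underlayers)) {
    for (u in x$underlayers) {
      cat(sprintf("  underlayer: sld %.2f, thickness %.1f A\n",
                  u$sld, u$thickness))
    }
  }
  invisible(x)
}

#' Tabulate a design result
#'
#' Flattens a `design_result` into a one-row data frame shaped like the
#' conventional results tables (condition columns plus the minimum
#' eigenvalue).
#'
#' @param result A `design_result`.
#' @return A one-row data frame.
#' @export
design_table <- function(result) {
  stopifnot(inherits(result, "design_result"))
  row <- list()
  if (!is.null(result$contrasts)) {
    for (i in seq_along(result$contrasts)) {
      row[[sprintf("contrast_%d", i)]] <- result$contrasts[i]
    }
  }
  if (!is.null(result$angles)) {
    for (i in seq_along(result$angles)) {
      row[[sprintf("angle_%d", i)]] <- result$angles[i]
    }
  }
  if (!is.null(result$time_fractions)) {
    for (i in seq_along(result$time_fractions)) {
      row[[sprintf("time_pct_%d", i)]] <- 100 * result$time_fractions[i]
    }
  }
  if (!is.null(result$underlayers)) {
    for (i in seq_along(result$underlayers)) {
      row[[sprintf("underlayer_sld_%d", i)]] <- result$underlayers[[i]]$sld
      row[[sprintf("underlayer_thickness_%d", i)]] <-
        result$underlayers[[i]]$thickness
    }
  }
  row$min_eigenvalue <- result$objective
  as.data.frame(row)
}
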