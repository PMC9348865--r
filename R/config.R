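# Fetch a required config field by dotted path; errors name the field path.
.cfg_get <- function(cfg, path, required = TRUE, default = NULL) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      if (required) {
        stop(sprintf("config: missing required field '%s'", path),
             call. = FALSE)
      }
      return(default)
    }
    node <- node[[p]]
  }
  node
}

# Build the flux profile described by a config's instrument block.
.cfg_flux <- function(cfg) {
  flux_file <- .cfg_get(cfg, "instrument.flux_file", required = FALSE)
  if (!is.null(flux_file)) {
    return(read_flux_table(flux_file,
                           polarized = isTRUE(.cfg_get(cfg, "instrument.polarized",
                                                       required = FALSE, default = FALSE))))
  }
  synthesize_flux(
    band = as.numeric(.cfg_get(cfg, "instrument.band", required = FALSE,
                               default = c(1, 14))),
    total_rate = .cfg_get(cfg, "instrument.total_rate", required = FALSE,
                          default = 5e5),
    polarized = isTRUE(.cfg_get(cfg, "instrument.polarized", required = FALSE,
                                default = FALSE)),
    theta_ref = .cfg_get(cfg, "instrument.theta_ref", required = FALSE,
                         default = 0.3))
}

# Build the parametric model described by a config's sample block.
.cfg_model <- function(cfg) {
  builtin <- .cfg_get(cfg, "sample.builtin", required = FALSE)
  if (!is.null(builtin)) {
    args <- .cfg_get(cfg, "sample.args", required = FALSE, default = list())
    return(do.call(builtin_model, c(list(name = builtin), args)))
  }
  layers_cfg <- .cfg_get(cfg, "sample.layers")
  layers <- lapply(layers_cfg, function(l) {
    do.call(slab_layer, l)
  })
  s <- slab_sample(
    layers,
    superphase_sld = .cfg_get(cfg, "sample.superphase_sld", required = FALSE,
                              default = 0),
    substrate_sld = .cfg_get(cfg, "sample.substrate_sld"),
    solvent_sld = .cfg_get(cfg, "sample.solvent_sld", required = FALSE,
                           default = .cfg_get(cfg, "sample.substrate_sld")),
    substrate_roughness = .cfg_get(cfg, "sample.substrate_roughness",
                                   required = FALSE, default = 0),
    scale = .cfg_get(cfg, "sample.scale", required = FALSE, default = 1),
    background = .cfg_get(cfg, "sample.background", required = FALSE,
                          default = 0))
  vary <- .cfg_get(cfg, "sample.vary", required = FALSE)
  if (is.null(vary)) return(s)
  vary_parameters(s, unlist(vary))
}

# Conditions from a config block: explicit per-angle times, or budget + splits.
.cfg_conditions <- function(cfg) {
  angles <- as.numeric(.cfg_get(cfg, "conditions.angles"))
  n_points <- .cfg_get(cfg, "conditions.n_points", required = FALSE,
                       default = 100)
  contrasts <- .cfg_get(cfg, "conditions.contrasts", required = FALSE,
                        default = NA_real_)
  spin <- .cfg_get(cfg, "conditions.spin", required = FALSE,
                   default = "unpolarized")
  spins <- if (identical(spin, "both")) c("up", "down") else spin
  times <- .cfg_get(cfg, "conditions.times", required = FALSE)
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(angles)) {
      stop("config: 'conditions.times' must match 'conditions.angles'",
           call. = FALSE)
    }
    conds <- list()
    for (cs in as.numeric(contrasts)) {
      for (j in seq_along(angles)) {
        for (sp in spins) {
          conds[[length(conds) + 1]] <-
            measurement_condition(angles[j], times[j] / length(spins),
                                  n_points = n_points, contrast_sld = cs,
                                  spin = sp)
        }
      }
    }
    return(conds)
  }
  budget <- .cfg_get(cfg, "conditions.budget")
  build_conditions(
    as.numeric(contrasts),
    as.numeric(.cfg_get(cfg, "conditions.contrast_fractions",
                        required = FALSE,
                        default = rep(1, length(contrasts)))),
    angles,
    as.numeric(.cfg_get(cfg, "conditions.angle_fractions", required = FALSE,
                        default = rep(1, length(angles)))),
    budget, n_points = n_points, spins = spins)
}

.write_manifest <- function(out_dir, command, seed, files, cfg_path) {
  manifest <- list(
    command = command, seed = seed,
    package = "refdesign",
    version = as.character(utils::packageVersion("refdesign")),
    config = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = basename(files))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run a configured command
#'
#' Executes one of the tool's subcommands from a YAML (or list)
#' configuration: `simulate` (one dataset per condition), `fisher`
#' (information report), `scan` (1D landscape), `optimize` (DE condition
#' search) or `discriminate` (likelihood-ratio vs time). Every run writes the
#' resolved configuration and a manifest next to its outputs, and is
#' deterministic given the configuration and seed.
#'
#' @param command One of `"simulate"`, `"fisher"`, `"scan"`, `"optimize"`,
#'   `"discriminate"`.
#' @param config Path to a YAML file or an equivalent nested list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's `seed`.
#' @return Invisibly, the list of written file paths.
#' @export
run_config <- function(command, config, out_dir = ".", seed = NULL) {
  command <- match.arg(command, c("simulate", "fisher", "scan", "optimize",
                                  "discriminate"))
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config: not a mapping", call. = FALSE)
  if (is.null(seed)) seed <- .cfg_get(cfg, "seed")
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$seed <- seed
  cfg_path <- file.path(out_dir, "resolved_config.yml")
  yaml::write_yaml(cfg, cfg_path)

  profile <- .cfg_flux(cfg)
  files <- character(0)

  if (command == "simulate") {
    model <- .cfg_model(cfg)
    sample <- if (inherits(model, "parametric_model")) model_sample(model) else model
    conds <- .cfg_conditions(cfg)
    datasets <- simulate_experiment(sample, conds, profile, seed = seed)
    for (i in seq_along(datasets)) {
      f <- file.path(out_dir, sprintf("condition_%02d.dat", i))
      write_refl_dat(datasets[[i]], f)
      files <- c(files, f)
    }
  } else if (command == "fisher") {
    model <- .cfg_model(cfg)
    if (!inherits(model, "parametric_model")) {
      stop("config: 'fisher' needs a parameterized sample ('sample.vary' or a builtin)",
           call. = FALSE)
    }
    conds <- .cfg_conditions(cfg)
    fr <- fisher_matrix(model, conds, profile)
    crb <- crb_uncertainties(fr)
    f <- file.path(out_dir, "fisher_report.json")
    jsonlite::write_json(
      list(parameters = as.list(fr$parameters),
           importance = as.list(fr$importance),
           raw_matrix = fr$raw_matrix, scaled_matrix = fr$matrix,
           eigenvalues = fr$eigenvalues,
           min_eigenvalue = fr$min_eigenvalue,
           crb_sigma = as.list(crb$per_parameter),
           crb_worst_combination = crb$worst_combination),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  } else if (command == "scan") {
    model <- .cfg_model(cfg)
    gr <- .cfg_get(cfg, "scan.grid")
    grid <- seq(as.numeric(gr$from), as.numeric(gr$to),
                length.out = as.integer(gr$n))
    variable <- .cfg_get(cfg, "scan.variable")
    obj <- switch(variable,
      contrast = {
        base <- as.numeric(.cfg_get(cfg, "scan.base_contrasts",
                                    required = FALSE, default = numeric(0)))
        o <- contrast_objective(model, profile,
               angles = as.numeric(.cfg_get(cfg, "conditions.angles")),
               angle_fractions = as.numeric(
                 .cfg_get(cfg, "conditions.angle_fractions", required = FALSE,
                          default = rep(1, length(.cfg_get(cfg, "conditions.angles"))))),
               budget = .cfg_get(cfg, "conditions.budget"),
               n_points = .cfg_get(cfg, "conditions.n_points",
                                   required = FALSE, default = 100))
        function(s) o(c(base, s), rep(1, length(base) + 1))
      },
      kinetic_contrast = {
        o <- kinetic_objective(model, profile,
               angle = as.numeric(.cfg_get(cfg, "conditions.angles"))[1],
               budget = .cfg_get(cfg, "conditions.budget"))
        function(s) o(s)
      },
      stop(sprintf("config: unknown scan variable '%s'", variable),
           call. = FALSE))
    res <- scan_1d(obj, grid)
    f <- file.path(out_dir, "scan.csv")
    utils::write.csv(res, f, row.names = FALSE)
    files <- c(files, f)
  } else if (command == "optimize") {
    model <- .cfg_model(cfg)
    what <- .cfg_get(cfg, "design.what")
    n <- .cfg_get(cfg, "design.n", required = FALSE, default = 2)
    ctrl <- .cfg_get(cfg, "design.de", required = FALSE, default = list())
    space <- design_space(
      time_budget = .cfg_get(cfg, "conditions.budget", required = FALSE,
                             default = 1e5))
    res <- switch(what,
      contrasts = optimize_contrasts(model, profile, n_contrasts = n,
        space = space, seed = seed,
        angles = as.numeric(.cfg_get(cfg, "conditions.angles")),
        angle_fractions = as.numeric(
          .cfg_get(cfg, "conditions.angle_fractions", required = FALSE,
                   default = rep(1, length(.cfg_get(cfg, "conditions.angles"))))),
        n_points = .cfg_get(cfg, "conditions.n_points", required = FALSE,
                            default = 100),
        control = ctrl),
      angles = optimize_angles(model, profile, n_angles = n, space = space,
        seed = seed, control = ctrl),
      underlayers = optimize_underlayers(model, profile, n_underlayers = n,
        space = space, seed = seed, control = ctrl),
      stop(sprintf("config: unknown design target '%s'", what),
           call. = FALSE))
    tab <- design_table(res)
    f_csv <- file.path(out_dir, "optimize.csv")
    utils::write.csv(tab, f_csv, row.names = FALSE)
    f_json <- file.path(out_dir, "optimize.json")
    jsonlite::write_json(
      list(what = what, seed = seed, objective = res$objective,
           table = tab, trace = res$trace),
      f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f_csv, f_json)
  } else if (command == "discriminate") {
    alt_args <- .cfg_get(cfg, "sample.args", required = FALSE,
                         default = list())
    model_alt <- do.call(builtin_model,
                         c(list(name = .cfg_get(cfg, "sample.builtin")),
                           alt_args))
    null_args <- alt_args; null_args$magnetic_sld <- 0
    model_null <- do.call(builtin_model,
                          c(list(name = .cfg_get(cfg, "sample.builtin")),
                            null_args))
    res <- likelihood_ratio_vs_time(
      model_alt, model_null,
      times = as.numeric(.cfg_get(cfg, "discriminate.times")),
      profile = profile,
      angles = as.numeric(.cfg_get(cfg, "conditions.angles", required = FALSE,
                                   default = c(0.5, 1.0, 2.0))),
      n_reps = .cfg_get(cfg, "discriminate.n_reps", required = FALSE,
                        default = 50),
      seed = seed)
    f <- file.path(out_dir, "discriminate.csv")
    utils::write.csv(as.data.frame(res), f, row.names = FALSE)
    files <- c(files, f)
  }

  files <- c(files, .write_manifest(out_dir, command, seed, files, cfg_path),
             cfg_path)
  invisible(files)
}
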