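# Physical constants and bound coherent scattering lengths (fm).
.const <- list(
  N_A = 6.02214076e23,
  # gamma_n * r_e / 2: magnetic scattering length per Bohr magneton (Angstrom)
  c_mag = 1.91304 * 2.8179403e-5 / 2,
  b = c(H = -3.7390, D = 6.6710, O = 5.8030, C = 6.6460, N = 9.3600,
        P = 5.1300, Si = 4.1491, Fe = 9.4500, Pt = 9.6000, Y = 7.7500,
        Al = 3.4490, Au = 7.6300)
)

#' Scattering length density from mass density
#'
#' `SLD = b * N_A * density / molar_mass`, returned in the user-facing units
#' of 1e-6 inverse square Angstrom.
#'
#' @param b_fm Total bound coherent scattering length per formula unit, in fm.
#' @param density Mass density in g/cm^3.
#' @param molar_mass Molar mass of the formula unit in g/mol.
#' @return SLD in 1e-6 A^-2.
#' @examples
#' # D2O: 2 b_D + b_O over 20.028 g/mol at 1.1044 g/cm^3 -> about 6.36
#' material_sld(2 * 6.671 + 5.803, 1.1044, 20.0276)
#' @export
material_sld <- function(b_fm, density, molar_mass) {
  if (density <= 0 || molar_mass <= 0) {
    stop("density and molar mass must be > 0", call. = FALSE)
  }
  n <- density * .const$N_A / molar_mass * 1e-24  # formula units per A^3
  n * b_fm * 1e-5 * 1e6                           # fm -> A; A^-2 -> 1e-6 A^-2
}

# Reference solvent/substrate SLDs computed from composition, not hardcoded.
.solvent_slds <- function() {
  b <- .const$b
  c(h2o = material_sld(2 * b[["H"]] + b[["O"]], 0.99707, 18.0153),
    d2o = material_sld(2 * b[["D"]] + b[["O"]], 1.1044, 20.0276),
    si  = material_sld(b[["Si"]], 2.329, 28.0855))
}

#' Solvent SLD of an H2O/D2O mixture
#'
#' Linear volume-fraction mix of the pure-water endpoint SLDs (each computed
#' from bound coherent scattering lengths and mass densities; approximately
#' -0.56 and 6.36 in 1e-6 A^-2). The physically allowed water-contrast
#' interval is therefore `[water_sld(0), water_sld(1)]`.
#'
#' @param d2o_fraction Volume fraction of D2O in `[0, 1]`.
#' @return Solvent SLD in 1e-6 A^-2.
#' @export
water_sld <- function(d2o_fraction) {
  if (any(d2o_fraction < 0) || any(d2o_fraction > 1)) {
    stop("'d2o_fraction' must lie in [0, 1]", call. = FALSE)
  }
  s <- .solvent_slds()
  (1 - d2o_fraction) * s[["h2o"]] + d2o_fraction * s[["d2o"]]
}

#' @rdname water_sld
#' @param sld Target solvent SLD in 1e-6 A^-2, within the water interval.
#' @return `d2o_fraction_for_sld()` returns the D2O fraction producing `sld`
#'   (e.g. silicon-matched water, SLD 2.07, needs about 38 percent D2O).
#' @export
d2o_fraction_for_sld <- function(sld) {
  s <- .solvent_slds()
  f <- (sld - s[["h2o"]]) / (s[["d2o"]] - s[["h2o"]])
  if (any(f < 0) || any(f > 1)) {
    stop("'sld' outside the pure-H2O..pure-D2O interval", call. = FALSE)
  }
  f
}

#' Surface excess of a monolayer from its area per molecule
#'
#' `Gamma = molar_mass / (N_A * apm)` converted to mg/m^2 (with `apm` in
#' square Angstrom this is `molar_mass / (6.022 * apm)`); surface excess is
#' inversely proportional to the area per molecule.
#'
#' @param apm Area per molecule in A^2, > 0.
#' @param molar_mass Molar mass in g/mol.
#' @return Surface excess Gamma in mg/m^2.
#' @export
surface_excess <- function(apm, molar_mass) {
  if (any(apm <= 0)) stop("'apm' must be > 0", call. = FALSE)
  1e3 * molar_mass / (.const$N_A * apm * 1e-20)
}

#' Magnetic SLD from an atomic moment
#'
#' `rho_mag = c_m * moment * number_density` with
#' `c_m = gamma_n r_e / 2 = 2.6955e-5` Angstrom per Bohr magneton, the
#' standard neutron magnetic conversion length.
#'
#' @param moment Atomic magnetic moment in Bohr magnetons.
#' @param number_density Atoms per cubic Angstrom, > 0.
#' @return Magnetic SLD in 1e-6 A^-2; linear in both arguments.
#' @examples
#' # ~0.009 mu_B per Pt atom (n = 0.0662 / A^3) -> about 0.0164e-6 A^-2
#' moment_to_magnetic_sld(0.0092, 0.0662)
#' @export
moment_to_magnetic_sld <- function(moment, number_density) {
  if (any(number_density <= 0)) {
    stop("'number_density' must be > 0", call. = FALSE)
  }
  .const$c_mag * moment * number_density * 1e6
}

#' Underlayer specification
#'
#' An extra deposited film inserted between the native oxide and the inner
#' bilayer headgroups to reshape the reflectivity. Underlayers carry a fixed
#' 2 Angstrom roughness and 0 percent hydration, and their SLD and thickness
#' must lie in `[1, 9]` (1e-6 A^-2) and `[0, 500]` Angstrom respectively (the
#' range of most non-isotopically-enriched film materials and of practical
#' depositions). Gold and permalloy, the common choices, have SLDs 4.7 and
#' 8.4.
#'
#' @param sld Underlayer SLD in 1e-6 A^-2, in `[1, 9]`.
#' @param thickness Underlayer thickness in Angstrom, in `[0, 500]`.
#' @return An object of class `underlayer`.
#' @export
underlayer <- function(sld, thickness) {
  if (sld < 1 || sld > 9) {
    stop("underlayer SLD must lie in [1, 9] (1e-6 A^-2)", call. = FALSE)
  }
  if (thickness < 0 || thickness > 500) {
    stop("underlayer thickness must lie in [0, 500] A", call. = FALSE)
  }
  structure(list(sld = sld, thickness = thickness, roughness = 2,
                 hydration = 0), class = "underlayer")
}

#' Contrast-parameterized supported lipid bilayer
#'
#' A solid-liquid bilayer model: silicon block (the beam enters through it) /
#' native oxide / inner headgroups / tailgroups / outer headgroups / bulk
#' water, with every hydrated layer mixed against a freely variable water
#' contrast SLD. Molecular volumes (hence dry layer SLDs) are held fixed, so
#' changing the contrast changes only the solvent-mixed SLDs. The deuterated
#' variant swaps the tail SLD only.
#'
#' Structural defaults are literature-typical placeholder values for a
#' phosphatidylcholine bilayer on silicon; every value can be overridden.
#' The varying parameter set used for the Fisher information is: oxide
#' thickness and hydration, oxide/bilayer roughness, headgroup thickness and
#' hydration, and tail thickness. With underlayers present the oxide
#' hydration is forced to 0 and both the oxide hydration and oxide/bilayer
#' roughness are dropped from the varying set (underlayer parameters are
#' nuisance parameters and are never part of the objective).
#'
#' @param tails `"h"` (hydrogenated, SLD about -0.37) or `"d"` (deuterated,
#'   SLD about 6.5).
#' @param solvent_sld Initial water contrast SLD (1e-6 A^-2).
#' @param underlayers List of 0 to 3 [underlayer()]s.
#' @param sio2_thickness,sio2_hydration,sio2_roughness Native oxide layer.
#' @param head_thickness,head_sld,head_hydration Headgroup layers (inner and
#'   outer share the structure).
#' @param tail_thickness,tail_sld_h,tail_sld_d,tail_hydration Combined
#'   tailgroup layer.
#' @param sio2_bilayer_roughness Roughness between oxide (or last underlayer)
#'   and the bilayer.
#' @param bilayer_roughness Internal and bilayer/water roughness.
#' @param background Constant background reflectivity.
#' @param scale Experimental scale factor.
#' @return A [parametric_model()] whose builder assembles the
#'   [slab_sample()]; factory arguments are kept in attribute `spec_args` so
#'   the model can be re-built with modified structure (see
#'   [add_underlayers()]).
#' @export
contrast_bilayer <- function(tails = c("h", "d"), solvent_sld = water_sld(1),
                             underlayers = list(),
                             sio2_thickness = 14.7, sio2_hydration = 0.17,
                             sio2_roughness = 3,
                             head_thickness = 9.6, head_sld = 1.88,
                             head_hydration = 0.40,
                             tail_thickness = 25.7, tail_sld_h = -0.37,
                             tail_sld_d = 6.50, tail_hydration = 0.08,
                             sio2_bilayer_roughness = 4,
                             bilayer_roughness = 3,
                             background = 1e-6, scale = 1) {
  tails <- match.arg(tails)
  args <- as.list(environment())
  if (inherits(underlayers, "underlayer")) underlayers <- list(underlayers)
  if (length(underlayers) > 3) stop("0-3 underlayers supported", call. = FALSE)
  if (!all(vapply(underlayers, inherits, logical(1), "underlayer"))) {
    stop("'underlayers' must be underlayer objects", call. = FALSE)
  }
  has_under <- length(underlayers) > 0
  tail_sld <- if (tails == "h") tail_sld_h else tail_sld_d
  si_sld <- .solvent_slds()[["si"]]

  theta <- c(sio2_thickness = sio2_thickness,
             if (!has_under) c(sio2_hydration = sio2_hydration,
                               sio2_bilayer_roughness = sio2_bilayer_roughness),
             head_thickness = head_thickness,
             head_hydration = head_hydration,
             tail_thickness = tail_thickness)
  lower <- c(sio2_thickness = 5,
             if (!has_under) c(sio2_hydration = 0, sio2_bilayer_roughness = 0.5),
             head_thickness = 5, head_hydration = 0, tail_thickness = 10)
  upper <- c(sio2_thickness = 30,
             if (!has_under) c(sio2_hydration = 0.5, sio2_bilayer_roughness = 10),
             head_thickness = 15, head_hydration = 0.8, tail_thickness = 40)

  build <- function(th) {
    th <- as.list(th)
    sio2_h <- if (has_under) 0 else th$sio2_hydration
    bil_rough <- if (has_under) sio2_bilayer_roughness else th$sio2_bilayer_roughness
    layers <- list(
      slab_layer(th$sio2_thickness, 3.47, roughness = sio2_roughness,
                 hydration = sio2_h, name = "SiO2"))
    prev_rough <- bil_rough
    if (has_under) {
      for (i in seq_along(underlayers)) {
        u <- underlayers[[i]]
        layers <- c(layers, list(
          slab_layer(u$thickness, u$sld, roughness = u$roughness,
                     hydration = u$hydration,
                     name = sprintf("underlayer%d", i))))
      }
      # bilayer sits on the last underlayer with the (fixed) bilayer roughness
      prev_rough <- bil_rough
    }
    layers <- c(layers, list(
      slab_layer(th$head_thickness, head_sld, roughness = prev_rough,
                 hydration = th$head_hydration, name = "inner_heads"),
      slab_layer(th$tail_thickness, tail_sld, roughness = bilayer_roughness,
                 hydration = tail_hydration, name = "tails"),
      slab_layer(th$head_thickness, head_sld, roughness = bilayer_roughness,
                 hydration = th$head_hydration, name = "outer_heads")))
    slab_sample(layers, superphase_sld = si_sld, substrate_sld = solvent_sld,
                solvent_sld = solvent_sld,
                substrate_roughness = bilayer_roughness, scale = scale,
                background = background, contrast_is_substrate = TRUE,
                name = sprintf("%s-tail bilayer", tails))
  }
  m <- parametric_model(build, theta, lower = lower, upper = upper,
                        name = sprintf("bilayer_%s_tail", tails))
  attr(m, "spec_args") <- args
  m
}

#' Insert or remove underlayers in a bilayer model
#'
#' Rebuilds a [contrast_bilayer()] model with the given underlayers inserted
#' between the native oxide and the inner headgroups. Following the insertion
#' rules, the oxide hydration is forced to 0 and both it and the
#' oxide/bilayer roughness are excluded from the varying (Fisher) parameter
#' set; the underlayer parameters themselves are nuisance parameters and
#' never enter the objective. Calling with an empty list restores the bare
#' model bit-exactly.
#'
#' @param model A model produced by [contrast_bilayer()].
#' @param underlayers List of 0 to 3 [underlayer()]s.
#' @return A new [parametric_model()].
#' @export
add_underlayers <- function(model, underlayers = list()) {
  args <- attr(model, "spec_args")
  if (is.null(args)) {
    stop("'model' must come from contrast_bilayer()", call. = FALSE)
  }
  args$underlayers <- underlayers
  do.call(contrast_bilayer, args)
}

#' Lipid monolayer parameterized by area per molecule
#'
#' An air/water monolayer (tails toward air, hydrated headgroups toward the
#' subphase) whose layer compositions derive from a single area-per-molecule
#' (APM) parameter: the tail layer SLD is `Sigma b_tail / (APM * t_tail)`
#' (the remainder of the layer is air), and the headgroup layer carries a
#' lipid volume fraction `V_head / (APM * t_head)` with the rest solvent
#' (defect plus bound water). Increasing the APM decreases the surface
#' excess. Deuteration swaps the tail scattering length only; molecular
#' volumes are fixed. Scattering lengths and volumes default to
#' literature-typical placeholder values for DPPG.
#'
#' @param deuterated Chain-deuterated tails?
#' @param apm Area per molecule in A^2 (> 0); 54.1 is a typical fitted value
#'   for an intact monolayer.
#' @param tail_b_h,tail_b_d Tail scattering lengths (fm) for the h-/d-
#'   isotopomer.
#' @param tail_volume,head_b,head_volume Molecular volumes (A^3) and head
#'   scattering length (fm).
#' @param tail_thickness,head_thickness Layer thicknesses in Angstrom.
#' @param roughness Interfacial roughness (Angstrom) used at all interfaces.
#' @param solvent_sld Subphase water contrast SLD (1e-6 A^-2).
#' @param molar_mass Lipid molar mass (g/mol), used by [surface_excess()].
#' @param background,scale As in [slab_sample()].
#' @return A single-parameter [parametric_model()] over `apm` with
#'   `spec_args` kept for re-building (see [kinetic_series()]).
#' @export
apm_monolayer <- function(deuterated = FALSE, apm = 54.1,
                          tail_b_h = -32.4, tail_b_d = 613.1,
                          tail_volume = 825, head_b = 60.0,
                          head_volume = 244,
                          tail_thickness = 16, head_thickness = 8,
                          roughness = 3.5, solvent_sld = 0,
                          molar_mass = 722.9,
                          background = 5e-7, scale = 1) {
  args <- as.list(environment())
  if (apm <= 0) stop("'apm' must be > 0", call. = FALSE)
  tail_b <- if (deuterated) tail_b_d else tail_b_h
  build <- function(th) {
    a <- th[["apm"]]
    if (a <= 0) stop("'apm' must be > 0", call. = FALSE)
    phi_t <- min(tail_volume / (a * tail_thickness), 1)
    phi_h <- min(head_volume / (a * head_thickness), 1)
    tail_sld_mat <- tail_b * 1e-5 / tail_volume * 1e6   # Sigma b / V
    layers <- list(
      slab_layer(tail_thickness, phi_t * tail_sld_mat, roughness = roughness,
                 hydration = 0, name = "tails"),
      slab_layer(head_thickness, head_b * 1e-5 / head_volume * 1e6,
                 roughness = roughness, hydration = 1 - phi_h,
                 name = "heads"))
    slab_sample(layers, superphase_sld = 0, substrate_sld = solvent_sld,
                solvent_sld = solvent_sld, substrate_roughness = roughness,
                scale = scale, background = background,
                contrast_is_substrate = TRUE,
                name = sprintf("%s-DPPG monolayer", if (deuterated) "d" else "h"))
  }
  m <- parametric_model(build, c(apm = apm), lower = c(apm = 30),
                        upper = c(apm = 1000),
                        name = if (deuterated) "monolayer_ddppg" else "monolayer_hdppg")
  attr(m, "spec_args") <- args
  attr(m, "molar_mass") <- molar_mass
  m
}

#' Kinetic snapshot series of a degrading monolayer
#'
#' Emulates a monolayer degrading during the measurement by increasing the
#' area per molecule (decreasing surface excess) over a monotone linear grid
#' of `n_steps` values spanning `[apm_start, apm_end]`; each snapshot is a
#' valid single-parameter model evaluated at its own APM.
#'
#' @param model An [apm_monolayer()] model.
#' @param apm_start,apm_end APM range in A^2, `apm_start < apm_end`; the
#'   canonical degradation series runs from a fitted 54.1 up to 500.
#' @param n_steps Number of snapshots, >= 2 (20 is typical).
#' @return List of `n_steps` [parametric_model()]s.
#' @export
kinetic_series <- function(model, apm_start = 54.1, apm_end = 500,
                           n_steps = 20) {
  args <- attr(model, "spec_args")
  if (is.null(args) || !"apm" %in% names(model$theta)) {
    stop("'model' must come from apm_monolayer()", call. = FALSE)
  }
  if (!(apm_start < apm_end) || n_steps < 2) {
    stop("need apm_start < apm_end and n_steps >= 2", call. = FALSE)
  }
  grid <- seq(apm_start, apm_end, length.out = n_steps)
  lapply(grid, function(a) {
    args$apm <- a
    do.call(apm_monolayer, args)
  })
}

#' Magnetic thin-film stack (garnet film with a platinum cap)
#'
#' An yttrium aluminium garnet substrate carrying an yttrium iron garnet film
#' and a platinum capping layer, measured from the air side with a polarized
#' (non-spin-flip) beam. A thin sub-slab of the platinum adjacent to the
#' garnet film carries an induced magnetic SLD; the magnetized sub-slab
#' thickness is fixed at 21 Angstrom regardless of the total platinum
#' thickness, so the total moment in the system does not grow as the cap is
#' thickened (for caps thinner than 21 Angstrom the magnetized slab is capped
#' at the full platinum thickness). The varying Fisher parameter is the
#' induced magnetic SLD itself. Nuclear SLDs default to literature-typical
#' placeholder values.
#'
#' @param yig_thickness Garnet film thickness in Angstrom, design interval
#'   `[400, 900]`.
#' @param pt_thickness Platinum cap thickness in Angstrom, design interval
#'   `[20, 100]`; 21 is the canonical fitted value.
#' @param magnetic_sld Induced magnetic SLD of the magnetized sub-slab
#'   (1e-6 A^-2); 0.0164 corresponds to roughly 0.009 Bohr magnetons per
#'   platinum atom.
#' @param magnetized_thickness Thickness of the magnetized sub-slab
#'   (Angstrom).
#' @param pt_sld,yig_sld,yag_sld Nuclear SLDs (1e-6 A^-2).
#' @param roughness Interfacial roughness (Angstrom).
#' @param background,scale As in [slab_sample()].
#' @return A single-parameter [parametric_model()] over `pt_magnetic_sld`,
#'   with `spec_args` kept for re-building at other thicknesses.
#' @export
magnetic_stack <- function(yig_thickness = 650, pt_thickness = 21,
                           magnetic_sld = 0.0164, magnetized_thickness = 21,
                           pt_sld = 6.36, yig_sld = 5.79, yag_sld = 5.97,
                           roughness = 3, background = 5e-7, scale = 1) {
  args <- as.list(environment())
  build <- function(th) {
    msld <- th[["pt_magnetic_sld"]]
    t_mag <- min(magnetized_thickness, pt_thickness)
    t_cap <- pt_thickness - t_mag
    layers <- list()
    if (t_cap > 0) {
      layers <- c(layers, list(
        slab_layer(t_cap, pt_sld, roughness = roughness, name = "Pt")))
    }
    layers <- c(layers, list(
      slab_layer(t_mag, pt_sld, roughness = if (t_cap > 0) 0 else roughness,
                 magnetic_sld = msld, name = "Pt_magnetized"),
      slab_layer(yig_thickness, yig_sld, roughness = roughness,
                 name = "YIG")))
    slab_sample(layers, superphase_sld = 0, substrate_sld = yag_sld,
                solvent_sld = 0, substrate_roughness = roughness,
                scale = scale, background = background,
                contrast_is_substrate = FALSE, name = "YIG/Pt stack")
  }
  m <- parametric_model(build, c(pt_magnetic_sld = magnetic_sld),
                        name = "yig_pt")
  attr(m, "spec_args") <- args
  m
}

#' Named built-in sample models
#'
#' Registry of the bundled parameterized models:
#' `"bilayer_h_tail"`, `"bilayer_d_tail"` ([contrast_bilayer()]),
#' `"monolayer_hdppg"`, `"monolayer_ddppg"` ([apm_monolayer()]) and
#' `"yig_pt"` ([magnetic_stack()]).
#'
#' @param name Registry name.
#' @param ... Overrides passed to the factory.
#' @return A [parametric_model()].
#' @export
builtin_model <- function(name, ...) {
  switch(name,
    bilayer_h_tail   = contrast_bilayer("h", ...),
    bilayer_d_tail   = contrast_bilayer("d", ...),
    monolayer_hdppg  = apm_monolayer(deuterated = FALSE, ...),
    monolayer_ddppg  = apm_monolayer(deuterated = TRUE, ...),
    yig_pt           = magnetic_stack(...),
    stop(sprintf("unknown built-in model '%s'", name), call. = FALSE))
}
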