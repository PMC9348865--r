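test_that("momentum transfer follows Q = 4 pi sin(theta) / lambda", {
  expect_equal(momentum_transfer(3.5, 0), 0)
  expect_equal(momentum_transfer(4 * pi, 30), 0.5)
  # direct arithmetic oracle
  expect_equal(momentum_transfer(2.5, 0.7), 4 * pi * sin(0.7 * pi / 180) / 2.5)
  # strictly increasing in angle, decreasing in wavelength
  ang <- seq(0.2, 4, by = 0.2)
  expect_true(all(diff(momentum_transfer(2.5, ang)) > 0))
  lam <- seq(1, 14, by = 0.5)
  expect_true(all(diff(momentum_transfer(lam, 0.7)) < 0))
  expect_error(momentum_transfer(-1, 0.5), "wavelength")
  expect_error(momentum_transfer(0, 0.5), "wavelength")
  expect_error(momentum_transfer(2.5, 95), "angle")
})

test_that("degenerate samples reflect as expected", {
  # no contrast anywhere: only the background remains
  s0 <- slab_sample(list(slab_layer(50, 3, roughness = 2, hydration = 0.3)),
                    superphase_sld = 3, substrate_sld = 3, solvent_sld = 3,
                    background = 1e-6, contrast_is_substrate = FALSE)
  expect_equal(reflectivity(s0, c(0.01, 0.05, 0.2)), rep(1e-6, 3))
  # total external reflection below the critical edge
  s1 <- slab_sample(substrate_sld = 6.36, superphase_sld = 2.07,
                    scale = 0.9, background = 1e-6,
                    contrast_is_substrate = FALSE)
  qc <- critical_edge(2.07, 6.36)
  expect_equal(reflectivity(s1, qc * c(0.3, 0.6, 0.95)),
               rep(0.9 + 1e-6, 3), tolerance = 1e-12)
  expect_error(reflectivity(s1, numeric(0)), "non-empty")
  expect_error(slab_layer(-5, 2), "thickness")
  expect_error(slab_layer(5, 2, hydration = 1.2), "hydration")
})

test_that("Abeles kernel matches an independent Parratt recursion", {
  set.seed(101)
  q <- exp(seq(log(0.005), log(0.4), length.out = 60))
  for (rep in 1:100) {
    s <- random_stack()
    geo <- sample_geometry(s)
    oracle <- parratt_reflectivity(q, effective_slds(s), geo$thicknesses,
                                   geo$roughnesses)
    got <- reflectivity(s, q)
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("reflectivity is reciprocal under stack reversal at zero roughness", {
  # reciprocity holds at equal free-space normal wavevector; the kernel's Q
  # lives in the incident medium, so map the common vacuum k_z into each
  # superphase before comparing
  set.seed(7)
  kvac <- seq(0.02, 0.15, length.out = 40)
  q_in_medium <- function(k, sup_sld) 2 * sqrt(k^2 - 4 * pi * sup_sld * 1e-6)
  for (rep in 1:10) {
    layers <- lapply(1:3, function(i) slab_layer(runif(1, 10, 150),
                                                 runif(1, 0, 8)))
    fwd <- slab_sample(layers, superphase_sld = 1, substrate_sld = 5,
                       solvent_sld = 0, contrast_is_substrate = FALSE)
    bwd <- slab_sample(rev(layers), superphase_sld = 5, substrate_sld = 1,
                       solvent_sld = 0, contrast_is_substrate = FALSE)
    expect_equal(reflectivity(fwd, q_in_medium(kvac, 1)),
                 reflectivity(bwd, q_in_medium(kvac, 5)),
                 tolerance = 1e-9)
  }
})

test_that("bare interface decays monotonically to Fresnel Q^-4 asymptotics", {
  s <- slab_sample(substrate_sld = 6.36, superphase_sld = 0,
                   contrast_is_substrate = FALSE)
  qc <- critical_edge(0, 6.36)
  q <- seq(qc * 1.05, qc * 12, length.out = 300)
  r <- reflectivity(s, q)
  expect_true(all(diff(r) < 0))
  expect_equal(reflectivity(s, 10 * qc), (qc / (2 * 10 * qc))^4,
               tolerance = 0.01)
})

test_that("spin channels reduce to nuclear SLD shifts", {
  mag <- slab_layer(30, 6.36, roughness = 2, magnetic_sld = 0.5)
  s <- slab_sample(list(mag, slab_layer(600, 5.79, roughness = 3)),
                   superphase_sld = 0, substrate_sld = 5.97,
                   solvent_sld = 0, substrate_roughness = 3,
                   contrast_is_substrate = FALSE)
  q <- seq(0.01, 0.25, length.out = 50)
  # with zero moment both channels equal the unpolarized curve exactly
  s0 <- s; s0$layers[[1]]$magnetic_sld <- 0
  expect_identical(reflectivity(s0, q, spin = "up"), reflectivity(s0, q))
  expect_identical(reflectivity(s0, q, spin = "down"), reflectivity(s0, q))
  # up/down equal unpolarized curves of nuclear +/- magnetic samples
  sp <- s; sp$layers[[1]]$magnetic_sld <- 0; sp$layers[[1]]$sld <- 6.36 + 0.5
  sm <- s; sm$layers[[1]]$magnetic_sld <- 0; sm$layers[[1]]$sld <- 6.36 - 0.5
  expect_equal(reflectivity(s, q, spin = "up"), reflectivity(sp, q))
  expect_equal(reflectivity(s, q, spin = "down"), reflectivity(sm, q))
  expect_false(isTRUE(all.equal(reflectivity(s, q, spin = "up"),
                                reflectivity(s, q, spin = "down"))))
})

test_that("Gaussian smearing conserves constants and matches dense quadrature", {
  expect_equal(smear(function(q) rep(3.7, length(q)), c(0.01, 0.1, 0.3), 0.05),
               rep(3.7, 3))
  s <- toy_one_layer()
  q <- exp(seq(log(0.008), log(0.3), length.out = 40))
  expect_identical(smear(function(qq) reflectivity(s, qq), q, 0),
                   reflectivity(s, q))
  bare <- function(qq) reflectivity(s, qq)
  got <- smear(bare, q, 0.02)
  oracle <- dense_smear(bare, q, 0.02, n = 601)
  expect_equal(got, oracle, tolerance = 1e-6)
  # background is flat, so smearing before or after adding it coincides
  expect_equal(reflectivity_smeared(s, q, 0.02), got, tolerance = 1e-12)
  expect_error(smear(bare, q, 1.2), "dq_over_q")
})
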