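# A sample whose scale factor is the single varying parameter gives
# lambda = theta * c per bin, the one-bin Poisson closed form FI = c / theta.
test_that("single linear parameter reproduces the closed-form Poisson FI", {
  fx <- test_flux()
  s <- toy_one_layer(background = 0)
  s$scale <- 0.7
  m <- vary_parameters(s, c(scale = "scale"))
  cond <- measurement_condition(0.7, 1000, n_points = 1)
  fr <- fisher_matrix(m, cond, fx)
  cm <- expected_counts(s, cond, fx)
  cc <- cm$expected / 0.7            # lambda = theta * cc
  expect_equal(fr$raw_matrix[1, 1], cc / 0.7, tolerance = 1e-9)
})

test_that("the FI is exactly linear in counting time and additive", {
  fx <- test_flux()
  m <- vary_parameters(toy_one_layer(),
                       c(thickness = "layer1.thickness", sld = "layer1.sld"))
  c1 <- measurement_condition(0.7, 1000, n_points = 30)
  c2 <- measurement_condition(2.3, 4000, n_points = 30)
  g1 <- fisher_matrix(m, c1, fx)$raw_matrix
  g2 <- fisher_matrix(m, c2, fx)$raw_matrix
  both <- fisher_matrix(m, list(c1, c2), fx)$raw_matrix
  expect_equal(both, g1 + g2, tolerance = 1e-12)
  c1x2 <- measurement_condition(0.7, 2000, n_points = 30)
  expect_equal(fisher_matrix(m, c1x2, fx)$raw_matrix, 2 * g1,
               tolerance = 1e-12)
})

test_that("importance scaling is the expected congruence transform", {
  set.seed(31)
  a <- matrix(rnorm(25), 5)
  g <- crossprod(a)  # random symmetric PSD
  expect_equal(importance_scale(g, rep(1, 5)), g)
  w <- runif(5, 0.5, 3)
  s1 <- importance_scale(g, w)
  expect_equal(s1, diag(w) %*% g %*% diag(w))
  w2 <- w; w2[3] <- 2 * w[3]
  s2 <- importance_scale(g, w2)
  expect_equal(s2[3, 3], 4 * s1[3, 3])
  expect_equal(s2[3, -3], 2 * s1[3, -3])
  expect_error(importance_scale(g, c(w[-5], -1)), "positive")
  # eigenvalues match a brute-force eigensolve of D G D
  expect_equal(sort(eigen(diag(w) %*% g %*% diag(w))$values),
               sort(eigen(s1)$values))
})

test_that("minimum eigenvalue agrees with characteristic-polynomial roots", {
  expect_equal(min_eigenvalue(diag(2)), 1)
  expect_equal(min_eigenvalue(diag(c(4, 9))), 4)
  set.seed(77)
  for (i in 1:5) {
    a <- matrix(rnorm(25), 5)
    g <- crossprod(a)
    cp <- pracma::charpoly(g)
    roots <- Re(polyroot(rev(cp)))
    expect_equal(min_eigenvalue(g), min(roots), tolerance = 1e-8)
  }
})

test_that("Cramer-Rao bounds behave under diagonal FI and time scaling", {
  fx <- test_flux()
  m <- vary_parameters(toy_one_layer(),
                       c(thickness = "layer1.thickness", sld = "layer1.sld"))
  fr1 <- fisher_matrix(m, measurement_condition(0.7, 100, n_points = 30), fx)
  fr100 <- fisher_matrix(m, measurement_condition(0.7, 10000, n_points = 30),
                         fx)
  expect_equal(fr100$eigenvalues, 100 * fr1$eigenvalues, tolerance = 1e-9)
  u1 <- crb_uncertainties(fr1)
  u100 <- crb_uncertainties(fr100)
  expect_equal(u1$worst_combination / u100$worst_combination, 10,
               tolerance = 1e-9)
  # diagonal FI: sigma_i = G_ii^(-1/2) exactly
  g <- diag(c(16, 25))
  fr <- refdesign:::new_fisher_result(g, c(1, 1),
                                      c(a = 1, b = 1))
  expect_equal(unname(crb_uncertainties(fr)$per_parameter), c(1 / 4, 1 / 5))
})

test_that("min eigenvalue is invariant under parameter reordering", {
  fx <- test_flux()
  s <- toy_one_layer()
  cond <- measurement_condition(0.7, 1000, n_points = 30)
  f1 <- fisher_matrix(vary_parameters(s, c(t = "layer1.thickness",
                                           s = "layer1.sld",
                                           b = "background")), cond, fx)
  f2 <- fisher_matrix(vary_parameters(s, c(b = "background",
                                           t = "layer1.thickness",
                                           s = "layer1.sld")), cond, fx)
  expect_equal(f1$min_eigenvalue, f2$min_eigenvalue, tolerance = 1e-10)
})

test_that("finite-difference steps are adequate on the bundled models", {
  fx <- test_flux()
  cond <- measurement_condition(0.7, 1000, n_points = 25)
  models <- list(contrast_bilayer("h"), contrast_bilayer("d"),
                 apm_monolayer(), magnetic_stack())
  conds <- list(measurement_condition(0.7, 1000, 25, contrast_sld = 6.36),
                measurement_condition(0.7, 1000, 25, contrast_sld = -0.56),
                measurement_condition(0.8, 1000, 25, contrast_sld = 0),
                measurement_condition(1.0, 1000, 25, spin = "up"))
  for (i in seq_along(models)) {
    g1 <- fisher_matrix(models[[i]], conds[[i]], fx, importance = NULL,
                        step_rel = 1e-3)$raw_matrix
    g2 <- fisher_matrix(models[[i]], conds[[i]], fx, importance = NULL,
                        step_rel = 5e-4)$raw_matrix
    expect_equal(g1, g2, tolerance = 1e-3)
  }
})

test_that("non-identifiable parameters are flagged by name", {
  fx <- test_flux()
  s <- toy_one_layer()
  m <- vary_parameters(s, c(solvent = "solvent_sld"))
  # solvent_sld is inert here (no hydrated layer): gradient is zero, matrix
  # singular; per-parameter bounds unbounded but worst-combination returned
  fr <- fisher_matrix(m, measurement_condition(0.7, 1000, n_points = 10), fx)
  expect_equal(fr$raw_matrix[1, 1], 0)
  expect_warning(u <- crb_uncertainties(fr), "singular")
  expect_true(is.infinite(u$per_parameter[[1]]))
  expect_true(is.infinite(u$worst_combination))
})

test_that("kinetic information adds over snapshots", {
  fx <- test_flux()
  mono <- apm_monolayer()
  cond <- measurement_condition(0.8, 450, n_points = 20, contrast_sld = 0)
  single <- fisher_matrix(mono, cond, fx, importance = 1)$raw_matrix[1, 1]
  expect_equal(kinetic_fisher(list(mono), cond, fx), single,
               tolerance = 1e-12)
  expect_equal(kinetic_fisher(list(mono, mono), cond, fx), 2 * single,
               tolerance = 1e-12)
  expect_error(kinetic_fisher(list(), cond, fx), "empty")
  # 20-snapshot series vs explicit per-snapshot hand summation
  series <- kinetic_series(mono, 54.1, 500, 20)
  total <- kinetic_fisher(series, cond, fx)
  hand <- 0
  for (snap in series) {
    cells <- refdesign:::.condition_cells(list(cond), fx, NULL)
    lam <- refdesign:::.lambda_from_cells(snap, snap$theta, cells, 0.02)
    h <- 1e-3 * abs(snap$theta[[1]])
    tp <- snap$theta; tp[[1]] <- tp[[1]] + h
    tm <- snap$theta; tm[[1]] <- tm[[1]] - h
    g <- (refdesign:::.lambda_from_cells(snap, tp, cells, 0.02) -
          refdesign:::.lambda_from_cells(snap, tm, cells, 0.02)) / (2 * h)
    hand <- hand + sum(g[lam > 0]^2 / lam[lam > 0])
  }
  expect_equal(total, hand, tolerance = 1e-10)
})
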