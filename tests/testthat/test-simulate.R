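test_that("expected counts are linear in counting time", {
  fx <- test_flux()
  s <- toy_one_layer()
  mk <- function(t) expected_counts(s, measurement_condition(0.7, t,
                                                             n_points = 40), fx)
  expect_equal(mk(0)$expected, rep(0, 40))
  c1 <- mk(500); c2 <- mk(1000)
  expect_equal(c2$expected, 2 * c1$expected, tolerance = 1e-14)
  expect_true(all(c1$expected >= 0))
  expect_equal(c1$expected, c1$incident * c1$r_model)
})

test_that("total reflection pins expected counts to the incident counts", {
  fx <- test_flux()
  bare <- slab_sample(substrate_sld = 6.36, superphase_sld = 0,
                      scale = 0.8, background = 1e-6,
                      contrast_is_substrate = FALSE)
  cond <- measurement_condition(0.25, 1000, n_points = 30)
  cm <- expected_counts(bare, cond, fx)
  qc <- critical_edge(0, 6.36)
  below <- cm$q < 0.9 * qc
  expect_true(any(below))
  expect_equal(cm$expected[below],
               cm$incident[below] * (0.8 + 1e-6), tolerance = 1e-9)
})

test_that("Poisson realization is reproducible and has correct moments", {
  fx <- test_flux()
  s <- toy_one_layer()
  cond <- measurement_condition(0.7, 2000, n_points = 20)
  cm <- expected_counts(s, cond, fx)
  d1 <- realize(cm, seed = 99)
  d2 <- realize(cm, seed = 99)
  expect_identical(d1, d2)
  expect_error(realize(cm), "seed")
  # zero expectation realizes to exactly zero
  cm0 <- expected_counts(s, measurement_condition(0.7, 0, n_points = 20), fx)
  expect_equal(realize(cm0, seed = 1)$r, rep(0, 20))
  # sample mean of n_k within 3 sigma of lambda_k over 10000 realizations
  set.seed(123)
  lam <- cm$expected
  nrep <- 10000
  draws <- matrix(rpois(nrep * length(lam), rep(lam, each = nrep)), nrow = nrep)
  mns <- colMeans(draws)
  expect_true(all(abs(mns - lam) <= 3 * sqrt(lam / nrep) + 1e-9))
  # dr uses the one-count floor on empty bins
  dz <- realize(expected_counts(s, measurement_condition(0.7, 1e-6,
                                                         n_points = 20), fx),
                seed = 2)
  expect_true(all(is.finite(dz$dr) & dz$dr > 0))
})

test_that("simulated uncertainties shrink as one over sqrt(time)", {
  fx <- test_flux()
  s <- toy_one_layer()
  times <- c(500, 2000, 8000, 32000)
  med_dr <- sapply(times, function(t) {
    cm <- expected_counts(s, measurement_condition(0.7, t, n_points = 30), fx)
    drs <- sapply(1:200, function(i) median(realize(cm, seed = i)$dr))
    mean(drs)
  })
  ratio <- med_dr[-4] / med_dr[-1]  # expect ~2 per 4x time step
  expect_equal(ratio, rep(2, 3), tolerance = 0.1)
})

test_that("datasets round-trip through 3/4-column ASCII", {
  fx <- test_flux()
  s <- toy_one_layer()
  cm <- expected_counts(s, measurement_condition(2.3, 3600, n_points = 25,
                                                 contrast_sld = 2.07), fx)
  d <- realize(cm, seed = 4)
  path <- withr::local_tempfile(fileext = ".dat")
  write_refl_dat(d, path)
  back <- read_refl_dat(path)
  expect_equal(back$q, d$q)
  expect_equal(back$r, d$r)
  expect_equal(back$dr, d$dr)
  expect_equal(back$dq, d$dq)
  md <- attr(back, "metadata")
  expect_equal(md$angle, 2.3)
  expect_equal(md$time, 3600)
  expect_equal(md$seed, 4)
  expect_identical(md$spin, "unpolarized")
  # 3-column file: dq treated as absent
  writeLines(c("# three columns", "0.01 0.9 0.01", "0.02 0.5 0.005"), path)
  d3 <- read_refl_dat(path)
  expect_null(d3$dq)
  expect_equal(d3$r, c(0.9, 0.5))
  # malformed line reported with its line number
  writeLines(c("# hdr", "0.01 0.9 0.01", "0.02 oops 0.005"), path)
  expect_error(read_refl_dat(path), "line 3")
})

test_that("a conventional 4-column .dat fixture parses", {
  path <- system.file("extdata", "synthetic_bilayer_d2o.dat",
                      package = "refdesign")
  d <- read_refl_dat(path)
  expect_s3_class(d, "refl_dataset")
  expect_equal(nrow(d), 10)
  expect_equal(d$q[1], 0.0112)
  expect_true(all(d$dr > 0))
  expect_equal(d$dq / d$q, rep(0.02, 10), tolerance = 1e-3)
})

test_that("multi-condition simulation returns one dataset per condition", {
  fx <- test_flux()
  s <- toy_one_layer()
  conds <- build_conditions(contrasts = c(6.36, -0.56),
                            contrast_fractions = c(1, 1),
                            angles = c(0.7, 2.3), angle_fractions = c(15, 60),
                            budget = 4500, n_points = 15)
  expect_length(conds, 4)
  expect_equal(sum(vapply(conds, `[[`, numeric(1), "time")), 4500)
  ds <- simulate_experiment(s, conds, fx, seed = 10)
  expect_length(ds, 4)
  expect_identical(attr(ds[[2]], "metadata")$seed, 11)
})
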