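test_that("cooperative activity matches the sequential-binding partition
           function", {
  expect_equal(cooperative_activity(1, 1), 1 - (1 / 2)^3)
  expect_equal(cooperative_activity(0, 0.3), 1)
  # brute-force Boltzmann sum over the 8 promoter microstates
  brute <- function(x, c) {
    j <- vapply(0:7, function(s) sum(as.integer(intToBits(s)[1:3])), 0L)
    w <- x^j / c^(j * (j - 1) / 2)
    1 - sum(w[j == 3]) / sum(w)
  }
  for (x in c(0.5, 2, 7)) for (cc in c(1, 0.1, 0.01))
    expect_equal(cooperative_activity(x, cc), brute(x, cc),
                 tolerance = 1e-12)
  # and against the stationary promoter marginal of the CME
  p <- with_load(preset_params("cooperative"), 2)
  ss <- steady_state(switch_model(p), M_max = 0L)
  expect_equal(ss$activity, cooperative_activity(2, p$c),
               tolerance = 1e-10)
})

test_that("independent sites reduce to 1 - (x/(1+x))^3", {
  x <- exp(seq(log(1e-3), log(1e3), length.out = 50))
  expect_equal(cooperative_activity(x, 1), 1 - (x / (1 + x))^3,
               tolerance = 1e-12)
})

test_that("EC thresholds solve classic response curves", {
  x <- exp(seq(log(1e-3), log(1e3), length.out = 2000))
  mm <- data.frame(Rt_tilde = x, activity = 1 / (1 + x))
  ec <- ec_thresholds(mm, relative = FALSE)
  expect_equal(unname(ec), c(1 / 9, 9), tolerance = 1e-3)
  expect_equal(effective_hill(ec[["EC90"]], ec[["EC10"]]), 1,
               tolerance = 1e-3)
  h3 <- data.frame(Rt_tilde = x, activity = 1 / (1 + x^3))
  ec3 <- ec_thresholds(h3, relative = FALSE)
  expect_equal(unname(ec3), c((1 / 9)^(1 / 3), 9^(1 / 3)),
               tolerance = 1e-3)
  expect_equal(effective_hill(ec3[["EC90"]], ec3[["EC10"]]), 3,
               tolerance = 1e-3)
})

test_that("the three-site non-cooperative curve gives EC90 ~ 0.866,
           EC10 ~ 27.98, n_eff ~ 1.26", {
  # independent oracle: root-finding on the closed form
  f <- function(x) 1 - (x / (1 + x))^3
  e90 <- uniroot(function(x) f(x) - 0.9, c(1e-3, 10), tol = 1e-12)$root
  e10 <- uniroot(function(x) f(x) - 0.1, c(1, 1e3), tol = 1e-12)$root
  expect_equal(e90, 0.866, tolerance = 1e-3)
  expect_equal(e10, 27.98, tolerance = 1e-3)
  h <- hill_summary(preset_params("cooperative_noncooperative"))
  expect_equal(h$EC90, e90, tolerance = 1e-4)
  expect_equal(h$EC10, e10, tolerance = 1e-4)
  expect_equal(h$n_eff, log(81) / log(e10 / e90), tolerance = 1e-4)
  expect_equal(h$n_eff, 1.2646, tolerance = 1e-4)
})

test_that("effective_hill validates its domain", {
  expect_error(effective_hill(2, 1), "EC90 < EC10")
  expect_error(effective_hill(-1, 2), "EC90 < EC10")
})

test_that("deep-titration limits switch sharply at the molar ratio", {
  p <- params_from_normalized("sequestration",
                              list(Ka_tilde = 1e-4, Ks_tilde = 1e-8),
                              A_T = 100)
  expect_equal(sequestration_activity(p, 0.5), 1, tolerance = 1e-3)
  expect_equal(sequestration_activity(p, 1.5), 0, tolerance = 1e-3)
})

test_that("mean-field activity agrees with the exact CME marginal to 2%
           for A_T = 100", {
  for (ka in 10^(-3:-1)) for (ks in 10^(-3:-1)) {
    p <- params_from_normalized("sequestration",
                                list(Ka_tilde = ka, Ks_tilde = ks),
                                A_T = 100)
    mf <- sequestration_activity(p, 0.9)
    cme <- steady_state(switch_model(with_load(p, 0.9)),
                        M_max = 0L)$activity
    expect_lt(abs(mf - cme) / cme, 0.02)
  }
})

test_that("activity curves are monotone non-increasing for every
           architecture", {
  presets <- c("cooperative", "cooperative_noncooperative",
               "sequestration_strong", "sequestration_weak",
               "sequestration_blocking",
               "sequestration_blocking_displacement")
  for (nm in presets) {
    cur <- activity_curve(preset_params(nm))
    expect_true(all(diff(cur$activity) <= 1e-8), info = nm)
    expect_true(all(cur$activity >= 0 & cur$activity <= 1), info = nm)
  }
})

test_that("cooperativity sharpens the transition monotonically", {
  n <- vapply(c(1, 0.3, 0.1, 0.03, 0.01), function(cc)
    hill_summary(preset_params("cooperative", c = cc))$n_eff, 0)
  expect_true(all(diff(n) > 0))
})

test_that("stronger activators sharpen the sequestration switch", {
  n <- vapply(c(10, 0.1, 0.02, 5e-3), function(ka)
    hill_summary(params_from_normalized(
      "sequestration", list(Ka_tilde = ka, Ks_tilde = 2.5e-5),
      A_T = 100))$n_eff, 0)
  expect_true(all(diff(n) > 0))
})

test_that("threshold search extends the grid when a target is not
           bracketed", {
  # a soft switch whose EC10 lies beyond the default [0, 2] load range
  p <- params_from_normalized("sequestration",
                              list(Ka_tilde = 0.1, Ks_tilde = 0.05),
                              A_T = 50)
  expect_error(ec_thresholds(activity_curve(p)), "extend")
  h <- hill_summary(p)
  expect_gt(h$EC10, 2)
  expect_true(is.finite(h$n_eff))
})

test_that("cme backend activity curve matches mean-field on a coarse
           grid", {
  p <- strong_preset()
  loads <- c(0.2, 0.8, 1.1)
  cur <- activity_curve(p, loads, backend = "cme")
  mf <- sequestration_activity(p, loads)
  expect_equal(cur$activity, mf, tolerance = 0.05)
})
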