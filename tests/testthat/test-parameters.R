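test_that("missing required constants are reported by name", {
  expect_error(switch_params("sequestration", K_a = 1, A_T = 10),
               "K_s")
  expect_error(switch_params("cooperative_binding", K_r = 10),
               "\\bc\\b")
  expect_error(switch_params("sequestration_blocking", K_a = 1, K_s = 1,
                             A_T = 10), "K_b")
  expect_error(switch_params("sequestration_blocking_displacement",
                             K_a = 1, K_s = 1, K_b = 1, A_T = 10), "K_d")
})

test_that("parameter validation enforces positivity and c <= 1", {
  expect_error(switch_params("cooperative_binding", K_r = 10, c = 1.5),
               "c must satisfy")
  expect_error(switch_params("cooperative_binding", K_r = -1, c = 0.5),
               "strictly positive")
  expect_error(switch_params("sequestration", K_a = 1, K_s = 0, A_T = 10),
               "strictly positive")
  expect_error(switch_params("sequestration", K_a = 1, K_s = 1,
                             A_T = 10.5), "non-negative integer")
  expect_error(
    with_load(switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10),
              -1))
})

test_that("irrelevant constants are ignored with a warning", {
  expect_warning(
    p <- switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                       c = 0.5),
    "\\bc\\b.*irrelevant")
  expect_null(p$c)
})

test_that("normalization is a bijection given the copy-number scale", {
  p <- switch_params("sequestration_blocking_displacement",
                     K_a = 0.05, K_s = 0.001, K_b = 1, K_d = 1000,
                     A_T = 100, R_T = 95)
  n <- normalized_params(p)
  expect_equal(n$Rt_tilde, 0.95)
  expect_equal(n$Ka_tilde, 5e-4)
  expect_equal(n$Kd_tilde, 10)
  q <- params_from_normalized(p$architecture, n, A_T = 100)
  for (k in c("K_a", "K_s", "K_b", "K_d", "A_T", "R_T"))
    expect_equal(q[[k]], p[[k]], info = k)
})

test_that("with_load rounds copy numbers for titration, not for the
           cooperative reservoir", {
  p <- with_load(switch_params("sequestration", K_a = 1, K_s = 1,
                               A_T = 10), 0.94)
  expect_identical(p$R_T, 9)
  pc <- with_load(switch_params("cooperative_binding", K_r = 20, c = 0.5),
                  0.94)
  expect_equal(pc$R_T, 18.8)
})

test_that("with_load under turnover calibrates the production rate", {
  p <- switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                     turnover = list(r_prod = 1, r_deg = 0.2))
  p <- with_load(p, 1.5)
  expect_equal(p$turnover$r_prod / p$turnover$r_deg, 15)
})

test_that("displacement cycle gap detects detailed balance", {
  gap <- function(Ka, Kb, Ks, Kd)
    thermo_cycle_gap(switch_params("sequestration_blocking_displacement",
                                   K_a = Ka, K_s = Ks, K_b = Kb, K_d = Kd,
                                   A_T = 10))
  expect_equal(gap(1, 1, 1, 1), 1.0)
  expect_equal(gap(0.01, 1, 0.01, 1), 1.0)
  expect_equal(gap(0.01, 0.1, 0.001, 10), 0.1)
  expect_error(thermo_cycle_gap(tiny_seq()), "displacement")
})

test_that("presets load from the shipped configuration", {
  p <- preset_params("sequestration_strong")
  expect_s3_class(p, "switch_params")
  expect_equal(normalized_params(p)$Ka_tilde, 5e-3)
  expect_error(preset_params("nope"), "unknown preset")
  # overrides pass through
  p2 <- preset_params("cooperative", c = 0.5)
  expect_equal(p2$c, 0.5)
})

test_that("turnover specification is validated", {
  expect_error(switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                             turnover = list(r_prod = 1)), "r_deg")
  expect_error(switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                             turnover = list(r_prod = 1, r_deg = -1)),
               "positive")
  expect_error(switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                             turnover = list(r_prod = 1, r_deg = 1,
                                             typo = TRUE)), "typo")
  p <- switch_params("sequestration", K_a = 1, K_s = 1, A_T = 10,
                     turnover = list(r_prod = 1, r_deg = 1))
  expect_true(p$turnover$deg_complex)
})
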