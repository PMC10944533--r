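test_that("state enumeration is exhaustive and matches hand counts", {
  # sequestration, A_T = R_T = 10: E_F admits n_RA 0..10, E_A 0..9
  m <- switch_model(tiny_seq())
  sp <- enumerate_states(m, M_max = 50)
  expect_equal(sp$n, 21L * 51L)
  expect_false(anyDuplicated(sp$keys) > 0)
  # cooperative: 8 promoter states x 51 mRNA levels
  mc <- switch_model(with_load(preset_params("cooperative"), 0.5))
  expect_equal(enumerate_states(mc, 50)$n, 408L)
  # M_max = 0 keeps only the promoter/complex core
  expect_equal(enumerate_states(mc, 0)$n, 8L)
  expect_equal(enumerate_states(m, 0)$n, 21L)
})

test_that("enumeration errors above the state cap", {
  m <- switch_model(tiny_seq())
  expect_error(enumerate_states(m, M_max = 50, max_states = 100),
               "reduce")
})

test_that("generator columns sum to zero", {
  for (p in tiny_all_models()) {
    m <- switch_model(p)
    sp <- enumerate_states(m, M_max = 20)
    Q <- build_generator(m, sp)
    expect_lt(max(abs(Matrix::colSums(Q))), 1e-12)
  }
})

test_that("a birth-death process yields a tridiagonal generator", {
  m <- constitutive_model(10, 1)
  sp <- enumerate_states(m, M_max = 30)
  Q <- as.matrix(build_generator(m, sp))
  off <- abs(row(Q) - col(Q)) > 1
  expect_true(all(Q[off] == 0))
})

test_that("equilibrium networks satisfy detailed balance; a driven
           displacement cycle does not", {
  flux_asym <- function(p) {
    m <- switch_model(p)
    sp <- enumerate_states(m, M_max = 0)
    Q <- as.matrix(build_generator(m, sp))
    diag(Q) <- 0
    ss <- steady_state(m, M_max = 0)
    F <- Q %*% diag(ss$p)
    max(abs(F - t(F))) / max(F)
  }
  expect_lt(flux_asym(tiny_seq("sequestration")), 1e-9)
  expect_lt(flux_asym(tiny_seq("sequestration_blocking")), 1e-9)
  # balanced cycle: K_a K_b = K_s K_d
  p_bal <- tiny_seq("sequestration_blocking_displacement",
                    K_a = 0.5, K_s = 0.05, K_b = 0.2, K_d = 2)
  expect_equal(thermo_cycle_gap(p_bal), 1)
  expect_lt(flux_asym(p_bal), 1e-9)
  # driven cycle
  p_drv <- tiny_seq("sequestration_blocking_displacement",
                    K_a = 0.5, K_s = 0.05, K_b = 0.2, K_d = 20)
  expect_gt(flux_asym(p_drv), 1e-3)
})

test_that("the engine reproduces the Poisson stationary law exactly", {
  ss <- steady_state(constitutive_model(10, 1))
  pois <- dpois(seq_along(ss$marginal) - 1, 10)
  expect_lt(max(abs(ss$marginal - pois / sum(pois))), 1e-9)
  ns <- noise_summary(ss)
  expect_equal(ns$fano, 1, tolerance = 1e-8)
  expect_equal(ns$cv, 1 / sqrt(10), tolerance = 1e-6)
  expect_equal(ns$n_modes, 1L)
})

test_that("the engine reproduces the telegraph closed form exactly", {
  k_on <- 1; k_off <- 1; alpha <- 10; beta <- 1
  ss <- steady_state(telegraph_model(k_on, k_off, alpha, beta))
  ns <- noise_summary(ss)
  mean_th <- alpha / beta * k_on / (k_on + k_off)
  fano_th <- 1 + alpha * k_off /
    ((k_on + k_off) * (k_on + k_off + beta))
  expect_equal(ns$mean, mean_th, tolerance = 1e-8)
  expect_equal(ns$fano, fano_th, tolerance = 1e-8)
  expect_equal(fano_th, 8 / 3)
})

test_that("doubling the truncation leaves the moments unchanged", {
  p <- with_load(strong_preset(), 1.05)
  m <- switch_model(p)
  s1 <- steady_state(m)
  s2 <- steady_state(m, M_max = 2L * s1$M_max)
  n1 <- noise_summary(s1); n2 <- noise_summary(s2)
  expect_lt(abs(n1$mean - n2$mean), 1e-6)
  expect_lt(abs(n1$fano - n2$fano), 1e-6)
  expect_lt(s1$tail_mass, 1e-8)
})

test_that("an infeasible truncation is reported with advice", {
  p <- with_load(strong_preset(), 0.5)
  expect_error(steady_state(switch_model(p), M_max = 3L,
                            auto_truncate = FALSE),
               "M_max")
})

test_that("mode counting merges plateaus and applies the mass floor", {
  ns <- noise_summary(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(ns$n_modes, 1L)
  mix <- 0.5 * c(1, rep(0, 40)) + 0.5 * dpois(0:40, 20)
  expect_equal(noise_summary(mix)$n_modes, 2L)
  # a bump below the mass floor is not a mode
  tiny_bump <- c(0.9, 0.05, 1e-5, 2e-5, 1e-5)
  expect_equal(noise_summary(tiny_bump)$n_modes, 1L)
  expect_equal(noise_summary(tiny_bump, min_peak = 1e-6)$n_modes, 2L)
})

test_that("degenerate mRNA marginals are flagged", {
  ns <- noise_summary(c(1, 0, 0))   # all mass at zero
  expect_equal(ns$mean, 0)
  expect_equal(ns$fano, 1)          # Poisson limit when variance is zero
  expect_true(is.na(ns$cv))
})

test_that("fano_curve identifies the failing load", {
  p <- strong_preset()
  expect_error(fano_curve(p, c(0.5), M_max = 3L, auto_truncate = FALSE),
               "Rt_tilde = 0.5")
  fc <- fano_curve(p, c(0.9, 1.05))
  expect_equal(fc$Rt_tilde, c(0.9, 1.05))
  expect_true(all(fc$fano > 0))
})
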