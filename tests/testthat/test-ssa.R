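test_that("identical seeds give identical trajectories", {
  m <- switch_model(tiny_seq())
  t1 <- simulate(m, seed = 42, t_end = 100)
  t2 <- simulate(m, seed = 42, t_end = 100)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  t3 <- simulate(m, seed = 43, t_end = 100)
  expect_false(identical(t1$times, t3$times))
})

test_that("stationary estimates recover known birth-death moments", {
  m <- constitutive_model(10, 1)
  tr <- simulate(m, seed = 7, t_end = 3000)
  est <- stationary_estimate(tr)
  expect_lt(abs(est$mean - 10), 3 * est$se_mean)
  expect_lt(abs(est$fano - 1), 3 * est$se_fano)
  expect_gte(est$n_batches, 20L)
  expect_true(all(c(est$se_mean, est$se_fano) > 0))
})

test_that("stationary estimates recover the telegraph Fano factor", {
  m <- telegraph_model(1, 1, 10, 1)
  est <- ssa_stationary(m, t_end = 20000, seed = 11)
  expect_lt(abs(est$mean - 5), 3 * est$se_mean)
  expect_lt(abs(est$fano - 8 / 3), 3 * est$se_fano)
})

test_that("streaming and logged estimators agree on the same trajectory", {
  m <- switch_model(with_load(strong_preset(), 1.05))
  est_s <- ssa_stationary(m, t_end = 4000, burn_in = 400, seed = 5)
  tr <- simulate(m, seed = 5, t_end = 4000)
  est_l <- stationary_estimate(tr, burn_in = 400)
  expect_equal(est_l$mean, est_s$mean, tolerance = 1e-8)
  expect_equal(est_l$variance, est_s$variance, tolerance = 1e-8)
  expect_equal(est_l$fano, est_s$fano, tolerance = 1e-8)
})

test_that("estimation contracts are enforced", {
  m <- constitutive_model(5, 1)
  tr <- simulate(m, seed = 1, t_end = 50)
  expect_error(stationary_estimate(tr, burn_in = 100), "burn_in")
  expect_error(stationary_estimate(tr, n_batches = 5), "20 batches")
  expect_error(ssa_stationary(m, t_end = 100, n_batches = 5), "n_batches")
})

test_that("noise-induced activation during repression produces large
           mRNA excursions (strong activator)", {
  p <- with_load(strong_preset(), 1.1)
  tr <- simulate(switch_model(p), seed = 4, t_end = 3000)
  est <- stationary_estimate(tr)
  m_idx <- match("M", tr$model$species)
  expect_gt(max(tr$states[, m_idx]), 10 * est$mean)
})

test_that("occupancy timeline collapses events into dwell intervals", {
  m <- constitutive_model(5, 1)
  tr <- simulate(m, seed = 2, t_end = 100)
  ot <- occupancy_timeline(tr)
  expect_equal(nrow(ot$intervals), 1L)   # promoter never switches
  expect_equal(ot$intervals$duration, 100)
  expect_equal(ot$summary$state, "ON")

  mt <- telegraph_model(0.5, 0.5, 5, 1)
  trt <- simulate(mt, seed = 3, t_end = 500)
  ott <- occupancy_timeline(trt)
  expect_setequal(unique(ott$intervals$state), c("ON", "OFF"))
  expect_equal(sum(ott$intervals$duration), 500, tolerance = 1e-9)
  # dwell times are exponential with mean 1/rate = 2
  expect_equal(mean(ott$intervals$duration), 2, tolerance = 0.5)
})

test_that("blocking shortens undesired-activation dwells during
           repression", {
  ps <- strong_preset(); pb <- preset_params("sequestration_blocking")
  dw <- function(p, load, state) {
    est <- ssa_stationary(switch_model(with_load(p, load)),
                          t_end = 3e4, seed = 11)
    est$dwell$mean_dwell[est$dwell$state == state]
  }
  d_seq <- dw(ps, hill_summary(ps)$EC10, "E_A")
  d_blk <- dw(pb, hill_summary(pb)$EC10, "E_A")
  expect_gt(d_seq, d_blk)
})

test_that("displacement shortens undesired-repression dwells during
           activation", {
  pb <- preset_params("sequestration_blocking")
  pt <- switch_params("sequestration_blocking_displacement",
                      K_a = 0.5, K_s = 0.0025, K_b = 1, K_d = 1000,
                      A_T = 100)
  dw <- function(p, load, state) {
    est <- ssa_stationary(switch_model(with_load(p, load)),
                          t_end = 3e4, seed = 11)
    est$dwell$mean_dwell[est$dwell$state == state]
  }
  d_blk <- dw(pb, hill_summary(pb)$EC90, "E_R")
  d_tri <- dw(pt, hill_summary(pt)$EC90, "E_R")
  expect_gt(d_blk, d_tri)
})

test_that("the event-log guard is enforced", {
  m <- constitutive_model(100, 1)
  expect_error(simulate(m, seed = 1, t_end = 1000, max_events = 1000),
               "max_events")
})
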