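test_that("fano_auc integrates the windows exactly for simple shapes", {
  win <- phase_windows(c(EC90 = 0.5, EC10 = 1), load_min = 0, load_max = 2)
  # constant Fano = 1: AUC equals the window width
  flat <- data.frame(Rt_tilde = seq(0, 2, 0.25), fano = 1)
  expect_equal(unname(fano_auc(flat, win)), c(0.5, 1.0))
  # linear 1 -> 3 over TRP window of width 1: trapezoid = 2
  lin <- data.frame(Rt_tilde = c(0, 0.5, 1, 2),
                    fano = c(1, 1, 1, 3))
  expect_equal(fano_auc(lin, win)[["AUC_TRP"]], 2)
  # window outside the table range
  expect_error(fano_auc(data.frame(Rt_tilde = c(0.6, 1.5),
                                   fano = c(1, 1)), win),
               "outside")
})

test_that("phase windows must be ordered and non-empty", {
  expect_error(phase_windows(c(EC90 = 1.2, EC10 = 1.0)), "EC90 < EC10")
  expect_error(phase_windows(c(EC90 = 0.5, EC10 = 3), load_max = 2),
               "EC90 < EC10")
  w <- phase_windows(c(EC90 = 0.9, EC10 = 1.1))
  expect_equal(w$TAP, c(0, 0.9))
  expect_equal(w$TRP, c(1.1, 2))
})

test_that("a small scan populates every cell deterministically", {
  sc <- scan_architectures("sequestration",
                           Ka_grid = c(1e-2, 1e-1),
                           Ks_grid = c(1e-5, 1e-4),
                           A_T = 20, n_auc = 3)
  expect_equal(nrow(sc), 4L)
  expect_true(all(sc$ok))
  expect_true(all(is.finite(sc$n_eff)))
  expect_true(all(is.finite(sc$fano_auc_tap)))
  sc2 <- scan_architectures("sequestration",
                            Ka_grid = c(1e-2, 1e-1),
                            Ks_grid = c(1e-5, 1e-4),
                            A_T = 20, n_auc = 3)
  expect_identical(sc, sc2)
  # failures are per-point flags, not errors: a switch too soft for the
  # load range is recorded with a message
  sc3 <- scan_architectures("sequestration", Ka_grid = 0.1, Ks_grid = 0.05,
                            A_T = 20, n_auc = 3)
  expect_false(sc3$ok[1])
  expect_match(sc3$message[1], ".")
})

test_that("matching a target to itself recovers the blocking constant", {
  ref <- preset_params("sequestration_blocking")
  m <- match_mean_curves(ref, ref)
  expect_equal(m$Kb_tilde, 0.01, tolerance = 0.02)
  expect_lt(m$sse, 1e-8)
  expect_lt(m$max_rel_diff, 1e-4)
  expect_false(m$boundary)
})

test_that("matched mean curves agree closely; degenerate optima are
           flagged", {
  ref <- strong_preset()
  tri <- switch_params("sequestration_blocking_displacement",
                       K_a = ref$K_a, K_s = ref$K_s, K_b = 1,
                       K_d = 10 * ref$A_T, A_T = ref$A_T,
                       alpha = ref$alpha, k_on = ref$k_on)
  m <- match_mean_curves(ref, tri)
  expect_lt(m$max_rel_diff, 0.02)
  # blocking-only target degenerates to the reference as K_b grows
  blk <- preset_params("sequestration_blocking")
  expect_warning(mb <- match_mean_curves(ref, blk), "boundary")
  expect_true(mb$boundary)
  expect_lt(mb$max_rel_diff, 0.01)
})

test_that("the deterministic ODE is monostable and matches the CME mean
           at large copy number", {
  p <- strong_preset()
  for (l in c(0.3, 0.95, 1.05, 1.7)) {
    o <- ode_steady_state(p, l)
    expect_equal(o$n_stable, 1L, info = paste("load", l))
  }
  # constitutive limit: a vanishing activator-DNA dissociation constant
  p0 <- params_from_normalized("sequestration",
                               list(Ka_tilde = 1e-8, Ks_tilde = 1e-4),
                               A_T = 100)
  o0 <- ode_steady_state(p0, 0)
  expect_equal(o0$steady_states$m_star[o0$steady_states$stable],
               p0$alpha / p0$beta, tolerance = 1e-4)
  # large-copy agreement with the exact CME mean
  p1k <- params_from_normalized(
    "sequestration", list(Ka_tilde = 5e-3, Ks_tilde = 2.5e-5), A_T = 1000)
  for (l in c(0.5, 0.98)) {
    od <- ode_steady_state(p1k, l)
    m_ode <- od$steady_states$m_star[od$steady_states$stable]
    act <- steady_state(switch_model(with_load(p1k, l)),
                        M_max = 0L)$activity
    m_cme <- p1k$alpha / p1k$beta * act
    expect_lt(abs(m_ode - m_cme) / m_cme, 0.10)
  }
  expect_error(ode_steady_state(
    strong_preset(turnover = list(r_prod = 1, r_deg = 1)), 1),
    "fixed")
})

test_that("repressor turnover lowers sensitivity and raises variance", {
  tc <- turnover_comparison("sequestration", A_T = 30, load_max = 1.6,
                            n_loads = 17, t_end = 5e4, seed = 3)
  fx <- tc[tc$variant == "fixed", ]
  to <- tc[tc$variant == "turnover", ]
  expect_lt(to$n_eff[1], fx$n_eff[1])
  for (pt in c("EC90", "EC10"))
    expect_gt(to$variance[to$point == pt] - 3 * to$se_variance[to$point == pt],
              fx$variance[fx$point == pt])
})

test_that("fast repressor cycling approaches the fixed pool (undepleted
           reservoir)", {
  pc <- preset_params("cooperative")
  pcf <- preset_params("cooperative",
                       turnover = list(r_prod = 1, r_deg = 20,
                                       deg_complex = FALSE))
  for (l in c(0.2, 0.4)) {
    a_fix <- steady_state(switch_model(with_load(pc, l)),
                          M_max = 0L)$activity
    a_to <- steady_state(switch_model(with_load(pcf, l)),
                         M_max = 0L)$activity
    expect_equal(a_to, a_fix, tolerance = 1e-3)
    f_fix <- noise_summary(steady_state(switch_model(with_load(pc, l))))$fano
    f_to <- noise_summary(steady_state(switch_model(with_load(pcf, l))))$fano
    expect_equal(f_to, f_fix, tolerance = 0.01)
  }
})

test_that("report recipes return claim tables", {
  rep <- switch_report("bimodal_strong_unimodal_weak")
  expect_true(all(c("recipe", "claim", "value", "reference", "holds")
                  %in% names(rep)))
  expect_type(rep$holds, "logical")
  expect_error(switch_report("not_a_recipe"), "unknown recipe")
})
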