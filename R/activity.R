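#' Equilibrium activity of the cooperative-binding switch
#'
#' Closed-form steady-state transcriptional activity of the three-site
#' cooperative repressor-binding promoter: the probability that at least
#' one operator site is unoccupied.  With sequential-binding statistical
#' weights (empty `1`, one bound `3x`, two bound `3x^2/c`, three bound
#' `x^3/c^3`, where `x = R_T / K_r` is the normalized load), the activity
#' is `1 - w_111 / Z`.  The free repressor is approximated by the total
#' `R_T` (single gene copy).
#'
#' @param Rt_tilde Normalized repressor load(s) `R_T / K_r`, non-negative.
#' @param c Cooperativity factor, `0 < c <= 1` (`c = 1`: independent sites).
#' @return Activity value(s) in `[0, 1]`.
#' @examples
#' cooperative_activity(1, 1)    # 1 - (1/2)^3
#' @export
cooperative_activity <- function(Rt_tilde, c) {
  if (any(Rt_tilde < 0)) stop("Rt_tilde must be non-negative", call. = FALSE)
  if (c <= 0) stop("cooperativity factor c must be positive", call. = FALSE)
  x <- Rt_tilde
  w111 <- (x / c)^3
  Z <- 1 + 3 * x + 3 * x^2 / c + w111
  1 - w111 / Z
}

# Free A, R and complex count from deterministic titration with the single
# promoter's occupancy removed from the solution totals.
.titrate <- function(A_T, R_T, K_s) {
  if (A_T <= 0 || R_T <= 0)
    return(list(A = max(A_T, 0), R = max(R_T, 0), RA = 0))
  S <- A_T + R_T + K_s
  RA <- 2 * A_T * R_T / (S + sqrt(S^2 - 4 * A_T * R_T))  # stable root
  list(A = A_T - RA, R = R_T - RA, RA = RA)
}

# Stationary distribution of the promoter chain given free/complex levels.
# Shared k_on cancels.  For the displacement architecture the three-state
# cycle is solved by the Markov-chain tree theorem; without displacement the
# chain is a reversible path and Boltzmann weights apply.
.promoter_probs <- function(p, A, R, RA) {
  arch <- p$architecture
  if (arch == "sequestration") {
    w <- c(E_F = 1, E_A = A / p$K_a)
  } else if (arch == "sequestration_blocking") {
    w <- c(E_F = 1, E_A = A / p$K_a, E_R = A * R / (p$K_a * p$K_b))
  } else {
    w <- c(
      E_F = p$K_a * (p$K_b + p$K_d) + R * p$K_d,
      E_A = A * (p$K_b + p$K_d) + RA * p$K_b,
      E_R = R * (A + RA) + RA * p$K_a
    )
  }
  w / sum(w)
}

# Self-consistent mean-field activity of the sequestration family at one
# load; R_T may be non-integer here (deterministic titration).
.seq_activity_point <- function(p, R_T, tol = 1e-10, max_iter = 1000L) {
  occA <- 0; occR <- 0
  prev <- c(Inf, Inf)
  for (it in seq_len(max_iter)) {
    f <- .titrate(p$A_T - occA, R_T - occR, p$K_s)
    pr <- .promoter_probs(p, f$A, f$R, f$RA)
    occA_new <- pr[["E_A"]] + if ("E_R" %in% names(pr)) pr[["E_R"]] else 0
    occR_new <- if ("E_R" %in% names(pr)) pr[["E_R"]] else 0
    if (max(abs(c(f$A, f$R) - prev)) < tol &&
        max(abs(c(occA_new - occA, occR_new - occR))) < tol)
      return(pr[["E_A"]])
    prev <- c(f$A, f$R)
    occA <- 0.5 * occA + 0.5 * occA_new   # damped update
    occR <- 0.5 * occR + 0.5 * occR_new
  }
  stop("mean-field activity did not converge at load Rt_tilde = ",
       format(R_T / p$A_T), call. = FALSE)
}

#' Mean-field activity of a sequestration-family switch
#'
#' Steady-state probability that the promoter is activator-bound
#' (`P(E_A)`), computed self-consistently: promoter-state occupancies from
#' the stationary distribution of the promoter chain with rates set by the
#' free activator, free repressor and complex levels; free levels from
#' deterministic titration (`RA = A * R / K_s`) with the promoter-bound
#' molecules removed from the conservation totals.  For the displacement
#' architecture the promoter cycle can be driven (see
#' [thermo_cycle_gap()]); its stationary distribution is then solved with
#' the shared-`k_on` kinetic splitting, which cancels from the result.
#'
#' @param params A sequestration-family [switch_params()] object.
#' @param Rt_tilde Vector of normalized loads `R_T / A_T` (continuous;
#'   titration is deterministic here).
#' @return Numeric vector of activities in `[0, 1]`.
#' @seealso [activity_curve()] for the curve object with EC thresholds, and
#'   the `"cme"` backend for the exact stochastic counterpart.
#' @export
sequestration_activity <- function(params, Rt_tilde) {
  stopifnot(inherits(params, "switch_params"))
  if (!.seq_family(params$architecture))
    stop("sequestration_activity applies to the sequestration family",
         call. = FALSE)
  vapply(Rt_tilde, function(l) .seq_activity_point(params, l * params$A_T),
         0)
}

#' Activity curve versus normalized repressor load
#'
#' @param params A [switch_params()] object (the load is swept, so `R_T`
#'   need not be set).
#' @param loads Grid of normalized loads.  Default: 400 logarithmic points
#'   on `[1e-2, 1e2]` (cooperative) or 400 linear points on `[0, 2]`
#'   (sequestration family).
#' @param backend `"meanfield"` (deterministic titration; default) or
#'   `"cme"` (exact promoter-marginal probability from the stationary
#'   chemical master equation with integer copy numbers).
#' @return An `activity_curve` object: a data frame with columns
#'   `Rt_tilde` and `activity`, carrying the architecture, normalized
#'   parameters and (for the mean-field backend) the continuous activity
#'   function used for threshold bisection.
#' @export
activity_curve <- function(params, loads = NULL,
                           backend = c("meanfield", "cme")) {
  stopifnot(inherits(params, "switch_params"))
  backend <- match.arg(backend)
  coop <- !.seq_family(params$architecture)
  if (is.null(loads)) {
    loads <- if (coop) exp(seq(log(1e-2), log(1e2), length.out = 400))
             else seq(0, 2, length.out = 400)
  }
  loads <- sort(loads)
  if (backend == "meanfield") {
    f <- if (coop) function(l) cooperative_activity(l, params$c)
         else function(l) sequestration_activity(params, l)
    act <- f(loads)
  } else {
    f <- NULL
    act <- vapply(loads, function(l) {
      ss <- steady_state(switch_model(with_load(params, l)), M_max = 0L)
      sum(ss$p[ss$space$transcribing])
    }, 0)
  }
  zero_load <- if (!is.null(f)) f(0) else if (loads[1] == 0) act[1] else {
    ss <- steady_state(switch_model(with_load(params, 0)), M_max = 0L)
    sum(ss$p[ss$space$transcribing])
  }
  out <- data.frame(Rt_tilde = loads, activity = act)
  structure(out,
            class = c("activity_curve", "data.frame"),
            architecture = params$architecture,
            normalized = normalized_params(params),
            backend = backend, fun = f, zero_load = zero_load)
}

#' EC90 and EC10 of a monotone activity curve
#'
#' Locates the loads at which the activity crosses 0.9 and 0.1 of its
#' maximum (the zero-load plateau).  By default the thresholds are relative
#' to the curve maximum, so that switches whose activator only partially
#' occupies the promoter (weak activators) are characterized by the shape
#' of their response; `relative = FALSE` uses absolute activity levels.
#' The crossing is bracketed on the grid and refined by bisection on the
#' continuous activity function when the curve carries one, otherwise on
#' the monotone piecewise-linear interpolant.
#'
#' @param curve An [activity_curve()] object (or a data frame with columns
#'   `Rt_tilde` and `activity`).
#' @param relative Logical; thresholds relative to the curve maximum.
#' @param tol Bisection tolerance on the activity value.
#' @return Named vector `c(EC90 =, EC10 =)`.
#' @export
ec_thresholds <- function(curve, relative = TRUE, tol = 1e-6) {
  g <- curve$Rt_tilde
  a <- curve$activity
  if (any(diff(a) > 1e-8))
    stop("activity curve is not monotone non-increasing", call. = FALSE)
  # anchor relative thresholds at the zero-load plateau, not the grid
  # maximum, so a grid that misses the plateau cannot silently rescale
  amax <- attr(curve, "zero_load")
  if (is.null(amax)) amax <- max(a)
  f <- attr(curve, "fun")
  one <- function(target) {
    i <- which(a[-length(a)] >= target & a[-1] <= target)
    if (!length(i))
      stop("target activity ", format(target), " not bracketed by the ",
           "curve; extend the load grid", call. = FALSE)
    i <- i[1]
    lo <- g[i]; hi <- g[i + 1]
    fi <- if (!is.null(f)) f else function(l) approx(g, a, xout = l)$y
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      v <- fi(mid)
      if (abs(v - target) < tol) return(mid)
      if (v > target) lo <- mid else hi <- mid
    }
    mid
  }
  targets <- c(0.9, 0.1) * if (relative) amax else 1
  c(EC90 = one(targets[1]), EC10 = one(targets[2]))
}

#' Effective Hill coefficient
#'
#' Sensitivity of a monotone dose-response curve, `log(81) /
#' log(EC10 / EC90)`.  Equals the Hill exponent for an exact Hill curve;
#' 1 for a Michaelis-Menten response.
#'
#' @param EC90,EC10 Loads at which the activity is 90% and 10% of maximal
#'   (`0 < EC90 < EC10`).  `EC90` may also be an [activity_curve()], in
#'   which case the thresholds are computed via [ec_thresholds()].
#' @param ... Passed to [ec_thresholds()] when a curve is supplied.
#' @return The effective Hill coefficient (positive scalar).
#' @export
effective_hill <- function(EC90, EC10 = NULL, ...) {
  if (inherits(EC90, "activity_curve") || is.data.frame(EC90)) {
    ec <- ec_thresholds(EC90, ...)
    EC90 <- ec[["EC90"]]; EC10 <- ec[["EC10"]]
  }
  if (!(EC90 > 0 && EC10 > EC90))
    stop("need 0 < EC90 < EC10", call. = FALSE)
  log(81) / log(EC10 / EC90)
}

#' Activity curve with EC thresholds and Hill coefficient
#'
#' Convenience wrapper: computes the activity curve, locates EC90/EC10
#' (auto-extending the load grid when a threshold is not bracketed) and
#' returns the Hill summary.
#'
#' @inheritParams activity_curve
#' @inheritParams ec_thresholds
#' @param max_extend Number of ten-fold grid extensions to attempt.
#' @return List with `EC90`, `EC10`, `n_eff` and the `curve`.
#' @export
hill_summary <- function(params, loads = NULL,
                         backend = c("meanfield", "cme"),
                         relative = TRUE, max_extend = 3L) {
  backend <- match.arg(backend)
  curve <- activity_curve(params, loads, backend)
  for (k in seq_len(max_extend + 1L)) {
    ec <- tryCatch(ec_thresholds(curve, relative = relative),
                   error = function(e) e)
    if (!inherits(ec, "error")) break
    if (k > max_extend) stop(ec)
    g <- curve$Rt_tilde
    wider <- if (!.seq_family(params$architecture))
      exp(seq(log(min(g) / 10), log(max(g) * 10),
              length.out = 2 * length(g)))
    else seq(0, max(g) * 10, length.out = 2 * length(g))
    curve <- activity_curve(params, wider, backend)
  }
  list(EC90 = ec[["EC90"]], EC10 = ec[["EC10"]],
       n_eff = effective_hill(ec[["EC90"]], ec[["EC10"]]),
       curve = curve)
}

#' @export
plot.activity_curve <- function(x, log = NULL, ...) {
  coop <- attr(x, "architecture") == "cooperative_binding"
  if (is.null(log)) log <- if (coop) "x" else ""
  graphics::plot(x$Rt_tilde, x$activity, type = "l", log = log,
                 xlab = expression(tilde(R)[T]),
                 ylab = "transcriptional activity", ...)
  invisible(x)
}
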