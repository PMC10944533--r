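#' Exact stochastic simulation of a switch model
#'
#' Gillespie direct-method simulation of the full reaction network.  The
#' event log (times and the complete state after every event, starting with
#' the initial state at time zero) is returned as a `switch_trajectory`;
#' identical seeds give identical trajectories.  For long runs where the
#' event log would be prohibitive, use [ssa_stationary()], which streams
#' the same simulation and returns only stationary summaries.
#'
#' @param object A [switch_model()].
#' @param nsim Number of trajectories (a list is returned when `nsim > 1`).
#' @param seed Integer seed (applied via [set.seed()]); `NULL` leaves the
#'   RNG state untouched.
#' @param t_end Simulation horizon (time units of `1/beta`).
#' @param init Initial state; default: free promoter, all molecules
#'   unbound, no mRNA.
#' @param max_events Guard on the event-log size.
#' @param ... Unused.
#' @return A `switch_trajectory`: `times`, `states` (one row per event),
#'   recorded `seed`, and streaming stationary accumulators used by
#'   [stationary_estimate()].
#' @export
simulate.switch_model <- function(object, nsim = 1, seed = NULL,
                                  t_end = 1000, init = NULL,
                                  max_events = 5e6, ...) {
  stopifnot(t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  one <- function(k) {
    res <- .ssa_run(object, t_end, burn_in = 0, n_batches = 1L,
                    record = TRUE, init = init, max_events = max_events)
    if (res$overflow)
      stop("event log exceeded max_events = ", max_events,
           "; shorten t_end or use ssa_stationary()", call. = FALSE)
    structure(list(
      model = object, times = res$times,
      states = `colnames<-`(res$states, object$species),
      t_end = t_end, seed = seed,
      n_events = res$n_events, transitions = res$transitions
    ), class = "switch_trajectory")
  }
  if (nsim == 1) one(1) else lapply(seq_len(nsim), one)
}

.ssa_run <- function(model, t_end, burn_in, n_batches, record,
                     init = NULL, max_events = Inf) {
  if (is.null(init)) init <- model$init
  if (!is.null(names(init))) init <- init[model$species]
  stopifnot(length(init) == length(model$species))
  ssa_core(as.integer(init), model$stoich, model$rate,
           ifelse(is.na(model$r1), 0L, as.integer(model$r1)),
           ifelse(is.na(model$r2), 0L, as.integer(model$r2)),
           t_end, burn_in, as.integer(n_batches),
           as.integer(model$mrna), as.integer(model$promoter),
           record, as.double(max_events))
}

#' Streaming stationary statistics by SSA
#'
#' Runs the Gillespie simulation without an event log and returns
#' time-averaged stationary statistics of the mRNA copy number with
#' batch-means standard errors, plus dwell-time summaries per promoter
#' state.  Used as the independent oracle for the CME engine.
#'
#' @param model A [switch_model()].
#' @param t_end Simulation horizon.
#' @param burn_in Initial span discarded before accumulation (default 10%
#'   of `t_end`).
#' @param n_batches Number of equal-time batches (at least 20).
#' @param seed Integer seed.
#' @return A `stationary_estimate` (see [stationary_estimate()]) with an
#'   additional `dwell` data frame (promoter state, total dwell time,
#'   visits, mean dwell).
#' @export
ssa_stationary <- function(model, t_end, burn_in = 0.1 * t_end,
                           n_batches = 20L, seed = NULL) {
  stopifnot(inherits(model, "switch_model"), n_batches >= 20L,
            t_end > burn_in)
  if (!is.null(seed)) set.seed(seed)
  res <- .ssa_run(model, t_end, burn_in, n_batches, record = FALSE)
  est <- .batch_estimate(res$batch_T, res$batch_m, res$batch_m2)
  est$dwell <- data.frame(
    state = model$species[model$promoter],
    total_time = res$dwell,
    visits = res$visits,
    mean_dwell = ifelse(res$visits > 0, res$dwell / res$visits, NA)
  )
  est$transitions <- res$transitions
  est$n_events <- res$n_events
  est$seed <- seed
  est
}

# batch-means estimates; Fano/variance SEs by the delta method on the
# batch (mean, raw second moment) pairs
.batch_estimate <- function(T_b, M_b, S_b) {
  keep <- T_b > 0
  T_b <- T_b[keep]; M_b <- M_b[keep]; S_b <- S_b[keep]
  B <- length(T_b)
  if (B < 20L)
    stop("fewer than 20 non-empty batches; lengthen the run", call. = FALSE)
  m_b <- M_b / T_b            # batch means
  s_b <- S_b / T_b            # batch raw second moments
  m <- sum(M_b) / sum(T_b)
  s <- sum(S_b) / sum(T_b)
  v <- s - m^2
  fano <- if (m > 0) v / m else NA_real_
  S2 <- stats::cov(cbind(m_b, s_b))     # batch covariance
  se_mean <- sqrt(S2[1, 1] / B)
  g_var <- c(-2 * m, 1)
  se_var <- sqrt(drop(t(g_var) %*% S2 %*% g_var) / B)
  g_fano <- c(-s / m^2 - 1, 1 / m)
  se_fano <- if (m > 0) sqrt(drop(t(g_fano) %*% S2 %*% g_fano) / B)
             else NA_real_
  structure(list(mean = m, variance = v, fano = fano,
                 se_mean = se_mean, se_variance = se_var,
                 se_fano = se_fano, n_batches = B),
            class = "stationary_estimate")
}

#' Time-averaged stationary estimate from a logged trajectory
#'
#' Time-weighted mean, variance and Fano factor of the mRNA copy number
#' over `[burn_in, t_end]`, with batch-means standard errors (Fano SE by
#' the delta method).
#'
#' @param trajectory A `switch_trajectory` from [simulate()].
#' @param burn_in Span discarded at the start (default 10% of the horizon).
#' @param n_batches Number of equal-time batches (at least 20).
#' @return A `stationary_estimate` list: `mean`, `variance`, `fano`, their
#'   standard errors and `n_batches`.
#' @export
stationary_estimate <- function(trajectory, burn_in = 0.1 * trajectory$t_end,
                                n_batches = 20L) {
  stopifnot(inherits(trajectory, "switch_trajectory"))
  t_end <- trajectory$t_end
  if (burn_in >= t_end)
    stop("burn_in must be shorter than the trajectory horizon",
         call. = FALSE)
  if (n_batches < 20L) stop("need at least 20 batches", call. = FALSE)
  tt <- c(trajectory$times, t_end)
  m <- trajectory$states[, trajectory$model$mrna]
  dt <- diff(tt)
  # exact piecewise-linear cumulative integrals of m and m^2
  cum1 <- c(0, cumsum(m * dt))
  cum2 <- c(0, cumsum(m^2 * dt))
  bounds <- seq(burn_in, t_end, length.out = n_batches + 1L)
  I1 <- approx(tt, cum1, xout = bounds, ties = "ordered")$y
  I2 <- approx(tt, cum2, xout = bounds, ties = "ordered")$y
  .batch_estimate(diff(bounds), diff(I1), diff(I2))
}

#' @export
print.stationary_estimate <- function(x, ...) {
  cat(sprintf(
    "<stationary_estimate> mean %.4f (SE %.2g), var %.4f (SE %.2g), Fano %.4f (SE %.2g), %d batches\n",
    x$mean, x$se_mean, x$variance, x$se_variance, x$fano, x$se_fano,
    x$n_batches))
  invisible(x)
}

#' Promoter occupancy timeline of a trajectory
#'
#' Collapses a logged trajectory into dwell intervals per promoter state:
#' each interval spans the consecutive events during which the promoter
#' stayed in one state.  The summary reports the mean dwell time per state,
#' which quantifies how quickly noise-induced excursions (undesired
#' activation during the repression phase, undesired repression during the
#' activation phase) are restored.
#'
#' @param trajectory A `switch_trajectory`.
#' @return List with `intervals` (data frame: state, t_start, t_end,
#'   duration) and `summary` (state, total time, n intervals, mean dwell).
#' @export
occupancy_timeline <- function(trajectory) {
  stopifnot(inherits(trajectory, "switch_trajectory"))
  model <- trajectory$model
  pr <- trajectory$states[, model$promoter, drop = FALSE]
  id <- max.col(pr)
  labels <- model$species[model$promoter]
  tt <- c(trajectory$times, trajectory$t_end)
  runs <- rle(id)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  intervals <- data.frame(
    state = labels[runs$values],
    t_start = tt[starts],
    t_end = tt[ends + 1L],
    stringsAsFactors = FALSE
  )
  intervals$duration <- intervals$t_end - intervals$t_start
  agg <- stats::aggregate(duration ~ state, intervals,
                   function(d) c(total = sum(d), n = length(d),
                                 mean = mean(d)))
  summary <- data.frame(state = agg$state,
                        total_time = agg$duration[, "total"],
                        n_intervals = agg$duration[, "n"],
                        mean_dwell = agg$duration[, "mean"])
  list(intervals = intervals, summary = summary)
}

#' @export
print.switch_trajectory <- function(x, ...) {
  cat("<switch_trajectory> ", length(x$times) - 1L, " events over t = [0, ",
      format(x$t_end), "], seed ",
      if (is.null(x$seed)) "<none>" else x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
plot.switch_trajectory <- function(x, species = NULL, ...) {
  m <- x$model
  if (is.null(species)) species <- m$species[m$mrna]
  i <- match(species, m$species)
  graphics::plot(x$times, x$states[, i], type = "s",
                 xlab = "time", ylab = species, ...)
  invisible(x)
}
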