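#' Enumerate the truncated state space of a switch model
#'
#' Exhaustive, duplicate-free enumeration of all states reachable under the
#' conservation laws, with the mRNA copy number truncated at `M_max` (and,
#' with repressor turnover, the free repressor truncated at `R_max`).
#' States are the product of the promoter/complex core (promoter indicator,
#' sequestered-complex count, free repressor under turnover) and the mRNA
#' level `0..M_max`.
#'
#' @param model A [switch_model()] (or an engine-validation model such as
#'   [telegraph_model()]).
#' @param M_max mRNA truncation level (`M_max = 0` gives the promoter-only
#'   chain used for activity computations).
#' @param R_max Free-repressor truncation level (turnover models only);
#'   default `mu + 10*sqrt(mu)` with `mu = r_prod / r_deg`.
#' @param max_states Resource cap; enumeration beyond it raises an error
#'   suggesting smaller copy numbers or truncation levels.
#' @return A `state_space` object: integer state matrix (rows = states,
#'   columns = species), integer keys, per-species caps, mRNA level,
#'   promoter label and transcribing flag per state.
#' @export
enumerate_states <- function(model, M_max, R_max = NULL,
                             max_states = 4e6) {
  stopifnot(inherits(model, "switch_model"), M_max >= 0)
  p <- model$params
  turnover <- !is.null(p$turnover)
  nsp <- length(model$species)
  idx <- setNames(seq_len(nsp), model$species)

  if (turnover && is.null(R_max)) {
    mu <- p$turnover$r_prod / p$turnover$r_deg
    R_max <- ceiling(mu + 10 * sqrt(mu) + 5)
  }

  caps <- rep(1, nsp)
  caps[model$mrna] <- M_max
  truncated <- model$mrna

  if (model$architecture %in% switch_architectures() &&
      .seq_family(model$architecture)) {
    A_T <- p$A_T
    R_T <- p$R_T
    has_block <- "E_R" %in% model$species
    proms <- model$species[model$promoter]
    core <- list()
    for (pr in proms) {
      aOcc <- as.integer(pr %in% c("E_A", "E_R"))
      rOcc <- as.integer(pr == "E_R")
      n_hi <- if (turnover) A_T - aOcc else min(A_T - aOcc, R_T - rOcc)
      if (n_hi < 0) next
      n_RA <- 0:n_hi
      r_free <- if (turnover) 0:R_max else R_T - n_RA - rOcc
      grid <- if (turnover) expand.grid(n_RA = n_RA, r = r_free)
              else data.frame(n_RA = n_RA, r = r_free)
      blk <- matrix(0L, nrow(grid), nsp)
      blk[, idx[pr]] <- 1L
      blk[, idx["RA"]] <- as.integer(grid$n_RA)
      blk[, idx["A"]] <- as.integer(A_T - grid$n_RA - aOcc)
      blk[, idx["R"]] <- as.integer(grid$r)
      core[[pr]] <- blk
    }
    core <- do.call(rbind, core)
    caps[idx["A"]] <- A_T
    caps[idx["RA"]] <- A_T
    caps[idx["R"]] <- if (turnover) R_max else max(R_T, 1)
    if (turnover) truncated <- c(truncated, idx[["R"]])
  } else if (model$architecture == "cooperative_binding") {
    core <- diag(8L)
    if (turnover) {
      core <- core[rep(1:8, each = R_max + 1L), , drop = FALSE]
      core <- cbind(core, rep(0:R_max, times = 8))
      caps[idx["R"]] <- R_max
      truncated <- c(truncated, idx[["R"]])
    }
    core <- cbind(core, 0L)  # mRNA column
    storage.mode(core) <- "integer"
  } else {
    # generic promoter-chain model (e.g. telegraph): indicators + mRNA only
    core <- matrix(0L, length(model$promoter), nsp)
    core[cbind(seq_along(model$promoter), model$promoter)] <- 1L
  }
  if (ncol(core) != nsp) stop("internal: core enumeration width mismatch")

  n_core <- nrow(core)
  n <- n_core * (M_max + 1L)
  if (n > max_states)
    stop("state space has ", n, " states, above the cap of ", max_states,
         "; reduce A_T, M_max or R_max", call. = FALSE)
  states <- core[rep(seq_len(n_core), times = M_max + 1L), , drop = FALSE]
  m <- rep(0:M_max, each = n_core)
  states[, model$mrna] <- m

  keys <- .state_keys(states, caps)
  if (anyDuplicated(keys)) stop("internal: duplicate states enumerated")

  prom_id <- max.col(states[, model$promoter, drop = FALSE])
  structure(list(
    states = states, keys = keys, caps = caps, m = m,
    promoter_id = prom_id,
    promoter_labels = model$species[model$promoter],
    transcribing = model$transcribing[prom_id],
    truncated = truncated, M_max = M_max,
    R_max = if (turnover) R_max else NA,
    n = n
  ), class = "state_space")
}

.state_keys <- function(states, caps) {
  w <- cumprod(c(1, caps[-length(caps)] + 1))
  if (prod(caps + 1) >= 2^53)
    stop("state key overflow; state space too large", call. = FALSE)
  drop(states %*% w)
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", x$n, " states (M_max = ", x$M_max,
      if (!is.na(x$R_max)) paste0(", R_max = ", x$R_max), ")\n", sep = "")
  invisible(x)
}

#' Build the CME generator matrix
#'
#' Sparse infinitesimal generator `Q` of the chemical master equation over
#' an enumerated state space: `Q[j, i]` is the propensity of the reaction
#' taking state `i` to state `j`, and each column sums to zero.  Reactions
#' that would leave the truncated region (mRNA above `M_max`, free
#' repressor above `R_max`) are dropped (reflecting truncation); the
#' adequacy of the truncation is verified downstream by the stationary tail
#' mass.
#'
#' @param model A [switch_model()].
#' @param space A `state_space` from [enumerate_states()].
#' @return A sparse `dgCMatrix` generator.
#' @export
build_generator <- function(model, space) {
  stopifnot(inherits(space, "state_space"))
  a <- propensities(model, space$states)
  if (any(a < 0)) stop("negative propensity encountered", call. = FALSE)
  dk <- drop(crossprod(model$stoich,
                       cumprod(c(1, space$caps[-length(space$caps)] + 1))))
  ii <- jj <- xx <- vector("list", ncol(a))
  for (r in seq_len(ncol(a))) {
    src <- which(a[, r] > 0)
    if (!length(src)) next
    tgt <- match(space$keys[src] + dk[r], space$keys)
    lost <- is.na(tgt)
    if (any(lost)) {
      # only transitions past a truncation boundary may be dropped
      gain <- which(model$stoich[, r] > 0)
      if (!any(gain %in% space$truncated))
        stop("internal: reaction '", colnames(model$stoich)[r],
             "' leaves the state space away from a truncation boundary")
      src <- src[!lost]; tgt <- tgt[!lost]
    }
    ii[[r]] <- tgt; jj[[r]] <- src; xx[[r]] <- a[src, r]
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  n <- space$n
  Q <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  colsum <- max(abs(Matrix::colSums(Q)))
  if (colsum > 1e-9)
    stop("generator consistency failure: column sums deviate by ",
         format(colsum), call. = FALSE)
  Q
}

# stationary solve of a generator: sparse LU with one row replaced by the
# normalization constraint, iterative refinement, and a uniformized
# power-iteration fallback.
.solve_stationary <- function(Q, rtol = 1e-10) {
  n <- nrow(Q)
  # residual tolerance relative to the largest exit rate (an absolute
  # criterion is not invariant to the choice of time unit)
  rtol <- rtol * max(1, max(abs(Matrix::diag(Q))))
  # fix one state's probability to 1 and solve the sparse remainder
  # (keeps the LU sparse, unlike appending a dense normalization row)
  j <- which.min(abs(Matrix::diag(Q)))[1]
  A <- Q[-j, -j, drop = FALSE]
  b <- -Q[-j, j]
  assemble <- function(x) {
    p <- numeric(n); p[-j] <- x; p[j] <- 1
    p / sum(p)
  }
  lu <- tryCatch(Matrix::lu(A), error = function(e) NULL)
  p <- NULL
  if (!is.null(lu)) {
    x <- as.numeric(Matrix::solve(lu, b))
    for (k in 1:3) {
      p <- assemble(x)
      if (max(abs(Q %*% p)) < rtol) break
      x <- x + as.numeric(Matrix::solve(lu, b - A %*% x))
    }
    p <- assemble(x)
  }
  ok <- function(p) {
    !is.null(p) && all(is.finite(p)) && min(p) > -1e-8 &&
      max(abs(Q %*% p)) < rtol
  }
  if (!ok(p)) {
    # fallback: power iteration on the uniformized chain
    lambda <- 1.05 * max(abs(Matrix::diag(Q))) + 1e-12
    P <- Q / lambda + Matrix::Diagonal(n)
    p <- rep(1 / n, n)
    for (k in seq_len(200000L)) {
      p_new <- as.numeric(P %*% p)
      p_new <- p_new / sum(p_new)
      if (k %% 50 == 0 && max(abs(Q %*% p_new)) < rtol) { p <- p_new; break }
      p <- p_new
    }
    if (max(abs(Q %*% p)) >= rtol)
      stop("stationary solve failed: residual ",
           format(max(abs(Q %*% p))), " above ", format(rtol), call. = FALSE)
  }
  p <- p / sum(p)
  if (min(p) < -1e-8)
    stop("stationary solve failed: negative probabilities", call. = FALSE)
  p[p < 0] <- 0
  p <- p / sum(p)
  list(p = p, residual = max(abs(Q %*% p)))
}

#' Exact stationary distribution of the truncated CME
#'
#' Solves `Q p = 0` with normalization by sparse LU (with iterative
#' refinement and a uniformized power-iteration fallback), then verifies
#' the residual and the truncation tail mass.  When the tail criterion
#' `P(m = M_max) < tail_tol` (and under turnover `P(r = R_max) <
#' tail_tol`) fails, the truncation is doubled and the solve repeated.
#'
#' @param model A [switch_model()].
#' @param M_max mRNA truncation; default `alpha/beta + 10*sqrt(alpha/beta)`
#'   (the constitutive Poisson bound).
#' @param R_max Free-repressor truncation under turnover.
#' @param tail_tol Maximum allowed probability on a truncation boundary.
#' @param rtol Residual tolerance for the stationary solve.
#' @param auto_truncate Double the truncation until the tail criterion
#'   passes (at most `max_doublings` times).
#' @param max_doublings Upper bound on automatic doublings.
#' @return A `switch_steady_state` object: state space, probability vector,
#'   mRNA marginal, transcriptional activity (probability of a transcribing
#'   promoter state) and solve diagnostics.
#' @export
steady_state <- function(model, M_max = NULL, R_max = NULL,
                         tail_tol = 1e-8, rtol = 1e-10,
                         auto_truncate = TRUE, max_doublings = 6L) {
  stopifnot(inherits(model, "switch_model"))
  if (is.null(M_max)) {
    mu <- model$params$alpha / model$params$beta
    M_max <- ceiling(mu + 10 * sqrt(mu))
  }
  for (k in seq_len(max_doublings + 1L)) {
    space <- enumerate_states(model, M_max = M_max, R_max = R_max)
    Q <- build_generator(model, space)
    sol <- .solve_stationary(Q, rtol = rtol)
    marginal <- as.numeric(rowsum(sol$p, space$m))
    tail_m <- if (M_max > 0) marginal[length(marginal)] else 0
    tail_r <- 0
    if (!is.na(space$R_max)) {
      ridx <- match("R", model$species)
      tail_r <- sum(sol$p[space$states[, ridx] == space$R_max])
    }
    if ((tail_m < tail_tol && tail_r < tail_tol) || !auto_truncate) break
    if (k > max_doublings)
      stop("truncation tail mass ", format(max(tail_m, tail_r)),
           " above ", format(tail_tol),
           " after ", max_doublings, " doublings; raise M_max/R_max",
           call. = FALSE)
    if (tail_m >= tail_tol) M_max <- 2L * max(M_max, 1L)
    if (tail_r >= tail_tol) R_max <- 2L * space$R_max
  }
  if (!auto_truncate && (tail_m >= tail_tol || tail_r >= tail_tol))
    stop("truncation tail mass ", format(max(tail_m, tail_r)),
         " above ", format(tail_tol), "; raise M_max/R_max", call. = FALSE)
  structure(list(
    model = model, space = space, p = sol$p, marginal = marginal,
    activity = sum(sol$p[space$transcribing]),
    residual = sol$residual, M_max = space$M_max, R_max = space$R_max,
    tail_mass = max(tail_m, tail_r)
  ), class = "switch_steady_state")
}

#' @export
print.switch_steady_state <- function(x, ...) {
  ns <- noise_summary(x)
  cat("<switch_steady_state> ", x$space$n, " states, residual ",
      format(x$residual, digits = 3), "\n", sep = "")
  cat(sprintf("  activity %.4f | mRNA mean %.3f var %.3f Fano %.3f (%s)\n",
              x$activity, ns$mean, ns$variance, ns$fano,
              if (ns$n_modes == 1) "unimodal"
              else paste0(ns$n_modes, " modes")))
  invisible(x)
}

#' mRNA noise summary of a stationary distribution
#'
#' Moments of the stationary mRNA marginal plus the number of modes (local
#' maxima after merging plateaus, counting only peaks carrying at least
#' `min_peak` probability).  For zero mean the CV is undefined (`NA`) and
#' the Fano factor is reported as the Poisson limit 1 only when the
#' variance is also zero, otherwise flagged `NA`.
#'
#' @param x A `switch_steady_state`, or a numeric probability vector over
#'   mRNA counts `0, 1, 2, ...`.
#' @param min_peak Minimum probability mass at a local maximum for it to
#'   count as a mode.
#' @return List with `mean`, `variance`, `fano`, `cv`, `n_modes`.
#' @export
noise_summary <- function(x, min_peak = 1e-4) {
  marginal <- if (inherits(x, "switch_steady_state")) x$marginal
              else as.numeric(x)
  marginal <- marginal / sum(marginal)
  m <- seq_along(marginal) - 1
  mu <- sum(m * marginal)
  v <- sum((m - mu)^2 * marginal)
  fano <- if (mu > 0) v / mu else if (v == 0) 1 else NA_real_
  cv <- if (mu > 0) sqrt(v) / mu else NA_real_
  list(mean = mu, variance = v, fano = fano, cv = cv,
       n_modes = .count_modes(marginal, min_peak))
}

# local maxima of a discrete distribution, merging equal-probability
# plateaus, requiring peak mass >= min_peak
.count_modes <- function(pr, min_peak) {
  r <- rle(pr)
  v <- r$values
  k <- length(v)
  if (k == 1) return(as.integer(v[1] >= min_peak))
  left <- c(-Inf, v[-k])
  right <- c(v[-1], -Inf)
  sum(v > left & v > right & v >= min_peak)
}

#' Noise statistics along a load grid
#'
#' One stationary CME solve per normalized load, summarizing the mRNA
#' marginal at each point.
#'
#' @param params A [switch_params()] object.
#' @param loads Vector of normalized loads.
#' @param M_max Optional fixed mRNA truncation (established automatically
#'   at the first load and reused otherwise).
#' @param ... Passed to [steady_state()].
#' @return A data frame with columns `Rt_tilde`, `activity`, `mean`,
#'   `variance`, `fano`, `cv`.
#' @export
fano_curve <- function(params, loads, M_max = NULL, ...) {
  stopifnot(inherits(params, "switch_params"))
  rows <- vector("list", length(loads))
  for (i in seq_along(loads)) {
    ss <- tryCatch(
      steady_state(switch_model(with_load(params, loads[i])),
                   M_max = M_max, ...),
      error = function(e)
        stop("fano_curve failed at load Rt_tilde = ", format(loads[i]),
             ": ", conditionMessage(e), call. = FALSE))
    if (is.null(M_max)) M_max <- ss$M_max
    ns <- noise_summary(ss)
    rows[[i]] <- data.frame(Rt_tilde = loads[i], activity = ss$activity,
                            mean = ns$mean, variance = ns$variance,
                            fano = ns$fano, cv = ns$cv)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("fano_curve", "data.frame"),
            architecture = params$architecture,
            normalized = normalized_params(params))
}

#' @export
plot.fano_curve <- function(x, ...) {
  graphics::plot(x$Rt_tilde, x$fano, type = "l",
                 xlab = expression(tilde(R)[T]), ylab = "Fano factor", ...)
  invisible(x)
}

# ---- engine-validation models -------------------------------------------

#' Two-state telegraph and constitutive models
#'
#' Minimal promoter models with known closed-form stationary statistics,
#' used to validate the CME and SSA engines.  The telegraph model switches
#' between an off and an on promoter state at constant rates and
#' transcribes only from the on state; its stationary mRNA mean is
#' `alpha/beta * k_on/(k_on + k_off)` and its Fano factor
#' `1 + alpha * k_off / ((k_on + k_off) * (k_on + k_off + beta))`.  The
#' constitutive model is always on and has a Poisson stationary
#' distribution with mean `alpha/beta`.
#'
#' @param k_on,k_off Promoter switching rates (1/time).
#' @param alpha,beta Transcription and mRNA decay rates.
#' @return A `switch_model` usable with [steady_state()] and [simulate()].
#' @export
telegraph_model <- function(k_on, k_off, alpha, beta) {
  stopifnot(k_on > 0, k_off > 0, alpha > 0, beta > 0)
  species <- c("OFF", "ON", "M")
  rx <- list(
    list(name = "switch_on", rate = k_on, r1 = 1L, r2 = NA_integer_,
         stoich = c(-1L, 1L, 0L)),
    list(name = "switch_off", rate = k_off, r1 = 2L, r2 = NA_integer_,
         stoich = c(1L, -1L, 0L)),
    list(name = "transcription", rate = alpha, r1 = 2L, r2 = NA_integer_,
         stoich = c(0L, 0L, 1L)),
    list(name = "mrna_decay", rate = beta, r1 = 3L, r2 = NA_integer_,
         stoich = c(0L, 0L, -1L))
  )
  params <- structure(list(architecture = "telegraph", alpha = alpha,
                           beta = beta, k_on = k_on, k_off = k_off,
                           R_T = NA, turnover = NULL),
                      class = "switch_params")
  .new_model(params, species, init = c(1L, 0L, 0L), rx,
             promoter = c(1L, 2L), transcribing = c(FALSE, TRUE),
             mrna = 3L, cons_A = NULL, cons_R = NULL)
}

#' @rdname telegraph_model
#' @export
constitutive_model <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  species <- c("ON", "M")
  rx <- list(
    list(name = "transcription", rate = alpha, r1 = 1L, r2 = NA_integer_,
         stoich = c(0L, 1L)),
    list(name = "mrna_decay", rate = beta, r1 = 2L, r2 = NA_integer_,
         stoich = c(0L, -1L))
  )
  params <- structure(list(architecture = "constitutive", alpha = alpha,
                           beta = beta, R_T = NA, turnover = NULL),
                      class = "switch_params")
  .new_model(params, species, init = c(1L, 0L), rx,
             promoter = 1L, transcribing = TRUE,
             mrna = 2L, cons_A = NULL, cons_R = NULL)
}
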