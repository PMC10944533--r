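#' Build the stochastic reaction network of a switch
#'
#' Translates a parameter set into an explicit finite mass-action reaction
#' network over a single gene copy.  Promoter states are represented as
#' mutually exclusive indicator species (occupancy states `E000`..`E111`
#' for the cooperative architecture; `E_F` free, `E_A` activator-bound and,
#' in the blocking/displacement architectures, `E_R` repressed for the
#' sequestration family), so that every reaction is first or second order
#' mass action.
#'
#' Kinetic convention: every binding reaction uses the shared association
#' rate constant `k_on`; the paired dissociation rate is `k_on * K` with
#' the dissociation constant `K` of that reaction.  For the cooperative
#' architecture the repressor pool is treated as an undepleted reservoir
#' (binding propensity proportional to `R_T`, which may be non-integer):
#' at most three of `R_T` molecules can be bound at once, and the published
#' activity and noise statistics are continuous functions of the load
#' `R_T / K_r`.  The sequestration family tracks every molecule discretely
#' and conserves `A_T` and (without turnover) `R_T` exactly.
#'
#' @param params A [switch_params()] object with `R_T` set (see
#'   [with_load()]).
#' @return An object of class `switch_model` with components `species`,
#'   `init` (default initial state: free promoter, nothing bound, no mRNA),
#'   `stoich` (species-by-reaction stoichiometry), per-reaction rate
#'   constants and reactant indices, promoter bookkeeping and conservation
#'   coefficient vectors.
#' @examples
#' m <- switch_model(with_load(preset_params("sequestration_strong"), 0.9))
#' m
#' @export
switch_model <- function(params) {
  stopifnot(inherits(params, "switch_params"))
  validate_params(params)
  if (is.null(params$R_T))
    stop("R_T is unset; fix the repressor load first, e.g. ",
         "with_load(params, Rt_tilde)", call. = FALSE)
  if (.seq_family(params$architecture)) .build_seq_model(params)
  else .build_coop_model(params)
}

# -- sequestration family -------------------------------------------------

.build_seq_model <- function(p) {
  has_block <- p$architecture %in%
    c("sequestration_blocking", "sequestration_blocking_displacement")
  has_disp <- p$architecture == "sequestration_blocking_displacement"
  turnover <- !is.null(p$turnover)

  species <- c("E_F", "E_A", if (has_block) "E_R", "A", "R", "RA", "M")
  idx <- setNames(seq_along(species), species)
  nsp <- length(species)

  rx <- list()
  add <- function(name, rate, r1 = NA_integer_, r2 = NA_integer_, d) {
    v <- setNames(integer(nsp), species)
    v[names(d)] <- unlist(d)
    rx[[length(rx) + 1L]] <<- list(name = name, rate = rate,
                                   r1 = r1, r2 = r2, stoich = unname(v))
  }
  k <- p$k_on
  add("activator_binding", k, idx["E_F"], idx["A"],
      list(E_F = -1L, A = -1L, E_A = 1L))
  add("activator_unbinding", k * p$K_a, idx["E_A"], NA,
      list(E_A = -1L, E_F = 1L, A = 1L))
  add("sequestration", k, idx["A"], idx["R"],
      list(A = -1L, R = -1L, RA = 1L))
  add("complex_dissociation", k * p$K_s, idx["RA"], NA,
      list(RA = -1L, A = 1L, R = 1L))
  if (has_block) {
    add("blocking", k, idx["E_A"], idx["R"],
        list(E_A = -1L, R = -1L, E_R = 1L))
    add("unblocking", k * p$K_b, idx["E_R"], NA,
        list(E_R = -1L, E_A = 1L, R = 1L))
  }
  if (has_disp) {
    add("displacement", k * p$K_d, idx["E_R"], NA,
        list(E_R = -1L, E_F = 1L, RA = 1L))
    add("complex_dna_binding", k, idx["E_F"], idx["RA"],
        list(E_F = -1L, RA = -1L, E_R = 1L))
  }
  add("transcription", p$alpha, idx["E_A"], NA, list(M = 1L))
  add("mrna_decay", p$beta, idx["M"], NA, list(M = -1L))
  if (turnover) {
    add("repressor_production", p$turnover$r_prod, NA, NA, list(R = 1L))
    add("repressor_degradation", p$turnover$r_deg, idx["R"], NA,
        list(R = -1L))
    if (p$turnover$deg_complex) {
      add("complex_repressor_degradation", p$turnover$r_deg, idx["RA"], NA,
          list(RA = -1L, A = 1L))
      if (has_block)
        add("blocked_repressor_degradation", p$turnover$r_deg, idx["E_R"],
            NA, list(E_R = -1L, E_A = 1L))
    }
  }

  init <- integer(nsp)
  init[idx["E_F"]] <- 1L
  init[idx["A"]] <- as.integer(p$A_T)
  init[idx["R"]] <- as.integer(p$R_T)

  cons_A <- integer(nsp)
  cons_A[idx[c("E_A", "A", "RA")]] <- 1L
  if (has_block) cons_A[idx["E_R"]] <- 1L
  cons_R <- integer(nsp)
  cons_R[idx[c("R", "RA")]] <- 1L
  if (has_block) cons_R[idx["E_R"]] <- 1L

  .new_model(p, species, init, rx,
             promoter = idx[c("E_F", "E_A", if (has_block) "E_R")],
             transcribing = c(FALSE, TRUE, if (has_block) FALSE),
             mrna = idx["M"], cons_A = cons_A,
             cons_R = if (turnover) NULL else cons_R)
}

# -- cooperative binding --------------------------------------------------

.coop_state_names <- function() {
  vapply(0:7, function(s)
    paste0("E", paste(rev(as.integer(intToBits(s)[1:3])), collapse = "")),
    "")
}

.build_coop_model <- function(p) {
  turnover <- !is.null(p$turnover)
  pnames <- .coop_state_names()
  species <- c(pnames, if (turnover) "R", "M")
  idx <- setNames(seq_along(species), species)
  nsp <- length(species)

  rx <- list()
  add <- function(name, rate, r1 = NA_integer_, r2 = NA_integer_, d) {
    v <- setNames(integer(nsp), species)
    v[names(d)] <- unlist(d)
    rx[[length(rx) + 1L]] <<- list(name = name, rate = rate,
                                   r1 = r1, r2 = r2, stoich = unname(v))
  }
  popcount <- function(s) sum(as.integer(intToBits(s)[1:3]))
  for (s in 0:7) {
    j <- popcount(s)
    for (site in 0:2) {
      bit <- bitwAnd(s, bitwShiftL(1L, site)) > 0L
      if (!bit) {
        # binding raises occupancy j -> j + 1 (dissociation constant c^j K_r)
        tgt <- bitwOr(s, bitwShiftL(1L, site))
        if (turnover) {
          d <- list(-1L, 1L, -1L)
          names(d) <- c(pnames[s + 1L], pnames[tgt + 1L], "R")
          add(sprintf("bind_site%d_%s", site + 1L, pnames[s + 1L]),
              p$k_on, idx[pnames[s + 1L]], idx["R"], d)
        } else {
          d <- list(-1L, 1L)
          names(d) <- c(pnames[s + 1L], pnames[tgt + 1L])
          add(sprintf("bind_site%d_%s", site + 1L, pnames[s + 1L]),
              p$k_on * p$R_T, idx[pnames[s + 1L]], NA, d)
        }
      } else {
        tgt <- bitwAnd(s, bitwNot(bitwShiftL(1L, site)))
        K <- p$c^(j - 1L) * p$K_r
        d <- if (turnover) {
          dd <- list(-1L, 1L, 1L)
          names(dd) <- c(pnames[s + 1L], pnames[tgt + 1L], "R")
          dd
        } else {
          dd <- list(-1L, 1L)
          names(dd) <- c(pnames[s + 1L], pnames[tgt + 1L])
          dd
        }
        add(sprintf("unbind_site%d_%s", site + 1L, pnames[s + 1L]),
            p$k_on * K, idx[pnames[s + 1L]], NA, d)
      }
    }
    if (s != 7L)
      add(sprintf("transcription_%s", pnames[s + 1L]), p$alpha,
          idx[pnames[s + 1L]], NA, list(M = 1L))
  }
  add("mrna_decay", p$beta, idx["M"], NA, list(M = -1L))
  if (turnover) {
    add("repressor_production", p$turnover$r_prod, NA, NA, list(R = 1L))
    add("repressor_degradation", p$turnover$r_deg, idx["R"], NA,
        list(R = -1L))
    if (p$turnover$deg_complex) {
      # DNA-bound repressor degrades in place (site emptied, no R released)
      for (s in 1:7) for (site in 0:2) {
        if (bitwAnd(s, bitwShiftL(1L, site)) > 0L) {
          tgt <- bitwAnd(s, bitwNot(bitwShiftL(1L, site)))
          d <- list(-1L, 1L)
          names(d) <- c(pnames[s + 1L], pnames[tgt + 1L])
          add(sprintf("degrade_site%d_%s", site + 1L, pnames[s + 1L]),
              p$turnover$r_deg, idx[pnames[s + 1L]], NA, d)
        }
      }
    }
  }

  init <- integer(nsp)
  init[idx["E000"]] <- 1L
  if (turnover) init[idx["R"]] <- as.integer(round(p$R_T))

  .new_model(p, species, init, rx,
             promoter = idx[pnames],
             transcribing = c(rep(TRUE, 7), FALSE),
             mrna = idx["M"], cons_A = NULL, cons_R = NULL)
}

.new_model <- function(params, species, init, rx, promoter, transcribing,
                       mrna, cons_A, cons_R) {
  stoich <- vapply(rx, `[[`, integer(length(species)), "stoich")
  structure(list(
    architecture = params$architecture,
    params = params,
    species = species,
    init = init,
    stoich = matrix(stoich, nrow = length(species),
                    dimnames = list(species, vapply(rx, `[[`, "", "name"))),
    rate = vapply(rx, `[[`, 0, "rate"),
    r1 = vapply(rx, `[[`, 0L, "r1"),
    r2 = vapply(rx, `[[`, 0L, "r2"),
    promoter = promoter,
    transcribing = transcribing,
    mrna = mrna,
    cons_A = cons_A,
    cons_R = cons_R
  ), class = "switch_model")
}

#' Reaction table of a switch model
#'
#' @param model A `switch_model`.
#' @return A data frame with one row per reaction: name, rate constant, and
#'   human-readable reactant and product strings.
#' @export
reactions <- function(model) {
  stopifnot(inherits(model, "switch_model"))
  fmt <- function(v, sign) {
    i <- which(sign * v > 0)
    if (!length(i)) return("0")
    paste(ifelse(abs(v[i]) > 1, paste0(abs(v[i]), " "), ""),
          model$species[i], sep = "", collapse = " + ")
  }
  # reactants = consumed species plus catalytic reactants (e.g. transcription)
  data.frame(
    name = colnames(model$stoich),
    rate = model$rate,
    reactants = vapply(seq_along(model$rate), function(j) {
      v <- model$stoich[, j]
      cat_sp <- setdiff(stats::na.omit(c(model$r1[j], model$r2[j])),
                        which(v < 0))
      r <- fmt(v, -1)
      if (length(cat_sp))
        r <- paste(c(if (r != "0") r, model$species[cat_sp]),
                   collapse = " + ")
      r
    }, ""),
    products = vapply(seq_along(model$rate), function(j) {
      v <- model$stoich[, j]
      cat_sp <- setdiff(stats::na.omit(c(model$r1[j], model$r2[j])),
                        which(v < 0))
      pr <- fmt(v, 1)
      if (length(cat_sp))
        pr <- paste(c(if (pr != "0") pr, model$species[cat_sp]),
                    collapse = " + ")
      pr
    }, ""),
    row.names = NULL
  )
}

#' Propensities of all reactions in given states
#'
#' Mass-action propensities; `states` is a matrix with one row per state
#' and one column per species.
#' @param model A `switch_model`.
#' @param states Integer matrix (rows = states, columns = species).
#' @return Matrix of propensities, rows = states, columns = reactions.
#' @export
propensities <- function(model, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  n <- nrow(states)
  a <- matrix(rep(model$rate, each = n), nrow = n)
  for (j in seq_along(model$rate)) {
    if (!is.na(model$r1[j])) a[, j] <- a[, j] * states[, model$r1[j]]
    if (!is.na(model$r2[j])) a[, j] <- a[, j] * states[, model$r2[j]]
  }
  colnames(a) <- colnames(model$stoich)
  a
}

#' Conserved molecule totals of a system state
#'
#' For the sequestration family, the total activator count
#' `A + RA + [promoter holds A]` and total repressor count
#' `R + RA + [promoter holds R]` are invariant along every trajectory
#' (the repressor total only while turnover is disabled).  For the
#' cooperative architecture the repressor is an undepleted reservoir, so
#' the repressor total is the constant `R_T` by construction and the
#' activator total is not defined (`NA`).
#'
#' @param model A `switch_model`.
#' @param state Named or positional integer vector of species counts.
#' @return Named numeric vector `c(A_total =, R_total =)`.
#' @export
conserved_totals <- function(model, state) {
  stopifnot(inherits(model, "switch_model"))
  if (!is.null(names(state))) state <- state[model$species]
  state <- as.numeric(state)
  if (length(state) != length(model$species))
    stop("state must have one count per species", call. = FALSE)
  if (any(state < 0))
    stop("invariant violation: negative species count", call. = FALSE)
  if (is.null(model$cons_A))
    return(c(A_total = NA_real_,
             R_total = if (is.null(model$params$turnover))
               model$params$R_T else NA_real_))
  c(A_total = sum(model$cons_A * state),
    R_total = if (is.null(model$cons_R)) NA_real_
              else sum(model$cons_R * state))
}

#' @export
print.switch_model <- function(x, ...) {
  cat("<switch_model> ", x$architecture, "\n", sep = "")
  cat("  species:  ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  reactions:", ncol(x$stoich), "\n")
  cat("  load Rt_tilde =",
      format(normalized_params(x$params)$Rt_tilde), "\n")
  invisible(x)
}

#' @export
summary.switch_model <- function(object, ...) {
  print(object)
  print(reactions(object))
  invisible(object)
}
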