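#' Switch architectures
#'
#' The four promoter architectures supported by the package.
#' `cooperative_binding` is the direct-repression switch: a repressor R binds
#' three operator sites with sequential dissociation constants `K_r`,
#' `c*K_r`, `c^2*K_r` and transcription is silenced only when all three
#' sites are occupied.  The remaining three architectures repress
#' indirectly: a repressor sequesters the free activator in solution
#' (`sequestration`), additionally binds the DNA-bound activator
#' (`sequestration_blocking`), and additionally evicts the DNA-bound
#' activator-repressor complex from the promoter
#' (`sequestration_blocking_displacement`).
#'
#' @return Character vector of architecture names.
#' @export
switch_architectures <- function() {
  c("cooperative_binding", "sequestration", "sequestration_blocking",
    "sequestration_blocking_displacement")
}

.seq_family <- function(architecture) architecture != "cooperative_binding"

# constants each architecture requires / understands
.arch_constants <- list(
  cooperative_binding                 = c("K_r", "c"),
  sequestration                       = c("K_a", "K_s"),
  sequestration_blocking              = c("K_a", "K_s", "K_b"),
  sequestration_blocking_displacement = c("K_a", "K_s", "K_b", "K_d")
)

#' Parameter set for a transcriptional switch
#'
#' Collects all kinetic and thermodynamic constants of one switch instance.
#' All dissociation constants are in molecules, rates in units of the mRNA
#' decay rate `beta` (the package convention is `beta = 1`, which defines
#' the unit of time).  Binding kinetics are split with a single shared
#' association rate constant `k_on` (per molecule per time); every
#' dissociation rate is `k_on * K` with the `K` of that reaction, so that
#' equilibrium constants are honoured exactly.
#'
#' @param architecture One of [switch_architectures()].
#' @param alpha mRNA transcription rate from a transcribing promoter state.
#' @param beta mRNA decay rate per molecule.
#' @param k_on Shared association rate constant (1/(molecule*time)).
#'   Activity curves are independent of `k_on`; noise statistics are not.
#' @param A_T Total activator copy number (sequestration family).
#' @param R_T Total repressor copy number.  May be left `NULL` and supplied
#'   later via [with_load()]; for the cooperative architecture `R_T` is a
#'   reservoir level and may be non-integer.
#' @param K_r,c Repressor-DNA dissociation constant and cooperativity factor
#'   (`0 < c <= 1`) of the cooperative architecture.
#' @param K_a Activator-DNA dissociation constant (molecules).
#' @param K_s Sequestration (activator-repressor) dissociation constant.
#' @param K_b Blocking dissociation constant (repressor binding the
#'   DNA-bound activator).
#' @param K_d Displacement dissociation constant (activator-repressor
#'   complex leaving the DNA).
#' @param turnover `NULL` for a fixed repressor pool, or a list with
#'   elements `r_prod` (repressor production, molecules/time), `r_deg`
#'   (repressor degradation, 1/time) and optionally `deg_complex`
#'   (logical, default `TRUE`: the repressor degrades wherever it sits,
#'   free or complexed, so the total pool fluctuates around
#'   `r_prod / r_deg`; `FALSE` degrades free repressor only, which pins the
#'   stationary mean of the *free* pool at `r_prod / r_deg` instead).
#'   With turnover enabled `R_T` is the initial count.
#'
#' @return An object of class `switch_params` (a validated list).
#' @examples
#' p <- switch_params("sequestration", K_a = 0.5, K_s = 0.0025, A_T = 100)
#' normalized_params(with_load(p, 0.9))
#' @export
switch_params <- function(architecture = switch_architectures(),
                          alpha = 20, beta = 1, k_on = 0.1,
                          A_T = 100, R_T = NULL,
                          K_r = NULL, c = NULL,
                          K_a = NULL, K_s = NULL, K_b = NULL, K_d = NULL,
                          turnover = NULL) {
  architecture <- match.arg(architecture)
  supplied <- list(K_r = K_r, c = c, K_a = K_a, K_s = K_s,
                   K_b = K_b, K_d = K_d)
  need <- .arch_constants[[architecture]]
  missing_k <- need[vapply(supplied[need], is.null, TRUE)]
  if (length(missing_k))
    stop("architecture '", architecture, "' requires constant(s): ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, TRUE)], need)
  if (length(extra))
    warning("constant(s) ", paste(extra, collapse = ", "),
            " are irrelevant for architecture '", architecture,
            "' and are ignored", call. = FALSE)
  supplied[extra] <- list(NULL)

  p <- c(list(architecture = architecture, alpha = alpha, beta = beta,
              k_on = k_on, A_T = A_T, R_T = R_T),
         supplied[!vapply(supplied, is.null, TRUE)],
         list(turnover = .check_turnover(turnover)))
  class(p) <- "switch_params"
  validate_params(p)
  p
}

.check_turnover <- function(turnover) {
  if (is.null(turnover)) return(NULL)
  if (!is.list(turnover) || !all(c("r_prod", "r_deg") %in% names(turnover)))
    stop("turnover must be a list with elements r_prod and r_deg",
         call. = FALSE)
  unknown <- setdiff(names(turnover), c("r_prod", "r_deg", "deg_complex"))
  if (length(unknown))
    stop("unknown turnover field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(turnover$deg_complex)) turnover$deg_complex <- TRUE
  turnover$deg_complex <- isTRUE(turnover$deg_complex)
  if (turnover$r_prod <= 0 || turnover$r_deg <= 0)
    stop("turnover rates must be strictly positive", call. = FALSE)
  turnover
}

#' @rdname switch_params
#' @param p A `switch_params` object.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "switch_params"))
  pos <- c("alpha", "beta", "k_on",
           intersect(names(p), c("K_r", "c", "K_a", "K_s", "K_b", "K_d")))
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  if (!is.null(p$c) && p$c > 1)
    stop("cooperativity factor c must satisfy 0 < c <= 1 (got ", p$c, ")",
         call. = FALSE)
  if (.seq_family(p$architecture)) {
    if (!is.numeric(p$A_T) || p$A_T < 0 || p$A_T != round(p$A_T))
      stop("A_T must be a non-negative integer", call. = FALSE)
    if (!is.null(p$R_T) && (p$R_T < 0 || p$R_T != round(p$R_T)))
      stop("R_T must be a non-negative integer for the sequestration family",
           call. = FALSE)
  } else if (!is.null(p$R_T) && p$R_T < 0) {
    stop("R_T must be non-negative", call. = FALSE)
  }
  invisible(p)
}

#' Set the repressor load of a parameter set
#'
#' The normalized load is `R_T / K_r` for the cooperative architecture and
#' the molar ratio `R_T / A_T` for the sequestration family.  For the
#' sequestration family the implied total repressor count is rounded to the
#' nearest integer (copy numbers are discrete); for the cooperative
#' architecture the repressor is a reservoir and the load is continuous.
#' With turnover enabled the load sets `r_prod = load * scale * r_deg`, so
#' the stationary mean of the fluctuating repressor pool matches the fixed
#' pool it replaces.
#'
#' @param p A `switch_params` object.
#' @param Rt_tilde Normalized repressor load (non-negative scalar).
#' @return The parameter set with `R_T` (and, under turnover, `r_prod`) set.
#' @export
with_load <- function(p, Rt_tilde) {
  stopifnot(inherits(p, "switch_params"), Rt_tilde >= 0)
  scale <- if (.seq_family(p$architecture)) p$A_T else p$K_r
  R_T <- Rt_tilde * scale
  if (.seq_family(p$architecture)) R_T <- round(R_T)
  p$R_T <- R_T
  if (!is.null(p$turnover)) {
    if (Rt_tilde == 0) {
      # the r_prod -> 0 stationary limit is the repressor-free fixed model
      p$turnover <- NULL
      p$R_T <- 0
    } else {
      p$turnover$r_prod <- Rt_tilde * scale * p$turnover$r_deg
      p$R_T <- round(Rt_tilde * scale)
      p$turnover <- .check_turnover(p$turnover)
    }
  }
  validate_params(p)
  p
}

#' Normalized (dimensionless) parameters
#'
#' Expresses a parameter set in the units used throughout the analysis:
#' dissociation constants divided by the total activator count `A_T`
#' (sequestration family) and the repressor load divided by `K_r`
#' (cooperative) or `A_T` (sequestration family).
#'
#' @param p A `switch_params` object.
#' @return Named list of normalized quantities present for the architecture.
#' @seealso [params_from_normalized()] for the inverse map.
#' @export
normalized_params <- function(p) {
  stopifnot(inherits(p, "switch_params"))
  if (.seq_family(p$architecture)) {
    out <- list(Rt_tilde = if (is.null(p$R_T)) NULL else p$R_T / p$A_T,
                Ka_tilde = p$K_a / p$A_T, Ks_tilde = p$K_s / p$A_T)
    if (!is.null(p$K_b)) out$Kb_tilde <- p$K_b / p$A_T
    if (!is.null(p$K_d)) out$Kd_tilde <- p$K_d / p$A_T
  } else {
    out <- list(Rt_tilde = if (is.null(p$R_T)) NULL else p$R_T / p$K_r,
                c = p$c)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' @rdname normalized_params
#' @param architecture One of [switch_architectures()] (sequestration family).
#' @param normalized Named list/vector with `Ka_tilde`, `Ks_tilde` and, as
#'   required by the architecture, `Kb_tilde`, `Kd_tilde`, plus optionally
#'   `Rt_tilde`.
#' @param A_T Total activator copy number fixing the molecule scale.
#' @param ... Passed on to [switch_params()] (e.g. `alpha`, `k_on`,
#'   `turnover`).
#' @export
params_from_normalized <- function(architecture, normalized, A_T = 100, ...) {
  stopifnot(.seq_family(architecture))
  n <- as.list(normalized)
  p <- switch_params(architecture,
                     A_T = A_T,
                     K_a = n$Ka_tilde * A_T,
                     K_s = n$Ks_tilde * A_T,
                     K_b = if (!is.null(n$Kb_tilde)) n$Kb_tilde * A_T,
                     K_d = if (!is.null(n$Kd_tilde)) n$Kd_tilde * A_T,
                     ...)
  if (!is.null(n$Rt_tilde)) p <- with_load(p, n$Rt_tilde)
  p
}

#' Figure-parameter presets
#'
#' Parameter sets used for the package's reference analyses.  The
#' dissociation constants were calibrated once so that each architecture
#' reproduces its published sensitivity regime (effective Hill coefficient
#' about 1.3 without cooperativity and 3 with strong cooperativity; about
#' 50 for strong-activator sequestration with or without blocking; about 2
#' for a weak activator; about 200 for the triple-mechanism switch), and
#' are shipped as a versioned configuration (`inst/extdata/presets.yaml`)
#' rather than hard-coded values.
#'
#' @param name Preset name, one of `"cooperative"`,
#'   `"cooperative_noncooperative"`, `"sequestration_strong"`,
#'   `"sequestration_weak"`, `"sequestration_blocking"`,
#'   `"sequestration_blocking_displacement"`.
#' @param ... Overrides passed to [switch_params()] (e.g. `A_T`, `k_on`,
#'   `turnover`).
#' @return A `switch_params` object.
#' @export
preset_params <- function(name, ...) {
  presets <- .load_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  spec <- presets[[name]]
  args <- modifyList(spec, list(...))
  do.call(switch_params, args)
}

.load_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "switchnoise")
  if (path == "") path <- file.path("inst", "extdata", "presets.yaml")
  yaml::read_yaml(path)
}

#' Thermodynamic consistency of the displacement cycle
#'
#' The displacement architecture closes a promoter cycle
#' `E_F -> E_A -> E_R -> E_F`.  The cycle satisfies detailed balance only
#' when the product of equilibrium constants around it is one, i.e. when
#' `(K_a * K_b) / (K_s * K_d) == 1`.  When the ratio differs from one the
#' promoter cycle is driven and its stationary distribution depends on the
#' kinetic splitting (here: one shared `k_on`), not only on the
#' dissociation constants.
#'
#' @param p A `switch_params` object of the displacement architecture.
#' @return The dimensionless ratio `(K_a * K_b) / (K_s * K_d)`.
#' @export
thermo_cycle_gap <- function(p) {
  stopifnot(inherits(p, "switch_params"))
  if (p$architecture != "sequestration_blocking_displacement")
    stop("thermo_cycle_gap applies to the displacement architecture only",
         call. = FALSE)
  (p$K_a * p$K_b) / (p$K_s * p$K_d)
}

#' @export
print.switch_params <- function(x, ...) {
  cat("<switch_params> ", x$architecture,
      if (!is.null(x$turnover)) " (repressor turnover)", "\n", sep = "")
  ks <- intersect(names(x), c("K_r", "c", "K_a", "K_s", "K_b", "K_d"))
  for (nm in ks) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  cat("  alpha = ", x$alpha, ", beta = ", x$beta, ", k_on = ", x$k_on,
      "\n", sep = "")
  if (.seq_family(x$architecture)) cat("  A_T = ", x$A_T, "\n", sep = "")
  cat("  R_T = ", if (is.null(x$R_T)) "<unset>" else format(x$R_T),
      "\n", sep = "")
  invisible(x)
}
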