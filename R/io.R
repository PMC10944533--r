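#' Load a run configuration
#'
#' Reads a YAML configuration with the architecture, its parameter section
#' and optional run options.  Unknown keys are errors (no silent typos);
#' parameters left at their defaults are reported so a run manifest can
#' record them as defaulted.
#'
#' Layout:
#' ```yaml
#' architecture: sequestration
#' parameters:            # arguments of switch_params()
#'   K_a: 0.5
#'   K_s: 0.0025
#'   A_T: 100
#' load: 0.9              # optional normalized repressor load
#' seed: 1                # optional
#' turnover:              # optional
#'   r_prod: 0.05
#'   r_deg: 0.001
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with `params` (a [switch_params()] object, load applied when
#'   given), `load`, `seed`, and `defaults` (names of parameters that were
#'   not set explicitly).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known_top <- c("architecture", "parameters", "load", "seed", "turnover")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$architecture))
    stop("config must name an architecture", call. = FALSE)
  pars <- cfg$parameters
  if (is.null(pars)) pars <- list()
  known_par <- setdiff(names(formals(switch_params)),
                       c("architecture", "turnover"))
  unknown <- setdiff(names(pars), known_par)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- setdiff(c("alpha", "beta", "k_on", "A_T"), names(pars))
  params <- do.call(switch_params,
                    c(list(architecture = cfg$architecture,
                           turnover = cfg$turnover), pars))
  if (!is.null(cfg$load)) params <- with_load(params, cfg$load)
  list(params = params, load = cfg$load, seed = cfg$seed,
       defaults = defaults)
}

#' Write a resolved configuration
#'
#' Inverse of [load_config()]: serializes a parameter set (plus optional
#' load and seed) so that reloading reproduces it exactly.
#'
#' @param params A [switch_params()] object.
#' @param path Output YAML path.
#' @param load,seed Optional run options to embed.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, load = NULL, seed = NULL) {
  stopifnot(inherits(params, "switch_params"))
  pars <- params[intersect(names(params),
                           c("alpha", "beta", "k_on", "A_T", "R_T", "K_r",
                             "c", "K_a", "K_s", "K_b", "K_d"))]
  pars$R_T <- NULL
  cfg <- list(architecture = params$architecture, parameters = pars)
  if (!is.null(params$turnover)) cfg$turnover <- params$turnover
  if (!is.null(load)) cfg$load <- load
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# deterministic number formatting: '.' decimal, scientific below 1e-4
.fmt_cell <- function(x) {
  if (is.na(x)) return("NA")
  if (!is.numeric(x)) return(as.character(x))
  if (x == 0) return("0")
  if (abs(x) < 1e-4) sprintf("%.6e", x) else sprintf("%.8g", x)
}

#' Write a deterministic TSV table
#'
#' Fixed column order, `.` decimal separator, scientific notation below
#' `1e-4`, `NA` for missing cells; byte-identical output for identical
#' input.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param schema Optional character vector of required column names (order
#'   enforced); a mismatch is an error.
#' @return `path`, invisibly.
#' @export
write_switch_table <- function(rows, path, schema = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(schema)) {
    if (!setequal(names(rows), schema))
      stop("table columns do not match the schema: expected {",
           paste(schema, collapse = ", "), "}, got {",
           paste(names(rows), collapse = ", "), "}", call. = FALSE)
    rows <- rows[, schema, drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = "\t"), con)
  if (nrow(rows)) {
    cells <- vapply(seq_len(nrow(rows)), function(i)
      paste(vapply(as.list(rows[i, , drop = FALSE]), function(v)
        .fmt_cell(v[[1]]), ""), collapse = "\t"), "")
    writeLines(cells, con)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a CLI run byte-identically: the
#' resolved parameters (including defaulted ones), seeds, package version,
#' timestamp and MD5 checksums of the outputs.
#'
#' @param path Manifest path (JSON).
#' @param params A [switch_params()] object.
#' @param outputs Character vector of output file paths to checksum.
#' @param seed Integer seed (or `NULL`).
#' @param defaults Names of defaulted parameters (from [load_config()]).
#' @param extra Named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, outputs = character(),
                           seed = NULL, defaults = character(),
                           extra = list()) {
  stopifnot(inherits(params, "switch_params"))
  pl <- params
  class(pl) <- NULL
  man <- c(list(
    package = "switchnoise",
    version = as.character(utils::packageVersion("switchnoise")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = pl,
    defaulted = as.list(defaults),
    seed = seed,
    outputs = as.list(setNames(
      as.character(tools::md5sum(outputs[file.exists(outputs)])),
      outputs[file.exists(outputs)]))
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
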