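# shared fixtures: small parameter sets built in code

tiny_seq <- function(architecture = "sequestration", A_T = 10, R_T = 10,
                     ...) {
  defaults <- list(K_a = 0.5, K_s = 0.05,
                   K_b = if (architecture != "sequestration") 0.2,
                   K_d = if (architecture ==
                             "sequestration_blocking_displacement") 1)
  defaults <- defaults[!vapply(defaults, is.null, TRUE)]
  do.call(switch_params,
          modifyList(c(list(architecture = architecture, A_T = A_T,
                            R_T = R_T, alpha = 5, beta = 1, k_on = 0.1),
                       defaults),
                     list(...)))
}

strong_preset <- function(...) preset_params("sequestration_strong", ...)

# all four architectures with small copy numbers, load applied
tiny_all_models <- function(A_T = 6, R_T = 6) {
  coop <- with_load(preset_params("cooperative"), R_T / 20)
  seqs <- lapply(c("sequestration", "sequestration_blocking",
                   "sequestration_blocking_displacement"),
                 function(a) tiny_seq(a, A_T = A_T, R_T = R_T))
  c(list(coop), seqs)
}
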