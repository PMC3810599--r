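# Physical constants (CODATA 2018 exact values where defined).
# All internal units are strict SI: m, s, V, A, S, F, mol/m^3, K.

#' Physical constants used throughout the package
#'
#' Faraday constant (C/mol), molar gas constant (J/(mol K)), elementary
#' charge (C) and the Avogadro constant (1/mol), as exact CODATA 2018
#' values.
#'
#' @format A named list with elements `F`, `R`, `e`, `N_A`.
#' @export
phys_const <- list(
  F   = 96485.33212331001,
  R   = 8.31446261815324,
  e   = 1.602176634e-19,
  N_A = 6.02214076e23
)
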