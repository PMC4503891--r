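# Monoisotopic mass constants. All values in Da.

RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MASS <- 18.010565
PROTON_MASS <- 1.007276

MOD_DELTA <- c(
  phospho = 79.966331,
  met_sulfoxide = 15.994915,
  met_sulfone = 31.989829
)

# residues a modification may sit on
MOD_TARGETS <- list(
  phospho = c("S", "T", "Y"),
  met_sulfoxide = "M",
  met_sulfone = "M"
)

#' Monoisotopic residue masses
#'
#' The monoisotopic residue (i.e. amino-acid minus water) masses used for all
#' peptide mass arithmetic, plus the water and proton masses and the mass
#' shifts of the supported modifications (phosphorylation, methionine
#' sulfoxide and sulfone).
#'
#' @return A list with elements `residues` (a tibble with columns `residue`
#'   and `mass_da`), `water_da`, `proton_da` and `mod_deltas` (a tibble with
#'   columns `kind` and `delta_da`).
#' @examples
#' residue_masses()$residues
#' @export
residue_masses <- function() {
  list(
    residues = tibble::tibble(
      residue = names(RESIDUE_MASS),
      mass_da = unname(RESIDUE_MASS)
    ),
    water_da = WATER_MASS,
    proton_da = PROTON_MASS,
    mod_deltas = tibble::tibble(
      kind = names(MOD_DELTA),
      delta_da = unname(MOD_DELTA)
    )
  )
}
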