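#' The study peptide table
#'
#' Loads the shipped table of troponin I (TnI) and alpha-tropomyosin (Tm)
#' peptides used throughout the pipeline: the TnI serine-23/24 phosphopeptides
#' and their properly cleaved non-phospho analog, the TnI C-terminal peptides
#' (unoxidized and Met-sulfoxide forms), the Tm serine-283 phosphopeptides in
#' three Met-oxidation states with their analogs, and the five reference
#' peptides per protein used for loading normalization. Each species carries
#' the observed m/z printed in the source report (where printed), the charge
#' state that reproduces it, and fixed simulated elution parameters
#' (retention time, Gaussian peak SD, response factor).
#'
#' @param path Optional path to an alternative peptide TSV with the same
#'   columns.
#' @return A tibble with columns `species_id`, `protein`, `sequence`,
#'   `start_residue`, `mods`, `charge`, `mz_printed`, `role` (one of
#'   `analog`, `phospho_mono`, `phospho_bis`, `cterm`, `reference`),
#'   `family` (`tni_ps`, `tm_ps`, `tni_cterm`, `reference`), `rt_min`,
#'   `peak_sd_min`, `response_factor`, plus a computed `mz_theoretical`
#'   column.
#' @examples
#' study_peptides()
#' @export
study_peptides <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_peptides.tsv",
                        package = "myofilquant", mustWork = TRUE)
  }
  fx <- readr::read_tsv(
    path,
    col_types = readr::cols(
      species_id = readr::col_character(),
      protein = readr::col_character(),
      sequence = readr::col_character(),
      start_residue = readr::col_integer(),
      mods = readr::col_character(),
      charge = readr::col_integer(),
      mz_printed = readr::col_double(),
      role = readr::col_character(),
      family = readr::col_character(),
      rt_min = readr::col_double(),
      peak_sd_min = readr::col_double(),
      response_factor = readr::col_double()
    ),
    progress = FALSE
  )
  fx$mods[is.na(fx$mods)] <- ""
  fx$mz_theoretical <- purrr::pmap_dbl(
    list(fx$sequence, fx$start_residue, fx$mods, fx$charge),
    function(seq, start, mods, z) {
      mz(peptide(seq, start_residue = start, mods = mods), charge = z)
    }
  )
  if (anyDuplicated(fx$species_id)) {
    abort("Peptide table has duplicated species_id values.")
  }
  fx
}

# reference species ids for one protein
reference_species <- function(fixture, protein) {
  fixture$species_id[fixture$role == "reference" & fixture$protein == protein]
}
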