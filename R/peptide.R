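#' Construct a modified tryptic peptide
#'
#' A peptide is the unit of all mass arithmetic in the package: an uppercase
#' one-letter sequence, its 1-based start residue in the parent protein, and
#' zero or more residue-anchored modifications. Phosphorylation is only
#' accepted on S/T/Y and methionine oxidation states only on M; at most one
#' modification per position.
#'
#' @param sequence Uppercase one-letter amino-acid string.
#' @param start_residue 1-based residue number of the first residue in the
#'   parent protein (defaults to 1 when the parent position is unknown).
#' @param mods Either `NULL`, a data frame with columns `position` (1-based
#'   index within the peptide) and `kind` (`"phospho"`, `"met_sulfoxide"` or
#'   `"met_sulfone"`), or a compact string such as `"phospho@3;phospho@4"`.
#'
#' @return An object of class `peptide`.
#' @examples
#' peptide("RSSANYR", start_residue = 22, mods = "phospho@3")
#' @export
peptide <- function(sequence, start_residue = 1L, mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty string.")
  }
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(unique(residues), names(RESIDUE_MASS))
  if (length(unknown) > 0L) {
    abort(paste0(
      "Unknown residue code(s) in sequence: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (!is.numeric(start_residue) || length(start_residue) != 1L ||
      is.na(start_residue) || start_residue < 1L) {
    abort("`start_residue` must be a single integer >= 1.")
  }
  mods <- parse_mods(mods)
  validate_mods(residues, mods)
  structure(
    list(
      sequence = sequence,
      start_residue = as.integer(start_residue),
      mods = mods
    ),
    class = "peptide"
  )
}

# "phospho@3;met_sulfoxide@8" -> tibble(position, kind); NULL/"" -> empty
parse_mods <- function(mods) {
  if (is.null(mods) || (is.character(mods) && length(mods) == 1L &&
                        (is.na(mods) || !nzchar(trimws(mods))))) {
    return(tibble::tibble(position = integer(), kind = character()))
  }
  if (is.character(mods)) {
    parts <- strsplit(trimws(mods), ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    pieces <- strsplit(parts, "@", fixed = TRUE)
    bad <- lengths(pieces) != 2L
    if (any(bad)) {
      abort(paste0("Malformed modification token(s): ",
                   paste(parts[bad], collapse = ", ")))
    }
    mods <- tibble::tibble(
      position = as.integer(vapply(pieces, `[[`, "", 2L)),
      kind = vapply(pieces, `[[`, "", 1L)
    )
  }
  mods <- tibble::as_tibble(mods)
  if (!all(c("position", "kind") %in% names(mods))) {
    abort("`mods` must have columns `position` and `kind`.")
  }
  mods$position <- as.integer(mods$position)
  mods[order(mods$position), c("position", "kind")]
}

validate_mods <- function(residues, mods) {
  if (nrow(mods) == 0L) return(invisible(TRUE))
  bad_kind <- setdiff(mods$kind, names(MOD_DELTA))
  if (length(bad_kind) > 0L) {
    abort(paste0("Unknown modification kind(s): ",
                 paste(bad_kind, collapse = ", ")))
  }
  if (any(mods$position < 1L | mods$position > length(residues))) {
    abort("Modification position outside the peptide.")
  }
  if (anyDuplicated(mods$position)) {
    abort("At most one modification per position.")
  }
  for (i in seq_len(nrow(mods))) {
    res <- residues[mods$position[i]]
    allowed <- MOD_TARGETS[[mods$kind[i]]]
    if (!res %in% allowed) {
      abort(paste0(
        "Modification '", mods$kind[i], "' not allowed on residue '", res,
        "' at position ", mods$position[i],
        " (allowed: ", paste(allowed, collapse = "/"), ")."
      ))
    }
  }
  invisible(TRUE)
}

#' @export
print.peptide <- function(x, ...) {
  modstr <- if (nrow(x$mods) == 0L) "none" else
    paste(paste0(x$mods$kind, "@", x$mods$position), collapse = "; ")
  cat("<peptide> ", x$sequence,
      " (start residue ", x$start_residue, "; mods: ", modstr, ")\n",
      sep = "")
  invisible(x)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water plus the mass shifts of
#' any modifications.
#'
#' @param pep A [peptide()] object, or a plain sequence string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(peptide("SSANYR"))
#' @export
monoisotopic_mass <- function(pep) {
  if (is.character(pep)) pep <- peptide(pep)
  stopifnot(inherits(pep, "peptide"))
  residues <- strsplit(pep$sequence, "")[[1]]
  sum(RESIDUE_MASS[residues]) + WATER_MASS +
    sum(MOD_DELTA[pep$mods$kind])
}

#' Mass-to-charge ratio of a protonated peptide ion
#'
#' `mz()` returns the full-precision theoretical m/z,
#' `(monoisotopic mass + charge x proton) / charge`. `mz_printed()` rounds to
#' two decimals with round-half-even, the convention used when comparing to
#' values printed in instrument reports.
#'
#' @param pep A [peptide()] object or sequence string.
#' @param charge Positive integer charge state (protonation level).
#' @return m/z (dimensionless Thomson units).
#' @examples
#' mz(peptide("KLQLK"), charge = 1)
#' mz_printed(peptide("RSSANYR", mods = "phospho@3"), charge = 2)
#' @export
mz <- function(pep, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || is.na(charge) ||
      charge < 1 || charge != round(charge)) {
    abort("`charge` must be a positive integer.")
  }
  (monoisotopic_mass(pep) + charge * PROTON_MASS) / charge
}

#' @rdname mz
#' @export
mz_printed <- function(pep, charge) {
  round(mz(pep, charge), 2)
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' enumerates products with up to `max_missed_cleavages` retained internal
#' sites. The zero-missed-cleavage products tile the protein exactly.
#'
#' @param protein_sequence Uppercase one-letter protein sequence.
#' @param max_missed_cleavages Non-negative integer.
#' @return A tibble with columns `sequence`, `start_residue` (1-based) and
#'   `missed_cleavages`, ordered by start position then length.
#' @examples
#' digest("AKRPGR")
#' digest("RSSANYR", max_missed_cleavages = 1)
#' @export
digest <- function(protein_sequence, max_missed_cleavages = 0L) {
  if (!is.character(protein_sequence) || length(protein_sequence) != 1L ||
      nchar(protein_sequence) < 1L) {
    abort("`protein_sequence` must be a single non-empty string.")
  }
  residues <- strsplit(protein_sequence, "")[[1]]
  unknown <- setdiff(unique(residues), names(RESIDUE_MASS))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown residue code(s): ", paste(unknown, collapse = ", ")))
  }
  if (max_missed_cleavages < 0L) {
    abort("`max_missed_cleavages` must be >= 0.")
  }
  n <- length(residues)
  # cut after position i when residue i is K/R and i+1 is not P
  cuts <- which(residues %in% c("K", "R"))
  cuts <- cuts[cuts == n | residues[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, if (!n %in% cuts) n else integer())
  bounds <- unique(bounds)
  starts <- head(bounds, -1L) + 1L
  ends <- tail(bounds, -1L)
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (m in 0:min(max_missed_cleavages, k - i)) {
      j <- i + m
      out[[length(out) + 1L]] <- tibble::tibble(
        sequence = paste(residues[starts[i]:ends[j]], collapse = ""),
        start_residue = starts[i],
        missed_cleavages = m
      )
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$start_residue, .data$missed_cleavages)
}

#' b- and y-series fragment ion ladders
#'
#' Computes the m/z ladder of prefix (b) or suffix (y) fragments of a
#' peptide at a given charge; modifications travel with their residue.
#' b ions are the prefix residue masses plus `charge` protons; y ions are the
#' suffix residue masses plus water plus `charge` protons.
#'
#' @param pep A [peptide()] object or sequence string.
#' @param series `"b"` or `"y"`.
#' @param charge Positive integer.
#' @return A tibble with columns `series`, `index` (1-based ladder index)
#'   and `mz`.
#' @examples
#' fragment_ions(peptide("AG"), "b")
#' @export
fragment_ions <- function(pep, series = c("b", "y"), charge = 1L) {
  if (is.character(pep)) pep <- peptide(pep)
  series <- match.arg(series)
  if (charge < 1 || charge != round(charge)) {
    abort("`charge` must be a positive integer.")
  }
  residues <- strsplit(pep$sequence, "")[[1]]
  n <- length(residues)
  res_mass <- unname(RESIDUE_MASS[residues])
  mod_mass <- numeric(n)
  if (nrow(pep$mods) > 0L) {
    mod_mass[pep$mods$position] <- MOD_DELTA[pep$mods$kind]
  }
  per_res <- res_mass + mod_mass
  idx <- seq_len(n - 1L)
  if (n == 1L) idx <- 1L  # degenerate single-residue ladder: b1 / y1 only
  frag_mass <- if (series == "b") {
    cumsum(per_res)[idx]
  } else {
    rev(cumsum(rev(per_res)))[n - idx + 1L] + WATER_MASS
  }
  tibble::tibble(
    series = series,
    index = idx,
    mz = (frag_mass + charge * PROTON_MASS) / charge
  )
}
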