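#' Ground truth for the synthetic LC-MS study
#'
#' Defines the generating conditions of a simulated phosphorylation study:
#' per-group site occupancies, C-terminal truncation fractions, methionine
#' oxidation distributions, run-to-run loading variability, peak-area noise
#' and phosphatase completeness. The defaults encode the study conditions the
#' quantifier is meant to recover: control TnI mono/bis occupancies of
#' 0.15/0.10 so that the experimental groups carry mono relative abundances
#' of 0.27 (IR2) and 0.19 (IDNR) and bis relative abundances of 4.2 (IR2)
#' and 2.8 (IDNR) versus control, Tm serine-283 occupancy elevated in IR2
#' only, and C-terminal abundance ratios of 1.09 (IR2) and 1.06 (IDNR).
#'
#' @param groups Tibble with columns `group`, `tni_mono_fraction`,
#'   `tni_bis_fraction`, `tm_phospho_fraction`, `tni_truncated_fraction`.
#'   Fractions are molar fractions of protein molecules in `[0,1]`;
#'   mono + bis must not exceed 1.
#' @param met_oxidation_probs Length-3 probability simplex over the Tm
#'   methionine states (unoxidized, sulfoxide, sulfone).
#' @param cterm_oxidation_probs Length-2 simplex over the TnI C-terminal
#'   methionine states (unoxidized, sulfoxide).
#' @param loading_sigma Log-normal SD of the per-run loading factor
#'   (dimensionless; 0 disables loading variability).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise applied to each species' integrated abundance (0 disables noise).
#' @param phosphatase_completeness Fraction of phosphate removed by the
#'   alkaline-phosphatase treatment in treated runs, in `[0,1]`.
#'
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth()
#' @export
ground_truth <- function(groups = NULL,
                         met_oxidation_probs = c(0.70, 0.20, 0.10),
                         cterm_oxidation_probs = c(0.80, 0.20),
                         loading_sigma = 0.2,
                         noise_cv = 0.10,
                         phosphatase_completeness = 1.0) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      group = c("control", "IR2", "IDNR"),
      tni_mono_fraction = c(0.15, 0.27 * 0.15, 0.19 * 0.15),
      tni_bis_fraction = c(0.10, 4.2 * 0.10, 2.8 * 0.10),
      tm_phospho_fraction = c(0.10, 0.30, 0.12),
      tni_truncated_fraction = c(0.10, 1 - 1.09 * 0.90, 1 - 1.06 * 0.90)
    )
  }
  truth <- structure(
    list(
      groups = tibble::as_tibble(groups),
      met_oxidation_probs = met_oxidation_probs,
      cterm_oxidation_probs = cterm_oxidation_probs,
      loading_sigma = loading_sigma,
      noise_cv = noise_cv,
      phosphatase_completeness = phosphatase_completeness
    ),
    class = "ground_truth"
  )
  violations <- validate_ground_truth(truth)
  if (nrow(violations) > 0L) {
    abort(paste0(
      "Invalid ground truth:\n",
      paste0("- ", violations$field, ": ", violations$message, collapse = "\n")
    ))
  }
  truth
}

#' Validate a ground-truth object
#'
#' @param truth A [ground_truth()] object (or a compatible list).
#' @return A tibble of violations with columns `field` and `message`;
#'   zero rows when the object is valid.
#' @export
validate_ground_truth <- function(truth) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  g <- truth$groups
  needed <- c("group", "tni_mono_fraction", "tni_bis_fraction",
              "tm_phospho_fraction", "tni_truncated_fraction")
  missing_cols <- setdiff(needed, names(g))
  if (length(missing_cols) > 0L) {
    add("groups", paste0("missing column(s): ",
                         paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(v))
  }
  for (col in setdiff(needed, "group")) {
    bad <- g[[col]] < 0 | g[[col]] > 1 | is.na(g[[col]])
    if (any(bad)) {
      add(col, paste0("must be in [0,1] for all groups (violated for ",
                      paste(g$group[bad], collapse = ", "), ")"))
    }
  }
  over <- g$tni_mono_fraction + g$tni_bis_fraction > 1
  if (any(over, na.rm = TRUE)) {
    add("tni_mono_fraction + tni_bis_fraction",
        paste0("must not exceed 1 (violated for ",
               paste(g$group[over], collapse = ", "), ")"))
  }
  for (nm in c("met_oxidation_probs", "cterm_oxidation_probs")) {
    p <- truth[[nm]]
    len <- if (nm == "met_oxidation_probs") 3L else 2L
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      add(nm, paste0("must be a length-", len, " probability simplex"))
    }
  }
  if (truth$loading_sigma < 0) add("loading_sigma", "must be >= 0")
  if (truth$noise_cv < 0) add("noise_cv", "must be >= 0")
  pc <- truth$phosphatase_completeness
  if (pc < 0 || pc > 1) add("phosphatase_completeness", "must be in [0,1]")
  if (length(v) == 0L) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  print(x$groups)
  cat("met oxidation probs:", paste(x$met_oxidation_probs, collapse = "/"),
      "\ncterm oxidation probs:", paste(x$cterm_oxidation_probs, collapse = "/"),
      "\nloading_sigma:", x$loading_sigma,
      " noise_cv:", x$noise_cv,
      " phosphatase_completeness:", x$phosphatase_completeness, "\n")
  invisible(x)
}

# Expected molar fraction of each fixture species per protein molecule,
# before loading/noise. Phosphatase treatment reassigns phospho species
# mass to the same-oxidation-state non-phospho analog with probability
# `phosphatase_completeness`.
species_fractions <- function(truth, group, treated,
                              fixture = study_peptides()) {
  g <- truth$groups[truth$groups$group == group, ]
  if (nrow(g) != 1L) abort(paste0("Unknown group: ", group))
  cpl <- if (treated) truth$phosphatase_completeness else 0
  mono <- g$tni_mono_fraction
  bis <- g$tni_bis_fraction
  p_tm <- g$tm_phospho_fraction
  trunc <- g$tni_truncated_fraction
  ox3 <- truth$met_oxidation_probs
  ox2 <- truth$cterm_oxidation_probs

  frac <- setNames(numeric(nrow(fixture)), fixture$species_id)
  frac["SSANYR"] <- (1 - mono - bis) + cpl * (mono + bis)
  frac["RS[p]SANYR"] <- mono * (1 - cpl)
  frac["RRS[p]S[p]ANYR"] <- bis * (1 - cpl)
  frac["NIDALSGMEGR"] <- (1 - trunc) * ox2[1]
  frac["NIDALSGM[ox]EGR"] <- (1 - trunc) * ox2[2]
  tm_analog <- c("AISEELDHALNDMTSI", "AISEELDHALNDM[ox]TSI",
                 "AISEELDHALNDM[ox2]TSI")
  tm_phos <- c("AISEELDHALNDMTS[p]I", "AISEELDHALNDM[ox]TS[p]I",
               "AISEELDHALNDM[ox2]TS[p]I")
  frac[tm_analog] <- ox3 * ((1 - p_tm) + cpl * p_tm)
  frac[tm_phos] <- ox3 * p_tm * (1 - cpl)
  frac[fixture$species_id[fixture$role == "reference"]] <- 1
  tibble::tibble(species_id = names(frac), fraction = unname(frac))
}

#' Simulate one LC-MS run
#'
#' Renders one sample run of the study as a set of extracted-ion
#' chromatogram (XIC) traces, one Gaussian elution peak per fixture species.
#' The integrated area of each trace equals (species molar fraction) x
#' (per-species response factor) x (run loading factor) x (multiplicative
#' log-normal noise). Treated runs have phosphate-carrying species
#' reassigned to their non-phospho analogs according to
#' `phosphatase_completeness`; truncated TnI molecules contribute no
#' C-terminal peptide; reference peptides respond only to loading.
#'
#' @param truth A [ground_truth()] object.
#' @param group Group label present in `truth$groups`.
#' @param treated Logical; was alkaline phosphatase applied before digestion?
#' @param replicate Replicate index (>= 1).
#' @param seed Integer seed for this run's random draws.
#' @param fixture Peptide table from [study_peptides()].
#' @param rt_step Retention-time grid spacing in minutes.
#'
#' @return An object of class `chromatogram_set`: a list with `meta` (run
#'   metadata including the realized loading factor and seed) and `traces`
#'   (tibble `species_id`, `rt_min`, `intensity`).
#' @examples
#' cs <- simulate_lcms_run(ground_truth(), "control", treated = FALSE,
#'                         replicate = 1, seed = 7)
#' head(cs$traces)
#' @export
simulate_lcms_run <- function(truth, group, treated, replicate, seed,
                              fixture = study_peptides(), rt_step = 0.05) {
  stopifnot(inherits(truth, "ground_truth"))
  if (replicate < 1) abort("`replicate` must be >= 1.")
  fr <- species_fractions(truth, group, treated, fixture)
  fr <- fr[match(fixture$species_id, fr$species_id), ]
  withr::with_seed(as.integer(seed), {
    loading <- if (truth$loading_sigma > 0) {
      rlnorm(1, meanlog = -truth$loading_sigma^2 / 2,
             sdlog = truth$loading_sigma)
    } else 1
    mult <- if (truth$noise_cv > 0) {
      sdlog <- sqrt(log(1 + truth$noise_cv^2))
      rlnorm(nrow(fixture), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(fixture))
  })
  area <- fr$fraction * fixture$response_factor * loading * mult
  lo <- floor((fixture$rt_min - 5 * fixture$peak_sd_min) / rt_step) * rt_step
  hi <- ceiling((fixture$rt_min + 5 * fixture$peak_sd_min) / rt_step) * rt_step
  npts <- as.integer(round((hi - lo) / rt_step)) + 1L
  grid <- rep(lo, npts) + rt_step * (sequence(npts) - 1)
  structure(
    list(
      meta = list(group = group, treated = treated,
                  replicate = as.integer(replicate),
                  seed = as.integer(seed), loading = loading),
      traces = tibble::tibble(
        species_id = rep(fixture$species_id, npts),
        rt_min = grid,
        intensity = rep(area, npts) *
          dnorm(grid, rep(fixture$rt_min, npts), rep(fixture$peak_sd_min, npts))
      )
    ),
    class = "chromatogram_set"
  )
}

#' @export
print.chromatogram_set <- function(x, ...) {
  cat("<chromatogram_set> group=", x$meta$group,
      " treated=", x$meta$treated,
      " replicate=", x$meta$replicate,
      " seed=", x$meta$seed,
      " (", dplyr::n_distinct(x$traces$species_id), " species, ",
      nrow(x$traces), " points)\n", sep = "")
  invisible(x)
}

#' Simulate a full paired LC-MS design
#'
#' Generates the complete study design: for every group in the ground truth,
#' `n_replicates` untreated and `n_replicates` phosphatase-treated runs.
#' Per-run seeds are derived deterministically from the master seed
#' (`seed + run index` in a fixed enumeration order) and recorded in each
#' run's metadata.
#'
#' @param truth A [ground_truth()] object.
#' @param n_replicates Replicates per group and treatment (study default 3).
#' @param seed Master integer seed.
#' @param fixture Peptide table.
#' @param rt_step Retention-time grid spacing in minutes.
#' @return A tibble with one row per run: `group`, `treated`, `replicate`,
#'   `run_seed` and a `cset` list-column of `chromatogram_set` objects.
#' @examples
#' runs <- simulate_lcms(ground_truth(), n_replicates = 2, seed = 1)
#' runs[, c("group", "treated", "replicate", "run_seed")]
#' @export
simulate_lcms <- function(truth = ground_truth(), n_replicates = 3,
                          seed = 1, fixture = study_peptides(),
                          rt_step = 0.05) {
  design <- tidyr::expand_grid(
    group = truth$groups$group,
    treated = c(FALSE, TRUE),
    replicate = seq_len(n_replicates)
  )
  design$run_seed <- as.integer(seed) + seq_len(nrow(design))
  design$cset <- purrr::pmap(
    list(design$group, design$treated, design$replicate, design$run_seed),
    function(g, tr, rep, s) {
      simulate_lcms_run(truth, g, tr, rep, s, fixture = fixture,
                        rt_step = rt_step)
    }
  )
  design
}

#' Write / read a chromatogram set as TSV
#'
#' The on-disk format is a tab-separated table (`species_id`, `rt_min`,
#' `intensity`) preceded by `# key=value` comment lines carrying the run
#' metadata (group, treated, replicate, seed, loading). The round trip is
#' lossless.
#'
#' @param cset A `chromatogram_set`.
#' @param path Output file path.
#' @return `write_chromatograms()` returns `path` invisibly;
#'   `read_chromatograms()` returns a `chromatogram_set`.
#' @examples
#' cs <- simulate_lcms_run(ground_truth(), "control", FALSE, 1, seed = 3)
#' f <- tempfile(fileext = ".tsv")
#' write_chromatograms(cs, f)
#' cs2 <- read_chromatograms(f)
#' identical(cs$traces, cs2$traces)
#' @export
write_chromatograms <- function(cset, path) {
  stopifnot(inherits(cset, "chromatogram_set"))
  m <- cset$meta
  header <- c(
    paste0("# group=", m$group),
    paste0("# treated=", m$treated),
    paste0("# replicate=", m$replicate),
    paste0("# seed=", m$seed),
    paste0("# loading=", sprintf("%.17g", m$loading)),
    "species_id\trt_min\tintensity"
  )
  body <- sprintf("%s\t%.17g\t%.17g",
                  cset$traces$species_id,
                  cset$traces$rt_min,
                  cset$traces$intensity)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_chromatograms
#' @export
read_chromatograms <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  kv <- strsplit(sub("^#\\s*", "", lines[meta_lines]), "=", fixed = TRUE)
  meta <- setNames(
    lapply(kv, function(x) paste(x[-1], collapse = "=")),
    vapply(kv, `[[`, "", 1L)
  )
  body <- lines[-meta_lines]
  if (length(body) < 1L || body[1] != "species_id\trt_min\tintensity") {
    abort("Missing or malformed chromatogram header row.")
  }
  rows <- body[-1]
  traces <- if (length(rows) == 0L) {
    tibble::tibble(species_id = character(), rt_min = numeric(),
                   intensity = numeric())
  } else {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad) > 0L) {
      abort(paste0("Malformed chromatogram row at line ",
                   meta_lines[length(meta_lines)] + 1L + bad[1], "."))
    }
    m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    vals <- suppressWarnings(cbind(as.numeric(m[, 2]), as.numeric(m[, 3])))
    if (anyNA(vals)) {
      abort(paste0("Non-numeric chromatogram value at line ",
                   meta_lines[length(meta_lines)] + 1L +
                     which(rowSums(is.na(vals)) > 0)[1], "."))
    }
    tibble::tibble(species_id = m[, 1], rt_min = vals[, 1],
                   intensity = vals[, 2])
  }
  structure(
    list(
      meta = list(
        group = meta$group,
        treated = as.logical(meta$treated),
        replicate = as.integer(meta$replicate),
        seed = as.integer(meta$seed),
        loading = as.numeric(meta$loading)
      ),
      traces = traces
    ),
    class = "chromatogram_set"
  )
}
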