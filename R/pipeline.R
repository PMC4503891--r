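#' Default study configuration
#'
#' One configuration object drives the whole reproducible run: the LC-MS
#' ground truth and design, the motility generation parameters, and the
#' moving-filament thresholds. It round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @return A list of class `study_config` with blocks `lcms` (fields
#'   `groups`, `met_oxidation_probs`, `cterm_oxidation_probs`,
#'   `loading_sigma`, `noise_cv`, `phosphatase_completeness`,
#'   `n_replicates`) and `motility` (fields `params`, `pCa_values`,
#'   `n_filaments`, `speed_cv`, `noise_sd`, `frames`, `frame_interval`,
#'   `velocity_threshold`, `straightness_threshold`).
#' @examples
#' cfg <- default_config()
#' validate_config(cfg)
#' @export
default_config <- function() {
  truth <- ground_truth()
  structure(
    list(
      lcms = list(
        groups = truth$groups,
        met_oxidation_probs = truth$met_oxidation_probs,
        cterm_oxidation_probs = truth$cterm_oxidation_probs,
        loading_sigma = truth$loading_sigma,
        noise_cv = truth$noise_cv,
        phosphatase_completeness = truth$phosphatase_completeness,
        n_replicates = 3L
      ),
      motility = list(
        params = motility_params(),
        pCa_values = c(7.5, 7.0, 6.75, 6.5, 6.25, 6.0, 5.0, 4.0),
        n_filaments = 50L,
        speed_cv = 0.10,
        noise_sd = 0.05,
        frames = 300L,
        frame_interval = 0.1,
        velocity_threshold = 0.25,
        straightness_threshold = 0.5
      )
    ),
    class = "study_config"
  )
}

config_truth <- function(config) {
  l <- config$lcms
  ground_truth(
    groups = l$groups,
    met_oxidation_probs = l$met_oxidation_probs,
    cterm_oxidation_probs = l$cterm_oxidation_probs,
    loading_sigma = l$loading_sigma,
    noise_cv = l$noise_cv,
    phosphatase_completeness = l$phosphatase_completeness
  )
}

#' Validate a study configuration
#'
#' Checks every invariant of the configuration (occupancy simplexes,
#' probability vectors, positive accquisition parameters, replicate counts)
#' and returns the violations as data rather than raising.
#'
#' @param config A `study_config` list.
#' @return Tibble with columns `field` and `message`; zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  for (block in c("lcms", "motility")) {
    if (is.null(config[[block]])) add(block, "missing configuration block")
  }
  if (!is.null(config$lcms)) {
    gt <- tryCatch(config_truth(config), error = function(e) e)
    if (inherits(gt, "error")) {
      # surface the individual violations instead of the constructor error
      fake <- structure(config$lcms, class = "ground_truth")
      fake$groups <- tibble::as_tibble(config$lcms$groups)
      gv <- tryCatch(validate_ground_truth(fake), error = function(e) NULL)
      if (is.null(gv) || nrow(gv) == 0L) {
        add("lcms", conditionMessage(gt))
      } else {
        for (i in seq_len(nrow(gv))) {
          add(paste0("lcms.", gv$field[i]), gv$message[i])
        }
      }
    }
    nr <- config$lcms$n_replicates
    if (is.null(nr) || nr < 1) add("lcms.n_replicates", "must be >= 1")
  }
  if (!is.null(config$motility)) {
    m <- config$motility
    p <- m$params
    needed <- c("condition", "vmax", "pca50", "n", "frac_max", "frac_min")
    if (is.null(p) || !all(needed %in% names(p))) {
      add("motility.params", paste0("must have columns ",
                                    paste(needed, collapse = ", ")))
    } else {
      if (any(p$vmax <= 0)) add("motility.params.vmax", "must be > 0")
      if (any(p$n <= 0)) add("motility.params.n", "must be > 0")
      if (any(p$frac_max < 0 | p$frac_max > 1 |
                p$frac_min < 0 | p$frac_min > 1 |
                p$frac_min > p$frac_max)) {
        add("motility.params.frac", "fractions must be in [0,1] with frac_min <= frac_max")
      }
    }
    if (is.null(m$pCa_values) || length(m$pCa_values) < 1 ||
        any(m$pCa_values < 3 | m$pCa_values > 9)) {
      add("motility.pCa_values", "must be non-empty and within [3, 9]")
    }
    if (is.null(m$n_filaments) || m$n_filaments < 1) {
      add("motility.n_filaments", "must be >= 1")
    }
    if (is.null(m$frame_interval) || m$frame_interval <= 0) {
      add("motility.frame_interval", "must be > 0")
    }
    if (is.null(m$frames) || m$frames < 2) add("motility.frames", "must be >= 2")
    if (!is.null(m$speed_cv) && m$speed_cv < 0) add("motility.speed_cv", "must be >= 0")
    if (!is.null(m$noise_sd) && m$noise_sd < 0) add("motility.noise_sd", "must be >= 0")
  }
  if (length(v) == 0L) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Write / read a study configuration as YAML
#'
#' @param config A `study_config` list.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `study_config`.
#' @export
write_config <- function(config, path) {
  ser <- list(
    lcms = c(
      list(groups = lapply(
        seq_len(nrow(config$lcms$groups)),
        function(i) as.list(config$lcms$groups[i, ])
      )),
      config$lcms[setdiff(names(config$lcms), "groups")]
    ),
    motility = c(
      list(params = lapply(
        seq_len(nrow(config$motility$params)),
        function(i) as.list(config$motility$params[i, ])
      )),
      config$motility[setdiff(names(config$motility), "params")]
    )
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    lcms = c(
      list(groups = dplyr::bind_rows(lapply(raw$lcms$groups, tibble::as_tibble))),
      raw$lcms[setdiff(names(raw$lcms), "groups")]
    ),
    motility = c(
      list(params = dplyr::bind_rows(lapply(raw$motility$params, tibble::as_tibble))),
      raw$motility[setdiff(names(raw$motility), "params")]
    )
  )
  cfg$lcms$met_oxidation_probs <- as.numeric(cfg$lcms$met_oxidation_probs)
  cfg$lcms$cterm_oxidation_probs <- as.numeric(cfg$lcms$cterm_oxidation_probs)
  cfg$motility$pCa_values <- as.numeric(cfg$motility$pCa_values)
  structure(cfg, class = "study_config")
}

# Deterministic per-stage seed derivation from the master seed, kept well
# below .Machine$integer.max for small master seeds.
stage_seed <- function(seed, stage) {
  offset <- c(lcms = 100003L, motility = 200003L)[[stage]]
  as.integer(seed) + offset
}

#' Run the full study pipeline
#'
#' Executes simulate-LCMS, quantify, simulate-motility and analyze-motility
#' under one master seed with deterministic per-stage seed derivation, and
#' assembles the study report: the per-group quantification table, the
#' per-condition Hill parameter table, the per-pCa motility summaries and a
#' provenance block (config hash, seeds, package version). Identical config
#' and seed give a byte-identical written report.
#'
#' @param config A `study_config`, e.g. [default_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given the report tables are
#'   written as TSV plus a combined JSON via [write_study_report()].
#' @param fixture Peptide table.
#' @return A list of class `study_report` with elements `phospho`,
#'   `hill`, `motility_summaries` and `provenance`.
#' @examples
#' \donttest{
#' rep <- run_study(seed = 1)
#' rep$phospho
#' }
#' @export
run_study <- function(config = default_config(), seed = 1, out_dir = NULL,
                      fixture = study_peptides()) {
  violations <- validate_config(config)
  if (nrow(violations) > 0L) {
    abort(paste0(
      "Invalid configuration:\n",
      paste0("- ", violations$field, ": ", violations$message,
             collapse = "\n")
    ))
  }
  lcms_seed <- stage_seed(seed, "lcms")
  mot_seed <- stage_seed(seed, "motility")

  truth <- config_truth(config)
  runs <- simulate_lcms(truth, n_replicates = config$lcms$n_replicates,
                        seed = lcms_seed, fixture = fixture)
  phospho <- quantify_runs(runs, fixture = fixture)

  m <- config$motility
  tracks <- simulate_motility_study(
    params = m$params, pCa_values = m$pCa_values,
    n_filaments = m$n_filaments, speed_cv = m$speed_cv,
    noise_sd = m$noise_sd, frames = m$frames,
    frame_interval = m$frame_interval, seed = mot_seed
  )
  mot <- analyze_motility(tracks,
                          velocity_threshold = m$velocity_threshold,
                          straightness_threshold = m$straightness_threshold)

  report <- structure(
    list(
      phospho = phospho,
      hill = mot$hill,
      motility_summaries = mot$summaries,
      provenance = list(
        master_seed = as.integer(seed),
        lcms_seed = lcms_seed,
        motility_seed = mot_seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("myofilquant"))
      )
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed:", x$provenance$master_seed,
      " config:", x$provenance$config_hash, "\n\nQuantification:\n")
  print(tibble::as_tibble(x$phospho), n = 20)
  cat("\nHill parameters:\n")
  print(x$hill)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `phospho_quant.tsv`, `hill_parameters.tsv`,
#' `motility_summaries.tsv` and a combined `study_report.json` into
#' `out_dir`. Output is deterministic for a fixed report.
#'
#' @param report A `study_report` from [run_study()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(report$phospho),
                   file.path(out_dir, "phospho_quant.tsv"))
  readr::write_tsv(report$hill, file.path(out_dir, "hill_parameters.tsv"))
  readr::write_tsv(report$motility_summaries,
                   file.path(out_dir, "motility_summaries.tsv"))
  jsonlite::write_json(
    list(
      phospho = tibble::as_tibble(report$phospho),
      hill = report$hill,
      motility_summaries = report$motility_summaries,
      provenance = report$provenance
    ),
    file.path(out_dir, "study_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
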