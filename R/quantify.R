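#' Integrate an extracted-ion-chromatogram trace
#'
#' Trapezoidal area under one XIC trace over a retention-time window. No
#' baseline model is applied: simulated peaks are baseline-free.
#'
#' @param trace Tibble with columns `rt_min` and `intensity`.
#' @param rt_start,rt_end Window bounds in minutes; must lie within the
#'   trace's grid extent.
#' @return Area in intensity x minutes (a single number).
#' @examples
#' tr <- tibble::tibble(rt_min = seq(0, 1, 0.01), intensity = 2)
#' integrate_xic(tr, 0, 1)  # 2 (height x width)
#' @export
integrate_xic <- function(trace, rt_start, rt_end) {
  if (rt_end <= rt_start) abort("`rt_end` must exceed `rt_start`.")
  if (nrow(trace) < 2L) abort("Trace must have at least 2 points.")
  if (rt_start < min(trace$rt_min) - 1e-9 ||
      rt_end > max(trace$rt_min) + 1e-9) {
    abort("Integration window lies outside the trace's retention-time grid.")
  }
  keep <- trace$rt_min >= rt_start - 1e-9 & trace$rt_min <= rt_end + 1e-9
  rt <- trace$rt_min[keep]
  y <- trace$intensity[keep]
  if (length(rt) < 2L) abort("Integration window contains fewer than 2 grid points.")
  ord <- order(rt)
  rt <- rt[ord]; y <- y[ord]
  sum(diff(rt) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Peak areas for every species in a run
#'
#' Integrates each species' trace over its fixed per-species window (the
#' full rendered extent, rt plus/minus five peak SDs).
#'
#' @param cset A `chromatogram_set`.
#' @param fixture Peptide table from [study_peptides()].
#' @return Tibble `species_id`, `area`, `rt_start`, `rt_end`.
#' @export
peak_areas <- function(cset, fixture = study_peptides()) {
  stopifnot(inherits(cset, "chromatogram_set"))
  rt_split <- split(cset$traces$rt_min, cset$traces$species_id)
  int_split <- split(cset$traces$intensity, cset$traces$species_id)
  one <- function(id) {
    rt <- rt_split[[id]]; y <- int_split[[id]]
    if (is.null(rt) || length(rt) < 2L) return(c(0, NA_real_, NA_real_))
    ord <- order(rt)
    rt <- rt[ord]; y <- y[ord]
    c(sum(diff(rt) * (head(y, -1) + tail(y, -1)) / 2), rt[1], rt[length(rt)])
  }
  m <- vapply(fixture$species_id, one, numeric(3), USE.NAMES = FALSE)
  tibble::tibble(species_id = fixture$species_id,
                 area = m[1, ], rt_start = m[2, ], rt_end = m[3, ])
}

#' Peak areas for a set of runs
#'
#' @param runs Tibble of runs as returned by [simulate_lcms()] (columns
#'   `group`, `treated`, `replicate` and list-column `cset`).
#' @param fixture Peptide table.
#' @return Long tibble `group`, `treated`, `replicate`, `species_id`, `area`.
#' @export
run_areas <- function(runs, fixture = study_peptides()) {
  purrr::pmap(
    list(runs$group, runs$treated, runs$replicate, runs$cset),
    function(g, tr, rep, cs) {
      a <- peak_areas(cs, fixture)
      tibble::tibble(group = g, treated = tr, replicate = rep,
                     species_id = a$species_id, area = a$area)
    }
  ) |> dplyr::bind_rows()
}

#' Reference-peptide normalization of one target area
#'
#' Divides a target peak area by each reference peptide's area within the
#' same run, yielding one loading-free ratio per reference. References with
#' zero area are excluded with a warning; if all references are unusable the
#' run cannot be normalized and an error is raised.
#'
#' @param target_area Non-negative target peak area.
#' @param reference_areas Named numeric vector of reference peak areas.
#' @return Tibble `reference`, `ratio`.
#' @examples
#' normalize_abundance(10, c(r1 = 5, r2 = 2))
#' @export
normalize_abundance <- function(target_area, reference_areas) {
  if (length(reference_areas) < 1L) abort("At least one reference is required.")
  if (is.null(names(reference_areas))) {
    names(reference_areas) <- paste0("ref", seq_along(reference_areas))
  }
  usable <- reference_areas > 0
  if (!any(usable)) {
    abort("All reference peptide areas are zero; run is unusable.")
  }
  if (!all(usable)) {
    warn(paste0("Dropping zero-area reference(s): ",
                paste(names(reference_areas)[!usable], collapse = ", ")))
  }
  tibble::tibble(
    reference = names(reference_areas)[usable],
    ratio = unname(target_area / reference_areas[usable])
  )
}

# Per-run normalized ratios of a summed target species set against each
# reference peptide of `ref_protein`. Returns group, treated, replicate,
# reference, ratio.
normalized_ratios <- function(areas, target_species, ref_protein,
                              fixture = study_peptides()) {
  refs <- reference_species(fixture, ref_protein)
  runs <- dplyr::distinct(areas, .data$group, .data$treated, .data$replicate)
  purrr::pmap(
    list(runs$group, runs$treated, runs$replicate),
    function(g, tr, rep) {
      a <- areas[areas$group == g & areas$treated == tr &
                   areas$replicate == rep, ]
      target <- sum(a$area[a$species_id %in% target_species])
      ref_areas <- setNames(
        a$area[match(refs, a$species_id)], refs
      )
      nr <- normalize_abundance(target, ref_areas)
      tibble::tibble(group = g, treated = tr, replicate = rep,
                     reference = nr$reference, ratio = nr$ratio)
    }
  ) |> dplyr::bind_rows()
}

#' Fraction phosphorylated by mass balance
#'
#' Implements the mass-balance estimate of site occupancy: for each
#' reference peptide r and replicate pair, `f_r = 1 - untreated_r /
#' treated_r`, where the ratios are the reference-normalized abundances of
#' the non-phosphorylated analog peptide(s) before and after complete
#' enzymatic dephosphorylation. For the Tm site the analog abundance is the
#' sum over the three methionine-oxidation forms. Estimates are clamped to
#' `[0,1]` with a warning (negative raw values arise from noise).
#'
#' @param areas Long area table from [run_areas()].
#' @param site `"tni_ps"` (TnI serines 23/24) or `"tm_ps"` (Tm serine 283).
#' @param fixture Peptide table.
#' @return A `phospho_quant` tibble: one row per group with columns `group`,
#'   `quantity`, `target`, `estimate`, `sd`, `sem`, `n_values`,
#'   `p_vs_control`; the per-reference/per-replicate values are kept in the
#'   `values` attribute.
#' @export
fraction_phosphorylated <- function(areas, site = c("tni_ps", "tm_ps"),
                                    fixture = study_peptides()) {
  site <- match.arg(site)
  fam <- fixture[fixture$family == site, ]
  analog_species <- fam$species_id[fam$role == "analog"]
  ref_protein <- unique(fam$protein)
  ratios <- normalized_ratios(areas, analog_species, ref_protein, fixture)
  u <- ratios[!ratios$treated, c("group", "replicate", "reference", "ratio")]
  t <- ratios[ratios$treated, c("group", "replicate", "reference", "ratio")]
  names(u)[4] <- "untreated"; names(t)[4] <- "treated"
  pairs <- dplyr::inner_join(u, t, by = c("group", "replicate", "reference"))
  usable <- pairs$treated > 0
  if (!all(usable)) {
    if (!any(usable)) abort("All treated-run reference ratios are zero.")
    warn("Dropping reference pair(s) with zero treated-run ratio.")
    pairs <- pairs[usable, ]
  }
  pairs$f_raw <- 1 - pairs$untreated / pairs$treated
  clamped <- pairs$f_raw < 0 | pairs$f_raw > 1
  if (any(clamped)) {
    warn(paste0("Clamped ", sum(clamped),
                " fraction-phosphorylated value(s) to [0,1]."))
  }
  pairs$f <- pmin(pmax(pairs$f_raw, 0), 1)
  target <- if (site == "tni_ps") "TnI S23/S24" else "Tm S283"
  summarize_quant(pairs, value_col = "f",
                  quantity = "fraction_phosphorylated", target = target)
}

#' Relative abundance of a phosphopeptide versus control
#'
#' For untreated runs only: each run's reference-normalized abundance of the
#' target species (summed over `target_species`) is divided by the mean
#' normalized abundance of the same species against the same reference in
#' the control group. The control group's own estimate is identically 1.
#'
#' @param areas Long area table from [run_areas()].
#' @param target_species Character vector of species ids whose areas are
#'   summed before normalization.
#' @param ref_protein Protein whose reference peptides are used
#'   (`"TnI"` or `"Tm"`).
#' @param control_group Label of the control group.
#' @param quantity,target Labels used in the output table.
#' @param fixture Peptide table.
#' @return A `phospho_quant` tibble (see [fraction_phosphorylated()]).
#' @export
relative_abundance <- function(areas, target_species, ref_protein,
                               control_group = "control",
                               quantity = "relative_abundance",
                               target = paste(target_species, collapse = "+"),
                               fixture = study_peptides()) {
  if (length(target_species) < 1L) abort("`target_species` must be non-empty.")
  ratios <- normalized_ratios(
    areas[!areas$treated, ], target_species, ref_protein, fixture
  )
  ctrl <- ratios[ratios$group == control_group, ] |>
    dplyr::group_by(.data$reference) |>
    dplyr::summarise(control_ratio = mean(.data$ratio), .groups = "drop")
  usable <- ctrl$control_ratio > 0
  if (!any(usable)) abort("All control reference ratios are zero.")
  if (!all(usable)) {
    warn(paste0("Dropping reference(s) with zero control ratio: ",
                paste(ctrl$reference[!usable], collapse = ", ")))
    ctrl <- ctrl[usable, ]
  }
  rel <- dplyr::inner_join(ratios, ctrl, by = "reference")
  rel$value <- rel$ratio / rel$control_ratio
  summarize_quant(rel, value_col = "value", quantity = quantity,
                  target = target, control_group = control_group)
}

#' C-terminal truncation ratio
#'
#' Relative abundance (vs control) of the summed TnI C-terminal peptide
#' forms (unoxidized and Met-sulfoxide), normalized with the TnI reference
#' peptides. A value below 1 indicates loss of the C-terminus in the
#' experimental group; redistribution between oxidation forms at fixed
#' truncation leaves the summed ratio unchanged.
#'
#' @inheritParams relative_abundance
#' @export
truncation_ratio <- function(areas, control_group = "control",
                             fixture = study_peptides()) {
  cterm <- fixture$species_id[fixture$family == "tni_cterm"]
  relative_abundance(areas, cterm, "TnI", control_group = control_group,
                     quantity = "truncation_ratio",
                     target = "TnI C-terminus", fixture = fixture)
}

# Aggregate per-(reference x replicate) values into per-group estimates with
# SD, SEM and a Student's t-test against the control group's values.
summarize_quant <- function(values, value_col, quantity, target,
                            control_group = "control") {
  values$value <- values[[value_col]]
  ctrl_values <- values$value[values$group == control_group]
  res <- values |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      sd = stats::sd(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_values = dplyr::n(),
      .groups = "drop"
    )
  res$p_vs_control <- purrr::map_dbl(res$group, function(g) {
    if (g == control_group || length(ctrl_values) < 2L) return(NA_real_)
    gv <- values$value[values$group == g]
    if (length(gv) < 2L) return(NA_real_)
    two_sample_t(gv, ctrl_values)$p_value
  })
  res <- dplyr::mutate(res, quantity = quantity, target = target,
                       .after = "group")
  attr(res, "values") <- tibble::as_tibble(values)
  class(res) <- c("phospho_quant", class(res))
  res
}

#' Per-measurement replicate values of a quantification result
#'
#' @param x A `phospho_quant` tibble.
#' @return The per-reference-peptide, per-replicate values the estimates
#'   were aggregated from.
#' @export
quant_values <- function(x) {
  attr(x, "values")
}

#' Classical two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test, with explicit conventions for the
#' degenerate zero-variance case: equal means give `p = 1`, unequal means
#' give `p = 0`.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return One-row tibble `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(1, 2, 3))
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 values.")
  }
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  stderr <- sqrt(pooled * (1 / length(a) + 1 / length(b)))
  # same near-zero guard as stats::t.test uses, with the documented
  # degenerate conventions instead of an error
  if (stderr < 10 * .Machine$double.eps * max(abs(mean(a)), abs(mean(b)), 1)) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      df = df,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a), mean_b = mean(b)
    ))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b)
  )
}

#' Full quantification report for a set of runs
#'
#' Runs the complete mass-balance quantification over a paired
#' untreated/treated design: fraction phosphorylated for TnI S23/S24 and Tm
#' S283, relative abundance of the mono- and bis-phosphorylated TnI peptides
#' versus control, and the C-terminal truncation ratio.
#'
#' @param runs Tibble of runs from [simulate_lcms()] (or assembled from
#'   [read_chromatograms()] files).
#' @param fixture Peptide table.
#' @param control_group Label of the control group.
#' @return A tidy tibble: `group`, `quantity`, `target`, `estimate`, `sd`,
#'   `sem`, `n_values`, `p_vs_control`.
#' @examples
#' \donttest{
#' runs <- simulate_lcms(ground_truth(), n_replicates = 3, seed = 1)
#' quantify_runs(runs)
#' }
#' @export
quantify_runs <- function(runs, fixture = study_peptides(),
                          control_group = "control") {
  areas <- run_areas(runs, fixture)
  out <- dplyr::bind_rows(
    fraction_phosphorylated(areas, "tni_ps", fixture),
    fraction_phosphorylated(areas, "tm_ps", fixture),
    relative_abundance(areas, "RS[p]SANYR", "TnI",
                       control_group = control_group,
                       quantity = "relative_abundance",
                       target = "TnI mono-phospho", fixture = fixture),
    relative_abundance(areas, "RRS[p]S[p]ANYR", "TnI",
                       control_group = control_group,
                       quantity = "relative_abundance",
                       target = "TnI bis-phospho", fixture = fixture),
    truncation_ratio(areas, control_group = control_group, fixture = fixture)
  )
  tibble::as_tibble(out)
}
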