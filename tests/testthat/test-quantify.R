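test_that("trapezoidal XIC integration matches closed forms", {
  rt <- seq(0, 10, 0.01)
  zero <- tibble::tibble(rt_min = rt, intensity = 0)
  expect_equal(integrate_xic(zero, 0, 10), 0)
  # rectangular pulse of height h and width w
  pulse <- tibble::tibble(rt_min = rt, intensity = ifelse(rt >= 2 & rt <= 5, 3, 0))
  expect_equal(integrate_xic(pulse, 2, 5), 3 * 3, tolerance = 1e-9)
  # Gaussian of amplitude A and SD s integrates to A*s*sqrt(2*pi)
  A <- 7; s <- 0.3
  gauss <- tibble::tibble(rt_min = rt, intensity = A * exp(-(rt - 5)^2 / (2 * s^2)))
  expect_equal(integrate_xic(gauss, 0, 10), A * s * sqrt(2 * pi),
               tolerance = 1e-3)
  expect_error(integrate_xic(gauss, -1, 10), "outside")
  expect_error(integrate_xic(gauss, 5, 4), "exceed")
})

test_that("reference normalization is a per-reference ratio with scale invariance", {
  nr <- normalize_abundance(10, c(r1 = 5, r2 = 2))
  expect_equal(nr$ratio, c(2, 5))
  expect_equal(normalize_abundance(0, c(r1 = 5, r2 = 2))$ratio, c(0, 0))
  # doubling every area leaves ratios unchanged
  expect_equal(normalize_abundance(20, c(r1 = 10, r2 = 4))$ratio, nr$ratio)
  expect_warning(out <- normalize_abundance(10, c(r1 = 5, r2 = 0)), "r2")
  expect_equal(out$reference, "r1")
  expect_error(normalize_abundance(10, c(r1 = 0, r2 = 0)), "unusable")
})

test_that("mass balance recovers the generating occupancies exactly without noise", {
  truth <- noiseless_truth()
  runs <- simulate_lcms(truth, n_replicates = 2, seed = 1, fixture = fx)
  q <- quantify_runs(runs, fixture = fx)
  g <- truth$groups
  for (i in seq_len(nrow(g))) {
    grp <- g$group[i]
    expect_equal(
      q$estimate[q$group == grp & q$target == "TnI S23/S24"],
      g$tni_mono_fraction[i] + g$tni_bis_fraction[i], tolerance = 1e-9
    )
    expect_equal(
      q$estimate[q$group == grp & q$target == "Tm S283"],
      g$tm_phospho_fraction[i], tolerance = 1e-9
    )
    expect_equal(
      q$estimate[q$group == grp & q$target == "TnI mono-phospho"],
      g$tni_mono_fraction[i] / g$tni_mono_fraction[1], tolerance = 1e-9
    )
    expect_equal(
      q$estimate[q$group == grp & q$target == "TnI bis-phospho"],
      g$tni_bis_fraction[i] / g$tni_bis_fraction[1], tolerance = 1e-9
    )
    expect_equal(
      q$estimate[q$group == grp & q$target == "TnI C-terminus"],
      (1 - g$tni_truncated_fraction[i]) / (1 - g$tni_truncated_fraction[1]),
      tolerance = 1e-9
    )
  }
  # per-reference replicate values are retained losslessly
  areas <- run_areas(runs, fx)
  fr <- fraction_phosphorylated(areas, "tni_ps", fx)
  vals <- quant_values(fr)
  expect_identical(nrow(vals), 2L * 3L * 5L)  # replicates x groups x references
})

test_that("direct mass-balance arithmetic: untreated 0.4 vs treated 0.8 gives f = 0.5", {
  # hand-built areas table with a single reference peptide
  areas <- tibble::tibble(
    group = "control", treated = rep(c(FALSE, TRUE), each = 21),
    replicate = 1L,
    species_id = rep(fx$species_id, 2),
    area = 0
  )
  set_area <- function(areas, treated, id, a) {
    areas$area[areas$treated == treated & areas$species_id == id] <- a
    areas
  }
  for (tr in c(FALSE, TRUE)) {
    for (ref in myofilquant:::reference_species(fx, "TnI")) {
      areas <- set_area(areas, tr, ref, 10)
    }
  }
  areas <- set_area(areas, FALSE, "SSANYR", 4)   # ratio 0.4
  areas <- set_area(areas, TRUE, "SSANYR", 8)    # ratio 0.8
  f <- fraction_phosphorylated(areas, "tni_ps", fx)
  expect_equal(f$estimate, 0.5, tolerance = 1e-12)
  # equal untreated and treated ratios mean no phosphorylation
  areas0 <- set_area(areas, TRUE, "SSANYR", 4)
  expect_equal(fraction_phosphorylated(areas0, "tni_ps", fx)$estimate, 0)
})

test_that("relative abundance is 1 for control and invariant to loading", {
  truth <- noiseless_truth()
  runs <- sim_untreated_runs(truth, seed = 4)
  areas <- run_areas(runs, fx)
  rel <- relative_abundance(areas, "RRS[p]S[p]ANYR", "TnI", fixture = fx)
  expect_equal(rel$estimate[rel$group == "control"], 1)
  idnr <- rel$estimate[rel$group == "IDNR"]
  # scale one experimental run's chromatogram globally: ratios cancel loading
  runs2 <- runs
  scaled <- runs2$cset[[which(runs2$group == "IDNR")[1]]]
  scaled$traces$intensity <- scaled$traces$intensity * 7.3
  runs2$cset[[which(runs2$group == "IDNR")[1]]] <- scaled
  rel2 <- relative_abundance(run_areas(runs2, fx), "RRS[p]S[p]ANYR", "TnI",
                             fixture = fx)
  expect_equal(rel2$estimate[rel2$group == "IDNR"], idnr, tolerance = 1e-12)
})

test_that("loading invariance holds for every reported quantity", {
  truth <- noiseless_truth()
  runs <- simulate_lcms(truth, n_replicates = 2, seed = 9, fixture = fx)
  q1 <- quantify_runs(runs, fixture = fx)
  # random global per-run rescalings leave all estimates unchanged
  withr::with_seed(11, {
    runs2 <- runs
    for (i in seq_len(nrow(runs2))) {
      cs <- runs2$cset[[i]]
      cs$traces$intensity <- cs$traces$intensity * runif(1, 0.2, 5)
      runs2$cset[[i]] <- cs
    }
    q2 <- quantify_runs(runs2, fixture = fx)
  })
  expect_equal(q2$estimate, q1$estimate, tolerance = 1e-10)
})

test_that("recovered phosphorylation is monotone in the generating occupancy", {
  occ <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  est <- vapply(occ, function(p) {
    g <- ground_truth()$groups[1, ]
    g$tni_mono_fraction <- p / 2
    g$tni_bis_fraction <- p / 2
    truth <- noiseless_truth(groups = g)
    runs <- simulate_lcms(truth, n_replicates = 1, seed = 2, fixture = fx)
    areas <- run_areas(runs, fx)
    fraction_phosphorylated(areas, "tni_ps", fx)$estimate
  }, numeric(1))
  expect_equal(est, occ, tolerance = 1e-9)
  expect_true(all(diff(est) > 0))
})

test_that("truncation ratio tracks the generating C-terminal loss and ignores oxidation shifts", {
  base <- ground_truth()$groups
  # no truncation anywhere: ratio 1
  g0 <- dplyr::mutate(base, tni_truncated_fraction = 0)
  runs0 <- sim_untreated_runs(noiseless_truth(groups = g0), seed = 21,
                              n_replicates = 1)
  tr0 <- truncation_ratio(run_areas(runs0, fx), fixture = fx)
  expect_equal(tr0$estimate, rep(1, 3), tolerance = 1e-9)
  # half the molecules truncated in IDNR only: ratio 0.5
  g1 <- dplyr::mutate(g0, tni_truncated_fraction = ifelse(group == "IDNR", 0.5, 0))
  runs1 <- sim_untreated_runs(noiseless_truth(groups = g1), seed = 22,
                              n_replicates = 1)
  tr1 <- truncation_ratio(run_areas(runs1, fx), fixture = fx)
  expect_equal(tr1$estimate[tr1$group == "IDNR"], 0.5, tolerance = 1e-9)
  # redistributing oxidation forms at fixed truncation leaves the ratio fixed
  runs2 <- sim_untreated_runs(
    noiseless_truth(groups = g1, cterm_oxidation_probs = c(0.3, 0.7)),
    seed = 23, n_replicates = 1
  )
  tr2 <- truncation_ratio(run_areas(runs2, fx), fixture = fx)
  expect_equal(tr2$estimate, tr1$estimate, tolerance = 1e-9)
})

test_that("pooled two-sample t-test follows the textbook formula and conventions", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(statistic = 0, df = 4L, p_value = 1,
                              mean_a = 2, mean_b = 2))
  # hand-computed pooled t for {1,2,3} vs {4,5,6}
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.6742346, tolerance = 1e-4)
  expect_equal(tt$p_value, 0.0213116, tolerance = 1e-4)
  # zero variance, unequal means
  degen <- two_sample_t(c(1, 1), c(2, 2))
  expect_identical(degen$p_value, 0)
  expect_identical(degen$statistic, -Inf)
  # clearly separated groups with tiny jitter
  withr::with_seed(5, {
    a <- rnorm(4, 0, 1e-6); b <- 1 + rnorm(4, 0, 1e-6)
  })
  expect_lt(two_sample_t(a, b)$p_value, 1e-6)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})
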