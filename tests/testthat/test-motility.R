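test_that("track simulation validates its parameters", {
  expect_error(simulate_tracks(0, 0.5, 1), "n_filaments")
  expect_error(simulate_tracks(5, 1.2, 1), "fraction_moving")
  expect_error(simulate_tracks(5, 0.5, -1), "mean_speed")
  expect_error(simulate_tracks(5, 0.5, 1, frames = 1), "frames")
  expect_error(simulate_tracks(5, 0.5, 1, frame_interval = 0), "frame_interval")
})

test_that("velocity equals displacement rate on noiseless tracks", {
  tr <- simulate_tracks(10, 1, 3.0, speed_cv = 0, noise_sd = 0,
                        frames = 50, seed = 1)
  steps <- tr |>
    dplyr::group_by(filament_id) |>
    dplyr::summarise(step = sqrt(diff(x_um)^2 + diff(y_um)^2)[1])
  expect_equal(steps$step, rep(0.3, 10), tolerance = 1e-12)
  v <- track_velocity(tr)
  expect_equal(v$velocity_um_s, rep(3.0, 10), tolerance = 1e-12)
  # straight-line 0.5 um steps at 0.1 s intervals give 5 um/s
  hand <- tibble::tibble(filament_id = 1L, frame = 1:20,
                         x_um = 0.5 * (0:19), y_um = 0)
  expect_equal(track_velocity(hand, frame_interval = 0.1)$velocity_um_s, 5.0)
  # stationary track reports zero
  still <- tibble::tibble(filament_id = 1L, frame = 1:20, x_um = 2, y_um = 3)
  expect_equal(track_velocity(still, frame_interval = 0.1)$velocity_um_s, 0)
})

test_that("velocity is invariant under translation and rotation", {
  tr <- simulate_tracks(5, 1, 2.5, frames = 60, seed = 8)
  v0 <- track_velocity(tr)$velocity_um_s
  th <- 0.83
  tr2 <- dplyr::mutate(tr,
                       x_new = cos(th) * x_um - sin(th) * y_um + 40,
                       y_new = sin(th) * x_um + cos(th) * y_um - 12,
                       x_um = x_new, y_um = y_new)
  attr(tr2, "frame_interval") <- 0.1
  expect_equal(track_velocity(tr2)$velocity_um_s, v0, tolerance = 1e-10)
})

test_that("moving/stalled classification is accurate on labelled synthetic tracks", {
  # perfect straight mover passes, pure jitter fails
  mover <- tibble::tibble(filament_id = 1L, frame = 1:30,
                          x_um = 0.5 * (0:29), y_um = 0)
  expect_true(classify_moving(mover, frame_interval = 0.1)$moving)
  withr::with_seed(2, {
    jitter <- tibble::tibble(filament_id = 1L, frame = 1:300,
                             x_um = rnorm(300, 0, 0.05),
                             y_um = rnorm(300, 0, 0.05))
  })
  expect_false(classify_moving(jitter, frame_interval = 0.1)$moving)
  # labelled mixture at the study's localization noise
  tr <- simulate_tracks(200, 0.5, 3.0, noise_sd = 0.05, seed = 31)
  truth <- attr(tr, "truth")
  cls <- classify_moving(tr)
  expect_gte(mean(cls$moving == truth$moving), 0.95)
})

test_that("stationary-track velocity floor matches the jitter prediction", {
  # mean speed of pure localization jitter: sigma*sqrt(pi)/dt
  tr <- simulate_tracks(300, 0, 1, noise_sd = 0.05, frames = 100, seed = 12)
  v <- track_velocity(tr)$velocity_um_s
  floor_theory <- 0.05 * sqrt(pi) / 0.1
  expect_equal(mean(v), floor_theory, tolerance = 0.02)
  # the floor exceeds the velocity threshold, which is why classification
  # rests on straightness
  expect_gt(floor_theory, 0.25)
})

test_that("motility summaries compose velocity, fraction moving and index", {
  tr <- simulate_tracks(20, 1, 2.0, speed_cv = 0, noise_sd = 0, seed = 3)
  s <- summarize_motility(tr)
  expect_equal(s$fraction_moving, 1)
  expect_equal(s$mean_velocity, 2.0, tolerance = 1e-9)
  expect_equal(s$motility_index, 2.0, tolerance = 1e-9)
  # half moving at v, half stalled: index v/2
  mover <- simulate_tracks(10, 1, 2.0, speed_cv = 0, noise_sd = 0, seed = 4)
  stalled <- simulate_tracks(10, 0, 1, speed_cv = 0, noise_sd = 0, seed = 5)
  stalled$filament_id <- stalled$filament_id + 10L
  both <- dplyr::bind_rows(mover, stalled)
  attr(both, "frame_interval") <- 0.1
  s2 <- summarize_motility(both)
  expect_equal(s2$fraction_moving, 0.5)
  expect_equal(s2$motility_index, 1.0, tolerance = 1e-9)
  # no movers: absent velocity, zero index
  s3 <- summarize_motility(stalled)
  expect_true(is.na(s3$mean_velocity))
  expect_equal(s3$motility_index, 0)
})

test_that("simulated speeds are statistically consistent with the target", {
  tr <- simulate_tracks(1000, 1, 4.0, speed_cv = 0.1, noise_sd = 0,
                        frames = 30, seed = 17)
  v <- track_velocity(tr)$velocity_um_s
  sem <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 4.0), 3 * sem)
})

test_that("the Hill fit recovers noiseless generating parameters", {
  pca <- seq(7.5, 4.0, length.out = 8)
  for (row in list(c(3.0, 6.34, 1.89), c(3.0, 6.47, 1.27),
                   c(3.75, 6.57, 3.46))) {
    curve <- tibble::tibble(pCa = pca,
                            velocity = hill_velocity(pca, row[1], row[2], row[3]))
    g <- glance(fit_hill(curve))
    expect_true(g$converged)
    expect_equal(g$vmax, row[1], tolerance = 1e-6)
    expect_equal(g$pca50, row[2], tolerance = 1e-6)
    expect_equal(g$n, row[3], tolerance = 1e-6)
  }
})

test_that("the fitted Hill curve halves at pCa50 and its pCa50 is scale-free", {
  pca <- seq(7.5, 4.0, length.out = 10)
  curve <- tibble::tibble(pCa = pca,
                          velocity = hill_velocity(pca, 2.4, 6.2, 2.2))
  g <- glance(fit_hill(curve))
  expect_equal(hill_velocity(g$pca50, g$vmax, g$pca50, g$n), g$vmax / 2,
               tolerance = 1e-9)
  # multiplying all velocities by a constant moves only Vmax
  g2 <- glance(fit_hill(dplyr::mutate(curve, velocity = velocity * 3.7)))
  expect_equal(g2$pca50, g$pca50, tolerance = 1e-6)
  expect_equal(g2$n, g$n, tolerance = 1e-6)
  expect_equal(g2$vmax, 3.7 * g$vmax, tolerance = 1e-6)
})

test_that("the implemented Hill exponent sign makes velocity fall as calcium is withdrawn", {
  pca <- seq(4, 8, 0.5)
  v <- hill_velocity(pca, 3, 6.34, 1.89)
  expect_true(all(diff(v) < 0))
  # the alternative printed sign would rise with pCa, contradicting the
  # observed velocity-pCa relation; kept as a regression guard
  v_alt <- 3 / (1 + 10^(1.89 * (6.34 - pca)))
  expect_true(all(diff(v_alt) > 0))
})

test_that("Hill fitting rejects degenerate inputs", {
  pca <- seq(7, 5, length.out = 6)
  expect_error(fit_hill(tibble::tibble(pCa = pca, velocity = 2)), "Degenerate")
  expect_error(fit_hill(tibble::tibble(pCa = c(6, 6, 6, 7),
                                       velocity = c(1, 2, 3, 4))),
               "4 distinct")
})

test_that("Kruskal-Wallis H matches hand-computed ranks and is rank-invariant", {
  d_same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  kw0 <- kruskal_wallis(tibble::tibble(v = rep(1, 6), g = rep(c("a", "b"), 3)),
                        v, g)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  kw <- kruskal_wallis(d, v, g)
  expect_equal(kw$statistic, 3.857142857, tolerance = 1e-9)
  # invariant under strictly monotone transforms
  kw2 <- kruskal_wallis(dplyr::mutate(d, v = exp(v)), v, g)
  expect_equal(kw2$statistic, kw$statistic, tolerance = 1e-12)
  expect_equal(kw2$p_value, kw$p_value, tolerance = 1e-12)
})

test_that("one-way ANOVA with Tukey HSD behaves classically", {
  d_id <- tibble::tibble(v = rep(c(1, 2), 3), g = rep(c("a", "b", "c"), each = 2))
  same <- tibble::tibble(v = rep(1, 6), g = rep(c("a", "b", "c"), each = 2))
  at0 <- anova_tukey(same, v, g)
  expect_equal(at0$anova$statistic, 0)
  expect_equal(at0$anova$p_value, 1)
  expect_true(all(at0$tukey$p_adj == 1))
  # two groups: F = t^2 and identical p
  withr::with_seed(9, {
    d2 <- tibble::tibble(v = c(rnorm(8), rnorm(8, 1)),
                         g = rep(c("a", "b"), each = 8))
  })
  at <- anova_tukey(d2, v, g)
  tt <- two_sample_t(d2$v[d2$g == "a"], d2$v[d2$g == "b"])
  expect_equal(at$anova$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(at$anova$p_value, tt$p_value, tolerance = 1e-9)
  # a 3-sigma mean shift is detected by the shifted pair almost always
  hits <- vapply(1:100, function(i) {
    withr::with_seed(1000 + i, {
      d3 <- tibble::tibble(v = c(rnorm(20), rnorm(20), rnorm(20, 3)),
                           g = rep(c("a", "b", "c"), each = 20))
    })
    res <- anova_tukey(d3, v, g)
    res$tukey$p_adj[res$tukey$comparison == "c-a"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("track tables round-trip through TSV", {
  tracks <- simulate_motility_study(n_filaments = 4, frames = 10,
                                    pCa_values = c(7, 6, 5, 4), seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tracks, f)
  back <- read_tracks(f)
  expect_equal(back$x_um, tracks$x_um)
  expect_equal(back$y_um, tracks$y_um)
  expect_identical(back$condition, tracks$condition)
  expect_equal(attr(back, "frame_interval"), attr(tracks, "frame_interval"))
  expect_identical(attr(back, "seed"), attr(tracks, "seed"))
})

test_that("the study-level analysis recovers per-condition calcium sensitivity ordering", {
  tracks <- simulate_motility_study(n_filaments = 25, frames = 60, seed = 14)
  an <- analyze_motility(tracks)
  expect_setequal(an$hill$condition, c("control", "IR2", "IDNR"))
  expect_true(all(an$hill$converged))
  # IDNR generated 25% faster and more calcium sensitive than control
  vc <- an$summaries[an$summaries$pCa == 4, ]
  expect_gt(vc$mean_velocity[vc$condition == "IDNR"],
            vc$mean_velocity[vc$condition == "control"])
  expect_gt(an$hill$pca50[an$hill$condition == "IDNR"],
            an$hill$pca50[an$hill$condition == "control"])
})
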