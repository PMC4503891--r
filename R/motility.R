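#' Velocity predicted by the Hill velocity-pCa relation
#'
#' `V(pCa) = Vmax / (1 + 10^(n * (pCa - pCa50)))` with `n > 0`: velocity
#' falls as calcium is withdrawn (pCa rises) and equals `Vmax/2` at
#' `pCa = pCa50`.
#'
#' @param pCa Negative log10 of free calcium concentration.
#' @param vmax Maximal velocity (um/s).
#' @param pca50 pCa at half-maximal velocity.
#' @param n Hill coefficient (> 0).
#' @return Velocity in the units of `vmax`.
#' @examples
#' hill_velocity(6.34, vmax = 3, pca50 = 6.34, n = 1.89)  # Vmax/2
#' @export
hill_velocity <- function(pCa, vmax, pca50, n) {
  vmax / (1 + 10^(n * (pCa - pca50)))
}

#' Simulate filament tracks for one condition and pCa
#'
#' Moving filaments advance along a persistent random direction at a
#' per-filament speed drawn around `mean_speed` with coefficient of
#' variation `speed_cv`; stalled filaments stay put. Every centroid is
#' perturbed by isotropic Gaussian localization noise. Acquisition defaults
#' mirror a 10 frames/s, 30 s video.
#'
#' @param n_filaments Number of filaments.
#' @param fraction_moving Expected fraction of moving filaments in `[0,1]`.
#' @param mean_speed Mean speed of moving filaments (um/s), > 0 when any
#'   filament moves.
#' @param speed_cv Per-filament speed coefficient of variation.
#' @param noise_sd Per-frame, per-axis localization noise SD (um).
#' @param frames Number of frames (>= 2).
#' @param frame_interval Seconds between frames.
#' @param seed Integer seed; recorded in the output attributes.
#' @return Tibble `filament_id`, `frame`, `x_um`, `y_um` with attributes
#'   `frame_interval`, `seed` and `truth` (per-filament moving label and
#'   generating speed).
#' @examples
#' tr <- simulate_tracks(5, 0.8, 3, frames = 30, seed = 1)
#' head(tr)
#' @export
simulate_tracks <- function(n_filaments, fraction_moving, mean_speed,
                            speed_cv = 0.10, noise_sd = 0.05,
                            frames = 300, frame_interval = 0.1, seed = 1) {
  if (n_filaments < 1) abort("`n_filaments` must be >= 1.")
  if (fraction_moving < 0 || fraction_moving > 1) {
    abort("`fraction_moving` must be in [0,1].")
  }
  if (fraction_moving > 0 && mean_speed <= 0) {
    abort("`mean_speed` must be > 0 when filaments move.")
  }
  if (speed_cv < 0 || noise_sd < 0) {
    abort("`speed_cv` and `noise_sd` must be >= 0.")
  }
  if (frames < 2) abort("`frames` must be >= 2.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  withr::with_seed(as.integer(seed), {
    moving <- rbinom(n_filaments, 1, fraction_moving) == 1
    speed <- ifelse(
      moving,
      pmax(rnorm(n_filaments, mean_speed, speed_cv * mean_speed), 0),
      0
    )
    theta <- runif(n_filaments, 0, 2 * pi)
    x0 <- runif(n_filaments, 0, 100)
    y0 <- runif(n_filaments, 0, 100)
    t_s <- (seq_len(frames) - 1L) * frame_interval
    tracks <- purrr::map(seq_len(n_filaments), function(i) {
      tibble::tibble(
        filament_id = i,
        frame = seq_len(frames),
        x_um = x0[i] + speed[i] * cos(theta[i]) * t_s +
          rnorm(frames, 0, noise_sd),
        y_um = y0[i] + speed[i] * sin(theta[i]) * t_s +
          rnorm(frames, 0, noise_sd)
      )
    }) |> dplyr::bind_rows()
  })
  attr(tracks, "frame_interval") <- frame_interval
  attr(tracks, "seed") <- as.integer(seed)
  attr(tracks, "truth") <- tibble::tibble(
    filament_id = seq_len(n_filaments), moving = moving, speed = speed
  )
  tracks
}

#' Per-filament velocity and path metrics
#'
#' Velocity is the mean frame-to-frame Euclidean displacement divided by the
#' frame interval (no smoothing). Straightness is net displacement divided
#' by path length; near 1 for directed motion, near 0 for stationary jitter.
#'
#' @param tracks Tibble `filament_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Seconds between frames; defaults to the tibble's
#'   `frame_interval` attribute.
#' @return Tibble `filament_id`, `velocity_um_s`, `straightness`,
#'   `net_um`, `path_um`, `n_frames`.
#' @export
track_metrics <- function(tracks, frame_interval = NULL) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval")
  if (is.null(frame_interval) || frame_interval <= 0) {
    abort("`frame_interval` must be supplied (seconds > 0).")
  }
  tracks |>
    dplyr::arrange(.data$filament_id, .data$frame) |>
    dplyr::group_by(.data$filament_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      path_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      net_um = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                      (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      velocity_um_s = .data$path_um / (.data$n_frames - 1L) / frame_interval,
      straightness = dplyr::if_else(.data$path_um > 0,
                                    .data$net_um / .data$path_um, 0)
    ) |>
    dplyr::select("filament_id", "velocity_um_s", "straightness",
                  "net_um", "path_um", "n_frames")
}

#' @rdname track_metrics
#' @return `track_velocity()` returns just `filament_id` and
#'   `velocity_um_s`.
#' @export
track_velocity <- function(tracks, frame_interval = NULL) {
  dplyr::select(track_metrics(tracks, frame_interval),
                "filament_id", "velocity_um_s")
}

#' Classify filaments as moving or stalled
#'
#' A filament counts as moving when its velocity exceeds
#' `velocity_threshold` and its straightness is at least
#' `straightness_threshold`. With realistic localization noise the velocity
#' of a stationary track has a positive floor (approximately
#' `noise_sd * sqrt(pi) / frame_interval`), so the straightness criterion
#' carries the discrimination; thresholds were tuned on labelled synthetic
#' tracks.
#'
#' @param metrics Tibble from [track_metrics()] (or raw tracks, which are
#'   converted).
#' @param velocity_threshold um/s, default 0.25.
#' @param straightness_threshold Dimensionless, default 0.5.
#' @param frame_interval Passed through when `metrics` is a raw track table.
#' @return The metrics tibble with a logical `moving` column added.
#' @export
classify_moving <- function(metrics, velocity_threshold = 0.25,
                            straightness_threshold = 0.5,
                            frame_interval = NULL) {
  if (velocity_threshold < 0 || straightness_threshold < 0) {
    abort("Thresholds must be >= 0.")
  }
  if (!"velocity_um_s" %in% names(metrics)) {
    metrics <- track_metrics(metrics, frame_interval)
  }
  dplyr::mutate(
    metrics,
    moving = .data$velocity_um_s > velocity_threshold &
      .data$straightness >= straightness_threshold
  )
}

#' Summarize a filament track set
#'
#' Mean velocity (with SEM) of moving filaments only, the fraction of
#' filaments moving, and the motility index (their product). When no
#' filament moves, velocity and SEM are `NA` and the index is 0.
#'
#' @param tracks Track tibble (one condition and pCa).
#' @param velocity_threshold,straightness_threshold Passed to
#'   [classify_moving()].
#' @param frame_interval Seconds between frames (attribute fallback).
#' @return One-row tibble `n_filaments`, `n_moving`, `fraction_moving`,
#'   `mean_velocity`, `sem_velocity`, `motility_index`.
#' @export
summarize_motility <- function(tracks, velocity_threshold = 0.25,
                               straightness_threshold = 0.5,
                               frame_interval = NULL) {
  cls <- classify_moving(tracks, velocity_threshold, straightness_threshold,
                         frame_interval = frame_interval)
  v <- cls$velocity_um_s[cls$moving]
  n <- nrow(cls)
  frac <- length(v) / n
  mean_v <- if (length(v) > 0) mean(v) else NA_real_
  tibble::tibble(
    n_filaments = n,
    n_moving = length(v),
    fraction_moving = frac,
    mean_velocity = mean_v,
    sem_velocity = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
    motility_index = if (length(v) > 0) mean_v * frac else 0
  )
}

#' Fit the Hill velocity-pCa relation
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of `V = Vmax / (1 + 10^(n (pCa - pCa50)))` to a
#' velocity-pCa curve. Weights are `1/SEM^2` when a `sem` column with finite
#' positive values is present, otherwise the fit is unweighted. Start
#' values: `Vmax` at the maximum observed velocity, `pCa50` at half-max by
#' linear interpolation, `n = 2`; bounds keep `Vmax` positive, `n` in
#' (0, 20] and `pCa50` within the data range plus/minus 1.
#'
#' @param curve Tibble with columns `pCa`, `velocity` and optionally `sem`.
#' @return An object of class `hill_fit` with elements `estimates` (tibble
#'   `term`, `estimate`, `std_error`), `rss`, `converged`, `n_points`,
#'   `data`, and `fitted`.
#' @examples
#' pca <- seq(7.5, 4, length.out = 8)
#' curve <- tibble::tibble(pCa = pca,
#'                         velocity = hill_velocity(pca, 3, 6.34, 1.89))
#' fit_hill(curve)
#' @export
fit_hill <- function(curve) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("pCa", "velocity") %in% names(curve))) {
    abort("`curve` needs columns `pCa` and `velocity`.")
  }
  curve <- curve[is.finite(curve$pCa) & is.finite(curve$velocity), ]
  if (dplyr::n_distinct(curve$pCa) < 4L) {
    abort("Hill fit needs at least 4 distinct pCa points.")
  }
  if (stats::sd(curve$velocity) == 0) {
    abort("Degenerate data: all velocities are equal; the Hill transition is unidentifiable.")
  }
  weights <- if ("sem" %in% names(curve) &&
                 all(is.finite(curve$sem)) && all(curve$sem > 0)) {
    1 / curve$sem^2
  } else {
    rep(1, nrow(curve))
  }
  vmax0 <- max(curve$velocity)
  # pCa at half max by interpolation on the sorted curve
  ord <- order(curve$pCa)
  pca_s <- curve$pCa[ord]; v_s <- curve$velocity[ord]
  half <- vmax0 / 2
  pca50_0 <- tryCatch(
    stats::approx(v_s, pca_s, xout = half, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(pca50_0)) pca50_0 <- mean(range(curve$pCa))
  lower <- c(vmax = 1e-9, pca50 = min(curve$pCa) - 1, n = 1e-6)
  upper <- c(vmax = 10 * vmax0, pca50 = max(curve$pCa) + 1, n = 20)
  # multi-start: the interpolated half-max start first, then coarse
  # alternatives across the pCa range in case the gradient is singular there
  pca50_starts <- unique(c(
    min(max(pca50_0, lower[["pca50"]]), upper[["pca50"]]),
    stats::quantile(curve$pCa, c(0.5, 0.25, 0.75), names = FALSE)
  ))
  fit <- NULL
  for (p0 in pca50_starts) {
    for (n0 in c(2, 1, 4)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          velocity ~ vmax / (1 + 10^(n * (pCa - pca50))),
          data = curve,
          start = list(vmax = vmax0, pca50 = p0, n = n0),
          lower = lower, upper = upper,
          weights = weights,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) e
      )
      if (!inherits(fit, "error")) break
    }
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    res <- structure(
      list(
        estimates = tibble::tibble(
          term = c("vmax", "pca50", "n"),
          estimate = NA_real_, std_error = NA_real_
        ),
        rss = NA_real_, converged = FALSE, n_points = nrow(curve),
        data = curve, fitted = NULL, message = conditionMessage(fit)
      ),
      class = "hill_fit"
    )
    return(res)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(est))
  })
  structure(
    list(
      estimates = tibble::tibble(
        term = names(est),
        estimate = unname(est),
        std_error = unname(se[names(est)])
      ),
      rss = sum(residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      n_points = nrow(curve),
      data = curve,
      fitted = fit
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", if (!x$converged) "(did not converge)", "\n")
  print(x$estimates)
  cat("RSS:", format(x$rss, digits = 4), " points:", x$n_points, "\n")
  invisible(x)
}

#' Hill-fit parameter extraction
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns the term/estimate/std.error table; `glance()`
#'   a one-row model summary.
#' @export
tidy.hill_fit <- function(x, ...) {
  dplyr::rename(x$estimates, std.error = "std_error")
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    vmax = x$estimates$estimate[x$estimates$term == "vmax"],
    pca50 = x$estimates$estimate[x$estimates$term == "pca50"],
    n = x$estimates$estimate[x$estimates$term == "n"],
    rss = x$rss,
    n_points = x$n_points,
    converged = x$converged
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Tidy wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with k-1 df). All-identical data give
#' `H = 0, p = 1`.
#'
#' @param data Data frame.
#' @param value,group Column names (unquoted) of the response and grouping
#'   variable.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
#'                     g = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, v, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  if (stats::sd(v) == 0) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- kruskal.test(v, g)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical one-way ANOVA ([stats::aov()]) followed by Tukey's honestly
#' significant difference test via the studentized-range distribution
#' ([stats::TukeyHSD()]). Zero within-group variance is handled with the
#' same conventions as [two_sample_t()].
#'
#' @inheritParams kruskal_wallis
#' @return List with `anova` (one-row tibble `statistic` (F), `df_between`,
#'   `df_within`, `p_value`) and `tukey` (tibble `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`).
#' @examples
#' d <- tibble::tibble(v = rnorm(30), g = rep(letters[1:3], each = 10))
#' anova_tukey(d, v, g)$anova
#' @export
anova_tukey <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  if (any(table(g) < 2L)) abort("Each group needs at least 2 values.")
  d <- data.frame(v = v, g = g)
  within_var <- stats::ave(v, g, FUN = var)
  if (all(within_var == 0)) {
    means <- tapply(v, g, mean)
    equal <- diff(range(means)) == 0
    pairs <- utils::combn(levels(g), 2)
    return(list(
      anova = tibble::tibble(
        statistic = if (equal) 0 else Inf,
        df_between = nlevels(g) - 1L,
        df_within = length(v) - nlevels(g),
        p_value = if (equal) 1 else 0
      ),
      tukey = tibble::tibble(
        comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
        diff = means[pairs[2, ]] - means[pairs[1, ]],
        lwr = NA_real_, upr = NA_real_,
        p_adj = ifelse(means[pairs[2, ]] == means[pairs[1, ]], 1, 0)
      )
    ))
  }
  fit <- aov(v ~ g, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(
    anova = tibble::tibble(
      statistic = s[["F value"]][1],
      df_between = s[["Df"]][1],
      df_within = s[["Df"]][2],
      p_value = s[["Pr(>F)"]][1]
    ),
    tukey = tibble::tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      lwr = tk[, "lwr"],
      upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  )
}

#' Default motility simulation parameters
#'
#' Per-condition Hill parameters for generating velocity-pCa track sets.
#' The calcium sensitivity (pCa50) and cooperativity (n) values are the
#' study's fitted parameters per condition; maximal velocities put the
#' failed-resuscitation (IDNR) filaments 25\% above control at full
#' activation. The percent-moving curve shares each condition's pCa50 with
#' a plateau of 0.85 and floor of 0.05.
#'
#' @return Tibble `condition`, `vmax`, `pca50`, `n`, `frac_max`,
#'   `frac_min`.
#' @export
motility_params <- function() {
  tibble::tibble(
    condition = c("control", "IR2", "IDNR"),
    vmax = c(3.0, 3.0, 3.75),
    pca50 = c(6.34, 6.47, 6.57),
    n = c(1.89, 1.27, 3.46),
    frac_max = 0.85,
    frac_min = 0.05
  )
}

#' Simulate a full velocity-pCa motility study
#'
#' For each condition and pCa, generates a filament track set whose moving
#' filaments slide at the condition's Hill-curve speed and whose moving
#' fraction follows a Hill-shaped activation curve between `frac_min` and
#' `frac_max`.
#'
#' @param params Tibble as from [motility_params()].
#' @param pCa_values pCa levels to image.
#' @param n_filaments Filaments per condition and pCa.
#' @param speed_cv,noise_sd,frames,frame_interval As in
#'   [simulate_tracks()].
#' @param seed Master integer seed; per-set seeds are derived as
#'   `seed + set index` and logged per track set.
#' @return Long tibble `condition`, `pCa`, `filament_id`, `frame`, `x_um`,
#'   `y_um`, `set_seed` with attribute `frame_interval`; the generating
#'   parameters are attached as attribute `params`.
#' @export
simulate_motility_study <- function(params = motility_params(),
                                    pCa_values = c(7.5, 7.0, 6.75, 6.5,
                                                   6.25, 6.0, 5.0, 4.0),
                                    n_filaments = 50, speed_cv = 0.10,
                                    noise_sd = 0.05, frames = 300,
                                    frame_interval = 0.1, seed = 1) {
  design <- tidyr::expand_grid(condition = params$condition,
                               pCa = pCa_values)
  design$set_seed <- as.integer(seed) + seq_len(nrow(design))
  out <- purrr::pmap(
    list(design$condition, design$pCa, design$set_seed),
    function(cond, pca, s) {
      p <- params[params$condition == cond, ]
      speed <- hill_velocity(pca, p$vmax, p$pca50, p$n)
      frac <- p$frac_min +
        (p$frac_max - p$frac_min) / (1 + 10^(p$n * (pca - p$pca50)))
      # below ~2% of Vmax nothing resolvable moves
      if (speed < 0.02 * p$vmax) {
        frac <- 0
        speed <- 1  # unused when nothing moves
      }
      tr <- simulate_tracks(n_filaments, frac, speed, speed_cv = speed_cv,
                            noise_sd = noise_sd, frames = frames,
                            frame_interval = frame_interval, seed = s)
      tr$condition <- cond
      tr$pCa <- pca
      tr$set_seed <- s
      tr
    }
  ) |> dplyr::bind_rows()
  out <- dplyr::select(out, "condition", "pCa", "filament_id", "frame",
                       "x_um", "y_um", "set_seed")
  attr(out, "frame_interval") <- frame_interval
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Analyze a motility study
#'
#' Summarizes each condition x pCa track set (mean moving velocity, percent
#' moving, motility index) and fits the Hill velocity-pCa relation per
#' condition using the per-pCa means weighted by their SEMs.
#'
#' @param tracks Long track tibble with columns `condition`, `pCa`,
#'   `filament_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Seconds between frames (attribute fallback).
#' @param velocity_threshold,straightness_threshold Moving-filament
#'   criteria.
#' @return List of class `motility_analysis` with `summaries` (per
#'   condition x pCa) and `hill` (per condition: `vmax`, `pca50`, `n`,
#'   their standard errors, `rss`, `converged`) plus `fits` (named list of
#'   `hill_fit` objects).
#' @export
analyze_motility <- function(tracks, frame_interval = NULL,
                             velocity_threshold = 0.25,
                             straightness_threshold = 0.5) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval")
  sets <- tracks |>
    dplyr::group_by(.data$condition, .data$pCa) |>
    tidyr::nest() |>
    dplyr::ungroup()
  sums <- purrr::pmap(
    list(sets$condition, sets$pCa, sets$data),
    function(cond, pca, d) {
      s <- summarize_motility(d, velocity_threshold, straightness_threshold,
                              frame_interval = frame_interval)
      dplyr::mutate(s, condition = cond, pCa = pca, .before = 1)
    }
  ) |> dplyr::bind_rows() |> dplyr::arrange(.data$condition, -.data$pCa)
  fits <- list()
  hill_rows <- list()
  for (cond in unique(sums$condition)) {
    cv <- sums[sums$condition == cond & sums$n_moving > 0, ]
    curve <- tibble::tibble(pCa = cv$pCa, velocity = cv$mean_velocity,
                            sem = cv$sem_velocity)
    fit <- tryCatch(fit_hill(curve), error = function(e) NULL)
    fits[[cond]] <- fit
    if (!is.null(fit)) {
      g <- glance(fit)
      se <- setNames(fit$estimates$std_error, fit$estimates$term)
      hill_rows[[cond]] <- tibble::tibble(
        condition = cond,
        vmax = g$vmax, vmax_se = se[["vmax"]],
        pca50 = g$pca50, pca50_se = se[["pca50"]],
        n = g$n, n_se = se[["n"]],
        rss = g$rss, converged = g$converged
      )
    }
  }
  structure(
    list(
      summaries = sums,
      hill = dplyr::bind_rows(hill_rows),
      fits = fits
    ),
    class = "motility_analysis"
  )
}

#' @export
print.motility_analysis <- function(x, ...) {
  cat("<motility_analysis>\n\nPer-condition Hill parameters:\n")
  print(x$hill)
  cat("\nPer-pCa summaries:\n")
  print(x$summaries, n = 12)
  invisible(x)
}

#' Write / read filament track tables
#'
#' Tab-separated long format (`condition`, `pCa`, `filament_id`, `frame`,
#' `x_um`, `y_um`) preceded by `# key=value` comment lines carrying
#' `frame_interval_s` and the master seed.
#'
#' @param tracks Long track tibble.
#' @param path File path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()` the
#'   track tibble with its `frame_interval` and `seed` attributes restored.
#' @export
write_tracks <- function(tracks, path) {
  fi <- attr(tracks, "frame_interval")
  sd <- attr(tracks, "seed")
  header <- c(
    paste0("# frame_interval_s=", sprintf("%.17g", fi %||% NA_real_)),
    paste0("# seed=", sd %||% NA_integer_),
    "condition\tpCa\tfilament_id\tframe\tx_um\ty_um"
  )
  body <- sprintf("%s\t%.17g\t%d\t%d\t%.17g\t%.17g",
                  tracks$condition, tracks$pCa,
                  as.integer(tracks$filament_id), as.integer(tracks$frame),
                  tracks$x_um, tracks$y_um)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  kv <- strsplit(sub("^#\\s*", "", lines[meta_idx]), "=", fixed = TRUE)
  meta <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  body <- lines[-meta_idx]
  if (length(body) < 1L ||
      body[1] != "condition\tpCa\tfilament_id\tframe\tx_um\ty_um") {
    abort("Missing or malformed track header row.")
  }
  rows <- body[-1]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L) {
    abort(paste0("Malformed track row at line ",
                 length(meta_idx) + 1L + bad[1], "."))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  out <- tibble::tibble(
    condition = m[, 1],
    pCa = as.numeric(m[, 2]),
    filament_id = as.integer(m[, 3]),
    frame = as.integer(m[, 4]),
    x_um = as.numeric(m[, 5]),
    y_um = as.numeric(m[, 6])
  )
  attr(out, "frame_interval") <- as.numeric(meta$frame_interval_s)
  attr(out, "seed") <- as.integer(meta$seed)
  out
}
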