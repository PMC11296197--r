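# -- seeding helpers ---------------------------------------------------------

# run code under a derived seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed from a base seed and integer indices, so any
# sample/position/exposure subset of a cohort is reproducible on its own
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (v in idx) {
    s <- (s * 69069 + (as.double(v) + 1) * 33554467) %% 2147483647
  }
  as.integer(s)
}

# inverse-CDF truncated normal: a fixed number of uniforms per draw keeps the
# stream alignment independent of the bounds
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("truncation bounds inverted")
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# -- configuration -----------------------------------------------------------

#' Configuration of a synthetic feather-colour cohort
#'
#' Defines the study conditions a simulated cohort emulates: per-sex latent
#' nanostructure parameter distributions, the matrix-mode measurement design
#' (21 grid positions, 6 exposures each), scattering-curve noise, triplicate
#' reflectance spectra, and the structure-to-colour links the analysis is
#' meant to recover. Defaults mirror the blue tit crown study design: 53 male
#' and 29 female samples; primary peaks near 0.045 per nm with male sponges
#' tuned slightly finer (more UV) than female ones; primary HWHM around 0.007
#' (males) and 0.008 (females); measured hue generated from the periodicity
#' prediction plus a -8 nm female offset (other structural elements lowering
#' realized female hue); brightness increasing with peak amplitude and
#' decreasing with peak position.
#'
#' @param n_males,n_females Cohort sizes (defaults 53 and 29).
#' @param years Calendar years samples are drawn from (uniformly).
#' @param q1_mean,q1_sd,q1_bounds Per-sex mean and sd (named `M`/`F`) and
#'   truncation bounds of the primary peak position, per nm.
#' @param h1_mean,h1_sd,h1_bounds Primary HWHM distribution, per nm.
#' @param a1_mean,a1_sd,a1_bounds Primary amplitude distribution (Porod
#'   units).
#' @param alpha_mean,alpha_sd,alpha_bounds Secondary/primary height ratio.
#' @param beta_mean,beta_sd,beta_bounds Secondary/primary position ratio.
#' @param h2_mean,h2_sd,h2_bounds Secondary HWHM distribution, per nm.
#' @param c_mean,c_sd,c_bounds Porod-space baseline distribution.
#' @param q_grid Momentum-transfer grid for simulated curves.
#' @param n_positions,n_exposures Matrix-mode design (replicate curves per
#'   sample = `n_positions * n_exposures`).
#' @param curve_noise_sd Additive Gaussian noise sd on the Porod-space curve,
#'   as a fraction of `a1` (default 0.02).
#' @param position_scale_sd Log-sd of the per-position lognormal intensity
#'   scale factor (varying amounts of feather in the beam).
#' @param within_sample_q1_sd Standard deviation (per nm) of position-to-
#'   position variation in sponge periodicity within one sample; default 0
#'   (the true extent of within-sample periodicity variation is an open
#'   biological question).
#' @param outlier_prob Probability that a replicate curve is an artefact
#'   (empty position or cosmic spike), default 0.
#' @param outlier_mode Which artefact type to inject: `"both"` (random mix,
#'   default), `"empty"` or `"spike"`.
#' @param spectral_noise_sd Additive noise sd on reflectance spectra (%).
#' @param hue_noise_sd Biological scatter (nm) of realized spectral hue
#'   around the periodicity prediction.
#' @param male_hue_offset,female_hue_offset Sex-specific offsets (nm) between
#'   the realized spectral hue and the periodicity prediction; default 0 and
#'   -8.
#' @param brightness_base Named per-sex baseline brightness (%).
#' @param brightness_a1_coef,brightness_q1_coef Structure-to-brightness link
#'   coefficients, in brightness units per within-sex sd of the amplitude and
#'   position respectively (defaults +1.5 and -1.0).
#' @param brightness_noise_sd Residual brightness noise (%).
#' @param spectral_peak_width Gaussian width (nm) of the reflectance peak.
#' @param spectral_base_frac Fraction of brightness contributed by the flat
#'   spectral baseline.
#' @param saxs_meas_rel_sd Named relative sds emulating the measurement +
#'   fitting error of each SAXS parameter in the table-level simulation path.
#' @param optical An [optical_model()] used to map periodicity to hue.
#' @param seed Integer base seed; every random quantity in the cohort is a
#'   deterministic function of it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_males = 53, n_females = 29,
    years = c(2007, 2022),
    q1_mean = c(M = 0.047, F = 0.044), q1_sd = c(M = 0.002, F = 0.002),
    q1_bounds = c(0.038, 0.06),
    h1_mean = c(M = 0.007, F = 0.008), h1_sd = c(M = 0.001, F = 0.0012),
    h1_bounds = c(0.003, 0.02),
    a1_mean = c(M = 110, F = 80), a1_sd = c(M = 25, F = 20),
    a1_bounds = c(20, 400),
    alpha_mean = c(M = 0.3, F = 0.3), alpha_sd = c(M = 0.05, F = 0.05),
    alpha_bounds = c(0.05, 1),
    beta_mean = c(M = 5 / 3, F = 5 / 3), beta_sd = c(M = 0.04, F = 0.04),
    beta_bounds = c(1.4, 2.0),
    h2_mean = c(M = 0.012, F = 0.012), h2_sd = c(M = 0.002, F = 0.002),
    h2_bounds = c(0.005, 0.03),
    c_mean = c(M = 2, F = 2), c_sd = c(M = 0.4, F = 0.4),
    c_bounds = c(0.5, 5),
    q_grid = seq(0.01, 0.25, length.out = 400),
    n_positions = 21, n_exposures = 6,
    curve_noise_sd = 0.02,
    position_scale_sd = 0.1,
    within_sample_q1_sd = 0,
    outlier_prob = 0,
    outlier_mode = c("both", "empty", "spike"),
    spectral_noise_sd = 0.5,
    hue_noise_sd = 2,
    male_hue_offset = 0, female_hue_offset = -8,
    brightness_base = c(M = 22, F = 18),
    brightness_a1_coef = 1.5, brightness_q1_coef = -1.0,
    brightness_noise_sd = 1.5,
    spectral_peak_width = 45,
    spectral_base_frac = 0.3,
    saxs_meas_rel_sd = c(q1 = 0.005, h1 = 0.05, a1 = 0.02,
                         alpha = 0.05, beta = 0.01, h2 = 0.05),
    optical = optical_model(),
    seed = 1) {
  outlier_mode <- match.arg(outlier_mode)
  cfg <- as.list(environment())
  stopifnot(n_males > 0, n_females > 0,
            outlier_prob >= 0, outlier_prob <= 1,
            curve_noise_sd >= 0, position_scale_sd >= 0,
            spectral_noise_sd >= 0, hue_noise_sd >= 0)
  for (nm in c("q1", "h1", "a1", "alpha", "beta", "h2", "c")) {
    b <- cfg[[paste0(nm, "_bounds")]]
    if (b[1] >= b[2]) stop(sprintf("truncation bounds inverted for `%s`", nm))
  }
  structure(cfg, class = "cohort_config")
}

# -- ground truth ------------------------------------------------------------

#' Draw the latent ground truth of a synthetic cohort
#'
#' Draws per-sample nanostructural parameters from sex-specific truncated
#' normal distributions, then derives each sample's realized spectral hue
#' (the periodicity prediction plus the sex offset and biological scatter)
#' and brightness (baseline plus the configured amplitude and position
#' links). Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per sample: `sample_index`, `sample`, `sex`,
#'   `year`, the seven model parameters (`q1`, `h1`, `a1`, `alpha`, `beta`,
#'   `h2`, `c`), `hue_true` (nm) and `brightness_true` (%).
#' @export
draw_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_males + config$n_females
  sex <- c(rep("M", config$n_males), rep("F", config$n_females))
  with_seed(derive_seed(config$seed, 1), {
    draw_par <- function(nm) {
      mu <- config[[paste0(nm, "_mean")]]
      sd <- config[[paste0(nm, "_sd")]]
      b <- config[[paste0(nm, "_bounds")]]
      vapply(seq_len(n), function(i) {
        rtruncnorm(1, mu[[sex[i]]], sd[[sex[i]]], b[1], b[2])
      }, numeric(1))
    }
    pars <- lapply(c(q1 = "q1", h1 = "h1", a1 = "a1", alpha = "alpha",
                     beta = "beta", h2 = "h2", c = "c"), draw_par)
    year <- sample(config$years, n, replace = TRUE)
    offset <- ifelse(sex == "M", config$male_hue_offset,
                     config$female_hue_offset)
    hue_true <- predict_hue(pars$q1, config$optical) + offset +
      rnorm(n, 0, config$hue_noise_sd)
    hue_true <- pmin(pmax(hue_true, 320), 700)
    z_within <- function(x) {
      stats::ave(x, sex, FUN = function(v) {
        s <- sd(v)
        if (is.finite(s) && s > 0) (v - mean(v)) / s else v * 0
      })
    }
    brightness_true <-
      unname(config$brightness_base[sex]) +
      config$brightness_a1_coef * z_within(pars$a1) +
      config$brightness_q1_coef * z_within(pars$q1) +
      rnorm(n, 0, config$brightness_noise_sd)
    brightness_true <- pmax(brightness_true, 1)
    tibble::tibble(
      sample_index = seq_len(n),
      sample = sprintf("S%03d", seq_len(n)),
      sex = sex, year = year,
      q1 = pars$q1, h1 = pars$h1, a1 = pars$a1, alpha = pars$alpha,
      beta = pars$beta, h2 = pars$h2, c = pars$c,
      hue_true = hue_true, brightness_true = brightness_true
    )
  })
}

# -- scattering curves -------------------------------------------------------

#' Simulate one matrix-mode replicate scattering curve
#'
#' Generates the curve recorded at one grid position and exposure of one
#' sample: the double-Gaussian Porod-space model of the sample's true
#' parameters, divided by q^4 back to intensity space, scaled by a
#' per-position lognormal factor (amount of feather material in the beam at
#' that position) and perturbed by additive Gaussian noise of sd
#' `curve_noise_sd * a1` in Porod space. With probability `outlier_prob` the
#' curve is replaced by an artefact: an empty position (near-zero signal) or
#' a cosmic-ray spike. Deterministic given `(config$seed, sample_index,
#' position, exposure)`.
#'
#' @param truth One row of a [draw_cohort()] tibble.
#' @param config The [cohort_config()].
#' @param position,exposure Indices of the matrix position and exposure.
#' @return A [scattering_curve()] tibble.
#' @export
simulate_curve <- function(truth, config, position = 1L, exposure = 1L) {
  stopifnot(inherits(config, "cohort_config"), nrow(truth) == 1)
  q <- config$q_grid
  pos_draw <- with_seed(
    derive_seed(config$seed, 2, truth$sample_index, position), {
      list(scale = rlnorm(1, 0, config$position_scale_sd),
           dq1 = rnorm(1, 0, config$within_sample_q1_sd %||% 0))
    }
  )
  scale <- pos_draw$scale
  params <- peak_params(c = truth$c, a1 = truth$a1,
                        q1 = max(truth$q1 + pos_draw$dq1, 0.038),
                        h1 = truth$h1, alpha = truth$alpha,
                        beta = truth$beta, h2 = truth$h2)
  with_seed(derive_seed(config$seed, 3, truth$sample_index, position, exposure), {
    noise_sd <- config$curve_noise_sd * truth$a1
    y <- peak_model(params, q) * scale + rnorm(length(q), 0, noise_sd)
    intens <- y / q^4
    sigma <- rep(noise_sd, length(q)) / q^4
    u <- runif(1)
    if (u < config$outlier_prob) {
      mode <- config$outlier_mode %||% "both"
      empty <- switch(mode, empty = TRUE, spike = FALSE, runif(1) < 0.5)
      if (empty) {
        # empty position: no feather in the beam
        intens <- abs(rnorm(length(q), 0, 1e-6))
      } else {
        # cosmic-ray spike in one bin
        hit <- sample.int(length(q), 1)
        intens[hit] <- intens[hit] + 50 * max(intens)
      }
    }
    scattering_curve(q, intens, sigma, sample = truth$sample,
                     position = position, exposure = exposure)
  })
}

#' Simulate every matrix-mode replicate curve of one sample
#'
#' @inheritParams simulate_curve
#' @return A long [scattering_curve()] tibble with
#'   `n_positions * n_exposures` replicate curves.
#' @export
simulate_sample_curves <- function(truth, config) {
  grid <- expand.grid(exposure = seq_len(config$n_exposures),
                      position = seq_len(config$n_positions))
  dplyr::bind_rows(purrr::map2(
    grid$position, grid$exposure,
    function(p, e) simulate_curve(truth, config, p, e)
  ))
}

# -- detector frames ---------------------------------------------------------

#' Render an isotropic scattering model onto a detector frame
#'
#' Produces a synthetic 2D exposure: every pixel's q is computed from the
#' geometry, the model intensity is evaluated there, scaled so the expected
#' total over unmasked pixels equals `total_counts`, and Poisson counts are
#' drawn. A circular beamstop mask of the given radius is applied around the
#' beam centre.
#'
#' @param curve_model Either a function `I(q)` or a [peak_params()] object
#'   (evaluated as the Porod-space model divided by q^4).
#' @param geometry A [saxs_geometry()].
#' @param dim Frame dimensions in pixels, default `c(201, 201)`.
#' @param total_counts Expected total photon count over unmasked pixels.
#' @param beamstop_radius_px Radius of the masked beamstop disc (pixels).
#' @param seed Integer seed for the Poisson draw.
#' @param poisson If `FALSE`, return the noiseless expected-count frame
#'   instead of a Poisson realisation (the exact binned reference for
#'   render-and-recover checks).
#' @return A [detector_frame()].
#' @export
simulate_frame <- function(curve_model, geometry, dim = c(201, 201),
                           total_counts = 1e7, beamstop_radius_px = 10,
                           seed = 1, poisson = TRUE) {
  stopifnot(inherits(geometry, "saxs_geometry"))
  if (!is.numeric(total_counts) || total_counts <= 0) {
    stop("`total_counts` must be positive")
  }
  imodel <- if (inherits(curve_model, "peak_params")) {
    function(q) peak_model(curve_model, q) / q^4
  } else {
    match.fun(curve_model)
  }
  shell <- detector_frame(matrix(0, dim[1], dim[2]), geometry)
  qpix <- pixel_q(shell)
  mask <- beamstop_mask(dim, geometry$beam_center_px, beamstop_radius_px)
  mu <- matrix(0, dim[1], dim[2])
  mu[mask] <- imodel(pmax(qpix[mask], 1e-12))
  mu[!is.finite(mu) | mu < 0] <- 0
  mu <- mu * (total_counts / sum(mu[mask]))
  counts <- matrix(0, dim[1], dim[2])
  counts[mask] <- if (poisson) {
    with_seed(seed, rpois(sum(mask), mu[mask]))
  } else {
    mu[mask]
  }
  detector_frame(counts, geometry, mask = mask)
}

# -- reflectance spectra -----------------------------------------------------

#' Simulate triplicate reflectance spectra for one sample
#'
#' Each replicate is a Gaussian reflectance peak centred on the sample's true
#' hue over a flat baseline, with additive measurement noise. Baseline and
#' peak amplitude are set so that in the noiseless limit the spectrum's
#' brightness equals the sample's true brightness (the baseline contributes
#' the fraction `spectral_base_frac` of it) and its hue equals the true hue
#' to the 1-nm grid resolution.
#'
#' @param truth One row of a [draw_cohort()] tibble.
#' @param config The [cohort_config()].
#' @param n_replicates Number of replicate measurements (default 3).
#' @return A long tibble: `sample`, `replicate`, `wavelength` (300-720 nm,
#'   1-nm steps), `reflectance` (%).
#' @export
simulate_spectra <- function(truth, config, n_replicates = 3) {
  stopifnot(inherits(config, "cohort_config"), nrow(truth) == 1)
  wl <- 300:720
  band <- wl >= 320 & wl <= 700
  w <- config$spectral_peak_width
  g <- exp(-(wl - truth$hue_true)^2 / (2 * w^2))
  gbar <- mean(g[band])
  base <- config$spectral_base_frac * truth$brightness_true
  amp <- (truth$brightness_true - base) / gbar
  purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    noise <- with_seed(
      derive_seed(config$seed, 4, truth$sample_index, rep_i),
      rnorm(length(wl), 0, config$spectral_noise_sd)
    )
    tibble::tibble(sample = truth$sample, replicate = rep_i,
                   wavelength = wl,
                   reflectance = base + amp * g + noise)
  })
}

# -- cohort table (fast path) ------------------------------------------------

#' Simulate a full cohort analysis table
#'
#' The fast, table-level simulation path: draws the latent cohort, emulates
#' the SAXS measurement + peak-fitting stage by perturbing each structural
#' parameter with its configured relative measurement error, simulates and
#' summarises triplicate reflectance spectra, and attaches the hue predicted
#' from the measured primary peak position. The physical stages this path
#' bypasses (frame reduction and Porod fitting) are exercised by
#' [simulate_sample_curves()] and [simulate_frame()].
#'
#' @param config A [cohort_config()].
#' @return A list with `truth` (the [draw_cohort()] tibble) and `table`, a
#'   cohort tibble with one row per sample: `sample`, `sex`, `year`, measured
#'   `q1`, `h1`, `a1`, `alpha`, `beta`, `h2`, derived `q2`, `a2`, `loga1`,
#'   `loga2`, colour variables `brightness`, `uv_chroma`, `hue` and
#'   `predicted_hue`.
#' @export
simulate_cohort_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- draw_cohort(config)
  n <- nrow(truth)
  meas <- with_seed(derive_seed(config$seed, 5), {
    rel <- config$saxs_meas_rel_sd
    out <- truth
    for (nm in names(rel)) {
      out[[nm]] <- truth[[nm]] * (1 + rnorm(n, 0, rel[[nm]]))
    }
    out
  })
  # variable-level replicate averaging, as in average_replicates(), without
  # the per-group data-frame machinery (this runs once per sample per cohort)
  colour <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    sp <- simulate_spectra(truth[i, ], config)
    reps <- lapply(split(sp, sp$replicate), summarize_reflectance)
    tibble::tibble(
      sample = truth$sample[i],
      brightness = mean(vapply(reps, `[[`, numeric(1), "brightness")),
      uv_chroma = mean(vapply(reps, `[[`, numeric(1), "uv_chroma")),
      hue = mean(vapply(reps, `[[`, numeric(1), "hue"))
    )
  }))
  tab <- tibble::tibble(
    sample = truth$sample, sex = truth$sex, year = truth$year,
    q1 = meas$q1, h1 = meas$h1, a1 = pmax(meas$a1, 0),
    alpha = meas$alpha, beta = meas$beta, h2 = meas$h2,
    q2 = meas$beta * meas$q1, a2 = meas$alpha * pmax(meas$a1, 0),
    loga1 = transform_amplitude(pmax(meas$a1, 0)),
    loga2 = transform_amplitude(meas$alpha * pmax(meas$a1, 0)),
    brightness = colour$brightness[match(truth$sample, colour$sample)],
    uv_chroma = colour$uv_chroma[match(truth$sample, colour$sample)],
    hue = colour$hue[match(truth$sample, colour$sample)]
  )
  tab$predicted_hue <- predict_hue(tab$q1, config$optical)
  list(truth = truth, table = tab)
}

# -- export ------------------------------------------------------------------

#' Export a synthetic cohort to disk in the analysis input formats
#'
#' Writes the directory layout the reduction/colorimetry readers consume:
#' `truth.csv`, `spectra.csv` (long), `config.yaml`, and one 3-column ASCII
#' `.dat` file per replicate curve under `curves/`. Everything round-trips
#' through [read_curve()] and `read.csv` within floating-point formatting
#' tolerance.
#'
#' @param truths A [draw_cohort()] tibble (may have zero rows).
#' @param curves Long curve tibble (e.g. bound [simulate_sample_curves()]
#'   output), or `NULL`.
#' @param spectra Long spectra tibble, or `NULL`.
#' @param outdir Output directory (created if missing).
#' @param config Optional [cohort_config()] to record as YAML.
#' @return `outdir`, invisibly.
#' @export
export_cohort <- function(truths, curves = NULL, spectra = NULL, outdir,
                          config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory")
  if (nrow(truths) == 0) warning("exporting an empty cohort")
  utils::write.csv(truths, file.path(outdir, "truth.csv"), row.names = FALSE)
  if (!is.null(spectra)) {
    utils::write.csv(spectra, file.path(outdir, "spectra.csv"),
                     row.names = FALSE)
  }
  if (!is.null(curves)) {
    cdir <- file.path(outdir, "curves")
    dir.create(cdir, showWarnings = FALSE)
    for (g in curve_groups(curves)) {
      fn <- sprintf("%s_p%02d_e%02d.dat", g$sample[1], g$position[1],
                    g$exposure[1])
      write_curve(g, file.path(cdir, fn))
    }
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$optical <- unclass(cfg$optical)
    cfg$q_grid <- list(min = min(config$q_grid), max = max(config$q_grid),
                       n = length(config$q_grid))
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  }
  invisible(outdir)
}
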