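test_that("cohorts are bit-reproducible given the seed", {
  cfg <- cohort_config(seed = 4)
  expect_identical(draw_cohort(cfg), draw_cohort(cfg))
  tr <- draw_cohort(cfg)
  expect_identical(simulate_curve(tr[3, ], cfg, 2, 5),
                   simulate_curve(tr[3, ], cfg, 2, 5))
  expect_identical(simulate_spectra(tr[3, ], cfg),
                   simulate_spectra(tr[3, ], cfg))
  # different indices give different draws
  expect_false(identical(simulate_curve(tr[3, ], cfg, 2, 5),
                         simulate_curve(tr[3, ], cfg, 2, 6)))
})

test_that("degenerate draws collapse onto the deterministic links", {
  cfg <- cohort_config(
    n_males = 4, n_females = 4,
    q1_sd = c(M = 0, F = 0), h1_sd = c(M = 0, F = 0), a1_sd = c(M = 0, F = 0),
    alpha_sd = c(M = 0, F = 0), beta_sd = c(M = 0, F = 0),
    h2_sd = c(M = 0, F = 0), c_sd = c(M = 0, F = 0),
    hue_noise_sd = 0, male_hue_offset = 0, female_hue_offset = 0,
    brightness_noise_sd = 0, seed = 5
  )
  tr <- draw_cohort(cfg)
  for (s in c("M", "F")) {
    expect_equal(unique(tr$hue_true[tr$sex == s]),
                 predict_hue(cfg$q1_mean[[s]], cfg$optical))
  }
  expect_error(cohort_config(q1_bounds = c(0.06, 0.038)), "inverted")
})

test_that("the cohort mean of male q1 matches the configured centre", {
  # law-of-large-numbers check across many cohorts
  means <- vapply(1:150, function(s) {
    tr <- draw_cohort(cohort_config(seed = 20000 + s))
    mean(tr$q1[tr$sex == "M"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.047), 0.0002)
})

test_that("noiseless simulated curves invert the Porod-space model exactly", {
  cfg <- cohort_config(curve_noise_sd = 0, position_scale_sd = 0, seed = 6)
  tr <- draw_cohort(cfg)[1, ]
  crv <- simulate_curve(tr, cfg, 1, 1)
  pars <- peak_params(c = tr$c, a1 = tr$a1, q1 = tr$q1, h1 = tr$h1,
                      alpha = tr$alpha, beta = tr$beta, h2 = tr$h2)
  expect_equal(porod_transform(crv)$y, peak_model(pars, crv$q),
               tolerance = 1e-12)
})

test_that("forced empty-position outliers are all flagged", {
  cfg <- cohort_config(outlier_prob = 1, outlier_mode = "empty",
                       n_positions = 3, n_exposures = 2, seed = 7)
  tr <- draw_cohort(cfg)[1, ]
  curves <- simulate_sample_curves(tr, cfg)
  fl <- detect_outlier_curves(curves)
  expect_true(all(fl$outlier))
})

test_that("artefact curves are flagged and excluded by the reduction", {
  cfg <- cohort_config(outlier_prob = 0.1, seed = 8)
  tr <- draw_cohort(cfg)[1, ]
  curves <- simulate_sample_curves(tr, cfg)
  fl <- detect_outlier_curves(curves)
  red <- reduce_sample(curves)
  fit <- fit_double_gaussian(red)
  expect_lt(abs(fit$params$q1 - tr$q1) / tr$q1, 0.01)
})

test_that("rendered frames recover the generating model after masking", {
  geom <- saxs_geometry(beam_center_px = c(101, 101))
  tru <- test_params()
  fr0 <- simulate_frame(tru, geom, dim = c(201, 201), total_counts = 1e6,
                        beamstop_radius_px = 0.5, poisson = FALSE)
  fr20 <- simulate_frame(tru, geom, dim = c(201, 201), total_counts = 1e6,
                         beamstop_radius_px = 20, poisson = FALSE)
  # above the beamstop cutoff the reductions agree up to the count
  # normalisation (masking removes low-q intensity from the total)
  q_cut <- q_from_angle(atan2(21 * geom$pixel_size_mm, geom$distance_mm) / 2,
                        geom$wavelength_nm)
  c0 <- azimuthal_average(fr0, n_bins = 100, q_range = c(q_cut, 0.25))
  c20 <- azimuthal_average(fr20, n_bins = 100, q_range = c(q_cut, 0.25))
  ratio <- c20$intensity / c0$intensity
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  expect_error(simulate_frame(tru, geom, total_counts = -1), "positive")
})

test_that("noiseless spectra hit the true hue and configured brightness", {
  cfg <- cohort_config(spectral_noise_sd = 0, seed = 9)
  tr <- draw_cohort(cfg)[5, ]
  sp <- simulate_spectra(tr, cfg)
  s <- average_replicates(sp)
  expect_lt(abs(s$hue - tr$hue_true), 1) # 1-nm grid resolution
  expect_equal(s$brightness, tr$brightness_true, tolerance = 1e-9)
})

test_that("UV chroma falls as the true hue moves from 360 toward 430 nm", {
  cfg <- cohort_config(spectral_noise_sd = 0, seed = 10)
  tr <- draw_cohort(cfg)[1, ]
  uv <- vapply(seq(360, 430, length.out = 5), function(h) {
    tri <- tr; tri$hue_true <- h
    average_replicates(simulate_spectra(tri, cfg))$uv_chroma
  }, numeric(1))
  expect_true(all(diff(uv) < 0))
})

test_that("replicate averaging stabilises the hue estimate", {
  sd_single <- sd(vapply(1:40, function(s) {
    cfg <- cohort_config(seed = 300 + s, spectral_noise_sd = 2)
    tr <- draw_cohort(cfg)[1, ]
    sp <- simulate_spectra(tr, cfg, n_replicates = 1)
    summarize_reflectance(sp)$hue - tr$hue_true
  }, numeric(1)))
  sd_avg <- sd(vapply(1:40, function(s) {
    cfg <- cohort_config(seed = 300 + s, spectral_noise_sd = 2)
    tr <- draw_cohort(cfg)[1, ]
    average_replicates(simulate_spectra(tr, cfg))$hue - tr$hue_true
  }, numeric(1)))
  expect_lt(sd_avg, sd_single)
})

test_that("exported cohorts round-trip through the format readers", {
  cfg <- cohort_config(n_males = 2, n_females = 1, n_positions = 2,
                       n_exposures = 1, seed = 12)
  tr <- draw_cohort(cfg)
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
    simulate_sample_curves(tr[i, ], cfg)
  }))
  spectra <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
    simulate_spectra(tr[i, ], cfg)
  }))
  out <- withr::local_tempdir()
  export_cohort(tr, curves, spectra, out, config = cfg)
  expect_true(file.exists(file.path(out, "truth.csv")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_equal(length(list.files(file.path(out, "curves"))), 3 * 2 * 1)
  tr2 <- utils::read.csv(file.path(out, "truth.csv"))
  expect_equal(tr2$q1, tr$q1, tolerance = 1e-9)
  f1 <- list.files(file.path(out, "curves"), full.names = TRUE)[1]
  c1 <- read_curve(f1)
  expect_equal(nrow(c1), length(cfg$q_grid))
  sp2 <- utils::read.csv(file.path(out, "spectra.csv"))
  expect_equal(nrow(sp2), nrow(spectra))
  # empty cohort still exports, with a warning
  expect_warning(export_cohort(tr[0, ], outdir = withr::local_tempdir()),
                 "empty")
})

test_that("full pipeline recovers latent peak parameters per sample", {
  cfg <- cohort_config(seed = 13)
  tr <- draw_cohort(cfg)
  for (i in c(1, 60)) { # one male, one female
    red <- reduce_sample(simulate_sample_curves(tr[i, ], cfg))
    fit <- fit_double_gaussian(red)
    expect_lt(abs(fit$params$q1 - tr$q1[i]) / tr$q1[i], 0.01)
    expect_lt(abs(fit$params$h1 - tr$h1[i]) / tr$h1[i], 0.1)
  }
})
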