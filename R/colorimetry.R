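#' Summarise a reflectance spectrum into brightness, UV chroma and hue
#'
#' The three reflectance variables used throughout the analysis are computed
#' on a canonical 1-nm grid from 320 to 700 nm (inclusive), obtained by
#' linear interpolation of the instrument grid:
#' * **brightness** -- mean per-cent reflectance over 320-700 nm;
#' * **UV chroma** -- reflectance in the 320-400 nm band divided by
#'   brightness. By default the band term is the band *mean*, so a flat
#'   spectrum has UV chroma exactly 1; `uv_convention = "sum"` instead uses
#'   band sum over full-range sum (flat spectrum: 81/381). The two
#'   conventions differ by a constant factor and rank samples identically.
#' * **hue** -- the wavelength of maximum reflectance on the grid, with ties
#'   resolved to the lowest wavelength.
#'
#' @param spectrum A data frame with columns `wavelength` (nm, covering at
#'   least 320-700) and `reflectance` (% relative to a white standard).
#' @param uv_convention `"mean"` (default) or `"sum"`; see Details.
#' @param smooth Odd boxcar width (in nm) applied before the hue argmax;
#'   default 0 (no smoothing).
#' @return A one-row tibble: `brightness`, `uv_chroma`, `hue`,
#'   `n_replicates` (= 1), `uv_convention`.
#' @examples
#' sp <- data.frame(wavelength = 300:720, reflectance = 50)
#' summarize_reflectance(sp) # brightness 50, uv_chroma 1, hue 320
#' @export
summarize_reflectance <- function(spectrum, uv_convention = c("mean", "sum"),
                                  smooth = 0) {
  uv_convention <- match.arg(uv_convention)
  stopifnot(all(c("wavelength", "reflectance") %in% names(spectrum)))
  wl <- spectrum$wavelength
  rf <- spectrum$reflectance
  if (any(!is.finite(rf))) stop("reflectance must be finite")
  if (min(wl) > 320 || max(wl) < 700) {
    stop("spectrum must cover the 320-700 nm range")
  }
  grid <- 320:700
  r <- approx(wl, rf, xout = grid, ties = mean)$y
  brightness <- mean(r)
  if (brightness == 0) stop("zero brightness: UV chroma is undefined")
  uv_band <- r[grid <= 400]
  uv_chroma <- if (uv_convention == "mean") {
    mean(uv_band) / brightness
  } else {
    sum(uv_band) / sum(r)
  }
  r_hue <- r
  if (smooth > 0) {
    k <- as.integer(smooth)
    if (k %% 2 == 0) k <- k + 1
    r_hue <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 2))
    r_hue[is.na(r_hue)] <- r[is.na(r_hue)]
  }
  hue <- grid[which.max(r_hue)] # which.max takes the first (lowest) tie
  tibble::tibble(brightness = brightness, uv_chroma = uv_chroma,
                 hue = as.numeric(hue), n_replicates = 1L,
                 uv_convention = uv_convention)
}

#' Average replicate reflectance measurements of one sample
#'
#' Replicate spectra of the same sample are summarised individually and the
#' three colour variables averaged arithmetically (variable-level averaging):
#' the sample hue is the mean of the replicate hues, not the argmax of a mean
#' spectrum.
#'
#' @param spectra A long data frame with columns `wavelength`, `reflectance`,
#'   `sample` and `replicate`; all rows must belong to one sample.
#' @inheritParams summarize_reflectance
#' @return A one-row tibble: `sample`, `brightness`, `uv_chroma`, `hue`,
#'   `n_replicates`, `uv_convention`.
#' @export
average_replicates <- function(spectra, uv_convention = c("mean", "sum"),
                               smooth = 0) {
  uv_convention <- match.arg(uv_convention)
  stopifnot(all(c("wavelength", "reflectance", "replicate") %in% names(spectra)))
  ids <- unique(spectra$sample %||% NA_character_)
  if (length(ids) > 1) stop("`spectra` mixes multiple sample ids")
  per_rep <- spectra |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(g, key) {
      summarize_reflectance(g, uv_convention = uv_convention, smooth = smooth)
    }) |>
    dplyr::ungroup()
  tibble::tibble(
    sample = as.character(ids[1]),
    brightness = mean(per_rep$brightness),
    uv_chroma = mean(per_rep$uv_chroma),
    hue = mean(per_rep$hue),
    n_replicates = nrow(per_rep),
    uv_convention = uv_convention
  )
}

#' Summarise every sample in a long spectra table
#'
#' @param spectra Long data frame with columns `wavelength`, `reflectance`,
#'   `sample`, `replicate` covering many samples.
#' @inheritParams summarize_reflectance
#' @return A tibble with one row per sample (see [average_replicates()]).
#' @export
summarize_spectra <- function(spectra, uv_convention = c("mean", "sum"),
                              smooth = 0) {
  uv_convention <- match.arg(uv_convention)
  spectra |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(g, key) {
      out <- average_replicates(
        dplyr::mutate(g, sample = key$sample),
        uv_convention = uv_convention, smooth = smooth
      )
      out[, setdiff(names(out), "sample")]
    }) |>
    dplyr::ungroup()
}

#' Plot reflectance spectra coloured by sample
#'
#' @param spectra Long spectra data frame (`wavelength`, `reflectance`,
#'   `sample`, optional `replicate`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  spectra <- tibble::as_tibble(spectra)
  if (!"replicate" %in% names(spectra)) spectra$replicate <- 1L
  spectra$.trace <- interaction(spectra$sample, spectra$replicate)
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$wavelength, y = .data$reflectance,
                               colour = .data$sample, group = .data$.trace)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance (%)") +
    ggplot2::theme(legend.position = "none")
}
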