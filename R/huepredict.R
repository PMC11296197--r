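#' Volume-averaged refractive index of the spongy layer
#'
#' The spongy layer is a two-phase keratin-air composite; the average
#' refractive index experienced by visible light is taken as the
#' volume-weighted mean of the phase indices,
#' `n_avg = f * n_keratin + (1 - f) * n_air`. With the keratin index 1.58 and
#' a keratin volume fraction of 0.57 this gives 1.3306, i.e. 1.33 at two
#' decimals. An alternative mixing rule averaging the squared indices
#' (Maxwell Garnett-like dielectric mixing at low contrast) is available via
#' `rule = "squared"` but is not the default.
#'
#' @param n_keratin Refractive index of keratin (default 1.58).
#' @param keratin_fraction Keratin volume fraction of the spongy layer, in
#'   `[0, 1]` (default 0.57).
#' @param n_air Refractive index of air (default 1.0).
#' @param rule `"linear"` (default, volume-weighted mean of indices) or
#'   `"squared"` (volume-weighted mean of squared indices, square-rooted).
#' @return The average refractive index (scalar).
#' @examples
#' round(average_refractive_index(1.58, 0.57), 2) # 1.33
#' @export
average_refractive_index <- function(n_keratin = 1.58, keratin_fraction = 0.57,
                                     n_air = 1.0,
                                     rule = c("linear", "squared")) {
  rule <- match.arg(rule)
  if (!is.numeric(keratin_fraction) || any(keratin_fraction < 0) ||
      any(keratin_fraction > 1)) {
    stop("`keratin_fraction` must lie in [0, 1]")
  }
  if (any(n_keratin < 1) || any(n_air < 1)) {
    stop("refractive indices must be >= 1")
  }
  if (rule == "linear") {
    keratin_fraction * n_keratin + (1 - keratin_fraction) * n_air
  } else {
    sqrt(keratin_fraction * n_keratin^2 + (1 - keratin_fraction) * n_air^2)
  }
}

#' Optical model of the spongy layer
#'
#' Bundles the refractive-index inputs and the derived average index used by
#' [predict_hue()]. The keratin fraction is treated as sexually uniform by
#' default; pass a different fraction to model sex-specific sponge density.
#'
#' @inheritParams average_refractive_index
#' @return A list of class `optical_model` with fields `n_keratin`,
#'   `keratin_fraction`, `n_air`, `rule` and `n_avg`.
#' @export
optical_model <- function(n_keratin = 1.58, keratin_fraction = 0.57,
                          n_air = 1.0, rule = c("linear", "squared")) {
  rule <- match.arg(rule)
  structure(
    list(
      n_keratin = n_keratin,
      keratin_fraction = keratin_fraction,
      n_air = n_air,
      rule = rule,
      n_avg = average_refractive_index(n_keratin, keratin_fraction, n_air, rule)
    ),
    class = "optical_model"
  )
}

#' @export
print.optical_model <- function(x, ...) {
  cat(sprintf("<optical_model> n_keratin = %.3g, keratin fraction = %.3g, n_avg = %.4f (%s rule)\n",
              x$n_keratin, x$keratin_fraction, x$n_avg, x$rule))
  invisible(x)
}

#' Predict hue from the primary scattering-peak position
#'
#' Constructive interference in a quasi-ordered structure of repeat distance
#' d = 2 pi / q1 reinforces the wavelength `lambda = 2 * d * n_avg` (normal
#' incidence, first order), so the predicted hue is
#' `2 * (2 pi / q1) * n_avg`. The prediction is strictly decreasing in `q1`:
#' more UV-tuned (finer) sponges have larger q1.
#'
#' @param q1 Primary peak position(s), reciprocal nm, positive.
#' @param optical An [optical_model()]; default uses keratin index 1.58 and
#'   fraction 0.57 (n_avg = 1.3306).
#' @return Predicted hue in nm, same length as `q1`.
#' @examples
#' predict_hue(0.045, optical_model(keratin_fraction = 0.57)) # ~371.6 nm
#' @export
predict_hue <- function(q1, optical = optical_model()) {
  stopifnot(inherits(optical, "optical_model"))
  if (!is.numeric(q1) || any(!is.finite(q1)) || any(q1 <= 0)) {
    stop("`q1` must be positive and finite")
  }
  2 * bragg_spacing(q1) * optical$n_avg
}

#' Add predicted hue to a per-sample fit table
#'
#' @param fits A data frame with a `q1` column (e.g. from [fit_samples()]).
#' @param optical An [optical_model()].
#' @return `fits` with a `predicted_hue` column appended (nm).
#' @export
add_predicted_hue <- function(fits, optical = optical_model()) {
  stopifnot("q1" %in% names(fits))
  dplyr::mutate(tibble::as_tibble(fits),
                predicted_hue = predict_hue(.data$q1, optical))
}
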