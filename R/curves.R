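#' Build a scattering-curve tibble
#'
#' A scattering curve is a tibble with one row per q bin and columns `sample`,
#' `position`, `exposure` (provenance), `q` (momentum transfer, reciprocal
#' nm, strictly increasing), `intensity` (normalised units) and `sigma`
#' (non-negative uncertainty). Several curves are stored stacked in one long
#' tibble and distinguished by the provenance columns.
#'
#' @param q Strictly increasing numeric vector of momentum transfer values.
#' @param intensity Numeric vector, same length as `q`.
#' @param sigma Non-negative numeric vector, same length as `q`.
#' @param sample,position,exposure Provenance labels recycled along the curve.
#' @return A tibble of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = rep(0, length(q)),
                             sample = NA_character_,
                             position = NA_integer_,
                             exposure = NA_integer_) {
  if (length(q) != length(intensity) || length(q) != length(sigma)) {
    stop("`q`, `intensity` and `sigma` must have equal length")
  }
  ord <- order(q)
  q <- q[ord]; intensity <- intensity[ord]; sigma <- sigma[ord]
  if (length(q) > 1 && any(diff(q) <= 0)) {
    stop("`q` must be strictly increasing (no duplicated q values)")
  }
  if (any(sigma < 0, na.rm = TRUE)) stop("`sigma` must be non-negative")
  out <- tibble::tibble(
    sample = as.character(sample),
    position = as.integer(position),
    exposure = as.integer(exposure),
    q = as.numeric(q),
    intensity = as.numeric(intensity),
    sigma = as.numeric(sigma)
  )
  class(out) <- c("scattering_curve", class(out))
  out
}

# split a long curve tibble into per-curve groups keyed by provenance
curve_groups <- function(curves) {
  key <- paste(curves$sample, curves$position, curves$exposure, sep = "\r")
  split(curves, factor(key, levels = unique(key)))
}

# check that all curves in a list share one q grid; returns the grid
shared_q_grid <- function(groups, tol = 1e-9) {
  qs <- groups[[1]]$q
  for (g in groups) {
    if (length(g$q) != length(qs) || any(abs(g$q - qs) > tol)) {
      stop("curves do not share a common q grid")
    }
  }
  qs
}

#' Flag outlier replicate curves by robust z-score
#'
#' Matrix-mode replicates of one sample occasionally contain artefacts: an
#' empty position (no feather in the beam, near-zero intensity) or a cosmic
#' ray spike (far too much intensity). Both move the summed intensity over the
#' analysis window far from the bulk of replicates, so a curve is flagged when
#' the robust z-score of its total windowed intensity -- `(total - median) /
#' mad(total)` -- exceeds `threshold` in absolute value. If the median
#' absolute deviation is zero (all totals identical), only curves deviating
#' from the shared total are flagged. Independently of the cohort, a curve
#' whose windowed total is statistically indistinguishable from zero given
#' its own uncertainties (total below `threshold` pooled sigmas) is flagged
#' as carrying no signal, so empty positions are caught even when most
#' replicates are empty. Inputs are not modified.
#'
#' @param curves Long scattering-curve tibble (replicates distinguished by
#'   `sample`/`position`/`exposure`). At least 3 curves on a shared q grid.
#' @param threshold Robust z-score threshold, default 3.5.
#' @param window Length-2 q window over which intensity is summed; default
#'   `c(0.038, 0.2)`, the peak-model fit window.
#' @return A tibble with one row per curve: the provenance columns,
#'   `total_intensity`, `zscore` and logical `outlier`.
#' @export
detect_outlier_curves <- function(curves, threshold = 3.5,
                                  window = c(0.038, 0.2)) {
  groups <- curve_groups(curves)
  meta <- dplyr::bind_rows(lapply(groups, function(g) g[1, c("sample", "position", "exposure")]))
  totals <- vapply(groups, function(g) {
    sel <- g$q >= window[1] & g$q <= window[2]
    sum(g$intensity[if (any(sel)) sel else TRUE])
  }, numeric(1))
  # a curve with no signal above its own noise floor carries no feathers
  no_signal <- vapply(groups, function(g) {
    sel <- g$q >= window[1] & g$q <= window[2]
    if (!any(sel)) sel <- rep(TRUE, nrow(g))
    floor_ <- sqrt(sum(g$sigma[sel]^2))
    floor_ > 0 && sum(g$intensity[sel]) < threshold * floor_
  }, logical(1))
  if (length(groups) < 3) {
    warning("fewer than 3 curves: outlier detection skipped, no flags set")
    z <- rep(0, length(groups))
    flag <- rep(FALSE, length(groups))
  } else {
    shared_q_grid(groups)
    med <- median(totals)
    s <- mad(totals)
    if (s == 0) {
      z <- ifelse(totals == med, 0, Inf * sign(totals - med))
    } else {
      z <- (totals - med) / s
    }
    flag <- abs(z) > threshold | no_signal
  }
  dplyr::bind_cols(meta, tibble::tibble(total_intensity = unname(totals),
                                        zscore = unname(z),
                                        outlier = unname(flag)))
}

#' Normalise replicate curves to a common intensity scale and average them
#'
#' Matrix-mode replicates differ by a multiplicative factor (varying amounts
#' of feather material in the beam), so each curve is rescaled before
#' averaging: the scale factor is the non-negative least-squares coefficient
#' that best matches the curve to the pointwise median curve over `window`.
#' The output intensity is the pointwise mean of the scaled curves and the
#' output sigma the standard error across them (a single input curve is
#' returned unchanged, with its own sigma).
#'
#' @param curves Long scattering-curve tibble of unflagged replicates sharing
#'   one q grid.
#' @param window Length-2 q window used to compute scale factors; default
#'   `c(0.038, 0.2)`.
#' @param sample Sample id for the output curve; defaults to the first input id.
#' @return A single averaged [scattering_curve()] tibble.
#' @export
normalize_and_average <- function(curves, window = c(0.038, 0.2),
                                  sample = NULL) {
  groups <- curve_groups(curves)
  if (length(groups) == 0) stop("no curves to average")
  sample <- sample %||% groups[[1]]$sample[1]
  if (length(groups) == 1) {
    g <- groups[[1]]
    return(scattering_curve(g$q, g$intensity, g$sigma, sample = sample))
  }
  qs <- shared_q_grid(groups)
  sel <- qs >= window[1] & qs <= window[2]
  if (!any(sel)) stop("`window` contains no q grid points")
  mat <- vapply(groups, function(g) g$intensity, numeric(length(qs)))
  # scale-invariant reference: the pointwise median of the curves after each
  # is brought to unit mean intensity over the window, so that rescaling any
  # input curve leaves the reference (and hence the output) unchanged
  win_means <- colMeans(mat[sel, , drop = FALSE])
  ok_ref <- is.finite(win_means) & win_means > 0
  if (!any(ok_ref)) stop("no usable curves: all have zero intensity in `window`")
  ref <- apply(sweep(mat[sel, ok_ref, drop = FALSE], 2, win_means[ok_ref],
                     `/`), 1, median)
  scales <- vapply(seq_len(ncol(mat)), function(j) {
    y <- mat[sel, j]
    ss <- sum(y^2)
    if (ss == 0) return(NA_real_)
    max(sum(y * ref) / ss, 0)
  }, numeric(1))
  usable <- is.finite(scales) & scales > 0
  if (!any(usable)) stop("no usable curves: all have zero intensity in `window`")
  if (any(!usable)) {
    warning(sprintf("%d curve(s) with zero or degenerate intensity over the window excluded",
                    sum(!usable)))
  }
  scaled <- sweep(mat[, usable, drop = FALSE], 2, scales[usable], `*`)
  n <- ncol(scaled)
  avg <- rowMeans(scaled)
  sigma <- if (n > 1) apply(scaled, 1, sd) / sqrt(n) else groups[[which(usable)]]$sigma
  scattering_curve(qs, avg, sigma, sample = sample)
}

#' Reduce the matrix-mode replicates of one sample to a single curve
#'
#' Convenience wrapper chaining [detect_outlier_curves()] and
#' [normalize_and_average()]: flags artefact replicates (empty positions,
#' cosmic spikes), drops them, and returns the scaled average of the rest.
#'
#' @inheritParams detect_outlier_curves
#' @inheritParams normalize_and_average
#' @param outlier_z Robust z threshold passed to [detect_outlier_curves()].
#' @return A single averaged [scattering_curve()] tibble.
#' @export
reduce_sample <- function(curves, outlier_z = 3.5, window = c(0.038, 0.2),
                          sample = NULL) {
  flags <- detect_outlier_curves(curves, threshold = outlier_z,
                                 window = window)
  groups <- curve_groups(curves)
  keep <- dplyr::bind_rows(groups[!flags$outlier])
  normalize_and_average(keep, window = window, sample = sample)
}

#' Read and write 3-column ASCII scattering curves
#'
#' The on-disk format is plain whitespace-delimited text with three columns
#' (q in reciprocal nm, intensity, sigma); lines starting with `#` are header
#' comments.
#'
#' @param path File path.
#' @param sample,position,exposure Provenance labels attached on read.
#' @return `read_curve()` returns a [scattering_curve()] tibble;
#'   `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path, sample = NA_character_,
                       position = NA_integer_, exposure = NA_integer_) {
  dat <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "intensity", "sigma"))
  scattering_curve(dat$q, dat$intensity, dat$sigma,
                   sample = sample, position = position, exposure = exposure)
}

#' @rdname read_curve
#' @param curve A [scattering_curve()] tibble (a single curve).
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample: %s  position: %s  exposure: %s",
                     curve$sample[1], curve$position[1], curve$exposure[1]),
             con)
  writeLines("# q_nm^-1  intensity  sigma", con)
  writeLines(sprintf("%.12e %.12e %.12e", curve$q, curve$intensity,
                     curve$sigma), con)
  invisible(path)
}
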