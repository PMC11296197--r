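#' A 2D detector frame with geometry and mask
#'
#' Container for one exposure of the area detector: a non-negative intensity
#' matrix, a same-shape logical mask (`TRUE` = usable pixel), the instrument
#' geometry, and provenance labels (sample id, matrix position, exposure
#' index). Matrix-mode experiments record one such frame per grid position and
#' exposure.
#'
#' @param intensities Numeric matrix of pixel intensities; finite and
#'   non-negative wherever the mask is `TRUE`.
#' @param geometry A [saxs_geometry()] object.
#' @param mask Logical matrix, same shape as `intensities`; default all `TRUE`.
#' @param sample,position,exposure Provenance labels: sample id (character),
#'   matrix position index and exposure index (integers).
#'
#' @return An object of class `detector_frame`.
#' @export
detector_frame <- function(intensities, geometry,
                           mask = NULL,
                           sample = NA_character_,
                           position = NA_integer_,
                           exposure = NA_integer_) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix")
  }
  if (!inherits(geometry, "saxs_geometry")) {
    stop("`geometry` must be a `saxs_geometry` object")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(intensities), ncol(intensities))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(intensities))) {
    stop("`mask` must be a logical matrix with the shape of `intensities`")
  }
  if (any(!is.finite(intensities[mask]))) {
    stop("`intensities` must be finite wherever `mask` is TRUE")
  }
  structure(
    list(
      intensities = intensities,
      mask = mask,
      geometry = geometry,
      sample = as.character(sample),
      position = as.integer(position),
      exposure = as.integer(exposure)
    ),
    class = "detector_frame"
  )
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("<detector_frame> %d x %d px, %d masked, sample=%s pos=%s exp=%s\n",
              nrow(x$intensities), ncol(x$intensities), sum(!x$mask),
              x$sample, x$position, x$exposure))
  invisible(x)
}

#' Apply background and instrumental corrections to a frame
#'
#' Standard pre-reduction corrections: dark-signal subtraction, empty-beam
#' (instrumental background) subtraction scaled by the sample transmission,
#' and division by exposure time, detector flatness and sample self-absorption
#' factors. Every omitted correction defaults to the identity, so
#' `correct_frame(frame)` returns the frame unchanged.
#'
#' The corrected intensity is
#' `(frame - dark - transmission * empty) / (exposure_time * flatness * absorption)`.
#' Masks of `dark` and `empty` are combined with the frame mask by logical AND.
#'
#' @param frame A [detector_frame()].
#' @param dark Optional dark-signal [detector_frame()] (same shape).
#' @param empty Optional empty-beam [detector_frame()] (same shape).
#' @param transmission Sample transmission factor scaling the empty-beam
#'   subtraction (scalar, default 1).
#' @param exposure_time Exposure time divisor (positive scalar, default 1).
#' @param flatness Detector flatness correction: scalar or matrix, default 1.
#' @param absorption Sample self-absorption correction: scalar or matrix,
#'   default 1.
#'
#' @return A corrected [detector_frame()] with the combined mask.
#' @export
correct_frame <- function(frame, dark = NULL, empty = NULL,
                          transmission = 1, exposure_time = 1,
                          flatness = 1, absorption = 1) {
  stopifnot(inherits(frame, "detector_frame"))
  if (!is.numeric(exposure_time) || length(exposure_time) != 1 ||
      !is.finite(exposure_time) || exposure_time <= 0) {
    stop("`exposure_time` must be a single positive number")
  }
  img <- frame$intensities
  mask <- frame$mask
  for (ref in list(dark, empty)) {
    if (!is.null(ref)) {
      if (!inherits(ref, "detector_frame")) {
        stop("`dark` and `empty` must be `detector_frame` objects")
      }
      if (!identical(dim(ref$intensities), dim(img))) {
        stop("correction frame shape does not match the frame")
      }
      mask <- mask & ref$mask
    }
  }
  if (!is.null(dark)) img <- img - dark$intensities
  if (!is.null(empty)) img <- img - transmission * empty$intensities
  denom <- exposure_time * flatness * absorption
  img <- img / denom
  out <- frame
  out$intensities <- img
  out$mask <- mask
  out
}

# q value of every pixel given the frame geometry (radial, small-angle exact:
# theta = atan(r / D) / 2).
pixel_q <- function(frame) {
  g <- frame$geometry
  nr <- nrow(frame$intensities)
  nc <- ncol(frame$intensities)
  dr <- (seq_len(nr) - g$beam_center_px[1]) * g$pixel_size_mm
  dc <- (seq_len(nc) - g$beam_center_px[2]) * g$pixel_size_mm
  r <- sqrt(outer(dr^2, dc^2, `+`))
  theta <- atan2(r, g$distance_mm) / 2
  q_from_angle(theta, g$wavelength_nm)
}

#' Azimuthally average a detector frame into a 1D scattering curve
#'
#' Maps every usable pixel to its momentum transfer q (via the radial
#' scattering angle and [q_from_angle()]) and averages intensities in
#' equal-width q bins. The per-bin intensity is the mean over contributing
#' pixels and the per-bin uncertainty is the standard error of that mean; a
#' bin with a single pixel falls back to the Poisson estimate
#' `sqrt(intensity)`. Bins with no contributing pixels are dropped, and bin
#' positions are reported at bin centres.
#'
#' @param frame A [detector_frame()].
#' @param n_bins Number of equal-width q bins (default 256, at least 2).
#' @param q_range Optional length-2 numeric giving the q window to bin over;
#'   default is the full range of unmasked pixel q values.
#'
#' @return A scattering-curve tibble with columns `sample`, `position`,
#'   `exposure`, `q`, `intensity`, `sigma`, ordered by increasing `q`.
#' @examples
#' geom <- saxs_geometry(beam_center_px = c(51, 51))
#' img <- matrix(100, 101, 101)
#' crv <- azimuthal_average(detector_frame(img, geom), n_bins = 32)
#' all(abs(crv$intensity - 100) < 1e-9)
#' @export
azimuthal_average <- function(frame, n_bins = 256, q_range = NULL) {
  stopifnot(inherits(frame, "detector_frame"))
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2) {
    stop("`n_bins` must be a single number >= 2")
  }
  qpix <- pixel_q(frame)
  use <- frame$mask
  if (!any(use)) stop("all pixels are masked: cannot form a scattering curve")
  qv <- qpix[use]
  iv <- frame$intensities[use]
  if (is.null(q_range)) {
    q_range <- range(qv)
  }
  stopifnot(length(q_range) == 2, q_range[2] >= q_range[1])
  if (q_range[1] == q_range[2]) {
    # degenerate case (e.g. a single usable pixel): one bin at that q
    sel <- qv == q_range[1]
    m <- mean(iv[sel])
    s <- if (sum(sel) > 1) sd(iv[sel]) / sqrt(sum(sel)) else sqrt(max(m, 0))
    return(scattering_curve(q_range[1], m, s, sample = frame$sample,
                            position = frame$position,
                            exposure = frame$exposure))
  }
  inwin <- qv >= q_range[1] & qv <= q_range[2]
  qv <- qv[inwin]
  iv <- iv[inwin]
  if (length(qv) == 0) stop("no unmasked pixels inside `q_range`")
  breaks <- seq(q_range[1], q_range[2], length.out = n_bins + 1)
  bin <- findInterval(qv, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n <- tabulate(bin, nbins = n_bins)
  s1 <- unname(tapply(iv, factor(bin, levels = seq_len(n_bins)), sum))
  s1[is.na(s1)] <- 0
  mean_i <- ifelse(n > 0, s1 / n, NA_real_)
  s2 <- unname(tapply(iv^2, factor(bin, levels = seq_len(n_bins)), sum))
  s2[is.na(s2)] <- 0
  # SEM with Poisson fallback for single-pixel bins
  var_i <- ifelse(n > 1, pmax(s2 - n * mean_i^2, 0) / (n - 1), NA_real_)
  sem <- ifelse(n > 1, sqrt(var_i / n), sqrt(pmax(mean_i, 0)))
  centres <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  keep <- n > 0
  scattering_curve(
    q = centres[keep], intensity = mean_i[keep], sigma = sem[keep],
    sample = frame$sample, position = frame$position, exposure = frame$exposure
  )
}

#' Read a detector frame from disk
#'
#' Reads a single-channel frame stored either as whitespace-delimited matrix
#' text or as a grayscale TIFF (requires the \pkg{tiff} package). Geometry and
#' an optional beamstop mask come from a YAML sidecar with keys
#' `wavelength_nm`, `distance_mm`, `beam_center_px`, `pixel_size_mm` and
#' optionally `mask_file` (matrix text of 0/1) or `beamstop_radius_px`.
#'
#' @param path Path to the frame file (`.tif`/`.tiff` or text matrix).
#' @param geometry Either a [saxs_geometry()] or the path to a YAML sidecar.
#' @param sample,position,exposure Provenance labels.
#' @return A [detector_frame()].
#' @export
read_frame <- function(path, geometry,
                       sample = NA_character_,
                       position = NA_integer_,
                       exposure = NA_integer_) {
  mask <- NULL
  if (is.character(geometry)) {
    side <- yaml::read_yaml(geometry)
    geom <- saxs_geometry(
      wavelength_nm = side$wavelength_nm %||% 0.154,
      distance_mm = side$distance_mm %||% 2507,
      beam_center_px = unlist(side$beam_center_px %||% c(0, 0)),
      pixel_size_mm = side$pixel_size_mm %||% 0.172
    )
    if (!is.null(side$mask_file)) {
      mpath <- file.path(dirname(geometry), side$mask_file)
      mask <- as.matrix(utils::read.table(mpath)) != 0
      dimnames(mask) <- NULL
    }
  } else {
    geom <- geometry
    side <- NULL
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the `tiff` package")
    }
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else {
    img <- as.matrix(utils::read.table(path))
    dimnames(img) <- NULL
  }
  if (is.null(mask) && !is.null(side$beamstop_radius_px) &&
      side$beamstop_radius_px > 0) {
    mask <- beamstop_mask(dim(img), geom$beam_center_px,
                          side$beamstop_radius_px)
  }
  detector_frame(img, geom, mask = mask, sample = sample,
                 position = position, exposure = exposure)
}

# circular beamstop mask: FALSE inside the disc
beamstop_mask <- function(dim, center_px, radius_px) {
  r2 <- outer((seq_len(dim[1]) - center_px[1])^2,
              (seq_len(dim[2]) - center_px[2])^2, `+`)
  r2 > radius_px^2
}

#' Write a detector frame as whitespace-delimited matrix text
#'
#' @param frame A [detector_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "detector_frame"))
  utils::write.table(frame$intensities, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
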