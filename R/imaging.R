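#' Multi-frame fluorescence image stack
#'
#' Container for one field of view (FOV): `frames` is an H x W x F array of
#' non-negative intensities in camera units.  Defaults mirror the ThT
#' acquisition geometry (512 x 512 EMCCD frames, 322 nm pixels, 50 ms
#' exposure, 50 frames averaged per FOV).
#'
#' @param frames numeric H x W x F array (a single H x W matrix is accepted
#'   as F = 1).
#' @param pixel_size_nm physical pixel size, nm.
#' @param exposure_ms exposure per frame, ms.
#' @param fov_id field-of-view identifier.
#' @param timepoint_h aggregation time point, hours.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_nm = 322, exposure_ms = 50,
                        fov_id = "fov1", timepoint_h = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x F array")
  if (dim(frames)[3] < 1L) stop("stack must contain at least one frame")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be > 0")
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 exposure_ms = exposure_ms, fov_id = fov_id,
                 timepoint_h = timepoint_h),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), %.5g nm/px, fov %s, t = %s h\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$fov_id,
              format(x$timepoint_h)))
  invisible(x)
}

#' Average an image stack over frames
#'
#' Pixelwise mean across all frames, the first step of the detection
#' pipeline: averaging F frames suppresses uncorrelated camera and shot
#' noise by a factor of sqrt(F).
#'
#' @param stack an [image_stack()] or H x W x F array.
#' @return H x W matrix.
#' @export
average_frames <- function(stack) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (is.matrix(frames)) return(frames)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`stack` must be an image_stack or an H x W x F array")
  if (dim(frames)[3] < 1L) stop("empty stack")
  rowMeans(frames, dims = 2L)
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  # the kernel cannot exceed the image; it stays normalised so the DC
  # component is preserved exactly even when truncated
  mx <- min(dim(image))
  mx <- if (mx %% 2L == 0L) mx - 1L else mx
  as.matrix(EBImage::gblur(image, sigma = sigma, radius = min(r, mx)))
}

#' Bandpass filter and blur an averaged image
#'
#' Difference-of-Gaussians bandpass (small-sigma blur minus large-sigma
#' blur) removes both the slowly modulated illumination background and
#' pixel-scale camera noise, followed by a final Gaussian blur to smooth
#' particle interiors before thresholding.  The operation is linear in the
#' input and removes the DC component exactly, so a pure low-frequency
#' background maps to (near) zero.
#'
#' @param image H x W matrix (typically from [average_frames()]).
#' @param low_sigma sigma of the small Gaussian, px (passes particles).
#' @param high_sigma sigma of the large Gaussian, px (estimates background);
#'   must exceed `low_sigma`.
#' @param blur_sigma sigma of the final smoothing blur, px (0 disables).
#' @return filtered H x W matrix, zero-mean for background-only input.
#' @export
bandpass_blur <- function(image, low_sigma = 1, high_sigma = 20,
                          blur_sigma = 1) {
  stopifnot(is.matrix(image))
  if (!(low_sigma > 0 && high_sigma > low_sigma))
    stop("need 0 < low_sigma < high_sigma, got ", low_sigma, ", ", high_sigma)
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  bp <- gaussian_blur(image, low_sigma) - gaussian_blur(image, high_sigma)
  gaussian_blur(bp, blur_sigma)
}

#' Label connected components of a binary mask
#'
#' 8-connected (default) or 4-connected labelling; labels are assigned in
#' deterministic order of each component's top-left pixel (lexicographic by
#' row, then column).
#'
#' @param mask logical H x W matrix.
#' @param connectivity 8 or 4.
#' @return integer H x W matrix; 0 is background, components are 1..n.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)

  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- vid[(c2[ok] - 1L) * h + r2[ok]]
    hit <- nb > 0L
    from <- c(from, vid[idx[ok]][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # deterministic relabel: order components by their (row, col)-first pixel
  ord <- order(rr, cc)
  first_seen <- memb[ord][!duplicated(memb[ord])]
  relabel <- integer(max(memb))
  relabel[first_seen] <- seq_along(first_seen)
  lab[idx] <- relabel[memb]
  lab
}

#' Segment particles in a filtered image
#'
#' Thresholds the (bandpass-filtered) image and extracts connected
#' components with pixel area inside `[min_area_px, max_area_px]`.
#' Centroids are intensity-weighted mean pixel positions (0-based
#' coordinates, pixel centers at integers).  Particles touching the image
#' border are kept but flagged, so size statistics can exclude their
#' truncated areas.  Output ordering follows each particle's top-left pixel
#' and is fully deterministic.
#'
#' If `intensity_threshold` is NULL it defaults to
#' `median(image) + 3 * mad(image)`: on a bandpass-filtered image the
#' background is centred near zero, so this is background plus three robust
#' sigmas.
#'
#' @param image H x W matrix, typically from [bandpass_blur()].
#' @param intensity_threshold absolute threshold on `image`, or NULL for
#'   the robust default.
#' @param min_area_px,max_area_px inclusive component-size bounds, px.
#' @param connectivity 8 (default) or 4.
#' @return An object of class `particle_set`: list with `table` (data frame
#'   `particle_id`, `centroid_row`, `centroid_col`, `area_px`,
#'   `touches_border`) and `pixels` (list of n x 2 matrices of 0-based
#'   (row, col) pixel coordinates), plus the threshold used.
#' @export
segment_particles <- function(image, intensity_threshold = NULL,
                              min_area_px = 4L,
                              max_area_px = floor(length(image) / 4),
                              connectivity = 8) {
  stopifnot(is.matrix(image))
  if (is.null(intensity_threshold))
    intensity_threshold <- stats::median(image) + 3 * stats::mad(image)
  if (intensity_threshold < 0)
    stop("`intensity_threshold` must be >= 0")
  if (!(min_area_px >= 1 && min_area_px <= max_area_px))
    stop("need 1 <= min_area_px <= max_area_px")
  h <- nrow(image); w <- ncol(image)
  lab <- label_components(image > intensity_threshold, connectivity)
  n <- max(lab)
  keep_tab <- list(); keep_pix <- list(); k <- 0L
  if (n > 0) {
    for (i in seq_len(n)) {
      idx <- which(lab == i)
      if (length(idx) < min_area_px || length(idx) > max_area_px) next
      rr <- ((idx - 1L) %% h)        # 0-based
      cc <- ((idx - 1L) %/% h)
      wgt <- image[idx]
      sw <- sum(wgt)
      cen <- if (sw > 0) c(sum(rr * wgt) / sw, sum(cc * wgt) / sw)
             else c(mean(rr), mean(cc))
      k <- k + 1L
      keep_tab[[k]] <- data.frame(
        particle_id = k,
        centroid_row = cen[1], centroid_col = cen[2],
        area_px = length(idx),
        touches_border = any(rr == 0L | rr == h - 1L |
                             cc == 0L | cc == w - 1L))
      keep_pix[[k]] <- cbind(row = rr, col = cc)
    }
  }
  tab <- if (k > 0) do.call(rbind, keep_tab)
         else data.frame(particle_id = integer(0), centroid_row = numeric(0),
                         centroid_col = numeric(0), area_px = integer(0),
                         touches_border = logical(0))
  structure(list(table = tab, pixels = keep_pix,
                 threshold = intensity_threshold, shape = c(h, w)),
            class = "particle_set")
}

#' Estimate the smooth image background
#'
#' Large-window median filter of the averaged raw image.  The window must be
#' much larger than a typical particle so that sparse bright particles do
#' not pull the local median up; the result is strictly positive for
#' positive inputs and scales linearly with the image.
#'
#' @param image H x W matrix of positive raw intensities.
#' @param window_px full window width in px (odd recommended); must be >= 3.
#' @return H x W background map.
#' @export
estimate_background <- function(image, window_px = 25) {
  stopifnot(is.matrix(image))
  if (window_px < 3) stop("`window_px` must be at least 3")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)  # constant image is its own background
  scaled <- (image - lo) / (hi - lo)          # medianFilter needs [0, 1]
  med <- as.matrix(EBImage::medianFilter(scaled, size = floor(window_px / 2)))
  med * (hi - lo) + lo
}

#' SBR-corrected particle intensity
#'
#' The signal-to-background ratio of a pixel is its intensity above the
#' local background divided by the background, `(I - bg) / bg`.  A
#' particle's corrected intensity is the sum of per-pixel SBR over its
#' boundary pixel set, computed on the *raw averaged* image (not the
#' filtered one), which makes the measure exactly invariant to any global
#' rescaling of illumination or camera gain.
#'
#' @param raw_avg_image H x W matrix of raw averaged intensities.
#' @param pixels n x 2 matrix of 0-based (row, col) pixel coordinates (one
#'   element of a [segment_particles()] `pixels` list).
#' @param background_map H x W background map, strictly positive on the
#'   particle pixels (see [estimate_background()]).
#' @return dimensionless summed SBR (>= 0 is not enforced pixelwise; dark
#'   pixels contribute negatively, sums for real particles are positive).
#' @export
sbr_intensity <- function(raw_avg_image, pixels, background_map) {
  stopifnot(is.matrix(raw_avg_image), is.matrix(background_map),
            all(dim(raw_avg_image) == dim(background_map)))
  if (!is.matrix(pixels) || ncol(pixels) != 2L || nrow(pixels) == 0L)
    stop("`pixels` must be a non-empty n x 2 matrix of (row, col)")
  idx <- pixels[, 2] * nrow(raw_avg_image) + pixels[, 1] + 1L
  bg <- background_map[idx]
  bad <- which(bg <= 0)
  if (length(bad))
    stop("non-positive background at pixel (row=", pixels[bad[1], 1],
         ", col=", pixels[bad[1], 2], "); cannot form SBR")
  sum((raw_avg_image[idx] - bg) / bg)
}

#' Detect and quantify particles in an image stack
#'
#' The full per-FOV pipeline: average frames, difference-of-Gaussians
#' bandpass + blur, robust thresholding and 8-connected segmentation on the
#' filtered image, then SBR-corrected intensities measured on the raw
#' averaged image against a large-window median background.  Detection and
#' quantification are deliberately separated: thresholds act on the
#' filtered image while intensities are always ratios of raw values.
#'
#' @param stack an [image_stack()].
#' @param low_sigma,high_sigma,blur_sigma bandpass settings, px.
#' @param intensity_threshold threshold on the filtered image (NULL for the
#'   robust default, see [segment_particles()]).
#' @param min_area_px,max_area_px particle size bounds, px.
#' @param connectivity 8 or 4.
#' @param background_window_px median-filter window for the background map.
#' @return data frame with one row per particle: `fov_id`, `timepoint_h`,
#'   `particle_id`, `centroid_row`, `centroid_col`, `area_px`, `area_um2`,
#'   `sbr_intensity`, `touches_border`.
#' @export
detect_particles <- function(stack, low_sigma = 1, high_sigma = 20,
                             blur_sigma = 1, intensity_threshold = NULL,
                             min_area_px = 4L,
                             max_area_px = NULL,
                             connectivity = 8,
                             background_window_px = 25) {
  stopifnot(inherits(stack, "image_stack"))
  avg <- average_frames(stack)
  if (is.null(max_area_px)) max_area_px <- floor(length(avg) / 4)
  filt <- bandpass_blur(avg, low_sigma, high_sigma, blur_sigma)
  seg <- segment_particles(filt, intensity_threshold, min_area_px,
                           max_area_px, connectivity)
  bg <- estimate_background(avg, background_window_px)
  tab <- seg$table
  px_um <- stack$pixel_size_nm / 1000
  tab$area_um2 <- tab$area_px * px_um^2
  tab$sbr_intensity <- vapply(seq_along(seg$pixels), function(i)
    sbr_intensity(avg, seg$pixels[[i]], bg), numeric(1))
  if (nrow(tab) == 0) {
    tab$area_um2 <- numeric(0); tab$sbr_intensity <- numeric(0)
  }
  cbind(data.frame(fov_id = rep(stack$fov_id, nrow(tab)),
                   timepoint_h = rep(stack$timepoint_h, nrow(tab))),
        tab[c("particle_id", "centroid_row", "centroid_col", "area_px",
              "area_um2", "sbr_intensity", "touches_border")])
}

#' Summarise particles in one field of view
#'
#' Per-FOV aggregate count, size distribution (um^2) and total SBR
#' intensity, the quantities tracked across aggregation time points.
#' Border-touching particles are counted but excluded from the size list by
#' default because their areas are truncated.
#'
#' @param particles data frame from [detect_particles()] (or a
#'   [segment_particles()] table with `area_um2` and `sbr_intensity`).
#' @param timepoint_h time point, hours (taken from the table if present).
#' @param include_border include border-touching particles in `areas`?
#' @return An object of class `fov_summary`: list with `count`, `areas`
#'   (um^2), `total_sbr`, `timepoint_h`.
#' @export
summarize_fov <- function(particles, timepoint_h = NULL,
                          include_border = FALSE) {
  stopifnot(is.data.frame(particles))
  if (is.null(timepoint_h))
    timepoint_h <- if ("timepoint_h" %in% names(particles) &&
                       nrow(particles) > 0) particles$timepoint_h[1]
                   else NA_real_
  sel <- if (include_border || nrow(particles) == 0) rep(TRUE, nrow(particles))
         else !particles$touches_border
  structure(list(count = nrow(particles),
                 areas = particles$area_um2[sel],
                 total_sbr = sum(particles$sbr_intensity),
                 timepoint_h = timepoint_h),
            class = "fov_summary")
}

#' @export
print.fov_summary <- function(x, ...) {
  cat(sprintf("FOV summary (t = %s h): %d particle(s), median area %.3g um^2, total SBR %.4g\n",
              format(x$timepoint_h), x$count,
              if (length(x$areas)) stats::median(x$areas) else NA_real_,
              x$total_sbr))
  invisible(x)
}
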