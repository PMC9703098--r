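#' Match particles between before/after digestion images
#'
#' Proteinase-K (PK) sensitivity is scored per aggregate by comparing the
#' same surface-attached particle before and after 30 min of digestion at a
#' fixed field of view.  Matching is by mutual nearest centroids within
#' `max_dist_px`: a pair is accepted only if each particle is the other's
#' nearest neighbour.  'Before' particles with no counterpart are treated
#' as fully digested (`intensity_after = 0`) rather than dropped, which
#' avoids biasing the population toward resistance.  'After' particles with
#' no counterpart (rare, e.g. drift-in) are ignored.
#'
#' @param before,after particle tables (as from [detect_particles()]) with
#'   `particle_id`, `centroid_row`, `centroid_col`, `sbr_intensity`, and
#'   optionally `fov_id` (checked for agreement when present in both).
#' @param max_dist_px maximum centroid distance for a match, px.
#' @return data frame with `particle_id` (from `before`), `intensity_before`,
#'   `intensity_after`, `remaining_fraction` and `matched` (FALSE for
#'   fully-digested assignments).
#' @export
match_particles <- function(before, after, max_dist_px = 2) {
  need <- c("particle_id", "centroid_row", "centroid_col", "sbr_intensity")
  stopifnot(is.data.frame(before), is.data.frame(after),
            all(need %in% names(before)), all(need %in% names(after)))
  if ("fov_id" %in% names(before) && "fov_id" %in% names(after) &&
      nrow(before) > 0 && nrow(after) > 0 &&
      !identical(unique(before$fov_id), unique(after$fov_id)))
    stop("`before` and `after` come from different FOVs: ",
         paste(unique(before$fov_id), collapse = ","), " vs ",
         paste(unique(after$fov_id), collapse = ","))
  nb <- nrow(before); na <- nrow(after)
  if (nb == 0)
    return(data.frame(particle_id = integer(0), intensity_before = numeric(0),
                      intensity_after = numeric(0),
                      remaining_fraction = numeric(0), matched = logical(0)))
  match_j <- rep(NA_integer_, nb)
  if (na > 0) {
    d <- sqrt(outer(before$centroid_row, after$centroid_row, "-")^2 +
              outer(before$centroid_col, after$centroid_col, "-")^2)
    nn_b <- apply(d, 1, which.min)           # nearest 'after' for each 'before'
    nn_a <- apply(d, 2, which.min)           # nearest 'before' for each 'after'
    for (i in seq_len(nb)) {
      j <- nn_b[i]
      if (nn_a[j] == i && d[i, j] <= max_dist_px) match_j[i] <- j
    }
  }
  i_after <- ifelse(is.na(match_j), 0, after$sbr_intensity[match_j])
  i_before <- before$sbr_intensity
  if (any(i_before <= 0))
    stop("non-positive 'before' intensity; cannot form remaining fraction")
  data.frame(particle_id = before$particle_id,
             intensity_before = i_before,
             intensity_after = i_after,
             remaining_fraction = i_after / i_before,
             matched = !is.na(match_j))
}

#' Classify Proteinase-K sensitivity from the remaining intensity fraction
#'
#' Classes follow the fractional *loss* of ThT intensity after 30 min of
#' digestion, `loss = 1 - f` where `f` is the remaining fraction:
#' sensitive for loss > 70%, partially sensitive for losses of 30%-70%
#' (closed interval: boundary losses of exactly 30% or 70% are "partial"),
#' resistant for loss < 30%.  `f > 1` (apparent brightening) is allowed and
#' classed resistant.
#'
#' @param f remaining fraction(s), >= 0; vectorised.
#' @return factor with levels `sensitive`, `partial`, `resistant`.
#' @examples
#' classify_pk(c(0.2, 0.5, 0.95))  # sensitive, partial, resistant
#' @export
classify_pk <- function(f) {
  if (any(!is.finite(f)) || any(f < 0))
    stop("remaining fraction must be finite and >= 0")
  loss <- 1 - f
  cls <- ifelse(loss > 0.7, "sensitive",
         ifelse(loss >= 0.3, "partial", "resistant"))
  factor(cls, levels = c("sensitive", "partial", "resistant"))
}

#' Summarise PK sensitivity classes as percentages
#'
#' @param results data frame with a `remaining_fraction` column (e.g. from
#'   [match_particles()]), or a factor/character vector of classes from
#'   [classify_pk()].
#' @return named numeric vector of percentages (`sensitive`, `partial`,
#'   `resistant`) summing to 100.
#' @export
pk_summary <- function(results) {
  cls <- if (is.data.frame(results)) {
    stopifnot("remaining_fraction" %in% names(results))
    classify_pk(results$remaining_fraction)
  } else {
    factor(as.character(results),
           levels = c("sensitive", "partial", "resistant"))
  }
  if (length(cls) == 0 || any(is.na(cls))) stop("no particles to summarise")
  out <- 100 * as.vector(table(cls)) / length(cls)
  names(out) <- levels(cls)
  out
}

#' Quantify holes in a supported lipid bilayer image
#'
#' Aggregate-induced disruption of a fluorescent supported lipid bilayer
#' (SLB) appears as dark holes in the averaged TIRF image.  Holes are
#' connected components of sub-threshold pixels with area of at least
#' `min_hole_px`; the default threshold is 50% of the robust bilayer
#' intensity (the image median, since holes are sparse).  Hole pixels and
#' bilayer pixels partition the image exactly.
#'
#' @param image averaged H x W bilayer image.
#' @param hole_threshold absolute intensity below which a pixel is "hole";
#'   NULL for the default `0.5 * median(image)`.
#' @param min_hole_px minimum hole area, px.
#' @param pixel_size_nm pixel size, nm (sCMOS TIRF default 87.21).
#' @param fov_id field-of-view identifier.
#' @param connectivity 8 or 4.
#' @return An object of class `hole_metrics`: list with `fov_id`, `n_holes`,
#'   `total_hole_area_um2`, `hole_px`, `bilayer_px` (hole_px + bilayer_px
#'   equals H*W), and the threshold used.  A threshold outside the image
#'   intensity range triggers a warning and an empty result.
#' @export
slb_hole_metrics <- function(image, hole_threshold = NULL, min_hole_px = 4L,
                             pixel_size_nm = 87.21, fov_id = "fov1",
                             connectivity = 8) {
  stopifnot(is.matrix(image))
  user_threshold <- !is.null(hole_threshold)
  if (!user_threshold) hole_threshold <- 0.5 * stats::median(image)
  empty <- function() structure(
    list(fov_id = fov_id, n_holes = 0L, total_hole_area_um2 = 0,
         hole_px = 0L, bilayer_px = length(image),
         threshold = hole_threshold),
    class = "hole_metrics")
  if (user_threshold &&
      (hole_threshold < min(image) || hole_threshold > max(image))) {
    warning("hole threshold ", format(hole_threshold),
            " lies outside the image intensity range; no holes scored")
    return(empty())
  }
  mask <- image < hole_threshold
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_hole_px)
  px_um <- pixel_size_nm / 1000
  structure(list(fov_id = fov_id,
                 n_holes = length(keep),
                 total_hole_area_um2 = sum(sizes[keep]) * px_um^2,
                 hole_px = sum(mask),
                 bilayer_px = length(image) - sum(mask),
                 threshold = hole_threshold),
            class = "hole_metrics")
}

#' @export
print.hole_metrics <- function(x, ...) {
  cat(sprintf("SLB holes (%s): %d hole(s), total area %.4g um^2\n",
              x$fov_id, x$n_holes, x$total_hole_area_um2))
  invisible(x)
}

#' Normalise hole metrics to a reference condition
#'
#' Per-condition mean hole count and total hole area, each divided by the
#' corresponding mean of the reference condition (e.g. wild-type aggregates
#' at 72 h), giving dimensionless fold changes.
#'
#' @param metrics data frame with columns `condition`, `n_holes`,
#'   `total_hole_area_um2` (one row per FOV), or a list of `hole_metrics`
#'   plus a `condition` vector of the same length.
#' @param reference the reference condition label.
#' @param condition condition labels when `metrics` is a list.
#' @return data frame with `condition`, `mean_n_holes`, `mean_area_um2`,
#'   `normalized_n`, `normalized_area`.
#' @export
normalize_to_reference <- function(metrics, reference, condition = NULL) {
  if (!is.data.frame(metrics)) {
    stopifnot(is.list(metrics), !is.null(condition),
              length(condition) == length(metrics))
    metrics <- data.frame(
      condition = condition,
      n_holes = vapply(metrics, `[[`, integer(1), "n_holes"),
      total_hole_area_um2 = vapply(metrics, `[[`, numeric(1),
                                   "total_hole_area_um2"))
  }
  stopifnot(all(c("condition", "n_holes", "total_hole_area_um2") %in%
                names(metrics)))
  if (!reference %in% metrics$condition)
    stop("reference condition '", reference, "' not present")
  agg <- stats::aggregate(cbind(n_holes, total_hole_area_um2) ~ condition,
                          data = metrics, FUN = mean)
  ref <- agg[agg$condition == reference, ]
  if (ref$n_holes == 0 || ref$total_hole_area_um2 == 0)
    stop("reference condition '", reference, "' has zero mean; cannot normalise")
  data.frame(condition = agg$condition,
             mean_n_holes = agg$n_holes,
             mean_area_um2 = agg$total_hole_area_um2,
             normalized_n = agg$n_holes / ref$n_holes,
             normalized_area = agg$total_hole_area_um2 /
               ref$total_hole_area_um2)
}

#' Fit an immunoblot standard curve
#'
#' Ordinary least-squares line through band intensity versus known protein
#' amount, used to convert unknown band intensities to concentrations.
#'
#' @param known_amounts known standard amounts (ng or nM), length >= 3.
#' @param band_intensities measured band intensities, a.u.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, and the calibration range.  A non-positive
#'   fitted slope is an error (an unusable curve).
#' @export
fit_standard_curve <- function(known_amounts, band_intensities) {
  stopifnot(is.numeric(known_amounts), is.numeric(band_intensities),
            length(known_amounts) == length(band_intensities))
  if (length(known_amounts) < 3L)
    stop("need at least 3 standards for a curve")
  fit <- stats::lm(band_intensities ~ known_amounts)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("standard curve has non-positive slope (", format(slope),
         "); intensities must increase with amount")
  ss_tot <- sum((band_intensities - mean(band_intensities))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 amount_range = range(known_amounts),
                 intensity_range = range(band_intensities)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: intensity = %.4g * amount + %.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Quantify monomer from a band intensity via the standard curve
#'
#' Inverse of the linear blot calibration: `amount = (I - intercept) /
#' slope`.  Intensities outside twice the calibrated intensity range are
#' still converted but flagged as extrapolated.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param band_intensity intensity(ies) to convert, a.u.
#' @return data frame with `band_intensity`, `amount` and `extrapolated`.
#' @export
quantify_monomer <- function(curve, band_intensity) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(band_intensity))
  lo <- curve$intensity_range[1]; hi <- curve$intensity_range[2]
  span <- hi - lo
  extrap <- band_intensity < lo - 0.5 * span | band_intensity > hi + span
  data.frame(band_intensity = band_intensity,
             amount = (band_intensity - curve$intercept) / curve$slope,
             extrapolated = extrap)
}

#' Percent reduction between before/after concentrations
#'
#' `100 * (1 - after / before)`: e.g. 1 uM before and 100 nM after 72 h of
#' aggregation is a 90% reduction in soluble monomer.
#'
#' @param before,after concentrations in the same units; `before` > 0.
#' @return percent reduction (negative if the amount increased).
#' @export
percent_reduction <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    stop("`before` must be finite and > 0")
  100 * (1 - after / before)
}
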