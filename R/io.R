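#' Read and write ThT trace CSV files
#'
#' Traces are exchanged as CSV with header columns `time_h`, `intensity_au`,
#' `label`, `replicate`.
#'
#' @param path file path.
#' @return `read_tht_csv()`: a list of [tht_trace()] objects, one per
#'   (label, replicate) combination.
#' @export
read_tht_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "intensity_au")
  if (!all(need %in% names(df)))
    stop("ThT CSV must have columns time_h, intensity_au (and optionally ",
         "label, replicate); found: ", paste(names(df), collapse = ", "))
  if (!"label" %in% names(df)) df$label <- "trace"
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  groups <- split(df, interaction(df$label, df$replicate, drop = TRUE))
  lapply(groups, function(g)
    tht_trace(g$time_h, g$intensity_au, label = g$label[1],
              replicate = g$replicate[1]))
}

#' @param trace a [tht_trace()].
#' @rdname read_tht_csv
#' @export
write_tht_csv <- function(trace, path) {
  stopifnot(inherits(trace, "tht_trace"))
  utils::write.csv(data.frame(time_h = trace$time_h,
                              intensity_au = trace$intensity,
                              label = attr(trace, "label"),
                              replicate = attr(trace, "replicate")),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' Columns `time_h`, `monomer_nM`, `number`, `mass_nM` (interface units:
#' hours and nanomolar).
#'
#' @param traj an `aggregation_trajectory` from [simulate_aggregation()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(is.data.frame(traj),
            all(c("time", "monomer", "number", "mass") %in% names(traj)))
  utils::write.csv(data.frame(time_h = traj$time / 3600,
                              monomer_nM = traj$monomer * 1e9,
                              number = traj$number,
                              mass_nM = traj$mass * 1e9),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a kinetic fit report as JSON
#'
#' @param fit a `kinetic_fit` from [fit_combined_rate()].
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  jsonlite::write_json(list(lambda_hat_s2 = fit$lambda_hat,
                            residual_norm = fit$residual_norm,
                            n_points = fit$n_points,
                            converged = fit$converged,
                            fixed = fit$fixed,
                            lambda_bounds_log10 = fit$bounds_log10),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write multi-frame TIFF image stacks
#'
#' Stacks are stored as 32-bit float TIFF with one directory per frame and
#' an optional JSON metadata sidecar (`pixel_size_nm`, `exposure_ms`,
#' `timepoint_h`, `fov_id`).  Intensities are written divided by
#' `scale` so they fit the float TIFF convention and rescaled on read.
#'
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @param scale intensity scale factor applied on write and undone on read.
#' @return `read_stack_tiff()`: an [image_stack()].
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]] * scale
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  image_stack(arr,
              pixel_size_nm = meta$pixel_size_nm %||% 322,
              exposure_ms = meta$exposure_ms %||% 50,
              fov_id = meta$fov_id %||% "fov1",
              timepoint_h = meta$timepoint_h %||% NA_real_)
}

#' @param stack an [image_stack()].
#' @rdname read_stack_tiff
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  stopifnot(inherits(stack, "image_stack"))
  f <- stack$frames
  frames <- lapply(seq_len(dim(f)[3]),
                   function(i) pmax(pmin(f[, , i] / scale, 1), 0))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = stack$pixel_size_nm,
                            exposure_ms = stack$exposure_ms,
                            fov_id = stack$fov_id,
                            timepoint_h = stack$timepoint_h),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a particle table as CSV
#'
#' @param particles data frame from [detect_particles()].
#' @param path file path.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE)
  invisible(path)
}
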