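default_config <- function() {
  list(
    seed = 1L,
    out_dir = "aggrekin-run",
    stages = character(0),
    kinetics = list(nc = 2L, rtol = 1e-8, atol = 1e-12,
                    lambda_bounds_log10 = c(-12, -4), plateau_fraction = 0.1,
                    lambda = 7e-9, solubility = 7e-7, m0 = 1e-6, P0 = 0,
                    duration_h = 72, n_points = 100),
    synth = list(mult_sigma = 0, add_sd = 0, scale = 1e9,
                 n_particles = 10, sbr = 5, shape = c(256L, 256L),
                 frames = 10L),
    imaging = list(low_sigma = 1, high_sigma = 20, blur_sigma = 1,
                   min_area_px = 4L, connectivity = 8,
                   background_window_px = 25, pixel_size_nm = 322),
    assays = list(max_dist_px = 2, min_hole_px = 4L,
                  slb_pixel_size_nm = 87.21)
  )
}

known_stages <- c("synth_trace", "fit", "synth_stack", "detect",
                  "summarize", "pk", "slb", "blot")

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML/JSON file path, a YAML/JSON string, or a list; checks it
#' against the configuration schema (unknown keys and unknown stages are
#' rejected, types and signs are checked), fills in defaults for everything
#' omitted, and returns a typed configuration.  All schema violations are
#' collected and reported together.
#'
#' @param raw path, YAML/JSON text, or list.
#' @return An object of class `run_config` (a fully defaulted named list).
#' @examples
#' cfg <- validate_config(list(stages = c("synth_trace", "fit")))
#' cfg$kinetics$lambda
#' @export
validate_config <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1L) {
    parsed <- tryCatch(
      if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw),
      error = function(e) stop("could not parse config: ",
                               conditionMessage(e)))
    if (!is.list(parsed)) stop("config must parse to a mapping/object")
    parsed
  } else if (is.list(raw)) raw
  else stop("`raw` must be a path, YAML/JSON text, or a list")

  defaults <- default_config()
  errs <- character(0)
  bad_top <- setdiff(names(cfg), names(defaults))
  if (length(bad_top))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(bad_top, collapse = ", ")))
  for (blk in c("kinetics", "synth", "imaging", "assays")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
      if (length(bad))
        errs <- c(errs, paste0("unknown key(s) in ", blk, ": ",
                               paste(bad, collapse = ", ")))
      defaults[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    }
  }
  for (key in c("seed", "out_dir", "stages"))
    if (!is.null(cfg[[key]])) defaults[[key]] <- cfg[[key]]
  cfg <- defaults

  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage))
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  k <- cfg$kinetics
  if (!is.numeric(k$lambda) || !is.finite(k$lambda) || k$lambda < 0)
    errs <- c(errs, "kinetics.lambda must be a finite number >= 0")
  if (!is.numeric(k$solubility) || k$solubility <= 0)
    errs <- c(errs, "kinetics.solubility must be > 0")
  if (!is.numeric(k$m0) || k$m0 <= 0)
    errs <- c(errs, "kinetics.m0 must be > 0")
  if (!is.numeric(k$nc) || length(k$nc) != 1 || k$nc < 1 ||
      k$nc != round(k$nc))
    errs <- c(errs, "kinetics.nc must be a positive integer")
  if (!is.numeric(k$P0) || k$P0 < 0)
    errs <- c(errs, "kinetics.P0 must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed))
    errs <- c(errs, "seed must be a single integer")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$kinetics$nc <- as.integer(cfg$kinetics$nc)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL   # hash the analysis settings, not the output location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order (`synth_trace`, `fit`,
#' `synth_stack`, `detect`, `summarize`, `pk`, `slb`, `blot`), writing all
#' artifacts under `config$out_dir` and returning (and writing) a run
#' report.  One global seed fans out to per-stage derived seeds
#' (`seed + stage index`) so stages are independently reproducible; a rerun
#' with the same configuration and seed produces identical artifact hashes.
#' A failed stage is recorded in the report and stages downstream of it are
#' skipped; the report is written even on partial failure.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @return An object of class `run_report`: list with `config_hash`,
#'   `stages` (per-stage status and outputs), `manifest` (file md5 sums),
#'   and `results` (in-memory stage results, e.g. the `kinetic_fit`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("aggrekin")),
                 config_hash = config_hash(cfg),
                 stages = list(), results = list())
  stages <- known_stages[known_stages %in% cfg$stages]
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped", outputs = character(0))
      return()
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     outputs = character(0))
    } else {
      report$stages[[name]] <<- list(status = "ok",
                                     outputs = res %||% character(0))
    }
  }

  stage_seed <- function(name) cfg$seed + match(name, known_stages)
  k <- cfg$kinetics

  for (st in stages) {
    run_stage(st, switch(st,
      synth_trace = function() {
        params <- rate_parameters(k$lambda, k$solubility, k$nc)
        init <- initial_state(k$m0, k$P0)
        g <- gen_tht_trace(params, init, n_points = k$n_points,
                           duration_h = k$duration_h,
                           mult_sigma = cfg$synth$mult_sigma,
                           add_sd = cfg$synth$add_sd,
                           scale = cfg$synth$scale,
                           seed = stage_seed("synth_trace"))
        state$trace <- g$trace
        p <- file.path(cfg$out_dir, "trace.csv")
        write_tht_csv(g$trace, p)
        p
      },
      fit = function() {
        if (is.null(state$trace))
          stop("fit stage needs a trace (enable synth_trace or provide one)")
        mass <- tht_to_mass(state$trace, m0 = k$m0, m_eq = k$solubility,
                            plateau_fraction = k$plateau_fraction)
        fit <- fit_combined_rate(mass,
                                 fixed = list(solubility = k$solubility,
                                              nc = k$nc, m0 = k$m0,
                                              P0 = k$P0),
                                 lambda_bounds_log10 = k$lambda_bounds_log10,
                                 rtol = k$rtol, atol = k$atol)
        report$results$fit <<- fit
        p <- file.path(cfg$out_dir, "fit.json")
        write_fit_json(fit, p)
        p
      },
      synth_stack = function() {
        s <- cfg$synth
        set.seed(stage_seed("synth_stack"))
        radii <- stats::runif(s$n_particles, 2, 4)
        pos <- place_particles(s$n_particles, s$shape, radii)
        sp <- scene_spec(particles = data.frame(row = pos$row, col = pos$col,
                                                radius = radii, sbr = s$sbr),
                         shape = s$shape, frames = s$frames,
                         pixel_size_nm = cfg$imaging$pixel_size_nm,
                         seed = stage_seed("synth_stack"))
        g <- gen_image_stack(sp)
        state$stack <- g$stack
        report$results$planted <<- g$truth
        p <- file.path(cfg$out_dir, "stack.tif")
        write_stack_tiff(g$stack, p)
        c(p, paste0(p, ".json"))
      },
      detect = function() {
        if (is.null(state$stack))
          stop("detect stage needs an image stack (enable synth_stack or provide one)")
        im <- cfg$imaging
        pt <- detect_particles(state$stack, low_sigma = im$low_sigma,
                               high_sigma = im$high_sigma,
                               blur_sigma = im$blur_sigma,
                               min_area_px = im$min_area_px,
                               connectivity = im$connectivity,
                               background_window_px = im$background_window_px)
        state$particles <- pt
        report$results$particles <<- pt
        p <- file.path(cfg$out_dir, "particles.csv")
        write_particles_csv(pt, p)
        p
      },
      summarize = function() {
        if (is.null(state$particles)) stop("summarize stage needs particles")
        sm <- summarize_fov(state$particles)
        report$results$fov_summary <<- sm
        p <- file.path(cfg$out_dir, "fov_summary.json")
        jsonlite::write_json(list(count = sm$count,
                                  median_area_um2 =
                                    if (length(sm$areas))
                                      stats::median(sm$areas) else NA,
                                  total_sbr = sm$total_sbr),
                             p, auto_unbox = TRUE, digits = NA)
        p
      },
      pk = function() {
        pair <- gen_pk_pair(seed = stage_seed("pk"))
        m <- match_particles(pair$before, pair$after,
                             max_dist_px = cfg$assays$max_dist_px)
        m$class <- classify_pk(m$remaining_fraction)
        report$results$pk <<- pk_summary(m)
        p <- file.path(cfg$out_dir, "pk_results.csv")
        utils::write.csv(m, p, row.names = FALSE)
        p2 <- file.path(cfg$out_dir, "pk_summary.json")
        jsonlite::write_json(as.list(pk_summary(m)), p2,
                             auto_unbox = TRUE, digits = NA)
        c(p, p2)
      },
      slb = function() {
        set.seed(stage_seed("slb"))
        pos <- place_particles(7, c(512L, 512L), 15, margin = 30,
                               min_sep = 40)
        holes <- data.frame(row = pos$row, col = pos$col,
                            radius = stats::runif(7, 5, 15))
        g <- gen_slb_image(holes, seed = stage_seed("slb"),
                           pixel_size_nm = cfg$assays$slb_pixel_size_nm)
        hm <- slb_hole_metrics(g$image,
                               min_hole_px = cfg$assays$min_hole_px,
                               pixel_size_nm = cfg$assays$slb_pixel_size_nm)
        report$results$slb <<- hm
        p <- file.path(cfg$out_dir, "slb_metrics.json")
        jsonlite::write_json(list(n_holes = hm$n_holes,
                                  total_hole_area_um2 = hm$total_hole_area_um2),
                             p, auto_unbox = TRUE, digits = NA)
        p
      },
      blot = function() {
        g <- gen_blot_standards(unknown_concs = c(1000, 100),
                                seed = stage_seed("blot"))
        curve <- fit_standard_curve(g$standards$amount, g$standards$intensity)
        est <- quantify_monomer(curve, g$unknowns$intensity)
        red <- percent_reduction(est$amount[1], est$amount[2])
        report$results$blot <<- list(curve = curve, estimates = est,
                                     percent_reduction = red)
        p <- file.path(cfg$out_dir, "blot.json")
        jsonlite::write_json(list(slope = curve$slope,
                                  intercept = curve$intercept,
                                  r_squared = curve$r_squared,
                                  estimates_nM = est$amount,
                                  percent_reduction = red),
                             p, auto_unbox = TRUE, digits = NA)
        p
      }))
  }

  outputs <- unlist(lapply(report$stages, `[[`, "outputs"))
  report$manifest <- if (length(outputs)) {
    h <- tools::md5sum(outputs)
    data.frame(path = names(h), md5 = unname(h), row.names = NULL)
  } else data.frame(path = character(0), md5 = character(0))
  report$ok <- !failed
  class(report) <- "run_report"
  rp <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(
    list(package_version = report$package_version,
         config_hash = report$config_hash,
         ok = report$ok,
         stages = lapply(report$stages, function(s)
           list(status = s$status, outputs = as.character(s$outputs),
                error = s$error %||% NULL)),
         manifest = report$manifest),
    rp, auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("aggrekin run report (config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
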