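#' Synthetic ThT trace from the kinetic model
#'
#' Simulates an aggregation mass curve and converts it to a fluorescence
#' trace: `intensity = scale * mass(t) * (1 + e_mult) + e_add`, with
#' multiplicative Gaussian noise `e_mult ~ N(0, mult_sigma)` per point and
#' additive Gaussian noise with standard deviation `add_sd` (a detector
#' floor).  Intensities are clipped at zero.  The ground truth (true
#' parameters and scale) is returned alongside for recovery studies.
#'
#' @param params a [rate_parameters()] object.
#' @param init an [initial_state()] object.
#' @param n_points number of time points (>= 10).
#' @param duration_h trace duration, hours.
#' @param mult_sigma multiplicative noise sigma (e.g. 0.05 for 5%).
#' @param add_sd additive noise standard deviation, a.u.
#' @param scale fluorescence per molar aggregate mass, a.u./M.
#' @param label,replicate trace metadata.
#' @param seed integer seed fixing all randomness (NULL leaves the RNG
#'   state untouched).
#' @return list with `trace` (a [tht_trace()]) and `truth` (list of
#'   `lambda`, `solubility`, `nc`, `m0`, `P0`, `scale`, `seed`).
#' @export
gen_tht_trace <- function(params, init, n_points = 100, duration_h = 72,
                          mult_sigma = 0.05, add_sd = 0, scale = 1e9,
                          label = "synthetic", replicate = 1L, seed = NULL) {
  if (n_points < 10) stop("`n_points` must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_h * 3600, length.out = n_points)
  traj <- simulate_aggregation(params, init, times)
  n <- length(times)
  e_mult <- if (mult_sigma > 0) stats::rnorm(n, 0, mult_sigma) else numeric(n)
  e_add <- if (add_sd > 0) stats::rnorm(n, 0, add_sd) else numeric(n)
  intensity <- pmax(0, scale * traj$mass * (1 + e_mult) + e_add)
  list(trace = tht_trace(time_h = times / 3600, intensity = intensity,
                         label = label, m0 = init$m0, replicate = replicate),
       truth = list(lambda = params$lambda, solubility = params$solubility,
                    nc = params$nc, m0 = init$m0, P0 = init$P0,
                    scale = scale, seed = seed))
}

#' Scene specification for a synthetic particle image stack
#'
#' Describes one field of view: planted particles (centroid, disk radius,
#' peak SBR), a low-frequency modulated background, and a noise model.
#' Defaults mirror the ThT acquisition: 512 x 512 px, 50 frames, 322 nm
#' pixels, a 2-D sinusoidal illumination modulation of period 128 px and
#' amplitude 10% of the offset, Poisson shot noise and Gaussian read noise
#' of 1% of the offset.
#'
#' @param particles data frame with `row`, `col` (0-based centroid
#'   positions), `radius` (px) and `sbr` (peak SBR > 0); may be empty.
#' @param shape image height/width, px.
#' @param frames number of frames.
#' @param offset background offset, a.u.
#' @param mod_amplitude background modulation amplitude, a.u.
#' @param mod_period background modulation period, px.
#' @param read_sd Gaussian read-noise sigma, a.u.
#' @param shot logical: apply Poisson shot noise?
#' @param psf_sigma Gaussian PSF sigma, px (~ diffraction limit at 40x/0.75
#'   NA with 322 nm pixels).
#' @param pixel_size_nm physical pixel size.
#' @param seed integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(particles = NULL, shape = c(512L, 512L), frames = 50L,
                       offset = 100, mod_amplitude = 10, mod_period = 128,
                       read_sd = 1, shot = TRUE, psf_sigma = 1.5,
                       pixel_size_nm = 322, seed = 1L) {
  if (is.null(particles))
    particles <- data.frame(row = numeric(0), col = numeric(0),
                            radius = numeric(0), sbr = numeric(0))
  stopifnot(is.data.frame(particles),
            all(c("row", "col", "radius", "sbr") %in% names(particles)))
  if (nrow(particles) > 0) {
    if (any(particles$sbr <= 0)) stop("peak SBR must be > 0")
    if (any(particles$row < 0 | particles$row >= shape[1] |
            particles$col < 0 | particles$col >= shape[2]))
      stop("particle centroids must lie within the image bounds")
  }
  if (offset <= 0) stop("`offset` must be > 0")
  structure(list(particles = particles, shape = as.integer(shape),
                 frames = as.integer(frames), offset = offset,
                 mod_amplitude = mod_amplitude, mod_period = mod_period,
                 read_sd = read_sd, shot = shot, psf_sigma = psf_sigma,
                 pixel_size_nm = pixel_size_nm, seed = seed),
            class = "scene_spec")
}

# smooth modulated background of a scene (no noise)
scene_background <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  r <- matrix(0:(h - 1), h, w)
  c <- matrix(0:(w - 1), h, w, byrow = TRUE)
  spec$offset + spec$mod_amplitude *
    sin(2 * pi * r / spec$mod_period) * sin(2 * pi * c / spec$mod_period)
}

# render one particle's PSF-blurred signal on a local patch and return the
# patch plus its (1-based) placement; amplitude pre-compensates the central
# attenuation of blurring a disk of the given radius with a Gaussian PSF
render_particle_patch <- function(row0, col0, radius, peak, psf_sigma) {
  margin <- ceiling(radius + 4 * psf_sigma + 2)
  side <- 2L * margin + 1L
  cen <- margin + 1
  rr <- matrix(seq_len(side) - cen, side, side)
  cc <- t(rr)
  # sub-pixel placement of the disk centre inside the patch
  fr <- row0 - floor(row0); fc <- col0 - floor(col0)
  disk <- ((rr - fr)^2 + (cc - fc)^2) <= radius^2
  atten <- 1 - exp(-radius^2 / (2 * psf_sigma^2))
  amp <- peak / atten
  patch <- matrix(0, side, side)
  patch[disk] <- amp
  list(patch = gaussian_blur(patch, psf_sigma),
       top = floor(row0) - margin + 1L,   # 1-based row of patch[1,1]
       left = floor(col0) - margin + 1L)
}

#' Generate a synthetic multi-frame particle image stack with ground truth
#'
#' Renders each planted particle as a uniform disk convolved with a
#' Gaussian PSF, with the disk amplitude set so the blurred peak equals
#' `sbr * background` at the particle centre; adds the modulated
#' background; then draws each frame with optional Poisson shot noise and
#' Gaussian read noise.  The per-particle truth table records centroid,
#' disk area and the integrated SBR of the noiseless rendered signal.
#'
#' @param spec a [scene_spec()].
#' @param fov_id,timepoint_h stack metadata.
#' @return list with `stack` (an [image_stack()]), `truth` (data frame
#'   `id`, `row`, `col`, `radius`, `area_px`, `peak_sbr`,
#'   `integrated_sbr`), and `clean` (the noiseless averaged image).
#' @export
gen_image_stack <- function(spec, fov_id = "fov1", timepoint_h = NA_real_) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  bg <- scene_background(spec)
  signal <- matrix(0, h, w)
  np <- nrow(spec$particles)
  truth <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), area_px = integer(0),
                      peak_sbr = numeric(0), integrated_sbr = numeric(0))
  if (np > 0) {
    rows <- vector("list", np)
    for (i in seq_len(np)) {
      p <- spec$particles[i, ]
      bg_at <- bg[round(p$row) + 1L, round(p$col) + 1L]
      rp <- render_particle_patch(p$row, p$col, p$radius,
                                  p$sbr * bg_at, spec$psf_sigma)
      side <- nrow(rp$patch)
      rs <- max(1L, rp$top); re <- min(h, rp$top + side - 1L)
      cs <- max(1L, rp$left); ce <- min(w, rp$left + side - 1L)
      pr <- (rs - rp$top + 1L):(re - rp$top + 1L)
      pc <- (cs - rp$left + 1L):(ce - rp$left + 1L)
      signal[rs:re, cs:ce] <- signal[rs:re, cs:ce] + rp$patch[pr, pc]
      rows[[i]] <- data.frame(
        id = i, row = p$row, col = p$col, radius = p$radius,
        area_px = sum(((matrix(0:(side - 1), side, side) - (side - 1) / 2)^2 +
                       (t(matrix(0:(side - 1), side, side)) -
                        (side - 1) / 2)^2) <= p$radius^2),
        peak_sbr = p$sbr,
        integrated_sbr = sum(rp$patch[pr, pc] / bg[rs:re, cs:ce]))
    }
    truth <- do.call(rbind, rows)
  }
  clean <- bg + signal
  set.seed(spec$seed)
  frames <- array(0, dim = c(h, w, spec$frames))
  for (f in seq_len(spec$frames)) {
    fr <- if (spec$shot) matrix(stats::rpois(h * w, clean), h, w) else clean
    if (spec$read_sd > 0)
      fr <- fr + matrix(stats::rnorm(h * w, 0, spec$read_sd), h, w)
    frames[, , f] <- fr
  }
  list(stack = image_stack(frames, pixel_size_nm = spec$pixel_size_nm,
                           fov_id = fov_id, timepoint_h = timepoint_h),
       truth = truth, clean = clean)
}

# place n non-overlapping particle centres uniformly, away from borders
place_particles <- function(n, shape, radius_px, margin = 12,
                            min_sep = 2 * max(radius_px, 0) + 6) {
  rows <- numeric(0); cols <- numeric(0)
  tries <- 0L
  while (length(rows) < n && tries < 500L * n) {
    tries <- tries + 1L
    r <- stats::runif(1, margin, shape[1] - 1 - margin)
    c <- stats::runif(1, margin, shape[2] - 1 - margin)
    if (length(rows) == 0 ||
        all(sqrt((rows - r)^2 + (cols - c)^2) > min_sep)) {
      rows <- c(rows, r); cols <- c(cols, c)
    }
  }
  if (length(rows) < n)
    stop("could not place ", n, " non-overlapping particles; image too small")
  data.frame(row = rows, col = cols)
}

#' Generate an aggregation time series of image stacks
#'
#' Emulates time-lapse imaging of an aggregating sample: at each requested
#' time point the number of planted particles is `round(count_scale *
#' Q(t))` where `Q(t)` is the simulated aggregate number (reduced units)
#' from the kinetic model, and particle radii are drawn from a lognormal
#' size model whose median may grow with time (static for WT-like samples,
#' growing for the mutant-like case).
#'
#' @param params,init kinetic model inputs ([rate_parameters()],
#'   [initial_state()]).
#' @param timepoints_h imaging time points, hours.
#' @param count_scale particles per unit Q.
#' @param meanlog_0 lognormal meanlog of the radius (px) at t = 0.
#' @param meanlog_growth_per_h linear growth of meanlog per hour (0 for a
#'   static size distribution).
#' @param sdlog lognormal sdlog of the radius.
#' @param sbr peak SBR given to every planted particle.
#' @param shape,frames,seed scene settings (see [scene_spec()]); smaller
#'   defaults than a full FOV keep series generation fast.
#' @param ... further arguments passed to [scene_spec()].
#' @return list of per-timepoint lists `(stack, truth, clean, timepoint_h,
#'   n_planted)`.
#' @export
gen_growth_series <- function(params, init, timepoints_h, count_scale,
                              meanlog_0 = log(3), meanlog_growth_per_h = 0,
                              sdlog = 0.25, sbr = 5,
                              shape = c(256L, 256L), frames = 10L,
                              seed = 1L, ...) {
  stopifnot(all(timepoints_h >= 0))
  times <- sort(unique(c(0, timepoints_h * 3600)))
  traj <- simulate_aggregation(params, init, times)
  q_at <- stats::approx(traj$time, traj$number, xout = timepoints_h * 3600)$y
  out <- vector("list", length(timepoints_h))
  for (k in seq_along(timepoints_h)) {
    t_h <- timepoints_h[k]
    n_k <- round(count_scale * q_at[k])
    set.seed(seed + k)
    if (n_k > 0) {
      radii <- pmin(8, pmax(2, stats::rlnorm(
        n_k, meanlog_0 + meanlog_growth_per_h * t_h, sdlog)))
      pos <- place_particles(n_k, shape, radii)
      particles <- data.frame(row = pos$row, col = pos$col,
                              radius = radii, sbr = sbr)
    } else particles <- NULL
    sp <- scene_spec(particles = particles, shape = shape, frames = frames,
                     seed = seed + 1000L * k, ...)
    g <- gen_image_stack(sp, fov_id = sprintf("t%02dh", round(t_h)),
                         timepoint_h = t_h)
    out[[k]] <- c(g, list(timepoint_h = t_h, n_planted = n_k))
  }
  out
}

#' Generate a matched before/after Proteinase-K pair
#'
#' Assigns each planted particle a true sensitivity class with the given
#' mixture fractions, draws its intensity loss uniformly within the class's
#' loss band, and builds 'after' data with the peak SBR scaled by
#' `(1 - loss)` and centroids jittered by up to `jitter_px`.  By default
#' only the ground-truth particle tables are produced (sufficient for
#' matching/classification studies); set `render = TRUE` to also render
#' before/after image stacks.
#'
#' The default loss bands lie strictly inside the classification intervals
#' (sensitive 0.75-0.95, partial 0.35-0.65, resistant 0.05-0.25) so the
#' planted class is recoverable from the intensity ratio alone.
#'
#' @param n_particles number of planted particles.
#' @param class_fractions named or ordered numeric vector `(sensitive,
#'   partial, resistant)` summing to 1.
#' @param loss_bands list of length-2 loss ranges per class.
#' @param jitter_px maximum uniform centroid jitter between before/after.
#' @param sbr_range range of 'before' peak SBR values.
#' @param shape image shape (used for particle placement and rendering).
#' @param render render image stacks as well?
#' @param seed integer seed.
#' @param ... passed to [scene_spec()] when rendering.
#' @return list with `before`, `after` (particle tables with
#'   `particle_id`, `centroid_row`, `centroid_col`, `sbr_intensity`),
#'   `truth` (table with true class and loss), and when rendering also
#'   `before_stack`, `after_stack`.
#' @export
gen_pk_pair <- function(n_particles = 100,
                        class_fractions = c(sensitive = 0.6, partial = 0.3,
                                            resistant = 0.1),
                        loss_bands = list(sensitive = c(0.75, 0.95),
                                          partial = c(0.35, 0.65),
                                          resistant = c(0.05, 0.25)),
                        jitter_px = 1, sbr_range = c(3, 8),
                        shape = c(512L, 512L), render = FALSE, seed = 1L,
                        ...) {
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must sum to 1")
  if (any(class_fractions < 0)) stop("`class_fractions` must be >= 0")
  set.seed(seed)
  classes <- sample(c("sensitive", "partial", "resistant"), n_particles,
                    replace = TRUE, prob = class_fractions)
  loss <- vapply(classes, function(cl)
    stats::runif(1, loss_bands[[cl]][1], loss_bands[[cl]][2]), numeric(1))
  radii <- stats::runif(n_particles, 2, 4)
  pos <- place_particles(n_particles, shape, radii,
                         min_sep = max(8, 4 * jitter_px))
  sbr_before <- stats::runif(n_particles, sbr_range[1], sbr_range[2])
  jr <- stats::runif(n_particles, -jitter_px, jitter_px)
  jc <- stats::runif(n_particles, -jitter_px, jitter_px)

  before <- data.frame(particle_id = seq_len(n_particles),
                       centroid_row = pos$row, centroid_col = pos$col,
                       sbr_intensity = sbr_before)
  after <- data.frame(particle_id = seq_len(n_particles),
                      centroid_row = pos$row + jr, centroid_col = pos$col + jc,
                      sbr_intensity = sbr_before * (1 - loss))
  truth <- data.frame(particle_id = seq_len(n_particles),
                      class = factor(classes, levels = c("sensitive",
                                                         "partial",
                                                         "resistant")),
                      loss = loss)
  out <- list(before = before, after = after, truth = truth)
  if (render) {
    sp_b <- scene_spec(particles = data.frame(row = pos$row, col = pos$col,
                                              radius = radii,
                                              sbr = sbr_before),
                       shape = shape, seed = seed + 1L, ...)
    keep <- after$sbr_intensity > 0.01
    sp_a <- scene_spec(particles = data.frame(row = after$centroid_row,
                                              col = after$centroid_col,
                                              radius = radii,
                                              sbr = after$sbr_intensity)[keep, ],
                       shape = shape, seed = seed + 2L, ...)
    out$before_stack <- gen_image_stack(sp_b, fov_id = "pk")$stack
    out$after_stack <- gen_image_stack(sp_a, fov_id = "pk")$stack
  }
  out
}

#' Generate a synthetic supported-lipid-bilayer image with holes
#'
#' A uniformly bright bilayer with planted dark circular holes (intensity
#' reduced by `hole_depth`), plus optional Gaussian noise.
#'
#' @param holes data frame with `row`, `col` (0-based centres) and `radius`
#'   (px); may be NULL/empty for an intact bilayer.
#' @param shape image shape, px.
#' @param bilayer_intensity bright bilayer level, a.u.
#' @param hole_depth fraction of intensity lost inside a hole (1 = black).
#' @param noise_sd Gaussian noise sigma, a.u.
#' @param pixel_size_nm pixel size (TIRF default 87.21 nm).
#' @param seed integer seed.
#' @return list with `image` (H x W matrix), `truth` (list `n_holes`,
#'   `total_area_um2`, `hole_px`, per-hole table).
#' @export
gen_slb_image <- function(holes = NULL, shape = c(512L, 512L),
                          bilayer_intensity = 1000, hole_depth = 0.95,
                          noise_sd = 10, pixel_size_nm = 87.21, seed = 1L) {
  if (is.null(holes))
    holes <- data.frame(row = numeric(0), col = numeric(0),
                        radius = numeric(0))
  stopifnot(all(c("row", "col", "radius") %in% names(holes)))
  h <- shape[1]; w <- shape[2]
  img <- matrix(bilayer_intensity, h, w)
  mask <- matrix(FALSE, h, w)
  if (nrow(holes) > 0) {
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (i in seq_len(nrow(holes))) {
      mask <- mask | ((rr - holes$row[i])^2 + (cc - holes$col[i])^2 <=
                        holes$radius[i]^2)
    }
    img[mask] <- bilayer_intensity * (1 - hole_depth)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  }
  px_um <- pixel_size_nm / 1000
  list(image = img,
       truth = list(n_holes = nrow(holes),
                    hole_px = sum(mask),
                    total_area_um2 = sum(mask) * px_um^2,
                    holes = holes))
}

#' Generate synthetic immunoblot standards and unknowns
#'
#' Linear blot model: `intensity = slope * conc + intercept`, with optional
#' multiplicative Gaussian noise.  Returns standards for curve fitting plus
#' unknown samples with their true concentrations for recovery tests.
#'
#' @param true_concs standard concentrations (>= 3), nM.
#' @param slope,intercept blot response parameters.
#' @param noise_frac multiplicative noise sigma as a fraction of intensity.
#' @param unknown_concs true concentrations of unknown samples, nM.
#' @param seed integer seed.
#' @return list with `standards` (data frame `amount`, `intensity`),
#'   `unknowns` (data frame `true_amount`, `intensity`), and `truth`
#'   (slope/intercept used).
#' @export
gen_blot_standards <- function(true_concs = c(100, 200, 400, 800),
                               slope = 0.01, intercept = 0,
                               noise_frac = 0, unknown_concs = numeric(0),
                               seed = 1L) {
  if (length(true_concs) < 3L) stop("need at least 3 standard concentrations")
  set.seed(seed)
  noisy <- function(conc) {
    i <- slope * conc + intercept
    if (noise_frac > 0) i <- i * (1 + stats::rnorm(length(i), 0, noise_frac))
    i
  }
  list(standards = data.frame(amount = true_concs,
                              intensity = noisy(true_concs)),
       unknowns = data.frame(true_amount = unknown_concs,
                             intensity = noisy(unknown_concs)),
       truth = list(slope = slope, intercept = intercept,
                    noise_frac = noise_frac, seed = seed))
}
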