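# shared fixtures: printed model parameters and small scene builders

wt_params <- function(nc = 2L) rate_parameters(7e-9, 7e-7, nc)
mut_params <- function(nc = 2L) rate_parameters(2e-8, 1e-7, nc)

hours_grid <- function(hours = 72, n = 100) seq(0, hours * 3600,
                                                length.out = n)

# log-spaced grid resolving early times, for curvature diagnostics
early_grid <- function(hours = 72, n = 300)
  c(0, 10^seq(1, log10(hours * 3600), length.out = n))

# a small scene with n isolated disks on a modulated background
disk_scene <- function(n = 5, shape = c(256L, 256L), radius = 3, sbr = 5,
                       seed = 1L, frames = 10L, ...) {
  set.seed(seed)
  pos <- aggrekin:::place_particles(n, shape, radius, margin = 15,
                                    min_sep = 2 * radius + 12)
  scene_spec(particles = data.frame(row = pos$row, col = pos$col,
                                    radius = radius, sbr = sbr),
             shape = shape, frames = frames, seed = seed, ...)
}

# greedy match of detections to planted truth within tol px
match_to_truth <- function(detected, truth, tol = 2) {
  used <- rep(FALSE, nrow(detected))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    if (nrow(detected) == 0) break
    d <- sqrt((detected$centroid_row - truth$row[i])^2 +
              (detected$centroid_col - truth$col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { used[j] <- TRUE; hits <- hits + 1L }
  }
  list(tp = hits, fp = nrow(detected) - hits, fn = nrow(truth) - hits)
}
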