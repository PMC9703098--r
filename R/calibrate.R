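#' Construct a ThT fluorescence trace
#'
#' Thioflavin-T (ThT) fluorescence reports on total aggregate mass: the dye
#' lights up on binding beta-sheet-rich aggregates, so the bulk intensity
#' follows \eqn{m_0 - m(t)} up to an instrument scale factor.  A trace is a
#' time/intensity table with minimal metadata.
#'
#' @param time_h times in hours, strictly increasing.
#' @param intensity fluorescence, arbitrary units, non-negative, same length
#'   as `time_h`.
#' @param label protein label (e.g. "WT", "R248Q").
#' @param m0 initial monomer concentration, molar (metadata).
#' @param replicate replicate identifier.
#' @return An object of class `tht_trace` (a data frame `time_h`,
#'   `intensity` with metadata attributes).
#' @export
tht_trace <- function(time_h, intensity, label = NA_character_,
                      m0 = NA_real_, replicate = NA_integer_) {
  stopifnot(is.numeric(time_h), is.numeric(intensity))
  if (length(time_h) != length(intensity))
    stop("`time_h` and `intensity` must have the same length")
  if (any(diff(time_h) <= 0)) stop("`time_h` must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("`intensity` must be finite and non-negative")
  structure(data.frame(time_h = time_h, intensity = intensity),
            label = label, m0 = m0, replicate = replicate,
            class = c("tht_trace", "data.frame"))
}

#' Convert a ThT trace to an aggregate-mass trajectory
#'
#' Calibrates intensity linearly so that the baseline maps to zero aggregate
#' mass and the plateau maps to the total convertible mass `m0 - m_eq`,
#' where `m_eq` is the measured solubility (steady-state free monomer).
#' The plateau is estimated as the mean of the final `plateau_fraction` of
#' points; if the trace is still rising there (last-decile rise exceeding 2%
#' of the total rise per 10% of the trace duration) the final intensity value
#' is used instead and the result is flagged with `attr(, "plateau_found") =
#' FALSE`.  Output mass is clipped at zero.
#'
#' @param trace a [tht_trace()] (or data frame with `time_h`, `intensity`).
#' @param m0 initial monomer concentration, molar.
#' @param m_eq equilibrium (soluble) monomer concentration, molar; must be
#'   below `m0`.
#' @param plateau_fraction fraction of trailing points averaged for the
#'   plateau estimate.
#' @return Data frame with `time` (s), `time_h` and `mass` (M), with
#'   attributes `plateau_found`, `baseline` and `plateau` (a.u.).
#' @examples
#' tr <- tht_trace(time_h = c(0, 24, 72), intensity = c(0, 50, 100))
#' tht_to_mass(tr, m0 = 1e-6, m_eq = 7e-7)$mass  # 0, 1.5e-7, 3e-7 M
#' @export
tht_to_mass <- function(trace, m0, m_eq, plateau_fraction = 0.1) {
  stopifnot(is.data.frame(trace),
            all(c("time_h", "intensity") %in% names(trace)))
  if (!is.finite(m0) || !is.finite(m_eq) || m0 <= 0 || m_eq < 0)
    stop("`m0` must be > 0 and `m_eq` >= 0 (molar)")
  if (m_eq >= m0)
    stop("calibration impossible: m_eq (", format(m_eq),
         " M) must be below m0 (", format(m0), " M)")
  ii <- trace$intensity
  tt <- trace$time_h
  n <- length(ii)
  baseline <- min(ii)
  n_tail <- max(1L, ceiling(plateau_fraction * n))
  tail_idx <- seq.int(n - n_tail + 1L, n)
  plateau <- mean(ii[tail_idx])

  # still-rising check: linear slope over the trailing decile, expressed as
  # rise per 10% of trace duration, against 2% of the total rise
  total_rise <- plateau - baseline
  plateau_found <- TRUE
  if (total_rise <= 0) {
    plateau_found <- FALSE
    plateau <- ii[n]
  } else if (n_tail >= 3L) {
    slope <- stats::coef(stats::lm(ii[tail_idx] ~ tt[tail_idx]))[2]
    duration <- tt[n] - tt[1]
    if (is.finite(slope) && slope * 0.1 * duration > 0.02 * total_rise) {
      plateau_found <- FALSE
      plateau <- ii[n]
      warning("no plateau detected (trace still rising); using final value")
    }
  }
  if (plateau <= baseline)
    stop("calibration impossible: plateau intensity does not exceed baseline")

  mass <- pmax(0, (ii - baseline) / (plateau - baseline)) * (m0 - m_eq)
  structure(data.frame(time = tt * 3600, time_h = tt, mass = mass),
            plateau_found = plateau_found, baseline = baseline,
            plateau = plateau)
}

#' Fit the combined nucleation-elongation rate to a mass trajectory
#'
#' One-parameter least-squares fit of the nucleation-growth model: with the
#' solubility fixed from the measured steady-state monomer and the
#' nucleation order fixed, the unseeded mass curve depends on a single free
#' parameter, the combined rate \eqn{\lambda = k_n k_+ m_0^{n_c}}.  The sum
#' of squared residuals between the simulated and observed mass is minimised
#' over log10(lambda) by bounded scalar optimisation ([stats::optimize()]),
#' which is deterministic given the data and settings.
#'
#' @param mass_traj data frame with `time` (s) and `mass` (M) columns, e.g.
#'   from [tht_to_mass()] or [simulate_aggregation()].
#' @param fixed named list with `solubility` (M), `m0` (M), and optionally
#'   `nc` (default 2) and `P0` (default 0, reduced seed units s^-1).
#' @param lambda_bounds_log10 search interval for log10(lambda).
#' @param tol convergence tolerance on log10(lambda).
#' @param rtol,atol solver tolerances passed to [simulate_aggregation()].
#' @return An object of class `kinetic_fit`: list with `lambda_hat` (s^-2),
#'   `residual_norm`, `n_points`, `converged`, and the `fixed` settings.
#'   An all-zero mass trace returns the lower search bound with
#'   `converged = FALSE`.
#' @examples
#' wt <- rate_parameters(lambda = 7e-9, solubility = 7e-7)
#' tr <- simulate_aggregation(wt, initial_state(1e-6),
#'                            seq(0, 72 * 3600, length.out = 100))
#' fit <- fit_combined_rate(tr, fixed = list(solubility = 7e-7, m0 = 1e-6))
#' fit$lambda_hat  # ~7e-9
#' @export
fit_combined_rate <- function(mass_traj, fixed,
                              lambda_bounds_log10 = c(-12, -4),
                              tol = 1e-10, rtol = 1e-8, atol = 1e-12) {
  stopifnot(is.data.frame(mass_traj),
            all(c("time", "mass") %in% names(mass_traj)))
  tt <- mass_traj$time
  mm <- mass_traj$mass
  if (any(!is.finite(tt)) || any(!is.finite(mm)))
    stop("non-finite values in the mass trajectory")
  if (any(mm < 0)) stop("mass trajectory must be non-negative")
  if (length(tt) < 5L) stop("need at least 5 points to fit")
  if (is.null(fixed$solubility) || is.null(fixed$m0))
    stop("`fixed` must supply `solubility` and `m0`")
  nc <- if (is.null(fixed$nc)) 2L else fixed$nc
  P0 <- if (is.null(fixed$P0)) 0 else fixed$P0
  lb <- lambda_bounds_log10[1]; ub <- lambda_bounds_log10[2]

  # simulate on the observed grid; prepend t = 0 if the data start later
  sim_times <- tt
  drop_first <- FALSE
  if (tt[1] > 0) { sim_times <- c(0, tt); drop_first <- TRUE }
  init <- initial_state(m0 = fixed$m0, P0 = P0)

  sim_mass <- function(l10) {
    p <- rate_parameters(lambda = 10^l10, solubility = fixed$solubility,
                         nc = nc)
    tr <- simulate_aggregation(p, init, sim_times, rtol = rtol, atol = atol)
    if (drop_first) tr$mass[-1] else tr$mass
  }
  objective <- function(l10) sum((sim_mass(l10) - mm)^2)

  result <- list(n_points = length(tt),
                 fixed = list(solubility = fixed$solubility, nc = nc,
                              m0 = fixed$m0, P0 = P0),
                 bounds_log10 = c(lb, ub))
  if (all(mm == 0)) {
    result$lambda_hat <- 10^lb
    result$residual_norm <- 0
    result$converged <- FALSE
    class(result) <- "kinetic_fit"
    return(result)
  }

  opt <- stats::optimize(objective, interval = c(lb, ub), tol = tol)
  l10_hat <- opt$minimum
  # ties toward smaller lambda: accept the lower bound if it does as well
  at_bound <- l10_hat - lb < 1e-4 || ub - l10_hat < 1e-4
  if (objective(lb) <= opt$objective) {
    l10_hat <- lb
    opt$objective <- objective(lb)
    at_bound <- TRUE
  }
  result$lambda_hat <- 10^l10_hat
  result$residual_norm <- sqrt(opt$objective)
  result$converged <- is.finite(opt$objective) && !at_bound
  class(result) <- "kinetic_fit"
  result
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("One-parameter nucleation-growth fit\n")
  cat(sprintf("  lambda_hat: %.4g s^-2 (converged: %s)\n",
              x$lambda_hat, x$converged))
  cat(sprintf("  residual norm: %.3g over %d points\n",
              x$residual_norm, x$n_points))
  cat(sprintf("  fixed: solubility = %.3g M, nc = %d, m0 = %.3g M, P0 = %.3g\n",
              x$fixed$solubility, as.integer(x$fixed$nc), x$fixed$m0,
              x$fixed$P0))
  invisible(x)
}
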