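#' Kinetic parameters of the nucleation-growth-dissociation model
#'
#' The model describes aggregation of an aggregation-prone precursor at
#' concentration \eqn{m(t)} into aggregates whose number concentration is
#' \eqn{P(t)}:
#' \deqn{dP/dt = k_n m(t)^{n_c}, \qquad dm/dt = -2 (k_+ m(t) - k_{off}) P(t)}
#' where \eqn{k_+}, \eqn{k_{off}} and \eqn{k_n} are the rates of growth,
#' aggregate dissociation and primary nucleation, and \eqn{n_c} is the
#' reaction order of primary nucleation.  Unseeded mass curves depend on the
#' individual rate constants only through the combined nucleation-elongation
#' rate \eqn{\lambda = k_n k_+ m_0^{n_c}} (units s\eqn{^{-2}}, normalised at
#' the initial monomer concentration \eqn{m_0}) and the solubility ratio
#' \eqn{k_{off}/k_+} (molar), which is the steady-state free-monomer
#' concentration.  `rate_parameters()` therefore stores the identifiable
#' pair (`lambda`, `solubility`) plus `nc`; an explicit decomposition into
#' `k_plus`/`k_n`/`k_off` may be supplied and is checked for consistency.
#'
#' @param lambda combined nucleation-elongation rate \eqn{\lambda}, s^-2.
#'   Must be finite and >= 0 (0 switches primary nucleation off).
#' @param solubility ratio \eqn{k_{off}/k_+}, molar; strictly positive.
#' @param nc reaction order of primary nucleation; positive integer.
#' @param k_plus,k_n,k_off optional explicit decomposition (elongation rate
#'   constant M^-1 s^-1, nucleation rate constant M^(1-nc) s^-1, dissociation
#'   rate in units such that `k_off / k_plus` is molar).  If any is given all
#'   three and `m_ref` are required.
#' @param m_ref reference (initial) monomer concentration, molar, used to
#'   check `k_n * k_plus * m_ref^nc == lambda`.
#'
#' @return An object of class `rate_parameters`.
#' @examples
#' ## printed wild-type parameters
#' rate_parameters(lambda = 7e-9, solubility = 7e-7, nc = 2)
#' @export
rate_parameters <- function(lambda, solubility, nc = 2L,
                            k_plus = NULL, k_n = NULL, k_off = NULL,
                            m_ref = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            is.numeric(solubility), length(solubility) == 1L)
  if (!is.finite(lambda) || lambda < 0)
    stop("`lambda` must be finite and non-negative (s^-2), got ", lambda)
  if (!is.finite(solubility) || solubility <= 0)
    stop("`solubility` (koff/k+) must be finite and strictly positive (M), got ",
         solubility)
  if (length(nc) != 1L || !is.finite(nc) || nc < 1 || nc != round(nc))
    stop("`nc` must be a positive integer, got ", nc)
  nc <- as.integer(nc)

  decomposition <- NULL
  if (!is.null(k_plus) || !is.null(k_n) || !is.null(k_off)) {
    if (is.null(k_plus) || is.null(k_n) || is.null(k_off) || is.null(m_ref))
      stop("a decomposition requires all of `k_plus`, `k_n`, `k_off`, `m_ref`")
    for (nm in c("k_plus", "k_n", "k_off", "m_ref")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("`", nm, "` must be a single finite positive number")
    }
    lam_dec <- k_n * k_plus * m_ref^nc
    if (abs(lam_dec - lambda) > 1e-9 * max(lambda, lam_dec))
      stop("inconsistent decomposition: k_n * k_plus * m_ref^nc = ",
           format(lam_dec), " but lambda = ", format(lambda))
    sol_dec <- k_off / k_plus
    if (abs(sol_dec - solubility) > 1e-9 * max(solubility, sol_dec))
      stop("inconsistent decomposition: k_off / k_plus = ", format(sol_dec),
           " but solubility = ", format(solubility))
    decomposition <- list(k_plus = k_plus, k_n = k_n, k_off = k_off,
                          m_ref = m_ref)
  }

  structure(list(lambda = lambda, solubility = solubility, nc = nc,
                 decomposition = decomposition),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Nucleation-growth rate parameters\n")
  cat(sprintf("  lambda (kn*k+*m0^nc): %.3g s^-2\n", x$lambda))
  cat(sprintf("  solubility (koff/k+): %.3g M (%.3g nM)\n",
              x$solubility, x$solubility * 1e9))
  cat(sprintf("  nc (nucleation reaction order): %d\n", x$nc))
  if (!is.null(x$decomposition))
    cat(sprintf("  decomposition: k+ = %.3g M^-1 s^-1, kn = %.3g, koff/k+ = %.3g M\n",
                x$decomposition$k_plus, x$decomposition$k_n,
                x$decomposition$k_off / x$decomposition$k_plus))
  invisible(x)
}

#' Initial state of an aggregation reaction
#'
#' Seeds enter in the reduced units of the model: `P0` is interpreted as
#' \eqn{Q_0 = k_+ P_0} (units s^-1), the product of the elongation rate
#' constant and the seed number concentration, which is the combination the
#' unseeded-plus-seeded mass curves actually depend on.  `M0` is the molar
#' monomer-equivalent mass already held in the seeds at time zero; it only
#' offsets the reported aggregate mass.
#'
#' @param m0 initial free monomer concentration, molar; strictly positive.
#' @param P0 initial seed term \eqn{Q_0 = k_+ P_0}, s^-1; non-negative.
#' @param M0 initial aggregate mass, molar; non-negative, and must be zero
#'   when `P0` is zero.
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(m0, P0 = 0, M0 = 0) {
  stopifnot(is.numeric(m0), length(m0) == 1L,
            is.numeric(P0), length(P0) == 1L,
            is.numeric(M0), length(M0) == 1L)
  if (!is.finite(m0) || m0 <= 0) stop("`m0` must be finite and > 0 (M)")
  if (!is.finite(P0) || P0 < 0) stop("`P0` must be finite and >= 0")
  if (!is.finite(M0) || M0 < 0) stop("`M0` must be finite and >= 0")
  if (P0 == 0 && M0 > 0)
    stop("`M0` must be 0 when `P0` is 0 (seed mass without seeds)")
  structure(list(m0 = m0, P0 = P0, M0 = M0), class = "initial_state")
}

#' Simulate the nucleation-growth-dissociation model
#'
#' Integrates the reduced form of the kinetic equations.  Substituting
#' \eqn{Q(t) = k_+ P(t)} and \eqn{x = m/m_0} turns the two-parameter-family
#' ambiguity of (\eqn{k_n}, \eqn{k_+}) into the single identifiable rate
#' \eqn{\lambda}:
#' \deqn{dQ/dt = \lambda x^{n_c}, \qquad dx/dt = -2 (x - s) Q}
#' with \eqn{s = } solubility\eqn{/m_0}.  Integration uses an adaptive
#' stiff-capable solver ([deSolve::lsoda()]) on the dimensionless monomer
#' fraction, with dense output on the supplied grid.
#'
#' @param params a [rate_parameters()] object.
#' @param init an [initial_state()] object.
#' @param times output time grid in seconds; must start at 0 and be strictly
#'   increasing.
#' @param rtol,atol relative / absolute solver tolerances (absolute tolerance
#'   applies to the dimensionless monomer fraction m/m0 and to Q in s^-1).
#' @return A data frame of class `aggregation_trajectory` with columns
#'   `time` (s), `monomer` (M), `number` (Q = k+*P, s^-1) and `mass`
#'   (M, equal to `m0 + M0 - monomer`), carrying `params` and `init` as
#'   attributes.
#' @examples
#' wt <- rate_parameters(lambda = 7e-9, solubility = 7e-7, nc = 2)
#' tr <- simulate_aggregation(wt, initial_state(m0 = 1e-6),
#'                            times = seq(0, 72 * 3600, length.out = 50))
#' tail(tr$monomer, 1) * 1e9  # ~700 nM, the steady-state solubility
#' @export
simulate_aggregation <- function(params, init, times,
                                 rtol = 1e-8, atol = 1e-12) {
  if (!inherits(params, "rate_parameters"))
    stop("`params` must be created by rate_parameters()")
  if (!inherits(init, "initial_state"))
    stop("`init` must be created by initial_state()")
  if (!is.numeric(times) || length(times) < 2L)
    stop("`times` must be a numeric vector of length >= 2")
  if (times[1] != 0) stop("`times` must start at 0")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")

  s <- params$solubility / init$m0
  nc <- params$nc
  lambda <- params$lambda
  deriv <- function(t, y, parms) {
    x <- y[1]; q <- y[2]
    list(c(-2 * (x - s) * q,
           lambda * (max(x, 0))^nc))
  }
  sol <- deSolve::lsoda(y = c(x = 1, q = init$P0), times = times,
                        func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop("integration failed at t = ", sol[nrow(sol), 1], " s; ",
         "last state x = ", sol[nrow(sol), 2],
         " (try loosening tolerances)")
  monomer <- sol[, "x"] * init$m0
  out <- data.frame(time = times,
                    monomer = monomer,
                    number = sol[, "q"],
                    mass = init$m0 + init$M0 - monomer)
  structure(out, params = params, init = init,
            class = c("aggregation_trajectory", "data.frame"))
}

#' Seeded simulation of the aggregation model
#'
#' Convenience wrapper around [simulate_aggregation()] that requires a
#' non-zero seed term, for studying self-seeding: preformed aggregates give
#' the mass curve a non-zero initial slope, in contrast to the
#' upward-curving, zero-initial-slope unseeded curves.
#'
#' @inheritParams simulate_aggregation
#' @return As [simulate_aggregation()].
#' @export
seeded_simulate <- function(params, init, times, rtol = 1e-8, atol = 1e-12) {
  if (!inherits(init, "initial_state") || init$P0 <= 0)
    stop("`init$P0` must be > 0 for a seeded simulation; use ",
         "simulate_aggregation() for the unseeded model")
  simulate_aggregation(params, init, times, rtol = rtol, atol = atol)
}

#' Steady-state free monomer concentration
#'
#' The fixed point of the monomer equation: elongation and dissociation
#' balance when \eqn{m = k_{off}/k_+}, so the analytic steady state is the
#' solubility ratio itself.  This is the level the free monomer relaxes to
#' whenever aggregation proceeds at all (m0 above solubility and either
#' seeds present or nucleation active).
#'
#' @param params a [rate_parameters()] object.
#' @return steady-state monomer concentration, molar.
#' @export
steady_state_monomer <- function(params) {
  if (!inherits(params, "rate_parameters"))
    stop("`params` must be created by rate_parameters()")
  params$solubility
}

#' Early-time scaling exponent of the aggregate mass curve
#'
#' Fits the slope of log(mass) against log(time) over the earliest part of a
#' trajectory.  For the unseeded primary-nucleation model the aggregate mass
#' grows as \eqn{M(t) \propto t^2} at early times (nuclei accumulate
#' linearly, each growing at a constant rate), so the slope tends to 2 as the
#' window shrinks; strongly seeded growth and precursor-limited first-order
#' kinetics (\eqn{M = A(1 - e^{-kt})}) both give slope ~1.  The exponent
#' therefore discriminates nucleated growth from precursor-limited
#' conversion.
#'
#' @param traj an `aggregation_trajectory` (or data frame with `time` and
#'   `mass` columns).
#' @param window early-time window expressed as a fraction of the half-time
#'   (time at which mass first reaches half its final value).
#' @param min_points minimum number of usable points required in the window.
#' @return the fitted dimensionless slope.
#' @export
early_time_exponent <- function(traj, window = 0.02, min_points = 3L) {
  stopifnot(is.data.frame(traj), all(c("time", "mass") %in% names(traj)))
  if (window <= 0 || window > 1) stop("`window` must be in (0, 1]")
  tt <- traj$time; mm <- traj$mass
  plateau <- max(mm)
  if (plateau <= 0) stop("trajectory has no aggregate mass; cannot fit slope")
  i_half <- which(mm >= plateau / 2)[1]
  t_half <- tt[i_half]
  keep <- tt > 0 & tt <= window * t_half & mm > 0
  if (sum(keep) < min_points)
    stop("only ", sum(keep), " usable points in the earliest ",
         format(window), " of the half-time; supply a denser early grid")
  fit <- stats::lm(log(mm[keep]) ~ log(tt[keep]))
  unname(stats::coef(fit)[2])
}
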