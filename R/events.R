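#' @rdname detect_peak_active_fraction
#' @param kind event label.
#' @param time event time, day.
#' @param value value of the watched variable at the event.
#' @param criterion human-readable detection criterion.
#' @param detected `FALSE` when the criterion was never met in the span.
#' @export
biofilm_event <- function(kind, time, value, criterion, detected = TRUE) {
  structure(list(kind = kind, time = time, value = value,
                 criterion = criterion, detected = detected),
            class = "biofilm_event")
}

#' @export
print.biofilm_event <- function(x, ...) {
  if (x$detected)
    cat(sprintf("  event %-22s t = %-9.4g value = %.6g  [%s]\n",
                x$kind, x$time, x$value, x$criterion))
  else
    cat(sprintf("  event %-22s not reached within span  [%s]\n",
                x$kind, x$criterion))
  invisible(x)
}

# Cubic interpolant of one trajectory column; the continuous stand-in for
# the solver's dense output when locating events between grid points.
traj_fun <- function(sim, col) {
  stats::splinefun(sim$trajectory$t, sim$trajectory[[col]],
                   method = "fmm")
}

#' Detect features of a simulated biofilm trajectory
#'
#' Three trajectory features mirror the observables usually read off growth
#' curves: the transient maximum of the active-biomass fraction, the time
#' at which the agar nutrient is effectively exhausted, and the time at
#' which thickness growth has effectively stopped. All three refine the
#' saved grid by interpolation (peak by continuous maximisation, crossings
#' by root finding), so detections are insensitive to the output grid.
#'
#' @param sim a [simulate_biofilm()] result.
#' @return A `biofilm_event` with the event kind, time (day), value, and
#'   the criterion applied. Crossing detectors return `detected = FALSE`
#'   instead of erroring when the criterion is never met in the span.
#'
#' @examples
#' sim <- simulate_biofilm()
#' detect_peak_active_fraction(sim)
#' detect_substrate_depletion(sim)
#' detect_steady_state(sim)
#' @export
detect_peak_active_fraction <- function(sim) {
  stopifnot(inherits(sim, "biofilm_sim"))
  tr <- sim$trajectory
  i <- which.max(tr$f)
  if (i == 1L)
    return(biofilm_event("peak_active_fraction", tr$t[1], tr$f[1],
                         "max f; attained at span start"))
  fn <- traj_fun(sim, "f")
  lo <- tr$t[max(i - 1L, 1L)]
  hi <- tr$t[min(i + 1L, nrow(tr))]
  opt <- stats::optimize(fn, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  biofilm_event("peak_active_fraction", opt$maximum, opt$objective,
                "max f by continuous refinement of the saved grid")
}

#' @rdname detect_peak_active_fraction
#' @param threshold_fraction depletion is declared when `S_a` first falls
#'   below this fraction of its initial value (default 0.01). The agar
#'   nutrient only asymptotes to zero, so an exact-zero crossing never
#'   occurs; the threshold makes "effectively exhausted" operational.
#' @export
detect_substrate_depletion <- function(sim, threshold_fraction = 0.01) {
  stopifnot(inherits(sim, "biofilm_sim"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  tr <- sim$trajectory
  target <- threshold_fraction * sim$init$S_a
  crit <- sprintf("first S_a < %g x S_a(0)", threshold_fraction)
  if (sim$init$S_a == 0 || tr$S_a[1] < target)
    return(biofilm_event("substrate_depleted", tr$t[1], tr$S_a[1], crit))
  i <- which(tr$S_a < target)[1]
  if (is.na(i))
    return(biofilm_event("substrate_depleted", NA_real_,
                         tr$S_a[nrow(tr)], crit, detected = FALSE))
  fn <- traj_fun(sim, "S_a")
  t_star <- stats::uniroot(function(t) fn(t) - target,
                           c(tr$t[i - 1L], tr$t[i]),
                           tol = .Machine$double.eps^0.5)$root
  biofilm_event("substrate_depleted", t_star, target, crit)
}

#' @rdname detect_peak_active_fraction
#' @param rel_rate_tol steady state is declared when the relative thickness
#'   growth rate `(dL/dt)/L` first drops below this value, day^-1 (default
#'   1e-4). The criterion is scale-free: it does not depend on the units or
#'   magnitude of `L`.
#' @export
detect_steady_state <- function(sim, rel_rate_tol = 1e-4) {
  stopifnot(inherits(sim, "biofilm_sim"))
  if (rel_rate_tol <= 0) stop("rel_rate_tol must be positive", call. = FALSE)
  tr <- sim$trajectory
  # exact relative growth rate along the grid, from the model itself
  rate <- vapply(seq_len(nrow(tr)), function(i) {
    d <- rhs_core(c(tr$f[i], tr$L[i], tr$S[i], tr$S_a[i]), sim$params)
    d[["L"]] / tr$L[i]
  }, numeric(1))
  crit <- sprintf("first (dL/dt)/L < %g per day", rel_rate_tol)
  if (rate[1] < rel_rate_tol)
    return(biofilm_event("steady_state_reached", tr$t[1], tr$L[1], crit))
  i <- which(rate < rel_rate_tol)[1]
  if (is.na(i))
    return(biofilm_event("steady_state_reached", NA_real_,
                         tr$L[nrow(tr)], crit, detected = FALSE))
  rfn <- stats::splinefun(tr$t, rate, method = "fmm")
  t_star <- stats::uniroot(function(t) rfn(t) - rel_rate_tol,
                           c(tr$t[i - 1L], tr$t[i]),
                           tol = .Machine$double.eps^0.5)$root
  biofilm_event("steady_state_reached", t_star, traj_fun(sim, "L")(t_star),
                crit)
}
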