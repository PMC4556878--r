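#' Solver settings for the biofilm integrator
#'
#' The system is stiff: thickness starts four orders of magnitude below the
#' agar nutrient concentration and the in-film nutrient balance develops a
#' near-discontinuity at depletion. Defaults therefore use a tight relative
#' tolerance and per-variable absolute tolerances matched to each
#' variable's scale.
#'
#' @param rtol relative tolerance, dimensionless.
#' @param atol absolute tolerances, named for `f`, `L`, `S`, `S_a` (a single
#'   number is recycled to all four).
#' @param tspan integration span in days, `c(start, end)` with start < end.
#' @param n_out number of equally spaced output times saved on the
#'   trajectory grid (event detection interpolates between them).
#' @param max_step maximum internal step, days (`Inf` leaves the solver
#'   free).
#' @return An object of class `solver_settings`.
#' @examples
#' solver_settings(tspan = c(0, 30))
#' @export
solver_settings <- function(rtol = 1e-8,
                            atol = c(f = 1e-12, L = 1e-12,
                                     S = 1e-10, S_a = 1e-10),
                            tspan = c(0, 10), n_out = 2001L,
                            max_step = Inf) {
  vars <- c("f", "L", "S", "S_a")
  if (length(atol) == 1L) atol <- rep(atol, 4L)
  if (is.null(names(atol))) names(atol) <- vars
  atol <- atol[vars]
  if (anyNA(atol) || any(atol <= 0) || rtol <= 0)
    stop("tolerances must be strictly positive (atol named f, L, S, S_a)",
         call. = FALSE)
  if (length(tspan) != 2L || !all(is.finite(tspan)) || tspan[1] >= tspan[2])
    stop("tspan must be c(start, end) with start < end", call. = FALSE)
  n_out <- as.integer(n_out)
  if (n_out < 10L) stop("n_out must be at least 10", call. = FALSE)
  if (max_step <= 0) stop("max_step must be positive", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, tspan = as.numeric(tspan),
                 n_out = n_out, max_step = max_step),
            class = "solver_settings")
}

#' Simulate biofilm growth on an agar plate
#'
#' Integrates the four-variable model with a stiff-capable solver
#' (`deSolve`'s lsoda) and returns the trajectory together with solver
#' metadata. Saved states are clipped to non-negative concentrations (the
#' solver may overshoot by roundoff near depletion); any clipping is
#' counted and flagged on the result. The reported inactive fraction
#' `f_bar = 1 - eps_a - f` and the conserved nutrient-equivalent mass are
#' derived columns, never integrated.
#'
#' @param params a [biofilm_params()]; default is the reference preset.
#' @param init a [biofilm_state()] initial condition.
#' @param settings a [solver_settings()].
#' @param horizon convenience override: a single end time in days, replacing
#'   `settings$tspan[2]`.
#' @return An object of class `biofilm_sim`: a list with `trajectory` (a
#'   data frame with columns `t`, `L`, `f`, `f_bar`, `S`, `S_a`,
#'   `conserved_mass`), `params`, `init`, `settings`, and `n_clipped`
#'   (states where a concentration was floored at zero).
#' @examples
#' sim <- simulate_biofilm()
#' summary(sim)
#' @seealso [detect_peak_active_fraction()], [detect_substrate_depletion()],
#'   [detect_steady_state()], [write_trajectory()]
#' @export
simulate_biofilm <- function(params = biofilm_params(),
                             init = biofilm_state(),
                             settings = solver_settings(),
                             horizon = NULL) {
  stopifnot(inherits(params, "biofilm_params"),
            inherits(init, "biofilm_state"),
            inherits(settings, "solver_settings"))
  check_state_params(init, params)
  if (!is.null(horizon)) {
    if (horizon <= settings$tspan[1])
      stop("horizon must exceed the span start", call. = FALSE)
    settings$tspan[2] <- horizon
  }
  times <- seq(settings$tspan[1], settings$tspan[2],
               length.out = settings$n_out)
  y0 <- c(f = init$f, L = init$L, S = init$S, S_a = init$S_a)
  deriv <- function(t, y, p) list(unname(rhs_core(y, p)))
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = params,
                      method = "lsoda", rtol = settings$rtol,
                      atol = unname(settings$atol),
                      hmax = if (is.finite(settings$max_step))
                        settings$max_step else NULL)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf(paste0("integration failed (istate = %d) at t = %.6g; ",
                        "last state: f = %.6g, L = %.6g, S = %.6g, ",
                        "S_a = %.6g"),
                 istate[1], out[nrow(out), 1], out[nrow(out), 2],
                 out[nrow(out), 3], out[nrow(out), 4], out[nrow(out), 5]),
         call. = FALSE)
  tr <- as.data.frame(unclass(out))
  names(tr) <- c("t", "f", "L", "S", "S_a")
  n_clipped <- sum(tr$S < 0) + sum(tr$S_a < 0)
  tr$S <- pmax(tr$S, 0)
  tr$S_a <- pmax(tr$S_a, 0)
  tr$f_bar <- 1 - params$eps_a - tr$f
  tr$conserved_mass <- tr$S_a * params$V_a +
    tr$S * params$sigma * tr$L +
    params$rho * params$sigma * (1 - params$eps_a) * tr$L / params$Y
  tr <- tr[, c("t", "L", "f", "f_bar", "S", "S_a", "conserved_mass")]
  structure(list(trajectory = tr, params = params, init = init,
                 settings = settings, n_clipped = n_clipped),
            class = "biofilm_sim")
}

#' @export
print.biofilm_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Biofilm growth simulation over [%g, %g] days (%d states%s)\n",
              x$settings$tspan[1], x$settings$tspan[2], nrow(tr),
              if (x$n_clipped > 0)
                sprintf(", %d clipped to S >= 0", x$n_clipped) else ""))
  cat(sprintf("  final state: L = %.4g cm, f = %.4g, S_a = %.4g mg/cm^3\n",
              tr$L[nrow(tr)], tr$f[nrow(tr)], tr$S_a[nrow(tr)]))
  invisible(x)
}

#' @export
summary.biofilm_sim <- function(object, ...) {
  tr <- object$trajectory
  ev <- list(peak_f = detect_peak_active_fraction(object),
             depletion = detect_substrate_depletion(object),
             steady = detect_steady_state(object))
  m0 <- tr$conserved_mass[1]
  drift <- max(abs(tr$conserved_mass - m0)) / m0
  structure(list(sim = object, events = ev, mass_drift = drift,
                 final = tr[nrow(tr), ],
                 L_inf = predicted_final_thickness(object$params,
                                                   object$init)),
            class = "summary.biofilm_sim")
}

#' @export
print.summary.biofilm_sim <- function(x, ...) {
  print(x$sim)
  cat(sprintf("  conserved-mass drift: %.3g (relative)\n", x$mass_drift))
  cat(sprintf("  conservation-law final thickness: %.4g cm\n", x$L_inf))
  for (ev in x$events) print(ev)
  invisible(x)
}

#' @export
as.data.frame.biofilm_sim <- function(x, ...) x$trajectory

#' @export
coef.biofilm_sim <- function(object, ...) unlist(object$params)

#' Plot a simulated biofilm trajectory
#'
#' Four base-graphics panels: thickness, active/inactive volume fractions,
#' in-film nutrient, and agar nutrient, each against time in days.
#'
#' @param x a `biofilm_sim` object.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.biofilm_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$t, tr$L, type = "l", xlab = "time (d)",
                 ylab = "thickness L (cm)", main = "Biofilm thickness", ...)
  graphics::plot(tr$t, tr$f, type = "l", ylim = c(0, 1 - x$params$eps_a),
                 xlab = "time (d)", ylab = "volume fraction",
                 main = "Active (solid) / inactive (dashed)", ...)
  graphics::lines(tr$t, tr$f_bar, lty = 2)
  graphics::plot(tr$t, tr$S, type = "l", xlab = "time (d)",
                 ylab = "S (mg/cm^3)", main = "Nutrient in film", ...)
  graphics::plot(tr$t, tr$S_a, type = "l", xlab = "time (d)",
                 ylab = "S_a (mg/cm^3)", main = "Nutrient in agar", ...)
  invisible(x)
}

#' Export a trajectory or a run summary to plain text
#'
#' `write_trajectory()` writes the state table as tab-separated text, one
#' row per saved time. `write_run_summary()` writes a small human-readable
#' report: parameter echo, solver settings, detected events and the
#' conserved-mass drift.
#'
#' @param sim a `biofilm_sim` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(sim, file) {
  stopifnot(inherits(sim, "biofilm_sim"))
  utils::write.table(sim$trajectory, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
write_run_summary <- function(sim, file) {
  stopifnot(inherits(sim, "biofilm_sim"))
  s <- summary(sim)
  con <- file(file, "w")
  on.exit(close(con))
  sink(con)
  print(s)
  cat("\nParameters:\n")
  print(sim$params)
  cat(sprintf("\nSolver: lsoda, rtol = %g, atol = [%s], span [%g, %g] d\n",
              sim$settings$rtol,
              paste(format(sim$settings$atol), collapse = ", "),
              sim$settings$tspan[1], sim$settings$tspan[2]))
  sink()
  invisible(file)
}
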