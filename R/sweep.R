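#' Specify a one-parameter sweep
#'
#' A sweep varies one of the five growth-controlling constants — yield `Y`,
#' maximum uptake rate `V_T`, diffusion coefficient `D`, biomass density
#' `rho`, or inactivation rate `b` — across a list of values while holding
#' the rest of the preset fixed, and summarises each run by its detected
#' events. Default values bracket the base preset by factors 1/2 and 2.
#'
#' @param parameter one of `"Y"`, `"V_T"`, `"D"`, `"rho"`, `"b"`.
#' @param values strictly positive values of that parameter, in its own
#'   units; default `c(0.5, 1, 2) * base[[parameter]]`.
#' @param base the [biofilm_params()] preset being perturbed.
#' @param init initial condition shared by all runs.
#' @param horizon simulation end time per run, days.
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec("Y")
#' sweep_spec("rho", values = c(150, 300, 600))
#' @export
sweep_spec <- function(parameter, values = NULL, base = biofilm_params(),
                       init = biofilm_state(), horizon = 10) {
  parameter <- match.arg(parameter, c("Y", "V_T", "D", "rho", "b"))
  stopifnot(inherits(base, "biofilm_params"),
            inherits(init, "biofilm_state"))
  if (is.null(values)) values <- c(0.5, 1, 2) * base[[parameter]]
  if (!length(values) || any(!is.finite(values)) || any(values <= 0))
    stop("values must be a nonempty vector of positive numbers",
         call. = FALSE)
  structure(list(parameter = parameter, values = as.numeric(values),
                 base = base, init = init, horizon = horizon),
            class = "sweep_spec")
}

#' @rdname sweep_spec
#' @param file path to a flat key-value sweep file with keys `parameter`
#'   (a name, not a number), `values` (comma-separated), and optionally
#'   `horizon`; remaining keys override the base preset as in
#'   [read_biofilm_config()].
#' @export
read_sweep_spec <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  if (!"parameter" %in% keys || !"values" %in% keys)
    stop("sweep file must define 'parameter' and 'values'", call. = FALSE)
  sweep_vals <- as.numeric(strsplit(vals[["values"]], ",")[[1]])
  rest <- vals[!keys %in% c("parameter", "values", "horizon")]
  cfg <- if (length(rest)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(sprintf("%s = %s", names(rest), rest), tf)
    read_biofilm_config(tf)
  } else list(params = biofilm_params(), init = biofilm_state())
  sweep_spec(vals[["parameter"]], sweep_vals, base = cfg$params,
             init = cfg$init,
             horizon = if ("horizon" %in% keys)
               as.numeric(vals[["horizon"]]) else 10)
}

#' Run a parameter sweep
#'
#' Performs one full integration plus event detection per parameter value.
#' A failed integration is recorded in that value's row (`ok = FALSE`)
#' without aborting the rest of the sweep. "Final thickness" is the
#' thickness at the steady-state event; when the run has not reached steady
#' state within the horizon the end-of-span thickness is used instead and
#' the row is flagged (`steady = FALSE`).
#'
#' @param spec a [sweep_spec()].
#' @param keep_sims keep the full `biofilm_sim` objects (default drops
#'   them; the summary table is usually all that is needed).
#' @return An object of class `biofilm_sweep` whose `results` element is a
#'   data frame with one row per value: `value`, `final_thickness` (cm),
#'   `steady`, `peak_f`, `peak_time` (d), `depletion_time` (d, `NA` if not
#'   depleted), `terminal_f` (at the end of the span), `ok`, `error`.
#' @examples
#' sw <- run_sweep(sweep_spec("rho", c(150, 300, 600)))
#' sw$results$final_thickness   # decreasing in rho
#' @export
run_sweep <- function(spec, keep_sims = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$values))
  sims <- if (keep_sims) vector("list", length(spec$values)) else NULL
  for (k in seq_along(spec$values)) {
    p <- spec$base
    p[[spec$parameter]] <- spec$values[k]
    p <- do.call(biofilm_params, unclass(p))
    row <- data.frame(value = spec$values[k], final_thickness = NA_real_,
                      steady = NA, peak_f = NA_real_, peak_time = NA_real_,
                      depletion_time = NA_real_, terminal_f = NA_real_,
                      ok = FALSE, error = NA_character_)
    res <- tryCatch({
      sim <- simulate_biofilm(p, spec$init, horizon = spec$horizon)
      if (keep_sims) sims[[k]] <- sim
      ss <- detect_steady_state(sim)
      pk <- detect_peak_active_fraction(sim)
      dp <- detect_substrate_depletion(sim)
      tr <- sim$trajectory
      row$final_thickness <- if (ss$detected) ss$value else tr$L[nrow(tr)]
      row$steady <- ss$detected
      row$peak_f <- pk$value
      row$peak_time <- pk$time
      row$depletion_time <- if (dp$detected) dp$time else NA_real_
      row$terminal_f <- tr$f[nrow(tr)]
      row$ok <- TRUE
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[k]] <- res
  }
  res <- do.call(rbind, rows)
  if (any(res$ok & !res$steady))
    warning("some runs did not reach steady state within the horizon; ",
            "end-of-span thickness reported", call. = FALSE)
  structure(list(spec = spec, results = res, sims = sims),
            class = "biofilm_sweep")
}

#' @export
print.biofilm_sweep <- function(x, ...) {
  cat(sprintf("Sweep of %s over {%s}, horizon %g d:\n", x$spec$parameter,
              paste(format(x$spec$values), collapse = ", "),
              x$spec$horizon))
  print(x$results[, c("value", "final_thickness", "peak_f",
                      "depletion_time", "terminal_f")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname run_sweep
#' @param sweep a `biofilm_sweep` object.
#' @param file output path for the tab-separated summary table.
#' @export
write_sweep_summary <- function(sweep, file) {
  stopifnot(inherits(sweep, "biofilm_sweep"))
  out <- cbind(parameter = sweep$spec$parameter, sweep$results)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Nutrient depletion time as a function of the diffusion coefficient
#'
#' Faster diffusion across the laminar sublayer drains the agar reservoir
#' sooner, while the final thickness — fixed by mass conservation — is
#' essentially independent of `D`. This helper sweeps `D` and returns the
#' per-value depletion times.
#'
#' @param values_of_D diffusion coefficients, cm^2 day^-1, all positive.
#' @param base the [biofilm_params()] preset.
#' @param init shared initial condition.
#' @param threshold_fraction depletion threshold as in
#'   [detect_substrate_depletion()].
#' @param horizon per-run horizon, days.
#' @return Data frame with columns `D`, `depletion_time` (d),
#'   `final_thickness` (cm).
#' @examples
#' compare_depletion_vs_D(c(0.432, 0.864, 1.728))
#' @export
compare_depletion_vs_D <- function(values_of_D, base = biofilm_params(),
                                   init = biofilm_state(),
                                   threshold_fraction = 0.01,
                                   horizon = 10) {
  if (any(values_of_D <= 0)) stop("all D must be positive", call. = FALSE)
  sw <- run_sweep(sweep_spec("D", values_of_D, base, init, horizon),
                  keep_sims = TRUE)
  dep <- vapply(seq_along(values_of_D), function(k) {
    if (!sw$results$ok[k]) return(NA_real_)
    ev <- detect_substrate_depletion(sw$sims[[k]], threshold_fraction)
    if (ev$detected) ev$time else NA_real_
  }, numeric(1))
  data.frame(D = values_of_D, depletion_time = dep,
             final_thickness = sw$results$final_thickness)
}

#' Active-fraction response to inactivation rate or uptake rate
#'
#' Sweeps either the inactivation coefficient `b` or the maximum uptake
#' rate `V_T` and reports, per value, the peak active fraction and the
#' late-time ("terminal") active fraction. Raising `b` lowers the peak;
#' raising `V_T` raises the peak but accelerates the subsequent decline, so
#' the terminal fraction falls with `V_T`. In every case the active
#' fraction decays toward zero once nutrient is exhausted.
#'
#' @param parameter `"b"` or `"V_T"`.
#' @param values positive sweep values.
#' @param base the [biofilm_params()] preset.
#' @param init shared initial condition.
#' @param horizon per-run horizon, days (default 30: long enough for the
#'   post-depletion decay to dominate).
#' @param terminal_time time at which the terminal fraction is read, days.
#' @return Data frame with columns `value`, `peak_f`, `peak_time`,
#'   `terminal_f`.
#' @examples
#' active_fraction_response("b", c(0.125, 0.25, 0.5))
#' @export
active_fraction_response <- function(parameter = c("b", "V_T"), values,
                                     base = biofilm_params(),
                                     init = biofilm_state(), horizon = 30,
                                     terminal_time = 25) {
  parameter <- match.arg(parameter)
  if (terminal_time <= 0 || terminal_time > horizon)
    stop("terminal_time must lie in (0, horizon]", call. = FALSE)
  sw <- run_sweep(sweep_spec(parameter, values, base, init, horizon),
                  keep_sims = TRUE)
  term <- vapply(seq_along(values), function(k) {
    if (!sw$results$ok[k]) return(NA_real_)
    traj_fun(sw$sims[[k]], "f")(terminal_time)
  }, numeric(1))
  data.frame(value = values, peak_f = sw$results$peak_f,
             peak_time = sw$results$peak_time, terminal_f = term)
}
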