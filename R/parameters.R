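#' Kinetic and geometric parameters of the biofilm growth model
#'
#' Constructs the parameter set of the agar-plate biofilm model. Units are
#' fixed package-wide to centimetres, milligrams and days; there is no unit
#' conversion layer. The defaults are the reference parameterisation for a
#' *Bacillus subtilis* colony on an MSgg agar plate, and every argument can
#' be overridden individually.
#'
#' @param K Monod half-saturation constant, mg cm^-3.
#' @param V_T maximum specific uptake rate of Monod kinetics,
#'   mg-nutrient mg-biomass^-1 day^-1.
#' @param Y yield coefficient, mg biomass produced per mg nutrient consumed.
#' @param b first-order inactivation rate of active biomass, day^-1.
#' @param D nutrient diffusion coefficient through the laminar sublayer
#'   between agar and biofilm, cm^2 day^-1.
#' @param sigma area of the film-agar interface, cm^2.
#' @param eps_a volume fraction of water in the biofilm, dimensionless,
#'   in `[0, 1)`.
#' @param rho biomass density, mg cm^-3.
#' @param V_a volume of the agar substrate, cm^3.
#' @param L_a thickness of the laminar diffusional sublayer, cm.
#'
#' @return An object of class `biofilm_params`: a named list of the ten
#'   constants, validated (all strictly positive; `0 <= eps_a < 1`).
#'
#' @examples
#' p <- biofilm_params()            # reference preset
#' p2 <- biofilm_params(Y = 0.25)   # halved yield
#' @seealso [biofilm_state()], [read_biofilm_config()]
#' @export
biofilm_params <- function(K = 0.0001, V_T = 12.96, Y = 0.5, b = 0.25,
                           D = 0.864, sigma = 1, eps_a = 0.8, rho = 300,
                           V_a = 0.5, L_a = 0.3) {
  p <- list(K = K, V_T = V_T, Y = Y, b = b, D = D, sigma = sigma,
            eps_a = eps_a, rho = rho, V_a = V_a, L_a = L_a)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$eps_a < 0 || p$eps_a >= 1)
    stop("eps_a must satisfy 0 <= eps_a < 1", call. = FALSE)
  pos <- setdiff(names(p), "eps_a")
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(p, class = "biofilm_params")
}

#' @export
print.biofilm_params <- function(x, ...) {
  cat("Biofilm growth model parameters (cm / mg / day):\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 6), " = ",
             format(v, digits = 6)), sep = "\n")
  invisible(x)
}

#' State of the biofilm model at one instant
#'
#' The model tracks four dynamic variables: biofilm thickness `L`, the
#' volume fraction `f` of active biomass, the average nutrient
#' concentration `S` inside the film, and the nutrient concentration `S_a`
#' in the agar reservoir. The inactive-biomass fraction is never stored: it
#' is implied by the closure `f + f_bar + eps_a = 1`. Defaults are the
#' reference initial condition (a freshly spotted colony on MSgg agar).
#'
#' @param L biofilm thickness, cm; must be strictly positive.
#' @param f active-biomass volume fraction, dimensionless.
#' @param S nutrient concentration in the biofilm, mg cm^-3.
#' @param S_a nutrient concentration in the agar, mg cm^-3.
#' @param t time stamp, day.
#'
#' @return An object of class `biofilm_state` (named list).
#' @examples
#' biofilm_state()                     # reference initial condition
#' biofilm_state(S_a = 30)             # double the initial nutrient load
#' @export
biofilm_state <- function(L = 0.0001, f = 0.15, S = 0.00004, S_a = 15,
                          t = 0) {
  s <- list(t = t, L = L, f = f, S = S, S_a = S_a)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("state component '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (L <= 0) stop("L must be strictly positive", call. = FALSE)
  if (S < 0 || S_a < 0) stop("S and S_a must be non-negative", call. = FALSE)
  if (f < 0) stop("f must be non-negative", call. = FALSE)
  structure(s, class = "biofilm_state")
}

#' @export
print.biofilm_state <- function(x, ...) {
  cat(sprintf("Biofilm state at t = %g d: L = %g cm, f = %g, S = %g, S_a = %g mg/cm^3\n",
              x$t, x$L, x$f, x$S, x$S_a))
  invisible(x)
}

# f must leave room for water: f <= 1 - eps_a (inactive fraction >= 0).
check_state_params <- function(state, params) {
  if (state$f > 1 - params$eps_a + 1e-12)
    stop("f exceeds 1 - eps_a: no room left for inactive biomass and water",
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write model configurations as flat key-value text
#'
#' A configuration file is plain text with one `key = value` pair per line
#' (`#` starts a comment). Parameter keys are the ten constants of
#' [biofilm_params()]; initial-condition keys are `L0`, `f0`, `S0`, `S_a0`.
#' Keys that are absent fall back to the reference preset, so a file
#' overriding a single constant is valid.
#'
#' @param file path to the configuration file.
#' @return `read_biofilm_config()` returns `list(params, init)` with a
#'   `biofilm_params` and a `biofilm_state`; `write_biofilm_config()`
#'   returns `file` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".cfg")
#' write_biofilm_config(biofilm_params(Y = 0.25), biofilm_state(), tf)
#' cfg <- read_biofilm_config(tf)
#' cfg$params$Y
#' @export
read_biofilm_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed configuration line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate key(s): ", paste(unique(keys[duplicated(keys)]),
                                     collapse = ", "), call. = FALSE)
  pk <- names(formals(biofilm_params))
  ik <- c(L0 = "L", f0 = "f", S0 = "S", S_a0 = "S_a")
  unknown <- setdiff(keys, c(pk, names(ik)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pargs <- as.list(vals[match(intersect(keys, pk), keys)])
  names(pargs) <- intersect(keys, pk)
  iargs <- as.list(vals[match(intersect(keys, names(ik)), keys)])
  names(iargs) <- ik[intersect(keys, names(ik))]
  list(params = do.call(biofilm_params, pargs),
       init = do.call(biofilm_state, iargs))
}

#' @rdname read_biofilm_config
#' @param params a `biofilm_params` object.
#' @param init a `biofilm_state` initial condition.
#' @export
write_biofilm_config <- function(params, init, file) {
  stopifnot(inherits(params, "biofilm_params"),
            inherits(init, "biofilm_state"))
  out <- c("# biofilm growth model configuration (units: cm, mg, day)",
           sprintf("%s = %.15g", names(params), unlist(params)),
           sprintf("%s = %.15g", c("L0", "f0", "S0", "S_a0"),
                   unlist(init[c("L", "f", "S", "S_a")])))
  writeLines(out, file)
  invisible(file)
}
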