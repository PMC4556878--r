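#' Optical density from transmitted intensity
#'
#' `OD = -log10(I / I0)`, with `I` the intensity transmitted through agar
#' plus colony and `I0` the intensity through bare agar. Measurement noise
#' can push `I` above `I0`; those points would give a negative OD and are
#' clipped to zero, with the number of clipped points attached as the
#' `"n_clipped"` attribute.
#'
#' @param I transmitted intensity, arbitrary units, strictly positive.
#'   Vectorised.
#' @param I0 reference intensity of bare agar, same units, strictly
#'   positive (scalar or vector of the same length).
#' @return Optical densities (dimensionless), non-negative, with attribute
#'   `n_clipped`.
#' @examples
#' optical_density(10, 100)        # one decade of attenuation: OD = 1
#' optical_density(50, 100)        # log10(2) = 0.30103
#' @export
optical_density <- function(I, I0) {
  if (any(!is.finite(I)) || any(I <= 0) || any(!is.finite(I0)) ||
      any(I0 <= 0))
    stop("intensities must be finite and strictly positive", call. = FALSE)
  od <- -log10(I / I0)
  n_clip <- sum(od < 0)
  od <- pmax(od, 0)
  attr(od, "n_clipped") <- n_clip
  od
}

#' Biofilm height from optical density
#'
#' Under the Beer-Lambert law the optical density of the colony is
#' proportional to its thickness, `OD = h / lambda`, where the attenuation
#' length `lambda` is the thickness that produces one unit of OD. Inverting
#' gives `h = OD * lambda`.
#'
#' @param od optical density, non-negative. Vectorised.
#' @param lambda attenuation length, cm, strictly positive.
#' @return Heights in cm.
#' @examples
#' height_from_od(2.5, 0.02)   # 0.05 cm
#' @export
height_from_od <- function(od, lambda) {
  if (any(!is.finite(od)) || any(od < 0))
    stop("od must be finite and non-negative", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number", call. = FALSE)
  od * lambda
}

#' Paired transmission/height profile along a colony cross-section
#'
#' Holds aligned samples along a cut through the colony: position,
#' transmitted intensity `I`, bare-agar reference `I0`, and optionally the
#' true height `h` measured from a side view (needed to fit the attenuation
#' length). Optical density is computed on construction.
#'
#' @param position positions along the cut, cm.
#' @param I transmitted intensities, > 0.
#' @param I0 reference intensity, > 0 (scalar or per-position).
#' @param h optional true heights, cm, >= 0.
#' @return An object of class `calibration_profile` (a data frame with
#'   columns `position`, `I`, `I0`, `od`, and `h` when supplied; attribute
#'   `n_clipped` counts OD values clipped at zero).
#' @seealso [fit_attenuation_length()], [synthesize_profile()],
#'   [read_profile()]
#' @export
calibration_profile <- function(position, I, I0, h = NULL) {
  n <- length(position)
  if (length(I0) == 1L) I0 <- rep(I0, n)
  if (length(I) != n || length(I0) != n)
    stop("position, I and I0 must have equal length", call. = FALSE)
  if (!is.null(h)) {
    if (length(h) != n) stop("h must match position in length", call. = FALSE)
    if (any(!is.finite(h)) || any(h < 0))
      stop("heights must be finite and non-negative", call. = FALSE)
  }
  od <- optical_density(I, I0)
  df <- data.frame(position = position, I = I, I0 = I0,
                   od = as.numeric(od))
  if (!is.null(h)) df$h <- h
  structure(df, class = c("calibration_profile", "data.frame"),
            n_clipped = attr(od, "n_clipped"))
}

#' @rdname calibration_profile
#' @param file path for tab-separated profile text (columns `position`,
#'   `I`, `I0`, optional `h`).
#' @export
read_profile <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  need <- c("position", "I", "I0")
  if (!all(need %in% names(df)))
    stop("profile file must have columns position, I, I0", call. = FALSE)
  calibration_profile(df$position, df$I, df$I0,
                      h = if ("h" %in% names(df)) df$h else NULL)
}

#' @rdname calibration_profile
#' @param profile a `calibration_profile`.
#' @export
write_profile <- function(profile, file) {
  stopifnot(inherits(profile, "calibration_profile"))
  cols <- intersect(c("position", "I", "I0", "h"), names(profile))
  utils::write.table(as.data.frame(profile)[, cols], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Fit the attenuation length from a paired profile
#'
#' Least squares through the origin of side-view height on top-view optical
#' density: `lambda` minimises `sum((h_i - od_i * lambda)^2)`, with the
#' closed-form solution `lambda = sum(od * h) / sum(od^2)`. The fit has no
#' intercept because zero optical density must correspond to zero height.
#' Points with zero OD carry no information about `lambda` and only
#' contribute to the residual through their measured height.
#'
#' @param profile a [calibration_profile()] carrying true heights `h`.
#' @return An object of class `attenuation_fit` with elements `lambda`
#'   (cm), `rms` (residual root-mean-square height, cm), `n` (points with
#'   OD > 0), and the profile. Supports `coef()`, `fitted()`,
#'   `residuals()`, and `predict(fit, newdata)` where `newdata` is an OD
#'   vector or a `calibration_profile`.
#' @examples
#' pr <- synthesize_profile(lambda = 0.02, noise_level = 0, seed = 1)
#' fit <- fit_attenuation_length(pr)
#' coef(fit)
#' @export
fit_attenuation_length <- function(profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  if (is.null(profile$h))
    stop("profile must carry true heights (h) to fit lambda", call. = FALSE)
  use <- profile$od > 0
  if (!any(use))
    stop("all optical densities are zero: lambda is unidentifiable",
         call. = FALSE)
  od <- profile$od
  h <- profile$h
  lambda <- sum(od[use] * h[use]) / sum(od[use]^2)
  resid <- h - od * lambda
  structure(list(lambda = lambda, rms = sqrt(mean(resid^2)),
                 n = sum(use), profile = profile),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("Beer-Lambert attenuation fit: lambda = %.6g cm (%d points, residual RMS %.3g cm)\n",
              x$lambda, x$n, x$rms))
  invisible(x)
}

#' @export
coef.attenuation_fit <- function(object, ...) c(lambda = object$lambda)

#' @export
fitted.attenuation_fit <- function(object, ...)
  object$profile$od * object$lambda

#' @export
residuals.attenuation_fit <- function(object, ...)
  object$profile$h - fitted(object)

#' @export
predict.attenuation_fit <- function(object, newdata = NULL, ...) {
  od <- if (is.null(newdata)) object$profile$od
        else if (inherits(newdata, "calibration_profile")) newdata$od
        else as.numeric(newdata)
  height_from_od(od, object$lambda)
}

#' Generate a synthetic transmission/height profile
#'
#' Forward-models the imaging geometry used to calibrate colony thickness:
#' a known height field is converted to transmitted intensity via
#' `I = I0 * 10^(-h / lambda)`, optionally degraded with multiplicative
#' log-normal intensity noise, and stored together with the true heights.
#' The built-in height fields are a flat slab, a smooth dome, and a plateau
#' with a raised rim — the "coffee ring" left when the inoculation drop
#' dries at its perimeter.
#'
#' @param shape `"plateau_rim"`, `"flat"`, or `"dome"`; alternatively pass
#'   explicit `heights`.
#' @param n number of sample positions along the cut.
#' @param width profile width, cm.
#' @param h0 characteristic height, cm.
#' @param lambda attenuation length used in the forward model, cm.
#' @param noise_level standard deviation of the multiplicative log-normal
#'   intensity noise (0.05 = 5% noise); 0 gives a noise-free profile.
#' @param seed integer seed making the noise reproducible; the global RNG
#'   state is left untouched.
#' @param I0 reference intensity.
#' @param heights optional explicit height field, cm (overrides `shape`).
#' @return A [calibration_profile()] carrying the true heights.
#' @examples
#' pr <- synthesize_profile("plateau_rim", n = 200, lambda = 0.02,
#'                          noise_level = 0.05, seed = 42)
#' fit_attenuation_length(pr)
#' @export
synthesize_profile <- function(shape = c("plateau_rim", "flat", "dome"),
                               n = 200L, width = 1, h0 = 0.04,
                               lambda = 0.02, noise_level = 0, seed = 1L,
                               I0 = 1000, heights = NULL) {
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (is.null(heights)) {
    shape <- match.arg(shape)
    x <- seq(0, width, length.out = n)
    u <- x / width
    heights <- switch(shape,
      flat = rep(h0, n),
      dome = h0 * sin(pi * u)^2,
      # central plateau with a raised rim on either side of the colony
      plateau_rim = {
        rim <- 0.6 * h0 * (exp(-((u - 0.12) / 0.05)^2) +
                           exp(-((u - 0.88) / 0.05)^2))
        body <- h0 * (u > 0.08 & u < 0.92)
        body + rim
      })
  } else {
    if (any(!is.finite(heights)) || any(heights < 0))
      stop("heights must be finite and non-negative", call. = FALSE)
    n <- length(heights)
    x <- seq(0, width, length.out = n)
  }
  I <- I0 * 10^(-heights / lambda)
  if (noise_level > 0) {
    noise <- with_local_seed(seed, stats::rnorm(n, 0, noise_level))
    I <- I * exp(noise)
  }
  calibration_profile(x, I, I0, h = heights)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
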