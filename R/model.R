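#' Monod saturation factor
#'
#' The dimensionless Monod factor `S / (K + S)` that scales the maximum
#' specific uptake rate by nutrient availability. It is zero at zero
#' substrate, one half at the half-saturation constant `K`, and approaches
#' (never reaches) one at saturating substrate.
#'
#' @param S nutrient concentration, mg cm^-3; non-negative. Vectorised.
#' @param K half-saturation constant, mg cm^-3; strictly positive.
#' @return The factor `S/(K+S)` in `[0, 1)`, monotone increasing in `S`.
#' @examples
#' monod(0, 1e-4)       # 0: no substrate
#' monod(1e-4, 1e-4)    # 0.5: half saturation
#' monod(15, 1e-4)      # ~1: saturating
#' @export
monod <- function(S, K) {
  if (any(!is.finite(S)) || any(S < 0))
    stop("S must be finite and non-negative", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single positive number", call. = FALSE)
  S / (K + S)
}

#' Time derivatives of the biofilm growth model
#'
#' Evaluates the right-hand side of the reduced four-variable system: the
#' active-fraction balance with logistic crowding against the non-water
#' volume `1 - eps_a`, the moving-boundary thickness equation, the in-film
#' nutrient balance (Fickian supply across the laminar sublayer minus Monod
#' consumption and growth dilution), and the agar reservoir drawdown.
#'
#' \deqn{df/dt = Y V_T \mu f (1 - f/(1-\epsilon_a)) - b f}
#' \deqn{dL/dt = f L Y V_T \mu / (1-\epsilon_a)}
#' \deqn{dS/dt = \frac{D}{L_a L}(S_a - S) - V_T \mu (\rho f + S Y f/(1-\epsilon_a))}
#' \deqn{dS_a/dt = -\sigma D (S_a - S) / (L_a V_a)}
#'
#' with \eqn{\mu = S/(K+S)} the Monod factor. `L = 0` is singular (the
#' in-film balance divides by `L`) and raises an error.
#'
#' @param state a [biofilm_state()].
#' @param params a [biofilm_params()].
#' @return Named numeric vector of derivatives `c(f=, L=, S=, S_a=)`, each
#'   in per-day units of its variable.
#' @examples
#' biofilm_rhs(biofilm_state(), biofilm_params())
#' @export
biofilm_rhs <- function(state, params) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(params, "biofilm_params"))
  check_state_params(state, params)
  if (state$L <= 0)
    stop("singular state: L must be strictly positive", call. = FALSE)
  d <- rhs_core(c(f = state$f, L = state$L, S = state$S, S_a = state$S_a),
                params)
  d
}

# Unclassed fast path shared by biofilm_rhs() and the integrator.
# y = c(f, L, S, S_a). Concentrations are floored at 0 inside the kinetic
# terms so that solver overshoot near depletion cannot feed negative
# substrate into the Monod factor or reverse the diffusive flux sign.
rhs_core <- function(y, p) {
  f <- y[[1L]]; L <- y[[2L]]
  S <- max(y[[3L]], 0); S_a <- max(y[[4L]], 0)
  phi <- 1 - p$eps_a
  mu <- S / (p$K + S)
  grad <- S_a - S
  c(f   = p$Y * p$V_T * mu * f * (1 - f / phi) - p$b * f,
    L   = f * L * p$Y * p$V_T * mu / phi,
    S   = (p$D / (p$L_a * L)) * grad -
          p$V_T * mu * (p$rho * f + S * p$Y * f / phi),
    S_a = -p$sigma * p$D * grad / (p$L_a * p$V_a))
}

#' Total nutrient-equivalent mass (a conserved first integral)
#'
#' The nutrient mass still in the agar, plus the nutrient dissolved in the
#' film, plus the nutrient equivalent of all biomass ever built
#' (`rho * sigma * (1-eps_a) * L / Y`). Along any exact solution of the
#' model this sum is constant: diffusion moves nutrient between the two
#' pools without loss, and consumption converts it to biomass at yield `Y`.
#' Numerical drift of this invariant is the package's primary integration
#' diagnostic.
#'
#' @param state a [biofilm_state()].
#' @param params a [biofilm_params()].
#' @return Total mass in mg: `S_a*V_a + S*sigma*L + rho*sigma*(1-eps_a)*L/Y`.
#' @examples
#' conserved_nutrient_mass(biofilm_state(), biofilm_params())
#' @export
conserved_nutrient_mass <- function(state, params) {
  stopifnot(inherits(state, "biofilm_state"),
            inherits(params, "biofilm_params"))
  with(c(unclass(state), unclass(params)),
       S_a * V_a + S * sigma * L + rho * sigma * (1 - eps_a) * L / Y)
}

#' Quasi-steady active fraction under abundant nutrient
#'
#' While substrate is saturating (`S >> K`), the active-fraction balance
#' decouples into a logistic equation whose positive equilibrium is
#' `(1 - eps_a) * (1 - b / (Y * V_T))`. This closed form is the ceiling the
#' simulated active fraction approaches during the nutrient-rich phase, and
#' an analytic upper bound for the trajectory peak.
#'
#' @param params a [biofilm_params()] with `Y * V_T > b` (otherwise active
#'   biomass only decays and no positive equilibrium exists).
#' @return The equilibrium active fraction, dimensionless.
#' @examples
#' quasi_steady_active_fraction(biofilm_params())   # ~0.1923
#' @export
quasi_steady_active_fraction <- function(params) {
  stopifnot(inherits(params, "biofilm_params"))
  if (params$Y * params$V_T <= params$b)
    stop("Y * V_T must exceed b: otherwise active biomass only decays",
         call. = FALSE)
  (1 - params$eps_a) * (1 - params$b / (params$Y * params$V_T))
}

#' Asymptotic biofilm thickness from nutrient-mass conservation
#'
#' If the film eventually exhausts all nutrient, conservation of the
#' nutrient-equivalent mass fixes the final thickness in closed form,
#' independent of the kinetics:
#' `L_inf = L(0) + Y * (S_a(0)*V_a + S(0)*sigma*L(0)) / (rho*sigma*(1-eps_a))`.
#' The simulated thickness approaches this value from below.
#'
#' @param params a [biofilm_params()].
#' @param init a [biofilm_state()] initial condition.
#' @return Predicted final thickness, cm.
#' @examples
#' predicted_final_thickness(biofilm_params(), biofilm_state())   # ~0.0626
#' @export
predicted_final_thickness <- function(params, init) {
  stopifnot(inherits(params, "biofilm_params"),
            inherits(init, "biofilm_state"))
  nutrient0 <- init$S_a * params$V_a + init$S * params$sigma * init$L
  init$L + params$Y * nutrient0 /
    (params$rho * params$sigma * (1 - params$eps_a))
}
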