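#' Hill-type muscle parameters
#'
#' Constructs the parameter set of a smooth, continuously differentiable
#' Hill-type muscle with first-order activation dynamics, fiber damping, and
#' either a rigid or a compliant (elastic) tendon. The characteristic-curve
#' constants default to a widely used smooth parameterization: a Gaussian
#' active force-length curve, an exponential passive force-length curve, a
#' log-based force-velocity curve, and an exponential tendon force-length
#' curve.
#'
#' @param f_iso maximum isometric force (N); must be positive.
#' @param l_opt optimal fiber length (m); must be positive.
#' @param l_slack tendon slack length (m); non-negative.
#' @param v_max maximum shortening velocity (optimal fiber lengths per
#'   second).
#' @param alpha_opt pennation angle at optimal fiber length (rad), in
#'   `[0, pi/2)`.
#' @param beta normalized fiber damping coefficient (dimensionless).
#' @param tau_act,tau_deact activation and deactivation time constants (s);
#'   `tau_act < tau_deact`.
#' @param rigid_tendon logical; if `TRUE` the tendon is inextensible and the
#'   muscle adds no extra state beyond activation.
#' @param curves named list overriding individual curve constants:
#'   `c1, c2, c3, kT` (tendon), `kpe, e0` (passive), `gamma_fl` (active
#'   force-length Gaussian width), `d1, d2, d3, d4` (force-velocity),
#'   `f_pass_scale` (multiplier on the passive curve; 0 disables passive
#'   fiber force, as some studies do for strongly stretched fixtures).
#' @return an object of class `muscle_params`.
#' @export
muscle_params <- function(f_iso, l_opt, l_slack,
                          v_max = 10, alpha_opt = 0, beta = 0.1,
                          tau_act = 0.015, tau_deact = 0.060,
                          rigid_tendon = TRUE, curves = list()) {
  stopifnot(f_iso > 0, l_opt > 0, l_slack >= 0,
            alpha_opt >= 0, alpha_opt < pi / 2,
            tau_act > 0, tau_deact > 0, tau_act < tau_deact,
            v_max > 0, beta >= 0)
  cc <- list(c1 = 0.200, c2 = 0.995, c3 = 0.250, kT = 35,
             kpe = 4, e0 = 0.6, gamma_fl = 0.45,
             d1 = -0.318, d2 = -8.149, d3 = -0.374, d4 = 0.886,
             f_pass_scale = 1)
  bad <- setdiff(names(curves), names(cc))
  if (length(bad)) stop("unknown curve constants: ", paste(bad, collapse = ", "))
  cc[names(curves)] <- curves
  structure(list(f_iso = f_iso, l_opt = l_opt, l_slack = l_slack,
                 v_max = v_max, alpha_opt = alpha_opt, beta = beta,
                 tau_act = tau_act, tau_deact = tau_deact,
                 rigid_tendon = rigid_tendon, curves = cc),
            class = "muscle_params")
}

#' Activation dynamics derivative
#'
#' First-order excitation-to-activation dynamics with asymmetric time
#' constants, smoothed with a tanh switch so the derivative is continuously
#' differentiable in both arguments:
#' \deqn{\dot a = \left[\frac{f + 1/2}{\tau_{act}(0.5 + 1.5a)} +
#'   \frac{(1/2 - f)(0.5 + 1.5a)}{\tau_{deact}}\right](e - a),\quad
#'   f = \tfrac12\tanh(b(e - a)),\ b = 0.1.}
#'
#' Vectorized over `e` and `a`.
#'
#' @param e excitation (dimensionless, nominally in `[0, 1]`).
#' @param a activation.
#' @param params a [muscle_params()] object.
#' @return `da/dt` in 1/s.
#' @export
activation_derivative <- function(e, a, params) {
  f <- 0.5 * tanh(0.1 * (e - a))
  ((f + 0.5) / (params$tau_act * (0.5 + 1.5 * a)) +
     (0.5 - f) * (0.5 + 1.5 * a) / params$tau_deact) * (e - a)
}

#' Muscle characteristic curves
#'
#' Evaluates the normalized active force-length, passive force-length,
#' force-velocity, and tendon force-length curves. All inputs may be vectors
#' (recycled); the tendon curve is returned raw (it is slightly negative at
#' the slack length); see [tendon_force_length()] for the smoothly floored
#' version used when forward-evaluating tendon force.
#'
#' @param lm_tilde normalized fiber length `l_M / l_opt`.
#' @param vm_tilde normalized fiber velocity `v_M / (l_opt v_max)`, negative
#'   shortening.
#' @param lt_tilde normalized tendon length `l_T / l_slack`.
#' @param params a [muscle_params()] object.
#' @return list with components `f_act`, `f_pass`, `f_v`, `f_t`.
#' @export
muscle_curves <- function(lm_tilde, vm_tilde, lt_tilde, params) {
  cc <- params$curves
  f_act <- exp(-(lm_tilde - 1)^2 / cc$gamma_fl)
  f_pass <- cc$f_pass_scale *
    (exp(cc$kpe * (lm_tilde - 1) / cc$e0) - 1) / (exp(cc$kpe) - 1)
  s <- cc$d2 * vm_tilde + cc$d3
  f_v <- cc$d1 * log(s + sqrt(s^2 + 1)) + cc$d4
  f_t <- cc$c1 * exp(cc$kT * (lt_tilde - cc$c2)) - cc$c3
  list(f_act = f_act, f_pass = f_pass, f_v = f_v, f_t = f_t)
}

#' Tendon force-length curve with smooth floor
#'
#' The raw exponential tendon curve is slightly negative at the slack length
#' (about -0.012 at `lt_tilde = 1`). To avoid non-physical compressive tendon
#' force the curve is floored at zero through a softplus with sharpness 100.
#'
#' @inheritParams muscle_curves
#' @param floor logical; apply the softplus floor (default `TRUE`).
#' @return normalized tendon force.
#' @export
tendon_force_length <- function(lt_tilde, params, floor = TRUE) {
  cc <- params$curves
  f <- cc$c1 * exp(cc$kT * (lt_tilde - cc$c2)) - cc$c3
  # overflow-safe softplus: log1p(exp(100 f))/100 = max(f, 0) + log1p(exp(-100 |f|))/100
  if (floor) pmax(f, 0) + log1p(exp(-100 * abs(f))) / 100 else f
}

#' Inverse tendon force-length curve
#'
#' Inverts the raw exponential tendon curve:
#' `lt_tilde = c2 + log((f_t + c3)/c1) / kT`. Requires `f_t > -c3`.
#'
#' @param f_t normalized tendon force.
#' @param params a [muscle_params()] object.
#' @param muscle_name optional name used in error messages.
#' @export
tendon_length_from_force <- function(f_t, params, muscle_name = "muscle") {
  cc <- params$curves
  if (any(Re(f_t) <= -cc$c3))
    stop("tendon curve inversion domain violation (f_t <= -c3) for ", muscle_name)
  cc$c2 + log((f_t + cc$c3) / cc$c1) / cc$kT
}

#' Rigid-tendon fiber kinematics
#'
#' With an inextensible tendon the fiber state follows from the path length
#' alone, under the constant-thickness pennation model
#' `l_M sin(alpha) = l_opt sin(alpha_opt)`:
#' \deqn{l_M = \sqrt{(l_{MT} - l_{T,slack})^2 + (l_{opt}\sin\alpha_{opt})^2}.}
#' The fiber velocity is the path velocity projected along the fiber.
#'
#' Vectorized over `l_mt` and `v_mt`.
#'
#' @param l_mt musculotendon path length (m).
#' @param v_mt musculotendon lengthening velocity (m/s).
#' @param params a [muscle_params()] object.
#' @param smooth apply a smooth softplus floor (width `0.02 l_opt`) to the
#'   fiber projection instead of raising an error for non-physical
#'   geometry. Used internally so the transcribed dynamics stay smooth and
#'   defined over the whole variable-bound box that the solver explores.
#' @return list with `lm_tilde`, `vm_tilde` (normalized by `l_opt * v_max`),
#'   and `cos_alpha`.
#' @export
rigid_tendon_kinematics <- function(l_mt, v_mt, params, smooth = FALSE) {
  proj <- l_mt - params$l_slack
  if (smooth) {
    eps <- 0.02 * params$l_opt
    proj <- 0.5 * (proj + sqrt(proj^2 + eps^2))
  } else if (any(Re(proj) <= 0))
    stop("non-physical rigid-tendon geometry: path length ",
         format(min(Re(l_mt))), " does not exceed the tendon slack length")
  h <- params$l_opt * sin(params$alpha_opt)
  l_m <- sqrt(proj^2 + h^2)
  cos_alpha <- proj / l_m
  # d l_M/dt = cos(alpha) * v_MT under constant fiber thickness
  v_m <- cos_alpha * v_mt
  list(lm_tilde = l_m / params$l_opt,
       vm_tilde = v_m / (params$l_opt * params$v_max),
       cos_alpha = cos_alpha)
}

# Fiber kinematics for a compliant tendon given the normalized tendon force
# state and its time derivative. Tendon length follows from inverting the
# tendon curve; tendon velocity from the chain rule through that curve.
compliant_fiber_kinematics <- function(ft_tilde, dft_dt, l_mt, v_mt, params,
                                       muscle_name = "muscle") {
  cc <- params$curves
  lt_tilde <- tendon_length_from_force(ft_tilde, params, muscle_name)
  l_t <- lt_tilde * params$l_slack
  # d lt/d ft of the raw curve inverse
  dlt_dft <- params$l_slack / (cc$kT * (ft_tilde + cc$c3))
  v_t <- dlt_dft * dft_dt
  proj <- l_mt - l_t
  h <- params$l_opt * sin(params$alpha_opt)
  l_m <- sqrt(proj^2 + h^2)
  cos_alpha <- proj / l_m
  v_m <- cos_alpha * (v_mt - v_t)
  list(lm_tilde = l_m / params$l_opt,
       vm_tilde = v_m / (params$l_opt * params$v_max),
       cos_alpha = cos_alpha)
}

#' Tendon equilibrium residual for a compliant tendon
#'
#' For a muscle with an elastic tendon the normalized tendon force is a state
#' and fiber-tendon force balance is enforced as an algebraic path residual:
#' \deqn{r = \tilde f_T - \cos\alpha\,(a f_{act}(\tilde l_M) f_v(\tilde v_M) +
#'   f_{pass}(\tilde l_M) + \beta \tilde v_M).}
#' The fiber state is reconstructed from `ft_tilde` and its derivative by
#' inverting the tendon curve. Zero residual is fiber-tendon equilibrium.
#'
#' Vectorized over all trajectory arguments.
#'
#' @param a activation.
#' @param l_mt,v_mt musculotendon length (m) and velocity (m/s).
#' @param ft_tilde normalized tendon force state (> `-c3`).
#' @param dft_dt time derivative of `ft_tilde` (1/s).
#' @param params a [muscle_params()] object.
#' @param muscle_name optional name for error messages.
#' @return residual in normalized force units.
#' @export
tendon_equilibrium_residual <- function(a, l_mt, v_mt, ft_tilde, dft_dt,
                                        params, muscle_name = "muscle") {
  fk <- compliant_fiber_kinematics(ft_tilde, dft_dt, l_mt, v_mt, params,
                                   muscle_name)
  cv <- muscle_curves(fk$lm_tilde, fk$vm_tilde, 1, params)
  ft_tilde - fk$cos_alpha *
    (a * cv$f_act * cv$f_v + cv$f_pass + params$beta * fk$vm_tilde)
}

#' Tendon force along the muscle path
#'
#' Rigid tendon: `F = f_iso * cos(alpha) * (a f_act f_v + f_pass + beta vM)`.
#' Compliant tendon: `F = f_iso * ft_tilde` (the tendon transmits the path
#' force by definition of the normalized tendon-force state).
#'
#' @param a activation.
#' @param l_mt,v_mt path length (m) and lengthening velocity (m/s).
#' @param params a [muscle_params()] object.
#' @param ft_tilde normalized tendon force state (compliant tendon only).
#' @param smooth see [rigid_tendon_kinematics()].
#' @return force in N, positive pulling the attachment points together.
#' @export
tendon_force <- function(a, l_mt, v_mt, params, ft_tilde = NULL,
                         smooth = FALSE) {
  if (params$rigid_tendon) {
    fk <- rigid_tendon_kinematics(l_mt, v_mt, params, smooth = smooth)
    cv <- muscle_curves(fk$lm_tilde, fk$vm_tilde, 1, params)
    params$f_iso * fk$cos_alpha *
      (a * cv$f_act * cv$f_v + cv$f_pass + params$beta * fk$vm_tilde)
  } else {
    if (is.null(ft_tilde))
      stop("compliant-tendon muscle requires the normalized tendon force state")
    params$f_iso * ft_tilde
  }
}

# Root-solve the tendon equilibrium residual for ft_tilde at fixed
# (a, l_mt, v_mt) with dft_dt = 0. Used to initialize compliant-tendon
# states; with beta > 0 the residual is strictly monotone in ft_tilde so the
# root is unique.
solve_tendon_equilibrium <- function(a, l_mt, v_mt, params,
                                     lower = -0.24, upper = 5) {
  f <- function(ft) tendon_equilibrium_residual(a, l_mt, v_mt, ft, 0, params)
  stats::uniroot(f, lower = lower + 1e-9, upper = upper,
                 tol = 1e-12, extendInt = "upX")$root
}
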