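# ---------------------------------------------------------------------------
# Continuous optimal-control problem definition.
# ---------------------------------------------------------------------------

#' Define an optimal-control problem
#'
#' Creates a continuous optimal-control problem over a model: a time horizon
#' (fixed or free final time), state and control bounds, goals (cost terms),
#' boundary constraints, path constraints, and free model parameters.
#'
#' For a multibody model the state vector is ordered q-block, u-block,
#' activation-block, tendon-force-block and the control vector is (muscle
#' excitations, coordinate-actuator controls); defaults are taken from the
#' model (coordinate/speed ranges, activations and excitations in
#' `[0.01, 1]`, normalized tendon force in `[0, 1.8]`).
#'
#' Alternatively `dynamics` supplies custom explicit dynamics
#' `f(t, X, U, params)` (vectorized over rows of the state matrix `X` and
#' control matrix `U`) with `states`/`controls` data frames declaring names
#' and bounds — used for benchmark problems that are not muscle-driven.
#'
#' @param model an [mbs_model()], or `NULL` with custom `dynamics`.
#' @param t0 initial time (fixed, default 0).
#' @param tf final time: a scalar for a fixed horizon or `c(lower, upper)`
#'   for a free final time.
#' @param dynamics optional custom dynamics function.
#' @param states,controls for custom dynamics: data frames with columns
#'   `name, lower, upper` (optional `initial_lower`, `initial_upper`,
#'   `final_lower`, `final_upper`).
#' @return object of class `ocp`.
#' @export
ocp <- function(model = NULL, t0 = 0, tf, dynamics = NULL,
                states = NULL, controls = NULL) {
  if (is.null(model) && is.null(dynamics))
    stop("either a model or custom dynamics must be supplied")
  tf_range <- if (length(tf) == 1) c(tf, tf) else as.numeric(tf)
  if (tf_range[2] < tf_range[1]) stop("tf bounds must be ordered")
  if (tf_range[1] <= t0) stop("tf must exceed t0")
  pad <- function(df) {
    for (cn in c("initial_lower", "initial_upper", "final_lower",
                 "final_upper"))
      if (is.null(df[[cn]]))
        df[[cn]] <- if (grepl("lower", cn)) df$lower else df$upper
    df
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "mbs_model"))
    validate_model(model)
    sl <- model_state_layout(model)
    cd <- model_coords(model)
    states <- data.frame(
      name = sl$names,
      lower = c(cd$lower, cd$speed_lower, rep(0.01, sl$na), rep(0, sl$nft)),
      upper = c(cd$upper, cd$speed_upper, rep(1, sl$na), rep(1.8, sl$nft)),
      stringsAsFactors = FALSE)
    cl <- model_control_layout(model)
    arange <- if (cl$nact)
      t(vapply(model$actuators, `[[`, numeric(2), "control_range"))
    else matrix(0, 0, 2)
    controls <- data.frame(
      name = cl$names,
      lower = c(rep(0.01, cl$ne), arange[, 1]),
      upper = c(rep(1, cl$ne), arange[, 2]),
      stringsAsFactors = FALSE)
  } else {
    states <- as.data.frame(states); controls <- as.data.frame(controls)
  }
  structure(list(model = model, t0 = t0, tf_range = tf_range,
                 states = pad(states), controls = pad(controls),
                 dynamics = dynamics,
                 goals = list(), boundary = list(), path = list(),
                 parameters = list()),
            class = "ocp")
}

#' @export
print.ocp <- function(x, ...) {
  cat("Optimal-control problem:", nrow(x$states), "states,",
      nrow(x$controls), "controls, t in [", x$t0, ",",
      if (x$tf_range[1] == x$tf_range[2]) x$tf_range[1] else
        paste0("[", x$tf_range[1], ", ", x$tf_range[2], "]"), "]\n")
  cat("Goals:", if (length(x$goals))
    paste(vapply(x$goals, `[[`, "", "kind"), collapse = ", ") else "none",
    "\n")
  cat(length(x$boundary), "boundary constraints;", length(x$path),
      "path constraints;", length(x$parameters), "free parameters\n")
  invisible(x)
}

#' Set bounds on a state
#'
#' @param problem an [ocp()].
#' @param name state name.
#' @param range,initial,final each `c(lower, upper)` or a scalar to pin the
#'   value; `NULL` leaves the current setting.
#' @export
set_state_info <- function(problem, name, range = NULL, initial = NULL,
                           final = NULL) {
  i <- match(name, problem$states$name)
  if (is.na(i)) stop("unknown state '", name, "'")
  as2 <- function(v) if (length(v) == 1) c(v, v) else as.numeric(v)
  if (!is.null(range)) {
    r <- as2(range)
    problem$states$lower[i] <- r[1]; problem$states$upper[i] <- r[2]
    problem$states$initial_lower[i] <- r[1]; problem$states$initial_upper[i] <- r[2]
    problem$states$final_lower[i] <- r[1]; problem$states$final_upper[i] <- r[2]
  }
  if (!is.null(initial)) {
    r <- as2(initial)
    problem$states$initial_lower[i] <- r[1]
    problem$states$initial_upper[i] <- r[2]
  }
  if (!is.null(final)) {
    r <- as2(final)
    problem$states$final_lower[i] <- r[1]
    problem$states$final_upper[i] <- r[2]
  }
  problem
}

#' Set bounds on a control
#'
#' @param problem an [ocp()].
#' @param name control name.
#' @param range `c(lower, upper)`.
#' @export
set_control_info <- function(problem, name, range) {
  i <- match(name, problem$controls$name)
  if (is.na(i)) stop("unknown control '", name, "'")
  problem$controls$lower[i] <- range[1]
  problem$controls$upper[i] <- range[2]
  problem
}

# --- goals ------------------------------------------------------------------

#' Goal constructors
#'
#' Goals are weighted cost terms. `goal_control_effort` integrates
#' `sum_i w_i |c_i|^p` over the model controls (default exponent 2, not
#' normalized by duration unless requested). `goal_state_tracking`
#' integrates `sum_s w_s (x_s - ref_s(t))^2` against a reference trajectory
#' (cubic interpolation through its samples; extrapolation is an error).
#' `goal_final_time` adds `weight * t_f`. `goal_joint_reaction` integrates
#' the squared norm of the reaction force at a joint.
#'
#' @param weight goal weight (>= 0).
#' @param exponent effort exponent (>= 1).
#' @param weights named per-channel weights (default 1 for every channel).
#' @param divide_by_duration normalize the effort integral by the duration.
#' @param reference an `oc_trajectory` whose states carry the tracked
#'   channels (matched by name).
#' @param body body whose parent-joint reaction is minimized
#'   (`goal_joint_reaction`).
#' @param name goal name used in the per-goal breakdown.
#' @return a goal specification for [add_goal()].
#' @export
goal_control_effort <- function(weight = 1, exponent = 2, weights = NULL,
                                divide_by_duration = FALSE,
                                name = "control_effort") {
  stopifnot(weight >= 0, exponent >= 1)
  list(kind = "control_effort", weight = weight, exponent = exponent,
       weights = weights, divide_by_duration = divide_by_duration,
       name = name)
}

#' @rdname goal_control_effort
#' @export
goal_state_tracking <- function(reference, weight = 1, weights = NULL,
                                name = "state_tracking") {
  stopifnot(weight >= 0, inherits(reference, "oc_trajectory"))
  list(kind = "state_tracking", weight = weight, reference = reference,
       weights = weights, name = name)
}

#' @rdname goal_control_effort
#' @export
goal_final_time <- function(weight = 1, name = "final_time") {
  stopifnot(weight >= 0)
  list(kind = "final_time", weight = weight, name = name)
}

#' @rdname goal_control_effort
#' @export
goal_joint_reaction <- function(body, weight = 1, name = "joint_reaction") {
  stopifnot(weight >= 0)
  list(kind = "joint_reaction", weight = weight, body = body, name = name)
}

#' Add a goal to a problem
#'
#' @param problem an [ocp()].
#' @param goal a goal specification (see [goal_control_effort()]).
#' @export
add_goal <- function(problem, goal) {
  stopifnot(inherits(problem, "ocp"), is.list(goal), goal$weight >= 0)
  nm <- goal$name
  k <- 1
  while (nm %in% names(problem$goals)) { nm <- paste0(goal$name, k); k <- k + 1 }
  problem$goals[[nm]] <- goal
  problem
}

# --- boundary constraints ---------------------------------------------------

#' Add a boundary constraint
#'
#' `type = "periodicity"` enforces `x_i(t_f) - sigma * x_j(t0) = 0` for each
#' pairing (with `sigma = -1` expressing symmetry/sign-flipped pairings).
#' `type = "average_speed"` enforces
#' `(x(t_f) - x(t0)) / (t_f - t0) - v_target = 0` on a position state.
#'
#' @param problem an [ocp()].
#' @param type `"periodicity"` or `"average_speed"`.
#' @param pairs list of pairings `list(final = <state>, initial = <state>,
#'   sigma = +-1)` (periodicity).
#' @param state position state name (average speed).
#' @param v_target target average speed.
#' @export
add_boundary_constraint <- function(problem,
                                    type = c("periodicity", "average_speed"),
                                    pairs = NULL, state = NULL,
                                    v_target = NULL) {
  type <- match.arg(type)
  if (type == "periodicity") {
    for (p in pairs)
      if (!all(c(p$final, p$initial) %in% problem$states$name))
        stop("periodicity pairing references missing states: ",
             p$final, ", ", p$initial)
    problem$boundary[[length(problem$boundary) + 1]] <-
      list(type = type, pairs = pairs)
  } else {
    if (!state %in% problem$states$name)
      stop("average-speed constraint references missing state '", state, "'")
    problem$boundary[[length(problem$boundary) + 1]] <-
      list(type = type, state = state, v_target = v_target)
  }
  problem
}

# --- path constraints -------------------------------------------------------

#' Add a path constraint
#'
#' `type = "control_bound"` restricts a control between time-varying bounds
#' (e.g. an envelope around a measured excitation); enforced at every
#' collocation point. `type = "custom"` adds user equality residuals
#' `fn(t, X, U)` (vectorized, returning an n x k matrix) at every point.
#'
#' @param problem an [ocp()].
#' @param type `"control_bound"` or `"custom"`.
#' @param control control name (control_bound).
#' @param lower,upper bound functions of time (control_bound).
#' @param fn residual function (custom).
#' @param n_eq number of residual rows per time point (custom).
#' @export
add_path_constraint <- function(problem, type = c("control_bound", "custom"),
                                control = NULL, lower = NULL, upper = NULL,
                                fn = NULL, n_eq = 1) {
  type <- match.arg(type)
  if (type == "control_bound") {
    if (!control %in% problem$controls$name)
      stop("unknown control '", control, "'")
    stopifnot(is.function(lower), is.function(upper))
    problem$path[[length(problem$path) + 1]] <-
      list(type = type, control = control, lower = lower, upper = upper)
  } else {
    stopifnot(is.function(fn))
    problem$path[[length(problem$path) + 1]] <-
      list(type = type, fn = fn, n_eq = n_eq)
  }
  problem
}

# --- free model parameters --------------------------------------------------

#' Register a free model parameter
#'
#' Exposes a scalar model property as an optimization variable. The property
#' is addressed by a path `"<collection>/<element>/<field>"`, e.g.
#' `"springs/knee_spring/stiffness"`, `"bodies/torso/mass"`, or
#' `"muscles/vasti/f_iso"`.
#'
#' @param problem an [ocp()].
#' @param path property path.
#' @param lower,upper parameter bounds.
#' @param name variable name (defaults to the path).
#' @export
add_parameter <- function(problem, path, lower, upper, name = path) {
  if (is.null(problem$model)) stop("parameters require a multibody model")
  model_get_property(problem$model, path) # errors on unknown path
  stopifnot(lower <= upper)
  problem$parameters[[name]] <- list(path = path, lower = lower,
                                     upper = upper)
  problem
}

model_get_property <- function(model, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("parameter path must be collection/element/field")
  coll <- switch(parts[1], bodies = model$bodies, muscles = model$muscles,
                 springs = model$springs, actuators = model$actuators,
                 contacts = model$contacts,
                 stop("unknown collection '", parts[1], "'"))
  el <- coll[[parts[2]]]
  if (is.null(el)) stop("unknown element '", parts[2], "' in ", parts[1])
  v <- if (parts[1] == "muscles" && parts[3] %in% names(el$params))
    el$params[[parts[3]]] else el[[parts[3]]]
  if (is.null(v) || !is.numeric(v) || length(v) != 1)
    stop("property '", parts[3], "' of ", parts[1], "/", parts[2],
         " is not a scalar")
  v
}

model_set_property <- function(model, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (parts[1] == "muscles" &&
      parts[3] %in% names(model$muscles[[parts[2]]]$params))
    model$muscles[[parts[2]]]$params[[parts[3]]] <- value
  else
    model[[parts[1]]][[parts[2]]][[parts[3]]] <- value
  model
}

# --- validation -------------------------------------------------------------

validate_problem <- function(problem) {
  stopifnot(inherits(problem, "ocp"))
  if (!length(problem$goals)) stop("problem must declare at least one goal")
  for (g in problem$goals) {
    if (g$weight < 0) stop("goal weight must be >= 0")
    ch <- names(g$weights)
    if (!is.null(ch)) {
      pool <- c(problem$states$name, problem$controls$name)
      if (!all(ch %in% pool))
        stop("goal '", g$name, "' references unknown channels: ",
             paste(setdiff(ch, pool), collapse = ", "))
    }
  }
  with(problem$states, if (any(lower > upper | initial_lower > initial_upper |
                               final_lower > final_upper))
    stop("state bounds have lower > upper"))
  with(problem$controls, if (any(lower > upper))
    stop("control bounds have lower > upper"))
  if (problem$tf_range[1] != problem$tf_range[2] &&
      (!is.finite(problem$tf_range[2])))
    stop("free final time requires finite bounds")
  for (g in problem$goals)
    if (g$kind == "state_tracking") {
      sp <- range(g$reference$time)
      if (sp[1] > problem$t0 + 1e-9 || sp[2] < problem$tf_range[2] - 1e-9)
        stop("tracking reference span [", sp[1], ", ", sp[2],
             "] does not cover the problem horizon")
      if (problem$tf_range[1] != problem$tf_range[2])
        stop("state tracking requires a fixed time horizon")
    }
  invisible(problem)
}
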