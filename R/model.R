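#' Create a planar multibody model
#'
#' Starts an empty planar (2-D) rigid-body model rooted at an immobile ground
#' body. Bodies are added with [add_body()] as a tree of pin, slider, weld,
#' planar (x, y, rotation), or point (x, y translation) joints; forces with
#' [add_muscle()], [add_torsional_spring()], [add_coordinate_actuator()] and
#' [add_contact_sphere()]; holonomic constraints (loop closures, coordinate
#' couplers) with [add_constraint()]. SI units and radians throughout.
#'
#' @param gravity gravity vector in m/s^2 (default `c(0, -9.80665)`).
#' @return an object of class `mbs_model`.
#' @export
mbs_model <- function(gravity = c(0, -9.80665)) {
  structure(list(
    bodies = list(),
    muscles = list(),
    springs = list(),
    actuators = list(),
    contacts = list(),
    constraints = list(),
    gravity = as.numeric(gravity)
  ), class = "mbs_model")
}

joint_ncoord <- c(pin = 1L, slider = 1L, weld = 0L, planar = 3L, point = 2L)

#' Add a rigid body with its parent joint
#'
#' @param model an [mbs_model()].
#' @param name body name (unique).
#' @param mass mass in kg (> 0).
#' @param inertia rotational inertia about the mass center in kg m^2
#'   (>= 0; irrelevant for `point` joints on point masses).
#' @param parent name of the parent body (`"ground"` for the root).
#' @param joint joint type: `"pin"` (1 rotational coordinate, rad),
#'   `"slider"` (1 translational coordinate along `axis`, m), `"weld"` (no
#'   coordinate), `"planar"` (x, y, rotation), or `"point"` (x, y translation
#'   only, for point masses).
#' @param joint_parent location of the joint in the parent frame (m).
#' @param joint_child location of the joint in this body's frame (m).
#' @param axis slider translation direction in the parent frame (unit
#'   vector).
#' @param com mass-center location in this body's frame (m).
#' @param coords coordinate name(s); defaults derived from the body name.
#' @param coord_range coordinate bounds, a vector `c(lower, upper)` recycled
#'   across coordinates or a matrix with one row per coordinate.
#' @param speed_range generalized-speed bounds, same conventions.
#' @export
add_body <- function(model, name, mass, inertia = 0, parent = "ground",
                     joint = c("pin", "slider", "weld", "planar", "point"),
                     joint_parent = c(0, 0), joint_child = c(0, 0),
                     axis = c(1, 0), com = c(0, 0), coords = NULL,
                     coord_range = c(-10, 10), speed_range = c(-50, 50)) {
  joint <- match.arg(joint)
  stopifnot(inherits(model, "mbs_model"))
  if (mass <= 0) stop("body '", name, "': mass must be > 0")
  if (inertia < 0) stop("body '", name, "': inertia must be >= 0")
  if (name %in% c("ground", vapply(model$bodies, `[[`, "", "name")))
    stop("duplicate body name '", name, "'")
  if (parent != "ground" &&
      !parent %in% vapply(model$bodies, `[[`, "", "name"))
    stop("unknown parent body '", parent, "' (add bodies parent-first)")
  nc <- joint_ncoord[[joint]]
  if (is.null(coords)) {
    coords <- switch(joint, pin = paste0(name, "_angle"),
                     slider = paste0(name, "_pos"), weld = character(0),
                     planar = paste0(name, c("_x", "_y", "_angle")),
                     point = paste0(name, c("_x", "_y")))
  }
  if (length(coords) != nc)
    stop("joint '", joint, "' needs ", nc, " coordinate name(s)")
  rng <- matrix(as.numeric(coord_range), ncol = 2, nrow = max(nc, 1),
                byrow = length(coord_range) == 2)
  srng <- matrix(as.numeric(speed_range), ncol = 2, nrow = max(nc, 1),
                 byrow = length(speed_range) == 2)
  model$bodies[[name]] <- list(
    name = name, mass = mass, inertia = inertia, parent = parent,
    joint = joint, joint_parent = as.numeric(joint_parent),
    joint_child = as.numeric(joint_child),
    axis = as.numeric(axis) / sqrt(sum(axis^2)), com = as.numeric(com),
    coords = coords, coord_range = rng[seq_len(nc), , drop = FALSE],
    speed_range = srng[seq_len(nc), , drop = FALSE])
  model
}

#' Add a Hill-type muscle along a polyline path
#'
#' The path is a sequence of attachment points, each fixed in a body frame
#' (straight-line segments, optionally through via points). The muscle
#' contributes generalized forces through its moment arms
#' `r_j = -d l_MT / d q_j`.
#'
#' @param model an [mbs_model()].
#' @param name muscle name.
#' @param params a [muscle_params()] object.
#' @param path list of attachment points, each `list(body = <name>,
#'   xy = c(x, y))` in that body's frame; at least two points.
#' @export
add_muscle <- function(model, name, params, path) {
  stopifnot(inherits(model, "mbs_model"), inherits(params, "muscle_params"))
  if (length(path) < 2)
    stop("muscle '", name, "' needs at least 2 attachment points")
  known <- c("ground", vapply(model$bodies, `[[`, "", "name"))
  for (p in path)
    if (!p$body %in% known) stop("muscle '", name, "': unknown body '", p$body, "'")
  model$muscles[[name]] <- list(name = name, params = params, path = path)
  model
}

#' Add a torsional spring on a coordinate
#'
#' Applies the moment `-k (q - q0)` to the named coordinate.
#'
#' @param model an [mbs_model()].
#' @param coord coordinate name.
#' @param stiffness spring stiffness k in N m/rad (>= 0).
#' @param equilibrium equilibrium angle q0 in rad.
#' @param name spring name (defaults to `<coord>_spring`).
#' @export
add_torsional_spring <- function(model, coord, stiffness, equilibrium = 0,
                                 name = paste0(coord, "_spring")) {
  stopifnot(inherits(model, "mbs_model"))
  model$springs[[name]] <- list(name = name, coord = coord,
                                stiffness = stiffness,
                                equilibrium = equilibrium)
  model
}

#' Add an ideal coordinate actuator (torque/reserve actuator)
#'
#' An idealized actuator applying `gain * control` directly to a coordinate.
#' Used for torque-driven models and for reserve actuators in the inverse
#' tool.
#'
#' @param model an [mbs_model()].
#' @param coord coordinate name.
#' @param name actuator name.
#' @param gain force per unit control (N or N m).
#' @param control_range admissible control range.
#' @export
add_coordinate_actuator <- function(model, coord, name = paste0(coord, "_act"),
                                    gain = 1, control_range = c(-Inf, Inf)) {
  stopifnot(inherits(model, "mbs_model"))
  model$actuators[[name]] <- list(name = name, coord = coord, gain = gain,
                                  control_range = as.numeric(control_range))
  model
}

#' Add a smooth sphere-plane contact element
#'
#' A sphere fixed to a body contacts the ground half-space `y <= 0` through a
#' smooth Hertz-like normal force with velocity-dependent dissipation and a
#' regularized friction force,
#' \deqn{F_n = k_c d_s^{3/2} (1 + 1.5 c_d v_n), \quad
#'   d_s = \tfrac12 (d + \sqrt{d^2 + \epsilon^2}),}
#' \deqn{F_t = -\mu F_n \tanh(v_t / v_s),}
#' which is C1-continuous in all arguments.
#'
#' @param model an [mbs_model()].
#' @param body body carrying the sphere.
#' @param xy sphere-center location in the body frame (m).
#' @param radius sphere radius (m).
#' @param stiffness contact stiffness k_c (N/m^1.5).
#' @param dissipation dissipation coefficient c_d (s/m).
#' @param friction friction coefficient mu.
#' @param eps depth-smoothing constant (m).
#' @param v_s tangential velocity-smoothing constant (m/s).
#' @param name element name.
#' @export
add_contact_sphere <- function(model, body, xy = c(0, 0), radius,
                               stiffness = 1e5, dissipation = 2,
                               friction = 0.8, eps = 1e-4, v_s = 0.05,
                               name = paste0(body, "_contact")) {
  stopifnot(inherits(model, "mbs_model"))
  model$contacts[[name]] <- list(name = name, body = body,
                                 xy = as.numeric(xy), radius = radius,
                                 stiffness = stiffness,
                                 dissipation = dissipation,
                                 friction = friction, eps = eps, v_s = v_s)
  model
}

#' Add a holonomic kinematic constraint
#'
#' Two kinds are supported: `"point_coincidence"` forces a point on body A to
#' coincide with a point on body B (two equations, a loop closure);
#' `"coordinate_coupling"` enforces a linear relation
#' `sum(coeffs * q[coords]) - constant = 0` (one equation). Constraints are
#' enforced with Lagrange multipliers in the dynamics and at the
#' position/velocity level during transcription.
#'
#' @param model an [mbs_model()].
#' @param type `"point_coincidence"` or `"coordinate_coupling"`.
#' @param body_a,xy_a,body_b,xy_b points for a coincidence constraint.
#' @param coords,coeffs,constant linear coupling definition.
#' @param name constraint name.
#' @export
add_constraint <- function(model,
                           type = c("point_coincidence", "coordinate_coupling"),
                           body_a = NULL, xy_a = c(0, 0),
                           body_b = "ground", xy_b = c(0, 0),
                           coords = NULL, coeffs = NULL, constant = 0,
                           name = paste0("constraint", length(model$constraints) + 1)) {
  type <- match.arg(type)
  stopifnot(inherits(model, "mbs_model"))
  cn <- if (type == "point_coincidence")
    list(name = name, type = type, body_a = body_a, xy_a = as.numeric(xy_a),
         body_b = body_b, xy_b = as.numeric(xy_b), neq = 2L)
  else
    list(name = name, type = type, coords = coords,
         coeffs = as.numeric(coeffs), constant = constant, neq = 1L)
  model$constraints[[name]] <- cn
  model
}

# ---------------------------------------------------------------------------
# Derived layout tables
# ---------------------------------------------------------------------------

#' Coordinate table of a model
#'
#' @param model an [mbs_model()].
#' @return data frame with one row per generalized coordinate: name, body,
#'   unit, and bounds on the coordinate and its speed.
#' @export
model_coords <- function(model) {
  out <- list()
  for (b in model$bodies) {
    nc <- length(b$coords)
    if (!nc) next
    unit <- switch(b$joint, pin = "rad", slider = "m",
                   planar = c("m", "m", "rad"), point = c("m", "m"))
    out[[b$name]] <- data.frame(
      name = b$coords, body = b$name, unit = unit,
      lower = b$coord_range[, 1], upper = b$coord_range[, 2],
      speed_lower = b$speed_range[, 1], speed_upper = b$speed_range[, 2],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(name = character(0), body = character(0),
                      unit = character(0), lower = numeric(0),
                      upper = numeric(0), speed_lower = numeric(0),
                      speed_upper = numeric(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

n_coords <- function(model) nrow(model_coords(model))
n_constraint_eq <- function(model)
  sum(vapply(model$constraints, `[[`, 0L, "neq"))

#' Validate a model
#'
#' Checks the structural invariants: positive masses, non-negative inertias,
#' fewer constraint equations than coordinates, muscle paths with at least
#' two points and positive length over the coordinate-bound box (probed on a
#' coarse grid of admissible configurations), and known coordinate references
#' in springs, actuators, and constraints.
#'
#' @param model an [mbs_model()].
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "mbs_model"))
  cd <- model_coords(model)
  nq <- nrow(cd)
  m <- n_constraint_eq(model)
  if (nq == 0 && length(model$bodies))
    stop("model has bodies but no coordinates")
  if (m >= nq && m > 0)
    stop("number of constraint equations (", m,
         ") must be smaller than the number of coordinates (", nq, ")")
  for (s in model$springs)
    if (!s$coord %in% cd$name) stop("spring '", s$name, "': unknown coordinate")
  for (a in model$actuators)
    if (!a$coord %in% cd$name) stop("actuator '", a$name, "': unknown coordinate")
  for (cn in model$constraints) {
    if (cn$type == "coordinate_coupling") {
      if (!all(cn$coords %in% cd$name))
        stop("constraint '", cn$name, "': unknown coordinate")
      if (length(cn$coords) != length(cn$coeffs))
        stop("constraint '", cn$name, "': coords/coeffs length mismatch")
    }
  }
  if (length(model$muscles) && nq > 0) {
    # probe path length over a coarse grid of admissible q
    probes <- lapply(seq_len(nq), function(j)
      seq(cd$lower[j], cd$upper[j], length.out = 3))
    Q <- as.matrix(do.call(expand.grid, probes))
    for (mus in model$muscles) {
      L <- muscle_path_lengths(model, Q, mus)
      if (any(L <= 0))
        stop("muscle '", mus$name, "': non-positive path length within bounds")
    }
  }
  invisible(model)
}

#' @export
print.mbs_model <- function(x, ...) {
  cd <- model_coords(x)
  cat("Planar multibody model:", length(x$bodies), "bodies,",
      nrow(cd), "coordinates,", length(x$muscles), "muscles,",
      length(x$springs), "springs,", length(x$actuators), "actuators,",
      length(x$contacts), "contact elements,",
      n_constraint_eq(x), "constraint equations\n")
  if (nrow(cd)) {
    cat("Coordinates:", paste(cd$name, collapse = ", "), "\n")
  }
  cat("Gravity: (", paste(format(x$gravity), collapse = ", "), ") m/s^2\n")
  invisible(x)
}

# State layout: q-block, u-block, a-block, ftilde-block (fixed, documented
# ordering). Returns name vectors and index helpers.
model_state_layout <- function(model) {
  cd <- model_coords(model)
  mus <- model$muscles
  act_names <- if (length(mus)) paste0(names(mus), "_activation") else character(0)
  compliant <- if (length(mus))
    names(mus)[!vapply(mus, function(m) m$params$rigid_tendon, TRUE)]
  else character(0)
  ft_names <- if (length(compliant)) paste0(compliant, "_ftilde") else character(0)
  q <- cd$name; u <- paste0(cd$name, "_u")
  list(q = q, u = u, a = act_names, ft = ft_names,
       names = c(q, u, act_names, ft_names),
       nq = length(q), na = length(act_names), nft = length(ft_names),
       compliant = compliant)
}

# Control layout: muscle excitations first, then actuator controls.
model_control_layout <- function(model) {
  exc <- if (length(model$muscles))
    paste0(names(model$muscles), "_excitation") else character(0)
  act <- names(model$actuators)
  list(excitation = exc, actuator = act, names = c(exc, act),
       ne = length(exc), nact = length(act))
}
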