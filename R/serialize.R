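# ---------------------------------------------------------------------------
# Structured-text (YAML) serialization of models and study definitions.
# ---------------------------------------------------------------------------

#' Write and read model configuration files
#'
#' A model is serialized as a structured key/value document with nested
#' lists: `gravity`, `bodies` (in definition order, parent-first), `muscles`
#' (with every muscle parameter and curve constant written explicitly),
#' `springs`, `actuators`, `contacts`, and `constraints`. Reading the
#' document back reproduces the model exactly (round-trip tested).
#'
#' @param model an [mbs_model()].
#' @param path file path (conventionally `.yaml`).
#' @return `write_model_config` returns the path invisibly;
#'   `read_model_config` returns an [mbs_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "mbs_model"))
  doc <- list(
    gravity = model$gravity,
    bodies = lapply(unname(model$bodies), function(b)
      list(name = b$name, mass = b$mass, inertia = b$inertia,
           parent = b$parent, joint = b$joint,
           joint_parent = b$joint_parent, joint_child = b$joint_child,
           axis = b$axis, com = b$com, coords = as.list(b$coords),
           coord_range = as.numeric(t(b$coord_range)),
           speed_range = as.numeric(t(b$speed_range)))),
    muscles = lapply(unname(model$muscles), function(m)
      list(name = m$name,
           params = c(m$params[c("f_iso", "l_opt", "l_slack", "v_max",
                                 "alpha_opt", "beta", "tau_act",
                                 "tau_deact", "rigid_tendon")],
                      list(curves = m$params$curves)),
           path = lapply(m$path, function(p)
             list(body = p$body, xy = p$xy)))),
    springs = lapply(unname(model$springs), function(s)
      s[c("name", "coord", "stiffness", "equilibrium")]),
    actuators = lapply(unname(model$actuators), function(a)
      a[c("name", "coord", "gain", "control_range")]),
    contacts = lapply(unname(model$contacts), function(ce)
      ce[c("name", "body", "xy", "radius", "stiffness", "dissipation",
           "friction", "eps", "v_s")]),
    constraints = lapply(unname(model$constraints), function(cn)
      cn[setdiff(names(cn), "neq")]))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- yaml::read_yaml(path)
  model <- mbs_model(gravity = as.numeric(doc$gravity))
  for (b in doc$bodies) {
    nc <- max(1, length(b$coords))
    model <- add_body(model, b$name, b$mass, b$inertia, parent = b$parent,
                      joint = b$joint,
                      joint_parent = as.numeric(b$joint_parent),
                      joint_child = as.numeric(b$joint_child),
                      axis = as.numeric(b$axis), com = as.numeric(b$com),
                      coords = as.character(unlist(b$coords)),
                      coord_range = matrix(as.numeric(b$coord_range),
                                           ncol = 2, byrow = TRUE),
                      speed_range = matrix(as.numeric(b$speed_range),
                                           ncol = 2, byrow = TRUE))
  }
  for (m in doc$muscles) {
    p <- m$params
    pars <- muscle_params(f_iso = p$f_iso, l_opt = p$l_opt,
                          l_slack = p$l_slack, v_max = p$v_max,
                          alpha_opt = p$alpha_opt, beta = p$beta,
                          tau_act = p$tau_act, tau_deact = p$tau_deact,
                          rigid_tendon = p$rigid_tendon,
                          curves = p$curves)
    model <- add_muscle(model, m$name, pars,
                        lapply(m$path, function(pt)
                          list(body = pt$body, xy = as.numeric(pt$xy))))
  }
  for (s in doc$springs)
    model <- add_torsional_spring(model, s$coord, s$stiffness,
                                  s$equilibrium, name = s$name)
  for (a in doc$actuators)
    model <- add_coordinate_actuator(model, a$coord, name = a$name,
                                     gain = a$gain,
                                     control_range = as.numeric(a$control_range))
  for (ce in doc$contacts)
    model <- add_contact_sphere(model, ce$body, xy = as.numeric(ce$xy),
                                radius = ce$radius,
                                stiffness = ce$stiffness,
                                dissipation = ce$dissipation,
                                friction = ce$friction, eps = ce$eps,
                                v_s = ce$v_s, name = ce$name)
  for (cn in doc$constraints) {
    if (cn$type == "point_coincidence")
      model <- add_constraint(model, "point_coincidence",
                              body_a = cn$body_a, xy_a = as.numeric(cn$xy_a),
                              body_b = cn$body_b, xy_b = as.numeric(cn$xy_b),
                              name = cn$name)
    else
      model <- add_constraint(model, "coordinate_coupling",
                              coords = as.character(unlist(cn$coords)),
                              coeffs = as.numeric(cn$coeffs),
                              constant = cn$constant, name = cn$name)
  }
  model
}

#' Write and read study configuration files
#'
#' A study document bundles a model (inline or by file reference), the
#' problem definition (time bounds, per-state range/initial/final
#' overrides, goals with weights, free parameters), and a solver section
#' (scheme, mesh intervals, dynamics mode, tolerances). Tracking-goal
#' references are stored as paths to STO-style time-series files. Custom
#' path-constraint functions are not serializable and are rejected.
#'
#' @param problem an [ocp()] over a multibody model.
#' @param config a [transcription_config()].
#' @param path output file path.
#' @param model_path optional path for the model document; by default the
#'   model is embedded inline.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns `list(problem, config)`.
#' @export
write_study_config <- function(problem, config = transcription_config(),
                               path, model_path = NULL) {
  stopifnot(inherits(problem, "ocp"))
  if (is.null(problem$model))
    stop("study configs require a multibody model")
  if (length(problem$path))
    stop("path constraints are not serializable to a study config")
  goals <- lapply(seq_along(problem$goals), function(i) {
    g <- problem$goals[[i]]
    out <- list(kind = g$kind, weight = g$weight, name = names(problem$goals)[i])
    if (g$kind == "control_effort") {
      out$exponent <- g$exponent
      out$divide_by_duration <- g$divide_by_duration
      if (!is.null(g$weights)) out$weights <- g$weights
    }
    if (g$kind == "state_tracking") {
      ref_file <- paste0(tools::file_path_sans_ext(path), "_",
                         names(problem$goals)[i], "_reference.sto")
      write_timeseries(g$reference, ref_file)
      out$reference <- basename(ref_file)
      if (!is.null(g$weights)) out$weights <- g$weights
    }
    if (g$kind == "joint_reaction") out$body <- g$body
    out
  })
  model_entry <- if (is.null(model_path)) {
    tmp <- tempfile(fileext = ".yaml")
    write_model_config(problem$model, tmp)
    list(inline = yaml::read_yaml(tmp))
  } else {
    write_model_config(problem$model, model_path)
    list(file = basename(model_path))
  }
  doc <- list(
    model = model_entry,
    problem = list(
      t0 = problem$t0, tf = problem$tf_range,
      states = lapply(seq_len(nrow(problem$states)), function(i)
        as.list(problem$states[i, ])),
      controls = lapply(seq_len(nrow(problem$controls)), function(i)
        as.list(problem$controls[i, ])),
      goals = goals,
      parameters = lapply(names(problem$parameters), function(nm)
        c(list(name = nm), problem$parameters[[nm]]))),
    solver = config[c("scheme", "n_intervals", "dynamics_mode", "conv_tol",
                      "con_tol", "fd_step", "multiplier_bound",
                      "gamma_bound", "accel_bound", "ftdot_scale",
                      "max_iterations")])
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)
  model <- if (!is.null(doc$model$inline)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(doc$model$inline, tmp, precision = 17)
    read_model_config(tmp)
  } else read_model_config(file.path(dir, doc$model$file))
  pd <- doc$problem
  prob <- ocp(model, t0 = pd$t0, tf = as.numeric(unlist(pd$tf)))
  for (s in pd$states) {
    prob <- set_state_info(prob, s$name,
                           range = c(s$lower, s$upper),
                           initial = c(s$initial_lower, s$initial_upper),
                           final = c(s$final_lower, s$final_upper))
  }
  for (s in pd$controls)
    prob <- set_control_info(prob, s$name, c(s$lower, s$upper))
  for (g in pd$goals) {
    goal <- switch(g$kind,
      control_effort = goal_control_effort(
        weight = g$weight, exponent = g$exponent,
        weights = g$weights,
        divide_by_duration = isTRUE(g$divide_by_duration), name = g$name),
      final_time = goal_final_time(weight = g$weight, name = g$name),
      state_tracking = goal_state_tracking(
        read_timeseries(file.path(dir, g$reference)),
        weight = g$weight, weights = g$weights, name = g$name),
      joint_reaction = goal_joint_reaction(g$body, weight = g$weight,
                                           name = g$name),
      stop("unknown goal kind '", g$kind, "'"))
    prob <- add_goal(prob, goal)
  }
  for (p in pd$parameters)
    prob <- add_parameter(prob, p$path, p$lower, p$upper, name = p$name)
  sv <- doc$solver
  config <- transcription_config(
    scheme = sv$scheme, n_intervals = sv$n_intervals,
    dynamics_mode = sv$dynamics_mode, conv_tol = sv$conv_tol,
    con_tol = sv$con_tol, fd_step = sv$fd_step,
    multiplier_bound = sv$multiplier_bound, gamma_bound = sv$gamma_bound,
    accel_bound = sv$accel_bound, ftdot_scale = sv$ftdot_scale,
    max_iterations = sv$max_iterations)
  list(problem = prob, config = config)
}
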