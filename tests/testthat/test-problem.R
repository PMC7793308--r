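# small fixed-time torque-driven pendulum used to probe goal values: with
# degenerate control bounds the "solution" is fully pinned, so goal values
# can be checked against closed forms.
pinned_problem <- function(ctrl = 0.5, T = 2, goals) {
  mod <- mbs_model(gravity = c(0, 0))
  mod <- add_body(mod, "rod", 1, 0.1, joint = "pin", com = c(0, -0.5),
                  coords = "th", coord_range = c(-50, 50),
                  speed_range = c(-50, 50))
  mod <- add_coordinate_actuator(mod, "th", name = "tq", gain = 1,
                                 control_range = c(ctrl, ctrl))
  prob <- ocp(mod, tf = T)
  for (g in goals) prob <- add_goal(prob, g)
  prob
}

goal_values_at_guess <- function(prob, cfg = transcription_config("trapezoidal", 10)) {
  nlp <- transcribe(prob, cfg)
  sum(nlp$eval(default_guess(nlp))$contrib)
}

test_that("effort integrand integrates weighted control powers", {
  # one control constant 0.5 for 2 s, w = 1, p = 2 -> integral 0.5
  p1 <- pinned_problem(0.5, 2, list(goal_control_effort(weight = 1)))
  expect_equal(goal_values_at_guess(p1), 0.5, tolerance = 1e-12)
  # zero controls -> 0; zero weights -> 0 regardless of controls
  p0 <- pinned_problem(0, 2, list(goal_control_effort(weight = 1)))
  expect_equal(goal_values_at_guess(p0), 0)
  pw <- pinned_problem(0.5, 2, list(goal_control_effort(
    weight = 1, weights = list(tq = 0))))
  expect_equal(goal_values_at_guess(pw), 0)
  # duration normalization divides by T
  pn <- pinned_problem(0.5, 2, list(goal_control_effort(
    weight = 1, divide_by_duration = TRUE)))
  expect_equal(goal_values_at_guess(pn), 0.25, tolerance = 1e-12)
  # non-default exponent
  p3 <- pinned_problem(0.5, 2, list(goal_control_effort(weight = 1,
                                                        exponent = 3)))
  expect_equal(goal_values_at_guess(p3), 2 * 0.5^3, tolerance = 1e-12)
})

test_that("tracking integrand penalizes squared deviation from reference", {
  tt <- seq(0, 2, 0.05)
  ref <- trajectory(tt, states = cbind(th = rep(0.3, length(tt)),
                                       th_u = rep(0, length(tt))))
  # the midpoint guess holds th = 0 (range symmetric), a constant offset
  # delta = 0.3 on one tracked channel over T = 2 gives w * delta^2 * T
  pr <- pinned_problem(0, 2, list(goal_state_tracking(ref, weight = 2,
                                                      weights = list(th = 1))))
  expect_equal(goal_values_at_guess(pr), 2 * 0.3^2 * 2, tolerance = 1e-12)
  # matching reference -> 0 (track the zero trajectory)
  ref0 <- trajectory(tt, states = cbind(th = rep(0, length(tt))))
  pr0 <- pinned_problem(0, 2, list(goal_state_tracking(ref0, weight = 2)))
  expect_equal(goal_values_at_guess(pr0), 0)
  # channel weight 0 ignores that channel
  prw <- pinned_problem(0, 2, list(goal_state_tracking(ref, weight = 2,
                                                       weights = list(th = 0))))
  expect_equal(goal_values_at_guess(prw), 0)
  # reference span must cover the horizon
  short <- trajectory(seq(0, 1, 0.05),
                      states = cbind(th = rep(0, 21)))
  ps <- pinned_problem(0, 2, list(goal_state_tracking(short)))
  expect_error(transcribe(ps, transcription_config("trapezoidal", 5)),
               "span")
})

test_that("final-time and joint-reaction goals evaluate correctly", {
  pt <- pinned_problem(0, 0.5, list(goal_final_time(weight = 1)))
  expect_equal(goal_values_at_guess(pt), 0.5)
  # static hanging pendulum: reaction magnitude m g, integrand (m g)^2
  m <- 1.3; g <- 9.80665
  mod <- mbs_model()
  mod <- add_body(mod, "rod", m, 0, joint = "pin", com = c(0, -0.5),
                  coords = "th", coord_range = c(0, 0),
                  speed_range = c(0, 0))
  prob <- ocp(mod, tf = 2)
  prob <- add_goal(prob, goal_joint_reaction("rod", weight = 1))
  expect_equal(goal_values_at_guess(prob), (m * g)^2 * 2, tolerance = 1e-8)
})

test_that("boundary constraints express periodicity and average speed", {
  dyn <- function(t, X, U, pars) cbind(U[, 1])
  mk <- function(...) {
    prob <- ocp(model = NULL, tf = 1, dynamics = dyn,
                states = data.frame(name = "p", lower = -5, upper = 5),
                controls = data.frame(name = "v", lower = -5, upper = 5))
    prob <- add_goal(prob, goal_control_effort(weight = 1))
    prob
  }
  # walk 1.24 m in 1 s with v_target = 1.24 m/s -> residual 0 at solution
  prob <- mk()
  prob <- set_state_info(prob, "p", initial = 0)
  prob <- add_boundary_constraint(prob, "average_speed", state = "p",
                                  v_target = 1.24)
  sol <- solve_ocp(prob, transcription_config("trapezoidal", 10,
                                              conv_tol = 1e-8,
                                              con_tol = 1e-8))
  expect_equal(sol$status, "converged")
  expect_equal(as.numeric(sol$states[nrow(sol$states), "p"]), 1.24,
               tolerance = 1e-6)
  # sign-flipped periodic pairing: p(tf) = -p(0)
  prob2 <- mk()
  prob2 <- set_state_info(prob2, "p", initial = 0.7)
  prob2 <- add_boundary_constraint(prob2, "periodicity",
                                   pairs = list(list(final = "p",
                                                     initial = "p",
                                                     sigma = -1)))
  sol2 <- solve_ocp(prob2, transcription_config("trapezoidal", 10,
                                                conv_tol = 1e-8,
                                                con_tol = 1e-8))
  expect_equal(as.numeric(sol2$states[nrow(sol2$states), "p"]), -0.7,
               tolerance = 1e-6)
  expect_error(add_boundary_constraint(mk(), "periodicity",
                                       pairs = list(list(final = "zz",
                                                         initial = "p"))),
               "missing states")
})

test_that("control-bound path constraints clip the admissible envelope", {
  dyn <- function(t, X, U, pars) cbind(U[, 1])
  prob <- ocp(model = NULL, tf = 1, dynamics = dyn,
              states = data.frame(name = "p", lower = -5, upper = 5),
              controls = data.frame(name = "v", lower = -5, upper = 5))
  prob <- set_state_info(prob, "p", initial = 0, final = 1)
  prob <- add_goal(prob, goal_control_effort(weight = 1))
  # envelope around a synthetic excitation trace +-0.3
  env <- function(t) 1 + 0.5 * sin(2 * pi * t)
  prob2 <- add_path_constraint(prob, "control_bound", control = "v",
                               lower = function(t) env(t) - 0.3,
                               upper = function(t) env(t) + 0.3)
  sol <- solve_ocp(prob2, transcription_config("trapezoidal", 20,
                                               conv_tol = 1e-8,
                                               con_tol = 1e-8))
  expect_equal(sol$status, "converged")
  tt <- sol$time
  expect_true(all(sol$controls[, "v"] >= env(tt) - 0.3 - 1e-9))
  expect_true(all(sol$controls[, "v"] <= env(tt) + 0.3 + 1e-9))
  # crossing bounds -> validation error
  prob3 <- add_path_constraint(prob, "control_bound", control = "v",
                               lower = function(t) 1 + t,
                               upper = function(t) 1 - t)
  expect_error(transcribe(prob3, transcription_config("trapezoidal", 5)),
               "lower exceeds upper")
  expect_error(add_path_constraint(prob, "control_bound", control = "zz",
                                   lower = identity, upper = identity),
               "unknown control")
})

test_that("registered parameters behave like degenerate-bound constants", {
  mod <- sit_to_stand_fixture(spring_stiffness = 35)
  prob_fixed <- sit_to_stand_problem(mod)
  prob_free <- sit_to_stand_problem(mod)
  prob_free <- add_parameter(prob_free, "springs/knee_spring/stiffness",
                             35, 35, name = "k")
  cfg <- transcription_config("hermite-simpson", 10,
                              conv_tol = 1e-6, con_tol = 1e-6)
  s1 <- solve_ocp(prob_fixed, cfg)
  s2 <- solve_ocp(prob_free, cfg)
  expect_equal(s1$objective, s2$objective, tolerance = 1e-6)
  expect_equal(as.numeric(s2$parameters["k"]), 35)
  expect_error(add_parameter(prob_fixed, "springs/nope/stiffness", 0, 1),
               "unknown element")
  expect_error(add_parameter(prob_fixed, "badpath", 0, 1), "path")
})

test_that("problem validation rejects ill-posed definitions", {
  mod <- suspended_mass_fixture()
  prob <- ocp(mod, tf = 1)
  expect_error(validate_problem(prob), "at least one goal")
  expect_error(goal_control_effort(weight = -1))
  prob2 <- add_goal(prob, goal_control_effort())
  prob2$states$lower[1] <- 99
  expect_error(validate_problem(prob2), "lower > upper")
  expect_error(set_state_info(prob, "nope", range = c(0, 1)),
               "unknown state")
  prob3 <- add_goal(prob, goal_control_effort(
    weights = list(bogus_channel = 1)))
  expect_error(validate_problem(prob3), "unknown channels")
})
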