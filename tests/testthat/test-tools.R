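test_that("shooting falls under gravity with zero excitation", {
  mod <- suspended_mass_fixture()
  # from a non-equilibrium rest pose with floor-level excitation the mass
  # initially accelerates downward
  x0 <- c(0, -0.1, 0, 0, 0.01, 0.01, 0.01)
  sh <- forward_shooting(mod, function(t) rep(0.01, 3), x0, c(0, 0.08),
                         t_out = seq(0, 0.08, 0.005))
  expect_lt(sh$states[nrow(sh$states), "y_u"], 0)
  expect_error(forward_shooting(mod, function(t) rep(0.01, 3),
                                c(0, -0.1), c(0, 0.1)))
})

test_that("torque-driven inverse recovers inverse-dynamics torques exactly", {
  mod <- mbs_model()
  mod <- add_body(mod, "rod", 2, 0.02, joint = "pin", com = c(0, -0.4),
                  coords = "th", coord_range = c(-3, 3),
                  speed_range = c(-20, 20))
  mod <- add_coordinate_actuator(mod, "th", name = "tq", gain = 1,
                                 control_range = c(-100, 100))
  tt <- seq(0, 1, 0.01)
  kin <- trajectory(tt, states = cbind(th = 0.5 * sin(2 * pi * tt)))
  inv <- solve_inverse(mod, kin,
                       transcription_config("hermite-simpson", 20,
                                            conv_tol = 1e-8, con_tol = 1e-8),
                       reserve_bound = Inf)
  expect_equal(inv$status, "converged")
  thf <- stats::splinefun(tt, kin$states[, 1], method = "fmm")
  Tg <- inv$time
  tau_ref <- inverse_dynamics(mod, matrix(thf(Tg)), matrix(thf(Tg, 1)),
                              matrix(thf(Tg, 2)))
  expect_equal(as.numeric(inv$controls[, "th_reserve"]),
               as.numeric(tau_ref), tolerance = 1e-8)
  expect_error(solve_inverse(mod, trajectory(tt), t_span = c(0, 1)),
               "missing coordinate")
  expect_error(solve_inverse(mod, kin, t_span = c(0, 2)), "data span")
})

test_that("a zero reserve budget on infeasible dynamics fails loudly", {
  # no muscles, reserves clamped to zero: the torque balance cannot hold
  mod <- mbs_model()
  mod <- add_body(mod, "rod", 2, 0.02, joint = "pin", com = c(0, -0.4),
                  coords = "th", coord_range = c(-3, 3))
  tt <- seq(0, 1, 0.01)
  kin <- trajectory(tt, states = cbind(th = 0.5 * sin(2 * pi * tt)))
  inv <- solve_inverse(mod, kin,
                       transcription_config("trapezoidal", 10),
                       reserve_bound = 0)
  expect_false(isTRUE(inv$success))
  expect_true(inv$status %in% c("infeasible", "max-iterations"))
})

test_that("re-solving from its own solution converges immediately", {
  prob <- sliding_mass_problem()
  cfg <- transcription_config("hermite-simpson", 10,
                              conv_tol = 1e-6, con_tol = 1e-6)
  s1 <- solve_ocp(prob, cfg)
  s2 <- solve_ocp(prob, cfg, guess = s1, lam0 = s1$lam)
  expect_equal(s2$status, "converged")
  expect_lte(s2$iterations, 10)
  expect_equal(s2$objective, s1$objective, tolerance = 1e-6)
})

test_that("tracking an already-optimal trajectory reproduces it", {
  # the prediction minimizes effort; tracking it with tight weights and the
  # same mesh is a fixed point of the tracking problem
  pred <- get_prediction()
  tr <- get_tracking()
  sol <- tr$solution
  expect_equal(sol$status, "converged")
  q_rms <- sqrt(mean((sol$states[, "x"] - pred$states[, "x"])^2 +
                       (sol$states[, "y"] - pred$states[, "y"])^2))
  expect_lt(q_rms, 1e-3) # kinematics match at constraint-tolerance scale
})

test_that("track and inverse agree on the recovered activations", {
  inv <- get_inverse()
  trk <- get_tracking()$solution
  act_cols <- grep("_activation$", colnames(inv$states), value = TRUE)
  ref <- vapply(act_cols, function(ch)
    stats::splinefun(trk$time, trk$states[, ch], method = "fmm")(inv$time),
    numeric(length(inv$time)))
  rms <- sqrt(mean((inv$states[, act_cols] - ref)^2))
  expect_lt(100 * rms / max(ref), 2)
})
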