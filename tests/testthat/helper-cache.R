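# Lazily computed, shared expensive fixtures. Each accessor solves its
# problem once per test run and memoises the result; later tests reuse it.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

get_prediction <- function() cached("prediction", predict_suspended_mass())

get_tracking <- function() cached("tracking", tracking_recovery(get_prediction()))

get_consistency <- function()
  cached("consistency", prediction_shooting_consistency(get_prediction()))

get_steering <- function() cached("steering", steering_accuracy())

get_sit_to_stand <- function()
  cached("sit_to_stand", spring_assist_experiment(n_intervals = 25))

get_coupler_solution <- function() cached("coupler", {
  solve_ocp(coupler_swing_problem(),
            transcription_config("hermite-simpson", 20,
                                 conv_tol = 1e-6, con_tol = 1e-6))
})

get_inverse <- function() cached("inverse", {
  pred <- get_prediction()
  tf <- max(pred$time); t0 <- pred$time[1]
  span <- c(t0 + 0.05 * (tf - t0), tf - 0.05 * (tf - t0))
  act_cols <- grep("_activation$", colnames(pred$states), value = TRUE)
  a0 <- vapply(act_cols, function(ch)
    stats::splinefun(pred$time, pred$states[, ch], method = "fmm")(span[1]), 0)
  solve_inverse(suspended_mass_fixture(), pred,
                transcription_config("hermite-simpson", 40,
                                     conv_tol = 1e-6, con_tol = 1e-6),
                t_span = span, reserve_bound = 0.25,
                initial_activation = a0)
})

# simple models reused across unit tests
pendulum_model <- function(m = 2, L = 0.7) {
  mod <- mbs_model()
  add_body(mod, "rod", mass = m, inertia = 0, joint = "pin",
           com = c(0, -L), coords = "theta", coord_range = c(-2 * pi, 2 * pi))
}

point_mass_model <- function(m = 1) {
  mod <- mbs_model()
  add_body(mod, "mass", mass = m, joint = "point",
           coords = c("x", "y"), coord_range = c(-1, 1))
}
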