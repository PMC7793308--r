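test_that("the grid follows the mesh-point conventions", {
  hs <- transcription_config("hermite-simpson", 25)
  expect_length(build_grid(hs, 0, 1), 51) # 2N+1 time points
  tr <- transcription_config("trapezoidal", 2)
  expect_equal(build_grid(tr, 0, 1), c(0, 0.5, 1))
  expect_error(transcription_config("trapezoidal", 1), "n_intervals")
  cfg <- transcription_config("trapezoidal", 5)
  cfg$n_intervals <- 1L
  expect_error(build_grid(cfg, 0, 1), "n_intervals")
  expect_error(build_grid(tr, 1, 1), "tf")
})

test_that("defect operators are exact up to their scheme's degree", {
  # trapezoidal: exact for integrands up to degree 1
  expect_equal(trapezoidal_defect(0, 1, 1, 1, 1), 0) # constant f
  # xdot = t on [0,1], exact endpoints x = t^2/2
  expect_equal(trapezoidal_defect(0, 0.5, 0, 1, 1), 0)
  # xdot = t^2: defect = 1/3 - 1/2 = -1/6
  expect_equal(trapezoidal_defect(0, 1 / 3, 0, 1, 1), -1 / 6)
  # Hermite-Simpson: exact through cubics; quartic leaves 1/5 - 5/24
  for (pw in 0:3) {
    x <- function(t) t^(pw + 1) / (pw + 1)
    f <- function(t) t^pw
    d <- hermite_simpson_defect(x(0), x(0.5), x(1), f(0), f(0.5), f(1), 1)
    expect_equal(d$integ, 0, tolerance = 1e-14)
    if (pw <= 2) expect_equal(d$interp, 0, tolerance = 1e-14)
  }
  d4 <- hermite_simpson_defect(0, 0.5^5 / 5, 1 / 5, 0, 0.5^4, 1, 1)
  expect_equal(d4$integ, 1 / 5 - 5 / 24, tolerance = 1e-14)
  expect_error(trapezoidal_defect(0, 1, 1, 1, -1))
})

test_that("decision-vector layout matches the counting formulas", {
  # sliding mass (1 coordinate, 1 control), trapezoidal N=10:
  # 11*(2+1) + 1 free-time variable = 34
  prob <- sliding_mass_problem()
  nlp <- transcribe(prob, transcription_config("trapezoidal", 10))
  expect_equal(nlp$nv, 34)
  # Hermite-Simpson N=10 point mass (2 states, 1 control): 21*3 + 1 = 64
  dyn <- function(t, X, U, pars) cbind(X[, 2], U[, 1])
  prob2 <- ocp(model = NULL, tf = c(0.5, 2), dynamics = dyn,
               states = data.frame(name = c("p", "v"), lower = -5, upper = 5),
               controls = data.frame(name = "u", lower = -1, upper = 1))
  prob2 <- add_goal(prob2, goal_final_time(1))
  nlp2 <- transcribe(prob2, transcription_config("hermite-simpson", 10))
  expect_equal(nlp2$nv, 64)
  # registering one scalar parameter adds exactly one variable
  prob3 <- sit_to_stand_problem(sit_to_stand_fixture(spring_stiffness = 0),
                                free_spring = TRUE)
  prob3f <- sit_to_stand_problem(sit_to_stand_fixture(spring_stiffness = 0))
  cfg <- transcription_config("hermite-simpson", 5)
  expect_equal(transcribe(prob3, cfg)$nv, transcribe(prob3f, cfg)$nv + 1)
  # layout index map is a bijection onto 1..nv
  L <- nlp2$layout
  idx <- c(L$i_dt, as.integer(L$ix), as.integer(L$iu), as.integer(L$igam),
           L$ipar)
  expect_equal(sort(idx), seq_len(nlp2$nv))
})

test_that("structured derivatives agree with dense finite differences", {
  prob <- sliding_mass_problem()
  for (cfg in list(transcription_config("trapezoidal", 6),
                   transcription_config("hermite-simpson", 4),
                   transcription_config("hermite-simpson", 4,
                                        dynamics_mode = "implicit"))) {
    nlp <- transcribe(prob, cfg)
    z <- default_guess(nlp) * 1.01 + 0.013
    chk <- nlp_check_derivatives(nlp, z)
    expect_lt(chk$g_err, 1e-7)
    expect_lt(chk$J_err, 1e-7)
  }
  # constrained fixture exercises the lambda/gamma columns
  nlp3 <- transcribe(coupler_swing_problem(),
                     transcription_config("hermite-simpson", 3))
  chk3 <- nlp_check_derivatives(nlp3, default_guess(nlp3) * 1.01 + 0.017)
  expect_lt(chk3$g_err, 1e-7)
  expect_lt(chk3$J_err, 1e-7)
})

test_that("implicit dynamics residual vanishes at forward-dynamics output", {
  mod <- suspended_mass_fixture()
  cfg <- transcription_config(dynamics_mode = "implicit")
  set.seed(3)
  X <- cbind(runif(4, -0.1, 0.1), runif(4, -0.22, -0.08),
             runif(4, -1, 1), runif(4, -1, 1),
             matrix(runif(12, 0.05, 0.9), 4))
  exc <- matrix(runif(12, 0.05, 0.9), 4)
  # explicit accelerations become the implicit unknowns
  dexp <- mbs_dynamics_batch(mod, X, exc, cfg, mode = "explicit")
  W <- dexp$Xdot[, 3:4]
  dimp <- mbs_dynamics_batch(mod, X, cbind(exc, W), cfg, mode = "implicit")
  expect_lt(max(abs(dimp$imp)), 1e-9)
  # the fast point-mass path agrees with the generic recursive path
  generic <- mbs_dynamics_batch(mod, X, exc,
                                transcription_config(), mode = "explicit",
                                cache = utils::modifyList(
                                  model_eval_cache(mod), list(simple = FALSE)))
  expect_lt(max(abs(dexp$Xdot - generic$Xdot)), 1e-10)
})

test_that("default guess is the midpoint of the variable bounds", {
  prob <- sliding_mass_problem()
  nlp <- transcribe(prob, transcription_config("hermite-simpson", 5))
  g <- default_guess(nlp)
  fin <- is.finite(nlp$lb) & is.finite(nlp$ub)
  expect_equal(g[fin], (nlp$lb[fin] + nlp$ub[fin]) / 2)
  expect_true(all(g >= nlp$lb & g <= nlp$ub))
})

test_that("solver input validation catches malformed programs", {
  prob <- sliding_mass_problem()
  nlp <- transcribe(prob, transcription_config("trapezoidal", 5))
  z <- default_guess(nlp); z[3] <- NaN
  expect_error(nlp_solve(nlp, z), "NaN")
  expect_error(nlp_solve(nlp, numeric(3)), "length")
  nlp_bad <- nlp; nlp_bad$lb[2] <- nlp_bad$ub[2] + 1
  expect_error(nlp_solve(nlp_bad, default_guess(nlp)), "infeasible bounds")
  # unbounded free time is rejected at validation
  mod <- mbs_model(gravity = c(0, 0))
  mod <- add_body(mod, "b", 1, joint = "slider", coords = "x")
  pb <- ocp(mod, tf = c(1, Inf))
  pb <- add_goal(pb, goal_final_time(1))
  expect_error(transcribe(pb, transcription_config("trapezoidal", 5)),
               "finite")
})

test_that("the NLP solver handles textbook programs", {
  # unconstrained quadratic: min (x-3)^2 -> x = 3
  nlp <- new_nlp(2, c(-10, -10), c(10, 10),
                 function(z) list(contrib = c((z[1] - 3)^2, z[2]^2),
                                  con = numeric(0)),
                 col_rows_con = list(integer(0), integer(0)),
                 col_rows_obj = list(1L, 2L),
                 colors = c(1L, 2L), n_con = 0L, n_contrib = 2L)
  r <- nlp_solve(nlp, c(0, 1), control = list(tol_kkt = 1e-8))
  expect_equal(r$status, "converged")
  expect_equal(r$z[1], 3, tolerance = 1e-6)
  # equality-constrained quadratic: min x^2 + y^2 s.t. x + y = 1
  nlp2 <- new_nlp(2, c(-10, -10), c(10, 10),
                  function(z) list(contrib = c(z[1]^2, z[2]^2),
                                   con = z[1] + z[2] - 1),
                  col_rows_con = list(1L, 1L),
                  col_rows_obj = list(1L, 2L),
                  colors = c(1L, 2L), n_con = 1L, n_contrib = 2L)
  r2 <- nlp_solve(nlp2, c(0, 0), control = list(tol_con = 1e-10,
                                                tol_kkt = 1e-8))
  expect_equal(r2$status, "converged")
  expect_equal(r2$z, c(0.5, 0.5), tolerance = 1e-6)
  # contradictory constraints are flagged, best iterate still returned
  nlp3 <- new_nlp(1, -10, 10,
                  function(z) list(contrib = 0 * z[1],
                                   con = c(z[1], z[1] - 1)),
                  col_rows_con = list(c(1L, 2L)),
                  col_rows_obj = list(1L),
                  colors = 1L, n_con = 2L, n_contrib = 1L)
  r3 <- nlp_solve(nlp3, 0.3, control = list(max_outer = 25))
  expect_true(r3$status %in% c("infeasible", "max-iterations"))
  expect_equal(r3$z[1], 0.5, tolerance = 1e-3) # least-squares compromise
})

test_that("sliding-mass minimum time converges to the bang-bang optimum", {
  prob <- sliding_mass_problem()
  cfg <- transcription_config("hermite-simpson", 10,
                              conv_tol = 1e-6, con_tol = 1e-6)
  sol <- solve_ocp(prob, cfg)
  expect_equal(sol$status, "converged")
  expect_equal(sol$objective, sliding_mass_min_time(), tolerance = 1e-4)
  expect_lt(sol$residuals$defect, 1e-6)
})

test_that("row scaling and goal quadrature leave the objective consistent", {
  # effort integral computed by the scheme quadrature matches adaptive
  # numerical integration of the interpolated controls within 1%
  prob <- sliding_mass_problem()
  prob$goals <- list()
  prob <- add_goal(prob, goal_control_effort(weight = 1))
  prob <- add_goal(prob, goal_final_time(weight = 0.05))
  sol <- solve_ocp(prob, transcription_config("hermite-simpson", 20,
                                              conv_tol = 1e-6,
                                              con_tol = 1e-6))
  expect_equal(sol$status, "converged")
  cf <- stats::approxfun(sol$time, sol$controls[, "force"])
  ref <- stats::integrate(function(t) cf(t)^2, min(sol$time), max(sol$time),
                          subdivisions = 400, rel.tol = 1e-9)$value
  expect_equal(sol$goal_values$control_effort, ref, tolerance = 0.01)
  # total objective equals the sum of the per-goal values to 1e-10
  expect_equal(sol$objective, sum(unlist(sol$goal_values)),
               tolerance = 1e-10)
})
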