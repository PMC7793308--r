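test_that("activation dynamics match direct evaluation of the rate law", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2)
  # oracle: evaluate the stated closed form independently
  rate <- function(e, a, ta = 0.015, td = 0.060) {
    f <- 0.5 * tanh(0.1 * (e - a))
    ((f + 0.5) / (ta * (0.5 + 1.5 * a)) + (0.5 - f) * (0.5 + 1.5 * a) / td) *
      (e - a)
  }
  expect_equal(activation_derivative(0.3, 0.3, p), 0) # fixed point
  expect_equal(activation_derivative(1, 0, p), rate(1, 0), tolerance = 1e-12)
  expect_equal(rate(1, 0), 77.1, tolerance = 1e-3)
  # deactivation branch: negative, magnitude set by tau_deact
  d <- activation_derivative(0, 1, p)
  expect_lt(d, 0)
  expect_equal(d, rate(0, 1), tolerance = 1e-12)
  slow <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2,
                        tau_deact = 0.120)
  expect_lt(abs(activation_derivative(0, 1, slow)), abs(d))
})

test_that("characteristic curves give the documented landmark values", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2)
  cv <- muscle_curves(1, 0, 1, p)
  expect_equal(cv$f_act, 1)
  expect_equal(cv$f_pass, 0)
  # oracle evaluations of the stated closed forms
  fv0 <- -0.318 * log(-0.374 + sqrt(0.374^2 + 1)) + 0.886
  expect_equal(cv$f_v, fv0, tolerance = 1e-12)
  expect_equal(cv$f_v, 1.002, tolerance = 1e-3)
  ft1 <- 0.2 * exp(35 * (1 - 0.995)) - 0.25
  expect_equal(cv$f_t, ft1, tolerance = 1e-12)
  expect_lt(abs(cv$f_t - (-0.012)), 5e-4)
  # softplus floor keeps the forward tendon curve non-negative
  expect_gte(tendon_force_length(0.98, p), 0)
  expect_equal(tendon_force_length(1.05, p, floor = TRUE),
               tendon_force_length(1.05, p, floor = FALSE),
               tolerance = 1e-6)
})

test_that("curves and activation dynamics are C1 on their domains", {
  # smoothness: the central-difference derivative is step-size independent
  # (a kink would make the two step sizes disagree at O(1))
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2)
  h <- 1e-4
  sweep <- seq(0.4, 1.8, by = 0.013)
  for (f in list(function(x) muscle_curves(x, 0, 1, p)$f_act,
                 function(x) muscle_curves(x, 0, 1, p)$f_pass,
                 function(v) muscle_curves(1, pmin(v, 1), 1, p)$f_v,
                 function(lt) tendon_force_length(0.6 + lt / 3, p),
                 function(a) activation_derivative(0.5, pmin(a, 1), p))) {
    d1 <- (f(sweep + h) - f(sweep - h)) / (2 * h)
    d2 <- (f(sweep + h / 16) - f(sweep - h / 16)) / (h / 8)
    expect_true(all(is.finite(d1)))
    expect_lt(max(abs(d1 - d2) / pmax(1, abs(d2))), 1e-4)
  }
})

test_that("force-velocity curve is monotone and near zero at max shortening", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2)
  v <- seq(-1, 1, 0.01)
  fv <- muscle_curves(1, v, 1, p)$f_v
  expect_true(all(diff(fv) > 0))
  expect_lt(abs(muscle_curves(1, -1, 1, p)$f_v), 0.05)
  lt <- seq(0.99, 1.06, 0.001)
  expect_true(all(diff(muscle_curves(1, 0, lt, p)$f_t) > 0))
})

test_that("tendon curve inverse round-trips to 1e-12", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2)
  lt <- seq(1.002, 1.05, length.out = 25)
  ft <- tendon_force_length(lt, p, floor = FALSE)
  expect_equal(tendon_length_from_force(ft, p), lt, tolerance = 1e-12)
  expect_error(tendon_length_from_force(-0.3, p, "calf"), "calf")
})

test_that("rigid-tendon kinematics follow the pennation geometry", {
  p0 <- muscle_params(f_iso = 10, l_opt = 0.1, l_slack = 0.2, alpha_opt = 0)
  fk <- rigid_tendon_kinematics(0.3, 0, p0)
  expect_equal(fk$lm_tilde, 1)
  expect_equal(fk$vm_tilde, 0)
  pa <- muscle_params(f_iso = 10, l_opt = 0.1, l_slack = 0.2,
                      alpha_opt = 0.2)
  fk2 <- rigid_tendon_kinematics(0.2 + 0.1 * cos(0.2), 0, pa)
  expect_equal(fk2$lm_tilde, 1, tolerance = 1e-12)
  expect_equal(fk2$cos_alpha, cos(0.2), tolerance = 1e-12)
  expect_error(rigid_tendon_kinematics(0.15, 0, p0), "path length")
})

test_that("tendon equilibrium residual has a unique root found by bisection", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2,
                     rigid_tendon = FALSE)
  grid <- expand.grid(a = c(0.05, 0.4, 0.9),
                      l_mt = c(0.29, 0.305, 0.32),
                      v_mt = c(-0.05, 0, 0.05))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    # bisection oracle, independent of the solver used elsewhere
    f <- function(ft) tendon_equilibrium_residual(g$a, g$l_mt, g$v_mt, ft, 0, p)
    lo <- -0.2499; hi <- 3
    expect_lt(f(lo), 0); expect_gt(f(hi), 0)
    for (k in 1:60) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
    root <- (lo + hi) / 2
    expect_lt(abs(f(root)), 1e-9)
    # monotonicity sweep => uniqueness
    fts <- seq(-0.24, 3, length.out = 80)
    expect_true(all(diff(f(fts)) > 0))
    # the root-solving helper agrees with the bisection oracle
    expect_equal(solve_tendon_equilibrium(g$a, g$l_mt, g$v_mt, p), root,
                 tolerance = 1e-7)
  }
})

test_that("passive slack state has near-zero equilibrium tendon force", {
  p <- muscle_params(f_iso = 100, l_opt = 0.1, l_slack = 0.2,
                     rigid_tendon = FALSE,
                     curves = list(f_pass_scale = 0))
  # fiber shorter than optimal, no activation: equilibrium near zero force
  ft0 <- solve_tendon_equilibrium(0, 0.27, 0, p)
  expect_lt(abs(ft0), 0.02)
  expect_lt(abs(tendon_equilibrium_residual(0, 0.27, 0, ft0, 0, p)), 1e-9)
})

test_that("tendon force covers rigid and compliant conventions", {
  pr <- muscle_params(f_iso = 50, l_opt = 0.1, l_slack = 0.2)
  expect_equal(tendon_force(0, 0.3, 0, pr), 0) # a=0, lm=1, passive=0 at opt
  fv0 <- muscle_curves(1, 0, 1, pr)$f_v
  expect_equal(tendon_force(1, 0.3, 0, pr), 50 * fv0, tolerance = 1e-12)
  pc <- muscle_params(f_iso = 50, l_opt = 0.1, l_slack = 0.2,
                      rigid_tendon = FALSE)
  expect_equal(tendon_force(0.3, 0.3, 0, pc, ft_tilde = 0.5), 25)
  expect_error(tendon_force(0.3, 0.3, 0, pc), "tendon force state")
})

test_that("parameter validation rejects non-physical muscles", {
  expect_error(muscle_params(-1, 0.1, 0.2))
  expect_error(muscle_params(10, 0.1, 0.2, tau_act = 0.1, tau_deact = 0.05))
  expect_error(muscle_params(10, 0.1, 0.2, alpha_opt = 2))
  expect_error(muscle_params(10, 0.1, 0.2, curves = list(bogus = 1)),
               "unknown curve")
})
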