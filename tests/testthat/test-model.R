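test_that("model builder enforces structural invariants", {
  mod <- mbs_model()
  expect_error(add_body(mod, "b", mass = 0), "mass")
  expect_error(add_body(mod, "b", mass = 1, inertia = -1), "inertia")
  mod <- add_body(mod, "b", mass = 1, joint = "pin", com = c(0, -1))
  expect_error(add_body(mod, "b", mass = 1), "duplicate")
  expect_error(add_body(mod, "c", mass = 1, parent = "nope"), "unknown parent")
  p <- muscle_params(10, 0.1, 0.05)
  expect_error(add_muscle(mod, "m", p, list(list(body = "b", xy = c(0, 0)))),
               "at least 2")
  # too many constraint equations
  mod2 <- add_constraint(mod, "coordinate_coupling", coords = "b_angle",
                         coeffs = 1)
  expect_error(validate_model(mod2), "constraint equations")
})

test_that("applied generalized forces sum all sources correctly", {
  # no force sources, spring at equilibrium, no gravity -> tau = 0
  mod <- mbs_model(gravity = c(0, 0))
  mod <- add_body(mod, "rod", 1, 0.1, joint = "pin", com = c(0, -0.5))
  mod <- add_torsional_spring(mod, "rod_angle", stiffness = 90,
                              equilibrium = 0.3)
  x0 <- c(0.3, 0)
  expect_equal(applied_generalized_forces(mod, x0), 0)
  # torsional spring k = 90 displaced 0.1 rad -> moment -9 N m
  expect_equal(applied_generalized_forces(mod, c(0.4, 0)), -9,
               tolerance = 1e-12)
  # single muscle: tau = moment arm * tendon force (scalar product oracle)
  p <- muscle_params(100, 0.12, 0.1, curves = list(f_pass_scale = 0))
  mod2 <- mbs_model(gravity = c(0, 0))
  mod2 <- add_body(mod2, "rod", 1, 0.1, joint = "pin", com = c(0, -0.5))
  mod2 <- add_muscle(mod2, "m", p,
                     list(list(body = "ground", xy = c(0.3, 0.1)),
                          list(body = "rod", xy = c(0, -0.3))))
  q <- 0.35
  pk <- muscle_path_kinematics(mod2, q, 0, "m")
  fmus <- tendon_force(0.7, pk$l_mt, 0, p)
  tau <- applied_generalized_forces(mod2, c(q, 0, 0.7), c(0.7))
  expect_equal(tau, as.numeric(pk$arms) * fmus, tolerance = 1e-10)
  # dimension mismatches name the offending block
  expect_error(applied_generalized_forces(mod2, c(q, 0)), "state block")
  expect_error(applied_generalized_forces(mod2, c(q, 0, 0.7), c(1, 2)),
               "control block")
})

test_that("forward dynamics reproduces closed-form pendulum behavior", {
  g <- 9.80665
  mod <- pendulum_model(m = 2, L = 0.7)
  expect_equal(forward_dynamics(mod, 0, 0, 0)$qdd, 0)
  expect_equal(forward_dynamics(mod, pi / 2, 0, 0)$qdd, -g / 0.7,
               tolerance = 1e-10)
  # free point mass under gravity only
  pm <- point_mass_model()
  expect_equal(forward_dynamics(pm, c(0, 0), c(0, 0), c(0, 0))$qdd,
               c(0, -g), tolerance = 1e-12)
})

test_that("inverse dynamics covers statics and Newton oracles", {
  g <- 9.80665
  mod <- pendulum_model(m = 2, L = 0.7)
  th <- 0.6
  expect_equal(inverse_dynamics(mod, th, 0, 0), 2 * g * 0.7 * sin(th),
               tolerance = 1e-10)
  pm <- point_mass_model()
  # qdd = 2g (downward): required force = m*g net of gravity
  expect_equal(inverse_dynamics(pm, c(0, 0), c(0, 0), c(0, -2 * g)),
               c(0, -g), tolerance = 1e-10)
})

test_that("forward/inverse dynamics round-trip to 1e-10 on random states", {
  set.seed(42)
  models <- list(pendulum_model(), point_mass_model())
  # a two-link chain exercises the recursive kinematics
  two <- mbs_model()
  two <- add_body(two, "l1", 1.5, 0.02, joint = "pin", com = c(0, -0.25))
  two <- add_body(two, "l2", 1.0, 0.01, parent = "l1", joint = "pin",
                  joint_parent = c(0, -0.5), com = c(0, -0.2))
  models$two_link <- two
  for (mod in models) {
    nq <- n_coords(mod)
    for (rep in 1:5) {
      q <- runif(nq, -1, 1); u <- runif(nq, -3, 3); tau <- runif(nq, -5, 5)
      fd <- forward_dynamics(mod, q, u, tau)
      expect_equal(inverse_dynamics(mod, q, u, fd$qdd), tau,
                   tolerance = 1e-10)
    }
  }
})

test_that("slider and planar joints propagate velocities consistently", {
  # cart (slider) with pendulum (pin) on top: compare qdd against a
  # Lagrangian closed form for the cart-pole
  M <- 1.2; m <- 0.4; L <- 0.6; g <- 9.80665
  mod <- mbs_model()
  mod <- add_body(mod, "cart", M, 0, joint = "slider", axis = c(1, 0),
                  coords = "s")
  mod <- add_body(mod, "pole", m, 0, parent = "cart", joint = "pin",
                  com = c(0, -L), coords = "th")
  set.seed(7)
  for (i in 1:4) {
    q <- runif(2, -1, 1); u <- runif(2, -2, 2); tau <- runif(2, -3, 3)
    fd <- forward_dynamics(mod, q, u, tau)
    th <- q[2]; thd <- u[2]
    Mm <- rbind(c(M + m, m * L * cos(th)),
                c(m * L * cos(th), m * L^2))
    rhs <- c(tau[1] + m * L * thd^2 * sin(th),
             tau[2] - m * g * L * sin(th))
    expect_equal(fd$qdd, as.numeric(solve(Mm, rhs)), tolerance = 1e-8)
  }
})

test_that("constraint evaluation matches geometric oracles", {
  # coordinate coupling: G row is the coupling coefficients
  mod <- coupler_fixture(ratio = 2)
  ce <- constraint_eval(mod, c(0.3, 0.6), c(0.5, 1.0))
  expect_equal(as.numeric(ce$phi), 0)
  expect_equal(as.numeric(ce$G[1, 1, ]), c(-2, 1))
  expect_equal(as.numeric(ce$Gu), 1.0 - 2 * 0.5)
  # two-link loop: closing the loop exactly gives phi = 0; a perturbed q
  # matches the brute-force endpoint-distance computation
  loop <- mbs_model()
  loop <- add_body(loop, "l1", 1, 0.01, joint = "pin", com = c(0, -0.25))
  loop <- add_body(loop, "l2", 1, 0.01, parent = "l1", joint = "pin",
                   joint_parent = c(0, -0.5), com = c(0, -0.25))
  loop <- add_constraint(loop, "point_coincidence", body_a = "l2",
                         xy_a = c(0, -0.5), body_b = "ground",
                         xy_b = c(0, -1))
  ce0 <- constraint_eval(loop, c(0, 0), c(0, 0))
  expect_equal(max(abs(ce0$phi)), 0, tolerance = 1e-14)
  q <- c(0.3, -0.45)
  # brute-force tip position by planar trigonometry:
  # R(theta) (0, -1/2) = (sin(theta)/2, -cos(theta)/2)
  tip <- c(0.5 * sin(q[1]), -0.5 * cos(q[1])) +
    c(0.5 * sin(q[1] + q[2]), -0.5 * cos(q[1] + q[2]))
  cep <- constraint_eval(loop, q, c(0, 0))
  expect_equal(as.numeric(cep$phi), tip - c(0, -1), tolerance = 1e-12)
  # constrained accelerations satisfy G qdd + Gdot u = 0
  u <- c(0.2, 0.4)
  fd <- forward_dynamics(mod, c(0.3, 0.6), u, c(0.5, 0))
  ce2 <- constraint_eval(mod, c(0.3, 0.6), u)
  expect_lt(abs(sum(ce2$G[1, 1, ] * fd$qdd) + ce2$Gdotu[1, 1]), 1e-8)
})

test_that("contact force follows the smooth sphere-plane model", {
  ce <- list(stiffness = 1e5, dissipation = 2, friction = 0.8,
             eps = 1e-4, v_s = 0.05, radius = 0.03)
  # far above ground the smoothing tail is negligible
  f <- contact_force(ce, -0.1, 0, 0)
  expect_lt(abs(f[2]), 1e-4 * ce$stiffness)
  # static penetration follows k d^1.5 (d >> eps)
  f2 <- contact_force(ce, 0.01, 0, 0)
  expect_equal(f2[2], 1e5 * 0.01^1.5, tolerance = 1e-4)
  # tanh saturation of friction
  f3 <- contact_force(ce, 0.01, 0, 1e3)
  expect_equal(f3[1], -0.8 * f3[2], tolerance = 1e-9)
  expect_equal(contact_force(ce, 0.01, 0, -1e3)[1], 0.8 * f3[2],
               tolerance = 1e-9)
  # C1 across d = 0: central-difference derivative jump below 1e-3 relative
  h <- 1e-8
  dplus <- (contact_force(ce, 2 * h, 0, 0)[2] - contact_force(ce, 0, 0, 0)[2]) / (2 * h)
  dminus <- (contact_force(ce, 0, 0, 0)[2] - contact_force(ce, -2 * h, 0, 0)[2]) / (2 * h)
  scale <- abs(dplus) + abs(dminus)
  expect_lt(abs(dplus - dminus) / max(scale, 1e-12), 1e-3)
})

test_that("joint reaction loads follow subtree force balance", {
  g <- 9.80665
  mod <- pendulum_model(m = 2, L = 0.7)
  # static hanging: magnitude m g
  r <- joint_reaction_load(mod, c(0, 0), NULL, "rod")
  expect_equal(sqrt(sum(r^2)), 2 * g, tolerance = 1e-10)
  # spinning at omega: centripetal term m L omega^2 added
  om <- 3
  r2 <- joint_reaction_load(mod, c(0, om), NULL, "rod")
  expect_equal(sqrt(sum(r2^2)), 2 * g + 2 * 0.7 * om^2, tolerance = 1e-8)
  # free point mass in free fall transmits nothing
  pm <- point_mass_model()
  r3 <- joint_reaction_load(pm, c(0, 0, 0, 0), NULL, "mass")
  expect_equal(max(abs(r3)), 0, tolerance = 1e-12)
  expect_error(joint_reaction_load(mod, c(0, 0), NULL, "nope"),
               "unknown joint")
})

test_that("unactuated pendulum conserves energy over 2 s", {
  m <- 2; L <- 0.7; g <- 9.80665
  mod <- pendulum_model(m = m, L = L)
  sh <- forward_shooting(mod, function(t) numeric(0), c(1, 0), c(0, 2),
                         t_out = seq(0, 2, 0.01), rtol = 1e-10, atol = 1e-12)
  E <- 0.5 * m * (L * sh$states[, 2])^2 - m * g * L * cos(sh$states[, 1])
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6)
})

test_that("model config files round-trip", {
  mod <- suspended_mass_fixture()
  f <- tempfile(fileext = ".yaml")
  write_model_config(mod, f)
  expect_equal(read_model_config(f), mod)
  mod2 <- coupler_fixture()
  f2 <- tempfile(fileext = ".yaml")
  write_model_config(mod2, f2)
  expect_equal(read_model_config(f2), mod2)
})
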