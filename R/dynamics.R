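# ---------------------------------------------------------------------------
# Multibody dynamics. The inverse-dynamics pass (exact Newton-Euler balance
# assembled through mass-center Jacobians) is the primitive; the mass matrix
# is extracted from it column-wise with unit accelerations, and forward
# dynamics solves the constrained equations of motion
#   [M  G'] [qdd ]   [tau - c(q,u)]
#   [G  0 ] [-lam] = [-(Gdot u)   ]
# where c(q,u) = inverse_dynamics(q, u, 0) contains the velocity bias and
# gravity. All entry points are batched: q, u, qdd may be vectors (one
# configuration) or n x nq matrices (one row per time point).
# ---------------------------------------------------------------------------

as_row <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Inverse dynamics
#'
#' Generalized forces required to produce accelerations `qdd` at state
#' `(q, u)`, i.e. `M(q) qdd + bias(q, u) - tau_gravity`. Round-trips with
#' [forward_dynamics()] exactly (same mass matrix and bias).
#'
#' @param model an [mbs_model()].
#' @param q,u,qdd coordinates, speeds, accelerations (vectors or n x nq
#'   matrices).
#' @return generalized-force matrix (n x nq), or vector when inputs are
#'   vectors.
#' @export
inverse_dynamics <- function(model, q, u, qdd) {
  vec <- !is.matrix(q)
  Q <- as_row(q); U <- as_row(u); A <- as_row(qdd)
  n <- nrow(Q); nq <- ncol(Q)
  kin <- fk_full(model, Q, U, A)
  J <- body_jacobians(model, Q)
  g <- model$gravity
  tau <- matrix(0, n, nq)
  for (b in model$bodies) {
    k <- kin[[b$name]]
    fa1 <- b$mass * (k$a_com[, 1] - g[1])
    fa2 <- b$mass * (k$a_com[, 2] - g[2])
    Ia <- b$inertia * k$alpha
    Jc <- J$Jcom[[b$name]]; Jt <- J$Jtheta[[b$name]]
    for (j in seq_len(nq))
      tau[, j] <- tau[, j] + fa1 * Jc[, 1, j] + fa2 * Jc[, 2, j] + Ia * Jt[, j]
  }
  if (vec) as.numeric(tau) else tau
}

#' Mass matrix
#'
#' @param model an [mbs_model()].
#' @param q coordinates (vector or matrix).
#' @return `nq x nq` matrix for a single configuration, or an
#'   `n x nq x nq` array for batched input.
#' @export
mass_matrix <- function(model, q) {
  vec <- !is.matrix(q)
  Q <- as_row(q); n <- nrow(Q); nq <- ncol(Q)
  Z <- matrix(0, n, nq)
  id0 <- inverse_dynamics(model, Q, Z, Z)
  M <- array(0, c(n, nq, nq))
  for (j in seq_len(nq)) {
    E <- Z; E[, j] <- 1
    M[, , j] <- inverse_dynamics(model, Q, Z, E) - id0
  }
  if (vec) matrix(M[1, , ], nq, nq) else M
}

#' Smooth sphere-halfspace contact force
#'
#' Evaluates the contact model of [add_contact_sphere()] for a penetration
#' depth `d` (positive when interpenetrating), penetration velocity `v_n`
#' (positive when deepening) and tangential velocity `v_t`. Vectorized.
#'
#' @param element a contact element entry (see [add_contact_sphere()]).
#' @param d penetration depth (m).
#' @param v_n normal (penetration) velocity (m/s).
#' @param v_t tangential velocity (m/s).
#' @return an `n x 3` matrix of forces `(tangential, normal, 0)`; the third
#'   component is identically zero in this planar implementation.
#' @export
contact_force <- function(element, d, v_n, v_t) {
  ds <- 0.5 * (d + sqrt(d^2 + element$eps^2))
  fn <- element$stiffness * ds^1.5 * (1 + 1.5 * element$dissipation * v_n)
  ft <- -element$friction * fn * tanh(v_t / element$v_s)
  cbind(ft, fn, 0)
}

#' Evaluate holonomic constraints
#'
#' Position residuals `phi(q)`, the constraint Jacobian `G = d phi/d q`
#' (exact, complex step), the velocity residual `G u`, and the velocity-level
#' bias `Gdot u` (directional central difference of `G u` along `u`).
#'
#' @param model an [mbs_model()].
#' @param q,u coordinates and speeds (vectors or matrices).
#' @return list with `phi` (n x m), `G` (n x m x nq), `Gu` (n x m),
#'   `Gdotu` (n x m).
#' @export
constraint_eval <- function(model, q, u = NULL) {
  Q <- as_row(q)
  n <- nrow(Q); nq <- ncol(Q)
  m <- n_constraint_eq(model)
  U <- if (is.null(u)) matrix(0, n, nq) else as_row(u)
  phi_fn <- function(Qx) {
    kin <- fk_full(model, Qx)
    cols <- list()
    cmap <- coord_index_map(model)
    cd <- model_coords(model)
    for (cn in model$constraints) {
      if (cn$type == "point_coincidence") {
        pa <- point_kinematics(model, Qx, cn$body_a, cn$xy_a, kin = kin)$pos
        pb <- point_kinematics(model, Qx, cn$body_b, cn$xy_b, kin = kin)$pos
        cols[[length(cols) + 1]] <- pa - pb
      } else {
        idx <- match(cn$coords, cd$name)
        v <- 0
        for (k in seq_along(idx)) v <- v + cn$coeffs[k] * Qx[, idx[k]]
        cols[[length(cols) + 1]] <- cbind(v - cn$constant)
      }
    }
    do.call(cbind, cols)
  }
  if (m == 0)
    return(list(phi = matrix(0, n, 0), G = array(0, c(n, 0, nq)),
                Gu = matrix(0, n, 0), Gdotu = matrix(0, n, 0)))
  phi <- Re(phi_fn(Q))
  G <- array(0, c(n, m, nq))
  for (j in seq_len(nq)) {
    Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
    G[, , j] <- Im(phi_fn(Qc)) / CS_H
  }
  dirG <- function(Qx) Im(phi_fn(Qx * (1 + 0i) + 1i * CS_H * U)) / CS_H
  Gu <- dirG(Q)
  dl <- 1e-6
  Gdotu <- (dirG(Q + dl * U) - dirG(Q - dl * U)) / (2 * dl)
  list(phi = phi, G = G, Gu = Gu, Gdotu = Gdotu)
}

#' Applied generalized forces
#'
#' Sums all force contributions at a state: muscle path forces mapped through
#' moment arms, torsional-spring moments, coordinate-actuator loads, contact
#' loads, and the constraint coupling `G' lambda`.
#'
#' @param model an [mbs_model()].
#' @param x full state (vector or n x nstate matrix) ordered per the model
#'   state layout: q-block, u-block, activation-block, tendon-force-block.
#' @param controls control vector/matrix ordered (muscle excitations,
#'   actuator controls). Excitations do not enter the force directly (force
#'   depends on the activation state) but the block is dimension-checked.
#' @param lambda constraint multipliers (vector/matrix with one column per
#'   constraint equation), or `NULL` for none.
#' @return generalized-force matrix (n x nq) or vector for vector input.
#' @export
applied_generalized_forces <- function(model, x, controls = NULL,
                                       lambda = NULL) {
  vec <- !is.matrix(x)
  X <- as_row(x)
  sl <- model_state_layout(model)
  cl <- model_control_layout(model)
  ns <- 2 * sl$nq + sl$na + sl$nft
  if (ncol(X) != ns)
    stop("state block has ", ncol(X), " columns, expected ", ns,
         " (q:", sl$nq, " u:", sl$nq, " a:", sl$na, " ftilde:", sl$nft, ")")
  n <- nrow(X); nq <- sl$nq
  Q <- X[, seq_len(nq), drop = FALSE]
  U <- X[, nq + seq_len(nq), drop = FALSE]
  nu <- cl$ne + cl$nact
  Uc <- if (is.null(controls)) matrix(0, n, nu) else as_row(controls)
  if (ncol(Uc) != nu)
    stop("control block has ", ncol(Uc), " columns, expected ", nu,
         " (excitations:", cl$ne, " actuators:", cl$nact, ")")
  m <- n_constraint_eq(model)
  Lam <- if (is.null(lambda)) matrix(0, n, m) else as_row(lambda)
  if (ncol(Lam) != m)
    stop("multiplier block has ", ncol(Lam), " columns, expected ", m)
  cd <- model_coords(model)
  tau <- matrix(0, n, nq)
  kin <- fk_full(model, Q, U)
  # muscles
  mus_names <- names(model$muscles)
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    pk <- muscle_path_kinematics(model, Q, U, mus)
    a <- X[, 2 * nq + i]
    ft <- if (!mus$params$rigid_tendon)
      X[, 2 * nq + sl$na + match(mus_names[i], sl$compliant)] else NULL
    f <- tendon_force(a, pk$l_mt, pk$v_mt, mus$params, ft_tilde = ft)
    tau <- tau + pk$arms * f
  }
  # torsional springs
  for (s in model$springs) {
    j <- match(s$coord, cd$name)
    tau[, j] <- tau[, j] - s$stiffness * (Q[, j] - s$equilibrium)
  }
  # coordinate actuators
  for (i in seq_along(model$actuators)) {
    a <- model$actuators[[i]]
    j <- match(a$coord, cd$name)
    tau[, j] <- tau[, j] + a$gain * Uc[, cl$ne + i]
  }
  # contact elements
  for (ce in model$contacts) {
    pkin <- point_kinematics(model, Q, ce$body, ce$xy, U = U, kin = kin)
    d <- ce$radius - pkin$pos[, 2]
    fo <- contact_force(ce, d, -pkin$vel[, 2], pkin$vel[, 1])
    Jp <- point_jacobian(model, Q, ce$body, ce$xy)
    for (j in seq_len(nq))
      tau[, j] <- tau[, j] + fo[, 1] * Jp[, 1, j] + fo[, 2] * Jp[, 2, j]
  }
  # constraint coupling G' lambda
  if (m > 0 && any(Lam != 0)) {
    ce <- constraint_eval(model, Q, U)
    for (j in seq_len(nq))
      for (k in seq_len(m))
        tau[, j] <- tau[, j] + ce$G[, k, j] * Lam[, k]
  }
  if (vec) as.numeric(tau) else tau
}

#' Forward dynamics
#'
#' Solves the constrained equations of motion for the accelerations and
#' constraint multipliers given applied generalized forces. For models
#' without kinematic constraints the multiplier block is empty and
#' `qdd = M^-1 (tau - c(q, u))`.
#'
#' @param model an [mbs_model()].
#' @param q,u coordinates and speeds (vectors or matrices).
#' @param tau applied generalized forces (same shape as `q`).
#' @param baumgarte optional Baumgarte stabilization frequency (1/s); the
#'   acceleration-level residual is augmented with
#'   `2*b*phidot + b^2*phi`. Default 0 (pure index-1 reduction).
#' @return list with `qdd` and `lambda` (n x m, empty for unconstrained
#'   models); vector input gives vector `qdd`.
#' @export
forward_dynamics <- function(model, q, u, tau, baumgarte = 0) {
  vec <- !is.matrix(q)
  Q <- as_row(q); U <- as_row(u); Tau <- as_row(tau)
  n <- nrow(Q); nq <- ncol(Q)
  m <- n_constraint_eq(model)
  cc <- inverse_dynamics(model, Q, U, matrix(0, n, nq))
  M <- mass_matrix(model, Q)
  qdd <- matrix(0, n, nq); lam <- matrix(0, n, m)
  ce <- if (m > 0) constraint_eval(model, Q, U) else NULL
  for (p in seq_len(n)) {
    Mp <- matrix(M[p, , ], nq, nq)
    rhs1 <- Tau[p, ] - cc[p, ]
    if (m > 0) {
      Gp <- matrix(ce$G[p, , ], m, nq)
      rhs2 <- -(ce$Gdotu[p, ] + 2 * baumgarte * ce$Gu[p, ] +
                  baumgarte^2 * ce$phi[p, ])
      K <- rbind(cbind(Mp, t(Gp)), cbind(Gp, matrix(0, m, m)))
      sol <- tryCatch(solve(K, c(rhs1, rhs2)), error = function(e)
        stop("singular KKT matrix at configuration q = (",
             paste(format(Q[p, ]), collapse = ", "), ")"))
      qdd[p, ] <- sol[seq_len(nq)]
      lam[p, ] <- -sol[nq + seq_len(m)]
    } else {
      qdd[p, ] <- tryCatch(solve(Mp, rhs1), error = function(e)
        stop("singular mass matrix at configuration q = (",
             paste(format(Q[p, ]), collapse = ", "), ")"))
    }
  }
  if (vec) list(qdd = as.numeric(qdd), lambda = as.numeric(lam))
  else list(qdd = qdd, lambda = lam)
}

#' Joint reaction load
#'
#' Reaction force transmitted from the parent body to the named body across
#' its parent joint, computed from the Newton-Euler balance of the subtree
#' distal to the joint: `F = sum_i (m_i a_i - m_i g - f_ext,i)` over the
#' subtree, where `f_ext` are muscle path and contact forces applied to
#' subtree bodies. The force is expressed in the child-body frame (the force
#' part only; moments are not reported).
#'
#' @param model an [mbs_model()].
#' @param x full state (vector or matrix, model state ordering).
#' @param controls controls (vector or matrix), as in
#'   [applied_generalized_forces()].
#' @param body name of the body whose parent joint is queried.
#' @return `n x 2` matrix (or length-2 vector) of reaction force in the
#'   child-body frame.
#' @export
joint_reaction_load <- function(model, x, controls = NULL, body) {
  if (!body %in% names(model$bodies))
    stop("unknown joint: no body named '", body, "'")
  vec <- !is.matrix(x)
  X <- as_row(x)
  sl <- model_state_layout(model)
  nq <- sl$nq; n <- nrow(X)
  Q <- X[, seq_len(nq), drop = FALSE]
  U <- X[, nq + seq_len(nq), drop = FALSE]
  cl <- model_control_layout(model)
  Uc <- if (is.null(controls)) matrix(0, n, cl$ne + cl$nact) else as_row(controls)
  tau <- applied_generalized_forces(model, X, Uc)
  fd <- forward_dynamics(model, Q, U, as_row(tau))
  kin <- fk_full(model, Q, U, as_row(fd$qdd))
  # subtree of `body`
  sub <- body
  repeat {
    kids <- names(model$bodies)[vapply(model$bodies, function(b)
      b$parent %in% sub, TRUE)]
    new <- setdiff(kids, sub)
    if (!length(new)) break
    sub <- c(sub, new)
  }
  g <- model$gravity
  Fw <- matrix(0, n, 2)
  for (bn in sub) {
    b <- model$bodies[[bn]]
    k <- kin[[bn]]
    Fw[, 1] <- Fw[, 1] + b$mass * (k$a_com[, 1] - g[1])
    Fw[, 2] <- Fw[, 2] + b$mass * (k$a_com[, 2] - g[2])
  }
  # subtract external (muscle, contact) forces applied to subtree bodies
  mus_names <- names(model$muscles)
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    pk <- muscle_path_kinematics(model, Q, U, mus)
    a <- X[, 2 * nq + i]
    ft <- if (!mus$params$rigid_tendon)
      X[, 2 * nq + sl$na + match(mus_names[i], sl$compliant)] else NULL
    tension <- tendon_force(a, pk$l_mt, pk$v_mt, mus$params, ft_tilde = ft)
    for (bf in muscle_body_forces(model, Q, mus, tension, kin = kin))
      if (bf$body %in% sub) Fw <- Fw - bf$force
  }
  for (ce in model$contacts) {
    if (!ce$body %in% sub) next
    pkin <- point_kinematics(model, Q, ce$body, ce$xy, U = U, kin = kin)
    d <- ce$radius - pkin$pos[, 2]
    fo <- contact_force(ce, d, -pkin$vel[, 2], pkin$vel[, 1])
    Fw <- Fw - fo[, 1:2, drop = FALSE]
  }
  th <- kin[[body]]$theta
  Fc <- cbind(cos(th) * Fw[, 1] + sin(th) * Fw[, 2],
              -sin(th) * Fw[, 1] + cos(th) * Fw[, 2])
  if (vec) as.numeric(Fc) else Fc
}
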