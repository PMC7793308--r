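# ---------------------------------------------------------------------------
# Direct-collocation transcription: continuous problem -> sparse NLP.
# ---------------------------------------------------------------------------

#' Transcription settings
#'
#' @param scheme `"hermite-simpson"` (third order; `2N+1` time points for
#'   `N` mesh intervals, with a collocation point at every interval
#'   midpoint) or `"trapezoidal"` (second order, `N+1` points).
#' @param n_intervals number of mesh intervals `N` (>= 2); uniform mesh.
#' @param dynamics_mode `"explicit"` (forward dynamics inside the state
#'   derivative) or `"implicit"` (accelerations become extra control
#'   variables and the inverse-dynamics residual is enforced as a path
#'   constraint).
#' @param conv_tol convergence tolerance on the KKT conditions.
#' @param con_tol largest permissible single constraint violation.
#' @param fd_step central finite-difference step for NLP derivatives.
#' @param multiplier_bound bound on constraint-multiplier variables.
#' @param gamma_bound bound on the Hermite-Simpson midpoint velocity
#'   correction variables.
#' @param accel_bound bound on implicit-mode acceleration variables.
#' @param ftdot_scale scaling (1/s) applied to the auxiliary control driving
#'   the normalized tendon-force state.
#' @param max_iterations solver iteration budget.
#' @return list of settings for [transcribe()] and [solve_ocp()].
#' @export
transcription_config <- function(scheme = c("hermite-simpson", "trapezoidal"),
                                 n_intervals = 25,
                                 dynamics_mode = c("explicit", "implicit"),
                                 conv_tol = 1e-3, con_tol = 1e-3,
                                 fd_step = 1e-6, multiplier_bound = 1000,
                                 gamma_bound = 0.1, accel_bound = 1e4,
                                 ftdot_scale = 50, max_iterations = 3000) {
  scheme <- match.arg(scheme)
  dynamics_mode <- match.arg(dynamics_mode)
  stopifnot(conv_tol > 0, con_tol > 0, fd_step > 0)
  if (n_intervals < 2) stop("n_intervals must be >= 2")
  list(scheme = scheme, n_intervals = as.integer(n_intervals),
       dynamics_mode = dynamics_mode, conv_tol = conv_tol,
       con_tol = con_tol, fd_step = fd_step,
       multiplier_bound = multiplier_bound, gamma_bound = gamma_bound,
       accel_bound = accel_bound, ftdot_scale = ftdot_scale,
       max_iterations = max_iterations)
}

#' Build the collocation time grid
#'
#' Uniform mesh on `[t0, tf]`; the Hermite-Simpson scheme adds the interval
#' midpoints, so `N` mesh intervals give `2N+1` time points (`N+1` for the
#' trapezoidal scheme).
#'
#' @param config a [transcription_config()].
#' @param t0,tf horizon endpoints (`tf > t0`).
#' @return numeric vector of time points.
#' @export
build_grid <- function(config, t0, tf) {
  if (config$n_intervals < 2) stop("n_intervals must be >= 2")
  if (tf <= t0) stop("tf must exceed t0")
  N <- config$n_intervals
  if (config$scheme == "trapezoidal") seq(t0, tf, length.out = N + 1)
  else seq(t0, tf, length.out = 2 * N + 1)
}

#' Collocation defect operators
#'
#' `trapezoidal_defect` returns
#' `x_{k+1} - x_k - h/2 (f_k + f_{k+1})`; exact when the state derivative is
#' linear in time. `hermite_simpson_defect` returns the Hermite
#' interpolation defect `x_mid - (x_k + x_{k+1})/2 - h/8 (f_k - f_{k+1})`
#' and the Simpson integration defect
#' `x_{k+1} - x_k - h/6 (f_k + 4 f_mid + f_{k+1})`; exact through cubic
#' trajectories. Arguments may be vectors (state blocks) or matrices
#' (rows = intervals).
#'
#' @param x_k,x_mid,x_k1 states at the interval start, midpoint, end.
#' @param f_k,f_mid,f_k1 state derivatives at those points.
#' @param h mesh interval length (> 0).
#' @return defect vector, or `list(interp, integ)` for Hermite-Simpson.
#' @export
trapezoidal_defect <- function(x_k, x_k1, f_k, f_k1, h) {
  stopifnot(all(h > 0))
  x_k1 - x_k - h / 2 * (f_k + f_k1)
}

#' @rdname trapezoidal_defect
#' @export
hermite_simpson_defect <- function(x_k, x_mid, x_k1, f_k, f_mid, f_k1, h) {
  stopifnot(all(h > 0))
  list(interp = x_mid - (x_k + x_k1) / 2 - h / 8 * (f_k - f_k1),
       integ = x_k1 - x_k - h / 6 * (f_k + 4 * f_mid + f_k1))
}

# ---------------------------------------------------------------------------
# Batched continuous dynamics for a multibody model.
#
# One call evaluates the state derivative (and implicit-mode residuals,
# holonomic-constraint residuals, and tendon-equilibrium residuals) at every
# time point simultaneously. All coordinate-dependent derivatives (mass
# matrix, moment arms, constraint Jacobian, contact-point Jacobians) come
# from a single set of complex-step forward-kinematics passes shared across
# force elements.
# ---------------------------------------------------------------------------

# A model is a "simple point mass" when it is one body on a translational
# point joint at the ground origin with all muscle/contact attachments at its
# origin and ground anchors: the mass matrix is a constant diagonal, muscle
# path lengths are |q - anchor| with analytic moment arms, and no
# complex-step kinematics passes are needed. This is a pure fast path: the
# generic branch computes identical quantities (cross-checked in the tests).
is_simple_point_mass <- function(model) {
  if (length(model$bodies) != 1L) return(FALSE)
  b <- model$bodies[[1]]
  if (b$joint != "point" || b$parent != "ground") return(FALSE)
  if (any(b$joint_parent != 0) || any(b$joint_child != 0) ||
      any(b$com != 0)) return(FALSE)
  if (length(model$constraints) || length(model$contacts)) return(FALSE)
  for (mus in model$muscles) {
    if (length(mus$path) != 2) return(FALSE)
    bodies <- vapply(mus$path, `[[`, "", "body")
    if (!setequal(bodies, c("ground", b$name))) return(FALSE)
    own <- mus$path[[which(bodies == b$name)]]
    if (any(own$xy != 0)) return(FALSE)
  }
  TRUE
}

# Per-model evaluation cache: layout tables, index lookups, and fast-path
# metadata computed once per transcription instead of at every dynamics
# evaluation. Invariant under free-parameter values (those only change
# scalar fields read from the model itself).
model_eval_cache <- function(model) {
  cd <- model_coords(model)
  sl <- model_state_layout(model)
  cl <- model_control_layout(model)
  anchors <- NULL
  simple <- is_simple_point_mass(model) && !sl$nft
  if (simple)
    anchors <- lapply(model$muscles, function(mus) {
      bodies <- vapply(mus$path, `[[`, "", "body")
      mus$path[[which(bodies == "ground")]]$xy
    })
  list(cd = cd, sl = sl, cl = cl, m = n_constraint_eq(model),
       simple = simple, anchors = anchors,
       spring_idx = vapply(model$springs,
                           function(s) match(s$coord, cd$name), 0L),
       act_idx = vapply(model$actuators,
                        function(a) match(a$coord, cd$name), 0L))
}

point_mass_dynamics_batch <- function(model, X, Uall, cfg, mode, gamma,
                                      cache) {
  b <- model$bodies[[1]]
  na <- cache$sl$na; ne <- cache$cl$ne; nact <- cache$cl$nact
  n <- nrow(X)
  Q <- X[, 1:2, drop = FALSE]; U <- X[, 3:4, drop = FALSE]
  A <- if (na) X[, 4 + seq_len(na), drop = FALSE] else NULL
  tau <- matrix(0, n, 2)
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    anchor <- cache$anchors[[i]]
    dx <- Q[, 1] - anchor[1]; dy <- Q[, 2] - anchor[2]
    L <- sqrt(dx^2 + dy^2)
    g1 <- dx / L; g2 <- dy / L          # d l / d q
    v <- g1 * U[, 1] + g2 * U[, 2]
    f <- tendon_force(A[, i], L, v, mus$params, smooth = TRUE)
    tau[, 1] <- tau[, 1] - g1 * f
    tau[, 2] <- tau[, 2] - g2 * f
  }
  for (si in seq_along(model$springs)) {
    s <- model$springs[[si]]; j <- cache$spring_idx[si]
    tau[, j] <- tau[, j] - s$stiffness * (Q[, j] - s$equilibrium)
  }
  for (i in seq_along(model$actuators)) {
    j <- cache$act_idx[i]
    tau[, j] <- tau[, j] + model$actuators[[i]]$gain * Uall[, ne + i]
  }
  gx <- model$gravity
  if (mode == "explicit") {
    udot <- cbind(tau[, 1] / b$mass + gx[1], tau[, 2] / b$mass + gx[2])
    imp <- NULL
  } else {
    off <- ne + nact
    W <- Uall[, off + 1:2, drop = FALSE]
    udot <- W
    imp <- cbind(b$mass * (W[, 1] - gx[1]) - tau[, 1],
                 b$mass * (W[, 2] - gx[2]) - tau[, 2])
  }
  adot <- NULL
  if (na) {
    adot <- matrix(0, n, na)
    for (i in seq_len(na))
      adot[, i] <- activation_derivative(Uall[, i], A[, i],
                                         model$muscles[[i]]$params)
  }
  list(Xdot = cbind(U, udot, adot), imp = imp, tendon = NULL,
       phi = NULL, Gu = NULL)
}

mbs_dynamics_batch <- function(model, X, Uall, cfg, mode = "explicit",
                               gamma = NULL, want_kin_rows = FALSE,
                               cache = NULL) {
  if (is.null(cache)) cache <- model_eval_cache(model)
  if (cache$simple)
    return(point_mass_dynamics_batch(model, X, Uall, cfg, mode, gamma,
                                     cache))
  sl <- cache$sl
  cl <- cache$cl
  nq <- sl$nq; na <- sl$na; nft <- sl$nft
  n <- nrow(X)
  m <- cache$m
  Q <- X[, seq_len(nq), drop = FALSE]
  U <- X[, nq + seq_len(nq), drop = FALSE]
  A <- if (na) X[, 2 * nq + seq_len(na), drop = FALSE] else NULL
  FT <- if (nft) X[, 2 * nq + na + seq_len(nft), drop = FALSE] else NULL
  ne <- cl$ne; nact <- cl$nact
  Exc <- if (ne) Uall[, seq_len(ne), drop = FALSE] else NULL
  ActU <- if (nact) Uall[, ne + seq_len(nact), drop = FALSE] else NULL
  off <- ne + nact
  Lam <- if (m) Uall[, off + seq_len(m), drop = FALSE] else NULL
  off <- off + m
  W <- if (mode == "implicit") Uall[, off + seq_len(nq), drop = FALSE] else NULL
  if (mode == "implicit") off <- off + nq
  Kft <- if (nft) Uall[, off + seq_len(nft), drop = FALSE] else NULL

  kin <- fk_full(model, Q, U)
  # complex-step passes, one per coordinate, shared by every consumer
  kin_c <- vector("list", nq)
  for (j in seq_len(nq)) {
    Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
    kin_c[[j]] <- fk_full(model, Qc)
  }
  bn <- names(model$bodies)
  Jcom <- lapply(bn, function(b)
    vapply(seq_len(nq), function(j) Im(kin_c[[j]][[b]]$com) / CS_H,
           matrix(0, n, 2)))
  names(Jcom) <- bn # n x 2 x nq arrays
  Jth <- lapply(bn, function(b)
    vapply(seq_len(nq), function(j) Im(kin_c[[j]][[b]]$theta) / CS_H,
           numeric(n)))
  names(Jth) <- bn # n x nq matrices (n>1) -- normalize below
  norm_jth <- function(x) if (is.matrix(x)) x else matrix(x, n, nq)
  Jth <- lapply(Jth, norm_jth)

  gvec <- model$gravity
  id_from_kin <- function(kin_acc) {
    tau <- matrix(0, n, nq)
    for (b in model$bodies) {
      k <- kin_acc[[b$name]]
      fa1 <- b$mass * (k$a_com[, 1] - gvec[1])
      fa2 <- b$mass * (k$a_com[, 2] - gvec[2])
      Ia <- b$inertia * k$alpha
      Jc <- Jcom[[b$name]]; Jt <- Jth[[b$name]]
      for (j in seq_len(nq))
        tau[, j] <- tau[, j] + fa1 * Jc[, 1, j] + fa2 * Jc[, 2, j] +
          Ia * Jt[, j]
    }
    tau
  }
  Z <- matrix(0, n, nq)
  cc <- id_from_kin(fk_full(model, Q, U, Z)) # velocity bias minus gravity

  # applied generalized forces
  tau <- matrix(0, n, nq)
  mus_l <- mus_v <- mus_arms <- list()
  mus_names <- names(model$muscles)
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    L <- Re(muscle_path_lengths(model, Q, mus, kin = kin))
    dl <- vapply(seq_len(nq), function(j)
      Im(muscle_path_lengths(model, Q, mus, kin = kin_c[[j]])) / CS_H,
      numeric(n))
    dl <- matrix(dl, n, nq)
    v <- rowSums(dl * U)
    ft <- if (!mus$params$rigid_tendon)
      FT[, match(mus_names[i], sl$compliant)] else NULL
    f <- tendon_force(A[, i], L, v, mus$params, ft_tilde = ft, smooth = TRUE)
    tau <- tau - dl * f
    mus_l[[i]] <- L; mus_v[[i]] <- v; mus_arms[[i]] <- -dl
  }
  cd <- cache$cd
  for (s in model$springs) {
    j <- match(s$coord, cd$name)
    tau[, j] <- tau[, j] - s$stiffness * (Q[, j] - s$equilibrium)
  }
  for (i in seq_along(model$actuators)) {
    a <- model$actuators[[i]]
    j <- match(a$coord, cd$name)
    tau[, j] <- tau[, j] + a$gain * ActU[, i]
  }
  for (ce in model$contacts) {
    pk <- point_kinematics(model, Q, ce$body, ce$xy, U = U, kin = kin)
    d <- ce$radius - pk$pos[, 2]
    fo <- contact_force(ce, d, -pk$vel[, 2], pk$vel[, 1])
    for (j in seq_len(nq)) {
      Jp <- Im(point_kinematics(model, Q * (1 + 0i), ce$body, ce$xy,
                                kin = kin_c[[j]])$pos) / CS_H
      tau[, j] <- tau[, j] + fo[, 1] * Jp[, 1] + fo[, 2] * Jp[, 2]
    }
  }
  # holonomic constraints: phi, G, G u (for path rows and G' lambda)
  phi <- Gu <- NULL
  G <- NULL
  if (m) {
    phi_from_kin <- function(kk, Qx) {
      cols <- list()
      for (cn in model$constraints) {
        if (cn$type == "point_coincidence") {
          pa <- point_kinematics(model, Qx, cn$body_a, cn$xy_a, kin = kk)$pos
          pb <- point_kinematics(model, Qx, cn$body_b, cn$xy_b, kin = kk)$pos
          cols[[length(cols) + 1]] <- pa - pb
        } else {
          idx <- match(cn$coords, cd$name)
          v <- 0
          for (k2 in seq_along(idx)) v <- v + cn$coeffs[k2] * Qx[, idx[k2]]
          cols[[length(cols) + 1]] <- cbind(v - cn$constant)
        }
      }
      do.call(cbind, cols)
    }
    phi <- Re(phi_from_kin(kin, Q))
    G <- array(0, c(n, m, nq))
    for (j in seq_len(nq)) {
      Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
      G[, , j] <- Im(phi_from_kin(kin_c[[j]], Qc)) / CS_H
    }
    Gu <- matrix(0, n, m)
    for (k2 in seq_len(m)) Gu[, k2] <- rowSums(matrix(G[, k2, ], n, nq) * U)
    if (!is.null(Lam))
      for (j in seq_len(nq))
        for (k2 in seq_len(m))
          tau[, j] <- tau[, j] + G[, k2, j] * Lam[, k2]
  }

  # accelerations
  if (mode == "explicit") {
    rhs <- tau - cc
    M <- array(0, c(n, nq, nq))
    for (j in seq_len(nq)) {
      E <- Z; E[, j] <- 1
      M[, , j] <- id_from_kin(fk_full(model, Q, Z, E)) -
        id_from_kin(fk_full(model, Q, Z, Z))
    }
    udot <- matrix(0, n, nq)
    if (nq == 1) {
      udot[, 1] <- rhs[, 1] / M[, 1, 1]
    } else if (nq == 2) {
      det <- M[, 1, 1] * M[, 2, 2] - M[, 1, 2] * M[, 2, 1]
      udot[, 1] <- (M[, 2, 2] * rhs[, 1] - M[, 1, 2] * rhs[, 2]) / det
      udot[, 2] <- (-M[, 2, 1] * rhs[, 1] + M[, 1, 1] * rhs[, 2]) / det
    } else {
      for (p in seq_len(n))
        udot[p, ] <- solve(matrix(M[p, , ], nq, nq), rhs[p, ])
    }
    imp <- NULL
  } else {
    udot <- W
    imp <- id_from_kin(fk_full(model, Q, U, W)) - tau
  }

  qdot <- U
  if (m && !is.null(gamma)) {
    for (j in seq_len(nq))
      for (k2 in seq_len(m))
        qdot[, j] <- qdot[, j] + G[, k2, j] * gamma[, k2]
  }
  adot <- NULL
  if (na) {
    adot <- matrix(0, n, na)
    for (i in seq_len(na))
      adot[, i] <- activation_derivative(Exc[, i], A[, i],
                                         model$muscles[[i]]$params)
  }
  ftdot <- if (nft) cfg$ftdot_scale * Kft else NULL
  tendon_res <- NULL
  if (nft) {
    tendon_res <- matrix(0, n, nft)
    for (k2 in seq_len(nft)) {
      i <- match(sl$compliant[k2], mus_names)
      tendon_res[, k2] <- tendon_equilibrium_residual(
        A[, i], mus_l[[i]], mus_v[[i]], FT[, k2],
        cfg$ftdot_scale * Kft[, k2], model$muscles[[i]]$params,
        mus_names[i])
    }
  }
  Xdot <- cbind(qdot, udot, adot, ftdot)
  list(Xdot = Xdot, imp = imp, tendon = tendon_res,
       phi = if (want_kin_rows) phi else NULL,
       Gu = if (want_kin_rows) Gu else NULL)
}

# ---------------------------------------------------------------------------
# NLP assembly
# ---------------------------------------------------------------------------

# Decision-variable layout. Ordering: optional duration slot, state block
# (point-major), control block (point-major; model controls, then constraint
# multipliers lambda, then implicit accelerations w, then tendon-derivative
# controls), Hermite-Simpson midpoint velocity corrections gamma, then
# parameters. The index map is a bijection onto 1..nv by construction.
build_layout <- function(problem, config) {
  model <- problem$model
  N <- config$n_intervals
  hs <- config$scheme == "hermite-simpson"
  n_pts <- if (hs) 2L * N + 1L else N + 1L
  nx <- nrow(problem$states)
  ctrl_names <- problem$controls$name
  m <- if (!is.null(model)) n_constraint_eq(model) else 0L
  nq <- if (!is.null(model)) n_coords(model) else 0L
  nft <- if (!is.null(model)) model_state_layout(model)$nft else 0L
  extra <- character(0)
  if (m) extra <- c(extra, paste0("lambda", seq_len(m)))
  if (config$dynamics_mode == "implicit") {
    if (is.null(model)) stop("implicit dynamics requires a multibody model")
    extra <- c(extra, paste0("w_", model_coords(model)$name))
  }
  if (nft) extra <- c(extra,
                      paste0(model_state_layout(model)$compliant, "_dftilde"))
  nu <- length(ctrl_names) + length(extra)
  free_time <- problem$tf_range[1] != problem$tf_range[2]
  k <- 0L
  i_dt <- if (free_time) { k <- k + 1L; 1L } else integer(0)
  ix <- matrix(k + seq_len(n_pts * nx), n_pts, nx); k <- k + n_pts * nx
  iu <- if (nu) matrix(k + seq_len(n_pts * nu), n_pts, nu) else
    matrix(0L, n_pts, 0); k <- k + n_pts * nu
  igam <- if (hs && m) matrix(k + seq_len(N * m), N, m) else NULL
  if (hs && m) k <- k + N * m
  np <- length(problem$parameters)
  ipar <- if (np) k + seq_len(np) else integer(0); k <- k + np
  mesh_idx <- if (hs) seq(1L, n_pts, by = 2L) else seq_len(n_pts)
  mid_idx <- if (hs) seq(2L, n_pts, by = 2L) else integer(0)
  list(free_time = free_time, i_dt = i_dt, ix = ix, iu = iu, igam = igam,
       ipar = ipar, nv = k, n_pts = n_pts, N = N, hs = hs, nx = nx,
       nu = nu, n_model_ctrl = length(ctrl_names), m = m, nft = nft,
       state_names = problem$states$name,
       control_names = c(ctrl_names, extra), np = np,
       mesh_idx = mesh_idx, mid_idx = mid_idx,
       tau_grid = seq(0, 1, length.out = n_pts))
}

# quadrature weights on the normalized grid (multiply by dt for time weights)
quad_weights_norm <- function(layout) {
  if (layout$hs) {
    w <- numeric(layout$n_pts)
    w[layout$mesh_idx] <- 2 / 6; w[c(1, layout$n_pts)] <- 1 / 6
    w[layout$mid_idx] <- 4 / 6
    w / layout$N
  } else {
    w <- rep(1, layout$n_pts); w[c(1, layout$n_pts)] <- 0.5
    w / layout$N
  }
}

goal_integrand_matrix <- function(problem, goals, model_p, Tt, X, Uall,
                                  layout, dt) {
  n <- length(Tt)
  out <- matrix(0, n, length(goals))
  for (gi in seq_along(goals)) {
    g <- goals[[gi]]
    val <- switch(g$kind,
      control_effort = {
        Um <- Uall[, seq_len(layout$n_model_ctrl), drop = FALSE]
        w <- rep(1, ncol(Um))
        if (!is.null(g$weights)) {
          w <- numeric(ncol(Um))
          idx <- match(names(g$weights),
                       layout$control_names[seq_len(layout$n_model_ctrl)])
          w[idx[!is.na(idx)]] <- unlist(g$weights)[!is.na(idx)]
        }
        v <- as.numeric(abs(Um)^g$exponent %*% w)
        if (isTRUE(g$divide_by_duration)) v / dt else v
      },
      state_tracking = {
        funs <- attr(g, "interp")
        if (is.null(funs)) funs <- traj_interpolant(g$reference)
        v <- 0
        for (ch in names(funs)) {
          si <- match(ch, layout$state_names)
          if (is.na(si)) next
          w <- if (!is.null(g$weights) && ch %in% names(g$weights))
            g$weights[[ch]] else 1
          v <- v + w * (X[, si] - funs[[ch]](Tt))^2
        }
        v
      },
      joint_reaction = {
        F <- joint_reaction_load(model_p, X, Uall[, seq_len(layout$n_model_ctrl),
                                                  drop = FALSE], g$body)
        F[, 1]^2 + F[, 2]^2
      },
      final_time = numeric(n))
    out[, gi] <- g$weight * val
  }
  out
}

goal_terminal_values <- function(problem, goals, tf) {
  vapply(goals, function(g)
    if (g$kind == "final_time") g$weight * tf else 0, 0)
}

#' Transcribe a continuous problem into a nonlinear program
#'
#' Applies the chosen collocation scheme on a uniform mesh. States and
#' controls (including constraint multipliers, implicit-mode accelerations,
#' and tendon-derivative controls) become variables at every grid point;
#' controls are treated as piecewise linear between grid points, with
#' Hermite-Simpson midpoint values free. A free final time is handled by
#' normalizing time to `[0, 1]` with the duration as an extra variable.
#' Holonomic constraints contribute position- and velocity-level rows at
#' every mesh point, multipliers enter the dynamics everywhere, and at
#' Hermite-Simpson midpoints the coordinate derivative is augmented with a
#' bounded velocity correction `G' gamma`.
#'
#' @param problem a validated [ocp()].
#' @param config a [transcription_config()].
#' @return an NLP structure for [nlp_solve()], carrying the layout map.
#' @export
transcribe <- function(problem, config = transcription_config()) {
  validate_problem(problem)
  layout <- build_layout(problem, config)
  model <- problem$model
  n_pts <- layout$n_pts; nx <- layout$nx; nu <- layout$nu
  N <- layout$N; hs <- layout$hs
  t0 <- problem$t0
  # cache tracking interpolants
  goals <- problem$goals
  for (gi in seq_along(goals))
    if (goals[[gi]]$kind == "state_tracking")
      attr(goals[[gi]], "interp") <- traj_interpolant(goals[[gi]]$reference)

  # ---- bounds --------------------------------------------------------------
  lb <- rep(-Inf, layout$nv); ub <- rep(Inf, layout$nv)
  if (layout$free_time) {
    lb[layout$i_dt] <- problem$tf_range[1] - t0
    ub[layout$i_dt] <- problem$tf_range[2] - t0
  }
  st <- problem$states
  for (j in seq_len(nx)) {
    lb[layout$ix[, j]] <- st$lower[j]; ub[layout$ix[, j]] <- st$upper[j]
    lb[layout$ix[1, j]] <- st$initial_lower[j]
    ub[layout$ix[1, j]] <- st$initial_upper[j]
    lb[layout$ix[n_pts, j]] <- st$final_lower[j]
    ub[layout$ix[n_pts, j]] <- st$final_upper[j]
  }
  ct <- problem$controls
  nmc <- layout$n_model_ctrl
  for (j in seq_len(nmc)) {
    lb[layout$iu[, j]] <- ct$lower[j]; ub[layout$iu[, j]] <- ct$upper[j]
  }
  extra_off <- nmc
  if (layout$m) {
    for (k in seq_len(layout$m)) {
      lb[layout$iu[, extra_off + k]] <- -config$multiplier_bound
      ub[layout$iu[, extra_off + k]] <- config$multiplier_bound
    }
    extra_off <- extra_off + layout$m
  }
  if (config$dynamics_mode == "implicit") {
    nq <- n_coords(model)
    for (k in seq_len(nq)) {
      lb[layout$iu[, extra_off + k]] <- -config$accel_bound
      ub[layout$iu[, extra_off + k]] <- config$accel_bound
    }
    extra_off <- extra_off + nq
  }
  if (layout$nft) {
    for (k in seq_len(layout$nft)) {
      lb[layout$iu[, extra_off + k]] <- -1
      ub[layout$iu[, extra_off + k]] <- 1
    }
  }
  if (!is.null(layout$igam)) {
    lb[layout$igam] <- -config$gamma_bound
    ub[layout$igam] <- config$gamma_bound
  }
  if (layout$np) {
    for (k in seq_len(layout$np)) {
      lb[layout$ipar[k]] <- problem$parameters[[k]]$lower
      ub[layout$ipar[k]] <- problem$parameters[[k]]$upper
    }
  }
  # time-varying control-bound path constraints -> per-point bounds
  if (length(problem$path)) {
    if (layout$free_time &&
        any(vapply(problem$path, function(p) p$type == "control_bound", TRUE)))
      stop("control-bound envelopes require a fixed time horizon")
    Tt <- t0 + (problem$tf_range[1] - t0) * layout$tau_grid
    for (p in problem$path) {
      if (p$type != "control_bound") next
      j <- match(p$control, ct$name)
      lo <- p$lower(Tt); hi <- p$upper(Tt)
      if (any(lo > hi))
        stop("control-bound path constraint: lower exceeds upper at t = ",
             format(Tt[which(lo > hi)[1]]))
      lb[layout$iu[, j]] <- pmax(lb[layout$iu[, j]], lo)
      ub[layout$iu[, j]] <- pmin(ub[layout$iu[, j]], hi)
    }
  }

  # ---- constraint row bookkeeping ------------------------------------------
  # rows per fine point accumulated while laying out the constraint vector
  pt_rows <- vector("list", n_pts)
  for (p in seq_len(n_pts)) pt_rows[[p]] <- integer(0)
  row_ct <- 0L
  defect_rows <- integer(0)
  add_rows <- function(pts, k) {
    rows <- row_ct + seq_len(k)
    for (p in pts) pt_rows[[p]] <<- c(pt_rows[[p]], rows)
    row_ct <<- row_ct + k
    rows
  }
  interval_pts <- function(k)
    if (hs) c(2L * k - 1L, 2L * k, 2L * k + 1L) else c(k, k + 1L)
  gam_rows <- vector("list", N)
  for (k in seq_len(N)) {
    nd <- if (hs) 2L * nx else nx
    r <- add_rows(interval_pts(k), nd)
    defect_rows <- c(defect_rows, r)
    gam_rows[[k]] <- r
  }
  imp_rows <- NULL
  if (!is.null(model) && config$dynamics_mode == "implicit") {
    nq <- n_coords(model)
    imp_rows <- lapply(seq_len(n_pts), function(p) add_rows(p, nq))
  }
  kin_rows <- NULL
  if (layout$m) {
    kin_rows <- lapply(layout$mesh_idx, function(p) add_rows(p, 2L * layout$m))
  }
  # Hermite-Simpson midpoint multipliers are tied to the linear interpolant
  # of the interval endpoints (lambda is piecewise linear); leaving them
  # free creates a sawtooth null mode under the Simpson weights that drifts
  # the multipliers to their bounds.
  lam_tie_rows <- NULL
  if (hs && layout$m)
    lam_tie_rows <- lapply(seq_len(N), function(k)
      add_rows(c(2L * k - 1L, 2L * k, 2L * k + 1L), layout$m))
  tendon_rows <- NULL
  if (layout$nft)
    tendon_rows <- lapply(seq_len(n_pts), function(p) add_rows(p, layout$nft))
  custom_paths <- Filter(function(p) p$type == "custom", problem$path)
  custom_rows <- NULL
  if (length(custom_paths)) {
    ncust <- sum(vapply(custom_paths, `[[`, 0, "n_eq"))
    custom_rows <- lapply(seq_len(n_pts), function(p) add_rows(p, ncust))
  }
  n_bnd <- 0L
  for (b in problem$boundary)
    n_bnd <- n_bnd + if (b$type == "periodicity") length(b$pairs) else 1L
  bnd_rows <- if (n_bnd) add_rows(c(1L, n_pts), n_bnd) else integer(0)
  n_con <- row_ct

  # row scaling: defect rows are divided by the characteristic magnitude of
  # their state (half the bound range) so all residuals are O(1)
  st_scale <- pmax(1, (pmin(problem$states$upper, 1e6) -
                         pmax(problem$states$lower, -1e6)) / 2)
  st_scale[!is.finite(st_scale) | st_scale <= 0] <- 1
  row_scale <- rep(1, n_con)
  if (hs) {
    per_int <- rep(1 / c(st_scale, st_scale), N)
  } else {
    per_int <- rep(1 / st_scale, N)
  }
  row_scale[defect_rows] <- per_int
  # implicit-mode inverse-dynamics residuals carry force/torque units;
  # normalize by the characteristic generalized force at the mid-box pose
  if (!is.null(imp_rows)) {
    qmid <- (pmax(problem$states$lower, -1e6) +
               pmin(problem$states$upper, 1e6))[seq_len(n_coords(model))] / 2
    Mmid <- mass_matrix(model, qmid)
    id0 <- inverse_dynamics(model, qmid, 0 * qmid, 0 * qmid)
    imp_scale <- 1 / pmax(1, diag(as.matrix(Mmid)), abs(id0))
    row_scale[unlist(imp_rows)] <- rep(imp_scale, layout$n_pts)
  }

  # objective contributions: one per fine point plus one per goal (terminal)
  n_goal <- length(goals)
  n_contrib <- n_pts + n_goal

  # ---- stencils and colors -------------------------------------------------
  col_rows_con <- vector("list", layout$nv)
  col_rows_obj <- vector("list", layout$nv)
  colors <- integer(layout$nv)
  # grid points three apart never share a constraint row, so a mod-3
  # coloring suffices; boundary-constraint rows couple the first and last
  # points to everything at those times, which then need their own classes
  cls_of_pt <- if (n_bnd) {
    function(p) if (p == 1L) 1L else if (p == n_pts) 2L else 3L + (p %% 3L)
  } else {
    function(p) 1L + (p %% 3L)
  }
  nslot <- nx + nu
  for (p in seq_len(n_pts)) {
    rows <- sort(unique(pt_rows[[p]]))
    orows <- p
    if (p == n_pts) orows <- c(orows, n_pts + seq_len(n_goal))
    cls <- cls_of_pt(p)
    for (j in seq_len(nx)) {
      v <- layout$ix[p, j]
      col_rows_con[[v]] <- rows; col_rows_obj[[v]] <- orows
      colors[v] <- (j - 1L) * 5L + cls
    }
    for (j in seq_len(nu)) {
      v <- layout$iu[p, j]
      col_rows_con[[v]] <- rows; col_rows_obj[[v]] <- orows
      colors[v] <- (nx + j - 1L) * 5L + cls
    }
  }
  next_color <- nslot * 5L
  if (!is.null(layout$igam)) {
    for (j in seq_len(layout$m)) {
      next_color <- next_color + 1L
      for (k in seq_len(N)) {
        v <- layout$igam[k, j]
        col_rows_con[[v]] <- gam_rows[[k]]
        col_rows_obj[[v]] <- integer(0)
        colors[v] <- next_color
      }
    }
  }
  if (layout$free_time) {
    next_color <- next_color + 1L
    v <- layout$i_dt
    col_rows_con[[v]] <- c(defect_rows, bnd_rows)
    col_rows_obj[[v]] <- seq_len(n_contrib)
    colors[v] <- next_color
  }
  for (k in seq_len(layout$np)) {
    next_color <- next_color + 1L
    v <- layout$ipar[k]
    col_rows_con[[v]] <- seq_len(n_con)
    col_rows_obj[[v]] <- seq_len(n_contrib)
    colors[v] <- next_color
  }
  # compress color ids
  colors <- match(colors, sort(unique(colors)))

  # ---- evaluation ----------------------------------------------------------
  fixed_dt <- problem$tf_range[1] - t0
  wq_norm <- quad_weights_norm(layout)
  dyn_cache <- if (!is.null(model)) model_eval_cache(model) else NULL
  mesh_idx <- layout$mesh_idx; mid_idx <- layout$mid_idx
  sidx <- seq_len(nx)

  unpack <- function(z) {
    dt <- if (layout$free_time) z[layout$i_dt] else fixed_dt
    X <- matrix(z[layout$ix], n_pts, nx)
    Uall <- if (nu) matrix(z[layout$iu], n_pts, nu) else matrix(0, n_pts, 0)
    gam <- if (!is.null(layout$igam))
      matrix(z[layout$igam], N, layout$m) else NULL
    pars <- if (layout$np) z[layout$ipar] else numeric(0)
    list(dt = dt, X = X, Uall = Uall, gamma = gam, pars = pars,
         Tt = t0 + dt * layout$tau_grid)
  }

  eval_fn <- function(z) {
    u <- unpack(z)
    model_p <- model
    if (layout$np)
      for (k in seq_len(layout$np))
        model_p <- model_set_property(model_p,
                                      problem$parameters[[k]]$path, u$pars[k])
    if (is.null(model)) {
      dyn <- list(Xdot = problem$dynamics(u$Tt, u$X,
                                          u$Uall[, seq_len(nmc), drop = FALSE],
                                          u$pars),
                  imp = NULL, tendon = NULL, phi = NULL, Gu = NULL)
    } else {
      gam_full <- NULL
      if (!is.null(u$gamma)) {
        gam_full <- matrix(0, n_pts, layout$m)
        gam_full[mid_idx, ] <- u$gamma
      }
      dyn <- mbs_dynamics_batch(model_p, u$X, u$Uall, config,
                                mode = config$dynamics_mode,
                                gamma = gam_full,
                                want_kin_rows = layout$m > 0,
                                cache = dyn_cache)
    }
    F <- dyn$Xdot
    h <- u$dt / N
    con <- numeric(n_con)
    if (hs) {
      i1 <- 2L * seq_len(N) - 1L; im <- i1 + 1L; i2 <- i1 + 2L
      dfi <- u$X[im, sidx, drop = FALSE] -
        (u$X[i1, sidx, drop = FALSE] + u$X[i2, sidx, drop = FALSE]) / 2 -
        h / 8 * (F[i1, sidx, drop = FALSE] - F[i2, sidx, drop = FALSE])
      dfg <- u$X[i2, sidx, drop = FALSE] - u$X[i1, sidx, drop = FALSE] -
        h / 6 * (F[i1, sidx, drop = FALSE] + 4 * F[im, sidx, drop = FALSE] +
                   F[i2, sidx, drop = FALSE])
      con[defect_rows] <- as.numeric(t(cbind(dfi, dfg)))
    } else {
      i1 <- seq_len(N); i2 <- i1 + 1L
      dfg <- u$X[i2, , drop = FALSE] - u$X[i1, , drop = FALSE] -
        h / 2 * (F[i1, , drop = FALSE] + F[i2, , drop = FALSE])
      con[defect_rows] <- as.numeric(t(dfg))
    }
    if (!is.null(imp_rows))
      con[unlist(imp_rows)] <- as.numeric(t(dyn$imp))
    if (!is.null(kin_rows))
      con[unlist(kin_rows)] <- as.numeric(t(cbind(
        dyn$phi[mesh_idx, , drop = FALSE], dyn$Gu[mesh_idx, , drop = FALSE])))
    if (!is.null(lam_tie_rows)) {
      lamcols <- nmc + seq_len(layout$m)
      lam_all <- u$Uall[, lamcols, drop = FALSE]
      i1 <- 2L * seq_len(N) - 1L
      tie <- lam_all[i1 + 1L, , drop = FALSE] -
        (lam_all[i1, , drop = FALSE] + lam_all[i1 + 2L, , drop = FALSE]) / 2
      con[unlist(lam_tie_rows)] <- as.numeric(t(tie))
    }
    if (!is.null(tendon_rows))
      con[unlist(tendon_rows)] <- as.numeric(t(dyn$tendon))
    if (!is.null(custom_rows)) {
      res <- do.call(cbind, lapply(custom_paths, function(p)
        p$fn(u$Tt, u$X, u$Uall[, seq_len(nmc), drop = FALSE])))
      con[unlist(custom_rows)] <- as.numeric(t(res))
    }
    if (n_bnd) {
      r <- numeric(0)
      for (b in problem$boundary) {
        if (b$type == "periodicity") {
          for (pp in b$pairs) {
            i_f <- match(pp$final, layout$state_names)
            i_i <- match(pp$initial, layout$state_names)
            sg <- if (is.null(pp$sigma)) 1 else pp$sigma
            r <- c(r, u$X[n_pts, i_f] - sg * u$X[1, i_i])
          }
        } else {
          i_s <- match(b$state, layout$state_names)
          r <- c(r, (u$X[n_pts, i_s] - u$X[1, i_s]) / u$dt - b$v_target)
        }
      }
      con[bnd_rows] <- r
    }
    gi <- goal_integrand_matrix(problem, goals, model_p, u$Tt, u$X, u$Uall,
                                layout, u$dt)
    contrib <- c((u$dt * wq_norm) * rowSums(gi),
                 goal_terminal_values(problem, goals, t0 + u$dt))
    list(contrib = contrib, con = con * row_scale)
  }

  nlp <- new_nlp(layout$nv, lb, ub, eval_fn, col_rows_con, col_rows_obj,
                 colors, n_con, n_contrib,
                 fd_step = config$fd_step, layout = layout)
  nlp$problem <- problem
  nlp$config <- config
  nlp$unpack <- unpack
  nlp$row_groups <- list(defect = defect_rows,
                         path = c(unlist(imp_rows), unlist(kin_rows),
                                  unlist(lam_tie_rows), unlist(tendon_rows),
                                  unlist(custom_rows)),
                         boundary = bnd_rows)
  nlp
}

#' Default initial guess: midpoint of the variable bounds
#'
#' Variables with one or both bounds infinite default to the finite bound or
#' zero.
#'
#' @param nlp a transcribed NLP.
#' @return numeric vector of length `nlp$nv`.
#' @export
default_guess <- function(nlp) {
  lo <- nlp$lb; hi <- nlp$ub
  g <- (lo + hi) / 2
  g[!is.finite(g)] <- 0
  g <- pmin(pmax(g, lo), hi)
  g[!is.finite(g)] <- 0
  g
}

# Pack a trajectory (e.g. a previous solution) into a decision vector for
# guess chaining; missing columns fall back to the midpoint guess.
pack_guess <- function(nlp, traj) {
  layout <- nlp$layout
  z <- default_guess(nlp)
  tf_guess <- traj$time[length(traj$time)]
  if (layout$free_time)
    z[layout$i_dt] <- min(max(tf_guess - nlp$problem$t0, nlp$lb[layout$i_dt]),
                          nlp$ub[layout$i_dt])
  dt <- if (layout$free_time) z[layout$i_dt] else
    nlp$problem$tf_range[1] - nlp$problem$t0
  Tt <- nlp$problem$t0 + dt * layout$tau_grid
  Tt <- pmin(pmax(Tt, traj$time[1]), traj$time[length(traj$time)])
  rs <- resample_trajectory(traj, Tt)
  for (j in seq_len(layout$nx)) {
    nm <- layout$state_names[j]
    if (nm %in% colnames(rs$states)) z[layout$ix[, j]] <- rs$states[, nm]
  }
  for (j in seq_len(layout$nu)) {
    nm <- layout$control_names[j]
    if (nm %in% colnames(rs$controls)) z[layout$iu[, j]] <- rs$controls[, nm]
    else if (nm %in% colnames(rs$multipliers))
      z[layout$iu[, j]] <- rs$multipliers[, nm]
  }
  if (layout$np) {
    pn <- names(nlp$problem$parameters)
    for (k in seq_len(layout$np))
      if (pn[k] %in% names(traj$parameters))
        z[layout$ipar[k]] <- traj$parameters[[pn[k]]]
  }
  pmin(pmax(z, nlp$lb), nlp$ub)
}
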