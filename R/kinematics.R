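# ---------------------------------------------------------------------------
# Batched planar kinematics.
#
# All kinematic quantities are evaluated for a whole grid of configurations at
# once: Q, U, A are n x nq matrices (one row per time point). Position-level
# functions accept complex matrices so that exact derivatives with respect to
# coordinates are available through complex-step differentiation
# (Im(f(q + i*h*e_j))/h with h = 1e-20, exact to machine precision for the
# sin/cos/sqrt arithmetic used here).
# ---------------------------------------------------------------------------

CS_H <- 1e-20

rot2 <- function(theta, v) {
  # v: length-2 vector or n x 2 matrix; theta: n-vector
  ct <- cos(theta); st <- sin(theta)
  if (is.matrix(v)) cbind(ct * v[, 1] - st * v[, 2], st * v[, 1] + ct * v[, 2])
  else cbind(ct * v[1] - st * v[2], st * v[1] + ct * v[2])
}

perp2 <- function(w) cbind(-w[, 2], w[, 1])

coord_index_map <- function(model) {
  idx <- list(); k <- 0L
  for (b in model$bodies) {
    nc <- length(b$coords)
    idx[[b$name]] <- if (nc) k + seq_len(nc) else integer(0)
    k <- k + nc
  }
  idx
}

# Full forward pass: positions always; velocities if U given; accelerations
# if A given. Returns per-body lists with theta/omega/alpha and
# origin/v_origin/a_origin plus mass-center kinematics.
fk_full <- function(model, Q, U = NULL, A = NULL) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  n <- nrow(Q)
  cmap <- coord_index_map(model)
  zero <- if (is.complex(Q)) rep(0 + 0i, n) else numeric(n)
  z2 <- cbind(zero, zero)
  out <- list(ground = list(theta = zero, omega = zero, alpha = zero,
                            origin = z2, v_origin = z2, a_origin = z2))
  getU <- function(j) if (is.null(U)) zero else U[, j]
  getA <- function(j) if (is.null(A)) zero else A[, j]
  for (b in model$bodies) {
    p <- out[[b$parent]]
    ci <- cmap[[b$name]]
    jt <- b$joint
    # kinematics of the moving attachment point expressed on the parent
    if (jt %in% c("pin", "weld")) {
      w <- matrix(rep(b$joint_parent, each = n), n)
      wu <- z2; wa <- z2
    } else if (jt == "slider") {
      q1 <- Q[, ci[1]]
      w <- cbind(b$joint_parent[1] + b$axis[1] * q1,
                 b$joint_parent[2] + b$axis[2] * q1)
      ax <- matrix(rep(b$axis, each = n), n)
      wu <- ax * getU(ci[1]); wa <- ax * getA(ci[1])
    } else { # planar or point: translation coords are the first two
      w <- cbind(b$joint_parent[1] + Q[, ci[1]],
                 b$joint_parent[2] + Q[, ci[2]])
      wu <- cbind(getU(ci[1]), getU(ci[2]))
      wa <- cbind(getA(ci[1]), getA(ci[2]))
    }
    Rw <- rot2(p$theta, w); Rwu <- rot2(p$theta, wu); Rwa <- rot2(p$theta, wa)
    anchor_p <- p$origin + Rw
    anchor_v <- p$v_origin + p$omega * perp2(Rw) + Rwu
    anchor_a <- p$a_origin + p$alpha * perp2(Rw) - p$omega^2 * Rw +
      2 * p$omega * perp2(Rwu) + Rwa
    # rotational coordinate
    if (jt == "pin") {
      theta <- p$theta + Q[, ci[1]]
      omega <- p$omega + getU(ci[1]); alpha <- p$alpha + getA(ci[1])
    } else if (jt == "planar") {
      theta <- p$theta + Q[, ci[3]]
      omega <- p$omega + getU(ci[3]); alpha <- p$alpha + getA(ci[3])
    } else {
      theta <- p$theta; omega <- p$omega; alpha <- p$alpha
    }
    Rjc <- rot2(theta, b$joint_child)
    origin <- anchor_p - Rjc
    v_origin <- anchor_v - omega * perp2(Rjc)
    a_origin <- anchor_a - alpha * perp2(Rjc) + omega^2 * Rjc
    Rcom <- rot2(theta, b$com)
    out[[b$name]] <- list(
      theta = theta, omega = omega, alpha = alpha,
      origin = origin, v_origin = v_origin, a_origin = a_origin,
      com = origin + Rcom,
      v_com = v_origin + omega * perp2(Rcom),
      a_com = a_origin + alpha * perp2(Rcom) - omega^2 * Rcom)
  }
  out
}

# Position (and optionally velocity) of a point fixed in a body frame,
# batched over configurations. Complex-safe in Q.
point_kinematics <- function(model, Q, body, xy, U = NULL, kin = NULL) {
  if (is.null(kin)) kin <- fk_full(model, Q, U)
  k <- kin[[body]]
  Rxy <- rot2(k$theta, xy)
  pos <- k$origin + Rxy
  if (is.null(U)) return(list(pos = pos))
  list(pos = pos, vel = k$v_origin + k$omega * perp2(Rxy))
}

# Complex-step Jacobians of body mass-center positions and orientations:
# returns list(Jcom = list over bodies of n x 2 x nq arrays,
#              Jtheta = list over bodies of n x nq matrices).
body_jacobians <- function(model, Q) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  n <- nrow(Q); nq <- ncol(Q)
  bn <- names(model$bodies)
  Jcom <- lapply(bn, function(b) array(0, c(n, 2, nq)))
  Jth <- lapply(bn, function(b) matrix(0, n, nq))
  names(Jcom) <- bn; names(Jth) <- bn
  for (j in seq_len(nq)) {
    Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
    kin <- fk_full(model, Qc)
    for (b in bn) {
      Jcom[[b]][, , j] <- Im(kin[[b]]$com) / CS_H
      Jth[[b]][, j] <- Im(kin[[b]]$theta) / CS_H
    }
  }
  list(Jcom = Jcom, Jtheta = Jth)
}

# Jacobian of a body-fixed point, via complex step; n x 2 x nq.
point_jacobian <- function(model, Q, body, xy) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  n <- nrow(Q); nq <- ncol(Q)
  J <- array(0, c(n, 2, nq))
  for (j in seq_len(nq)) {
    Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
    J[, , j] <- Im(point_kinematics(model, Qc, body, xy)$pos) / CS_H
  }
  J
}

# ---------------------------------------------------------------------------
# Muscle path geometry
# ---------------------------------------------------------------------------

# Polyline path lengths for all configurations; complex-safe.
muscle_path_lengths <- function(model, Q, muscle, kin = NULL) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  if (is.null(kin)) kin <- fk_full(model, Q)
  pts <- lapply(muscle$path, function(p)
    point_kinematics(model, Q, p$body, p$xy, kin = kin)$pos)
  L <- 0
  for (k in seq_len(length(pts) - 1)) {
    d <- pts[[k + 1]] - pts[[k]]
    L <- L + sqrt(d[, 1]^2 + d[, 2]^2)
  }
  L
}

#' Muscle path kinematics: length, lengthening rate, moment arms
#'
#' Computes the polyline path length through the muscle's attachment points,
#' its rate of change, and the moment arm about each generalized coordinate,
#' `r_j = -d l_MT / d q_j` (exact, via complex-step differentiation of the
#' path length). The lengthening rate is `v_MT = sum_j (d l_MT/d q_j) u_j`.
#'
#' @param model an [mbs_model()].
#' @param Q,U coordinate and speed matrices (rows = time points) or vectors.
#' @param muscle muscle name or muscle entry.
#' @return list with `l_mt` (n), `v_mt` (n), `arms` (n x nq).
#' @export
muscle_path_kinematics <- function(model, Q, U, muscle) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  if (!is.matrix(U)) U <- matrix(U, nrow = 1)
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  n <- nrow(Q); nq <- ncol(Q)
  l <- muscle_path_lengths(model, Q, muscle)
  dl <- matrix(0, n, nq)
  for (j in seq_len(nq)) {
    Qc <- Q * (1 + 0i); Qc[, j] <- Qc[, j] + 1i * CS_H
    dl[, j] <- Im(muscle_path_lengths(model, Qc, muscle)) / CS_H
  }
  v <- rowSums(dl * U)
  list(l_mt = as.numeric(l), v_mt = v, arms = -dl)
}

# Cartesian forces a muscle with scalar path tension f applies to each body
# along its polyline; returns list of per-body force accumulators
# (n x 2 matrices) and application points. Used for joint reaction loads.
muscle_body_forces <- function(model, Q, muscle, tension, kin = NULL) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1)
  if (is.null(kin)) kin <- fk_full(model, Q)
  pts <- lapply(muscle$path, function(p)
    point_kinematics(model, Q, p$body, p$xy, kin = kin)$pos)
  np <- length(pts)
  out <- list()
  for (k in seq_len(np)) {
    f <- 0
    if (k > 1) {
      d <- pts[[k - 1]] - pts[[k]]
      f <- f + d / sqrt(d[, 1]^2 + d[, 2]^2) * tension
    }
    if (k < np) {
      d <- pts[[k + 1]] - pts[[k]]
      f <- f + d / sqrt(d[, 1]^2 + d[, 2]^2) * tension
    }
    b <- muscle$path[[k]]$body
    out[[length(out) + 1]] <- list(body = b, point = pts[[k]], force = f)
  }
  out
}
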