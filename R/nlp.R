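#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve
NULL

# ---------------------------------------------------------------------------
# Nonlinear program container
#
# A finite-dimensional program produced by transcription (or built directly in
# tests):
#   minimize    sum(eval(z)$contrib)
#   subject to  eval(z)$con == 0,  lb <= z <= ub
#
# eval(z) returns list(contrib = <objective contribution vector>,
#                      con     = <equality constraint vector>).
# The objective is carried as a vector of local contributions (quadrature
# terms plus terminal goals) so that its gradient has the same banded
# structure as the constraint Jacobian and both are obtained from one set of
# structure-exploiting central finite differences.
#
# Structural sparsity is declared per variable:
#   col_rows_con[[j]] : constraint rows that can depend on variable j
#   col_rows_obj[[j]] : contribution entries that can depend on variable j
#   colors[j]         : color id; variables sharing a color must have
#                       disjoint row sets and are perturbed together.
# ---------------------------------------------------------------------------

new_nlp <- function(nv, lb, ub, eval_fn, col_rows_con, col_rows_obj, colors,
                    n_con, n_contrib, hdiag = NULL, fd_step = 1e-6,
                    layout = NULL) {
  stopifnot(length(lb) == nv, length(ub) == nv, length(colors) == nv)
  nlp <- list(nv = nv, lb = lb, ub = ub, eval = eval_fn,
              col_rows_con = col_rows_con, col_rows_obj = col_rows_obj,
              colors = colors, n_con = n_con, n_contrib = n_contrib,
              hdiag = hdiag, fd_step = fd_step, layout = layout)
  nlp$plan <- build_fd_plan(nlp)
  nlp
}

# Static finite-difference plan: flattened triplet structure of the sparse
# Jacobian, the permutation into dgCMatrix slot order, and per-color entry
# maps, so each nlp_derivatives call fills preallocated vectors instead of
# rebuilding index arrays.
build_fd_plan <- function(nlp) {
  nv <- nlp$nv; ncolor <- max(nlp$colors)
  len_con <- lengths(nlp$col_rows_con)
  trip_row <- unlist(nlp$col_rows_con, use.names = FALSE)
  trip_col <- rep.int(seq_len(nv), len_con)
  nent <- length(trip_row)
  template <- sparseMatrix(i = trip_row, j = trip_col, x = rep(0, nent),
                           dims = c(nlp$n_con, nv))
  perm <- sparseMatrix(i = trip_row, j = trip_col,
                       x = as.numeric(seq_len(nent)),
                       dims = c(nlp$n_con, nv))@x
  slot_in_color <- integer(nv)
  cols <- split(seq_len(nv), factor(nlp$colors, levels = seq_len(ncolor)))
  for (cc in cols) slot_in_color[cc] <- seq_along(cc)
  fcol_ent <- factor(nlp$colors[trip_col], levels = seq_len(ncolor))
  len_obj <- lengths(nlp$col_rows_obj)
  obj_row <- unlist(nlp$col_rows_obj, use.names = FALSE)
  obj_col <- rep.int(seq_len(nv), len_obj)
  fcol_obj <- factor(nlp$colors[obj_col], levels = seq_len(ncolor))
  list(ncolor = ncolor, cols = cols, nent = nent,
       template = template, perm = perm,
       ent = split(seq_len(nent), fcol_ent),
       ent_row = split(trip_row, fcol_ent),
       ent_slot = split(slot_in_color[trip_col], fcol_ent),
       obj_row = split(obj_row, fcol_obj),
       obj_slot = split(slot_in_color[obj_col], fcol_obj),
       obj_colid = split(obj_col, fcol_obj))
}

nlp_objective <- function(nlp, z) sum(nlp$eval(z)$contrib)

# Structure-exploiting central finite differences: one forward/backward pair
# per color yields the full sparse constraint Jacobian, the objective
# gradient, and (from the second differences against the base evaluation)
# the exact diagonals of the constraint and objective Hessians. Returns
# list(J, g, C2 = sparse matrix of second partials d2c_i/dz_j^2 with the
# same pattern as J, o2 = objective-Hessian diagonal, nfev).
nlp_derivatives <- function(nlp, z, base = NULL, central = TRUE) {
  h0 <- nlp$fd_step
  plan <- nlp$plan
  g <- numeric(nlp$nv)
  o2 <- numeric(nlp$nv)
  vals <- numeric(plan$nent)
  vals2 <- if (central) numeric(plan$nent) else NULL
  if (is.null(base)) base <- nlp$eval(z)
  nfev <- 0L
  for (col in seq_len(plan$ncolor)) {
    jj <- plan$cols[[col]]
    hj <- h0 * pmax(1, abs(z[jj]))
    dz <- numeric(nlp$nv); dz[jj] <- hj
    rp <- nlp$eval(z + dz)
    nfev <- nfev + 1L
    if (central) {
      rm <- nlp$eval(z - dz)
      nfev <- nfev + 1L
      dcon <- (rp$con - rm$con) / 2
      dobj <- (rp$contrib - rm$contrib) / 2
    } else {
      dcon <- rp$con - base$con
      dobj <- rp$contrib - base$contrib
    }
    ei <- plan$ent[[col]]
    he <- hj[plan$ent_slot[[col]]]
    vals[ei] <- dcon[plan$ent_row[[col]]] / he
    if (central)
      vals2[ei] <- (rp$con - 2 * base$con + rm$con)[plan$ent_row[[col]]] /
        he^2
    orow <- plan$obj_row[[col]]
    if (length(orow)) {
      ho <- hj[plan$obj_slot[[col]]]
      oc <- plan$obj_colid[[col]]
      s <- rowsum(dobj[orow] / ho, oc, reorder = FALSE)
      g[as.integer(rownames(s))] <- s[, 1]
      if (central) {
        s2 <- rowsum((rp$contrib - 2 * base$contrib + rm$contrib)[orow] /
                       ho^2, oc, reorder = FALSE)
        o2[as.integer(rownames(s2))] <- s2[, 1]
      }
    }
  }
  J <- plan$template; J@x <- vals[plan$perm]
  C2 <- NULL
  if (central) { C2 <- plan$template; C2@x <- vals2[plan$perm] }
  list(J = J, g = g, C2 = C2, o2 = if (central) o2 else NULL, nfev = nfev)
}

#' Solve a transcribed nonlinear program
#'
#' Sparse augmented-Lagrangian method with projected-Newton inner iterations.
#' The inner Hessian model is the Gauss-Newton matrix
#' `rho * J'J + diag(hdiag) + damping`, factorized with a sparse Cholesky
#' decomposition; variable bounds are handled by an active-set projection and
#' a backtracking line search on the augmented Lagrangian. Outer iterations
#' perform first-order multiplier updates with a standard penalty schedule.
#'
#' Returns the best iterate even without convergence, flagged through
#' `status` (`"converged"`, `"max-iterations"`, or `"infeasible"`).
#'
#' @param nlp an NLP structure as assembled by the transcription layer.
#' @param z0 initial guess (length `nlp$nv`); values are clipped into the
#'   bounds. `NaN` entries are a hard error before the solver runs.
#' @param lam0 optional warm-start multipliers for the equality constraints.
#' @param control list of solver settings: `tol_con` (constraint tolerance,
#'   default 1e-3), `tol_kkt` (convergence tolerance on the projected
#'   Lagrangian gradient, default 1e-3), `max_outer`, `max_inner`,
#'   `rho0`, `rho_max`, `max_total_iter`, `verbose`.
#' @return list with `z`, `lam`, `objective`, `status`, `iterations`,
#'   `viol` (max constraint violation), `kkt` (projected gradient norm),
#'   `nfev`.
#' @export
nlp_solve <- function(nlp, z0, lam0 = NULL, control = list()) {
  ct <- utils::modifyList(list(
    tol_con = 1e-3, tol_kkt = 1e-3, max_outer = 40, max_inner = 40,
    rho0 = 100, rho_max = 1e7, max_total_iter = 3000, verbose = FALSE,
    damp0 = 1e-8, feasibility_phase = TRUE, polish_iters = 8,
    max_restarts = 3), control)

  if (any(is.na(z0)) || any(!is.finite(z0)))
    stop("initial guess contains NaN or non-finite values")
  if (length(z0) != nlp$nv)
    stop("initial guess has length ", length(z0), ", expected ", nlp$nv)
  if (any(nlp$lb > nlp$ub))
    stop("infeasible bounds: lower exceeds upper for variable(s) ",
         paste(utils::head(which(nlp$lb > nlp$ub), 5), collapse = ", "))

  lb <- nlp$lb; ub <- nlp$ub
  z <- pmin(pmax(z0, lb), ub)
  m <- nlp$n_con

  total_it <- 0L; nfev <- 0L
  eps_act <- 1e-11

  # Projected-Newton minimization of
  #   obj_scale * f(z) + lam' c(z) + rho/2 ||c(z)||^2   over  lb <= z <= ub.
  damp <- ct$damp0
  C2_cache <- NULL; o2_cache <- NULL
  inner_solve <- function(z, lam, rho, obj_scale, max_it, inner_tol,
                          frozen = integer(0)) {
    lb <- lb; ub <- ub
    if (length(frozen)) { lb[frozen] <- z[frozen]; ub[frozen] <- z[frozen] }
    L_prev <- Inf; stag <- 0L
    for (it in seq_len(max_it)) {
      total_it <<- total_it + 1L
      e <- nlp$eval(z); nfev <<- nfev + 1L
      # central differences when close to optimality (tight inner tolerance)
      # or periodically to refresh the cached Hessian diagonals; cheaper
      # forward differences otherwise
      central <- inner_tol < 1e-5 || it %% 4L == 1L || is.null(C2_cache)
      der <- nlp_derivatives(nlp, z, base = e, central = central)
      nfev <<- nfev + der$nfev
      if (central) { C2_cache <<- der$C2; o2_cache <<- der$o2 }
      cv <- e$con
      gal <- obj_scale * der$g +
        if (m) as.numeric(crossprod(der$J, lam + rho * cv)) else 0
      act <- (z <= lb + eps_act & gal > 0) | (z >= ub - eps_act & gal < 0)
      pg <- gal; pg[act] <- 0
      if (max(abs(pg)) < inner_tol) break
      fr <- which(!act)
      if (!length(fr)) break
      Lval <- obj_scale * sum(e$contrib) +
        if (m) sum(lam * cv) + rho / 2 * sum(cv^2) else 0
      if (L_prev - Lval < 1e-13 * max(1, abs(Lval))) {
        stag <- stag + 1L
        if (stag >= 2L) break # no measurable merit progress; stop early
      } else stag <- 0L
      L_prev <- Lval
      # exact augmented-Lagrangian Hessian diagonal (clamped to >= 0):
      # objective part + sum_i (lam_i + rho c_i) d2c_i/dz_j^2; the rho J'J
      # Gauss-Newton term carries the remaining (row-space) curvature.
      # The pure second derivatives vary slowly, so cached values from the
      # last central-difference iteration are reused in between.
      hdv <- pmax(0, obj_scale * o2_cache +
                    if (m) as.numeric(crossprod(C2_cache, lam + rho * cv))
                  else 0)
      step_ok <- FALSE
      for (try in 1:8) {
        H <- Diagonal(length(fr), hdv[fr] + damp)
        if (m) {
          Jf <- der$J[, fr, drop = FALSE]
          H <- H + rho * crossprod(Jf)
        }
        d <- tryCatch(as.numeric(solve(H, -gal[fr])),
                      error = function(e2) NULL)
        if (is.null(d) || any(!is.finite(d))) { damp <<- max(damp, 1e-6) * 100; next }
        dfull <- numeric(nlp$nv); dfull[fr] <- d
        a <- 1
        for (ls in 1:25) {
          zn <- pmin(pmax(z + a * dfull, lb), ub)
          en <- nlp$eval(zn); nfev <<- nfev + 1L
          Ln <- obj_scale * sum(en$contrib) +
            if (m) sum(lam * en$con) + rho / 2 * sum(en$con^2) else 0
          if (is.finite(Ln) &&
              Ln <= Lval - 1e-8 * a * abs(sum(gal[fr] * d)) + 1e-14 * abs(Lval)) {
            step_ok <- TRUE; break
          }
          a <- a / 2
        }
        if (step_ok) {
          z <- zn
          # Levenberg-style damping update from the step quality: full steps
          # relax the damping, backtracked steps tighten it so the next
          # model is trusted over a smaller region
          if (a >= 1) damp <<- max(ct$damp0, damp / 3)
          else if (a <= 1 / 8) damp <<- min(1e6, damp * 8)
          else damp <<- min(1e6, damp * 2)
          break
        }
        damp <<- min(1e8, max(damp, 1e-8) * 30)
      }
      if (!step_ok) break
      if (total_it >= ct$max_total_iter) break
    }
    z
  }

  if (m == 0L) {
    lam <- numeric(0); rho <- 0
  } else {
    lam <- if (is.null(lam0)) numeric(m) else lam0
    rho <- ct$rho0
    # feasibility-first phase: Gauss-Newton on ||c||^2 with the objective
    # switched off, so cost terms cannot drive the iterate away from the
    # constraint manifold before multiplier estimates exist. A free duration
    # variable is frozen at its guess here: shrinking the horizon toward
    # zero spuriously reduces the defect norm without approaching the
    # feasible manifold.
    if (isTRUE(ct$feasibility_phase) && is.null(lam0)) {
      frozen <- if (!is.null(nlp$layout) && length(nlp$layout$i_dt))
        nlp$layout$i_dt else integer(0)
      z <- inner_solve(z, numeric(m), 1, 0, ct$max_inner,
                       max(0.2 * ct$tol_con, 1e-6), frozen = frozen)
      if (ct$verbose) {
        e0 <- nlp$eval(z)
        message(sprintf("feasibility phase: viol %.2e after %d iterations",
                        max(abs(e0$con)), total_it))
      }
    }
  }
  viol_prev <- Inf
  status <- "max-iterations"
  kkt <- Inf; viol <- Inf

  kkt_best <- Inf; stall <- 0L
  restarts_left <- ct$max_restarts
  for (outer in seq_len(max(1L, if (m == 0L) 1L else ct$max_outer))) {
    # loose inner tolerance while far from the constraint manifold; once
    # (near-)feasible, aim below the convergence tolerance so the accepted
    # iterate satisfies it with margin after the multiplier update
    inner_tol <- if (viol_prev <= 10 * ct$tol_con) 0.2 * ct$tol_kkt
    else ct$tol_kkt * max(1, rho / 1e4)
    z <- inner_solve(z, lam, rho, 1, ct$max_inner, inner_tol)
    e <- nlp$eval(z); nfev <- nfev + 1L
    cv <- e$con
    viol <- if (m) max(abs(cv)) else 0
    # first-order (Hestenes-Powell) multiplier update
    if (m) lam <- lam + rho * cv
    der <- nlp_derivatives(nlp, z); nfev <- nfev + der$nfev
    glag <- der$g + if (m) as.numeric(crossprod(der$J, lam)) else 0
    act <- (z <= lb + eps_act & glag > 0) | (z >= ub - eps_act & glag < 0)
    pg <- glag; pg[act] <- 0
    kkt <- max(abs(pg))
    if (ct$verbose)
      message(sprintf("outer %d rho %.1e viol %.2e kkt %.2e obj %.8g it %d",
                      outer, rho, viol, kkt, sum(e$contrib), total_it))
    if (viol <= ct$tol_con && kkt <= ct$tol_kkt) {
      status <- "converged"
      # short polish: a few extra Newton iterations sharpen the primal
      # iterate along near-flat directions where the projected-gradient
      # measure is already at its finite-difference noise floor
      if (ct$polish_iters > 0)
        z <- inner_solve(z, lam, rho, 1, ct$polish_iters, 0)
      e <- nlp$eval(z); nfev <- nfev + 1L
      viol <- if (m) max(abs(e$con)) else 0
      break
    }
    if (m == 0L) { status <- if (kkt <= ct$tol_kkt) "converged" else "max-iterations"; break }
    if (total_it >= ct$max_total_iter) break
    # raise the penalty only while the violation is not contracting; a
    # moderate ceiling keeps the finite-difference Jacobian noise from being
    # amplified through rho * J' c
    if (viol > 0.25 * viol_prev && viol > ct$tol_con)
      rho <- min(rho * 5, ct$rho_max)
    if (rho >= ct$rho_max && viol > sqrt(ct$tol_con) && viol >= viol_prev)
      { status <- "infeasible"; break }
    if (kkt < 0.7 * kkt_best) { kkt_best <- kkt; stall <- 0L }
    else if (viol <= ct$tol_con) stall <- stall + 1L
    if (stall >= 5L) {
      # feasible but dual progress has stalled. An escalated penalty
      # ill-conditions the inner Newton model; restarting it at rho0 with
      # the accumulated multiplier estimates typically restores fast
      # progress (the multipliers carry the information the penalty was
      # substituting for).
      if (restarts_left > 0L) {
        restarts_left <- restarts_left - 1L
        rho <- ct$rho0
        damp <- ct$damp0
        stall <- 0L; kkt_best <- kkt
        viol_prev <- Inf
        if (ct$verbose) message("restarting with rho = ", rho)
        next
      }
      break # out of restarts; return the best iterate
    }
    viol_prev <- min(viol_prev, viol)
  }
  list(z = z, lam = lam, objective = nlp_objective(nlp, z), status = status,
       iterations = total_it, viol = viol, kkt = kkt, nfev = nfev)
}

# Gradient check utility: compares the structured FD gradient/Jacobian
# against dense central differences at a point. Used in tests.
nlp_check_derivatives <- function(nlp, z, h = 1e-6) {
  der <- nlp_derivatives(nlp, z)
  g_dense <- numeric(nlp$nv)
  J_dense <- matrix(0, nlp$n_con, nlp$nv)
  for (j in seq_len(nlp$nv)) {
    dz <- numeric(nlp$nv); hj <- h * max(1, abs(z[j])); dz[j] <- hj
    rp <- nlp$eval(z + dz); rm <- nlp$eval(z - dz)
    g_dense[j] <- sum(rp$contrib - rm$contrib) / (2 * hj)
    if (nlp$n_con) J_dense[, j] <- (rp$con - rm$con) / (2 * hj)
  }
  list(g_err = max(abs(der$g - g_dense)),
       J_err = if (nlp$n_con) max(abs(as.matrix(der$J) - J_dense)) else 0)
}
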