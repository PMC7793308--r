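# ---------------------------------------------------------------------------
# Solving a transcribed problem and packaging the result.
# ---------------------------------------------------------------------------

#' Solve an optimal-control problem by direct collocation
#'
#' Transcribes the problem with the given settings, builds the initial guess
#' (midpoint of the variable bounds unless a guess is supplied), runs the
#' sparse augmented-Lagrangian solver, and returns a solution trajectory
#' with the solver status, objective, per-goal breakdown, and a post-solve
#' residual audit (defect, path, and boundary residuals re-evaluated outside
#' the solver).
#'
#' @param problem an [ocp()].
#' @param config a [transcription_config()].
#' @param guess `NULL` (midpoint of bounds), an `oc_trajectory` (e.g. a
#'   previous solution, for guess chaining), or a raw decision vector.
#' @param lam0 warm-start multipliers (from a previous solution's `lam`).
#' @param verbose print solver progress.
#' @return an `oc_solution`.
#' @export
solve_ocp <- function(problem, config = transcription_config(),
                      guess = NULL, lam0 = NULL, verbose = FALSE) {
  nlp <- transcribe(problem, config)
  z0 <- if (is.null(guess)) default_guess(nlp)
  else if (inherits(guess, "oc_trajectory")) pack_guess(nlp, guess)
  else as.numeric(guess)
  res <- nlp_solve(nlp, z0, lam0 = lam0,
                   control = list(tol_con = config$con_tol,
                                  tol_kkt = config$conv_tol,
                                  max_total_iter = config$max_iterations,
                                  verbose = verbose))
  solution_from_z(nlp, res)
}

solution_from_z <- function(nlp, res) {
  layout <- nlp$layout
  problem <- nlp$problem
  u <- nlp$unpack(res$z)
  nmc <- layout$n_model_ctrl
  states <- u$X; colnames(states) <- layout$state_names
  controls <- u$Uall[, seq_len(nmc), drop = FALSE]
  colnames(controls) <- layout$control_names[seq_len(nmc)]
  mult <- u$Uall[, setdiff(seq_len(layout$nu), seq_len(nmc)), drop = FALSE]
  if (ncol(mult)) colnames(mult) <- layout$control_names[-seq_len(nmc)]
  if (!is.null(u$gamma)) {
    gam_full <- matrix(0, layout$n_pts, layout$m)
    gam_full[layout$mid_idx, ] <- u$gamma
    colnames(gam_full) <- paste0("gamma", seq_len(layout$m))
    mult <- cbind(mult, gam_full)
  }
  pars <- u$pars
  if (length(pars)) names(pars) <- names(problem$parameters)
  traj <- trajectory(u$Tt, states, controls, mult, pars)

  # per-goal breakdown with the transcription quadrature
  goals <- problem$goals
  for (gi in seq_along(goals))
    if (goals[[gi]]$kind == "state_tracking")
      attr(goals[[gi]], "interp") <- traj_interpolant(goals[[gi]]$reference)
  model_p <- problem$model
  if (layout$np && !is.null(model_p))
    for (k in seq_len(layout$np))
      model_p <- model_set_property(model_p, problem$parameters[[k]]$path,
                                    u$pars[k])
  wq <- u$dt * quad_weights_norm(layout)
  gi_mat <- goal_integrand_matrix(problem, goals, model_p, u$Tt, u$X, u$Uall,
                                  layout, u$dt)
  term <- goal_terminal_values(problem, goals, problem$t0 + u$dt)
  gv <- as.numeric(crossprod(gi_mat, wq)) + term
  names(gv) <- names(goals)

  e <- nlp$eval(res$z)
  rg <- nlp$row_groups
  mx <- function(ix) if (length(ix)) max(abs(e$con[ix])) else 0
  residuals <- list(defect = mx(rg$defect), path = mx(rg$path),
                    boundary = mx(rg$boundary))
  ok <- res$status == "converged" &&
    max(residuals$defect, residuals$path, residuals$boundary) <=
    nlp$config$con_tol
  new_solution(traj, success = ok, status = res$status,
               objective = res$objective, iterations = res$iterations,
               goal_values = as.list(gv), residuals = residuals,
               lam = res$lam, z = res$z)
}

#' Audit a decision vector against the transcription constraints
#'
#' Re-evaluates all defect, path, and boundary residuals for a solution (or
#' any decision vector) outside the solver.
#'
#' @param nlp a transcribed NLP.
#' @param z decision vector (e.g. `solution$z`).
#' @return list of maximum absolute residuals per group.
#' @export
audit_residuals <- function(nlp, z) {
  e <- nlp$eval(z)
  rg <- nlp$row_groups
  mx <- function(ix) if (length(ix)) max(abs(e$con[ix])) else 0
  list(defect = mx(rg$defect), path = mx(rg$path), boundary = mx(rg$boundary))
}
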