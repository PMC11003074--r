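# Protocol-based automatic iterative optimisation (PBAIO): an inner
# projected-gradient fluence optimiser wrapped in an outer loop that applies
# dynamic positioning (the delta rule) and dynamic weighting to the P3
# trade-off objectives between optimisation passes.

#' PBAIO configuration
#'
#' @param delta_volume the positioning offset delta for volume-type (%Vol)
#'   parameters, percentage points (default 2).
#' @param delta_dose delta for dose-type (Gy) parameters (default 1 Gy).
#' @param inner_iterations projected-gradient iterations per inner
#'   optimisation pass.
#' @param outer_loops number of reposition/reweight outer loops.
#' @param weight_exponent exponent alpha of the multiplicative weight
#'   update.
#' @param weight_clip per-loop clip factor rho (> 1) bounding each
#'   multiplicative weight change to `[1/rho, rho]`.
#' @param penalty_target the target objective value tau the dynamic
#'   weighting drives each WF-scaled P3 penalty towards.
#' @param weight_span total adaptation span: each P3 optimiser weight is
#'   kept within `[WF / weight_span, WF * weight_span]` of its stored
#'   weighting factor, so adaptation cannot invert the P1/P2/P3 hierarchy
#'   or silence a navigated trade-off.
#' @param p1_weight,p2_weight the hard-coded P1 and P2 optimiser weights
#'   (1000 and 250).
#' @param convergence_tol relative objective-change stopping tolerance of
#'   the inner optimiser.
#' @param seed integer recorded on the plan (the pipeline itself is
#'   deterministic).
#' @return object of class `pbaio_config`.
#' @export
pbaio_config <- function(delta_volume = 2.0, delta_dose = 1.0,
                         inner_iterations = 60L, outer_loops = 8L,
                         weight_exponent = 0.5, weight_clip = 4,
                         penalty_target = 1, weight_span = 2,
                         p1_weight = 1000, p2_weight = 250,
                         convergence_tol = 1e-7, seed = 1L) {
  stopifnot(delta_volume >= 0, delta_dose >= 0, weight_clip > 1,
            penalty_target > 0, weight_span >= 1,
            inner_iterations >= 0, outer_loops >= 0)
  structure(list(
    delta_volume = delta_volume, delta_dose = delta_dose,
    inner_iterations = as.integer(inner_iterations),
    outer_loops = as.integer(outer_loops),
    weight_exponent = weight_exponent, weight_clip = weight_clip,
    penalty_target = penalty_target, weight_span = weight_span,
    p1_weight = p1_weight, p2_weight = p2_weight,
    convergence_tol = convergence_tol, seed = as.integer(seed)
  ), class = "pbaio_config")
}

#' Initialise objective states from a protocol
#'
#' P1 goals receive the hard-coded optimiser weight 1000, P2 goals 250, and
#' P3 goals their stored weighting factor.  Dynamic targets start at the
#' protocol targets (their initial value has negligible impact because the
#' positioning rule overwrites them after the first pass).
#'
#' @param protocol an `autoplan_protocol`.
#' @param config a [pbaio_config()].
#' @return list of [objective_state()].
#' @export
init_states <- function(protocol, config = pbaio_config()) {
  lapply(protocol$goals, function(g) {
    w <- switch(g$priority,
      P1 = config$p1_weight,
      P2 = config$p2_weight,
      P3 = g$weighting_factor
    )
    objective_state(g, optimiser_weight = w)
  })
}

# Is this goal subject to dynamic positioning, and what is its achieved
# DVH parameter on a dose?  Returns NULL for goals that are not moved
# (P1/P2, falloff and conformality goals).
positioning_achieved <- function(state, dose, geometry) {
  g <- state$goal
  if (g$priority != "P3") return(NULL)
  mask <- switch(g$goal_type,
    dv_max = , mean_dose = , max_dose = resolve_roi(geometry, g$roi),
    return(NULL)
  )
  switch(g$goal_type,
    dv_max = list(value = volume_at_dose(dose, mask, g$dose_level),
                  kind = "volume"),
    mean_dose = list(value = mean(dose[mask]), kind = "dose"),
    max_dose = list(value = max(dose[mask]), kind = "dose")
  )
}

#' Dynamic positioning update (the delta rule)
#'
#' For every P3 goal with a dose-volume, mean or max parameter, the dynamic
#' target is set a constant offset delta below the currently achieved value
#' of that parameter, floored at zero: `max(0, achieved - delta)` with
#' delta = `delta_volume` for %Vol parameters and `delta_dose` for Gy
#' parameters.  P1/P2 targets and falloff goals are never moved.
#'
#' @param states list of objective states.
#' @param dose current dose array.
#' @param geometry,protocol geometry and protocol.
#' @param config a [pbaio_config()].
#' @return the updated states.
#' @export
update_positions <- function(states, dose, geometry, protocol,
                             config = pbaio_config()) {
  for (i in seq_along(states)) {
    ach <- positioning_achieved(states[[i]], dose, geometry)
    if (is.null(ach)) next
    delta <- if (ach$kind == "volume") config$delta_volume else config$delta_dose
    states[[i]]$dynamic_target <- max(0, ach$value - delta)
  }
  states
}

#' Dynamic weighting update
#'
#' Multiplicative fixed-point rule: each P3 optimiser weight is scaled by
#' `clip(((WF * last_penalty) / tau)^alpha, 1/rho, rho)`.  At the fixed
#' point `WF * penalty = tau`, so the stored weighting factor sets the
#' relative residual penalty of each trade-off, which is what makes WF the
#' cross-patient balancing knob.  P1/P2 weights are untouched.
#'
#' @param states list of objective states with `last_penalty` recorded.
#' @param config a [pbaio_config()].
#' @return the updated states.
#' @export
update_weights <- function(states, config = pbaio_config()) {
  for (i in seq_along(states)) {
    s <- states[[i]]
    if (s$goal$priority != "P3") next
    if (is.na(s$last_penalty))
      stop("update_weights: last_penalty not recorded for a P3 state")
    ratio <- (s$goal$weighting_factor * s$last_penalty) / config$penalty_target
    fac <- ratio^config$weight_exponent
    fac <- min(max(fac, 1 / config$weight_clip), config$weight_clip)
    w <- s$optimiser_weight * fac
    wf <- s$goal$weighting_factor
    w <- min(max(w, wf / config$weight_span), wf * config$weight_span)
    states[[i]]$optimiser_weight <- w
  }
  states
}

# ---- inner optimiser ---------------------------------------------------

# Compiled objective over the influence rows: value, voxel gradient and
# per-goal penalties in one pass.
compile_states <- function(states, geometry, protocol, influence) {
  lapply(states, function(s)
    compile_goal(s$goal, geometry, protocol, influence$voxel_index))
}

compiled_objective <- function(states, geometry, protocol, influence,
                               compiled = NULL) {
  cgs <- compiled %||% compile_states(states, geometry, protocol, influence)
  n_vox <- nrow(influence$matrix)
  function(dvec, states) {
    gvec <- numeric(n_vox)
    pens <- numeric(length(states))
    total <- 0
    for (i in seq_along(states)) {
      pe <- penalty_eval(cgs[[i]], dvec, states[[i]]$dynamic_target, protocol)
      pens[i] <- pe$value
      w <- states[[i]]$optimiser_weight
      total <- total + w * pe$value
      if (length(pe$pos)) gvec[pe$pos] <- gvec[pe$pos] + w * pe$grad
    }
    list(value = total, gvox = gvec, penalties = pens)
  }
}

#' Inner fluence optimisation (projected gradient descent)
#'
#' Minimises the weighted composite objective over nonnegative beamlet
#' weights by projected gradient descent with a Barzilai-Borwein initial
#' step and backtracking line search; accepted steps never increase the
#' objective, and the routine is deterministic given its inputs.
#'
#' @param influence an `influence_matrix`.
#' @param states list of objective states (weights and dynamic targets are
#'   held fixed during the inner pass).
#' @param fluence_init nonnegative starting fluence.
#' @param n_iter maximum iterations (0 returns `fluence_init`).
#' @param geometry,protocol,config context objects.
#' @param compiled optional precompiled goal regions (internal reuse across
#'   outer loops).
#' @return list with `fluence`, `objective` (the per-iteration accepted
#'   objective values, starting with the initial one) and `penalties`
#'   (per-goal penalties at the final fluence, named by goal id).
#' @export
inner_optimise <- function(influence, states, fluence_init, n_iter,
                           geometry, protocol, config = pbaio_config(),
                           compiled = NULL) {
  stopifnot(all(fluence_init >= 0))
  obj <- compiled_objective(states, geometry, protocol, influence, compiled)
  M <- influence$matrix
  x <- as.numeric(fluence_init)
  ev <- function(x) obj(as.numeric(M %*% x), states)
  cur <- ev(x)
  if (!is.finite(cur$value)) stop("non-finite objective")
  trace <- cur$value
  if (n_iter == 0)
    return(list(fluence = x, objective = trace,
                penalties = stats::setNames(cur$penalties,
                  vapply(states, function(s) s$id, character(1)))))
  grad <- function(gvox) as.numeric(Matrix::crossprod(M, gvox))
  g <- grad(cur$gvox)
  step <- 1 / max(sum(g^2), 1e-12)^0.5   # conservative first step
  x_old <- NULL; g_old <- NULL
  for (it in seq_len(n_iter)) {
    if (!is.null(x_old)) {
      dx <- x - x_old; dg <- g - g_old
      denom <- sum(dx * dg)
      step <- if (denom > 1e-300) sum(dx * dx) / denom else step * 2
      if (!is.finite(step) || step <= 0) step <- 1e-3
    }
    accepted <- FALSE
    for (bt in 1:30) {
      x_new <- pmax(0, x - step * g)
      new <- ev(x_new)
      if (is.finite(new$value) && new$value <= cur$value) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    x_old <- x; g_old <- g
    rel <- (cur$value - new$value) / max(cur$value, 1e-300)
    x <- x_new; cur <- new
    g <- grad(cur$gvox)
    trace <- c(trace, cur$value)
    if (rel < config$convergence_tol || cur$value == 0) break
  }
  list(fluence = x, objective = trace,
       penalties = stats::setNames(cur$penalties,
         vapply(states, function(s) s$id, character(1))))
}

# ---- the full planning loop -------------------------------------------

#' Generate an automated plan
#'
#' Runs the PBAIO loop: `outer_loops` rounds of inner fluence optimisation
#' followed by dynamic positioning and dynamic weighting of the P3
#' objectives, a final inner optimisation, and plan normalisation so the
#' PTV60 median dose equals the prescription.  Bit-reproducible given the
#' same inputs.
#'
#' @param geometry a `patient_geometry` with PTVs built.
#' @param protocol an `autoplan_protocol`.
#' @param beam_cfg a [beam_config()].
#' @param config a [pbaio_config()].
#' @param influence optionally a prebuilt influence matrix for this
#'   geometry (reused across plans during Pareto dataset generation).
#' @return object of class `pgap_plan`: list with `fluence`, `dose`
#'   (normalised, Gy), `protocol`, `log` (per-outer-loop state rows),
#'   `normalisation` (the final scale factor), `objective_trace`, `seed`.
#' @export
autoplan <- function(geometry, protocol, beam_cfg = beam_config(),
                     config = pbaio_config(), influence = NULL) {
  if (is.null(influence)) influence <- build_influence_matrix(geometry, beam_cfg)
  states <- init_states(protocol, config)
  compiled <- compile_states(states, geometry, protocol, influence)

  # start from a uniform fluence scaled so the PTV60 median is near the
  # prescription (deterministic)
  d1 <- compute_dose(influence, rep(1, ncol(influence$matrix)))
  med1 <- dose_at_volume(d1, geometry$masks$PTV60, 50)
  if (med1 <= 0) stop("influence matrix deposits no dose in PTV60")
  x <- rep(protocol$prescription / med1, ncol(influence$matrix))

  log_rows <- list()
  snapshot <- function(loop, states) {
    data.frame(
      loop = loop,
      goal = vapply(states, function(s) s$id, character(1)),
      priority = vapply(states, function(s) s$goal$priority, character(1)),
      dynamic_target = vapply(states, function(s) as.numeric(s$dynamic_target),
                              numeric(1)),
      weight = vapply(states, function(s) s$optimiser_weight, numeric(1)),
      penalty = vapply(states, function(s) as.numeric(s$last_penalty),
                       numeric(1)),
      stringsAsFactors = FALSE
    )
  }

  trace <- numeric(0)
  for (loop in seq_len(config$outer_loops)) {
    res <- inner_optimise(influence, states, x, config$inner_iterations,
                          geometry, protocol, config, compiled = compiled)
    x <- res$fluence
    trace <- c(trace, res$objective)
    for (i in seq_along(states)) states[[i]]$last_penalty <- res$penalties[[i]]
    dose <- compute_dose(influence, x)
    states <- update_positions(states, dose, geometry, protocol, config)
    states <- update_weights(states, config)
    log_rows[[loop]] <- snapshot(loop, states)
  }
  res <- inner_optimise(influence, states, x, config$inner_iterations,
                        geometry, protocol, config, compiled = compiled)
  x <- res$fluence
  trace <- c(trace, res$objective)
  for (i in seq_along(states)) states[[i]]$last_penalty <- res$penalties[[i]]
  log_rows[[config$outer_loops + 1L]] <- snapshot(config$outer_loops + 1L, states)

  dose <- compute_dose(influence, x)
  norm <- normalise_plan(dose, geometry, protocol$prescription)

  structure(list(
    fluence = x * norm$factor, dose = norm$dose, protocol = protocol,
    log = do.call(rbind, log_rows), normalisation = norm$factor,
    objective_trace = trace, seed = config$seed,
    beam_config = influence$config %||% beam_cfg, pbaio_config = config
  ), class = "pgap_plan")
}

#' @export
print.pgap_plan <- function(x, ...) {
  cat(sprintf("pgap_plan: %d beamlets, final objective %.4g, norm factor %.4f\n",
              length(x$fluence), utils::tail(x$objective_trace, 1),
              x$normalisation))
  invisible(x)
}
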