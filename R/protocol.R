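# AutoPlan protocol data model, goal penalty functions and falloff
# threshold construction.
#
# Planning goals come in three priority levels: P1 (critical normal tissue /
# conformality), P2 (target coverage and homogeneity) and P3 (all other
# trade-offs).  P1 and P2 optimiser weights are hard-coded constants (1000
# and 250); P3 goals carry a stored weighting factor (WF) that is the
# calibration knob set through Pareto navigation.

GOAL_TYPES <- c("min_dose", "max_dose", "dv_max", "mean_dose", "median_max",
                "dose_falloff_external", "dose_falloff_intra",
                "conformality_max")
GOAL_UNITS <- c("Gy", "%Presc,PTV", "%Presc", "%Vol")

#' Construct a planning goal
#'
#' @param roi structure name the goal applies to.
#' @param priority `"P1"`, `"P2"` or `"P3"`.
#' @param goal_type one of `min_dose`, `max_dose`, `dv_max` (a Vd Gy
#'   volume ceiling), `mean_dose`, `median_max` (a D50% ceiling),
#'   `dose_falloff_external`, `dose_falloff_intra`, `conformality_max`.
#' @param target goal target value in `units` (for `dv_max` the volume
#'   limit in %Vol; for dose goals the dose).
#' @param units `"Gy"`, `"%Presc,PTV"` (percent of the ROI's own PTV
#'   prescription), `"%Presc"` (percent of the overall prescription) or
#'   `"%Vol"`.
#' @param weighting_factor positive WF; required for P3 goals (P1/P2
#'   weights are implicit constants).
#' @param dose_level for `dv_max`: the Vd dose level in Gy.
#' @param falloff for falloff goals: list with `high_dose` (Gy),
#'   `low_dose` (Gy) and `gradient` (in %Presc per cm).
#' @param distance for `conformality_max`: shell stand-off distance in cm.
#' @return object of class `planning_goal`.
#' @export
planning_goal <- function(roi, priority, goal_type, target, units,
                          weighting_factor = NULL, dose_level = NULL,
                          falloff = NULL, distance = NULL) {
  if (!priority %in% c("P1", "P2", "P3")) stop("priority must be P1/P2/P3")
  if (!goal_type %in% GOAL_TYPES)
    stop(sprintf("unknown goal_type '%s'", goal_type))
  if (!units %in% GOAL_UNITS) stop(sprintf("unknown units '%s'", units))
  is_falloff <- goal_type %in% c("dose_falloff_external", "dose_falloff_intra")
  if (priority == "P3" && !is.numeric(weighting_factor))
    stop(sprintf("P3 goal on '%s' requires a weighting_factor", roi))
  if (!is.null(weighting_factor) && weighting_factor <= 0)
    stop("weighting_factor must be > 0")
  if (is_falloff) {
    if (is.null(falloff)) stop("falloff goals require falloff parameters")
    stopifnot(all(c("high_dose", "low_dose", "gradient") %in% names(falloff)))
    if (falloff$high_dose < falloff$low_dose)
      stop("falloff high_dose must be >= low_dose")
  } else if (!is.null(falloff)) {
    stop("falloff parameters only allowed on falloff goals")
  }
  if (goal_type == "conformality_max") {
    if (is.null(distance)) stop("conformality_max requires a distance (cm)")
  } else if (!is.null(distance)) {
    stop("distance only allowed on conformality_max goals")
  }
  if (goal_type == "dv_max" && is.null(dose_level))
    stop("dv_max goals require a dose_level (Gy)")
  structure(list(
    roi = roi, priority = priority, goal_type = goal_type,
    target = target, units = units, weighting_factor = weighting_factor,
    dose_level = dose_level, falloff = falloff, distance = distance
  ), class = "planning_goal")
}

# Stable goal identifier used by navigation dimensions and logs.
goal_id <- function(goal) {
  extra <- if (!is.null(goal$dose_level)) sprintf("%g", goal$dose_level) else ""
  paste(goal$roi, goal$goal_type, extra, sep = "|")
}

#' Construct an AutoPlan protocol
#'
#' @param name protocol name.
#' @param institution profile label (`"instA"` / `"instB"`).
#' @param goals list of [planning_goal()] objects.
#' @param prescriptions named numeric of per-PTV prescriptions (Gy).
#' @param prescription overall prescription (Gy).
#' @param version schema version string.
#' @return object of class `autoplan_protocol`.
#' @export
autoplan_protocol <- function(name, institution, goals,
                              prescriptions = c("PTV60" = 60, "PTV57.5" = 57.5,
                                                "PTV48" = 48),
                              prescription = 60, version = "1.0") {
  stopifnot(length(goals) > 0)
  for (g in goals) {
    if (!inherits(g, "planning_goal")) stop("goals must be planning_goal objects")
  }
  structure(list(
    name = name, institution = institution, prescriptions = prescriptions,
    prescription = prescription, goals = goals, version = version
  ), class = "autoplan_protocol")
}

#' @export
print.autoplan_protocol <- function(x, ...) {
  cat(sprintf("autoplan_protocol '%s' (%s): %d goals, prescription %g Gy\n",
              x$name, x$institution, length(x$goals), x$prescription))
  invisible(x)
}

#' The packaged prostate AutoPlan protocols
#'
#' The final calibrated protocols for the two institution profiles:
#' a P1 conformality ceiling, seven P2 target goals, the standard P3
#' dose-volume / mean / max trade-off goals and three dose fall-off goals.
#' The `instB` variant removes four low-weight rectum/bladder goals, adds
#' two bowel goals (WF 0.413), raises the intra-PTV57.5 falloff WF to 29.8
#' and lowers the PTV48 falloff high dose level to 54.0 Gy.
#'
#' @param institution `"instA"` or `"instB"`.
#' @return an [autoplan_protocol()].
#' @export
chhip_protocol <- function(institution = c("instA", "instB")) {
  institution <- match.arg(institution)
  A <- institution == "instA"
  p3 <- function(roi, type, target, units, wf, level = NULL)
    planning_goal(roi, "P3", type, target, units, weighting_factor = wf,
                  dose_level = level)
  p2 <- function(roi, type, target)
    planning_goal(roi, "P2", type, target, "%Presc,PTV")

  goals <- list(
    planning_goal("PTV48", "P1", "conformality_max", 46.8, "Gy",
                  distance = 1.5),
    p2("PTV60", "min_dose", 98.7),
    p2("PTV60", "max_dose", 101.7),
    p2("PTV60", "median_max", 99.5),
    p2("PTV57.5", "min_dose", 98.7),
    p2("PTV57.5", "max_dose", 102.5),
    p2("PTV48", "min_dose", 97.3),
    p2("PTV48", "max_dose", 104.9),
    p3("Rectum", "dv_max", 0.0, "%Vol", 3.5, level = 23.4),
    p3("Rectum", "dv_max", 0.0, "%Vol", 3.5, level = 31.5)
  )
  if (A) {
    goals <- c(goals, list(
      p3("Rectum", "dv_max", 0.0, "%Vol", 0.044, level = 39.6),
      p3("Rectum", "dv_max", 0.0, "%Vol", 0.088, level = 47.7)
    ))
  }
  goals <- c(goals, list(
    p3("Rectum", "dv_max", 0.0, "%Vol", 29.9, level = 51.8)
  ))
  if (A) {
    goals <- c(goals, list(
      p3("Rectum", "dv_max", 0.0, "%Vol", 3.5, level = 55.9)
    ))
  }
  goals <- c(goals, list(
    p3("Rectum", "max_dose", 60.0, "Gy", 0.586),
    p3("Rectum", "mean_dose", 5.0, "Gy", 5.84),
    p3("Bladder", "dv_max", 0.0, "%Vol", 0.316, level = 30.0),
    p3("Bladder", "dv_max", 0.0, "%Vol", 0.316, level = 39.6),
    p3("Bladder", "dv_max", 0.0, "%Vol", 0.316, level = 47.7),
    p3("Bladder", "dv_max", 0.0, "%Vol", 0.316, level = 51.8)
  ))
  if (A) {
    goals <- c(goals, list(
      p3("Bladder", "dv_max", 0.0, "%Vol", 0.316, level = 55.9)
    ))
  }
  goals <- c(goals, list(
    p3("Bladder", "max_dose", 54.0, "Gy", 0.316),
    p3("Bladder", "mean_dose", 5.0, "Gy", 3.73)
  ))
  if (!A) {
    goals <- c(goals, list(
      p3("Bowel", "dv_max", 0.0, "%Vol", 0.413, level = 36.0),
      p3("Bowel", "dv_max", 0.0, "%Vol", 0.413, level = 45.6)
    ))
  }
  goals <- c(goals, list(
    planning_goal("External", "P3", "dose_falloff_external", 0, "Gy",
                  weighting_factor = 204,
                  falloff = list(high_dose = 60.0, low_dose = 30.0,
                                 gradient = 50)),
    planning_goal("PTV57.5", "P3", "dose_falloff_intra", 0, "Gy",
                  weighting_factor = if (A) 10.7 else 29.8,
                  falloff = list(high_dose = 54.0, low_dose = 54.0,
                                 gradient = 75)),
    planning_goal("PTV48", "P3", "dose_falloff_intra", 0, "Gy",
                  weighting_factor = 29.8,
                  falloff = list(high_dose = if (A) 54.6 else 54.0,
                                 low_dose = 45.6, gradient = 75))
  ))
  autoplan_protocol(
    name = sprintf("prostate-60Gy20F-%s", institution),
    institution = institution, goals = goals
  )
}

# ---- JSON serialisation ------------------------------------------------

PROTOCOL_FIELDS <- c("version", "name", "institution", "prescription",
                     "prescriptions", "goals")
GOAL_FIELDS <- c("roi", "priority", "goal_type", "target", "units",
                 "weighting_factor", "dose_level", "falloff", "distance")

#' Write a protocol to JSON
#' @param protocol an `autoplan_protocol`.
#' @param path output file path.
#' @export
save_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "autoplan_protocol"))
  goals <- lapply(protocol$goals, function(g) {
    out <- g[!vapply(g, is.null, logical(1))]
    unclass(out)
  })
  obj <- list(
    version = protocol$version, name = protocol$name,
    institution = protocol$institution,
    prescription = protocol$prescription,
    prescriptions = as.list(protocol$prescriptions),
    goals = goals
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a protocol from JSON
#'
#' Strict schema validation: unknown top-level or goal fields are rejected,
#' P3 goals must carry a positive weighting factor, falloff / distance
#' parameters must be present exactly when the goal type requires them.
#'
#' @param path JSON file path.
#' @return an [autoplan_protocol()].
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop(sprintf("protocol file '%s' not found", path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(obj), PROTOCOL_FIELDS)
  if (length(unknown))
    stop(sprintf("unknown protocol field(s): %s", paste(unknown, collapse = ", ")))
  for (req in PROTOCOL_FIELDS) {
    if (is.null(obj[[req]])) stop(sprintf("missing protocol field '%s'", req))
  }
  goals <- lapply(obj$goals, function(g) {
    unknown <- setdiff(names(g), GOAL_FIELDS)
    if (length(unknown))
      stop(sprintf("unknown goal field(s): %s", paste(unknown, collapse = ", ")))
    planning_goal(
      roi = g$roi, priority = g$priority, goal_type = g$goal_type,
      target = as.numeric(g$target), units = g$units,
      weighting_factor = if (!is.null(g$weighting_factor)) as.numeric(g$weighting_factor),
      dose_level = if (!is.null(g$dose_level)) as.numeric(g$dose_level),
      falloff = if (!is.null(g$falloff)) lapply(g$falloff, as.numeric),
      distance = if (!is.null(g$distance)) as.numeric(g$distance)
    )
  })
  autoplan_protocol(
    name = obj$name, institution = obj$institution, goals = goals,
    prescriptions = vapply(obj$prescriptions, as.numeric, numeric(1)),
    prescription = as.numeric(obj$prescription),
    version = obj$version
  )
}

# ---- target resolution -------------------------------------------------

#' Resolve a goal target value to Gy
#'
#' `%Presc,PTV` targets resolve against the ROI's own PTV prescription,
#' `%Presc` against the overall prescription, `Gy` passes through.  `%Vol`
#' targets are volumes and cannot be resolved to a dose.
#'
#' @param goal a `planning_goal`.
#' @param protocol the enclosing `autoplan_protocol`.
#' @param value optionally a value (in the goal's units) to resolve instead
#'   of the goal's stored target (used for dynamic targets).
#' @return dose in Gy.
#' @export
resolve_target_dose <- function(goal, protocol, value = goal$target) {
  switch(goal$units,
    "Gy" = value,
    "%Presc" = value / 100 * protocol$prescription,
    "%Presc,PTV" = {
      if (!goal$roi %in% names(protocol$prescriptions))
        stop(sprintf("'%%Presc,PTV' goal on non-PTV ROI '%s'", goal$roi))
      value / 100 * protocol$prescriptions[[goal$roi]]
    },
    "%Vol" = stop("a %Vol target is a volume, not a dose"),
    stop("unknown units")
  )
}

falloff_gradient_gy_cm <- function(goal, protocol) {
  goal$falloff$gradient / 100 * protocol$prescription
}

# ---- falloff threshold maps -------------------------------------------

#' Per-voxel dose falloff threshold map
#'
#' threshold(v) = max(low, high - g * d(v)) with g the falloff gradient in
#' Gy/cm and d(v) the Euclidean centre distance (cm) from the falloff source
#' region.  For `dose_falloff_external` the source is the union of the PTVs
#' and the applicable region is external minus the PTVs; for
#' `dose_falloff_intra` the source is the next-higher-prescription PTV and
#' the region the goal's ROI minus all higher PTVs.
#'
#' @param goal a falloff `planning_goal`.
#' @param geometry geometry with PTVs built.
#' @param protocol enclosing protocol.
#' @return 3-D numeric array of thresholds (Gy), `NA` outside the
#'   applicable region.
#' @export
falloff_threshold_map <- function(goal, geometry, protocol) {
  if (!goal$goal_type %in% c("dose_falloff_external", "dose_falloff_intra"))
    stop("goal is not a falloff type")
  m <- geometry$masks
  ptv_union <- m$PTV60 | m$`PTV57.5` | m$PTV48
  if (goal$goal_type == "dose_falloff_external") {
    source <- ptv_union
    region <- m$External & !ptv_union
  } else {
    if (goal$roi == "PTV57.5") {
      source <- m$PTV60
      region <- m$`PTV57.5` & !m$PTV60
    } else if (goal$roi == "PTV48") {
      source <- m$`PTV57.5`
      region <- m$PTV48 & !(m$`PTV57.5` | m$PTV60)
    } else {
      stop(sprintf("no falloff source region defined for ROI '%s'", goal$roi))
    }
  }
  if (!any(source)) stop("falloff source region is empty")
  src_key <- if (goal$goal_type == "dose_falloff_external") "edt_ptv_union"
             else paste0("edt_", goal$roi)
  d_cm <- sqrt(geometry_sq_edt(geometry, src_key, source)) / 10
  thr <- goal$falloff$high_dose -
    falloff_gradient_gy_cm(goal, protocol) * d_cm
  thr[thr < goal$falloff$low_dose] <- goal$falloff$low_dose
  thr[!region] <- NA_real_
  thr
}

# ---- objective state ---------------------------------------------------

#' Construct an objective state for a goal
#'
#' The mutable optimisation-time companion of a planning goal: the dynamic
#' target (the moving objective position, in the goal's native units), the
#' current optimiser weight and the last recorded penalty.
#'
#' @param goal a `planning_goal`.
#' @param optimiser_weight positive weight.
#' @param dynamic_target initial target in native units (defaults to the
#'   goal's protocol target).
#' @export
objective_state <- function(goal, optimiser_weight,
                            dynamic_target = goal$target) {
  stopifnot(optimiser_weight > 0)
  structure(list(
    goal = goal, id = goal_id(goal), dynamic_target = dynamic_target,
    optimiser_weight = optimiser_weight, last_penalty = NA_real_
  ), class = "objective_state")
}

# ---- penalties ---------------------------------------------------------

# Optimisation ROI of a dose goal.  Dose level / coverage goals on a
# nested PTV act on its subtraction region (the PTV minus all
# higher-prescription PTVs): a 104.9% ceiling on PTV48 is only meaningful
# outside the boost volumes it contains.  All other goals use the ROI as is.
goal_roi_mask <- function(goal, geometry, protocol) {
  ptvs <- names(protocol$prescriptions)
  if (goal$roi %in% ptvs &&
      goal$goal_type %in% c("min_dose", "max_dose", "median_max")) {
    higher <- ptvs[protocol$prescriptions > protocol$prescriptions[[goal$roi]]]
    m <- resolve_roi(geometry, goal$roi)
    for (h in higher) {
      hm <- geometry$masks[[h]]
      if (!is.null(hm)) m <- m & !hm
    }
    if (any(m)) return(m)
  }
  resolve_roi(geometry, goal$roi)
}

# Precompute everything static about a goal for fast repeated evaluation:
# region voxel positions within the influence row ordering, resolved dose
# levels, falloff thresholds, shells.
compile_goal <- function(goal, geometry, protocol, voxel_index) {
  region <- switch(goal$goal_type,
    conformality_max = conformality_shell(
      resolve_roi(geometry, goal$roi), goal$distance,
      geometry$masks$External, geometry$spacing),
    dose_falloff_external = ,
    dose_falloff_intra = {
      thr <- falloff_threshold_map(goal, geometry, protocol)
      !is.na(thr)
    },
    goal_roi_mask(goal, geometry, protocol)
  )
  if (!any(region))
    stop(sprintf("goal region for '%s' (%s) is empty", goal$roi, goal$goal_type))
  idx_full <- which(region)
  pos <- match(idx_full, voxel_index)
  if (anyNA(pos))
    stop(sprintf("goal region for '%s' extends outside the external contour",
                 goal$roi))
  out <- list(goal = goal, pos = pos, n = length(pos))
  if (goal$goal_type %in% c("dose_falloff_external", "dose_falloff_intra")) {
    thr <- falloff_threshold_map(goal, geometry, protocol)
    out$threshold <- thr[idx_full]
  }
  out
}

# Penalty + gradient of one compiled goal given the dose vector over the
# influence rows.  `dynamic_target` in the goal's native units.
# Returns list(value, pos, grad) with grad the partials w.r.t. the doses at
# `pos` (zero entries dropped).
penalty_eval <- function(cg, dvec, dynamic_target, protocol) {
  g <- cg$goal
  d <- dvec[cg$pos]
  n <- cg$n
  switch(g$goal_type,
    min_dose = {
      t_gy <- resolve_target_dose(g, protocol, dynamic_target)
      def <- pmax(0, t_gy - d)
      list(value = sum(def^2) / n, pos = cg$pos, grad = -2 * def / n)
    },
    max_dose = ,
    conformality_max = {
      t_gy <- resolve_target_dose(g, protocol, dynamic_target)
      exc <- pmax(0, d - t_gy)
      list(value = sum(exc^2) / n, pos = cg$pos, grad = 2 * exc / n)
    },
    mean_dose = {
      t_gy <- resolve_target_dose(g, protocol, dynamic_target)
      exc <- max(0, mean(d) - t_gy)
      list(value = exc^2, pos = cg$pos, grad = rep(2 * exc / n, n))
    },
    median_max = {
      # a D50% ceiling: dose-volume objective at 50% volume with the dose
      # level given by the goal's (resolved) target
      level <- resolve_target_dose(g, protocol, dynamic_target)
      dv_penalty(d, level, 50, n, cg$pos)
    },
    dv_max = {
      dv_penalty(d, g$dose_level, dynamic_target, n, cg$pos)
    },
    dose_falloff_external = ,
    dose_falloff_intra = {
      exc <- pmax(0, d - cg$threshold)
      list(value = sum(exc^2) / n, pos = cg$pos, grad = 2 * exc / n)
    },
    stop("unknown goal type")
  )
}

# Dose-volume ceiling penalty: V(level Gy) <= vol_target %.
# Tail rule: of the voxels above the dose level, the hottest
# floor(vol_target% * N) are allowed; the remaining (lowest-dose violating
# tail) are penalised quadratically toward the level.  Continuous in dose:
# contributions vanish as a voxel's dose approaches the level, and tied
# voxels contribute identically.
dv_penalty <- function(d, level, vol_target, n, pos) {
  above <- which(d > level)
  k_allow <- floor(vol_target / 100 * n)
  if (length(above) <= k_allow)
    return(list(value = 0, pos = pos[integer(0)], grad = numeric(0)))
  ord <- above[order(d[above], decreasing = TRUE)]
  tail_idx <- ord[(k_allow + 1):length(ord)]
  exc <- d[tail_idx] - level
  list(value = sum(exc^2) / n, pos = pos[tail_idx], grad = 2 * exc / n)
}

#' Penalty of one objective state on a dose distribution
#'
#' One-sided quadratic, volume-normalised penalty forms (see the methods
#' vignette): min_dose sum(max(0, T - d))^2 / N; max_dose, median ceilings,
#' conformality and falloff goals penalise excess above the (per-voxel)
#' threshold; mean_dose penalises (max(0, mean - T))^2; dv_max penalises the
#' violating low-dose tail of the voxels above the dose level.
#'
#' @param state an [objective_state()].
#' @param dose 3-D dose array.
#' @param geometry a `patient_geometry`.
#' @param protocol the protocol (needed to resolve relative units).
#' @return nonnegative penalty; the gradient with respect to the voxel doses
#'   is attached as attributes `grad_index` (linear voxel indices) and
#'   `grad` (partials).
#' @export
goal_penalty <- function(state, dose, geometry, protocol) {
  vi <- which(geometry$masks$External)
  cg <- compile_goal(state$goal, geometry, protocol, vi)
  dvec <- dose[vi]
  pe <- penalty_eval(cg, dvec, state$dynamic_target, protocol)
  structure(pe$value, grad_index = vi[pe$pos], grad = pe$grad)
}

#' Weighted composite objective over a set of objective states
#'
#' @param states list of [objective_state()].
#' @param dose 3-D dose array.
#' @param geometry,protocol as in [goal_penalty()].
#' @return the weighted penalty sum; per-goal penalties are attached as
#'   attribute `penalties` (named by goal id) and the updated states (with
#'   `last_penalty` recorded) as attribute `states`.
#' @export
composite_objective <- function(states, dose, geometry, protocol) {
  stopifnot(length(states) > 0)
  pens <- numeric(length(states))
  total <- 0
  for (i in seq_along(states)) {
    p <- goal_penalty(states[[i]], dose, geometry, protocol)
    pens[i] <- as.numeric(p)
    states[[i]]$last_penalty <- pens[i]
    total <- total + states[[i]]$optimiser_weight * pens[i]
  }
  names(pens) <- vapply(states, function(s) s$id, character(1))
  structure(total, penalties = pens, states = states)
}
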