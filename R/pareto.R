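# Pareto dataset generation over navigation dimensions, multilinear
# interpolation navigation, and calibration commit / averaging.

#' Define a navigation dimension
#'
#' A dimension is one navigable parameter of one planning goal: either its
#' weighting factor or its target value, together with the parameter values
#' sampled when the Pareto dataset is generated.
#'
#' @param goal_id stable goal identifier (`"ROI|goal_type|dose_level"`, see
#'   [protocol_goal_ids()]).
#' @param kind `"weighting_factor"` or `"target"`.
#' @param values 2 to 7 strictly increasing sampled parameter values
#'   (weighting factors must be positive).
#' @param label optional short label.
#' @export
navigation_dimension <- function(goal_id, kind = c("weighting_factor", "target"),
                                 values, label = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2 || length(values) > 7)
    stop("a navigation dimension needs 2-7 sampled values")
  if (any(diff(values) <= 0)) stop("sampled values must be strictly increasing")
  if (kind == "weighting_factor" && any(values <= 0))
    stop("weighting factor samples must be > 0")
  structure(list(goal_id = goal_id, kind = kind, values = values,
                 label = label %||% paste0(goal_id, ":", substr(kind, 1, 2))),
            class = "navigation_dimension")
}

#' Goal identifiers of a protocol
#' @param protocol an `autoplan_protocol`.
#' @return character vector of `"ROI|goal_type|dose_level"` ids, in goal
#'   order.
#' @export
protocol_goal_ids <- function(protocol) {
  vapply(protocol$goals, goal_id, character(1))
}

find_goal_index <- function(protocol, id) {
  ids <- protocol_goal_ids(protocol)
  i <- which(ids == id)
  if (length(i) != 1)
    stop(sprintf("goal id '%s' matches %d goals in the protocol", id, length(i)))
  i
}

#' Cartesian grid of sampled parameter-value combinations
#'
#' All parameter-value permutations across the dimensions, in lexicographic
#' order with the FIRST dimension varying fastest.  A warning is emitted
#' above `warn_dims` dimensions (exhaustive sampling grows as the product of
#' the sample counts) or when the grid exceeds `warn_plans` plans.
#'
#' @param dimensions list of [navigation_dimension()].
#' @param warn_dims soft dimension limit (default 4).
#' @param warn_plans soft plan-count limit (default 256).
#' @return data.frame, one column per dimension (named by label), one row
#'   per combination.
#' @export
build_grid <- function(dimensions, warn_dims = 4L, warn_plans = 256L) {
  if (!length(dimensions)) stop("at least one dimension required")
  for (d in dimensions) stopifnot(inherits(d, "navigation_dimension"))
  n <- prod(vapply(dimensions, function(d) length(d$values), numeric(1)))
  if (length(dimensions) > warn_dims)
    warning(sprintf(
      "%d navigation dimensions: exhaustive Pareto sampling is typically practical below 5",
      length(dimensions)))
  if (n > warn_plans)
    warning(sprintf("grid of %d plans: dataset generation cost grows as the grid cardinality", n))
  g <- expand.grid(lapply(dimensions, function(d) d$values),
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- vapply(dimensions, function(d) d$label, character(1))
  g
}

apply_dimension_values <- function(protocol, dimensions, values) {
  for (k in seq_along(dimensions)) {
    dim <- dimensions[[k]]
    i <- find_goal_index(protocol, dim$goal_id)
    if (dim$kind == "weighting_factor") {
      protocol$goals[[i]]$weighting_factor <- values[[k]]
    } else {
      protocol$goals[[i]]$target <- values[[k]]
    }
  }
  protocol
}

#' Generate a Pareto navigation dataset
#'
#' For every combination of sampled dimension values the base protocol is
#' cloned, the dimension parameters overwritten, and a full automated plan
#' generated with a shared influence matrix and configuration, so plans
#' differ only through the navigated parameters.
#'
#' @param geometry a `patient_geometry` with PTVs.
#' @param protocol base protocol.
#' @param dimensions list of [navigation_dimension()].
#' @param beam_cfg,config engine and loop configuration shared by all plans.
#' @param influence optional prebuilt influence matrix.
#' @return object of class `pareto_dataset`: list with `dimensions`, `grid`
#'   (the combination table), `plans` (list parallel to the grid rows),
#'   `protocol`, `geometry`.
#' @export
generate_dataset <- function(geometry, protocol, dimensions,
                             beam_cfg = beam_config(),
                             config = pbaio_config(), influence = NULL) {
  grid <- build_grid(dimensions)
  if (is.null(influence)) influence <- build_influence_matrix(geometry, beam_cfg)
  plans <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    proto_r <- apply_dimension_values(protocol, dimensions,
                                      as.numeric(grid[r, , drop = TRUE]))
    plans[[r]] <- tryCatch(
      autoplan(geometry, proto_r, beam_cfg, config, influence = influence),
      error = function(e) stop(sprintf(
        "autoplan failed for combination %d (%s): %s",
        r, paste(sprintf("%s=%g", names(grid), as.numeric(grid[r, ])),
                 collapse = ", "),
        conditionMessage(e)))
    )
  }
  structure(list(dimensions = dimensions, grid = grid, plans = plans,
                 protocol = protocol, geometry = geometry),
            class = "pareto_dataset")
}

#' @export
print.pareto_dataset <- function(x, ...) {
  cat(sprintf("pareto_dataset: %d dimensions, %d plans\n",
              length(x$dimensions), length(x$plans)))
  invisible(x)
}

# Locate the enclosing cell and interpolation coefficient along each
# dimension.  Returns list(lo = lower sample index, t = coefficient).
cell_coords <- function(dimensions, position) {
  lo <- integer(length(dimensions)); tt <- numeric(length(dimensions))
  for (k in seq_along(dimensions)) {
    v <- dimensions[[k]]$values
    p <- position[[k]]
    if (p < min(v) - 1e-12 || p > max(v) + 1e-12)
      stop(sprintf("position %g outside sampled range [%g, %g] of dimension '%s'",
                   p, min(v), max(v), dimensions[[k]]$label))
    i <- findInterval(p, v, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(v) - 1L)
    lo[k] <- i
    tt[k] <- (p - v[i]) / (v[i + 1] - v[i])
  }
  list(lo = lo, t = tt)
}

# Row index into the lexicographic grid (first dimension fastest) from
# per-dimension sample indices.
grid_row_index <- function(dimensions, idx) {
  sizes <- vapply(dimensions, function(d) length(d$values), integer(1))
  r <- 1L; mult <- 1L
  for (k in seq_along(idx)) {
    r <- r + (idx[k] - 1L) * mult
    mult <- mult * sizes[k]
  }
  r
}

resolve_position <- function(dataset, position) {
  labels <- vapply(dataset$dimensions, function(d) d$label, character(1))
  if (!is.null(names(position)) && all(names(position) %in% labels))
    position <- position[labels]
  if (length(position) != length(dataset$dimensions))
    stop("position must supply one value per dimension")
  as.numeric(position)
}

#' Interpolate the navigated dose distribution
#'
#' Multilinear interpolation over the enclosing grid cell: with per-dimension
#' coefficients t_d = (value - lower)/(upper - lower), the navigated dose is
#' the voxel-wise sum over the cell's 2^D corner plans weighted by
#' prod_d (t_d or 1 - t_d).  No extrapolation outside the sampled ranges.
#'
#' @param dataset a `pareto_dataset`.
#' @param position numeric vector (optionally named by dimension label) of
#'   navigated parameter values.
#' @return 3-D dose array.
#' @export
interpolate <- function(dataset, position) {
  position <- resolve_position(dataset, position)
  cc <- cell_coords(dataset$dimensions, position)
  D <- length(dataset$dimensions)
  corners <- expand.grid(rep(list(0:1), D), KEEP.OUT.ATTRS = FALSE)
  dose <- NULL
  for (r in seq_len(nrow(corners))) {
    bits <- as.integer(corners[r, ])
    wgt <- prod(ifelse(bits == 1, cc$t, 1 - cc$t))
    if (wgt == 0) next
    row <- grid_row_index(dataset$dimensions, cc$lo + bits)
    contrib <- dataset$plans[[row]]$dose * wgt
    dose <- if (is.null(dose)) contrib else dose + contrib
  }
  dose
}

#' Evaluate plan metrics at a navigated position
#'
#' Evaluates a panel of DVH metrics on the interpolated dose (no plan
#' re-optimisation is run), optionally alongside the metrics of a stored
#' reference position.
#'
#' @param dataset a `pareto_dataset`.
#' @param position navigated parameter values.
#' @param metric_specs list of metric specs: each a list with `kind` (one of
#'   `D_percent`, `D_abs_volume`, `V_dose_percent`, `V_dose_abs`, `Dmean`,
#'   `Dmax`, `D1_percent`, `HI`, `CI`), `roi`, optional `param` and
#'   `subtract` flag.
#' @param reference optional second position evaluated as a reference.
#' @return data.frame with `metric`, `value` and (when a reference is given)
#'   `reference`.
#' @export
navigate_metrics <- function(dataset, position, metric_specs,
                             reference = NULL) {
  dose <- interpolate(dataset, position)
  vals <- vapply(metric_specs, function(sp)
    evaluate_metric(dose, dataset$geometry, sp), numeric(1))
  out <- data.frame(
    metric = vapply(metric_specs, metric_label, character(1)),
    value = vals, stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    rdose <- interpolate(dataset, reference)
    out$reference <- vapply(metric_specs, function(sp)
      evaluate_metric(rdose, dataset$geometry, sp), numeric(1))
  }
  out
}

#' Commit a navigated position into the protocol
#'
#' Writes the navigated parameter values back into the base protocol: for
#' weighting-factor dimensions the navigated value overwrites the goal's WF,
#' for target dimensions its target.  All other goals are untouched.
#'
#' @param dataset a `pareto_dataset`.
#' @param position navigated parameter values.
#' @param protocol protocol to update (defaults to the dataset's base
#'   protocol).
#' @return a valid `autoplan_protocol`.
#' @export
commit_calibration <- function(dataset, position, protocol = dataset$protocol) {
  position <- resolve_position(dataset, position)
  cell_coords(dataset$dimensions, position)  # validates range
  apply_dimension_values(protocol, dataset$dimensions, as.list(position))
}

#' Average calibrations from several navigated patients
#'
#' Per-goal weighting factors are averaged across the input protocols
#' (arithmetic by default, geometric optionally); goal structure and targets
#' must agree.
#'
#' @param protocols list of structurally identical `autoplan_protocol`s.
#' @param method `"arithmetic"` or `"geometric"`.
#' @return merged `autoplan_protocol`.
#' @export
merge_calibrations <- function(protocols, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  stopifnot(length(protocols) >= 1)
  base <- protocols[[1]]
  ids <- protocol_goal_ids(base)
  for (p in protocols[-1]) {
    if (!identical(protocol_goal_ids(p), ids))
      stop("protocols do not share goal structure")
  }
  for (i in seq_along(base$goals)) {
    targets <- vapply(protocols, function(p) p$goals[[i]]$target, numeric(1))
    if (any(abs(targets - targets[1]) > 1e-9))
      stop(sprintf("targets disagree for goal '%s'", ids[i]))
    if (base$goals[[i]]$priority == "P3") {
      wfs <- vapply(protocols, function(p) p$goals[[i]]$weighting_factor,
                    numeric(1))
      base$goals[[i]]$weighting_factor <-
        if (method == "arithmetic") mean(wfs) else exp(mean(log(wfs)))
    }
  }
  base
}
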