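# Plain-text serialisation of geometries and plan summaries.
#
# Masks are stored run-length encoded in column-major voxel order inside a
# JSON container; the round trip is exact.

#' Write a patient geometry to JSON
#' @param geometry a `patient_geometry`.
#' @param path output path (conventionally `.json`).
#' @export
write_patient_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "patient_geometry"))
  masks <- lapply(geometry$masks, function(m) {
    r <- rle(as.integer(m))
    list(lengths = r$lengths, values = r$values)
  })
  obj <- list(
    format = "pgap-geometry", version = "1.0",
    grid_shape = geometry$grid_shape, spacing = geometry$spacing,
    seed = geometry$seed, anatomy_params = geometry$anatomy_params,
    masks = masks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patient geometry from JSON
#' @param path file written by [write_patient_geometry()].
#' @return a `patient_geometry`.
#' @export
read_patient_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pgap-geometry"))
    stop("not a pgap geometry file")
  gs <- as.integer(obj$grid_shape)
  masks <- lapply(obj$masks, function(m) {
    v <- inverse.rle(structure(list(lengths = as.integer(m$lengths),
                                    values = as.integer(m$values)),
                               class = "rle"))
    array(as.logical(v), gs)
  })
  ap <- obj$anatomy_params
  geom <- structure(list(
    grid_shape = gs, spacing = as.numeric(obj$spacing), masks = masks,
    seed = as.integer(obj$seed), anatomy_params = ap
  ), class = "patient_geometry")
  validate_geometry(geom)
}

#' Write a plan summary (fluence, log, metric panel) to a directory
#'
#' Runtime output helper used by the command-line interface: writes
#' `fluence.csv`, `log.csv`, `metrics.csv` and `plan.json` (normalisation,
#' seed, configurations) under `dir`.
#'
#' @param plan a `pgap_plan`.
#' @param geometry the planning geometry.
#' @param dir output directory (created).
#' @export
write_plan_summary <- function(plan, geometry, dir) {
  stopifnot(inherits(plan, "pgap_plan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(beamlet = seq_along(plan$fluence),
                              weight = plan$fluence),
                   file.path(dir, "fluence.csv"), row.names = FALSE)
  utils::write.csv(plan$log, file.path(dir, "log.csv"), row.names = FALSE)
  panel <- study_metric_panel(plan$protocol$institution)
  utils::write.csv(evaluate_metric_panel(plan$dose, geometry, panel),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(normalisation = plan$normalisation, seed = plan$seed,
         final_objective = utils::tail(plan$objective_trace, 1),
         protocol = plan$protocol$name,
         beam_config = unclass(plan$beam_config),
         pbaio_config = unclass(plan$pbaio_config)),
    file.path(dir, "plan.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
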