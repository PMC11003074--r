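# Simplified linear dose model: beamlet influence matrix for an arc of
# coplanar static beams.
#
# Each beam is a parallel beamlet fan at one gantry angle; a beamlet deposits
#   output_scale * exp(-mu_atten * depth) * exp(-lateral^2 / (2 sigma^2))
# at a voxel, where depth is the radiological path length from the body
# surface along the beam direction and lateral the in-plane + axial offset
# from the beamlet axis.  The kernel constants are deliberately simple and
# non-clinical; they exist to make target-coverage vs organ-sparing
# trade-offs real for the optimiser, not to model a linac.

#' Beam / beamlet configuration
#'
#' @param n_beams number of equispaced static beams over 360 degrees
#'   (default 36, approximating a single full arc).
#' @param beamlet_width beamlet grid pitch in mm.
#' @param mu_atten linear attenuation per mm of depth (default 0.005/mm).
#' @param sigma_lateral Gaussian penumbra sigma in mm (default 4 mm).
#' @param output_scale Gy per unit fluence weight at zero depth.
#' @param support_sigma beamlet support truncation radius in sigmas.
#' @param sparsity_floor influence entries below
#'   `sparsity_floor * output_scale` are dropped from the sparse matrix.
#' @param bev_margin margin (mm) added around the target's beam's-eye-view
#'   bounding box when tiling beamlets.
#' @return object of class `beam_config`.
#' @export
beam_config <- function(n_beams = 36L, beamlet_width = 8, mu_atten = 0.005,
                        sigma_lateral = 4, output_scale = 1,
                        support_sigma = 2.5, sparsity_floor = 1e-4,
                        bev_margin = 10) {
  stopifnot(n_beams >= 4L, mu_atten > 0, sigma_lateral > 0,
            beamlet_width > 0, output_scale > 0)
  structure(list(
    n_beams = as.integer(n_beams), beamlet_width = beamlet_width,
    mu_atten = mu_atten, sigma_lateral = sigma_lateral,
    output_scale = output_scale, support_sigma = support_sigma,
    sparsity_floor = sparsity_floor, bev_margin = bev_margin
  ), class = "beam_config")
}

#' Build the beamlet influence matrix for a geometry
#'
#' Beamlets tile the beam's-eye-view bounding box of the target (the union
#' of the PTVs when present, otherwise prostate + seminal vesicles) with a
#' margin, for every beam angle.  Rows correspond to voxels inside the
#' external contour (all other voxels receive zero dose by construction).
#'
#' @param geometry a `patient_geometry`.
#' @param config a [beam_config()].
#' @return object of class `influence_matrix`: list with the sparse `matrix`
#'   (voxels-in-external x beamlets, Gy per unit weight), `voxel_index`
#'   (linear indices of the rows in the full grid), `beamlets` (data.frame
#'   of beam / lateral / axial beamlet coordinates), `grid_shape`, `spacing`,
#'   `config`.
#' @export
build_influence_matrix <- function(geometry, config = beam_config()) {
  stopifnot(inherits(geometry, "patient_geometry"),
            inherits(config, "beam_config"))
  gs <- geometry$grid_shape; sp <- geometry$spacing
  ext <- geometry$masks$External
  if (!any(ext)) stop("external mask is empty")
  m <- geometry$masks
  target <- if (!is.null(m$PTV48)) (m$PTV60 | m$`PTV57.5` | m$PTV48)
            else (m$Prostate | m$SeminalVesicles)
  if (!any(target)) stop("target bounding box is empty")

  co <- coord_arrays(gs, sp)
  vi <- which(ext)
  xv <- co$x[vi]; yv <- co$y[vi]; zv <- co$z[vi]
  xt <- co$x[target]; yt <- co$y[target]; zt <- co$z[target]

  sig <- config$sigma_lateral
  R <- config$support_sigma * sig
  w <- config$beamlet_width
  floor_abs <- config$sparsity_floor * config$output_scale
  zr <- range(zt)
  z_centres <- seq(zr[1] - config$bev_margin, zr[2] + config$bev_margin, by = w)

  rows <- list(); cols <- list(); vals <- list(); k <- 0L
  blt_meta <- list()
  n_blt <- 0L

  for (b in seq_len(config$n_beams)) {
    theta <- 2 * pi * (b - 1) / config$n_beams
    cu <- cos(theta); su <- sin(theta)
    u <- xv * cu + yv * su          # lateral, in axial plane
    s <- -xv * su + yv * cu         # along-beam coordinate (depth axis)
    ut <- xt * cu + yt * su
    ur <- range(ut)
    u_centres <- seq(ur[1] - config$bev_margin, ur[2] + config$bev_margin, by = w)

    # Radiological depth: voxels binned onto the beamlet lattice; entry depth
    # per (u, z) ray bin is the minimum along-beam coordinate of external
    # voxels in that bin.
    iu <- round((u - u_centres[1]) / w)
    iz <- round((zv - z_centres[1]) / w)
    key <- iu * 10000L + iz
    smin <- tapply(s, key, min)
    depth <- pmax(0, s - smin[as.character(key)])
    att <- exp(-config$mu_atten * depth) * config$output_scale

    ord_z <- lapply(z_centres, function(zc) which(abs(zv - zc) <= R))
    for (jz in seq_along(z_centres)) {
      idx_z <- ord_z[[jz]]
      if (!length(idx_z)) { n_blt <- n_blt + length(u_centres); next }
      gz <- exp(-((zv[idx_z] - z_centres[jz])^2) / (2 * sig^2))
      for (ju in seq_along(u_centres)) {
        n_blt <- n_blt + 1L
        sel <- which(abs(u[idx_z] - u_centres[ju]) <= R)
        if (!length(sel)) next
        ii <- idx_z[sel]
        val <- att[ii] * gz[sel] *
          exp(-((u[ii] - u_centres[ju])^2) / (2 * sig^2))
        keep <- val >= floor_abs
        if (!any(keep)) next
        k <- k + 1L
        rows[[k]] <- ii[keep]
        cols[[k]] <- rep.int(n_blt, sum(keep))
        vals[[k]] <- val[keep]
      }
    }
    # beamlet columns were assigned z-row by z-row with u varying fastest
    blt_meta[[b]] <- data.frame(
      beam = b, angle = theta,
      u = rep(u_centres, times = length(z_centres)),
      z = rep(z_centres, each = length(u_centres))
    )
  }

  meta <- do.call(rbind, blt_meta)
  rownames(meta) <- NULL

  mat <- Matrix::sparseMatrix(
    i = unlist(rows), j = unlist(cols), x = unlist(vals),
    dims = c(length(vi), n_blt)
  )
  structure(list(
    matrix = mat, voxel_index = vi, beamlets = meta,
    grid_shape = gs, spacing = sp, config = config
  ), class = "influence_matrix")
}

#' Construct an influence matrix object from raw components
#'
#' Low-level constructor used for analytic toy problems in tests and
#' examples: wraps an arbitrary nonnegative matrix as an
#' `influence_matrix`.
#'
#' @param matrix numeric or sparse matrix, voxels (rows) x beamlets (cols).
#' @param voxel_index linear indices of the rows in the full grid.
#' @param grid_shape,spacing grid description.
#' @export
influence_matrix <- function(matrix, voxel_index, grid_shape,
                             spacing = c(1, 1, 1)) {
  stopifnot(nrow(matrix) == length(voxel_index), all(matrix >= 0))
  structure(list(
    matrix = Matrix::Matrix(matrix, sparse = TRUE), voxel_index = voxel_index,
    beamlets = NULL, grid_shape = as.integer(grid_shape),
    spacing = spacing, config = NULL
  ), class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("influence_matrix: %d voxels x %d beamlets, %.2f%% dense\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix))))
  invisible(x)
}

#' Compute the dose distribution for a fluence vector
#'
#' Linear dose model: dose = influence x fluence, reshaped onto the grid.
#'
#' @param influence an `influence_matrix`.
#' @param fluence nonnegative weight vector, one entry per beamlet.
#' @return 3-D dose array (Gy) of the influence grid shape; zero outside the
#'   external contour.
#' @export
compute_dose <- function(influence, fluence) {
  stopifnot(inherits(influence, "influence_matrix"))
  if (length(fluence) != ncol(influence$matrix))
    stop("fluence length does not match beamlet count")
  if (any(fluence < 0)) stop("fluence weights must be >= 0")
  d <- as.numeric(influence$matrix %*% fluence)
  arr <- array(0, influence$grid_shape)
  arr[influence$voxel_index] <- d
  arr
}

#' Normalise a plan so the PTV60 median dose equals the prescription
#'
#' Scales the dose by a single factor such that D50% of PTV60 equals the
#' prescription (default 60 Gy) exactly.
#'
#' @param dose 3-D dose array.
#' @param geometry geometry with a nonempty `PTV60` mask.
#' @param prescription target median dose, Gy.
#' @return list with `dose` (scaled array) and `factor` (the scale applied).
#' @export
normalise_plan <- function(dose, geometry, prescription = 60) {
  ptv <- geometry$masks$PTV60
  if (is.null(ptv) || !any(ptv)) stop("PTV60 mask missing or empty")
  med <- dose_at_volume(dose, ptv, 50)
  if (med <= 0) stop("cannot normalise: PTV60 median dose is zero")
  f <- prescription / med
  list(dose = dose * f, factor = f)
}
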