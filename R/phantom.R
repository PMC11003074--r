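# Procedural prostate phantom generation.
#
# The phantom emulates prostate-only anatomy treated under a hypofractionated
# simultaneous-integrated-boost protocol (60 Gy in 20 fractions): prostate and
# proximal seminal vesicles as targets; rectum, bladder and -- for the
# institution-B profile -- femoral heads and bowel as organs at risk.  All
# structures are boolean masks on one regular voxel grid so that every
# downstream stage (dose engine, optimisation, metrics) is testable without
# clinical data.

#' Default anatomy configuration for the prostate phantom
#'
#' Organ sizes are in mm and are jittered patient-to-patient by uniform draws
#' (half-width given by the `*_jitter` entries) seeded from the patient seed.
#' The external (body) contour is an elliptical cylinder whose semi-axes are
#' 90% of the grid half-extent, so anatomy scales with the chosen grid.
#'
#' @param grid_shape integer triple of voxel counts; default 64 x 64 x 48.
#' @param spacing voxel spacing in mm (default 4 mm isotropic).
#' @param profile `"instA"` (rectum + bladder OARs) or `"instB"` (adds
#'   femoral heads and bowel).
#' @return named list of anatomy parameters accepted by [generate_patient()].
#' @export
anatomy_defaults <- function(grid_shape = c(64L, 64L, 48L),
                             spacing = c(4, 4, 4),
                             profile = c("instA", "instB")) {
  profile <- match.arg(profile)
  list(
    grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    profile = profile,
    external_fraction = 0.90,     # body semi-axes as fraction of half extent
    prostate_semiaxes = c(22, 20, 20),
    prostate_jitter = 2,
    prostate_centre_y = 6,        # mm posterior of grid centre
    prostate_centre_z = -8,       # mm inferior of grid centre
    sv_length = 20,               # proximal seminal-vesicle extent, mm
    sv_radius = 8,
    rectum_radius = 13,
    rectum_jitter = 2,
    rectum_gap = 0,               # voxels between prostate and rectum
    bladder_semiaxes = c(30, 26, 24),
    bladder_jitter = 3,
    femhead_radius = 19,
    bowel_semiaxes = c(34, 22, 18)
  )
}

#' Generate a synthetic prostate patient geometry
#'
#' Builds the labelled voxel anatomy: `External` (elliptic-cylinder body),
#' `Prostate` (ellipsoid), `SeminalVesicles` (posterior-superior lobe of
#' configurable proximal length), `Rectum` (posterior tube abutting -- face
#' adjacent to, never overlapping -- the prostate), `Bladder`
#' (superior-anterior ellipsoid) and, for the `instB` profile, `FemoralHead_L`,
#' `FemoralHead_R` and `Bowel`.  Anatomy parameters are jittered by uniform
#' draws seeded by `seed`, so regeneration with the same seed and
#' configuration reproduces the masks bit for bit.
#'
#' @param seed integer RNG seed for the anatomical jitter.
#' @param anatomy_config named list overriding entries of [anatomy_defaults()].
#' @return an object of class `patient_geometry`: list with `grid_shape`,
#'   `spacing`, `masks` (named list of logical arrays), `seed` and
#'   `anatomy_params` (the realised, jittered parameter values).
#' @export
generate_patient <- function(seed = 1L, anatomy_config = list()) {
  cfg <- utils::modifyList(
    anatomy_defaults(
      grid_shape = anatomy_config$grid_shape %||% c(64L, 64L, 48L),
      spacing = anatomy_config$spacing %||% c(4, 4, 4),
      profile = anatomy_config$profile %||% "instA"
    ),
    anatomy_config
  )
  gs <- as.integer(cfg$grid_shape)
  sp <- as.numeric(cfg$spacing)
  if (any(gs < 32L)) stop("grid_shape must be at least 32 voxels per axis")
  if (any(sp < 1) || any(sp > 5)) stop("spacing must lie in [1, 5] mm")

  draws <- with_local_seed(seed, {
    list(
      pro = stats::runif(3, -cfg$prostate_jitter, cfg$prostate_jitter),
      rec = stats::runif(1, -cfg$rectum_jitter, cfg$rectum_jitter),
      bla = stats::runif(3, -cfg$bladder_jitter, cfg$bladder_jitter),
      sv  = stats::runif(1, -2, 2)
    )
  })

  pro_ax <- cfg$prostate_semiaxes + draws$pro
  rec_r <- cfg$rectum_radius + draws$rec
  bla_ax <- cfg$bladder_semiaxes + draws$bla
  sv_len <- max(5, cfg$sv_length + draws$sv)
  if (any(pro_ax <= 0) || rec_r <= 0 || any(bla_ax <= 0))
    stop("organ radii must be positive")

  co <- coord_arrays(gs, sp)
  half <- gs * sp / 2
  ext_ax <- cfg$external_fraction * half[1:2]

  external <- (co$x / ext_ax[1])^2 + (co$y / ext_ax[2])^2 <= 1

  pc <- c(0, cfg$prostate_centre_y, cfg$prostate_centre_z)
  prostate <- ellipsoid_mask(co, pc, pro_ax)

  # Seminal vesicles: posterior-superior lobe rising from the prostate apex.
  sv_c <- c(0, pc[2] + 0.5 * pro_ax[2], pc[3] + pro_ax[3] + sv_len / 2 - 4)
  sv <- ellipsoid_mask(co, sv_c, c(1.6 * cfg$sv_radius, cfg$sv_radius, sv_len / 2))

  # Rectum: posterior tube along z, anterior wall tangent to the prostate
  # surface (configurable voxel gap; 0 = abutting).
  rec_y <- pc[2] + pro_ax[2] + rec_r + cfg$rectum_gap * sp[2]
  rectum <- (co$x / rec_r)^2 + ((co$y - rec_y) / rec_r)^2 <= 1
  rectum <- rectum & abs(co$z) <= 0.85 * half[3]
  rectum <- rectum & !prostate
  sv <- sv & !rectum & !prostate

  # Bladder: superior-anterior of the prostate.
  bla_c <- c(0, pc[2] - pro_ax[2] - 0.55 * bla_ax[2], pc[3] + pro_ax[3] + 0.45 * bla_ax[3])
  bladder <- ellipsoid_mask(co, bla_c, bla_ax) & !prostate & !sv & !rectum

  masks <- list(
    External = external, Prostate = prostate, SeminalVesicles = sv,
    Rectum = rectum, Bladder = bladder
  )

  params <- list(
    prostate_semiaxes = pro_ax, prostate_centre = pc,
    rectum_radius = rec_r, rectum_centre_y = rec_y,
    bladder_semiaxes = bla_ax, bladder_centre = bla_c,
    sv_length = sv_len, external_semiaxes = ext_ax,
    profile = cfg$profile
  )

  if (cfg$profile == "instB") {
    fh_x <- 0.62 * half[1]
    fh <- cfg$femhead_radius
    for (side in c("L", "R")) {
      sgn <- if (side == "L") -1 else 1
      m <- ellipsoid_mask(co, c(sgn * fh_x, pc[2], pc[3]), rep(fh, 3))
      masks[[paste0("FemoralHead_", side)]] <- m
    }
    bw_c <- c(0, bla_c[2] - 4, min(pc[3] + pro_ax[3] + sv_len + cfg$bowel_semiaxes[3],
                                   0.80 * half[3] - cfg$bowel_semiaxes[3]) )
    bowel <- ellipsoid_mask(co, bw_c, cfg$bowel_semiaxes) & !bladder & !sv & !rectum
    masks$Bowel <- bowel
    params$femhead_radius <- fh
  }

  for (nm in setdiff(names(masks), "External")) {
    if (any(masks[[nm]] & !external))
      stop(sprintf("structure '%s' extends outside the external contour", nm))
  }

  geom <- structure(
    list(grid_shape = gs, spacing = sp, masks = masks, seed = as.integer(seed),
         anatomy_params = params,
         cache = new.env(parent = emptyenv())),
    class = "patient_geometry"
  )
  validate_geometry(geom)
  geom
}

ellipsoid_mask <- function(co, centre, semiaxes) {
  ((co$x - centre[1]) / semiaxes[1])^2 +
    ((co$y - centre[2]) / semiaxes[2])^2 +
    ((co$z - centre[3]) / semiaxes[3])^2 <= 1
}

#' Validate the invariants of a patient geometry
#'
#' Checks mask shapes, containment within the external contour, prostate /
#' rectum disjointness and (when PTVs are present) the nesting
#' PTV60 ⊆ PTV57.5 ⊆ PTV48.  Called by the constructors; exported because it
#' is useful after manual mask surgery.
#'
#' @param geometry a `patient_geometry`.
#' @return `geometry`, invisibly; errors describe the violated invariant.
#' @export
validate_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "patient_geometry"))
  gs <- geometry$grid_shape
  for (nm in names(geometry$masks)) {
    m <- geometry$masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(gs)))
      stop(sprintf("mask '%s' does not match grid_shape", nm))
  }
  ext <- geometry$masks$External
  for (nm in setdiff(names(geometry$masks), "External")) {
    if (any(geometry$masks[[nm]] & !ext))
      stop(sprintf("mask '%s' is not contained in External", nm))
  }
  if (any(geometry$masks$Prostate & geometry$masks$Rectum))
    stop("Prostate and Rectum overlap")
  ms <- geometry$masks
  if (all(c("PTV60", "PTV57.5", "PTV48") %in% names(ms))) {
    if (any(ms$PTV60 & !ms$`PTV57.5`)) stop("PTV60 not contained in PTV57.5")
    if (any(ms$`PTV57.5` & !ms$PTV48)) stop("PTV57.5 not contained in PTV48")
  }
  invisible(geometry)
}

#' @export
print.patient_geometry <- function(x, ...) {
  cat(sprintf("patient_geometry: %s grid at %s mm, seed %d (%s)\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "/"),
              x$seed, x$anatomy_params$profile))
  vols <- vapply(x$masks, sum, numeric(1)) * voxel_volume_cc(x$spacing)
  for (nm in names(vols)) cat(sprintf("  %-16s %8.1f cc\n", nm, vols[nm]))
  invisible(x)
}

#' Anisotropic margin expansion of a structure mask
#'
#' Morphological expansion with direction-dependent margins: an output voxel
#' is set iff its centre lies within the direction-dependent margin of some
#' input voxel centre, where the margin surface interpolates ellipsoidally
#' between the six axis margins.  Margins are given in the fixed order
#' left (-x), right (+x), anterior (-y), posterior (+y), inferior (-z),
#' superior (+z); posterior is +y throughout the package.
#'
#' @param mask logical 3-D array.
#' @param margins numeric length-6 (mm) in the order above, or a single
#'   number for an isotropic margin.
#' @param spacing voxel spacing triple, mm.
#' @return logical array of the same shape, a superset of `mask`.
#' @export
expand_structure <- function(mask, margins, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (length(margins) == 1L) margins <- rep(margins, 6L)
  stopifnot(length(margins) == 6L)
  if (any(margins < 0)) stop("margins must be >= 0")
  dm <- dim(mask)
  ext_mm <- dm * spacing
  if (any(margins[c(1, 3, 5)] > ext_mm[c(1, 2, 3)]) ||
      any(margins[c(2, 4, 6)] > ext_mm[c(1, 2, 3)]))
    stop("margin exceeds grid extent")
  rx <- floor(max(margins[1:2]) / spacing[1])
  ry <- floor(max(margins[3:4]) / spacing[2])
  rz <- floor(max(margins[5:6]) / spacing[3])
  out <- mask
  eps <- 1e-9
  for (dx in seq(-rx, rx)) {
    mx <- if (dx < 0) margins[1] else margins[2]
    tx <- margin_term(dx * spacing[1], mx)
    if (tx > 1 + eps) next
    for (dy in seq(-ry, ry)) {
      my <- if (dy < 0) margins[3] else margins[4]
      ty <- margin_term(dy * spacing[2], my)
      if (tx + ty > 1 + eps) next
      for (dz in seq(-rz, rz)) {
        mz <- if (dz < 0) margins[5] else margins[6]
        tz <- margin_term(dz * spacing[3], mz)
        if (tx + ty + tz > 1 + eps) next
        out <- shift_or(out, mask, c(dx, dy, dz))
      }
    }
  }
  out
}

margin_term <- function(offset_mm, margin_mm) {
  if (offset_mm == 0) return(0)
  if (margin_mm <= 0) return(Inf)
  (offset_mm / margin_mm)^2
}

#' Construct the planning target volumes from the margin recipe
#'
#' PTV60 = prostate expanded 5 mm (0 mm posteriorly); PTV57.5 = prostate
#' expanded 10 mm (5 mm posteriorly); PTV48 = (prostate + seminal vesicles)
#' expanded 10 mm isotropically; all intersected with the external contour.
#' The resulting masks are nested PTV60 ⊆ PTV57.5 ⊆ PTV48.
#'
#' @param geometry a `patient_geometry` containing `Prostate` and
#'   `SeminalVesicles` masks.
#' @return the geometry with `PTV60`, `PTV57.5` and `PTV48` masks added.
#' @export
build_ptvs <- function(geometry) {
  stopifnot(inherits(geometry, "patient_geometry"))
  for (need in c("Prostate", "SeminalVesicles")) {
    if (is.null(geometry$masks[[need]]))
      stop(sprintf("missing prerequisite mask '%s'", need))
  }
  sp <- geometry$spacing
  ext <- geometry$masks$External
  pro <- geometry$masks$Prostate
  sv <- geometry$masks$SeminalVesicles
  # margin order: left, right, anterior, posterior(+y), inferior, superior
  ptv60 <- expand_structure(pro, c(5, 5, 5, 0, 5, 5), sp) & ext
  ptv575 <- expand_structure(pro, c(10, 10, 10, 5, 10, 10), sp) & ext
  target48 <- pro | sv
  ptv48 <- expand_structure(target48, 10, sp) & ext
  geometry$masks$PTV60 <- ptv60
  geometry$masks$`PTV57.5` <- ptv575
  geometry$masks$PTV48 <- ptv48
  validate_geometry(geometry)
}

#' Conformality shell around a source structure
#'
#' The region of the external contour whose voxel centres lie at least
#' `distance_cm` from any source voxel centre (and outside the source) --
#' the region on which a primary conformality max-dose goal applies.
#'
#' @param source logical source mask (nonempty).
#' @param distance_cm shell stand-off distance in cm.
#' @param external logical external mask.
#' @param spacing spacing triple, mm.
#' @return logical mask.
#' @export
conformality_shell <- function(source, distance_cm, external, spacing) {
  if (!any(source)) stop("conformality_shell: empty source mask")
  if (distance_cm < 0) stop("distance must be >= 0")
  d <- euclidean_distance_mm(source, spacing)
  external & !source & d >= distance_cm * 10 - 1e-9
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
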