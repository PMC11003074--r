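# Shared voxel-grid helpers.
#
# Coordinate convention (used everywhere in the package):
#   axis 1 = x = patient left-right, axis 2 = y = anterior-posterior with
#   +y pointing POSTERIOR, axis 3 = z = inferior-superior with +z SUPERIOR.
#   Voxel centres are placed symmetrically about the grid centre, i.e. centre
#   of voxel i along an axis with n voxels and spacing s is (i - (n+1)/2) * s mm.

vox_centres <- function(n, s) (seq_len(n) - (n + 1) / 2) * s

#' Voxel centre coordinate vectors of a grid
#'
#' @param grid_shape integer triple of voxel counts (x, y, z).
#' @param spacing numeric triple of voxel spacings in mm.
#' @return list with numeric vectors `x`, `y`, `z` of voxel centre
#'   coordinates (mm), origin at the grid centre.
#' @keywords internal
coord_axes <- function(grid_shape, spacing) {
  list(
    x = vox_centres(grid_shape[1], spacing[1]),
    y = vox_centres(grid_shape[2], spacing[2]),
    z = vox_centres(grid_shape[3], spacing[3])
  )
}

# Full coordinate arrays (each of dim grid_shape), built lazily where needed.
coord_arrays <- function(grid_shape, spacing) {
  ax <- coord_axes(grid_shape, spacing)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  list(
    x = array(rep(ax$x, times = ny * nz), grid_shape),
    y = array(rep(rep(ax$y, each = nx), times = nz), grid_shape),
    z = array(rep(ax$z, each = nx * ny), grid_shape)
  )
}

# Exact squared Euclidean distance transform (mm^2) to the TRUE voxels of
# `mask`, anisotropic spacing.  Separable: one axis-aligned lower-envelope
# pass per axis; each pass is exact, so the composition is the exact
# centre-to-centre EDT (verified against brute force in the test suite).
sq_edt <- function(mask, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("sq_edt: mask is empty")
  d <- array(Inf, dim(mask))
  d[mask] <- 0
  for (ax in 1:3) d <- edt_pass(d, ax, spacing[ax])
  d
}

# One separable EDT pass along `axis`: D'[i] = min_j D[j] + ((i-j)*s)^2,
# vectorised over all lines perpendicular to the axis.
edt_pass <- function(d, axis, s) {
  dm <- dim(d)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(d, perm), nrow = dm[axis])
  n <- nrow(m)
  out <- matrix(Inf, n, ncol(m))
  idx <- seq_len(n)
  for (j in idx) {
    row <- m[j, ]
    if (!any(is.finite(row))) next
    off2 <- ((idx - j) * s)^2
    for (i in idx) {
      cand <- row + off2[i]
      out[i, ] <- pmin(out[i, ], cand)
    }
  }
  res <- array(out, dm[perm])
  aperm(res, order(perm))
}

euclidean_distance_mm <- function(mask, spacing) sqrt(sq_edt(mask, spacing))

# Shift a logical array by an integer voxel offset and OR it into `acc`.
shift_or <- function(acc, mask, off) {
  dm <- dim(mask)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      if (o >= dm[a]) return(acc)
      src[[a]] <- seq_len(dm[a] - o)
      dst[[a]] <- seq_len(dm[a] - o) + o
    } else {
      if (-o >= dm[a]) return(acc)
      src[[a]] <- seq_len(dm[a] + o) - o
      dst[[a]] <- seq_len(dm[a] + o)
    }
  }
  acc[dst[[1]], dst[[2]], dst[[3]]] <-
    acc[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  acc
}

# Linear indices of TRUE voxels.
mask_which <- function(mask) which(mask)

voxel_volume_cc <- function(spacing) prod(spacing) / 1000

# Memoised squared-EDT per geometry: `patient_geometry` objects carry a
# cache environment (shared across copies, since environments are
# reference objects), so repeated goal compilation against one anatomy
# computes each distance transform once.
geometry_sq_edt <- function(geometry, key, mask) {
  cache <- geometry$cache
  if (is.null(cache)) return(sq_edt(mask, geometry$spacing))
  if (is.null(cache[[key]])) cache[[key]] <- sq_edt(mask, geometry$spacing)
  cache[[key]]
}
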