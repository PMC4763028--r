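#' Voxel phantom
#'
#' A 3D grid of relative electron densities (water = 1) with named binary
#' structure masks. Axis convention: x runs to the patient's left, y from
#' anterior to posterior, z from inferior to superior; a voxel `(i, j, k)`
#' (0-based) occupies the half-open box
#' `[origin + i * spacing, origin + (i + 1) * spacing)` per axis.
#'
#' @param density 3D numeric array of relative electron densities (>= 0).
#' @param spacing voxel spacing in cm, length-3 (or scalar, recycled).
#' @param origin position (cm) of the corner of voxel (0,0,0); length-3.
#' @param structures named list of logical arrays with the same shape as
#'   `density`; must contain nonempty `BODY` and `PTV` masks, and every mask
#'   must be contained in `BODY`.
#' @param isocenter optional default isocenter (cm) used by planning helpers.
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(density, spacing, origin, structures,
                          isocenter = NULL) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  origin <- as.numeric(origin)
  stopifnot(length(dim(density)) == 3, length(origin) == 3,
            all(spacing > 0))
  if (any(density < 0))
    .emxrt_stop("emxrt_geometry", "densities must be nonnegative")
  if (!all(c("BODY", "PTV") %in% names(structures)))
    .emxrt_stop("emxrt_geometry", "structures must include BODY and PTV masks")
  body <- structures$BODY
  for (nm in names(structures)) {
    m <- structures[[nm]]
    if (!identical(dim(m), dim(density)))
      .emxrt_stop("emxrt_geometry", "mask '%s' shape differs from density", nm)
    if (!any(m))
      .emxrt_stop("emxrt_geometry", "mask '%s' is empty", nm)
    if (nm != "BODY" && any(m & !body))
      .emxrt_stop("emxrt_geometry", "mask '%s' extends outside BODY", nm)
  }
  structure(list(shape = dim(density), spacing = spacing, origin = origin,
                 density = density, structures = structures,
                 isocenter = isocenter),
            class = "voxel_phantom")
}

#' Voxel center coordinates of a phantom
#'
#' @param phantom a `voxel_phantom`.
#' @return list of three vectors (`x`, `y`, `z`) of per-axis voxel center
#'   coordinates in cm.
#' @export
voxel_centers <- function(phantom) {
  lapply(1:3, function(a)
    phantom$origin[a] + (seq_len(phantom$shape[a]) - 0.5) * phantom$spacing[a])
}

#' Volume of one voxel in cm3
#' @param phantom a `voxel_phantom`.
#' @export
voxel_volume <- function(phantom) prod(phantom$spacing)

# internal: full coordinate arrays (same shape as density)
.coord_arrays <- function(shape, spacing, origin) {
  cx <- origin[1] + (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 0.5) * spacing[3]
  list(X = array(cx, shape),
       Y = array(rep(cy, each = shape[1]), shape),
       Z = array(rep(cz, each = shape[1] * shape[2]), shape))
}

.sphere <- function(co, center, radius)
  (co$X - center[1])^2 + (co$Y - center[2])^2 + (co$Z - center[3])^2 <= radius^2

# axis-aligned cylinder along z
.cylinder_z <- function(co, center_xy, radius, zlim)
  (co$X - center_xy[1])^2 + (co$Y - center_xy[2])^2 <= radius^2 &
    co$Z >= zlim[1] & co$Z <= zlim[2]

.ellipsoid <- function(co, center, semi)
  ((co$X - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1

#' Water slab phantom with an embedded spherical target
#'
#' The calibration geometry of the energy selector: a uniform water slab
#' entered anteriorly (y = 0), with a spherical target of diameter `TS`
#' centered on the beam axis at depth `EP`. The phantom's default isocenter
#' is the sphere center, so an anterior beam reproduces the (EP, TS)
#' scenario exactly.
#'
#' @param EP depth (cm) of the sphere center below the entrance surface;
#'   must be at least `TS / 2` so the target is fully inside.
#' @param TS sphere diameter in cm.
#' @param thickness slab thickness (cm) along the beam; must cover the
#'   target (`>= EP + TS / 2`).
#' @param lateral lateral slab width (cm) in x and z; default wide enough
#'   for the target plus margin.
#' @param spacing voxel spacing in cm (isotropic default 0.25).
#' @return a `voxel_phantom` with BODY and PTV masks.
#' @export
make_selector_phantom <- function(EP, TS, thickness,
                                  lateral = max(TS + 6, 10),
                                  spacing = 0.25) {
  if (EP < TS / 2)
    .emxrt_stop("emxrt_geometry",
                "EP (%.1f) must be at least the target radius TS/2 (%.1f)", EP, TS / 2)
  if (thickness < EP + TS / 2)
    .emxrt_stop("emxrt_geometry",
                "thickness (%.1f) must cover the target (need >= %.1f)",
                thickness, EP + TS / 2)
  spacing <- rep(spacing, length.out = 3)
  shape <- c(ceiling(lateral / spacing[1]), ceiling(thickness / spacing[2]),
             ceiling(lateral / spacing[3]))
  origin <- c(-lateral / 2, 0, -lateral / 2)
  co <- .coord_arrays(shape, spacing, origin)
  body <- array(TRUE, shape)
  ptv <- .sphere(co, c(0, EP, 0), TS / 2)
  density <- array(1, shape)
  voxel_phantom(density, spacing, origin,
                list(BODY = body, PTV = ptv),
                isocenter = c(0, EP, 0))
}

#' Synthetic patient-like phantom archetypes
#'
#' Deterministic voxel phantoms standing in for patient CT geometries:
#' \describe{
#'   \item{lung_like}{thorax-like body with two low-density (0.25) lungs, a
#'     small PTV inside the right lung, spinal cord and esophagus OARs.}
#'   \item{deep_pelvic}{large pelvis-like body with the PTV at >= 9 cm
#'     water-equivalent depth and two lateral femoral-head OARs plus a
#'     posterior rectum-like OAR.}
#'   \item{brain_like}{head-like body with the PTV abutting brainstem and
#'     chiasm OAR masks.}
#' }
#' Structure positions are jittered by a few millimetres from the seed, so
#' phantoms are reproducible given `(name, seed)` yet not all identical.
#' Density is assigned by region label (no CT calibration).
#'
#' @param name archetype name.
#' @param seed integer seed controlling the jitter.
#' @param spacing voxel spacing in cm (isotropic default 0.25).
#' @return a `voxel_phantom` with BODY, PTV and at least two OAR masks.
#' @export
make_archetype <- function(name = c("lung_like", "deep_pelvic", "brain_like"),
                           seed = 1, spacing = 0.25) {
  name <- tryCatch(match.arg(name),
                   error = function(e) .emxrt_stop("emxrt_lookup",
                                                   "unknown archetype '%s'", name[1]))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  jit <- function(n = 1, s = 0.3) runif(n, -s, s)
  spacing <- rep(spacing, length.out = 3)
  if (name == "lung_like") {
    ext <- c(32, 22, 12)             # lateral, AP, SI extent in cm
    shape <- ceiling(ext / spacing)
    origin <- c(-ext[1] / 2, 0, -ext[3] / 2)
    co <- .coord_arrays(shape, spacing, origin)
    body <- .ellipsoid(co, c(0, ext[2] / 2, 0), c(ext[1] / 2, ext[2] / 2, 1e6)) &
      co$Z >= -ext[3] / 2 & co$Z <= ext[3] / 2
    lungL <- .ellipsoid(co, c(-8 + jit(), 10 + jit(), 0), c(5.5, 6.5, 5))
    lungR <- .ellipsoid(co, c(8 + jit(), 10 + jit(), 0), c(5.5, 6.5, 5))
    ptv_c <- c(8 + jit(s = 0.5), 9 + jit(s = 0.5), 0 + jit(s = 0.5))
    ptv <- .sphere(co, ptv_c, 1.5)
    cord <- .cylinder_z(co, c(0 + jit(s = 0.1), 18.5 + jit(s = 0.2)), 0.6,
                        c(-ext[3] / 2, ext[3] / 2))
    eso <- .cylinder_z(co, c(-1 + jit(s = 0.2), 15 + jit(s = 0.2)), 0.8,
                       c(-ext[3] / 2, ext[3] / 2))
    lungs <- (lungL | lungR) & body
    density <- array(1, shape)
    density[!body] <- 0.001
    density[lungs & !ptv] <- 0.25
    structures <- list(BODY = body, PTV = ptv & body, LUNGS = lungs,
                       CORD = cord & body, ESOPHAGUS = eso & body)
    iso <- ptv_c
  } else if (name == "deep_pelvic") {
    ext <- c(36, 26, 12)
    shape <- ceiling(ext / spacing)
    origin <- c(-ext[1] / 2, 0, -ext[3] / 2)
    co <- .coord_arrays(shape, spacing, origin)
    body <- .ellipsoid(co, c(0, ext[2] / 2, 0), c(ext[1] / 2, ext[2] / 2, 1e6)) &
      co$Z >= -ext[3] / 2 & co$Z <= ext[3] / 2
    ptv_c <- c(0 + jit(s = 0.2), 13 + jit(s = 0.4), 0 + jit(s = 0.2))
    ptv <- .sphere(co, ptv_c, 3)
    femL <- .sphere(co, c(-11 + jit(s = 0.2), 13 + jit(s = 0.3), 0), 2.2)
    femR <- .sphere(co, c(11 + jit(s = 0.2), 13 + jit(s = 0.3), 0), 2.2)
    rect <- .cylinder_z(co, c(0 + jit(s = 0.1), 19 + jit(s = 0.3)), 1.5,
                        c(-4, 4))
    density <- array(1, shape)
    density[!body] <- 0.001
    density[(femL | femR) & body] <- 1.4   # bone-like femoral heads
    structures <- list(BODY = body, PTV = ptv & body,
                       FEMUR_L = femL & body, FEMUR_R = femR & body,
                       RECTUM = rect & body & !ptv)
    iso <- ptv_c
  } else { # brain_like
    ext <- c(16, 20, 12)
    shape <- ceiling(ext / spacing)
    origin <- c(-ext[1] / 2, 0, -ext[3] / 2)
    co <- .coord_arrays(shape, spacing, origin)
    body <- .ellipsoid(co, c(0, ext[2] / 2, 0),
                       c(ext[1] / 2, ext[2] / 2, ext[3] / 2 + 2))
    ptv_c <- c(2.5 + jit(s = 0.3), 8 + jit(s = 0.3), 0.5 + jit(s = 0.2))
    ptv <- .sphere(co, ptv_c, 2.3)
    stem <- .cylinder_z(co, c(0 + jit(s = 0.1), 11.5 + jit(s = 0.2)), 1.0,
                        c(-4, 1))
    chiasm <- .sphere(co, c(0 + jit(s = 0.1), 9.5 + jit(s = 0.1), 1.5), 0.6)
    density <- array(1, shape)
    density[!body] <- 0.001
    structures <- list(BODY = body, PTV = ptv & body,
                       BRAINSTEM = stem & body & !ptv,
                       CHIASM = chiasm & body & !ptv)
    iso <- ptv_c
  }
  voxel_phantom(density, spacing, origin, structures, isocenter = iso)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %.2f x %.2f x %.2f cm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  for (nm in names(x$structures))
    cat(sprintf("  %-10s %7d voxels (%.1f cm3)\n", nm,
                sum(x$structures[[nm]]),
                sum(x$structures[[nm]]) * voxel_volume(x)))
  invisible(x)
}
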