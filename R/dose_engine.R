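#' Beamlet grid for one beam
#'
#' Divides the field of one beam into square beamlets (default 1 x 1 cm at
#' the isocenter plane) covering the beam's-eye-view projection of the PTV
#' plus a margin ring. Each beamlet has its own divergent axis from the
#' source through its center in the isocenter plane.
#'
#' @param phantom a `voxel_phantom`.
#' @param ray a `beam_ray` (the central axis).
#' @param size beamlet side length at the isocenter, cm.
#' @param margin number of beamlet rings added beyond the PTV projection.
#' @return object of class `beamlet_grid`: matrix `centers` (n x 2, iso-plane
#'   coordinates in cm), the in-plane basis `e1`, `e2`, the `ray`, `size`.
#' @export
beamlet_grid <- function(phantom, ray, size = 1, margin = 1) {
  stopifnot(inherits(ray, "beam_ray"), size > 0)
  u <- ray$direction
  # in-plane basis perpendicular to the beam
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  co <- voxel_centers(phantom)
  idx <- which(phantom$structures$PTV, arr.ind = TRUE)
  V <- cbind(co[[1]][idx[, 1]], co[[2]][idx[, 2]], co[[3]][idx[, 3]])
  W <- sweep(V, 2, ray$source)
  t <- as.numeric(W %*% u)
  if (any(t <= 0))
    .emxrt_stop("emxrt_geometry", "PTV voxels behind the source")
  px <- as.numeric(W %*% e1) * ray$sad / t
  py <- as.numeric(W %*% e2) * ray$sad / t
  kx <- floor(min(px) / size - margin):ceiling(max(px) / size - 1 + margin)
  ky <- floor(min(py) / size - margin):ceiling(max(py) / size - 1 + margin)
  centers <- as.matrix(expand.grid(x = (kx + 0.5) * size,
                                   y = (ky + 0.5) * size))
  structure(list(centers = centers, e1 = e1, e2 = e2, ray = ray, size = size),
            class = "beamlet_grid")
}

#' Dose deposition coefficients for one beam
#'
#' Computes, for every beamlet of a [beamlet_grid()], the relative dose per
#' unit beamlet weight to every BODY voxel with a deterministic divergent
#' pencil-beam kernel:
#' depth dose from the beam's percent-depth-dose curve evaluated at the
#' water-equivalent depth of the voxel along the beamlet axis, a separable
#' error-function lateral profile in beam's-eye-view (iso-plane)
#' coordinates — so adjacent beamlets tile into a flat open field — and an
#' inverse-square correction. Columns are normalized so the open-field
#' composite of all beamlets equals 1 at water-equivalent dmax on the
#' central axis. Entries below `drop_tol` times the column maximum are
#' dropped and the matrix is stored sparse.
#'
#' @param phantom a `voxel_phantom`.
#' @param grid a `beamlet_grid`.
#' @param curve a `pdd_curve` for the beam energy.
#' @param profile a `beam_profile` for the beam energy.
#' @param drop_tol sparse drop threshold relative to each column maximum.
#' @return object of class `ddc_matrix`: sparse `A`
#'   (`length(voxel_index)` x n beamlets), `voxel_index` (linear indices of
#'   BODY voxels in the phantom grid), the `grid`, and `meta` (drop
#'   threshold, normalization).
#' @export
compute_ddc <- function(phantom, grid, curve, profile, drop_tol = 1e-4) {
  stopifnot(inherits(grid, "beamlet_grid"), inherits(curve, "pdd_curve"))
  ray <- grid$ray
  body_idx <- which(phantom$structures$BODY)
  co <- voxel_centers(phantom)
  ai <- arrayInd(body_idx, phantom$shape)
  V <- cbind(co[[1]][ai[, 1]], co[[2]][ai[, 2]], co[[3]][ai[, 3]])
  W <- sweep(V, 2, ray$source)
  t0 <- as.numeric(W %*% ray$direction)
  # beam's-eye-view coordinates of every voxel at the isocenter plane
  bev1 <- as.numeric(W %*% grid$e1) * ray$sad / t0
  bev2 <- as.numeric(W %*% grid$e2) * ray$sad / t0
  n_b <- nrow(grid$centers)
  # reference point: water-equivalent dmax on the central axis, used to
  # normalize the open-field composite to 1 there (evaluated analytically,
  # independent of the voxel grid)
  cum0 <- .axis_cumulative_wed(phantom, ray$source, ray$direction)
  P_ref <- NULL
  if (!is.null(cum0) && max(cum0$wed) > curve$dmax_depth) {
    t_dmax <- approx(cum0$wed, cum0$t, curve$dmax_depth, ties = "ordered")$y
    P_ref <- ray$source + t_dmax * ray$direction
  }
  open_field <- 0
  cols_i <- vector("list", n_b); cols_x <- vector("list", n_b)
  for (j in seq_len(n_b)) {
    Pj <- ray$isocenter + grid$centers[j, 1] * grid$e1 +
      grid$centers[j, 2] * grid$e2
    uj <- Pj - ray$source
    uj <- uj / sqrt(sum(uj^2))
    cum <- .axis_cumulative_wed(phantom, ray$source, uj)
    if (is.null(cum)) next
    t <- as.numeric(W %*% uj)
    wed <- approx(cum$t, cum$wed, t, rule = 2)$y
    a <- pdd_at(curve, pmax(wed, 0)) / 100 *
      off_axis_ratio(profile, bev1 - grid$centers[j, 1], grid$size / 2) *
      off_axis_ratio(profile, bev2 - grid$centers[j, 2], grid$size / 2) *
      (ray$sad / t)^2
    a[t <= 0 | wed <= 0] <- 0
    if (!is.null(P_ref)) {
      wp <- P_ref - ray$source
      tp <- sum(wp * uj)
      p1 <- sum(wp * grid$e1) * ray$sad / sum(wp * ray$direction)
      p2 <- sum(wp * grid$e2) * ray$sad / sum(wp * ray$direction)
      wedp <- approx(cum$t, cum$wed, tp, rule = 2)$y
      if (tp > 0 && wedp > 0)
        open_field <- open_field + pdd_at(curve, wedp) / 100 *
          off_axis_ratio(profile, p1 - grid$centers[j, 1], grid$size / 2) *
          off_axis_ratio(profile, p2 - grid$centers[j, 2], grid$size / 2) *
          (ray$sad / tp)^2
    }
    ma <- max(a)
    if (ma <= 0) next
    keep <- a >= drop_tol * ma
    cols_i[[j]] <- which(keep)
    cols_x[[j]] <- a[keep]
  }
  counts <- vapply(cols_i, length, integer(1))
  A <- Matrix::sparseMatrix(
    i = unlist(cols_i), j = rep(seq_len(n_b), counts), x = unlist(cols_x),
    dims = c(length(body_idx), n_b))
  # normalize: open-field composite = 1 at water-equivalent dmax on-axis
  norm <- if (open_field > 0) open_field else 1
  A <- A / norm
  structure(list(A = A, voxel_index = body_idx, grid = grid,
                 meta = list(drop_tol = drop_tol, normalization = norm,
                             energy_mv = curve$energy_mv)),
            class = "ddc_matrix")
}

# cumulative water-equivalent depth along an axis, measured from the body
# entrance; returns breakpoints t (distance from source) and wed values
.axis_cumulative_wed <- function(phantom, source, direction) {
  cr <- .grid_crossings(phantom, source, direction)
  if (is.null(cr)) return(NULL)
  body <- phantom$structures$BODY[cr$idx]
  if (!any(body)) return(NULL)
  first <- which(body)[1]
  dens <- phantom$density[cr$idx]
  dens[seq_len(first - 1)] <- 0  # upstream of skin
  list(t = cr$breaks, wed = c(0, cumsum(dens * cr$len)))
}

#' Superpose weighted beamlets into a dose grid
#'
#' The dose to voxel i is the weighted sum over beamlets of the dose
#' deposition coefficients, `d = A x`.
#'
#' @param ddc a `ddc_matrix` (or a plain list of them, summed after
#'   concatenation by [combine_ddc()]).
#' @param x nonnegative beamlet weights, one per column.
#' @return object of class `dose_grid`: field `values` is a 3D array on the
#'   phantom grid (zero outside BODY), plus `shape`.
#' @export
accumulate_dose <- function(ddc, x) {
  stopifnot(inherits(ddc, "ddc_matrix"))
  if (length(x) != ncol(ddc$A))
    .emxrt_stop("emxrt_shape", "weight length %d != %d beamlets",
                length(x), ncol(ddc$A))
  if (any(x < 0))
    .emxrt_stop("emxrt_domain", "beamlet weights must be nonnegative")
  d <- as.numeric(ddc$A %*% x)
  structure(list(values_body = d, voxel_index = ddc$voxel_index),
            class = "dose_grid")
}

#' Expand a dose grid to a full 3D array
#' @param dose a `dose_grid`.
#' @param phantom the `voxel_phantom` it was computed on.
#' @export
dose_array <- function(dose, phantom) {
  arr <- array(0, phantom$shape)
  arr[dose$voxel_index] <- dose$values_body
  arr
}

#' Concatenate the beamlet columns of several beams
#'
#' @param ddcs list of `ddc_matrix` objects computed on the same phantom.
#' @return a single `ddc_matrix` whose columns are all beams' beamlets, with
#'   a `beam_of` attribute mapping columns to beams.
#' @export
combine_ddc <- function(ddcs) {
  stopifnot(length(ddcs) >= 1)
  vi <- ddcs[[1]]$voxel_index
  for (d in ddcs) stopifnot(identical(d$voxel_index, vi))
  A <- do.call(cbind, lapply(ddcs, function(d) d$A))
  structure(list(A = A, voxel_index = vi, grid = NULL,
                 meta = list(beams = length(ddcs)),
                 beam_of = rep(seq_along(ddcs),
                               vapply(ddcs, function(d) ncol(d$A), integer(1)))),
            class = "ddc_matrix")
}
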